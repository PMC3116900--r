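test_that("uniform specified strain passes the patch test", {
  cv <- small_sheet(3)
  C <- isotropic_stiffness(elastic_material())
  growth <- uniform_growth(cv, kpar = 0.08, kper = 0.03, kthick = 0.05)
  sys <- assemble_elastic_system(cv, C, growth)
  sol <- solve_displacements(sys, solver = "direct")
  def <- decompose_growth(cv, sol)
  ## resultant strain equals specified strain element by element
  spec <- voigt_rows_to_tensors(growth$eps_a)  # uniform, same on both layers
  expect_equal(def$strain, spec, tolerance = 1e-9)
  expect_equal(def$strain_a, def$strain_b, tolerance = 1e-9)
  expect_lt(max(abs(def$vorticity)), 1e-9)
})

test_that("the unconstrained stiffness has exactly six rigid modes", {
  cv <- small_sheet(2)
  sys <- assemble_elastic_system(cv, isotropic_stiffness(elastic_material()))
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(abs(ev) < 1e-9 * scale), 6)
  expect_equal(ncol(sys$Q), 6)
})

test_that("equilibrium displacements are independent of rigid placement", {
  cv <- small_sheet(3)
  C <- isotropic_stiffness(elastic_material())
  growth <- uniform_growth(cv, kpar = 0.05, kper = 0.02)
  solve_for <- function(cv) {
    sys <- assemble_elastic_system(cv, C, growth)
    solve_displacements(sys, solver = "direct")$u
  }
  u1 <- solve_for(cv)
  cv2 <- cv
  cv2$pos_a <- cv2$pos_a + rep(c(3, -2, 5), each = n_vertices(cv))
  cv2$pos_b <- cv2$pos_b + rep(c(3, -2, 5), each = n_vertices(cv))
  expect_equal(solve_for(cv2), u1, tolerance = 1e-8)
})

test_that("iterative solvers agree with the dense direct solve", {
  cv <- small_sheet(4)
  C <- isotropic_stiffness(elastic_material())
  growth <- uniform_growth(cv, kpar = 0.06, kper = 0.01)
  sys <- assemble_elastic_system(cv, C, growth,
                                 constraint_set(cv, fix_z = cv$labels$boundary))
  u0 <- solve_displacements(sys, solver = "direct")$u
  for (s in c("cgs", "minres")) {
    u <- solve_displacements(sys, tol = 1e-10, solver = s)$u
    expect_equal(u, u0, tolerance = 1e-6)
  }
})

test_that("the equilibrium solution minimises the residual-strain energy", {
  cv <- small_sheet(3)
  growth <- uniform_growth(cv, kpar = 0.1)
  sys <- assemble_elastic_system(cv, isotropic_stiffness(elastic_material()),
                                 growth)
  sol <- solve_displacements(sys, solver = "direct")
  e0 <- residual_energy(sys, sol$q)
  expect_gte(e0, -1e-12)
  set.seed(3)
  for (k in 1:5) {
    dq <- rnorm(length(sol$q))
    dq <- 1e-3 * dq / sqrt(sum(dq^2))
    expect_gt(residual_energy(sys, sol$q + dq), e0)
  }
})

test_that("constraints are honoured exactly", {
  cv <- small_sheet(4)
  C <- isotropic_stiffness(elastic_material())
  growth <- uniform_growth(cv, kpar = 0.05, kper = 0.05)
  n <- n_vertices(cv)

  cs <- constraint_set(cv, fix_z = cv$labels$boundary)
  sol <- solve_displacements(assemble_elastic_system(cv, C, growth, cs),
                             solver = "direct")
  idx <- c(cv$labels$boundary, cv$labels$boundary + n)
  expect_equal(sol$u[idx, 3], rep(0, length(idx)))

  cs2 <- constraint_set(cv, fix_xyz = cv$labels$centre)
  sol2 <- solve_displacements(assemble_elastic_system(cv, C, growth, cs2),
                              solver = "direct")
  expect_equal(sol2$u[c(cv$labels$centre, cv$labels$centre + n), ],
               matrix(0, 2, 3))

  ## flatness: paired surface vertices move by opposite z, so the midplane
  ## stays exactly planar while the thickness may change
  cs3 <- constraint_set(cv, flat = TRUE)
  sol3 <- solve_displacements(assemble_elastic_system(cv, C, growth, cs3),
                              solver = "direct")
  za <- sol3$u[seq_len(n), 3]; zb <- sol3$u[n + seq_len(n), 3]
  expect_equal(za + zb, rep(0, n), tolerance = 1e-12)
})

test_that("displacement gradients are exact for affine fields", {
  cv <- small_sheet(3, bow = 0.05)
  A <- matrix(c(0.02, 0.01, 0, -0.01, 0.03, 0.005, 0, 0.002, -0.01), 3, 3,
              byrow = TRUE)
  pos <- rbind(cv$pos_a, cv$pos_b)
  u <- pos %*% t(A)
  def <- decompose_growth(cv, u)
  for (e in seq_len(n_elements(cv)))
    expect_equal(def$grad[e, , ], A, tolerance = 1e-12)
  expect_equal(def$strain, def$strain_a, tolerance = 1e-12)
})

test_that("solver input validation", {
  cv <- small_sheet(2)
  sys <- assemble_elastic_system(cv, isotropic_stiffness(elastic_material()))
  expect_error(solve_displacements(sys, tol = 0), "positive")
  ## zero force returns the zero solution
  sol <- solve_displacements(sys)
  expect_equal(max(abs(sol$u)), 0)
})
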