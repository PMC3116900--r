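test_that("diffusion matrices have the discrete conservation structure", {
  cv <- small_sheet(5, bow = 0.05)
  sys <- diffusion_system(cv)
  expect_equal(max(abs(Matrix::rowSums(sys$L))), 0, tolerance = 1e-12)
  expect_equal(as.matrix(sys$L), t(as.matrix(sys$L)), tolerance = 1e-12)
  expect_equal(sum(sys$M), sum(triangle_areas(cv)), tolerance = 1e-12)
  lum <- diffusion_system(cv, lumped = TRUE)
  expect_true(Matrix::isDiagonal(lum$M))
  expect_equal(Matrix::rowSums(lum$M), Matrix::rowSums(sys$M),
               tolerance = 1e-12)
})

test_that("pure diffusion conserves mass exactly", {
  cv <- small_sheet(6)
  sys <- diffusion_system(cv)
  set.seed(21)
  c0 <- runif(n_vertices(cv))
  f <- factor_field("S", "signalling", n_vertices(cv), init = c0, D = 0.3)
  m0 <- field_mass(f, sys)
  for (k in 1:5) f <- step_signalling_field(f, sys, dt = 0.05, tol = 1e-10)
  expect_equal(field_mass(f, sys), m0, tolerance = 1e-10)
  ## diffusion smooths: variance decreases
  expect_lt(stats::var(f$values), stats::var(c0))
})

test_that("decay follows the analytic exponential on a uniform field", {
  cv <- small_sheet(4)
  sys <- diffusion_system(cv)
  f <- factor_field("S", "signalling", n_vertices(cv), init = 1,
                    D = 0.2, decay = 1.5)
  dt <- 0.01
  for (k in 1:100) f <- step_signalling_field(f, sys, dt, tol = 1e-10)
  ## uniform field: no diffusion flux, implicit-Euler decay (1+d dt)^-k
  expect_equal(f$values, rep((1 + 1.5 * dt)^-100, n_vertices(cv)),
               tolerance = 1e-6)
})

test_that("steady state matches the 1D cosh profile", {
  ## strip clamped to 1 at both x-ends: c'' = (d/D) c,
  ## c(x) = cosh(x sqrt(d/D)) / cosh(L/2 sqrt(d/D))
  cv <- build_flat_sheet(40, 4, side = 1, thickness = 0.05)
  n <- n_vertices(cv)
  D <- 0.1; d <- 4
  f <- factor_field("S", "signalling", n, init = 0, D = D, decay = d,
                    clamp = list(vertices = c(cv$labels$edge_left,
                                              cv$labels$edge_right),
                                 value = 1))
  f <- steady_state_field(f, diffusion_system(cv))
  x <- canvas_midplane(cv)[, 1]
  lam <- sqrt(d / D)
  exact <- cosh(lam * x) / cosh(lam / 2)
  expect_equal(f$values, exact, tolerance = 5e-3)
  ## implicit stepping converges to the same state
  g <- factor_field("S", "signalling", n, init = 0, D = D, decay = d,
                    clamp = list(vertices = c(cv$labels$edge_left,
                                              cv$labels$edge_right),
                                 value = 1))
  sys <- diffusion_system(cv)
  for (k in 1:400) g <- step_signalling_field(g, sys, 0.1, tol = 1e-8)
  expect_equal(g$values, f$values, tolerance = 1e-4)
})

test_that("explicit scheme enforces its stability bound", {
  cv <- small_sheet(6)
  sys <- diffusion_system(cv, lumped = TRUE)
  f <- factor_field("S", "signalling", n_vertices(cv),
                    init = as.numeric(seq_len(n_vertices(cv)) == 1), D = 1)
  expect_error(step_signalling_field(f, sys, dt = 10, scheme = "explicit"),
               "stability")
  ## a stable lumped explicit step respects the maximum principle
  f2 <- step_signalling_field(f, sys, dt = 1e-4, scheme = "explicit")
  expect_true(all(f2$values >= -1e-14 & f2$values <= 1 + 1e-14))
})

test_that("steady state requires decay or clamps", {
  cv <- small_sheet(3)
  f <- factor_field("S", "signalling", n_vertices(cv), init = 1, D = 1)
  expect_error(steady_state_field(f, diffusion_system(cv)), "undetermined")
})

test_that("static material factors pass through stepping untouched", {
  cv <- small_sheet(3)
  vals <- canvas_midplane(cv)[, 1]
  f <- factor_field("LIN", "signalling", n_vertices(cv), init = vals,
                    D = 0, dilutable = FALSE)
  f2 <- step_signalling_field(f, diffusion_system(cv), 0.5)
  expect_identical(f2$values, vals)
})

test_that("dilution conserves total amount under non-uniform growth", {
  cv <- small_sheet(5)
  n <- n_vertices(cv)
  set.seed(9)
  c0 <- runif(n)
  vol_old <- vertex_control_volumes(cv)
  vol_new <- vol_old * runif(n, 1, 2.5)   # non-uniform expansion
  fields <- list(S = factor_field("S", "signalling", n, init = c0, D = 1),
                 ID = factor_field("ID", "identity", n, init = 1))
  out <- apply_dilution(fields, vol_old, vol_new)
  expect_equal(sum(out$S$values * vol_new), sum(c0 * vol_old),
               tolerance = 1e-12)
  ## identities are never diluted
  expect_identical(out$ID$values, fields$ID$values)
  expect_error(apply_dilution(fields, vol_old, -vol_new), "control volume")
})

test_that("clamped vertices are held through steps and dilution", {
  cv <- small_sheet(4)
  n <- n_vertices(cv)
  f <- factor_field("S", "signalling", n, init = 0, D = 0.5,
                    clamp = list(vertices = cv$labels$centre, value = 1))
  sys <- diffusion_system(cv)
  for (k in 1:10) f <- step_signalling_field(f, sys, 0.05)
  expect_equal(f$values[cv$labels$centre], 1)
  expect_true(all(f$values >= -1e-12))
  out <- apply_dilution(list(S = f), vertex_control_volumes(cv),
                        2 * vertex_control_volumes(cv))
  expect_equal(out$S$values[cv$labels$centre], 1)
})
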