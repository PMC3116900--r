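test_that("Voigt row / tensor conversions round trip", {
  set.seed(5)
  v <- matrix(rnorm(18), 3, 6)
  a <- voigt_rows_to_tensors(v)
  expect_equal(tensors_to_voigt_rows(a), v, tolerance = 1e-14)
  ## engineering convention: off-diagonal tensor entry is half the Voigt one
  expect_equal(a[1, 2, 3], v[1, 4] / 2)
  expect_equal(a[1, 1, 2], v[1, 6] / 2)
})

test_that("specified growth has the prescribed trace and axes", {
  cv <- small_sheet(3)
  dt <- 0.2
  g <- uniform_growth(cv, kpar = 0.3, kper = 0.1, kthick = 0.05, dt = dt,
                      axis = c(1, 0, 0))
  ## trace = (kpar + kper + kthick) dt on every element and layer
  tr <- rowSums(g$eps_a[, 1:3, drop = FALSE])
  expect_equal(tr, rep((0.3 + 0.1 + 0.05) * dt, n_elements(cv)),
               tolerance = 1e-12)
  ## flat sheet, axis x: eps = diag(kpar, kper, kthick) dt
  expect_equal(g$eps_a[1, ], c(0.3, 0.1, 0.05, 0, 0, 0) * dt,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$eps_a, g$eps_b, tolerance = 1e-12)
})

test_that("growth tensors are axial (axis sign does not matter)", {
  cv <- small_sheet(3)
  g1 <- uniform_growth(cv, kpar = 0.3, kper = 0.1, axis = c(1, 2, 0))
  g2 <- uniform_growth(cv, kpar = 0.3, kper = 0.1, axis = -c(1, 2, 0))
  expect_equal(g1$eps_a, g2$eps_a, tolerance = 1e-12)
})

test_that("swapping rates matches rotating the axis by 90 degrees", {
  cv <- small_sheet(3)
  g1 <- uniform_growth(cv, kpar = 0.3, kper = 0.1, axis = c(1, 0, 0))
  g2 <- uniform_growth(cv, kpar = 0.1, kper = 0.3, axis = c(0, 1, 0))
  expect_equal(g1$eps_a, g2$eps_a, tolerance = 1e-12)
})

test_that("absent polarity falls back to isotropic in-plane growth", {
  cv <- small_sheet(3)
  frame <- local_frame(cv, polarity_state(cv, "absent"))
  expect_true(all(!frame$polarised))
  spec <- growth_spec(cv, kpar_a = 0.4, kper_a = 0)
  g <- assemble_specified_growth(spec, frame, dt = 1)
  ## mean fallback: in-plane isotropic at (kpar + kper)/2
  expect_equal(g$eps_a[, 1], rep(0.2, n_elements(cv)), tolerance = 1e-12)
  expect_equal(g$eps_a[, 2], rep(0.2, n_elements(cv)), tolerance = 1e-12)
  gk <- assemble_specified_growth(spec, frame, 1, isotropic_fallback = "kpar")
  expect_equal(gk$eps_a[, 1], rep(0.4, n_elements(cv)), tolerance = 1e-12)
})

test_that("vertex rates average onto elements", {
  cv <- small_sheet(2)
  mid <- canvas_midplane(cv)
  spec <- growth_spec(cv, kpar_a = mid[, 1])
  tri <- cv$tri
  expect_equal(spec$kpar_a,
               (mid[tri[, 1], 1] + mid[tri[, 2], 1] + mid[tri[, 3], 1]) / 3)
})

test_that("non-finite rates are rejected", {
  cv <- small_sheet(2)
  frame <- local_frame(cv, polarity_state(cv, "absent"))
  spec <- growth_spec(cv, kpar_a = NaN)
  expect_error(assemble_specified_growth(spec, frame, 0.1), "non-finite")
})

test_that("local frames are orthonormal with in-plane axes", {
  cv <- small_sheet(3, bow = 0.1)
  pol <- update_polarity(polarity_state(cv, "external",
                                        external_dir = c(1, 0, 0)), cv)
  fr <- local_frame(cv, pol)
  m <- n_elements(cv)
  expect_equal(rowSums(fr$u * fr$v), rep(0, m), tolerance = 1e-12)
  expect_equal(rowSums(fr$u * fr$n), rep(0, m), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(fr$u^2)), rep(1, m), tolerance = 1e-12)
  expect_equal(fr$n, triangle_normals(cv), tolerance = 1e-12)
})
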