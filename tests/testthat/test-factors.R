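test_that("factor field construction and validation", {
  f <- factor_field("A", "signalling", 5, init = 2, D = 1, decay = 0.5)
  expect_equal(f$values, rep(2, 5))
  expect_true(f$dilutable)
  expect_error(factor_field("B", "identity", 5, D = 1), "identity")
  expect_error(factor_field("B", "identity", 5, dilutable = TRUE), "diluted")
  g <- factor_field("C", "signalling", 4, init = c(1, 2, 3, 4),
                    clamp = list(vertices = c(1, 4), value = c(9, 9)))
  expect_equal(g$values, c(9, 2, 3, 9))
})

test_that("promotion and inhibition multipliers", {
  x <- c(0, 1, 2)
  expect_equal(pro(0.5, x), c(1, 1.5, 2))
  expect_equal(inh(0.5, x), 1 / c(1, 1.5, 2))
  expect_equal(pro(0, x), rep(1, 3))
  expect_error(pro(-1, x))
  expect_error(inh(1, c(-1, 0)))
})

test_that("threshold rule latches", {
  id <- rep(0, 4)
  id <- apply_threshold_rule(c(0.5, 0.1, 0.4, 0.2), 0.3, id)
  expect_equal(id, c(0, 1, 0, 1))
  ## signal rises again but expression persists
  id <- apply_threshold_rule(c(0.5, 0.9, 0.4, 0.9), 0.3, id)
  expect_equal(id, c(0, 1, 0, 1))
  expect_equal(apply_threshold_rule(c(1, 1), -Inf, c(0, 0)), c(0, 0))
})

test_that("the gradient of a linear field is exact", {
  cv <- small_sheet(4)
  mid <- canvas_midplane(cv)
  vals <- 2 * mid[, 1] - 3 * mid[, 2]
  g <- compute_pol_gradient(cv, vals)
  expect_equal(g, matrix(rep(c(2, -3, 0), each = n_elements(cv)),
                         ncol = 3), tolerance = 1e-12)
  expect_equal(compute_pol_gradient(cv, rep(1, n_vertices(cv))),
               matrix(0, n_elements(cv), 3))
})

test_that("live polarity points down-gradient", {
  cv <- small_sheet(4)
  pol <- factor_field("POL", "signalling", n_vertices(cv),
                      init = canvas_midplane(cv)[, 1])
  st <- update_polarity(polarity_state(cv, "live"), cv, pol)
  expect_equal(st$axis, matrix(rep(c(-1, 0, 0), each = n_elements(cv)),
                               ncol = 3), tolerance = 1e-12)
  expect_true(all(st$mode == "live"))
})

test_that("external polarity is the in-plane projection of the lab axis", {
  cv <- build_cylinder(1, 2, closed_top = FALSE, resolution = 8)
  st <- update_polarity(polarity_state(cv, "external",
                                       external_dir = c(0, 0, 1)), cv)
  nrm <- triangle_normals(cv)
  expect_equal(rowSums(st$axis * nrm), rep(0, n_elements(cv)),
               tolerance = 1e-12)
  expect_equal(sqrt(rowSums(st$axis^2)), rep(1, n_elements(cv)),
               tolerance = 1e-12)
  expect_true(all(st$axis[, 3] > 0.9))  # wall triangles are near-vertical
})

test_that("frozen axes are convected by the deformation gradient", {
  cv <- small_sheet(3)
  pol <- factor_field("POL", "signalling", n_vertices(cv),
                      init = canvas_midplane(cv)[, 1])
  st <- update_polarity(polarity_state(cv, "live"), cv, pol)
  st <- freeze_polarity(st)
  expect_true(all(st$mode == "frozen"))
  ## in-plane 90-degree rotation: axis (-1,0,0) should become (0,-1,0)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  m <- n_elements(cv)
  def <- list(grad = array(rep(R - diag(3), each = m), c(m, 3, 3)))
  cv2 <- cv
  cv2$pos_a <- cv$pos_a %*% t(R); cv2$pos_b <- cv$pos_b %*% t(R)
  st2 <- update_polarity(st, cv2, deformation = def)
  expect_equal(st2$axis, matrix(rep(c(0, -1, 0), each = m), ncol = 3),
               tolerance = 1e-12)
})

test_that("shallow gradients follow the configured policy", {
  cv <- small_sheet(3)
  n <- n_vertices(cv)
  flat_pol <- factor_field("POL", "signalling", n, init = 1)

  ## freeze policy: axes established earlier are latched
  grad_pol <- factor_field("POL", "signalling", n,
                           init = canvas_midplane(cv)[, 1])
  st <- update_polarity(polarity_state(cv, "live", shallow_policy = "freeze"),
                        cv, grad_pol)
  st <- update_polarity(st, cv, flat_pol)
  expect_true(all(st$mode == "frozen"))
  expect_equal(st$axis[1, ], c(-1, 0, 0), tolerance = 1e-12)

  ## freeze policy without a prior axis: stays live and axis-free
  st0 <- update_polarity(polarity_state(cv, "live", shallow_policy = "freeze"),
                         cv, flat_pol)
  expect_true(all(st0$mode == "live"))
  expect_equal(max(abs(st0$axis)), 0)

  ## absent policy: axis drops but recovers when the gradient steepens
  sta <- update_polarity(polarity_state(cv, "live", shallow_policy = "absent"),
                         cv, grad_pol)
  sta <- update_polarity(sta, cv, flat_pol)
  expect_equal(max(abs(sta$axis)), 0)
  expect_true(all(sta$mode == "live"))
  sta <- update_polarity(sta, cv, grad_pol)
  expect_equal(sta$axis[1, ], c(-1, 0, 0), tolerance = 1e-12)
})

test_that("the interaction contract rejects geometry edits", {
  cv <- small_sheet(2)
  sim <- simulation(cv)
  bad <- function(state) {
    state$canvas$pos_a[1, 1] <- 99
    list(kpar = 1)
  }
  ## the hook gets a copy, so mutating it must not slip through silently;
  ## mutating the copy is harmless and allowed
  expect_silent(run_interaction(bad, sim))
  ## shorthand expansion
  out <- run_interaction(function(state) list(kpar = 2, kper = 1), sim)
  expect_equal(out$kpar_a, rep(2, n_vertices(cv)))
  expect_equal(out$kpar_b, rep(2, n_vertices(cv)))
  expect_equal(out$kper_a, rep(1, n_vertices(cv)))
  expect_equal(out$kthick, rep(0, n_vertices(cv)))
})
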