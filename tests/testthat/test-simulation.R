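test_that("configuration and timestep control", {
  expect_error(sim_config(dt = 0), "non-positive")
  cfg <- sim_config(dt = 5)
  expect_equal(choose_timestep(list(kpar_a = 1, kper_a = 0), cfg), 0.1)
  expect_equal(choose_timestep(list(kpar_a = 0), cfg), 5)
  expect_equal(choose_timestep(list(kpar_a = -2), cfg), 0.05)
  expect_equal(choose_timestep(list(kpar_a = 1), cfg, dt_target = 0.01), 0.01)
})

test_that("a zero-growth step moves nothing and advances time", {
  cv <- small_sheet(3)
  sim <- simulation(cv, config = sim_config(dt = 0.5))
  s1 <- simulate_step(sim)
  expect_equal(s1$canvas$pos_a, cv$pos_a)
  expect_equal(s1$time, 0.5)
  expect_equal(s1$step, 1L)
  expect_equal(s1$history$max_rotation, 0)
  ## identical reruns are bitwise deterministic
  s2 <- simulate_step(sim)
  expect_identical(s1$canvas, s2$canvas)
})

test_that("uniform anisotropic growth compounds multiplicatively", {
  p <- case_preset("A", resolution = 6, overrides = list(duration = 0.3))
  sim <- run_simulation(p$sim, until = 0.3)
  mid <- canvas_midplane(sim$canvas)
  ## iterative solves at the default tolerance leave ~1e-8 relative error
  expect_equal(diff(range(mid[, 2])), 1.1^3, tolerance = 1e-6)
  expect_equal(diff(range(mid[, 1])), 1, tolerance = 1e-6)
})

test_that("the rotation cap halves the time step and redoes the solve", {
  ## graded growth bends the sheet, so element rotations are nonzero; an
  ## artificially tiny rotation cap must force dt halvings
  p <- case_preset("J", resolution = 8)
  p$sim$config$max_step_rotation <- 1e-5 * pi / 180
  p$sim$config$max_halvings <- 4L
  expect_error(simulate_step(p$sim), "halvings")
  p2 <- case_preset("J", resolution = 8)
  p2$sim$config$max_step_rotation <- 0.02 * pi / 180
  s <- simulate_step(p2$sim)
  expect_lt(s$last_dt, p2$sim$config$dt)
  expect_lte(s$history$max_rotation, 0.02 * pi / 180)
})

test_that("remeshing keeps the simulation consistent mid-run", {
  p <- case_preset("H", resolution = 5, overrides = list(duration = 0.8))
  sim <- run_simulation(p$sim, until = 0.8)
  expect_gt(n_elements(sim$canvas), n_elements(p$sim$canvas))
  ## area still compounds like the analytic law despite the remesh
  expect_equal(tail(sim$history$area, 1), (1.1^8)^2, tolerance = 1e-6)
  ## history bookkeeping matches the final state
  expect_equal(tail(sim$history$n_vertices, 1), n_vertices(sim$canvas))
})

test_that("snapshots land exactly on the requested times", {
  cv <- small_sheet(3)
  sim <- simulation(cv, interaction = function(state) list(kpar = 0.1),
                    constraints = morphocanvas:::cs_flat,
                    config = sim_config(dt = 0.3))
  out <- run_simulation(sim, until = 1, snapshot_times = c(0.5, 1))
  expect_named(out$snapshots, c("0.5", "1"))
  expect_equal(out$snapshots[["0.5"]]$time, 0.5, tolerance = 1e-12)
  expect_equal(out$time, 1, tolerance = 1e-12)
  sm <- summary(out)
  expect_s3_class(sm, "summary.simulation")
  expect_output(print(sm))
})

test_that("dilution acts during growth and identities are inherited", {
  n0 <- 6
  cv <- build_flat_sheet(n0, n0)
  n <- n_vertices(cv)
  fields <- list(
    S = factor_field("S", "signalling", n, init = 1, D = 0),
    ID = factor_field("ID", "identity", n,
                      init = as.numeric(canvas_midplane(cv)[, 1] > 0)))
  sim <- simulation(cv, fields = fields,
                    interaction = function(state) list(kpar = 0.5, kper = 0.5),
                    constraints = morphocanvas:::cs_flat,
                    ## remeshing off: midpoint interpolation is not exactly
                    ## conservative and would confound the dilution check
                    config = sim_config(dt = 0.2, remesh = FALSE))
  out <- run_simulation(sim, until = 1)
  ## total amount of S is conserved while area grows
  expect_equal(field_mass(out$fields$S, vertex_control_volumes(out$canvas)),
               field_mass(fields$S, vertex_control_volumes(cv)),
               tolerance = 1e-10)
  expect_lt(max(out$fields$S$values), 1)
  ## identity stays binary through the run
  expect_true(all(out$fields$ID$values %in% c(0, 1)))
})

test_that("clones deform passively with the tissue", {
  p <- case_preset("A", resolution = 10, overrides = list(duration = 0.4))
  p$sim$clones <- mark_circular_clones(p$sim$canvas, 3, 0.05, seed = 5)
  sim <- run_simulation(p$sim, until = 0.4)
  st <- clone_shape_stats(sim$canvas, sim$clones)
  ## the tissue stretched 1.1^4 in y only; clones report the same ratio
  expect_equal(st$anisotropy, rep(1.1^4, 3), tolerance = 0.02)
  expect_equal(st$angle_deg, rep(90, 3), tolerance = 1)
})

test_that("residual accumulates only when retained", {
  for (ret in c(0, 1)) {
    p <- case_preset(if (ret == 0) "U" else "W", resolution = 8,
                     overrides = list(duration = 0.2))
    sim <- run_simulation(p$sim, until = 0.2)
    if (ret == 0) expect_equal(residual_norm(sim$store), 0)
    else expect_gt(residual_norm(sim$store), 0)
  }
})

test_that("identity latching in a full model run", {
  r <- run_case("Z", resolution = 8, overrides = list(duration = 0.4))
  inner <- r$sim$fields$INNER$values
  expect_true(all(inner %in% c(0, 1)))
  expect_gt(mean(inner), 0)
  ## the latched region is central: all INNER vertices lie inside the rim
  mid <- canvas_midplane(r$sim$canvas)
  rad <- sqrt(mid[, 1]^2 + mid[, 2]^2)
  expect_lt(max(rad[inner == 1]), max(rad))
})
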