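## The growth simulation loop.
##
## Each step, in order: (1) interaction function, (2) diffusion of
## signalling factors, (3) specified-growth assembly, (4) elastic solve and
## vertex update (with the remeshing check immediately after), (5) dilution
## with identity inheritance, (6) residual-strain discard/retain, (7) time
## advance, (8) summary/snapshot.  Steps are kept small enough that the
## linear elastic solve stays valid: growth per step is capped, and steps
## whose element rotations are too large are redone with a halved time
## step.

#' Simulation configuration
#'
#' @param dt target time step (upper bound; steps may be shortened).
#' @param max_step_growth cap on |rate| * dt per step (default 10\%).
#' @param max_step_rotation cap on element rotation per step, degrees; a
#'   solved step exceeding it is discarded and redone with half the time
#'   step.
#' @param solver,solver_tol elastic solver and its relative tolerance.
#' @param diffusion_tol implicit diffusion solve tolerance.
#' @param remesh enable edge splitting when elements grow too long.
#' @param quality_pass run the edge-flip quality pass after each split.
#' @param lumped_mass use the lumped mass matrix for diffusion.
#' @param max_halvings cap on time-step halvings within one step.
#' @export
sim_config <- function(dt = 0.05, max_step_growth = 0.10,
                       max_step_rotation = 10,
                       solver = "cgs", solver_tol = 1e-6,
                       diffusion_tol = 1e-4,
                       remesh = TRUE, quality_pass = FALSE,
                       lumped_mass = FALSE, max_halvings = 8L) {
  if (dt <= 0 || max_step_growth <= 0 || max_step_rotation <= 0)
    stop("sim_config: non-positive step control parameter")
  structure(list(dt = dt, max_step_growth = max_step_growth,
                 max_step_rotation = max_step_rotation * pi / 180,
                 solver = solver, solver_tol = solver_tol,
                 diffusion_tol = diffusion_tol,
                 remesh = remesh, quality_pass = quality_pass,
                 lumped_mass = lumped_mass,
                 max_halvings = as.integer(max_halvings)),
            class = "sim_config")
}

#' Create a simulation state
#'
#' @param canvas the initial canvas.
#' @param material an \code{\link{elastic_material}}.
#' @param fields named list of \code{\link{factor_field}}s.
#' @param polariser name of the field acting as polariser (or NULL for no
#'   polarity).
#' @param polarity a \code{\link{polarity_state}}; defaults to live
#'   polarity when a polariser is named.
#' @param interaction the interaction function (see
#'   \code{\link{run_interaction}}).
#' @param constraints function(canvas) returning a
#'   \code{\link{constraint_set}}; called fresh each step so label-based
#'   constraints survive remeshing.
#' @param retention per-vertex residual retention fraction (scalar or
#'   vector, may also be set by the interaction function).
#' @param clones clone markers from \code{\link{mark_circular_clones}}.
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{simulation}.
#' @export
simulation <- function(canvas, material = elastic_material(),
                       fields = list(), polariser = NULL, polarity = NULL,
                       interaction = NULL,
                       constraints = function(cv) constraint_set(cv),
                       retention = 0, clones = NULL,
                       config = sim_config()) {
  if (!inherits(canvas, "canvas")) stop("expected a canvas")
  if (!is.null(polariser) && is.null(fields[[polariser]]))
    stop("polariser field '", polariser, "' not among the fields")
  if (is.null(polarity) && !is.null(polariser))
    polarity <- polarity_state(canvas, "live")
  el <- edge_list(canvas)
  sim <- structure(list(
    canvas = canvas, material = material,
    stiffness = isotropic_stiffness(material),
    fields = fields, polariser = polariser, polarity = polarity,
    interaction = interaction, constraints = constraints,
    retention = retention, clones = clones, store = residual_store(canvas),
    config = config, time = 0, step = 0L,
    reference_edge = mean(edge_lengths(canvas, el)),
    initial_area = sum(triangle_areas(canvas)),
    history = NULL, last_deformation = NULL), class = "simulation")
  if (!is.null(polarity))
    sim$polarity <- update_polarity(sim$polarity, canvas,
                                    if (!is.null(polariser)) fields[[polariser]])
  sim
}

#' @export
print.simulation <- function(x, ...) {
  cat("simulation at t =", format(x$time), "(step", x$step, ")\n")
  print(x$canvas)
  invisible(x)
}

#' Equilibrate all signalling fields (setup phase)
#'
#' Replaces each signalling field by its diffusion-production-decay steady
#' state on the current geometry, then refreshes polarity.  Used before
#' growth begins so organiser-anchored gradients are fully established.
#'
#' @param sim a \code{simulation}.
#' @export
equilibrate_fields <- function(sim) {
  sys <- diffusion_system(sim$canvas, lumped = sim$config$lumped_mass)
  for (nm in names(sim$fields)) {
    f <- sim$fields[[nm]]
    ## material factors (no diffusion, no decay) have no dynamics to
    ## equilibrate; they keep their initial pattern
    if (f$kind == "signalling" && (f$D > 0 || f$decay > 0))
      sim$fields[[nm]] <- steady_state_field(f, sys)
  }
  if (!is.null(sim$polarity))
    sim$polarity <- update_polarity(sim$polarity, sim$canvas,
                                    if (!is.null(sim$polariser))
                                      sim$fields[[sim$polariser]])
  sim
}

#' Choose the time step from the growth-rate cap
#'
#' dt = min(target, max_step_growth / max |rate|); rotation is handled
#' after the solve by halving and repeating.
#'
#' @param rates list or vector of growth-rate values active this step.
#' @param config a \code{sim_config}.
#' @param dt_target upper bound (defaults to \code{config$dt}).
#' @export
choose_timestep <- function(rates, config, dt_target = config$dt) {
  kmax <- max(abs(unlist(rates)), 0)
  if (kmax <= 0) return(dt_target)
  min(dt_target, config$max_step_growth / kmax)
}

## per-vertex quantity -> per-element mean
vertex_to_element <- function(cv, x) {
  x <- rep_len(x, n_vertices(cv))
  (x[cv$tri[, 1]] + x[cv$tri[, 2]] + x[cv$tri[, 3]]) / 3
}

#' Advance the simulation by one step
#'
#' @param sim a \code{simulation}.
#' @param dt_max optional cap on this step's time step (e.g. to land
#'   exactly on a requested output time).
#' @return the updated \code{simulation}; the actual step taken is in
#'   \code{sim$last_dt}.
#' @export
simulate_step <- function(sim, dt_max = Inf) {
  cfg <- sim$config
  cv <- sim$canvas

  ## 1. interaction function: growth rates, factor regulation, retention
  act <- run_interaction(sim$interaction, sim)
  if (!is.null(act$retention)) sim$retention <- act$retention
  for (nm in names(act$production))
    sim$fields[[nm]]$production <- rep_len(act$production[[nm]], n_vertices(cv))
  for (nm in names(act$decay))
    sim$fields[[nm]]$decay <- act$decay[[nm]]
  for (nm in names(act$identities)) {
    if (sim$fields[[nm]]$kind != "identity")
      stop("interaction function set identity values on non-identity factor '",
           nm, "'")
    sim$fields[[nm]]$values <- rep_len(act$identities[[nm]], n_vertices(cv))
  }
  if (identical(act$polarity, "freeze")) {
    sim$polarity <- freeze_polarity(sim$polarity)
  } else if (inherits(act$polarity, "polarity_state")) {
    sim$polarity <- act$polarity
  }

  rates <- act[c("kpar_a", "kpar_b", "kper_a", "kper_b", "kthick")]
  dt <- choose_timestep(rates, cfg, min(cfg$dt, dt_max))

  ## 2. diffusion of signalling factors
  dsys <- diffusion_system(cv, lumped = cfg$lumped_mass)
  for (nm in names(sim$fields))
    if (sim$fields[[nm]]$kind == "signalling")
      sim$fields[[nm]] <- step_signalling_field(sim$fields[[nm]], dsys, dt,
                                                tol = cfg$diffusion_tol)

  ## 3. specified growth (polarity from the end of the previous step)
  frame <- local_frame(cv, sim$polarity)
  spec <- growth_spec(cv, kpar_a = rates$kpar_a, kpar_b = rates$kpar_b,
                      kper_a = rates$kper_a, kper_b = rates$kper_b,
                      kthick = rates$kthick)
  cs <- sim$constraints(cv)

  ## 4. elastic solve, redoing with halved dt while rotations are too big
  for (halving in 0:cfg$max_halvings) {
    growth <- assemble_specified_growth(spec, frame, dt)
    sys <- assemble_elastic_system(cv, sim$stiffness, growth, cs)
    sol <- solve_displacements(sys, tol = cfg$solver_tol, solver = cfg$solver)
    def <- decompose_growth(cv, sol)
    if (max(def$rotation_angle) <= cfg$max_step_rotation) break
    if (halving == cfg$max_halvings)
      stop("element rotation per step stayed above the cap after ",
           cfg$max_halvings, " time-step halvings")
    dt <- dt / 2
  }

  ## vertex update; record control volumes around it for dilution
  vol_old <- vertex_control_volumes(cv)
  cv <- apply_displacements(cv, sol)
  ratio <- vol_old / vertex_control_volumes(cv)

  ## residual bookkeeping and frozen-axis convection use this step's
  ## per-element deformation, so they run on the pre-remesh connectivity
  resid <- step_residual(growth, def)
  sim$store <- convect_residual(sim$store, def)
  sim$store <- accumulate_residual(sim$store, resid,
                                   vertex_to_element(cv, sim$retention))
  if (!is.null(sim$polarity))
    sim$polarity <- update_polarity(sim$polarity, cv,
                                    if (!is.null(sim$polariser))
                                      sim$fields[[sim$polariser]],
                                    deformation = def)

  ## remeshing check (between the vertex update and dilution)
  if (cfg$remesh) {
    old_pos <- if (!is.null(sim$clones)) clone_positions(cv, sim$clones)
    rm <- split_long_edges(cv, sim$reference_edge, sim$fields)
    if (rm$changed) {
      cv <- rm$canvas
      sim$fields <- rm$fields
      ## dilution ratio on new vertices: mean of the parent edge endpoints
      ratio <- c(ratio, (ratio[rm$new_vertex_edge[, 1]] +
                           ratio[rm$new_vertex_edge[, 2]]) / 2)
      if (is.matrix(sim$retention) || length(sim$retention) > 1L) {
        r <- rep_len(sim$retention, length(vol_old))
        sim$retention <- c(r, (r[rm$new_vertex_edge[, 1]] +
                                 r[rm$new_vertex_edge[, 2]]) / 2)
      }
      sim$store <- remap_residual(sim$store, rm$parent_of_new)
      if (!is.null(sim$polarity))
        sim$polarity <- remap_polarity(sim$polarity, rm$parent_of_new)
      if (!is.null(sim$clones))
        sim$clones <- reanchor_clones(cv, sim$clones, rm$parent_of_new, old_pos)
      if (cfg$quality_pass) {
        qp <- improve_quality(cv)
        if (qp$changed) {
          cv <- qp$canvas
          sim$store <- remap_residual(sim$store, qp$parent_of_new)
          if (!is.null(sim$polarity))
            sim$polarity <- remap_polarity(sim$polarity, qp$parent_of_new)
        }
      }
    }
  }

  ## dilution of signalling factors; identities inherit unchanged
  sim$fields <- dilute_fields_by_ratio(sim$fields, ratio)

  sim$canvas <- cv
  sim$last_deformation <- def
  sim$last_dt <- dt
  sim$time <- sim$time + dt
  sim$step <- sim$step + 1L
  row <- data.frame(step = sim$step, time = sim$time, dt = dt,
                    area = sum(triangle_areas(cv)),
                    volume = sum(element_volumes(cv)),
                    n_vertices = n_vertices(cv),
                    n_elements = n_elements(cv),
                    max_rotation = max(def$rotation_angle),
                    residual_norm = residual_norm(sim$store),
                    solver_iterations = sol$iterations)
  sim$history <- rbind(sim$history, row)
  sim
}

#' Run the simulation to a target time
#'
#' @param sim a \code{simulation}.
#' @param until target time.
#' @param snapshot_times times at which to keep a copy of the state; steps
#'   are shortened to land on them exactly.
#' @param max_steps safety cap on the number of steps.
#' @param verbose print one line per step.
#' @return the final \code{simulation}, with \code{sim$snapshots} a named
#'   list of states at the requested times.
#' @export
run_simulation <- function(sim, until, snapshot_times = numeric(0),
                           max_steps = 10000L, verbose = FALSE) {
  if (until < sim$time) stop("target time lies in the past")
  snapshot_times <- sort(snapshot_times[snapshot_times > sim$time &
                                          snapshot_times <= until])
  snaps <- if (is.null(sim$snapshots)) list() else sim$snapshots
  eps <- 1e-9 * max(1, until)
  while (sim$time < until - eps) {
    if (sim$step >= max_steps)
      stop("simulation exceeded max_steps = ", max_steps)
    next_stop <- c(snapshot_times[snapshot_times > sim$time + eps], until)[1]
    sim <- simulate_step(sim, dt_max = next_stop - sim$time)
    if (verbose)
      cat(sprintf("step %4d  t = %8.4f  area = %10.5f  verts = %d\n",
                  sim$step, sim$time,
                  utils::tail(sim$history$area, 1), n_vertices(sim$canvas)))
    hit <- abs(snapshot_times - sim$time) <= eps
    if (any(hit)) {
      nm <- format(snapshot_times[hit][1])
      sim_copy <- sim; sim_copy$snapshots <- NULL; sim_copy$history <- NULL
      snaps[[nm]] <- sim_copy
    }
  }
  sim$snapshots <- snaps
  sim
}

#' Summary table of a simulation run
#' @param object a \code{simulation}.
#' @param ... unused.
#' @export
summary.simulation <- function(object, ...) {
  h <- object$history
  if (is.null(h)) h <- data.frame()
  structure(list(history = h, time = object$time,
                 area_multiple = if (nrow(h)) utils::tail(h$area, 1) /
                   object$initial_area else 1),
            class = "summary.simulation")
}

#' @export
print.summary.simulation <- function(x, ...) {
  cat("simulation summary: t =", format(x$time),
      " area multiple =", format(x$area_multiple), "\n")
  if (nrow(x$history)) print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}
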