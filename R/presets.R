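## Named model presets.
##
## Each preset bundles a canvas generator, factor declarations, an
## interaction function and constraints into a ready-to-run simulation:
## the twenty-six lettered demonstration models (2D sheets A-I, 3D sheets
## J-Q, tubes R-T, residual-strain experiments U-Y, threshold patterning
## Z) and the invagination demonstration driven by asymmetric per-surface
## growth.  Magnitudes are of order 1 per unit time for the sheets and
## 0.018 per unit time for the tubes; durations are chosen to reach the
## documented areal multiples.

preset_names <- function() c(LETTERS, "invagination")

## constraint builders (label-based so they survive remeshing)
cs_flat <- function(cv) constraint_set(cv, flat = TRUE)
cs_boundary_z <- function(cv) constraint_set(cv, fix_z = cv$labels$boundary)
cs_base_z <- function(cv) constraint_set(cv, fix_z = cv$labels$base)
cs_free <- function(cv) constraint_set(cv)

## linear-in-x material factor: carried with the canvas, neither diffusing
## nor diluted ("most strongly expressed along the right edge")
lin_x_factor <- function(cv) {
  x <- canvas_midplane(cv)[, 1]
  factor_field("LIN", "signalling", n_vertices(cv),
               init = (x - min(x)) / (max(x) - min(x)),
               D = 0, dilutable = FALSE)
}

## clip the tiny negative undershoots a consistent-mass diffusion solve
## can produce near steep clamped gradients on coarse meshes
nonneg <- function(x) pmax(x, 0)

pol_factor <- function(cv, plus, minus, D = 1) {
  factor_field("POL", "signalling", n_vertices(cv), init = 0.5, D = D,
               dilutable = FALSE,
               clamp = list(vertices = c(plus, minus),
                            value = rep(c(1, 0), c(length(plus), length(minus)))))
}

#' Build a preset simulation
#'
#' Constructs the named demonstration model: canvas, factors, interaction
#' function and constraints, with the signalling fields already
#' equilibrated (setup phase).
#'
#' @param name one of \code{LETTERS} or \code{"invagination"}.
#' @param resolution mesh resolution parameter (grid cells per side for
#'   sheets, rings for discs, circumferential vertices for tubes); default
#'   close to the documented element counts.
#' @param overrides named list of parameter overrides; recognised names
#'   depend on the preset (e.g. \code{K}, \code{duration}, \code{dt},
#'   \code{thickness}).
#' @return list with the prepared \code{sim}, the recommended
#'   \code{duration}, \code{snapshot_times}, a \code{description}, and for
#'   the residual experiments a \code{followup} function (cut/release and
#'   relax) applied after growth.
#' @export
case_preset <- function(name, resolution = NULL, overrides = list()) {
  name <- as.character(name)
  if (!name %in% preset_names())
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  ov <- function(key, default)
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  switch(name,
         A = , B = , C = , D = , E = , F = , G = , H = , I =
           preset_sheet2d(name, resolution, ov),
         J = , K = , L = , M = , N = , O = , P = , Q =
           preset_sheet3d(name, resolution, ov),
         R = , S = , T = preset_tube(name, resolution, ov),
         U = , V = , W = , X = preset_residual(name, resolution, ov),
         Y = preset_tube_residual(resolution, ov),
         Z = preset_disc_threshold(resolution, ov),
         invagination = preset_invagination(resolution, ov))
}

## ---------------------------------------------------------------------------
## 2D sheets (A-I): flat square kept planar by the flatness constraint

preset_sheet2d <- function(name, resolution, ov) {
  res <- if (is.null(resolution)) 40L else as.integer(resolution)
  K <- ov("K", 1)
  duration <- ov("duration", 1.2)
  dt <- ov("dt", 0.1)
  cv <- build_flat_sheet(res, res, side = 1, thickness = ov("thickness", 0.1))
  fields <- list()
  polariser <- NULL
  polarity <- NULL
  freeze_after_setup <- FALSE
  if (name %in% c("A", "C", "E", "F", "G", "H", "I")) {
    polariser <- "POL"
    org <- switch(name,
                  F = list(plus = cv$labels$midline_y,
                           minus = c(cv$labels$edge_top, cv$labels$edge_bottom)),
                  G = list(plus = c(cv$labels$edge_top, cv$labels$edge_bottom),
                           minus = cv$labels$midline_y),
                  list(plus = cv$labels$edge_bottom,
                       minus = cv$labels$edge_top))
    fields$POL <- pol_factor(cv, org$plus, org$minus)
    polarity <- polarity_state(cv, "live")
    freeze_after_setup <- name != "E"
  }
  if (name == "D") polarity <- polarity_state(cv, "external",
                                              external_dir = c(0, 1, 0))
  if (name %in% c("B", "C", "D", "I"))
    fields$LIN <- lin_x_factor(cv)
  hook <- switch(
    name,
    ## uniform anisotropic growth along the frozen polarity
    A = , E = , F = , G = function(state)
      list(kpar = K, kper = 0),
    ## isotropic, graded across the sheet
    B = function(state)
      list(kpar = K * state$fields$LIN$values,
           kper = K * state$fields$LIN$values),
    ## anisotropic and graded (A + B); D identical but external frame
    C = , D = function(state)
      list(kpar = K * state$fields$LIN$values, kper = 0),
    ## uniform isotropic enlargement
    H = function(state) list(kpar = K, kper = K),
    ## anisotropic with the cross-gradient applied perpendicular
    I = function(state)
      list(kpar = 0, kper = K * state$fields$LIN$values))
  sim <- simulation(cv, fields = fields, polariser = polariser,
                    polarity = polarity, interaction = hook,
                    constraints = cs_flat,
                    config = sim_config(dt = dt,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  if (freeze_after_setup) sim$polarity <- freeze_polarity(sim$polarity)
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       description = paste0("2D sheet model ", name))
}

## ---------------------------------------------------------------------------
## 3D sheets (J-Q): bowed square, boundary fixed vertically

preset_sheet3d <- function(name, resolution, ov) {
  res <- if (is.null(resolution)) 32L else as.integer(resolution)
  K <- ov("K", 1)
  duration <- ov("duration", 0.8)
  dt <- ov("dt", 0.1)
  cv <- build_flat_sheet(res, res, side = 1,
                         thickness = ov("thickness", 0.05),
                         bow = ov("bow", 0.02))
  centre <- cv$labels$centre
  fields <- list(
    ## signal diffusing from a central organiser; breadth set per case
    CEN = factor_field("CEN", "signalling", n_vertices(cv), init = 0,
                       D = ov("D_cen", switch(name, K = 0.2, 0.02)),
                       decay = ov("decay_cen", switch(name, K = 1, 4)),
                       dilutable = FALSE,
                       clamp = list(vertices = centre, value = 1)))
  polariser <- NULL; polarity <- NULL
  if (name == "L") {
    ## radial polarity away from the central organiser
    polariser <- "CEN"
    polarity <- polarity_state(cv, "live", shallow_policy = "absent")
  }
  if (name %in% c("N", "O", "P", "Q"))
    fields$LIN <- lin_x_factor(cv)
  gain <- ov("gain", switch(name, J = 3, K = 2, L = 8, M = 20,
                            N = 2, O = 3, P = 4, Q = 4))
  hook <- switch(
    name,
    ## isotropic growth promoted by the central signal: a small spike (J)
    ## or, with the broad signal, a central bulge (K)
    J = , K = function(state) {
      k <- K * (pro(gain, nonneg(state$fields$CEN$values)) - 1)
      list(kpar = k, kper = k)
    },
    ## strong radial anisotropic growth at the centre: tall sharp spike
    L = function(state)
      list(kpar = K * (pro(gain, nonneg(state$fields$CEN$values)) - 1), kper = 0),
    ## growth suppressed at the centre: surrounding growth raises a
    ## rounded projection
    M = function(state) {
      k <- K * inh(gain, nonneg(state$fields$CEN$values))
      list(kpar = k, kper = k)
    },
    ## interacting central and lateral fields: an offset (asymmetric) spur;
    ## Q mirrors P by reversing the lateral gradient
    N = , O = , P = function(state) {
      k <- K * (pro(gain, nonneg(state$fields$CEN$values) *
                      state$fields$LIN$values) - 1)
      list(kpar = k, kper = k)
    },
    Q = function(state) {
      k <- K * (pro(gain, nonneg(state$fields$CEN$values) *
                      (1 - state$fields$LIN$values)) - 1)
      list(kpar = k, kper = k)
    })
  sim <- simulation(cv, fields = fields, polariser = polariser,
                    polarity = polarity, interaction = hook,
                    constraints = cs_boundary_z,
                    config = sim_config(dt = dt,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       description = paste0("3D sheet model ", name))
}

## ---------------------------------------------------------------------------
## Tubes (R-T): cylinder closed at the top, base fixed vertically

preset_tube <- function(name, resolution, ov) {
  res <- if (is.null(resolution)) 40L else as.integer(resolution)
  K <- ov("K", 0.018)
  duration <- ov("duration", log(2.2) / 0.018)
  dt <- ov("dt", 4)
  cv <- build_cylinder(radius = 1, height = 3, closed_top = TRUE,
                       resolution = res, thickness = ov("thickness", 0.1))
  fields <- list()
  polariser <- NULL; polarity <- NULL
  if (name == "S") {
    ## axial polarity: signal from the base organiser up the tube
    polariser <- "POL"
    fields$POL <- pol_factor(cv, plus = cv$labels$base,
                             minus = cv$labels$apex)
    polarity <- polarity_state(cv, "live")
  }
  if (name == "T") {
    ## growth restricted to the rim neighbourhood, directed upward
    fields$RIM <- factor_field("RIM", "signalling", n_vertices(cv), init = 0,
                               D = ov("D_rim", 0.3),
                               decay = ov("decay_rim", 1.5),
                               dilutable = FALSE,
                               clamp = list(vertices = cv$labels$rim, value = 1))
    polarity <- polarity_state(cv, "external", external_dir = c(0, 0, 1))
  }
  hook <- switch(
    name,
    R = function(state) list(kpar = K, kper = K),       # isotropic ballooning
    S = function(state) list(kpar = K, kper = 0),       # anisotropic arching
    T = function(state) {
      k <- K * ov("gain", 6) * nonneg(state$fields$RIM$values)
      list(kpar = k, kper = 0)
    })
  sim <- simulation(cv, fields = fields, polariser = polariser,
                    polarity = polarity, interaction = hook,
                    constraints = cs_base_z,
                    config = sim_config(dt = dt,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  if (name == "S") sim$polarity <- freeze_polarity(sim$polarity)
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       description = paste0("tube model ", name))
}

## ---------------------------------------------------------------------------
## Residual-strain experiments (U-X): grow, then cut or release

preset_residual <- function(name, resolution, ov) {
  res <- if (is.null(resolution)) 24L else as.integer(resolution)
  K <- ov("K", 1)
  duration <- ov("duration", 0.5)
  dt <- ov("dt", 0.1)
  retention <- if (name %in% c("U", "V")) 0 else 1
  cv <- build_flat_sheet(res, res, side = 1, thickness = ov("thickness", 0.1))
  ## isotropic growth promoted around the centre: incompatible in the
  ## plane, so the flatness constraint forces residual strain to build up
  ## (or be dissipated, for the control cases U and V)
  fields <- list(
    CEN = factor_field("CEN", "signalling", n_vertices(cv), init = 0,
                       D = ov("D_cen", 0.05), decay = ov("decay_cen", 2),
                       dilutable = FALSE,
                       clamp = list(vertices = cv$labels$centre, value = 1)))
  gain <- ov("gain", 4)
  hook <- function(state) {
    k <- K * (pro(gain, nonneg(state$fields$CEN$values)) - 1)
    list(kpar = k, kper = k)
  }
  sim <- simulation(cv, fields = fields, interaction = hook,
                    constraints = cs_flat, retention = retention,
                    config = sim_config(dt = dt, remesh = FALSE,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  cut_after <- name %in% c("U", "W")
  followup <- function(sim) {
    cv <- sim$canvas
    if (cut_after) {
      ## cutting duplicates vertices only; the per-element store carries over
      cv <- cut_along_path(cv, midline_cut_path(cv))$canvas
    } else if (residual_norm(sim$store) > 0) {
      ## a flat sheet carrying incompatible retained strain is an unstable
      ## equilibrium on release: the out-of-plane force is exactly zero by
      ## mirror symmetry, so a deterministic solver never buckles.  Seed
      ## the bifurcation with a tiny smooth imperfection (1% of thickness)
      mid <- canvas_midplane(cv)
      bump <- 1e-3 * cospi(mid[, 1]) * cospi(mid[, 2])
      cv$pos_a[, 3] <- cv$pos_a[, 3] + bump
      cv$pos_b[, 3] <- cv$pos_b[, 3] + bump
    }
    relax_residual(cv, sim$store, sim$material, constraints = cs_free(cv),
                   solver_tol = sim$config$solver_tol, max_iters = 500L)
  }
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       followup = followup,
       description = paste0("residual-strain experiment ", name,
                            if (cut_after) " (cut then relax)"
                            else " (release then relax)"))
}

## shortest edge path across the sheet along the horizontal midline,
## from the left boundary to the centre
midline_cut_path <- function(cv) {
  mid <- canvas_midplane(cv)
  cand <- cv$labels$midline_y
  if (is.null(cand) || length(cand) < 2)
    stop("canvas has no midline_y label to cut along")
  cand <- cand[order(mid[cand, 1])]
  cand[seq_len(ceiling(length(cand) / 2))]
}

## ---------------------------------------------------------------------------
## Case Y: tube grown with surface-asymmetric growth and full retention,
## then cut into eight meridional strips that curl on release

preset_tube_residual <- function(resolution, ov) {
  res <- if (is.null(resolution)) 32L else as.integer(resolution)
  K <- ov("K", 0.018)
  duration <- ov("duration", 30)
  dt <- ov("dt", 4)
  cv <- build_cylinder(radius = 1, height = 3, closed_top = FALSE,
                       resolution = res, thickness = ov("thickness", 0.1))
  ## the inner surface grows faster than the outer; the closed tube cannot
  ## bend to realise the difference, so a through-thickness residual is
  ## retained and the strips curl when the cuts release it
  asym <- ov("asymmetry", 0.5)
  retention <- ov("retention", 1)
  hook <- function(state)
    list(kpar_a = K * (1 + asym), kper_a = K * (1 + asym),
         kpar_b = K * (1 - asym), kper_b = K * (1 - asym))
  sim <- simulation(cv, interaction = hook, constraints = cs_base_z,
                    retention = retention,
                    config = sim_config(dt = dt, remesh = FALSE,
                                        solver_tol = ov("solver_tol", 1e-6)))
  followup <- function(sim) {
    cv <- sim$canvas
    for (path in eight_cut_paths(cv))
      cv <- cut_along_path(cv, path)$canvas
    relax_residual(cv, sim$store, sim$material, constraints = cs_free(cv),
                   solver_tol = sim$config$solver_tol)
  }
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       followup = followup,
       description = "tube with one-sided retention, cut into 8 strips (Y)")
}

## eight meridional vertex chains down an open tube
eight_cut_paths <- function(cv) {
  mid <- canvas_midplane(cv)
  th <- atan2(mid[, 2], mid[, 1])
  el <- edge_list(cv)
  lapply(seq_len(8L) * pi / 4, function(a) {
    ## greedy walk from the rim to the base staying near azimuth a
    near <- abs(((th - a + pi) %% (2 * pi)) - pi)
    start <- which.max(mid[, 3] - near)  # highest vertex near the azimuth
    path <- start
    repeat {
      v <- path[length(path)]
      nb <- c(el$edges[el$edges[, 1] == v, 2], el$edges[el$edges[, 2] == v, 1])
      nb <- setdiff(nb, path)
      nb <- nb[mid[nb, 3] < mid[v, 3] - 1e-9]
      if (!length(nb)) break
      path <- c(path, nb[which.min(near[nb])])
    }
    path
  })
}

## ---------------------------------------------------------------------------
## Case Z: threshold patterning on a disc

preset_disc_threshold <- function(resolution, ov) {
  res <- if (is.null(resolution)) 24L else as.integer(resolution)
  K <- ov("K", 0.5)
  duration <- ov("duration", 1)
  dt <- ov("dt", 0.1)
  threshold <- ov("threshold", 0.3)
  cv <- build_disc(radius = 1, resolution = res,
                   thickness = ov("thickness", 0.05))
  fields <- list(
    ## signal produced at the rim organiser, decaying inward: a bowl
    S = factor_field("S", "signalling", n_vertices(cv), init = 0,
                     D = ov("D_s", 0.2), decay = ov("decay_s", 2),
                     dilutable = TRUE,
                     clamp = list(vertices = cv$labels$rim, value = 1)),
    INNER = factor_field("INNER", "identity", n_vertices(cv), init = 0))
  hook <- function(state) {
    s <- nonneg(state$fields$S$values)
    inner <- apply_threshold_rule(s, threshold, state$fields$INNER$values)
    k <- K * inner
    list(kpar = k, kper = k, identities = list(INNER = inner))
  }
  sim <- simulation(cv, fields = fields, interaction = hook,
                    constraints = cs_boundary_z_disc,
                    config = sim_config(dt = dt,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       description = "disc with rim signal and threshold patterning (Z)")
}

cs_boundary_z_disc <- function(cv) constraint_set(cv, fix_z = cv$labels$rim)

## ---------------------------------------------------------------------------
## Invagination: asymmetric per-surface growth (shrink outside, expand
## inside) over a central region of a sheet

preset_invagination <- function(resolution, ov) {
  res <- if (is.null(resolution)) 32L else as.integer(resolution)
  K <- ov("K", 1)
  duration <- ov("duration", 0.6)
  dt <- ov("dt", 0.05)
  cv <- build_flat_sheet(res, res, side = 1,
                         thickness = ov("thickness", 0.05),
                         bow = ov("bow", 0.02))
  fields <- list(
    CEN = factor_field("CEN", "signalling", n_vertices(cv), init = 0,
                       D = ov("D_cen", 0.05), decay = ov("decay_cen", 3),
                       dilutable = FALSE,
                       clamp = list(vertices = cv$labels$centre, value = 1)))
  hook <- function(state) {
    c_ <- nonneg(state$fields$CEN$values)
    ## B surface (upper, outside) shrinks, A surface (lower, inside)
    ## expands where the central signal is high
    list(kpar_a = K * c_, kper_a = K * c_,
         kpar_b = -K * c_, kper_b = -K * c_)
  }
  sim <- simulation(cv, fields = fields, interaction = hook,
                    constraints = cs_boundary_z,
                    config = sim_config(dt = dt,
                                        solver_tol = ov("solver_tol", 1e-6)))
  sim <- equilibrate_fields(sim)
  list(sim = sim, duration = duration,
       snapshot_times = ov("snapshot_times", duration),
       description = "invagination by asymmetric per-surface growth")
}

#' Run a named preset
#'
#' Builds the preset, runs it to its recommended duration (or an
#' overridden one), applies any follow-up experiment (cutting/release and
#' relaxation for the residual-strain presets), and returns snapshots.
#'
#' @inheritParams case_preset
#' @param verbose print progress.
#' @return list with the final \code{sim}, \code{snapshots},
#'   \code{summary} (one data-frame row per snapshot, see
#'   \code{\link{summarize_snapshots}}), and \code{followup} results where
#'   applicable.
#' @export
run_case <- function(name, resolution = NULL, overrides = list(),
                     verbose = FALSE) {
  p <- case_preset(name, resolution, overrides)
  sim <- run_simulation(p$sim, until = p$duration,
                        snapshot_times = p$snapshot_times,
                        verbose = verbose)
  fu <- if (!is.null(p$followup)) p$followup(sim)
  snaps <- sim$snapshots
  if (is.null(snaps) || !length(snaps)) {
    final <- sim; final$snapshots <- NULL
    snaps <- stats::setNames(list(final), format(sim$time))
  }
  list(sim = sim, snapshots = snaps,
       summary = summarize_snapshots(snaps),
       followup = fu, description = p$description)
}

#' Summary table of snapshots
#'
#' One row per snapshot: time, areal growth multiple, mean resultant
#' anisotropy over the last step, residual-store norm, clone statistics
#' when clones are tracked, and mesh size.
#'
#' @param snapshots named list of simulation states (see
#'   \code{\link{run_simulation}}).
#' @return a data frame.
#' @export
summarize_snapshots <- function(snapshots) {
  rows <- lapply(snapshots, function(s) {
    aniso <- if (!is.null(s$last_deformation)) {
      ev <- apply(s$last_deformation$strain, 1,
                  function(m) { e <- eigen(m, symmetric = TRUE)$values
                                max(e) - min(e) })
      mean(ev)
    } else 0
    cl <- if (!is.null(s$clones)) {
      st <- clone_shape_stats(s$canvas, s$clones)
      c(clone_anisotropy = mean(st$anisotropy[is.finite(st$anisotropy)]))
    } else c(clone_anisotropy = NA_real_)
    data.frame(time = s$time,
               area_multiple = sum(triangle_areas(s$canvas)) / s$initial_area,
               max_strain_anisotropy = aniso,
               residual_norm = residual_norm(s$store),
               clone_anisotropy = unname(cl),
               n_elements = n_elements(s$canvas))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
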