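## Regulatory factor fields on the midplane mesh.
##
## Identity factors are non-propagating regional labels; signalling factors
## diffuse, are produced and decay, and are diluted by growth.  Factor
## concentrations do not vary through the thickness, so one value per
## midplane vertex suffices.

#' Create a factor field
#'
#' @param name factor name.
#' @param kind "identity" (no propagation, never diluted) or "signalling".
#' @param n number of midplane vertices.
#' @param init initial values (scalar or length-n vector).
#' @param D diffusion constant (length^2 / time); must be 0 for identity
#'   factors.
#' @param decay uniform decay rate (1 / time).
#' @param production per-vertex production rate (scalar or vector).
#' @param dilutable logical; is the factor diluted by volumetric growth?
#'   Identity factors are never dilutable.
#' @param clamp named clamps: integer vertex indices (values held fixed at
#'   their current value each step) or a list \code{list(vertices=, value=)}.
#' @return object of class \code{factor_field}.
#' @export
factor_field <- function(name, kind = c("identity", "signalling"), n,
                         init = 0, D = 0, decay = 0, production = 0,
                         dilutable = NULL, clamp = NULL) {
  kind <- match.arg(kind)
  if (kind == "identity" && D != 0)
    stop("identity factors do not propagate: D must be 0")
  if (is.null(dilutable)) dilutable <- kind == "signalling"
  if (kind == "identity" && dilutable)
    stop("identity factors are never diluted")
  values <- rep_len(init, n)
  clamp_idx <- integer(); clamp_val <- numeric()
  if (!is.null(clamp)) {
    if (is.list(clamp)) {
      clamp_idx <- as.integer(clamp$vertices)
      clamp_val <- rep_len(clamp$value, length(clamp_idx))
    } else {
      clamp_idx <- as.integer(clamp)
      clamp_val <- values[clamp_idx]
    }
    values[clamp_idx] <- clamp_val
  }
  structure(list(name = name, kind = kind, values = values, D = D,
                 decay = decay, production = rep_len(production, n),
                 dilutable = dilutable,
                 clamp_idx = clamp_idx, clamp_val = clamp_val),
            class = "factor_field")
}

#' Promotion multiplier
#'
#' Standard regulatory-network helper: an elementwise multiplier that tends
#' to 1 as the regulator vanishes and increases with it,
#' \code{pro(k, x) = 1 + k x}.
#'
#' @param k gain (>= 0).
#' @param x regulator concentrations (>= 0 elementwise).
#' @export
pro <- function(k, x) {
  if (k < 0) stop("pro: gain must be non-negative")
  if (any(x < 0)) stop("pro: negative concentrations")
  1 + k * x
}

#' Inhibition multiplier
#'
#' Elementwise multiplier equal to 1 at x = 0, decreasing towards 0,
#' \code{inh(k, x) = 1 / (1 + k x)}.
#'
#' @inheritParams pro
#' @export
inh <- function(k, x) {
  if (k < 0) stop("inh: gain must be non-negative")
  if (any(x < 0)) stop("inh: negative concentrations")
  1 / (1 + k * x)
}

#' Threshold-latching rule for identity factors
#'
#' Sets the identity factor to 1 wherever the signal has dropped below the
#' threshold; once expressed it stays expressed (latching).
#'
#' @param signal per-vertex signal values.
#' @param threshold scalar threshold (finite, or -Inf for never).
#' @param identity per-vertex identity values (0/1).
#' @return updated identity values.
#' @export
apply_threshold_rule <- function(signal, threshold, identity) {
  if (is.na(threshold)) stop("threshold must not be NA")
  identity[signal < threshold] <- 1
  identity
}

## ---------------------------------------------------------------------------
## Polarity

#' Gradient of a factor field over each midplane triangle
#'
#' The gradient of the linear interpolant, lying in the triangle plane;
#' zero where the field is locally constant or the triangle degenerate.
#'
#' @param cv a canvas.
#' @param values per-vertex scalar values (or a \code{factor_field}).
#' @return M x 3 matrix of per-element gradient vectors.
#' @export
compute_pol_gradient <- function(cv, values) {
  if (inherits(values, "factor_field")) values <- values$values
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  p1 <- mid[tri[, 1], , drop = FALSE]
  p2 <- mid[tri[, 2], , drop = FALSE]
  p3 <- mid[tri[, 3], , drop = FALSE]
  nraw <- row_cross(p2 - p1, p3 - p1)
  a2 <- row_norm(nraw)                   # 2 * area
  nhat <- nraw / ifelse(a2 > 0, a2, 1)
  ## grad phi_i = nhat x e_i / (2A), e_i the edge opposite vertex i
  g1 <- row_cross(nhat, p3 - p2)
  g2 <- row_cross(nhat, p1 - p3)
  g3 <- row_cross(nhat, p2 - p1)
  grad <- (values[tri[, 1]] * g1 + values[tri[, 2]] * g2 +
             values[tri[, 3]] * g3) / ifelse(a2 > 0, a2, 1)
  grad[a2 <= 1e-300, ] <- 0
  grad
}

#' Create a polarity state
#'
#' Per-element growth axis derived from the polariser gradient.  Modes:
#' \code{live} (axis follows the current gradient), \code{frozen} (axis
#' fixed to the canvas and convected with it), \code{external} (axis is the
#' in-plane projection of a fixed lab-frame direction), \code{absent} (no
#' axis; growth isotropic).
#'
#' @param cv a canvas.
#' @param mode initial mode for all elements.
#' @param gradient_threshold minimum |grad POL| for a usable axis; when
#'   NULL a default of 1e-6 x (POL range) / (canvas diameter) is chosen at
#'   the first update.
#' @param shallow_policy what a live axis does when the gradient falls
#'   below the threshold: freeze there, or become absent (isotropic).
#' @param external_dir lab-frame direction for \code{external} mode.
#' @return object of class \code{polarity_state}.
#' @export
polarity_state <- function(cv, mode = c("live", "frozen", "external", "absent"),
                           gradient_threshold = NULL,
                           shallow_policy = c("freeze", "absent"),
                           external_dir = c(0, 1, 0)) {
  mode <- match.arg(mode)
  m <- n_elements(cv)
  structure(list(axis = matrix(0, m, 3),
                 mode = rep(mode, m),
                 gradient_threshold = gradient_threshold,
                 shallow_policy = match.arg(shallow_policy),
                 external_dir = external_dir / sqrt(sum(external_dir^2))),
            class = "polarity_state")
}

#' Update the polarity state
#'
#' Live axes follow the (negated, normalised) polariser gradient where it
#' is steep enough, and follow the shallow-gradient policy elsewhere.
#' Frozen axes are convected by the element deformation gradient, then
#' re-projected into the element plane and renormalised.  External axes are
#' the in-plane projection of the configured lab direction.
#'
#' @param state a \code{polarity_state}.
#' @param cv the current canvas.
#' @param pol the polariser \code{factor_field} (or per-vertex values).
#' @param deformation optional \code{deformation_result} of the last step,
#'   used to convect frozen axes.
#' @return the updated \code{polarity_state}.
#' @export
update_polarity <- function(state, cv, pol = NULL, deformation = NULL) {
  m <- n_elements(cv)
  nrm <- triangle_normals(cv)
  ## convect frozen axes with the deformation gradient
  frz <- state$mode == "frozen"
  if (any(frz) && !is.null(deformation)) {
    g <- deformation$grad
    for (e in which(frz)) {
      a <- state$axis[e, ] + g[e, , ] %*% state$axis[e, ]
      state$axis[e, ] <- a
    }
  }
  live <- state$mode == "live"
  if (any(live)) {
    if (is.null(pol)) stop("live polarity requires the polariser field")
    vals <- if (inherits(pol, "factor_field")) pol$values else pol
    grad <- compute_pol_gradient(cv, vals)
    thr <- state$gradient_threshold
    if (is.null(thr)) {
      mid <- canvas_midplane(cv)
      diam <- max(apply(mid, 2, function(z) diff(range(z))))
      thr <- 1e-6 * diff(range(vals)) / max(diam, .Machine$double.eps)
      state$gradient_threshold <- thr
    }
    gn <- row_norm(grad)
    steep <- live & gn >= thr
    state$axis[steep, ] <- -grad[steep, , drop = FALSE]
    shallow <- live & gn < thr
    if (any(shallow)) {
      if (state$shallow_policy == "freeze") {
        ## latch axes that were usable before; elements that never had an
        ## axis stay live (and grow isotropically) until a gradient appears
        had_axis <- shallow & row_norm(state$axis) > 0
        state$mode[had_axis] <- "frozen"
      } else {
        ## absent policy: drop the axis while the gradient is shallow;
        ## the element stays live and regains polarity if it steepens
        state$axis[shallow, ] <- 0
      }
    }
  }
  ext <- state$mode == "external"
  if (any(ext))
    state$axis[ext, ] <- matrix(state$external_dir, sum(ext), 3, byrow = TRUE)
  ## project into the element plane and renormalise; zero-axis live
  ## elements (not yet polarised) are left alone
  act <- state$mode != "absent" & row_norm(state$axis) > 0
  if (any(act)) {
    a <- state$axis[act, , drop = FALSE]
    nn <- nrm[act, , drop = FALSE]
    a <- a - nn * rowSums(a * nn)
    len <- row_norm(a)
    degen <- len < 1e-12
    state$axis[act, ] <- a / ifelse(len > 0, len, 1)
    if (any(degen)) {
      idx <- which(act)[degen]
      state$mode[idx] <- "absent"
      state$axis[idx, ] <- 0
    }
  }
  state
}

#' Freeze all live polarity axes (fix them to the canvas)
#' @param state a \code{polarity_state}.
#' @export
freeze_polarity <- function(state) {
  live <- state$mode == "live" & row_norm(state$axis) > 0
  state$mode[live] <- "frozen"
  state$mode[state$mode == "live"] <- "absent"
  state
}

## ---------------------------------------------------------------------------
## Interaction function

#' Run the model's interaction function
#'
#' The interaction function is called once per step, before diffusion, with
#' the full simulation state.  It returns growth-rate fields, factor
#' production/decay updates, a residual-strain retention field and polarity
#' mode switches.  It must not modify the mesh geometry: a checksum of the
#' vertex positions is compared before and after the call.
#'
#' @param hook function of one argument (the simulation state), returning a
#'   list with any of: \code{kpar_a}, \code{kpar_b}, \code{kper_a},
#'   \code{kper_b}, \code{kthick} (per-vertex growth rates; \code{kpar} and
#'   \code{kper} are shorthand for both surfaces), \code{production} /
#'   \code{decay} (named lists of per-vertex rates by factor),
#'   \code{identities} (named list of per-vertex values for identity
#'   factors, e.g. from \code{\link{apply_threshold_rule}}),
#'   \code{retention} (per-vertex retention fraction in [0,1]),
#'   \code{polarity} (a replacement \code{polarity_state} or the string
#'   "freeze").  NULL entries keep current values.
#' @param state the simulation state (see \code{\link{simulate_step}}).
#' @return the hook's (normalised) output list.
#' @export
run_interaction <- function(hook, state) {
  n <- n_vertices(state$canvas)
  if (is.null(hook))
    return(list(kpar_a = numeric(n), kpar_b = numeric(n),
                kper_a = numeric(n), kper_b = numeric(n),
                kthick = numeric(n)))
  checksum <- sum(state$canvas$pos_a) + sum(state$canvas$pos_b)
  out <- hook(state)
  new_checksum <- sum(state$canvas$pos_a) + sum(state$canvas$pos_b)
  if (!identical(checksum, new_checksum))
    stop("interaction function modified the mesh geometry (contract violation)")
  if (!is.null(out$kpar)) { out$kpar_a <- out$kpar_b <- out$kpar; out$kpar <- NULL }
  if (!is.null(out$kper)) { out$kper_a <- out$kper_b <- out$kper; out$kper <- NULL }
  for (nm in c("kpar_a", "kpar_b", "kper_a", "kper_b", "kthick"))
    out[[nm]] <- if (is.null(out[[nm]])) numeric(n) else rep_len(out[[nm]], n)
  out
}
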