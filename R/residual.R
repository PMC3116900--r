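## Residual strain bookkeeping.
##
## The residual strain of a step is the specified strain that was not
## realised as shape change (specified minus resultant, per element and
## through-thickness layer).  It may be discarded each step (dissipation),
## or retained - fully or per-region - as stored pre-stress that can later
## be released by cutting or by removing constraints.

#' Create an empty residual store
#' @param cv a canvas.
#' @return object of class \code{residual_store}: per-layer M x 3 x 3
#'   tensor arrays \code{eps_a}, \code{eps_b}.
#' @export
residual_store <- function(cv) {
  m <- n_elements(cv)
  structure(list(eps_a = array(0, c(m, 3, 3)), eps_b = array(0, c(m, 3, 3))),
            class = "residual_store")
}

#' Per-step residual strain (specified minus resultant)
#'
#' @param growth a \code{specified_growth}.
#' @param deformation a \code{deformation_result} for the same step.
#' @return list of per-layer M x 3 x 3 arrays.
#' @export
step_residual <- function(growth, deformation) {
  list(eps_a = voigt_rows_to_tensors(growth$eps_a) - deformation$strain_a,
       eps_b = voigt_rows_to_tensors(growth$eps_b) - deformation$strain_b)
}

#' Accumulate residual strain into the store
#'
#' @param store a \code{residual_store}.
#' @param step per-layer residual of the step (see
#'   \code{\link{step_residual}}).
#' @param retention per-element retention fraction in [0, 1] (scalar or
#'   vector); 0 discards, 1 retains fully.
#' @return the updated store.
#' @export
accumulate_residual <- function(store, step, retention = 0) {
  m <- dim(store$eps_a)[1]
  r <- rep_len(retention, m)
  if (any(r < 0 | r > 1)) stop("retention fraction outside [0, 1]")
  store$eps_a <- store$eps_a + r * step$eps_a
  store$eps_b <- store$eps_b + r * step$eps_b
  store
}

## rotation matrices from skew increments (Rodrigues on the axial vector)
rotations_from_vorticity <- function(vort) {
  m <- dim(vort)[1]
  R <- array(0, c(m, 3, 3))
  wx <- vort[, 3, 2]; wy <- vort[, 1, 3]; wz <- vort[, 2, 1]
  th <- sqrt(wx^2 + wy^2 + wz^2)
  for (e in seq_len(m)) {
    if (th[e] < 1e-300) { R[e, , ] <- diag(3); next }
    k <- c(wx[e], wy[e], wz[e]) / th[e]
    Km <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                 byrow = TRUE)
    R[e, , ] <- diag(3) + sin(th[e]) * Km + (1 - cos(th[e])) * (Km %*% Km)
  }
  R
}

#' Convect stored residual strain with element rotations
#'
#' Each stored tensor is conjugated by the element's incremental rotation
#' (from the vorticity of the last deformation), so retained strain stays
#' expressed in the material's current orientation.
#'
#' @param store a \code{residual_store}.
#' @param deformation a \code{deformation_result}.
#' @return the updated store.
#' @export
convect_residual <- function(store, deformation) {
  R <- rotations_from_vorticity(deformation$vorticity)
  conj1 <- function(arr) {
    for (e in seq_len(dim(arr)[1])) {
      Re <- R[e, , ]
      arr[e, , ] <- Re %*% arr[e, , ] %*% t(Re)
    }
    arr
  }
  store$eps_a <- conj1(store$eps_a)
  store$eps_b <- conj1(store$eps_b)
  store
}

#' Norm of the stored residual strain
#' @param store a \code{residual_store}.
#' @export
residual_norm <- function(store) {
  sqrt(sum(store$eps_a^2) + sum(store$eps_b^2))
}

#' Stored-strain energy density sum
#'
#' Volume-weighted store : C : store, the elastic energy that full release
#' of the stored strain could liberate.
#'
#' @param cv the canvas.
#' @param store a \code{residual_store}.
#' @param stiffness 6x6 Voigt stiffness.
#' @export
stored_energy <- function(cv, store, stiffness) {
  vol <- element_volumes(cv)
  en <- function(arr) {
    v <- tensors_to_voigt_rows(arr)
    rowSums((v %*% unclass(stiffness)) * v)
  }
  sum(vol / 2 * (en(store$eps_a) + en(store$eps_b)) / 2)
}

#' Incrementally release stored residual strain
#'
#' Releases retained strain by repeatedly applying a small fraction of the
#' store as specified strain, solving the elastic equilibrium, subtracting
#' the realised strain, and convecting the remainder with the incremental
#' rotations, until the canvas stops moving.  Large release deformations
#' (cut tissue springing open) are thereby reached through a sequence of
#' small-strain solves; the stored energy decreases monotonically.
#'
#' @param cv a canvas.
#' @param store a \code{residual_store}.
#' @param material an \code{elastic_material}.
#' @param constraints a \code{constraint_set} (default none).
#' @param fraction_per_iter fraction of the store applied per iteration.
#' @param tol convergence threshold on the relative change of the store
#'   norm per iteration.
#' @param max_iters iteration cap.
#' @param solver_tol,solver elastic solve settings.
#' @return list with the relaxed \code{canvas}, the remaining \code{store},
#'   the per-iteration \code{energy} trace and \code{displacement} (max
#'   vertex displacement per iteration).
#' @export
relax_residual <- function(cv, store, material,
                           constraints = NULL,
                           fraction_per_iter = 0.1, tol = 1e-6,
                           max_iters = 200L,
                           solver_tol = 1e-8, solver = "cgs") {
  C <- isotropic_stiffness(material)
  energy <- numeric(0)
  maxdisp <- numeric(0)
  norm0 <- residual_norm(store)
  if (norm0 == 0)
    return(list(canvas = cv, store = store, energy = energy,
                displacement = maxdisp, iterations = 0L))
  for (it in seq_len(max_iters)) {
    energy <- c(energy, stored_energy(cv, store, C))
    growth <- list(eps_a = fraction_per_iter * tensors_to_voigt_rows(store$eps_a),
                   eps_b = fraction_per_iter * tensors_to_voigt_rows(store$eps_b))
    if (is.null(constraints)) constraints <- constraint_set(cv)
    sys <- assemble_elastic_system(cv, C, growth, constraints)
    sol <- solve_displacements(sys, tol = solver_tol, solver = solver)
    def <- decompose_growth(cv, sol)
    cv <- apply_displacements(cv, sol)
    ## remainder: everything specified but not realised stays in the store
    store$eps_a <- store$eps_a - def$strain_a
    store$eps_b <- store$eps_b - def$strain_b
    store <- convect_residual(store, def)
    maxdisp <- c(maxdisp, max(row_norm(sol$u)))
    change <- residual_norm(store)
    if (it > 1 && abs(energy[it] - energy[it - 1]) <=
        tol * max(energy[1], .Machine$double.eps) &&
        maxdisp[it] <= tol * max(1, max(maxdisp)))
      break
  }
  if (it == max_iters && maxdisp[it] > tol * max(1, max(maxdisp)))
    warning("residual relaxation reached the iteration cap before settling")
  list(canvas = cv, store = store, energy = energy,
       displacement = maxdisp, iterations = it)
}

## remap a residual store across a remesh (children inherit the parent's
## tensors)
remap_residual <- function(store, parent_of_new) {
  store$eps_a <- store$eps_a[parent_of_new, , , drop = FALSE]
  store$eps_b <- store$eps_b[parent_of_new, , , drop = FALSE]
  store
}
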