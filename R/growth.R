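## Specified growth tensors.
##
## Growth rates parallel and perpendicular to the polarity axis, given per
## surface, plus a thickness rate, define a symmetric strain increment per
## element and through-thickness layer.  The tensor's eigenvectors are the
## polarity axis, its in-plane perpendicular, and the element normal; where
## polarity is absent, in-plane growth is isotropic.

#' Per-element local orthonormal frame
#'
#' Right-handed triple (u = polarity axis, v = in-plane perpendicular,
#' n = element normal).  Where polarity is absent an arbitrary but
#' deterministic in-plane pair is used (first edge direction).
#'
#' @param cv a canvas.
#' @param polarity a \code{polarity_state}, or NULL for no polarity.
#' @return list of M x 3 matrices \code{u}, \code{v}, \code{n} and logical
#'   \code{polarised}.
#' @export
local_frame <- function(cv, polarity = NULL) {
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  nraw <- tri_normals_raw(mid, tri)
  a2 <- row_norm(nraw)
  if (any(a2 <= 0)) stop("zero-area element in local_frame")
  n <- nraw / a2
  m <- nrow(tri)
  polarised <- rep(FALSE, m)
  u <- matrix(0, m, 3)
  if (!is.null(polarity)) {
    polarised <- polarity$mode != "absent" & row_norm(polarity$axis) > 0
    u[polarised, ] <- polarity$axis[polarised, , drop = FALSE]
  }
  ## fallback in-plane direction: first edge of the triangle
  if (any(!polarised)) {
    e1 <- mid[tri[, 2], , drop = FALSE] - mid[tri[, 1], , drop = FALSE]
    e1 <- e1 - n * rowSums(e1 * n)
    u[!polarised, ] <- normalize_rows(e1)[!polarised, , drop = FALSE]
  }
  ## re-orthogonalise u against n, then v = n x u
  u <- normalize_rows(u - n * rowSums(u * n))
  v <- row_cross(n, u)
  list(u = u, v = v, n = n, polarised = polarised)
}

#' Per-element growth rate specification
#'
#' Averages per-vertex growth-rate fields onto elements.  Negative rates
#' (contraction) are permitted.
#'
#' @param cv a canvas.
#' @param kpar_a,kpar_b per-vertex rate parallel to polarity on surfaces A
#'   and B (1/time).
#' @param kper_a,kper_b perpendicular in-plane rates.
#' @param kthick thickness growth rate.
#' @return object of class \code{growth_spec} (per-element rates).
#' @export
growth_spec <- function(cv, kpar_a = 0, kpar_b = kpar_a,
                        kper_a = 0, kper_b = kper_a, kthick = 0) {
  n <- n_vertices(cv)
  tri <- cv$tri
  elem_mean <- function(x) {
    x <- rep_len(x, n)
    (x[tri[, 1]] + x[tri[, 2]] + x[tri[, 3]]) / 3
  }
  structure(list(kpar_a = elem_mean(kpar_a), kpar_b = elem_mean(kpar_b),
                 kper_a = elem_mean(kper_a), kper_b = elem_mean(kper_b),
                 kthick = elem_mean(kthick)),
            class = "growth_spec")
}

#' Assemble specified growth tensors
#'
#' For each element and through-thickness layer, the strain increment
#' dt * (kpar u u' + kper v v' + kthick n n') in the local frame, returned
#' in engineering Voigt form (xx, yy, zz, 2yz, 2xz, 2xy) ready for the
#' elastic assembly.  Where polarity is absent, kpar and kper are replaced
#' by their mean (isotropic in-plane growth preserving the specified areal
#' rate); alternatives are configurable.
#'
#' @param spec a \code{growth_spec}.
#' @param frame a \code{local_frame}.
#' @param dt time step.
#' @param isotropic_fallback rate used in-plane where polarity is absent.
#' @return object of class \code{specified_growth}: engineering-Voigt
#'   matrices \code{eps_a}, \code{eps_b} (M x 6) and the per-layer rate
#'   fields actually used.
#' @export
assemble_specified_growth <- function(spec, frame, dt,
                                      isotropic_fallback = c("mean", "kpar", "kper")) {
  isotropic_fallback <- match.arg(isotropic_fallback)
  bad <- !is.finite(spec$kpar_a + spec$kpar_b + spec$kper_a + spec$kper_b +
                      spec$kthick)
  if (any(bad))
    stop("non-finite growth rate in element ", which(bad)[1])
  iso <- !frame$polarised
  fb <- function(kp, kq) switch(isotropic_fallback,
                                mean = (kp + kq) / 2, kpar = kp, kper = kq)
  kpar_a <- spec$kpar_a; kper_a <- spec$kper_a
  kpar_b <- spec$kpar_b; kper_b <- spec$kper_b
  if (any(iso)) {
    kpar_a[iso] <- kper_a[iso] <- fb(spec$kpar_a, spec$kper_a)[iso]
    kpar_b[iso] <- kper_b[iso] <- fb(spec$kpar_b, spec$kper_b)[iso]
  }
  u <- frame$u; v <- frame$v; n <- frame$n
  layer <- function(kpar, kper) {
    ## symmetric tensor kpar u u' + kper v v' + kthick n n', Voigt rows
    txx <- kpar * u[, 1]^2 + kper * v[, 1]^2 + spec$kthick * n[, 1]^2
    tyy <- kpar * u[, 2]^2 + kper * v[, 2]^2 + spec$kthick * n[, 2]^2
    tzz <- kpar * u[, 3]^2 + kper * v[, 3]^2 + spec$kthick * n[, 3]^2
    tyz <- kpar * u[, 2] * u[, 3] + kper * v[, 2] * v[, 3] +
      spec$kthick * n[, 2] * n[, 3]
    txz <- kpar * u[, 1] * u[, 3] + kper * v[, 1] * v[, 3] +
      spec$kthick * n[, 1] * n[, 3]
    txy <- kpar * u[, 1] * u[, 2] + kper * v[, 1] * v[, 2] +
      spec$kthick * n[, 1] * n[, 2]
    dt * cbind(txx, tyy, tzz, 2 * tyz, 2 * txz, 2 * txy)
  }
  structure(list(eps_a = layer(kpar_a, kper_a),
                 eps_b = layer(kpar_b, kper_b),
                 rates = list(kpar_a = kpar_a, kpar_b = kpar_b,
                              kper_a = kper_a, kper_b = kper_b,
                              kthick = spec$kthick),
                 dt = dt),
            class = "specified_growth")
}

#' Convert engineering-Voigt rows to 3x3 symmetric tensors
#' @param v M x 6 matrix (xx, yy, zz, 2yz, 2xz, 2xy).
#' @return M x 3 x 3 array.
#' @export
voigt_rows_to_tensors <- function(v) {
  m <- nrow(v)
  a <- array(0, c(m, 3, 3))
  a[, 1, 1] <- v[, 1]; a[, 2, 2] <- v[, 2]; a[, 3, 3] <- v[, 3]
  a[, 2, 3] <- a[, 3, 2] <- v[, 4] / 2
  a[, 1, 3] <- a[, 3, 1] <- v[, 5] / 2
  a[, 1, 2] <- a[, 2, 1] <- v[, 6] / 2
  a
}

#' Convert 3x3 symmetric tensors to engineering-Voigt rows
#' @param a M x 3 x 3 array.
#' @export
tensors_to_voigt_rows <- function(a) {
  cbind(a[, 1, 1], a[, 2, 2], a[, 3, 3],
        2 * a[, 2, 3], 2 * a[, 1, 3], 2 * a[, 1, 2])
}
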