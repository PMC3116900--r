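## Finite-element diffusion-production-decay of signalling factors on the
## midplane triangulation, plus the separate dilution step.
##
## The operator works per unit midplane area (concentrations are constant
## through the thickness); dilution uses the full wedge control volumes.

#' Assemble the diffusion system matrices
#'
#' P1 mass (consistent, with a lumped option) and cotangent stiffness on
#' the current midplane.  Rebuild after the mesh moves.
#'
#' @param cv a canvas.
#' @param lumped use the row-sum lumped mass matrix.
#' @return object of class \code{diffusion_system} with sparse matrices
#'   \code{M} and \code{L} (both N x N; L positive semidefinite with zero
#'   row sums).
#' @export
diffusion_system <- function(cv, lumped = FALSE) {
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  n <- n_vertices(cv)
  p1 <- mid[tri[, 1], , drop = FALSE]
  p2 <- mid[tri[, 2], , drop = FALSE]
  p3 <- mid[tri[, 3], , drop = FALSE]
  ar <- row_norm(row_cross(p2 - p1, p3 - p1)) / 2
  ## cotangent weights: L_ij = -(cot alpha_k)/2 for edge opposite vertex k
  cot_at <- function(a, b, c) {  # angle at vertex a
    u <- b - a; v <- c - a
    rowSums(u * v) / pmax(row_norm(row_cross(u, v)), 1e-300)
  }
  c1 <- cot_at(p1, p2, p3); c2 <- cot_at(p2, p3, p1); c3 <- cot_at(p3, p1, p2)
  ## off-diagonal entries (symmetric), diagonal from zero row sums
  ii <- c(tri[, 2], tri[, 3], tri[, 1], tri[, 3], tri[, 1], tri[, 2])
  jj <- c(tri[, 3], tri[, 2], tri[, 3], tri[, 1], tri[, 2], tri[, 1])
  xx <- -c(c1, c1, c2, c2, c3, c3) / 2
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  ## consistent mass: area/12 * (2 on diagonal, 1 off)
  mi <- c(tri[, 1], tri[, 2], tri[, 3], ii)
  mj <- c(tri[, 1], tri[, 2], tri[, 3], jj)
  mx <- c(rep(ar / 6, 3), rep(ar / 12, 6))
  M <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))
  if (lumped) M <- Matrix::Diagonal(n, Matrix::rowSums(M))
  structure(list(M = M, L = L, n = n, lumped = lumped),
            class = "diffusion_system")
}

#' One diffusion-production-decay step for a signalling factor
#'
#' Advances dc/dt = D lap(c) + p - d c by one step of backward (default)
#' or forward Euler, holding clamped vertices fixed.  Dilution is handled
#' separately (see \code{\link{apply_dilution}}).  With p = d = 0 and no
#' clamped vertices the implicit step conserves total mass exactly.
#'
#' @param field a signalling \code{factor_field}.
#' @param sys a \code{diffusion_system} for the current geometry.
#' @param dt time step.
#' @param scheme backward (unconditionally stable, default) or forward
#'   Euler; the forward scheme errors when dt exceeds its stability bound.
#' @param tol relative tolerance of the implicit sparse solve.
#' @return the updated \code{factor_field}.
#' @export
step_signalling_field <- function(field, sys, dt,
                                  scheme = c("implicit", "explicit"),
                                  tol = 1e-4) {
  if (field$kind != "signalling")
    stop("step_signalling_field: '", field$name, "' is not a signalling factor")
  scheme <- match.arg(scheme)
  ## a factor with no transport, decay or production is static; skip the
  ## mass-matrix solve (which would introduce roundoff)
  if (field$D == 0 && field$decay == 0 && all(field$production == 0))
    return(field)
  c0 <- field$values
  M <- sys$M; L <- sys$L
  p <- field$production
  d <- field$decay
  Dc <- field$D
  clamped <- field$clamp_idx
  if (scheme == "explicit") {
    ml <- Matrix::rowSums(M)
    rate_bound <- max(Dc * Matrix::diag(L) / ml + d)
    if (rate_bound > 0 && dt > 2 / rate_bound)
      stop(sprintf("explicit diffusion step dt = %g exceeds the stability bound %g",
                   dt, 2 / rate_bound))
    cn <- c0 + dt * (as.vector(-Dc * (L %*% c0)) / ml + p - d * c0)
  } else {
    A <- M + dt * (Dc * L + d * M)
    rhs <- as.vector(M %*% (c0 + dt * p))
    if (length(clamped)) {
      ## impose c = clamp value on clamped rows
      A <- as(A, "TsparseMatrix")
      keep <- !(A@i + 1L) %in% clamped
      A <- Matrix::sparseMatrix(i = A@i[keep] + 1L, j = A@j[keep] + 1L,
                                x = A@x[keep], dims = dim(A))
      A <- A + Matrix::sparseMatrix(i = clamped, j = clamped,
                                    x = rep(1, length(clamped)),
                                    dims = dim(A))
      rhs[clamped] <- field$clamp_val
    }
    cn <- as.vector(Matrix::solve(A, rhs))
  }
  if (length(clamped)) cn[clamped] <- field$clamp_val
  field$values <- cn
  field
}

#' Steady state of the diffusion-production-decay equation
#'
#' Solves D lap(c) = p - d c directly with clamped vertices held at their
#' clamp values.  Used for model setup phases, where the polariser and
#' other signals are equilibrated before growth begins.
#'
#' @param field a signalling \code{factor_field}.
#' @param sys a \code{diffusion_system}.
#' @return the \code{factor_field} at steady state.
#' @export
steady_state_field <- function(field, sys) {
  if (field$kind != "signalling")
    stop("steady_state_field: '", field$name, "' is not a signalling factor")
  A <- field$D * sys$L + field$decay * sys$M
  rhs <- as.vector(sys$M %*% field$production)
  clamped <- field$clamp_idx
  if (length(clamped) == 0 && field$decay == 0)
    stop("steady state undetermined: no decay and no clamped vertices")
  if (length(clamped)) {
    A <- as(A, "TsparseMatrix")
    keep <- !(A@i + 1L) %in% clamped
    A <- Matrix::sparseMatrix(i = A@i[keep] + 1L, j = A@j[keep] + 1L,
                              x = A@x[keep], dims = dim(A))
    A <- A + Matrix::sparseMatrix(i = clamped, j = clamped,
                                  x = rep(1, length(clamped)), dims = dim(A))
    rhs[clamped] <- field$clamp_val
  }
  field$values <- as.vector(Matrix::solve(A, rhs))
  field
}

#' Dilute signalling factors by volumetric expansion
#'
#' After a growth step, the concentration of every dilutable signalling
#' factor is reduced in proportion to the expansion of its vertex control
#' volume: c_new V_new = c_old V_old.  Identity and non-dilutable factors
#' are untouched.
#'
#' @param fields named list of \code{factor_field}s.
#' @param vol_old,vol_new per-vertex control volumes before and after the
#'   deformation (see \code{\link{vertex_control_volumes}}).
#' @return the updated list of fields.
#' @export
apply_dilution <- function(fields, vol_old, vol_new) {
  if (any(vol_old <= 0) || any(vol_new <= 0))
    stop("non-positive control volume in dilution")
  dilute_fields_by_ratio(fields, vol_old / vol_new)
}

dilute_fields_by_ratio <- function(fields, ratio) {
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (f$kind == "signalling" && f$dilutable) {
      f$values <- f$values * ratio
      if (length(f$clamp_idx)) f$values[f$clamp_idx] <- f$clamp_val
      fields[[nm]] <- f
    }
  }
  fields
}

#' Total tracked mass of a field
#' @param field a \code{factor_field} or value vector.
#' @param weights per-vertex weights: a \code{diffusion_system} (consistent
#'   mass), or a vector of control areas/volumes.
#' @export
field_mass <- function(field, weights) {
  v <- if (inherits(field, "factor_field")) field$values else field
  if (inherits(weights, "diffusion_system"))
    sum(as.vector(weights$M %*% v))
  else
    sum(v * weights)
}
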