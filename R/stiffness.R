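## Isotropic elastic stiffness and general 4th-rank tensor utilities.
##
## Only the shear modulus / Poisson-ratio pair enters the model; the
## absolute stiffness scale cancels from the equilibrium because all forces
## arise from the material acting against itself.

#' Elastic material parameters
#'
#' @param shear_modulus shear modulus (arbitrary units; the scale cancels
#'   from all computed deformations).
#' @param poisson Poisson's ratio, in [0, 0.5).  Default 0.3.
#' @return object of class \code{elastic_material}.
#' @export
elastic_material <- function(shear_modulus = 1, poisson = 0.3) {
  if (shear_modulus <= 0) stop("shear modulus must be positive")
  if (poisson < 0 || poisson >= 0.5)
    stop("Poisson ratio must lie in [0, 0.5); the equations degenerate at 0.5")
  structure(list(shear_modulus = shear_modulus, poisson = poisson),
            class = "elastic_material")
}

## raw 6x6 isotropic Voigt matrix without validity checks (used by the
## positive-definiteness boundary search)
voigt_isotropic_raw <- function(mu, nu) {
  lambda <- 2 * mu * nu / (1 - 2 * nu)
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lambda
  C
}

#' Isotropic stiffness matrix in Voigt form
#'
#' Standard 6x6 matrix with Lame lambda = 2 mu nu / (1 - 2 nu); Voigt order
#' xx, yy, zz, yz, xz, xy with engineering shear.
#'
#' @param material an \code{elastic_material}.
#' @return 6 x 6 symmetric positive-definite matrix of class
#'   \code{stiffness_voigt}.
#' @export
isotropic_stiffness <- function(material) {
  if (!inherits(material, "elastic_material"))
    material <- do.call(elastic_material, as.list(material))
  C <- voigt_isotropic_raw(material$shear_modulus, material$poisson)
  structure(C, class = c("stiffness_voigt", "matrix"))
}

#' Count the independent components of a general elasticity tensor
#'
#' Enumerates all 81 index quadruples (i,j,k,l) of a 4th-rank tensor in 3D
#' and counts the orbits under the minor symmetries (ij) <-> (ji),
#' (kl) <-> (lk) and the major symmetry (ij,kl) <-> (kl,ij).
#'
#' @return The number of independent components (21).
#' @export
count_stiffness_components <- function() {
  quads <- expand.grid(i = 1:3, j = 1:3, k = 1:3, l = 1:3)
  canon <- apply(quads, 1, function(q) {
    a <- sort(q[1:2]); b <- sort(q[3:4])
    pair <- rbind(a, b)
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    paste(pair, collapse = "-")
  })
  length(unique(canon))
}

#' Locate the positive-definiteness boundary of the isotropic stiffness
#'
#' Bisects on the Poisson ratio to find where the 6x6 isotropic Voigt
#' matrix loses positive definiteness (the physical limit nu = 0.5).
#'
#' @param lower,upper bracketing interval (must straddle the boundary).
#' @param tol bisection tolerance.
#' @param mu shear modulus used for the probe matrices.
#' @export
poisson_pd_boundary <- function(lower = 0.25, upper = 0.75, tol = 1e-10,
                                mu = 1) {
  is_pd <- function(nu) {
    C <- voigt_isotropic_raw(mu, nu)
    all(is.finite(C)) && !inherits(try(chol(C), silent = TRUE), "try-error")
  }
  if (!is_pd(lower) || is_pd(upper))
    stop("interval does not bracket the positive-definiteness boundary")
  while (upper - lower > tol) {
    midp <- (lower + upper) / 2
    if (is_pd(midp)) lower <- midp else upper <- midp
  }
  (lower + upper) / 2
}

## ---------------------------------------------------------------------------
## 4th-rank tensor utilities (Mandel representation)

#' Isotropic stiffness as a full 4th-rank tensor
#' @param material an \code{elastic_material}.
#' @return 3 x 3 x 3 x 3 array.
#' @export
isotropic_stiffness_tensor <- function(material) {
  mu <- material$shear_modulus; nu <- material$poisson
  lambda <- 2 * mu * nu / (1 - 2 * nu)
  d <- diag(3)
  C <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C[i, j, k, l] <- lambda * d[i, j] * d[k, l] +
      mu * (d[i, k] * d[j, l] + d[i, l] * d[j, k])
  C
}

mandel_index <- matrix(c(1, 1, 2, 2, 3, 3, 2, 3, 1, 3, 1, 2), 6, 2, byrow = TRUE)
mandel_factor <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))

#' Convert a 4th-rank stiffness tensor to its 6x6 Mandel matrix
#' @param C a 3 x 3 x 3 x 3 array with minor symmetries.
#' @export
tensor4_to_mandel <- function(C) {
  M <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    M[a, b] <- C[mandel_index[a, 1], mandel_index[a, 2],
                 mandel_index[b, 1], mandel_index[b, 2]] *
      mandel_factor[a] * mandel_factor[b]
  M
}

#' Convert a symmetric 3x3 tensor to/from its Mandel 6-vector
#' @param s a symmetric 3 x 3 matrix.
#' @export
sym_to_mandel <- function(s) {
  c(s[1, 1], s[2, 2], s[3, 3],
    sqrt(2) * s[2, 3], sqrt(2) * s[1, 3], sqrt(2) * s[1, 2])
}

#' @rdname sym_to_mandel
#' @param v a Mandel 6-vector.
#' @export
mandel_to_sym <- function(v) {
  s <- diag(v[1:3])
  s[2, 3] <- s[3, 2] <- v[4] / sqrt(2)
  s[1, 3] <- s[3, 1] <- v[5] / sqrt(2)
  s[1, 2] <- s[2, 1] <- v[6] / sqrt(2)
  s
}

#' Rotate a 4th-rank tensor
#' @param C a 3 x 3 x 3 x 3 array.
#' @param R a 3 x 3 rotation matrix.
#' @export
rotate_tensor4 <- function(C, R) {
  ## contract one index at a time
  out <- C
  for (ax in 1:4) {
    out <- apply(out, setdiff(1:4, ax), function(v) as.vector(R %*% v))
    ## apply() puts the contracted axis first; rotate dims back
    out <- aperm(out, order(c(ax, setdiff(1:4, ax))))
  }
  out
}

#' Orthotropic stiffness perturbation
#'
#' Builds a 4th-rank tensor that is orthotropic with respect to the given
#' axes: in its principal frame the Mandel matrix is block-diagonal with an
#' arbitrary symmetric 3x3 normal block and a diagonal shear block.
#'
#' @param axes 3 x 3 rotation matrix whose columns are the principal axes.
#' @param normal_block symmetric 3 x 3 matrix coupling the normal strains.
#' @param shear_diag length-3 vector of shear stiffnesses.
#' @return 3 x 3 x 3 x 3 array.
#' @export
orthotropic_tensor <- function(axes, normal_block, shear_diag) {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- (normal_block + t(normal_block)) / 2
  M[4:6, 4:6] <- diag(2 * shear_diag)   # Mandel shear factor
  C <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) for (b in 1:6) {
    i <- mandel_index[a, 1]; j <- mandel_index[a, 2]
    k <- mandel_index[b, 1]; l <- mandel_index[b, 2]
    val <- M[a, b] / (mandel_factor[a] * mandel_factor[b])
    C[i, j, k, l] <- val; C[j, i, k, l] <- val
    C[i, j, l, k] <- val; C[j, i, l, k] <- val
  }
  rotate_tensor4(C, axes)
}

#' Equivalent specified strain of a stiffness modulation under turgor
#'
#' For a tissue in equilibrium under isotropic background stiffness and
#' turgor, a small orthotropic change in stiffness deforms the tissue
#' exactly as a specified strain kappa = -S (dC (S p)) would, where S is the
#' isotropic compliance.  When the turgor stress is isotropic, the
#' principal axes of kappa coincide with those of dC, so the same polarity
#' pattern serves either description of growth.
#'
#' @param material isotropic background \code{elastic_material}.
#' @param dC stiffness change, 3 x 3 x 3 x 3 array (orthotropic for the
#'   axis-coincidence property).
#' @param p turgor stress tensor (3 x 3 symmetric; a scalar is interpreted
#'   as an isotropic pressure).
#' @param warn_large warn when |dC| exceeds 10\% of |C|.
#' @return list with \code{kappa} (3 x 3 specified strain), \code{axes}
#'   (its eigenvectors) and \code{rates} (eigenvalues).
#' @export
equivalent_specified_strain <- function(material, dC, p = 1,
                                       warn_large = TRUE) {
  if (is.numeric(p) && length(p) == 1L) p <- diag(3) * p
  C <- isotropic_stiffness_tensor(material)
  Cm <- tensor4_to_mandel(C)
  dCm <- tensor4_to_mandel(dC)
  if (warn_large && norm(dCm, "F") > 0.1 * norm(Cm, "F"))
    warning("stiffness change is not small relative to the background")
  S <- tryCatch(solve(Cm), error = function(e)
    stop("singular background stiffness"))
  kap <- -as.vector(S %*% (dCm %*% (S %*% sym_to_mandel(p))))
  kappa <- mandel_to_sym(kap)
  ev <- eigen(kappa, symmetric = TRUE)
  list(kappa = kappa, axes = ev$vectors, rates = ev$values)
}
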