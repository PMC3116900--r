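## Virtual-work elastic equilibrium on the wedge mesh.
##
## Degrees of freedom are the 3 displacement components of every surface
## vertex (A vertices first, then B), 6N in total.  Specified growth enters
## as an equivalent nodal force; constrained DOFs are eliminated through a
## sparse transformation matrix which also realises the flatness coupling
## (paired A/B vertices move symmetrically in z, leaving one thickness
## unknown per pair).  Remaining rigid-body modes are regularised and
## projected out so solutions are deterministic.

#' Constraint set for the elastic solve
#'
#' @param cv a canvas.
#' @param fix_z,fix_xyz integer vectors of midplane vertex indices whose
#'   paired surface vertices are fixed in z only, or in all three axes.
#' @param flat logical; couple every A/B vertex pair so the midplane stays
#'   planar while the thickness may vary.
#' @return object of class \code{constraint_set}: a 2N x 3 logical matrix
#'   \code{fixed} and a logical \code{flat}.
#' @export
constraint_set <- function(cv, fix_z = integer(), fix_xyz = integer(),
                           flat = FALSE) {
  n <- n_vertices(cv)
  fixed <- matrix(FALSE, 2L * n, 3L)
  both <- function(v) c(v, v + n)
  if (length(fix_z)) fixed[both(fix_z), 3] <- TRUE
  if (length(fix_xyz)) fixed[both(fix_xyz), ] <- TRUE
  structure(list(fixed = fixed, flat = isTRUE(flat), n = n),
            class = "constraint_set")
}

## sparse transformation u_full = T q from reduced coordinates;
## pair columns carry (-1/2, +1/2) for (z_A, z_B) thickness unknowns
constraint_transform <- function(cs) {
  n <- cs$n
  ndof <- 6L * n
  dof_z_a <- (seq_len(n) - 1L) * 3L + 3L
  dof_z_b <- (seq_len(n) + n - 1L) * 3L + 3L
  is_pair <- rep(FALSE, n)
  if (cs$flat) is_pair <- !(cs$fixed[seq_len(n), 3] | cs$fixed[seq_len(n) + n, 3])
  fixed_dof <- which(t(cs$fixed))  # dof index = (vertex-1)*3 + axis
  fixed <- rep(FALSE, ndof); fixed[fixed_dof] <- TRUE
  pair_dof <- rep(FALSE, ndof)
  pair_dof[c(dof_z_a[is_pair], dof_z_b[is_pair])] <- TRUE
  free <- !fixed & !pair_dof
  nfree <- sum(free); npair <- sum(is_pair)
  ii <- c(which(free), dof_z_a[is_pair], dof_z_b[is_pair])
  jj <- c(seq_len(nfree),
          nfree + seq_len(npair), nfree + seq_len(npair))
  xx <- c(rep(1, nfree), rep(-0.5, npair), rep(0.5, npair))
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(ndof, nfree + npair))
  list(T = T, free = free, is_pair = is_pair, nfree = nfree, npair = npair)
}

#' Assemble the elastic equilibrium system
#'
#' Builds the sparse stiffness matrix and the equivalent nodal force of the
#' specified growth field, applies the constraints, and identifies the
#' remaining rigid-body modes.
#'
#' @param cv a canvas.
#' @param stiffness 6x6 Voigt stiffness matrix (see
#'   \code{\link{isotropic_stiffness}}).
#' @param growth specified growth as returned by
#'   \code{\link{assemble_specified_growth}}, or NULL for zero growth.
#' @param constraints a \code{\link{constraint_set}} (default: none).
#' @return object of class \code{elastic_system} with the reduced sparse
#'   matrix \code{K}, force \code{f}, transformation \code{T}, orthonormal
#'   rigid modes \code{Q} (reduced coordinates), per-element volumes and
#'   the constant term of the residual-strain energy.
#' @export
assemble_elastic_system <- function(cv, stiffness, growth = NULL,
                                    constraints = NULL) {
  n <- n_vertices(cv)
  m <- n_elements(cv)
  if (is.null(constraints)) constraints <- constraint_set(cv)
  pos <- rbind(cv$pos_a, cv$pos_b)
  wedge <- cbind(cv$tri, cv$tri + n)
  if (is.null(growth))
    growth <- list(eps_a = matrix(0, m, 6), eps_b = matrix(0, m, 6))
  if (any(!is.finite(growth$eps_a)) || any(!is.finite(growth$eps_b))) {
    bad <- which(!is.finite(rowSums(growth$eps_a) + rowSums(growth$eps_b)))[1]
    stop("non-finite specified growth in element ", bad)
  }
  asm <- wedge_assemble_cpp(pos, wedge, unclass(stiffness),
                            growth$eps_a, growth$eps_b)
  Kfull <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                                dims = c(6L * n, 6L * n))
  tr <- constraint_transform(constraints)
  K <- Matrix::t(tr$T) %*% Kfull %*% tr$T
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  f <- as.vector(Matrix::t(tr$T) %*% asm$f)
  Q <- rigid_modes_reduced(pos, tr)
  structure(list(K = K, f = f, transform = tr, Q = Q, n = n,
                 volumes = asm$vol, energy_const = sum(asm$econst) / 2,
                 ndof_full = 6L * n),
            class = "elastic_system")
}

## orthonormal basis (reduced coordinates) of rigid modes representable
## under the constraint transformation
rigid_modes_reduced <- function(pos, tr) {
  nv <- nrow(pos)
  cen <- colMeans(pos)
  modes <- matrix(0, 3L * nv, 6L)
  for (k in 1:3) modes[seq(k, 3L * nv, by = 3L), k] <- 1
  rel <- sweep(pos, 2, cen)
  rots <- list(cbind(0, -rel[, 3], rel[, 2]),
               cbind(rel[, 3], 0, -rel[, 1]),
               cbind(-rel[, 2], rel[, 1], 0))
  for (k in 1:3) modes[, 3L + k] <- as.vector(t(rots[[k]]))
  colnorm2 <- Matrix::colSums(tr$T^2)
  keep <- NULL
  for (k in 1:6) {
    r <- modes[, k]
    q <- as.vector(Matrix::t(tr$T) %*% r) / colnorm2
    if (sqrt(sum((as.vector(tr$T %*% q) - r)^2)) <= 1e-8 * sqrt(sum(r^2)))
      keep <- cbind(keep, q)
  }
  if (is.null(keep)) return(matrix(0, ncol(tr$T), 0L))
  qr.Q(qr(keep))[, seq_len(qr(keep)$rank), drop = FALSE]
}

#' Solve the constrained equilibrium for vertex displacements
#'
#' Rigid-body modes are regularised during the solve and projected out of
#' the solution, so results are reproducible: the solution is the unique
#' equilibrium orthogonal to all rigid motions.
#'
#' @param system an \code{elastic_system}.
#' @param tol relative residual tolerance.
#' @param norm residual norm, root-mean-square or maximum absolute.
#' @param solver conjugate gradient squared (default), minimum residual, or
#'   a dense direct solve (small systems / reference checks).
#' @param max_iter iteration cap for the iterative solvers.
#' @return object of class \code{deformation_solution}: displacement matrix
#'   \code{u} (2N x 3, A rows then B rows), reduced solution \code{q},
#'   iteration count and final relative residual.
#' @export
solve_displacements <- function(system, tol = 1e-6,
                                norm = c("rms", "max"),
                                solver = c("cgs", "minres", "direct"),
                                max_iter = 20000L) {
  norm <- match.arg(norm)
  solver <- match.arg(solver)
  if (tol <= 0) stop("tolerance must be positive")
  K <- system$K; f <- system$f; Q <- system$Q
  nd <- length(f)
  nrmfun <- if (norm == "rms") function(x) sqrt(mean(x^2)) else function(x) max(abs(x))
  if (nrmfun(f) == 0) {
    q <- numeric(nd)
    return(deformation_solution(system, q, 0L, 0))
  }
  beta <- mean(abs(Matrix::diag(K)))
  if (beta == 0) beta <- 1
  amul <- function(x) {
    y <- as.vector(K %*% x)
    if (ncol(Q)) y <- y + beta * as.vector(Q %*% crossprod(Q, x))
    y
  }
  if (solver == "direct") {
    A <- as.matrix(K)
    if (ncol(Q)) A <- A + beta * tcrossprod(as.matrix(Q))
    q <- solve(A, f)
    it <- 1L
  } else {
    dK <- Matrix::diag(K)
    if (ncol(Q)) dK <- dK + beta * Matrix::rowSums(Q^2)
    dK[dK <= 0] <- beta
    pre <- function(x) x / dK
    res <- if (solver == "cgs") {
      krylov_cgs(amul, pre, f, tol, nrmfun, max_iter)
    } else {
      krylov_minres(amul, f, tol, nrmfun, max_iter)
    }
    ## the squared-residual recurrence of cgs can break down on nearly
    ## singular free-free systems; fall back to the slower but monotone
    ## minimum-residual iteration before giving up
    if (!res$converged && solver == "cgs")
      res <- krylov_minres(amul, f, tol, nrmfun, max_iter)
    if (!res$converged)
      stop(sprintf("elastic solve did not converge: relative %s residual %.3g after %d iterations",
                   norm, res$relres, res$iter))
    q <- res$x; it <- res$iter
  }
  if (ncol(Q)) q <- q - as.vector(Q %*% crossprod(Q, q))
  relres <- nrmfun(as.vector(K %*% q) - f) / nrmfun(f)
  deformation_solution(system, q, it, relres)
}

deformation_solution <- function(system, q, iter, relres) {
  u_full <- as.vector(system$transform$T %*% q)
  u <- matrix(u_full, ncol = 3, byrow = TRUE)
  structure(list(u = u, q = q, iterations = iter, relres = relres),
            class = "deformation_solution")
}

## preconditioned conjugate gradient squared (Sonneveld)
krylov_cgs <- function(amul, pre, b, tol, nrmfun, max_iter) {
  n <- length(b)
  x <- numeric(n); r <- b; rt <- r
  bnorm <- nrmfun(b)
  rho_old <- 1; p <- u <- qv <- numeric(n)
  for (it in seq_len(max_iter)) {
    rho <- sum(rt * r)
    if (rho == 0) break
    if (it == 1L) {
      u <- r; p <- u
    } else {
      bet <- rho / rho_old
      u <- r + bet * qv
      p <- u + bet * (qv + bet * p)
    }
    phat <- pre(p)
    v <- amul(phat)
    sig <- sum(rt * v)
    if (sig == 0) break
    alpha <- rho / sig
    qv <- u - alpha * v
    uhat <- pre(u + qv)
    x <- x + alpha * uhat
    r <- r - alpha * amul(uhat)
    if (nrmfun(r) <= tol * bnorm)
      return(list(x = x, iter = it, converged = TRUE,
                  relres = nrmfun(r) / bnorm))
    rho_old <- rho
  }
  list(x = x, iter = max_iter, converged = nrmfun(r) <= tol * bnorm,
       relres = nrmfun(r) / bnorm)
}

## MINRES (Paige & Saunders), unpreconditioned
krylov_minres <- function(amul, b, tol, nrmfun, max_iter) {
  n <- length(b)
  x <- numeric(n)
  bnorm <- nrmfun(b)
  v_old <- numeric(n); v <- b
  beta <- sqrt(sum(v * v)); v <- v / beta
  c_old <- 1; s_old <- 0; c_cur <- 1; s_cur <- 0
  w_old <- numeric(n); w_oold <- numeric(n)
  eta <- beta
  beta_old <- beta
  for (it in seq_len(max_iter)) {
    av <- amul(v)
    alpha <- sum(v * av)
    vn <- av - alpha * v - beta_old * v_old
    beta_new <- sqrt(sum(vn * vn))
    ## apply previous rotations
    rho1 <- c_cur * alpha - c_old * s_cur * beta_old
    rho2 <- s_cur * alpha + c_old * c_cur * beta_old
    rho3 <- s_old * beta_old
    gam <- sqrt(rho1^2 + beta_new^2)
    c_new <- rho1 / gam; s_new <- beta_new / gam
    w <- (v - rho3 * w_oold - rho2 * w_old) / gam
    x <- x + c_new * eta * w
    eta <- -s_new * eta
    r <- amul(x) - b
    if (nrmfun(r) <= tol * bnorm)
      return(list(x = x, iter = it, converged = TRUE,
                  relres = nrmfun(r) / bnorm))
    if (beta_new == 0) break
    v_old <- v; v <- vn / beta_new
    w_oold <- w_old; w_old <- w
    c_old <- c_cur; s_old <- s_cur; c_cur <- c_new; s_cur <- s_new
    beta_old <- beta_new
  }
  r <- amul(x) - b
  list(x = x, iter = max_iter, converged = nrmfun(r) <= tol * bnorm,
       relres = nrmfun(r) / bnorm)
}

#' Apply a displacement solution to the canvas
#' @param cv a canvas.
#' @param sol a \code{deformation_solution} (or a 2N x 3 matrix).
#' @return the displaced canvas.
#' @export
apply_displacements <- function(cv, sol) {
  u <- if (inherits(sol, "deformation_solution")) sol$u else sol
  n <- n_vertices(cv)
  cv$pos_a <- cv$pos_a + u[seq_len(n), , drop = FALSE]
  cv$pos_b <- cv$pos_b + u[n + seq_len(n), , drop = FALSE]
  cv
}

#' Decompose a displacement field into resultant growth components
#'
#' Computes the per-element displacement gradient (at the element centre
#' and at the two surface layers) and splits it into its symmetric part
#' (resultant strain) and skew part (vorticity).
#'
#' @param cv the canvas the displacements refer to.
#' @param sol a \code{deformation_solution} or 2N x 3 displacement matrix.
#' @return object of class \code{deformation_result} with per-element 3x3
#'   arrays \code{grad}, \code{strain}, \code{vorticity} (element centre)
#'   and \code{strain_a}, \code{strain_b} (surface layers), plus
#'   \code{rotation_angle}, the per-element rotation magnitude in radians.
#' @export
decompose_growth <- function(cv, sol) {
  u <- if (inherits(sol, "deformation_solution")) sol$u else sol
  n <- n_vertices(cv)
  pos <- rbind(cv$pos_a, cv$pos_b)
  wedge <- cbind(cv$tri, cv$tri + n)
  uflat <- as.vector(t(u))
  g <- wedge_gradients_cpp(pos, wedge, uflat, c(0, -1, 1))
  m <- n_elements(cv)
  to_arr <- function(gm) {
    a <- array(0, c(m, 3, 3))
    for (j in 1:3) for (i in 1:3) a[, i, j] <- gm[, 3 * (j - 1) + i]
    a
  }
  grad <- to_arr(g[[1]])
  strain <- (grad + aperm(grad, c(1, 3, 2))) / 2
  vort <- (grad - aperm(grad, c(1, 3, 2))) / 2
  ga <- to_arr(g[[2]]); gb <- to_arr(g[[3]])
  rot <- sqrt(vort[, 3, 2]^2 + vort[, 1, 3]^2 + vort[, 2, 1]^2)
  structure(list(u = u,
                 grad = grad, strain = strain, vorticity = vort,
                 strain_a = (ga + aperm(ga, c(1, 3, 2))) / 2,
                 strain_b = (gb + aperm(gb, c(1, 3, 2))) / 2,
                 rotation_angle = rot),
            class = "deformation_result")
}

#' Residual-strain energy of a candidate displacement
#'
#' The quadratic functional whose minimiser is the equilibrium: one half of
#' the volume integral of (strain(u) - specified) : C : (strain(u) -
#' specified).  Useful for verifying that equilibrium solutions are energy
#' minima.
#'
#' @param system an \code{elastic_system} assembled with the specified
#'   growth of interest.
#' @param q reduced-coordinate displacement (e.g. \code{sol$q}).
#' @export
residual_energy <- function(system, q) {
  0.5 * sum(q * as.vector(system$K %*% q)) - sum(q * system$f) +
    system$energy_const
}
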