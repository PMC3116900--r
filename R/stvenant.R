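## Strain-field compatibility.
##
## A symmetric strain field is realisable as the symmetric gradient of some
## displacement field exactly when the Saint-Venant compatibility tensor
##
##   R_ijkl = d2 e_ij / dx_k dx_l + d2 e_kl / dx_i dx_j
##          - d2 e_ik / dx_j dx_l - d2 e_jl / dx_i dx_k
##
## vanishes identically.  Specified growth fields are generally
## incompatible; the shortfall appears as residual strain (and, for thin
## sheets, as out-of-plane buckling).  The checks here differentiate
## closed-form strain expressions symbolically, so compatible fields give
## residuals at machine precision rather than at a discretisation scale.

strain_names <- c("xx", "yy", "zz", "yz", "xz", "xy")

#' Closed-form strain field
#'
#' @param xx,yy,zz,yz,xz,xy tensor strain components as expressions (or
#'   one-sided formulas) in the variables \code{x}, \code{y}, \code{z}.
#'   Shears are tensor components (not engineering doubles).
#' @return object of class \code{strain_expressions}: a 3x3 matrix-list of
#'   expressions.
#' @export
#' @examples
#' s <- strain_expressions(xx = quote(x^2), yy = quote(y^2), xy = quote(x * y))
#' stvenant_residual(s)  # compatible: ~0
strain_expressions <- function(xx = 0, yy = 0, zz = 0,
                               yz = 0, xz = 0, xy = 0) {
  as_expr <- function(e) {
    if (inherits(e, "formula")) e <- e[[2]]
    if (is.numeric(e)) e <- substitute(v, list(v = e))
    if (!is.language(e) && !is.numeric(e))
      stop("strain components must be expressions in x, y, z")
    e
  }
  comp <- lapply(list(xx = xx, yy = yy, zz = zz, yz = yz, xz = xz, xy = xy),
                 as_expr)
  eps <- matrix(list(), 3, 3)
  eps[[1, 1]] <- comp$xx; eps[[2, 2]] <- comp$yy; eps[[3, 3]] <- comp$zz
  eps[[2, 3]] <- eps[[3, 2]] <- comp$yz
  eps[[1, 3]] <- eps[[3, 1]] <- comp$xz
  eps[[1, 2]] <- eps[[2, 1]] <- comp$xy
  structure(eps, class = "strain_expressions")
}

#' Strain field of a closed-form displacement field
#'
#' Differentiates the displacement expressions symbolically and forms the
#' (small-strain) symmetric gradient.  Any smooth displacement field yields
#' a compatible strain field, which makes this the natural generator of
#' positive test cases for \code{\link{stvenant_residual}}.
#'
#' @param ux,uy,uz displacement components as expressions in \code{x},
#'   \code{y}, \code{z}.
#' @return a \code{strain_expressions} object.
#' @export
strain_from_displacement <- function(ux = 0, uy = 0, uz = 0) {
  as_expr <- function(e) {
    if (inherits(e, "formula")) e <- e[[2]]
    if (is.numeric(e)) e <- substitute(v, list(v = e))
    e
  }
  u <- lapply(list(ux, uy, uz), as_expr)
  vars <- c("x", "y", "z")
  dd <- function(i, j) stats::D(u[[i]], vars[j])
  sym <- function(i, j) call("/", call("+", dd(i, j), dd(j, i)), 2)
  strain_expressions(xx = dd(1, 1), yy = dd(2, 2), zz = dd(3, 3),
                     yz = sym(2, 3), xz = sym(1, 3), xy = sym(1, 2))
}

#' Saint-Venant compatibility residual of a strain field
#'
#' Forms every component of the compatibility tensor by symbolic double
#' differentiation and evaluates it at the sample points.  A field is
#' compatible (realisable by a displacement) exactly when the residual is
#' zero; symbolic differentiation keeps compatible fields at rounding
#' error regardless of how wiggly they are.
#'
#' By symmetry only 6 of the 81 components are independent; all 81 are
#' evaluated and the maximum absolute value reported.
#'
#' @param strain a \code{strain_expressions} object.
#' @param points data frame or matrix of sample points with columns
#'   \code{x}, \code{y}, \code{z}; default a fixed 3x3x3 lattice on
#'   [-1, 1]^3.
#' @return the maximum absolute residual over components and points, with
#'   the full per-point component maxima in attribute \code{"per_point"}.
#' @export
stvenant_residual <- function(strain, points = NULL) {
  if (!inherits(strain, "strain_expressions"))
    stop("expected a strain_expressions object")
  if (is.null(points)) {
    g <- seq(-1, 1, length.out = 3)
    points <- expand.grid(x = g, y = g, z = g)
  }
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points)))
    stop("sample points need columns x, y, z")
  vars <- c("x", "y", "z")
  cache <- new.env(parent = emptyenv())
  d2 <- function(i, j, k, l) {
    key <- paste(i, j, k, l)
    if (!is.null(cache[[key]])) return(cache[[key]])
    e <- stats::D(stats::D(strain[[i, j]], vars[k]), vars[l])
    v <- eval(e, points)
    v <- rep_len(as.numeric(v), nrow(points))
    cache[[key]] <- v
    v
  }
  per_point <- numeric(nrow(points))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    r <- d2(i, j, k, l) + d2(k, l, i, j) - d2(i, k, j, l) - d2(j, l, i, k)
    per_point <- pmax(per_point, abs(r))
  }
  structure(max(per_point), per_point = per_point)
}

#' Random smooth compatible strain field
#'
#' Draws random low-order polynomial displacement components and returns
#' the corresponding (compatible by construction) strain field.  Intended
#' for property tests of \code{\link{stvenant_residual}}.
#'
#' @param degree maximum monomial degree of the displacement components.
#' @param rng a function(n) returning n random coefficients; defaults to
#'   \code{stats::rnorm}.
#' @return a \code{strain_expressions} object.
#' @export
random_compatible_strain <- function(degree = 4, rng = stats::rnorm) {
  mono <- list()
  for (p in 0:degree) for (q in 0:(degree - p)) for (r in 0:(degree - p - q))
    mono[[length(mono) + 1L]] <- c(p, q, r)
  poly <- function() {
    co <- rng(length(mono))
    terms <- mapply(function(m, ce) {
      e <- substitute(v, list(v = ce))
      if (m[1] > 0) e <- call("*", e, call("^", quote(x), m[1]))
      if (m[2] > 0) e <- call("*", e, call("^", quote(y), m[2]))
      if (m[3] > 0) e <- call("*", e, call("^", quote(z), m[3]))
      e
    }, mono, co, SIMPLIFY = FALSE)
    Reduce(function(a, b) call("+", a, b), terms)
  }
  strain_from_displacement(poly(), poly(), poly())
}

#' Radial in-plane strain field (incompatible in general)
#'
#' The planar field with radial component f(r) and circumferential
#' component g(r) about the origin, written in Cartesian components.  With
#' \code{f} different from \code{g} (anisotropic growth about a centre) the
#' field is incompatible, which is what drives buckling of sheets grown
#' with radial organisers.
#'
#' @param f,g expressions in \code{r} for the radial and circumferential
#'   strain.
#' @return a \code{strain_expressions} object (plane components only).
#' @export
radial_strain_field <- function(f = quote(r^2), g = quote(0 * r)) {
  as_expr <- function(e) { if (inherits(e, "formula")) e <- e[[2]]; e }
  f <- as_expr(f); g <- as_expr(g)
  rsub <- quote((x^2 + y^2)^(1/2))
  subst <- function(e) eval(call("substitute", e, list(r = rsub)))
  fr <- subst(f); gr <- subst(g)
  ## eps = f(r) rhat rhat' + g(r) that that', rhat = (x, y)/r; evaluate
  ## away from the origin
  r2 <- quote(x^2 + y^2)
  comp <- function(na, nb) {
    call("/", call("+", call("*", fr, na), call("*", gr, nb)), r2)
  }
  strain_expressions(
    xx = comp(quote(x^2), quote(y^2)),
    yy = comp(quote(y^2), quote(x^2)),
    xy = call("/", call("*", call("-", fr, gr), quote(x * y)), r2))
}
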