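## Clone tracking: virtual circular marked clones sampled as boundary points
## in barycentric coordinates.  Clones are diagnostics only - they deform
## passively with the canvas and never feed back on the mechanics.

## locate points (K x 3) on the midplane: nearest triangle + barycentric
## weights (clamped to the triangle, renormalised).
locate_on_midplane <- function(cv, pts, candidates = NULL) {
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  cen <- (mid[tri[, 1], , drop = FALSE] + mid[tri[, 2], , drop = FALSE] +
            mid[tri[, 3], , drop = FALSE]) / 3
  el <- integer(nrow(pts)); w <- matrix(0, nrow(pts), 3)
  use <- if (is.null(candidates)) seq_len(nrow(tri)) else candidates
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    d2 <- (cen[use, 1] - p[1])^2 + (cen[use, 2] - p[2])^2 + (cen[use, 3] - p[3])^2
    ## check a few nearest triangles, keep the best (smallest out-of-triangle
    ## clamping error)
    ord <- use[order(d2)[seq_len(min(8L, length(use)))]]
    best <- NULL; best_err <- Inf
    for (t in ord) {
      bw <- bary_weights(mid[tri[t, 1], ], mid[tri[t, 2], ], mid[tri[t, 3], ], p)
      err <- sum(pmax(-bw$w, 0)) + bw$dist
      if (err < best_err) { best <- list(t = t, w = bw$w); best_err <- err }
    }
    wcl <- pmax(best$w, 0); wcl <- wcl / sum(wcl)
    el[i] <- best$t; w[i, ] <- wcl
  }
  list(element = el, weights = w)
}

## barycentric weights of the in-plane projection of p onto triangle (p1,p2,p3)
bary_weights <- function(p1, p2, p3, p) {
  e1 <- p2 - p1; e2 <- p3 - p1; d <- p - p1
  g <- matrix(c(sum(e1 * e1), sum(e1 * e2), sum(e1 * e2), sum(e2 * e2)), 2, 2)
  rhs <- c(sum(e1 * d), sum(e2 * d))
  ab <- tryCatch(solve(g, rhs), error = function(e) c(1 / 3, 1 / 3))
  w <- c(1 - ab[1] - ab[2], ab[1], ab[2])
  resid <- d - ab[1] * e1 - ab[2] * e2   # out-of-plane distance
  list(w = w, dist = sqrt(sum(resid^2)))
}

#' Mark circular clones on a canvas
#'
#' Places \code{n} non-overlapping circular clones of the given radius at
#' random positions on the midplane, each traced by \code{npts} boundary
#' points stored in barycentric coordinates so they deform passively with
#' the mesh.
#'
#' @param cv a canvas.
#' @param n number of clones.
#' @param radius clone radius (must be small relative to the canvas).
#' @param seed RNG seed (placement is deterministic for a fixed seed).
#' @param npts boundary points per clone (>= 24).
#' @param max_tries placement attempts before giving up.
#' @return An object of class \code{clone_set}: a list of clones, each with
#'   \code{element} and \code{weights} for its boundary points, plus the
#'   initial singular values of its point cloud.
#' @export
mark_circular_clones <- function(cv, n, radius, seed = 1L, npts = 24L,
                                 max_tries = 100L * n + 200L) {
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  diam <- max(apply(mid, 2, function(z) diff(range(z))))
  if (radius >= diam / 2) stop("clone radius too large for this canvas")
  ar <- triangle_areas(cv)
  ## quick capacity check: discs of spacing 2.2 r cannot pack beyond this
  if (n * pi * (1.1 * radius)^2 > sum(ar))
    stop(sprintf("could not place %d non-overlapping clones (placed 0): canvas too small", n))
  cum_ar <- cumsum(ar) / sum(ar)
  nrm <- triangle_normals(cv)
  centres <- matrix(0, 0, 3)
  clones <- list()
  rng <- local_rng(seed)
  tries <- 0L
  while (length(clones) < n && tries < max_tries) {
    tries <- tries + 1L
    ## random point: area-weighted triangle, uniform barycentric
    t <- findInterval(rng(1), cum_ar) + 1L
    t <- min(t, nrow(tri))
    r12 <- rng(2)
    if (sum(r12) > 1) r12 <- 1 - r12
    ctr <- (1 - r12[1] - r12[2]) * mid[tri[t, 1], ] +
      r12[1] * mid[tri[t, 2], ] + r12[2] * mid[tri[t, 3], ]
    if (nrow(centres) > 0 &&
        min(sqrt(rowSums(sweep(centres, 2, ctr)^2))) < 2.2 * radius) next
    ## tangent frame at the centre
    nvec <- nrm[t, ]
    e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * nvec) * nvec
    if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * nvec) * nvec
    e1 <- e1 / sqrt(sum(e1^2)); e2 <- cross3(nvec, e1)
    th <- 2 * pi * (seq_len(npts) - 1) / npts
    pts <- t(sapply(th, function(a) ctr + radius * (cos(a) * e1 + sin(a) * e2)))
    loc <- locate_on_midplane(cv, pts)
    ## reject clones whose boundary falls off the mesh (near holes/rims)
    got <- clone_positions_one(cv, loc)
    if (max(sqrt(rowSums((got - pts)^2))) > 0.2 * radius) next
    sv <- clone_singvals(got)
    clones[[length(clones) + 1L]] <-
      list(element = loc$element, weights = loc$weights, sv0 = sv)
    centres <- rbind(centres, ctr)
  }
  if (length(clones) < n)
    stop(sprintf("could not place %d non-overlapping clones (placed %d)",
                 n, length(clones)))
  structure(clones, class = "clone_set")
}

## small deterministic uniform RNG independent of the global stream
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- 1
  function(k = 1) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

clone_positions_one <- function(cv, clone) {
  mid <- canvas_midplane(cv)
  tri <- cv$tri
  t <- tri[clone$element, , drop = FALSE]
  clone$weights[, 1] * mid[t[, 1], , drop = FALSE] +
    clone$weights[, 2] * mid[t[, 2], , drop = FALSE] +
    clone$weights[, 3] * mid[t[, 3], , drop = FALSE]
}

#' Current world positions of clone boundary points
#' @param cv a canvas.
#' @param clones a \code{clone_set}.
#' @return list of K x 3 matrices.
#' @export
clone_positions <- function(cv, clones) {
  lapply(clones, function(cl) clone_positions_one(cv, cl))
}

## singular values of a centred clone point cloud; for npts uniform samples
## of an affine image of a circle these are proportional to the singular
## values of the affine map.
clone_singvals <- function(pts) {
  x <- sweep(pts, 2, colMeans(pts))
  svd(x, nu = 0, nv = 0)$d[1:2]
}

#' Shape statistics of tracked clones
#'
#' Fits the best ellipse (principal components of the boundary point cloud)
#' to each clone.  For a locally affine deformation the anisotropy ratio
#' equals the singular-value ratio of the deformation.
#'
#' @param cv the (possibly deformed) canvas.
#' @param clones a \code{clone_set} previously marked on it.
#' @return data.frame with one row per clone: \code{area_ratio} (current /
#'   initial ellipse area), \code{anisotropy} (major/minor axis, >= 1, Inf
#'   for degenerate collinear clones, flagged in \code{degenerate}),
#'   \code{angle_deg} (major axis angle from the x axis in the xy plane,
#'   in [0, 180)).
#' @export
clone_shape_stats <- function(cv, clones) {
  out <- lapply(clones, function(cl) {
    pts <- clone_positions_one(cv, cl)
    x <- sweep(pts, 2, colMeans(pts))
    sv <- svd(x, nu = 0, nv = 3)
    s <- sv$d[1:2]
    degen <- s[2] < 1e-12 * s[1]
    major <- sv$v[, 1]
    ang <- atan2(major[2], major[1]) * 180 / pi
    ang <- ang %% 180
    data.frame(area_ratio = prod(s) / prod(cl$sv0),
               anisotropy = if (degen) Inf else s[1] / s[2],
               angle_deg = ang, degenerate = degen)
  })
  do.call(rbind, out)
}

## re-anchor clone points after remeshing, given a map from new triangles to
## their parent (old) triangle and the OLD world positions of the points.
reanchor_clones <- function(cv_new, clones, parent_of_new, old_positions) {
  children <- split(seq_len(nrow(cv_new$tri)), parent_of_new)
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    pts <- old_positions[[i]]
    for (k in seq_along(cl$element)) {
      cand <- children[[as.character(cl$element[k])]]
      loc <- locate_on_midplane(cv_new, pts[k, , drop = FALSE], candidates = cand)
      cl$element[k] <- loc$element
      cl$weights[k, ] <- loc$weights
    }
    clones[[i]] <- cl
  }
  clones
}
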