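## Remeshing: edge subdivision and quality improvement.
##
## Growth stretches elements; when edges get too long they are split and
## the new vertices placed by interpolating subdivision (butterfly scheme)
## on each surface, so repeated refinement converges to a smooth limit
## surface rather than flattening curved regions.  Factor fields are
## interpolated onto the new vertices; element data (polarity, residual
## strain) is inherited from the parent element.

#' Edge lengths of the midplane triangulation
#' @param cv a canvas.
#' @param el optional precomputed \code{\link{edge_list}}.
#' @export
edge_lengths <- function(cv, el = edge_list(cv)) {
  mid <- canvas_midplane(cv)
  row_norm(mid[el$edges[, 1], , drop = FALSE] -
             mid[el$edges[, 2], , drop = FALSE])
}

## butterfly stencil for one edge: endpoints 1/2, opposite vertices 1/8,
## four wing vertices -1/16; returns NULL when the full interior stencil is
## unavailable (boundary edge or missing wing), in which case the caller
## falls back to the midpoint.
butterfly_stencil <- function(e, el) {
  t1 <- el$tri1[e]; t2 <- el$tri2[e]
  if (is.na(t1) || is.na(t2)) return(NULL)
  opp <- function(t) {
    k <- which(el$tri_edge[t, ] == e)
    el$tri_vert[t, k]
  }
  c1 <- opp(t1); c2 <- opp(t2)
  a <- el$edges[e, 1]; b <- el$edges[e, 2]
  ## wing opposite edge (p, q) across from triangle t
  wing <- function(t, p, q) {
    k <- which(el$tri_vert[t, ] != p & el$tri_vert[t, ] != q)
    we <- el$tri_edge[t, k]
    tw <- if (!is.na(el$tri1[we]) && el$tri1[we] != t) el$tri1[we] else el$tri2[we]
    if (is.na(tw)) return(NA_integer_)
    opp2 <- which(el$tri_edge[tw, ] == we)
    el$tri_vert[tw, opp2]
  }
  w <- c(wing(t1, a, c1), wing(t1, b, c1), wing(t2, a, c2), wing(t2, b, c2))
  if (anyNA(w)) return(NULL)
  list(idx = c(a, b, c1, c2, w),
       wts = c(1 / 2, 1 / 2, 1 / 8, 1 / 8, rep(-1 / 16, 4)))
}

#' Split over-long edges of the canvas
#'
#' Two-threshold rule: a remeshing pass is triggered when any midplane edge
#' exceeds \code{upper} times the reference length, and the pass then
#' splits every edge longer than \code{lower} times the reference, so
#' freshly split edges sit well below the trigger and passes are not
#' re-triggered every step.  New vertex positions come from the butterfly
#' interpolating subdivision stencil applied to each surface (midpoint on
#' boundary edges and wherever the interior stencil is incomplete).
#' Triangles with 1, 2 or 3 split edges are replaced by 2, 3 or 4 children.
#'
#' Factor fields are linearly interpolated onto new vertices; identity
#' factors are then re-thresholded at 0.5 so they stay binary.  Vertex
#' labels are inherited where both edge endpoints carry the label.
#'
#' @param cv a canvas.
#' @param reference reference edge length (typically the mean initial edge
#'   length of the model).
#' @param fields named list of \code{factor_field}s to carry across.
#' @param lower,upper split and trigger multiples of \code{reference}.
#' @param force split all edges above \code{lower} even if none exceeds the
#'   trigger.
#' @return list with the new \code{canvas}, logical \code{changed},
#'   \code{fields}, \code{parent_of_new} (parent element index per new
#'   element), and \code{new_vertex_edge} (K x 2 parent endpoints of each
#'   added vertex).
#' @export
split_long_edges <- function(cv, reference, fields = list(),
                             lower = 1.5, upper = 2, force = FALSE) {
  if (reference <= 0) stop("non-positive reference edge length")
  if (lower >= upper) stop("split threshold must lie below the trigger threshold")
  el <- edge_list(cv)
  ## tri_vert[t, k]: vertex of triangle t opposite its edge k (edge k joins
  ## the other two vertices, matching the edge_list convention)
  el$tri_vert <- cv$tri
  len <- edge_lengths(cv, el)
  if (!force && max(len) <= upper * reference)
    return(list(canvas = cv, changed = FALSE, fields = fields,
                parent_of_new = seq_len(n_elements(cv)),
                new_vertex_edge = matrix(0L, 0L, 2L)))
  split <- len > lower * reference
  if (!any(split))
    return(list(canvas = cv, changed = FALSE, fields = fields,
                parent_of_new = seq_len(n_elements(cv)),
                new_vertex_edge = matrix(0L, 0L, 2L)))

  n <- n_vertices(cv)
  sidx <- which(split)
  new_id <- rep(NA_integer_, nrow(el$edges))
  new_id[sidx] <- n + seq_along(sidx)

  ## new vertex positions on each surface
  place <- function(pos) {
    out <- matrix(0, length(sidx), 3)
    for (q in seq_along(sidx)) {
      st <- butterfly_stencil(sidx[q], el)
      out[q, ] <- if (is.null(st)) {
        colMeans(pos[el$edges[sidx[q], ], , drop = FALSE])
      } else {
        colSums(pos[st$idx, , drop = FALSE] * st$wts)
      }
    }
    out
  }
  pos_a <- rbind(cv$pos_a, place(cv$pos_a))
  pos_b <- rbind(cv$pos_b, place(cv$pos_b))
  midpt_a <- (cv$pos_a[el$edges[sidx, 1], , drop = FALSE] +
                cv$pos_a[el$edges[sidx, 2], , drop = FALSE]) / 2
  midpt_b <- (cv$pos_b[el$edges[sidx, 1], , drop = FALSE] +
                cv$pos_b[el$edges[sidx, 2], , drop = FALSE]) / 2

  ## children per triangle; m_k = new vertex on edge k (opposite vertex k)
  mid <- (pos_a + pos_b) / 2
  tris <- list(); parent <- integer(0)
  for (t in seq_len(n_elements(cv))) {
    v <- cv$tri[t, ]
    mk <- new_id[el$tri_edge[t, ]]
    ns <- sum(!is.na(mk))
    if (ns == 0L) {
      tris[[length(tris) + 1L]] <- v; parent <- c(parent, t)
      next
    }
    if (ns == 1L) {
      ## rotate so the split edge is edge 1 (opposite v1)
      r <- which(!is.na(mk))
      rot <- switch(r, c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
      v <- v[rot]; m1 <- mk[r]
      kids <- list(c(v[1], v[2], m1), c(v[1], m1, v[3]))
    } else if (ns == 2L) {
      ## rotate so the unsplit edge is edge 3: m on edges 1 and 2
      r <- which(is.na(mk))
      rot <- switch(r, c(2L, 3L, 1L), c(3L, 1L, 2L), c(1L, 2L, 3L))
      v <- v[rot]; m <- mk[rot]
      m1 <- m[1]; m2 <- m[2]
      ## split the quad (v1, v2, m1, m2) along its shorter diagonal
      d1 <- sum((mid[v[1], ] - mid[m1, ])^2)
      d2 <- sum((mid[v[2], ] - mid[m2, ])^2)
      quad <- if (d1 <= d2) {
        list(c(v[1], v[2], m1), c(v[1], m1, m2))
      } else {
        list(c(v[2], m1, m2), c(v[1], v[2], m2))
      }
      kids <- c(list(c(m2, m1, v[3])), quad)
    } else {
      kids <- list(c(v[1], mk[3], mk[2]), c(v[2], mk[1], mk[3]),
                   c(v[3], mk[2], mk[1]), c(mk[1], mk[2], mk[3]))
    }
    for (kid in kids) tris[[length(tris) + 1L]] <- kid
    parent <- c(parent, rep(t, length(kids)))
  }
  tri_new <- do.call(rbind, tris)
  storage.mode(tri_new) <- "integer"

  ## labels: new vertex inherits labels common to both endpoints
  labels <- lapply(cv$labels, function(set) {
    inherit <- new_id[sidx][el$edges[sidx, 1] %in% set &
                             el$edges[sidx, 2] %in% set]
    sort(c(set, inherit))
  })

  ## the interpolating stencil can overshoot in strongly curved regions and
  ## place a vertex so that the two surfaces cross or a surface triangle
  ## flips; revert such vertices to the plain midpoint, which subdivides
  ## the parent wedge conservatively
  bad_new_vertices <- function() {
    tn <- function(pos) {
      p1 <- pos[tri_new[, 1], , drop = FALSE]
      p2 <- pos[tri_new[, 2], , drop = FALSE]
      p3 <- pos[tri_new[, 3], , drop = FALSE]
      row_cross(p2 - p1, p3 - p1)
    }
    na <- tn(pos_a); nb <- tn(pos_b)
    d <- (pos_b - pos_a)[t(tri_new), , drop = FALSE]
    nm <- (na + nb)[rep(seq_len(nrow(tri_new)), each = 3), , drop = FALSE]
    off <- matrix(rowSums(d * nm), ncol = 3, byrow = TRUE)
    bad_el <- rowSums(na * nb) <= 0 | apply(off, 1, min) <= 0
    vb <- unique(as.vector(tri_new[bad_el, , drop = FALSE]))
    vb[vb > n]
  }
  vb <- bad_new_vertices()
  if (length(vb)) {
    q <- vb - n
    pos_a[vb, ] <- midpt_a[q, , drop = FALSE]
    pos_b[vb, ] <- midpt_b[q, , drop = FALSE]
  }

  cv_new <- canvas(pos_a, pos_b, tri_new, labels)

  ## interpolate fields; identities re-thresholded to stay binary
  ends <- el$edges[sidx, , drop = FALSE]
  fields <- lapply(fields, function(f) {
    vnew <- (f$values[ends[, 1]] + f$values[ends[, 2]]) / 2
    f$values <- c(f$values, vnew)
    f$production <- c(f$production,
                      (f$production[ends[, 1]] + f$production[ends[, 2]]) / 2)
    if (f$kind == "identity") f$values <- as.numeric(f$values >= 0.5)
    if (length(f$clamp_idx)) f$values[f$clamp_idx] <- f$clamp_val
    f
  })

  list(canvas = cv_new, changed = TRUE, fields = fields,
       parent_of_new = parent, new_vertex_edge = ends)
}

## carry a polarity state across a remesh: children inherit the parent
## element's axis and mode (axes are re-projected at the next update)
remap_polarity <- function(state, parent_of_new) {
  state$axis <- state$axis[parent_of_new, , drop = FALSE]
  state$mode <- state$mode[parent_of_new]
  state
}

#' Improve element quality by edge flipping
#'
#' Flips interior edges where the flip increases the smaller of the minimum
#' angles of the two adjacent triangles.  Edges on the boundary, flips that
#' would duplicate an existing edge, and flips across strongly bent creases
#' (dihedral guard) are left alone, so the pass is shape-preserving.
#'
#' @param cv a canvas.
#' @param min_gain minimum min-angle improvement (radians) for a flip.
#' @param max_dihedral maximum angle (radians) between the normals of the
#'   two adjacent triangles for the edge to be considered flat enough.
#' @param max_sweeps sweep cap.
#' @return list with the new \code{canvas}, \code{changed},
#'   \code{parent_of_new} and the number of \code{flips}.
#' @export
improve_quality <- function(cv, min_gain = 1e-3, max_dihedral = pi / 6,
                            max_sweeps = 5L) {
  tri <- cv$tri
  mid <- canvas_midplane(cv)
  min_angle <- function(p1, p2, p3) {
    a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2))
    cc <- sqrt(sum((p1 - p2)^2))
    if (min(a, b, cc) == 0) return(0)
    ang <- function(u, v, w) acos(max(-1, min(1, (v^2 + w^2 - u^2) / (2 * v * w))))
    min(ang(a, b, cc), ang(b, a, cc), ang(cc, a, b))
  }
  parent <- seq_len(nrow(tri))
  nflips <- 0L
  for (sweep in seq_len(max_sweeps)) {
    el <- edge_list(tri)
    flipped_any <- FALSE
    touched <- rep(FALSE, nrow(tri))
    ekey <- paste(el$edges[, 1], el$edges[, 2])
    for (e in seq_len(nrow(el$edges))) {
      t1 <- el$tri1[e]; t2 <- el$tri2[e]
      if (is.na(t1) || is.na(t2) || touched[t1] || touched[t2]) next
      a <- el$edges[e, 1]; b <- el$edges[e, 2]
      c1 <- setdiff(tri[t1, ], c(a, b)); c2 <- setdiff(tri[t2, ], c(a, b))
      if (length(c1) != 1L || length(c2) != 1L || c1 == c2) next
      if (paste(min(c1, c2), max(c1, c2)) %in% ekey) next
      ## dihedral guard
      n1 <- row_cross(rbind(mid[tri[t1, 2], ] - mid[tri[t1, 1], ]),
                      rbind(mid[tri[t1, 3], ] - mid[tri[t1, 1], ]))
      n2 <- row_cross(rbind(mid[tri[t2, 2], ] - mid[tri[t2, 1], ]),
                      rbind(mid[tri[t2, 3], ] - mid[tri[t2, 1], ]))
      l1 <- row_norm(n1); l2 <- row_norm(n2)
      if (l1 == 0 || l2 == 0) next
      cosd <- sum(n1 * n2) / (l1 * l2)
      if (cosd < cos(max_dihedral)) next
      before <- min(min_angle(mid[a, ], mid[b, ], mid[c1, ]),
                    min_angle(mid[a, ], mid[b, ], mid[c2, ]))
      after <- min(min_angle(mid[c1, ], mid[c2, ], mid[a, ]),
                   min_angle(mid[c1, ], mid[c2, ], mid[b, ]))
      if (after <= before + min_gain) next
      ## orient the new pair consistently with t1 (a -> b seen from c1)
      ord_ab <- {
        k <- match(a, tri[t1, ])
        if (tri[t1, (k %% 3L) + 1L] == b) c(a, b) else c(b, a)
      }
      tri[t1, ] <- c(c1, ord_ab[1], c2)
      tri[t2, ] <- c(c1, c2, ord_ab[2])
      touched[c(t1, t2)] <- TRUE
      flipped_any <- TRUE
      nflips <- nflips + 1L
    }
    if (!flipped_any) break
  }
  if (nflips == 0L)
    return(list(canvas = cv, changed = FALSE,
                parent_of_new = seq_len(nrow(tri)), flips = 0L))
  cv_new <- canvas(cv$pos_a, cv$pos_b, tri, cv$labels)
  list(canvas = cv_new, changed = TRUE, parent_of_new = parent,
       flips = nflips)
}
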