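## Canvas: two-surface pentahedral mesh.
##
## A canvas stores the two triangulated surfaces A and B (isomorphic meshes
## over the same vertex index set) from which the midplane and thickness are
## derived.  All factor fields live on midplane vertices; the wedge elements
## used for elasticity span the paired A/B triangles.

#' Construct a canvas from paired surface positions
#'
#' @param pos_a,pos_b numeric N x 3 matrices of vertex positions on the two
#'   surfaces (A below, B above, in the local normal sense).
#' @param tri integer M x 3 matrix of midplane triangle connectivity
#'   (1-based vertex indices, consistently oriented).
#' @param labels named list of integer vertex index sets marking regions
#'   (e.g. boundary edges, organiser seeds).
#' @return An object of class \code{canvas}.
#' @export
canvas <- function(pos_a, pos_b, tri, labels = list()) {
  pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
  storage.mode(tri) <- "integer"
  stopifnot(ncol(pos_a) == 3L, ncol(pos_b) == 3L, ncol(tri) == 3L,
            nrow(pos_a) == nrow(pos_b))
  if (max(tri) > nrow(pos_a) || min(tri) < 1L)
    stop("triangle indices out of range")
  cv <- structure(list(pos_a = pos_a, pos_b = pos_b, tri = tri,
                       labels = labels), class = "canvas")
  validate_canvas(cv)
  cv
}

#' @export
print.canvas <- function(x, ...) {
  cat("canvas:", n_vertices(x), "midplane vertices,", n_elements(x),
      "wedge elements\n")
  cat("  midplane area:", format(sum(triangle_areas(x))),
      " mean thickness:", format(mean(canvas_thickness(x))), "\n")
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

validate_canvas <- function(cv) {
  if (any(!is.finite(cv$pos_a)) || any(!is.finite(cv$pos_b)))
    stop("non-finite vertex positions")
  ar <- triangle_areas(cv)
  if (any(ar <= 0)) stop("degenerate midplane triangle (non-positive area)")
  vol <- element_volumes(cv)
  if (any(vol <= 0)) stop("wedge element with non-positive volume")
  invisible(cv)
}

#' @rdname canvas
#' @param cv a canvas.
#' @export
n_vertices <- function(cv) nrow(cv$pos_a)

#' @rdname canvas
#' @export
n_elements <- function(cv) nrow(cv$tri)

#' Midplane vertex positions (average of the two surfaces)
#' @param cv a canvas.
#' @return N x 3 matrix.
#' @export
canvas_midplane <- function(cv) (cv$pos_a + cv$pos_b) / 2

#' Per-vertex thickness |posA - posB|
#' @param cv a canvas.
#' @export
canvas_thickness <- function(cv) sqrt(rowSums((cv$pos_a - cv$pos_b)^2))

## cross products of rows of two n x 3 matrices
row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

row_norm <- function(u) sqrt(rowSums(u^2))

normalize_rows <- function(u) {
  n <- row_norm(u)
  n[n == 0] <- 1
  u / n
}

## un-normalised triangle normals (2 * area * unit normal) on given positions
tri_normals_raw <- function(pos, tri) {
  p1 <- pos[tri[, 1], , drop = FALSE]
  p2 <- pos[tri[, 2], , drop = FALSE]
  p3 <- pos[tri[, 3], , drop = FALSE]
  row_cross(p2 - p1, p3 - p1)
}

#' Midplane triangle areas
#' @param cv a canvas.
#' @export
triangle_areas <- function(cv) row_norm(tri_normals_raw(canvas_midplane(cv), cv$tri)) / 2

#' Unit midplane triangle normals
#' @param cv a canvas.
#' @export
triangle_normals <- function(cv) normalize_rows(tri_normals_raw(canvas_midplane(cv), cv$tri))

#' Area-weighted unit vertex normals on the midplane
#' @param cv a canvas.
#' @export
vertex_normals <- function(cv) {
  raw <- tri_normals_raw(canvas_midplane(cv), cv$tri)
  vn <- matrix(0, n_vertices(cv), 3)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate2(cv$tri[, k], raw[, 1], n_vertices(cv))
    vn[, 2] <- vn[, 2] + tabulate2(cv$tri[, k], raw[, 2], n_vertices(cv))
    vn[, 3] <- vn[, 3] + tabulate2(cv$tri[, k], raw[, 3], n_vertices(cv))
  }
  normalize_rows(vn)
}

## sum w by integer bin (fast accumulate; empty bins give 0)
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' Wedge element volumes
#'
#' Each pentahedron is decomposed into three tetrahedra; their signed
#' volumes are summed.
#' @param cv a canvas.
#' @export
element_volumes <- function(cv) {
  a <- cv$pos_a; b <- cv$pos_b; t <- cv$tri
  tet_vol <- function(p1, p2, p3, p4)
    rowSums(row_cross(p2 - p1, p3 - p1) * (p4 - p1)) / 6
  a1 <- a[t[, 1], , drop = FALSE]; a2 <- a[t[, 2], , drop = FALSE]
  a3 <- a[t[, 3], , drop = FALSE]
  b1 <- b[t[, 1], , drop = FALSE]; b2 <- b[t[, 2], , drop = FALSE]
  b3 <- b[t[, 3], , drop = FALSE]
  ## orientation: A below, B above a counter-clockwise midplane triangle
  abs(tet_vol(a1, a2, a3, b1) + tet_vol(a2, a3, b1, b2) +
        tet_vol(a3, b1, b2, b3))
}

#' Per-vertex control volumes (one third of each adjacent wedge)
#' @param cv a canvas.
#' @export
vertex_control_volumes <- function(cv) {
  vol <- element_volumes(cv)
  out <- numeric(n_vertices(cv))
  for (k in 1:3)
    out <- out + tabulate2(cv$tri[, k], vol / 3, n_vertices(cv))
  out
}

#' Per-vertex control areas on the midplane
#' @param cv a canvas.
#' @export
vertex_control_areas <- function(cv) {
  ar <- triangle_areas(cv)
  out <- numeric(n_vertices(cv))
  for (k in 1:3)
    out <- out + tabulate2(cv$tri[, k], ar / 3, n_vertices(cv))
  out
}

#' Unique edge list of the midplane triangulation
#'
#' @param cv a canvas (or an integer triangle matrix).
#' @return list with \code{edges} (E x 2, each row sorted), \code{tri1},
#'   \code{tri2} (adjacent triangle indices, \code{NA} for boundary edges),
#'   and \code{tri_edge} (M x 3 edge index per triangle, edge k opposite
#'   vertex k).
#' @export
edge_list <- function(cv) {
  tri <- if (is.matrix(cv)) cv else cv$tri
  m <- nrow(tri)
  ## edge k of a triangle is opposite local vertex k
  e <- rbind(tri[, c(2, 3)], tri[, c(3, 1)], tri[, c(1, 2)])
  es <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(es[, 1], es[, 2])
  idx <- match(key, unique(key))
  nuni <- max(idx)
  edges <- es[!duplicated(idx), , drop = FALSE]
  tri_of <- rep(seq_len(m), 3)
  tri1 <- rep(NA_integer_, nuni); tri2 <- rep(NA_integer_, nuni)
  first <- !duplicated(idx)
  tri1[idx[first]] <- tri_of[first]
  dup <- duplicated(idx)
  if (any(idx[dup][duplicated(idx[dup])] > 0))
    stop("non-manifold edge (more than two adjacent triangles)")
  tri2[idx[dup]] <- tri_of[dup]
  list(edges = edges, tri1 = tri1, tri2 = tri2,
       tri_edge = matrix(idx, m, 3))
}

#' Boundary vertex indices of the midplane mesh
#' @param cv a canvas.
#' @export
boundary_vertices <- function(cv) {
  el <- edge_list(cv)
  bnd <- is.na(el$tri2)
  sort(unique(as.vector(el$edges[bnd, ])))
}

#' Boundary edges (E x 2) of the midplane mesh
#' @param cv a canvas.
#' @export
boundary_edges <- function(cv) {
  el <- edge_list(cv)
  el$edges[is.na(el$tri2), , drop = FALSE]
}

#' Euler characteristic V - E + F of the midplane mesh
#' @param cv a canvas.
#' @export
euler_characteristic <- function(cv) {
  el <- edge_list(cv)
  n_vertices(cv) - nrow(el$edges) + n_elements(cv)
}

## ---------------------------------------------------------------------------
## Built-in canvas generators

offset_surfaces <- function(mid, tri, thickness, labels = list()) {
  cv0 <- structure(list(pos_a = mid, pos_b = mid + 1e-8, tri = tri),
                   class = "canvas")
  vn <- vertex_normals(cv0)
  canvas(mid - vn * thickness / 2, mid + vn * thickness / 2, tri, labels)
}

#' Build a flat square canvas
#'
#' A structured triangulated square of side \code{side} centred on the
#' origin, with an optional smooth upward bow (a cosine bump peaking at the
#' centre, zero on the boundary) used to break up/down symmetry in
#' out-of-plane growth models.
#'
#' @param nx,ny number of grid cells along x and y (>= 1).
#' @param side side length.
#' @param thickness canvas thickness (> 0).
#' @param bow peak height of the central bump (>= 0).
#' @return A \code{canvas} with labels \code{boundary}, \code{edge_bottom},
#'   \code{edge_top}, \code{edge_left}, \code{edge_right}, \code{midline_y}
#'   (vertices nearest the horizontal midline) and \code{centre}.
#' @export
build_flat_sheet <- function(nx, ny, side = 1, thickness = 0.1, bow = 0) {
  if (nx < 1 || ny < 1 || side <= 0 || thickness <= 0 || bow < 0)
    stop("build_flat_sheet: non-positive dimension parameter")
  xs <- seq(-side / 2, side / 2, length.out = nx + 1)
  ys <- seq(-side / 2, side / 2, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  z <- bow * cos(pi * g$x / side) * cos(pi * g$y / side)
  mid <- cbind(g$x, g$y, z)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i   # i along x, j along y
  tri <- matrix(0L, 2L * nx * ny, 3L)
  r <- 1L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v00 <- vid(i, j); v10 <- vid(i + 1L, j)
    v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
    if ((i + j) %% 2L == 0L) {        # alternate diagonals for symmetry
      tri[r, ] <- c(v00, v10, v11); tri[r + 1L, ] <- c(v00, v11, v01)
    } else {
      tri[r, ] <- c(v00, v10, v01); tri[r + 1L, ] <- c(v10, v11, v01)
    }
    r <- r + 2L
  }
  nvert <- (nx + 1L) * (ny + 1L)
  iall <- seq_len(nvert)
  tol <- side * 1e-9
  labels <- list(
    edge_bottom = iall[abs(mid[, 2] + side / 2) < tol],
    edge_top    = iall[abs(mid[, 2] - side / 2) < tol],
    edge_left   = iall[abs(mid[, 1] + side / 2) < tol],
    edge_right  = iall[abs(mid[, 1] - side / 2) < tol],
    midline_y   = iall[abs(mid[, 2] - ys[which.min(abs(ys))]) < tol],
    centre      = iall[which.min(rowSums(mid[, 1:2]^2))]
  )
  labels$boundary <- sort(unique(c(labels$edge_bottom, labels$edge_top,
                                   labels$edge_left, labels$edge_right)))
  offset_surfaces(mid, tri, thickness, labels)
}

#' Build a disc canvas
#'
#' Rings of vertices around a central vertex; ring j has 6j vertices.
#'
#' @param radius disc radius (> 0).
#' @param resolution number of rings (>= 1).
#' @param thickness canvas thickness (> 0).
#' @return A \code{canvas} with labels \code{rim} (outer boundary loop) and
#'   \code{centre}.
#' @export
build_disc <- function(radius, resolution = 8, thickness = 0.05) {
  if (radius <= 0 || resolution < 1 || thickness <= 0)
    stop("build_disc: non-positive parameter")
  nr <- as.integer(resolution)
  pts <- matrix(0, 1, 3)
  ring_start <- integer(nr + 1L)  # index of first vertex of ring j (ring 0 = centre)
  ring_start[1] <- 1L
  for (j in seq_len(nr)) {
    nj <- 6L * j
    ring_start[j + 1L] <- nrow(pts) + 1L
    th <- 2 * pi * (seq_len(nj) - 1L) / nj
    pts <- rbind(pts, cbind(radius * j / nr * cos(th),
                            radius * j / nr * sin(th), 0))
  }
  ring_n <- c(1L, 6L * seq_len(nr))
  tri <- NULL
  ## ring 1 fan around centre
  r1 <- ring_start[2]
  for (k in seq_len(6L))
    tri <- rbind(tri, c(1L, r1 + k - 1L, r1 + (k %% 6L)))
  ## between ring j-1 (inner, ni verts) and ring j (outer, no verts):
  ## march both rings in angle order; ni + no triangles per annulus
  if (nr >= 2L) for (j in 2:nr) {
    ni <- ring_n[j]; no <- ring_n[j + 1L]
    si <- ring_start[j]; so <- ring_start[j + 1L]
    ii <- 0L; io <- 0L    # number of advances made on each ring
    while (ii < ni || io < no) {
      vi <- si + (ii %% ni); vo <- so + (io %% no)
      adv_outer <- io < no && (ii >= ni || (io + 1L) / no <= (ii + 1L) / ni)
      if (adv_outer) {
        vo_next <- so + ((io + 1L) %% no)
        tri <- rbind(tri, c(vi, vo, vo_next))
        io <- io + 1L
      } else {
        vi_next <- si + ((ii + 1L) %% ni)
        tri <- rbind(tri, c(vi, vo, vi_next))
        ii <- ii + 1L
      }
    }
  }
  storage.mode(tri) <- "integer"
  labels <- list(rim = seq.int(ring_start[nr + 1L], nrow(pts)),
                 centre = 1L)
  offset_surfaces(pts, tri, thickness, labels)
}

#' Build a cylindrical canvas, optionally closed at the top
#'
#' Axis along z, base ring at z = 0.  The closed top is a triangle fan
#' around an apex vertex.
#'
#' @param radius,height cylinder radius and height (> 0); \code{height}
#'   must exceed 1e-3 * radius.
#' @param closed_top logical; close the top end with a cap?
#' @param resolution number of vertices around the circumference (>= 3).
#' @param thickness canvas thickness (> 0).
#' @return A \code{canvas} with labels \code{base} (z = 0 ring), \code{rim}
#'   (top ring) and, when closed, \code{apex}.
#' @export
build_cylinder <- function(radius, height, closed_top = TRUE,
                           resolution = 24, thickness = 0.05) {
  if (radius <= 0 || thickness <= 0) stop("build_cylinder: non-positive parameter")
  if (height <= 1e-3 * radius) stop("build_cylinder: degenerate height")
  nc <- as.integer(resolution)
  if (nc < 3L) stop("build_cylinder: resolution too low to form a cap (< 3)")
  dz_target <- 2 * pi * radius / nc
  nz <- max(2L, round(height / dz_target))
  zs <- seq(0, height, length.out = nz + 1L)
  th <- 2 * pi * (seq_len(nc) - 1L) / nc
  mid <- NULL
  for (j in seq_along(zs)) {
    off <- if (j %% 2L == 0L) pi / nc else 0   # stagger rings
    mid <- rbind(mid, cbind(radius * cos(th + off), radius * sin(th + off), zs[j]))
  }
  vid <- function(ring, k) (ring - 1L) * nc + ((k - 1L) %% nc) + 1L
  tri <- NULL
  for (j in seq_len(nz)) for (k in seq_len(nc)) {
    a <- vid(j, k); b <- vid(j, k + 1L)
    c2 <- vid(j + 1L, k); d <- vid(j + 1L, k + 1L)
    if (j %% 2L == 1L) {
      tri <- rbind(tri, c(a, b, c2), c(b, d, c2))
    } else {
      tri <- rbind(tri, c(a, b, d), c(a, d, c2))
    }
  }
  labels <- list(base = vid(1L, seq_len(nc)),
                 rim = vid(nz + 1L, seq_len(nc)))
  if (closed_top) {
    apex <- nrow(mid) + 1L
    mid <- rbind(mid, c(0, 0, height + 0.3 * radius))
    for (k in seq_len(nc))
      tri <- rbind(tri, c(vid(nz + 1L, k), vid(nz + 1L, k + 1L), apex))
    labels$apex <- apex
  }
  storage.mode(tri) <- "integer"
  ## outward normals: orient triangles so normals point away from the axis
  cvtmp <- structure(list(pos_a = mid, pos_b = mid + 1e-8, tri = tri),
                     class = "canvas")
  nrm <- triangle_normals(cvtmp)
  cen <- (mid[tri[, 1], ] + mid[tri[, 2], ] + mid[tri[, 3], ]) / 3
  outward <- cbind(cen[, 1], cen[, 2], pmax(cen[, 3] - height, 0))
  flip <- rowSums(nrm * outward) < 0
  tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]
  offset_surfaces(mid, tri, thickness, labels)
}

#' Import a midplane mesh from a Wavefront OBJ file
#'
#' Triangular faces only; the two surfaces are offset by a uniform
#' thickness along vertex normals.
#' @param path OBJ file path.
#' @param thickness canvas thickness.
#' @export
read_canvas_obj <- function(path, thickness = 0.05) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  mid <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                               function(p) as.numeric(p[1:3])))
  tri <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                               function(p) as.integer(sub("/.*", "", p[1:3]))))
  offset_surfaces(mid, tri, thickness)
}
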