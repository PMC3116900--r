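## Cutting the canvas along a chain of midplane edges.  Cutting duplicates
## vertices so the two sides become disconnected; it moves nothing and
## changes no areas, so a canvas with no stored residual strain does not
## deform when cut.

#' Cut the canvas along a path of midplane edges
#'
#' Vertices strictly inside the path (and path endpoints lying on the mesh
#' boundary) are duplicated on both surfaces and the triangles on one side
#' re-wired to the duplicates, so the two sides are disconnected across the
#' cut.  A path running along the mesh boundary separates nothing and
#' leaves the canvas unchanged.
#'
#' @param cv a canvas.
#' @param path integer vector of vertex indices forming a connected,
#'   non-self-crossing chain of existing midplane edges.
#' @return list with the cut \code{canvas} and \code{vertex_map}, an
#'   integer vector over new vertex indices giving the original vertex each
#'   one copies (identity for undisturbed vertices); use it to copy
#'   per-vertex fields.
#' @export
cut_along_path <- function(cv, path) {
  path <- as.integer(path)
  if (length(path) < 2L) stop("cut path needs at least two vertices")
  if (anyDuplicated(path)) stop("cut path must not cross itself")
  el <- edge_list(cv)
  ekey <- paste(el$edges[, 1], el$edges[, 2])
  pe <- cbind(pmin(path[-length(path)], path[-1]),
              pmax(path[-length(path)], path[-1]))
  pidx <- match(paste(pe[, 1], pe[, 2]), ekey)
  if (anyNA(pidx)) stop("cut path contains non-edges of the mesh")
  is_path_edge <- logical(nrow(el$edges))
  is_path_edge[pidx] <- TRUE

  tri <- cv$tri
  pos_a <- cv$pos_a; pos_b <- cv$pos_b
  labels <- cv$labels
  nvert <- nrow(pos_a)
  vertex_map <- seq_len(nvert)

  ## incident triangles per vertex
  for (v in path) {
    inc <- which(tri[, 1] == v | tri[, 2] == v | tri[, 3] == v)
    if (length(inc) < 2L) next
    ## adjacency among incident triangles: share a non-path edge through v
    comp <- seq_along(inc)     # union-find by repeated sweeps (fans are tiny)
    for (a in seq_along(inc)) for (b in seq_along(inc)) {
      if (a >= b) next
      sh <- intersect(tri[inc[a], ], tri[inc[b], ])
      if (length(sh) != 2L || !(v %in% sh)) next
      other <- vertex_map[setdiff(sh, v)]   # original id of the opposite vertex
      eid <- match(paste(min(v, other), max(v, other)), ekey)
      if (is.na(eid) || is_path_edge[eid]) next
      ## adjacent only through the full edge (two shared triangles)
      if (!(inc[a] %in% c(el$tri1[eid], el$tri2[eid])) ||
          !(inc[b] %in% c(el$tri1[eid], el$tri2[eid]))) next
      old <- comp[b]; comp[comp == old] <- comp[a]
    }
    groups <- split(inc, comp)
    if (length(groups) < 2L) next
    ## keep original vertex in the group containing the smallest triangle id
    keep <- which.min(vapply(groups, min, 0L))
    for (g in seq_along(groups)) {
      if (g == keep) next
      newv <- nrow(pos_a) + 1L
      pos_a <- rbind(pos_a, pos_a[v, ]); pos_b <- rbind(pos_b, pos_b[v, ])
      vertex_map <- c(vertex_map, v)
      for (t in groups[[g]]) tri[t, ][tri[t, ] == v] <- newv
      for (nm in names(labels))
        if (v %in% labels[[nm]]) labels[[nm]] <- c(labels[[nm]], newv)
    }
  }
  list(canvas = canvas(pos_a, pos_b, tri, labels), vertex_map = vertex_map)
}
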