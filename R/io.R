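## Mesh export.
##
## Snapshots are written as legacy-ASCII VTK polydata (midplane mesh with
## per-vertex factor fields and per-element growth/polarity data), or as
## plain PLY / OBJ surfaces for viewers that do not read VTK.

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a canvas to a legacy-ASCII VTK polydata file
#'
#' The midplane triangulation is written by default; per-vertex scalars
#' (factor fields) become POINT_DATA and per-element quantities CELL_DATA.
#' Symmetric per-element tensors may be passed as M x 6 matrices
#' (components xx, yy, zz, yz, xz, xy with engineering shears) and are
#' written as six scalar arrays.
#'
#' @param cv a canvas.
#' @param path output file path.
#' @param point_data named list of per-vertex numeric vectors (a
#'   \code{factor_field} is accepted and its values taken).
#' @param cell_data named list of per-element vectors, M x 3 matrices
#'   (written as VECTORS, e.g. polarity axes) or M x 6 Voigt matrices.
#' @param surface which surface to write: midplane, A or B.
#' @return the path, invisibly.
#' @export
write_canvas_vtk <- function(cv, path, point_data = list(),
                             cell_data = list(),
                             surface = c("midplane", "a", "b")) {
  surface <- match.arg(surface)
  pos <- switch(surface, midplane = canvas_midplane(cv),
                a = cv$pos_a, b = cv$pos_b)
  tri <- cv$tri
  n <- nrow(pos); m <- nrow(tri)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("canvas snapshot")
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS ", n, " double")
  writeLines(apply(pos, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  wl("POLYGONS ", m, " ", 4L * m)
  writeLines(paste(3L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  write_attr <- function(name, x) {
    if (inherits(x, "factor_field")) x <- x$values
    if (is.matrix(x) && ncol(x) == 3L) {
      wl("VECTORS ", name, " double")
      writeLines(apply(x, 1, function(p) paste(fmt_num(p), collapse = " ")),
                 con)
    } else if (is.matrix(x) && ncol(x) == 6L) {
      comp <- c("xx", "yy", "zz", "yz", "xz", "xy")
      for (k in 1:6) {
        wl("SCALARS ", name, "_", comp[k], " double 1")
        wl("LOOKUP_TABLE default")
        writeLines(fmt_num(x[, k]), con)
      }
    } else {
      wl("SCALARS ", name, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(fmt_num(as.numeric(x)), con)
    }
  }
  if (length(point_data)) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) write_attr(nm, point_data[[nm]])
  }
  if (length(cell_data)) {
    wl("CELL_DATA ", m)
    for (nm in names(cell_data)) write_attr(nm, cell_data[[nm]])
  }
  invisible(path)
}

#' Write a canvas surface as ASCII PLY
#' @inheritParams write_canvas_vtk
#' @export
write_canvas_ply <- function(cv, path, surface = c("midplane", "a", "b")) {
  surface <- match.arg(surface)
  pos <- switch(surface, midplane = canvas_midplane(cv),
                a = cv$pos_a, b = cv$pos_b)
  tri <- cv$tri
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pos)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tri)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(pos, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(paste(3L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  invisible(path)
}

#' Write a canvas surface as Wavefront OBJ
#' @inheritParams write_canvas_vtk
#' @export
write_canvas_obj <- function(cv, path, surface = c("midplane", "a", "b")) {
  surface <- match.arg(surface)
  pos <- switch(surface, midplane = canvas_midplane(cv),
                a = cv$pos_a, b = cv$pos_b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", apply(pos, 1, function(p)
    paste(fmt_num(p), collapse = " "))), con)
  writeLines(paste("f", cv$tri[, 1], cv$tri[, 2], cv$tri[, 3]), con)
  invisible(path)
}

#' Write a snapshot of a simulation state
#'
#' Writes the midplane VTK file with all factor fields as point data and,
#' as cell data, the polarity axes and the resultant strain of the last
#' step (Voigt components).
#'
#' @param sim a \code{simulation}.
#' @param path output VTK path.
#' @export
write_snapshot <- function(sim, path) {
  cell <- list()
  if (!is.null(sim$polarity)) cell$polarity <- sim$polarity$axis
  if (!is.null(sim$last_deformation))
    cell$resultant_strain <-
      tensors_to_voigt_rows(sim$last_deformation$strain)
  write_canvas_vtk(sim$canvas, path, point_data = sim$fields,
                   cell_data = cell)
}
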