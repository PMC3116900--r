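test_that("flat sheet has the expected counts, labels and measures", {
  cv <- build_flat_sheet(4, 3, side = 2, thickness = 0.2)
  expect_s3_class(cv, "canvas")
  expect_equal(n_vertices(cv), 5 * 4)
  expect_equal(n_elements(cv), 2 * 4 * 3)
  expect_equal(sum(triangle_areas(cv)), 4, tolerance = 1e-12)
  expect_equal(canvas_thickness(cv), rep(0.2, n_vertices(cv)), tolerance = 1e-12)
  expect_equal(canvas_midplane(cv)[, 3], rep(0, n_vertices(cv)))
  expect_length(cv$labels$edge_bottom, 5)
  expect_length(cv$labels$edge_left, 4)
  expect_length(cv$labels$boundary, 2 * (4 + 3))
  expect_equal(euler_characteristic(cv), 1)
  ## on an even grid the centre label is the exact origin
  cv2 <- build_flat_sheet(4, 4)
  expect_equal(unname(canvas_midplane(cv2)[cv2$labels$centre, ]), c(0, 0, 0))
})

test_that("midline label exists at odd and even resolutions", {
  for (n in 4:7) {
    cv <- build_flat_sheet(n, n)
    expect_gte(length(cv$labels$midline_y), 2)
    mid <- canvas_midplane(cv)
    expect_lt(diff(range(mid[cv$labels$midline_y, 2])), 1e-12)
  }
})

test_that("disc and cylinder builders produce valid closed labels", {
  d <- build_disc(1, resolution = 5)
  expect_equal(euler_characteristic(d), 1)
  expect_equal(sum(triangle_areas(d)), pi, tolerance = 0.05)
  rimr <- sqrt(rowSums(canvas_midplane(d)[d$labels$rim, 1:2]^2))
  expect_equal(rimr, rep(1, length(rimr)), tolerance = 1e-12)

  cl <- build_cylinder(1, 3, closed_top = TRUE, resolution = 12)
  expect_equal(euler_characteristic(cl), 1)   # capped tube ~ disc
  expect_true(all(c("base", "rim", "apex") %in% names(cl$labels)))
  op <- build_cylinder(1, 3, closed_top = FALSE, resolution = 12)
  expect_equal(euler_characteristic(op), 0)   # open tube ~ annulus
  expect_equal(canvas_midplane(op)[op$labels$base, 3],
               rep(0, length(op$labels$base)))
})

test_that("normals are unit and outward-consistent on the cylinder wall", {
  cv <- build_cylinder(1, 3, closed_top = FALSE, resolution = 10)
  nrm <- triangle_normals(cv)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, n_elements(cv)), tolerance = 1e-12)
  mid <- canvas_midplane(cv)
  cen <- (mid[cv$tri[, 1], ] + mid[cv$tri[, 2], ] + mid[cv$tri[, 3], ]) / 3
  radial <- cbind(cen[, 1], cen[, 2], 0)
  expect_true(all(rowSums(nrm * radial) > 0))
})

test_that("edge list conventions hold", {
  cv <- small_sheet(3)
  el <- edge_list(cv)
  ## edge k of triangle t joins the two vertices other than tri[t, k]
  for (t in seq_len(n_elements(cv))) for (k in 1:3) {
    e <- el$tri_edge[t, k]
    expect_setequal(el$edges[e, ], setdiff(cv$tri[t, ], cv$tri[t, k]))
  }
  ## boundary edge count of an nx x ny grid is 2(nx+ny)
  expect_equal(sum(is.na(el$tri2)), 2 * (3 + 3))
  expect_setequal(boundary_vertices(cv), cv$labels$boundary)
})

test_that("control measures partition totals", {
  cv <- small_sheet(5, thickness = 0.3)
  expect_equal(sum(vertex_control_areas(cv)), sum(triangle_areas(cv)),
               tolerance = 1e-12)
  expect_equal(sum(vertex_control_volumes(cv)), sum(element_volumes(cv)),
               tolerance = 1e-12)
  ## flat prism volumes are exactly area x thickness
  expect_equal(sum(element_volumes(cv)), 1 * 0.3, tolerance = 1e-12)
})

test_that("canvas constructor validates input", {
  cv <- small_sheet(2)
  expect_error(canvas(cv$pos_a, cv$pos_b[-1, ], cv$tri))
  bad_tri <- cv$tri; bad_tri[1, 1] <- 999L
  expect_error(canvas(cv$pos_a, cv$pos_b, bad_tri))
})

test_that("OBJ round trip preserves the midplane", {
  cv <- small_sheet(3, bow = 0.1)
  path <- tempfile(fileext = ".obj")
  on.exit(unlink(path))
  write_canvas_obj(cv, path)
  cv2 <- read_canvas_obj(path, thickness = 0.1)
  expect_equal(canvas_midplane(cv2), unname(canvas_midplane(cv)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cv2$tri, cv$tri, ignore_attr = TRUE)
})
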