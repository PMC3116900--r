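test_that("the two-threshold rule triggers and splits correctly", {
  cv <- small_sheet(4)
  ref <- mean(edge_lengths(cv))
  ## below the trigger: untouched even though some edges exceed 'lower'
  out <- split_long_edges(cv, ref / 1.5)
  expect_false(out$changed)
  expect_equal(out$canvas$tri, cv$tri)
  ## above the trigger: splitting strictly shortens the longest edge
  out2 <- split_long_edges(cv, ref / 2.5)
  expect_true(out2$changed)
  len2 <- edge_lengths(out2$canvas)
  expect_lt(max(len2), max(edge_lengths(cv)))
  ## force splits without the trigger
  out3 <- split_long_edges(cv, ref / 1.8, force = TRUE)
  expect_true(out3$changed)
})

test_that("splitting preserves area, topology and parentage", {
  cv <- small_sheet(4)
  ref <- mean(edge_lengths(cv))
  out <- split_long_edges(cv, ref / 2.5)
  cv2 <- out$canvas
  expect_equal(sum(triangle_areas(cv2)), sum(triangle_areas(cv)),
               tolerance = 1e-12)
  expect_equal(euler_characteristic(cv2), euler_characteristic(cv))
  expect_length(out$parent_of_new, n_elements(cv2))
  expect_true(all(out$parent_of_new %in% seq_len(n_elements(cv))))
  ## children tile their parent exactly (area bookkeeping per parent)
  a_new <- tapply(triangle_areas(cv2), out$parent_of_new, sum)
  expect_equal(as.numeric(a_new), triangle_areas(cv), tolerance = 1e-12)
  ## original vertices are untouched
  expect_equal(cv2$pos_a[seq_len(n_vertices(cv)), ], cv$pos_a)
})

test_that("fields are interpolated, identities re-binarised, labels inherited", {
  cv <- small_sheet(4)
  n <- n_vertices(cv)
  mid <- canvas_midplane(cv)
  fields <- list(
    LIN = factor_field("LIN", "signalling", n, init = 2 * mid[, 1] + 1,
                       D = 0, dilutable = FALSE),
    ID = factor_field("ID", "identity", n, init = as.numeric(mid[, 1] > 0)))
  ref <- mean(edge_lengths(cv))
  out <- split_long_edges(cv, ref / 2.5, fields = fields)
  mid2 <- canvas_midplane(out$canvas)
  ## a linear field stays exact under edge-midpoint interpolation
  expect_equal(out$fields$LIN$values, 2 * mid2[, 1] + 1, tolerance = 1e-12)
  expect_true(all(out$fields$ID$values %in% c(0, 1)))
  ## boundary labels survive: new bottom-edge vertices are labelled
  bot <- out$canvas$labels$edge_bottom
  expect_true(all(abs(mid2[bot, 2] + 0.5) < 1e-9))
  expect_gt(length(bot), length(cv$labels$edge_bottom))
  ## every new vertex records its parent edge endpoints
  expect_equal(nrow(out$new_vertex_edge), n_vertices(out$canvas) - n)
  expect_true(all(out$new_vertex_edge %in% seq_len(n)))
})

test_that("butterfly placement beats the midpoint on a curved surface", {
  cv <- build_cylinder(1, 3, closed_top = FALSE, resolution = 14)
  n <- n_vertices(cv)
  ref <- mean(edge_lengths(cv))
  out <- split_long_edges(cv, ref / 2.5)
  mid2 <- canvas_midplane(out$canvas)
  newv <- (n + 1):n_vertices(out$canvas)
  r_new <- sqrt(rowSums(mid2[newv, 1:2, drop = FALSE]^2))
  ## midpoint radius of the parent edges, for comparison
  mid1 <- canvas_midplane(cv)
  mp <- (mid1[out$new_vertex_edge[, 1], ] + mid1[out$new_vertex_edge[, 2], ]) / 2
  r_mid <- sqrt(rowSums(mp[, 1:2, drop = FALSE]^2))
  ## interpolating subdivision pushes interior new vertices back toward the
  ## unit cylinder, closer than the chord midpoint on average
  expect_lt(mean(abs(r_new - 1)), mean(abs(r_mid - 1)))
})

test_that("triangle split templates cover the 1-, 2- and 3-split cases", {
  ## a single triangle with selectively long edges exercises each template
  one_tri <- function(p1, p2, p3) {
    midp <- rbind(p1, p2, p3)
    canvas(sweep(midp, 2, c(0, 0, 0.05)),
           sweep(midp, 2, c(0, 0, -0.05)),
           matrix(1:3, 1, 3))
  }
  ## equilateral-ish: all three split -> 4 children
  cv3 <- one_tri(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.9, 0))
  out3 <- split_long_edges(cv3, 0.3, force = TRUE)
  expect_equal(n_elements(out3$canvas), 4)
  expect_equal(sum(triangle_areas(out3$canvas)), sum(triangle_areas(cv3)),
               tolerance = 1e-12)
  ## long thin: only the long edges split
  cv1 <- one_tri(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.1, 0))
  out1 <- split_long_edges(cv1, 0.45, force = TRUE)
  expect_equal(n_elements(out1$canvas), 2)
  expect_equal(sum(triangle_areas(out1$canvas)), sum(triangle_areas(cv1)),
               tolerance = 1e-12)
  cv2 <- one_tri(c(0, 0, 0), c(1, 0, 0), c(0.9, 0.55, 0))
  out2 <- split_long_edges(cv2, 0.55, force = TRUE)
  expect_equal(n_elements(out2$canvas), 3)
  expect_equal(sum(triangle_areas(out2$canvas)), sum(triangle_areas(cv2)),
               tolerance = 1e-12)
})

test_that("quality pass flips edges without moving vertices", {
  ## two skinny triangles across a short diagonal: the flip improves angles
  midp <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0.2, 0), c(0, 0.2, 0))
  cv <- canvas(sweep(midp, 2, c(0, 0, 0.02)),
               sweep(midp, 2, c(0, 0, -0.02)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  out <- improve_quality(cv)
  expect_equal(out$canvas$pos_a, cv$pos_a)
  expect_equal(sum(triangle_areas(out$canvas)), sum(triangle_areas(cv)),
               tolerance = 1e-12)
  min_angle <- function(cv) {
    mid <- canvas_midplane(cv)
    ang <- function(a, b, c) {
      u <- mid[b, ] - mid[a, ]; v <- mid[c, ] - mid[a, ]
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
    min(apply(cv$tri, 1, function(t)
      min(ang(t[1], t[2], t[3]), ang(t[2], t[3], t[1]), ang(t[3], t[1], t[2]))))
  }
  if (out$changed) expect_gt(min_angle(out$canvas), min_angle(cv))
})

test_that("the dihedral guard protects creases", {
  ## a sharply folded pair of triangles must not be flipped
  midp <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.2, 0), c(0.5, 0.2, 0.9))
  midp2 <- midp; midp2[4, ] <- c(0.5, -0.2, 0.9)
  cv <- canvas(sweep(midp2, 2, c(0, 0, 0.02)),
               sweep(midp2, 2, c(0, 0, -0.02)),
               rbind(c(1L, 2L, 3L), c(2L, 1L, 4L)))
  out <- improve_quality(cv)
  expect_equal(out$canvas$tri, cv$tri)
})

test_that("polarity and residual stores remap across a split", {
  cv <- small_sheet(3)
  pol <- update_polarity(polarity_state(cv, "external",
                                        external_dir = c(1, 0, 0)), cv)
  store <- residual_store(cv)
  store$eps_a[, 1, 1] <- seq_len(n_elements(cv))
  ref <- mean(edge_lengths(cv))
  out <- split_long_edges(cv, ref / 2.5)
  st2 <- morphocanvas:::remap_polarity(pol, out$parent_of_new)
  expect_equal(nrow(st2$axis), n_elements(out$canvas))
  rs2 <- morphocanvas:::remap_residual(store, out$parent_of_new)
  expect_equal(rs2$eps_a[, 1, 1], out$parent_of_new)
})
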