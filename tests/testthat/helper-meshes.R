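# Shared small fixtures for the unit tests.

small_sheet <- function(n = 4, side = 1, thickness = 0.1, bow = 0)
  build_flat_sheet(n, n, side = side, thickness = thickness, bow = bow)

# total turning angle (sum of absolute exterior angles, radians) of the
# polyline through the given vertices ordered by x
chain_turning <- function(cv, vertices) {
  mid <- canvas_midplane(cv)
  p <- mid[vertices[order(mid[vertices, 1])], , drop = FALSE]
  seg <- diff(p)
  seg <- seg / sqrt(rowSums(seg^2))
  dots <- rowSums(seg[-nrow(seg), , drop = FALSE] * seg[-1, , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, dots))))
}

# uniform growth spec helper: every element gets the same rates
uniform_growth <- function(cv, kpar = 0, kper = 0, kthick = 0, dt = 1,
                           axis = c(1, 0, 0)) {
  pol <- polarity_state(cv, "external", external_dir = axis)
  pol <- update_polarity(pol, cv)
  frame <- local_frame(cv, pol)
  spec <- growth_spec(cv, kpar_a = kpar, kper_a = kper, kthick = kthick)
  assemble_specified_growth(spec, frame, dt)
}

## total turning angle along the four (initially straight) boundary edges
## of a rectangular sheet: the in-plane curvature measure used by the
## shape-class regressions
boundary_turning <- function(cv) {
  turn <- function(vertices, coord) {
    mid <- canvas_midplane(cv)
    p <- mid[vertices[order(mid[vertices, coord])], , drop = FALSE]
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    dots <- rowSums(seg[-nrow(seg), , drop = FALSE] * seg[-1, , drop = FALSE])
    sum(acos(pmin(1, pmax(-1, dots))))
  }
  lb <- cv$labels
  turn(lb$edge_bottom, 1) + turn(lb$edge_top, 1) +
    turn(lb$edge_left, 2) + turn(lb$edge_right, 2)
}
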