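---
title: "Growing shapes: from rate fields to organ form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing shapes: from rate fields to organ form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphocanvas)
```

A growing organ is modelled here as a *canvas*: two triangulated
surfaces, A and B, joined through the thickness into one layer of wedge
finite elements. Regulatory factors live on the vertices, a polariser
field orients growth, and linear elasticity converts *specified* growth
(what each element would do in isolation) into *resultant* growth (what
tissue continuity allows). This vignette walks through the pieces and
ends with a residual-strain cutting experiment.

## A canvas and its factors

```{r canvas}
cv <- build_flat_sheet(16, 16, side = 1, thickness = 0.1)
cv
names(cv$labels)
```

Vertex labels (`edge_bottom`, `centre`, …) are the handles everything
else attaches to: organiser clamps, constraints, cut paths. They are
inherited through remeshing, so models stay valid as the mesh refines.

A signalling factor diffuses and decays on the midplane mesh; clamped
vertices act as organisers. `equilibrate_fields()` runs the setup phase
to steady state:

```{r factors}
fields <- list(
  CEN = factor_field("CEN", "signalling", n_vertices(cv), init = 0,
                     D = 0.05, decay = 2, dilutable = FALSE,
                     clamp = list(vertices = cv$labels$centre, value = 1)))
```

## Specified growth and the interaction function

Growth is specified by an interaction function mapping the current state
to rate fields. `pro(g, x) = 1 + g*x` is the standard promotion
multiplier; here the central signal promotes isotropic in-plane growth:

```{r interaction}
hook <- function(state) {
  k <- pro(4, state$fields$CEN$values) - 1
  list(kpar = k, kper = k)
}
```

A graded isotropic field like this is *incompatible*: no displacement
field realises it exactly. The symbolic St. Venant oracle makes the
distinction sharp:

```{r compatibility}
## compatible: any strain derived from a smooth displacement field
stvenant_residual(strain_from_displacement(ux = quote(x^2 * y),
                                           uy = quote(x + y^3)))
## incompatible: anisotropic growth about a centre
pts <- expand.grid(x = c(0.5, 1), y = c(0.4, 0.9), z = 0)
stvenant_residual(radial_strain_field(), pts)
```

## Growing with retention, then cutting

With `retention = 1` the unrealised part of specified growth accumulates
as stored pre-stress instead of being forgotten. The sheet is kept flat,
so the extra area the centre wants cannot buckle away:

```{r grow}
sim <- simulation(cv, fields = fields, interaction = hook,
                  constraints = function(cv) constraint_set(cv, flat = TRUE),
                  retention = 1,
                  config = sim_config(dt = 0.1, remesh = FALSE))
sim <- equilibrate_fields(sim)
out <- run_simulation(sim, until = 0.5)
residual_norm(out$store)
```

Cutting introduces no motion by itself — it only duplicates vertices
along the path. Relaxation then releases the store in small increments,
each a linear solve, until the canvas stops moving:

```{r cut}
cut <- cut_along_path(out$canvas, morphocanvas:::midline_cut_path(out$canvas))
relaxed <- relax_residual(cut$canvas, out$store, out$material,
                          solver_tol = 1e-8)
max(relaxed$displacement)      # the cut springs open
head(relaxed$energy)           # stored energy drains
tail(relaxed$energy, 1)
```

Re-running with `retention = 0` (the default) dissipates residual strain
at every step; the same cut then reveals nothing — the control
experiment distinguishing stored pre-stress from shape.

## Presets

The preset gallery wraps canonical configurations; each returns a prepared
simulation plus metadata, and `run_case()` runs it to its documented
duration (applying cut/release follow-ups where the case has one):

```{r presets, eval = FALSE}
run_case("A")     # uniform anisotropic growth: a lengthening rectangle
run_case("L")     # radial polarity: a tall central spike
run_case("T")     # rim organiser on a tube: the rim carried upward
run_case("W")     # retention + midline cut: the cut curves open
```
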