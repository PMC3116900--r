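## Model definitions from configuration files.
##
## A model file (YAML or JSON) declares the canvas generator, the factor
## fields, constraints, step control and the interaction function, so
## models can be run from the command line without writing R code.

#' Load a model definition and build a simulation
#'
#' The file may be YAML or JSON with top-level keys:
#' \describe{
#'   \item{canvas}{\code{type} (\code{flat_sheet}, \code{disc},
#'     \code{cylinder} or \code{obj}) plus the generator's arguments.}
#'   \item{factors}{list of declarations: \code{name}, \code{kind},
#'     \code{D}, \code{decay}, \code{dilutable}, \code{init} (number, or
#'     an R expression in \code{x}, \code{y}, \code{z} as a string),
#'     \code{clamp} (\code{label} naming a canvas vertex label, and
#'     \code{value}).}
#'   \item{polariser}{factor name; \code{polarity_mode} one of live,
#'     frozen, external, absent; \code{external_dir}.}
#'   \item{constraints}{\code{flat} (logical), \code{fix_z} /
#'     \code{fix_xyz} (label names).}
#'   \item{interaction}{either \code{preset} (reuse a named preset's
#'     hook is not supported; use \code{file}) or \code{file}, an R source
#'     file defining a function \code{interaction(state)}.}
#'   \item{config}{arguments to \code{\link{sim_config}}.}
#'   \item{run}{\code{duration}, \code{snapshot_times}.}
#' }
#'
#' @param path model file path.
#' @return list with the built \code{sim}, \code{duration} and
#'   \code{snapshot_times}, as from \code{\link{case_preset}}.
#' @export
read_model_config <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$canvas$type)) stop("model file lacks canvas$type")
  gen_args <- spec$canvas[setdiff(names(spec$canvas), "type")]
  cv <- switch(spec$canvas$type,
               flat_sheet = do.call(build_flat_sheet, gen_args),
               disc = do.call(build_disc, gen_args),
               cylinder = do.call(build_cylinder, gen_args),
               obj = do.call(read_canvas_obj, gen_args),
               stop("unknown canvas type '", spec$canvas$type, "'"))
  n <- n_vertices(cv)
  mid <- canvas_midplane(cv)
  env <- list2env(list(x = mid[, 1], y = mid[, 2], z = mid[, 3]))

  fields <- list()
  for (fd in spec$factors) {
    init <- fd$init
    if (is.character(init)) init <- eval(parse(text = init)[[1]], env)
    if (is.null(init)) init <- 0
    clamp <- NULL
    if (!is.null(fd$clamp)) {
      verts <- cv$labels[[fd$clamp$label]]
      if (is.null(verts))
        stop("clamp label '", fd$clamp$label, "' not found on the canvas")
      clamp <- list(vertices = verts,
                    value = if (is.null(fd$clamp$value)) 1 else fd$clamp$value)
    }
    fields[[fd$name]] <- factor_field(
      fd$name, kind = if (is.null(fd$kind)) "signalling" else fd$kind,
      n = n, init = init,
      D = if (is.null(fd$D)) 0 else fd$D,
      decay = if (is.null(fd$decay)) 0 else fd$decay,
      production = if (is.null(fd$production)) 0 else fd$production,
      dilutable = fd$dilutable, clamp = clamp)
  }

  polarity <- NULL
  if (!is.null(spec$polarity_mode) && spec$polarity_mode != "none")
    polarity <- polarity_state(
      cv, spec$polarity_mode,
      external_dir = if (is.null(spec$external_dir)) c(0, 1, 0)
      else as.numeric(spec$external_dir))

  cs <- spec$constraints
  constraints <- function(canvas) {
    lab <- function(nm) if (is.null(nm)) integer() else {
      v <- canvas$labels[[nm]]
      if (is.null(v)) stop("constraint label '", nm, "' not found")
      v
    }
    constraint_set(canvas, fix_z = lab(cs$fix_z), fix_xyz = lab(cs$fix_xyz),
                   flat = isTRUE(cs$flat))
  }

  hook <- NULL
  if (!is.null(spec$interaction$file)) {
    henv <- new.env(parent = globalenv())
    sys.source(spec$interaction$file, envir = henv)
    hook <- get("interaction", envir = henv)
    if (!is.function(hook))
      stop("interaction file must define a function 'interaction'")
  }

  cfg_args <- if (is.null(spec$config)) list() else spec$config
  sim <- simulation(cv, fields = fields, polariser = spec$polariser,
                    polarity = polarity, interaction = hook,
                    constraints = constraints,
                    retention = if (is.null(spec$retention)) 0
                    else spec$retention,
                    config = do.call(sim_config, cfg_args))
  sim <- equilibrate_fields(sim)
  list(sim = sim,
       duration = if (is.null(spec$run$duration)) 1 else spec$run$duration,
       snapshot_times = if (is.null(spec$run$snapshot_times)) numeric(0)
       else as.numeric(spec$run$snapshot_times),
       description = if (is.null(spec$description)) basename(path)
       else spec$description)
}
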