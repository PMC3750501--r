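#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing the model, the
#' specification features, and the algorithm settings, fills in defaults,
#' and validates the result. Validation is exhaustive: all violations are
#' reported at once, and unknown keys are rejected by name.
#'
#' The configuration has four blocks:
#'
#' * `model` — `type: sensor` selects the built-in sensor construct
#'   (with `x5_total`); `type: mass_action` takes `species`, `params` and
#'   `reactions` for [mass_action_network()]. Common keys: `horizon`,
#'   `rtol`, `atol`, `n_grid`, `x0` (`steady_state`, `zero`, or an explicit
#'   vector) and `input` (`breakpoints`/`levels`).
#' * `spec` — `features`: a list of `{species, windows, targets}` entries
#'   for [weighted_deviation_kernel()].
#' * `algorithm` — `design_parameters`, `eps`, `region` (`lo`/`hi`),
#'   `max_balls`, `coverage_target`, `n_mc`, `rho` (`n_delta`,
#'   `n_samples`), `delta_cap`, `delta_min_frac`, `gn_tol_frac`,
#'   `n_err_samples`, `seed`.
#' * `output` — `directory`.
#'
#' @param path file to read.
#' @return validated configuration, class `run_config`.
#' @seealso [run_pipeline()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' Write a configuration back to YAML
#' @param config a `run_config` (or plain list in the same shape).
#' @param path destination file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_defaults <- function() {
  list(
    model = list(type = "sensor", x5_total = 10, horizon = 600,
                 rtol = 1e-8, atol = 1e-10, n_grid = 400,
                 x0 = "steady_state",
                 input = list(breakpoints = 0, levels = 0)),
    spec = list(features = list()),
    algorithm = list(design_parameters = c("k7", "k9"),
                     eps = NULL, region = NULL,
                     max_balls = 50, coverage_target = 0.98,
                     n_mc = 1e5,
                     rho = list(n_delta = 4, n_samples = 20),
                     delta_cap = NULL, delta_min_frac = 1e-3,
                     gn_tol_frac = 1e-3, n_err_samples = 5,
                     seed = 1),
    output = list(directory = "specmap_out"))
}

# fill defaults into x, recursing one level into named sub-lists
merge_defaults <- function(x, defaults) {
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) {
      x[nm] <- defaults[nm]
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
               is.list(x[[nm]])) {
      x[[nm]] <- merge_defaults(x[[nm]], defaults[[nm]])
    }
  }
  x
}

validate_config <- function(raw) {
  cc <- check_collector()
  known_top <- c("model", "spec", "algorithm", "output")
  for (nm in setdiff(names(raw), known_top))
    cc$add(FALSE, sprintf("unknown top-level key '%s'", nm))

  cfg <- merge_defaults(raw, config_defaults())

  known <- list(
    model = c("type", "x5_total", "horizon", "rtol", "atol", "n_grid", "x0",
              "input", "species", "params", "reactions"),
    spec = "features",
    algorithm = c("design_parameters", "eps", "region", "max_balls",
                  "coverage_target", "n_mc", "rho", "delta_cap",
                  "delta_min_frac", "gn_tol_frac", "n_err_samples", "seed"),
    output = "directory")
  for (blk in names(known))
    for (nm in setdiff(names(cfg[[blk]]), known[[blk]]))
      cc$add(FALSE, sprintf("unknown key '%s' in block '%s'", nm, blk))

  mdl <- cfg$model
  cc$add(mdl$type %in% c("sensor", "mass_action"),
         sprintf("model type must be 'sensor' or 'mass_action', got '%s'",
                 mdl$type))
  cc$add(is.numeric(mdl$horizon) && mdl$horizon > 0, "model horizon must be > 0")
  cc$add(mdl$rtol > 0 && mdl$atol > 0, "solver tolerances must be > 0")
  inp <- mdl$input
  cc$add(length(inp$breakpoints) == length(inp$levels),
         "input breakpoints and levels must have equal length")
  cc$add(!is.unsorted(inp$breakpoints, strictly = TRUE),
         "input breakpoints must be strictly increasing")
  cc$add(all(inp$levels >= 0), "input levels must be nonnegative")
  if (is.character(mdl$x0))
    cc$add(mdl$x0 %in% c("steady_state", "zero"),
           sprintf("x0 policy must be 'steady_state', 'zero' or a vector, got '%s'",
                   mdl$x0))
  if (mdl$type == "mass_action") {
    cc$add(!is.null(mdl$species) && !is.null(mdl$params) &&
             !is.null(mdl$reactions),
           "mass_action model needs species, params and reactions")
  }

  alg <- cfg$algorithm
  if (!is.null(alg$eps))
    cc$add(is.numeric(alg$eps) && alg$eps > 0, "eps must be > 0")
  cc$add(alg$max_balls >= 1, "max_balls must be at least 1")
  cc$add(alg$coverage_target > 0 && alg$coverage_target <= 1,
         "coverage_target must be in (0, 1]")
  cc$add(alg$n_mc >= 100, "n_mc must be at least 100")
  cc$add(is.numeric(alg$seed) && alg$seed == round(alg$seed),
         "seed must be an integer")
  if (!is.null(alg$region)) {
    cc$add(!is.null(alg$region$lo) && !is.null(alg$region$hi) &&
             length(alg$region$lo) == length(alg$region$hi) &&
             all(unlist(alg$region$lo) < unlist(alg$region$hi)),
           "algorithm region must have lo < hi per axis")
  }

  for (i in seq_along(cfg$spec$features)) {
    fe <- cfg$spec$features[[i]]
    cc$add(!is.null(fe$species), sprintf("feature %d: species missing", i))
    cc$add(!is.null(fe$windows), sprintf("feature %d: windows missing", i))
    cc$add(!is.null(fe$targets) || !is.null(fe$target),
           sprintf("feature %d: targets missing", i))
  }

  cc$fail_if_any("invalid configuration")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  model:    ", x$model$type,
      sprintf("(horizon %g s)", x$model$horizon), "\n")
  cat("  features: ", length(x$spec$features), "\n")
  cat("  design:   ", paste(x$algorithm$design_parameters, collapse = ", "),
      "\n")
  if (!is.null(x$algorithm$eps)) cat("  eps:      ", x$algorithm$eps, "\n")
  invisible(x)
}

# --- realization helpers: config blocks -> package objects ----------------

config_network <- function(config) {
  mdl <- config$model
  if (mdl$type == "sensor") {
    sensor_network(x5_total = mdl$x5_total)
  } else {
    reactions <- lapply(mdl$reactions, function(rx) {
      list(rate = rx$rate,
           reactants = unlist(rx$reactants),
           products = unlist(rx$products),
           input_exponent = rx$input_exponent %||% 0)
    })
    mass_action_network(species = unlist(mdl$species),
                        params = unlist(mdl$params),
                        reactions = reactions)
  }
}

config_input <- function(config) {
  input_signal(unlist(config$model$input$breakpoints),
               unlist(config$model$input$levels))
}

config_setup <- function(config, network) {
  mdl <- config$model
  x0 <- if (is.character(mdl$x0)) {
    if (mdl$x0 == "zero") rep(0, network$n)
    else tryCatch(
      steady_state(network, input_level = input_level(config_input(config), 0)),
      specmap_steady_state_failure = function(e) {
        sm_log("WARN", "steady state did not converge, using zero state")
        rep(0, network$n)
      })
  } else as.numeric(unlist(mdl$x0))
  simulation_setup(x0, mdl$horizon, rtol = mdl$rtol, atol = mdl$atol,
                   n_grid = mdl$n_grid)
}

config_kernel <- function(config, network) {
  feats <- lapply(config$spec$features, function(fe) {
    list(species = fe$species,
         windows = if (is.list(fe$windows))
           do.call(rbind, lapply(fe$windows, unlist)) else fe$windows,
         target = unlist(fe$targets %||% fe$target))
  })
  weighted_deviation_kernel(feats, network$species)
}

config_region <- function(config) {
  rg <- config$algorithm$region
  if (is.null(rg)) stop("configuration has no algorithm$region block")
  specification_region(unlist(rg$lo), unlist(rg$hi))
}
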