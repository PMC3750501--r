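# Result serialization and the command pipeline tying the modules together.

config_hash <- function(config) rlang::hash(unclass(config))

# every artifact records how it was produced
artifact_meta <- function(config, seed) {
  list(config_hash = config_hash(config), seed = seed,
       package = "specmap",
       version = as.character(utils::packageVersion("specmap")))
}

sm_write_json <- function(obj, path, meta) {
  obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sm_write_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", meta$config_hash,
                     format(meta$seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

linmap_to_list <- function(lin) {
  list(k0 = as.list(lin$k0_design),
       f0 = lin$f0,
       L = as.numeric(t(lin$L)),        # row-major
       L_dim = dim(lin$L),
       subset = lin$subset$names,
       horizon = lin$horizon,
       rtol = lin$rtol, atol = lin$atol)
}

ellipsoid_to_list <- function(ell) {
  list(center = ell$center,
       semi_axes = ell$semi_axes,
       axes = apply(ell$axes, 2, identity, simplify = FALSE),
       delta = ell$delta)
}

# per-stage seeds derived from the one global seed, so each stage is
# independently reproducible; offsets stay far below 2^31
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(rho = base + 11L, cover = base + 23L, mc = base + 37L,
       samples = base + 51L)
}

#' Run a pipeline stage from a configuration
#'
#' Executes one named stage of the design pipeline and writes its artifacts
#' to the output directory. Every JSON artifact carries the configuration
#' hash and seed; CSVs carry them in a leading `#` comment line.
#'
#' Stages:
#' * `simulate` — nominal trajectory to `trajectory.csv`.
#' * `features` — nominal feature vector to `features.json` / `features.csv`.
#' * `linearize` — linearized map at the nominal design to `linmap.json`.
#' * `invert` — pseudoinverse, nonlinearity bound, maximal admissible ball
#'   at `eps`, parameter ellipsoid (`ellipsoid.json`) and parameter samples
#'   (`samples.csv`).
#' * `cover` — the full region-covering run: `balls.json`,
#'   `ellipsoids.json`, `coverage_report.json`, `samples.csv`.
#'
#' @param config a [load_config()] result.
#' @param command one of `simulate`, `features`, `linearize`, `invert`,
#'   `cover`.
#' @param outdir output directory (default from the config).
#' @param seed overrides the config seed.
#' @return (invisibly) a list of the objects computed, with
#'   `$files` naming the artifacts written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "features", "linearize",
                                     "invert", "cover"),
                         outdir = NULL, seed = NULL) {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$algorithm$seed
  seeds <- stage_seeds(seed)
  outdir <- outdir %||% config$output$directory
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- artifact_meta(config, seed)
  fp <- function(name) file.path(outdir, name)

  network <- config_network(config)
  input <- config_input(config)
  setup <- config_setup(config, network)
  subset <- design_subset(network, unlist(config$algorithm$design_parameters))
  kernel <- if (length(config$spec$features))
    config_kernel(config, network) else NULL
  files <- character(0)
  out <- list()

  if (command == "simulate") {
    traj <- simulate_network(network, setup = setup, input = input)
    sm_write_csv(as.data.frame(traj), fp("trajectory.csv"), meta)
    files <- "trajectory.csv"
    out$trajectory <- traj
  }

  if (command %in% c("features", "linearize", "invert", "cover") &&
      is.null(kernel))
    stop("command '", command, "' needs spec$features in the configuration")

  if (command == "features") {
    traj <- simulate_network(network, setup = setup, input = input)
    f <- evaluate_features(traj, kernel)
    sm_write_json(list(features = f), fp("features.json"), meta)
    sm_write_csv(data.frame(feature = paste0("psi", seq_along(f)),
                            value = f),
                 fp("features.csv"), meta)
    files <- c("features.json", "features.csv")
    out$features <- f
  }

  if (command == "linearize") {
    lin <- linearize(network, kernel, setup = setup, input = input,
                     subset = subset)
    sm_write_json(linmap_to_list(lin), fp("linmap.json"), meta)
    files <- "linmap.json"
    out$linmap <- lin
  }

  if (command == "invert") {
    if (is.null(config$algorithm$eps)) stop("invert needs algorithm$eps")
    lin <- linearize(network, kernel, setup = setup, input = input,
                     subset = subset)
    pinv <- pseudo_inverse(lin$L)
    diam <- if (!is.null(config$algorithm$region))
      config_region(config)$diam else vnorm(lin$f0)
    delta_cap <- config$algorithm$delta_cap %||% (diam / 2)
    grid <- delta_cap * rev(1 / 2^(seq_len(config$algorithm$rho$n_delta) - 1))
    rho <- estimate_rho(network, kernel, lin, grid,
                        n_samples = config$algorithm$rho$n_samples,
                        seed = seeds$rho, setup = setup, input = input,
                        subset = subset, pinv = pinv)
    delta <- max_ball_radius(rho, pinv, config$algorithm$eps, delta_cap)
    ell <- map_ball(pinv, feature_ball(lin$f0, delta), lin$k0_design)
    smp <- sample_ellipsoid(ell, max(config$algorithm$n_err_samples, 20),
                            seed = seeds$samples)
    sm_write_json(c(linmap_to_list(lin),
                    list(rho = list(delta_grid = rho$delta_grid,
                                    rho_values = rho$rho_values),
                         eps = config$algorithm$eps, delta = delta)),
                  fp("linmap.json"), meta)
    sm_write_json(ellipsoid_to_list(ell), fp("ellipsoid.json"), meta)
    df <- as.data.frame(unclass(smp)[seq_len(nrow(smp)), , drop = FALSE])
    names(df) <- subset$names
    sm_write_csv(df, fp("samples.csv"), meta)
    files <- c("linmap.json", "ellipsoid.json", "samples.csv")
    out <- c(out, list(linmap = lin, rho = rho, delta = delta,
                       ellipsoid = ell))
  }

  if (command == "cover") {
    if (is.null(config$algorithm$eps)) stop("cover needs algorithm$eps")
    region <- config_region(config)
    res <- cover_region(
      region, network, kernel, eps = config$algorithm$eps,
      max_balls = config$algorithm$max_balls, seed = seeds$cover,
      setup = setup, input = input, subset = subset,
      rho_config = config$algorithm$rho,
      delta_cap = config$algorithm$delta_cap,
      delta_min_frac = config$algorithm$delta_min_frac,
      coverage_target = config$algorithm$coverage_target,
      n_mc = config$algorithm$n_mc,
      gn_tol_frac = config$algorithm$gn_tol_frac,
      n_err_samples = config$algorithm$n_err_samples)
    sm_write_json(list(balls = lapply(res$balls, function(b)
      list(center = b$center, radius = b$radius))),
      fp("balls.json"), meta)
    sm_write_json(list(ellipsoids = lapply(res$ellipsoids,
                                           ellipsoid_to_list)),
                  fp("ellipsoids.json"), meta)
    sm_write_json(list(coverage_fraction = res$coverage_fraction,
                       coverage_se = res$coverage_se,
                       n_balls = res$n_balls, n_mc = res$n_mc,
                       eps = res$eps, seed = seed,
                       complete = res$complete),
                  fp("coverage_report.json"), meta)
    smp <- do.call(rbind, lapply(res$ellipsoids, function(e)
      tryCatch(sample_ellipsoid(e, config$algorithm$n_err_samples,
                                seed = seeds$samples),
               error = function(err) NULL)))
    if (!is.null(smp)) {
      df <- as.data.frame(smp)
      names(df) <- subset$names
      sm_write_csv(df, fp("samples.csv"), meta)
      files <- c(files, "samples.csv")
    }
    files <- c("balls.json", "ellipsoids.json", "coverage_report.json", files)
    out$coverage <- res
    sm_log("INFO", "coverage %.4f with %d balls",
           res$coverage_fraction, res$n_balls)
  }

  out$files <- file.path(outdir, files)
  invisible(out)
}

#' Case-study configuration
#'
#' Path of (or the parsed) configuration for the shipped sensor case study:
#' the five-state sensor construct under a rectangular inhibitor pulse, two
#' weighted squared-deviation features (monomer and dimer), design rates
#' `k7` and `k9`, and the rectangular specification region used by the
#' covering experiment.
#'
#' @param parsed if `TRUE` (default) return the validated `run_config`;
#'   otherwise the file path.
#' @return a `run_config` or a path.
#' @export
sensor_case_study <- function(parsed = TRUE) {
  path <- system.file("extdata", "sensor_case_study.yaml",
                      package = "specmap", mustWork = TRUE)
  if (parsed) load_config(path) else path
}
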