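#' Load a pipeline configuration
#'
#' Configurations are YAML files (or plain named lists) with blocks
#' matching the pipeline stages: `population`, `imaging`, `model`,
#' `detection`, `stats`, plus run-level fields (`seed`, `frame_times`,
#' `fractions`, paths). Every run writes its fully resolved
#' configuration, including the seed, as JSON next to its outputs.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Named list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

resolve_block <- function(config, name, constructor) {
  args <- config[[name]]
  if (is.null(args)) args <- list()
  do.call(constructor, args)
}

write_provenance <- function(outdir, config, seed, command) {
  path <- file.path(outdir, paste0(command, "_config.json"))
  jsonlite::write_json(c(list(command = command, seed = seed), config),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Synthesize a droplet image dataset
#'
#' Generates a seeded droplet population, renders one frame per requested
#' time at the prescribed assembled fractions (either an explicit
#' `fractions` vector or a kinetic trajectory simulated from the `model`
#' block), and writes TIFFs, ground truth, manifest, and provenance to
#' `outdir`.
#'
#' @param config Configuration (list or YAML path) with blocks
#'   `population` (arguments of [sample_droplet_population()]), `imaging`
#'   ([imaging_params()]), and either `fractions` + `frame_times` or
#'   `model` (arguments of [rate_params()] plus `t_end`,
#'   `active_fraction`, `R0`) + `frame_times`; optional
#'   `fraction_jitter_sdlog`.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Master seed (overrides `config$seed`).
#' @return Invisibly, the written paths (see [write_frames()]).
#' @export
run_synthesize <- function(config, outdir = NULL, seed = NULL) {
  config <- load_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no outdir given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pop_args <- config$population %||% list()
  pop_args$seed <- derive_seed(seed, "population-stage")
  pop <- do.call(sample_droplet_population, pop_args)
  imaging <- resolve_block(config, "imaging", imaging_params)
  imaging$rng_seed <- derive_seed(seed, "imaging-stage")
  frame_times <- config$frame_times %||% 0
  if (!is.null(config$model)) {
    margs <- config$model
    t_end <- margs$t_end %||% max(frame_times)
    active_fraction <- margs$active_fraction %||% 0
    R0 <- margs$R0 %||% 0
    margs[c("t_end", "active_fraction", "R0", "n_points")] <- NULL
    params <- do.call(rate_params, margs)
    traj <- simulate_assembly(
      params, initial_state(params, active_fraction = active_fraction,
                            R0 = R0),
      t_end = t_end, n_points = config$model$n_points %||% 401)
  } else {
    fr <- config$fractions %||% 0
    fr <- rep_len(fr, length(frame_times))
    traj <- data.frame(time = frame_times, f = fr)
    if (length(frame_times) == 1L) {
      traj <- rbind(traj, data.frame(time = frame_times + 1, f = fr))
    }
  }
  frames <- render_timeseries(
    traj, pop, imaging, frame_times,
    fraction_jitter_sdlog = config$fraction_jitter_sdlog %||% 0.2,
    seed = derive_seed(seed, "render-stage"))
  paths <- write_frames(frames, outdir,
                        prefix = config$prefix %||% "frame",
                        extra = list(seed = seed))
  write_provenance(outdir, config, seed, "synthesize")
  invisible(paths)
}

#' Analyze an image series into condensation statistics
#'
#' Detects droplets in every frame of a series, computes per-droplet
#' skewness/kurtosis, aggregates population mean +/- SD per time point,
#' and writes two CSVs (per-droplet rows and per-timepoint rows), an
#' exclusion log, and provenance.
#'
#' @param config Configuration with `indir` (a directory produced by
#'   [run_synthesize()]) or `manifest` (path to a manifest CSV), an
#'   optional `detection` block ([detection_config()]), and optional
#'   `mode`, `bin_width`, `subsample`.
#' @param outdir Output directory.
#' @param seed Seed for the optional random droplet subsampling.
#' @return Invisibly, the [analyze_frames()] result.
#' @export
run_analyze <- function(config, outdir = NULL, seed = NULL) {
  config <- load_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no outdir given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- config$manifest %||% {
    ind <- config$indir %||% stop("config needs 'indir' or 'manifest'")
    hits <- list.files(ind, pattern = "_manifest\\.csv$",
                       full.names = TRUE)
    if (length(hits) == 0L) stop("no *_manifest.csv found in ", ind)
    hits[1L]
  }
  series <- read_frame_series(manifest)
  det_cfg <- resolve_block(config, "detection", detection_config)
  res <- analyze_frames(series$images, det_cfg, times = series$times,
                        mode = config$mode %||% "unique",
                        bin_width = config$bin_width %||% 1,
                        subsample = config$subsample %||% Inf,
                        seed = seed)
  per_frame_det <- do.call(rbind, lapply(res$detections, function(d) {
    d$pixel_values <- NULL
    d
  }))
  write.csv(per_frame_det,
            file.path(outdir, "detections.csv"), row.names = FALSE)
  write.csv(res$per_droplet,
            file.path(outdir, "per_droplet_moments.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$timecourse),
            file.path(outdir, "timecourse.csv"), row.names = FALSE)
  excl <- res$per_droplet[!is.na(res$per_droplet$excluded_reason), ,
                          drop = FALSE]
  write.csv(excl, file.path(outdir, "excluded_droplets.csv"),
            row.names = FALSE)
  write_provenance(outdir, config, seed, "analyze")
  invisible(res)
}

#' Simulate the assembly model (optionally sweeping a parameter)
#'
#' Integrates the tile-assembly ODE model from a configuration, writes
#' the trajectory CSV and pulse-metrics JSON, and, when a `sweep` block
#' is present, a tidy long-format CSV over the swept values. With a
#' `render` block, additionally renders a synthetic image series that
#' follows the simulated trajectory (a full in silico experiment).
#'
#' @param config Configuration with a `model` block ([rate_params()]
#'   arguments plus `t_end`, `n_points`, `active_fraction`, `R0`,
#'   `threshold`), optional `sweep` (`name`, `values`), optional `render`
#'   (blocks `population`, `imaging`, `frame_times`).
#' @param outdir Output directory.
#' @param seed Seed used only by the optional render stage.
#' @return Invisibly, a list with `sim`, `metrics`, and optionally
#'   `sweep` and render paths.
#' @export
run_simulate <- function(config, outdir = NULL, seed = NULL) {
  config <- load_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no outdir given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  margs <- config$model %||% list()
  t_end <- margs$t_end %||% 600
  n_points <- margs$n_points %||% 401
  active_fraction <- margs$active_fraction %||% 0
  R0 <- margs$R0 %||% 0
  threshold <- margs$threshold %||% 0.1
  margs[c("t_end", "n_points", "active_fraction", "R0", "threshold")] <- NULL
  params <- do.call(rate_params, margs)
  init <- initial_state(params, active_fraction = active_fraction, R0 = R0)
  sim <- simulate_assembly(params, init, t_end = t_end,
                           n_points = n_points)
  metrics <- pulse_metrics(sim, threshold)
  write_trajectory_csv(sim, file.path(outdir, "trajectory.csv"))
  jsonlite::write_json(
    list(metrics = unclass(metrics), params = unclass(params)),
    file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  out <- list(sim = sim, metrics = metrics)
  if (!is.null(config$sweep)) {
    sw <- sweep_parameter(params, config$sweep$name, config$sweep$values,
                          t_end = t_end, n_points = n_points,
                          threshold = threshold,
                          active_fraction = active_fraction, R0 = R0)
    long <- do.call(rbind, lapply(sw, function(s) {
      df <- as.data.frame(s$sim)
      df[[config$sweep$name]] <- s$value
      df
    }))
    write.csv(long, file.path(outdir, "sweep_trajectories.csv"),
              row.names = FALSE)
    write.csv(sweep_summary(sw, config$sweep$name),
              file.path(outdir, "sweep_metrics.csv"), row.names = FALSE)
    out$sweep <- sw
  }
  if (!is.null(config$render)) {
    rc <- config$render
    rc$model <- NULL
    pop_args <- rc$population %||% list()
    pop_args$seed <- derive_seed(seed, "render-population")
    pop <- do.call(sample_droplet_population, pop_args)
    imaging <- do.call(imaging_params, rc$imaging %||% list())
    frame_times <- rc$frame_times %||%
      seq(0, t_end, length.out = 6)
    frames <- render_timeseries(
      sim, pop, imaging, frame_times,
      fraction_jitter_sdlog = rc$fraction_jitter_sdlog %||% 0.2,
      seed = derive_seed(seed, "render-stage"))
    out$render_paths <- write_frames(frames, outdir, prefix = "sim_frame",
                                     extra = list(seed = seed))
  }
  write_provenance(outdir, config, seed, "simulate")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
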