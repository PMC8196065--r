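#' Summarize one droplet's pixel distribution as condensation moments
#'
#' Computes the per-droplet skewness and excess kurtosis that track
#' nanotube condensation. Two modes are available:
#' \describe{
#'   \item{`"unique"` (default)}{The pixel sample is first reduced to its
#'     unique binned brightness values ([unique_value_reduction()]), and
#'     the moments are computed over that list. Discarding occupancy
#'     weights emphasizes the appearance of new bright intensity levels
#'     (condensed filaments) over how many pixels carry them.}
#'   \item{`"pixels"`}{Standard occupancy-weighted moments over all
#'     interior pixels. Statistically conventional; recommended when
#'     comparing against analytic distributions.}
#' }
#' The two modes genuinely differ (the unique reduction flattens the
#' histogram), so the mode is recorded in the output and population
#' summaries must never mix modes.
#'
#' Droplets whose reduced sample is degenerate (fewer than 4 values, or
#' zero variance, as in a fully uniform interior) are returned with
#' `excluded_reason` set instead of moments.
#'
#' @param droplet One row of a [detect_droplets()] result (or any list
#'   with `pixel_values`, `droplet_id`, `frame_index`), or a bare numeric
#'   vector of pixel values.
#' @param mode `"unique"` or `"pixels"`.
#' @param bin_width Bin width (gray levels) for the unique reduction.
#' @param bias_correct Use bias-corrected G1/G2 estimators (default) or
#'   plain moment estimators.
#' @return A one-row data.frame (class `moment_summary`): `droplet_id`,
#'   `frame_index`, `n_values`, `mean_intensity`, `sd_intensity`,
#'   `skewness`, `excess_kurtosis`, `mode`, `excluded_reason` (NA when
#'   valid).
#' @examples
#' summarize_droplet(c(10, 10, 11, 12, 40, 10, 11), mode = "pixels")
#' @export
summarize_droplet <- function(droplet, mode = c("unique", "pixels"),
                              bin_width = 1, bias_correct = TRUE) {
  mode <- match.arg(mode)
  if (is.numeric(droplet)) {
    droplet <- list(pixel_values = droplet, droplet_id = 1L,
                    frame_index = 1L)
  }
  vals <- if (is.data.frame(droplet)) droplet$pixel_values[[1L]]
    else droplet$pixel_values
  id <- as.integer(droplet$droplet_id[1])
  fidx <- as.integer(droplet$frame_index[1])
  out <- data.frame(droplet_id = id, frame_index = fidx,
                    n_values = NA_integer_, mean_intensity = NA_real_,
                    sd_intensity = NA_real_, skewness = NA_real_,
                    excess_kurtosis = NA_real_, mode = mode,
                    excluded_reason = NA_character_)
  class(out) <- c("moment_summary", "data.frame")
  if (length(vals) == 0L) {
    out$excluded_reason <- "no pixels"
    return(out)
  }
  x <- if (mode == "unique") unique_value_reduction(vals, bin_width)
    else as.numeric(vals)
  out$n_values <- length(x)
  if (length(x) < 4L) {
    out$excluded_reason <- "too few values"
    return(out)
  }
  if (max(x) == min(x)) {
    out$excluded_reason <- "zero variance"
    return(out)
  }
  out$mean_intensity <- mean(x)
  out$sd_intensity <- sd(x)
  out$skewness <- sample_skewness(x, bias_correct)
  out$excess_kurtosis <- sample_excess_kurtosis(x, bias_correct)
  out
}

#' Summarize every droplet detected in a frame
#'
#' @param detections A [detect_droplets()] result.
#' @inheritParams summarize_droplet
#' @return data.frame with one row per detection (see
#'   [summarize_droplet()]), including excluded droplets with their
#'   reasons.
#' @export
summarize_frame <- function(detections, mode = c("unique", "pixels"),
                            bin_width = 1, bias_correct = TRUE) {
  mode <- match.arg(mode)
  if (nrow(detections) == 0L) {
    return(summarize_droplet(numeric(0), mode, bin_width)[0, ])
  }
  do.call(rbind, lapply(seq_len(nrow(detections)), function(i) {
    summarize_droplet(detections[i, ], mode, bin_width, bias_correct)
  }))
}

#' Aggregate per-droplet moments into a population time point
#'
#' Reports the unweighted mean and sample standard deviation (n-1
#' denominator) of skewness and excess kurtosis over the valid droplets
#' of one frame, the machine-readable equivalent of one point in a
#' mean +/- SD condensation timecourse. Excluded droplets are counted but
#' do not contribute. For a single valid droplet the SD is reported as 0
#' and flagged (`single_droplet`), keeping downstream tables numeric.
#'
#' @param summaries data.frame from [summarize_frame()].
#' @param time_min Acquisition time of the frame (minutes).
#' @return One-row data.frame (class `population_timepoint`): `time_min`,
#'   `n_droplets`, `n_excluded`, `mean_skewness`, `sd_skewness`,
#'   `mean_kurtosis`, `sd_kurtosis`, `single_droplet`.
#' @examples
#' s <- data.frame(skewness = c(0.5, 1.5), excess_kurtosis = c(0, 1),
#'                 excluded_reason = NA)
#' aggregate_population(s, time_min = 30)
#' @export
aggregate_population <- function(summaries, time_min) {
  valid <- summaries[is.na(summaries$excluded_reason), , drop = FALSE]
  n <- nrow(valid)
  if (n == 0L) {
    stop("no valid droplets at time ", time_min, " min")
  }
  out <- data.frame(
    time_min = time_min,
    n_droplets = n,
    n_excluded = nrow(summaries) - n,
    mean_skewness = mean(valid$skewness),
    sd_skewness = if (n > 1L) sd(valid$skewness) else 0,
    mean_kurtosis = mean(valid$excess_kurtosis),
    sd_kurtosis = if (n > 1L) sd(valid$excess_kurtosis) else 0,
    single_droplet = n == 1L)
  class(out) <- c("population_timepoint", "data.frame")
  out
}

#' Assemble population time points into a condensation timecourse
#'
#' @param timepoints List of [aggregate_population()] rows (or a
#'   data.frame of them), one per frame.
#' @return data.frame of class `condensation_timecourse`, sorted by
#'   strictly increasing `time_min`. Duplicate time stamps are an error
#'   (frames must map to distinct acquisition times).
#' @export
build_timecourse <- function(timepoints) {
  if (is.data.frame(timepoints)) tp <- timepoints
  else tp <- do.call(rbind, timepoints)
  if (is.null(tp) || nrow(tp) == 0L) stop("no timepoints")
  if (anyDuplicated(tp$time_min)) {
    stop("duplicate time stamps: ",
         paste(tp$time_min[duplicated(tp$time_min)], collapse = ", "))
  }
  tp <- tp[order(tp$time_min), , drop = FALSE]
  rownames(tp) <- NULL
  class(tp) <- c("condensation_timecourse", "data.frame")
  tp
}

#' Analyze a series of rendered or loaded frames into a timecourse
#'
#' Convenience wrapper running detection, per-droplet moments, and
#' population aggregation over a list of frames.
#'
#' @param frames List of `rendered_frame` objects, or a list of plain
#'   matrices (then `times` must be given).
#' @param config A [detection_config()].
#' @param times Frame times in minutes (defaults to each frame's
#'   `time_min`).
#' @param mode,bin_width Passed to [summarize_frame()].
#' @param subsample Optionally analyze at most this many randomly chosen
#'   droplets per frame (emulating the random per-timepoint sampling of
#'   the acquisition protocol); `Inf` analyzes all.
#' @param seed Seed for the optional subsampling.
#' @return List: `timecourse` (a [build_timecourse()] data.frame),
#'   `per_droplet` (all moment summaries), `detections` (per-frame
#'   detection tables).
#' @export
analyze_frames <- function(frames, config = detection_config(),
                           times = NULL, mode = c("unique", "pixels"),
                           bin_width = 1, subsample = Inf, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(times)) {
    times <- vapply(frames, function(f) {
      if (is.list(f) && !is.null(f$time_min)) f$time_min else NA_real_
    }, numeric(1))
  }
  if (anyNA(times)) stop("frame times missing: supply `times`")
  dets <- vector("list", length(frames))
  sums <- vector("list", length(frames))
  tps <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    img <- if (is.list(frames[[k]])) frames[[k]]$image else frames[[k]]
    det <- detect_droplets(img, config, frame_index = k)
    if (nrow(det) > 0L && is.finite(subsample) && nrow(det) > subsample) {
      pick <- with_seed(derive_seed(seed, k),
                        sample.int(nrow(det), subsample))
      det <- det[sort(pick), , drop = FALSE]
    }
    dets[[k]] <- det
    if (nrow(det) == 0L) next
    s <- summarize_frame(det, mode, bin_width)
    sums[[k]] <- s
    tps[[k]] <- tryCatch(aggregate_population(s, times[k]),
                         error = function(e) NULL)
  }
  tps <- tps[!vapply(tps, is.null, logical(1))]
  if (length(tps) == 0L) stop("no droplets detected in any frame")
  list(timecourse = build_timecourse(tps),
       per_droplet = do.call(rbind, sums),
       detections = dets)
}
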