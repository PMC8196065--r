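#' Plot a condensation timecourse
#'
#' Mean skewness (solid) and mean excess kurtosis (dashed) against time,
#' each with +/- SD whiskers — the standard visualization of droplet
#' condensation experiments.
#'
#' @param x A `condensation_timecourse` from [build_timecourse()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.condensation_timecourse <- function(x, ...) {
  rng <- range(c(x$mean_skewness - x$sd_skewness,
                 x$mean_skewness + x$sd_skewness,
                 x$mean_kurtosis - x$sd_kurtosis,
                 x$mean_kurtosis + x$sd_kurtosis))
  graphics::plot(x$time_min, x$mean_skewness, type = "b", pch = 16,
                 ylim = rng, xlab = "time (min)",
                 ylab = "population moment", ...)
  graphics::arrows(x$time_min, x$mean_skewness - x$sd_skewness,
                   x$time_min, x$mean_skewness + x$sd_skewness,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(x$time_min, x$mean_kurtosis, type = "b", pch = 18,
                  lty = 2)
  graphics::arrows(x$time_min, x$mean_kurtosis - x$sd_kurtosis,
                   x$time_min, x$mean_kurtosis + x$sd_kurtosis,
                   angle = 90, code = 3, length = 0.03, lty = 2)
  graphics::legend("topleft", c("skewness", "excess kurtosis"),
                   lty = c(1, 2), pch = c(16, 18), bty = "n")
  invisible(x)
}

#' Plot an assembly-model trajectory
#'
#' Fraction of assembled tiles against time.
#'
#' @param x An `assembly_sim` from [simulate_assembly()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.assembly_sim <- function(x, ...) {
  graphics::plot(x$time, x$f, type = "l", xlab = "time (min)",
                 ylab = "fraction of assembled tiles", ylim = c(0, 1),
                 ...)
  invisible(x)
}
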