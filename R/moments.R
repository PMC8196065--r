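#' Sample skewness of a pixel-intensity sample
#'
#' Skewness measures the asymmetry of the distribution of pixel brightness
#' about its mean. For droplets filled with dispersed free tiles the
#' interior brightness is close to symmetric and skewness is near zero; as
#' tiles condense into nanotubes a bright tail appears and skewness grows.
#' The default estimator is the bias-corrected sample skewness
#' \deqn{G_1 = \frac{n^2}{(n-1)(n-2)} \frac{m_3}{s^3},}
#' where \eqn{m_3} is the third central moment (denominator \eqn{n}) and
#' \eqn{s} the sample standard deviation (denominator \eqn{n-1}). This is
#' the convention used by common data-analysis libraries, so values are
#' directly comparable with published droplet timecourses. Set
#' `bias_correct = FALSE` for the plain moment estimator
#' \eqn{b_1 = m_3 / m_2^{3/2}}.
#'
#' Both estimators are exactly invariant under positive affine rescaling
#' `v -> a*v + b` (`a > 0`) of the input, which is what makes the statistic
#' insensitive to exposure time as long as no pixel saturates.
#'
#' @param values Numeric vector of at least 3 values with positive variance.
#' @param bias_correct Use the bias-corrected `G1` estimator (default) or
#'   the plain moment estimator.
#' @return Skewness (dimensionless scalar).
#' @seealso [sample_excess_kurtosis()], [summarize_droplet()]
#' @examples
#' sample_skewness(c(1, 2, 3, 4, 5)) # symmetric -> 0
#' sample_skewness(rexp(1e4))        # ~ 2
#' @export
sample_skewness <- function(values, bias_correct = TRUE) {
  values <- check_moment_input(values, min_n = 3L)
  n <- length(values)
  d <- values - mean(values)
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  if (bias_correct) {
    s <- sqrt(sum(d^2) / (n - 1))
    n^2 / ((n - 1) * (n - 2)) * m3 / s^3
  } else {
    m3 / m2^1.5
  }
}

#' Sample excess kurtosis of a pixel-intensity sample
#'
#' Excess kurtosis measures the "tailedness" of the pixel-brightness
#' distribution relative to a normal distribution (Fisher convention: a
#' normal sample gives 0). Unpolymerized droplet interiors give near-zero
#' or slightly negative values; localized bright nanotubes produce heavy
#' right tails and large positive values. The default is the bias-corrected
#' estimator
#' \deqn{G_2 = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \frac{\sum d_i^4}{s^4}
#'   - 3\frac{(n-1)^2}{(n-2)(n-3)},}
#' matching common data-analysis libraries. `bias_correct = FALSE` gives
#' the plain estimator \eqn{b_2 = m_4/m_2^2 - 3}.
#'
#' @inheritParams sample_skewness
#' @param values Numeric vector of at least 4 values with positive variance.
#' @return Excess kurtosis (dimensionless scalar; normal -> 0).
#' @examples
#' sample_excess_kurtosis(rnorm(1e4))  # ~ 0
#' sample_excess_kurtosis(runif(1e4))  # ~ -1.2
#' @export
sample_excess_kurtosis <- function(values, bias_correct = TRUE) {
  values <- check_moment_input(values, min_n = 4L)
  n <- length(values)
  d <- values - mean(values)
  if (bias_correct) {
    s2 <- sum(d^2) / (n - 1)
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(d^4) / s2^2 -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else {
    mean(d^4) / mean(d^2)^2 - 3
  }
}

check_moment_input <- function(values, min_n) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("pixel values contain NA")
  n <- length(values)
  if (n < min_n) {
    stop(sprintf("need at least %d values, got %d", min_n, n))
  }
  if (max(values) == min(values)) {
    stop("zero variance: moments undefined for a constant sample")
  }
  values
}

#' Reduce a pixel sample to its unique binned brightness values
#'
#' Histograms the pixel values with a fixed bin width (bins anchored at
#' zero, value assigned by its left bin edge) and returns the sorted left
#' edges of all occupied bins, each exactly once. Occupancy weights are
#' discarded, so a value observed in one pixel counts the same as a value
#' observed in a thousand pixels. This reduction is the basis of the
#' `"unique"` moment mode of [summarize_droplet()]; see that help page for
#' a discussion of how it differs from ordinary occupancy-weighted moments.
#'
#' @param values Numeric vector of pixel values (non-empty).
#' @param bin_width Histogram bin width in gray levels (> 0, default 1).
#' @return Sorted numeric vector of unique occupied-bin left edges.
#' @examples
#' unique_value_reduction(c(5, 5, 5, 7)) # c(5, 7)
#' @export
unique_value_reduction <- function(values, bin_width = 1) {
  if (length(values) == 0L) stop("empty pixel sample")
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  values <- as.numeric(values)
  if (anyNA(values)) stop("pixel values contain NA")
  sort(unique(floor(values / bin_width)) * bin_width)
}
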