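# Independent direct-formula oracles for the moment estimators. These are
# deliberately written from the textbook definitions (explicit loops over
# central moments) and share no code with the package implementation.

oracle_g1 <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  m3 <- sum((x - xb)^3) / n
  s <- sqrt(sum((x - xb)^2) / (n - 1))
  n^2 / ((n - 1) * (n - 2)) * m3 / s^3
}

oracle_g2 <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  s2 <- sum((x - xb)^2) / (n - 1)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum((x - xb)^4) / s2^2 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# brute-force unique-binned-value reduction: enumerate occupied histogram
# bins directly
oracle_unique_bins <- function(x, w) {
  bins <- unique(floor(x / w))
  sort(bins * w)
}

# standard error of a statistic estimated by splitting a sample into
# blocks (conservative: block-level estimates are noisier than the full-
# sample estimate)
block_se <- function(x, stat, nblocks = 100) {
  n <- length(x)
  idx <- rep(seq_len(nblocks), length.out = n)
  vals <- vapply(seq_len(nblocks), function(b) stat(x[idx == b]),
                 numeric(1))
  sd(vals) / sqrt(nblocks)
}

# small rendered scene shared across detection/stats tests
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- sample_droplet_population(8, c(320, 320), c(6, 14),
                                       seed = 42,
                                       assembled_fraction = 0.3)
      cache <<- render_frame(pop, imaging_params(rng_seed = 42))
    }
    cache
  }
})
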