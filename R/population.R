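#' Sample a non-overlapping droplet population
#'
#' Draws a population of water-in-oil droplets as produced by the vortex
#' ("shaken") emulsification protocol, which yields a broad radius
#' distribution of roughly 1 to >20 micrometers. Radii are drawn
#' log-uniformly over `radius_range_um` (the protocol constrains only the
#' range, and a log-uniform law spreads droplets evenly across size
#' decades); centers are placed by rejection sampling so that no two
#' droplet disks overlap and no disk touches the border margin.
#'
#' Per-droplet encapsulated tile amounts are jittered by a multiplicative
#' lognormal factor (`partition_sdlog`) emulating partitioning noise: the
#' unequal encapsulation of reagents across droplets, strongest in small
#' volumes. Set it to 0 for identical loading.
#'
#' Coordinates are 1-based `(row, col)` pixel indices, matching R matrix
#' indexing; `radius_px = radius_um / pixel_size_um` is kept real-valued
#' (no rounding).
#'
#' @param n Number of droplets (>= 0).
#' @param frame_shape Integer vector `c(rows, cols)` of the target frame.
#' @param radius_range_um Radius range in micrometers, `c(min, max)`,
#'   min > 0.
#' @param pixel_size_um Pixel size (micrometers per pixel).
#' @param seed Integer seed; the population is reproducible from it.
#' @param tile_total Nominal encapsulated tile budget per droplet
#'   (nM-equivalent brightness budget).
#' @param assembled_fraction Initial assembled fraction assigned to every
#'   droplet (in `[0, 1]`).
#' @param partition_sdlog Lognormal sdlog of the partitioning-noise factor
#'   applied to `tile_total` (0 disables).
#' @param surface_localized Logical; mark droplets whose nanotubes wrap
#'   along the inner surface (rendered as annulus-confined filaments).
#' @param border_margin_px Margin (pixels) that no droplet disk may enter.
#' @param min_gap_px Minimum clearance between droplet rims (pixels).
#' @param max_attempts Rejection-sampling attempts per droplet before the
#'   placement fails with an error naming how many droplets were placed.
#' @return A data.frame of class `droplet_population` with one row per
#'   droplet: `droplet_id`, `center_row`, `center_col`, `radius_um`,
#'   `radius_px`, `tile_total`, `assembled_fraction`, `surface_localized`.
#'   The frame shape and pixel size are attached as attributes
#'   `frame_shape` and `pixel_size_um`.
#' @examples
#' pop <- sample_droplet_population(20, c(512, 512), c(5, 20), seed = 1)
#' range(pop$radius_px)
#' @export
sample_droplet_population <- function(n, frame_shape,
                                      radius_range_um = c(1, 20),
                                      pixel_size_um = 1, seed = 1L,
                                      tile_total = 500,
                                      assembled_fraction = 0,
                                      partition_sdlog = 0.2,
                                      surface_localized = FALSE,
                                      border_margin_px = 4,
                                      min_gap_px = 2,
                                      max_attempts = 5000L) {
  stopifnot(n >= 0, length(frame_shape) == 2L,
            length(radius_range_um) == 2L, radius_range_um[1] > 0,
            radius_range_um[2] >= radius_range_um[1],
            pixel_size_um > 0,
            assembled_fraction >= 0, assembled_fraction <= 1)
  max_r_px <- radius_range_um[2] / pixel_size_um
  if (any(frame_shape < 2 * (max_r_px + border_margin_px) + 1) && n > 0) {
    stop("frame too small to place a droplet of maximum radius ",
         radius_range_um[2], " um")
  }
  empty <- data.frame(droplet_id = integer(), center_row = numeric(),
                      center_col = numeric(), radius_um = numeric(),
                      radius_px = numeric(), tile_total = numeric(),
                      assembled_fraction = numeric(),
                      surface_localized = logical())
  if (n == 0L) {
    return(structure(empty, frame_shape = as.integer(frame_shape),
                     pixel_size_um = pixel_size_um,
                     class = c("droplet_population", "data.frame")))
  }
  pop <- with_seed(derive_seed(seed, "population"), {
    r_um <- exp(runif(n, log(radius_range_um[1]), log(radius_range_um[2])))
    r_um <- sort(r_um, decreasing = TRUE) # place big droplets first
    r_px <- r_um / pixel_size_um
    rows <- cols <- numeric(n)
    for (i in seq_len(n)) {
      lo_r <- 1 + border_margin_px + r_px[i]
      hi_r <- frame_shape[1] - border_margin_px - r_px[i]
      lo_c <- 1 + border_margin_px + r_px[i]
      hi_c <- frame_shape[2] - border_margin_px - r_px[i]
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          d2 <- (rows[j] - cand[1])^2 + (cols[j] - cand[2])^2
          ok <- all(d2 > (r_px[j] + r_px[i] + min_gap_px)^2)
        }
        if (ok) { rows[i] <- cand[1]; cols[i] <- cand[2]; placed <- TRUE; break }
      }
      if (!placed) {
        stop(sprintf(
          "droplet placement failed after %d attempts: placed %d of %d droplets",
          max_attempts, i - 1L, n))
      }
    }
    tt <- tile_total *
      if (partition_sdlog > 0) rlnorm(n, -partition_sdlog^2 / 2, partition_sdlog)
      else rep(1, n)
    data.frame(droplet_id = seq_len(n), center_row = rows, center_col = cols,
               radius_um = r_um, radius_px = r_px, tile_total = tt,
               assembled_fraction = assembled_fraction,
               surface_localized = surface_localized)
  })
  structure(pop, frame_shape = as.integer(frame_shape),
            pixel_size_um = pixel_size_um,
            class = c("droplet_population", "data.frame"))
}
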