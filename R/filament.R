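#' Simulate a confined worm-like-chain filament inside a droplet
#'
#' Grows a discrete worm-like chain emulating a DNA nanotube (or bundle)
#' confined to a droplet's equatorial disk. Successive segments of length
#' `step_um` turn by Gaussian angles with variance `2 * step_um /
#' persistence_um`, so the mean cosine of the turning angle is
#' `exp(-step_um / persistence_um)` (the 2D worm-like-chain tangent
#' correlation; DNA nanotube persistence lengths are of order 4-5 um).
#' The chain is confined by specular reflection at the disk boundary
#' (shrunk by one step). In `surface_localized` mode the chain is instead
#' confined to an annulus spanning 0.85-1.0 of the droplet radius,
#' emulating nanotube bundles that wrap along the inner droplet surface.
#'
#' @param droplet One-row data.frame (a [sample_droplet_population()] row)
#'   with `center_row`, `center_col`, `radius_px`, and optionally
#'   `surface_localized`.
#' @param length_um Total contour length to grow (micrometers, > 0).
#' @param persistence_um Persistence length (micrometers, > 0).
#' @param step_um Discretization step (micrometers).
#' @param pixel_size_um Pixel size (micrometers per pixel).
#' @param seed Integer seed.
#' @param surface_localized Override the droplet's surface flag.
#' @return A `filament_path`: list with `vertices` (matrix of sub-pixel
#'   `(row, col)` frame coordinates), `step_um`, `persistence_um`.
#' @examples
#' pop <- sample_droplet_population(1, c(128, 128), c(10, 10), seed = 1)
#' fil <- simulate_filament(pop[1, ], length_um = 20, seed = 2)
#' nrow(fil$vertices)
#' @export
simulate_filament <- function(droplet, length_um, persistence_um = 4.5,
                              step_um = 0.1, pixel_size_um = 1, seed = 1L,
                              surface_localized = NULL) {
  stopifnot(length_um > 0, step_um > 0, pixel_size_um > 0)
  if (persistence_um <= 0) stop("persistence_um must be > 0")
  r_px <- droplet$radius_px
  step_px <- step_um / pixel_size_um
  if (r_px <= step_px) stop("droplet radius must exceed one step")
  surface <- if (is.null(surface_localized)) {
    isTRUE(droplet$surface_localized)
  } else surface_localized
  r_out <- r_px - step_px
  r_in <- if (surface) 0.85 * r_px else 0
  r_out <- if (surface) min(r_out, r_px) else r_out
  n_steps <- max(1L, ceiling(length_um / step_um))
  sd_turn <- sqrt(2 * step_um / persistence_um)
  ctr <- c(droplet$center_row, droplet$center_col)

  with_seed(derive_seed(seed, "filament"), {
    # start point uniform over the allowed region
    rad0 <- sqrt(runif(1, (r_in / r_out)^2, 1)) * r_out
    ang0 <- runif(1, 0, 2 * pi)
    pos <- rad0 * c(cos(ang0), sin(ang0))
    theta <- runif(1, 0, 2 * pi)
    verts <- matrix(NA_real_, n_steps + 1L, 2L)
    verts[1L, ] <- pos
    for (k in seq_len(n_steps)) {
      theta <- theta + rnorm(1, 0, sd_turn)
      prop <- pos + step_px * c(cos(theta), sin(theta))
      d <- sqrt(sum(prop^2))
      if (d > r_out || d < r_in) {
        # specular reflection about the violated circular boundary
        bound <- if (d > r_out) r_out else r_in
        u <- prop / d
        prop <- u * (2 * bound - d)
        v <- c(cos(theta), sin(theta))
        v <- v - 2 * sum(v * u) * u
        theta <- atan2(v[2], v[1])
        d2 <- sqrt(sum(prop^2))
        if (d2 > r_out || d2 < r_in) {
          # corner case (thin annulus): clamp radially
          prop <- prop / d2 * min(max(d2, r_in), r_out)
        }
      }
      pos <- prop
      verts[k + 1L, ] <- pos
    }
    verts <- sweep(verts, 2L, ctr, `+`)
    colnames(verts) <- c("row", "col")
    structure(list(vertices = verts, step_um = step_um,
                   persistence_um = persistence_um),
              class = "filament_path")
  })
}

#' Generate the filament set for one droplet at a given assembled fraction
#'
#' The total *visible* filament contour length per droplet follows a
#' coarsening law: a network of thin nanotubes appears quickly at low
#' assembled fraction, and further assembled mass then thickens existing
#' bundles more than it extends the network (nanotubes elongate, join and
#' bundle as condensation proceeds). Concretely
#' `L = V * filament_density * f/(f + 0.05) * (1 - 0.7 f)`,
#' with `V` the droplet volume (um^3); the rendered brightness per unit
#' length still scales with the assembled mass `f * tile_total`, so
#' bundles grow brighter as the visible network slowly shrinks. The length
#' is split into chains of typical contour length
#' `length_scale * diameter`, emulating nanotubes that span and wrap the
#' droplet. How nanotube number and length scale with assembled mass is
#' not experimentally constrained; this coarsening law is a documented
#' modeling choice.
#'
#' @param droplet One-row [sample_droplet_population()] data.frame.
#' @param pixel_size_um Pixel size (micrometers per pixel).
#' @param seed Integer seed.
#' @param filament_density Peak contour length per droplet volume
#'   (um/um^3).
#' @param length_scale Typical chain length in units of droplet diameter.
#' @param persistence_um,step_um Passed to [simulate_filament()].
#' @return List of `filament_path` objects (possibly empty).
#' @export
droplet_filaments <- function(droplet, pixel_size_um = 1, seed = 1L,
                              filament_density = 0.004, length_scale = 1.2,
                              persistence_um = 4.5, step_um = 0.25) {
  f <- droplet$assembled_fraction
  if (f <= 0) return(list())
  vol_um3 <- 4 / 3 * pi * droplet$radius_um^3
  total_um <- vol_um3 * filament_density * f / (f + 0.05) * (1 - 0.7 * f)
  # even the smallest droplet spreads its assembled mass over a short
  # visible contour rather than a single diffraction-limited dot
  total_um <- max(total_um, 2)
  typical_um <- length_scale * 2 * droplet$radius_um
  n_fil <- max(1L, round(total_um / typical_um))
  len_each <- total_um / n_fil
  if (len_each < 2 * step_um) { n_fil <- 1L; len_each <- max(total_um, 2 * step_um) }
  lapply(seq_len(n_fil), function(i) {
    simulate_filament(droplet, length_um = len_each,
                      persistence_um = persistence_um, step_um = step_um,
                      pixel_size_um = pixel_size_um,
                      seed = derive_seed(seed, i))
  })
}
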