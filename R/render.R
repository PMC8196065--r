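#' Imaging parameters for the synthetic microscope
#'
#' Describes the virtual widefield fluorescence microscope and camera used
#' by [render_frame()]. The free-tile signal of a droplet is rendered as a
#' two-dimensional projection of the fluorophore-filled sphere: an
#' in-focus equatorial slab of thickness `focal_depth_um` (sharp rim) plus
#' the out-of-focus remainder of the spherical chord, blurred with a
#' defocus kernel whose width scales with droplet radius
#' (`defocus_sigma_frac * radius`). The two parts sum exactly to the
#' spherical chord depth `2*sqrt(R^2 - r^2)` before blurring, so the total
#' signal collected from a droplet is proportional to its encapsulated
#' tile budget regardless of how the signal is distributed.
#'
#' @param pixel_size_um Pixel size (micrometers per pixel).
#' @param psf_sigma_px In-focus point-spread-function sigma (pixels).
#' @param exposure_gain Camera gain: expected gray levels per unit of
#'   projected signal (nM-equivalent x micrometer depth).
#' @param read_noise_sd Gaussian read noise SD (gray levels).
#' @param bit_depth Camera bit depth (default 16).
#' @param background_level Constant background offset (gray levels).
#' @param focal_depth_um Thickness of the in-focus slab (micrometers).
#' @param defocus_sigma_frac Defocus blur sigma as a fraction of the
#'   droplet radius.
#' @param filament_halo_frac Fraction of filament fluorescence rendered
#'   as a defocused halo rather than sharp line splats; nanotube bundles
#'   are three-dimensional tangles of which only part lies in the focal
#'   slab.
#' @param rng_seed Default seed used by [render_frame()] when none is
#'   given.
#' @return A list of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 1, psf_sigma_px = 1,
                           exposure_gain = 0.15, read_noise_sd = 10,
                           bit_depth = 16L, background_level = 200,
                           focal_depth_um = 2, defocus_sigma_frac = 0.25,
                           filament_halo_frac = 0.5, rng_seed = 1L) {
  stopifnot(pixel_size_um > 0, psf_sigma_px >= 0, exposure_gain > 0,
            read_noise_sd >= 0, bit_depth >= 8L, background_level >= 0,
            focal_depth_um > 0, defocus_sigma_frac >= 0,
            filament_halo_frac >= 0, filament_halo_frac < 1)
  structure(list(pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
                 exposure_gain = exposure_gain, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 focal_depth_um = focal_depth_um,
                 defocus_sigma_frac = defocus_sigma_frac,
                 filament_halo_frac = filament_halo_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "imaging_params")
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

# bilinear splat of weighted sub-pixel points into a patch matrix
splat_points <- function(patch, rows, cols, weights) {
  nr <- nrow(patch); nc <- ncol(patch)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    w <- weights * (if (dr == 0) 1 - fr else fr) *
      (if (dc == 0) 1 - fc else fc)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    if (any(ok)) {
      idx <- cbind(rr[ok], cc[ok])
      # accumulate duplicates correctly
      lin <- (idx[, 2] - 1L) * nr + idx[, 1]
      tab <- rowsum(w[ok], lin)
      patch[as.integer(rownames(tab))] <- patch[as.integer(rownames(tab))] +
        tab[, 1]
    }
  }
  patch
}

#' Render a synthetic fluorescence frame of a droplet population
#'
#' Renders each droplet as the sum of a dispersed free-tile term and a
#' condensed filament term, conserving the total signal: free tiles
#' contribute `(1 - f) * tile_total` spread over the spherical projection
#' (in-focus slab + defocused remainder, see [imaging_params()]), and
#' assembled tiles contribute `f * tile_total` concentrated along
#' worm-like-chain filament splats. The frame is then convolved with the
#' in-focus PSF, Poisson shot noise and Gaussian read noise are applied,
#' and the result is quantized to integer gray levels. Any pixel reaching
#' 90% of the camera ceiling aborts the render with advice to lower
#' `exposure_gain`, because downstream moment statistics are only
#' exposure-invariant while no pixel saturates.
#'
#' @param droplets A [sample_droplet_population()] data.frame (its
#'   `assembled_fraction` column sets each droplet's condensation state).
#' @param imaging An [imaging_params()] object.
#' @param filaments Optional list of `filament_path` lists, named by
#'   `droplet_id`; when `NULL`, filaments are generated automatically via
#'   [droplet_filaments()] from the droplet's assembled fraction.
#' @param time_min Acquisition time stamp (minutes).
#' @param frame_shape Frame dimensions; defaults to the population's
#'   `frame_shape` attribute.
#' @param seed Integer seed (defaults to `imaging$rng_seed`); identical
#'   seeds and parameters give bit-identical frames.
#' @param return_noiseless Attach the pre-noise expected image as
#'   attribute `"noiseless"`.
#' @return A `rendered_frame`: list with `image` (integer matrix, gray
#'   levels), `truth` (the droplet data.frame plus a `signal_total`
#'   column), `time_min`, and `imaging`.
#' @examples
#' pop <- sample_droplet_population(3, c(160, 160), c(5, 12), seed = 1)
#' fr <- render_frame(pop, imaging_params(rng_seed = 7))
#' range(fr$image)
#' @export
render_frame <- function(droplets, imaging = imaging_params(),
                         filaments = NULL, time_min = 0,
                         frame_shape = attr(droplets, "frame_shape"),
                         seed = imaging$rng_seed,
                         return_noiseless = FALSE) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (is.null(frame_shape)) stop("frame_shape missing")
  canvas <- matrix(0, frame_shape[1], frame_shape[2])
  n <- nrow(droplets)
  signal_total <- numeric(n)
  px <- imaging$pixel_size_um
  for (i in seq_len(n)) {
    d <- droplets[i, ]
    r <- d$radius_px
    f <- d$assembled_fraction
    ext <- ceiling(r + max(8, 4 * imaging$defocus_sigma_frac * r))
    r1 <- max(1L, floor(d$center_row - ext)); r2 <- min(frame_shape[1], ceiling(d$center_row + ext))
    c1 <- max(1L, floor(d$center_col - ext)); c2 <- min(frame_shape[2], ceiling(d$center_col + ext))
    pr <- r1:r2; pc <- c1:c2
    dd2 <- outer((pr - d$center_row)^2, (pc - d$center_col)^2, `+`)
    chord_um <- 2 * sqrt(pmax(r^2 - dd2, 0)) * px
    slab <- pmin(chord_um, imaging$focal_depth_um)
    haze <- gauss_blur(chord_um - slab, imaging$defocus_sigma_frac * r)
    vol <- sum(chord_um) # projected volume (um * px^2)
    patch <- (1 - f) * d$tile_total * (slab + haze)
    if (f > 0) {
      fils <- if (!is.null(filaments)) filaments[[as.character(d$droplet_id)]]
        else droplet_filaments(d, pixel_size_um = px,
                               seed = derive_seed(seed, d$droplet_id))
      if (length(fils)) {
        fi <- matrix(0, length(pr), length(pc))
        for (fil in fils) {
          v <- fil$vertices
          w <- rep(fil$step_um / px, nrow(v))
          fi <- splat_points(fi, v[, 1] - r1 + 1, v[, 2] - c1 + 1, w)
        }
        s <- sum(fi)
        if (s > 0) {
          # nanotube bundles are three-dimensional tangles: only part of
          # their mass lies in the focal slab (rendered as sharp, slightly
          # widened line splats); the rest contributes a defocused halo
          fi <- fi * (f * d$tile_total * vol / s)
          sharp <- gauss_blur(fi, 1)
          halo <- gauss_blur(fi, max(2, imaging$defocus_sigma_frac * r))
          hf <- imaging$filament_halo_frac
          patch <- patch + (1 - hf) * sharp + hf * halo
        }
      }
    }
    signal_total[i] <- d$tile_total * vol
    canvas[pr, pc] <- canvas[pr, pc] + patch
  }
  expected <- imaging$background_level +
    imaging$exposure_gain * gauss_blur(canvas, imaging$psf_sigma_px)
  img <- with_seed(derive_seed(seed, "noise"), {
    shot <- rpois(length(expected), pmax(expected, 0))
    round(shot + rnorm(length(expected), 0, imaging$read_noise_sd))
  })
  img <- matrix(pmax(img, 0), frame_shape[1], frame_shape[2])
  ceiling_val <- 2^imaging$bit_depth - 1
  if (max(img) >= 0.9 * ceiling_val) {
    stop(sprintf(paste0("saturated render: max pixel %d >= 0.9 * %d; ",
                        "lower exposure_gain"), max(img), ceiling_val))
  }
  storage.mode(img) <- "integer"
  truth <- droplets
  truth$signal_total <- signal_total
  out <- structure(list(image = img, truth = truth, time_min = time_min,
                        imaging = imaging),
                   class = "rendered_frame")
  if (return_noiseless) attr(out, "noiseless") <- expected
  out
}

#' Render a time series of frames following an assembly trajectory
#'
#' Renders one frame per requested time, setting every droplet's
#' assembled fraction to the trajectory value at that time (linearly
#' interpolated), optionally modulated per droplet by a fixed lognormal
#' factor emulating partitioning noise in the *kinetics* (a droplet that
#' encapsulated fewer transcription components assembles less). Droplet
#' positions and identities persist across frames; filaments are
#' regenerated each frame (individual droplets are not tracked by the
#' analysis, matching the acquisition protocol).
#'
#' @param trajectory An `assembly_sim` from [simulate_assembly()], or any
#'   data.frame with `time` (or `time_min`) and `f` columns.
#' @param population A [sample_droplet_population()] data.frame.
#' @param imaging An [imaging_params()] object.
#' @param frame_times Non-empty numeric vector of times (min) within the
#'   trajectory range.
#' @param fraction_jitter_sdlog Lognormal sdlog of the per-droplet
#'   multiplicative factor on the assembled fraction (0 disables).
#' @param seed Integer master seed.
#' @return List of `rendered_frame` objects, one per time.
#' @export
render_timeseries <- function(trajectory, population,
                              imaging = imaging_params(), frame_times,
                              fraction_jitter_sdlog = 0.2,
                              seed = imaging$rng_seed) {
  if (length(frame_times) == 0L) stop("frame_times must be non-empty")
  tr <- as.data.frame(trajectory)
  tcol <- if ("time" %in% names(tr)) "time" else "time_min"
  if (!tcol %in% names(tr) || !"f" %in% names(tr)) {
    stop("trajectory needs 'time' (or 'time_min') and 'f' columns")
  }
  if (any(frame_times < min(tr[[tcol]]) | frame_times > max(tr[[tcol]]))) {
    stop("frame_times outside trajectory time range")
  }
  f_at <- approx(tr[[tcol]], tr$f, xout = frame_times)$y
  n <- nrow(population)
  jit <- if (fraction_jitter_sdlog > 0) {
    with_seed(derive_seed(seed, "fraction-jitter"),
              rlnorm(n, -fraction_jitter_sdlog^2 / 2, fraction_jitter_sdlog))
  } else rep(1, n)
  lapply(seq_along(frame_times), function(k) {
    pop <- population
    pop$assembled_fraction <- pmin(1, pmax(0, f_at[k] * jit))
    render_frame(pop, imaging, time_min = frame_times[k],
                 seed = derive_seed(seed, 1000L + k))
  })
}
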