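#' Droplet detection configuration
#'
#' Tuning parameters for [detect_droplets()]. The defaults suit the
#' synthetic renders of this package and typical widefield droplet
#' images with a pixel size around 1 um: droplets smaller than
#' `min_radius_px` carry too few interior pixels for stable moment
#' estimates, and the rim shrink excludes the bright rim and
#' surface-adsorption artifacts at the water-oil interface.
#'
#' @param min_radius_px,max_radius_px Radius search range (pixels,
#'   `min_radius_px >= 3`).
#' @param border_margin_px Detections whose disk enters this border strip
#'   are discarded (their interiors may be clipped).
#' @param rim_shrink_fraction Fraction of the radius stripped from the
#'   rim before pixels are extracted (in `[0, 0.5)`).
#' @param min_pixels Minimum interior pixel count for a valid detection.
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma for the
#'   gradient computation.
#' @param median_radius Radius of a median prefilter applied before
#'   geometry estimation; removes thin bright filaments so they cannot
#'   distort rim localization (0 disables). Pixel statistics are always
#'   extracted from the unfiltered image.
#' @param edge_quantile Quantile of the gradient magnitude above which a
#'   pixel votes in the Hough accumulator.
#' @param min_score Accumulator score threshold (votes per unit
#'   circumference, after smoothing) for a candidate circle.
#' @param min_coverage Minimum azimuthal coverage: fraction of 16 angular
#'   sectors around the candidate that contain an inward-pointing edge
#'   pixel at the candidate radius. Separates closed droplet rims from
#'   clusters of bright filaments.
#' @param radius_step Radius grid step (pixels) of the Hough search.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(min_radius_px = 5, max_radius_px = 30,
                             border_margin_px = 4,
                             rim_shrink_fraction = 0.1,
                             min_pixels = 50, smoothing_sigma_px = 2,
                             median_radius = 3,
                             edge_quantile = 0.9, min_score = 0.8,
                             min_coverage = 0.6, radius_step = 1) {
  stopifnot(min_radius_px >= 3, max_radius_px >= min_radius_px,
            rim_shrink_fraction >= 0, rim_shrink_fraction < 0.5,
            min_pixels >= 20, smoothing_sigma_px >= 0,
            edge_quantile > 0, edge_quantile < 1, min_score > 0,
            min_coverage >= 0, min_coverage <= 1, radius_step > 0)
  structure(as.list(environment()), class = "detection_config")
}

#' Detect droplets in a grayscale fluorescence frame
#'
#' Locates circular droplets with a gradient-direction circular Hough
#' transform: the image is normalized (making the detector invariant
#' under positive affine rescaling, up to quantization), smoothed, and
#' strong-gradient pixels vote for a circle center one radius along their
#' gradient direction (droplet interiors are brighter than the oil
#' background, so rim gradients point inward). Accumulator peaks are
#' scored per unit circumference, refined to sub-pixel centers, and their
#' radii re-estimated from the radial intensity profile (the crossing of
#' 20% of the rim contrast). Overlapping candidates are resolved by
#' non-maximum suppression: when two centers are closer than half the sum
#' of their radii, only the stronger peak survives. Detections touching
#' the border margin are discarded, and each survivor carries the pixel
#' values of its rim-shrunken interior disk.
#'
#' A simpler fallback (`method = "threshold"`: Otsu threshold, connected
#' components, circularity filter >= 0.8) is provided for low-contrast
#' frames where the Hough transform finds nothing.
#'
#' Droplets are detected independently in every frame; the output carries
#' no identity linking across frames (the acquisition protocol samples a
#' random set of droplets per time point rather than tracking).
#'
#' @param image 2D numeric matrix of gray levels.
#' @param config A [detection_config()].
#' @param method `"hough"` (default) or `"threshold"`.
#' @param frame_index Integer stamped into the output rows.
#' @return A data.frame of class `droplet_detections` with columns
#'   `droplet_id`, `center_row`, `center_col`, `radius_px`, `score`,
#'   `n_pixels`, `frame_index`, and a list column `pixel_values` holding
#'   each detection's interior sample. Zero rows when nothing is found
#'   (a blank image is not an error).
#' @examples
#' pop <- sample_droplet_population(3, c(200, 200), c(6, 15), seed = 3)
#' fr <- render_frame(pop, imaging_params(rng_seed = 3))
#' det <- detect_droplets(fr$image)
#' nrow(det)
#' @export
detect_droplets <- function(image, config = detection_config(),
                            method = c("hough", "threshold"),
                            frame_index = 1L) {
  method <- match.arg(method)
  if (length(dim(image)) != 2L || !is.numeric(image[1])) {
    stop("image must be a 2D numeric matrix")
  }
  image <- matrix(as.numeric(image), nrow(image), ncol(image))
  empty <- empty_detections()
  rng <- range(image)
  if (nrow(image) < 2 * config$min_radius_px || rng[1] == rng[2]) {
    return(empty)
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  if (config$median_radius > 0) {
    # median prefilter: removes thin bright filaments and hot pixels while
    # preserving the droplet body and rim; geometry is estimated on the
    # filtered image, pixel samples are taken from the original
    norm <- as.matrix(EBImage::medianFilter(norm, config$median_radius))
    norm <- (norm - min(norm)) / max(diff(range(norm)), 1e-12)
  }
  edges <- edge_map(norm, config)
  cand <- if (method == "hough") hough_candidates(edges, config)
    else threshold_candidates(norm, config)
  if (nrow(cand) == 0L) return(empty)
  # refine radii from the radial intensity profile; the oil background is
  # the image-wide median (droplets cover a small area fraction)
  bg_global <- median(norm)
  cand$radius_px <- vapply(seq_len(nrow(cand)), function(i) {
    refine_radius(norm, cand$center_row[i], cand$center_col[i],
                  cand$radius_px[i], bg_global,
                  1.2 * config$max_radius_px)
  }, numeric(1))
  cand <- cand[cand$radius_px <= 1.2 * config$max_radius_px &
                 cand$radius_px >= config$min_radius_px, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # robust circle fit to the rim edges for sub-pixel centers; the radius is
  # then re-estimated from the radial profile at the corrected center (the
  # 50% rim crossing localizes the radius better than the fit, whose edge
  # band is biased by smoothing on small droplets)
  ctr <- refine_centers(edges, cand)
  cand$center_row <- ctr$row; cand$center_col <- ctr$col
  cand$radius_px <- vapply(seq_len(nrow(cand)), function(i) {
    refine_radius(norm, cand$center_row[i], cand$center_col[i],
                  cand$radius_px[i], bg_global,
                  1.2 * config$max_radius_px)
  }, numeric(1))
  cand <- cand[cand$radius_px <= 1.2 * config$max_radius_px &
                 cand$radius_px >= config$min_radius_px, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # concentric Hough candidates collapse onto one circle after refinement
  key <- paste(round(cand$center_row), round(cand$center_col),
               round(2 * cand$radius_px))
  cand <- cand[!duplicated(key), , drop = FALSE]
  # re-score every candidate at its refined geometry: a genuine droplet rim
  # is voted for from all directions, clusters of bright filaments are not
  cs <- rim_coverage(edges, cand)
  cand$coverage <- cs$coverage
  cand$rim_strength <- cs$strength
  cand$fit_resid <- cs$resid
  cand <- cand[cand$coverage >= config$min_coverage, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # a droplet is filled: just inside the rim the image sits above the oil
  # background all the way around. Phantom circles through rim arcs of
  # *adjacent* droplets span background gaps and fail this test.
  supp <- vapply(seq_len(nrow(cand)), function(i) {
    interior_support(norm, cand$center_row[i], cand$center_col[i],
                     cand$radius_px[i], bg_global)
  }, numeric(1))
  cand <- cand[supp >= 0.9, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # rank by rim completeness and circle-fit quality; rim gradient strength
  # (capped, so a few very bright filament edges cannot outrank a complete
  # faint rim) breaks remaining ties
  cand$score <- 10 * cand$coverage - 4 * cand$fit_resid +
    pmin(cand$rim_strength, 5)
  # non-maximum suppression, strongest first
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    j <- which(keep)
    d <- sqrt((cand$center_row[j] - cand$center_row[i])^2 +
                (cand$center_col[j] - cand$center_col[i])^2)
    # suppress when centers are closer than half the radius sum, and also
    # when this candidate's center falls inside an accepted circle (real
    # droplets never overlap, but knots of bright filaments inside a large
    # droplet can masquerade as small circles)
    keep[i] <- all(d >= 0.5 * (cand$radius_px[j] + cand$radius_px[i])) &&
      all(d >= cand$radius_px[j])
  }
  cand <- cand[keep, , drop = FALSE]
  # border margin and interior extraction
  m <- config$border_margin_px
  inside <- cand$center_row - cand$radius_px > m &
    cand$center_col - cand$radius_px > m &
    cand$center_row + cand$radius_px <= nrow(image) - m &
    cand$center_col + cand$radius_px <= ncol(image) - m
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  pix <- lapply(seq_len(nrow(cand)), function(i) {
    extract_droplet_pixels(image, c(cand$center_row[i], cand$center_col[i]),
                           cand$radius_px[i], config$rim_shrink_fraction)
  })
  n_pix <- lengths(pix)
  ok <- n_pix >= config$min_pixels
  cand <- cand[ok, , drop = FALSE]
  pix <- pix[ok]
  if (nrow(cand) == 0L) return(empty)
  out <- data.frame(droplet_id = seq_len(nrow(cand)),
                    center_row = cand$center_row,
                    center_col = cand$center_col,
                    radius_px = cand$radius_px,
                    score = cand$score,
                    n_pixels = lengths(pix),
                    frame_index = as.integer(frame_index))
  out$pixel_values <- pix
  class(out) <- c("droplet_detections", "data.frame")
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  out <- data.frame(droplet_id = integer(), center_row = numeric(),
                    center_col = numeric(), radius_px = numeric(),
                    score = numeric(), n_pixels = integer(),
                    frame_index = integer())
  out$pixel_values <- list()
  class(out) <- c("droplet_detections", "data.frame")
  out
}

# fast weighted bincount over integer indices (avoids factor coercion)
weighted_bincount <- function(idx, w) {
  ord <- order(idx)
  io <- idx[ord]; wo <- w[ord]
  last <- which(c(io[-1L] != io[-length(io)], TRUE))
  list(idx = io[last],
       sum = diff(c(0, cumsum(wo)[last])),
       count = diff(c(0L, last)))
}

# strong-gradient pixels with their unit gradient directions
edge_map <- function(norm, config) {
  sm <- gauss_blur(norm, config$smoothing_sigma_px)
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  # quantile threshold for dense frames, with a noise floor so that a
  # frame holding few droplets (mostly flat background) does not flood the
  # edge set with noise gradients; both terms rescale with the image, so
  # affine invariance is preserved
  thr <- max(quantile(mag, config$edge_quantile), 3 * median(mag))
  if (thr <= 0) {
    return(list(er = integer(), ec = integer(), ur = numeric(),
                uc = numeric(), em = numeric(), thr = 0,
                dim = c(nr, nc)))
  }
  e <- which(mag > thr)
  # edges come out sorted by column (R stores matrices column-major),
  # allowing fast windowed lookups via findInterval
  list(er = (e - 1L) %% nr + 1L, ec = (e - 1L) %/% nr + 1L,
       ur = gr[e] / mag[e], uc = gc[e] / mag[e], em = mag[e],
       thr = as.numeric(thr), dim = c(nr, nc))
}

# indices of edge pixels within a bounding box around a candidate circle
edge_window <- function(edges, cr, cc, r, pad = 3) {
  i1 <- findInterval(cc - r - pad, edges$ec) + 1L
  i2 <- findInterval(cc + r + pad, edges$ec)
  if (i2 < i1) return(integer())
  idx <- i1:i2
  idx[abs(edges$er[idx] - cr) <= r + pad]
}

# fraction of the annulus just inside the rim that sits above background
interior_support <- function(norm, cr, cc, r, bg) {
  r1 <- max(1L, floor(cr - r)); r2 <- min(nrow(norm), ceiling(cr + r))
  c1 <- max(1L, floor(cc - r)); c2 <- min(ncol(norm), ceiling(cc + r))
  pr <- r1:r2; pc <- c1:c2
  dd2 <- outer((pr - cr)^2, (pc - cc)^2, `+`)
  sel <- dd2 >= (0.7 * r)^2 & dd2 <= (0.9 * r)^2
  if (sum(sel) < 8L) return(0)
  vals <- norm[pr, pc][sel]
  rim_int <- median(vals)
  if (rim_int <= bg) return(0)
  mean(vals > bg + 0.25 * (rim_int - bg))
}

# algebraic (Kasa) least-squares circle through (r, c) points
fit_circle_kasa <- function(r, c) {
  A <- cbind(2 * r, 2 * c, 1)
  b <- r^2 + c^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  rad2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(rad2) || rad2 <= 0) return(NULL)
  c(row = sol[1], col = sol[2], radius = sqrt(rad2))
}

# refine each candidate by a robust circle fit to its rim-aligned edge
# pixels: fit, trim outliers (bright filament edges that slipped into the
# rim band), refit
refine_centers <- function(edges, cand) {
  row <- cand$center_row; col <- cand$center_col; rad <- cand$radius_px
  for (i in seq_len(nrow(cand))) {
    for (pass in 1:2) {
      w <- edge_window(edges, row[i], col[i], rad[i])
      if (length(w) < 8L) break
      dr <- edges$er[w] - row[i]; dc <- edges$ec[w] - col[i]
      d <- sqrt(dr^2 + dc^2)
      sel <- abs(d - rad[i]) <= 2 & d > 1
      if (sum(sel) < 8L) break
      align <- -(edges$ur[w][sel] * dr[sel] + edges$uc[w][sel] * dc[sel]) / d[sel]
      keep <- align > 0.85
      if (sum(keep) < 8L) break
      pr <- edges$er[w][sel][keep]; pc <- edges$ec[w][sel][keep]
      fit <- fit_circle_kasa(pr, pc)
      if (is.null(fit)) break
      res <- abs(sqrt((pr - fit[1])^2 + (pc - fit[2])^2) - fit[3])
      cut <- max(1, 2.5 * median(res))
      if (any(res > cut) && sum(res <= cut) >= 8L) {
        fit <- fit_circle_kasa(pr[res <= cut], pc[res <= cut])
        if (is.null(fit)) break
      }
      # guard against runaway fits far from the accumulator evidence
      if (abs(fit[3] - rad[i]) > 0.4 * rad[i] ||
          sqrt((fit[1] - row[i])^2 + (fit[2] - col[i])^2) > 0.5 * rad[i]) break
      row[i] <- fit[1]; col[i] <- fit[2]; rad[i] <- fit[3]
    }
  }
  list(row = row, col = col, radius = rad)
}

# azimuthal rim coverage and mean aligned rim gradient for candidate circles
rim_coverage <- function(edges, cand) {
  n <- nrow(cand)
  coverage <- numeric(n); strength <- numeric(n)
  resid <- rep(2, n)
  for (i in seq_len(n)) {
    w <- edge_window(edges, cand$center_row[i], cand$center_col[i],
                     cand$radius_px[i])
    if (length(w) == 0L) next
    dr <- edges$er[w] - cand$center_row[i]
    dc <- edges$ec[w] - cand$center_col[i]
    d <- sqrt(dr^2 + dc^2)
    sel <- abs(d - cand$radius_px[i]) <= 2 & d > 1
    if (!any(sel)) next
    align <- -(edges$ur[w][sel] * dr[sel] + edges$uc[w][sel] * dc[sel]) / d[sel]
    sel2 <- align > 0.7
    if (!any(sel2)) next
    dd <- d[sel][sel2]
    sector <- floor((atan2(dc[sel][sel2], dr[sel][sel2]) + pi) / (2 * pi) * 16)
    coverage[i] <- length(unique(pmin(sector, 15L))) / 16
    strength[i] <- sum(edges$em[w][sel][sel2]) /
      (2 * pi * cand$radius_px[i] * edges$thr)
    # circle-fit quality: rim-pixel distances spread around the radius;
    # an off-center candidate shows a residual close to its center offset
    if (length(dd) >= 5L) resid[i] <- sd(dd)
  }
  list(coverage = coverage, strength = strength, resid = resid)
}

hough_candidates <- function(edges, config) {
  if (length(edges$er) == 0L) return(data.frame())
  nr <- edges$dim[1]; nc <- edges$dim[2]
  er <- edges$er; ec <- edges$ec; ur <- edges$ur; uc <- edges$uc
  em <- edges$em; thr <- edges$thr
  radii <- seq(config$min_radius_px, config$max_radius_px,
               by = config$radius_step)
  cands <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    vr <- round(er + r * ur); vc <- round(ec + r * uc)
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    # gradient-magnitude-weighted votes: the sharp droplet rim outvotes
    # the weak interior gradient of the defocused dome, which would
    # otherwise spawn concentric phantom circles at small radii
    acc_vec <- numeric(nr * nc)
    wb <- weighted_bincount((vc[ok] - 1L) * nr + vr[ok], em[ok])
    acc_vec[wb$idx] <- wb$sum
    acc <- gauss_blur(matrix(acc_vec, nr, nc), 1)
    # score: mean voting gradient per unit circumference, in units of the
    # edge threshold (scale-free under affine rescaling of the image)
    score <- acc / (2 * pi * r * thr)
    pk <- local_maxima(score, config$min_score)
    if (nrow(pk) > 0L) {
      pk$radius_px <- r
      cands[[k]] <- pk
    }
  }
  cands <- do.call(rbind, cands)
  if (is.null(cands)) return(data.frame())
  cands
}

local_maxima <- function(score, min_score) {
  nr <- nrow(score); nc <- ncol(score)
  core <- score[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= min_score
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max &
      core >= score[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(data.frame())
  data.frame(center_row = idx[, 1] + 1, center_col = idx[, 2] + 1,
             score = core[idx])
}

threshold_candidates <- function(norm, config) {
  sm <- gauss_blur(norm, config$smoothing_sigma_px)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- EBImage::bwlabel(sm > th)
  ft <- EBImage::computeFeatures.shape(mask)
  if (is.null(ft) || nrow(ft) == 0L) return(data.frame())
  mom <- EBImage::computeFeatures.moment(mask)
  area <- ft[, "s.area"]; per <- pmax(ft[, "s.perimeter"], 1)
  circ <- 4 * pi * area / per^2
  r_est <- sqrt(area / pi)
  keep <- circ >= 0.8 & r_est >= config$min_radius_px &
    r_est <= config$max_radius_px
  if (!any(keep)) return(data.frame())
  data.frame(center_row = mom[keep, "m.cx"], center_col = mom[keep, "m.cy"],
             score = circ[keep], radius_px = r_est[keep])
}

# radius from the radial mean-intensity profile. The droplet rim is a
# blurred downward step from the interior level to the oil background, so
# the true radius sits at the 50% crossing between the near-center interior
# level and the global background. The crossing is searched outward from
# half the accumulator radius, which also rescues "phantom" candidates that
# the Hough stage placed concentrically inside a large droplet (their
# profile never drops to background until the true rim).
refine_radius <- function(norm, cr, cc, r0, bg, rmax) {
  rmax <- max(rmax, 1.2 * r0)
  r1 <- max(1L, floor(cr - rmax)); r2 <- min(nrow(norm), ceiling(cr + rmax))
  c1 <- max(1L, floor(cc - rmax)); c2 <- min(ncol(norm), ceiling(cc + rmax))
  pr <- r1:r2; pc <- c1:c2
  dd <- sqrt(outer((pr - cr)^2, (pc - cc)^2, `+`))
  vals <- norm[pr, pc]
  h <- 0.5
  wb <- weighted_bincount(as.integer(dd / h), as.numeric(vals))
  prof <- wb$sum / wb$count
  rad <- (wb$idx + 0.5) * h
  ok <- rad <= rmax
  prof <- prof[ok]; rad <- rad[ok]
  if (length(prof) < 5L) return(r0)
  rim_int <- mean(prof[rad >= 0.55 * r0 & rad <= 0.85 * r0])
  if (!is.finite(rim_int) || rim_int <= bg) return(r0)
  level <- (rim_int + bg) / 2
  below <- prof < level
  start <- which(rad >= 0.5 * r0)[1L]
  if (is.na(start)) return(r0)
  cross <- which(!below[-length(below)] & below[-1L])
  cross <- cross[cross >= start]
  if (length(cross) == 0L) return(r0)
  i <- cross[1L]
  rr <- rad[i] + (level - prof[i]) * (rad[i + 1L] - rad[i]) /
    (prof[i + 1L] - prof[i])
  if (!is.finite(rr) || rr < 0.5 * r0) r0 else rr
}

#' Extract the interior pixel values of a droplet disk
#'
#' Returns the values of all pixels whose centers lie strictly within the
#' disk shrunk by `rim_shrink_fraction` (half-open convention: distance
#' `< (1 - shrink) * radius`), excluding the bright rim.
#'
#' @param image 2D numeric matrix.
#' @param center Numeric `(row, col)` of the droplet center (1-based).
#' @param radius_px Droplet radius (pixels).
#' @param rim_shrink_fraction Fraction of the radius to strip (in
#'   `[0, 0.5)`).
#' @return Numeric vector of pixel values.
#' @examples
#' img <- matrix(1:400, 20, 20)
#' length(extract_droplet_pixels(img, c(10, 10), 5, 0.1))
#' @export
extract_droplet_pixels <- function(image, center, radius_px,
                                   rim_shrink_fraction = 0.1) {
  stopifnot(length(center) == 2L, radius_px > 0,
            rim_shrink_fraction >= 0, rim_shrink_fraction < 0.5)
  r_eff <- (1 - rim_shrink_fraction) * radius_px
  if (center[1] - r_eff < 1 || center[2] - r_eff < 1 ||
      center[1] + r_eff > nrow(image) || center[2] + r_eff > ncol(image)) {
    stop("shrunken droplet disk extends outside the image")
  }
  pr <- floor(center[1] - r_eff):ceiling(center[1] + r_eff)
  pc <- floor(center[2] - r_eff):ceiling(center[2] + r_eff)
  dd2 <- outer((pr - center[1])^2, (pc - center[2])^2, `+`)
  image[pr, pc][dd2 < r_eff^2]
}

#' Match detections against ground-truth droplets
#'
#' Greedy nearest matching: truth-detection pairs are accepted in order
#' of increasing center distance, each side used at most once, while the
#' distance is below `max_dist_factor` times the truth radius. Used to
#' score recall/precision and localization error of the detector on
#' synthetic frames.
#'
#' @param truth data.frame with `center_row`, `center_col`, `radius_px`.
#' @param detections A [detect_droplets()] result.
#' @param max_dist_factor Acceptance radius in units of the truth radius.
#' @return A list: `matches` (data.frame of `truth_row`, `det_row`,
#'   `dist`, `truth_radius`, `det_radius`), `recall`, `precision`,
#'   `mean_center_error`, `mean_radius_error_frac`.
#' @export
match_droplets <- function(truth, detections, max_dist_factor = 0.5) {
  nt <- nrow(truth); nd <- nrow(detections)
  if (nt == 0L || nd == 0L) {
    return(list(matches = data.frame(), recall = ifelse(nt == 0, NA, 0),
                precision = ifelse(nd == 0, NA, 0),
                mean_center_error = NA_real_,
                mean_radius_error_frac = NA_real_))
  }
  d <- sqrt(outer(truth$center_row, detections$center_row, `-`)^2 +
              outer(truth$center_col, detections$center_col, `-`)^2)
  lim <- max_dist_factor * truth$radius_px
  pairs <- which(d <= matrix(lim, nt, nd), arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(list(matches = data.frame(), recall = 0, precision = 0,
                mean_center_error = NA_real_,
                mean_radius_error_frac = NA_real_))
  }
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs[i, 1]; di <- pairs[i, 2]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      truth_row = ti, det_row = di, dist = d[ti, di],
      truth_radius = truth$radius_px[ti],
      det_radius = detections$radius_px[di])
  }
  m <- do.call(rbind, rows)
  list(matches = m,
       recall = nrow(m) / nt,
       precision = nrow(m) / nd,
       mean_center_error = mean(m$dist),
       mean_radius_error_frac = mean(abs(m$det_radius - m$truth_radius) /
                                       m$truth_radius))
}
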