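#' Write rendered frames to disk as 16-bit TIFF plus ground truth
#'
#' Writes one grayscale TIFF per frame (or a single multi-page stack), a
#' ground-truth CSV (`frame`, `droplet_id`, `center_row`, `center_col`,
#' `radius_px`, `assembled_fraction`, plus tile budget and signal total),
#' a frame manifest CSV (`filename`, `time_min`) mapping files to
#' acquisition times, and a JSON sidecar recording the imaging parameters
#' and seed, so a dataset can be re-rendered bit-identically.
#'
#' @param frames List of `rendered_frame` objects from [render_frame()]
#'   or [render_timeseries()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param multi_page Write one multi-page TIFF instead of one file per
#'   frame.
#' @param extra Optional named list merged into the JSON sidecar (e.g.
#'   the master seed or generator configuration).
#' @return Invisibly, the paths written (`images`, `truth`, `manifest`,
#'   `sidecar`).
#' @export
write_frames <- function(frames, dir, prefix = "frame",
                         multi_page = FALSE, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bit <- frames[[1]]$imaging$bit_depth
  maxval <- 2^bit - 1
  imgs <- lapply(frames, function(f) f$image / maxval)
  if (multi_page) {
    path <- file.path(dir, paste0(prefix, ".tif"))
    tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
    files <- rep(basename(path), length(frames))
  } else {
    files <- sprintf("%s_%03d.tif", prefix, seq_along(frames))
    for (k in seq_along(frames)) {
      tiff::writeTIFF(imgs[[k]], file.path(dir, files[k]),
                      bits.per.sample = 16L)
    }
  }
  truth <- do.call(rbind, lapply(seq_along(frames), function(k) {
    t <- frames[[k]]$truth
    if (nrow(t) == 0L) return(NULL)
    cbind(frame = k, time_min = frames[[k]]$time_min, t)
  }))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  if (is.null(truth)) {
    truth <- data.frame(frame = integer(), time_min = numeric(),
                        droplet_id = integer(), center_row = numeric(),
                        center_col = numeric(), radius_um = numeric(),
                        radius_px = numeric(), tile_total = numeric(),
                        assembled_fraction = numeric(),
                        surface_localized = logical(),
                        signal_total = numeric())
  }
  write.csv(truth, truth_path, row.names = FALSE)
  manifest <- data.frame(filename = files,
                         page = if (multi_page) seq_along(frames) else 1L,
                         time_min = vapply(frames, `[[`, numeric(1),
                                           "time_min"))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.csv"))
  write.csv(manifest, manifest_path, row.names = FALSE)
  sidecar <- c(list(imaging = unclass(frames[[1]]$imaging),
                    n_frames = length(frames)), extra)
  sidecar_path <- file.path(dir, paste0(prefix, "_params.json"))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(images = file.path(dir, unique(files)),
                 truth = truth_path, manifest = manifest_path,
                 sidecar = sidecar_path))
}

#' Read a grayscale image frame (TIFF or PNG) as integer gray levels
#'
#' @param path Image file (`.tif`/`.tiff` single or multi-page, or
#'   `.png`).
#' @param page Page index for multi-page TIFF.
#' @param bit_depth Bit depth used to rescale the normalized values back
#'   to integer gray levels.
#' @return Integer matrix.
#' @export
read_frame <- function(path, page = 1L, bit_depth = 16L) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (page > length(pages)) stop("page ", page, " beyond TIFF stack")
    pages[[page]]
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package")
    }
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p
  } else {
    stop("unsupported image format: .", ext)
  }
  out <- round(img * (2^bit_depth - 1))
  storage.mode(out) <- "integer"
  out
}

#' Read an image series from a manifest
#'
#' The manifest CSV maps image files (and pages, for multi-page stacks)
#' to acquisition times — the imaging cadence of droplet experiments is
#' irregular, so times are data, not an index.
#'
#' @param manifest_path CSV with columns `filename`, `time_min`, and
#'   optionally `page`.
#' @param dir Directory holding the image files (defaults to the
#'   manifest's directory).
#' @param bit_depth Passed to [read_frame()].
#' @return List with `images` (list of integer matrices) and `times`.
#' @export
read_frame_series <- function(manifest_path, dir = dirname(manifest_path),
                              bit_depth = 16L) {
  man <- read.csv(manifest_path)
  if (!all(c("filename", "time_min") %in% names(man))) {
    stop("manifest needs 'filename' and 'time_min' columns")
  }
  if (is.null(man$page)) man$page <- 1L
  imgs <- lapply(seq_len(nrow(man)), function(i) {
    read_frame(file.path(dir, man$filename[i]), man$page[i], bit_depth)
  })
  list(images = imgs, times = man$time_min)
}

#' Write an assembly-model trajectory to CSV
#'
#' @param sim An `assembly_sim` from [simulate_assembly()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(sim, path) {
  write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
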