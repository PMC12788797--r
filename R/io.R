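#' Read a trajectory CSV
#'
#' Expects at minimum the columns `frame`, `trajectory`, `x`, `y`
#' (coordinates in um unless `pixel_size` is given, in which case pixel
#' coordinates are converted at ingest); `cell_id` and `day_id` are carried
#' through when present and any extra columns are preserved untouched.
#'
#' @param path CSV file.
#' @param pixel_size if the file stores pixel coordinates, the um/px
#'   conversion factor (e.g. 0.16); `NULL` means coordinates are already um.
#' @return A localization tibble.
#' @export
read_trajectory_csv <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("frame", "trajectory", "x", "y"), basename(path))
  if (nrow(df) == 0) warn(sprintf("%s contains a header but no rows", basename(path)))
  if (!is.null(pixel_size)) {
    df$x <- df$x * pixel_size
    df$y <- df$y * pixel_size
  }
  df$frame <- as.integer(df$frame)
  df
}

#' @rdname read_trajectory_csv
#' @param locs localization table to write.
#' @export
write_trajectory_csv <- function(locs, path) {
  readr::write_csv(locs, path)
  invisible(path)
}

#' Write / read a diffusion spectrum as JSON
#'
#' Full-precision (17 significant digit) round trip of the grid,
#' occupations and metadata. On read, the occupations are validated to sum
#' to 1 within 1e-9; a file with a different format version errors and one
#' with missing metadata gets defaults with a warning.
#'
#' @param spectrum a `diffusion_spectrum`.
#' @param path JSON file.
#' @return `write_spectrum` the path, invisibly; `read_spectrum` a
#'   `diffusion_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  payload <- list(
    format = "smtkit_spectrum",
    version = 1L,
    D = spectrum$spectrum$D,
    occupation = spectrum$spectrum$occupation,
    occupation_raw = spectrum$spectrum$occupation_raw,
    grid = spectrum$grid[c("sigma_loc", "frame_interval", "focal_depth")],
    metadata = list(n_jumps = spectrum$n_jumps, n_segments = spectrum$n_segments,
                    n_cells = spectrum$n_cells, splitsize = spectrum$splitsize,
                    defoc_correct = spectrum$defoc_correct,
                    iterations = spectrum$iterations,
                    converged = spectrum$converged,
                    loglik_final = sum(vapply(spectrum$loglik,
                                              function(tr) tr[length(tr)],
                                              numeric(1)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "smtkit_spectrum") || !identical(as.integer(p$version), 1L)) {
    abort("unrecognized spectrum file format/version")
  }
  occ <- as.numeric(p$occupation)
  if (abs(sum(occ) - 1) > 1e-9) {
    abort("invalid spectrum: occupations do not sum to 1")
  }
  md <- p$metadata
  if (is.null(md)) {
    warn("spectrum file has no metadata; using defaults")
    md <- list()
  }
  grid <- diffusion_grid(d_min = min(p$D), d_max = max(p$D), n = length(p$D),
                         sigma_loc = p$grid$sigma_loc %||% 0.03,
                         frame_interval = p$grid$frame_interval %||% 0.00748,
                         focal_depth = p$grid$focal_depth %||% 0.7)
  grid$D <- as.numeric(p$D)  # preserve stored grid bit-for-bit
  structure(list(
    spectrum = tibble::tibble(D = as.numeric(p$D), occupation = occ,
                              occupation_raw = as.numeric(p$occupation_raw)),
    grid = grid,
    loglik = list(final = as.numeric(md$loglik_final %||% NA_real_)),
    n_jumps = md$n_jumps %||% NA_integer_,
    n_segments = md$n_segments %||% NA_integer_,
    n_cells = md$n_cells %||% NA_integer_,
    splitsize = md$splitsize %||% NA_integer_,
    defoc_correct = md$defoc_correct %||% NA,
    iterations = md$iterations %||% NA_integer_,
    converged = md$converged %||% NA),
    class = "diffusion_spectrum")
}

#' Write / read a FRAP movie as multi-frame TIFF plus JSON metadata
#'
#' The stack is stored as 32-bit grayscale TIFF pages rescaled to \[0, 1\]
#' (the affine rescaling is recorded in the metadata and undone on read);
#' timestamps, bleach frame and spot geometry go to a JSON sidecar.
#'
#' @param movie a `frap_movie`.
#' @param tiff_path,meta_path output files.
#' @return `write_frap_movie` the tiff path, invisibly; `read_frap_movie`
#'   a `frap_movie` (with `config = NULL`).
#' @export
write_frap_movie <- function(movie, tiff_path, meta_path) {
  stack <- movie$stack
  lo <- min(stack)
  hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f) (stack[, , f] - lo) / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(timestamps = movie$timestamps, bleach_frame = movie$bleach_frame,
               spot_center_px = movie$spot_center_px,
               spot_radius_px = movie$spot_radius_px,
               pixel_size = movie$pixel_size,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_frap_movie
#' @export
read_frap_movie <- function(tiff_path, meta_path) {
  if (!file.exists(tiff_path) || !file.exists(meta_path)) {
    abort("movie or metadata file not found")
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (f in seq_along(pages)) {
    stack[, , f] <- pages[[f]] * meta$intensity_scale + meta$intensity_offset
  }
  structure(list(stack = stack, timestamps = as.numeric(meta$timestamps),
                 bleach_frame = as.integer(meta$bleach_frame),
                 spot_center_px = as.numeric(meta$spot_center_px),
                 spot_radius_px = as.numeric(meta$spot_radius_px),
                 pixel_size = as.numeric(meta$pixel_size),
                 config = NULL),
            class = "frap_movie")
}
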