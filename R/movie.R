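#' Construct a fluorescence movie object
#'
#' Frames are stored as a 3-D array \code{[row (y), column (x), time]} with
#' pixel (1,1) at the top-left; columns run along the tonotopic axis.
#' Micrometre coordinates map to pixels via \code{px = floor(um /
#' pixel_size_um) + 1}.
#'
#' @param frames 3-D numeric array, \code{height x width x n_frames}.
#' @param frame_rate_hz Acquisition rate (fps).
#' @param pixel_size_um Pixel side in micrometres.
#' @return An object of class \code{"fluorescence_movie"}.
#' @export
fluorescence_movie <- function(frames, frame_rate_hz, pixel_size_um) {
  stopifnot(length(dim(frames)) == 3L, all(dim(frames) >= 1L),
            pixel_size_um > 0, frame_rate_hz > 0)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "fluorescence_movie")
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("fluorescence_movie: %d x %d px, %d frames @ %.4g fps, %.4g um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

um_to_px <- function(um, pixel_size_um) as.integer(floor(um / pixel_size_um)) + 1L

# Temporal profile of a wave: half-Gaussian rise to the peak, exponential
# fall; peak at onset + 0.4 * duration, rise sigma and fall constant scaled
# to the duration so ~95% of the event mass lies within [onset, onset+dur].
wave_time_profile <- function(t, onset_s, duration_s) {
  peak <- onset_s + 0.4 * duration_s
  sigma <- 0.15 * duration_s
  tau_fall <- 0.25 * duration_s
  out <- numeric(length(t))
  rise <- t >= onset_s & t < peak
  fall <- t >= peak
  out[rise] <- exp(-((t[rise] - peak)^2) / (2 * sigma^2))
  out[fall] <- exp(-(t[fall] - peak) / tau_fall)
  out
}

#' Render a synthetic movie from traces and a wave schedule
#'
#' Cells are painted as filled squares (side \code{roi_side_um}) carrying
#' their raw trace value; waves are painted as time-modulated elliptical
#' intensity fields inside the GER band, multiplying the background so that
#' the pixelwise dF/F0 at the wave peak equals the scheduled amplitude.
#' During the rise phase the footprint propagates radially outward from the
#' wave center, reaching the full scheduled extent at the profile peak (so
#' detected events initiate inside the field, as intercellular waves do).
#' Optional pixel noise is added on top.
#'
#' @param traces Raw \code{trace_matrix} (one row per cell in
#'   \code{cell_map} order).
#' @param cell_map A [make_cell_map()] layout (provides the GER band and
#'   field size).
#' @param wave_schedule data.frame as returned by [realize_wave_schedule()],
#'   or \code{NULL} for no waves.
#' @param n_px Movie side in pixels (square frames).
#' @param roi_side_um Painted cell-square side, micrometres.
#' @param background Background intensity level (raw units).
#' @param pixel_noise_sd SD of additive Gaussian pixel noise as a fraction
#'   of the background level.
#' @param seed RNG seed for the pixel noise.
#' @return A \code{fluorescence_movie}.
#' @export
render_movie <- function(traces, cell_map, wave_schedule = NULL,
                         n_px = 512L, roi_side_um = 3.7,
                         background = 20, pixel_noise_sd = 0.02,
                         seed = 1L) {
  field <- attr(cell_map, "field_um")
  if (is.null(field)) stop("cell_map lacks a 'field_um' attribute")
  n_frames <- ncol(traces$values)
  px <- field / n_px
  if (any(cell_map$x_um < 0 | cell_map$x_um > field |
          cell_map$y_um < 0 | cell_map$y_um > field))
    stop("cells outside the frame")
  frames <- array(background, dim = c(n_px, n_px, n_frames))
  # wave fields first, so cell squares overwrite them where they overlap
  if (!is.null(wave_schedule) && nrow(wave_schedule) > 0) {
    band <- attr(cell_map, "ger_band")
    t_frames <- (seq_len(n_frames) - 1L) / traces$frame_rate_hz
    y_c <- (band$y_min_um + band$y_max_um) / 2
    b_semi <- (band$y_max_um - band$y_min_um) / 2
    xs <- (seq_len(n_px) - 0.5) * px
    ys <- (seq_len(n_px) - 0.5) * px
    for (k in seq_len(nrow(wave_schedule))) {
      w <- wave_schedule[k, ]
      prof <- wave_time_profile(t_frames, w$onset_s, w$duration_s)
      active <- which(prof > 1e-3)
      if (!length(active)) next
      a_semi <- w$extent_um / 2
      dist2 <- outer(((ys - y_c) / b_semi)^2, ((xs - w$center_um) / a_semi)^2,
                     "+")
      t_peak <- w$onset_s + 0.4 * w$duration_s
      for (f in active) {
        # footprint propagates radially from the center during the rise
        # phase, reaching the full scheduled extent at the profile peak
        grow <- min(1, max(0, (t_frames[f] - w$onset_s) /
                                (t_peak - w$onset_s)))
        idx <- which(dist2 <= grow^2)
        if (!length(idx)) next
        frames[, , f][idx] <- frames[, , f][idx] +
          background * w$amplitude * prof[f]
      }
    }
  }
  half_lo <- floor((round_half_up(roi_side_um / px) - 1L) / 2)
  half_hi <- ceiling((round_half_up(roi_side_um / px) - 1L) / 2)
  for (i in seq_len(nrow(cell_map))) {
    cx <- um_to_px(cell_map$x_um[i], px)
    cy <- um_to_px(cell_map$y_um[i], px)
    rows <- max(1L, cy - half_lo):min(n_px, cy + half_hi)
    cols <- max(1L, cx - half_lo):min(n_px, cx + half_hi)
    frames[rows, cols, ] <- rep(traces$values[i, ],
                                each = length(rows) * length(cols))
  }
  if (pixel_noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(derive_seed(seed, 2000000L))
    frames <- frames + stats::rnorm(length(frames), 0,
                                    pixel_noise_sd * background)
  }
  fluorescence_movie(frames, traces$frame_rate_hz, px)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Read / write movies as multi-page TIFF
#'
#' Movies are written as 16-bit multi-page TIFF; intensities are scaled by
#' \code{1 / max} into \eqn{[0, 1]} on write and restored on read via a
#' JSON metadata sidecar (\code{<path>.json}) that also records the frame
#' rate and pixel size, since baseline TIFF carries no authoritative values
#' for them.
#'
#' @param movie A \code{fluorescence_movie}.
#' @param path TIFF file path.
#' @param frame_rate_hz,pixel_size_um Acquisition metadata for
#'   \code{read_movie_tiff}; required when no sidecar is present, and
#'   overriding the sidecar when given.
#' @return \code{read_movie_tiff}: a \code{fluorescence_movie}.
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(movie$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(movie$frames)[3]), function(f)
    pmin(pmax(movie$frames[, , f] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = scale,
                            frame_rate_hz = movie$frame_rate_hz,
                            pixel_size_um = movie$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
    if (is.null(frame_rate_hz)) frame_rate_hz <- as.numeric(meta$frame_rate_hz)
    if (is.null(pixel_size_um)) pixel_size_um <- as.numeric(meta$pixel_size_um)
  }
  if (is.null(frame_rate_hz) || is.null(pixel_size_um))
    stop("frame_rate_hz and pixel_size_um must be supplied for TIFFs ",
         "without embedded acquisition metadata")
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * scale
  fluorescence_movie(arr, frame_rate_hz, pixel_size_um)
}
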