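#' Translation registration of a movie to its first frame
#'
#' Estimates, for every frame, the integer-pixel translation that best
#' aligns it to the first frame by FFT cross-correlation, restricted to a
#' square search radius, and applies it (edge pixels vacated by the shift
#' are filled with the frame median). Rotation is not estimated: drift of
#' the acutely dissected preparation is dominantly translational.
#'
#' @param movie A \code{fluorescence_movie} with at least 2 frames.
#' @param max_shift_px Search radius in pixels.
#' @return List with \code{movie} (registered) and \code{shifts}, an
#'   \code{n_frames x 2} matrix of applied corrections \code{(dx, dy)} in
#'   pixels (a frame whose content moved +3 px in x gets \code{dx = -3}).
#' @export
register_translation <- function(movie, max_shift_px = 20L) {
  d <- dim(movie$frames)
  if (d[3] < 2L) stop("registration needs at least 2 frames")
  ref <- movie$frames[, , 1]
  fref <- stats::fft(ref - mean(ref))
  n_r <- d[1]; n_c <- d[2]
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
  out <- movie$frames
  # candidate circular displacements within the search radius
  offs <- -max_shift_px:max_shift_px
  ridx <- ((offs %% n_r) + n_r) %% n_r + 1L
  cidx <- ((offs %% n_c) + n_c) %% n_c + 1L
  for (f in 2:d[3]) {
    fr <- movie$frames[, , f]
    cc <- Re(stats::fft(Conj(fref) * stats::fft(fr - mean(fr)),
                        inverse = TRUE))
    win <- cc[ridx, cidx]
    best <- arrayInd(which.max(win), dim(win))
    dy_content <- offs[best[1]]   # content displacement of frame vs ref
    dx_content <- offs[best[2]]
    dx <- -dx_content; dy <- -dy_content
    shifts[f, ] <- c(dx, dy)
    if (dx != 0L || dy != 0L)
      out[, , f] <- shift_frame(fr, dx, dy)
  }
  list(movie = fluorescence_movie(out, movie$frame_rate_hz,
                                  movie$pixel_size_um),
       shifts = shifts)
}

# Integer translation with median fill; dx moves content along columns (x),
# dy along rows (y).
shift_frame <- function(frame, dx, dy) {
  n_r <- nrow(frame); n_c <- ncol(frame)
  out <- matrix(stats::median(frame), n_r, n_c)
  src_r <- seq_len(n_r) - dy
  src_c <- seq_len(n_c) - dx
  ok_r <- src_r >= 1L & src_r <= n_r
  ok_c <- src_c >= 1L & src_c <= n_c
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Flag recordings with excessive drift
#'
#' Recordings whose registration shifts exceed the tolerance anywhere are
#' discarded from correlation analyses, since residual motion inflates
#' pairwise correlations.
#'
#' @param shifts Shift matrix from [register_translation()].
#' @param max_drift_px Tolerance in pixels (default 8 px, about 2 um at the
#'   wave-mode pixel size). The comparison is strict: a shift exactly at the
#'   threshold does not flag.
#' @return \code{TRUE} if the recording should be discarded.
#' @export
flag_drift <- function(shifts, max_drift_px = 8) {
  any(abs(shifts) > max_drift_px)
}

#' Extract per-cell traces by square-ROI averaging
#'
#' One trace per cell: the unweighted mean over a square ROI of side
#' \code{roi_side_um} centred on the cell. The side is converted to pixels
#' by rounding half-up; ROIs extending past the frame are clipped, not
#' rejected.
#'
#' @param movie A \code{fluorescence_movie}.
#' @param cell_map A \code{cell_map} (micrometre coordinates).
#' @param roi_side_um ROI side, micrometres.
#' @return A raw \code{trace_matrix}.
#' @export
extract_roi_traces <- function(movie, cell_map, roi_side_um = 3.7) {
  d <- dim(movie$frames)
  px <- movie$pixel_size_um
  side_px <- max(1L, round_half_up(roi_side_um / px))
  half_lo <- floor((side_px - 1L) / 2)
  half_hi <- ceiling((side_px - 1L) / 2)
  vals <- matrix(0, nrow(cell_map), d[3])
  for (i in seq_len(nrow(cell_map))) {
    cx <- um_to_px(cell_map$x_um[i], px)
    cy <- um_to_px(cell_map$y_um[i], px)
    if (cx < 1L || cx > d[2] || cy < 1L || cy > d[1])
      stop(sprintf("cell '%s' centre lies outside the frame",
                   cell_map$id[i]))
    rows <- max(1L, cy - half_lo):min(d[1], cy + half_hi)
    cols <- max(1L, cx - half_lo):min(d[2], cx + half_hi)
    vals[i, ] <- apply(movie$frames[rows, cols, , drop = FALSE], 3, mean)
  }
  trace_matrix(vals, movie$frame_rate_hz, "raw",
               as.data.frame(unclass(cell_map)))
}

#' Convert raw traces to dF/F0
#'
#' \eqn{\Delta F / F_0 = (F - F_0) / F_0} per cell and frame, with
#' \eqn{F_0} the per-cell mean of the first \code{f0_n_frames} frames.
#' \code{f0_n_frames = 1} reproduces the literal "fluorescence at the onset
#' of the recording"; the default averages 10 frames for noise robustness.
#'
#' @param traces A raw \code{trace_matrix}.
#' @param f0_n_frames Number of leading frames averaged into \eqn{F_0}.
#' @return A \code{trace_matrix} with \code{units = "dff"}.
#' @export
compute_dff <- function(traces, f0_n_frames = 10L) {
  if (traces$units != "raw") stop("compute_dff expects raw traces")
  if (f0_n_frames < 1L) stop("'f0_n_frames' must be >= 1")
  f0_n_frames <- min(as.integer(f0_n_frames), ncol(traces$values))
  f0 <- rowMeans(traces$values[, seq_len(f0_n_frames), drop = FALSE])
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("F0 <= 0 for cell(s): ",
         paste(traces$cells$id[bad], collapse = ", "))
  trace_matrix(sweep(sweep(traces$values, 1, f0, "-"), 1, f0, "/"),
               traces$frame_rate_hz, "dff", traces$cells)
}

#' Pixelwise dF/F0 of a movie
#'
#' Per-pixel baseline \eqn{F_0} from the mean of the first
#' \code{f0_n_frames} frames; used by wave segmentation.
#'
#' @inheritParams compute_dff
#' @param movie A \code{fluorescence_movie}.
#' @return A \code{fluorescence_movie} whose frames hold dF/F0 values.
#' @export
compute_movie_dff <- function(movie, f0_n_frames = 10L) {
  d <- dim(movie$frames)
  f0_n_frames <- min(as.integer(f0_n_frames), d[3])
  f0 <- apply(movie$frames[, , seq_len(f0_n_frames), drop = FALSE], c(1, 2),
              mean)
  if (any(f0 <= 0)) stop("pixel baseline F0 <= 0; cannot form dF/F0")
  out <- array(0, dim = d)
  for (f in seq_len(d[3])) out[, , f] <- movie$frames[, , f] / f0 - 1
  fluorescence_movie(out, movie$frame_rate_hz, movie$pixel_size_um)
}
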