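#' Build a wave-centred analysis window
#'
#' A 400-frame window (13.2 s at 30.3 fps) centred on the frame of maximal
#' wave intensity. Windows that would extend beyond the recording are
#' rejected outright (never shrunk): comparing correlation samples of
#' unequal length against the background window would bias the rank test.
#'
#' @param peak_frame Frame of maximal wave intensity.
#' @param n_frames_total Frames in the recording.
#' @param length_frames Window length (frames).
#' @return An \code{analysis_window} (list: \code{start_frame},
#'   \code{end_frame} — half-open \code{[start, end)} — and \code{kind}),
#'   or \code{NULL} if the window does not fit.
#' @export
make_wave_window <- function(peak_frame, n_frames_total,
                             length_frames = 400L) {
  half <- length_frames %/% 2L
  start <- peak_frame - half
  end <- start + length_frames
  if (start < 1L || end - 1L > n_frames_total) return(NULL)
  structure(list(start_frame = as.integer(start),
                 end_frame = as.integer(end), kind = "wave"),
            class = "analysis_window")
}

window_frames <- function(window) window$start_frame:(window$end_frame - 1L)

#' Pick the earliest wave-free background window
#'
#' Finds the earliest run of \code{length_frames} contiguous frames during
#' which no catalogued wave is active (a wave occupies
#' \code{[onset_frame, last_frame]}).
#'
#' @param catalog A \code{wave_catalog} (or list of \code{wave_event}s).
#' @param n_frames_total Frames in the recording.
#' @param length_frames Window length (frames).
#' @return An \code{analysis_window} of kind \code{"background"}, or
#'   \code{NULL} if no wave-free stretch of that length exists.
#' @export
pick_background_window <- function(catalog, n_frames_total,
                                   length_frames = 400L) {
  events <- if (inherits(catalog, "wave_catalog")) catalog$events else catalog
  busy <- logical(n_frames_total)
  for (ev in events) {
    busy[max(1L, ev$onset_frame):min(n_frames_total, ev$last_frame)] <- TRUE
  }
  free <- rle(!busy)
  ends <- cumsum(free$lengths)
  starts <- ends - free$lengths + 1L
  ok <- which(free$values & free$lengths >= length_frames)
  if (!length(ok)) return(NULL)
  start <- starts[ok[1]]
  structure(list(start_frame = as.integer(start),
                 end_frame = as.integer(start + length_frames),
                 kind = "background"),
            class = "analysis_window")
}

#' Pairwise Spearman correlation matrix over a window
#'
#' Spearman's rank correlation (average ranks on ties) between every pair
#' of cells, restricted to the window frames. Pairs in which either trace
#' is constant in-window have undefined rank correlation; they are set to
#' \code{NA} and counted, never zero-filled.
#'
#' @param traces \code{trace_matrix} (dF/F0; conditioned traces are
#'   recommended so bleaching trends do not inflate all pairs).
#' @param window An \code{analysis_window}.
#' @return An object of class \code{"correlation_result"}:
#'   \code{r_matrix} (symmetric, unit diagonal), \code{n_pairs_valid},
#'   \code{excluded_pairs}, \code{rsavg} (filled by [fisher_average()]),
#'   \code{window}.
#' @export
spearman_matrix <- function(traces, window) {
  vals <- traces$values[, window_frames(window), drop = FALSE]
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 cells")
  constant <- apply(vals, 1, function(v) max(v) == min(v))
  r <- suppressWarnings(stats::cor(t(vals), method = "spearman"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  ut <- r[upper.tri(r)]
  structure(list(r_matrix = r,
                 n_pairs_valid = sum(!is.na(ut)),
                 excluded_pairs = sum(is.na(ut)),
                 rsavg = NA_real_,
                 window = window),
            class = "correlation_result")
}

#' Fisher-z average of pairwise correlations
#'
#' \eqn{z = \mathrm{arctanh}(r_s)}, \eqn{r_{s,avg} = \tanh(\langle z
#' \rangle)} over the defined upper-triangle coefficients. Coefficients are
#' clipped to \eqn{1 - 10^{-7}} in magnitude before the transform.
#'
#' @param r_matrix Symmetric correlation matrix (or a
#'   \code{correlation_result}).
#' @param clip Clipping margin at \eqn{|r| = 1}.
#' @return \code{rsavg}, or \code{NA} (with a warning) if no pair is
#'   defined.
#' @export
fisher_average <- function(r_matrix, clip = 1e-7) {
  if (inherits(r_matrix, "correlation_result"))
    r_matrix <- r_matrix$r_matrix
  r <- r_matrix[upper.tri(r_matrix)]
  r <- r[!is.na(r)]
  if (!length(r)) {
    warning("no defined pairs; rsavg is undefined")
    return(NA_real_)
  }
  z <- atanh(pmin(pmax(r, -1 + clip), 1 - clip))
  tanh(mean(z))
}

#' Test for a synchronization increase during a wave
#'
#' One-sided Mann-Whitney U-test of whether the pairwise coefficients in
#' the wave window are greater than those in the background window
#' (significance at \eqn{P < 0.001}). Pairwise coefficients share cells and
#' are therefore not strictly independent samples; the test treats them as
#' exchangeable under the null, as is conventional for this statistic.
#'
#' @param wave_result,background_result \code{correlation_result}s over the
#'   same cell set.
#' @param alpha Significance level.
#' @param wave_id Optional identifier carried into the result.
#' @return An object of class \code{"sync_result"}: \code{wave_id},
#'   \code{rsavg_wave}, \code{rsavg_background}, \code{p_increase},
#'   \code{significant}, plus both correlation results.
#' @export
test_sync_increase <- function(wave_result, background_result,
                               alpha = 0.001, wave_id = NA) {
  w <- wave_result$r_matrix[upper.tri(wave_result$r_matrix)]
  b <- background_result$r_matrix[upper.tri(background_result$r_matrix)]
  w <- w[!is.na(w)]; b <- b[!is.na(b)]
  if (!length(w) || !length(b)) {
    warning("no defined pairs on one side; synchronization test undefined")
    p <- NA_real_
  } else {
    p <- stats::wilcox.test(w, b, alternative = "greater",
                            exact = FALSE)$p.value
  }
  structure(list(wave_id = wave_id,
                 rsavg_wave = fisher_average(wave_result$r_matrix),
                 rsavg_background = fisher_average(background_result$r_matrix),
                 p_increase = p,
                 significant = isTRUE(p < alpha),
                 correlation = wave_result,
                 correlation_background = background_result),
            class = "sync_result")
}

#' Integral of a smoothed trace over a window
#'
#' The trace is smoothed with a Savitzky-Golay filter (window length 11,
#' polynomial order 1 — an 11-point moving average, which preserves linear
#' segments exactly) and summed over the window divided by the frame rate;
#' units dF/F0 * s.
#'
#' @param trace dF/F0 vector.
#' @param window An \code{analysis_window}.
#' @param frame_rate_hz Acquisition rate.
#' @param sg_length,sg_order Savitzky-Golay parameters.
#' @return The integral (scalar).
#' @export
trace_integral <- function(trace, window, frame_rate_hz,
                           sg_length = 11L, sg_order = 1L) {
  if (window$end_frame - 1L > length(trace) || window$start_frame < 1L)
    stop("window extends beyond the trace")
  sm <- signal::sgolayfilt(trace, p = sg_order, n = sg_length)
  sum(sm[window_frames(window)]) / frame_rate_hz
}

#' Per-cell activity increase versus distance from a wave
#'
#' For every cell, the integral of its smoothed dF/F0 trace over the
#' wave-centred window and over the background window, the fractional
#' increase \code{(wave - background) / |background|}, and the Euclidean
#' distance from the cell centre to the nearest pixel of the wave footprint.
#' Cells with a zero background integral are excluded (and counted).
#'
#' @param traces dF/F0 \code{trace_matrix}.
#' @param cell_map Cell positions (um).
#' @param wave_event A \code{wave_event}.
#' @param background_window Background \code{analysis_window}.
#' @param bin_edges_um Distance bin edges (right-open bins).
#' @param window_length_frames Wave-window length.
#' @return List with \code{per_cell} (data.frame: \code{id},
#'   \code{distance_um}, \code{integral_wave}, \code{integral_background},
#'   \code{fractional_increase}), \code{binned} (data.frame: \code{bin},
#'   \code{mean}, \code{se}, \code{n}), \code{n_excluded}.
#' @export
activity_increase_by_distance <- function(traces, cell_map, wave_event,
                                          background_window,
                                          bin_edges_um = c(0, 50, 100, 150,
                                                           Inf),
                                          window_length_frames = 400L) {
  ww <- make_wave_window(wave_event$peak_frame, ncol(traces$values),
                         window_length_frames)
  if (is.null(ww)) stop("wave window does not fit inside the recording")
  fs <- traces$frame_rate_hz
  n_cells <- nrow(traces$values)
  dist <- vapply(seq_len(n_cells), function(i)
    wave_distance_um(wave_event, cell_map$x_um[i], cell_map$y_um[i]),
    numeric(1))
  iw <- vapply(seq_len(n_cells), function(i)
    trace_integral(traces$values[i, ], ww, fs), numeric(1))
  ib <- vapply(seq_len(n_cells), function(i)
    trace_integral(traces$values[i, ], background_window, fs), numeric(1))
  ok <- ib != 0
  per_cell <- data.frame(id = traces$cells$id[ok],
                         distance_um = dist[ok],
                         integral_wave = iw[ok],
                         integral_background = ib[ok],
                         fractional_increase = (iw[ok] - ib[ok]) / abs(ib[ok]))
  bins <- cut(per_cell$distance_um, bin_edges_um, right = FALSE,
              include.lowest = TRUE)
  agg <- lapply(split(per_cell$fractional_increase, bins), function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  binned <- data.frame(bin = names(agg),
                       do.call(rbind, agg), row.names = NULL)
  list(per_cell = per_cell, binned = binned, n_excluded = sum(!ok))
}

#' Regress synchronization against wave extension
#'
#' Ordinary least squares of \code{rsavg} on the longitudinal wave
#' extension; slope in um^-1 with its standard error, the regression
#' F-test p-value, and Pearson's r.
#'
#' @param points data.frame with columns \code{extension_um} and
#'   \code{rsavg} (rows with \code{NA} are dropped).
#' @return An object of class \code{"regression_result"}: \code{slope},
#'   \code{slope_se}, \code{p_slope}, \code{pearson_r}, \code{intercept},
#'   \code{n_points}. All-equal extensions yield \code{NA} slope with a
#'   warning.
#' @export
regress_sync_vs_extension <- function(points) {
  pts <- points[stats::complete.cases(points[, c("extension_um", "rsavg")]), ]
  if (nrow(pts) < 3L) stop("need at least 3 points for a defined fit")
  if (max(pts$extension_um) == min(pts$extension_um)) {
    warning("all extensions equal; slope undefined")
    return(structure(list(slope = NA_real_, slope_se = NA_real_,
                          p_slope = NA_real_, pearson_r = NA_real_,
                          intercept = mean(pts$rsavg),
                          n_points = nrow(pts)),
                     class = "regression_result"))
  }
  fit <- stats::lm(rsavg ~ extension_um, data = pts)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)["extension_um"]),
                 slope_se = unname(sm$coefficients["extension_um",
                                                   "Std. Error"]),
                 p_slope = unname(p),
                 pearson_r = stats::cor(pts$extension_um, pts$rsavg),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 n_points = nrow(pts)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("rsavg ~ extension: slope %.3g +/- %.3g um^-1 (F-test p = %.3g, Pearson r = %.3g, n = %d)\n",
              x$slope, x$slope_se, x$p_slope, x$pearson_r, x$n_points))
  invisible(x)
}

#' Compare OHC activity increases for small versus large waves
#'
#' Welch two-sample t-test of the per-cell fractional integral increases
#' grouped by wave extension: small waves (strictly below
#' \code{small_max_um}) versus large waves (strictly above
#' \code{large_min_um}); waves in between belong to neither class.
#'
#' @param increases data.frame with columns \code{extension_um} and
#'   \code{fractional_increase}.
#' @param small_max_um,large_min_um Class boundaries (strict).
#' @return List: \code{mean_small}, \code{mean_large}, \code{n_small},
#'   \code{n_large}, \code{t}, \code{p}.
#' @export
compare_wave_size_classes <- function(increases, small_max_um = 75,
                                      large_min_um = 150) {
  small <- increases$fractional_increase[increases$extension_um <
                                           small_max_um]
  large <- increases$fractional_increase[increases$extension_um >
                                           large_min_um]
  if (!length(small) || !length(large))
    stop("both wave-size classes must be nonempty")
  tt <- stats::t.test(large, small)
  list(mean_small = mean(small), mean_large = mean(large),
       n_small = length(small), n_large = length(large),
       t = unname(tt$statistic), p = tt$p.value)
}
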