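# n x n banded 1-D Gaussian convolution matrix with edge renormalization
gauss_conv_matrix <- function(n, sigma) {
  r <- ceiling(2 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1L & idx <= n
    K[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

#' Detect intercellular Ca2+ waves in a dF/F0 movie
#'
#' Automated replacement for manual thresholding: per-pixel baseline level
#' and noise are estimated robustly (median and scaled MAD over frames
#' sampled evenly across the whole recording, so occasional waves cannot
#' inflate the threshold), frames restricted to the GER band are
#' Gaussian-smoothed, pixels exceeding the baseline by more than
#' \code{k_sigma} times their baseline SD are marked, and marked pixels are
#' grouped into spatiotemporal connected components (8-connected in space,
#' 1-frame adjacency in time; components that merge are counted once). A
#' component becomes a wave event if its maximal single-frame area reaches
#' \code{min_area_um2} and its first suprathreshold footprint does not touch
#' the field border (events entering from outside the field of view are
#' excluded). Events whose maximal footprint touches the field border in x
#' are kept but flagged \code{censored} (their extension is a lower bound).
#'
#' @param movie_dff \code{fluorescence_movie} holding dF/F0 values (see
#'   [compute_movie_dff()]).
#' @param ger_band List with \code{y_min_um}, \code{y_max_um}: the GER band
#'   in which waves are segmented.
#' @param k_sigma Detection threshold in units of the per-pixel baseline SD
#'   (default 5, matching the wave-onset rule).
#' @param min_area_um2 Minimum peak area of an event (um^2).
#' @param baseline_frames Number of frames, sampled evenly across the
#'   recording, used for the robust per-pixel baseline statistics
#'   (default 100).
#' @param smooth_sigma_px Gaussian spatial smoothing SD in pixels.
#' @return A \code{wave_catalog}: list with \code{events} (list of
#'   \code{wave_event}), \code{duration_s}, \code{events_per_min},
#'   \code{n_excluded_boundary}.
#' @export
detect_waves <- function(movie_dff, ger_band, k_sigma = 5,
                         min_area_um2 = 100, baseline_frames = 100L,
                         smooth_sigma_px = 1) {
  d <- dim(movie_dff$frames)
  px <- movie_dff$pixel_size_um
  if (is.null(ger_band$y_min_um) || is.null(ger_band$y_max_um) ||
      ger_band$y_max_um <= ger_band$y_min_um)
    stop("empty GER band")
  r0 <- max(1L, um_to_px(ger_band$y_min_um, px))
  r1 <- min(d[1], um_to_px(ger_band$y_max_um, px))
  if (r1 < r0) stop("empty GER band")
  rows <- r0:r1
  n_t <- d[3]
  K1 <- gauss_conv_matrix(length(rows), smooth_sigma_px)
  K2 <- gauss_conv_matrix(d[2], smooth_sigma_px)
  smooth_block <- function(f_idx) {
    # separable Gaussian over the spatial dims of a block of frames
    a <- movie_dff$frames[rows, , f_idx, drop = FALSE]
    dd <- dim(a)
    a <- K1 %*% matrix(a, dd[1])
    dim(a) <- dd
    a <- aperm(a, c(2L, 1L, 3L))
    a <- K2 %*% matrix(a, dd[2])
    dim(a) <- dd[c(2L, 1L, 3L)]
    aperm(a, c(2L, 1L, 3L))
  }
  # robust per-pixel baseline: median / scaled MAD over frames sampled
  # evenly across the recording, so waves cannot inflate the threshold
  n_base <- min(max(2L, as.integer(baseline_frames)), n_t)
  base <- smooth_block(unique(round(seq(1L, n_t, length.out = n_base))))
  bm <- matrix(base, length(rows) * d[2])
  base_med <- matrix(matrixStats::rowMedians(bm), length(rows), d[2])
  base_sd <- matrix(matrixStats::rowMads(bm), length(rows), d[2])
  # guard degenerate pixels: never let the threshold collapse to ~0
  floor_sd <- max(stats::median(base_sd), 1e-6)
  base_sd <- pmax(base_sd, floor_sd)
  thr <- base_med + k_sigma * base_sd

  labels <- vector("list", n_t)   # per-frame labelled masks
  n_lab <- integer(n_t)
  block_size <- max(1L, min(n_t, as.integer(2^24 / (length(rows) * d[2]))))
  for (b0 in seq(1L, n_t, by = block_size)) {
    f_idx <- b0:min(n_t, b0 + block_size - 1L)
    sm <- smooth_block(f_idx)
    for (j in seq_along(f_idx)) {
      f <- f_idx[j]
      bin <- sm[, , j] > thr
      if (any(bin)) {
        lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
        labels[[f]] <- as.matrix(EBImage::imageData(lab))
        n_lab[f] <- max(labels[[f]])
      }
    }
  }
  # union-find over (frame, label) nodes linked by 8-neighbour overlap
  offset <- c(0L, cumsum(n_lab))[seq_len(n_t)]
  total <- sum(n_lab)
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  box3 <- EBImage::makeBrush(3L, shape = "box")
  for (f in 2:n_t) {
    if (n_lab[f] == 0L || n_lab[f - 1L] == 0L) next
    prev_dil <- as.matrix(EBImage::imageData(
      EBImage::dilate(EBImage::Image((labels[[f - 1L]] > 0) * 1), box3)))
    ov <- which(prev_dil > 0 & labels[[f]] > 0)
    if (!length(ov)) next
    # map each current label to every previous label it touches
    cur <- labels[[f]][ov]
    # previous label at the same pixel may be 0 (dilated halo); look it up
    prev <- labels[[f - 1L]][ov]
    halo <- prev == 0L
    if (any(halo)) {
      # resolve halo pixels to the nearest previous label via dilation of
      # each label is costly; instead use grayscale dilation of the label map
      prev_lab_dil <- as.matrix(EBImage::imageData(
        EBImage::dilate(EBImage::Image(labels[[f - 1L]]), box3)))
      prev[halo] <- prev_lab_dil[ov[halo]]
    }
    keep <- prev > 0L
    pairs <- unique(cbind(prev[keep], cur[keep]))
    for (k in seq_len(nrow(pairs)))
      unite(offset[f - 1L] + pairs[k, 1L], offset[f] + pairs[k, 2L])
  }
  comp_of <- vapply(seq_len(total), find, integer(1))

  duration_s <- n_t / movie_dff$frame_rate_hz
  flat <- movie_dff$frames
  dim(flat) <- c(d[1] * d[2], n_t)
  events <- list()
  n_excl <- 0L
  for (comp in unique(comp_of)) {
    nodes <- which(comp_of == comp)
    frames_in <- integer(0); areas <- integer(0)
    foot <- list()
    for (nd in nodes) {
      f <- findInterval(nd - 1L, offset)  # frame index of node
      lab <- nd - offset[f]
      pix <- which(labels[[f]] == lab, arr.ind = TRUE)
      key <- as.character(f)
      foot[[key]] <- rbind(foot[[key]], pix)
      frames_in <- c(frames_in, f)
    }
    fr <- sort(unique(frames_in))
    areas <- vapply(as.character(fr), function(k) nrow(foot[[k]]), integer(1))
    peak_area <- max(areas)
    if (peak_area * px^2 < min_area_um2) next
    onset_frame <- fr[1]
    first_foot <- foot[[as.character(onset_frame)]]
    touches_border <- function(pix)
      any(pix[, 1] + r0 - 1L <= 1L | pix[, 1] + r0 - 1L >= d[1] |
            pix[, 2] <= 1L | pix[, 2] >= d[2])
    if (touches_border(first_foot)) {   # initiated outside the field
      n_excl <- n_excl + 1L
      next
    }
    f_max <- fr[which.max(areas)]
    mask_pix <- foot[[as.character(f_max)]]
    # refine the footprint at the half-maximum contour: spatial smoothing
    # dilates the k_sigma contour outward by ~2 smoothing SDs, but leaves
    # the 50%-of-peak crossing of a sharp wave edge at the true edge, so
    # extension is measured there rather than at the detection threshold
    sm <- smooth_block(f_max)
    dim(sm) <- dim(sm)[1:2]
    sm <- sm - base_med
    half <- sm >= 0.5 * max(sm[mask_pix])
    hl <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(half * 1))))
    keep_lab <- setdiff(unique(hl[mask_pix]), 0L)
    if (length(keep_lab)) {
      mask_pix <- which(matrix(hl %in% keep_lab, nrow(hl)), arr.ind = TRUE)
    }
    mask <- data.frame(row = mask_pix[, 1] + r0 - 1L, col = mask_pix[, 2])
    censored <- any(mask$col <= 1L | mask$col >= d[2])
    lin <- (mask$col - 1L) * d[1] + mask$row
    mean_trace <- colMeans(flat[lin, , drop = FALSE])
    rel_peak <- which.max(mean_trace[onset_frame:n_t])
    peak_frame <- onset_frame + rel_peak - 1L
    events[[length(events) + 1L]] <- wave_event(
      onset_frame = onset_frame, peak_frame = peak_frame,
      last_frame = fr[length(fr)], mask = mask,
      pixel_size_um = px,
      mean_trace = mean_trace, amplitude = max(mean_trace),
      censored = censored)
  }
  # chronological order
  if (length(events))
    events <- events[order(vapply(events, `[[`, 0, "onset_frame"))]
  wave_catalog(events, duration_s, n_excluded_boundary = n_excl)
}

#' Construct a wave event
#'
#' @param onset_frame First suprathreshold frame.
#' @param peak_frame Frame of maximal mask-mean dF/F0 (>= onset).
#' @param last_frame Last frame of the spatiotemporal component.
#' @param mask data.frame of pixels (\code{row}, \code{col}) at the frame of
#'   maximal extension.
#' @param pixel_size_um Pixel size (um).
#' @param mean_trace Mask-mean dF/F0 per frame (the average cytosolic
#'   calcium rise over the wave footprint).
#' @param amplitude Maximum of \code{mean_trace}.
#' @param censored \code{TRUE} if the footprint is truncated by the field
#'   edge in x (extension underestimated).
#' @return An object of class \code{"wave_event"}; \code{extension_um} is
#'   filled in via [measure_extension()].
#' @export
wave_event <- function(onset_frame, peak_frame, last_frame, mask,
                       pixel_size_um, mean_trace = NULL, amplitude = NA_real_,
                       censored = FALSE) {
  stopifnot(onset_frame <= peak_frame, nrow(mask) >= 1L)
  ev <- structure(list(onset_frame = as.integer(onset_frame),
                       peak_frame = as.integer(peak_frame),
                       last_frame = as.integer(last_frame),
                       mask = mask, pixel_size_um = pixel_size_um,
                       mean_trace = mean_trace, amplitude = amplitude,
                       censored = isTRUE(censored),
                       extension_um = NA_real_),
                  class = "wave_event")
  ev$extension_um <- measure_extension(ev, pixel_size_um)
  ev
}

#' Longitudinal extension of a wave
#'
#' Bounding-box extent of the event mask along the tonotopic (x) axis:
#' \code{(max_col - min_col + 1) * pixel_size_um}.
#'
#' @param event A \code{wave_event}.
#' @param pixel_size_um Pixel size (um).
#' @return Extension in micrometres.
#' @export
measure_extension <- function(event, pixel_size_um = event$pixel_size_um) {
  (max(event$mask$col) - min(event$mask$col) + 1L) * pixel_size_um
}

#' Bundle events into a wave catalog
#'
#' @param events List of \code{wave_event}s.
#' @param duration_s Recording duration (s).
#' @param n_excluded_boundary Number of candidate events discarded because
#'   they entered the field from outside (first footprint on the border).
#' @return A \code{wave_catalog} with \code{events_per_min =
#'   60 * n_events / duration_s}.
#' @export
wave_catalog <- function(events, duration_s, n_excluded_boundary = 0L) {
  stopifnot(duration_s > 0)
  structure(list(events = events, duration_s = duration_s,
                 events_per_min = 60 * length(events) / duration_s,
                 n_excluded_boundary = as.integer(n_excluded_boundary)),
            class = "wave_catalog")
}

#' @export
print.wave_catalog <- function(x, ...) {
  cat(sprintf("wave_catalog: %d events in %.1f s (%.3g events/min)\n",
              length(x$events), x$duration_s, x$events_per_min))
  if (length(x$events)) {
    ext <- vapply(x$events, `[[`, 0, "extension_um")
    cat(sprintf("  extensions: %.1f-%.1f um (%d censored)\n",
                min(ext), max(ext),
                sum(vapply(x$events, `[[`, TRUE, "censored"))))
  }
  invisible(x)
}

#' Wave onset by the 5-SD rule
#'
#' First frame whose value exceeds the baseline mean by
#' \code{k_sigma} baseline SDs, computed over a stated wave-free window.
#'
#' @param mean_trace Wave-ROI mean dF/F0 per frame.
#' @param baseline_window Integer vector of frames (wave-free) used for the
#'   baseline mean and SD.
#' @param k_sigma Threshold in baseline SDs (default 5).
#' @param event_frames Optional frames known to contain the event; if the
#'   baseline window overlaps them an error is raised.
#' @return Onset frame, or \code{NA_integer_} if the threshold is never
#'   crossed.
#' @export
wave_onset <- function(mean_trace, baseline_window, k_sigma = 5,
                       event_frames = NULL) {
  if (!is.null(event_frames) && length(intersect(baseline_window,
                                                 event_frames)))
    stop("baseline window overlaps the event")
  mu <- mean(mean_trace[baseline_window])
  sigma <- stats::sd(mean_trace[baseline_window])
  hit <- which(mean_trace > mu + k_sigma * sigma)
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Radial propagation delay between two onsets
#'
#' @param onset_source_frame,onset_target_frame Onset frames (e.g. GER
#'   source and a distal Deiters' cell); \code{NA} onsets yield \code{NA}.
#' @param frame_rate_hz Acquisition rate.
#' @return Delay in seconds (may be negative, reported as-is).
#' @export
propagation_delay <- function(onset_source_frame, onset_target_frame,
                              frame_rate_hz) {
  if (is.na(onset_source_frame) || is.na(onset_target_frame))
    return(NA_real_)
  (onset_target_frame - onset_source_frame) / frame_rate_hz
}

#' Convert a ground-truth wave schedule to wave events
#'
#' Rasterizes each scheduled wave's elliptical GER footprint on a synthetic
#' pixel grid so that trace-level analyses (synchronization, distance
#' binning) can run without rendering a movie. Onset and peak frames follow
#' the wave time profile used by [render_movie()].
#'
#' @param schedule data.frame from [realize_wave_schedule()].
#' @param config The matching [simulation_config()].
#' @param ger_band GER band (from the cell map).
#' @param pixel_size_um Rasterization pixel size (um).
#' @return A \code{wave_catalog}.
#' @export
schedule_to_events <- function(schedule, config, ger_band,
                               pixel_size_um = 1) {
  fs <- config$frame_rate_hz
  n_t <- config$n_frames
  n_px <- ceiling(config$field_um / pixel_size_um)
  y_c <- (ger_band$y_min_um + ger_band$y_max_um) / 2
  b_semi <- (ger_band$y_max_um - ger_band$y_min_um) / 2
  xs <- (seq_len(n_px) - 0.5) * pixel_size_um
  ys <- (seq_len(n_px) - 0.5) * pixel_size_um
  t_frames <- (seq_len(n_t) - 1L) / fs
  events <- list()
  if (!is.null(schedule) && nrow(schedule)) {
    for (k in seq_len(nrow(schedule))) {
      w <- schedule[k, ]
      onset_frame <- min(n_t, floor(w$onset_s * fs) + 1L)
      peak_frame <- min(n_t, floor((w$onset_s + 0.4 * w$duration_s) * fs) + 1L)
      last_frame <- min(n_t, floor((w$onset_s + w$duration_s) * fs) + 1L)
      inside <- outer(((ys - y_c) / b_semi)^2,
                      ((xs - w$center_um) / (w$extent_um / 2))^2, "+") <= 1
      pix <- which(inside, arr.ind = TRUE)
      if (!nrow(pix)) next
      mask <- data.frame(row = pix[, 1], col = pix[, 2])
      prof <- wave_time_profile(t_frames, w$onset_s, w$duration_s)
      events[[length(events) + 1L]] <- wave_event(
        onset_frame = onset_frame, peak_frame = peak_frame,
        last_frame = last_frame, mask = mask,
        pixel_size_um = pixel_size_um,
        mean_trace = w$amplitude * prof, amplitude = w$amplitude,
        censored = (w$center_um - w$extent_um / 2) < 0 ||
          (w$center_um + w$extent_um / 2) > config$field_um)
    }
  }
  wave_catalog(events, n_t / fs)
}

#' Euclidean distance from a point to a wave footprint
#'
#' Distance (um) from a cell centre to the nearest mask pixel of the event
#' (0 if the centre lies inside the footprint).
#'
#' @param event A \code{wave_event}.
#' @param x_um,y_um Point coordinates (um).
#' @return Distance in micrometres.
#' @export
wave_distance_um <- function(event, x_um, y_um) {
  px <- event$pixel_size_um
  mx <- (event$mask$col - 0.5) * px
  my <- (event$mask$row - 0.5) * px
  d2 <- (mx - x_um)^2 + (my - y_um)^2
  d <- sqrt(min(d2))
  if (d <= px) 0 else d
}
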