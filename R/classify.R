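#' Welch power spectral density (internal)
#'
#' Hann-tapered, 50%-overlap segment-averaged one-sided periodogram,
#' returned as a density so that white noise of variance \eqn{\sigma^2}
#' sampled at \eqn{f_s} has a flat PSD of \eqn{2\sigma^2/f_s}.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param n_seg Segment length (frames).
#' @return List with \code{freq} (Hz, excluding DC) and \code{psd}.
#' @keywords internal
welch_psd <- function(x, fs, n_seg = 256L) {
  n <- length(x)
  if (n < n_seg) stop(sprintf("need at least %d frames", n_seg))
  step <- n_seg %/% 2L
  starts <- seq(1L, n - n_seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_seg - 1L)) / n_seg))
  norm <- fs * sum(w^2)
  half <- n_seg %/% 2L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / norm
    acc <- acc + 2 * sp[2:(half + 1L)]
  }
  list(freq = fs * (1:half) / n_seg, psd = acc / length(starts))
}

#' Estimate the noise floor from the high-frequency band
#'
#' Computes the one-sided Welch PSD and averages it over frequencies above
#' 66% of the Nyquist frequency, where the calcium signal (indicator decay
#' ~ 0.3 s) contributes essentially nothing; returns the SD of a white
#' process with that high-band density, i.e.
#' \code{sqrt(mean(psd_high) * fs / 2)}.
#'
#' @param values Trace (any units); use the detrended, unsmoothed trace —
#'   a temporal smoothing filter attenuates exactly this band.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param band_fraction Lower edge of the averaging band as a fraction of
#'   Nyquist.
#' @return Estimated noise SD in the units of \code{values}.
#' @export
estimate_noise_floor <- function(values, frame_rate_hz,
                                 band_fraction = 0.66) {
  p <- welch_psd(values, frame_rate_hz)
  hi <- p$freq > band_fraction * frame_rate_hz / 2
  sqrt(mean(p$psd[hi]) * frame_rate_hz / 2)
}

#' Condition a dF/F0 trace for classification
#'
#' The per-trace conditioning chain: (i) centred moving average of length 3
#' (edges use shrunken windows); (ii) subtraction of a least-squares
#' polynomial of order 5 in the frame index, removing slow calcium drifts
#' and photobleaching decay; the detrended trace is then normalized to its
#' maximum. The noise floor is estimated (via [estimate_noise_floor()]) on
#' the detrended but \emph{unsmoothed} trace, because the length-3 moving
#' average has a transfer-function null near two-thirds of Nyquist and would
#' empty the very band the estimator reads; it is reported both in raw
#' (\code{noise_sd_raw}) and max-normalized (\code{noise_sd}) units.
#'
#' Traces whose post-detrend maximum is not positive cannot be normalized;
#' they are marked degenerate and classified inactive downstream.
#'
#' @param trace Numeric dF/F0 vector (>= 12 frames).
#' @param frame_rate_hz Sampling rate (Hz).
#' @return An object of class \code{"conditioned_trace"}: \code{values}
#'   (normalized), \code{noise_sd}, \code{noise_sd_raw}, \code{raw_max},
#'   \code{max_signal_sd} (= raw_max / noise_sd_raw), \code{degenerate},
#'   \code{frame_rate_hz}.
#' @export
condition_trace <- function(trace, frame_rate_hz) {
  n <- length(trace)
  if (n < 12L) stop("conditioning needs at least 12 frames")
  smoothed <- moving_average3(trace)
  detr_s <- detrend_poly(smoothed, degree = 5L)
  detr_u <- detrend_poly(trace, degree = 5L)
  noise_raw <- if (n >= 256L) {
    estimate_noise_floor(detr_u, frame_rate_hz)
  } else {
    stats::sd(diff(detr_u)) / sqrt(2)  # short-trace fallback
  }
  raw_max <- max(detr_s)
  # a tolerance relative to the input scale catches traces (e.g. constants)
  # whose residuals are pure floating-point dust
  degenerate <- !is.finite(raw_max) ||
    raw_max <= 1e-10 * max(1, max(abs(trace)))
  values <- if (degenerate) detr_s else detr_s / raw_max
  structure(list(values = values,
                 noise_sd = if (degenerate) noise_raw else noise_raw / raw_max,
                 noise_sd_raw = noise_raw,
                 raw_max = raw_max,
                 max_signal_sd = if (noise_raw > 0) raw_max / noise_raw else Inf,
                 degenerate = degenerate,
                 frame_rate_hz = frame_rate_hz),
            class = "conditioned_trace")
}

moving_average3 <- function(x) {
  n <- length(x)
  out <- (c(x[1], x[-n]) + x + c(x[-1], x[n]))
  out[2:(n - 1)] <- out[2:(n - 1)] / 3
  out[1] <- (x[1] + x[2]) / 2
  out[n] <- (x[n - 1] + x[n]) / 2
  out
}

detrend_poly <- function(x, degree = 5L) {
  i <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, stats::poly(i, degree)), x)
  as.numeric(fit$residuals)
}

#' Infer spikes by nonnegative AR(1) deconvolution
#'
#' The indicator transient is modelled as an AR(1) kernel with per-frame
#' decay \eqn{\gamma = e^{-1/(\tau f_s)}}. The per-frame normalized spike
#' count is the nonnegative innovation \eqn{s_i = \max(y_i - \gamma
#' y_{i-1}, 0)}. Because the length-3 smoothing upstream spreads each
#' spike's innovation mass over three adjacent frames, sparsity is enforced
#' on the 3-frame aggregated innovation \eqn{a_i = s_{i-1} + s_i +
#' s_{i+1}}, which recaptures the full per-spike mass: frames within one
#' frame of an aggregate exceeding \code{lambda} times the noise SD
#' propagated to the aggregate domain (a closed form in \eqn{\gamma}) keep
#' their innovations, all others are zeroed. Under this convention a single
#' unit-amplitude transient carries total innovation mass \eqn{S = \sum_i
#' s_i = 1}, so \eqn{S} counts spikes in units of one unit-amplitude
#' transient.
#'
#' The default \code{lambda = 4.5} sets the expected number of spurious
#' noise-driven events per 4,000-frame recording to about 0.01.
#'
#' @param conditioned A [condition_trace()] result (its normalized values
#'   and noise floor are used).
#' @param kernel_tau_s Indicator decay constant (s).
#' @param lambda Sparsity threshold in SDs of the aggregated innovation
#'   noise.
#' @return An object of class \code{"spike_estimate"}: \code{s} (per-frame
#'   counts), \code{S} (cumulative count \eqn{\sum s_i}), \code{n_events}
#'   (local maxima of the aggregated innovation above the threshold, so one
#'   spike is one event regardless of how noise fragments its innovations).
#' @export
infer_spikes <- function(conditioned, kernel_tau_s = 0.3, lambda = 4.5) {
  stopifnot(kernel_tau_s > 0)
  y <- conditioned$values
  n <- length(y)
  gamma <- exp(-1 / (kernel_tau_s * conditioned$frame_rate_hz))
  innov <- pmax(y - gamma * c(0, y[-n]), 0)
  agg <- innov + c(0, innov[-n]) + c(innov[-1], 0)
  thr <- max(lambda * conditioned$noise_sd * agg_noise_factor(gamma), 1e-10)
  centers <- agg > thr
  keep <- centers | c(FALSE, centers[-n]) | c(centers[-1], FALSE)
  s <- ifelse(keep, innov, 0)
  # one event per local maximum of the aggregated innovation above the
  # threshold: well-separated spikes keep distinct maxima regardless of
  # amplitude, while spikes within ~1.5 frames merge (noiseless
  # equal-amplitude spikes can tie into one plateau up to 3 frames apart,
  # but measurement noise breaks such ties in practice)
  peaks <- centers & agg >= c(-Inf, agg[-n]) & agg > c(agg[-1], -Inf)
  structure(list(s = s, S = sum(s),
                 n_events = sum(peaks)),
            class = "spike_estimate")
}

# SD of the 3-frame aggregated AR(1) innovation of MA3-smoothed white
# noise, per unit SD of the unsmoothed noise (closed form in gamma).
agg_noise_factor <- function(gamma) {
  u <- 1 - gamma
  ssq <- 1 + 2 * u^2 + gamma^2
  lag1 <- u + u^2 - gamma * u
  lag2 <- u - gamma * u
  sqrt((ssq + (4 / 3) * lag1 + (2 / 3) * lag2) / 3)
}

#' Calibrate the cumulative-spike-count activity threshold
#'
#' The activity threshold on \eqn{S} is taken as the 99th percentile of
#' \eqn{S} over pure-noise simulations pushed through the identical
#' conditioning and deconvolution chain, bounding the false-active rate at
#' about 1% by construction. Because conditioning normalizes each trace to
#' its maximum, the calibration is invariant to the noise scale and is run
#' at unit SD.
#'
#' @param n_frames,frame_rate_hz Recording geometry.
#' @param kernel_tau_s,lambda Passed to [infer_spikes()].
#' @param n_sims Number of noise simulations.
#' @param probs Quantile used as threshold.
#' @param seed RNG seed.
#' @return Threshold on \eqn{S} (scalar).
#' @export
calibrate_s_threshold <- function(n_frames, frame_rate_hz,
                                  kernel_tau_s = 0.3, lambda = 4.5,
                                  n_sims = 500L, probs = 0.99, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  S <- numeric(n_sims)
  for (k in seq_len(n_sims)) {
    set.seed(derive_seed(seed, 3000000L + k))
    tr <- stats::rnorm(n_frames)
    cond <- condition_trace(tr, frame_rate_hz)
    S[k] <- infer_spikes(cond, kernel_tau_s, lambda)$S
  }
  as.numeric(stats::quantile(S, probs, names = FALSE))
}

#' Classify a cell as active or inactive
#'
#' A cell is active iff its cumulative spike count exceeds the threshold.
#' The consistency rule flags calls whose maximum signal disagrees with the
#' label — active with a maximum below 4 noise SDs, or inactive with a
#' maximum above 4 noise SDs — for review; flagged cells are never silently
#' relabelled. Degenerate conditioned traces are inactive and unflagged.
#'
#' @param estimate A [infer_spikes()] result.
#' @param conditioned The matching [condition_trace()] result.
#' @param S_threshold Activity threshold on \eqn{S} (see
#'   [calibrate_s_threshold()]).
#' @param review_sd Consistency-rule boundary in noise SDs.
#' @return An object of class \code{"activity_call"}: \code{label}
#'   (\code{"active"}/\code{"inactive"}), \code{flagged_for_review},
#'   \code{S}, \code{max_signal_sd}.
#' @export
classify_activity <- function(estimate, conditioned, S_threshold,
                              review_sd = 4) {
  stopifnot(S_threshold >= 0)
  if (conditioned$degenerate) {
    return(structure(list(label = "inactive", flagged_for_review = FALSE,
                          S = estimate$S,
                          max_signal_sd = conditioned$max_signal_sd),
                     class = "activity_call"))
  }
  active <- estimate$S > S_threshold
  flagged <- (active && conditioned$max_signal_sd < review_sd) ||
    (!active && conditioned$max_signal_sd > review_sd)
  structure(list(label = if (active) "active" else "inactive",
                 flagged_for_review = flagged,
                 S = estimate$S,
                 max_signal_sd = conditioned$max_signal_sd),
            class = "activity_call")
}

#' Spike frequency of a trace
#'
#' Number of discrete inferred events divided by the recording duration
#' (the duration is always computed from \code{n_frames / frame_rate_hz}).
#' Because events are counted as distinct maxima of the 3-frame aggregated
#' innovation, two spikes landing on the same or adjacent frames merge into
#' one counted event — a classical detector dead time of about 1.5 frames.
#' The raw event rate \eqn{r} therefore estimates
#' \eqn{\lambda e^{-\lambda\delta}} with \eqn{\delta = 1.5 / f_s}; by
#' default the returned rate inverts this relation so that Poisson firing
#' is recovered without bias (set \code{correct_dead_time = FALSE} for the
#' raw \code{n_events / duration_s}).
#'
#' @param estimate A [infer_spikes()] result.
#' @param duration_s Recording duration (s).
#' @param correct_dead_time Apply the dead-time inversion (default).
#' @return Rate in Hz.
#' @export
spike_frequency <- function(estimate, duration_s,
                            correct_dead_time = TRUE) {
  stopifnot(duration_s > 0)
  r <- estimate$n_events / duration_s
  if (!correct_dead_time || r == 0) return(r)
  fs <- length(estimate$s) / duration_s
  delta <- 1.5 / fs
  # invert r = lambda * exp(-lambda * delta) on the stable branch
  r <- min(r, exp(-1) / delta * (1 - 1e-12))
  stats::uniroot(function(l) l * exp(-l * delta) - r,
                 lower = r, upper = 1 / delta, tol = 1e-12)$root
}

#' Classify every cell of a dF/F0 trace matrix
#'
#' Runs [condition_trace()], [infer_spikes()], [classify_activity()] and
#' [spike_frequency()] per cell. If \code{S_threshold} is \code{NULL} it is
#' calibrated for this recording geometry via [calibrate_s_threshold()].
#' Cells flagged by the 4-SD consistency rule are kept or dropped according
#' to \code{flag_policy} (the reference analysis dropped discordant cells).
#'
#' @param traces \code{trace_matrix} with \code{units = "dff"}.
#' @param kernel_tau_s,lambda,S_threshold,review_sd See the per-trace
#'   functions.
#' @param flag_policy \code{"keep"} or \code{"drop"} flagged cells (dropped
#'   cells stay in the table with \code{label = NA}).
#' @param seed Seed for threshold calibration.
#' @return data.frame (one row per cell): \code{id}, \code{label},
#'   \code{flagged}, \code{S}, \code{max_signal_sd}, \code{n_events},
#'   \code{rate_hz}; the calibrated threshold is attached as attribute
#'   \code{"S_threshold"}.
#' @export
classify_cells <- function(traces, kernel_tau_s = 0.3, lambda = 4.5,
                           S_threshold = NULL,
                           flag_policy = c("keep", "drop"),
                           review_sd = 4, seed = 1L) {
  if (traces$units != "dff") stop("classification expects dF/F0 traces")
  flag_policy <- match.arg(flag_policy)
  if (is.null(S_threshold))
    S_threshold <- calibrate_s_threshold(ncol(traces$values),
                                         traces$frame_rate_hz,
                                         kernel_tau_s, lambda, seed = seed)
  duration_s <- trace_duration_s(traces)
  res <- lapply(seq_len(nrow(traces$values)), function(i) {
    cond <- condition_trace(traces$values[i, ], traces$frame_rate_hz)
    est <- infer_spikes(cond, kernel_tau_s, lambda)
    call <- classify_activity(est, cond, S_threshold, review_sd)
    data.frame(id = traces$cells$id[i], label = call$label,
               flagged = call$flagged_for_review, S = call$S,
               max_signal_sd = call$max_signal_sd,
               n_events = est$n_events,
               rate_hz = spike_frequency(est, duration_s))
  })
  out <- do.call(rbind, res)
  if (flag_policy == "drop") out$label[out$flagged] <- NA_character_
  attr(out, "S_threshold") <- S_threshold
  out
}
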