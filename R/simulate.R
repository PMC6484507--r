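#' Realize the wave schedule of a simulated recording
#'
#' If the configuration carries an explicit \code{wave_schedule} it is
#' returned as-is; otherwise wave onsets are drawn as a homogeneous Poisson
#' process at \code{wave_rate_per_min}, extents uniformly from
#' \code{wave_extent_range_um}, and centres uniformly along the tonotopic
#' axis. The realized schedule is part of the ground truth.
#'
#' @param config A [simulation_config()].
#' @return data.frame with columns \code{onset_s}, \code{extent_um},
#'   \code{center_um}, \code{amplitude}, \code{duration_s}.
#' @export
realize_wave_schedule <- function(config) {
  if (!is.null(config$wave_schedule)) return(config$wave_schedule)
  duration_s <- config$n_frames / config$frame_rate_hz
  empty <- data.frame(onset_s = numeric(0), extent_um = numeric(0),
                      center_um = numeric(0), amplitude = numeric(0),
                      duration_s = numeric(0))
  if (config$wave_rate_per_min <= 0) return(empty)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(config$seed, 0L))
  rate_s <- config$wave_rate_per_min / 60
  n <- stats::rpois(1L, rate_s * duration_s)
  if (n == 0L) return(empty)
  onset <- sort(stats::runif(n, 0, duration_s))
  extent <- stats::runif(n, config$wave_extent_range_um[1],
                         config$wave_extent_range_um[2])
  center <- stats::runif(n, 0, config$field_um)
  data.frame(onset_s = onset, extent_um = extent, center_um = center,
             amplitude = config$wave_amplitude,
             duration_s = config$wave_duration_s)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Rate multiplier applied to a cell at tonotopic position x during waves.
# g(extent) = min(extent / field, 1); distance is longitudinal distance to
# the wave footprint [center - extent/2, center + extent/2].
wave_rate_multiplier <- function(t, x_um, schedule, config) {
  mult <- rep(1, length(t))
  if (!config$coupling_enabled || nrow(schedule) == 0L) return(mult)
  for (k in seq_len(nrow(schedule))) {
    w <- schedule[k, ]
    active <- t >= w$onset_s & t <= w$onset_s + w$duration_s
    if (!any(active)) next
    d <- max(0, abs(x_um - w$center_um) - w$extent_um / 2)
    g <- min(w$extent_um / config$field_um, 1)
    boost <- 1 + config$coupling_gain * g * exp(-d / config$coupling_length_um)
    mult[active] <- pmax(mult[active], boost)
  }
  mult
}

#' Sample per-cell spike trains
#'
#' Each OHC fires as an inhomogeneous Poisson process whose rate is the sum
#' of a constant background (\code{baseline_rate_hz}) and, in burst mode, a
#' two-state burst process (exponential inter-burst intervals and burst
#' durations, constant within-burst rate). During each wave in the schedule
#' the whole rate is multiplied by the distance- and extension-dependent
#' coupling factor (see [simulation_config()]); with
#' \code{coupling_enabled = FALSE} waves leave OHC firing untouched.
#'
#' The rate is piecewise-constant at frame resolution, so the expected spike
#' count over any span of frames equals the integrated rate. Each cell uses
#' its own RNG stream derived from the master seed, so adding cells never
#' reshuffles existing ones.
#'
#' @param cell_map A [make_cell_map()] layout.
#' @param config A [simulation_config()].
#' @param schedule Realized wave schedule (default [realize_wave_schedule()]).
#' @return List (length \code{n_cells}) of numeric vectors of spike times (s).
#' @export
sample_spike_trains <- function(cell_map, config,
                                schedule = realize_wave_schedule(config)) {
  n_frames <- config$n_frames
  fs <- config$frame_rate_hz
  dt <- 1 / fs
  t_frames <- (seq_len(n_frames) - 1L) * dt
  duration_s <- n_frames * dt
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  spikes <- vector("list", nrow(cell_map))
  for (i in seq_len(nrow(cell_map))) {
    set.seed(derive_seed(config$seed, i))
    rate <- rep(config$baseline_rate_hz, n_frames)
    bp <- config$burst_params
    if (!is.null(bp) && bp$rate_hz > 0 && bp$interval_mean_s > 0) {
      t_on <- cumsum(stats::rexp(ceiling(duration_s / bp$interval_mean_s * 3) + 5,
                                 1 / bp$interval_mean_s))
      t_on <- t_on[t_on < duration_s]
      if (length(t_on)) {
        len <- stats::rexp(length(t_on), 1 / max(bp$duration_mean_s, 1e-9))
        for (b in seq_along(t_on)) {
          in_burst <- t_frames >= t_on[b] & t_frames < t_on[b] + len[b]
          rate[in_burst] <- rate[in_burst] + bp$rate_hz
        }
      }
    }
    rate <- rate * wave_rate_multiplier(t_frames, cell_map$x_um[i],
                                        schedule, config)
    counts <- stats::rpois(n_frames, rate * dt)
    idx <- rep.int(seq_len(n_frames), counts)
    spikes[[i]] <- if (length(idx))
      sort(t_frames[idx] + stats::runif(length(idx), 0, dt)) else numeric(0)
  }
  names(spikes) <- as.character(cell_map$id)
  spikes
}

#' Render fluorescence traces from spike trains
#'
#' Trace model per cell:
#' \deqn{F(t) = F_0 e^{-t/\tau_b}\,\bigl(1 + \sum_k A\,
#'   e^{-(t - t_k)/\tau}\,1[t \ge t_k]\bigr) + \epsilon(t)}
#' with indicator decay \eqn{\tau} (\code{kernel_tau_s}), per-spike amplitude
#' \eqn{A} (\code{kernel_amp}), photobleaching constant \eqn{\tau_b}, and
#' additive Gaussian noise of SD \code{noise_sd} (dF/F0 units, i.e.
#' \code{noise_sd * f0} in raw units). The sum of indicator transients is
#' evaluated exactly at the frame times by a recursive AR(1) filter on
#' partially-decayed per-frame impulses.
#'
#' @param spike_times List of per-cell spike-time vectors (seconds).
#' @param config A [simulation_config()].
#' @param cell_map Optional cell metadata attached to the trace matrix.
#' @param schedule Realized wave schedule stored in the ground truth.
#' @return List with elements \code{traces} (raw \code{trace_matrix}) and
#'   \code{ground_truth} (list: \code{spike_times}, \code{wave_events_true},
#'   \code{noiseless_traces} — cells x frames dF/F0 before noise and bleach).
#' @export
render_traces <- function(spike_times, config, cell_map = NULL,
                          schedule = NULL) {
  n_cells <- length(spike_times)
  n_frames <- config$n_frames
  fs <- config$frame_rate_hz
  t_frames <- (seq_len(n_frames) - 1L) / fs
  gamma <- exp(-1 / (config$kernel_tau_s * fs))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  clean <- matrix(0, n_cells, n_frames)
  raw <- matrix(0, n_cells, n_frames)
  bleach <- if (is.finite(config$bleach_tau_s))
    exp(-t_frames / config$bleach_tau_s) else rep(1, n_frames)
  for (i in seq_len(n_cells)) {
    imp <- numeric(n_frames)
    ts <- spike_times[[i]]
    if (length(ts)) {
      if (any(ts < 0 | ts >= n_frames / fs))
        stop("spike times must lie within the recording")
      frame <- ceiling(ts * fs) + 1L      # first frame sample at/after spike
      frame[frame > n_frames] <- n_frames
      part <- config$kernel_amp * exp(-((frame - 1L) / fs - ts) /
                                        config$kernel_tau_s)
      for (k in seq_along(frame)) imp[frame[k]] <- imp[frame[k]] + part[k]
    }
    clean[i, ] <- as.numeric(stats::filter(imp, gamma, method = "recursive"))
    set.seed(derive_seed(config$seed, 1000000L + i))
    noise <- stats::rnorm(n_frames, 0, config$noise_sd * config$f0)
    raw[i, ] <- config$f0 * bleach * (1 + clean[i, ]) + noise
  }
  cells <- if (!is.null(cell_map)) as.data.frame(unclass(cell_map)) else NULL
  list(traces = trace_matrix(raw, fs, "raw", cells),
       ground_truth = list(spike_times = spike_times,
                           wave_events_true = schedule,
                           noiseless_traces = clean))
}

#' Simulate a complete annotated recording
#'
#' Convenience wrapper chaining [make_cell_map()],
#' [realize_wave_schedule()], [sample_spike_trains()] and
#' [render_traces()]. Identical configuration (including seed) yields
#' bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with \code{traces} (raw \code{trace_matrix}),
#'   \code{cell_map}, \code{ground_truth} and \code{config}.
#' @examples
#' rec <- simulate_recording(simulation_config(n_cells = 6, n_frames = 600))
#' rec$traces
#' @export
simulate_recording <- function(config) {
  cm <- make_cell_map(config)
  schedule <- realize_wave_schedule(config)
  spikes <- sample_spike_trains(cm, config, schedule)
  out <- render_traces(spikes, config, cm, schedule)
  list(traces = out$traces, cell_map = cm,
       ground_truth = out$ground_truth, config = config)
}
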