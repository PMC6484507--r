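# helper: a conditioned trace holding an exact AR(1) transient, bypassing
# condition_trace so the deconvolution can be checked against closed forms
transient_cond <- function(amplitudes, onsets, n = 400L, fs = 30.3,
                           tau = 0.3, noise_sd = 1e-8) {
  gamma <- exp(-1 / (tau * fs))
  y <- numeric(n)
  for (k in seq_along(onsets)) {
    idx <- onsets[k]:n
    y[idx] <- y[idx] + amplitudes[k] * gamma^(seq_along(idx) - 1)
  }
  structure(list(values = y, noise_sd = noise_sd, noise_sd_raw = noise_sd,
                 raw_max = max(y), max_signal_sd = max(y) / noise_sd,
                 degenerate = FALSE, frame_rate_hz = fs),
            class = "conditioned_trace")
}

test_that("the moving average uses shrunken windows at the edges", {
  x <- c(3, 6, 9, 12, 30)
  m <- ohcsync:::moving_average3(x)
  expect_equal(m[1], (3 + 6) / 2)
  expect_equal(m[2], (3 + 6 + 9) / 3)
  expect_equal(m[3], (6 + 9 + 12) / 3)
  expect_equal(m[5], (12 + 30) / 2)
  expect_length(m, 5L)
})

test_that("detrending removes an order-5 polynomial exactly", {
  i <- seq_len(500) / 500
  drift <- 2 + 3 * i - 5 * i^2 + i^3 - 0.5 * i^4 + 0.2 * i^5
  set.seed(3)
  signal <- stats::rnorm(500, sd = 0.1)
  resid <- ohcsync:::detrend_poly(drift + signal)
  # the polynomial is annihilated; what remains is the projected signal
  expect_equal(resid, ohcsync:::detrend_poly(signal), tolerance = 1e-9)
  expect_lt(max(abs(ohcsync:::detrend_poly(drift))), 1e-9)
})

test_that("Welch density is flat at 2*sigma^2/fs for white noise", {
  set.seed(21)
  fs <- 30.3
  x <- stats::rnorm(200000, sd = 0.05)
  p <- ohcsync:::welch_psd(x, fs)
  expect_equal(mean(p$psd), 2 * 0.05^2 / fs, tolerance = 0.02)
  # integrating the one-sided density over [0, Nyquist] recovers sigma^2
  expect_equal(mean(p$psd) * fs / 2, 0.05^2, tolerance = 0.02)
})

test_that("the noise floor reads the high band and ignores slow signal", {
  set.seed(22)
  fs <- 30.3
  noise <- stats::rnorm(8000, sd = 0.05)
  expect_equal(estimate_noise_floor(noise, fs), 0.05, tolerance = 0.05)
  # a large low-frequency oscillation leaves the >66%-Nyquist band alone
  slow <- 2 * sin(2 * pi * 0.5 * seq_len(8000) / fs)
  expect_equal(estimate_noise_floor(noise + slow, fs),
               estimate_noise_floor(noise, fs), tolerance = 0.02)
})

test_that("conditioning normalizes to the max and flags degenerate traces", {
  set.seed(5)
  tr <- stats::rnorm(1000, sd = 0.05)
  tr[400:410] <- tr[400:410] + 1
  cond <- condition_trace(tr, 30.3)
  expect_false(cond$degenerate)
  expect_equal(max(cond$values), 1, tolerance = 1e-12)
  expect_equal(cond$noise_sd, cond$noise_sd_raw / cond$raw_max,
               tolerance = 1e-12)
  # a constant trace has no positive maximum after detrending
  flat <- condition_trace(rep(2, 1000), 30.3)
  expect_true(flat$degenerate)
  expect_error(condition_trace(stats::rnorm(5), 30.3), "12")
})

test_that("noiseless deconvolution recovers S = total transient amplitude", {
  # unit transient -> S = 1 and exactly one counted event
  est <- infer_spikes(transient_cond(1, 100L))
  expect_equal(est$S, 1, tolerance = 1e-6)
  expect_equal(est$n_events, 1L)
  # S is additive in amplitude and in spike count
  est2 <- infer_spikes(transient_cond(2.5, 100L))
  expect_equal(est2$S, 2.5, tolerance = 1e-6)
  est3 <- infer_spikes(transient_cond(c(1, 1, 1), c(50L, 150L, 250L)))
  expect_equal(est3$S, 3, tolerance = 1e-6)
  expect_equal(est3$n_events, 3L)
})

test_that("event counting merges adjacent spikes but separates distant ones", {
  # two spikes four frames apart keep distinct aggregate maxima
  expect_equal(infer_spikes(transient_cond(c(1, 1), c(100L, 104L)))$n_events,
               2L)
  # one frame apart they merge into a single event
  expect_equal(infer_spikes(transient_cond(c(1, 1), c(100L, 101L)))$n_events,
               1L)
  # a doubled spike on one frame is one event with twice the mass
  est <- infer_spikes(transient_cond(2, 100L))
  expect_equal(est$n_events, 1L)
  expect_equal(est$S, 2, tolerance = 1e-6)
})

test_that("sub-threshold innovations are zeroed by the sparsity rule", {
  # amplitude below lambda * noise * aggregate factor leaves S = 0
  cond <- transient_cond(1, 100L, noise_sd = 0.5)
  est <- infer_spikes(cond, lambda = 4.5)
  expect_equal(est$S, 0)
  expect_equal(est$n_events, 0L)
})

test_that("the aggregate noise factor matches a Monte-Carlo estimate", {
  set.seed(9)
  gamma <- exp(-1 / (0.3 * 30.3))
  x <- stats::rnorm(400000)
  sm <- ohcsync:::moving_average3(x)
  innov <- sm - gamma * c(0, sm[-length(sm)])
  n <- length(innov)
  agg <- innov + c(0, innov[-n]) + c(innov[-1], 0)
  expect_equal(stats::sd(agg), ohcsync:::agg_noise_factor(gamma),
               tolerance = 0.01)
})

test_that("the 4-SD consistency rule flags discordant calls only", {
  mk_cond <- function(msd) structure(list(degenerate = FALSE,
                                          max_signal_sd = msd),
                                     class = "conditioned_trace")
  mk_est <- function(S) structure(list(S = S), class = "spike_estimate")
  # active with a strong signal: concordant
  expect_false(classify_activity(mk_est(5), mk_cond(10), 1)$flagged_for_review)
  # active but the maximum is under 4 SD: flagged, never relabelled
  a <- classify_activity(mk_est(5), mk_cond(3), 1)
  expect_identical(a$label, "active")
  expect_true(a$flagged_for_review)
  # inactive with a maximum above 4 SD: flagged
  b <- classify_activity(mk_est(0), mk_cond(8), 1)
  expect_identical(b$label, "inactive")
  expect_true(b$flagged_for_review)
  # inactive and weak: concordant
  expect_false(classify_activity(mk_est(0), mk_cond(1), 1)$flagged_for_review)
  # degenerate traces are inactive and unflagged regardless of S
  d <- classify_activity(mk_est(99),
                         structure(list(degenerate = TRUE, max_signal_sd = Inf),
                                   class = "conditioned_trace"), 1)
  expect_identical(d$label, "inactive")
  expect_false(d$flagged_for_review)
})

test_that("threshold calibration is deterministic and leaves the RNG alone", {
  t1 <- calibrate_s_threshold(512L, 30.3, n_sims = 50L, seed = 7L)
  set.seed(1234)
  before <- .Random.seed
  t2 <- calibrate_s_threshold(512L, 30.3, n_sims = 50L, seed = 7L)
  expect_identical(before, .Random.seed)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
})

test_that("spike frequency inverts the 1.5-frame counting dead time", {
  est <- structure(list(s = numeric(3030), n_events = 40L),
                   class = "spike_estimate")
  expect_equal(spike_frequency(est, 100, correct_dead_time = FALSE), 0.4)
  # round trip: lambda -> observed rate -> corrected estimate
  fs <- 3030 / 100
  delta <- 1.5 / fs
  lambda <- 2
  r_obs <- lambda * exp(-lambda * delta)
  est2 <- structure(list(s = numeric(3030),
                         n_events = round(r_obs * 100)),
                    class = "spike_estimate")
  expect_equal(spike_frequency(est2, 100), lambda, tolerance = 0.02)
  # zero events stay zero under correction
  est0 <- structure(list(s = numeric(3030), n_events = 0L),
                    class = "spike_estimate")
  expect_equal(spike_frequency(est0, 100), 0)
})

test_that("classification recovers a known Poisson firing rate without bias", {
  cfg <- simulation_config(n_cells = 200, cell_spacing_um = 2,
                           n_frames = 4000, baseline_rate_hz = 0.5,
                           burst_params = NULL, wave_rate_per_min = 0,
                           seed = 31L)
  rec <- simulate_recording(cfg)
  tab <- classify_cells(compute_dff(rec$traces))
  expect_equal(nrow(tab), 200L)
  # all cells fire at 0.5 Hz for 132 s; essentially all must be called active
  expect_gt(mean(tab$label == "active"), 0.98)
  # the dead-time-corrected mean rate is within 3 SEs of the truth
  se <- stats::sd(tab$rate_hz) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$rate_hz) - 0.5), 3 * se)
})

test_that("cell classification is equivariant under row permutation", {
  cfg <- simulation_config(n_cells = 12, n_frames = 600, seed = 44L)
  rec <- simulate_recording(cfg)
  dff <- compute_dff(rec$traces)
  thr <- calibrate_s_threshold(600L, dff$frame_rate_hz, n_sims = 50L)
  t1 <- classify_cells(dff, S_threshold = thr)
  perm <- c(5:12, 1:4)
  shuffled <- trace_matrix(dff$values[perm, ], dff$frame_rate_hz, "dff",
                           dff$cells[perm, ])
  t2 <- classify_cells(shuffled, S_threshold = thr)
  expect_equal(t2$S, t1$S[perm], tolerance = 1e-12)
  expect_identical(t2$label, t1$label[perm])
  expect_error(classify_cells(rec$traces), "dF/F0")
})
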