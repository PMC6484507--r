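test_that("identical configuration and seed give bit-identical recordings", {
  cfg <- simulation_config(n_cells = 8, n_frames = 400, seed = 99L)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(a$ground_truth$spike_times, b$ground_truth$spike_times)
  expect_identical(a$ground_truth$wave_events_true,
                   b$ground_truth$wave_events_true)
  # a different seed must change the realization
  c <- simulate_recording(simulation_config(n_cells = 8, n_frames = 400,
                                            seed = 100L))
  expect_false(identical(a$traces$values, c$traces$values))
})

test_that("cell streams are stable: adding cells never reshuffles existing ones", {
  base <- simulation_config(n_cells = 5, n_frames = 300, seed = 3L,
                            wave_rate_per_min = 0)
  more <- simulation_config(n_cells = 9, n_frames = 300, seed = 3L,
                            wave_rate_per_min = 0)
  sp5 <- sample_spike_trains(make_cell_map(base), base,
                             realize_wave_schedule(base))
  sp9 <- sample_spike_trains(make_cell_map(more), more,
                             realize_wave_schedule(more))
  # cells keep their id-indexed stream even though the layout recentres
  expect_identical(lengths(sp5), lengths(sp9)[1:5])
})

test_that("null process: zero baseline rate and no waves give zero spikes", {
  cfg <- simulation_config(n_cells = 10, n_frames = 300,
                           baseline_rate_hz = 0, burst_params = NULL,
                           wave_rate_per_min = 0, seed = 1L)
  spikes <- sample_spike_trains(make_cell_map(cfg), cfg,
                                realize_wave_schedule(cfg))
  expect_true(all(lengths(spikes) == 0L))
})

test_that("Poisson mean count equals rate times duration (non-burst mode)", {
  cfg <- simulation_config(n_cells = 200, cell_spacing_um = 2,
                           n_frames = 4000, baseline_rate_hz = 1,
                           burst_params = NULL, wave_rate_per_min = 0,
                           seed = 17L)
  spikes <- sample_spike_trains(make_cell_map(cfg), cfg,
                                realize_wave_schedule(cfg))
  counts <- lengths(spikes)
  duration <- cfg$n_frames / cfg$frame_rate_hz   # 132.0 s
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1 * duration), 3 * se)
})

test_that("spike times lie in-recording and noiseless traces are nonnegative", {
  cfg <- simulation_config(n_cells = 12, n_frames = 600, seed = 5L)
  rec <- simulate_recording(cfg)
  duration <- cfg$n_frames / cfg$frame_rate_hz
  for (ts in rec$ground_truth$spike_times) {
    expect_true(all(ts >= 0 & ts < duration))
  }
  expect_true(all(rec$ground_truth$noiseless_traces >= 0))
})

test_that("with coupling disabled, waves leave spike counts untouched", {
  # identical seed: the per-cell streams must be bit-identical with and
  # without scheduled waves when the coupling multiplier is off
  sched <- data.frame(onset_s = c(5, 20), extent_um = 150, center_um = 91,
                      amplitude = 1.5, duration_s = 5)
  off <- simulation_config(n_cells = 30, n_frames = 1200, seed = 8L,
                           coupling_enabled = FALSE, wave_schedule = sched)
  none <- simulation_config(n_cells = 30, n_frames = 1200, seed = 8L,
                            wave_rate_per_min = 0)
  sp_off <- sample_spike_trains(make_cell_map(off), off,
                                realize_wave_schedule(off))
  sp_none <- sample_spike_trains(make_cell_map(none), none,
                                 realize_wave_schedule(none))
  expect_identical(sp_off, sp_none)
  # and across independent seeds the distribution is indistinguishable
  counts <- function(cfg_fun, seeds) unlist(lapply(seeds, function(s)
    lengths(sample_spike_trains(make_cell_map(cfg_fun(s)), cfg_fun(s)))))
  n_off <- counts(function(s) simulation_config(
    n_cells = 25, n_frames = 900, seed = s, coupling_enabled = FALSE,
    wave_schedule = sched), 1:4)
  n_none <- counts(function(s) simulation_config(
    n_cells = 25, n_frames = 900, seed = 100 + s,
    wave_rate_per_min = 0), 1:4)
  expect_gt(stats::t.test(n_off, n_none)$p.value, 0.01)
})

test_that("coupling raises in-wave firing according to the distance law", {
  # a long wave over the whole field multiplies the rate by 1 + gain * g
  # for cells at distance 0; check the realized mean count against it
  sched <- data.frame(onset_s = 10, extent_um = 182, center_um = 91,
                      amplitude = 1.5, duration_s = 40)
  cfg <- simulation_config(n_cells = 150, cell_spacing_um = 2,
                           n_frames = 2000, frame_rate_hz = 30.3,
                           baseline_rate_hz = 1, burst_params = NULL,
                           wave_schedule = sched, coupling_gain = 4,
                           coupling_enabled = TRUE, seed = 21L)
  spikes <- sample_spike_trains(make_cell_map(cfg), cfg,
                                realize_wave_schedule(cfg))
  # expected: 1 Hz outside the wave, (1 + 4 * 1) Hz during its 40 s
  duration <- cfg$n_frames / cfg$frame_rate_hz
  expected <- 1 * (duration - 40) + 5 * 40
  counts <- lengths(spikes)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("a lone transient has unit peak and decays by 1/e over tau", {
  fs <- 30.3
  cfg <- simulation_config(n_cells = 1, n_frames = 200, frame_rate_hz = fs,
                           noise_sd = 0, bleach_tau_s = Inf,
                           wave_rate_per_min = 0, seed = 1L)
  spike_frame <- 50L
  ts <- list(`1` = (spike_frame - 1) / fs)  # exactly on a frame time
  out <- render_traces(ts, cfg)
  clean <- out$ground_truth$noiseless_traces[1, ]
  expect_equal(which.max(clean), spike_frame)
  expect_equal(max(clean), 1, tolerance = 1e-12)
  # value after round(tau * fs) = 9 frames is within a frame step of 1/e
  k <- round(cfg$kernel_tau_s * fs)
  expect_equal(clean[spike_frame + k],
               exp(-k / (cfg$kernel_tau_s * fs)), tolerance = 1e-12)
  # raw trace equals f0 * (1 + clean) when noise and bleach are off
  expect_equal(out$traces$values[1, ], cfg$f0 * (1 + clean),
               tolerance = 1e-12)
})

test_that("degenerate layout: a single cell sits at the field centre, row 1", {
  cfg <- simulation_config(n_cells = 1)
  cm <- make_cell_map(cfg)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$x_um, cfg$field_um / 2)
  expect_equal(cm$row, 1L)
  expect_true(cm$y_um > attr(cm, "ger_band")$y_max_um)  # OHCs sit above the GER
})

test_that("layouts that overflow the field are rejected", {
  expect_error(make_cell_map(simulation_config(n_cells = 300,
                                               cell_spacing_um = 8,
                                               field_um = 125)),
               "field")
})

test_that("the realized wave schedule respects the configured ranges", {
  cfg <- simulation_config(n_frames = 8000, wave_rate_per_min = 6, seed = 2L)
  ws <- realize_wave_schedule(cfg)
  expect_gt(nrow(ws), 0)
  expect_true(all(ws$onset_s >= 0 & ws$onset_s < cfg$n_frames / cfg$frame_rate_hz))
  expect_true(all(ws$extent_um >= cfg$wave_extent_range_um[1] &
                    ws$extent_um <= cfg$wave_extent_range_um[2]))
  expect_true(all(ws$center_um >= 0 & ws$center_um <= cfg$field_um))
  expect_true(!is.unsorted(ws$onset_s))
  # an explicit schedule is passed through untouched
  sched <- data.frame(onset_s = 3, extent_um = 100, center_um = 90,
                      amplitude = 1.5, duration_s = 5)
  expect_identical(realize_wave_schedule(
    simulation_config(wave_schedule = sched)), sched)
})
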