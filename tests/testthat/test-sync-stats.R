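# independent oracle: rank with average ties, then textbook Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

win <- function(n) structure(list(start_frame = 1L, end_frame = n + 1L,
                                  kind = "wave"), class = "analysis_window")

test_that("wave windows are centred, half-open, and rejected when out of bounds", {
  w <- make_wave_window(peak_frame = 1000L, n_frames_total = 4000L)
  expect_equal(w$start_frame, 800L)
  expect_equal(w$end_frame, 1200L)
  expect_length(ohcsync:::window_frames(w), 400L)
  # 400 frames at 30.3 fps span 13.2 s
  expect_equal(400 / 30.3, 13.2, tolerance = 1e-3)
  expect_null(make_wave_window(100L, 4000L))   # would start before frame 1
  expect_null(make_wave_window(3900L, 4000L))  # would run past the end
})

test_that("the background window is the earliest wave-free stretch", {
  ev <- function(a, b) wave_event(a, a, b,
                                  mask = data.frame(row = 1L, col = 1L),
                                  pixel_size_um = 1)
  cat_ <- wave_catalog(list(ev(100L, 300L), ev(1000L, 1100L)), 60)
  bg <- pick_background_window(cat_, 2000L, length_frames = 400L)
  expect_equal(bg$start_frame, 301L)
  expect_equal(bg$end_frame, 701L)
  # no free stretch long enough -> NULL
  expect_null(pick_background_window(cat_, 2000L, length_frames = 1500L))
})

test_that("spearman_matrix matches the brute-force oracle to 1e-10", {
  set.seed(42)
  for (k in 1:200) {
    vals <- matrix(stats::rnorm(10 * 50), 10, 50)
    if (k %% 3 == 0) vals <- round(vals)  # inject ties
    tr <- trace_matrix(vals, 10, "dff", data.frame(id = 1:10))
    res <- spearman_matrix(tr, win(50))
    i <- sample(10, 1); j <- sample(setdiff(1:10, i), 1)
    expect_equal(res$r_matrix[i, j], oracle_spearman(vals[i, ], vals[j, ]),
                 tolerance = 1e-10)
  }
  # frozen worked value: ranks displaced pairwise -> 1 - 6*4/(5*24) = 0.8
  tr <- trace_matrix(rbind(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 10, "dff",
                     data.frame(id = 1:2))
  expect_equal(spearman_matrix(tr, win(5))$r_matrix[1, 2], 0.8,
               tolerance = 1e-12)
})

test_that("rank correlations are invariant under monotone per-cell transforms", {
  set.seed(7)
  vals <- matrix(stats::rnorm(6 * 80), 6, 80)
  tr <- trace_matrix(vals, 10, "dff", data.frame(id = 1:6))
  warped <- trace_matrix(exp(3 * vals) - 0.5, 10, "dff", data.frame(id = 1:6))
  expect_equal(spearman_matrix(tr, win(80))$r_matrix,
               spearman_matrix(warped, win(80))$r_matrix, tolerance = 1e-12)
})

test_that("constant in-window traces yield NA pairs that are counted, not zeroed", {
  vals <- rbind(stats::rnorm(30), stats::rnorm(30), rep(1, 30))
  tr <- trace_matrix(vals, 10, "dff", data.frame(id = 1:3))
  res <- spearman_matrix(tr, win(30))
  expect_true(is.na(res$r_matrix[1, 3]))
  expect_true(is.na(res$r_matrix[2, 3]))
  expect_false(is.na(res$r_matrix[1, 2]))
  expect_equal(res$n_pairs_valid, 1L)
  expect_equal(res$excluded_pairs, 2L)
})

test_that("fisher averaging reproduces its closed form and fixed points", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0
  r[1, 3] <- r[3, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- 0.9
  expect_equal(fisher_average(r), tanh((atanh(0) + 2 * atanh(0.9)) / 3),
               tolerance = 1e-12)
  # all off-diagonal entries equal r -> rsavg == r (fixed point)
  for (val in c(-0.7, 0, 0.3, 0.999999)) {
    m <- matrix(val, 4, 4); diag(m) <- 1
    expect_equal(fisher_average(m), val, tolerance = 1e-6)
  }
  # |r| = 1 entries are clipped, not infinite
  m <- matrix(1, 3, 3)
  expect_true(is.finite(fisher_average(m)))
  # no defined pairs -> NA with a warning
  m <- diag(2); m[1, 2] <- m[2, 1] <- NA
  expect_warning(val <- fisher_average(m), "no defined pairs")
  expect_true(is.na(val))
})

test_that("two-cell fisher average of {0, 0.9} equals the printed 0.627", {
  r <- diag(2)
  vals <- c(0, 0.9)
  z <- atanh(vals)
  expect_equal(tanh(mean(z)), 0.627, tolerance = 5e-4)
})

test_that("the rank-sum test detects extreme separation and respects the null", {
  mk <- function(v) {
    m <- matrix(v, 10, 10); diag(m) <- 1
    structure(list(r_matrix = m), class = "correlation_result")
  }
  hi <- mk(0.9); lo <- mk(0.0)
  res <- test_sync_increase(hi, lo)
  expect_lt(res$p_increase, 0.001)
  expect_true(res$significant)
  expect_equal(res$rsavg_wave, 0.9, tolerance = 1e-6)
  expect_equal(res$rsavg_background, 0, tolerance = 1e-12)
  # identical samples can never be called an increase
  res0 <- test_sync_increase(hi, hi)
  expect_gte(res0$p_increase, 0.5)
  expect_false(res0$significant)
  # exchangeable (but non-degenerate) samples: one-sided p is central
  set.seed(3)
  mkr <- function() {
    v <- stats::rnorm(45)
    m <- matrix(1, 10, 10)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    structure(list(r_matrix = tanh(m)), class = "correlation_result")
  }
  ps <- replicate(40, test_sync_increase(mkr(), mkr())$p_increase)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("trace integrals follow the Savitzky-Golay worked values", {
  fs <- 30.3
  w <- structure(list(start_frame = 1L, end_frame = 401L, kind = "wave"),
                 class = "analysis_window")
  # constant 0.2 over 400 frames -> 0.2 * 400 / 30.3 = 2.64
  expect_equal(trace_integral(rep(0.2, 450), w, fs), 0.2 * 400 / fs,
               tolerance = 1e-10)
  expect_equal(0.2 * 400 / fs, 2.64, tolerance = 1e-2)
  expect_equal(trace_integral(rep(0, 450), w, fs), 0)
  # an order-1 fit preserves linear ramps exactly (away from nothing:
  # sgolay pads with sub-filters, so the whole ramp is preserved)
  ramp <- seq(0, 1, length.out = 450)
  expect_equal(trace_integral(ramp, w, fs), sum(ramp[1:400]) / fs,
               tolerance = 1e-8)
  expect_error(trace_integral(rep(1, 100), w, fs), "window")
})

test_that("activity increases: distance handling and excluded denominators", {
  ev <- wave_event(onset_frame = 500L, peak_frame = 500L, last_frame = 600L,
                   mask = expand.grid(row = 10:20, col = 30:60),
                   pixel_size_um = 1)
  cm <- data.frame(id = 1:3, x_um = c(45, 45, 100), y_um = c(15, 80, 15),
                   row = 1L)
  # cell 1 inside the footprint, cell 2 is 60 um above it, cell 3 is 40 right
  expect_equal(wave_distance_um(ev, 45, 15), 0)
  expect_equal(wave_distance_um(ev, 45, 80), 80 - 19.5, tolerance = 0.8)
  expect_equal(wave_distance_um(ev, 100, 15), 100 - 59.5, tolerance = 0.8)
  vals <- rbind(rep(1, 1000), rep(1, 1000), rep(0, 1000))
  vals[1, 500:520] <- 2
  tr <- trace_matrix(vals, 30.3, "dff", data.frame(id = 1:3))
  bg <- structure(list(start_frame = 1L, end_frame = 401L,
                       kind = "background"), class = "analysis_window")
  inc <- activity_increase_by_distance(tr, cm, ev, bg)
  # the zero-background cell is excluded and counted
  expect_equal(inc$n_excluded, 1L)
  expect_equal(nrow(inc$per_cell), 2L)
  # wave == background integral -> fractional increase 0 for cell 2
  expect_equal(inc$per_cell$fractional_increase[2], 0, tolerance = 1e-10)
  expect_gt(inc$per_cell$fractional_increase[1], 0)
})

test_that("the extension regression matches an exact line and flags a flat design", {
  L <- c(20, 60, 100, 140, 180)
  pts <- data.frame(extension_um = L, rsavg = 0.002 * L + 0.1)
  # lm warns about the deliberately exact fit; that is the point here
  fit <- suppressWarnings(regress_sync_vs_extension(pts))
  expect_equal(fit$slope, 0.002, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_lt(fit$p_slope, 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-8)
  expect_error(regress_sync_vs_extension(pts[1:2, ]), "3")
  flat <- data.frame(extension_um = rep(80, 5), rsavg = stats::rnorm(5))
  expect_warning(f2 <- regress_sync_vs_extension(flat), "extension")
  expect_true(is.na(f2$slope))
})

test_that("wave size classes use strict boundaries and a Welch test", {
  d <- data.frame(extension_um = c(50, 60, 74, 75, 150, 151, 160, 170),
                  fractional_increase = c(1, 1.2, 0.9, 5, 5, 3.0, 3.2, 2.8))
  res <- compare_wave_size_classes(d)
  # the 75 and 150 um waves belong to neither class
  expect_equal(res$n_small, 3L)
  expect_equal(res$n_large, 3L)
  expect_equal(res$mean_small, mean(c(1, 1.2, 0.9)), tolerance = 1e-12)
  expect_equal(res$mean_large, mean(c(3.0, 3.2, 2.8)), tolerance = 1e-12)
  oracle <- stats::t.test(c(3.0, 3.2, 2.8), c(1, 1.2, 0.9))
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_error(compare_wave_size_classes(d[d$extension_um < 100, ]), "class")
})
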