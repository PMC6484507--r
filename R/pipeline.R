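#' Condition every trace of a dF/F0 matrix for correlation analysis
#'
#' Applies the per-trace conditioning chain (length-3 moving average and
#' order-5 polynomial detrend) without max-normalization — Spearman
#' statistics are invariant to the positive rescaling anyway — so that
#' photobleaching trends shared by all cells do not inflate every pairwise
#' correlation.
#'
#' @param traces \code{trace_matrix} with \code{units = "dff"}.
#' @return A \code{trace_matrix} of conditioned dF/F0 traces.
#' @export
condition_traces <- function(traces) {
  if (traces$units != "dff") stop("expected dF/F0 traces")
  vals <- t(apply(traces$values, 1, function(v)
    detrend_poly(moving_average3(v), 5L)))
  trace_matrix(vals, traces$frame_rate_hz, "dff", traces$cells)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) -> classify -> waves -> synchronization.
#' With \code{sim_config} the recording is simulated and wave events are
#' taken from the realized ground-truth schedule; with \code{movie} the
#' movie is registered, drift-checked, ROI traces extracted and waves
#' segmented with [detect_waves()]; with \code{traces} alone the wave-
#' dependent stages require a catalog simulated or detected elsewhere.
#'
#' Per wave, a 400-frame window centred on the wave peak is compared
#' against the earliest wave-free background window: pairwise Spearman
#' matrices, Fisher-z averages, the one-sided Mann-Whitney increase test,
#' and per-cell integral increases by distance. Waves are then pooled into
#' the rsavg-versus-extension regression and the small/large wave class
#' comparison. Every accepted or rejected wave leaves a log line.
#'
#' @param mode One of \code{"all"}, \code{"simulate"}, \code{"classify"},
#'   \code{"waves"}, \code{"sync"}; stages outside the mode are skipped.
#' @param sim_config A [simulation_config()], or path to its YAML file.
#' @param traces A \code{trace_matrix} (raw or dff) or traces CSV path.
#' @param movie A \code{fluorescence_movie} or multi-page TIFF path.
#' @param cell_map A \code{cell_map} or cell-map JSON path (required with
#'   \code{movie}).
#' @param out_dir If non-NULL, report files are written there.
#' @param s_threshold Activity threshold (NULL = calibrate per run).
#' @param k_sigma Wave-detection threshold (baseline SDs).
#' @param min_area_um2 Minimum wave peak area.
#' @param max_drift_px Drift rejection tolerance (px).
#' @param f0_n_frames Frames averaged into F0.
#' @param kernel_tau_s Indicator decay constant (s).
#' @param window_length_frames Analysis window length.
#' @param seed Master seed (overrides the simulation config's seed when
#'   given).
#' @param verbose Print stage summaries.
#' @return A \code{run_report} list; see the elements documented in the
#'   package vignette.
#' @export
run_pipeline <- function(mode = c("all", "simulate", "classify", "waves",
                                  "sync"),
                         sim_config = NULL, traces = NULL, movie = NULL,
                         cell_map = NULL, out_dir = NULL,
                         s_threshold = NULL, k_sigma = 5,
                         min_area_um2 = 100, max_drift_px = 8,
                         f0_n_frames = 10L, kernel_tau_s = 0.3,
                         window_length_frames = 400L,
                         seed = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  if (is.character(sim_config)) sim_config <- read_simulation_config(sim_config)
  if (is.character(traces)) traces <- read_traces_csv(traces)
  if (is.character(cell_map)) cell_map <- read_cell_map(cell_map)
  if (is.character(movie)) movie <- read_movie_tiff(movie)
  if (!is.null(seed) && !is.null(sim_config)) sim_config$seed <- as.integer(seed)
  if (is.null(seed)) seed <- if (!is.null(sim_config)) sim_config$seed else 1L

  catalog <- NULL
  ground_truth <- NULL
  drift <- NULL

  if (!is.null(sim_config)) {
    rec <- simulate_recording(sim_config)
    traces <- rec$traces
    cell_map <- rec$cell_map
    ground_truth <- rec$ground_truth
    catalog <- schedule_to_events(ground_truth$wave_events_true, sim_config,
                                  attr(cell_map, "ger_band"))
    note("simulated %d cells x %d frames; %d scheduled waves",
         nrow(traces$values), ncol(traces$values), length(catalog$events))
  }
  if (mode == "simulate") {
    report <- list(mode = mode, seed = seed, config = unclass(sim_config),
                   traces = traces, cell_map = cell_map,
                   ground_truth = ground_truth, catalog = catalog, log = log,
                   version = as.character(utils::packageVersion("ohcsync")))
    class(report) <- "run_report"
    if (!is.null(out_dir)) write_run_report(report, out_dir)
    return(report)
  }

  if (!is.null(movie)) {
    reg <- register_translation(movie)
    drift <- list(discard = flag_drift(reg$shifts, max_drift_px),
                  max_shift_px = max(abs(reg$shifts)))
    note("registration: max shift %d px%s", drift$max_shift_px,
         if (drift$discard) " -- recording flagged for discard" else "")
    movie <- reg$movie
    if (is.null(cell_map)) stop("a cell map is required with a movie input")
    traces <- extract_roi_traces(movie, cell_map)
  }
  if (is.null(traces)) stop("no traces available: supply sim_config, traces or movie")
  if (traces$units == "raw") traces <- compute_dff(traces, f0_n_frames)

  cells <- NULL
  if (mode %in% c("all", "classify")) {
    cells <- classify_cells(traces, kernel_tau_s = kernel_tau_s,
                            S_threshold = s_threshold, seed = seed)
    note("classified %d cells: %d active, %d flagged",
         nrow(cells), sum(cells$label == "active", na.rm = TRUE),
         sum(cells$flagged))
  }

  if (is.null(catalog) && !is.null(movie) &&
      mode %in% c("all", "waves", "sync")) {
    band <- attr(cell_map, "ger_band")
    if (is.null(band)) stop("cell map lacks a GER band; wave detection needs one")
    catalog <- detect_waves(compute_movie_dff(movie, f0_n_frames), band,
                            k_sigma = k_sigma, min_area_um2 = min_area_um2)
    note("detected %d waves (%.3g events/min)", length(catalog$events),
         catalog$events_per_min)
  }

  sync_df <- NULL; regression <- NULL; increases <- NULL
  size_class <- NULL; binned <- NULL
  if (mode %in% c("all", "sync") && !is.null(catalog) &&
      length(catalog$events) > 0) {
    n_frames <- ncol(traces$values)
    bg <- pick_background_window(catalog, n_frames, window_length_frames)
    if (is.null(bg)) {
      note("no wave-free background window of %d frames; synchronization analysis aborted",
           window_length_frames)
    } else {
      note("background window [%d, %d)", bg$start_frame, bg$end_frame)
      cond <- condition_traces(traces)
      bg_res <- spearman_matrix(cond, bg)
      # Integrals are compared across windows taken at different times, so
      # they are computed on the detrended traces with the unit baseline
      # restored (i.e. F/F0 rather than dF/F0): photobleaching would
      # otherwise dominate the window difference, and the strictly positive
      # denominator keeps the fractional increase stable.
      int_traces <- trace_matrix(cond$values + 1, traces$frame_rate_hz,
                                 units = "dff", cells = traces$cells)
      rows <- list(); inc_rows <- list(); wave_means <- list()
      for (k in seq_along(catalog$events)) {
        ev <- catalog$events[[k]]
        ww <- make_wave_window(ev$peak_frame, n_frames, window_length_frames)
        if (is.null(ww)) {
          note("wave %d rejected: window around peak frame %d out of bounds",
               k, ev$peak_frame)
          next
        }
        overlapping <- any(vapply(catalog$events[-k], function(e2)
          ww$start_frame <= e2$last_frame & e2$onset_frame <= ww$end_frame - 1L,
          logical(1)))
        w_res <- spearman_matrix(cond, ww)
        sr <- test_sync_increase(w_res, bg_res, wave_id = k)
        inc <- activity_increase_by_distance(int_traces, cell_map, ev, bg,
                                             window_length_frames =
                                               window_length_frames)
        rows[[length(rows) + 1L]] <- data.frame(
          wave_id = k, extension_um = ev$extension_um,
          censored = ev$censored, overlapping = overlapping,
          amplitude = ev$amplitude,
          rsavg = sr$rsavg_wave, rsavg_background = sr$rsavg_background,
          p_increase = sr$p_increase, significant = sr$significant)
        inc$per_cell$wave_id <- k
        inc$per_cell$extension_um <- ev$extension_um
        inc_rows[[length(inc_rows) + 1L]] <- inc$per_cell
        wave_means[[length(wave_means) + 1L]] <- data.frame(
          wave_id = k, extension_um = ev$extension_um,
          fractional_increase = mean(inc$per_cell$fractional_increase))
        note("wave %d accepted: L = %.1f um, rsavg %.3f vs %.3f (p = %.3g)%s%s",
             k, ev$extension_um, sr$rsavg_wave, sr$rsavg_background,
             sr$p_increase, if (ev$censored) ", censored" else "",
             if (overlapping) ", overlapping" else "")
      }
      if (length(rows)) {
        sync_df <- do.call(rbind, rows)
        increases <- do.call(rbind, inc_rows)
        wave_level <- do.call(rbind, wave_means)
        if (nrow(sync_df) >= 3L &&
            max(sync_df$extension_um) > min(sync_df$extension_um))
          regression <- regress_sync_vs_extension(sync_df)
        binned <- pooled_distance_bins(increases)
        size_class <- tryCatch(compare_wave_size_classes(wave_level),
                               error = function(e) {
                                 note("size-class comparison skipped: %s",
                                      conditionMessage(e))
                                 NULL
                               })
      }
    }
  }

  report <- list(mode = mode, seed = seed,
                 config = if (!is.null(sim_config)) unclass(sim_config),
                 thresholds = list(s_threshold = if (!is.null(cells))
                   attr(cells, "S_threshold") else s_threshold,
                   k_sigma = k_sigma, min_area_um2 = min_area_um2,
                   max_drift_px = max_drift_px, f0_n_frames = f0_n_frames),
                 drift = drift, cells = cells,
                 catalog = catalog, sync = sync_df,
                 regression = regression,
                 increases = increases, increase_binned = binned,
                 size_class = size_class,
                 traces = traces, cell_map = cell_map,
                 ground_truth = ground_truth,
                 log = log,
                 version = as.character(utils::packageVersion("ohcsync")))
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# Pool per-cell fractional increases across waves into distance bins.
pooled_distance_bins <- function(increases,
                                 bin_edges_um = c(0, 50, 100, 150, Inf)) {
  bins <- cut(increases$distance_um, bin_edges_um, right = FALSE,
              include.lowest = TRUE)
  agg <- lapply(split(increases$fractional_increase, bins), function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  data.frame(bin = names(agg), do.call(rbind, agg), row.names = NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (mode '%s', seed %d, ohcsync %s)\n",
              x$mode, x$seed, x$version))
  if (!is.null(x$cells))
    cat(sprintf("  cells: %d (%d active, %d flagged; S threshold %.3g)\n",
                nrow(x$cells), sum(x$cells$label == "active", na.rm = TRUE),
                sum(x$cells$flagged), x$thresholds$s_threshold))
  if (!is.null(x$catalog))
    cat(sprintf("  waves: %d (%.3g events/min)\n", length(x$catalog$events),
                x$catalog$events_per_min))
  if (!is.null(x$sync))
    cat(sprintf("  sync: %d analysed waves, %d significant\n",
                nrow(x$sync), sum(x$sync$significant)))
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}

#' Serialize a run report
#'
#' Writes \code{report.json} (config echo, thresholds, wave summaries, the
#' regression and class comparison, the log), plus CSV side-tables
#' (\code{cells.csv}, \code{sync.csv}, \code{increases.csv}) and the traces
#' (\code{traces.csv}).
#'
#' @param report A \code{run_report}.
#' @param out_dir Output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  core <- list(mode = report$mode, seed = report$seed,
               version = report$version,
               config = report$config[setdiff(names(report$config),
                                              "wave_schedule")],
               thresholds = report$thresholds,
               drift = report$drift,
               events_per_min = if (!is.null(report$catalog))
                 report$catalog$events_per_min,
               sync = report$sync,
               regression = if (!is.null(report$regression))
                 unclass(report$regression),
               increase_binned = report$increase_binned,
               size_class = report$size_class,
               log = report$log)
  jsonlite::write_json(core, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$cells))
    utils::write.csv(report$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
  if (!is.null(report$sync))
    utils::write.csv(report$sync, file.path(out_dir, "sync.csv"),
                     row.names = FALSE)
  if (!is.null(report$increases))
    utils::write.csv(report$increases, file.path(out_dir, "increases.csv"),
                     row.names = FALSE)
  if (!is.null(report$traces))
    write_traces_csv(report$traces, file.path(out_dir, "traces.csv"))
  if (!is.null(report$catalog))
    write_wave_catalog(report$catalog, file.path(out_dir, "waves.json"))
  invisible(out_dir)
}
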