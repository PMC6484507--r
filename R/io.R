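#' Read and write trace matrices as CSV
#'
#' Layout: commented header lines carrying the acquisition metadata
#' (\code{# frame_rate_hz: ...}, \code{# units: ...}), then a header row
#' \code{id,x_um,y_um,row,f1,...,fN} and one row per cell.
#'
#' @param traces A \code{trace_matrix}.
#' @param path CSV file path.
#' @return \code{read_traces_csv}: a \code{trace_matrix}.
#' @export
write_traces_csv <- function(traces, path) {
  meta <- traces$cells
  for (col in c("x_um", "y_um", "row"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  df <- cbind(meta[, c("id", "x_um", "y_um", "row")],
              as.data.frame(traces$values))
  names(df) <- c("id", "x_um", "y_um", "row",
                 paste0("f", seq_len(ncol(traces$values))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz: %.10g", traces$frame_rate_hz), con)
  writeLines(sprintf("# units: %s", traces$units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty traces file: ", path)
  comments <- grep("^#", lines, value = TRUE)
  fr_line <- grep("frame_rate_hz", comments, value = TRUE)
  if (!length(fr_line))
    stop("missing '# frame_rate_hz:' header line in ", path)
  frame_rate <- as.numeric(sub(".*frame_rate_hz:\\s*", "", fr_line[1]))
  units_line <- grep("units", comments, value = TRUE)
  units <- if (length(units_line))
    trimws(sub(".*units:\\s*", "", units_line[1])) else "raw"
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("traces file has no data rows: ", path)
  nf <- utils::count.fields(textConnection(body), sep = ",")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row %d in %s (%d fields, expected %d)",
                 bad, path, nf[bad], nf[1]))
  }
  df <- utils::read.csv(textConnection(body))
  frame_cols <- grep("^f[0-9]+$", names(df))
  if (!length(frame_cols)) stop("no frame columns (f1..fN) in ", path)
  trace_matrix(as.matrix(df[, frame_cols]), frame_rate, units,
               df[, c("id", "x_um", "y_um", "row"), drop = FALSE])
}

#' Write a wave catalog as JSON
#'
#' Events are serialized with onset/peak frames, extension, censoring flag
#' and the bounding box of the maximal footprint (pixel coordinates); pixel
#' masks and mean traces are summarized, not dumped.
#'
#' @param catalog A \code{wave_catalog}.
#' @param path JSON file path.
#' @export
write_wave_catalog <- function(catalog, path) {
  events <- lapply(catalog$events, function(ev) {
    list(onset_frame = ev$onset_frame, peak_frame = ev$peak_frame,
         last_frame = ev$last_frame, extension_um = ev$extension_um,
         censored = ev$censored, amplitude = ev$amplitude,
         mask_bbox_px = list(row_min = min(ev$mask$row),
                             row_max = max(ev$mask$row),
                             col_min = min(ev$mask$col),
                             col_max = max(ev$mask$col)),
         mask_area_px = nrow(ev$mask))
  })
  jsonlite::write_json(list(duration_s = catalog$duration_s,
                            events_per_min = catalog$events_per_min,
                            events = events),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Area of a pixel mask in um^2 (used for the minimum-area rule).
mask_area_um2 <- function(mask, pixel_size_um) {
  nrow(mask) * pixel_size_um^2
}

#' Rasterize a rectangle and return its area
#'
#' Utility for sizing rectangular regions (e.g. a stimulation or ROI
#' rectangle) on the pixel grid: the rectangle is rasterized at the given
#' pixel size and the resulting mask area returned in um^2.
#'
#' @param width_um,height_um Rectangle sides (um).
#' @param pixel_size_um Pixel size (um); \code{NULL} returns the exact
#'   geometric area.
#' @return Area in um^2.
#' @export
rect_area_um2 <- function(width_um, height_um, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) return(width_um * height_um)
  nx <- round_half_up(width_um / pixel_size_um)
  ny <- round_half_up(height_um / pixel_size_um)
  mask <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  mask_area_um2(mask, pixel_size_um)
}
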