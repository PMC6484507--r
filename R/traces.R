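#' Construct a trace matrix (cells x frames)
#'
#' The common substrate of all downstream statistics: one fluorescence trace
#' per cell, either raw intensity (\code{units = "raw"}) or fractional change
#' relative to the recording onset (\code{units = "dff"}).
#'
#' @param values Numeric matrix, one row per cell, one column per frame.
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param units \code{"raw"} or \code{"dff"}.
#' @param cells Optional data.frame of cell metadata with at least an
#'   \code{id} column (typically \code{id}, \code{x_um}, \code{y_um},
#'   \code{row}); defaults to sequential ids.
#' @return An object of class \code{"trace_matrix"}.
#' @export
trace_matrix <- function(values, frame_rate_hz, units = c("raw", "dff"),
                         cells = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (anyNA(values)) stop("trace values must not contain missing frames")
  if (frame_rate_hz <= 0) stop("'frame_rate_hz' must be > 0")
  if (is.null(cells)) {
    cells <- data.frame(id = seq_len(nrow(values)))
  }
  if (nrow(cells) != nrow(values))
    stop("cell metadata rows must match the number of traces")
  if (anyDuplicated(cells$id)) stop("cell ids must be unique")
  rownames(values) <- as.character(cells$id)
  structure(list(values = values, frame_rate_hz = frame_rate_hz,
                 units = units, cells = cells),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("trace_matrix [%s]: %d cells x %d frames @ %.4g fps (%.1f s)\n",
              x$units, nrow(x$values), ncol(x$values), x$frame_rate_hz,
              ncol(x$values) / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Recording duration in seconds
#' @param traces A \code{trace_matrix}.
#' @return Duration \code{n_frames / frame_rate_hz} in seconds.
#' @export
trace_duration_s <- function(traces) {
  ncol(traces$values) / traces$frame_rate_hz
}
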