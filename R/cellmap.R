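#' Lay out outer hair cells on the tonotopic grid
#'
#' Positions `n_cells` OHCs in up to three rows parallel to the tonotopic
#' (x) axis, mirroring the three OHC rows of the organ of Corti, centred in
#' the imaging field. The greater epithelial ridge (GER) is modelled as a
#' band on the low-y side of the field; its y-range is attached as the
#' \code{ger_band} attribute and used both to paint waves into synthetic
#' movies and to restrict wave segmentation.
#'
#' @param config A [simulation_config()].
#' @return A data.frame of class \code{"cell_map"} with columns \code{id},
#'   \code{x_um}, \code{y_um}, \code{row}, plus attribute \code{ger_band}
#'   (list with \code{y_min_um}, \code{y_max_um}) and \code{field_um}.
#' @examples
#' cm <- make_cell_map(simulation_config(n_cells = 9, field_um = 125))
#' range(cm$x_um)
#' @export
make_cell_map <- function(config) {
  n <- config$n_cells
  field <- config$field_um
  spacing <- config$cell_spacing_um
  n_rows <- min(3L, n)
  per_row <- ceiling(n / n_rows)
  span <- (per_row - 1L) * spacing
  if (span >= field)
    stop(sprintf("field (%g um) too small for %d cells per row at %g um spacing",
                 field, per_row, spacing))
  row_spacing <- spacing  # radial inter-row spacing matches tonotopic pitch
  ids <- seq_len(n)
  row <- ((ids - 1L) %% n_rows) + 1L
  col <- ((ids - 1L) %/% n_rows) + 1L
  n_in_row <- tabulate(row, nbins = n_rows)
  x <- field / 2 + (col - (n_in_row[row] + 1) / 2) * spacing
  y <- field * 0.55 + (row - (n_rows + 1) / 2) * row_spacing
  if (any(x < 0 | x > field | y < 0 | y > field))
    stop("cell layout exceeds the field; reduce n_cells or spacing")
  cm <- data.frame(id = ids, x_um = x, y_um = y, row = row)
  attr(cm, "ger_band") <- list(y_min_um = 0.05 * field,
                               y_max_um = 0.40 * field)
  attr(cm, "field_um") <- field
  class(cm) <- c("cell_map", "data.frame")
  cm
}

#' Read / write a cell map as JSON
#'
#' Format: \code{{"cells": [{"id", "x_um", "y_um", "row"}, ...],
#' "ger_band": {"y_min_um", "y_max_um"}, "field_um"}}.
#'
#' @param path JSON file path.
#' @return \code{read_cell_map}: a \code{cell_map} data.frame.
#' @export
read_cell_map <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$cells)) stop("cell map JSON must contain a 'cells' array")
  cm <- as.data.frame(obj$cells)
  need <- c("id", "x_um", "y_um", "row")
  if (!all(need %in% names(cm)))
    stop("cell entries must have fields ", paste(need, collapse = ", "))
  if (anyDuplicated(cm$id)) stop("cell ids must be unique")
  attr(cm, "ger_band") <- obj$ger_band
  attr(cm, "field_um") <- obj$field_um
  class(cm) <- c("cell_map", "data.frame")
  cm
}

#' @rdname read_cell_map
#' @param cell_map A \code{cell_map}.
#' @export
write_cell_map <- function(cell_map, path) {
  obj <- list(cells = as.data.frame(unclass(cell_map)),
              ger_band = attr(cell_map, "ger_band"),
              field_um = attr(cell_map, "field_um"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
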