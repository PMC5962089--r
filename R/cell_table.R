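#' Construct and validate a cell table
#'
#' A cell table describes the study grid: one row per cell with a unique id,
#' planar cell-centre coordinates, a positive area, and the fraction `P` of
#' the cell covered by the protected-area network. The row order of the table
#' is the canonical cell order; every aligned structure (presence vectors,
#' predictor columns, favourability surfaces) follows it.
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param x,y numeric cell-centre coordinates (arbitrary planar units).
#' @param area numeric positive cell areas, one unit for all cells.
#'   Defaults to 1 for every cell (near-equal-area grids).
#' @param P numeric fraction of each cell covered by the network, in [0, 1].
#'   Defaults to 0 (no protection).
#' @return A `data.frame` of class `cell_table` with columns
#'   `cell_id`, `x`, `y`, `area`, `P`.
#' @seealso [read_cell_table()], [coverage_fraction()]
#' @export
cell_table <- function(cell_id, x, y, area = rep(1, length(cell_id)),
                       P = rep(0, length(cell_id))) {
  df <- data.frame(cell_id = as.character(cell_id),
                   x = as.numeric(x), y = as.numeric(y),
                   area = as.numeric(area), P = as.numeric(P),
                   stringsAsFactors = FALSE)
  validate_cell_table(df)
}

validate_cell_table <- function(df, source = "cell table") {
  required <- c("cell_id", "x", "y", "area", "P")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) < 2L)
    stop(sprintf("%s: at least 2 cells are required, got %d", source,
                 nrow(df)), call. = FALSE)
  for (col in c("x", "y", "area", "P")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("%s: non-numeric or missing value in column '%s' at row %d",
                   source, col, bad[1L]), call. = FALSE)
  }
  dup <- which(duplicated(df$cell_id))
  if (length(dup) > 0L)
    stop(sprintf("%s: duplicate cell_id '%s' at row %d", source,
                 df$cell_id[dup[1L]], dup[1L]), call. = FALSE)
  bad_p <- which(df$P < 0 | df$P > 1)
  if (length(bad_p) > 0L)
    stop(sprintf("%s: column 'P' outside [0, 1] at row %d (value %g)",
                 source, bad_p[1L], df$P[bad_p[1L]]), call. = FALSE)
  bad_a <- which(df$area <= 0)
  if (length(bad_a) > 0L)
    stop(sprintf("%s: column 'area' not positive at row %d (value %g)",
                 source, bad_a[1L], df$area[bad_a[1L]]), call. = FALSE)
  class(df) <- c("cell_table", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read a cell table from CSV
#'
#' Expects a header row with columns `cell_id`, `x`, `y`, `P` and optionally
#' `area` (defaults to 1 when absent). File row order becomes the canonical
#' cell order. Each validation failure raises an error naming the offending
#' row and column.
#'
#' @param path path to a CSV file.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "x", "y", "P")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("'%s': missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!"area" %in% names(df)) df$area <- 1
  for (col in c("x", "y", "area", "P")) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad) > 0L)
        stop(sprintf("'%s': non-numeric value '%s' in column '%s' at row %d",
                     path, df[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
      df[[col]] <- v
    }
  }
  df$cell_id <- as.character(df$cell_id)
  validate_cell_table(df[, c("cell_id", "x", "y", "area", "P")],
                      source = sprintf("'%s'", path))
}

#' Write a cell table to CSV
#'
#' @param cells a [cell_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(inherits(cells, "cell_table"))
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Area-weighted coverage fraction of the protected network
#'
#' The fraction `c` of the whole study area covered by the network:
#' `sum(P * area) / sum(area)`. With equal cell areas this reduces to
#' `mean(P)`.
#'
#' @param cells a [cell_table()].
#' @return a single number in [0, 1].
#' @export
coverage_fraction <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  sum(cells$P * cells$area) / sum(cells$area)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, coverage fraction c = %.6g\n",
              nrow(x), coverage_fraction(x)))
  NextMethod()
}
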