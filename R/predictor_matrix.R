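#' Construct a predictor matrix grouped into named sets
#'
#' Environmental predictors are real-valued columns over the grid cells,
#' each assigned to exactly one predictor set (e.g. climate, topography,
#' lithology, land use, human activity). Correlation pruning during
#' screening operates within sets. Missing values are rejected, not imputed.
#'
#' @param data a numeric matrix or data.frame of predictors, rows aligned to
#'   the canonical cell order.
#' @param set_map named character vector: variable name -> set name. Every
#'   column of `data` must appear exactly once.
#' @param cells the [cell_table()] the rows align to.
#' @return An object of class `predictor_matrix`: a list with `data`
#'   (numeric matrix) and `set_map`.
#' @export
predictor_matrix <- function(data, set_map, cells) {
  stopifnot(inherits(cells, "cell_table"))
  m <- as.matrix(data)
  rownames(m) <- NULL
  if (nrow(m) != nrow(cells))
    stop(sprintf("predictors have %d rows but the cell table has %d cells",
                 nrow(m), nrow(cells)), call. = FALSE)
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("predictor columns must have unique names", call. = FALSE)
  if (!is.numeric(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m))[1L]
    rc <- arrayInd(bad, dim(m))
    stop(sprintf("missing or non-numeric predictor value at row %d, variable '%s'",
                 rc[1L], colnames(m)[rc[2L]]), call. = FALSE)
  }
  unmapped <- setdiff(colnames(m), names(set_map))
  if (length(unmapped) > 0L)
    stop(sprintf("variable(s) without a predictor set: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  structure(list(data = m, set_map = set_map[colnames(m)]),
            class = "predictor_matrix")
}

#' Read a predictor matrix and its set map from CSV
#'
#' The predictor CSV has a leading `cell_id` column; rows are realigned to
#' the canonical cell order. The set map CSV has columns `variable,set`.
#'
#' @param path predictor CSV path.
#' @param set_map_path set map CSV path.
#' @param cells the [cell_table()].
#' @return a [predictor_matrix()].
#' @export
read_predictor_matrix <- function(path, set_map_path, cells) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "cell_id")
    stop(sprintf("'%s': first column must be 'cell_id'", path), call. = FALSE)
  unknown <- setdiff(df$cell_id, cells$cell_id)
  if (length(unknown) > 0L)
    stop(sprintf("'%s': unknown cell_id '%s'", path, unknown[1L]),
         call. = FALSE)
  idx <- match(cells$cell_id, df$cell_id)
  if (anyNA(idx))
    stop(sprintf("'%s': no row for cell_id '%s'", path,
                 cells$cell_id[which(is.na(idx))[1L]]), call. = FALSE)
  sm <- utils::read.csv(set_map_path, stringsAsFactors = FALSE)
  predictor_matrix(df[idx, -1L, drop = FALSE],
                   stats::setNames(sm$set, sm$variable), cells)
}

#' Write a predictor matrix (and optionally its set map) to CSV
#'
#' @param predictors a [predictor_matrix()].
#' @param cells the [cell_table()] supplying cell ids.
#' @param path predictor CSV path.
#' @param set_map_path optional set map CSV path.
#' @return `path`, invisibly.
#' @export
write_predictor_matrix <- function(predictors, cells, path,
                                   set_map_path = NULL) {
  stopifnot(inherits(predictors, "predictor_matrix"))
  out <- data.frame(cell_id = cells$cell_id, predictors$data,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(set_map_path))
    utils::write.csv(data.frame(variable = names(predictors$set_map),
                                set = unname(predictors$set_map)),
                     set_map_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf("predictor_matrix: %d variables in %d sets over %d cells\n",
              ncol(x$data), length(unique(x$set_map)), nrow(x$data)))
  print(table(x$set_map))
  invisible(x)
}
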