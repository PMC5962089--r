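# Per-cell map export: ESRI ASCII grid for regular lattices, CSV fallback.

# Infer a regular rectangular lattice from cell-centre coordinates.
# Returns list(xs, ys, dx, dy, index matrix mapping) or NULL when the cells
# do not form a complete regular lattice.
infer_lattice <- function(cells, tol = 1e-9) {
  xs <- sort(unique(cells$x))
  ys <- sort(unique(cells$y))
  if (length(xs) < 1L || length(ys) < 1L) return(NULL)
  spacing_ok <- function(v) {
    if (length(v) == 1L) return(TRUE)
    d <- diff(v)
    max(d) - min(d) <= tol * max(abs(v), 1)
  }
  if (!spacing_ok(xs) || !spacing_ok(ys)) return(NULL)
  if (length(xs) * length(ys) != nrow(cells)) return(NULL)
  ix <- vapply(cells$x, function(v) which.min(abs(xs - v)), 0L)
  iy <- vapply(cells$y, function(v) which.min(abs(ys - v)), 0L)
  if (anyDuplicated(cbind(ix, iy))) return(NULL)
  dx <- if (length(xs) > 1L) xs[2L] - xs[1L] else 1
  dy <- if (length(ys) > 1L) ys[2L] - ys[1L] else dx
  list(xs = xs, ys = ys, dx = dx, dy = dy, ix = ix, iy = iy)
}

#' Export a per-cell map
#'
#' Writes one real value per grid cell either as an ESRI ASCII grid (when the
#' cells form a regular rectangular lattice and cell spacing is equal in x
#' and y) or as a two-column `cell_id,value` CSV. ASCII grids use
#' `NODATA_value -9999`; `NA` values are written as NODATA.
#'
#' @param values numeric vector aligned to the canonical cell order.
#' @param cells the [cell_table()].
#' @param path output file path.
#' @param format `"auto"` (ASCII if the lattice is regular, else CSV),
#'   `"ascii"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(values, cells, path,
                           format = c("auto", "ascii", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(cells, "cell_table"))
  if (length(values) != nrow(cells))
    stop(sprintf("values has length %d but there are %d cells",
                 length(values), nrow(cells)), call. = FALSE)
  lat <- infer_lattice(cells)
  square <- !is.null(lat) && abs(lat$dx - lat$dy) <= 1e-9 * max(lat$dx, lat$dy)
  if (format == "auto") format <- if (square) "ascii" else "csv"
  if (format == "ascii") {
    if (is.null(lat))
      stop("cells do not form a regular rectangular lattice; use format = \"csv\"",
           call. = FALSE)
    if (abs(lat$dx - lat$dy) > 1e-9 * max(lat$dx, lat$dy))
      stop("x and y cell spacing differ; ASCII grids need square cells, use format = \"csv\"",
           call. = FALSE)
    ncols <- length(lat$xs); nrows <- length(lat$ys)
    grid <- matrix(NA_real_, nrow = nrows, ncol = ncols)
    grid[cbind(lat$iy, lat$ix)] <- values
    grid[is.na(grid)] <- -9999
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", ncols),
      sprintf("nrows %d", nrows),
      sprintf("xllcorner %.10g", lat$xs[1L] - lat$dx / 2),
      sprintf("yllcorner %.10g", lat$ys[1L] - lat$dy / 2),
      sprintf("cellsize %.10g", lat$dx),
      "NODATA_value -9999"), con)
    # ASCII grids are written north to south: top row = largest y
    for (r in seq(nrows, 1L)) {
      writeLines(paste(formatC(grid[r, ], format = "g", digits = 15),
                       collapse = " "), con)
    }
  } else {
    utils::write.csv(data.frame(cell_id = cells$cell_id, value = values),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path ASCII grid path as written by [write_cell_map()].
#' @return list with `header` (named numeric vector) and `values` (matrix,
#'   row 1 = northernmost row as stored in the file).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  header <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2L]), 0),
                            vapply(hdr, `[`, "", 1L))
  vals <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- do.call(rbind, vals)
  m[m == header[["NODATA_value"]]] <- NA_real_
  list(header = header, values = m)
}

#' Read a per-cell map back into canonical cell order
#'
#' Inverse of [write_cell_map()] for both formats.
#'
#' @param path map file path.
#' @param cells the [cell_table()] defining canonical order.
#' @param format `"ascii"` or `"csv"`.
#' @return numeric vector aligned to `cells`.
#' @export
read_cell_map <- function(path, cells, format = c("ascii", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(df$value[match(cells$cell_id, df$cell_id)])
  }
  g <- read_ascii_grid(path)
  lat <- infer_lattice(cells)
  if (is.null(lat))
    stop("cells do not form a regular lattice", call. = FALSE)
  nrows <- length(lat$ys)
  # undo the north-to-south row order
  grid <- g$values[seq(nrows, 1L), , drop = FALSE]
  grid[cbind(lat$iy, lat$ix)]
}
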