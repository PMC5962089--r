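#' Construct a species presence/absence dataset
#'
#' Holds 0/1 presence vectors for one or more species, aligned to the
#' canonical cell order of a [cell_table()]. Species observed in every cell
#' or in none are flagged unfittable (a presence/absence model needs both
#' classes) and are skipped by the modelling stages rather than aborting a
#' run.
#'
#' @param presence a matrix or data.frame of 0/1 values, one column per
#'   species, rows aligned to `cells`.
#' @param cells the [cell_table()] the rows align to.
#' @param groups optional named character vector mapping species name to a
#'   taxonomic group label (`amphibian`, `reptile`, `bird`, `mammal`,
#'   `other`). Species without a label get `"other"`.
#' @return An object of class `species_dataset`: a list with elements
#'   `presence` (integer matrix, cells x species), `species` (data.frame with
#'   `species`, `group`, `n1`, `n0`, `fittable`), and `cell_id`.
#' @export
species_dataset <- function(presence, cells, groups = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  m <- as.matrix(presence)
  rownames(m) <- NULL
  if (is.null(colnames(m)))
    colnames(m) <- paste0("sp", seq_len(ncol(m)))
  if (nrow(m) != nrow(cells))
    stop(sprintf("presence has %d rows but the cell table has %d cells",
                 nrow(m), nrow(cells)), call. = FALSE)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0L) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("presence entry not in {0, 1} at row %d, species '%s'",
                 rc[1L], colnames(m)[rc[2L]]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  n1 <- colSums(m)
  n0 <- nrow(m) - n1
  fittable <- n1 > 0L & n0 > 0L
  if (any(!fittable))
    warning(sprintf("species with no presences or no absences flagged unfittable: %s",
                    paste(colnames(m)[!fittable], collapse = ", ")),
            call. = FALSE)
  grp <- rep("other", ncol(m))
  names(grp) <- colnames(m)
  if (!is.null(groups)) {
    known <- intersect(names(groups), colnames(m))
    grp[known] <- unname(groups[known])
  }
  structure(list(
    presence = m,
    species = data.frame(species = colnames(m), group = unname(grp),
                         n1 = as.integer(n1), n0 = as.integer(n0),
                         fittable = fittable, stringsAsFactors = FALSE),
    cell_id = cells$cell_id
  ), class = "species_dataset")
}

#' Read a presence/absence matrix from CSV
#'
#' The first column must be `cell_id`; every other column is one species with
#' 0/1 entries. Rows may be in any order: they are realigned to the canonical
#' order of `cells`. Group labels can be supplied either via `groups` or a
#' two-column side-car CSV (`species`, `group`).
#'
#' @param path path to the presence CSV.
#' @param cells the [cell_table()] defining canonical cell order.
#' @param groups optional named character vector (species -> group).
#' @param groups_file optional path to a `species,group` CSV side-car.
#' @return a [species_dataset()].
#' @export
read_presence_matrix <- function(path, cells, groups = NULL,
                                 groups_file = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "cell_id")
    stop(sprintf("'%s': first column must be 'cell_id', got '%s'",
                 path, names(df)[1L]), call. = FALSE)
  unknown <- setdiff(df$cell_id, cells$cell_id)
  if (length(unknown) > 0L)
    stop(sprintf("'%s': unknown cell_id '%s'", path, unknown[1L]),
         call. = FALSE)
  missing <- setdiff(cells$cell_id, df$cell_id)
  if (length(missing) > 0L)
    stop(sprintf("'%s': no row for cell_id '%s'", path, missing[1L]),
         call. = FALSE)
  idx <- match(cells$cell_id, df$cell_id)
  m <- as.matrix(df[idx, -1L, drop = FALSE])
  if (!is.null(groups_file)) {
    g <- utils::read.csv(groups_file, stringsAsFactors = FALSE)
    groups <- stats::setNames(g$group, g$species)
  }
  species_dataset(m, cells, groups = groups)
}

#' Write a presence/absence matrix to CSV
#'
#' @param dataset a [species_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "species_dataset"))
  out <- data.frame(cell_id = dataset$cell_id, dataset$presence,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("species_dataset: %d species over %d cells (%d fittable)\n",
              nrow(x$species), length(x$cell_id), sum(x$species$fittable)))
  print(x$species)
  invisible(x)
}
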