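# The Insecurity Index family: per-cell Insecurity, Overall Insecurity and
# Security, Representativeness (favourability- and occurrence-based), group
# maps, and the permuted-coverage null model.

#' Per-cell Insecurity Index
#'
#' The favourability of a species in a cell not covered by protection:
#' `I_ij = F_ij * (1 - P_j)`, equivalently `F_ij - F_ij * P_j`. A fully
#' protected cell (`P = 1`) has zero insecurity; an unprotected cell's
#' insecurity equals its favourability.
#'
#' @param F per-cell favourability in [0, 1], aligned to `cells`.
#' @param cells a [cell_table()] carrying the coverage column `P`.
#' @return per-cell Insecurity values in [0, 1].
#' @export
cell_insecurity <- function(F, cells) {
  stopifnot(inherits(cells, "cell_table"))
  if (length(F) != nrow(cells))
    stop(sprintf("F has length %d but there are %d cells",
                 length(F), nrow(cells)), call. = FALSE)
  F * (1 - cells$P)
}

#' Overall Insecurity Index
#'
#' The share of a species' fuzzy set of favourable areas lying outside the
#' protected network: `I_i = sum_j I_ij / sum_j F_ij`, equivalently one minus
#' the favourability-weighted mean coverage.
#'
#' @param I per-cell Insecurity values.
#' @param F per-cell favourability values; `sum(F)` must be positive.
#' @return a single number in [0, 1].
#' @export
overall_insecurity <- function(I, F) {
  if (length(I) != length(F))
    stop("I and F must have the same length", call. = FALSE)
  sF <- sum(F)
  if (sF <= 0)
    stop("overall insecurity is undefined when sum(F) = 0", call. = FALSE)
  sum(I) / sF
}

#' Representativeness of favourable areas in the network
#'
#' The Overall Security `S = 1 - I_i` (the favourability-weighted mean
#' coverage) divided by the coverage fraction `c` of the whole study area.
#' `R > 1` means the network covers the species' favourable areas more than
#' expected by chance; `R < 1` means less.
#'
#' @param S Overall Security, `1 - I_i`.
#' @param c coverage fraction of the study area, positive.
#' @return Representativeness, a non-negative real.
#' @export
representativeness <- function(S, c) {
  if (c <= 0)
    stop("representativeness is undefined for coverage fraction c <= 0",
         call. = FALSE)
  S / c
}

#' Occurrence-based Representativeness
#'
#' Same construction with observed presence/absence in place of
#' favourability: the mean coverage over presence cells, divided by `c`.
#'
#' @param presence 0/1 vector with at least one presence.
#' @param cells a [cell_table()].
#' @param c coverage fraction; defaults to the area-weighted
#'   [coverage_fraction()] of `cells`.
#' @return list with `S_occ` and `R_occ`.
#' @export
occurrence_representativeness <- function(presence, cells,
                                          c = coverage_fraction(cells)) {
  stopifnot(inherits(cells, "cell_table"))
  n1 <- sum(presence)
  if (n1 == 0)
    stop("occurrence representativeness is undefined with no presences",
         call. = FALSE)
  S_occ <- sum(presence * cells$P) / n1
  list(S_occ = S_occ, R_occ = representativeness(S_occ, c))
}

#' Group Insecurity map
#'
#' Sums the per-cell Insecurity surfaces of all species in a taxonomic group
#' and normalizes by the maximum over the study area, giving a 0-1 map of
#' where the group's favourable areas are least protected. An all-zero sum is
#' returned as all zeros with a warning.
#'
#' @param I_surfaces list (or matrix columns) of aligned per-cell Insecurity
#'   vectors.
#' @return normalized per-cell map in [0, 1].
#' @export
group_insecurity_map <- function(I_surfaces) {
  if (is.list(I_surfaces)) {
    lens <- lengths(I_surfaces)
    if (length(unique(lens)) != 1L)
      stop("Insecurity surfaces are not aligned", call. = FALSE)
    m <- do.call(cbind, I_surfaces)
  } else m <- as.matrix(I_surfaces)
  g <- rowSums(m)
  mx <- max(g)
  if (mx == 0) {
    warning("all-zero group Insecurity map", call. = FALSE)
    return(g)
  }
  g / mx
}

#' Permuted-coverage null model for one species
#'
#' Each replicate permutes the full vector of coverage values `P_j` uniformly
#' at random across cells, recomputes the Overall Security, and counts how
#' often the actual Security strictly exceeds the permuted one. A species
#' beating all replicates is well-represented by the network; one beating
#' none is under-represented. Ties count as failures (conservative: a flat
#' coverage layer scores 0).
#'
#' @param F per-cell favourability.
#' @param cells a [cell_table()].
#' @param n_reps number of permutation replicates (default 20).
#' @param seed integer seed for reproducibility.
#' @return An object of class `randomization_result`: list with `actual_S`,
#'   `random_S` (length `n_reps`), `times_actual_gt_random`, `n_reps`,
#'   `seed`.
#' @export
randomization_test <- function(F, cells, n_reps = 20, seed = NULL) {
  stopifnot(inherits(cells, "cell_table"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  security <- function(P) 1 - sum(F * (1 - P)) / sum(F)
  actual <- security(cells$P)
  random_S <- vapply(seq_len(n_reps),
                     function(i) security(sample(cells$P)), 0)
  structure(list(actual_S = actual, random_S = random_S,
                 times_actual_gt_random = sum(actual > random_S),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization_result: actual S = %.6g beats %d of %d permuted networks\n",
    x$actual_S, x$times_actual_gt_random, x$n_reps))
  invisible(x)
}

#' Full Insecurity assessment of one species
#'
#' Composes the per-cell Insecurity surface, Overall Insecurity and Security,
#' favourability- and occurrence-based Representativeness, and the
#' permuted-coverage null model.
#'
#' @param F per-cell favourability.
#' @param presence 0/1 vector (for occurrence Representativeness).
#' @param cells a [cell_table()].
#' @param n_reps permutation replicates.
#' @param seed integer seed for the null model.
#' @param coverage optional coverage fraction override; defaults to the
#'   area-weighted [coverage_fraction()] of `cells` (use the override to pin
#'   a published network fraction such as 0.00667).
#' @return An object of class `species_assessment`: list with `I_surface`,
#'   `I_overall`, `S`, `R`, `S_occ`, `R_occ`, `c` and `randomization`.
#' @export
assess_species <- function(F, presence, cells, n_reps = 20, seed = NULL,
                           coverage = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  c_used <- if (is.null(coverage)) coverage_fraction(cells) else coverage
  I <- cell_insecurity(F, cells)
  I_i <- overall_insecurity(I, F)
  S <- 1 - I_i
  occ <- occurrence_representativeness(presence, cells, c = c_used)
  rnd <- randomization_test(F, cells, n_reps = n_reps, seed = seed)
  structure(list(I_surface = I, I_overall = I_i, S = S,
                 R = representativeness(S, c_used),
                 S_occ = occ$S_occ, R_occ = occ$R_occ,
                 c = c_used, randomization = rnd),
            class = "species_assessment")
}

#' @export
print.species_assessment <- function(x, ...) {
  cat(sprintf(
    "species_assessment: I = %.3f, S = %.3f, R = %.3f (R_occ = %.3f), beats %d/%d permutations\n",
    x$I_overall, x$S, x$R, x$R_occ,
    x$randomization$times_actual_gt_random, x$randomization$n_reps))
  invisible(x)
}
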