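# Per-species predictor screening: within-set correlation pruning, the
# trend-surface spatial descriptor, and FDR filtering of univariate
# relationships with the species distribution.

# Univariate logistic-regression likelihood-ratio p-value of one candidate
# against the intercept-only model. Returns NA (with a message in `cause`)
# when the fit fails.
univariate_lrt_p <- function(presence, x) {
  if (stats::sd(x) == 0) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(stats::glm(presence ~ x, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  stats::pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
}

#' Prune highly correlated predictors within each set
#'
#' Iteratively, among the remaining within-set pairs whose absolute Pearson
#' correlation exceeds `r_threshold`, the pair with the largest `|r|` is
#' resolved by dropping the member with the *larger* univariate
#' likelihood-ratio p-value against the species distribution (i.e. the least
#' significant individual relationship); ties are broken by input column
#' order (the earlier column is kept). Zero-variance columns are dropped
#' outright. Pruning never compares variables across sets.
#'
#' @param predictors a [predictor_matrix()].
#' @param presence 0/1 vector aligned to cells.
#' @param r_threshold absolute-correlation threshold (default 0.8).
#' @return list with `survivors` (character), `dropped` (data.frame with
#'   columns `dropped`, `kept`, `r`, `cause`), and `p` (named univariate
#'   p-values for all candidates).
#' @export
prune_correlated <- function(predictors, presence, r_threshold = 0.8) {
  stopifnot(inherits(predictors, "predictor_matrix"))
  X <- predictors$data
  p_uni <- vapply(colnames(X),
                  function(v) univariate_lrt_p(presence, X[, v]), 0)
  dropped <- data.frame(dropped = character(0), kept = character(0),
                        r = numeric(0), cause = character(0),
                        stringsAsFactors = FALSE)
  survivors <- character(0)
  for (set in unique(predictors$set_map)) {
    vars <- names(predictors$set_map)[predictors$set_map == set]
    const <- vars[vapply(vars, function(v) stats::sd(X[, v]) == 0, TRUE)]
    for (v in const)
      dropped[nrow(dropped) + 1L, ] <- list(v, NA_character_, NA_real_,
                                            "zero variance")
    vars <- setdiff(vars, const)
    while (length(vars) > 1L) {
      r <- stats::cor(X[, vars, drop = FALSE])
      diag(r) <- 0
      if (max(abs(r)) <= r_threshold) break
      ij <- arrayInd(which.max(abs(r)), dim(r))
      a <- vars[min(ij)]; b <- vars[max(ij)]     # a earlier in column order
      pa <- p_uni[a]; pb <- p_uni[b]
      # drop the less significant member (a failed fit counts as least
      # significant); on ties keep the earlier column
      drop_b <- if (is.na(pa) && !is.na(pb)) FALSE
                else if (!is.na(pa) && is.na(pb)) TRUE
                else is.na(pa) || pb >= pa
      loser <- if (drop_b) b else a
      winner <- if (drop_b) a else b
      dropped[nrow(dropped) + 1L, ] <- list(loser, winner, r[ij],
                                            "correlation")
      vars <- setdiff(vars, loser)
    }
    survivors <- c(survivors, vars)
  }
  # preserve input column order among survivors
  survivors <- colnames(X)[colnames(X) %in% survivors]
  list(survivors = survivors, dropped = dropped, p = p_uni)
}

#' Trend-surface spatial descriptor
#'
#' Fits a logistic regression of presence on the nine cubic trend-surface
#' terms of the standardized coordinates — X, Y, X^2, XY, Y^2, X^3, X^2Y,
#' XY^2, Y^3 — then backward-eliminates terms by AIC. The descriptor is the
#' linear predictor of the retained model: a single spatial variable that
#' absorbs broad-scale spatial autocorrelation in the species distribution.
#' On (quasi-)complete separation the fit falls back to the intercept-only
#' model, giving a constant descriptor, and is flagged.
#'
#' @param cells a [cell_table()].
#' @param presence 0/1 vector aligned to cells.
#' @return list with `descriptor` (per-cell linear predictor), `terms`
#'   (retained term names), `model` (the glm), `separation` (logical flag).
#' @export
trend_surface_descriptor <- function(cells, presence) {
  stopifnot(inherits(cells, "cell_table"))
  if (sum(presence) < 10)
    warning("fewer than 10 presences: trend surface may be unstable",
            call. = FALSE)
  d <- as.data.frame(cubic_terms(cells$x, cells$y))
  d$presence <- presence
  full <- suppressWarnings(
    stats::glm(presence ~ ., data = d, family = stats::binomial()))
  model <- suppressWarnings(stats::step(full, direction = "backward",
                                        trace = 0))
  # complete separation: the retained model's coefficients diverge (terms
  # are standardized, so finite effects stay far below this bound)
  beta <- stats::coef(model)[-1L]
  if (!model$converged || (length(beta) > 0 && max(abs(beta)) > 15)) {
    model <- stats::glm(presence ~ 1, data = d, family = stats::binomial())
    return(list(descriptor = rep(unname(stats::coef(model)[1L]),
                                 nrow(cells)),
                terms = character(0), model = model, separation = TRUE))
  }
  list(descriptor = as.numeric(stats::predict(model, type = "link")),
       terms = setdiff(names(stats::coef(model)), "(Intercept)"),
       model = model, separation = FALSE)
}

#' Benjamini-Hochberg selection on a vector of p-values
#'
#' Step-up FDR control at level `q`: retains every hypothesis whose adjusted
#' p-value is at most `q`. `method = "BY"` switches to Benjamini-Yekutieli.
#'
#' @param p numeric p-values (NAs never selected).
#' @param q FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return logical vector: TRUE where the null is rejected.
#' @export
fdr_select <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  adj <- stats::p.adjust(p, method = method)
  !is.na(adj) & adj <= q
}

#' FDR filter of candidate predictors
#'
#' Computes the univariate logistic-regression likelihood-ratio p-value of
#' each candidate column and keeps those significant under FDR control at
#' level `q`. Candidates whose univariate fit fails are skipped and logged
#' with an NA p-value.
#'
#' @param candidates numeric matrix of candidate columns (post-pruning
#'   survivors plus the spatial descriptor), aligned to cells.
#' @param presence 0/1 vector.
#' @param q FDR level (default 0.05).
#' @param method FDR variant passed to [fdr_select()].
#' @return data.frame with columns `variable`, `p`, `p_adj`, `retained`.
#' @export
fdr_filter <- function(candidates, presence, q = 0.05,
                       method = c("BH", "BY")) {
  method <- match.arg(method)
  m <- as.matrix(candidates)
  p <- vapply(seq_len(ncol(m)),
              function(i) univariate_lrt_p(presence, m[, i]), 0)
  data.frame(variable = colnames(m), p = p,
             p_adj = stats::p.adjust(p, method = method),
             retained = fdr_select(p, q, method),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full predictor screening for one species
#'
#' Composes the three screening stages: within-set correlation pruning, the
#' trend-surface spatial descriptor (assigned to predictor set `"spatial"`
#' and screened like any other candidate), and FDR filtering.
#'
#' @param predictors a [predictor_matrix()].
#' @param presence 0/1 vector.
#' @param cells the [cell_table()].
#' @param r_threshold correlation-pruning threshold.
#' @param q FDR level.
#' @param method FDR variant.
#' @return An object of class `screening_report`: list with `pruning`,
#'   `trend`, `fdr` stage outputs, `survivors` (character vector of final
#'   candidates) and `data` (numeric matrix of the surviving columns,
#'   including `spatial` when retained).
#' @export
screen_predictors <- function(predictors, presence, cells,
                              r_threshold = 0.8, q = 0.05,
                              method = c("BH", "BY")) {
  method <- match.arg(method)
  pruning <- prune_correlated(predictors, presence, r_threshold)
  trend <- suppressWarnings(trend_surface_descriptor(cells, presence))
  cand <- cbind(predictors$data[, pruning$survivors, drop = FALSE],
                spatial = trend$descriptor)
  if (stats::sd(trend$descriptor) == 0)   # constant descriptor cannot enter
    cand <- cand[, setdiff(colnames(cand), "spatial"), drop = FALSE]
  fdr <- fdr_filter(cand, presence, q = q, method = method)
  survivors <- fdr$variable[fdr$retained]
  structure(list(pruning = pruning, trend = trend, fdr = fdr,
                 survivors = survivors,
                 data = cand[, survivors, drop = FALSE]),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "screening_report: %d dropped by pruning, %d FDR candidates, %d survivors\n",
    nrow(x$pruning$dropped), nrow(x$fdr), length(x$survivors)))
  if (length(x$survivors)) cat("survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}
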