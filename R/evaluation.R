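# Model evaluation: threshold classification (kappa, sensitivity,
# specificity, CCR at F = 0.5), rank-based AUC, and the Hosmer-Lemeshow
# goodness-of-fit test on fixed-width probability bins.

#' Threshold classification metrics
#'
#' Classifies cells as predicted-present where the score (favourability)
#' meets the threshold and compares against observed presence. Cohen's kappa
#' uses chance agreement computed from the prediction and observation
#' marginals. An empty observed class makes the corresponding rate `NaN` and
#' triggers a warning.
#'
#' @param F per-cell scores (favourability).
#' @param presence 0/1 vector.
#' @param threshold classification threshold in (0, 1); default 0.5, which on
#'   the favourability scale corresponds to probability = prevalence.
#' @return list with `sensitivity`, `specificity`, `CCR`, `kappa` and the
#'   confusion counts `TP`, `FP`, `TN`, `FN`.
#' @export
classification_metrics <- function(F, presence, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  pred <- F >= threshold
  obs <- presence == 1L
  TP <- sum(pred & obs); FP <- sum(pred & !obs)
  TN <- sum(!pred & !obs); FN <- sum(!pred & obs)
  n <- TP + FP + TN + FN
  if (TP + FN == 0L || TN + FP == 0L)
    warning("one observed class is empty: sensitivity/specificity undefined",
            call. = FALSE)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  ccr <- (TP + TN) / n
  pe <- ((TP + FP) / n) * ((TP + FN) / n) +
        ((TN + FN) / n) * ((TN + FP) / n)
  kappa <- if (pe == 1) 0 else (ccr - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, CCR = ccr, kappa = kappa,
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic: the probability
#' that a random presence cell scores above a random absence cell, with ties
#' counted 1/2. Because the favourability transform is strictly increasing in
#' probability, AUC is identical on the probability and favourability scales.
#'
#' @param F per-cell scores.
#' @param presence 0/1 vector with at least one presence and one absence.
#' @return AUC in [0, 1].
#' @export
auc <- function(F, presence) {
  pos <- presence == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires at least one presence and one absence", call. = FALSE)
  r <- rank(F)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit test on fixed-width bins
#'
#' Bins predicted probabilities into 10 fixed-width intervals [0, 0.1), ...,
#' [0.9, 1.0] (not deciles). For each nonempty bin `g` with `n_g` cells,
#' observed presence count `O_g` and mean predicted probability `pi_g`, the
#' contribution is `(O_g - n_g pi_g)^2 / (n_g pi_g (1 - pi_g))`. The
#' statistic sums over nonempty bins, with `df = g - 2` and a chi-square
#' upper-tail p-value. With fewer than 3 nonempty bins the statistic is
#' reported but the p-value suppressed.
#'
#' @param p per-cell predicted probabilities in [0, 1].
#' @param presence 0/1 vector.
#' @param bins number of fixed-width bins (default 10, width 0.1).
#' @return list with `statistic`, `df`, `p.value` (NA when suppressed) and a
#'   per-bin `table`.
#' @export
hosmer_lemeshow <- function(p, presence, bins = 10) {
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]",
                               call. = FALSE)
  breaks <- seq(0, 1, length.out = bins + 1)
  g <- findInterval(p, breaks, rightmost.closed = TRUE)
  tab <- do.call(rbind, lapply(sort(unique(g)), function(b) {
    idx <- g == b
    n_g <- sum(idx)
    pib <- mean(p[idx])
    O <- sum(presence[idx])
    E <- n_g * pib
    contrib <- if (pib <= 0 || pib >= 1) {
      if (O == E) 0 else Inf   # degenerate bin with certain prediction
    } else (O - E)^2 / (n_g * pib * (1 - pib))
    data.frame(bin = b, n = n_g, pi_bar = pib, observed = O,
               expected = E, contribution = contrib)
  }))
  statistic <- sum(tab$contribution)
  k <- nrow(tab)
  df <- k - 2L
  if (k < 3L) {
    warning("fewer than 3 nonempty bins: Hosmer-Lemeshow p-value suppressed",
            call. = FALSE)
    return(list(statistic = statistic, df = df, p.value = NA_real_,
                table = tab))
  }
  list(statistic = statistic, df = df,
       p.value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
       table = tab)
}

#' Evaluate a fitted favourability model
#'
#' Classification at the favourability threshold, rank-based AUC, and the
#' Hosmer-Lemeshow test on the probability scale.
#'
#' @param fm a [favourability_model()].
#' @param presence 0/1 vector the model was fitted on.
#' @param threshold favourability classification threshold.
#' @param hl_bins Hosmer-Lemeshow bin count.
#' @return list of class `evaluation_report` with `kappa`, `sensitivity`,
#'   `specificity`, `CCR`, `AUC`, `HL`, `HL_df`, `HL_p`.
#' @export
evaluate_model <- function(fm, presence, threshold = 0.5, hl_bins = 10) {
  stopifnot(inherits(fm, "favourability_model"))
  cls <- classification_metrics(fm$F, presence, threshold)
  hl <- hosmer_lemeshow(fm$p, presence, bins = hl_bins)
  structure(list(kappa = cls$kappa, sensitivity = cls$sensitivity,
                 specificity = cls$specificity, CCR = cls$CCR,
                 AUC = auc(fm$F, presence),
                 HL = hl$statistic, HL_df = hl$df, HL_p = hl$p.value),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "kappa %.3f | sens %.3f | spec %.3f | CCR %.3f | AUC %.3f | HL %.3f (df %d, p %s)\n",
    x$kappa, x$sensitivity, x$specificity, x$CCR, x$AUC, x$HL, x$HL_df,
    ifelse(is.na(x$HL_p), "NA", sprintf("%.3f", x$HL_p))))
  invisible(x)
}
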