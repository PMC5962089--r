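#' The favourability transform
#'
#' Converts the logit `y` of a presence/absence logistic regression into
#' favourability
#' \deqn{F = \frac{e^y}{n_1/n_0 + e^y}}
#' where `n1` and `n0` are the total numbers of presences and absences. The
#' transform removes the effect of species prevalence from the predicted
#' probability: `F = 0.5` exactly where the predicted probability equals the
#' prevalence `n1/(n1+n0)`, and when `n1 = n0` favourability coincides with
#' probability. `F` is a strictly increasing function of `y` (and of `p`) and
#' can be read as the fuzzy membership degree of a cell in the set of areas
#' favourable to the species.
#'
#' Logits are clipped to +/-35 before exponentiation; beyond the clip range
#' `F` is returned as exactly 0 or 1 and the result carries a `clipped`
#' attribute.
#'
#' @param y numeric vector of logits.
#' @param n1,n0 positive presence and absence counts.
#' @return numeric vector of favourability values in [0, 1].
#' @export
favourability <- function(y, n1, n0) {
  if (n1 <= 0 || n0 <= 0)
    stop("favourability requires n1 > 0 and n0 > 0", call. = FALSE)
  hi <- y > 35; lo <- y < -35
  yc <- pmin(pmax(y, -35), 35)
  # F = e^y / (n1/n0 + e^y) = 1 / (1 + (n1/n0) e^{-y}), stable for large |y|
  f <- 1 / (1 + (n1 / n0) * exp(-yc))
  f[hi] <- 1; f[lo] <- 0
  if (any(hi | lo)) attr(f, "clipped") <- which(hi | lo)
  f
}

#' Favourability from predicted probability
#'
#' Equivalent form of the transform on the probability scale:
#' `F = (p/(1-p)) / (n1/n0 + p/(1-p))`.
#'
#' @param p probabilities in (0, 1); exact 0/1 map to F = 0/1.
#' @param n1,n0 positive presence and absence counts.
#' @return numeric vector of favourability values.
#' @export
favourability_from_prob <- function(p, n1, n0) {
  favourability(stats::qlogis(p), n1, n0)
}

#' Forward-backward stepwise logistic regression by AIC
#'
#' Starting from the intercept-only model, repeatedly takes the single add or
#' drop move with the largest AIC decrease over the survivor scope, stopping
#' when no move decreases AIC (the classic bidirectional `step()` search).
#' With an empty scope the intercept-only model is returned, whose fitted
#' probability is the prevalence in every cell. (Quasi-)complete separation
#' is flagged on the returned object (`separation` attribute) and the
#' coefficients reported as fitted.
#'
#' @param presence 0/1 vector.
#' @param survivors numeric matrix of candidate columns (screening
#'   survivors), aligned to cells; may have zero columns.
#' @return a fitted `glm` object with a logical `separation` attribute.
#' @export
fit_stepwise_logistic <- function(presence, survivors) {
  if (sum(presence) == 0L || sum(presence) == length(presence))
    stop("presence vector needs at least one presence and one absence",
         call. = FALSE)
  d <- data.frame(presence = presence)
  vars <- character(0)
  if (!is.null(survivors) && NCOL(survivors) > 0L) {
    m <- as.matrix(survivors)
    vars <- colnames(m)
    d <- cbind(d, as.data.frame(m))
  }
  separated <- FALSE
  capture <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1",
              conditionMessage(w))) separated <<- TRUE
    invokeRestart("muffleWarning")
  })
  null <- capture(stats::glm(presence ~ 1, data = d,
                             family = stats::binomial()))
  if (length(vars) == 0L) {
    attr(null, "separation") <- FALSE
    return(null)
  }
  upper <- stats::reformulate(vars, response = "presence")
  fit <- capture(stats::step(null,
                             scope = list(lower = ~1, upper = upper),
                             direction = "both", trace = 0))
  if (separated)
    warning("(quasi-)complete separation detected in the stepwise fit",
            call. = FALSE)
  attr(fit, "separation") <- separated
  fit
}

#' Fit a favourability model for one species
#'
#' Runs the stepwise logistic regression over the screening survivors and
#' applies the favourability transform to the fitted logits.
#'
#' @param presence 0/1 vector.
#' @param survivors numeric matrix of screened candidate columns.
#' @return An object of class `favourability_model`: list with `model` (the
#'   glm), `terms`, `coefficients`, `n1`, `n0`, and per-cell `y` (logit),
#'   `p` (probability), `F` (favourability), plus `separation`.
#' @export
favourability_model <- function(presence, survivors) {
  fit <- suppressWarnings(fit_stepwise_logistic(presence, survivors))
  n1 <- sum(presence); n0 <- length(presence) - n1
  y <- as.numeric(stats::predict(fit, type = "link"))
  structure(list(model = fit,
                 terms = setdiff(names(stats::coef(fit)), "(Intercept)"),
                 coefficients = stats::coef(fit),
                 n1 = n1, n0 = n0,
                 y = y,
                 p = stats::plogis(y),
                 F = as.numeric(favourability(y, n1, n0)),
                 separation = isTRUE(attr(fit, "separation"))),
            class = "favourability_model")
}

#' @export
print.favourability_model <- function(x, ...) {
  cat(sprintf("favourability_model: %d term(s), n1 = %d, n0 = %d (prevalence %.3f)\n",
              length(x$terms), x$n1, x$n0, x$n1 / (x$n1 + x$n0)))
  print(x$coefficients)
  invisible(x)
}
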