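# PM risk score: linear-booster weights on the final panel, weighted-sum
# score, and quartile stratification into low / moderate / high risk.

#' Fit per-protein weights of the PM risk score
#'
#' Fits an L2-regularized additive linear classifier (ridge-penalized logistic
#' regression, the convergence target of a linear booster with L2 shrinkage)
#' of PM status on the panel's z-scored expression and extracts the slope of
#' each protein as its weight. The intercept is dropped: the score is used
#' only for ranking and stratification.
#'
#' @param m [expr_matrix()] (`log2z`) of tumour samples.
#' @param panel character vector of panel protein ids.
#' @param pm_labels per-column PM status (0/1).
#' @param lambda L2 penalty (default 1).
#' @param seed recorded in the model metadata (the fit is deterministic).
#' @return list of class `pm_risk_model`: `panel`, `weights` (named), `lambda`,
#'   `seed`, `cutpoints` (NULL until [stratify()] is run on a cohort).
#' @export
fit_weights <- function(m, panel, pm_labels, lambda = 1, seed = 1L) {
  missing <- setdiff(panel, protein_ids(m))
  if (length(missing)) {
    stop(sprintf("panel protein(s) missing from the matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  y <- as.integer(as.logical(as.integer(pm_labels)))
  if (length(unique(y)) != 2) stop("both classes must be present", call. = FALSE)
  X <- t(m$values[panel, , drop = FALSE])
  fit <- ridge_logistic(X, y, lambda = lambda)
  structure(list(panel = panel, weights = fit$coef[panel], lambda = lambda,
                 seed = seed, cutpoints = NULL),
            class = "pm_risk_model")
}

#' PM risk score: weighted sum of panel expression
#'
#' `score_s = sum_j w_j * z[j, s]`, linear in expression.
#'
#' @param model a [fit_weights()] model (or any list with `panel`, `weights`).
#' @param m [expr_matrix()] containing every panel protein.
#' @return named numeric vector of per-sample scores.
#' @export
pm_risk_score <- function(model, m) {
  missing <- setdiff(model$panel, protein_ids(m))
  if (length(missing)) {
    stop(sprintf("panel protein(s) missing from the matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  drop(crossprod(m$values[model$panel, , drop = FALSE], model$weights[model$panel]))
}

#' Quartile risk stratification
#'
#' Splits a cohort at the 25th and 75th percentiles of its own scores
#' (linear-interpolation quantiles): `score >= q3` is high risk, `score <= q1`
#' low risk, the middle half moderate. Cutpoints can be supplied to apply a
#' previously fixed stratification.
#'
#' @param scores named numeric vector of PM risk scores (>= 4 subjects).
#' @param cutpoints optional `c(q1, q3)` overriding the cohort quantiles.
#' @return factor (`low`, `moderate`, `high`) named by subject, with attribute
#'   `cutpoints`.
#' @export
stratify <- function(scores, cutpoints = NULL) {
  if (length(scores) < 4) stop("at least 4 subjects required", call. = FALSE)
  if (is.null(cutpoints)) {
    cutpoints <- unname(stats::quantile(scores, c(0.25, 0.75), type = 7))
  }
  if (diff(cutpoints) <= 0) {
    stop("degenerate score distribution: quartile cutpoints coincide", call. = FALSE)
  }
  lev <- ifelse(scores >= cutpoints[2], "high",
                ifelse(scores <= cutpoints[1], "low", "moderate"))
  out <- factor(lev, levels = c("low", "moderate", "high"))
  names(out) <- names(scores)
  attr(out, "cutpoints") <- cutpoints
  out
}

#' @export
print.pm_risk_model <- function(x, ...) {
  cat(sprintf("<pm_risk_model> %d-protein PM risk score\n", length(x$panel)))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.pm_risk_model <- function(object, ...) object$weights

#' @param object a `pm_risk_model`.
#' @param newdata an [expr_matrix()] to score.
#' @param ... unused.
#' @rdname fit_weights
#' @export
predict.pm_risk_model <- function(object, newdata, ...) {
  pm_risk_score(object, newdata)
}
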