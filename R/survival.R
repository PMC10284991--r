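# Survival validation of a risk stratification: Kaplan-Meier curves with
# Greenwood variance, log-rank testing, and (adjusted) Cox regression.
# Standard estimators are delegated to the survival package (Breslow ties by
# default); tests carry independent brute-force oracles.

#' Kaplan-Meier estimate per group
#'
#' Product-limit survival estimate with Greenwood standard errors for each
#' level of `group`.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param group optional grouping factor (single group if omitted).
#' @return named list (one entry per group) of data.frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `std_err` (SE of the survival
#'   probability, Greenwood).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(droplevels(as.factor(group)))
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  out <- lapply(levels(group), function(g) {
    i <- group == g
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1,
                             conf.type = "plain")
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv, std_err = fit$std.err * fit$surv)
  })
  stats::setNames(out, levels(group))
}

#' Log-rank test
#'
#' Standard observed-vs-expected log-rank statistic over the pooled event
#' times; p-value from a chi-square distribution with (groups - 1) degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @param group grouping with at least two nonempty levels.
#' @return list `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("at least two groups required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression (HR, CI, p per covariate)
#'
#' Partial-likelihood fit with Breslow tie handling (Efron available); returns
#' the hazard ratio, Wald 95% confidence interval and p-value for every
#' covariate.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame `covariate`, `coef`, `hr`, `lower95`, `upper95`, `p`;
#'   attribute `fit` carries the underlying `coxph` object.
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(data$event) < length(covariates) + 1) {
    stop("too few events for the number of covariates", call. = FALSE)
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  # instability is detected explicitly below, so coxph's own warnings about
  # near-infinite coefficients are redundant here
  fit <- suppressWarnings(survival::coxph(f, data = data, ties = ties))
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit)))) {
    stop("Cox model failed to converge (possibly monotone likelihood)", call. = FALSE)
  }
  if (any(sqrt(diag(fit$var)) > 1e3)) {
    stop("Cox model unstable: near-infinite coefficient (perfect separation?)",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- cf / se
  out <- data.frame(covariate = names(cf), coef = unname(cf),
                    hr = exp(unname(cf)),
                    lower95 = exp(unname(cf - 1.96 * se)),
                    upper95 = exp(unname(cf + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Validate a risk signature against survival
#'
#' Scores a cohort with the signature model, stratifies it into quartile risk
#' groups, and tests the extreme strata: Kaplan-Meier curves and a log-rank
#' test for high vs low risk (the moderate stratum is excluded from the
#' extreme-quartile comparison), plus univariate and covariate-adjusted Cox
#' regression with high-vs-low risk as the exposure.
#'
#' @param model a [fit_weights()] model.
#' @param m [expr_matrix()] of the validation cohort (one column per subject).
#' @param clinical data.frame with `subject_id`, `os_months`, `os_event` and
#'   any adjustment covariates; one row per subject, matching `m` columns.
#' @param adjust character vector of covariates for the adjusted Cox model
#'   (default `c("age", "stage")`; use `character(0)` for none).
#' @param cutpoints optional fixed stratification cutpoints (default: this
#'   cohort's own quartiles).
#' @return list of class `signature_validation`: `scores`, `strata`,
#'   `group_sizes`, `km` (high/low curves), `logrank`, `cox_univariate`,
#'   `cox_adjusted` (NULL when `adjust` is empty).
#' @export
validate_signature <- function(model, m, clinical, adjust = c("age", "stage"),
                               cutpoints = NULL) {
  idx <- match(sample_ids(m), clinical$subject_id)
  if (anyNA(idx)) stop("clinical table does not cover every scored subject", call. = FALSE)
  clinical <- clinical[idx, , drop = FALSE]
  scores <- pm_risk_score(model, m)
  strata <- stratify(scores, cutpoints = cutpoints)
  extreme <- strata != "moderate"
  dat <- data.frame(time = clinical$os_months, event = clinical$os_event,
                    risk_high = as.integer(strata == "high"),
                    clinical, stringsAsFactors = FALSE)
  de <- dat[extreme, , drop = FALSE]
  km <- km_estimate(de$time, de$event,
                    ifelse(de$risk_high == 1, "high", "low"))
  lr <- logrank_test(de$time, de$event, de$risk_high)
  cox_uni <- cox_fit(de, "risk_high")
  cox_adj <- if (length(adjust)) cox_fit(de, c("risk_high", adjust)) else NULL
  structure(list(scores = scores, strata = strata,
                 group_sizes = table(strata), km = km, logrank = lr,
                 cox_univariate = cox_uni, cox_adjusted = cox_adj,
                 cutpoints = attr(strata, "cutpoints")),
            class = "signature_validation")
}

#' @export
print.signature_validation <- function(x, ...) {
  gs <- x$group_sizes
  cat(sprintf("<signature_validation> n = %d (low %d / moderate %d / high %d)\n",
              sum(gs), gs[["low"]], gs[["moderate"]], gs[["high"]]))
  cat(sprintf("  high vs low log-rank: chi^2 = %.3f, p = %.4g\n",
              x$logrank$chisq, x$logrank$p))
  hr <- x$cox_univariate[x$cox_univariate$covariate == "risk_high", ]
  cat(sprintf("  univariate HR (high vs low) = %.3f (95%% CI %.3f-%.3f, p = %.4g)\n",
              hr$hr, hr$lower95, hr$upper95, hr$p))
  if (!is.null(x$cox_adjusted)) {
    hra <- x$cox_adjusted[x$cox_adjusted$covariate == "risk_high", ]
    cat(sprintf("  adjusted HR (high vs low) = %.3f (95%% CI %.3f-%.3f, p = %.4g)\n",
                hra$hr, hra$lower95, hra$upper95, hra$p))
  }
  invisible(x)
}
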