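# End-to-end orchestration: preprocessing -> differential calling -> module
# selection -> combinatorial panel selection -> risk model -> survival
# validation, as one fitting function returning a classed model object.

#' Control parameters for the signature-discovery pipeline
#'
#' Collects every stage's tunables with the defaults used throughout:
#' unique-peptide and FOT filters, SAM-style FDR/FC thresholds and permutation
#' count, per-pair test settings, module count, external-filter threshold,
#' combination-search size range and budget, top-combination count and panel
#' size, CV folds and classifier backend, ridge penalty, Cox adjustment
#' covariates, and the master seed.
#'
#' @param min_unique,min_fot,floor protein filter and log-floor settings.
#' @param fdr,fc,n_perm SAM-style test: FDR target, linear fold-change
#'   threshold, permutation count.
#' @param pair_p,pair_min_frac,pair_df per-pair fold-change test settings.
#' @param k number of phenotype modules for clustering (`"auto"` = silhouette
#'   choice, the default).
#' @param k_max largest module count tried under `k = "auto"`.
#' @param ext_p external transcriptome filter p-value threshold.
#' @param size_range,budget,top_n,panel_size combination search and frequency
#'   selection. `budget` caps the number of CV-scored combinations; the
#'   exhaustive space of a ~20-protein pool over sizes 3-10 is several hundred
#'   thousand combinations, so desk-scale runs sample within this budget.
#' @param folds,model cross-validation folds and classifier backend
#'   (`"gbtree"` boosted stumps or the deterministic `"logistic"` ridge).
#' @param lambda ridge penalty of the linear-booster weight fit.
#' @param adjust covariates for the adjusted Cox validation.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pm_control`.
#' @export
pm_control <- function(min_unique = 2, min_fot = 1e-5, floor = 1e-8,
                       fdr = 0.05, fc = 1.5, n_perm = 100,
                       pair_p = 0.05, pair_min_frac = 0.5, pair_df = "ml",
                       k = "auto", k_max = 8, ext_p = 0.05,
                       size_range = c(3, 10), budget = 2000, top_n = 500,
                       panel_size = 10, folds = 5,
                       model = c("gbtree", "logistic"), lambda = 1,
                       adjust = c("age", "stage"), seed = 1L) {
  structure(list(min_unique = min_unique, min_fot = min_fot, floor = floor,
                 fdr = fdr, fc = fc, n_perm = n_perm, pair_p = pair_p,
                 pair_min_frac = pair_min_frac, pair_df = pair_df, k = k,
                 k_max = k_max, ext_p = ext_p, size_range = size_range, budget = budget,
                 top_n = top_n, panel_size = panel_size, folds = folds,
                 model = match.arg(model), lambda = lambda, adjust = adjust,
                 seed = as.integer(seed)),
            class = "pm_control")
}

#' Fit the PM proteomic signature end-to-end
#'
#' Runs the whole discovery procedure on a paired tumour/normal cohort:
#' \enumerate{
#'   \item FOT normalization, unique-peptide/FOT filtering, log2 z-scoring;
#'   \item tumour-vs-normal differential proteins as the intersection of the
#'     paired SAM-style permutation test and the per-pair t-distribution
#'     fold-change test;
#'   \item second-level SAM-style comparison of PM vs PM-free tumours on those
#'     proteins;
#'   \item phenotype-profile clustering of the second-level differential
#'     proteins, SNR ranking, selection of the top-SNR (PM-associated) module,
#'     and optional concordance filtering against an external transcriptome;
#'   \item importance-ranked pool sizing, budgeted combination enumeration
#'     scored by stratified cross-validated AUC, and frequency ranking of the
#'     top combinations into the final panel;
#'   \item linear-booster (ridge logistic) weights on the panel, the weighted
#'     PM risk score, quartile stratification, and survival validation
#'     (Kaplan-Meier / log-rank / Cox) of high vs low risk.
#' }
#'
#' @param expr raw-state [expr_matrix()], proteins x samples (tumour and
#'   paired normal columns).
#' @param peptides data.frame `protein_id`, `unique_peptides`.
#' @param samples sample annotation data.frame (see [read_samples_csv()]).
#' @param external optional external transcriptome [expr_matrix()] for module
#'   filtering.
#' @param external_samples data.frame `sample_id`, `pm_status` for `external`.
#' @param control a [pm_control()] list.
#' @return An object of class `pm_signature` with components `panel`,
#'   `risk_model`, `scores`, `strata`, `validation`, `dep` (first-level
#'   results), `group_dep` (second-level), `modules`, `selection`, `control`,
#'   and `n` (cohort sizes). Supports `print()`, `summary()`, `coef()`,
#'   `predict()` and `plot()`.
#' @seealso [run_pm_pipeline()] to run on a simulated cohort in one call.
#' @export
fit_pm_signature <- function(expr, peptides, samples, external = NULL,
                             external_samples = NULL, control = pm_control()) {
  stopifnot(inherits(control, "pm_control"))
  seed <- control$seed

  pre <- preprocess_expression(expr, peptides, min_unique = control$min_unique,
                               min_fot = control$min_fot, floor = control$floor)
  z <- pre$z
  # fold changes are thresholded on the log2 FOT scale, where a linear ratio
  # is meaningful; the moderated statistic runs on the z-scores
  xlog <- log2(pmax(pre$fot$values, control$floor))
  ann <- samples[match(sample_ids(z), samples$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("`samples` must annotate every column of `expr`", call. = FALSE)

  # (1) tumour vs normal, paired: SAM-style test /\ per-pair fold-change test
  tissue <- factor(ann$tissue, levels = c("T", "N"))
  sam1 <- sam_test(z, tissue, paired = TRUE, subject = ann$subject_id,
                   n_perm = control$n_perm, fdr = control$fdr, fc = control$fc,
                   seed = child_seed(seed, 1L), fc_matrix = xlog)
  t_ids <- ann$sample_id[ann$tissue == "T"]
  n_ids <- ann$sample_id[ann$tissue == "N"]
  pairs <- data.frame(
    tumor = t_ids,
    normal = n_ids[match(ann$subject_id[ann$tissue == "T"],
                         ann$subject_id[ann$tissue == "N"])],
    stringsAsFactors = FALSE)
  zt <- expr_matrix(z$values[, t_ids, drop = FALSE], "log2z")
  pairfc <- pairfc_test(xlog[, t_ids, drop = FALSE],
                        xlog[, pairs$normal, drop = FALSE],
                        pairs, p_thresh = control$pair_p,
                        min_frac = control$pair_min_frac, df = control$pair_df)
  deps1 <- overlap_deps(sam1, pairfc)
  if (!length(deps1)) stop("no tumour-vs-normal differential proteins called", call. = FALSE)

  # (2) PM vs PM-free among tumours, restricted to first-level DEPs
  pm_t <- ann$pm_status[match(t_ids, ann$sample_id)]
  zt_dep <- expr_matrix(z$values[deps1, t_ids, drop = FALSE], "log2z")
  gd <- group_dep(zt_dep, factor(ifelse(pm_t == 1, "PM", "PMfree"),
                                 levels = c("PM", "PMfree")),
                  dep_ids = deps1, n_perm = control$n_perm, fdr = control$fdr,
                  fc = control$fc, seed = child_seed(seed, 2L),
                  fc_matrix = xlog[deps1, t_ids, drop = FALSE])
  deps2 <- gd$protein_id[gd$called]
  if (length(deps2) < 2) stop("fewer than 2 PM-associated differential proteins", call. = FALSE)

  # (3) phenotype modules ranked by SNR; pick the PM-associated module
  pheno <- ifelse(ann$tissue == "N", "normal",
                  ifelse(ann$pm_status == 1, "PM", "PM-free"))
  k <- if (identical(control$k, "auto")) "auto" else min(control$k, length(deps2))
  modules <- cluster_deps(z, pheno, deps2, k = k,
                          k_max = min(control$k_max, length(deps2) - 1),
                          seed = child_seed(seed, 3L))
  modules <- rank_modules(modules, z, pheno)
  module <- select_pm_module(modules)

  # (4) external transcriptome concordance filter
  directions <- stats::setNames(gd$direction, gd$protein_id)
  pool <- if (!is.null(external)) {
    external_filter(module, external, external_samples$pm_status,
                    directions, p_thresh = control$ext_p)
  } else module
  if (length(pool) < 2) stop("candidate pool too small after filtering", call. = FALSE)

  # (5) budgeted combination search over the filtered pool, frequency
  # selection; the nested-prefix size search is kept as a diagnostic (on a
  # near-separable small cohort it saturates at AUC 1 and is uninformative)
  Xp <- t(z$values[pool, t_ids, drop = FALSE])
  y <- pm_t
  bp <- best_panel_size(Xp, y, folds = control$folds,
                        seed = child_seed(seed, 4L), model = control$model)
  size_range <- pmin(control$size_range, length(pool))
  combos <- enumerate_and_score(Xp, y, pool = pool, size_range = size_range,
                                budget = control$budget, folds = control$folds,
                                seed = child_seed(seed, 5L),
                                model = control$model)
  marg <- vapply(pool, function(p) {
    a <- auc_rank(Xp[, p], y); max(a, 1 - a)
  }, numeric(1))
  selection <- frequency_select(combos, top_n = control$top_n,
                                panel_size = min(control$panel_size,
                                                 length(pool)),
                                marginal_auc = marg)

  # (6) weights, PM risk score, quartile strata, survival validation
  risk_model <- fit_weights(zt, selection$panel, y, lambda = control$lambda,
                            seed = child_seed(seed, 6L))
  m_subj <- expr_matrix(
    `colnames<-`(z$values[, t_ids, drop = FALSE],
                 ann$subject_id[match(t_ids, ann$sample_id)]), "log2z")
  scores <- pm_risk_score(risk_model, m_subj)
  strata <- stratify(scores)
  risk_model$cutpoints <- attr(strata, "cutpoints")
  clinical <- ann[ann$tissue == "T",
                  c("subject_id", "os_months", "os_event", "age", "stage",
                    "pm_status")]
  validation <- tryCatch(
    validate_signature(risk_model, m_subj, clinical, adjust = control$adjust),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "validation_failure"))

  structure(list(panel = selection$panel, risk_model = risk_model,
                 scores = scores, strata = strata, validation = validation,
                 dep = list(sam = sam1, pairfc = pairfc, overlap = deps1),
                 group_dep = gd, modules = modules, module = module,
                 pool = pool, pool_size_search = bp,
                 combos = combos, selection = selection, control = control,
                 n = c(proteins = nrow(expr$values),
                       retained = nrow(z$values),
                       subjects = length(t_ids), pm = sum(y),
                       dep_tn = length(deps1), dep_pm = length(deps2),
                       module = length(module), pool = length(pool))),
            class = "pm_signature")
}

#' Simulate a cohort and fit the signature pipeline in one call
#'
#' Generates a synthetic cohort (and external transcriptome), fits
#' [fit_pm_signature()], and optionally writes every artifact with a
#' provenance record. Re-running with identical configuration reproduces the
#' artifacts byte for byte.
#'
#' @param sim_config a [pm_sim_config()].
#' @param control a [pm_control()]; its seed defaults to the simulation seed.
#' @param out_dir optional directory to write artifacts into: expression /
#'   peptide / sample tables, model JSON, the machine-readable report JSON and
#'   `provenance.json` (parameters, seeds, input checksums).
#' @param use_external whether to simulate and apply the external
#'   transcriptome filter (default TRUE).
#' @return list of class `pm_pipeline_run`: `sim` (the simulated data), `fit`
#'   (the `pm_signature`), `report` (plain-list summary), `out_dir`.
#' @export
run_pm_pipeline <- function(sim_config = pm_sim_config(),
                            control = pm_control(seed = sim_config$seed),
                            out_dir = NULL, use_external = TRUE) {
  sim <- simulate_cohort(sim_config)
  ext <- if (use_external) simulate_external_transcriptome(sim_config, sim$truth)
  fit <- fit_pm_signature(sim$expr, sim$peptides, sim$samples,
                          external = if (use_external) ext$expr,
                          external_samples = if (use_external) ext$samples,
                          control = control)
  report <- pipeline_report(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_tsv(sim$expr, file.path(out_dir, "expression_raw.tsv"))
    utils::write.table(sim$peptides, file.path(out_dir, "peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_samples_csv(sim$samples, file.path(out_dir, "samples.csv"))
    jsonlite::write_json(
      list(panel = fit$panel, weights = as.list(fit$risk_model$weights),
           cutpoints = list(q1 = fit$risk_model$cutpoints[1],
                            q3 = fit$risk_model$cutpoints[2]),
           seed = control$seed),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    prov <- list(
      sim_config = unclass(sim_config), control = unclass(control),
      checksums = as.list(tools::md5sum(file.path(out_dir, c(
        "expression_raw.tsv", "peptides.tsv", "samples.csv")))))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(sim = sim, fit = fit, report = report, out_dir = out_dir),
            class = "pm_pipeline_run")
}

# plain-list, JSON-ready summary of a fitted pipeline
pipeline_report <- function(fit) {
  val <- fit$validation
  ok <- inherits(val, "signature_validation")
  list(
    n = as.list(fit$n),
    panel = fit$panel,
    weights = as.list(fit$risk_model$weights),
    cutpoints = list(q1 = unname(fit$risk_model$cutpoints[1]),
                     q3 = unname(fit$risk_model$cutpoints[2])),
    strata_sizes = as.list(table(fit$strata)),
    module_snr = as.list(fit$modules$snr),
    selection_mode = fit$selection$mode,
    best_combo_auc = max(fit$combos$mean_cv_auc),
    logrank_p = if (ok) val$logrank$p else NA,
    hr_high_vs_low = if (ok)
      val$cox_univariate$hr[val$cox_univariate$covariate == "risk_high"] else NA,
    hr_adjusted = if (ok && !is.null(val$cox_adjusted))
      val$cox_adjusted$hr[val$cox_adjusted$covariate == "risk_high"] else NA,
    seed = fit$control$seed)
}

#' @export
print.pm_signature <- function(x, ...) {
  cat("PM proteomic risk signature\n")
  cat(sprintf("  cohort: %d subjects (%d PM / %d PM-free), %d/%d proteins retained\n",
              x$n[["subjects"]], x$n[["pm"]],
              x$n[["subjects"]] - x$n[["pm"]],
              x$n[["retained"]], x$n[["proteins"]]))
  cat(sprintf("  DEPs: %d tumour-vs-normal, %d PM-associated; module of %d, pool of %d\n",
              x$n[["dep_tn"]], x$n[["dep_pm"]], x$n[["module"]], x$n[["pool"]]))
  cat(sprintf("  panel (%d): %s\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  best combination mean CV AUC: %.3f (%s search)\n",
              max(x$combos$mean_cv_auc), x$selection$mode))
  if (inherits(x$validation, "signature_validation")) {
    cat(sprintf("  high vs low risk: log-rank p = %.4g\n", x$validation$logrank$p))
  }
  invisible(x)
}

#' @export
summary.pm_signature <- function(object, ...) {
  print(object)
  cat("\nWeights:\n")
  print(round(object$risk_model$weights, 4))
  cat("\nModule SNRs:\n")
  print(round(object$modules$snr, 3))
  cat("\nRisk strata:\n")
  print(table(object$strata))
  if (inherits(object$validation, "signature_validation")) {
    cat("\nSurvival validation (high vs low):\n")
    print(object$validation)
  }
  invisible(object)
}

#' @export
coef.pm_signature <- function(object, ...) object$risk_model$weights

#' Score and stratify a new cohort with a fitted signature
#'
#' @param object a fitted `pm_signature`.
#' @param newdata [expr_matrix()] (`log2z`) containing the panel proteins, one
#'   column per subject.
#' @param type `"score"` (numeric PM risk scores) or `"risk"` (quartile
#'   strata; by default recomputed on the new cohort's own quartiles).
#' @param cutpoints `"cohort"` (default) restratifies by the new cohort's
#'   quartiles; `"training"` reuses the training cutpoints.
#' @param ... unused.
#' @export
predict.pm_signature <- function(object, newdata, type = c("score", "risk"),
                                 cutpoints = c("cohort", "training"), ...) {
  type <- match.arg(type)
  cutpoints <- match.arg(cutpoints)
  sc <- pm_risk_score(object$risk_model, newdata)
  if (type == "score") return(sc)
  stratify(sc, cutpoints = if (cutpoints == "training")
    object$risk_model$cutpoints)
}

#' Kaplan-Meier plot of the high vs low risk strata
#'
#' @param x a fitted `pm_signature` whose survival validation succeeded.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pm_signature <- function(x, ...) {
  if (!inherits(x$validation, "signature_validation")) {
    stop("no survival validation available to plot", call. = FALSE)
  }
  km <- x$validation$km
  xmax <- max(unlist(lapply(km, function(k) k$time)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Months", ylab = "Overall survival",
                 main = "PM risk: high vs low", ...)
  cols <- c(high = "firebrick", low = "steelblue")
  for (g in names(km)) {
    k <- km[[g]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)), do.points = FALSE,
                    col = cols[[g]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(km), col = cols[names(km)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' @export
print.pm_pipeline_run <- function(x, ...) {
  cat("<pm_pipeline_run>\n")
  print(x$fit)
  invisible(x)
}
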