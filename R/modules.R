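# Phenotype-differential module selection: cluster differential proteins by
# their phenotype-conditioned profiles, rank modules by signal-to-noise, pick
# the PM-associated module, then filter it against an external transcriptome.

#' Cluster differential proteins into phenotype-conditioned modules
#'
#' Each differential protein is represented by a three-value profile — its mean
#' z-expression in PM tumours, PM-free tumours, and normal tissues — and the
#' profiles are partitioned into `k` modules by seeded k-means (multiple
#' restarts; deterministic given the seed).
#'
#' @param m [expr_matrix()] in `log2z` state containing tumour and normal
#'   columns.
#' @param pm_labels per-column phenotype: `"PM"`, `"PM-free"` or `"normal"`.
#' @param deps character vector of differential protein ids to cluster.
#' @param k number of modules (default 8, `1 <= k <= |deps|`), or `"auto"`:
#'   choose `k` in `1..k_max` by the gap statistic (uniform reference in the
#'   PCA-aligned bounding box, 25 references, one-standard-error rule) — a
#'   homogeneous profile cloud is one module, not `k_max` fragments.
#' @param k_max largest `k` tried when `k = "auto"`.
#' @param seed RNG seed for the k-means restarts.
#' @return list of class `module_assignment`: `assignment` (named integer
#'   module index per protein), `profiles` (the clustered profile matrix),
#'   `k`; SNRs are attached by [rank_modules()].
#' @export
cluster_deps <- function(m, pm_labels, deps, k = 8, k_max = 8, seed = 1L) {
  assert_state(m, "log2z", "cluster_deps()")
  pm_labels <- as.character(pm_labels)
  if (length(pm_labels) != ncol(m$values)) {
    stop("`pm_labels` length must match samples", call. = FALSE)
  }
  missing <- setdiff(deps, protein_ids(m))
  if (length(missing)) {
    stop(sprintf("unknown proteins: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  auto <- identical(k, "auto")
  if (!auto) {
    if (k > length(deps)) stop("`k` must not exceed the number of proteins", call. = FALSE)
    if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  }
  grp <- list(pm = pm_labels == "PM", pmfree = pm_labels == "PM-free",
              normal = pm_labels == "normal")
  X <- m$values[deps, , drop = FALSE]
  prof <- cbind(
    pm = rowMeans(X[, grp$pm, drop = FALSE]),
    pmfree = rowMeans(X[, grp$pmfree, drop = FALSE]),
    normal = if (any(grp$normal)) rowMeans(X[, grp$normal, drop = FALSE]) else 0)
  run_km <- function(kk) {
    if (kk == length(deps)) return(stats::setNames(seq_along(deps), deps))
    km <- with_seed(seed, stats::kmeans(prof, centers = kk, nstart = 10,
                                        iter.max = 50))
    stats::setNames(km$cluster, deps)
  }
  if (auto) {
    k <- gap_statistic_k(prof, k_max = min(k_max, length(deps) - 1),
                         seed = child_seed(seed, 7L))
    assignment <- if (k == 1L) stats::setNames(rep(1L, length(deps)), deps)
      else run_km(k)
  } else {
    assignment <- run_km(k)
  }
  structure(list(assignment = assignment, profiles = prof, k = k),
            class = "module_assignment")
}

# Tibshirani gap statistic: number of k-means clusters supported by the data
# against a uniform reference in the PCA-aligned bounding box; returns the
# smallest k with gap(k) >= gap(k+1) - se(k+1) (k = 1 means no structure).
gap_statistic_k <- function(X, k_max, B = 25, seed = 1L) {
  n <- nrow(X)
  k_max <- max(1L, min(k_max, n - 1L))
  if (k_max == 1L || n < 4) return(1L)
  ks <- seq_len(k_max)
  wss <- function(M, kk) {
    if (kk == 1) sum(scale(M, scale = FALSE)^2)
    else stats::kmeans(M, centers = kk, nstart = 5, iter.max = 50)$tot.withinss
  }
  ctr <- scale(X, scale = FALSE)
  sv <- svd(ctr)
  scores <- ctr %*% sv$v
  rng <- apply(scores, 2, range)
  with_seed(seed, {
    log_w_obs <- vapply(ks, function(kk) log(wss(X, kk)), numeric(1))
    log_w_ref <- vapply(seq_len(B), function(b) {
      ref <- vapply(seq_len(ncol(X)), function(j) {
        stats::runif(n, rng[1, j], rng[2, j])
      }, numeric(n))
      ref <- ref %*% t(sv$v)
      vapply(ks, function(kk) log(wss(ref, kk)), numeric(1))
    }, numeric(length(ks)))
    log_w_ref <- matrix(log_w_ref, nrow = length(ks))
    gap <- rowMeans(log_w_ref) - log_w_obs
    se <- apply(log_w_ref, 1, stats::sd) * sqrt(1 + 1 / B)
    for (kk in ks[-length(ks)]) {
      if (gap[kk] >= gap[kk + 1] - se[kk + 1]) return(kk)
    }
    k_max
  })
}

#' Signal-to-noise ratio of a protein module between PM and PM-free tumours
#'
#' Per protein, `SNR_p = |mu_PM - mu_PMfree| / (sd_PM + sd_PMfree + eps)`;
#' the module SNR aggregates member proteins by the mean (or median).
#'
#' @param m [expr_matrix()] (`log2z`) whose columns are tumour samples.
#' @param pm_labels per-column status, `"PM"` / `"PM-free"`.
#' @param proteins module member ids.
#' @param agg aggregation over members: `"mean"` (default) or `"median"`.
#' @param eps stabilizer added to the denominator (default 1e-8).
#' @return single numeric module SNR.
#' @export
module_snr <- function(m, pm_labels, proteins, agg = c("mean", "median"),
                       eps = 1e-8) {
  agg <- match.arg(agg)
  if (!length(proteins)) stop("module is empty", call. = FALSE)
  pm_labels <- as.character(pm_labels)
  i1 <- which(pm_labels == "PM")
  i2 <- which(pm_labels == "PM-free")
  if (length(i1) < 2 || length(i2) < 2) {
    stop("both phenotype groups need at least 2 samples", call. = FALSE)
  }
  X <- m$values[proteins, , drop = FALSE]
  mu1 <- rowMeans(X[, i1, drop = FALSE])
  mu2 <- rowMeans(X[, i2, drop = FALSE])
  s1 <- apply(X[, i1, drop = FALSE], 1, stats::sd)
  s2 <- apply(X[, i2, drop = FALSE], 1, stats::sd)
  snr_p <- abs(mu1 - mu2) / (s1 + s2 + eps)
  if (agg == "mean") mean(snr_p) else stats::median(snr_p)
}

#' Attach SNRs to a module assignment and select the PM-associated module
#'
#' `rank_modules()` computes every module's SNR; `select_pm_module()` returns
#' the members of the module attaining the maximum SNR (ties broken by the
#' smaller module index).
#'
#' @param assignment a [cluster_deps()] result.
#' @inheritParams module_snr
#' @return `rank_modules()`: the assignment with `snr` (named numeric per
#'   module) and `selected_module` filled in. `select_pm_module()`: character
#'   vector of selected member protein ids.
#' @export
rank_modules <- function(assignment, m, pm_labels, agg = "mean") {
  idx <- sort(unique(assignment$assignment))
  snr <- vapply(idx, function(i) {
    module_snr(m, pm_labels, names(assignment$assignment)[assignment$assignment == i],
               agg = agg)
  }, numeric(1))
  names(snr) <- idx
  assignment$snr <- snr
  assignment$selected_module <- idx[which.max(snr)]  # which.max takes first max
  assignment
}

#' @rdname rank_modules
#' @export
select_pm_module <- function(assignment) {
  if (is.null(assignment$snr)) {
    stop("run rank_modules() first to attach SNRs", call. = FALSE)
  }
  sel <- assignment$selected_module
  sort(names(assignment$assignment)[assignment$assignment == sel])
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d proteins in %d modules\n",
              length(x$assignment), x$k))
  if (!is.null(x$snr)) {
    cat("  SNR:", paste(sprintf("%s=%.3f", names(x$snr), x$snr), collapse = " "),
        sprintf("(selected: %d)\n", x$selected_module))
  }
  invisible(x)
}

#' Filter module proteins against an external transcriptome cohort
#'
#' Keeps module proteins whose external two-sample Welch test between PM and
#' PM-free samples is significant and whose external mean-difference sign
#' agrees with the proteomic direction. Proteins absent from the external
#' matrix are dropped with a warning.
#'
#' @param proteins module member ids.
#' @param ext external [expr_matrix()] (genes x samples).
#' @param ext_pm per-column PM status of the external cohort (0/1 or logical).
#' @param directions named vector over `proteins`: proteomic direction,
#'   `"up"`/`"down"` or the signed effect.
#' @param p_thresh Welch p-value threshold (default 0.05).
#' @return character vector of retained protein ids.
#' @export
external_filter <- function(proteins, ext, ext_pm, directions, p_thresh = 0.05) {
  present <- proteins %in% protein_ids(ext)
  if (!any(present)) stop("no module proteins present in the external matrix", call. = FALSE)
  if (any(!present)) {
    warning(sprintf("dropping %d module protein(s) absent from external data: %s",
                    sum(!present),
                    paste(utils::head(proteins[!present], 5), collapse = ", ")))
  }
  proteins <- proteins[present]
  pm <- as.integer(ext_pm) == 1L
  dir_num <- directions[proteins]
  if (is.character(dir_num)) dir_num <- ifelse(dir_num == "up", 1, -1)
  keep <- vapply(proteins, function(p) {
    x1 <- ext$values[p, pm]
    x0 <- ext$values[p, !pm]
    tt <- stats::t.test(x1, x0)
    tt$p.value < p_thresh && sign(mean(x1) - mean(x0)) == sign(dir_num[[p]])
  }, logical(1))
  out <- proteins[keep]
  if (!length(out)) {
    stop("external filtering removed every module protein; consider relaxing `p_thresh`",
         call. = FALSE)
  }
  out
}
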