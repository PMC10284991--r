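# Cross-validated-AUC combinatorial panel selection: score protein
# combinations by mean AUC under stratified k-fold cross-validation, keep the
# top-scoring combinations, and rank proteins by their frequency among them.

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a random positive scores above a
#' random negative, with ties counting one half.
#'
#' @param scores numeric predictions.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- as.integer(as.logical(as.integer(labels)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y, folds, seed) {
  y <- as.integer(as.logical(as.integer(y)))
  if (min(table(y)) < folds) {
    stop(sprintf("smallest class has %d samples; use <= that many folds",
                 min(table(y))), call. = FALSE)
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Cross-validated AUC of a protein combination
#'
#' Stratified k-fold cross-validation with a fixed seed: the classifier is
#' refit on each training split and the held-out samples are scored; the
#' per-fold AUCs and their mean are returned.
#'
#' @param X samples x features numeric matrix (already restricted to the
#'   combination).
#' @param y binary labels (0/1).
#' @param folds number of folds (default 5).
#' @param seed seed controlling the fold split.
#' @param model `"gbtree"` (gradient-boosted stumps, default) or `"logistic"`
#'   (deterministic ridge logistic regression).
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`), so many combinations can share one split.
#' @return list of class `combo_score`: `combo` (sorted feature names),
#'   `mean_cv_auc`, `fold_aucs`.
#' @export
cv_auc <- function(X, y, folds = 5, seed = 1L, model = "gbtree",
                   fold_id = NULL) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(as.integer(y)))
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  ks <- sort(unique(fold_id))
  fold_aucs <- vapply(ks, function(k) {
    tr <- fold_id != k
    fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], model = model)
    auc_rank(predict(fit, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  structure(list(combo = sort(colnames(X)), mean_cv_auc = mean(fold_aucs),
                 fold_aucs = fold_aucs), class = "combo_score")
}

#' Choose the candidate-pool size by nested-prefix cross-validation
#'
#' Ranks the pool by importance from a full classifier fit (total split gain
#' for the tree booster; marginal univariate AUC for the logistic backend),
#' scores every nested prefix of sizes `1..|pool|` by [cv_auc()], and returns
#' the size attaining the maximum mean CV AUC (ties go to the smaller size).
#'
#' @param X samples x features matrix over the full pool.
#' @param y binary labels.
#' @param folds,seed,model as in [cv_auc()].
#' @return list: `size` (chosen count), `ranked` (pool in importance order),
#'   `prefix_auc` (mean CV AUC per prefix size).
#' @export
best_panel_size <- function(X, y, folds = 5, seed = 1L, model = "gbtree") {
  X <- as.matrix(X)
  if (!ncol(X)) stop("empty pool", call. = FALSE)
  y <- as.integer(as.logical(as.integer(y)))
  fit <- fit_classifier(X, y, model = model)
  imp <- classifier_importance(fit, X, y)
  ranked <- colnames(X)[order(-imp, colnames(X))]
  fold_id <- stratified_folds(y, folds, seed)
  prefix_auc <- vapply(seq_along(ranked), function(s) {
    cv_auc(X[, ranked[seq_len(s)], drop = FALSE], y, model = model,
           fold_id = fold_id)$mean_cv_auc
  }, numeric(1))
  list(size = which.max(prefix_auc), ranked = ranked, prefix_auc = prefix_auc)
}

#' Enumerate and score protein combinations under a budget
#'
#' Lists combinations of pool members with sizes in `size_range`. When the
#' total count is within `budget` the enumeration is exhaustive; otherwise
#' `budget` distinct combinations are sampled uniformly (sizes drawn
#' proportionally to the number of combinations of each size). Every
#' combination is scored by [cv_auc()] on one shared stratified fold split.
#'
#' @param X samples x features matrix over the pool.
#' @param y binary labels.
#' @param pool character vector of candidate features (default all columns).
#' @param size_range inclusive combination-size range (default `c(3, 10)`).
#' @param budget maximum number of combinations scored (default 200000).
#' @param folds,seed,model as in [cv_auc()].
#' @return list of class `combo_scores`: `combos` (list of sorted id vectors),
#'   `mean_cv_auc` (numeric), `fold_aucs` (folds x combos matrix), `mode`
#'   (`"exhaustive"` or `"sampled"`), `seed`.
#' @export
enumerate_and_score <- function(X, y, pool = colnames(X),
                                size_range = c(3, 10), budget = 200000,
                                folds = 5, seed = 1L, model = "gbtree") {
  X <- as.matrix(X)
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  sizes <- max(1, size_range[1]):min(length(pool), size_range[2])
  if (!length(sizes) || size_range[1] > length(pool)) {
    stop("size range incompatible with pool size", call. = FALSE)
  }
  counts <- choose(length(pool), sizes)
  total <- sum(counts)
  pool <- sort(pool)
  if (total <= budget) {
    mode <- "exhaustive"
    combos <- unlist(lapply(sizes, function(s) {
      utils::combn(pool, s, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    mode <- "sampled"
    combos <- with_seed(child_seed(seed, 11L), {
      seen <- new.env(hash = TRUE)
      out <- vector("list", budget)
      got <- 0L
      while (got < budget) {
        s <- sizes[sample.int(length(sizes), 1, prob = counts)]
        cb <- sort(sample(pool, s))
        key <- paste(cb, collapse = "|")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- cb
        }
      }
      out
    })
  }
  fold_id <- stratified_folds(y, folds, seed)
  sc <- lapply(combos, function(cb) {
    cv_auc(X[, cb, drop = FALSE], y, model = model, fold_id = fold_id)
  })
  structure(list(combos = combos,
                 mean_cv_auc = vapply(sc, `[[`, numeric(1), "mean_cv_auc"),
                 fold_aucs = vapply(sc, `[[`, numeric(length(unique(fold_id))),
                                    "fold_aucs"),
                 mode = mode, seed = seed),
            class = "combo_scores")
}

#' Select the final panel by frequency in the top combinations
#'
#' Sorts scored combinations by mean CV AUC (ties: smaller combination, then
#' lexicographic), keeps the best `top_n`, counts how often each protein
#' appears among them, and returns the `panel_size` most frequent proteins
#' (frequency ties: higher marginal univariate AUC, then lexicographic).
#'
#' @param scores a [enumerate_and_score()] result.
#' @param top_n number of top combinations retained (default 500).
#' @param panel_size final panel size (default 10).
#' @param marginal_auc optional named vector of per-protein univariate AUC
#'   distances used to break frequency ties.
#' @return list of class `selection_report`: `panel`, `frequency` (named
#'   counts over all proteins seen in the top combos), `top_combos` (indices
#'   into `scores$combos`), `mode`.
#' @export
frequency_select <- function(scores, top_n = 500, panel_size = 10,
                             marginal_auc = NULL) {
  n <- length(scores$combos)
  if (!n) stop("no scored combinations", call. = FALSE)
  sizes <- lengths(scores$combos)
  keys <- vapply(scores$combos, paste, character(1), collapse = "|")
  ord <- order(-scores$mean_cv_auc, sizes, keys)
  top <- ord[seq_len(min(top_n, n))]
  freq <- sort(table(unlist(scores$combos[top])), decreasing = TRUE)
  freq <- stats::setNames(as.integer(freq), names(freq))
  if (length(freq) < panel_size) {
    stop(sprintf("only %d distinct proteins in the top combinations; cannot form a panel of %d",
                 length(freq), panel_size), call. = FALSE)
  }
  ids <- names(freq)
  marg <- if (is.null(marginal_auc)) stats::setNames(rep(0, length(ids)), ids) else
    marginal_auc[ids]
  sel_ord <- order(-freq, -marg, ids)
  panel <- sort(ids[sel_ord][seq_len(panel_size)])
  structure(list(panel = panel, frequency = freq, top_combos = top,
                 mode = scores$mode), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> panel of %d proteins (%s enumeration)\n",
              length(x$panel), x$mode))
  cat("  ", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
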