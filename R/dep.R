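# Differential-expression calling: a SAM-style moderated-difference statistic
# with a permutation FDR, a per-pair fold-change test against a fitted
# t-distribution, and their intersection.

# moderated statistic pieces ------------------------------------------------

# r = mean difference, s = its standard error (pooled for unpaired data)
sam_r_s <- function(X, idx1, idx2, paired) {
  if (paired) {
    D <- X[, idx1, drop = FALSE] - X[, idx2, drop = FALSE]
    k <- ncol(D)
    r <- rowMeans(D)
    s <- sqrt(apply(D, 1, stats::var) / k)
  } else {
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(X[, idx1, drop = FALSE])
    m2 <- rowMeans(X[, idx2, drop = FALSE])
    ss1 <- apply(X[, idx1, drop = FALSE], 1, stats::var) * (n1 - 1)
    ss2 <- apply(X[, idx2, drop = FALSE], 1, stats::var) * (n2 - 1)
    r <- m1 - m2
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  }
  list(r = r, s = s)
}

# moderated statistic with a guard for zero-variance rows
sam_d <- function(r, s, s0) {
  den <- s + s0
  out <- r / den
  z <- den == 0
  if (any(z)) out[z] <- ifelse(r[z] == 0, 0, sign(r[z]) * Inf)
  out
}

# Tusher-style fudge constant: percentile of {s} minimizing the coefficient of
# variation of the MAD of d across five s-quantile bins.
choose_s0 <- function(r, s, grid = seq(0, 95, by = 5)) {
  if (all(s == 0)) return(1e-8)
  cand <- unique(stats::quantile(s, grid / 100, type = 7))
  bins <- cut(rank(s, ties.method = "first"), breaks = 5, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- sam_d(r, s, s0)
    mads <- tapply(d, bins, stats::mad)
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  unname(cand[which.min(cvs)])
}

# count, for each cutoff, how many |values| are >= cutoff (ties inclusive)
count_ge <- function(abs_vals, cutoffs) {
  sorted_neg <- sort(-abs_vals)
  findInterval(-cutoffs, sorted_neg)
}

#' SAM-style permutation differential-expression test
#'
#' Computes, per protein, the moderated statistic `d = r / (s + s0)` where `r`
#' is the (paired or unpaired) mean difference and `s` its standard error, and
#' `s0` a fudge constant chosen Tusher-style from the percentiles of `s`.
#' A permutation null (random label permutations; random sign flips for paired
#' data; exhaustive enumeration whenever the number of distinct permutations
#' does not exceed `n_perm`) yields an estimated FDR at every symmetric cutoff
#' `delta`: `median permuted calls * pi0 / observed calls`. The smallest
#' `delta` whose FDR is at or below the target is used for calling; calls
#' additionally require the linear fold-change criterion.
#'
#' @param m an [expr_matrix()] in `log2z` state.
#' @param labels two-level factor/character vector over the columns of `m`
#'   (the first level in sort order is treated as the "case" class).
#' @param paired if `TRUE`, `subject` pairs case and control columns and the
#'   null is built from per-pair sign flips.
#' @param subject subject identifier per column (required when `paired`).
#' @param n_perm number of permutations (>= 10; default 100).
#' @param fdr target false discovery rate (default 0.05).
#' @param fc linear fold-change threshold (default 1.5): calls require
#'   `2^r >= fc` (up) or `<= 1/fc` (down).
#' @param s0 optional fixed fudge constant overriding the automatic choice.
#' @param pi0 proportion of null proteins assumed in the FDR estimate
#'   (default 1, conservative).
#' @param seed RNG seed for sampled permutations.
#' @param fc_matrix optional log2-abundance matrix (same dimnames as `m`) from
#'   which fold changes are computed; defaults to `m`'s values. Use this to
#'   test on z-scores while thresholding fold change on the log2 FOT scale,
#'   where a linear ratio is meaningful.
#' @return A `data.frame` of class `dep_result` with one row per protein:
#'   `protein_id`, `d_stat`, `fold_change` (linear), `q_value`, `called`,
#'   `direction`; attributes `delta` (chosen cutoff), `s0`, `perm_d`
#'   (permutation statistics), `fdr_table` (cutoff vs estimated FDR),
#'   `exhaustive` (whether the null enumerated all distinct permutations).
#' @export
sam_test <- function(m, labels, paired = FALSE, subject = NULL, n_perm = 100,
                     fdr = 0.05, fc = 1.5, s0 = NULL, pi0 = 1, seed = 1L,
                     fc_matrix = NULL) {
  assert_state(m, "log2z", "sam_test()")
  if (n_perm < 10) stop("`n_perm` must be >= 10", call. = FALSE)
  X <- m$values
  lev <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) stop("`labels` length must match samples", call. = FALSE)
  if (length(lev) != 2) stop("exactly two classes required", call. = FALSE)
  idx1 <- which(labels == lev[1])
  idx2 <- which(labels == lev[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("at least 2 samples per class required", call. = FALSE)
  }

  if (paired) {
    if (is.null(subject)) stop("`subject` required for paired test", call. = FALSE)
    ord <- match(subject[idx1], subject[idx2])
    if (anyNA(ord) || length(idx1) != length(idx2)) {
      stop("pairing incomplete: every case needs a matching control subject",
           call. = FALSE)
    }
    idx2 <- idx2[ord]
  }

  rs <- sam_r_s(X, idx1, idx2, paired)
  if (is.null(s0)) s0 <- choose_s0(rs$r, rs$s)
  d <- sam_d(rs$r, rs$s, s0)

  # permutation null, exhaustive when feasible
  if (paired) {
    k <- length(idx1)
    n_distinct <- 2^k
    exhaustive <- n_distinct <= n_perm
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(1, -1)), k)))
    } else {
      with_seed(seed, matrix(sample(c(1, -1), k * n_perm, replace = TRUE),
                             nrow = n_perm))
    }
    D <- X[, idx1, drop = FALSE] - X[, idx2, drop = FALSE]
    perm_d <- apply(signs, 1, function(sg) {
      Ds <- sweep(D, 2, sg, "*")
      r <- rowMeans(Ds)
      s <- sqrt(apply(Ds, 1, stats::var) / k)
      sam_d(r, s, s0)
    })
  } else {
    n <- ncol(X)
    n1 <- length(idx1)
    n_distinct <- choose(n, n1)
    exhaustive <- n_distinct <= n_perm
    sets <- if (exhaustive) {
      utils::combn(seq_len(n), n1, simplify = FALSE)
    } else {
      with_seed(seed, replicate(n_perm, sample.int(n, n1), simplify = FALSE))
    }
    perm_d <- vapply(sets, function(g1) {
      g2 <- setdiff(seq_len(ncol(X)), g1)
      rs_p <- sam_r_s(X, g1, g2, FALSE)
      sam_d(rs_p$r, rs_p$s, s0)
    }, numeric(nrow(X)))
  }

  abs_d <- abs(d)
  cutoffs <- sort(unique(abs_d))
  obs_calls <- count_ge(abs_d, cutoffs)
  perm_calls <- matrix(
    apply(perm_d, 2, function(v) count_ge(abs(v), cutoffs)),
    nrow = length(cutoffs))
  med_calls <- apply(perm_calls, 1, stats::median)
  fdr_hat <- pmin(1, pi0 * med_calls / pmax(obs_calls, 1))
  fdr_table <- data.frame(delta = cutoffs, n_called = obs_calls,
                          median_perm = med_calls, fdr = fdr_hat)

  ok <- which(fdr_hat <= fdr)
  delta <- if (length(ok)) cutoffs[min(ok)] else Inf
  # q-value: minimum estimated FDR over all cutoffs at which the protein is
  # still called (i.e. cutoffs <= |d|)
  run_min <- cummin(fdr_hat)
  q <- run_min[findInterval(abs_d, cutoffs)]

  if (is.null(fc_matrix)) {
    fold_change <- 2^rs$r
  } else {
    if (!identical(dimnames(fc_matrix), dimnames(X))) {
      stop("`fc_matrix` must share dimnames with `m`", call. = FALSE)
    }
    fold_change <- 2^sam_r_s(fc_matrix, idx1, idx2, paired)$r
  }
  fc_ok <- fold_change >= fc | fold_change <= 1 / fc
  called <- abs_d >= delta & fc_ok

  res <- data.frame(protein_id = rownames(X), d_stat = d,
                    fold_change = fold_change, q_value = q,
                    called = called,
                    direction = ifelse(d >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "delta") <- delta
  attr(res, "s0") <- s0
  attr(res, "perm_d") <- perm_d
  attr(res, "fdr_table") <- fdr_table
  attr(res, "exhaustive") <- exhaustive
  class(res) <- c("dep_result", "data.frame")
  res
}

#' Per-pair fold-change test against a fitted t-distribution
#'
#' For each tumour/normal pair, the vector of per-protein log2 fold changes is
#' fit by a location-scale t-distribution (location = median, scale =
#' 1.4826 * MAD, degrees of freedom either fixed or profiled by maximum
#' likelihood over a grid); each protein gets a two-tail p-value
#' `2 * (1 - F_t(|lfc - loc| / scale))`. A protein is called when its
#' significant pairs (p < `p_thresh`) all share one sign and number at least
#' `min_frac` of all pairs.
#'
#' @param tumor,normal [expr_matrix()] objects (or plain named matrices) of
#'   log2 abundances on the same proteins.
#' @param pairs data.frame with columns `tumor`, `normal` mapping each tumour
#'   sample id to exactly one normal sample id.
#' @param p_thresh per-pair two-tail p-value threshold (default 0.05).
#' @param min_frac minimum fraction of pairs that must be significant with a
#'   consistent sign (default 0.5).
#' @param df degrees of freedom of the fitted t-distribution: a fixed number,
#'   or `"ml"` (default) to profile the likelihood over a grid per pair.
#' @return data.frame `protein_id`, `n_sig_up`, `n_sig_down`, `called`,
#'   `direction`; attributes `pair_pvalues` (proteins x pairs p matrix) and
#'   `pair_df` (fitted degrees of freedom per pair).
#' @export
pairfc_test <- function(tumor, normal, pairs, p_thresh = 0.05, min_frac = 0.5,
                        df = "ml") {
  if (is.matrix(tumor)) tumor <- expr_matrix(tumor, "raw")
  if (is.matrix(normal)) normal <- expr_matrix(normal, "raw")
  if (!identical(protein_ids(tumor), protein_ids(normal))) {
    stop("tumor and normal matrices must share the same proteins", call. = FALSE)
  }
  if (!all(pairs$tumor %in% sample_ids(tumor)) ||
      !all(pairs$normal %in% sample_ids(normal))) {
    stop("unmatched pair: sample id absent from matrix", call. = FALSE)
  }
  if (anyDuplicated(pairs$tumor) || anyDuplicated(pairs$normal)) {
    stop("each sample may appear in exactly one pair", call. = FALSE)
  }
  lfc <- tumor$values[, pairs$tumor, drop = FALSE] -
    normal$values[, pairs$normal, drop = FALSE]
  n_pairs <- ncol(lfc)
  df_grid <- c(1, 2, 3, 4, 5, 7, 10, 15, 20, 30, 50, 100)
  pmat <- matrix(NA_real_, nrow(lfc), n_pairs,
                 dimnames = list(rownames(lfc), pairs$tumor))
  smat <- pmat
  pair_df <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    loc <- stats::median(lfc[, j])
    sc <- stats::mad(lfc[, j])
    if (sc == 0) {
      stop(sprintf("degenerate fold-change distribution in pair %s (MAD = 0)",
                   pairs$tumor[j]), call. = FALSE)
    }
    z <- (lfc[, j] - loc) / sc
    dfj <- if (identical(df, "ml")) {
      ll <- vapply(df_grid, function(d) sum(stats::dt(z, d, log = TRUE)),
                   numeric(1))
      df_grid[which.max(ll)]
    } else df
    pair_df[j] <- dfj
    pmat[, j] <- 2 * (1 - stats::pt(abs(z), df = dfj))
    smat[, j] <- sign(z)
  }
  sig <- pmat < p_thresh
  n_up <- rowSums(sig & smat > 0)
  n_down <- rowSums(sig & smat < 0)
  n_sig <- n_up + n_down
  dominant <- pmax(n_up, n_down)
  consistent <- (n_up == 0 | n_down == 0)
  called <- consistent & dominant >= min_frac * n_pairs & n_sig > 0
  res <- data.frame(protein_id = rownames(lfc), n_sig_up = n_up,
                    n_sig_down = n_down, called = called,
                    direction = ifelse(n_up >= n_down, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "pair_pvalues") <- pmat
  attr(res, "pair_df") <- pair_df
  res
}

#' Intersect the two differential-expression call sets
#'
#' The final differential proteins are those called by both the SAM-style test
#' and the per-pair fold-change test.
#'
#' @param a a [sam_test()] result.
#' @param b a [pairfc_test()] result.
#' @return character vector of protein ids called by both.
#' @export
overlap_deps <- function(a, b) {
  if (!setequal(a$protein_id, b$protein_id)) {
    stop("protein universes differ between the two call sets", call. = FALSE)
  }
  sort(intersect(a$protein_id[a$called], b$protein_id[b$called]))
}

#' Second-level comparison: PM vs PM-free among tumour samples
#'
#' Runs an unpaired [sam_test()] between PM and PM-free tumours, restricted to
#' proteins already called differential tumour-vs-normal.
#'
#' @param m_tumor [expr_matrix()] (`log2z`) of tumour samples only, restricted
#'   to first-level differential proteins.
#' @param pm_labels per-column PM status (two classes, e.g. 0/1).
#' @param dep_ids the first-level differential protein set; every protein in
#'   `m_tumor` must belong to it.
#' @inheritParams sam_test
#' @return A `dep_result` as from [sam_test()].
#' @export
group_dep <- function(m_tumor, pm_labels, dep_ids, n_perm = 100, fdr = 0.05,
                      fc = 1.5, seed = 1L, fc_matrix = NULL) {
  extra <- setdiff(protein_ids(m_tumor), dep_ids)
  if (length(extra)) {
    stop(sprintf("proteins not in the first-level DEP set: %s",
                 paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
  }
  sam_test(m_tumor, pm_labels, paired = FALSE, n_perm = n_perm, fdr = fdr,
           fc = fc, seed = seed, fc_matrix = fc_matrix)
}

#' @export
print.dep_result <- function(x, ...) {
  cat(sprintf("<dep_result> %d proteins, %d called (delta = %.4g, s0 = %.4g)\n",
              nrow(x), sum(x$called), attr(x, "delta"), attr(x, "s0")))
  invisible(x)
}
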