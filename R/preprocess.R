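#' Fraction-of-total (FOT) normalization
#'
#' Rescales every sample column of a raw intensity matrix so each protein's
#' value is its fraction of that sample's total intensity:
#' `fot[p, s] = raw[p, s] / sum_p raw[p, s]`. Column sums of the result are 1.
#'
#' @param m an [expr_matrix()] in `raw` state with nonnegative values.
#' @return An [expr_matrix()] in `fot` state.
#' @export
fot_normalize <- function(m) {
  assert_state(m, "raw", "fot_normalize()")
  v <- m$values
  neg <- which(colSums(v < 0) > 0)
  if (length(neg)) {
    stop(sprintf("negative intensities in sample(s): %s",
                 paste(colnames(v)[neg], collapse = ", ")), call. = FALSE)
  }
  tot <- colSums(v)
  zero <- which(tot <= 0)
  if (length(zero)) {
    stop(sprintf("all-zero sample column(s): %s",
                 paste(colnames(v)[zero], collapse = ", ")), call. = FALSE)
  }
  expr_matrix(sweep(v, 2, tot, "/"), "fot")
}

#' Filter proteins by unique-peptide support and FOT abundance
#'
#' Retains proteins identified with at least `min_unique` unique peptides and
#' quantified above `min_fot` (fraction of total) in at least one sample.
#' Original protein ordering is preserved; the removal reason for each dropped
#' protein is recorded in the `filter_log` attribute.
#'
#' @param m an [expr_matrix()] in `fot` state.
#' @param peptides data.frame with columns `protein_id`, `unique_peptides`
#'   covering every protein in `m`.
#' @param min_unique minimum unique peptides (default 2).
#' @param min_fot FOT threshold: keep proteins whose maximum FOT over samples
#'   exceeds it (default 1e-5).
#' @return Filtered [expr_matrix()] in `fot` state, with attribute
#'   `filter_log` (data.frame `protein_id`, `reason`).
#' @export
filter_proteins <- function(m, peptides, min_unique = 2, min_fot = 1e-5) {
  assert_state(m, "fot", "filter_proteins()")
  pid <- protein_ids(m)
  idx <- match(pid, peptides$protein_id)
  if (anyNA(idx)) {
    stop(sprintf("proteins missing from peptide table: %s",
                 paste(utils::head(pid[is.na(idx)], 5), collapse = ", ")),
         call. = FALSE)
  }
  np <- peptides$unique_peptides[idx]
  max_fot <- apply(m$values, 1, max)
  keep <- np >= min_unique & max_fot > min_fot
  reason <- ifelse(np < min_unique,
                   ifelse(max_fot <= min_fot, "peptides+fot", "peptides"),
                   "fot")
  log <- data.frame(protein_id = pid[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  out <- expr_matrix(m$values[keep, , drop = FALSE], "fot")
  attr(out, "filter_log") <- log
  out
}

#' Per-sample log2 z-score normalization
#'
#' Takes `log2(max(FOT, floor))` and standardizes each sample column to mean 0,
#' SD 1 over the retained proteins (each sample scaled by its own SD).
#' A per-protein (row-wise) orientation is available via `by = "protein"`.
#'
#' @param m a filtered [expr_matrix()] in `fot` state.
#' @param floor positive floor applied to FOT values before log2 (zeros are
#'   otherwise unloggable); default 1e-8.
#' @param by standardization orientation: `"sample"` (default, each column) or
#'   `"protein"` (each row).
#' @return An [expr_matrix()] in `log2z` state.
#' @export
log2_zscore <- function(m, floor = 1e-8, by = c("sample", "protein")) {
  assert_state(m, "fot", "log2_zscore()")
  by <- match.arg(by)
  if (!is.numeric(floor) || floor <= 0) stop("`floor` must be > 0", call. = FALSE)
  x <- log2(pmax(m$values, floor))
  if (by == "sample") {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    if (any(sd == 0)) {
      stop(sprintf("constant sample column(s): %s",
                   paste(colnames(x)[sd == 0], collapse = ", ")), call. = FALSE)
    }
    z <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  } else {
    mu <- rowMeans(x)
    sd <- apply(x, 1, stats::sd)
    if (any(sd == 0)) {
      stop(sprintf("constant protein row(s): %s",
                   paste(rownames(x)[sd == 0], collapse = ", ")), call. = FALSE)
    }
    z <- sweep(sweep(x, 1, mu, "-"), 1, sd, "/")
  }
  expr_matrix(z, "log2z")
}

#' Run the full preprocessing chain raw -> FOT -> filter -> log2 z-score
#'
#' @inheritParams fot_normalize
#' @inheritParams filter_proteins
#' @inheritParams log2_zscore
#' @return list with `fot` (filtered FOT matrix) and `z` (log2z matrix).
#' @export
preprocess_expression <- function(m, peptides, min_unique = 2, min_fot = 1e-5,
                                  floor = 1e-8) {
  fot <- filter_proteins(fot_normalize(m), peptides,
                         min_unique = min_unique, min_fot = min_fot)
  list(fot = fot, z = log2_zscore(fot, floor = floor))
}
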