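#' Expression matrix with an explicit normalization state
#'
#' A thin container for a proteins x samples abundance matrix that carries its
#' normalization state (`"raw"`, `"fot"` or `"log2z"`), so the pipeline can
#' enforce the order raw -> FOT -> filter -> log2 z-score and reject
#' out-of-order calls.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimensions must carry unique names (protein and sample identifiers).
#' @param state normalization state, one of `"raw"`, `"fot"`, `"log2z"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("P", 1:3), c("s1", "s2"))), "raw")
#' dim(m)
#' @export
expr_matrix <- function(values, state = c("raw", "fot", "log2z")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop("`values` must have row (protein) and column (sample) names", call. = FALSE)
  }
  if (anyDuplicated(pid)) stop("duplicate protein ids", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample ids", call. = FALSE)
  structure(list(values = values, state = state), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d proteins x %d samples, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

protein_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

assert_state <- function(m, state, what) {
  if (!inherits(m, "expr_matrix")) {
    stop(sprintf("%s expects an `expr_matrix`", what), call. = FALSE)
  }
  if (!identical(m$state, state)) {
    stop(sprintf("%s expects state '%s' but got '%s' (pipeline order is raw -> fot -> log2z)",
                 what, state, m$state), call. = FALSE)
  }
  invisible(m)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is a plain TSV whose first column is `protein_id` and
#' remaining columns are sample intensities, one column per sample.
#'
#' @param path file path.
#' @param state normalization state recorded on the returned object.
#' @return `read_expression_tsv()` returns an [expr_matrix()];
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, state = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "protein_id") stop("first column must be `protein_id`", call. = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$protein_id
  expr_matrix(v, state)
}

#' @param m an [expr_matrix()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(protein_id = protein_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample annotation table
#'
#' Columns: `sample_id, subject_id, tissue (T|N), group (Syn|Meta|Con),
#' pm_status (0|1), os_months, os_event, age, stage`.
#'
#' @param path file path.
#' @param samples a sample annotation `data.frame`.
#' @export
read_samples_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_samples_csv
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
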