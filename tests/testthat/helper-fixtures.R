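# Shared fixture builders; everything is generated in code under fixed seeds.

# raw-state matrix with named dims
raw_matrix <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, "raw")
}

# z-state matrix straight from numbers (state tag only; used where the tests
# need direct control over the values)
z_matrix <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, "log2z")
}

# two-class z matrix with an optional planted shift in the first `n_shift`
# proteins of group 1
two_class_z <- function(P, n1, n2, shift = 0, n_shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(P * (n1 + n2), 0, sd), P, n1 + n2)
  if (n_shift > 0) v[seq_len(n_shift), seq_len(n1)] <- v[seq_len(n_shift), seq_len(n1)] + shift
  rownames(v) <- sprintf("P%03d", seq_len(P))
  colnames(v) <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  list(m = z_matrix(v), labels = rep(c("g1", "g2"), c(n1, n2)))
}

# exponential survival with a binary or continuous covariate effect
sim_surv <- function(n, beta, x = NULL, base_rate = 0.05, cens_rate = 0.02,
                     seed = 1) {
  set.seed(seed)
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, base_rate * exp(beta * x))
  t_c <- rexp(n, cens_rate)
  data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), x = x)
}
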