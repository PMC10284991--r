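test_that("sam_test calls nothing on an exact null of duplicated groups", {
  set.seed(21)
  half <- matrix(rnorm(40 * 3), 40, 3)
  v <- cbind(half, half)  # group 2 is a copy of group 1
  colnames(v) <- sprintf("s%02d", 1:6)
  rownames(v) <- sprintf("P%03d", 1:40)
  res <- sam_test(z_matrix(v), rep(c("g1", "g2"), each = 3), seed = 1)
  expect_equal(sum(res$called), 0)
  expect_true(all(res$d_stat == 0))
})

test_that("sam_test permutation null is exhaustive for small designs", {
  set.seed(8)
  tc <- two_class_z(8, 3, 3, shift = 2.5, n_shift = 2, seed = 8)
  res <- sam_test(tc$m, tc$labels, n_perm = 100, seed = 1)
  expect_true(attr(res, "exhaustive"))
  expect_equal(ncol(attr(res, "perm_d")), choose(6, 3))
})

test_that("sam_test q-values are valid and calls respect both thresholds", {
  tc <- two_class_z(200, 8, 8, shift = 2, n_shift = 30, seed = 4)
  res <- sam_test(tc$m, tc$labels, seed = 2)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  fc_ok <- res$fold_change >= 1.5 | res$fold_change <= 1 / 1.5
  expect_true(all(!res$called | (res$q_value <= 0.05 & fc_ok)))
})

test_that("sam_test recovers strong planted shifts", {
  hits <- vapply(1:5, function(s) {
    tc <- two_class_z(500, 10, 10, shift = 2, n_shift = 50, seed = s)
    res <- sam_test(tc$m, tc$labels, seed = s)
    mean(res$called[1:50])
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("sam_test statistic is invariant to protein order and row shifts", {
  tc <- two_class_z(60, 5, 5, shift = 1.5, n_shift = 10, seed = 9)
  res <- sam_test(tc$m, tc$labels, seed = 3)
  # reorder proteins
  perm <- sample(nrow(tc$m$values))
  m2 <- z_matrix(tc$m$values[perm, ])
  res2 <- sam_test(m2, tc$labels, seed = 3)
  expect_equal(res2$d_stat[match(res$protein_id, res2$protein_id)], res$d_stat)
  # add a constant to every sample of one protein: d unchanged
  v3 <- tc$m$values
  v3[5, ] <- v3[5, ] + 100
  res3 <- sam_test(z_matrix(v3), tc$labels, seed = 3)
  expect_equal(res3$d_stat[5], res$d_stat[5], tolerance = 1e-9)
})

test_that("sam_test validates inputs", {
  tc <- two_class_z(10, 3, 3, seed = 1)
  expect_error(sam_test(tc$m, tc$labels, n_perm = 5), "n_perm")
  expect_error(sam_test(tc$m, rep("g1", 6)), "two classes")
  expect_error(sam_test(tc$m, c("g1", rep("g2", 5))), "2 samples")
  expect_error(sam_test(tc$m, tc$labels, paired = TRUE), "subject")
})

test_that("pairfc_test p-values follow the fitted t-distribution", {
  set.seed(31)
  P <- 100
  lfc_t <- rnorm(P, 0, 0.1)
  lfc_t[1] <- 5  # one outlier gene
  tum <- matrix(lfc_t, ncol = 1, dimnames = list(sprintf("P%03d", 1:P), "T1"))
  nor <- matrix(0, ncol = 1, nrow = P, dimnames = list(sprintf("P%03d", 1:P), "N1"))
  pairs <- data.frame(tumor = "T1", normal = "N1")
  res <- pairfc_test(tum, nor, pairs, df = 4)
  pv <- attr(res, "pair_pvalues")[, 1]
  # independent oracle: standardize by median/MAD, evaluate the t CDF
  loc <- median(lfc_t); sc <- mad(lfc_t)
  oracle <- 2 * (1 - pt(abs((lfc_t - loc) / sc), df = 4))
  expect_equal(unname(pv), unname(oracle), tolerance = 1e-12)
  expect_lt(pv["P001"], 0.05)
  expect_gt(min(pv[-1][abs(lfc_t[-1] - loc) < 0.05]), 0.5)
  expect_true(res$called[1])
  # gene at the fitted location has p = 1
  at_loc <- which.min(abs(lfc_t - loc))
  expect_gt(pv[at_loc], 0.9)
})

test_that("pairfc_test requires sign consistency across pairs", {
  set.seed(32)
  P <- 60
  base <- rnorm(P, 0, 0.1)
  l1 <- base; l1[1] <- 4   # significant up in pair 1
  l2 <- base; l2[1] <- -4  # significant down in pair 2
  tum <- cbind(T1 = l1, T2 = l2)
  rownames(tum) <- sprintf("P%03d", 1:P)
  nor <- matrix(0, P, 2, dimnames = list(rownames(tum), c("N1", "N2")))
  pairs <- data.frame(tumor = c("T1", "T2"), normal = c("N1", "N2"))
  res <- pairfc_test(tum, nor, pairs, min_frac = 0.5, df = 4)
  expect_false(res$called[1])
  # same sign in both pairs -> called
  l2b <- base; l2b[1] <- 4
  tum2 <- cbind(T1 = l1, T2 = l2b)
  rownames(tum2) <- rownames(tum)
  res2 <- pairfc_test(tum2, nor, pairs, min_frac = 0.5, df = 4)
  expect_true(res2$called[1])
})

test_that("pairfc_test rejects degenerate and mismatched input", {
  P <- 10
  tum <- matrix(1, P, 1, dimnames = list(sprintf("P%03d", 1:P), "T1"))
  nor <- matrix(0, P, 1, dimnames = list(sprintf("P%03d", 1:P), "N1"))
  expect_error(pairfc_test(tum, nor, data.frame(tumor = "T1", normal = "N1")),
               "MAD = 0")
  set.seed(1)
  tum2 <- matrix(rnorm(P), P, 1, dimnames = list(sprintf("P%03d", 1:P), "T1"))
  expect_error(pairfc_test(tum2, nor, data.frame(tumor = "TX", normal = "N1")),
               "unmatched")
})

test_that("overlap_deps intersects calls and checks the universe", {
  mk <- function(ids, called) {
    data.frame(protein_id = ids, called = ids %in% called,
               stringsAsFactors = FALSE)
  }
  u <- c("p1", "p2", "p3", "p4")
  expect_equal(overlap_deps(mk(u, c("p1", "p2", "p3")), mk(u, c("p2", "p3", "p4"))),
               c("p2", "p3"))
  expect_equal(overlap_deps(mk(u, c("p1")), mk(u, character(0))), character(0))
  # generic random instance vs set-intersection oracle
  set.seed(14)
  ids <- sprintf("g%03d", 1:100)
  a <- sample(ids, 40); b <- sample(ids, 40)
  expect_setequal(overlap_deps(mk(ids, a), mk(ids, b)), intersect(a, b))
  expect_error(overlap_deps(mk(u, "p1"), mk(u[-1], "p2")), "universes")
})

test_that("group_dep enforces the first-level restriction and finds planted groups", {
  tc <- two_class_z(100, 14, 6, shift = 1.5, n_shift = 20, seed = 6)
  expect_error(group_dep(tc$m, tc$labels, dep_ids = sprintf("P%03d", 1:50)),
               "first-level")
  # shift 3 = SNR 1.5 x (sd 1 + sd 1): essentially every module protein called
  hits <- vapply(1:5, function(s) {
    tcs <- two_class_z(100, 14, 6, shift = 3, n_shift = 20, seed = s)
    res <- group_dep(tcs$m, tcs$labels, dep_ids = protein_ids(tcs$m), seed = s)
    mean(res$called[1:20])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
  # shuffled labels destroy the structure
  set.seed(77)
  null_calls <- {
    tcs <- two_class_z(100, 14, 6, shift = 0, n_shift = 0, seed = 11)
    res <- group_dep(tcs$m, sample(tcs$labels), dep_ids = protein_ids(tcs$m),
                     seed = 11)
    sum(res$called)
  }
  expect_lte(null_calls, 3)
})
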