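test_that("auc_rank matches trivial limits and the all-pairs oracle", {
  expect_equal(auc_rank(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(5)
  big <- auc_rank(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(big - 0.5), 0.05)
  expect_error(auc_rank(1:5, rep(1, 5)), "both classes")

  # random instance with ties vs brute-force pairwise counting
  set.seed(6)
  s <- round(rnorm(30), 1)
  y <- rbinom(30, 1, 0.5); y[1] <- 1; y[2] <- 0
  pos <- s[y == 1]; neg <- s[y == 0]
  oracle <- 0
  for (a in pos) for (b in neg) oracle <- oracle + (a > b) + 0.5 * (a == b)
  oracle <- oracle / (length(pos) * length(neg))
  expect_identical(auc_rank(s, y), oracle)
})

test_that("cv_auc is stratified, seeded and sane at the limits", {
  set.seed(7)
  y <- rep(c(1, 0), c(12, 12))
  X <- cbind(f1 = y + rnorm(24, 0, 1e-6))
  cs <- cv_auc(X, y, folds = 5, seed = 1, model = "logistic")
  expect_equal(cs$mean_cv_auc, 1)
  expect_equal(cs$mean_cv_auc, mean(cs$fold_aucs), tolerance = 1e-12)

  # determinism
  Xn <- cbind(f1 = rnorm(24))
  a <- cv_auc(Xn, y, folds = 5, seed = 3, model = "gbtree")
  b <- cv_auc(Xn, y, folds = 5, seed = 3, model = "gbtree")
  expect_identical(a$fold_aucs, b$fold_aucs)

  # pure noise is near 0.5 on average
  null_auc <- vapply(1:20, function(s) {
    set.seed(s)
    cv_auc(cbind(f1 = rnorm(24)), y, folds = 5, seed = s,
           model = "logistic")$mean_cv_auc
  }, numeric(1))
  expect_gt(mean(null_auc), 0.3)
  expect_lt(mean(null_auc), 0.7)

  # stratification guard
  expect_error(cv_auc(Xn, rep(c(1, 0), c(3, 21)), folds = 5, seed = 1),
               "folds")
})

test_that("best_panel_size finds a compact informative prefix", {
  sizes <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    y <- rep(c(1, 0), each = n / 2)
    X <- cbind(a = y * 2 + rnorm(n, 0, 1), b = y * 2 + rnorm(n, 0, 1),
               c = rnorm(n), d = rnorm(n), e = rnorm(n))
    best_panel_size(X, y, folds = 5, seed = s, model = "logistic")$size
  }, numeric(1))
  expect_gte(sum(sizes %in% 2:3), 8)

  # single-feature pool
  set.seed(1)
  y <- rep(c(1, 0), each = 10)
  expect_equal(best_panel_size(cbind(a = rnorm(20)), y, seed = 1,
                               model = "logistic")$size, 1)

  # identical copies tie -> smallest size
  Xc <- cbind(a = y + rnorm(20, 0, 0.4))
  Xc <- cbind(Xc, b = Xc[, "a"], c = Xc[, "a"])
  expect_equal(best_panel_size(Xc, y, seed = 2, model = "logistic")$size, 1)
})

test_that("enumerate_and_score respects the exhaustive/sampled contract", {
  set.seed(11)
  n <- 20
  y <- rep(c(1, 0), each = n / 2)
  X5 <- matrix(rnorm(n * 5), n, dimnames = list(NULL, letters[1:5]))
  sc <- enumerate_and_score(X5, y, size_range = c(1, 5), budget = 1000,
                            seed = 1, model = "logistic")
  expect_equal(length(sc$combos), 31)  # 2^5 - 1
  expect_identical(sc$mode, "exhaustive")

  X12 <- matrix(rnorm(n * 12), n, dimnames = list(NULL, letters[1:12]))
  sc2 <- enumerate_and_score(X12, y, size_range = c(3, 10), budget = 200,
                             seed = 1, model = "logistic")
  expect_identical(sc2$mode, "sampled")
  expect_equal(length(sc2$combos), 200)
  keys <- vapply(sc2$combos, paste, character(1), collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(lengths(sc2$combos) >= 3 & lengths(sc2$combos) <= 10))

  expect_error(enumerate_and_score(X5, y, budget = 0), "budget")
})

test_that("combination scores match an independent rescoring oracle", {
  set.seed(12)
  n <- 30
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(a = y * 3 + rnorm(n), b = rnorm(n), c = rnorm(n))
  sc <- enumerate_and_score(X, y, size_range = c(1, 3), budget = 100,
                            seed = 4, model = "logistic")
  # rebuild the shared fold split and rescore each combo independently
  fold_id <- pmsig:::stratified_folds(y, 5, 4)
  oracle <- vapply(sc$combos, function(cb) {
    aucs <- vapply(sort(unique(fold_id)), function(k) {
      tr <- fold_id != k
      fit <- ridge_logistic(X[tr, cb, drop = FALSE], y[tr])
      auc_rank(predict(fit, X[!tr, cb, drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_equal(sc$mean_cv_auc, oracle, tolerance = 1e-12)
  expect_equal(order(-sc$mean_cv_auc), order(-oracle))
})

test_that("frequency_select ranks proteins by top-combination frequency", {
  combos <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"))
  sc <- structure(list(combos = combos,
                       mean_cv_auc = c(0.9, 0.8, 0.7, 0.6),
                       mode = "exhaustive"), class = "combo_scores")
  rep1 <- frequency_select(sc, top_n = 3, panel_size = 2)
  expect_equal(rep1$panel[1], "a")  # in every top combo
  expect_equal(unname(rep1$frequency["a"]), 3)

  # fewer combos than top_n: all retained
  rep2 <- frequency_select(sc, top_n = 500, panel_size = 2)
  expect_equal(length(rep2$top_combos), 4)

  expect_error(frequency_select(sc, top_n = 1, panel_size = 3), "distinct")
})

test_that("panel selection recovers planted informative proteins", {
  overlaps <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    inf <- sapply(1:10, function(i) y * 1.5 + rnorm(n))
    noise <- matrix(rnorm(n * 10), n)
    X <- cbind(inf, noise)
    colnames(X) <- c(sprintf("inf%02d", 1:10), sprintf("ns%02d", 1:10))
    sc <- enumerate_and_score(X, y, size_range = c(3, 6), budget = 400,
                              seed = s, model = "logistic")
    rep <- frequency_select(sc, top_n = 100, panel_size = 10)
    length(grep("^inf", rep$panel))
  }, numeric(1))
  expect_gte(mean(overlaps), 8)
})

test_that("adding a perfect duplicated feature never lowers the best AUC", {
  set.seed(13)
  n <- 24
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  base <- max(enumerate_and_score(X, y, size_range = c(1, 2), budget = 50,
                                  seed = 2, model = "logistic")$mean_cv_auc)
  X2 <- cbind(X, p = y)
  withp <- max(enumerate_and_score(X2, y, size_range = c(1, 3), budget = 50,
                                   seed = 2, model = "logistic")$mean_cv_auc)
  expect_gte(withp, base)
})
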