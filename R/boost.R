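# Classification backends for panel scoring and weight fitting.
#
# - ridge_logistic(): L2-penalised logistic regression by IRLS. This is the
#   convergence target of an additive linear booster with L2 shrinkage, and is
#   fully deterministic — used both as the "linear booster" for weight
#   extraction and as the deterministic CV backend.
# - gb_stump(): a small gradient-boosted decision-stump classifier (logistic
#   loss, shrinkage, L2 leaf penalty) for the tree-booster route.

#' L2-regularized logistic regression (linear-booster equivalent)
#'
#' Fits `P(y = 1) = plogis(b0 + X w)` with an L2 penalty `lambda * ||w||^2 / 2`
#' on the slopes (intercept unpenalized) by iteratively reweighted least
#' squares.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary response (0/1).
#' @param lambda L2 penalty (default 1).
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return list of class `ridge_logistic`: `intercept`, `coef` (named),
#'   `lambda`.
#' @export
ridge_logistic <- function(X, y, lambda = 1, maxit = 100, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p + 1)
  Xi <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    # penalized IRLS normal equations
    H <- crossprod(Xi, Xi * w) + pen
    g <- crossprod(Xi, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  cf <- beta[-1]
  names(cf) <- colnames(X)
  structure(list(intercept = beta[1], coef = cf, lambda = lambda),
            class = "ridge_logistic")
}

#' @param object fitted model.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @rdname ridge_logistic
#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  drop(as.matrix(newdata)[, names(object$coef), drop = FALSE] %*% object$coef) +
    object$intercept
}

# best squared-error split of gradient residuals on one feature
stump_best_split <- function(x, grad, hess, lambda) {
  ord <- order(x)
  xs <- x[ord]; g <- grad[ord]; h <- hess[ord]
  cg <- cumsum(g); ch <- cumsum(h)
  G <- cg[length(cg)]; H <- ch[length(ch)]
  # candidate splits between distinct consecutive values
  valid <- which(diff(xs) > 0)
  if (!length(valid)) return(NULL)
  gl <- cg[valid]; hl <- ch[valid]
  gain <- gl^2 / (hl + lambda) + (G - gl)^2 / (H - hl + lambda) -
    G^2 / (H + lambda)
  i <- which.max(gain)
  list(gain = gain[i],
       threshold = (xs[valid[i]] + xs[valid[i] + 1]) / 2,
       left = -gl[i] / (hl[i] + lambda),
       right = -(G - gl[i]) / (H - hl[i] + lambda))
}

#' Gradient-boosted decision stumps for binary classification
#'
#' Boosts depth-1 trees on the logistic loss with shrinkage `eta` and an L2
#' leaf penalty, xgboost-style. Intended for the small-n panel-scoring setting;
#' deterministic (no subsampling).
#'
#' @param X samples x features matrix.
#' @param y binary response (0/1).
#' @param rounds boosting rounds (default 50).
#' @param eta learning rate (default 0.3).
#' @param lambda L2 leaf penalty (default 1).
#' @return list of class `gb_stump` with the stump ensemble, the base score
#'   (log-odds of the class prior) and per-feature total gain (`importance`).
#' @export
gb_stump <- function(X, y, rounds = 50, eta = 0.3, lambda = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  base <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  pred <- rep(base, nrow(X))
  stumps <- vector("list", rounds)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  for (r in seq_len(rounds)) {
    mu <- stats::plogis(pred)
    grad <- mu - y
    hess <- pmax(mu * (1 - mu), 1e-10)
    best <- NULL; best_j <- NA_integer_
    for (j in seq_len(ncol(X))) {
      sp <- stump_best_split(X[, j], grad, hess, lambda)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp; best_j <- j
      }
    }
    if (is.null(best) || best$gain <= 0) break
    contrib <- eta * ifelse(X[, best_j] <= best$threshold, best$left, best$right)
    pred <- pred + contrib
    stumps[[r]] <- list(feature = colnames(X)[best_j], threshold = best$threshold,
                        left = eta * best$left, right = eta * best$right)
    imp[best_j] <- imp[best_j] + best$gain
  }
  stumps <- stumps[!vapply(stumps, is.null, logical(1))]
  structure(list(base = base, stumps = stumps, importance = imp),
            class = "gb_stump")
}

#' @param object fitted ensemble.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @rdname gb_stump
#' @export
predict.gb_stump <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pred <- rep(object$base, nrow(newdata))
  for (st in object$stumps) {
    pred <- pred + ifelse(newdata[, st$feature] <= st$threshold,
                          st$left, st$right)
  }
  pred
}

# uniform fit/predict/importance interface used by the selection module
fit_classifier <- function(X, y, model = c("gbtree", "logistic"), seed = 1L) {
  model <- match.arg(model)
  if (model == "gbtree") gb_stump(X, y) else ridge_logistic(X, y)
}

classifier_importance <- function(fit, X, y) {
  if (inherits(fit, "gb_stump")) return(fit$importance)
  # logistic backend: rank by marginal univariate AUC distance from 0.5
  vapply(colnames(X), function(j) abs(auc_rank(X[, j], y) - 0.5), numeric(1))
}
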