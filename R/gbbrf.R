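# Gradient boosting with a small random forest as the per-round weak
# learner. Each round fits trees_per_round bootstrap + feature-subsampled
# regression trees to the log-loss pseudo-residuals y - p; leaf outputs are
# one-step Newton values regularised by lambda; the forest increment is the
# mean over its trees, shrunk by the learning rate.

#' Binary cross-entropy (log loss)
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-15, 1 - 1e-15]`.
#'
#' @param labels 0/1 numeric vector (or logical / two-level factor, in
#'   which case the second level counts as 1).
#' @param probs predicted positive-class probabilities, same length.
#' @return Non-negative scalar.
#' @export
log_loss <- function(labels, probs) {
  y <- .as_binary(labels)
  if (length(y) != length(probs)) stop("labels and probs lengths differ")
  p <- pmin(pmax(probs, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

.as_binary <- function(labels, positive = NULL) {
  if (is.factor(labels)) {
    pos <- positive %||% levels(labels)[[nlevels(labels)]]
    as.numeric(labels == pos)
  } else if (is.logical(labels)) as.numeric(labels)
  else {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.numeric(labels)
  }
}

#' Gradient boosting based on random forests (GBBRF)
#'
#' Fits an additive model under binary log loss. The score starts at the
#' empirical log-odds `f0 = log(n_pos / n_neg)`; each round adds
#' `learning_rate` times the mean output of a forest of regression trees
#' fitted to the pseudo-residuals `y - p`. Tree leaves hold the Newton step
#' `sum(r) / (sum(p * (1 - p)) + lambda)` over their training rows.
#'
#' @param x numeric feature matrix, or a [labeled_dataset()] (then `y` is
#'   ignored).
#' @param y binary labels (two-level factor, logical, or 0/1).
#' @param n_rounds number of boosting rounds (default 500).
#' @param learning_rate shrinkage applied to each round (default 0.1).
#' @param lambda leaf regulariser in the Newton denominator (default 5).
#' @param max_depth maximum tree depth (default 3).
#' @param trees_per_round forest size per round (default 10).
#' @param feature_fraction fraction of features examined per split;
#'   default `sqrt(p)/p`.
#' @param bootstrap draw a bootstrap row sample per tree (default `TRUE`).
#' @param min_leaf minimum samples per leaf (default 2).
#' @param seed optional integer; `set.seed(seed)` is called when given, so
#'   refitting is bit-identical.
#' @param positive label treated as the positive class when `y` is a factor.
#' @return An object of class `gbbrf`: list with `f0`, `rounds` (list of
#'   forests), `train_logloss` (per-round trace), the configuration, and
#'   the label levels.
#' @examples
#' d <- synth_blobs(60, 20, dim = 2, separation = 4, seed = 1)
#' fit <- gbbrf(d, n_rounds = 20, trees_per_round = 3, seed = 1)
#' fit
#' head(predict(fit, d$features))
#' @export
gbbrf <- function(x, y = NULL, n_rounds = 500, learning_rate = 0.1, lambda = 5,
                  max_depth = 3, trees_per_round = 10, feature_fraction = NULL,
                  bootstrap = TRUE, min_leaf = 2, seed = NULL, positive = NULL) {
  if (inherits(x, "labeled_dataset")) {
    positive <- positive %||% x$positive
    y <- x$labels
    x <- x$features
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (is.null(y)) stop("labels required")
  yl <- if (is.factor(y)) y else factor(.as_binary(y), levels = c(0, 1))
  yb <- .as_binary(yl, positive)
  if (length(yb) != nrow(x)) stop("x and y lengths differ")
  n_pos <- sum(yb == 1); n_neg <- sum(yb == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  stopifnot(n_rounds >= 0, learning_rate >= 0, lambda >= 0, max_depth >= 1,
            trees_per_round >= 1, min_leaf >= 1)
  p <- ncol(x)
  if (is.null(feature_fraction)) feature_fraction <- sqrt(p) / p
  stopifnot(feature_fraction > 0, feature_fraction <= 1)
  mtry <- max(1L, min(p, as.integer(round(feature_fraction * p))))
  if (!is.null(seed)) set.seed(seed)

  f0 <- log(n_pos / n_neg)
  score <- rep(f0, nrow(x))
  rounds <- vector("list", n_rounds)
  trace <- numeric(n_rounds)
  for (m in seq_len(n_rounds)) {
    prob <- stats::plogis(score)
    r <- yb - prob
    w <- prob * (1 - prob)
    fit <- cpp_fit_round(x, r, w, lambda, as.integer(trees_per_round),
                         as.integer(max_depth), as.integer(min_leaf),
                         mtry, isTRUE(bootstrap))
    rounds[[m]] <- fit$trees
    score <- score + learning_rate * fit$h
    trace[[m]] <- log_loss(yb, stats::plogis(score))
  }

  structure(list(f0 = f0, rounds = rounds, train_logloss = trace,
                 learning_rate = learning_rate, lambda = lambda,
                 max_depth = max_depth, trees_per_round = trees_per_round,
                 feature_fraction = feature_fraction, mtry = mtry,
                 bootstrap = isTRUE(bootstrap), min_leaf = min_leaf,
                 n_features = p, levels = levels(yl),
                 positive = if (is.null(positive)) levels(yl)[[length(levels(yl))]] else positive),
            class = "gbbrf")
}

#' Boosting score (logit scale) of a GBBRF model
#' @param object a `gbbrf` model.
#' @param newdata feature matrix with the training width.
#' @return Numeric vector `f0 + eta * sum_m h_m(x)`.
#' @export
gbbrf_score <- function(object, newdata) {
  stopifnot(inherits(object, "gbbrf"))
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ", object$n_features)
  score <- rep(object$f0, nrow(newdata))
  for (forest in object$rounds)
    score <- score + object$learning_rate * cpp_predict_forest(forest, newdata)
  score
}

#' Predict from a GBBRF model
#' @param object a `gbbrf` model.
#' @param newdata feature matrix.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   labels at the 0.5 threshold, `"link"` for the raw score.
#' @param ... unused.
#' @return Numeric vector or factor.
#' @export
predict.gbbrf <- function(object, newdata, type = c("prob", "class", "link"), ...) {
  type <- match.arg(type)
  score <- gbbrf_score(object, newdata)
  if (type == "link") return(score)
  prob <- stats::plogis(score)
  if (type == "prob") return(prob)
  neg <- setdiff(object$levels, object$positive)[[1L]]
  factor(ifelse(prob >= 0.5, object$positive, neg), levels = object$levels)
}

#' @export
print.gbbrf <- function(x, ...) {
  cat("gbbrf model: ", length(x$rounds), " rounds x ", x$trees_per_round,
      " trees (depth <= ", x$max_depth, ", mtry = ", x$mtry, ")\n", sep = "")
  cat("f0 (log-odds) = ", format(x$f0, digits = 6),
      "; learning rate = ", x$learning_rate, "; lambda = ", x$lambda, "\n", sep = "")
  if (length(x$train_logloss) > 0L)
    cat("final training log-loss = ",
        format(x$train_logloss[[length(x$train_logloss)]], digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gbbrf <- function(object, ...) {
  tl <- object$train_logloss
  cat("GBBRF: ", length(object$rounds), " rounds, ", object$trees_per_round,
      " trees/round, depth <= ", object$max_depth, ", lambda = ", object$lambda,
      ", eta = ", object$learning_rate, "\n", sep = "")
  if (length(tl) > 0L) {
    cat("training log-loss: start ", format(tl[[1L]], digits = 6), " -> end ",
        format(tl[[length(tl)]], digits = 6), "\n", sep = "")
    cat("monotone non-increasing: ", all(diff(tl) <= 1e-12), "\n", sep = "")
  }
  invisible(object)
}
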