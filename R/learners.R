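# Uniform interface over the base learners used in stacking: every learner
# is fitted from (x, y) and predicts a positive-class probability. RF, SVM,
# NB, KNN and LR are library-backed; GBBRF is this package's own classifier.

.LEARNER_NAMES <- c("GBBRF", "RF", "SVM", "KNN", "LR", "NB")

#' Fit a base learner by name
#'
#' @param name one of `"GBBRF"`, `"RF"`, `"SVM"`, `"KNN"`, `"LR"`, `"NB"`,
#'   the degenerate `"constant"` learner (always predicts 0.5), or a list
#'   with elements `fit(x, y, positive)` and `predict(model, x)` defining a
#'   custom learner.
#' @param x numeric feature matrix.
#' @param y two-level factor labels.
#' @param positive positive class label (default: second level).
#' @param opts named list of per-learner options: `gbbrf` (argument list
#'   for [gbbrf()]), `rf_ntree` (default 500), `knn_k` (default 5),
#'   `svm` (argument list for [e1071::svm()]).
#' @return An object of class `base_learner`.
#' @export
fit_base_learner <- function(name, x, y, positive = NULL, opts = list()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))  # canonical names for the model frames
  y <- as.factor(y)
  positive <- positive %||% levels(y)[[nlevels(y)]]
  yb <- factor(ifelse(y == positive, "pos", "neg"), levels = c("neg", "pos"))

  if (is.list(name)) {
    model <- name$fit(x, y, positive)
    return(structure(list(name = name$name %||% "custom", model = model,
                          predict_fn = name$predict, positive = positive),
                     class = "base_learner"))
  }
  if (!(name %in% c(.LEARNER_NAMES, "constant")))
    stop("unknown learner: ", name)

  model <- switch(name,
    "constant" = list(),
    "GBBRF" = do.call(gbbrf, c(list(x = x, y = yb, positive = "pos"),
                               opts$gbbrf %||% list())),
    "RF" = {
      # randomForest stalls on an all-constant design; degrade to the
      # empirical class rate (majority prediction) in that case
      if (all(apply(x, 2, function(col) max(col) == min(col))))
        list(const = mean(yb == "pos"))
      else randomForest::randomForest(x, yb, ntree = opts$rf_ntree %||% 500L)
    },
    "NB" = e1071::naiveBayes(x, yb),
    "KNN" = list(x = x, y = yb, k = opts$knn_k %||% 5L),
    "LR" = {
      df <- data.frame(.y = yb, x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    "SVM" = {
      m <- do.call(e1071::svm, c(list(x = x, y = yb), opts$svm %||% list()))
      dv <- .svm_decision(m, x)
      cal <- if (stats::sd(dv) > 0)
        suppressWarnings(stats::glm(yb ~ dv, family = stats::binomial(),
                                    data = data.frame(yb = yb, dv = dv)))
      else NULL
      list(svm = m, cal = cal, fallback = mean(yb == "pos"))
    })
  structure(list(name = name, model = model, positive = positive),
            class = "base_learner")
}

# decision values oriented so larger means more "pos"
.svm_decision <- function(m, x) {
  dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
  d <- as.numeric(dv[, 1L])
  if (grepl("^neg/", colnames(dv)[[1L]])) -d else d
}

#' Predict positive-class probabilities from a base learner
#' @param object a `base_learner`.
#' @param x feature matrix.
#' @param ... unused.
#' @return Numeric vector in `[0, 1]`.
#' @export
predict.base_learner <- function(object, x, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(object$predict_fn)) return(object$predict_fn(object$model, x))
  switch(object$name,
    "constant" = rep(0.5, nrow(x)),
    "GBBRF" = predict(object$model, x, type = "prob"),
    "RF" = {
      if (!is.null(object$model$const)) rep(object$model$const, nrow(x))
      else unname(predict(object$model, x, type = "prob")[, "pos"])
    },
    "NB" = unname(predict(object$model, x, type = "raw")[, "pos"]),
    "KNN" = .knn_prob(object$model, x),
    "LR" = unname(suppressWarnings(
      predict(object$model, newdata = as.data.frame(x), type = "response"))),
    "SVM" = {
      dv <- .svm_decision(object$model$svm, x)
      if (is.null(object$model$cal)) rep(object$model$fallback, nrow(x))
      else unname(suppressWarnings(
        predict(object$model$cal, newdata = data.frame(dv = dv), type = "response")))
    })
}

# positive vote fraction among the k nearest training rows
.knn_prob <- function(model, x) {
  k <- min(model$k, nrow(model$x))
  pred <- class::knn(model$x, x, model$y, k = k, prob = TRUE)
  win <- attr(pred, "prob")
  ifelse(pred == "pos", win, 1 - win)
}

#' @export
print.base_learner <- function(x, ...) {
  cat("base_learner:", x$name, "\n")
  invisible(x)
}
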