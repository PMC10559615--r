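# Stratified k-fold cross-validation and binary classification metrics
# (accuracy, positive-class precision/recall/F-measure, rank-based AUC).

#' Stratified k-fold partition
#'
#' Indices of each class are shuffled and dealt into `k` folds whose
#' per-class counts differ by at most one sample, so every fold mirrors the
#' global class proportions.
#'
#' @param labels two-level factor (or coercible).
#' @param k number of folds.
#' @param seed optional integer; `set.seed(seed)` is called when given.
#' @return List of `k` disjoint integer index vectors covering all samples.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.factor(labels)
  stopifnot(k >= 2)
  if (!is.null(seed)) set.seed(seed)
  counts <- table(labels)
  if (any(counts < k))
    stop("class '", names(counts)[which.min(counts)], "' has fewer than k = ",
         k, " samples")
  folds <- vector("list", k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    at <- cumsum(c(0L, sizes))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[seq(at[[f]] + 1L, at[[f + 1L]])])
  }
  lapply(folds, sort)
}

#' Confusion matrix of binary predictions
#' @param truth true labels (factor/0-1).
#' @param pred predicted labels, same coding.
#' @param positive positive class value (default: second factor level of
#'   `truth`).
#' @return Object of class `confusion_matrix`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  t_bin <- .as_binary(as.factor(truth), positive)
  p_bin <- .as_binary(factor(pred, levels = levels(as.factor(truth))), positive)
  structure(list(tp = sum(t_bin == 1 & p_bin == 1),
                 tn = sum(t_bin == 0 & p_bin == 0),
                 fp = sum(t_bin == 0 & p_bin == 1),
                 fn = sum(t_bin == 1 & p_bin == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"), predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Binary metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, positive-class precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)` and F-measure `2PR/(P+R)`. A metric whose denominator is
#' zero is reported as 0 with a warning.
#'
#' @param cm a [confusion_matrix()], or `tp` given with `tn`, `fp`, `fn`.
#' @param tn,fp,fn counts when `cm` is the `tp` count.
#' @return Named list: `accuracy`, `precision`, `recall`, `f_measure`.
#' @export
compute_metrics <- function(cm, tn = NULL, fp = NULL, fn = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- structure(list(tp = cm, tn = tn, fp = fp, fn = fn),
                    class = "confusion_matrix")
  }
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator); reporting 0"); 0 }
    else num / den
  }
  acc <- safe_div(cm$tp + cm$tn, total, "accuracy")
  prec <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  rec <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f_measure = f)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive sample is
#' scored above a random negative one, ties counted one half — identical to
#' trapezoidal integration of the ROC curve.
#'
#' @param labels two-level factor (or 0/1).
#' @param scores numeric scores, larger = more positive.
#' @param positive positive class value.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores, positive = NULL) {
  y <- .as_binary(as.factor(labels), positive)
  if (length(y) != length(scores)) stop("labels and scores lengths differ")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# fit/predict dispatch shared by cross_validate
.fit_model <- function(model, train, learner_opts, seed = NULL) {
  if (inherits(model, "stacking_spec")) {
    spec <- model
    if (length(spec$learner_opts) == 0L) spec$learner_opts <- learner_opts
    if (is.null(spec$seed)) spec$seed <- seed
    fit_stacked(train, spec = spec)
  } else if (is.character(model) && grepl("^stacking[1-5]$", model)) {
    fit_stacked(train, spec = stacking_preset(model, seed = seed,
                                              learner_opts = learner_opts))
  } else {
    fit_base_learner(model, train$features, train$labels, train$positive,
                     learner_opts)
  }
}

#' Cross-validated evaluation of a classification pipeline
#'
#' Runs stratified k-fold cross-validation of a model (a base learner name,
#' a stacking preset name, or a [stacking_spec()]) with optional
#' resampling, in one of two pipeline orders:
#' \describe{
#'   \item{safe (default)}{split first, resample only the training folds,
#'     evaluate on untouched original samples — synthetic rows can never
#'     reach a test fold.}
#'   \item{paper}{resample the whole dataset, shuffle, then split — the
#'     order many published pipelines use; synthetic neighbours of test
#'     points may then leak into training, so its scores read optimistic.}
#' }
#'
#' @param data a [labeled_dataset()].
#' @param model model specification (e.g. `"GBBRF"`, `"stacking3"`, or a
#'   [stacking_spec()]).
#' @param resample a [resample_spec()], a method name, or `"none"`.
#' @param k number of folds (default 5).
#' @param mode `"safe"` or `"paper"`.
#' @param seed integer seed for folds, resampling and stochastic learners.
#' @param learner_opts options forwarded to [fit_base_learner()].
#' @param aggregate `"mean"` (unweighted mean over folds, default) or
#'   `"pooled"` (metrics from the summed confusion matrix; AUC still
#'   averaged).
#' @return An object of class `metrics_report`: per-fold metric data frame,
#'   aggregated means, fold sizes, count of synthetic rows in each test
#'   fold, mode, seed.
#' @examples
#' d <- synth_blobs(60, 20, dim = 2, separation = 4, seed = 1)
#' rep <- cross_validate(d, model = "LR", resample = "smote", k = 3, seed = 1)
#' rep
#' @export
cross_validate <- function(data, model, resample = "none", k = 5,
                           mode = c("safe", "paper"), seed = 1,
                           learner_opts = list(),
                           aggregate = c("mean", "pooled")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(data, "labeled_dataset"), k >= 2)
  if (is.character(resample)) resample <- resample_spec(resample)
  set.seed(seed)

  if (mode == "paper") {
    full <- apply_resample(data, resample)
    full <- .subset_dataset(full, sample(nrow(full$features)))  # shuffle
    folds <- stratified_folds(full$labels, k)
    eval_data <- full
  } else {
    folds <- stratified_folds(data$labels, k)
    eval_data <- data
  }

  per_fold <- vector("list", k)
  syn_in_test <- integer(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(eval_data$features)), test_idx)
    train <- .subset_dataset(eval_data, train_idx)
    if (mode == "safe") train <- apply_resample(train, resample)
    test <- .subset_dataset(eval_data, test_idx)
    syn_in_test[[f]] <- sum(test$synthetic)

    fit <- .fit_model(model, train, learner_opts, seed = seed + f)
    prob <- if (inherits(fit, "base_learner")) predict(fit, test$features)
            else predict(fit, test$features, type = "prob")
    neg <- setdiff(levels(test$labels), test$positive)[[1L]]
    pred <- factor(ifelse(prob >= 0.5, test$positive, neg),
                   levels = levels(test$labels))
    cm <- confusion_matrix(test$labels, pred, test$positive)
    met <- suppressWarnings(compute_metrics(cm))
    met$auc_roc <- roc_auc(test$labels, prob, test$positive)
    per_fold[[f]] <- c(fold = f, n_test = length(test_idx), unlist(met),
                       tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
  }
  df <- as.data.frame(do.call(rbind, per_fold))

  metric_names <- c("accuracy", "precision", "recall", "f_measure", "auc_roc")
  if (aggregate == "mean") {
    means <- colMeans(df[metric_names])
  } else {
    pooled <- suppressWarnings(compute_metrics(
      sum(df$tp), sum(df$tn), sum(df$fp), sum(df$fn)))
    means <- c(unlist(pooled), auc_roc = mean(df$auc_roc))
  }

  structure(list(per_fold = df, means = means, k = k, seed = seed,
                 mode = mode, aggregate = aggregate,
                 model = if (is.character(model)) model else class(model)[[1L]],
                 resample = resample$method,
                 synthetic_in_test = syn_in_test,
                 n = nrow(eval_data$features)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("metrics_report: ", x$k, "-fold stratified CV (", x$mode, " mode, ",
      x$aggregate, " aggregation), model = ", x$model,
      ", resample = ", x$resample, ", seed = ", x$seed, "\n", sep = "")
  cat("synthetic rows in test folds:", paste(x$synthetic_in_test, collapse = " "), "\n")
  print(round(x$per_fold[c("fold", "n_test", "accuracy", "precision",
                           "recall", "f_measure", "auc_roc")], digits),
        row.names = FALSE)
  cat("aggregated:", paste(sprintf("%s=%.*f", names(x$means), digits, x$means),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a metrics report to a list (for JSON output)
#' @param x a `metrics_report`.
#' @return Nested list mirroring the report.
#' @export
report_as_list <- function(x) {
  stopifnot(inherits(x, "metrics_report"))
  list(model = x$model, resample = x$resample, mode = x$mode, k = x$k,
       seed = x$seed, n = x$n, aggregate = x$aggregate,
       synthetic_in_test = x$synthetic_in_test,
       per_fold = x$per_fold, means = as.list(x$means))
}
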