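# Two-level stacked generalization: level-0 learners produce out-of-fold
# positive-class probabilities which train a level-1 meta-learner; for
# deployment the level-0 learners are refit on the full training data.

#' Stacking specification
#'
#' @param level0 ordered character vector of base learner names from
#'   `GBBRF, RF, SVM, KNN, LR, NB` (unique, non-empty). Column order of the
#'   meta-feature matrix follows this order.
#' @param level1 the meta-learner name.
#' @param oof_folds stratified folds used to build out-of-fold meta
#'   features (default 5).
#' @param seed integer seed driving fold assignment and the stochastic
#'   learners.
#' @param meta_features `"proba"` (default) feeds the level-1 learner the
#'   level-0 probabilities; `"label"` feeds hard 0/1 predictions.
#' @param learner_opts options passed to [fit_base_learner()].
#' @return An object of class `stacking_spec`.
#' @export
stacking_spec <- function(level0, level1, oof_folds = 5, seed = NULL,
                          meta_features = c("proba", "label"),
                          learner_opts = list()) {
  meta_features <- match.arg(meta_features)
  if (length(level0) == 0L) stop("level0 must be non-empty")
  if (anyDuplicated(level0)) stop("level0 names must be unique")
  chk <- c(.LEARNER_NAMES, "constant")
  bad <- setdiff(Filter(is.character, as.list(level0)), chk)
  if (length(bad) > 0L) stop("unknown level-0 learner(s): ", paste(bad, collapse = ", "))
  if (is.character(level1) && !(level1 %in% chk)) stop("unknown level-1 learner: ", level1)
  stopifnot(oof_folds >= 2)
  structure(list(level0 = level0, level1 = level1, oof_folds = oof_folds,
                 seed = seed, meta_features = meta_features,
                 learner_opts = learner_opts),
            class = "stacking_spec")
}

#' Named stacking presets
#'
#' The five shipped level-0/level-1 combinations:
#' \describe{
#'   \item{stacking1}{level 1 RF; level 0 NB, SVM, KNN, RF}
#'   \item{stacking2}{level 1 GBBRF; level 0 RF, KNN, SVM, LR, GBBRF}
#'   \item{stacking3}{level 1 RF; level 0 GBBRF, NB, SVM, KNN, RF}
#'   \item{stacking4}{level 1 RF; level 0 GBBRF, LR, SVM, KNN, RF}
#'   \item{stacking5}{level 1 KNN; level 0 GBBRF, LR, SVM, KNN, RF}
#' }
#'
#' @param name preset name, `"stacking1"` .. `"stacking5"`.
#' @param ... further arguments passed to [stacking_spec()] (seed,
#'   oof_folds, learner_opts, ...).
#' @return A [stacking_spec()].
#' @export
stacking_preset <- function(name, ...) {
  presets <- list(
    stacking1 = list(level1 = "RF",    level0 = c("NB", "SVM", "KNN", "RF")),
    stacking2 = list(level1 = "GBBRF", level0 = c("RF", "KNN", "SVM", "LR", "GBBRF")),
    stacking3 = list(level1 = "RF",    level0 = c("GBBRF", "NB", "SVM", "KNN", "RF")),
    stacking4 = list(level1 = "RF",    level0 = c("GBBRF", "LR", "SVM", "KNN", "RF")),
    stacking5 = list(level1 = "KNN",   level0 = c("GBBRF", "LR", "SVM", "KNN", "RF")))
  if (!(name %in% names(presets))) stop("unknown preset: ", name)
  p <- presets[[name]]
  stacking_spec(level0 = p$level0, level1 = p$level1, ...)
}

#' Out-of-fold meta features
#'
#' Column `l` holds, for every sample, the positive-class probability (or
#' hard label, per the spec) predicted by learner `l` trained on the
#' stratified folds excluding that sample's fold — so no sample's own label
#' ever reaches the model scoring it.
#'
#' @param x feature matrix or [labeled_dataset()].
#' @param y labels (ignored when `x` is a `labeled_dataset`).
#' @param spec a [stacking_spec()].
#' @param positive positive class label.
#' @return `n x L` matrix, one column per level-0 learner (in `spec$level0`
#'   order), with attribute `fold` giving each sample's fold id.
#' @export
oof_meta_features <- function(x, y = NULL, spec, positive = NULL) {
  if (inherits(x, "labeled_dataset")) {
    positive <- positive %||% x$positive
    y <- x$labels
    x <- x$features
  }
  y <- as.factor(y)
  positive <- positive %||% levels(y)[[nlevels(y)]]
  if (!is.null(spec$seed)) set.seed(spec$seed)
  folds <- stratified_folds(y, spec$oof_folds)
  L <- length(spec$level0)
  meta <- matrix(NA_real_, nrow(x), L)
  colnames(meta) <- vapply(seq_len(L), function(i) {
    li <- spec$level0[[i]]
    if (is.character(li)) li else (li$name %||% paste0("custom", i))
  }, character(1))
  fold_id <- integer(nrow(x))
  for (f in seq_along(folds)) fold_id[folds[[f]]] <- f
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(x)), test)
    if (nlevels(droplevels(y[train])) < 2L)
      stop("training partition without both classes; reduce oof_folds")
    for (l in seq_len(L)) {
      fit <- fit_base_learner(spec$level0[[l]], x[train, , drop = FALSE],
                              y[train], positive, spec$learner_opts)
      meta[test, l] <- predict(fit, x[test, , drop = FALSE])
    }
  }
  if (spec$meta_features == "label") meta <- (meta >= 0.5) * 1
  attr(meta, "fold") <- fold_id
  meta
}

#' Fit a two-level stacked model
#'
#' The level-1 learner is fitted on the out-of-fold meta features; the
#' level-0 learners are then refit on the full training data for
#' deployment.
#'
#' @inheritParams oof_meta_features
#' @return An object of class `stacked_model`.
#' @examples
#' d <- synth_blobs(60, 20, dim = 2, separation = 4, seed = 1)
#' spec <- stacking_spec(c("RF", "LR"), "LR", seed = 1)
#' m <- fit_stacked(d, spec = spec)
#' head(predict(m, d$features))
#' @export
fit_stacked <- function(x, y = NULL, spec, positive = NULL) {
  if (inherits(x, "labeled_dataset")) {
    positive <- positive %||% x$positive
    y <- x$labels
    x <- x$features
  }
  y <- as.factor(y)
  positive <- positive %||% levels(y)[[nlevels(y)]]
  stopifnot(inherits(spec, "stacking_spec"))
  meta <- oof_meta_features(x, y, spec, positive)
  meta_x <- meta
  attr(meta_x, "fold") <- NULL
  level1 <- fit_base_learner(spec$level1, meta_x, y, positive, spec$learner_opts)
  level0 <- lapply(spec$level0, function(nm)
    fit_base_learner(nm, x, y, positive, spec$learner_opts))
  structure(list(level0 = level0, level1 = level1, spec = spec,
                 meta_colnames = colnames(meta), positive = positive,
                 levels = levels(y), n_features = ncol(x)),
            class = "stacked_model")
}

#' Predict from a stacked model
#'
#' New meta features are the full-data level-0 learners' probabilities in
#' the stored column order; the output is the level-1 prediction on them.
#'
#' @param object a `stacked_model`.
#' @param newdata feature matrix with training width.
#' @param type `"prob"` (positive-class probability) or `"class"`.
#' @param ... unused.
#' @return Numeric vector or factor.
#' @export
predict.stacked_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ", object$n_features)
  meta <- vapply(object$level0, function(l) predict(l, newdata),
                 numeric(nrow(newdata)))
  meta <- matrix(meta, nrow = nrow(newdata),
                 dimnames = list(NULL, object$meta_colnames))
  if (object$spec$meta_features == "label") meta <- (meta >= 0.5) * 1
  prob <- predict(object$level1, meta)
  if (type == "prob") return(prob)
  neg <- setdiff(object$levels, object$positive)[[1L]]
  factor(ifelse(prob >= 0.5, object$positive, neg), levels = object$levels)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("stacked_model: level 0 [", paste(x$meta_colnames, collapse = ", "),
      "] -> level 1 ", x$level1$name, "\n", sep = "")
  cat("meta features:", x$spec$meta_features, "; oof folds:", x$spec$oof_folds, "\n")
  invisible(x)
}
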