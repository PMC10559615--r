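# Resamplers for imbalanced binary data: SMOTE (synthetic minority
# oversampling by interpolation toward minority nearest neighbours), random
# undersampling of the majority class, and their hybrid.

#' Labeled dataset container
#'
#' Binds a feature matrix to binary labels; the unit flowing through
#' resampling, boosting, stacking and cross-validation. Rows appended by
#' SMOTE carry `synthetic = TRUE`.
#'
#' @param features numeric matrix (rows = samples).
#' @param labels factor (or coercible) with exactly two levels.
#' @param ids optional sample identifiers (default: rownames or `s1..sn`).
#' @param synthetic optional logical flags, default all `FALSE`.
#' @param positive label value of the positive (usually minority/disease)
#'   class; defaults to the second factor level.
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels`, `ids`, `synthetic`, `positive`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL, synthetic = NULL,
                            positive = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) > 2L) stop("labels must have at most two levels")
  if (nrow(features) != length(labels)) stop("features and labels lengths differ")
  if (nrow(features) < 1L || ncol(features) < 1L) stop("empty feature matrix")
  if (is.null(ids)) ids <- rownames(features) %||% paste0("s", seq_len(nrow(features)))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(features))
  if (is.null(positive)) positive <- levels(labels)[[nlevels(labels)]]
  if (!(positive %in% levels(labels))) stop("positive level '", positive, "' not in labels")
  stopifnot(length(ids) == nrow(features), length(synthetic) == nrow(features))
  structure(list(features = features, labels = labels, ids = as.character(ids),
                 synthetic = as.logical(synthetic), positive = positive),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("labeled_dataset: ", nrow(x$features), " samples x ", ncol(x$features),
      " features; ", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      " (positive = ", x$positive, "); ", sum(x$synthetic), " synthetic\n", sep = "")
  invisible(x)
}

.class_counts <- function(data) {
  pos <- data$labels == data$positive
  list(pos = which(pos), neg = which(!pos))
}

# minority/majority index split; errors on single-class input
.min_maj <- function(data) {
  cc <- .class_counts(data)
  if (length(cc$pos) == 0L || length(cc$neg) == 0L)
    stop("both classes must be present")
  if (length(cc$pos) <= length(cc$neg)) list(min = cc$pos, maj = cc$neg)
  else list(min = cc$neg, maj = cc$pos)
}

.subset_dataset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  ids = data$ids[idx], synthetic = data$synthetic[idx],
                  positive = data$positive)
}

#' SMOTE: synthetic minority oversampling
#'
#' Appends synthetic minority rows until `minority/majority >= ratio`. Each
#' synthetic row is `x_i + u * (x' - x_i)` with `u ~ Uniform(0, 1)` and
#' `x'` drawn uniformly from the `k` nearest minority neighbours of the
#' base point `x_i` (Euclidean distance, ties broken by lower original
#' index). Base points cycle through the minority rows in order; the
#' remainder is drawn uniformly. Original rows are never modified.
#'
#' @param data a [labeled_dataset()].
#' @param k neighbour count (default 5); silently reduced to
#'   `minority size - 1` with a warning when larger.
#' @param ratio target minority/majority ratio in (0, 1].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the output is bit-identical across runs.
#' @return A `labeled_dataset` with the original rows first (untouched) and
#'   synthetic rows appended, flagged via `synthetic`.
#' @export
smote <- function(data, k = 5, ratio = 1, seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), k >= 1, ratio > 0, ratio <= 1)
  if (!is.null(seed)) set.seed(seed)
  mm <- .min_maj(data)
  n_min <- length(mm$min); n_maj <- length(mm$maj)
  if (n_min < 2L) stop("minority class needs at least 2 samples for SMOTE")
  if (k > n_min - 1L) {
    warning("k reduced from ", k, " to ", n_min - 1L, " (minority size)")
    k <- n_min - 1L
  }
  n_target <- ceiling(ratio * n_maj)
  n_syn <- max(0L, n_target - n_min)
  if (n_syn == 0L) return(data)

  xm <- data$features[mm$min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  # k nearest minority neighbours per minority row; order() breaks ties by index
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i) order(d[i, ])[seq_len(k)]))

  base <- rep(seq_len(n_min), n_syn %/% n_min)
  rem <- n_syn %% n_min
  if (rem > 0L) base <- c(base, sample(n_min, rem))
  pick <- if (k == 1L) rep(1L, n_syn) else sample(k, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  syn <- xm[base, , drop = FALSE] +
    u * (xm[nn[cbind(base, pick)], , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(syn) <- NULL

  min_label <- data$labels[mm$min[1L]]
  labeled_dataset(rbind(data$features, syn),
                  factor(c(as.character(data$labels), rep(as.character(min_label), n_syn)),
                         levels = levels(data$labels)),
                  ids = c(data$ids, paste0("syn", seq_len(n_syn))),
                  synthetic = c(data$synthetic, rep(TRUE, n_syn)),
                  positive = data$positive)
}

#' Random undersampling of the majority class
#'
#' Uniformly subsamples majority rows without replacement until
#' `minority/majority >= ratio`; all retained rows are originals and keep
#' their input order.
#'
#' @inheritParams smote
#' @return A `labeled_dataset` containing a subset of the input rows.
#' @export
rus <- function(data, ratio = 1, seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), ratio > 0, ratio <= 1)
  if (!is.null(seed)) set.seed(seed)
  mm <- .min_maj(data)
  n_keep <- min(length(mm$maj), ceiling(length(mm$min) / ratio))
  keep_maj <- sort(mm$maj[sample(length(mm$maj), n_keep)])
  .subset_dataset(data, sort(c(mm$min, keep_maj)))
}

#' Hybrid SMOTE + random undersampling
#'
#' SMOTE first raises the minority to an intermediate ratio `r1`, then RUS
#' trims the majority to reach `ratio`. `r1` defaults to the geometric
#' midpoint `sqrt(r0 * ratio)` between the initial ratio `r0` and the
#' target, so both classes move.
#'
#' @inheritParams smote
#' @param r1 intermediate minority/majority ratio after the SMOTE stage;
#'   clamped to `[r0, ratio]`.
#' @return A `labeled_dataset`.
#' @export
smote_rus <- function(data, k = 5, ratio = 1, r1 = NULL, seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.null(seed)) set.seed(seed)
  mm <- .min_maj(data)
  r0 <- length(mm$min) / length(mm$maj)
  if (is.null(r1)) r1 <- sqrt(r0 * ratio)
  r1 <- min(max(r1, r0), ratio)
  out <- if (r1 > r0) smote(data, k = k, ratio = r1) else data
  rus(out, ratio = ratio)
}

#' Resampling specification
#'
#' Bundles a resampling method with its parameters, for use by
#' [apply_resample()] and [cross_validate()].
#'
#' @param method one of `"smote"`, `"rus"`, `"smote-rus"`, `"none"`.
#' @param k SMOTE neighbour count.
#' @param ratio target minority/majority ratio.
#' @param r1 intermediate ratio for `"smote-rus"` (`NULL` = geometric midpoint).
#' @param seed optional integer seed.
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(method = c("smote", "rus", "smote-rus", "none"),
                          k = 5, ratio = 1, r1 = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(k >= 1, ratio > 0, ratio <= 1)
  structure(list(method = method, k = k, ratio = ratio, r1 = r1, seed = seed),
            class = "resample_spec")
}

#' Apply a resampling specification
#' @param data a [labeled_dataset()].
#' @param spec a [resample_spec()] or a method name understood by it.
#' @return A `labeled_dataset`.
#' @export
apply_resample <- function(data, spec) {
  if (is.character(spec)) spec <- resample_spec(spec)
  stopifnot(inherits(spec, "resample_spec"))
  switch(spec$method,
    "none" = data,
    "smote" = smote(data, k = spec$k, ratio = spec$ratio, seed = spec$seed),
    "rus" = rus(data, ratio = spec$ratio, seed = spec$seed),
    "smote-rus" = smote_rus(data, k = spec$k, ratio = spec$ratio,
                            r1 = spec$r1, seed = spec$seed))
}
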