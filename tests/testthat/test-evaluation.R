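test_that("stratified folds partition indices with balanced class counts", {
  y <- factor(rep(c("pos", "neg"), each = 10))
  folds <- stratified_folds(y, 5, seed = 1)
  expect_equal(sort(unlist(folds)), 1:20)
  for (f in folds) {
    expect_equal(sum(y[f] == "pos"), 2)
    expect_equal(sum(y[f] == "neg"), 2)
  }

  y2 <- factor(c(rep("pos", 7), rep("neg", 13)))
  folds2 <- stratified_folds(y2, 5, seed = 2)
  expect_equal(sort(unlist(folds2)), 1:20)
  pos_counts <- vapply(folds2, function(f) sum(y2[f] == "pos"), integer(1))
  neg_counts <- vapply(folds2, function(f) sum(y2[f] == "neg"), integer(1))
  expect_true(all(pos_counts %in% 1:2))
  expect_true(all(neg_counts %in% 2:3))
  expect_equal(sum(pos_counts), 7)
  expect_equal(sum(neg_counts), 13)

  expect_error(stratified_folds(factor(c("a", rep("b", 9))), 5), "fewer than k")
})

test_that("metrics match the worked example and degenerate cases", {
  m <- compute_metrics(8, tn = 9, fp = 1, fn = 2)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f_measure, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))

  perfect <- compute_metrics(5, tn = 5, fp = 0, fn = 0)
  expect_true(all(unlist(perfect) == 1))

  worst <- suppressWarnings(compute_metrics(0, tn = 3, fp = 2, fn = 4))
  expect_equal(worst$precision, 0)
  expect_equal(worst$recall, 0)
  expect_equal(worst$f_measure, 0)
  w <- capture_warnings(compute_metrics(0, tn = 3, fp = 0, fn = 0))
  expect_length(w, 2)                       # precision and recall undefined
  expect_match(w, "undefined", all = TRUE)
})

test_that("metrics agree with brute-force confusion tallies on random cases", {
  set.seed(3)
  for (i in 1:40) {
    n <- 25
    truth <- factor(sample(c("neg", "pos"), n, replace = TRUE),
                    levels = c("neg", "pos"))
    pred <- factor(sample(c("neg", "pos"), n, replace = TRUE),
                   levels = c("neg", "pos"))
    cm <- confusion_matrix(truth, pred, positive = "pos")
    expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, n)
    met <- suppressWarnings(compute_metrics(cm))
    expect_identical(met$accuracy, mean(truth == pred))
    if (cm$tp + cm$fp > 0)
      expect_identical(met$precision, sum(pred == "pos" & truth == "pos") / sum(pred == "pos"))
    if (cm$tp + cm$fn > 0)
      expect_identical(met$recall, sum(pred == "pos" & truth == "pos") / sum(truth == "pos"))
  }
})

test_that("roc_auc is the pairwise rank probability, ties counted a half", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(4)
  for (i in 1:20) {
    y <- c(rep(1, 8), rep(0, 12))
    s <- round(runif(20), 1)   # induces ties
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-9)
    if (!any(duplicated(s)))
      expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- c(rep(1, 30), rep(0, 70))
  s <- rnorm(100) + y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("safe-mode CV keeps synthetic rows out of test folds; paper mode
           is labeled and may leak them", {
  d <- synth_blobs(60, 20, dim = 2, separation = 3, seed = 6)
  safe <- cross_validate(d, "LR", resample = "smote", k = 4, seed = 6)
  expect_identical(safe$mode, "safe")
  expect_true(all(safe$synthetic_in_test == 0))
  expect_equal(sum(safe$per_fold$n_test), 80)

  paper <- cross_validate(d, "LR", resample = "smote", k = 4,
                          mode = "paper", seed = 6)
  expect_identical(paper$mode, "paper")
  expect_gt(sum(paper$synthetic_in_test), 0)
  expect_equal(sum(paper$per_fold$n_test), 120)  # resampled to 60/60
})

test_that("cross-validation is deterministic and solves the separable toy", {
  d <- synth_blobs(60, 20, dim = 2, separation = 6, seed = 0)
  # separability oracle: a hard margin exists along the centre axis
  mu <- colMeans(d$features[d$labels == "minority", ]) -
    colMeans(d$features[d$labels == "majority", ])
  proj <- d$features %*% mu
  expect_gt(min(proj[d$labels == "minority"]), max(proj[d$labels == "majority"]))
  r1 <- cross_validate(d, "GBBRF", resample = "smote", k = 2, seed = 0,
                       learner_opts = list(gbbrf = list(n_rounds = 30,
                                                        trees_per_round = 5)))
  expect_equal(unname(r1$means[["accuracy"]]), 1)
  r2 <- cross_validate(d, "GBBRF", resample = "smote", k = 2, seed = 0,
                       learner_opts = list(gbbrf = list(n_rounds = 30,
                                                        trees_per_round = 5)))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$means, r2$means)
})

test_that("pooled aggregation reproduces metrics of the summed confusion matrix", {
  d <- synth_blobs(40, 16, dim = 2, separation = 1, seed = 8)
  r <- cross_validate(d, "NB", resample = "none", k = 4, seed = 8,
                      aggregate = "pooled")
  pooled <- suppressWarnings(compute_metrics(
    sum(r$per_fold$tp), sum(r$per_fold$tn), sum(r$per_fold$fp), sum(r$per_fold$fn)))
  expect_equal(unname(r$means[["accuracy"]]), pooled$accuracy)
  expect_equal(unname(r$means[["f_measure"]]), pooled$f_measure)
})
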