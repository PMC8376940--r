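test_that("confusion counts tabulate the four cells", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c1[c("tp", "tn", "fp", "fn")]),
               c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))

  c2 <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c2$tp + c2$tn, 0L)
  expect_equal(c(c2$fp, c2$fn), c(2L, 2L))

  c3 <- confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c3[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 1L, fn = 1L))

  expect_error(confusion(c(1, 2), c(1, 0)), "0.*or 1")
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metrics reproduce their closed forms", {
  perfect <- classification_metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1))

  flat <- classification_metrics(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(flat[["accuracy"]], 0.5)
  expect_equal(flat[["mcc"]], 0)

  m <- classification_metrics(list(tp = 45, tn = 40, fp = 10, fn = 5))
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["precision"]], 45 / 55)
  expect_equal(m[["precision"]], 0.81818, tolerance = 1e-5)
  expect_equal(m[["sensitivity"]], 0.90)
  expect_equal(m[["mcc"]], 1750 / sqrt(6187500))
  expect_equal(m[["mcc"]], 0.70353, tolerance = 1e-5)
})

test_that("zero denominators report 0 with a degenerate flag", {
  m <- classification_metrics(list(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_equal(m[["precision"]], 0)
  expect_true("precision" %in% attr(m, "degenerate"))
  expect_true("mcc" %in% attr(m, "degenerate"))
  m2 <- classification_metrics(list(tp = 5, tn = 5, fp = 2, fn = 1))
  expect_length(attr(m2, "degenerate"), 0L)
})

test_that("metrics agree with label-vector statistics on random tables", {
  set.seed(1)
  for (i in 1:200) {
    cts <- as.list(sample(1:60, 4, replace = TRUE))
    names(cts) <- c("tp", "tn", "fp", "fn")
    m <- classification_metrics(cts)
    # independent oracle: rebuild the label vectors and use plain statistics
    y <- c(rep(1, cts$tp), rep(0, cts$tn), rep(0, cts$fp), rep(1, cts$fn))
    p <- c(rep(1, cts$tp), rep(0, cts$tn), rep(1, cts$fp), rep(0, cts$fn))
    expect_equal(m[["accuracy"]], mean(y == p))
    expect_equal(m[["precision"]], mean(y[p == 1]))
    expect_equal(m[["sensitivity"]], mean(p[y == 1]))
    expect_equal(m[["mcc"]], cor(y, p), tolerance = 1e-12)
  }
})

test_that("MCC is symmetric under the TP<->TN, FP<->FN swap", {
  set.seed(2)
  for (i in 1:50) {
    v <- sample(0:40, 4, replace = TRUE)
    a <- classification_metrics(list(tp = v[1], tn = v[2], fp = v[3], fn = v[4]))
    b <- classification_metrics(list(tp = v[2], tn = v[1], fp = v[4], fn = v[3]))
    expect_equal(a[["mcc"]], b[["mcc"]])
  }
})

test_that("AUC follows the Mann-Whitney statistic with tie handling", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  # 4 positive-negative pairs, 3 concordant
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(40)
  base <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, base)
  expect_equal(roc_auc(y, rank(s, ties.method = "average"))$auc, base)
  expect_equal(roc_auc(y, 3 * s - 100)$auc, base)
})

test_that("AUC matches an established ROC implementation", {
  set.seed(4)
  y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("ROC points span (0,0) to (1,1) and are monotone", {
  set.seed(5)
  y <- rbinom(30, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(30)
  roc <- roc_auc(y, s)$roc
  expect_equal(unlist(roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("stratified folds balance sizes and classes", {
  labels <- rep(c(0, 1), c(60, 40))
  fold <- ppirof:::stratified_folds(labels, 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_per_fold <- tapply(labels, fold, sum)
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  expect_error(ppirof:::stratified_folds(rep(c(0, 1), c(3, 97)), 5),
               "at least k_folds")
})

test_that("cross-validation is deterministic and aggregates per-fold metrics", {
  ds <- small_benchmark()
  rof <- rof_config(n_subsets = 5, n_trees = 5, seed = 3)
  r1 <- cross_validate(ds$pairs, ds$descriptors, small_olpp_cfg(), rof,
                       k_folds = 5, seed = 11)
  r2 <- cross_validate(ds$pairs, ds$descriptors, small_olpp_cfg(), rof,
                       k_folds = 5, seed = 11)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 5L)
  expect_equal(unname(r1$mean["accuracy"]),
               mean(r1$per_fold$accuracy), tolerance = 1e-12)
  expect_equal(unname(r1$sd["auc"]), sd(r1$per_fold$auc), tolerance = 1e-12)
  expect_true(all(r1$per_fold$accuracy >= 0 & r1$per_fold$accuracy <= 1))
  expect_true(all(abs(r1$per_fold$mcc) <= 1))
})

test_that("a missing descriptor fails with the offending protein id", {
  ds <- small_benchmark()
  desc <- ds$descriptors[-1, , drop = FALSE]
  dropped <- rownames(ds$descriptors)[1]
  expect_error(
    cross_validate(ds$pairs, desc, small_olpp_cfg(),
                   rof_config(n_subsets = 5, n_trees = 3, seed = 1),
                   k_folds = 5, seed = 1),
    dropped, fixed = TRUE
  )
})

test_that("grid search reports the full factorial accuracy table", {
  ds <- small_benchmark()
  rof <- rof_config(n_trees = 3, seed = 5)
  gs <- grid_search(ds$pairs, ds$descriptors, k_values = c(2, 4),
                    l_values = c(1, 3), olpp = small_olpp_cfg(), rof = rof,
                    k_folds = 5, seed = 9)
  expect_equal(nrow(gs$table), 4L)
  expect_true(all(c(2, 4) %in% gs$table$K))
  expect_true(gs$best$mean_accuracy == max(gs$table$mean_accuracy))

  one <- grid_search(ds$pairs, ds$descriptors, k_values = 4, l_values = 3,
                     olpp = small_olpp_cfg(), rof = rof, k_folds = 5, seed = 9)
  direct <- cross_validate(ds$pairs, ds$descriptors, small_olpp_cfg(),
                           rof_config(n_subsets = 4, n_trees = 3,
                                      sample_fraction = rof$sample_fraction,
                                      bootstrap = rof$bootstrap, seed = rof$seed),
                           k_folds = 5, seed = 9)
  expect_equal(one$table$mean_accuracy, unname(direct$mean["accuracy"]))
})
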