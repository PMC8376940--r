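#' Binary confusion counts
#'
#' Tabulates true/false positives and negatives with class 1 (interacting)
#' as the positive class.
#'
#' @param y_true,y_pred integer vectors of 0/1 labels, equal length.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (length(y_true) < 1L) stop("need at least one sample")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0 (non-interacting) or 1 (interacting)")
  }
  structure(list(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' Accuracy, precision, sensitivity and MCC from confusion counts
#'
#' Standard binary-classification measures:
#' Acc = (TP + TN) / total, Pre = TP / (TP + FP), Sen = TP / (TP + FN),
#' and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TN+FP)(TP+FN)).
#' A metric whose denominator is zero is reported as 0 and flagged in the
#' `degenerate` attribute rather than propagating NaN.
#'
#' @param counts a [confusion()] result, or a list with tp/tn/fp/fn.
#' @return Named numeric vector (accuracy, precision, sensitivity, mcc)
#'   with a `degenerate` character attribute naming any zero-denominator
#'   metrics.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1L) stop("empty confusion table")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  acc <- (tp + tn) / total
  pre <- safe(tp, tp + fp, "precision")
  sen <- safe(tp, tp + fn, "sensitivity")
  mcc_den2 <- (tp + fp) * (tn + fn) * (tn + fp) * (tp + fn)
  mcc <- safe(tp * tn - fp * fn, sqrt(mcc_den2), "mcc")
  out <- c(accuracy = acc, precision = pre, sensitivity = sen, mcc = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, with ties counting one half. The ROC points
#' sweep every unique score as a threshold (predict positive when
#' score >= threshold), with (0, 0) and (1, 1) always included; the
#' X axis is the false positive rate, the Y axis the true positive rate.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores numeric scores, higher = more likely positive.
#' @return List with `roc` (data frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("lengths differ")
  if (!all(y_true %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present")
  }
  r <- rank(scores)  # midranks: ties count 1/2
  auc <- (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0L) / n_neg, 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(roc = roc, auc = auc)
}

stratified_folds <- function(labels, k_folds, seed) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < k_folds)) {
    stop("every class needs at least k_folds = ", k_folds, " members")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the full PPI pipeline
#'
#' Stratified k-fold protocol with no information leakage: in each fold
#' the OLPP embedding is fitted only on descriptors of proteins that
#' appear in the training pairs, every protein is then embedded with that
#' fitted map, pair features are the concatenated embeddings, a Rotation
#' Forest is trained on the training pairs and evaluated on the held-out
#' fold (classification at the highest-confidence class; ROC scores are
#' the class-1 confidences).
#'
#' @param pairs data frame with `id_a`, `id_b`, `label` (0/1).
#' @param descriptors matrix of per-protein 400-dim descriptors, protein
#'   ids as rownames.
#' @param olpp an [olpp_config()].
#' @param rof a [rof_config()].
#' @param k_folds number of folds (default 5).
#' @param seed seed for the fold assignment; the Rotation Forest uses its
#'   own config seed.
#' @return Object of class `ppi_cv_report`: `per_fold` (data frame of
#'   fold, accuracy, precision, sensitivity, mcc, auc), `mean`, `sd`
#'   (sample standard deviation over folds), `roc` (per-fold ROC point
#'   data frame) and `config` (echo of all settings).
#' @export
cross_validate <- function(pairs, descriptors, olpp = olpp_config(),
                           rof = rof_config(), k_folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(pairs), all(c("id_a", "id_b", "label") %in% names(pairs)))
  descriptors <- as.matrix(descriptors)
  labels <- as.integer(pairs$label)
  fold <- stratified_folds(labels, k_folds, seed)
  per_fold <- vector("list", k_folds)
  rocs <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    train_pairs <- pairs[train_idx, , drop = FALSE]
    test_pairs <- pairs[test_idx, , drop = FALSE]
    train_prot <- unique(c(train_pairs$id_a, train_pairs$id_b))
    missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(descriptors))
    if (length(missing) > 0L) {
      stop("no descriptor for protein id(s): ", paste(missing, collapse = ", "))
    }
    model_olpp <- fit_olpp(descriptors[train_prot, , drop = FALSE], olpp)
    emb <- predict(model_olpp, descriptors)
    tr <- make_pair_features(emb, train_pairs)
    te <- make_pair_features(emb, test_pairs)
    model_rof <- rotation_forest(tr$x, tr$label, rof)
    conf <- predict_confidence(model_rof, te$x)
    pred <- as.integer(as.character(predict(model_rof, te$x)))
    cm <- classification_metrics(confusion(te$label, pred))
    ra <- roc_auc(te$label, conf[, "1"])
    per_fold[[f]] <- data.frame(fold = f, accuracy = cm[["accuracy"]],
                                precision = cm[["precision"]],
                                sensitivity = cm[["sensitivity"]],
                                mcc = cm[["mcc"]], auc = ra$auc)
    rocs[[f]] <- cbind(fold = f, ra$roc)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "precision", "sensitivity", "mcc", "auc")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_cols]),
    sd = vapply(per_fold[metric_cols], stats::sd, 0),
    roc = do.call(rbind, rocs),
    config = list(olpp = unclass(olpp), rof = unclass(rof),
                  k_folds = as.integer(k_folds), seed = as.integer(seed))
  ), class = "ppi_cv_report")
}

#' @export
print.ppi_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n",
              x$config$k_folds, x$config$seed))
  cat(sprintf("  K = %d subsets, L = %d trees, d = %d embedding dims\n",
              x$config$rof$n_subsets, x$config$rof$n_trees,
              x$config$olpp$embed_dim))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Grid search over the Rotation Forest parameters K and L
#'
#' Runs the full cross-validated pipeline for every (K, L) cell and
#' reports the mean accuracy surface; the best cell breaks ties toward
#' the smaller L, then the smaller K.
#'
#' @param pairs,descriptors,olpp,k_folds,seed as in [cross_validate()].
#' @param k_values integer vector of subset counts K to try.
#' @param l_values integer vector of tree counts L to try.
#' @param rof base [rof_config()] supplying the remaining settings.
#' @return List with `table` (data frame K, L, mean_accuracy) and `best`
#'   (its selected row).
#' @export
grid_search <- function(pairs, descriptors, k_values, l_values,
                        olpp = olpp_config(), rof = rof_config(),
                        k_folds = 5L, seed = 1L) {
  if (length(k_values) == 0L || length(l_values) == 0L) {
    stop("'k_values' and 'l_values' must be non-empty")
  }
  grid <- expand.grid(K = as.integer(k_values), L = as.integer(l_values))
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- rof_config(n_subsets = grid$K[i], n_trees = grid$L[i],
                      sample_fraction = rof$sample_fraction,
                      bootstrap = rof$bootstrap, seed = rof$seed)
    acc[i] <- cross_validate(pairs, descriptors, olpp, cfg,
                             k_folds = k_folds, seed = seed)$mean[["accuracy"]]
  }
  tab <- cbind(grid, mean_accuracy = acc)
  best <- tab[order(-tab$mean_accuracy, tab$L, tab$K), ][1L, ]
  list(table = tab, best = best)
}

#' Write an evaluation report as JSON and its ROC points as TSV
#'
#' @param report a `ppi_cv_report`.
#' @param json_path output path for the JSON report.
#' @param roc_path optional output path for the ROC points TSV.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, roc_path = NULL) {
  payload <- list(
    config = report$config,
    per_fold = report$per_fold,
    mean = as.list(report$mean),
    sd = as.list(report$sd)
  )
  jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  if (!is.null(roc_path)) {
    utils::write.table(report$roc, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
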