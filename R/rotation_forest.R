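#' Configuration for a Rotation Forest ensemble
#'
#' @param n_subsets K, the number of disjoint feature subsets each tree's
#'   rotation is built from (default 10).
#' @param n_trees L, the number of decision trees (default 35).
#' @param sample_fraction fraction of the training set bootstrapped when
#'   estimating each subset's principal-component coefficients
#'   (default 0.75). The resample affects only the rotation; trees always
#'   train on the full rotated set.
#' @param bootstrap draw the PCA sample with replacement (`TRUE`, the
#'   default). With `bootstrap = FALSE` and `sample_fraction = 1` the
#'   rotation is estimated on the full, unresampled training set --
#'   useful for deterministic reductions.
#' @param seed integer seed making fit and predict fully reproducible.
#' @return A list of class `rof_config`.
#' @export
rof_config <- function(n_subsets = 10L, n_trees = 35L, sample_fraction = 0.75,
                       bootstrap = TRUE, seed = 1L) {
  n_subsets <- as.integer(n_subsets)
  n_trees <- as.integer(n_trees)
  if (n_subsets < 1L) stop("'n_subsets' (K) must be >= 1")
  if (n_trees < 1L) stop("'n_trees' (L) must be >= 1")
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 || sample_fraction > 1) {
    stop("'sample_fraction' must be in (0, 1]")
  }
  structure(list(n_subsets = n_subsets, n_trees = n_trees,
                 sample_fraction = sample_fraction,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "rof_config")
}

#' Random disjoint partition of the feature set
#'
#' Shuffles the feature indices (using the current RNG state) and splits
#' them into K contiguous chunks; when K does not divide n, the first
#' n mod K chunks receive one extra feature. The chunks are disjoint and
#' cover every feature.
#'
#' @param n_features number of features n.
#' @param k number of subsets K, between 1 and n.
#' @return List of K integer index vectors.
#' @export
partition_features <- function(n_features, k) {
  n_features <- as.integer(n_features)
  k <- as.integer(k)
  if (k < 1L || k > n_features) {
    stop("'k' must be between 1 and n_features (", n_features, ")")
  }
  perm <- sample.int(n_features)
  base <- n_features %/% k
  extra <- n_features %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  split(perm, rep(seq_len(k), times = sizes))
}

#' Build one sparse rotation matrix
#'
#' For each feature subset, draws a bootstrap sample of the training
#' rows, runs PCA on the sampled columns, and keeps *all* of the subset's
#' principal-component coefficient vectors as one orthonormal diagonal
#' block. The blocks are then placed back in original feature order, so
#' the result is an n x n matrix that is exactly zero outside the
#' subset blocks, and `x %*% rotation` gives the rotated feature values.
#' A zero-variance subset falls back to an identity block (with a
#' warning) rather than failing.
#'
#' @param x N x n training matrix.
#' @param labels class labels (unused by the rotation itself; accepted so
#'   the signature matches the fitting step).
#' @param partition list of disjoint index vectors from
#'   [partition_features()].
#' @param sample_fraction fraction of rows resampled per subset.
#' @param bootstrap sample with replacement? With `bootstrap = FALSE` and
#'   `sample_fraction = 1` the full training set is used as-is.
#' @return List of class `rotation_spec`: `partition` and the n x n
#'   `rotation` matrix.
#' @export
build_rotation <- function(x, labels = NULL, partition, sample_fraction = 0.75,
                           bootstrap = TRUE) {
  x <- as.matrix(x)
  n_samp <- nrow(x)
  n_feat <- ncol(x)
  if (n_samp < 2L) stop("need at least 2 training samples")
  rotation <- matrix(0, n_feat, n_feat)
  col_at <- 0L
  for (idx in partition) {
    c_j <- length(idx)
    rows <- if (bootstrap || sample_fraction < 1) {
      sample.int(n_samp, size = ceiling(sample_fraction * n_samp),
                 replace = bootstrap)
    } else {
      seq_len(n_samp)
    }
    xs <- x[rows, idx, drop = FALSE]
    v <- apply(xs, 2L, stats::var)
    if (all(v < .Machine$double.eps)) {
      warning("zero-variance feature subset; using identity block")
      block <- diag(c_j)
    } else {
      # eigen(cov) keeps all C_j coefficient vectors even when the
      # bootstrap sample is rank-deficient (prcomp would truncate)
      block <- eigen(stats::cov(xs), symmetric = TRUE)$vectors
    }
    rotation[idx, col_at + seq_len(c_j)] <- block
    col_at <- col_at + c_j
  }
  structure(list(partition = partition, rotation = rotation),
            class = "rotation_spec")
}

rpart_full <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                                   xval = 0L, maxcompete = 0L,
                                   maxsurrogate = 0L, usesurrogate = 0L)

#' Fit a Rotation Forest classifier
#'
#' Trains L CART trees (Gini impurity, grown to purity), each in its own
#' randomly rotated feature space: a fresh random partition of the
#' features into K subsets, per-subset PCA coefficients estimated on a
#' 75% bootstrap resample, assembled into a sparse block rotation matrix;
#' the tree then trains on the *full* training set rotated by that
#' matrix. The per-tree rotations are what decorrelate the ensemble.
#'
#' @param x N x n numeric feature matrix.
#' @param y class labels (two or more classes; coerced to factor).
#' @param config a [rof_config()].
#' @return Object of class `rotation_forest`: `config`, `classes`, and
#'   `members` (a list of L `(rotation, tree)` pairs).
#' @export
rotation_forest <- function(x, y, config = rof_config()) {
  stopifnot(inherits(config, "rof_config"))
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) < 2L) stop("need at least 2 training samples")
  if (nlevels(y) < 2L) stop("'y' must contain at least two classes")
  if (length(y) != nrow(x)) stop("'x' and 'y' lengths differ")
  if (config$n_subsets > ncol(x)) {
    stop("'n_subsets' (K = ", config$n_subsets, ") exceeds the number of features (",
         ncol(x), ")")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  members <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    part <- partition_features(ncol(x), config$n_subsets)
    spec <- build_rotation(x, y, part, config$sample_fraction, config$bootstrap)
    xr <- x %*% spec$rotation
    colnames(xr) <- paste0("r", seq_len(ncol(xr)))
    df <- as.data.frame(xr)
    df$.y <- y
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         control = rpart_full)
    members[[i]] <- list(rotation = spec, tree = tree)
  }
  structure(list(config = config, classes = levels(y), members = members,
                 n_features = ncol(x)),
            class = "rotation_forest")
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("Rotation Forest: L = %d trees, K = %d subsets, %d features, classes: %s\n",
              x$config$n_trees, x$config$n_subsets, x$n_features,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Ensemble class confidences
#'
#' Averages the per-tree leaf class-probability estimates over the L
#' trees, each tree seeing the samples rotated into its own feature
#' space: m_j(x) = (1/L) sum_i d_ij(x G_i). Rows sum to one.
#'
#' @param model a fitted [rotation_forest()].
#' @param x samples x n matrix.
#' @return samples x classes matrix of averaged confidences.
#' @export
predict_confidence <- function(model, x) {
  stopifnot(inherits(model, "rotation_forest"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("'x' has ", ncol(x), " features but the model was fitted on ",
         model$n_features)
  }
  acc <- matrix(0, nrow(x), length(model$classes),
                dimnames = list(rownames(x), model$classes))
  for (m in model$members) {
    xr <- x %*% m$rotation$rotation
    colnames(xr) <- paste0("r", seq_len(ncol(xr)))
    p <- stats::predict(m$tree, as.data.frame(xr), type = "prob")
    acc <- acc + p[, model$classes, drop = FALSE]
  }
  acc / length(model$members)
}

#' Predict class labels with a Rotation Forest
#'
#' Assigns each sample to the class with the highest average confidence;
#' exact ties resolve to the lower class index.
#'
#' @param object a fitted [rotation_forest()].
#' @param newdata samples x n matrix.
#' @param type `"class"` for labels, `"prob"` for the confidence matrix.
#' @param ... ignored.
#' @return Factor of predicted labels, or the confidence matrix.
#' @export
predict.rotation_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  conf <- predict_confidence(object, newdata)
  if (type == "prob") return(conf)
  idx <- max.col(conf, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}
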