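#' Configuration for an OLPP embedding
#'
#' @param n_neighbors number of nearest neighbours used when building the
#'   affinity graph (small positive integer).
#' @param heat_t heat-kernel bandwidth t in exp(-||xi - xj||^2 / t), or
#'   `"auto"` to use the mean squared distance over graph edges.
#' @param embed_dim target dimension d of the embedding.
#' @param pca_tol relative eigenvalue cutoff of the PCA pre-projection:
#'   components with eigenvalue <= pca_tol * largest are discarded (the
#'   "drop the null space" step).
#' @param ridge non-negative ridge added to X D X^T before inversion;
#'   `NULL` selects 1e-8 * trace(X D X^T) / rank.
#' @return A list of class `olpp_config`.
#' @export
olpp_config <- function(n_neighbors = 5L, heat_t = "auto", embed_dim = 100L,
                        pca_tol = 1e-8, ridge = NULL) {
  n_neighbors <- as.integer(n_neighbors)
  embed_dim <- as.integer(embed_dim)
  if (n_neighbors < 1L) stop("'n_neighbors' must be >= 1")
  if (embed_dim < 1L) stop("'embed_dim' must be >= 1")
  if (!identical(heat_t, "auto") && (!is.numeric(heat_t) || heat_t <= 0)) {
    stop("'heat_t' must be positive or \"auto\"")
  }
  if (!is.numeric(pca_tol) || pca_tol <= 0) stop("'pca_tol' must be > 0")
  if (!is.null(ridge) && (!is.numeric(ridge) || ridge < 0)) {
    stop("'ridge' must be non-negative")
  }
  structure(list(n_neighbors = n_neighbors, heat_t = heat_t,
                 embed_dim = embed_dim, pca_tol = pca_tol, ridge = ridge),
            class = "olpp_config")
}

#' PCA pre-projection
#'
#' Centers the data and retains the principal directions whose covariance
#' eigenvalues exceed `pca_tol` times the largest one, i.e. discards the
#' (numerically) null part of the covariance so that X D X^T is
#' invertible downstream.
#'
#' @param x n x m data matrix (rows = samples).
#' @param pca_tol relative eigenvalue cutoff.
#' @return List with `mean` (length-m centering vector) and `w_pca`
#'   (m x r projection, unit-norm eigenvector columns, eigenvalue order).
#' @export
pca_projection <- function(x, pca_tol = 1e-8) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples for the PCA projection")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc) / (nrow(x) - 1L)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[1L] <= 0) stop("degenerate data: covariance has no positive eigenvalue")
  keep <- which(e$values > pca_tol * e$values[1L])
  keep <- keep[keep <= nrow(x) - 1L]  # at most n-1 non-null directions
  if (length(keep) == 0L) stop("degenerate data: all eigenvalues below cutoff")
  list(mean = mu, w_pca = e$vectors[, keep, drop = FALSE])
}

#' k-nearest-neighbour adjacency graph
#'
#' Connects i and j when i is among the `n_neighbors` Euclidean nearest
#' neighbours of j *or* vice versa (OR-symmetrization), with no
#' self-edges.
#'
#' @param x n x m data matrix.
#' @param n_neighbors neighbours per node, between 1 and n - 1.
#' @return n x n logical adjacency matrix, symmetric, FALSE diagonal.
#' @export
build_knn_graph <- function(x, n_neighbors) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 1L || n_neighbors >= n) {
    stop("'n_neighbors' must be between 1 and n - 1 (n = ", n, ")")
  }
  d <- as.matrix(stats::dist(x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[-1L][seq_len(n_neighbors)]  # drop self
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

#' Heat-kernel edge weights
#'
#' W_ij = exp(-||xi - xj||^2 / t) where i and j are linked, and 0
#' otherwise. With `heat_t = "auto"` the bandwidth t is the mean squared
#' distance over the graph's edges, so a typical edge gets weight
#' exp(-1).
#'
#' @param x n x m data matrix.
#' @param adjacency symmetric logical adjacency from [build_knn_graph()].
#' @param heat_t positive bandwidth, or `"auto"`.
#' @return Symmetric n x n weight matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
heat_weights <- function(x, adjacency, heat_t = "auto") {
  x <- as.matrix(x)
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("'adjacency' must be symmetric")
  }
  d2 <- as.matrix(stats::dist(x))^2
  if (identical(heat_t, "auto")) {
    if (!any(adjacency)) stop("cannot auto-select heat_t on an edgeless graph")
    heat_t <- mean(d2[adjacency])
  }
  if (heat_t <= 0) stop("'heat_t' must be positive")
  w <- exp(-d2 / heat_t)
  w[!adjacency] <- 0
  diag(w) <- 0
  attr(w, "heat_t") <- heat_t
  w
}

#' Degree matrix and graph Laplacian
#'
#' D is diagonal with the column sums of W; the Laplacian is L = D - W.
#' Every row of L sums to zero and L is positive semi-definite for
#' non-negative symmetric W.
#'
#' @param w symmetric non-negative weight matrix.
#' @return List with `d` (diagonal degree matrix) and `l` (Laplacian).
#' @export
degree_laplacian <- function(w) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("'w' must be non-negative")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10, check.attributes = FALSE))) {
    stop("'w' must be symmetric")
  }
  d <- diag(colSums(w), nrow(w))
  list(d = d, l = d - w)
}

# Smallest generalized eigenvector of (sym) a w = lambda (sym pd) b w,
# via Cholesky reduction to an ordinary symmetric problem.
smallest_gen_eigvec <- function(a, b) {
  r <- chol(b)
  ri <- backsolve(r, diag(nrow(r)))
  c <- crossprod(ri, a %*% ri)
  c <- (c + t(c)) / 2
  e <- eigen(c, symmetric = TRUE)
  z <- e$vectors[, ncol(c)]  # eigenvalues are in decreasing order
  v <- ri %*% z
  v / sqrt(sum(v^2))
}

# Fix an eigenvector's sign: largest-magnitude entry positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Orthogonal basis of the locality-preserving embedding
#'
#' Extracts d mutually orthogonal directions o_1..o_d that successively
#' minimize the locality objective o^T X L X^T o relative to the
#' degree-weighted norm o^T X D X^T o. o_1 solves the generalized
#' eigenproblem X L X^T o = lambda X D X^T o at the smallest eigenvalue;
#' each later o_k minimizes the same ratio subject to exact orthogonality
#' to o_1..o_(k-1). The constrained minimizer is the smallest-eigenvalue
#' eigenvector of the deflated operator
#' \{I - (XDX^T)^-1 A B^-1 A^T\} (XDX^T)^-1 X L X^T with
#' A = \[o_1..o_(k-1)\], B = A^T (XDX^T)^-1 A; it is computed here in the
#' orthogonal complement of span(A), which yields the identical vector
#' through a symmetric-definite solve while avoiding the deflated
#' operator's spurious null modes (see the methods vignette).
#'
#' @param xp r x n matrix of PCA-space sample coordinates (columns =
#'   samples).
#' @param d_mat diagonal degree matrix from [degree_laplacian()].
#' @param l_mat graph Laplacian.
#' @param embed_dim number of basis vectors d (<= r).
#' @param ridge ridge added to X D X^T; `NULL` for the default
#'   1e-8 * trace / r.
#' @return r x d matrix of unit-norm, mutually orthogonal columns.
#' @export
orthogonal_basis <- function(xp, d_mat, l_mat, embed_dim, ridge = NULL) {
  xp <- as.matrix(xp)
  r <- nrow(xp)
  embed_dim <- as.integer(embed_dim)
  if (embed_dim > r) {
    stop("'embed_dim' (", embed_dim, ") exceeds the PCA-space rank (", r, ")")
  }
  xdx <- xp %*% d_mat %*% t(xp)
  xlx <- xp %*% l_mat %*% t(xp)
  xdx <- (xdx + t(xdx)) / 2
  xlx <- (xlx + t(xlx)) / 2
  if (is.null(ridge)) ridge <- 1e-8 * sum(diag(xdx)) / r
  xdx <- xdx + diag(ridge, r)

  basis <- matrix(0, r, embed_dim)
  basis[, 1L] <- fix_sign(smallest_gen_eigvec(xlx, xdx))
  if (embed_dim > 1L) {
    for (k in 2:embed_dim) {
      a <- basis[, seq_len(k - 1L), drop = FALSE]
      # orthonormal basis q of the complement of span(a)
      q <- qr.Q(qr(a), complete = TRUE)[, k:r, drop = FALSE]
      av <- smallest_gen_eigvec(crossprod(q, xlx %*% q),
                                crossprod(q, xdx %*% q))
      basis[, k] <- fix_sign(q %*% av)
    }
  }
  basis
}

# Explicit deflated operator M^(k) of the iterative construction; kept as
# an internal cross-check of orthogonal_basis (tests assert both routes
# return the same direction).
olpp_deflation_matrix <- function(xdx, xlx, a) {
  minv <- solve(xdx)
  t0 <- minv %*% xlx
  if (is.null(a) || ncol(a) == 0L) return(t0)
  b <- crossprod(a, minv %*% a)
  (diag(nrow(xdx)) - minv %*% a %*% solve(b) %*% t(a)) %*% t0
}

#' Fit an OLPP embedding
#'
#' Composes the full pipeline on an n x m matrix of sample descriptors:
#' PCA pre-projection (null-space removal), k-nearest-neighbour graph,
#' heat-kernel weights, graph Laplacian, iterative orthogonal-basis
#' extraction, and assembly of the combined linear map
#' W = W_PCA W_OLPP so that a new sample x embeds as
#' y = W^T (x - mean). Entirely deterministic: no randomness is involved.
#'
#' @param x n x m numeric matrix, one row per sample.
#' @param config an [olpp_config()].
#' @return An object of class `olpp`: list with `mean`, `w_pca`, `basis`,
#'   `w` (the combined m x d transform), `heat_t` (resolved bandwidth)
#'   and `config`.
#' @export
fit_olpp <- function(x, config = olpp_config()) {
  stopifnot(inherits(config, "olpp_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < config$n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 samples (got ", n, ")")
  }
  pca <- pca_projection(x, config$pca_tol)
  scores <- sweep(x, 2L, pca$mean) %*% pca$w_pca  # n x r
  adj <- build_knn_graph(scores, config$n_neighbors)
  w_graph <- heat_weights(scores, adj, config$heat_t)
  dl <- degree_laplacian(w_graph)
  if (config$embed_dim > ncol(pca$w_pca)) {
    stop("'embed_dim' (", config$embed_dim, ") exceeds the PCA-space rank (",
         ncol(pca$w_pca), ")")
  }
  basis <- orthogonal_basis(t(scores), dl$d, dl$l, config$embed_dim,
                            config$ridge)
  structure(list(
    mean = pca$mean,
    w_pca = pca$w_pca,
    basis = basis,
    w = pca$w_pca %*% basis,
    heat_t = attr(w_graph, "heat_t"),
    config = config
  ), class = "olpp")
}

#' @export
print.olpp <- function(x, ...) {
  cat(sprintf("OLPP embedding: %d -> %d (PCA rank %d, %d neighbours, t = %.4g)\n",
              length(x$mean), ncol(x$w), ncol(x$w_pca),
              x$config$n_neighbors, x$heat_t))
  invisible(x)
}

#' Embed new samples with a fitted OLPP model
#'
#' @param object a fitted `olpp` model.
#' @param newdata k x m matrix of samples in the original descriptor
#'   space.
#' @param ... ignored.
#' @return k x d matrix of embedded coordinates (rownames preserved).
#' @export
predict.olpp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean)) {
    stop("'newdata' has ", ncol(newdata), " columns but the model was fitted on ",
         length(object$mean))
  }
  sweep(newdata, 2L, object$mean) %*% object$w
}

#' Save / load an OLPP model as portable JSON
#'
#' @param model a fitted `olpp` model.
#' @param path file path.
#' @return `path` (write) or the restored `olpp` object (read).
#' @export
write_olpp_model <- function(model, path) {
  stopifnot(inherits(model, "olpp"))
  payload <- list(
    mean = model$mean, w_pca = model$w_pca, basis = model$basis,
    heat_t = model$heat_t,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_olpp_model
#' @export
read_olpp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- !vapply(p$config, function(x) is.null(x) || length(x) == 0L, logical(1))
  cfg <- do.call(olpp_config, p$config[keep])
  structure(list(
    mean = as.numeric(p$mean),
    w_pca = as.matrix(p$w_pca),
    basis = as.matrix(p$basis),
    w = as.matrix(p$w_pca) %*% as.matrix(p$basis),
    heat_t = p$heat_t,
    config = cfg
  ), class = "olpp")
}
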