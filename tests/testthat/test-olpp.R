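test_that("PCA pre-projection keeps exactly the non-null directions", {
  set.seed(1)
  # points on a 2-D plane embedded in 5-D
  basis2 <- matrix(rnorm(10), 2, 5)
  x <- matrix(rnorm(40 * 2), 40, 2) %*% basis2
  p <- pca_projection(x, 1e-8)
  expect_equal(ncol(p$w_pca), 2L)
  expect_equal(crossprod(p$w_pca), diag(2), tolerance = 1e-12)

  # full-rank isotropic data with m < n keeps all m
  x2 <- matrix(rnorm(50 * 4), 50, 4)
  expect_equal(ncol(pca_projection(x2, 1e-8)$w_pca), 4L)

  # constant data is degenerate
  expect_error(pca_projection(rbind(rep(1, 3), rep(1, 3)), 1e-8), "degenerate")
})

test_that("knn graph follows the OR-symmetrized nearest-neighbour rule", {
  # 1-D points 0, 1, 10 with one neighbour each: edges 0-1 and 1-10 only
  x <- matrix(c(0, 1, 10), 3, 1)
  adj <- build_knn_graph(x, 1)
  expect_identical(adj, t(adj))
  expect_true(adj[1, 2] && adj[2, 3])
  expect_false(adj[1, 3])
  expect_false(any(diag(adj)))

  # n_neighbors = n - 1 gives the complete graph
  set.seed(2)
  y <- matrix(rnorm(12), 6, 2)
  full <- build_knn_graph(y, 5)
  expect_true(all(full[upper.tri(full)]))

  expect_error(build_knn_graph(y, 6), "between 1 and n - 1")
})

test_that("heat-kernel weights follow exp(-d^2/t) with the zero rule", {
  x <- matrix(c(0, 0, 1, 0, 5, 5), 3, 2, byrow = TRUE)
  adj <- matrix(c(FALSE, TRUE, FALSE,
                  TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE), 3, 3)
  w <- heat_weights(x, adj, heat_t = 1)
  expect_equal(w[1, 2], exp(-1))
  expect_equal(w[1, 2], 0.367879, tolerance = 1e-5)
  expect_equal(w[1, 3], 0)  # unlinked pairs get zero weight
  expect_equal(diag(w), rep(0, 3), ignore_attr = TRUE)

  # coincident linked points have weight 1
  xc <- rbind(c(1, 1), c(1, 1), c(9, 9))
  wc <- heat_weights(xc, adj, heat_t = 2)
  expect_equal(wc[1, 2], 1)

  # "auto" uses the mean squared edge distance
  wa <- heat_weights(x, adj, heat_t = "auto")
  expect_equal(attr(wa, "heat_t"), 1)
  expect_error(heat_weights(x, matrix(FALSE, 3, 3), "auto"), "edgeless")
  expect_error(heat_weights(x, matrix(c(rep(TRUE, 3), rep(FALSE, 6)), 3, 3), 1),
               "symmetric")
})

test_that("degree and Laplacian matrices satisfy their identities", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  dl <- degree_laplacian(w)
  expect_equal(dl$d, diag(c(1, 1)))
  expect_equal(dl$l, matrix(c(1, -1, -1, 1), 2, 2))

  expect_equal(degree_laplacian(matrix(0, 3, 3))$l, matrix(0, 3, 3))

  set.seed(3)
  a <- matrix(runif(49), 7, 7)
  w2 <- (a + t(a)) / 2
  diag(w2) <- 0
  l2 <- degree_laplacian(w2)$l
  expect_lt(max(abs(rowSums(l2))), 1e-12)
  expect_gt(min(eigen(l2, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  expect_error(degree_laplacian(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(degree_laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
})

test_that("first basis vector solves the generalized eigenproblem", {
  for (seed in 1:5) {
    pr <- small_olpp_problem(n = 30, m = 5, seed = seed)
    b <- orthogonal_basis(pr$xp, pr$d, pr$l, 1, ridge = 0)
    v <- gen_eig_smallest(pr$xp, pr$d, pr$l)
    expect_gte(abs(sum(b[, 1] * v)), 1 - 1e-8)
  }
})

test_that("basis vectors are unit-norm and mutually orthogonal", {
  pr <- small_olpp_problem(n = 30, m = 5, seed = 9)
  b <- orthogonal_basis(pr$xp, pr$d, pr$l, 4)
  g <- crossprod(b)
  expect_lt(max(abs(g - diag(4))), 1e-8)
  expect_error(orthogonal_basis(pr$xp, pr$d, pr$l, 99), "exceeds")
})

test_that("second basis vector matches the explicit deflated operator", {
  pr <- small_olpp_problem(n = 25, m = 4, seed = 5)
  xdx <- pr$xp %*% pr$d %*% t(pr$xp)
  r <- nrow(pr$xp)
  ridge <- 1e-8 * sum(diag(xdx)) / r
  b <- orthogonal_basis(pr$xp, pr$d, pr$l, 2, ridge = ridge)
  m2 <- ppirof:::olpp_deflation_matrix(xdx + diag(ridge, r),
                                       pr$xp %*% pr$l %*% t(pr$xp),
                                       b[, 1, drop = FALSE])
  e <- eigen(m2)
  real_ok <- which(abs(Im(e$values)) < 1e-8)
  # smallest-eigenvalue eigenvector that satisfies the orthogonality
  # constraint (the operator's exact-zero modes are spurious)
  for (i in real_ok[order(Re(e$values[real_ok]))]) {
    u <- Re(e$vectors[, i])
    u <- u / sqrt(sum(u^2))
    if (abs(sum(u * b[, 1])) < 1e-6) {
      expect_gte(abs(sum(u * b[, 2])), 1 - 1e-6)
      break
    }
  }
})

test_that("second basis vector attains the brute-force constrained minimum", {
  pr <- small_olpp_problem(n = 20, m = 3, seed = 13)
  xdx <- pr$xp %*% pr$d %*% t(pr$xp)
  xlx <- pr$xp %*% pr$l %*% t(pr$xp)
  b <- orthogonal_basis(pr$xp, pr$d, pr$l, 2, ridge = 0)
  rayleigh <- function(w) {
    as.numeric(t(w) %*% xlx %*% w) / as.numeric(t(w) %*% xdx %*% w)
  }
  # sweep the unit circle of the 2-D orthogonal complement of o_1
  q <- qr.Q(qr(b[, 1, drop = FALSE]), complete = TRUE)[, 2:3]
  theta <- seq(0, pi, length.out = 20000L)
  grid_min <- min(vapply(theta, function(th) {
    rayleigh(q %*% c(cos(th), sin(th)))
  }, 0))
  expect_lte(rayleigh(b[, 2]), grid_min + 1e-10 * abs(grid_min))
})

test_that("fitting is deterministic and the transform is affine-linear", {
  set.seed(21)
  x <- matrix(rnorm(40 * 6), 40, 6)
  cfg <- olpp_config(n_neighbors = 4, embed_dim = 3)
  m1 <- fit_olpp(x, cfg)
  m2 <- fit_olpp(x, cfg)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$basis, m2$basis)

  # the training mean embeds at the origin
  expect_equal(unname(predict(m1, matrix(m1$mean, 1))), matrix(0, 1, 3),
               tolerance = 1e-12)

  # rows transform independently
  expect_equal(predict(m1, x[3, , drop = FALSE]),
               predict(m1, x)[3, , drop = FALSE])

  # linearity after centering
  a <- 0.3
  combo <- a * x[1, ] + (1 - a) * x[2, ]
  expect_equal(predict(m1, matrix(combo, 1)),
               a * predict(m1, x[1, , drop = FALSE]) +
                 (1 - a) * predict(m1, x[2, , drop = FALSE]),
               tolerance = 1e-10)

  expect_error(predict(m1, matrix(0, 2, 5)), "columns")
})

test_that("embedding preserves locality on two well-separated clusters", {
  set.seed(31)
  n_half <- 30
  x <- rbind(matrix(rnorm(n_half * 10), n_half, 10),
             matrix(rnorm(n_half * 10, mean = 8), n_half, 10))
  cl <- rep(1:2, each = n_half)
  ratio <- function(z) {
    d <- as.matrix(dist(z))
    same <- outer(cl, cl, "==") & upper.tri(d)
    diff <- outer(cl, cl, "!=") & upper.tri(d)
    mean(d[same]) / mean(d[diff])
  }
  m <- fit_olpp(x, olpp_config(n_neighbors = 5, embed_dim = 2))
  expect_lt(ratio(predict(m, x)), ratio(x))
})

test_that("full-dimensional embedding keeps full column rank", {
  set.seed(41)
  x <- matrix(rnorm(25 * 4), 25, 4)
  m <- fit_olpp(x, olpp_config(n_neighbors = 3, embed_dim = 4))
  expect_equal(qr(m$w)$rank, 4L)
})

test_that("OLPP models survive a JSON round trip", {
  set.seed(51)
  x <- matrix(rnorm(30 * 5), 30, 5)
  m <- fit_olpp(x, olpp_config(n_neighbors = 4, embed_dim = 2))
  f <- tempfile(fileext = ".json")
  write_olpp_model(m, f)
  m2 <- read_olpp_model(f)
  expect_equal(m2$w, m$w, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
})
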