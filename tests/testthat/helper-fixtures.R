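# Shared fixture builders; everything is generated in code at test time.

rand_pssm <- function(t_len, seed = 1L, id = "px") {
  set.seed(seed)
  new_pssm(matrix(sample(-9:9, t_len * 20L, replace = TRUE), t_len, 20L), id)
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# a small OLPP problem: PCA-space coordinates plus graph matrices
small_olpp_problem <- function(n = 30L, m = 5L, seed = 1L, nn = 4L) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  pca <- pca_projection(x, 1e-8)
  scores <- sweep(x, 2L, pca$mean) %*% pca$w_pca
  adj <- build_knn_graph(scores, nn)
  w <- heat_weights(scores, adj, "auto")
  dl <- degree_laplacian(w)
  list(x = x, scores = scores, xp = t(scores), d = dl$d, l = dl$l)
}

# dense generalized eigensolver on X L X^T w = lambda X D X^T w via the
# (independent) nonsymmetric route
gen_eig_smallest <- function(xp, d_mat, l_mat, ridge = 0) {
  xdx <- xp %*% d_mat %*% t(xp) + diag(ridge, nrow(xp))
  xlx <- xp %*% l_mat %*% t(xp)
  e <- eigen(solve(xdx) %*% xlx)
  i <- which.min(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sqrt(sum(v^2))
}

# small synthetic benchmark shared by evaluation-level tests
small_benchmark <- function(effect = 2, seed = 7L) {
  synth_pair_dataset(synth_spec(n_proteins = 60L, n_pairs = 120L,
                                effect = effect, seed = seed))
}

small_olpp_cfg <- function() olpp_config(n_neighbors = 5L, embed_dim = 20L)
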