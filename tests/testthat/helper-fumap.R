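# Shared fixtures and independent oracles, all built in code.

# Symmetric membership matrix with entries uniform in (0,1), zero diagonal.
random_membership_graph <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n, n)
  A[upper.tri(A, diag = TRUE)] <- 0
  symmetrize(A) # t-conorm mirrors the lower triangle: a + 0 - 0 = a
}

# fuzzy_graph wrapper around an explicit symmetric membership matrix
graph_from_matrix <- function(M) {
  diag(M) <- 0
  structure(
    list(memberships = M,
         repulsion_weights = rowSums(M) / (2 * nrow(M)),
         n = nrow(M), k = NA_integer_),
    class = "fuzzy_graph"
  )
}

# Exhaustive k-NN oracle: full pairwise distances, per-row stable sort.
brute_knn <- function(X, k) {
  n <- nrow(X)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- ord; dst[i, ] <- d[ord]
  }
  list(indices = idx, distances = dst)
}

# Grid sum-of-squares objective of the similarity-curve fit, for the
# independent Nelder-Mead oracle.
curve_fit_oracle <- function(min_dist, grid_max = 3, grid_points = 300L) {
  d <- seq(0, grid_max, length.out = grid_points)
  y <- psi_curve(d, min_dist)
  obj <- function(p) sum((1 / (1 + exp(p[1]) * d^(2 * exp(p[2]))) - y)^2)
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

all_losses <- c("umap_ce", "fuzzy_ce", "symmetric_ce", "modified_ce")

default_curve <- fit_ab(0.1)
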