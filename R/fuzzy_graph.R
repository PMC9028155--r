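#' Euclidean distance between two vectors
#'
#' Plain L2 distance, the metric used throughout the high-dimensional phase.
#'
#' @param u,v Numeric vectors of equal length with finite entries.
#' @return A single non-negative number.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("euclidean_distance(): 'u' and 'v' must have the same length (",
         length(u), " vs ", length(v), ")")
  }
  if (!all(is.finite(u)) || !all(is.finite(v))) {
    stop("euclidean_distance(): inputs must be finite")
  }
  sqrt(sum((u - v)^2))
}

#' Exact k-nearest-neighbour table
#'
#' Brute-force exact search over all pairwise Euclidean distances. The object
#' itself is never its own neighbour; ties are broken by ascending row index
#' so the result is fully deterministic.
#'
#' @param X Numeric matrix, one observation per row.
#' @param k Number of neighbours, \code{1 <= k <= nrow(X) - 1}.
#' @return A list with integer matrix \code{indices} (n x k) and numeric
#'   matrix \code{distances} (n x k, sorted non-decreasing per row).
#' @export
knn_table <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("knn_table(): need at least two observations")
  if (!all(is.finite(X))) stop("knn_table(): X must be finite")
  k <- as.integer(k)
  if (k < 1 || k > n - 1) {
    stop("knn_table(): k must be in [1, n-1], got k=", k, " with n=", n)
  }
  D <- as.matrix(stats::dist(X))
  indices <- matrix(0L, n, k)
  distances <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf # self excluded
    ord <- order(d, method = "radix")[seq_len(k)] # radix sort is stable: ties by index
    indices[i, ] <- ord
    distances[i, ] <- d[ord]
  }
  list(indices = indices, distances = distances)
}

#' Calibrate the smooth k-NN kernel bandwidth for one observation
#'
#' Finds \code{rho} (distance to the nearest neighbour) and solves, by
#' bracketed bisection, for the bandwidth \code{sigma} such that the total
#' membership mass \code{sum(exp((rho - d_l) / sigma))} over the k neighbour
#' distances equals \code{log2(k)}. The sum is monotone increasing in sigma,
#' ranging from the number of rho-ties (sigma -> 0) up to k (sigma -> Inf),
#' so a root exists iff the tie count is below the target. When it is not
#' (all-ties rows), sigma is clamped to \code{sigma_floor_factor * mean(d)}
#' and the \code{clamped} flag is set.
#'
#' @param distances_row Non-negative finite numeric vector of the k neighbour
#'   distances (sorted or not).
#' @param k Neighbour count, must be >= 2 (the target log2(k) is degenerate
#'   below that).
#' @param tol Residual tolerance on the membership-mass equation.
#' @param max_iter Bisection step cap.
#' @param sigma_floor_factor Floor for sigma, as a fraction of the mean
#'   neighbour distance.
#' @return A list with \code{rho}, \code{sigma} and logical \code{clamped}.
#' @export
smooth_knn_calibrate <- function(distances_row, k = length(distances_row),
                                 tol = 1e-5, max_iter = 64L,
                                 sigma_floor_factor = 1e-3) {
  d <- as.numeric(distances_row)
  if (k < 2) stop("smooth_knn_calibrate(): k must be >= 2")
  if (length(d) != k) stop("smooth_knn_calibrate(): length(distances_row) != k")
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("smooth_knn_calibrate(): distances must be finite and non-negative")
  }
  rho <- min(d)
  target <- log2(k)
  mass <- function(sigma) sum(exp((rho - d) / sigma))
  n_ties <- sum(d == rho)
  floor_sigma <- max(sigma_floor_factor * mean(d), .Machine$double.xmin)
  if (n_ties >= target) {
    # mass(sigma) >= n_ties >= target for every sigma: no root
    return(list(rho = rho, sigma = floor_sigma, clamped = TRUE))
  }
  lo <- 1; hi <- 1
  it <- 0L
  while (mass(hi) < target && it < 64L) { hi <- hi * 2; it <- it + 1L }
  it <- 0L
  while (mass(lo) > target && it < 64L) { lo <- lo / 2; it <- it + 1L }
  sigma <- (lo + hi) / 2
  for (step in seq_len(max_iter)) {
    sigma <- (lo + hi) / 2
    m <- mass(sigma)
    if (abs(m - target) <= tol) break
    if (m > target) hi <- sigma else lo <- sigma
  }
  if (sigma < floor_sigma) {
    return(list(rho = rho, sigma = floor_sigma, clamped = TRUE))
  }
  list(rho = rho, sigma = sigma, clamped = abs(mass(sigma) - target) > tol)
}

#' Fuzzy membership values for one observation's neighbour row
#'
#' Converts calibrated neighbour distances to membership strengths
#' \code{exp((rho - d) / sigma)}; positions outside the neighbour set are 0.
#' The rho-attaining neighbour gets membership exactly 1.
#'
#' @param rho,sigma Calibration scalars for this row (\code{sigma > 0}).
#' @param distances_row Neighbour distances.
#' @param indices_row Integer neighbour ids (positions in 1..n).
#' @param n Total number of observations.
#' @return A sparse numeric vector of length n.
#' @export
membership_row <- function(rho, sigma, distances_row, indices_row, n) {
  if (sigma <= 0) stop("membership_row(): sigma must be positive")
  mu <- exp((rho - distances_row) / sigma)
  mu <- pmin(mu, 1)
  Matrix::sparseVector(x = mu, i = as.integer(indices_row), length = n)
}

#' Symmetrize a directed membership matrix by the probabilistic t-conorm
#'
#' Applies \code{a + b - a*b} to each unordered pair, turning the directed
#' neighbour graph into an undirected fuzzy graph. 1 is absorbing and 0
#' neutral, so the rho-neighbour saturation (mu = 1) survives symmetrization.
#'
#' @param directed A square matrix (dense or \code{Matrix} sparse) with
#'   entries in [0, 1] and zero diagonal.
#' @return An object of class \code{fuzzy_graph}: a list with the symmetric
#'   \code{memberships} matrix and the per-row \code{repulsion_weights}
#'   \code{w_i = sum_k(mu_ik) / (2n)} used by the reduced-repulsion loss.
#' @export
symmetrize <- function(directed) {
  if (nrow(directed) != ncol(directed)) stop("symmetrize(): matrix must be square")
  rng <- range(if (methods::is(directed, "sparseMatrix")) directed@x else directed)
  if (length(rng) && (rng[1] < 0 || rng[2] > 1)) {
    stop("symmetrize(): memberships must lie in [0, 1]")
  }
  M <- directed + Matrix::t(directed) - directed * Matrix::t(directed)
  Matrix::diag(M) <- 0
  new_fuzzy_graph(M)
}

new_fuzzy_graph <- function(M, knn = NULL, calibration = NULL, k = NA_integer_) {
  n <- nrow(M)
  structure(
    list(
      memberships = M,
      repulsion_weights = as.numeric(Matrix::rowSums(M)) / (2 * n),
      n = n,
      k = k,
      knn = knn,
      calibration = calibration
    ),
    class = "fuzzy_graph"
  )
}

#' Build the fuzzy weighted undirected graph of a dataset
#'
#' The first phase of the embedding pipeline: exact k-NN search, per-row
#' smooth k-NN calibration of (rho, sigma), exponential memberships, and
#' probabilistic t-conorm symmetrization. The result is a symmetric n x n
#' matrix of membership strengths in [0, 1] with zero diagonal; every row
#' contains at least one entry equal to 1 (its nearest neighbour).
#'
#' Storage is sparse when \code{k < n/4} and dense otherwise (the
#' \code{k = n - 1} regime fills the matrix anyway).
#'
#' @param X Numeric observation matrix (n rows).
#' @param k Neighbour count, \code{2 <= k <= n - 1}.
#' @param metric Distance metric id; only \code{"euclidean"} is shipped.
#' @param tol Calibration residual tolerance.
#' @return A \code{fuzzy_graph} object (see \code{\link{symmetrize}}), also
#'   carrying the k-NN table and calibration vectors \code{rho}, \code{sigma},
#'   \code{sigma_clamped}.
#' @examples
#' X <- matrix(rnorm(60), 30, 2)
#' g <- build_fuzzy_graph(X, k = 5)
#' range(as.matrix(g$memberships))
#' @export
build_fuzzy_graph <- function(X, k = 10, metric = "euclidean", tol = 1e-5) {
  metric <- match.arg(metric, "euclidean")
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2) stop("build_fuzzy_graph(): k must be >= 2")
  nn <- knn_table(X, k)
  rho <- numeric(n); sigma <- numeric(n); clamped <- logical(n)
  mu <- matrix(0, n, k)
  for (i in seq_len(n)) {
    cal <- smooth_knn_calibrate(nn$distances[i, ], k, tol = tol)
    rho[i] <- cal$rho; sigma[i] <- cal$sigma; clamped[i] <- cal$clamped
    mu[i, ] <- pmin(exp((cal$rho - nn$distances[i, ]) / cal$sigma), 1)
  }
  P <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.integer(t(nn$indices)),
    x = as.numeric(t(mu)),
    dims = c(n, n)
  )
  M <- P + Matrix::t(P) - P * Matrix::t(P)
  Matrix::diag(M) <- 0
  if (k >= n / 4) M <- as.matrix(M)
  new_fuzzy_graph(
    M,
    knn = nn,
    calibration = list(rho = rho, sigma = sigma, sigma_clamped = clamped),
    k = k
  )
}

#' @export
print.fuzzy_graph <- function(x, ...) {
  nnz <- if (is.matrix(x$memberships)) sum(x$memberships > 0) else
    length(x$memberships@x)
  cat("Fuzzy weighted undirected graph\n")
  cat("  objects:", x$n, "  k:", x$k, "\n")
  cat("  stored entries:", nnz,
      sprintf("(%.2f%% dense)\n", 100 * nnz / x$n^2))
  if (!is.null(x$calibration)) {
    cat("  sigma clamped rows:", sum(x$calibration$sigma_clamped), "\n")
  }
  invisible(x)
}

# dense numeric matrix view of the memberships
graph_dense <- function(graph) {
  M <- graph$memberships
  if (is.matrix(M)) M else as.matrix(M)
}

#' Export a fuzzy graph as a coordinate list
#'
#' Writes one \code{i j mu} line per stored non-zero (upper triangle only,
#' the graph being symmetric) for inspection or external graph tooling.
#'
#' @param graph A \code{fuzzy_graph}.
#' @param path Output file path.
#' @export
write_graph_coordlist <- function(graph, path) {
  M <- graph_dense(graph)
  idx <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], mu = M[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
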