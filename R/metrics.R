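#' Structure-preservation metrics for embeddings
#'
#' Quantitative counterparts of the usual visual judgement of an embedding:
#' local neighbourhood preservation (\code{\link{knn_recall}},
#' \code{\link{trustworthiness}}), global distance-rank preservation
#' (\code{\link{global_distance_spearman}}) and cluster recovery
#' (\code{\link{cluster_recovery_ari}}). All are invariant under rigid
#' transformations of the embedding.
#'
#' @name fumap-metrics
NULL

knn_sets <- function(X, q) {
  nn <- knn_table(X, q)
  nn$indices
}

#' Neighbourhood recall between input space and embedding
#'
#' Mean over objects of the fraction of each object's q nearest neighbours
#' in the input space that are also among its q nearest neighbours in the
#' embedding.
#'
#' @param X Input observation matrix.
#' @param Y Embedding matrix with the same number of rows.
#' @param q Neighbourhood size, \code{1 <= q < n}.
#' @return A number in [0, 1].
#' @export
knn_recall <- function(X, Y, q = 15L) {
  n <- nrow(X)
  if (nrow(Y) != n) stop("knn_recall(): row counts differ")
  q <- as.integer(q)
  if (q < 1 || q >= n) stop("knn_recall(): q must be in [1, n-1]")
  hi <- knn_sets(X, q)
  lo <- knn_sets(Y, q)
  mean(vapply(seq_len(n),
              function(i) length(intersect(hi[i, ], lo[i, ])) / q,
              numeric(1)))
}

#' Trustworthiness of an embedding
#'
#' Penalizes intrusions: points that are among the q nearest neighbours in
#' the embedding but not in the input space, weighted by how far down the
#' input-space ranking they sit. 1 means no intrusions.
#'
#' @inheritParams knn_recall
#' @return A number in [0, 1].
#' @export
trustworthiness <- function(X, Y, q = 15L) {
  n <- nrow(X)
  if (nrow(Y) != n) stop("trustworthiness(): row counts differ")
  q <- as.integer(q)
  if (q < 1 || q > (n - 2) / 2) {
    stop("trustworthiness(): q must satisfy 1 <= q <= (n-2)/2")
  }
  DX <- as.matrix(stats::dist(X))
  lo <- knn_sets(Y, q)
  penalty <- 0
  for (i in seq_len(n)) {
    d <- DX[i, ]; d[i] <- Inf
    rank_in_X <- rank(d, ties.method = "first")
    r <- rank_in_X[lo[i, ]]
    penalty <- penalty + sum(pmax(r - q, 0))
  }
  1 - 2 / (n * q * (2 * n - 3 * q - 1)) * penalty
}

#' Global distance rank correlation
#'
#' Spearman correlation between input-space and embedding distances over a
#' seeded sample of object pairs (all pairs when \code{pair_sample} covers
#' them). Operationalizes "global structure preservation" as the
#' preservation of the distance ranking.
#'
#' @inheritParams knn_recall
#' @param pair_sample Number of pairs to sample.
#' @param seed Integer seed for the pair sample.
#' @return A number in [-1, 1].
#' @export
global_distance_spearman <- function(X, Y, pair_sample = 10000L, seed = 0L) {
  n <- nrow(X)
  if (nrow(Y) != n) stop("global_distance_spearman(): row counts differ")
  if (pair_sample < 2) stop("global_distance_spearman(): pair_sample must be >= 2")
  npairs <- n * (n - 1) / 2
  if (pair_sample >= npairs) {
    dx <- as.numeric(stats::dist(X))
    dy <- as.numeric(stats::dist(Y))
  } else {
    sel <- with_seed(seed, sample.int(npairs, pair_sample))
    # map linear pair index (column-major lower triangle of dist) to (i, j)
    DX <- as.matrix(stats::dist(X)); DY <- as.matrix(stats::dist(Y))
    pairs <- which(lower.tri(DX))[sel]
    dx <- DX[pairs]; dy <- DY[pairs]
  }
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
    stop("global_distance_spearman(): degenerate (constant) distances")
  }
  stats::cor(dx, dy, method = "spearman")
}

#' Cluster recovery in the embedding
#'
#' Adjusted Rand index between supplied generating labels and a k-means
#' partition of the embedding (seeded, multiple restarts, best inertia
#' kept). Scores how well the embedding separates the generating clusters.
#'
#' @param Y Embedding matrix.
#' @param labels Integer label vector, one per row of \code{Y}.
#' @param n_clusters Number of clusters to fit (>= 2); defaults to the
#'   number of distinct labels.
#' @param seed Integer seed.
#' @param restarts k-means restarts.
#' @return The adjusted Rand index, in [-1, 1].
#' @export
cluster_recovery_ari <- function(Y, labels, n_clusters = length(unique(labels)),
                                 seed = 0L, restarts = 10L) {
  if (length(labels) != nrow(Y)) stop("cluster_recovery_ari(): label length mismatch")
  if (n_clusters < 2) stop("cluster_recovery_ari(): n_clusters must be >= 2")
  km <- with_seed(seed,
                  stats::kmeans(Y, centers = n_clusters, nstart = restarts,
                                iter.max = 100L))
  mclust::adjustedRandIndex(km$cluster, labels)
}

#' Full metric report for an embedding
#'
#' @param X Input observation matrix.
#' @param Y Embedding.
#' @param labels Optional generating labels for the ARI.
#' @param q Neighbourhood size for the local metrics.
#' @param pair_sample,seed Pair-sampling controls for the global metric.
#' @return A named list with \code{trustworthiness}, \code{knn_recall},
#'   \code{global_distance_spearman}, optionally
#'   \code{cluster_recovery_ari}, and \code{q}.
#' @export
metric_report <- function(X, Y, labels = NULL, q = 15L,
                          pair_sample = 10000L, seed = 0L) {
  out <- list(
    trustworthiness = trustworthiness(X, Y, q),
    knn_recall = knn_recall(X, Y, q),
    global_distance_spearman = global_distance_spearman(X, Y, pair_sample, seed),
    q = as.integer(q)
  )
  if (!is.null(labels)) {
    out$cluster_recovery_ari <- cluster_recovery_ari(Y, labels, seed = seed)
  }
  out
}
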