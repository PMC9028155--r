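#' Fit a fuzzy cross-entropy low-dimensional embedding
#'
#' The main entry point: builds the fuzzy weighted k-NN graph of \code{X},
#' fits the low-dimensional similarity curve for \code{min_dist}, and
#' minimizes the selected fuzzy information-discrimination loss with
#' full-batch Adam from a spectral initialization. No sampling is involved
#' anywhere: gradients are exact over all object pairs, so any
#' differentiable divergence between the fuzzy graph and the embedding
#' similarities can serve as the loss.
#'
#' The four shipped losses differ in their repulsion weighting and
#' symmetry. The reduced-repulsion loss (\code{"umap_ce"}) excels at local
#' structure with small \code{k}; the plain (\code{"fuzzy_ce"}) and
#' symmetric (\code{"symmetric_ce"}) cross entropies preserve more global
#' structure when \code{k} is large (up to \code{n - 1}).
#'
#' @param X Numeric observation matrix (n rows), or a
#'   \code{labeled_dataset}.
#' @param k Neighbour count, \code{2 <= k <= n - 1}; the string
#'   \code{"n-1"} selects the full-graph regime.
#' @param min_dist Target-space packing-density hyperparameter in (0, 1].
#' @param loss Loss id or a \code{\link{loss_spec}}.
#' @param n_components Target dimensionality (2 or 3 recommended).
#' @param n_iter Adam iteration limit (every iteration runs).
#' @param seed Integer seed (spectral-fallback initialization).
#' @param labels Optional integer labels stored for plotting/metrics
#'   (taken from \code{X} when it is a \code{labeled_dataset}).
#' @param eta,beta1,beta2,epsilon,bias_correction Adam hyperparameters.
#' @param verbose Print progress.
#' @return An object of class \code{fumap} with components
#'   \code{embedding} (n x m matrix), \code{trace} (loss per iteration,
#'   length \code{n_iter + 1}), \code{graph}, \code{curve}, \code{spec},
#'   \code{labels} and \code{call}.
#' @examples
#' ds <- make_blobs(n = 90, n_centers = 3, seed = 1)
#' fit <- fumap(ds, k = 8, n_iter = 30, seed = 1)
#' print(fit)
#' head(fit$embedding)
#' @export
fumap <- function(X, k = 10, min_dist = 0.1, loss = "umap_ce",
                  n_components = 2L, n_iter = 150L, seed = 42L,
                  labels = NULL, eta = 1, beta1 = 0.9, beta2 = 0.999,
                  epsilon = 1e-8, bias_correction = TRUE, verbose = FALSE) {
  if (inherits(X, "labeled_dataset")) {
    if (is.null(labels)) labels <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (identical(k, "n-1")) k <- n - 1L
  k <- as.integer(k)
  if (n_components > ncol(X)) {
    stop("fumap(): n_components must not exceed the input dimensionality")
  }
  spec <- as_loss_spec(loss)
  cl <- match.call()
  if (verbose) message("Building fuzzy graph (n = ", n, ", k = ", k, ")")
  graph <- build_fuzzy_graph(X, k)
  curve <- fit_ab(min_dist)
  if (verbose) {
    message(sprintf("Curve fit: a = %.4f, b = %.4f", curve$a, curve$b))
  }
  opt <- optimize_embedding(graph, curve, spec, m = n_components,
                            n_iter = n_iter, seed = seed, eta = eta,
                            beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                            bias_correction = bias_correction)
  if (verbose) {
    message(sprintf("Loss: %.4f -> %.4f over %d iterations",
                    opt$trace[1], opt$trace[length(opt$trace)], n_iter))
  }
  structure(
    list(embedding = opt$coordinates, trace = opt$trace, graph = graph,
         curve = curve, spec = spec, labels = labels, X = X,
         n_iter = as.integer(n_iter), seed = as.integer(seed), call = cl),
    class = "fumap"
  )
}

#' @export
print.fumap <- function(x, ...) {
  cat("Fuzzy cross-entropy embedding\n")
  cat("  loss:", x$spec$loss_id,
      " gradient mode:", x$spec$gradient_mode, "\n")
  cat("  n =", x$graph$n, " k =", x$graph$k,
      " min_dist =", x$curve$min_dist,
      " m =", ncol(x$embedding), "\n")
  cat(sprintf("  curve: a = %.4f, b = %.4f\n", x$curve$a, x$curve$b))
  cat(sprintf("  loss %.4f -> %.4f over %d iterations\n",
              x$trace[1], x$trace[length(x$trace)], x$n_iter))
  invisible(x)
}

#' Summarize a fitted embedding
#'
#' Reports the configuration, the loss decrease, and (computing them on
#' demand) the structure-preservation metrics against the original data.
#'
#' @param object A \code{fumap} fit.
#' @param q Neighbourhood size for the local metrics.
#' @param ... Unused.
#' @return An object of class \code{summary.fumap}.
#' @export
summary.fumap <- function(object, q = 15L, ...) {
  q <- min(q, floor((object$graph$n - 2) / 2))
  rep <- metric_report(object$X, object$embedding, labels = object$labels,
                       q = q, seed = object$seed)
  structure(list(fit = object, metrics = rep), class = "summary.fumap")
}

#' @export
print.summary.fumap <- function(x, ...) {
  print(x$fit)
  m <- x$metrics
  cat(sprintf("  trustworthiness (q=%d): %.4f\n", m$q, m$trustworthiness))
  cat(sprintf("  knn recall      (q=%d): %.4f\n", m$q, m$knn_recall))
  cat(sprintf("  global distance Spearman: %.4f\n", m$global_distance_spearman))
  if (!is.null(m$cluster_recovery_ari)) {
    cat(sprintf("  cluster recovery ARI: %.4f\n", m$cluster_recovery_ari))
  }
  invisible(x)
}

#' @export
coef.fumap <- function(object, ...) {
  c(a = object$curve$a, b = object$curve$b)
}

#' Plot a fitted embedding
#'
#' Plain 2-D scatter of the embedding, coloured by label when labels are
#' available.
#'
#' @param x A \code{fumap} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.fumap <- function(x, ...) {
  Y <- x$embedding
  col <- if (is.null(x$labels)) "black" else
    grDevices::hcl.colors(length(unique(x$labels)), "Dark 2")[
      match(x$labels, sort(unique(x$labels)))]
  graphics::plot(Y[, 1], Y[, 2], col = col, pch = 19, cex = 0.5,
                 xlab = "dim 1", ylab = "dim 2",
                 main = paste0(x$spec$loss_id, " embedding"), ...)
  invisible(x)
}
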