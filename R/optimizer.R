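# Spectral coordinates of one connected membership matrix: eigenvectors of
# the symmetric normalized Laplacian for the m smallest positive
# eigenvalues, sign-fixed (first non-zero component positive), rescaled to
# max-abs 1. Returns NULL when the decomposition cannot deliver m columns.
component_spectral <- function(M, m) {
  n <- nrow(M)
  if (n <= m) return(NULL)
  deg <- rowSums(M)
  if (any(deg <= 0)) return(NULL)
  s <- 1 / sqrt(deg)
  L <- diag(n) - (s * M) * rep(s, each = n) # I - D^-1/2 M D^-1/2, symmetric
  eig <- tryCatch(eigen(L, symmetric = TRUE), error = function(e) NULL)
  if (is.null(eig)) return(NULL)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  pos <- which(vals > 1e-8)
  if (length(pos) < m) return(NULL)
  Y <- vecs[, pos[seq_len(m)], drop = FALSE]
  for (j in seq_len(m)) {
    nz <- which(abs(Y[, j]) > 0)[1]
    if (!is.na(nz) && Y[nz, j] < 0) Y[, j] <- -Y[, j]
  }
  mx <- max(abs(Y))
  if (mx > 0) Y <- Y / mx
  Y
}

#' Spectral initialization of the embedding
#'
#' Laplacian-eigenmap start: eigenvectors of the symmetric normalized graph
#' Laplacian \code{I - D^(-1/2) M D^(-1/2)} associated with the m smallest
#' positive eigenvalues, sign-fixed (first non-zero component of each
#' eigenvector positive) and rescaled so the largest absolute coordinate is
#' 10. The result is deterministic.
#'
#' A disconnected fuzzy graph has repeated zero Laplacian eigenvalues and
#' no meaningful joint spectral ordering, so each connected component is
#' embedded spectrally on its own (rescaled to unit size) and the
#' components are placed on a coarse grid well apart from one another
#' before the global rescale --- the same strategy reference UMAP
#' implementations use. Components too small for a spectral solve, or any
#' component whose eigendecomposition fails, get a seeded uniform layout in
#' their grid cell instead, with a warning.
#'
#' @param graph A \code{fuzzy_graph}.
#' @param m Target dimensionality (2 or 3 for visualization).
#' @param seed Integer seed for the random fallback layouts.
#' @return An n x m numeric matrix.
#' @export
spectral_init <- function(graph, m = 2L, seed = 42L) {
  M <- graph_dense(graph)
  n <- nrow(M)
  m <- as.integer(m)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(M > 0, mode = "undirected")
  )
  Y <- matrix(0, n, m)
  used_fallback <- FALSE
  spacing <- 4 # component grid pitch, in units of component radius (1)
  g <- ceiling(sqrt(comp$no))
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    Sub <- M[idx, idx, drop = FALSE]
    Yc <- component_spectral(Sub, m)
    if (is.null(Yc)) {
      used_fallback <- TRUE
      Yc <- with_seed(seed + ci,
                      matrix(stats::runif(length(idx) * m, -1, 1),
                             length(idx), m))
    }
    offset <- numeric(m)
    offset[1] <- ((ci - 1) %% g) * spacing
    if (m >= 2) offset[2] <- ((ci - 1) %/% g) * spacing
    Y[idx, ] <- Yc + rep(offset, each = length(idx))
  }
  if (used_fallback) {
    warning("spectral_init(): seeded uniform layout used for ",
            "component(s) without a spectral solution", call. = FALSE)
  }
  Y <- sweep(Y, 2, colMeans(Y))
  Y * (10 / max(abs(Y)))
}

#' Create an Adam optimizer state
#'
#' Moment accumulators and hyperparameters for the full-batch Adam update.
#' Defaults follow the study conditions: step size \code{eta = 1},
#' \code{beta1 = 0.9}, \code{beta2 = 0.999}, \code{epsilon = 1e-8}.
#'
#' @param n,m Embedding dimensions.
#' @param eta Step size.
#' @param beta1,beta2 First/second moment decay rates.
#' @param epsilon Denominator stabilizer.
#' @param bias_correction Apply the canonical bias-corrected update
#'   (default); \code{FALSE} uses the raw moments, for ablation.
#' @return An object of class \code{adam_state}.
#' @export
adam_state <- function(n, m, eta = 1, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, bias_correction = TRUE) {
  structure(
    list(t = 0L, c = matrix(0, n, m), v = matrix(0, n, m),
         eta = eta, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         bias_correction = isTRUE(bias_correction)),
    class = "adam_state"
  )
}

#' One full-batch Adam step
#'
#' Updates the exponentially decayed first and second gradient moments and
#' moves the coordinates by the canonical bias-corrected Adam rule
#' \code{y <- y - eta * c_hat / (sqrt(v_hat) + epsilon)}.
#'
#' @param state An \code{adam_state}.
#' @param grad Gradient matrix, same shape as \code{current}.
#' @param current Current coordinate matrix.
#' @return A list with updated \code{state} and \code{coordinates}.
#' @export
adam_step <- function(state, grad, current) {
  if (!all(dim(grad) == dim(current))) stop("adam_step(): shape mismatch")
  if (!all(is.finite(grad))) {
    stop("adam_step(): non-finite gradient at iteration ", state$t + 1L)
  }
  state$t <- state$t + 1L
  state$c <- state$beta1 * state$c + (1 - state$beta1) * grad
  state$v <- state$v - (1 - state$beta2) * (state$v - grad^2)
  if (state$bias_correction) {
    chat <- state$c / (1 - state$beta1^state$t)
    vhat <- state$v / (1 - state$beta2^state$t)
  } else {
    chat <- state$c
    vhat <- state$v
  }
  coordinates <- current - state$eta * chat / (sqrt(vhat) + state$epsilon)
  list(state = state, coordinates = coordinates)
}

#' Optimize an embedding by full-batch Adam
#'
#' Runs \code{\link{spectral_init}} (unless a start is supplied) and exactly
#' \code{n_iter} Adam steps on the selected loss, recording the loss value
#' before the first step and after every step.
#'
#' @param graph A \code{fuzzy_graph}.
#' @param params \code{curve_params} for the low-dimensional similarity.
#' @param spec A \code{loss_spec} or loss id.
#' @param m Target dimensionality.
#' @param n_iter Iteration limit (every iteration is executed; no early
#'   stopping).
#' @param seed Seed for the initialization fallback.
#' @param init Optional n x m start matrix overriding the spectral start.
#' @param eta,beta1,beta2,epsilon,bias_correction Adam hyperparameters, see
#'   \code{\link{adam_state}}.
#' @return A list with \code{coordinates} (n x m), \code{trace} (numeric,
#'   length \code{n_iter + 1}) and the final \code{state}.
#' @export
optimize_embedding <- function(graph, params, spec = "umap_ce", m = 2L,
                               n_iter = 150L, seed = 42L, init = NULL,
                               eta = 1, beta1 = 0.9, beta2 = 0.999,
                               epsilon = 1e-8, bias_correction = TRUE) {
  spec <- as_loss_spec(spec)
  n_iter <- as.integer(n_iter)
  if (n_iter < 0) stop("optimize_embedding(): n_iter must be >= 0")
  Y <- if (is.null(init)) spectral_init(graph, m, seed) else as.matrix(init)
  if (nrow(Y) != graph$n) stop("optimize_embedding(): init size mismatch")
  state <- adam_state(nrow(Y), ncol(Y), eta = eta, beta1 = beta1,
                      beta2 = beta2, epsilon = epsilon,
                      bias_correction = bias_correction)
  trace <- numeric(n_iter + 1L)
  trace[1L] <- loss_value(graph, Y, params, spec)
  if (n_iter > 0L) {
    for (it in seq_len(n_iter)) {
      g <- fuzzy_gradient(graph, Y, params, spec)
      upd <- adam_step(state, g, Y)
      state <- upd$state
      Y <- upd$coordinates
      trace[it + 1L] <- loss_value(graph, Y, params, spec)
    }
  }
  list(coordinates = Y, trace = trace, state = state)
}
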