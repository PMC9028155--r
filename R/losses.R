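#' Loss specification for embedding optimization
#'
#' Selects one of the four fuzzy information-discrimination losses and the
#' numerical conventions used when evaluating it:
#' \describe{
#'   \item{umap_ce}{weighted fuzzy cross entropy with reduced repulsion,
#'     the loss effectively optimized by the reference UMAP implementation;
#'     the repulsive weight is the row-mass term \code{w_i = sum_k(mu_ik)/(2n)}
#'     instead of \code{1 - mu_ij}.}
#'   \item{fuzzy_ce}{plain logarithmic fuzzy cross entropy.}
#'   \item{symmetric_ce}{symmetric fuzzy cross entropy,
#'     \code{(mu - nu) * log(mu (1-nu) / (nu (1-mu)))}.}
#'   \item{modified_ce}{modified fuzzy cross entropy against the mixture
#'     \code{(mu + nu) / 2}.}
#' }
#'
#' Membership values are clipped to \code{[mu_clip, 1 - mu_clip]} inside
#' logarithms and ratios only (never in the stored graph): the
#' nearest-neighbour membership is exactly 1 and non-neighbours are exactly
#' 0, so the logarithms are singular without clipping.
#'
#' \code{gradient_mode = "chain_rule"} multiplies the per-pair distance
#' derivative by \code{(y_i - y_j) / d_ij}, the correct differential of the
#' Euclidean distance; \code{"paper_literal"} omits the \code{1/d_ij} factor
#' and reproduces the printed per-coordinate assembly exactly as published.
#'
#' @param loss_id One of \code{"umap_ce"}, \code{"fuzzy_ce"},
#'   \code{"symmetric_ce"}, \code{"modified_ce"}.
#' @param mu_clip Clipping bound in (0, 0.5).
#' @param gradient_mode \code{"chain_rule"} (default) or
#'   \code{"paper_literal"}.
#' @return An object of class \code{loss_spec}.
#' @export
loss_spec <- function(loss_id = c("umap_ce", "fuzzy_ce", "symmetric_ce", "modified_ce"),
                      mu_clip = 1e-4,
                      gradient_mode = c("chain_rule", "paper_literal")) {
  loss_id <- match.arg(loss_id)
  gradient_mode <- match.arg(gradient_mode)
  if (mu_clip <= 0 || mu_clip >= 0.5) stop("loss_spec(): mu_clip must be in (0, 0.5)")
  structure(list(loss_id = loss_id, mu_clip = mu_clip,
                 gradient_mode = gradient_mode),
            class = "loss_spec")
}

as_loss_spec <- function(spec) {
  if (inherits(spec, "loss_spec")) spec else loss_spec(spec)
}

# Pairwise distance matrix of the embedding with the degenerate-distance
# floor applied off-diagonal.
embedding_distances <- function(Y, floor = 1e-8) {
  D <- as.matrix(stats::dist(Y))
  D[D < floor] <- floor
  diag(D) <- 0
  D
}

# Shared per-pair quantities. All matrices n x n, diagonal meaningless.
pair_quantities <- function(graph, Y, params, spec) {
  Mu <- graph_dense(graph)
  n <- nrow(Mu)
  if (nrow(Y) != n) stop("losses: graph and embedding sizes differ")
  D <- embedding_distances(Y)
  Df <- D; diag(Df) <- 1 # placeholder to keep powers finite on the diagonal
  t_ <- params$a * Df^(2 * params$b)
  V <- 1 / (1 + t_)
  eps <- spec$mu_clip
  Mc <- pmin(pmax(Mu, eps), 1 - eps)
  list(Mu = Mu, Mc = Mc, D = Df, t = t_, V = V, n = n,
       logV = -log1p(t_), log1mV = log(t_) - log1p(t_))
}

#' Evaluate a fuzzy information-discrimination loss
#'
#' Computes the selected divergence between the fuzzy graph memberships mu
#' and the low-dimensional similarities \code{nu = 1/(1 + a d^(2b))}, summed
#' over all ordered pairs i != j. The plain, symmetric and modified cross
#' entropies are non-negative and vanish iff mu = nu on the clipped domain;
#' the reduced-repulsion loss is not bounded below by zero.
#'
#' @param graph A \code{fuzzy_graph}.
#' @param Y Numeric n x m embedding matrix.
#' @param params \code{curve_params} from \code{\link{fit_ab}}.
#' @param spec A \code{loss_spec} or a loss id string.
#' @return A single finite number.
#' @export
loss_value <- function(graph, Y, params, spec = "umap_ce") {
  spec <- as_loss_spec(spec)
  q <- pair_quantities(graph, Y, params, spec)
  Mu <- q$Mu; Mc <- q$Mc; V <- q$V
  term <- switch(spec$loss_id,
    umap_ce = {
      W <- matrix(graph$repulsion_weights, q$n, q$n)
      Mu * (log(Mc) - q$logV) + W * (log(1 - Mc) - q$log1mV)
    },
    fuzzy_ce =
      Mu * (log(Mc) - q$logV) + (1 - Mu) * (log(1 - Mc) - q$log1mV),
    symmetric_ce =
      (Mu - V) * (log(Mc) - log(1 - Mc) + q$log1mV - q$logV),
    modified_ce =
      Mu * (log(Mc) - log((Mc + V) / 2)) +
        (1 - Mu) * (log(1 - Mc) - log(((1 - Mc) + q$t * V) / 2))
  )
  diag(term) <- 0
  out <- sum(term)
  if (!is.finite(out)) {
    bad <- which(!is.finite(term), arr.ind = TRUE)[1, ]
    stop("loss_value(): non-finite contribution at pair (", bad[1], ", ", bad[2], ")")
  }
  out
}

# Matrix of per-ordered-pair derivatives d(loss_ij)/d(d_ij).
# Row i of the umap_ce coefficient uses that row's repulsion weight w_i.
pair_grad_coeff <- function(graph, Y, params, spec) {
  q <- pair_quantities(graph, Y, params, spec)
  Mu <- q$Mu; Mc <- q$Mc; V <- q$V; t_ <- q$t; D <- q$D
  b <- params$b
  G <- 2 * b * t_ / (D * (1 + t_)) # = 2 a b d^(2b-1) / (1 + a d^(2b))
  C <- switch(spec$loss_id,
    umap_ce = {
      W <- matrix(graph$repulsion_weights, q$n, q$n)
      Mu * G - W * G / t_
    },
    fuzzy_ce = Mu * G - (1 - Mu) * G / t_,
    symmetric_ce = {
      L <- log(Mc) - log(1 - Mc) + q$log1mV - q$logV
      (2 * b / D) * (L * t_ / (1 + t_)^2 + (Mu - V))
    },
    modified_ce =
      (Mu / (Mc + V) - (1 - Mu) / ((1 - Mc) + (1 - V))) * G / (1 + t_)
  )
  diag(C) <- 0
  C
}

#' Per-pair gradient coefficient of a loss with respect to distance
#'
#' The scalar derivative of one ordered pair's loss contribution with
#' respect to the low-dimensional distance \code{d}. The full coordinate
#' gradient accumulates these over both orderings of each pair (see
#' \code{\link{fuzzy_gradient}}).
#'
#' @param mu Membership of the pair in [0, 1].
#' @param w_i Repulsion weight of the first object's row (used by
#'   \code{umap_ce} only).
#' @param d Positive low-dimensional distance.
#' @param a,b Curve coefficients.
#' @param spec Loss spec or id.
#' @return A single number.
#' @export
grad_coeff <- function(mu, w_i, d, a, b, spec = "umap_ce") {
  spec <- as_loss_spec(spec)
  if (d <= 0) stop("grad_coeff(): d must be positive")
  graph <- structure(
    list(memberships = matrix(c(0, mu, mu, 0), 2, 2),
         repulsion_weights = c(w_i, w_i), n = 2L, k = 1L),
    class = "fuzzy_graph"
  )
  params <- structure(list(a = a, b = b), class = "curve_params")
  Y <- matrix(c(0, d, 0, 0), 2, 2)
  pair_grad_coeff(graph, Y, params, spec)[1, 2]
}

#' Analytic gradient of a fuzzy loss with respect to the embedding
#'
#' Assembles the coordinate gradient from the per-pair distance derivatives.
#' Both ordered contributions of each pair are accumulated (the reduced
#' repulsion weight makes them unequal for \code{umap_ce}). In
#' \code{chain_rule} mode each term is
#' \code{coeff * (y_i - y_j) / d_ij}; in \code{paper_literal} mode the
#' \code{1/d_ij} factor is dropped, reproducing the published assembly.
#' Distances below 1e-8 are floored.
#'
#' @inheritParams loss_value
#' @return An n x m numeric matrix; row i is the partial gradient of the
#'   loss with respect to \code{y_i}. Rows sum to (numerically) zero by
#'   translation invariance of the loss.
#' @export
fuzzy_gradient <- function(graph, Y, params, spec = "umap_ce") {
  spec <- as_loss_spec(spec)
  C <- pair_grad_coeff(graph, Y, params, spec)
  E <- C + t(C)
  if (spec$gradient_mode == "chain_rule") {
    D <- embedding_distances(Y)
    diag(D) <- 1
    E <- E / D
  }
  diag(E) <- 0
  G <- rowSums(E) * Y - E %*% Y
  if (!all(is.finite(G))) stop("fuzzy_gradient(): non-finite gradient")
  G
}

#' Central-difference numerical gradient (test oracle)
#'
#' Differentiates \code{\link{loss_value}} coordinate by coordinate with
#' central differences. Used to arbitrate the analytic gradient formulas;
#' quadratic accuracy in \code{step}.
#'
#' @inheritParams loss_value
#' @param step Positive finite-difference step.
#' @return An n x m numeric matrix.
#' @export
numerical_gradient <- function(graph, Y, params, spec = "umap_ce", step = 1e-5) {
  spec <- as_loss_spec(spec)
  if (step <= 0) stop("numerical_gradient(): step must be positive")
  G <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      Yp <- Y; Yp[i, j] <- Y[i, j] + step
      Ym <- Y; Ym[i, j] <- Y[i, j] - step
      G[i, j] <- (loss_value(graph, Yp, params, spec) -
                    loss_value(graph, Ym, params, spec)) / (2 * step)
    }
  }
  G
}
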