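#' Target similarity curve for the low-dimensional space
#'
#' The plateau-then-exponential curve the smooth similarity is fitted
#' against: 1 for distances up to \code{min_dist}, then an exponential decay
#' \code{exp(min_dist - d)}. Continuous at \code{d = min_dist}.
#'
#' @param d Non-negative distance(s) in the target space.
#' @param min_dist Positive plateau width; the packing-density hyperparameter.
#' @return Values in (0, 1].
#' @export
psi_curve <- function(d, min_dist) {
  if (min_dist <= 0) stop("psi_curve(): min_dist must be positive")
  if (any(d < 0)) stop("psi_curve(): distances must be non-negative")
  ifelse(d <= min_dist, 1, exp(min_dist - d))
}

#' Smooth low-dimensional similarity
#'
#' \code{nu(d) = 1 / (1 + a * d^(2b))}: 1 at d = 0, strictly decreasing.
#'
#' @param d Non-negative distance(s).
#' @param a,b Positive curve coefficients (see \code{\link{fit_ab}}).
#' @return Values in (0, 1].
#' @export
low_dim_similarity <- function(d, a, b) {
  1 / (1 + a * d^(2 * b))
}

#' Fit the similarity-curve coefficients for a given min_dist
#'
#' Least-squares fit of the smooth curve \code{1/(1 + a d^(2b))} to the
#' plateau-exponential target \code{\link{psi_curve}} on a fixed evaluation
#' grid, via Levenberg-Marquardt from (a, b) = (1, 1). With a fixed grid and
#' fixed start the fit is deterministic.
#'
#' The default grid is 300 equally spaced points on [0, 3]: for the
#' recommended \code{min_dist} range (0, 1] both curves are essentially flat
#' beyond d = 3.
#'
#' @param min_dist Positive plateau width, must be below \code{grid_max}.
#' @param grid_max Upper end of the evaluation grid.
#' @param grid_points Number of grid points.
#' @return An object of class \code{curve_params}: list with \code{a},
#'   \code{b}, \code{min_dist} and \code{fit_rmse} (root-mean-square residual
#'   over the grid).
#' @examples
#' fit_ab(0.1)
#' @export
fit_ab <- function(min_dist, grid_max = 3, grid_points = 300L) {
  if (min_dist <= 0 || min_dist >= grid_max) {
    stop("fit_ab(): min_dist must lie in (0, grid_max)")
  }
  d <- seq(0, grid_max, length.out = grid_points)
  y <- psi_curve(d, min_dist)
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + a * d^(2 * b)),
    start = list(a = 1, b = 1),
    lower = c(1e-6, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) stop("fit_ab(): curve fit failed to converge")
  rmse <- sqrt(mean(stats::resid(fit)^2))
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]),
         min_dist = min_dist, fit_rmse = rmse),
    class = "curve_params"
  )
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("Similarity curve for min_dist = %g: a = %.6f, b = %.6f (fit RMSE %.2e)\n",
              x$min_dist, x$a, x$b, x$fit_rmse))
  invisible(x)
}
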