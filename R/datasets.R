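#' Synthetic and bundled benchmark datasets
#'
#' Generators for the three 2-D benchmark shapes used throughout the package
#' (Gaussian blobs, interleaved half moons, concentric circles) and a loader
#' for the bundled 8x8 handwritten-digits set. Each returns a
#' \code{labeled_dataset}: a list with numeric matrix \code{X}, integer
#' \code{labels} starting at 0, and a \code{name}.
#'
#' @name fumap-datasets
NULL

new_labeled_dataset <- function(X, labels, name) {
  structure(list(X = X, labels = as.integer(labels), name = name),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset '%s'> %d observations x %d features, %d classes\n",
              x$name, nrow(x$X), ncol(x$X), length(unique(x$labels))))
  invisible(x)
}

#' Isotropic Gaussian blobs
#'
#' Unit-variance isotropic Gaussian clusters with centers drawn uniformly in
#' \code{[-10, 10]^2}; points are assigned to clusters round-robin so class
#' counts differ by at most one.
#'
#' @param n Total number of points.
#' @param n_centers Number of clusters.
#' @param seed Integer seed.
#' @return A \code{labeled_dataset}.
#' @export
make_blobs <- function(n = 1500L, n_centers = 3L, seed = 0L) {
  if (n < n_centers) stop("make_blobs(): n must be >= n_centers")
  with_seed(seed, {
    centers <- matrix(stats::runif(2 * n_centers, -10, 10), n_centers, 2)
    labels <- rep_len(seq_len(n_centers) - 1L, n)
    X <- centers[labels + 1L, , drop = FALSE] + matrix(stats::rnorm(2 * n), n, 2)
    new_labeled_dataset(X, labels, "blobs")
  })
}

#' Two interleaved half moons
#'
#' The conventional construction: the upper arc of the unit circle and a
#' lower arc shifted by (1, -0.5), each sampled at equally spaced angles,
#' plus isotropic Gaussian noise.
#'
#' @param n Total number of points (split evenly, odd n gives the first moon
#'   one extra point).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A \code{labeled_dataset}.
#' @export
make_moons <- function(n = 1500L, noise_sd = 0.05, seed = 0L) {
  if (noise_sd < 0) stop("make_moons(): noise_sd must be >= 0")
  n1 <- ceiling(n / 2); n2 <- n - n1
  t1 <- seq(0, pi, length.out = n1)
  t2 <- seq(0, pi, length.out = n2)
  X <- rbind(
    cbind(cos(t1), sin(t1)),
    cbind(1 - cos(t2), 0.5 - sin(t2))
  )
  labels <- c(rep(0L, n1), rep(1L, n2))
  with_seed(seed, {
    X <- X + matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
    new_labeled_dataset(X, labels, "moons")
  })
}

#' Two concentric circles
#'
#' Outer circle of unit radius and inner circle of radius
#' \code{radius_ratio}, sampled at equally spaced angles, plus isotropic
#' Gaussian noise.
#'
#' @param n Total number of points.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param radius_ratio Inner/outer radius ratio in (0, 1).
#' @param seed Integer seed.
#' @return A \code{labeled_dataset}.
#' @export
make_circles <- function(n = 1500L, noise_sd = 0.05, radius_ratio = 0.5,
                         seed = 0L) {
  if (noise_sd < 0) stop("make_circles(): noise_sd must be >= 0")
  if (radius_ratio <= 0 || radius_ratio >= 1) {
    stop("make_circles(): radius_ratio must be in (0, 1)")
  }
  n1 <- ceiling(n / 2); n2 <- n - n1
  t1 <- seq(0, 2 * pi, length.out = n1 + 1L)[-(n1 + 1L)]
  t2 <- seq(0, 2 * pi, length.out = n2 + 1L)[-(n2 + 1L)]
  X <- rbind(
    cbind(cos(t1), sin(t1)),
    radius_ratio * cbind(cos(t2), sin(t2))
  )
  labels <- c(rep(0L, n1), rep(1L, n2))
  with_seed(seed, {
    X <- X + matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
    new_labeled_dataset(X, labels, "circles")
  })
}

#' Load the bundled 8x8 handwritten-digits dataset
#'
#' 1797 grey-scale 8x8 digit images flattened to 64 integer features in
#' [0, 16], with class labels 0-9. Shipped as plain-text resources inside
#' the package (one character per pixel, base-17 encoded).
#'
#' @param path Optional path to a CSV fallback (64 feature columns followed
#'   by a label column, no header) used instead of the bundled resource.
#' @return A \code{labeled_dataset}.
#' @export
load_digits <- function(path = NULL) {
  if (is.null(path)) {
    files <- system.file("extdata",
                         paste0("digits-", 1:3, ".txt"),
                         package = "fumap")
    if (any(files == "")) {
      stop("load_digits(): bundled digits resource not found; ",
           "pass a CSV file via 'path' (64 feature columns + label column)")
    }
    lines <- unlist(lapply(files, readLines))
    chars <- do.call(rbind, strsplit(lines, ""))
    decode <- function(ch) ifelse(ch == "g", 16L, strtoi(ch, base = 16L))
    X <- matrix(decode(chars[, 1:64]), nrow = length(lines), ncol = 64)
    labels <- as.integer(chars[, 65])
  } else {
    tab <- utils::read.csv(path, header = FALSE)
    X <- as.matrix(tab[, 1:64])
    labels <- as.integer(tab[[65]])
  }
  new_labeled_dataset(X, labels, "digits")
}

#' Subsample a labeled dataset
#'
#' Uniform without-replacement row sample, carrying labels along.
#'
#' @param ds A \code{labeled_dataset}.
#' @param size Sample size, \code{<= nrow(ds$X)}.
#' @param seed Integer seed.
#' @return A \code{labeled_dataset}.
#' @export
subsample <- function(ds, size, seed = 0L) {
  n <- nrow(ds$X)
  if (size > n) stop("subsample(): size exceeds dataset size")
  with_seed(seed, {
    idx <- sample.int(n, size)
    new_labeled_dataset(ds$X[idx, , drop = FALSE], ds$labels[idx], ds$name)
  })
}
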