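test_that("every loss vanishes when the embedding similarities equal the memberships", {
  set.seed(3)
  Y <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(Y))
  V <- low_dim_similarity(D, default_curve$a, default_curve$b)
  diag(V) <- 0
  g <- graph_from_matrix(V)
  for (id in all_losses) {
    expect_equal(loss_value(g, Y, default_curve, id), 0, tolerance = 1e-10)
  }
})

test_that("fuzzy cross entropy reproduces the hand-computed single-pair value", {
  # mu = 0.75 against nu = 0.5 (a = b = 1, d = 1), two ordered pairs
  params <- structure(list(a = 1, b = 1, min_dist = NA), class = "curve_params")
  g <- graph_from_matrix(matrix(c(0, 0.75, 0.75, 0), 2, 2))
  Y <- matrix(c(0, 1, 0, 0), 2, 2)
  expected <- 2 * (0.75 * log(1.5) + 0.25 * log(0.5))
  expect_equal(loss_value(g, Y, params, "fuzzy_ce"), expected, tolerance = 1e-12)
})

test_that("the symmetric loss is invariant to swapping the two fuzzy sets", {
  set.seed(8)
  Y <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(Y))
  V <- low_dim_similarity(D, default_curve$a, default_curve$b); diag(V) <- 0
  Mu <- as.matrix(random_membership_graph(6, 81)$memberships)
  # evaluate (mu || nu) via the API, and (nu || mu) by using V as memberships
  # of a graph scored against an embedding whose similarities equal Mu: the
  # per-pair formula is symmetric, so compare term sums directly
  f <- function(M, N) sum((M - N) * log((M * (1 - N)) / (N * (1 - M))), na.rm = TRUE)
  eps <- 1e-4
  Mc <- pmin(pmax(Mu, eps), 1 - eps); Vc <- pmin(pmax(V, eps), 1 - eps)
  off <- !diag(6)
  expect_equal(f(Mc[off], Vc[off]), f(Vc[off], Mc[off]), tolerance = 1e-10)
})

test_that("plain, symmetric and modified losses are non-negative; reduced repulsion is not", {
  set.seed(14)
  for (rep in 1:5) {
    g <- random_membership_graph(8, 100 + rep)
    Y <- matrix(rnorm(16), 8, 2)
    expect_gte(loss_value(g, Y, default_curve, "fuzzy_ce"), 0)
    expect_gte(loss_value(g, Y, default_curve, "symmetric_ce"), 0)
    expect_gte(loss_value(g, Y, default_curve, "modified_ce"), 0)
  }
  # spread the points far apart: nu ~ 0, attraction dominates and the
  # reduced-repulsion loss can descend below zero after optimization, so it
  # is not a divergence; here we just confirm it is unconstrained in sign
  # by evaluating at a configuration where it goes negative.
  g <- graph_from_matrix(matrix(c(0, 1e-3, 1e-3, 0), 2, 2))
  Y <- matrix(c(0, 0.01, 0, 0), 2, 2)
  expect_lt(loss_value(g, Y, default_curve, "umap_ce"), 0)
})

test_that("per-pair gradient coefficients match 1-D numerical derivatives", {
  set.seed(4)
  for (rep in 1:10) {
    mu <- runif(1, 0.05, 0.95)
    w <- runif(1, 0.01, 0.4)
    d <- runif(1, 0.3, 3)
    for (id in all_losses) {
      g <- graph_from_matrix(matrix(c(0, mu, mu, 0), 2, 2))
      g$repulsion_weights <- c(w, w)
      params <- default_curve
      f <- function(dd) loss_value(g, matrix(c(0, dd, 0, 0), 2, 2), params, id)
      h <- 1e-6
      num <- (f(d + h) - f(d - h)) / (2 * h)
      ana <- 2 * grad_coeff(mu, w, d, params$a, params$b, id) # two ordered pairs
      expect_equal(ana, num, tolerance = 1e-5)
    }
  }
})

test_that("at mu = 0 the reduced-repulsion coefficient is pure repulsion", {
  a <- default_curve$a; b <- default_curve$b
  d <- 1.3; w <- 0.2
  coeff <- grad_coeff(0, w, d, a, b, "umap_ce")
  t_ <- a * d^(2 * b)
  expect_equal(coeff, -w * 2 * b / (d * (1 + t_)), tolerance = 1e-12)
})

test_that("mu = nu is not a stationary pair for the reduced-repulsion loss", {
  a <- default_curve$a; b <- default_curve$b
  d <- 1.1
  nu <- low_dim_similarity(d, a, b)
  c_umap <- grad_coeff(nu, 0.1, d, a, b, "umap_ce")     # w_i != 1 - mu
  c_fuzzy <- grad_coeff(nu, 0.1, d, a, b, "fuzzy_ce")
  expect_equal(c_fuzzy, 0, tolerance = 1e-10)           # true fixed point
  expect_gt(abs(c_umap), 1e-3)                          # reduced repulsion breaks it
})

test_that("analytic chain-rule gradients agree with the central-difference oracle", {
  for (s in 1:3) {
    g <- random_membership_graph(12, 40 + s)
    set.seed(40 + s)
    Y <- matrix(rnorm(24), 12, 2)
    for (id in all_losses) {
      ga <- fuzzy_gradient(g, Y, default_curve, loss_spec(id))
      gn <- numerical_gradient(g, Y, default_curve, loss_spec(id))
      expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-4)
    }
  }
})

test_that("losses are translation invariant and gradient rows sum to zero", {
  g <- random_membership_graph(10, 77)
  set.seed(77)
  Y <- matrix(rnorm(20), 10, 2)
  shift <- matrix(rep(c(3.2, -1.7), each = 10), 10, 2)
  for (id in all_losses) {
    expect_equal(loss_value(g, Y, default_curve, id),
                 loss_value(g, Y + shift, default_curve, id),
                 tolerance = 1e-9)
    grad <- fuzzy_gradient(g, Y, default_curve, id)
    expect_lt(max(abs(colSums(grad))), 1e-8 * max(abs(grad)))
  }
})

test_that("paper-literal mode differs from chain rule by exactly 1/d per pair", {
  # a single pair isolates one distance: literal = chain * d
  g <- graph_from_matrix(matrix(c(0, 0.6, 0.6, 0), 2, 2))
  for (d in c(0.5, 2.5)) {
    Y <- matrix(c(0, d, 0, 0), 2, 2)
    for (id in all_losses) {
      gc <- fuzzy_gradient(g, Y, default_curve, loss_spec(id, gradient_mode = "chain_rule"))
      gl <- fuzzy_gradient(g, Y, default_curve, loss_spec(id, gradient_mode = "paper_literal"))
      expect_equal(gl, gc * d, tolerance = 1e-10)
    }
  }
})

test_that("the chain-rule reduced-repulsion gradient matches the reference force form", {
  # attractive descent force per pair: -2ab d^(2(b-1))/(1 + a d^(2b)) (y_i - y_j),
  # weighted by mu; repulsive: +2b/(d^2 (1 + a d^(2b))) (y_i - y_j), weighted by w_i
  a <- default_curve$a; b <- default_curve$b
  mu <- 0.8; w <- 0.15; d <- 1.7
  t_ <- a * d^(2 * b)
  attr_force <- mu * 2 * a * b * d^(2 * (b - 1)) / (1 + t_)
  rep_force <- w * 2 * b / (d^2 * (1 + t_))
  expect_equal(grad_coeff(mu, w, d, a, b, "umap_ce") / d, # chain-rule per-coordinate weight
               attr_force - rep_force, tolerance = 1e-12)
})

test_that("gradients stay finite under the degenerate-distance guard", {
  g <- graph_from_matrix(matrix(c(0, 0.9, 0.9, 0), 2, 2))
  Y <- matrix(c(0, 0, 0, 0), 2, 2) # coincident points
  for (id in all_losses) {
    expect_true(all(is.finite(fuzzy_gradient(g, Y, default_curve, id))))
    expect_true(is.finite(loss_value(g, Y, default_curve, id)))
  }
})

test_that("the numerical oracle itself is exact on a quadratic", {
  # loss restricted to one coordinate is smooth; check the oracle machinery
  # on f(Y) = sum(Y^2) via a fake graph of zeros is not expressible, so use
  # a tiny instance and compare two step sizes for quadratic convergence
  g <- random_membership_graph(6, 55)
  set.seed(55)
  Y <- matrix(rnorm(12), 6, 2)
  ga <- fuzzy_gradient(g, Y, default_curve, "fuzzy_ce")
  e1 <- max(abs(numerical_gradient(g, Y, default_curve, "fuzzy_ce", step = 1e-2) - ga))
  e2 <- max(abs(numerical_gradient(g, Y, default_curve, "fuzzy_ce", step = 1e-3) - ga))
  expect_lt(e2, e1 / 20) # O(step^2) contraction (100x up to roundoff)
})

test_that("loss specs validate their arguments", {
  expect_error(loss_spec("umap_ce", mu_clip = 0), "mu_clip")
  expect_error(loss_spec("nope"), "arg")
  expect_error(grad_coeff(0.5, 0.1, -1, 1, 1), "positive")
})
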