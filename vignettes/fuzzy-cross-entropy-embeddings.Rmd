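---
title: "Fuzzy cross-entropy embeddings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy cross-entropy embeddings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`fumap` embeds an $n \times h$ observation matrix $X$ into $\mathbb{R}^m$
(usually $m = 2$) in two phases.

**Phase 1 — fuzzy graph.** For each observation the exact $k$ nearest
neighbours are found under the Euclidean metric (ties broken by ascending
row index; an observation is never its own neighbour). With
$\rho_i = \min_l d_{il}$, a per-row bandwidth $\sigma_i$ is calibrated by
bisection so that

$$\sum_{l=1}^{k} \exp\!\big((\rho_i - d_{il})/\sigma_i\big) = \log_2 k ,$$

after which memberships $\mu_{ij} = \exp((\rho_i - d_{ij})/\sigma_i)$ are
assigned to neighbours (zero elsewhere) and symmetrized with the
probabilistic t-conorm $\mu_{ij} + \mu_{ji} - \mu_{ij}\mu_{ji}$. The
nearest neighbour of every row has $\mu = 1$ exactly, and 1 is absorbing
under the t-conorm, so every row of the symmetric graph attains 1. The
left side of the calibration equation is monotone in $\sigma$ and ranges
from the number of $\rho$-ties up to $k$; when the tie count already
reaches $\log_2 k$ (degenerate all-ties rows) no root exists and
$\sigma$ is clamped to $10^{-3} \times \mathrm{mean}(d_{i\cdot})$, with a
flag recording the clamp.

**Phase 2 — embedding.** Low-dimensional similarities are
$\nu_{ij} = (1 + a d_{ij}^{2b})^{-1}$, with $(a, b)$ fitted once per run
by least squares against the plateau-exponential target
$\psi(d) = 1$ for $d \le d_{\min}$, $e^{d_{\min} - d}$ otherwise. One of
four divergences between the fuzzy sets $\mu$ and $\nu$ (see the README
table) is then minimized over the coordinates by full-batch Adam. No
sampling is used anywhere: every gradient is exact over all ordered pairs,
which is what makes the loss pluggable — any differentiable divergence of
$(\mu, \nu)$ can be dropped in.

The gradients are analytic. Each loss contributes, per ordered pair, a
scalar $\partial \ell_{ij} / \partial d_{ij}$ (`grad_coeff()`), assembled
into coordinates as
$\sum_{j \ne i} (c_{ij} + c_{ji}) \, (y_i - y_j)/d_{ij}$; both orderings
matter because the reduced-repulsion loss weights repulsion by the row
mass $w_i = \sum_k \mu_{ik}/(2n)$, which differs between the two
directions of a pair. A central-difference oracle
(`numerical_gradient()`) is shipped and tested against every loss.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | neighbour count; `"n-1"` gives the full graph. Small `k` favours local structure, large `k` global structure. |
| `min_dist` | 0.1 | plateau width of the target curve, in target-space distance units; recommended range (0, 1]. Smaller values pack clusters more densely. |
| `loss` | `"umap_ce"` | divergence minimized; see README. |
| `n_iter` | 150 | Adam iteration limit; every iteration runs (no early stopping). |
| `eta, beta1, beta2, epsilon` | 1, 0.9, 0.999, 1e-8 | Adam step size, moment decays, stabilizer. |
| `mu_clip` | 1e-4 | clipping bound applied to $\mu$ inside logarithms only. |
| `gradient_mode` | `"chain_rule"` | see "Design choices". |

# Numerical choices

* **Membership clipping.** After symmetrization $\mu = 1$ (nearest
  neighbours) and $\mu = 0$ (non-neighbours) occur exactly, so
  $\ln(1-\mu)$ and $\ln \mu$ are singular. $\mu$ is clipped to
  $[10^{-4}, 1 - 10^{-4}]$ inside logarithm and ratio evaluations only;
  the stored graph is never modified. Factors multiplying those
  logarithms keep the unclipped value, so terms with $\mu \in \{0, 1\}$
  vanish exactly where they should.
* **Degenerate distances.** Pairwise target-space distances below
  $10^{-8}$ are floored at $10^{-8}$, keeping $\ln(1-\nu)$ and the
  repulsive coefficients finite for coincident points. $\ln(1-\nu)$ is
  evaluated as $\ln t - \ln(1+t)$ with $t = a d^{2b}$, which avoids the
  catastrophic cancellation of computing $1 - \nu$ near $\nu = 1$.
* **$\sigma$ search.** Geometric bracket expansion from 1.0 followed by
  up to 64 bisections, stopping when the membership-mass residual is
  $\le 10^{-5}$. The floor $10^{-3} \times$ mean row distance handles
  all-ties rows; the `clamped` flag makes the fallback observable.
* **Curve fit.** Levenberg–Marquardt (via minpack.lm) from
  $(a, b) = (1, 1)$, iteration cap 200, on a fixed grid of 300 equally
  spaced points on $[0, 3]$: both curves are essentially flat beyond
  $d = 3$ for the recommended $d_{\min}$ range, so widening the grid only
  dilutes the fit with zeros. Fixed grid + fixed start makes the fit
  deterministic. The tests compare it against an independent Nelder–Mead
  minimizer of the same objective.
* **k-NN determinism.** Brute-force exact search with stable radix
  ordering; at the scales this package targets ($n \le$ a few thousand)
  exact search costs little and removes a stochastic dependency. The
  neighbour table is a plain interface, so an approximate backend could
  replace it without touching anything downstream.
* **Storage.** The graph is sparse (`Matrix`) when $k < n/4$ and dense
  otherwise — the $k = n-1$ regime fills the matrix anyway.

# Design choices where the design was open

**Gradient assembly.** Published per-coordinate assemblies of this family
multiply $\partial \ell / \partial d_{ij}$ directly by $(y_i - y_j)$,
omitting the $1/d_{ij}$ factor that the differential of the Euclidean
distance carries. The chain-rule form is the default here because the
central-difference oracle confirms it (relative agreement $\sim 10^{-8}$
in the tests), and because the classical attractive/repulsive force
expressions with their $d^{2(b-1)}$ dependence are consistent with it.
`gradient_mode = "paper_literal"` retains the printed form — the two
differ per pair by exactly a factor $d_{ij}$, which a test pins down.

**Adam update.** The canonical bias-corrected update
$y \leftarrow y - \eta\, \hat c / (\sqrt{\hat v} + \epsilon)$ is
implemented. Compact pseudocode renderings of Adam sometimes drop the
previous iterate, the square root and the bias correction from the
update line; such a rule is not a consistent iteration (it discards the
current position entirely), so the canonical rule of the original Adam
formulation is used, with `bias_correction = FALSE` available for
ablation.

**Modified cross entropy gradient.** The per-term derivative fractions of
the attractive and repulsive parts are kept separate (each with its own
denominator) rather than collapsed into a single combined expression;
the combined closed form in circulation drops those denominators. The
numerical oracle arbitrates, not an assumed intent.

**Spectral initialization of disconnected graphs.** With moderate `k` on
clustered data the fuzzy graph is routinely disconnected, and a
disconnected Laplacian has no meaningful joint spectral ordering. Each
connected component is therefore embedded spectrally on its own
(symmetric normalized Laplacian, $m$ smallest positive eigenvalues,
sign-fixed, rescaled to unit size) and components are placed on a coarse
grid four component-radii apart before a global rescale to max-abs 10 —
the same strategy reference implementations use. A seeded uniform layout
is kept as the fallback for components too small for a spectral solve or
failed decompositions, and it warns. A fully random layout for any
disconnected graph was considered and rejected: it throws away the
initialization structure exactly in the common case, and measurably
degrades cluster recovery on the two-cluster benchmarks.

**Initialization scale.** Spectral coordinates are rescaled to maximum
absolute value 10 so that unit Adam steps ($\eta = 1$) are meaningful
relative to coordinate magnitudes.

# The synthetic generators

`make_blobs` (isotropic unit-variance Gaussians, centers uniform in
$[-10, 10]^2$, round-robin assignment, 3 centers by default),
`make_moons` (two interleaved unit half-circles, lower arc shifted by
$(1, -0.5)$, Gaussian noise sd 0.05 by default) and `make_circles`
(concentric circles, radius ratio 0.5, noise 0.05) emulate the standard
2-D benchmark suite at its standard size of 1500 points; the bundled
digits set (1797 images, 64 integer features in $[0, 16]$) provides a
genuinely high-dimensional case. What they do **not** emulate: unequal
cluster sizes, anisotropic or heavy-tailed noise, missing values, or the
count statistics of, say, expression data. Passing tests on these
generators shows the pipeline preserves the structure they contain —
compact clusters, one-dimensional manifolds, nested shapes — and nothing
more.

# Problem sizes in the tests

The test suite and the acceptance script keep inputs small by design:
gradient checks on $n = 15$ instances, graph invariants on $n \le 100$
fixtures, end-to-end runs on 300-point datasets with 150 iterations, and
one 1500-point graph-construction check. These sizes were chosen so the
full pipeline, including the $O(n^2)$ full-batch gradients, runs
comfortably on a single CPU while still exercising every regime
(sparse and dense graphs, connected and disconnected, 2-D and 64-D
input).

# Known limitations

* Full-batch gradients are $O(n^2 m)$ per iteration; beyond
  $n \sim 10^4$ a sampling scheme (deliberately out of scope) would be
  needed.
* Only the Euclidean input metric is shipped, behind a `metric` argument
  ready for extension.
* There is no out-of-sample `predict`: the model is transductive, as is
  usual for this family.
* The reduced-repulsion loss is not a divergence (it is unbounded
  below), so its trace values are comparable within a run but not across
  datasets.
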