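# fumap

Fuzzy cross-entropy losses for UMAP-style low-dimensional embedding, in R.

## The problem

High-dimensional data — image features, single-cell expression profiles,
any table with tens to thousands of columns — can only be inspected
visually after being mapped to two or three dimensions. UMAP-style
manifold learning does this in two phases. First it summarizes the data as
a **fuzzy weighted neighbour graph**: for each observation `x_i` the
distances to its `k` nearest neighbours are converted to membership
strengths

```
mu_ij = exp((rho_i - d_ij) / sigma_i)
```

where `rho_i` is the distance to the nearest neighbour and `sigma_i` is
calibrated per observation so that the total membership mass equals
`log2(k)`; the directed memberships are then symmetrized with the
probabilistic t-conorm `mu + mu' - mu*mu'`. Second, it positions points
`y_i` in the plane so that the smooth low-dimensional similarity

```
nu_ij = 1 / (1 + a * d_ij^(2b))
```

(`a`, `b` least-squares–fitted to a plateau-then-exponential target curve
controlled by `min_dist`) matches the graph memberships, by minimizing a
divergence between the fuzzy sets `mu` and `nu`.

Reference UMAP implementations optimize that divergence by sampled
stochastic gradient descent, which hard-wires one particular loss — a
cross entropy whose repulsive weight is drastically reduced. This package
instead optimizes **full-batch, without sampling**, which makes the loss
pluggable. Four fuzzy information-discrimination measures are shipped,
each with its analytically derived gradient:

| loss id        | per-pair divergence                                            |
|----------------|----------------------------------------------------------------|
| `umap_ce`      | `mu ln(mu/nu) + w_i ln((1-mu)/(1-nu))`, `w_i = sum_k(mu_ik)/2n` |
| `fuzzy_ce`     | `mu ln(mu/nu) + (1-mu) ln((1-mu)/(1-nu))`                       |
| `symmetric_ce` | `(mu - nu) ln( mu(1-nu) / (nu(1-mu)) )`                         |
| `modified_ce`  | `mu ln(mu/m) + (1-mu) ln((1-mu)/(1-m))`, `m = (mu+nu)/2`        |

Optimization uses full-batch Adam (`eta = 1`, `beta1 = 0.9`,
`beta2 = 0.999`, 150 iterations by default) from a spectral (Laplacian
eigenmap) initialization. The practical payoff: `fuzzy_ce` and
`symmetric_ce` with a large neighbour count (up to `k = n-1`) preserve
markedly more of the **global** structure of the data than the
reduced-repulsion loss, which excels at **local** structure with small
`k`. The package ships quantitative metrics (k-NN recall,
trustworthiness, global distance Spearman correlation, cluster-recovery
ARI) so that comparison is a number, not a visual impression.

## Worked example

```r
library(fumap)

ds  <- make_blobs(n = 300, n_centers = 3, seed = 1)
fit <- fumap(ds, k = 10, min_dist = 0.1, loss = "umap_ce",
             n_iter = 150, seed = 1)
summary(fit)
```

```
Fuzzy cross-entropy embedding
  loss: umap_ce  gradient mode: chain_rule 
  n = 300  k = 10  min_dist = 0.1  m = 2 
  curve: a = 1.5769, b = 0.8951
  loss -373.1440 -> -634.2927 over 150 iterations
  trustworthiness (q=15): 0.9855
  knn recall      (q=15): 0.7478
  global distance Spearman: 0.8732
  cluster recovery ARI: 1.0000
```

Reading this: the similarity curve fitted for `min_dist = 0.1` has
`a = 1.577`, `b = 0.895`; the loss decreased over all 150 Adam iterations;
the embedding keeps 98.6% trustworthiness and ~75% of each point's
15-neighbourhood; a k-means partition of the embedding recovers the three
generating clusters exactly (ARI = 1). `plot(fit)` draws the embedding
coloured by label; `fit$embedding` is the n x 2 coordinate matrix and
`fit$trace` the per-iteration loss.

To compare global-structure preservation on the bundled handwritten
digits:

```r
ds <- subsample(load_digits(), 300, seed = 1)
f1 <- fumap(ds, k = "n-1", loss = "fuzzy_ce", seed = 1)   # global-friendly
f2 <- fumap(ds, k = 10,    loss = "umap_ce",  seed = 1)   # local-friendly
global_distance_spearman(ds$X, f1$embedding, seed = 1)    # ~0.50
global_distance_spearman(ds$X, f2$embedding, seed = 1)    # ~0.37
```

A command-line front end lives in `inst/cli/fumap.R` (subcommands
`generate`, `fit-ab`, `gradcheck`, `embed`, `metrics`); run it with
`Rscript $(Rscript -e 'cat(system.file("cli","fumap.R",package="fumap"))') embed --help`.

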