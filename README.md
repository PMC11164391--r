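# pathmetrics

Density-sensitive, geometry-preserving embedding and clustering for
single-cell RNA-seq (and other high-dimensional) data, built on
power-weighted path metrics.

## The problem

Clustering single-cell data runs into two failure modes at once: cell types
along developmental trajectories form *elongated* clusters that centroid
methods such as k-means chop into pieces, while transitional cells form
*bridges* of intermediate density that make purely density-based methods
(DBSCAN and friends) merge distinct populations. `pathmetrics` targets
exactly this regime with a metric that balances the two signals.

## The method

For cells $a, b$ in a data set $X$, the $p$-power weighted path metric is

$$\ell_p(a,b) = \inf_{(x_0,\dots,x_s)} \Big(\sum_{i=0}^{s-1} \lVert x_{i+1}-x_i\rVert_2^{\,p}\Big)^{1/p},$$

the infimum over sequences of data points connecting $a$ to $b$. At $p = 1$
it reduces to Euclidean/geodesic distance; as $p \to \infty$ it converges to
the bottleneck-edge distance. Many short hops through dense data are cheap;
one long hop across a void is expensive — so the metric is density
sensitive while still measuring geometry.

The pipeline (`pm_profile()`):

1. local-averaging denoising over $K_1 = 12$ nearest neighbours;
2. $K_2$-NN graph ($K_2 = \min(n-1, 500)$), edge weights
   $\lVert x_i - x_j\rVert^p$, all-pairs Dijkstra, $1/p$ root;
3. classical MDS of the path distances, embedding dimension selected at
   the largest eigenratio $\lambda_i/\lambda_{i+1}$ with
   $3 \le i \le 39$ and $\lambda_i/\lambda_1 \ge 0.01$;
4. size-constrained k-means (20 replicates, minimum cluster size
   $\lceil\sqrt n/2\rceil$, tiny clusters merged into their nearest
   neighbour).

A landmark mode (`landmarks = q`) computes path distances from $q$ seeded
random landmarks only and places the remaining cells by triangulation,
making the pipeline quasi-linear in $n$.

Also included: evaluation statistics (adjusted Rand index, entropy of
cluster purity/accuracy, geometric perturbation $\pi$ of cluster layouts,
elongation score $G_1$), seeded benchmark generators (overlapping balls,
elongated Gaussians with a bridge, Swiss-roll bands, rotation orbits of
symmetric matrices, and a Poisson–Gamma marker-gene count simulator), and
CSV/TSV/MatrixMarket readers and writers.

## Worked example

```r
library(pathmetrics)

toy <- simulate_ewb(seed = 1)       # 620 cells, 3 elongated clusters + bridge
fit <- pm_profile(toy, k = 3, seed = 1)
fit
#> <pm_fit> n = 620, d = 2 | p = 2, k1 = 12, k2 = 500
#>   embedding: r = 3 (sqrt_eigenvalue)
#>   clusters: k = 3, sizes 211, 200, 209
#>   total time: 3.0s

evaluate_clustering(toy$labels, fit$clusters)
#> # A tibble: 1 × 3
#>     ari    ecp    eca
#>   <dbl>  <dbl>  <dbl>
#> 1 0.995 0.0100 0.0101

geometric_perturbation(toy$x, fit$embedding, toy$labels)
#> <pm_perturbation> pi = 0.11307 (c* = 1.71497)
```

An ARI of 0.995 means the three planted populations are recovered almost
exactly (a handful of bridge-interior cells swap); plain k-means on the
same data scores around 0.3 because the clusters' 20:1 elongation rivals
their separation and its cuts land across the long axes. The perturbation π ≈ 0.10 says the embedding preserved the
relative distances between cluster centers to within about 10% after
optimal rescaling. `tidy(fit)` returns a per-cell tibble of coordinates and labels,
`autoplot(fit)` draws the embedding.

For data on disk: `read_matrix("counts.csv")` (cells × features with ids),
then pipe into `pm_profile()`. A thin command-line front end with
`simulate` / `embed` / `cluster` / `evaluate` subcommands is installed at
`system.file("scripts", "scpmp", package = "pathmetrics")`.

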