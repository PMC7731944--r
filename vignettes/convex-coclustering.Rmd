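---
title: "Convex co-clustering of multiway arrays: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex co-clustering of multiway arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocotensor)
```

## The problem and the model

Many data sets are naturally multiway: gene-by-region-by-time expression
arrays, user-by-item-by-context interaction rates, sender-by-recipient-by-day
communication counts. Co-clustering asks for a simultaneous partition of the
indices along *every* mode, so that the tensor, suitably reordered, looks
block-constant — a *checkerbox*, the D-way analogue of a checkerboard
biclustering.

The generative model behind the estimator is

$$x_{i_1 \cdots i_D} = c^*_{r_1 \cdots r_D} + \varepsilon_{i_1 \cdots i_D},$$

where index $i_d$ belongs to mode-$d$ cluster $r_d$, $\mathcal{C}^*$ is a
$k_1 \times \cdots \times k_D$ array of co-cluster means, and the noise is
independent with mean zero (we simulate it as Gaussian, possibly with a
different variance in every co-cluster cell). Equivalently
$\mathcal{U}^* = \mathcal{C}^* \times_1 M_1 \times_2 \cdots \times_D M_D$
through binary membership matrices $M_d$ with unit row sums.

Finding the partitions directly is combinatorial, so the package minimizes the
strongly convex surrogate

$$F_\gamma(\mathcal{U}) \;=\; \tfrac12\,\lVert \mathcal{X} - \mathcal{U}
\rVert_F^2 \;+\; \gamma \sum_{d=1}^D \sum_{(i,j) \in E_d} w_{d,ij}\,
\lVert \mathcal{U} \times_d (e_i^\top - e_j^\top) \rVert_F ,$$

a fusion (group-lasso-on-differences) penalty on all pairs of mode-$d$
subarrays joined by an edge of a per-mode similarity graph. The $\ell_2$ norm
of the block difference is not differentiable at zero, so as $\gamma$ grows
whole subarrays *coalesce exactly*; shared values define the clusters. At
$\gamma = 0$ the minimizer is the data itself (every index its own cluster);
for large $\gamma$, with connected similarity graphs, it is the grand mean
(one co-cluster). In between, the unique minimizer
$\hat{\mathcal{U}}_\gamma$ traces a continuous solution path.

Useful structural facts, all verified as properties in the test suite: the
minimizer is unique (strong convexity), 1-Lipschitz (nonexpansive) in the
data, jointly continuous in $(\mathcal{X}, \gamma)$, and equivariant under
mode-wise permutations of the input.

## The dual algorithm

Splitting $v_{d,l} = A_{d,l} u$ (with $A_{d,l}$ the vectorized edge-difference
map) and dualizing the constraints gives the Lagrangian dual

$$\max_\lambda \; \tfrac12 \lVert x \rVert_2^2 - \tfrac12 \lVert x -
A^\top \lambda \rVert_2^2 \quad \text{s.t.}\quad \lVert \lambda_{d,l}
\rVert_2 \le \gamma\, w_{d,l} \;\; \forall d, l,$$

a least-squares problem over a product of Euclidean balls. The package solves
it by projected gradient — a gradient step on the smooth quadratic followed by
a per-block ball projection — with optional FISTA-style momentum. The primal
solution is recovered *exactly* from any dual solution as
$\hat u = x - A^\top \hat\lambda$ (the dual may be non-unique but
$A^\top\hat\lambda$ is common to all solutions, so $\hat u$ is unique). All
operator applications are matrix-free: applying $A_d$ and $A_d^\top$ costs one
sparse incidence-matrix product against the mode-$d$ matricization, linear in
the data size per edge. Dense Kronecker operators exist only inside the test
oracles.

Numerical choices:

* **Step size.** $\eta = 1/\hat L$ where $\hat L$ estimates the largest
  eigenvalue of $A A^\top$ by power iteration on the matrix-free operator
  (100 iterations, fixed seed). The estimate converges from below, but
  projected gradient on this quadratic is stable for any $\eta < 2/L$, and at
  this budget the estimate is accurate to well under 1%; no safety margin is
  applied, which keeps the single-edge case at its exact value
  $\eta = 1/\lVert e_i^\top - e_j^\top \rVert^2 = 1/2$. The step is computed
  once per graph and reused along the whole path.
* **Stopping.** Relative duality gap $(F - G)/\max(1, F) \le$ `tol`
  (default $10^{-6}$), evaluated every 10 iterations to amortize the gap
  computation; hard cap of 20,000 iterations with a `converged` flag.
* **Acceleration.** FISTA momentum with a function-value restart: when the
  dual objective decreases, the momentum is dropped and the step retried
  from the plain iterate. (A gradient-based restart was evaluated and
  rejected: under heavy ball projection it misfires and collapses the
  acceleration.) Plain projected gradient (`accelerate = FALSE`) is retained
  as an option and is the reference for the monotone-ascent test.
* **Warm starts.** Along an ascending $\gamma$ grid each solve starts from
  the previous dual variables projected onto the new (larger) feasible set;
  the tests confirm warm and cold starts agree to well within $10^{-5}$
  relative.

## Fusion weights

Uniform weights $w_{d,ij} = 1/n_d$ on the complete graph
(`weight_config(scheme = "theory_uniform")`) are the configuration under
which the estimator's error bound is cleanest, and they are exposed for
study. In practice sparse, data-adaptive weights cluster far better, and the
default pipeline builds them in four stages:

1. **Tucker denoising.** A rank-$(r_1, \ldots, r_D)$ Tucker approximation
   (truncated higher-order SVD refined by orthogonal iteration) replaces the
   data in the weight computation. A checkerbox mean is inherently low
   Tucker rank, so truncation strips noise from the pairwise distances
   without disturbing the block structure. Default ranks are the shape
   heuristic $r_d = \min(n_d, \max(2, \lceil \sqrt{n_d} \rceil))$ — a
   deterministic choice driven only by the dimensions; any per-mode ranks
   can be supplied instead, or denoising turned off.
2. **k-nearest neighbours.** Edge $(i,j)$ is kept iff $j$ is among the $k$
   nearest subarrays of $i$ *or vice versa*. The default $k$ is the smallest
   value whose union-rule graph is connected, found by exact scan (the
   quadratic cost of exact k-NN is immaterial at the mode lengths this
   package targets). Distance ties break toward the smaller index.
3. **Gaussian kernel.** Pre-weights
   $\tilde w_{d,ij} = \exp(-\tau_d\, \mathrm{dist}(i,j)^2)$ on retained
   edges. The inverse scale is set from the median $m$ of the masked
   distances as $\tau_d = 1/m^2$, so the exponent is dimensionless; the
   convention $\tau_d = 1/m$ is selectable (`tau_convention = "inverse"`),
   and $\tau_d = 0$ reproduces uniform weights on the k-NN graph. The median
   is taken over the masked (k-NN) pairs only.
4. **Normalization.** Each mode's weights are rescaled to sum to $n_d / n$,
   so no single mode's penalty dominates as $\gamma$ grows.

Edges are dropped when their normalized weight falls more than twelve
decades below the mode's largest weight: such a term is smaller than the
double-precision rounding error of the per-mode penalty sum, so the edge
cannot influence the estimate, and the penalty value needed to fuse it lies
beyond any reachable grid — keeping it only stalls full fusion. On strongly
separated data the Gaussian kernel drives cross-cluster weights into this
regime (values like $10^{-150}$), the mode graphs disconnect, and the
package warns: the objective then separates over the components, and the
attainable full-fusion limit is one cluster per component rather than the
grand mean. The doubling search for $\gamma_{\max}$ is aware of this and
stops at per-component fusion, which also keeps the default grid
concentrated on the penalty range where structure actually changes.

## Tuning and partition extraction

The path is scored by an extended BIC,

$$\mathrm{eBIC}(\gamma) = n \log\!\big(\mathrm{RSS}_\gamma / n\big) +
2\, \mathrm{df}_\gamma \log n,$$

with $n$ the total element count, $\mathrm{RSS}_\gamma = \lVert \mathcal{X} -
\hat{\mathcal{U}}_\gamma \rVert_F^2$ and $\mathrm{df}_\gamma$ the number of
co-clusters $\prod_d \hat k_d$ (one estimated mean per cell). The selected
$\gamma^\star$ minimizes the criterion over the *non-saturated* grid points,
ties toward the smaller $\gamma$. A saturated fit ($\mathrm{df} = n$, every
element its own co-cluster) interpolates the data, so its likelihood term
diverges to $-\infty$ as its RSS vanishes and the criterion carries no
information there; such points are excluded from selection (they are
reported in the path summary), falling back to the plain minimum only if
every grid point is saturated. An RSS floor of $10^{-12} \lVert x \rVert^2$
additionally keeps the criterion finite at an exact fit. The default grid is geometric
with 30 points from $10^{-4}\gamma_{\max}$ to $\gamma_{\max}$, where
$\gamma_{\max}$ is found by doubling from 1 until the fit is fully fused —
one co-cluster for connected mode graphs, one cluster per component
otherwise. The cap is 60 doublings: because each mode's weights are
normalized to sum to $n_d/n$, individual weights scale like
$(n_d/n)/|E_d|$ and the fusing regime for a $10^5$-element tensor sits at
$\gamma \sim 10^8$–$10^{11}$, far above what a lower cap could reach.
$\gamma = 0$ is excluded by default
because of the exact-fit degeneracy. A `theory = TRUE` grid spanning
$[2\log(n)/(nD),\, 2 c_0 \log(n)/(nD)]$ is available for experiments with
uniform weights.

Partitions are read off the fit, not re-estimated. In exact arithmetic two
subarrays are co-clustered iff their difference block is zero; in floating
point the package marks an edge fused when **either**

* its dual block is strictly interior to its ball,
  $\lVert \hat\lambda_{d,l} \rVert_2 \le (1 - \delta)\,\gamma w_{d,l}$ with
  $\delta = 10^{-3}$ (an interior dual constraint forces the primal
  difference to vanish at the optimum), **or**
* the primal difference norm is numerically zero,
  $\lVert v_{d,l} \rVert_2 \le \epsilon_{\mathrm{abs}} +
  \epsilon_{\mathrm{rel}} \lVert x \rVert_F$ with
  $\epsilon_{\mathrm{abs}} = 10^{-10}$, $\epsilon_{\mathrm{rel}} = 10^{-8}$.

The dual test is only consulted for edges whose ball radius
$\gamma w_{d,l}$ itself exceeds the numerical threshold: when the radius is
below floating-point noise at the problem's scale (which happens exactly for
those underflow-small cross-cluster weights), the dual block's position
inside or outside a ball of radius $10^{-150}$ carries no information and
only the primal test may declare fusion. The two rules agree on essentially
all edges of well-converged fits, which the test suite checks. Components of
the fused-edge graph are extracted by breadth-first search from the smallest
unvisited index, giving deterministic, order-independent labels, and
co-cluster means are cell averages of the data.

## Synthetic generators

`simulate_checkerbox()` emulates the checkerbox study design: balanced or
imbalanced cluster sizes per mode, homoskedastic or per-cell heteroskedastic
Gaussian noise, and cubical or rectangular shapes. Co-cluster means default
to a single iid draw from Normal$(0, \Delta^2)$ with $\Delta = 3$ — the
mean-separation scale against which every recovery property in this package
is phrased, since separation enters all claims only through the ratio
$\Delta/\sigma$. Blocks are laid out contiguously and can be shuffled by a
seeded permutation to exercise permutation equivariance.

`simulate_cp_shapes()` builds the deliberately misspecified rank-2 symmetric
CP model: an $80 \times 2$ factor matrix whose rows trace either two
interleaved half-moon crescents or a bullseye (two concentric annuli — inner
radius 1, outer radius 3, small radial jitter; the half-moons are unit-radius
crescents offset by $(1, 0.5)$), and the mean tensor $\sum_{i=1,2} a_i \circ
a_i \circ a_i$. The true two-class structure is non-convex in factor space,
which is precisely what defeats k-means on CP factors while the
graph-following fusion penalty can still trace it.

What these generators do *not* emulate: dependent or heavy-tailed noise,
missing entries (the estimator requires complete tensors; imputation is out
of scope), and non-Gaussian error families. Passing recovery tests here
therefore demonstrates correctness of the estimator and its tuning under the
stated generative conditions, not robustness on arbitrary real data.

## Baselines

Two standard comparators are included behind the same label/ARI interface:
`cpd_kmeans()` (rank-$R$ CP decomposition by seeded multi-start ALS, then
independent k-means on each factor matrix's rows) and `cotec_kmeans()`
(k-means directly on each mode's matricization rows). Default CP rank
candidates are $\{2,3,4,5\}$ chosen by best relative fit; k-means uses 10
restarts. The number of clusters is chosen by the gap statistic with a
uniform-over-bounding-box reference (`cluster::clusGap`, `spaceH0 =
"original"`) and the usual one-standard-error rule, candidates $1..8$ by
default. These are intentionally *good* implementations of the baselines —
their characteristic failures (imbalance, non-convex classes) are properties
of the methods, not of sloppy tuning.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic data generated at call time. Sizes were chosen so that each check
isolates one property at desk scale: oracle comparisons on shapes up to
$4 \times 4 \times 3$ against dense-matrix ADMM; path and limit checks on
$\sim 15^3$; cluster-recovery studies at $20^3$ with 2 clusters per mode
($\Delta = 3$, $\sigma = 1$ balanced; $\sigma = 0.5$ with a 0.2 imbalance
ratio); an error-decay sweep over $10^3, 15^3, 20^3$; and the CP bullseye
contrast at $40^3$ (20 rows per class) with a 10-point grid. The
qualitative conclusions — exact recovery at these noise levels, monotone
error decay in the mode length, the fusion estimator dominating
CPD+k-means on non-convex classes — are stable across seeds. On the
bullseye the checkerbox mean model is deliberately misspecified (slices
vary continuously around each ring), so the eBIC selects a partition finer
than the two rings; that partition *refines* the true classes and scores
well above CPD+k-means, which mixes them, but exact two-class recovery is
not the expected outcome under this generative model and is not claimed.

## Known limitations

* Complete tensors only; no missing-value handling.
* The $O(n_d^2)$ exact k-NN and dense solver iterates are designed for desk
  scale (modes up to a few hundred), not for very large tensors.
* Disconnected similarity graphs are solved as-is but cannot fully fuse;
  eBIC selection still works within components.
* The eBIC is used exactly as printed above, with no additional
  hyperparameter on the df term.
* Error bounds and consistency arguments motivate, but are not verified by,
  this implementation; the package checks behavioural properties
  (nonexpansiveness, continuity, equivariance, recovery, error decay) by
  simulation.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_checkerbox(checkerbox_spec(
  dims = c(20, 20, 20), clusters = c(2, 2, 2),
  delta = 3, sigma = 1, seed = 7
))
res <- coco(sim$x)
glance(res)
tidy(res)          # the whole path: gamma, RSS, df, eBIC, per-mode k
autoplot(res)      # eBIC against gamma with the selection marked
sapply(1:3, function(d)
  adjusted_rand_index(res$clustering$labels[[d]], sim$labels[[d]]))
```
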