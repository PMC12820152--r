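---
title: "Spatial metagene pattern recognition: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial metagene pattern recognition: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatmf)
```

## The problem and the model

Spot-based spatial transcriptomics yields a non-negative matrix
$X \in \mathbb{R}^{n \times p}$ over $n$ capture locations with known 2-D
coordinates and $p$ features. `spatmf` models $X$ as a small number of
spatially coherent expression programs: $X \approx WH$ with $W \ge 0$
holding $r$ spatial patterns (one activity value per spot) and $H \ge 0$
holding the corresponding metagene signatures. The fit minimizes

$$\|X - WH\|_F^2 + \alpha\,\mathrm{tr}(\Omega W^\top L W)
  + \beta\|W\|_1 + \tfrac{\gamma}{2}\sum_{i<j}\langle h_i,h_j\rangle^2 .$$

Each term has a distinct job. The Laplacian quadratic form equals
$\tfrac12 \sum_{ij} A_{ij} \sum_k \Omega_{kk} (W_{ik} - W_{jk})^2$: it
charges patterns for differing across graph edges, i.e. it asks patterns
to vary smoothly over the tissue. The $\ell_1$ penalty keeps patterns
localized and starves noise components. The pairwise inner-product
penalty on rows of $H$ keeps metagenes distinct, preventing one program
from being split across near-duplicate factors.

**Assumptions.** Expression programs are additive and non-negative;
spatial coherence is informative (a program that varies like white noise
across neighboring spots is treated as noise); and the graph built from
coordinates plus expression similarity reflects true tissue adjacency.
Sharp one-spot-wide structures violate the smoothness assumption and will
be blurred — a known limitation of any Laplacian-smoothed method.

## The spatial graph

Spots within Euclidean distance $r^{*} = \lambda\sqrt{(x_{max}-x_{min})
(y_{max}-y_{min})/n}$ (strictly; ties at the radius are excluded) are
connected, with edge weight
$A_{ij} = \exp(-d_{cos}^2(X_{i\cdot},X_{j\cdot})/2d^{*2})$ so that
spatially adjacent but transcriptionally dissimilar spots (e.g. across a
tissue boundary) are weakly coupled. The bandwidth $d^{*}$ is the
$1/n_c$ quantile of the cosine-distance population.

Numerical choices made here, all of which only matter for degenerate
inputs: self-pairs are excluded (a self-loop cancels in $L$ and only
inflates degrees); all-zero expression rows get cosine distance 1 to
everything rather than NaN; if the bandwidth quantile is 0 because
profiles repeat, the smallest positive distance is used (warning), and if
every distance is 0 the weights degrade to a radius indicator. For up to
5 000 spots the quantile uses all off-diagonal pairs, exactly as the
formula reads; beyond that the population is restricted to spatially
adjacent pairs, which scales linearly — `quantile_pop` forces either
mode.

$\lambda = 1.2$ is the default scale. The supported diagnostic is the
mean neighbor count: `neighbor_stats()` flags graphs whose mean leaves
the 6–10 band, in which case $\lambda$ should be adjusted. On a
unit-spaced square grid $\lambda = 1.2$ yields rook adjacency (4
neighbors, flagged); the simulation benchmark therefore uses
$\lambda = 1.8$, which adds the diagonals (8 neighbors, inside the band).

## Pattern significance and the update schedule

$PSS_i = \cos(p_i, h_i)$ with $p_i = X^\top w_i/\|w_i\|_1$ measures
whether a pattern's claimed signature matches what is actually expressed
where the pattern is active; degenerate patterns score 0 by convention.
$\Omega = \mathrm{diag}(PSS)$ makes the spatial penalty adaptive:
high-PSS patterns are smoothed, low-PSS (noise) patterns are not — so
noise is not artificially smoothed into plausible-looking structure, and
is instead eliminated by the reconstruction and sparsity terms.

PSS is refreshed once per outer iteration, before the $W$ step. Within an
iteration $\Omega$ is held fixed; under a fixed $\Omega$ each
multiplicative half-step provably does not increase the objective, while
across refreshes small increases are possible in principle (the trace
records every value, so they are visible when they occur). This is the
coherent resolution of wanting both adaptive weights and monotone steps;
asserting monotonicity only under frozen $\Omega$ is the property the
test suite and the acceptance measurements check.

The update rules are derived from the stated objective by the standard
multiplicative split of the KKT gradient into positive and negative
parts:

$$W \leftarrow W \odot \frac{XH^\top + \alpha A W \Omega}
 {WHH^\top + \alpha D W \Omega + \beta/2 + \delta}, \qquad
 H \leftarrow H \odot \frac{W^\top X}
 {W^\top W H + \tfrac{\gamma}{2}(HH^\top H - \mathrm{diag}(HH^\top)H)
  + \delta}$$

with $\delta = 10^{-12}$ guarding the division. The $\beta/2$ and
$\gamma/2$ factors are what make the fixed points of these rules exact
stationary points of the objective as written (the gradient of
$\|X-WH\|_F^2$ carries a factor 2 that the penalty gradients do not);
the acceptance suite verifies this directly by comparing
$W \odot \partial f/\partial W$ against central finite differences at
convergence. Zeros are absorbing, so factors stay non-negative forever.

Initialization is $\mathrm{Uniform}(0,1)\cdot\sqrt{\bar X / r}$ from a
user seed — the scale puts $WH$ at the data's magnitude so early
multiplicative steps are well-conditioned — and every fit is
bit-reproducible from its seed. Convergence is declared when the relative
objective change drops below `tol` (default $10^{-5}$) or at `max_iter`
(default 200).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 (user-chosen; 0.3–1.0 for tissue domains, 0.1–0.3 for fine niches) | spatial smoothing strength |
| `beta` | `alpha / 15` | sparsity of $W$ |
| `gamma` | `1.5e-4 * p` | metagene orthogonality; scales with $p$ because inner products grow with dimension |
| `r` | 30 | pattern count; deliberately generous, surplus patterns are filtered later |
| `lambda` | 1.2 | graph radius scale (tune to 6–10 mean neighbors) |
| `eps_pattern` | 0.3 | pattern-specific threshold on $Pr$ (strict `>`) |
| `eps_svg` | 0.7 | SVG threshold on relative reconstruction error (strict `<`) |
| `n_cluster`, `n_c` | 8 | domain count and bandwidth quantile parameter |
| `N1`, `N2` | `max(0, r - 5 - n_cluster)`, 3 | patterns dropped by norm, then by PSS, before clustering |

`N1` is clamped at zero because the formula goes negative for small `r`.
Both downstream thresholds are strict inequalities, so values exactly at
the threshold are excluded.

## Preprocessing

For sequencing-based platforms: library-size normalization to a common
row total (default $10^4$, the standard single-cell convention) followed
by $\log(1+x)$; Moran's I feature selection on the analysis graph (the
weighted adjacency doubles as the Moran weight matrix — one convention,
not two); and closed-neighborhood unweighted averaging of each spot with
its graph neighbors. The default order is normalize → select → average:
selection before averaging scores each gene's raw spatial signal rather
than the artificially smoothed one. Image-based panels are small and are
used raw. Multi-omics modalities are preprocessed independently and
concatenated column-wise over identical spot sets; no cross-modality
rescaling is applied beyond that.

Features with zero total expression are flagged and must be dropped
before fitting ($err_i$ would be undefined). Duplicate coordinates are
flagged but not merged.

## The synthetic benchmark

`simulate_layers()` plants the truth every test is scored against:
an $n_{side} \times n_{side}$ unit grid; $r_{true}$ horizontal bands with
Gaussian-smoothed edges (bandwidth 1 grid unit) mimicking laminar cortex;
metagene rows with disjoint support blocks and $\mathrm{Uniform}(1,2)$
loadings; $X = \max(0, W_{true}H_{true} + \mathcal{N}(0,\sigma))$,
optionally Poisson-resampled; and background genes built by
spot-permuting structured genes — identical marginal distribution,
destroyed spatial signal, which is exactly the null an SVG detector must
reject. A `bumps` geometry provides non-laminar patterns, and
`simulate_multislice()` / `simulate_multiomics()` share $H$ across slices
and $W$ across modalities respectively.

The versioned benchmark configuration is `n_side = 30` (900 spots),
`r_true = 6`, `p = 300` with 60 background genes, `noise_sd = 0.3`,
seeds 0–4. The fit uses `r = 10 > r_true` so the pattern-filtering step
is exercised, `alpha = 0.5` (mid recommended range), and `lambda = 1.8`
(see above). Problem sizes elsewhere in the suite (e.g. 200 × 100 for the
monotonicity sweep, 10 × 8 for the finite-difference stationarity check)
were chosen so each property is measured at a scale where the independent
oracle — exhaustive loops, finite differences, enumeration — is itself
trustworthy.

What passing these tests shows: the optimizer descends its objective and
reaches stationary points; planted smooth patterns, their gene supports,
domains and SVG labels are recovered under moderate Gaussian noise; and
denoising genuinely increases spatial autocorrelation. What it does not
show: robustness to platform-specific artifacts absent from the
generator — zero-inflation and over-dispersion beyond Poisson, segment
misassignment, batch effects between slices (explicitly out of scope),
or irregular (non-grid) spot layouts, although nothing in the method
assumes a lattice.

## Other design decisions

* **Pattern ordering.** Fitted patterns are returned sorted by
  descending PSS, so "key patterns" are the leading columns. No PSS
  cutoff is imposed; the ranking plus the filtering counts are the
  supported interface.
* **Multislice PSS is per-slice.** The spatial penalty is a per-slice
  sum with $\mathrm{diag}(PSS)$ inside, so each slice weighs its own
  patterns; the shared $H$ update aggregates
  $\sum_s W_s^\top X_s$ over $\sum_s W_s^\top W_s H$. With one slice
  this code path *is* the single-slice fit, bit for bit.
* **Ties.** Feature selection and pattern filtering break ties by
  ascending original index; documented and tested.
* **Sentinels.** All-zero data columns get $err = \infty$ (never
  selected, flagged) rather than being silently dropped; all-zero $Pr$
  columns are flagged and zeroed.
* **Sparse inputs.** $X$ may be a sparse `Matrix`; $A$, $D$, $L$ stay
  sparse throughout; $W$, $H$ are dense. No $n \times n$ dense matrix is
  ever materialized by the fitting path.
* **k-means** uses 10 seeded restarts (best inertia kept); labels are
  1-based integers, R's convention.

## Limitations

Rank selection is manual (`r = 30` default; 40–50 for very heterogeneous
samples). The objective is non-convex, so different seeds give different
local optima — on the benchmark the recovered patterns agree across
seeds, but on real data comparing a few seeds is prudent. Multislice
fitting assumes shared programs across sections and has no batch
correction. Histology images, 3-D coordinates and enrichment analyses
are out of scope; the package emits ranked gene/peak lists for external
enrichment tools.
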