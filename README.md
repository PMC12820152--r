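# spatmf — spatial metagene patterns by graph-regularized NMF

Spatially resolved transcriptomics measures expression at thousands of
spots with known tissue coordinates, but the biology lives in *programs*:
coordinated groups of genes whose activity varies smoothly across the
tissue. `spatmf` recognizes these programs directly. It factorizes the
spot-by-gene matrix into non-negative spatial **patterns** and
**metagenes**, regularized on a spatial neighborhood graph so that
patterns respect tissue geometry, and uses the factorization for the
analyses practitioners actually want: pattern-specific gene lists,
spatially variable gene (SVG) detection, spatial domain delineation,
expression denoising, multi-omics integration (RNA + protein + ATAC over
the same spots), and joint fitting of several tissue sections.

## The model

Given a non-negative expression matrix $X \in \mathbb{R}^{n \times p}$
(n spots, p features) and a spatial graph with Laplacian $L = D - A$,
`spatmf` solves

$$\min_{W \ge 0,\; H \ge 0}\ \|X - WH\|_F^2
  + \alpha\, \mathrm{tr}(\Omega W^\top L W)
  + \beta \|W\|_1
  + \frac{\gamma}{2} \sum_{i<j} \langle h_i, h_j \rangle^2$$

where the columns of $W$ (n × r) are spatial metagene expression
patterns, the rows of $H$ (r × p) are metagene signatures,
$\Omega = \mathrm{diag}(PSS)$ holds per-pattern **pattern significance
scores**, $\beta\|W\|_1$ promotes localized sparse patterns, and the last
term penalizes similar metagenes so patterns stay distinct.

The graph connects spots closer than a radius
$r^* = \lambda\sqrt{(x_{max}-x_{min})(y_{max}-y_{min})/n}$ and weights
each edge by expression similarity,
$A_{ij} = \exp(-d_{cos}^2(X_{i\cdot}, X_{j\cdot}) / 2 d^{*2})$, with the
bandwidth $d^*$ set to the $1/n_c$ quantile of the cosine-distance
population.

The PSS of pattern $i$ compares the signature $h_i$ with the mean
expression where the pattern is active,
$p_i = X^\top w_i / \|w_i\|_1$, as the cosine similarity
$PSS_i = \langle p_i, h_i\rangle / (\|p_i\|_2 \|h_i\|_2)$. It is refreshed
every iteration: coherent patterns are smoothed strongly, noise patterns
are left for the sparsity penalty to shrink away. Optimization uses
seeded multiplicative updates derived from the objective's KKT
conditions, so factors stay non-negative and the objective never
increases within an iteration.

Downstream, pattern contributions $Pr_{ij} = (\Lambda H)_{ij} / \sum_k
(\Lambda H)_{kj}$ with $\Lambda = \mathrm{diag}(\|w_i\|_2)$ give
pattern-specific genes ($Pr_{ij} > \epsilon^*$), the relative
reconstruction error $err_i = \|X_{\cdot i} - (WH)_{\cdot i}\|_2 /
\|X_{\cdot i}\|_2$ gives SVGs ($err_i < \epsilon$), k-means on
norm-and-PSS-filtered pattern columns gives spatial domains, and $WH$ is
the denoised matrix.

## Worked example

```r
library(spatmf)

# 20x20 grid, 4 planted cortical-like layers, 96 structured + 24 noise genes
sim <- simulate_layers(n_side = 20, r_true = 4, p = 120, n_background = 24,
                       noise_sd = 0.3, seed = 0)
g <- spatial_graph(sim$dataset, lambda = 1.8, n_c = 4)
g
#> spatial_graph: 400 spots, 1482 edges
#>   radius 1.71 (lambda = 1.8), bandwidth d* = 0.3018
#>   mean neighbors 7.41

fit <- spatmf(sim$dataset, g, r = 6, alpha = 0.5, seed = 0, n_cluster = 4,
              N1 = 0, N2 = 0)
fit
#> spatmf fit: 400 spots x 120 features, r = 6 patterns
#>   stopped at max_iter after 200 iterations (objective 5578.86)
#>   alpha = 0.5, beta = 0.03333, gamma = 0.018
#>   PSS (descending):  0.925 0.923 0.890 0.885 0.460 0.402
```

The four planted layers surface as the four high-PSS patterns (PSS ≈
0.89–0.93); the two surplus components score much lower (≈ 0.4) and are
the ones the domain step filters out. Continuing:

```r
length(select_svgs(fit))                          # 101 of 120 features
labels <- cluster_domains(fit, n_cluster = 4, seed = 1)
adjusted_rand_index(labels, sim$truth$domain_labels)   # 1.000
rr <- refinement_report(fit)
c(rr$mean_before, rr$mean_after, rr$fraction_improved)
#> 0.649 0.818 0.99
```

So SVG selection recovers essentially all 96 structured genes (plus a few
borderline calls), the domains match the planted layers exactly, and
denoising raises the mean per-gene Moran's I from 0.65 to 0.82 with 99%
of features improved.

A command-line wrapper with `simulate`, `fit`, `multislice-fit`, `svg`,
`genes`, `domains`, `denoise` and `graph-stats` subcommands is installed
at `system.file("exec", "spatmf", package = "spatmf")`; see `?run_cli`.

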