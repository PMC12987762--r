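---
title: "Distance-penalized co-accessibility: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-penalized co-accessibility: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaccess)
```

## The problem

Cis-regulatory elements — enhancers, promoters, insulators — coordinate gene
expression through 3D chromatin contacts that can span hundreds of kilobases.
Single-cell ATAC-seq measures the accessibility of such elements across
thousands of cells but says nothing directly about which elements interact.
The co-accessibility idea is statistical: elements that open and close
together across cells are candidates for functional interaction. `coaccess`
estimates a sparse network of such pairwise co-accessibility scores from a
cells × peaks count matrix, and groups strongly co-accessible peaks into
cis-co-accessibility networks (CCANs).

## The model

For the peaks of one genomic window, let $S$ be the Pearson correlation
matrix of peak counts across cells (or metacells). The estimator is a
graphical lasso with an *element-wise* penalty matrix:

$$\hat\Theta = \arg\min_{\Theta \succ 0}\;
  \mathrm{tr}(S\Theta) - \log\det\Theta
  + \sum_{i \ne j} \rho_{ij}\,|\Theta_{ij}|,
\qquad
W = \hat\Theta^{-1},$$

where the penalty grows with genomic distance following the power-law decay
of chromatin contact frequency:

$$\rho_{ij} = \left(1 - d_{ij}^{-s}\right)\alpha,$$

with $d_{ij}$ the midpoint distance of peaks $i,j$ in kilobases, $s$ the
contact-decay exponent, and $\alpha$ a global sparsity scale. Distant pairs
are penalized close to $\alpha$, adjacent pairs hardly at all, so the prior
encodes that regulatory contacts are predominantly short-range. Reported
co-accessibility scores are the regularized covariance as correlations,
$W_{ij}/\sqrt{W_{ii}W_{jj}} \in [-1, 1]$.

Because a scalar-penalty graphical lasso cannot express per-pair weights,
the solver is written for this package: block coordinate descent on $W$
with a soft-thresholding lasso inner loop (compiled via RcppArmadillo).
Zeros of $\hat\Theta$ are exact by construction. The test suite checks the
solver against the closed-form 2×2 solution and an independent
proximal-gradient minimizer of the same objective, and verifies the KKT
conditions ($W_{ij} - S_{ij} = \rho_{ij}\,\mathrm{sign}(\hat\Theta_{ij})$
on the support, $|W_{ij} - S_{ij}| \le \rho_{ij}$ off it) at returned
solutions.

Fitting is windowed: each chromosome is tiled with windows of
`window_size` (the maximum distance at which interactions are considered)
advancing by half a window, so every pair closer than half a window is
jointly modelled at least once. Pairs scored in several windows are
reconciled by the arithmetic mean; pairs whose window scores disagree in
sign are conservatively zeroed and counted. The sparse count matrix is held
column-oriented, so extracting a window's peaks is a column slice — the
dominant cost at scale.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `s` | 0.75 human/mouse, 0.85 fly | — | contact-frequency decay exponent; 0.75 follows the tension-globule polymer model, 0.85 the fly estimate |
| `window_size` | 500 000 | bp | maximum cis-interaction distance and window width |
| `distance_scale` | 1000 | bp | distance unit of the power law (d in kb); in raw base pairs $d^{-s}$ would be numerically flat and the penalty gradient lost |
| `distance_constraint` | `window_size / 2` | bp | boundary between short- and long-range pairs in the α calibration |
| `alpha` | calibrated | — | sparsity scale of the penalty |
| `max_elements` | 200 | peaks | windows larger than this are skipped (cubic solver cost) |
| `ridge` | 1e-4 | — | diagonal lift when the empirical matrix is near-singular |
| `tol`, `max_iter` | 1e-4, 100 | — | solver convergence controls |
| `zero_tol` | 1e-10 | — | magnitude below which a score is stored as exact zero |

Organism presets (`organism_preset()`) bundle the literature values so users
need not choose `s` by hand.

The input statistic is the *correlation* matrix rather than the covariance:
it makes a single α commensurable across windows of different depth and
peak variance, and the final scores are then themselves on a correlation
scale.

## Calibrating α

α is the lowest value such that a fitted window satisfies two sparsity
constraints: at least 20% of its peak pairs have a zero entry (minimal
sparsity), and at most 5% of its long-range pairs (midpoint distance beyond
`distance_constraint`) are non-zero (most connections short-range). Per
window, the lowest feasible α is found by bisection on a log grid over
$[10^{-4}, 10^4]$ (depth 50); the final α is the mean over a random sample
of up to `n_sample_windows = 100` eligible windows. Windows for which no α
in range is feasible are skipped with a warning.

**Where the criteria are measured.** The two constraints are evaluated on
the entries of the precision matrix $\hat\Theta$ (equivalently partial
correlations) by default, not on the reported $W$-based scores
(`sparsity_basis = "score"` switches). This choice was made deliberately
after examining both: $W = \hat\Theta^{-1}$ is dense within every connected
component of the precision graph, so a chain of strong adjacent links makes
*marginally* associated long-range pairs non-zero in $W$ even when no
direct long-range dependence exists. Measured on $W$, the long-range
criterion then punishes legitimate short-range chains and pushes α high
enough to sever them — on planted-block data this destroys the very modules
the method is meant to find. The precision entries are the model's direct
conditional connections, which is what "connections are short-range" can
sensibly constrain.

A related caveat is worth stating honestly: the per-window constraints are
guaranteed at each window's *own* α. At the *mean* α (the aggregation the
procedure prescribes) windows whose own α exceeds the mean can violate the
long-range bound — with a few hundred cells the feasible α of a window
tracks its noise-correlation extremes ($\mathrm{sd} \approx 1/\sqrt{n}$),
so per-window α's scatter and the strictest window retains a noticeable
fraction of long-range noise edges at the mean. The calibration keeps the mean as the aggregate (the established
convention for this procedure) rather than the max, because the max
over-sparsifies every other window.

## Metacells

Optionally, highly similar cells are aggregated before network estimation
to reduce sparsity. Cells are embedded by latent semantic indexing — TF-IDF
(tf = count / cell total; idf = $\log(1 + n_{cells}/(1 + n_{detected}))$,
smoothed) followed by truncated SVD, rows L2-normalized — and grouped
directly in that space: candidate seeds are visited in seeded-random order,
each group being the seed plus its `k = 50` nearest neighbours, accepted
unless it shares more than 90% of members with an accepted group, up to a
cap of 5000 metacells. Grouping happens in the LSI space itself rather than
in a UMAP/t-SNE projection, because such 2-D embeddings do not preserve
inter-cell distances and make nearest-neighbour sets unreliable. All
components, including the first, are retained by default (`drop_first`
exists for depth-dominated data). The 5000 cap and k = 50 follow the
established lineage; the overlap threshold is permissive by design and
exposed.

The default pipeline applies *no* binarization and *no* total-count
normalization: raw single-cell counts give the best downstream
enhancer–promoter recovery, and per-cell normalization can be actively
harmful. Both transforms remain available behind flags for comparison
studies.

## CCAN extraction

CCANs are Louvain communities (resolution 1.0, seeded) of the graph that
keeps pairs with $|score| \ge$ cutoff, weighted by $|score|$ — absolute
values, since negative co-accessibility also binds modules. Communities
need `min_ccan_size = 3` members. The automatic cutoff scans a 0.01 grid
and picks the cutoff maximizing the number of qualifying communities; ties
are broken by the partition's modularity, then by the smallest cutoff. The
modularity tie-break matters: Louvain resolves strongly modular blocks even
before weak noise edges are removed, so the community count is flat over
long cutoff ranges and the count alone cannot locate the signal/noise
boundary; modularity peaks exactly where the noise edges drop out.

## Evaluating against chromatin-contact references

Predicted links can be benchmarked against a reference interaction table
(promoter capture Hi-C style; both fragments' coordinates, optional score,
same genome build as the peaks). For every promoter fragment, all peaks
with midpoints within 500 kb form the candidate universe. A candidate is a
true positive when each of its two regions overlaps one of the two regions
of some reference pair by at least one base (half-open arithmetic, same
chromosome, either end assignment — peaks are unstranded). A
(promoter, peak) candidate inherits the *maximum* network score between any
peak overlapping the promoter fragment and the candidate peak, zero when no
link exists: the strongest compatible prediction is the one a ranking
evaluation should credit. ROC curves and AUC use trapezoidal tie handling.
Note the usual caveat: contact maps are an imperfect ground truth for
coordinated accessibility, and large reference fragments against narrow
peaks inflate false negatives.

## The synthetic generator

`simulate_accessibility()` plants known structure so every stage is
testable without external data. Region midpoints are uniform on one
chromosome (default density one peak per 25 kb, a realistic peak spacing)
and sorted; planted blocks are contiguous runs covering `block_coverage =
0.6` of the regions, so modules stay compact relative to the long-range
threshold — the regime the model assumes — with independent background
peaks between them (setting `block_coverage = 1` reproduces the degenerate
regime where modules span the long-range boundary and the calibration turns
destructive). Within a cell, regions of a block share a standard-normal
latent factor with loading $\sqrt{\rho}$; counts come from a Gaussian
copula with Poisson marginals, `qpois(pnorm(z), depth_mean / n_regions)`
(default one expected count per region), or probit-threshold Bernoulli
detection. The copula link preserves the planted correlation well
(ρ = 0.8 latent gives roughly 0.74 in counts at the default depth).

What it does *not* emulate: fragment-level Tn5 chemistry, per-cell depth
variation, batch effects, doublets, trans contacts, peak-width variation,
or distance-decaying within-block correlation. Passing tests on this
generator therefore demonstrate the estimator's correctness and the
pipeline's contracts — not biological performance on real assays.

The test suite runs the full pipeline on generated data at desk scale
(300–500 cells, 40–80 regions, windows of 10–30 peaks) and requires the
recovered CCAN partition to reach an adjusted Rand index of at least 0.8
against the planted blocks; these sizes keep the whole suite in the
minutes range while still exercising multi-window reconciliation.

## Numerical notes and degenerate inputs

* Zero-variance peak columns get correlation 0 off-diagonal (1 on the
  diagonal); a ridge of 1e-4 is added when the smallest eigenvalue of $S$
  falls below it.
* Solver zeros are exact (soft-thresholding), so "non-zero entry" in the
  calibration is well defined up to `zero_tol = 1e-10` applied to reported
  scores.
* Windows with fewer than 2 peaks are unfittable and skipped; windows
  larger than `max_elements` are skipped with a logged warning listing
  them.
* Sign-conflicting pairs across windows are zeroed, never averaged into a
  misleading intermediate.
* All randomness (window sampling, seed visiting order, Louvain) flows from
  explicit seed arguments; identical inputs and seeds give byte-identical
  link tables for any worker count.
* Trans-chromosomal pairs are never modelled; distances are midpoint-based
  (symmetric, robust to peak-width variation; the anchor convention for
  distance is otherwise arbitrary).

## Known limitations

* Scores are point estimates; no uncertainty quantification.
* The mean-α aggregation caveat above: per-window sparsity guarantees do
  not transfer exactly to the pooled α at small cell counts.
* The count-maximizing cutoff scan can admit small spurious modules when
  many weak background links exist; inspect `select_cutoff`'s choice or set
  the cutoff explicitly for small networks.
* Windows larger than `max_elements` peaks are skipped rather than fitted
  approximately; dense peak annotations may need a larger `max_elements`
  (cubic cost) or stricter peak filtering.
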