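# coaccess

Cis-regulatory DNA interactions — enhancer–promoter contacts and their kin —
leave a statistical footprint in single-cell ATAC-seq: elements that open
and close together across cells. `coaccess` turns a cells × peaks count
matrix into a sparse network of **co-accessibility scores** between peak
pairs, and groups strongly co-accessible peaks into **cis-co-accessibility
networks (CCANs)**. It is aimed at anyone analysing scATAC-seq who wants
candidate regulatory links without chromatin-conformation data: regulatory
genomics labs, gene-regulatory-network pipelines, atlas builders.

## The model

For the peaks of a genomic window, with $S$ the correlation matrix of peak
counts across cells, co-accessibility comes from a graphical lasso with an
element-wise, genomic-distance penalty:

$$\hat\Theta = \arg\min_{\Theta \succ 0}\;
  \mathrm{tr}(S\Theta) - \log\det\Theta + \sum_{i\ne j}\rho_{ij}|\Theta_{ij}|,
\qquad
\rho_{ij} = \bigl(1 - d_{ij}^{-s}\bigr)\,\alpha,$$

where $d_{ij}$ is the pair's midpoint distance in kb and $s$ the power-law
decay exponent of chromatin contact frequency (0.75 human/mouse, 0.85
*Drosophila*; `--organism` presets). Scores are the regularized covariance
$W = \hat\Theta^{-1}$ as correlations, in $[-1, 1]$. Fits run in 500 kb
sliding windows (the maximum cis-interaction distance) with 50% overlap;
α is auto-calibrated so each window keeps ≥ 20% zero pairs and ≤ 5%
non-zero long-range (> 250 kb) connections. CCANs are seeded Louvain
communities of the $|score| \ge$ cutoff graph, the cutoff chosen by a grid
scan. A planted-block synthetic generator, metacell aggregation (LSI +
k-NN grouping, capped at 5000), and a PC-HiC-style ROC evaluation of
predicted links round out the toolkit. The solver (block coordinate
descent with a per-entry penalty matrix, RcppArmadillo) is part of the
package; see `vignette("coaccessibility-model")` for assumptions and
design notes.

## Worked example

```r
library(coaccess)

# synthetic chromosome: 500 cells, 60 peaks over 1.5 Mb, 6 planted
# co-accessible modules, latent within-module correlation 0.8
sim <- simulate_accessibility(synthetic_spec(
  n_cells = 500, n_regions = 60, n_blocks = 6,
  within_block_corr = 0.8, seed = 1))
sim$matrix
#> AccessibilityMatrix: 500 cells x 60 regions (1 chromosome), 62.96% non-zero

res <- run_pipeline(sim$matrix, run_config(seed = 1), out_dir = "run1")
#> windows: 6 (size 500000 bp, step 250000 bp)
#> calibrated alpha = 0.0597385 over 6 window(s)
#> network: 826 non-zero pairs, 6 window(s) fitted, 0 skipped, 9 sign conflict(s)
#> selected CCAN cutoff = 0.07
#> CCANs: 6 module(s)

head(link_table(res$network, min_abs_score = 0.3), 3)
#>              Peak1              Peak2  coaccess
#> 1 chr1_20079_20579   chr1_34985_35485 0.6835851
#> 2 chr1_20079_20579   chr1_92649_93149 0.7118886
#> 3 chr1_20079_20579 chr1_105983_106483 0.6732538
```

The calibrated α (0.060) is the sparsity scale of the distance penalty;
826 peak pairs get a non-zero score, and the 6 recovered CCANs (6 peaks
each) match the planted modules exactly — `chr1_20079_20579` and
`chr1_34985_35485`, 15 kb apart with score 0.68, sit in the same module.
`run1/` holds the link table (TSV), BEDPE, CCAN table/BED, the resolved
config (YAML) and a run log.

A command-line front-end wraps the same steps
(`simulate | metacells | network | ccans | evaluate | run`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "coaccess.R", package = "coaccess"))')
Rscript $CLI run --mtx counts.mtx --peaks peaks.txt --barcodes barcodes.txt \
    --organism human --out-dir out
Rscript $CLI evaluate --links out/links.tsv --reference pchic.tsv --out roc.tsv
```

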