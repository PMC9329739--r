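# APAmodes

Modality calling for alternative polyadenylation (APA) usage in single
cells.

Most genes have several poly(A) sites, and which site a transcript ends at
varies not only between cell types but from cell to cell. Given a
poly(A)-site × cell UMI count matrix derived from 3'-tag scRNA-seq (sites
already called and quantified by an upstream peak caller), APAmodes
classifies, for each gene or poly(A) site, the cross-cell pattern of APA
usage into one of three modalities — **unimodal** (usage alike across
cells), **bimodal** (two cell subpopulations preferring different sites),
**multimodal** (more than two) — or marks it **undetected**. It is aimed
at transcriptomics researchers studying APA heterogeneity across cell
populations and differentiation stages.

## Method

Per-cell usage of site *i* within a gene is quantified by the poly(A)
usage index

```
PUI_i = log2( (pc_i + 1) / exp(mean(ln(pc + 1))) )
```

(the site's pseudocounted expression over the geometric mean across the
gene's sites; `NA` when the gene is unexpressed in the cell), or by the
usage ratio `pc_i / sum(pc)`, transformed `log2(ratio + 1)` for
major/minor-site analyses. For each feature, the non-missing per-cell
signals η are modelled as a univariate Gaussian mixture

```
P(η | θ) = Σ_{i=1..M} p_i φ(η | μ_i, Σ_i),   M ≤ 3,
```

fitted by EM with k-means initialisation for M = 1, 2, 3 and scored by
`BIC = (3M − 1) ln(n) − 2 loglik` (smaller is better). The component
count is then corrected: the worst of the three BIC values is discarded;
of the remaining two, if `BIC(s)/BIC(l) > 0.95` (s = smaller BIC,
l = larger) the smaller component count wins, otherwise the count with
the smaller BIC; finally any fit containing a component of fewer than 10
cells makes the feature undetected. Cells with missing signal are removed
per feature (no imputation). The package also ships the expression
filters for 3'UTR and non-3'UTR pipelines, modality-transition
bookkeeping across cell types (same / change / appear / disappear), a
fully seeded ground-truthed simulator (15 modality groups, missing-value
and noise injection, unbalanced bimodal designs) and evaluation utilities
(confusion matrices, adjusted Rand index).

## Worked example

```r
library(APAmodes)

# 15-group benchmark: 3 unimodal, 5 bimodal, 7 multimodal groups,
# 2 replicate rows each, 100 cells, component sd 0.1
sim <- simulateSignalMatrix(defaultGroupSpecs(), nCells = 100,
                            replicates = 2, seed = 7)
calls <- identifyModalities(sim$signal, seed = 11)
calls
#> ModalityCalls: 30 feature(s)
#>   unimodal: 6, bimodal: 10, multimodal: 14, undetected: 0

ev <- countModalityErrors(sim$truth, calls)
ev$n_errors
#> [1] 0
ev$confusion
#>             called
#> true         unimodal bimodal multimodal undetected
#>   unimodal          6       0          0          0
#>   bimodal           0      10          0          0
#>   multimodal        0       0         14          0
#>   undetected        0       0          0          0
round(ev$ari_by_modality, 3)
#>   unimodal    bimodal multimodal undetected
#>      1.000      1.000      0.994         NA
```

Every one of the 30 simulated features is assigned its generating
modality (`n_errors` 0, all counts on the confusion diagonal), and the
inferred per-cell component memberships agree with the generating
components almost perfectly (adjusted Rand index ≈ 1; `NA` for the
undetected row of the table because no feature was undetected).

For real data the entry points are `readSiteMatrix()` (Matrix Market or
dense TSV counts + site annotation TSV), `filter3UTR()` /
`filterNon3UTR()`, `buildSignalMatrix()` (modes `gene_proximal_PUI`,
`site_PUI`, `major_ratio`, `minor_ratio`), `identifyModalities()`,
`compareModalities()` and `transitionSummary()`; `runPipeline()` wires
them together and `inst/scripts/apamodes.R` exposes
`simulate` / `modality` / `dynamics` subcommands for shell use. The
methods vignette (`vignettes/apa-modality-calling.Rmd`) documents the
model, filter boundaries, numerical choices and the benchmark design.

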