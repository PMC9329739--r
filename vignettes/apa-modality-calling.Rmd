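---
title: "Calling APA usage modalities in single cells: model, filters and benchmark design"
author: "APAmodes maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling APA usage modalities in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(APAmodes)
```

## The problem

Most genes carry several poly(A) sites, and which site a transcript is
cleaved at (alternative polyadenylation, APA) varies from cell to cell.
Given a poly(A)-site-by-cell UMI count matrix from 3'-tag scRNA-seq (as
produced by peak-calling tools upstream of this package), APAmodes asks,
for each gene or site, *what the cross-cell pattern of APA usage looks
like*: is usage alike in all cells (unimodal), split between two cell
subpopulations preferring different sites (bimodal), spread over more than
two subpopulations (multimodal), or not decidable from the data
(undetected)?

## Usage signals

Counts are first turned into per-cell usage signals. For the counts
$pc = (pc_1, \dots, pc_m)$ of one gene's sites in one cell, the poly(A)
usage index of site $i$ is

$$\mathrm{PUI}_i \;=\; \log_2 \frac{pc_i + 1}
{\exp\!\big(\mathrm{mean}(\ln(pc + 1))\big)},$$

the log2 ratio of the site's pseudocounted expression to the geometric mean
across the gene's sites; the PUI values of a gene's sites in one cell
always average to zero, and $\mathrm{PUI} > 0$ means above-average usage.
For the proximal 3'UTR site (the one nearest the stop codon: smallest
genomic position on the + strand, largest on the $-$ strand) a positive
PUI therefore indicates 3'UTR shortening. If the gene has no expressed
site in a cell the signal is undefined (`NA`); such cells are *removed*
for that feature before fitting -- no imputation is attempted.

For major/minor-site analyses the usage ratio $pc_i / \sum_j pc_j$ is used
instead, transformed as $\log_2(\mathrm{ratio} + 1)$ so that its range is
on the same order of magnitude as typical PUI values. The major (minor)
site is the gene's most (least) expressed site by counts summed over the
analysed cell population, with ties resolved by annotation order. PUI is
deliberately *not* used for major/minor sites: by construction the major
site's PUI is always high and the minor's always low, which would force
two-site genes into a trivial unimodal call.

## Expression filters

Two pipelines feed the caller, with filters applied in the documented
order (sites, then cells, then gene-level rules) and "expressed" meaning
count > 0:

* **3'UTR pipeline** (`filter3UTR`): drop sites expressed in less than a
  quarter of cells; then drop cells in which less than one tenth of the
  retained sites are expressed; then keep only genes with at least two
  retained 3'UTR sites. The cell-rule denominator is the post-filter site
  count (sequential reading of the rules).
* **non-3'UTR pipeline** (`filterNon3UTR`): keep genes with more than
  three sites in total, of which at least one non-3'UTR and at least two
  3'UTR; keep per gene only the strongest non-3'UTR site; then drop sites
  expressed in less than half of the cells and cells expressing at most
  half of the retained sites. The retained non-3'UTR site's PUI (computed
  within its gene) is the signal.

Filters warn instead of failing when everything is removed, and attach a
report (`filterReport()`) whose removal counts reconcile exactly with the
shape change.

## The mixture model and the component correction

For one feature, the non-missing per-cell signals $\eta$ are modelled as a
univariate Gaussian mixture

$$P(\eta \mid \theta) = \sum_{i=1}^{M} p_i\,
\phi(\eta \mid \mu_i, \Sigma_i), \qquad M \le 3 .$$

Fits for $M = 1, 2, 3$ are obtained by EM; the 1-component fit is closed
form. EM is initialised from the best of 10 k-means partitions (by
within-cluster sum of squares) and refined for at most `maxIter`
iterations; component variances are floored at `varFloor`. Each fit is
scored by $\mathrm{BIC} = (3k - 1)\ln n - 2\,\ell$ (smaller is better),
with $3k - 1$ free parameters ($k$ means, $k$ variances, $k - 1$ weights).

The component count is then corrected:

1. discard the candidate with the worst (largest) BIC;
2. of the remaining two, let $s$ hold the smaller and $l$ the larger BIC;
   if $\mathrm{BIC}(s)/\mathrm{BIC}(l) > 0.95$ the fits count as equally
   good and the **smaller component count** of the two wins, otherwise $s$
   wins;
3. if any posterior-argmax component of the selected fit holds fewer than
   10 cells, the feature is **undetected** ($M = -1$). Features with
   fewer than 10 non-missing cells are undetected outright, since the
   component-size rule makes smaller inputs undecidable anyway.

Memberships are posterior argmax under the selected fit; components are
reported in order of increasing mean.

### Numerical choices

Several choices here are deliberate and worth making explicit:

* **The ratio test is applied verbatim whatever the BIC signs.** For
  tightly concentrated signals the log-likelihood is positive and the BIC
  negative; the ratio of two negative BICs exceeds 1, so the rule then
  always reduces to the smaller component count. This conservative bias
  matches the correction's intent (prefer fewer components when the
  evidence for more is marginal), and in the regime where genuine
  multimodal structure lives (three components spread over a few PUI
  units) the BICs are positive and the test discriminates normally.
* **Limited EM refinement (`maxIter = 10`) and a variance floor on the
  signal scale (`varFloor = 1e-3`)** both act as regularisation against
  the unbounded-likelihood failure of the mixture MLE: a component
  collapsing onto two near-identical points gains enough likelihood to
  beat the BIC penalty, which would occasionally (measured at about 4 in
  10\,000 unimodal vectors under full convergence and a 1e-6 floor) make
  the 1-component fit look worst of the three and force a spurious split.
  With these defaults the measured rate is below 1 in 10\,000. Both are
  user-settable through `modalityControl()`.
* **Ties** in BIC resolve to the smaller component count; k-means empty
  clusters are revived at the farthest point; all randomness flows from
  one seed through R's RNG, so every result is reproducible.
* For vectors of more than 2000 observations the k-means restarts run on
  a 1000-point random subsample (scored on the full data) and the winning
  centers are refined by one full-data Lloyd pass before EM -- the
  standard subset-seeding trick, which leaves results on separated data
  unchanged while keeping thousands of large fits fast.
* **Degenerate inputs**: a constant vector has a valid 1-component fit at
  the variance floor; vectors with fewer distinct values than components
  make that component count infeasible (infinite BIC), never an error at
  the calling level.

## The simulation benchmark

`defaultGroupSpecs()` encodes the benchmark design used throughout the
tests: 15 groups -- 3 unimodal (means 2, $-2$, 0), 5 bimodal
((2,$-2$), (2,0.5), ($-2$,$-0.5$), (2,0), ($-2$,0)) and 7 multimodal
((2,$-2$,0), (2,1,0.5), ($-2$,$-1$,$-0.5$), (2,1,0), ($-2$,$-1$,0),
(2,1,$-2$), ($-2$,$-1$,2)) -- each replicated 100 times at 100 cells per
row, with equal component proportions allocated deterministically
(remainders to earlier components) so that sizes are exact.

The design's dispersion parameter is 0.1. We interpret it as the
component **standard deviation**: several multimodal groups have adjacent
means only 0.5 apart, which at sd 0.1 are separated by 5 sd while at
sd $\sqrt{0.1} \approx 0.32$ they would overlap almost completely and no
method could recover them. `defaultGroupSpecs(dispersionIs = "variance")`
restores the literal variance reading.

Degradations are modelled separately and recorded in the ground truth:

* **Missing values** (`injectMissing`): per row, `round(fraction * n)`
  entries become `NA`, resampled (bounded retries) so that every true
  component keeps more than 10 observed cells -- fractions up to 60% on
  100 cells remain feasible, and the guard mirrors the component-size
  rule of the caller.
* **Noise** (`injectNoise`): a fraction of entries is perturbed by an
  additive uniform draw from $[-0.5, 0.5]$. The perturbation is
  label-preserving: a noised cell still originates from its generating
  component. The amplitude (5 component sd) sits below half the smallest
  bimodal component separation (1.5) but above half the adjacent
  multimodal separation (0.5), so noise corrupts multimodal memberships
  before bimodal ones -- bimodal membership recovery (adjusted Rand
  index) stays near 1 up to 30% noise while multimodal recovery degrades,
  which is the qualitative behaviour the benchmark probes. A
  replacement-noise model (resampling values uniformly over the row's
  range) was rejected: it erases the generating label, making
  near-perfect membership recovery impossible in principle for any
  caller.
* **Unbalanced bimodal** (`simulateUnbalancedBimodal`): component ratios
  5:5 to 9:1 at means $\pm 10$, sd 0.1; the 9:1 group's minor component
  holds exactly 10 of 100 cells, the smallest size the component-size
  rule tolerates.

What the generator does *not* emulate: count-level sampling (signals are
drawn directly at the PUI level), cell-type structure, doublets, ambient
contamination, or the long-tailed, zero-inflated sparsity of real
scRNA-seq. Passing the benchmark therefore demonstrates correct recovery
of well-separated Gaussian usage structure under dropout and mild
perturbation -- not performance on arbitrary real data.

## Evaluation

`countModalityErrors()` scores calls against ground truth: a row is an
error whenever the called modality differs from the generating one
(including detected truths called undetected); the confusion matrix is
reported over all four labels, errors are aggregated both per row and per
generating group, and the adjusted Rand index between generating component
labels and called memberships is computed per row over non-missing cells
and averaged within each true modality. The ARI implementation is the
standard contingency-table form, unit-tested against an exhaustive
pair-counting oracle on all set partitions of small item sets.

## Problem sizes and operating characteristics

The packaged checks run the full 1500-row benchmark at 100 cells
(noise-free and at missing fractions up to 60%), the 8000-cell variant
across missing fractions 5--60%, the five unbalanced-ratio designs, and
100-seed parameter-recovery sweeps; the complete suite runs in a few
minutes on one CPU.

Two operating characteristics deserve honest mention:

* At 100 cells, the two multimodal groups with adjacent means 0.5 apart
  sit close to the correction rule's decision boundary: their
  BIC(3)/BIC(2) ratio distribution straddles 0.95, so a few rows per
  thousand can be reduced to bimodal by the closeness rule itself. This
  is a property of the method's fixed constants, not of the fit (fully
  converged EM gives identical BICs, and an independent mixture
  implementation reproduces them to 0.1).
* At 50--60% missing (40--50 observed cells), the BIC genuinely prefers
  two components for a noticeable share of those same tight multimodal
  rows: with ~13 cells per component the likelihood gain of splitting a
  merged pair no longer clears the $3\ln n$ penalty. Modality error
  counts at high missingness are therefore dominated by this
  3-called-as-2 mode, concentrated in two of the fifteen groups, while
  bimodal and unimodal groups remain essentially error-free.

## A worked example

```{r example, eval = FALSE}
sim <- simulateSignalMatrix(defaultGroupSpecs(), nCells = 100,
                            replicates = 10, seed = 1)
calls <- identifyModalities(sim$signal, seed = 2)
calls
ev <- countModalityErrors(sim$truth, calls)
ev$confusion
```

For real data, `readSiteMatrix()` loads the count matrix and annotations,
`filter3UTR()` / `filterNon3UTR()` apply the expression filters,
`buildSignalMatrix()` produces the signal rows, and
`compareModalities()` / `transitionSummary()` track how a feature's
modality changes across cell types (same / change / appear / disappear,
where a feature filtered out in one cell type counts as undetected
there). `runPipeline()` wires the stages together and writes TSV tables
plus a JSON manifest of the resolved configuration.

## Known limitations

* The caller assumes Gaussian components on the PUI / transformed-ratio
  scale; strongly skewed or heavy-tailed usage distributions can inflate
  the component count.
* Components closer than a few standard deviations are not separable at
  realistic cell counts; the component-size rule additionally hides any
  subpopulation below 10 cells.
* Missing cells are removed per feature, so each feature may be fitted on
  a different cell subset; no imputation or sharing of information across
  features is attempted.
* Major/minor site labels are population-level (summed counts), not
  per-cell.
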