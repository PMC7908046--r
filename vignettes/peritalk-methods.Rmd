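---
title: "peritalk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peritalk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

Peritoneal dialysis (PD) progressively remodels the peritoneal membrane;
long-term exposure to dialysate drives peritoneal fibrosis (PF), the main
reason patients must abandon the therapy. Droplet single-cell RNA-seq of
peritoneal tissue and dialysis effluent makes it possible to follow this
process cell population by cell population across three disease stages:
healthy control tissue (`hc`), effluent after short-term PD (`st`, under
two weeks) and effluent after long-term PD (`lt`, over six years).

`peritalk` implements the analysis layer of such a study as a reusable,
fully tested pipeline:

1. **Composition** — per-sample cell-type proportions and stage
   comparisons (Mann-Whitney U).
2. **Differential expression** — per-cell-type, between-stage gene tests
   with a fold-change-plus-Bonferroni calling rule.
3. **Enrichment** — preranked GSEA (re-implemented weighted
   Kolmogorov-Smirnov statistic with a gene-set permutation null) and a
   local hypergeometric over-representation test on user-supplied GMT
   collections.
4. **Crosstalk** — the centerpiece: a ligand-receptor interaction network
   built from cell-type pseudobulk CPM with a hard activity threshold,
   typically revealing fibroblasts as a signaling hub.

Because the original patient data cannot be shipped, a negative-binomial
simulator with *planted ground truth* generates structurally equivalent
datasets; every downstream stage is validated against the planted truth.

## Normalization

All quantities derive from counts per million (CPM). Per cell,
$\mathrm{CPM}_{gc} = 10^6 \, x_{gc} / \sum_g x_{gc}$. Cell-type (or
cell-type-by-stage) **pseudobulk** profiles are computed
*sum-then-normalize*: member cells' raw counts are summed and the CPM is
taken on the summed vector. The mean-of-per-cell-CPM alternative is
available (`method = "mean"`), but the sum is the default because it
weights cells by their actual evidence and is robust to per-cell library
size variation; with equal library sizes the two coincide.

Per-cell expression used by the differential tests is
$\log_2(\mathrm{CPM}/100 + 1)$ — the counts-per-10k convention with
pseudocount 1 — chosen so that differences on this scale line up with the
$\log_2$ fold-change threshold of the calling rule.

Variable genes are ranked by the coefficient of variation (sample
standard deviation over mean, denominator $n-1$) of their pseudobulk CPM
across cell-cluster strata, not across cells; zero-mean genes are
excluded and ties break by gene symbol so the ranking is deterministic.

## The crosstalk rule

Given a directed ligand-receptor pair table (curated from experimentally
validated interaction databases) and pseudobulk CPM profiles, an
interaction *sender → receiver* via *(ligand, receptor)* is called

$$\textit{active} \iff \mathrm{CPM}_\text{ligand}^\text{sender} > \tau
\;\wedge\; \mathrm{CPM}_\text{receptor}^\text{receiver} > \tau,
\qquad \tau = 50 \text{ CPM}.$$

Numerical choices, all exposed as arguments:

* The inequality is **strict** ("above 50 CPM"); `strict = FALSE` gives
  $\geq$. A gene at exactly 50 CPM is inactive by default.
* **Autocrine** pairs (sender = receiver) are evaluated by default and can
  be disabled.
* Genes absent from the matrix score CPM 0 — a pair referencing an
  unmeasured gene is evaluable and inactive, not an error.
* Interactions are directional: `(A, B)` and `(B, A)` are distinct rows
  of the pair table.
* By default profiles are stratified *within* each stage
  (`by_group = TRUE`), so each stage has its own network; the
  across-stages variant is a flag. `compare_crosstalk()` classifies each
  edge from one stage to another as gained / lost / shared / absent.

The summary matrix reports, per ordered cell-type pair, both the count of
active ligand-receptor pairs and the distinct-ligand / distinct-receptor
tallies, since an interaction-count heatmap can reasonably be read either
way; both are emitted rather than guessing.

## Differential expression

Within one cell type, two stages are compared per gene on the
log-normalized per-cell values with a two-sided Welch *t*-test by default
(the pooled-variance Student's *t* and the Mann-Whitney test are flags).
The Welch default reflects the unequal group sizes (6/6/4 samples). A
gene is a DEG iff

$$|\log_2 \mathrm{FC}| \geq 0.58 \quad\text{and}\quad
p_\text{Bonferroni} < 0.05,$$

where $\log_2\mathrm{FC} = \log_2\frac{\overline{\mathrm{CPM}}_A +
1}{\overline{\mathrm{CPM}}_B + 1}$ over per-cell CPM means, and 0.58
$= \log_2 1.5$ to two decimals. The Bonferroni family is the set of genes
actually tested within that one (cell type, comparison) — not all genes
in all comparisons; Benjamini-Hochberg is available by flag. Only genes
detected in at least one cell of either stratum are tested; genes with
an identical value in every cell are skipped (not an error).

This stage deliberately does **not** re-implement a negative-binomial
GLM: the per-cell *t*-test on log-normalized values is the implemented
method, a simple and transparent choice for within-cell-type two-group
comparisons at hundreds of cells per stratum. This is the package's main
methodological simplification and the reason DEG lists from NB-GLM
tools will not match row for row.

## Enrichment

`enrichment_score()` is the weighted Kolmogorov-Smirnov running sum:
walking the ranked list, a hit increments by $|s|^p / \sum_{hits}|s|^p$
(default $p = 1$; $p = 0$ is the classic unweighted form), a miss
decrements by $1/(N - N_{hits})$; the enrichment score is the value of
maximal absolute deviation, signed. The implementation used for the
permutation null evaluates the same quantity from the sorted hit
positions alone in $O(k)$, which the test suite checks against the
$O(N)$ cumulative form, against an independently coded naive oracle, and
against an independent external implementation.

`gsea_preranked()` uses a **gene-set permutation** null (random same-size
draws from the ranked list), the natural null when the input is a
preranked list rather than per-sample expression. The permutation p-value
is side-conditional, as in the canonical GSEA method: for a positive ES,
$p = (1 + \#\{ES^* \geq ES\}) / (1 + \#\{ES^* \geq 0\})$, symmetrically
for negative. Two deliberate details:

* the $+1$ correction means $p$ is never exactly zero (a divergence from
  implementations that report 0);
* conditioning on the sign side keeps null p-values uniform, which the
  test suite verifies with a Kolmogorov-Smirnov uniformity check.

NES is ES over the mean |null ES| of matching sign; the FDR *q* is the
standard NES-based pooled-null ratio, capped at 1. Defaults: sets of
5–500 genes after intersection with the ranked list, 10,000 permutations,
ranking metric signed $\log_2$FC (sign × $-\log_{10} p$ by flag — the
ranking metric is a genuinely open choice and is documented, not
attributed).

Over-representation analysis is the upper-tail hypergeometric test
$P(X \geq \text{overlap})$ against a user-stated universe (the genes
actually tested for DE), with BH adjustment across sets. It is a local,
auditable replacement for web-service enrichment tools.

## The simulator and its planted truth

`simulate_dataset()` draws UMI counts per cell from a negative binomial
(the standard overdispersed count law for droplet scRNA-seq; the noise
model is a package choice, not sourced from data):

$$x_{gc} \sim \mathrm{NB}\left(\mu = L_c \cdot
\frac{r_{g,t(c),k(c)}}{\sum_g r}, \;\text{size} = \theta\right)$$

with $L_c$ lognormal library sizes, and stratum rates $r$ = baseline ×
marker multiplier × $2^{\text{planted effect}}$. Cell counts per sample
are Poisson around configured per-type means.

Ligand/receptor genes are handled specially: their rate is **calibrated
analytically** so the (cell type, stage) pseudobulk CPM lands on a stated
target — solving $r_i = t_i R_\text{rest} / (1 - T)$ for target fractions
$t_i$ — which makes the set of truly active circuits exactly derivable
from the configuration. Realized CPMs of planted targets are verified
post hoc within ±20%; one violating draw triggers a single deterministic
resample from seed + 1 (so a given seed can reproduce the draw of its
successor). At the default dispersion ($\theta = 2$) an occasional
residual miss slightly above 20% remains in small strata; it never
approaches the factor-of-two margin that separates planted circuits
(≥ 100 CPM) from background (8 CPM) around the 50 CPM threshold.

The truth manifest lists three things, all derived from the
configuration, never from the realized draw: planted DE genes (including
the expression changes *implied* by ligand-receptor calibration whenever
the between-stage target fold clears 1.5×), truly active circuits at the
50 CPM threshold, and expected per-stage cell-type proportions.

Two structural constraints keep the truth exact:

* a gene may not appear in both `de_spec` and the ligand-receptor
  universe — calibration pins its CPM, so a DE effect there would be
  silently unrealizable (config validation error);
* planted DE effects should be a small fraction of the library.
  Because CPM is compositional, planting large effects on highly
  expressed genes deflates every other gene's CPM and creates real
  secondary differential expression that the manifest does not list.
  The shipped configuration keeps planted mass under a few percent of
  the library; the default gene naming keeps filler genes at their
  natural baseline positions for the same reason.

### The shipped study configuration

`paper_like_config()` emulates the cohort at desk scale: 15 cell types
(mesothelial cell, fibroblast, myofibroblast, peritoneal cell, monocyte,
macrophage, T, B, NK, pDC, cDC, mast, plasma, endothelial, neutrophil),
**6 / 6 / 4 samples** for hc / st / lt (the long-term group size follows
the cohort summary; one methods passage says six long-term patients — the
discrepancy is noted here and the smaller number used), 2,000 genes,
~300 cells per sample, dispersion 2, lognormal libraries (median 4,000
UMIs, sdlog 0.35). Planted structure mirrors the study's headline
biology:

* fibroblast-hub short-term circuits (CCL5→CCR5 to T cells and
  macrophages, CCL2→CCR2 to monocytes, CXCL8→CXCR1 to neutrophils,
  TGFB1→TGFBR1 to mesothelial cells) at 110–160 CPM, an incoming
  IL6→IL6R edge from mesothelial cells, and a healthy-control
  VEGFA→FLT1 edge so stage comparisons contain lost as well as gained
  edges;
* antigen-presentation genes (CD74, HLA-DRA, HLA-DMA, HLA-DQA1) up
  1.5 log2 and PTGDS down 1.2 log2 in fibroblasts of both dialysis
  stages;
* composition shifts into long-term dialysis: fibroblast, monocyte and
  macrophage fractions fall; myofibroblast, T and NK fractions rise.

Every cell type keeps at least 15 expected cells per sample. This floor
is a correctness constraint, not cosmetics: in a stratum of only a few
dozen cells the 8-CPM background of a ligand-receptor gene corresponds
to an expected pseudobulk count near 1, and Poisson-level noise could
push it over the 50 CPM activity threshold, creating false network
edges; at ≥ 60 cells per stratum the crossing probability is
negligible (≪ 1e-6 per gene-stratum).

What the simulator does **not** emulate: doublets, ambient RNA, batch
effects, realistic manifold geometry (no PCA/UMAP structure), gene-gene
correlation, and cell-type misassignment. Passing tests therefore show
that the *pipeline's rules and statistics* behave as specified on data
with known structure — not that the biological conclusions of any real
dataset are correct.

## Reproducibility machinery

All randomness flows from a single integer seed. The pipeline derives
per-stage seeds by a stable hash of the stage name, so a stage rerun in
isolation reproduces its in-pipeline result. The run manifest records a
content hash of the configuration (a 31-bit polynomial rolling hash of
its canonical JSON — a fingerprint for change detection, not a
cryptographic digest) and contains no timestamp, so identical
config + seed yields byte-identical output trees.

Problem sizes used by the validation suite are deliberately desk-scale
choices: 20 seeds of the full shipped configuration for exact circuit
recovery; 50 seeds of a 300-gene, 100-cells-per-stratum design for DE
sensitivity/FDR; 500 random sets for the GSEA null-uniformity check; 100
seeds for GSEA power at 1,000 permutations; 2,000 permutations for the
end-to-end run. The shipped defaults for real use are larger (10,000
permutations).

## Known limitations

* No multiplicity correction across cell types in composition testing
  (the per-type starring convention); with 15 types at α = 0.05, expect
  ~0.75 false stars per comparison under the null.
* The DE stage tests cells, not samples: cells from the same patient are
  treated as independent, which overstates confidence on real data where
  patients are the experimental unit. On simulated data without a
  patient random effect the calibration is exact; on real data a
  pseudobulk-per-sample or mixed-model approach would be more
  conservative.
* Bonferroni ≠ FDR: the calling rule follows the stricter Bonferroni
  convention; BH is available but results are labeled accordingly.
* The crosstalk rule is a hard threshold on mean expression: no
  specificity permutation (CellPhoneDB-style), no expression-product
  scoring, no spatial constraints. Edges are hypotheses, not evidence of
  signaling.

## A minimal session

```{r example}
library(peritalk)

cfg <- paper_like_config(seed = 1)
ds  <- simulate_dataset(cfg)

pb    <- pseudobulk_cpm(ds$counts, ds$cells, by_group = TRUE)
calls <- call_interactions(pb, cfg$lr_pairs, threshold = 50)
st    <- subset(calls, group == "st")
focal_network(st, "fibroblast")

deg <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
gsea <- gsea_preranked(rank_genes(deg),
                       list(UP = cfg$de_spec$gene[cfg$de_spec$log2_effect > 0]),
                       n_perm = 2000, seed = 1, min_size = 3)

compare_composition(ds$cells, "st", "lt")
```
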