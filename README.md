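# peritalk

Cell-type crosstalk, composition and expression analysis for peritoneal
dialysis single-cell RNA-seq.

Peritoneal dialysis (PD) gradually turns the peritoneal membrane
fibrotic. Single-cell RNA-seq of peritoneal tissue and dialysis effluent
across three stages — healthy control (`hc`), short-term PD (`st`) and
long-term PD (`lt`) — shows *which* cell populations change and *how
they talk to each other* as fibrosis progresses, with fibroblasts
emerging as a pro-inflammatory signaling hub. `peritalk` packages that
analysis as tested, reusable R functions for anyone working with staged,
multi-sample, multi-cell-type UMI count data.

At its core is the pseudobulk CPM crosstalk rule. With per-cell-type
counts-per-million computed sum-then-normalize, a directed
ligand-receptor interaction *sender → receiver* is

```
active  ⇔  CPM(ligand | sender) > 50  AND  CPM(receptor | receiver) > 50
```

with a strict inequality at the threshold. Around it sit the supporting
stages: per-sample composition testing (Mann-Whitney U, exact at small
n), per-cell-type differential expression (Welch t on log2(CPM/100 + 1),
called at |log2FC| ≥ 0.58 with Bonferroni p < 0.05), preranked GSEA
(weighted Kolmogorov-Smirnov score, gene-set permutation null) and
hypergeometric over-representation on GMT collections. A
negative-binomial simulator with planted ground truth — markers,
differential genes, active circuits, stage-wise proportions — stands in
for the patient data and makes every stage testable end to end.

## A worked example

Simulate the shipped study-scale configuration (15 cell types, 6/6/4
samples per stage, 2,000 genes) and build the short-term-stage network:

```r
library(peritalk)

cfg <- paper_like_config(seed = 1)
ds  <- simulate_dataset(cfg)            # counts, cell table, truth manifest

pb    <- pseudobulk_cpm(ds$counts, ds$cells, by_group = TRUE)
calls <- call_interactions(pb, cfg$lr_pairs, threshold = 50)
st    <- calls[calls$group == "st", ]
st[st$active, c("sender","ligand","receiver","receptor",
                "ligand_cpm","receptor_cpm")]
#>       sender ligand    receiver receptor ligand_cpm receptor_cpm
#>   fibroblast   CCL5  macrophage     CCR5      151.9        165.5
#>   fibroblast  TGFB1 mesothelial   TGFBR1      123.8        115.1
#>   fibroblast   CCL2    monocyte     CCR2      136.4        123.9
#>   fibroblast  CXCL8  neutrophil    CXCR1      171.6        163.3
#>   fibroblast   CCL5           T     CCR5      151.9        137.2
#>  mesothelial    IL6  fibroblast     IL6R      106.8        116.1
```

Every called edge is a planted circuit: the fibroblast sends chemokine
and TGFB1 signals to immune and mesothelial populations and receives
IL6, each endpoint above 50 CPM in its own cell type. The focal view
summarizes the hub:

```r
focal_network(st, "fibroblast")
#> focal crosstalk network for 'fibroblast': 1 incoming, 5 outgoing
#>       partner n_edges
#> 1 mesothelial       2
#> 2  macrophage       1
#> 3    monocyte       1
#> 4  neutrophil       1
#> 5           T       1
```

Differential expression in fibroblasts, short-term versus control — the
planted antigen-presentation program tops the list (log2FC is the
fold change on CPM with pseudocount 1; pct the fraction of cells
expressing):

```r
deg <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
head(deg[, c("gene","log2fc","p_adj","pct_a","pct_b","significant")])
#>      gene log2fc    p_adj pct_a  pct_b significant
#>      CCL5   4.99 1.80e-31 0.417 0.0176        TRUE
#>     CXCL8   4.04 1.96e-31 0.450 0.0396        TRUE
#>   HLA-DRA   1.49 1.95e-29 0.988 0.9119        TRUE
#>      CD74   1.47 3.86e-28 0.988 0.9163        TRUE
#>  HLA-DQA1   1.58 1.62e-27 0.961 0.8678        TRUE
#>     PTGDS  -1.46 1.55e-24 0.707 0.9251        TRUE
```

And the composition shift into long-term dialysis (per-sample fractions,
Mann-Whitney U, 6 vs 4 samples):

```r
comp <- compare_composition(ds$cells, "st", "lt")
comp[comp$significant, c("cell_type","mean_a","mean_b","u_stat","p","direction")]
#>      cell_type mean_a mean_b u_stat       p direction
#>     fibroblast 0.1546 0.0539      0 0.00952      down
#>     macrophage 0.1127 0.0508      0 0.00952      down
#>       monocyte 0.1082 0.0577      0 0.00952      down
#>  myofibroblast 0.0416 0.0896      0 0.00952        up
#>             NK 0.0402 0.0831      0 0.00952        up
#>              T 0.0642 0.1593      0 0.00952      up
```

Fibroblast, monocyte and macrophage fractions fall while myofibroblast,
T and NK fractions rise — the planted stage transition, recovered at the
minimal attainable exact p for 6-vs-4 samples (2/210 ≈ 0.0095).

`run_pipeline(pipeline_config(...))` chains all stages (normalize →
composition → DE → enrichment → crosstalk) into a directory of TSVs plus
a JSON manifest, byte-identical under a fixed seed; a thin command-line
wrapper lives at `inst/cli/peritalk.R`. The methods vignette
(`vignettes/peritalk-methods.Rmd`) documents the model, parameter
choices, simulator design and known limitations.

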