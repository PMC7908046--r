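Package: peritalk
Title: Cell-Type Crosstalk, Composition and Expression Analysis for
    Peritoneal Dialysis Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet single-cell RNA-seq of peritoneal
    effluent and tissue across dialysis stages (healthy control, short-term
    and long-term peritoneal dialysis). Provides 10x-convention Matrix Market
    input/output, counts-per-million (CPM) and per-cell-type pseudobulk
    normalization, coefficient-of-variation variable-gene selection,
    per-sample cell-type composition testing (Mann-Whitney U), per-cell-type
    differential expression with a fold-change plus Bonferroni calling rule,
    preranked gene set enrichment analysis (weighted Kolmogorov-Smirnov
    statistic with gene-set permutation) and hypergeometric
    over-representation analysis, and the CPM-thresholded ligand-receptor
    crosstalk network in which an interaction is called active only when the
    ligand and the receptor each exceed a CPM threshold in their respective
    cell types. A negative-binomial simulator with planted ground truth
    (markers, differential genes, active ligand-receptor circuits) supports
    end-to-end validation without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
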