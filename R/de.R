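#' Per-gene log2 fold change between groups within one cell type
#'
#' log2FC = log2((meanCPM_A + pc) / (meanCPM_B + pc)) where meanCPM is the
#' mean of per-cell CPM within the stratum and `pc` is a pseudocount
#' (default 1 on the CPM scale). The 0.58 calling threshold corresponds to
#' a 1.5-fold change (log2(1.5) = 0.585).
#'
#' @param counts Count matrix.
#' @param cells Cell table.
#' @param cell_type Cell type defining the stratum.
#' @param group_a,group_b Groups compared (A over B).
#' @param pseudocount Added to both mean CPMs (default 1).
#' @return Named numeric vector over all genes.
#' @export
log2_fold_change <- function(counts, cells, cell_type, group_a, group_b,
                             pseudocount = 1) {
  al <- align_cells(counts, cells)
  ia <- al$cells$cell_type == cell_type & al$cells$group == group_a
  ib <- al$cells$cell_type == cell_type & al$cells$group == group_b
  if (!any(ia) || !any(ib))
    stop("empty stratum for cell type '", cell_type, "'")
  cpm <- cpm_per_cell(al$counts)
  ma <- Matrix::rowMeans(cpm[, ia, drop = FALSE])
  mb <- Matrix::rowMeans(cpm[, ib, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p) with m = number of tests supplied.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values, same length.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Per-cell-type differential expression between two groups
#'
#' Tests genes on log-normalized per-cell expression
#' (log2(CPM/100 + 1)) with a two-sided Welch t-test by default
#' (`var_equal = TRUE` for the pooled-variance Student's t,
#' `method = "wilcox"` for Mann-Whitney). Only genes detected in at least
#' one cell of either stratum are tested; genes with an identical value in
#' every cell of both strata are skipped, not an error. Adjustment is
#' Bonferroni (default) over the genes actually tested in this cell type
#' and comparison; a gene is called significant iff
#' |log2FC| >= `lfc_threshold` AND adjusted p < `alpha`.
#'
#' @param counts Count matrix.
#' @param cells Cell table.
#' @param cell_type Cell type stratum (>= 2 cells per group required).
#' @param group_a,group_b Groups compared (fold change is A over B).
#' @param method `"t"` (default) or `"wilcox"`.
#' @param var_equal Pooled-variance Student's t instead of Welch.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.58).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param pseudocount Pseudocount for the fold change, CPM scale.
#' @return data.frame ordered by raw p: `cell_type`, `comparison`, `gene`,
#'   `mean_a`, `mean_b` (mean log-normalized expression), `pct_a`, `pct_b`
#'   (fraction of cells with count > 0), `log2fc`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
de_test <- function(counts, cells, cell_type, group_a, group_b,
                    method = c("t", "wilcox"), var_equal = FALSE,
                    p_adjust = c("bonferroni", "BH"),
                    lfc_threshold = 0.58, alpha = 0.05, pseudocount = 1) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  al <- align_cells(counts, cells)
  ia <- which(al$cells$cell_type == cell_type & al$cells$group == group_a)
  ib <- which(al$cells$cell_type == cell_type & al$cells$group == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 cells per stratum in cell type '", cell_type, "'")
  sub <- al$counts[, c(ia, ib), drop = FALSE]
  cpm <- cpm_per_cell(sub)
  lx <- log_normalize(cpm)
  a_cols <- seq_along(ia)
  b_cols <- length(ia) + seq_along(ib)
  cnt_a <- sub[, a_cols, drop = FALSE]
  cnt_b <- sub[, b_cols, drop = FALSE]
  pct_a <- Matrix::rowSums(cnt_a > 0) / length(ia)
  pct_b <- Matrix::rowSums(cnt_b > 0) / length(ib)
  la <- as.matrix(lx[, a_cols, drop = FALSE])
  lb <- as.matrix(lx[, b_cols, drop = FALSE])
  expressed <- pct_a > 0 | pct_b > 0
  lfc_all <- {
    ma <- Matrix::rowMeans(cpm[, a_cols, drop = FALSE])
    mb <- Matrix::rowMeans(cpm[, b_cols, drop = FALSE])
    log2((ma + pseudocount) / (mb + pseudocount))
  }
  genes <- rownames(sub)[expressed]
  p_raw <- vapply(genes, function(g) {
    x <- la[g, ]; y <- lb[g, ]
    vals <- c(x, y)
    if (all(vals == vals[1])) return(NA_real_)  # constant gene: skip
    if (method == "t") {
      tryCatch(t.test(x, y, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)
    } else {
      suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }, numeric(1))
  keep <- !is.na(p_raw)
  genes <- genes[keep]
  p_raw <- p_raw[keep]
  p_adj_v <- if (p_adjust == "bonferroni") bonferroni_adjust(p_raw) else
    p.adjust(p_raw, method = "BH")
  out <- data.frame(
    cell_type = cell_type,
    comparison = paste0(group_a, "_vs_", group_b),
    gene = genes,
    mean_a = rowMeans(la)[genes],
    mean_b = rowMeans(lb)[genes],
    pct_a = pct_a[genes],
    pct_b = pct_b[genes],
    log2fc = lfc_all[genes],
    p_raw = p_raw,
    p_adj = p_adj_v,
    stringsAsFactors = FALSE)
  out$significant <- abs(out$log2fc) >= lfc_threshold & out$p_adj < alpha
  out <- out[order(out$p_raw, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-map summary table for selected genes
#'
#' Per (gene, cell type, group): mean log-normalized expression and the
#' fraction of cells expressing (count > 0), the two quantities encoded by
#' dot color and dot size in per-cluster expression dot-maps. If DE result
#' tables are supplied, a `flagged` column marks (gene, cell type)
#' combinations significant in every one of the supplied comparisons —
#' the "red box" convention for genes changed in both st-vs-hc and
#' lt-vs-hc.
#'
#' @param counts Count matrix.
#' @param cells Cell table.
#' @param genes Genes to summarize; unknown genes are skipped with a
#'   warning.
#' @param de_results Optional list of data.frames from [de_test()] (one
#'   per comparison, same cell types).
#' @return Tidy data.frame: `gene`, `cell_type`, `group`, `mean_expr`,
#'   `pct_expr` (+ `flagged` when `de_results` given).
#' @export
dotmap_table <- function(counts, cells, genes, de_results = NULL) {
  al <- align_cells(counts, cells)
  unknown <- setdiff(genes, rownames(al$counts))
  if (length(unknown)) {
    warning("unknown gene(s) skipped: ", paste(unknown, collapse = ", "))
    genes <- setdiff(genes, unknown)
  }
  lx <- log_normalize(cpm_per_cell(al$counts))
  key <- interaction(al$cells$cell_type, al$cells$group, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    ct <- al$cells$cell_type[idx[1]]
    gr <- as.character(al$cells$group[idx[1]])
    sub_l <- lx[genes, idx, drop = FALSE]
    sub_c <- al$counts[genes, idx, drop = FALSE]
    data.frame(gene = genes, cell_type = ct, group = gr,
               mean_expr = Matrix::rowMeans(sub_l),
               pct_expr = Matrix::rowSums(sub_c > 0) / length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(de_results)) {
    sig_keys <- lapply(de_results, function(d) {
      paste(d$gene[d$significant], d$cell_type[d$significant])
    })
    k <- paste(out$gene, out$cell_type)
    out$flagged <- Reduce(`&`, lapply(sig_keys, function(s) k %in% s))
  }
  out
}
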