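#' Counts per million, per cell
#'
#' CPM_gc = count_gc / total_c * 1e6. Every retained cell must have a
#' positive total; zero-total cells are a hard error (they carry no
#' expression information and would divide by zero) and are listed by
#' barcode so they can be filtered upstream.
#'
#' @param counts Count matrix (genes x cells).
#' @return A `dgCMatrix` of CPM values; every column sums to 1e6.
#' @export
cpm_per_cell <- function(counts) {
  counts <- validate_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  out <- counts %*% Matrix::Diagonal(x = 1e6 / totals)
  dimnames(out) <- dimnames(counts)
  as(out, "CsparseMatrix")
}

#' Per-cell-type (x optional group) pseudobulk CPM profiles
#'
#' For each stratum — a cell type, or a (cell type, group) pair when
#' `by_group = TRUE` — member cells' counts are aggregated and the CPM is
#' computed on the aggregate. The default (`method = "sum"`)
#' sums raw counts then normalizes the summed vector (robust to per-cell
#' library-size variation); `method = "mean"` averages per-cell CPM
#' instead. Strata with zero cells do not appear.
#'
#' @param counts Count matrix.
#' @param cells Cell table (validated; restricted to common cells).
#' @param by_group Stratify by (cell type, group) instead of cell type only.
#' @param method `"sum"` (sum-then-normalize, default) or `"mean"`.
#' @return An object of class `pseudobulk` with elements `cpm` (genes x
#'   strata matrix, each column summing to 1e6), and `meta` (data.frame:
#'   `stratum`, `cell_type`, `group`, `n_cells`, `total_counts`).
#' @export
pseudobulk_cpm <- function(counts, cells, by_group = FALSE,
                           method = c("sum", "mean")) {
  method <- match.arg(method)
  al <- align_cells(counts, cells)
  counts <- al$counts
  cells <- al$cells
  key <- if (by_group) {
    paste(cells$cell_type, as.character(cells$group), sep = "|")
  } else {
    as.character(cells$cell_type)
  }
  strata <- unique(key)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("zero-total cell(s) present; filter before pseudobulk")
  cpm <- matrix(0, nrow(counts), length(strata),
                dimnames = list(rownames(counts), strata))
  n_cells <- integer(length(strata))
  total_counts <- numeric(length(strata))
  per_cell <- if (method == "mean") cpm_per_cell(counts) else NULL
  for (i in seq_along(strata)) {
    idx <- which(key == strata[i])
    n_cells[i] <- length(idx)
    total_counts[i] <- sum(totals[idx])
    if (method == "sum") {
      s <- Matrix::rowSums(counts[, idx, drop = FALSE])
      cpm[, i] <- s / sum(s) * 1e6
    } else {
      m <- Matrix::rowMeans(per_cell[, idx, drop = FALSE])
      cpm[, i] <- m / sum(m) * 1e6
    }
  }
  meta <- data.frame(
    stratum = strata,
    cell_type = if (by_group) sub("\\|[^|]*$", "", strata) else strata,
    group = if (by_group) sub("^.*\\|", "", strata) else NA_character_,
    n_cells = n_cells,
    total_counts = total_counts,
    stringsAsFactors = FALSE
  )
  structure(list(cpm = cpm, meta = meta, method = method),
            class = "pseudobulk")
}

#' @exportS3Method base::print
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk CPM profiles: %d genes x %d strata (method=%s)\n",
              nrow(x$cpm), ncol(x$cpm), x$method))
  print(x$meta)
  invisible(x)
}

#' Log-normalize a CPM matrix
#'
#' value = log2(CPM / 100 + 1), i.e. log2 of counts-per-10k with
#' pseudocount 1 — the same scale as the fold-change threshold used in
#' differential calling. Monotone; zeros map to zero.
#'
#' @param cpm_matrix Non-negative CPM matrix (dense or sparse).
#' @return Matrix of the same shape.
#' @export
log_normalize <- function(cpm_matrix) {
  if (is(cpm_matrix, "Matrix")) {
    if (length(cpm_matrix@x) && min(cpm_matrix@x) < 0)
      stop("negative values in CPM matrix")
    cpm_matrix@x <- log2(cpm_matrix@x / 100 + 1)
    return(cpm_matrix)
  }
  if (any(cpm_matrix < 0)) stop("negative values in CPM matrix")
  log2(cpm_matrix / 100 + 1)
}

#' Highly variable genes by coefficient of variation across strata
#'
#' Per gene, CV = sd / mean of its pseudobulk CPM across cell-cluster
#' strata (sample sd, denominator n - 1). Genes with zero mean are
#' excluded; the top `n_top` by descending CV are returned, ties broken by
#' gene symbol ascending.
#'
#' @param profiles A `pseudobulk` object with at least two strata.
#' @param n_top Number of genes to return (<= number of genes).
#' @return Character vector of gene symbols, most variable first.
#' @export
hvg_by_cv <- function(profiles, n_top) {
  stopifnot(inherits(profiles, "pseudobulk"))
  cpm <- profiles$cpm
  if (ncol(cpm) < 2) stop("need at least 2 strata to compute CV")
  if (n_top > nrow(cpm)) stop("n_top exceeds gene count")
  mu <- rowMeans(cpm)
  s <- apply(cpm, 1, sd)
  keep <- mu > 0
  cv <- s[keep] / mu[keep]
  g <- rownames(cpm)[keep]
  ord <- order(-cv, g)
  g[ord][seq_len(min(n_top, length(g)))]
}
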