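#' Per-sample cell-type proportions
#'
#' @param cells Validated cell table.
#' @return data.frame with `sample_id`, `group`, then one column per cell
#'   type; each row's type fractions sum to 1.
#' @export
compute_proportions <- function(cells) {
  cells <- validate_cell_table(cells)
  if (!nrow(cells)) stop("empty cell table")
  tab <- table(cells$sample_id, cells$cell_type)
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  grp <- cells$group[match(rownames(frac), cells$sample_id)]
  out <- data.frame(sample_id = rownames(frac),
                    group = as.character(grp),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame.matrix(frac))
}

#' Mann-Whitney U test
#'
#' U is computed with the midrank convention for ties; the reported
#' statistic is min(U_A, U_B). The two-tailed p-value comes from the exact
#' permutation distribution when nA + nB <= 16 and there are no ties, and
#' otherwise from the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return `list(u =, u_a =, p =)`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  exact <- (na + nb) <= 16 && !any(duplicated(c(a, b)))
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(u = min(u_a, u_b), u_a = u_a, p = min(p, 1))
}

#' Compare cell-type composition between two groups
#'
#' Per cell type present in either group, per-sample fractions are
#' compared with the Mann-Whitney U test; the significance flag is
#' two-tailed p < alpha with no multiplicity correction across cell types
#' (the convention of per-type starring in stage-comparison figures —
#' noted as a limitation).
#'
#' @param cells Cell table.
#' @param group_a,group_b Group labels from [GROUP_LEVELS].
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `cell_type`, `n_a`, `n_b` (sample counts),
#'   `mean_a`, `mean_b` (mean fractions), `u_stat`, `p`, `direction`
#'   (`"up"`/`"down"`/`"none"`: change in B relative to A), `significant`.
#' @export
compare_composition <- function(cells, group_a, group_b, alpha = 0.05) {
  cells <- validate_cell_table(cells)
  stopifnot(group_a %in% GROUP_LEVELS, group_b %in% GROUP_LEVELS)
  cells <- cells[cells$group %in% c(group_a, group_b), , drop = FALSE]
  props <- compute_proportions(cells)
  for (g in c(group_a, group_b)) {
    if (sum(props$group == g) < 2)
      stop("group '", g, "' has fewer than 2 samples; U test degenerate")
  }
  types <- setdiff(names(props), c("sample_id", "group"))
  res <- lapply(types, function(ct) {
    va <- props[props$group == group_a, ct]
    vb <- props[props$group == group_b, ct]
    if (all(va == 0) && all(vb == 0)) return(NULL)
    mw <- mann_whitney_u(va, vb)
    d <- mean(vb) - mean(va)
    data.frame(cell_type = ct, n_a = length(va), n_b = length(vb),
               mean_a = mean(va), mean_b = mean(vb),
               u_stat = mw$u, p = mw$p,
               direction = if (d > 0) "up" else if (d < 0) "down" else "none",
               significant = mw$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
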