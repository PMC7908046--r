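#' Build a ranked gene list from a DE table
#'
#' Default metric is the signed log2 fold change; `"signed_logp"` ranks by
#' sign(log2FC) x (-log10 raw p) instead. Scores are sorted descending with
#' ties broken by gene symbol ascending, so the ranking is deterministic.
#'
#' @param deg_results data.frame from [de_test()] (one cell type, one
#'   comparison).
#' @param metric `"log2fc"` (default) or `"signed_logp"`.
#' @return data.frame `gene`, `score`, ordered score-descending.
#' @export
rank_genes <- function(deg_results, metric = c("log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  if (!nrow(deg_results)) stop("empty DE table")
  score <- switch(metric,
    log2fc = deg_results$log2fc,
    signed_logp = sign(deg_results$log2fc) *
      -log10(pmax(deg_results$p_raw, 1e-300)))
  ord <- order(-score, deg_results$gene)
  out <- data.frame(gene = deg_results$gene[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' GSEA weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom: a gene in the set increments the
#' running sum by |score|^p / sum over hits of |score|^p, a gene outside
#' the set decrements it by 1/(N - N_hits). The enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed).
#' `weight_p = 0` gives the classic unweighted Kolmogorov-Smirnov form.
#'
#' @param ranked data.frame `gene`, `score` (score descending) as from
#'   [rank_genes()].
#' @param gene_set Character vector; must overlap the ranked genes.
#' @param weight_p Score weight exponent p >= 0 (default 1).
#' @return `list(es =, running_sum =)` with `running_sum` of length N.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(weight_p >= 0)
  hits <- ranked$gene %in% gene_set
  n <- length(hits)
  n_hits <- sum(hits)
  if (n_hits == 0) stop("gene set has no overlap with the ranked list")
  if (n_hits == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked$score)^weight_p
  denom <- sum(w[hits])
  inc <- if (denom > 0) w / denom else rep(1 / n_hits, n)
  step <- ifelse(hits, inc, -1 / (n - n_hits))
  rs <- cumsum(step)
  es <- rs[which.max(abs(rs))]
  list(es = es, running_sum = rs)
}

# Enrichment score from sorted hit positions only: the running sum is
# piecewise decreasing between hits, so its extremes occur just before or
# just after a hit. O(k) per evaluation; used by the permutation null.
# pos: sorted hit positions; w: |score|^p over the whole list; n: length.
.es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  wh <- w[pos]
  denom <- sum(wh)
  cw <- if (denom > 0) cumsum(wh) / denom else seq_len(k) / k
  miss <- 1 / (n - k)
  gap <- (pos - seq_len(k)) * miss   # cumulative miss decrement before hit i
  after <- cw - gap                  # running sum just after hit i
  before <- c(0, cw[-k]) - gap       # running sum just before hit i
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked GSEA with gene-set permutation
#'
#' For each gene set (after intersection with the ranked list and size
#' filtering), the observed enrichment score is compared with a null of
#' `n_perm` random same-size gene draws from the ranked list. The
#' permutation p-value is side-conditional, as in the canonical GSEA
#' implementation: for a positive ES, (1 + #[null ES* >= ES]) /
#' (1 + #[null ES* >= 0]), and symmetrically for a negative ES. The +1
#' correction keeps p away from exactly zero, and conditioning on the
#' sign side keeps null p-values uniform. NES = ES / mean(|null ES| of
#' matching sign); the FDR q is the standard NES-based ratio over the
#' pooled null, capped at 1.
#'
#' @param ranked data.frame `gene`, `score`, score descending.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param min_size,max_size Set-size filter after intersection (5, 500).
#' @param weight_p Weight exponent (default 1).
#' @return data.frame: `set`, `n_hits`, `es`, `nes`, `p_perm`, `fdr_q`,
#'   `leading_edge` (semicolon-joined), ordered by `p_perm`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 10000, seed = NULL,
                           min_size = 5, max_size = 500, weight_p = 1) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_p
  members <- lapply(collection, function(s) which(ranked$gene %in% s))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stop("no gene set within the size filter overlaps the list")
  members <- members[keep]
  res <- lapply(names(members), function(nm) {
    pos <- sort(members[[nm]])
    k <- length(pos)
    es <- .es_from_positions(pos, w, n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      .es_from_positions(sort(sample.int(n, k)), w, n)
    }, numeric(1))
    same_side <- if (es >= 0) null_es >= 0 else null_es < 0
    p <- (1 + sum(same_side & abs(null_es) >= abs(es))) /
      (1 + sum(same_side))
    denom <- if (any(same_side)) mean(abs(null_es[same_side])) else
      mean(abs(null_es))
    nes <- if (denom > 0) es / denom else 0
    # normalize the null the same way for the pooled FDR
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    null_nes <- ifelse(null_es >= 0,
                       null_es / ifelse(is.nan(pos_mean), 1, pos_mean),
                       null_es / ifelse(is.nan(neg_mean), 1, neg_mean))
    # leading edge: set members at or before (after, for negative ES) the
    # extremum of the running sum
    rs <- enrichment_score(ranked, ranked$gene[pos], weight_p)$running_sum
    peak <- which.max(abs(rs))
    le_pos <- if (es >= 0) pos[pos <= peak] else pos[pos >= peak]
    data.frame(set = nm, n_hits = k, es = es, nes = nes, p_perm = p,
               null_nes = I(list(null_nes)),
               leading_edge = paste(ranked$gene[le_pos], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  pooled <- unlist(res$null_nes)
  res$fdr_q <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$nes[i]
    if (nes >= 0) {
      n_side <- sum(pooled >= 0)
      o_side <- sum(res$nes >= 0)
      null_frac <- if (n_side) sum(pooled >= nes) / n_side else 0
      obs_frac <- if (o_side) sum(res$nes >= nes) / o_side else 0
    } else {
      n_side <- sum(pooled < 0)
      o_side <- sum(res$nes < 0)
      null_frac <- if (n_side) sum(pooled <= nes) / n_side else 0
      obs_frac <- if (o_side) sum(res$nes <= nes) / o_side else 0
    }
    if (obs_frac == 0) return(1)
    min(1, null_frac / obs_frac)
  }, numeric(1))
  res$null_nes <- NULL
  res <- res[order(res$p_perm, -abs(res$nes), res$set),
             c("set", "n_hits", "es", "nes", "p_perm", "fdr_q",
               "leading_edge")]
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test P(X >= overlap) per gene set, with
#' Benjamini-Hochberg adjustment across sets. Gene sets are intersected
#' with the universe first; query genes outside the universe are dropped
#' with a warning.
#'
#' @param query Character vector of genes of interest (e.g. significant
#'   DEGs).
#' @param collection Named list of gene sets.
#' @param universe Character vector of all testable genes.
#' @return data.frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_hyper`, `p_adj`, ordered by `p_hyper`.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("empty query after restriction to universe")
  }
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    ov <- length(intersect(query, s))
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s),
               query_size = length(query),
               universe_size = length(universe),
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_hyper, method = "BH")
  out <- out[order(out$p_hyper, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
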