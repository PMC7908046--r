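# Independent oracles used across tests. These are deliberately naive
# re-derivations (loops, enumeration) kept separate from the package code.

# Step-by-step weighted KS running sum, O(N) loop.
naive_es <- function(ranked, gene_set, weight_p = 1) {
  rs <- 0
  best <- 0
  hits <- ranked$gene %in% gene_set
  w <- abs(ranked$score)^weight_p
  denom <- sum(w[hits])
  n <- nrow(ranked)
  nh <- sum(hits)
  trace <- numeric(n)
  for (i in seq_len(n)) {
    rs <- rs + if (hits[i]) {
      if (denom > 0) w[i] / denom else 1 / nh
    } else {
      -1 / (n - nh)
    }
    trace[i] <- rs
    if (abs(rs) > abs(best)) best <- rs
  }
  list(es = best, running_sum = trace)
}

# Exact two-tailed Mann-Whitney p by enumeration of all group assignments.
enum_mw_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  n <- length(pool)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, u_of)
  mu <- na * (length(b)) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# A small, fast simulation configuration for unit tests.
quick_config <- function(seed = 1, n_genes = 120, cells = 40,
                         samples = c(hc = 2, st = 2, lt = 2),
                         de_spec = NULL, lr_spec = NULL, lr_pairs = NULL,
                         markers = list(), dispersion = 2) {
  sim_config(
    n_genes = n_genes,
    cell_types = data.frame(name = c("fibroblast", "mesothelial"),
                            cells_hc = cells, cells_st = cells,
                            cells_lt = cells),
    markers = markers,
    samples_per_group = samples,
    dispersion = dispersion,
    de_spec = de_spec, lr_spec = lr_spec, lr_pairs = lr_pairs,
    seed = seed)
}

# Hand-constructed pseudobulk object (genes x strata CPM), unstratified.
make_pseudobulk <- function(cpm, groups = NULL) {
  meta <- data.frame(
    stratum = colnames(cpm),
    cell_type = if (is.null(groups)) colnames(cpm) else
      sub("\\|[^|]*$", "", colnames(cpm)),
    group = if (is.null(groups)) NA_character_ else groups,
    n_cells = 10L,
    total_counts = 1e5,
    stringsAsFactors = FALSE)
  structure(list(cpm = cpm, meta = meta, method = "sum"),
            class = "pseudobulk")
}

# Random count matrix + cell table for I/O round trips.
random_dataset <- function(seed = 1, n_genes = 30, n_cells = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("C%03d", 1:n_cells)))
  cells <- data.frame(
    cell_id = colnames(m),
    sample_id = rep(c("s1", "s2"), length.out = n_cells),
    group = rep(c("hc", "st"), length.out = n_cells),
    cell_type = rep(c("fibroblast", "T"), each = n_cells / 2),
    stringsAsFactors = FALSE)
  list(counts = Matrix::Matrix(m, sparse = TRUE), cells = cells)
}
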