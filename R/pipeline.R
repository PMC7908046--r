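#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' objects. Thresholds default to the study constants: 50 CPM for
#' crosstalk activity, |log2FC| >= 0.58 plus Bonferroni p < 0.05 for
#' differential calling, and 10,000 permutations for preranked GSEA.
#'
#' @param counts Count matrix, or path to a `.mtx` file (then `features`
#'   and `barcodes` must be given).
#' @param cells Cell table or path.
#' @param lr_pairs Ligand-receptor pair table or path.
#' @param gmt Gene-set collection, path to a GMT, or NULL to skip
#'   enrichment.
#' @param features,barcodes Sidecar paths when `counts` is a path.
#' @param out_dir Output directory for result TSVs and the manifest.
#' @param cpm_threshold Crosstalk activity threshold (default 50).
#' @param lfc_threshold DE fold-change threshold (default 0.58).
#' @param alpha Significance level (default 0.05).
#' @param n_perm GSEA permutations (default 10000).
#' @param min_size,max_size GSEA set-size filter (5, 500).
#' @param comparisons List of c(groupA, groupB) pairs (defaults to
#'   st-vs-hc, lt-vs-hc, lt-vs-st).
#' @param de_cell_types Cell types to test (NULL = all with enough cells).
#' @param focal_types Focal types for network views (default
#'   "fibroblast").
#' @param pseudobulk_by_group Compute crosstalk pseudobulks within each
#'   group (default TRUE).
#' @param seed Global seed; per-stage seeds are derived stably from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, cells, lr_pairs, gmt = NULL,
                            features = NULL, barcodes = NULL,
                            out_dir = "peritalk_results",
                            cpm_threshold = 50, lfc_threshold = 0.58,
                            alpha = 0.05, n_perm = 10000,
                            min_size = 5, max_size = 500,
                            comparisons = list(c("st", "hc"), c("lt", "hc"),
                                               c("lt", "st")),
                            de_cell_types = NULL,
                            focal_types = "fibroblast",
                            pseudobulk_by_group = TRUE,
                            seed = 1) {
  stopifnot(cpm_threshold > 0, lfc_threshold > 0, alpha > 0)
  for (cmp in comparisons) {
    if (!all(cmp %in% GROUP_LEVELS))
      stop("comparison groups must be drawn from: ",
           paste(GROUP_LEVELS, collapse = ", "))
  }
  structure(list(
    counts = counts, cells = cells, lr_pairs = lr_pairs, gmt = gmt,
    features = features, barcodes = barcodes, out_dir = out_dir,
    cpm_threshold = cpm_threshold, lfc_threshold = lfc_threshold,
    alpha = alpha, n_perm = n_perm, min_size = min_size,
    max_size = max_size, comparisons = comparisons,
    de_cell_types = de_cell_types, focal_types = focal_types,
    pseudobulk_by_group = pseudobulk_by_group,
    seed = as.integer(seed)), class = "pipeline_config")
}

# Stable per-stage seed derivation so that stage reruns are independently
# reproducible under one global seed.
stage_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load -> normalize (pseudobulk, HVG) -> composition ->
#' differential expression per cell type and comparison -> enrichment
#' (preranked GSEA and over-representation of significant genes, when a
#' gene-set collection is configured) -> ligand-receptor crosstalk per
#' group with focal views. All results are written as TSVs under
#' `out_dir`, plus a JSON manifest recording the config hash, seed and
#' per-stage row counts. Identical config + seed reproduces byte-identical
#' outputs. A failing stage aborts with the stage name; a `failed/<stage>`
#' marker directory is left next to any partial outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results bundle and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      dir.create(file.path(out_dir, "failed", stage),
                 recursive = TRUE, showWarnings = FALSE)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  rows <- list()

  # -- load -----------------------------------------------------------
  dat <- counts_stage("load", {
    counts <- if (is.character(config$counts)) {
      read_counts(config$counts, config$features, config$barcodes)
    } else validate_counts(config$counts)
    cells <- if (is.character(config$cells)) read_cell_table(config$cells)
      else validate_cell_table(config$cells)
    pairs <- if (is.character(config$lr_pairs)) {
      if (!file.exists(config$lr_pairs))
        stop("ligand-receptor pair file not found: ", config$lr_pairs)
      read_lr_pairs(config$lr_pairs)
    } else validate_lr_pairs(config$lr_pairs)
    gmt <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    align <- align_cells(counts, cells)
    c(align, list(pairs = pairs, gmt = gmt))
  })
  rows$load <- ncol(dat$counts)

  # -- normalize ------------------------------------------------------
  norm <- counts_stage("normalize", {
    pb_type <- pseudobulk_cpm(dat$counts, dat$cells, by_group = FALSE)
    pb_group <- pseudobulk_cpm(dat$counts, dat$cells,
                               by_group = config$pseudobulk_by_group)
    hvg <- hvg_by_cv(pb_type, n_top = min(200L, nrow(dat$counts)))
    .write_tsv(data.frame(gene = hvg), file.path(out_dir, "hvg.tsv"))
    list(pb_type = pb_type, pb_group = pb_group, hvg = hvg)
  })
  rows$normalize <- ncol(norm$pb_group$cpm)

  # -- composition ----------------------------------------------------
  comp <- counts_stage("composition", {
    props <- compute_proportions(dat$cells)
    .write_tsv(props, file.path(out_dir, "proportions.tsv"))
    res <- list()
    for (cmp in config$comparisons) {
      r <- compare_composition(dat$cells, cmp[1], cmp[2],
                               alpha = config$alpha)
      .write_tsv(r, file.path(out_dir, sprintf("composition_%s_vs_%s.tsv",
                                               cmp[1], cmp[2])))
      res[[paste(cmp, collapse = "_vs_")]] <- r
    }
    list(proportions = props, tests = res)
  })
  rows$composition <- nrow(comp$proportions)

  # -- differential expression ---------------------------------------
  de <- counts_stage("differential_expression", {
    types <- config$de_cell_types %||% unique(dat$cells$cell_type)
    res <- list()
    for (ct in types) for (cmp in config$comparisons) {
      na <- sum(dat$cells$cell_type == ct & dat$cells$group == cmp[1])
      nb <- sum(dat$cells$cell_type == ct & dat$cells$group == cmp[2])
      if (na < 2 || nb < 2) next
      d <- de_test(dat$counts, dat$cells, ct, cmp[1], cmp[2],
                   lfc_threshold = config$lfc_threshold,
                   alpha = config$alpha)
      nm <- sprintf("%s_%s_vs_%s", ct, cmp[1], cmp[2])
      .write_tsv(d, file.path(out_dir, paste0("deg_", gsub("[^A-Za-z0-9_.-]",
                                                           "_", nm), ".tsv")))
      res[[nm]] <- d
    }
    res
  })
  rows$differential_expression <- sum(vapply(de, nrow, integer(1)))

  # -- enrichment -----------------------------------------------------
  enr <- counts_stage("enrichment", {
    if (is.null(dat$gmt)) return(list())
    res <- list()
    for (nm in names(de)) {
      d <- de[[nm]]
      ranked <- rank_genes(d)
      g <- tryCatch(
        gsea_preranked(ranked, dat$gmt, n_perm = config$n_perm,
                       seed = stage_seed(config$seed, paste0("gsea_", nm)),
                       min_size = config$min_size,
                       max_size = config$max_size),
        error = function(e) NULL)
      if (!is.null(g))
        .write_tsv(g, file.path(out_dir, paste0("gsea_", gsub(
          "[^A-Za-z0-9_.-]", "_", nm), ".tsv")))
      sig <- d$gene[d$significant]
      o <- if (length(sig)) ora_hypergeometric(sig, dat$gmt, d$gene) else NULL
      if (!is.null(o))
        .write_tsv(o, file.path(out_dir, paste0("ora_", gsub(
          "[^A-Za-z0-9_.-]", "_", nm), ".tsv")))
      res[[nm]] <- list(gsea = g, ora = o)
    }
    res
  })
  rows$enrichment <- length(enr)

  # -- crosstalk ------------------------------------------------------
  ct <- counts_stage("crosstalk", {
    calls <- call_interactions(norm$pb_group, dat$pairs,
                               threshold = config$cpm_threshold)
    .write_tsv(as.data.frame(calls), file.path(out_dir, "interactions.tsv"))
    groups <- unique(calls$group)
    mats <- list()
    focals <- list()
    for (g in groups) {
      sub <- calls[is.na(calls$group) | calls$group %in% g, , drop = FALSE]
      if (!is.na(g)) sub <- calls[calls$group == g, , drop = FALSE]
      class(sub) <- class(calls)
      m <- crosstalk_matrix(sub)
      tag <- if (is.na(g)) "all" else g
      .write_tsv(m, file.path(out_dir, sprintf("crosstalk_matrix_%s.tsv",
                                               tag)))
      mats[[tag]] <- m
      for (f in config$focal_types) {
        if (!f %in% c(sub$sender, sub$receiver)) next
        fn <- focal_network(sub, f)
        .write_tsv(fn$incoming, file.path(out_dir, sprintf(
          "focal_%s_%s_incoming.tsv", f, tag)))
        .write_tsv(fn$outgoing, file.path(out_dir, sprintf(
          "focal_%s_%s_outgoing.tsv", f, tag)))
        focals[[paste(f, tag, sep = "_")]] <- fn
      }
    }
    list(calls = calls, matrices = mats, focal = focals)
  })
  rows$crosstalk <- sum(ct$calls$active)

  # -- manifest -------------------------------------------------------
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL  # output location is not a parameter
  cfg_for_hash$counts <- if (is.character(config$counts)) config$counts
    else config_hash(list(dim(dat$counts), sum(dat$counts)))
  cfg_for_hash$cells <- if (is.character(config$cells)) config$cells
    else config_hash(dat$cells)
  cfg_for_hash$lr_pairs <- if (is.character(config$lr_pairs))
    config$lr_pairs else config_hash(dat$pairs)
  cfg_for_hash$gmt <- if (is.character(config$gmt)) config$gmt
    else if (!is.null(dat$gmt)) config_hash(lapply(dat$gmt, identity))
    else NULL
  manifest <- list(
    package_version = as.character(packageVersion("peritalk")),
    seed = config$seed,
    config_hash = config_hash(unclass(cfg_for_hash)),
    stage_rows = rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = dat, normalize = norm, composition = comp,
                 de = de, enrichment = enr, crosstalk = ct,
                 manifest = manifest))
}
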