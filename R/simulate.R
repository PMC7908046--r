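#' Build a simulation configuration
#'
#' Describes a grouped, multi-sample, multi-cell-type droplet scRNA-seq
#' experiment with planted ground truth. Counts are drawn from a negative
#' binomial whose mean is baseline x cell-type marker multiplier x group
#' DE multiplier, scaled to each cell's lognormal library size. Genes that
#' participate in the ligand-receptor universe are instead calibrated
#' analytically so that the (cell type, group) pseudobulk CPM lands on a
#' stated target, which makes the set of truly active ligand-receptor
#' circuits exactly derivable.
#'
#' @param n_genes Total number of genes. Filler genes are named `G0001`...
#' @param genes Optional explicit gene symbols (length `n_genes`); symbols
#'   named in `markers`, `de_spec` and `lr_spec` must occur here.
#' @param baseline_mean Per-gene relative expression rate (recycled /
#'   defaulted to a deterministic long-tailed profile when `NULL`).
#' @param cell_types data.frame with columns `name` and mean cells per
#'   sample per group: `cells_hc`, `cells_st`, `cells_lt`.
#' @param markers Named list: cell type -> marker gene symbols, upweighted
#'   by `marker_fold` in their own type.
#' @param marker_fold Multiplier applied to a marker gene in its own type.
#' @param samples_per_group Named integer vector over `hc`, `st`, `lt`.
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param library_size `c(meanlog=, sdlog=)` of the per-cell total-count
#'   lognormal.
#' @param de_spec data.frame(`cell_type`, `gene`, `group`, `log2_effect`):
#'   multiplicative group effects, 2^log2_effect on the mean.
#' @param lr_spec data.frame(`sender`, `ligand`, `receiver`, `receptor`,
#'   `group`, `target_cpm`): planted circuits; the ligand is calibrated to
#'   `target_cpm` in (sender, group) pseudobulk, the receptor in
#'   (receiver, group).
#' @param lr_pairs data.frame(`ligand`, `receptor`): the directed pair
#'   table handed to the crosstalk stage (defaults to the distinct pairs of
#'   `lr_spec`).
#' @param lr_background_cpm Pseudobulk CPM target for ligand/receptor
#'   universe genes in strata without an `lr_spec` row (default 8, well
#'   below the 50 CPM activity threshold).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       genes = NULL,
                       baseline_mean = NULL,
                       cell_types = data.frame(
                         name = c("fibroblast", "mesothelial"),
                         cells_hc = 50, cells_st = 50, cells_lt = 50),
                       markers = list(),
                       marker_fold = 8,
                       samples_per_group = c(hc = 3, st = 3, lt = 3),
                       dispersion = 2,
                       library_size = c(meanlog = log(4000), sdlog = 0.35),
                       de_spec = NULL,
                       lr_spec = NULL,
                       lr_pairs = NULL,
                       lr_background_cpm = 8,
                       seed = 1) {
  if (is.null(genes)) {
    named <- unique(c(unlist(markers, use.names = FALSE),
                      de_spec$gene, lr_spec$ligand, lr_spec$receptor,
                      lr_pairs$ligand, lr_pairs$receptor))
    filler <- sprintf("G%04d", seq_len(n_genes))
    # filler-style names keep their natural position (and hence their
    # baseline); real symbols take the leading, well-expressed slots
    extra <- setdiff(named, filler)
    genes <- filler
    free <- which(!filler %in% named)
    if (length(extra) > length(free))
      stop("more named genes than n_genes")
    genes[free[seq_along(extra)]] <- extra
  }
  if (length(genes) != n_genes) stop("genes must have length n_genes")
  if (anyDuplicated(genes)) stop("duplicated gene symbols")
  if (is.null(baseline_mean)) {
    # deterministic long-tailed baseline: a few high expressors, long tail
    i <- seq_len(n_genes)
    baseline_mean <- 5 / (0.15 * i + 1) + 0.2
  }
  baseline_mean <- rep_len(baseline_mean, n_genes)
  if (is.null(lr_pairs) && !is.null(lr_spec))
    lr_pairs <- unique(lr_spec[c("ligand", "receptor")])
  cfg <- structure(list(
    n_genes = n_genes, genes = genes, baseline_mean = baseline_mean,
    cell_types = cell_types, markers = markers, marker_fold = marker_fold,
    samples_per_group = samples_per_group, dispersion = dispersion,
    library_size = library_size,
    de_spec = de_spec, lr_spec = lr_spec, lr_pairs = lr_pairs,
    lr_background_cpm = lr_background_cpm, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (any(cfg$baseline_mean <= 0)) stop("baseline_mean must be positive")
  req <- c("cells_hc", "cells_st", "cells_lt")
  if (!all(c("name", req) %in% names(cfg$cell_types)))
    stop("cell_types needs columns name, cells_hc, cells_st, cells_lt")
  if (any(cfg$cell_types[req] < 1))
    stop("mean cells per sample must be >= 1 for every type and group")
  if (!all(GROUP_LEVELS %in% names(cfg$samples_per_group)) ||
      any(cfg$samples_per_group[GROUP_LEVELS] < 1))
    stop("samples_per_group must name hc, st, lt with counts >= 1")
  named <- unique(c(unlist(cfg$markers, use.names = FALSE),
                    cfg$de_spec$gene, cfg$lr_spec$ligand, cfg$lr_spec$receptor,
                    cfg$lr_pairs$ligand, cfg$lr_pairs$receptor))
  if (length(setdiff(named, cfg$genes)))
    stop("gene(s) named in markers/de_spec/lr_spec absent from gene list: ",
         paste(utils::head(setdiff(named, cfg$genes), 5), collapse = ", "))
  if (!is.null(cfg$de_spec)) {
    if (any(!is.finite(cfg$de_spec$log2_effect)))
      stop("de_spec log2 effects must be finite")
    lr_genes <- unique(c(cfg$lr_pairs$ligand, cfg$lr_pairs$receptor))
    clash <- intersect(unique(cfg$de_spec$gene), lr_genes)
    if (length(clash))
      stop("gene(s) in both de_spec and the ligand-receptor universe ",
           "(their CPM is pinned by calibration, so a DE effect there is ",
           "unrealizable): ", paste(clash, collapse = ", "))
  }
  if (!is.null(cfg$lr_spec) && any(cfg$lr_spec$target_cpm <= 0))
    stop("lr_spec target_cpm must be positive")
  cfg
}

# Target pseudobulk CPM per (gene, cell_type, group) for every gene in the
# ligand-receptor universe: the lr_spec target where one is planted, the
# background target elsewhere. Returns a lookup matrix genes x strata or
# NULL when there is no LR universe.
.lr_target_map <- function(cfg) {
  lr_genes <- unique(c(cfg$lr_pairs$ligand, cfg$lr_pairs$receptor))
  if (!length(lr_genes)) return(NULL)
  types <- cfg$cell_types$name
  strata <- as.vector(outer(types, GROUP_LEVELS, paste, sep = "|"))
  tgt <- matrix(cfg$lr_background_cpm, length(lr_genes), length(strata),
                dimnames = list(lr_genes, strata))
  if (!is.null(cfg$lr_spec)) {
    for (i in seq_len(nrow(cfg$lr_spec))) {
      r <- cfg$lr_spec[i, ]
      tgt[r$ligand, paste(r$sender, r$group, sep = "|")] <- r$target_cpm
      tgt[r$receptor, paste(r$receiver, r$group, sep = "|")] <- r$target_cpm
    }
  }
  tgt
}

# Relative expression rate vector for one (cell_type, group) stratum.
.stratum_rates <- function(cfg, type, group, lr_targets) {
  rate <- cfg$baseline_mean
  names(rate) <- cfg$genes
  mk <- cfg$markers[[type]]
  if (length(mk)) rate[mk] <- rate[mk] * cfg$marker_fold
  if (!is.null(cfg$de_spec)) {
    hit <- cfg$de_spec$cell_type == type & cfg$de_spec$group == group
    if (any(hit)) {
      d <- cfg$de_spec[hit, ]
      rate[d$gene] <- rate[d$gene] * 2^d$log2_effect
    }
  }
  if (!is.null(lr_targets)) {
    stratum <- paste(type, group, sep = "|")
    t_frac <- lr_targets[, stratum] / 1e6
    total_frac <- sum(t_frac)
    if (total_frac >= 0.9)
      stop(sprintf("infeasible lr targets in stratum %s: fractions sum to %.2f",
                   stratum, total_frac))
    rest <- sum(rate[setdiff(cfg$genes, rownames(lr_targets))])
    rate[rownames(lr_targets)] <- t_frac * rest / (1 - total_frac)
  }
  rate
}

#' Simulate a grouped single-cell dataset with planted truth
#'
#' Draws a dataset under the configured conditions (see [sim_config()])
#' and returns the count matrix, cell table and a truth manifest listing
#' planted differential genes, truly active ligand-receptor circuits at
#' the stated activity threshold, and expected cell-type proportions.
#' Planted ligand/receptor pseudobulk CPMs are verified post hoc against
#' their targets (within 20%); if any misses, the whole draw is resampled
#' once from `seed + 1`.
#'
#' @param config A `sim_config`.
#' @param truth_threshold CPM threshold at which `true_active` is derived
#'   (default 50, matching the crosstalk activity rule).
#' @return `list(counts=, cells=, truth=)`; `truth` has elements
#'   `true_de` (cell_type, gene, comparison, sign), `true_active` (group,
#'   sender, ligand, receiver, receptor), `true_proportions` (group x
#'   cell type matrix) and `seed_used`.
#' @export
simulate_dataset <- function(config, truth_threshold = 50) {
  config <- validate_sim_config(config)
  out <- .simulate_once(config, config$seed)
  ok <- .check_lr_calibration(config, out)
  if (!ok) {
    out <- .simulate_once(config, config$seed + 1L)
    if (!.check_lr_calibration(config, out))
      warning("planted ligand-receptor CPMs off target by >20% after resample")
  }
  out$truth <- c(.derive_truth(config, truth_threshold),
                 list(seed_used = out$seed_used))
  out
}

.simulate_once <- function(cfg, seed) {
  set.seed(seed, kind = "Mersenne-Twister")
  lr_targets <- .lr_target_map(cfg)
  types <- cfg$cell_types$name
  blocks <- list()
  meta <- list()
  for (group in GROUP_LEVELS) {
    nsamp <- cfg$samples_per_group[[group]]
    rates <- lapply(types, .stratum_rates, cfg = cfg, group = group,
                    lr_targets = lr_targets)
    names(rates) <- types
    for (s in seq_len(nsamp)) {
      sample_id <- sprintf("%s_%d", group, s)
      for (ti in seq_along(types)) {
        mu_cells <- cfg$cell_types[[paste0("cells_", group)]][ti]
        n_cells <- rpois(1, mu_cells)
        if (n_cells == 0) next
        p <- rates[[types[ti]]]
        p <- p / sum(p)
        lib <- rlnorm(n_cells, cfg$library_size[["meanlog"]],
                      cfg$library_size[["sdlog"]])
        mu <- outer(p, lib)
        cnt <- matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                      nrow = cfg$n_genes)
        blocks[[length(blocks) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sample_id, group = group, cell_type = types[ti],
          n = n_cells, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
  meta <- do.call(rbind, meta)
  cells <- data.frame(
    cell_id = sprintf("CELL%06d", seq_len(ncol(counts))),
    sample_id = rep(meta$sample_id, meta$n),
    group = factor(rep(meta$group, meta$n), levels = GROUP_LEVELS),
    cell_type = rep(meta$cell_type, meta$n),
    stringsAsFactors = FALSE)
  dimnames(counts) <- list(cfg$genes, cells$cell_id)
  list(counts = validate_counts(counts), cells = cells, seed_used = seed)
}

.check_lr_calibration <- function(cfg, out, tol = 0.2) {
  if (is.null(cfg$lr_spec) || !nrow(cfg$lr_spec)) return(TRUE)
  pb <- pseudobulk_cpm(out$counts, out$cells, by_group = TRUE)
  ok <- TRUE
  for (i in seq_len(nrow(cfg$lr_spec))) {
    r <- cfg$lr_spec[i, ]
    for (side in list(c(r$ligand, r$sender), c(r$receptor, r$receiver))) {
      stratum <- paste(side[2], r$group, sep = "|")
      if (!stratum %in% colnames(pb$cpm)) { ok <- FALSE; next }
      got <- pb$cpm[side[1], stratum]
      if (abs(got - r$target_cpm) > tol * r$target_cpm) ok <- FALSE
    }
  }
  ok
}

.derive_truth <- function(cfg, threshold) {
  lr_targets <- .lr_target_map(cfg)
  true_de <- NULL
  if (!is.null(cfg$de_spec) && nrow(cfg$de_spec)) {
    true_de <- data.frame(
      cell_type = cfg$de_spec$cell_type,
      gene = cfg$de_spec$gene,
      comparison = paste0(cfg$de_spec$group, "_vs_hc"),
      sign = sign(cfg$de_spec$log2_effect),
      stringsAsFactors = FALSE)
  }
  # ligand/receptor calibration also plants expression changes: a gene
  # targeted at different CPM in group g than in hc within one cell type
  # is true DE there whenever the fold clears the 1.5x calling scale
  if (!is.null(lr_targets)) {
    for (type in cfg$cell_types$name) {
      t_hc <- lr_targets[, paste(type, "hc", sep = "|")]
      for (group in setdiff(GROUP_LEVELS, "hc")) {
        lfc <- log2(lr_targets[, paste(type, group, sep = "|")] / t_hc)
        hit <- abs(lfc) >= 0.58
        if (any(hit)) {
          true_de <- rbind(true_de, data.frame(
            cell_type = type, gene = rownames(lr_targets)[hit],
            comparison = paste0(group, "_vs_hc"),
            sign = sign(lfc[hit]), stringsAsFactors = FALSE))
        }
      }
    }
    if (!is.null(true_de)) rownames(true_de) <- NULL
  }
  true_active <- NULL
  if (!is.null(lr_targets) && !is.null(cfg$lr_pairs)) {
    types <- cfg$cell_types$name
    rows <- list()
    for (group in GROUP_LEVELS) {
      for (sender in types) for (receiver in types) {
        lc <- lr_targets[cfg$lr_pairs$ligand, paste(sender, group, sep = "|")]
        rc <- lr_targets[cfg$lr_pairs$receptor,
                         paste(receiver, group, sep = "|")]
        hit <- lc > threshold & rc > threshold
        if (any(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = group, sender = sender,
            ligand = cfg$lr_pairs$ligand[hit],
            receiver = receiver, receptor = cfg$lr_pairs$receptor[hit],
            stringsAsFactors = FALSE)
        }
      }
    }
    true_active <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(), sender = character(),
                 ligand = character(), receiver = character(),
                 receptor = character(), stringsAsFactors = FALSE)
    rownames(true_active) <- NULL
  }
  prop <- sapply(GROUP_LEVELS, function(g) {
    m <- cfg$cell_types[[paste0("cells_", g)]]
    m / sum(m)
  })
  rownames(prop) <- cfg$cell_types$name
  list(true_de = true_de, true_active = true_active,
       true_proportions = t(prop))
}

#' Write a simulated dataset to disk
#'
#' Emits the 10x-style matrix triplet, the cell table TSV, and a JSON
#' truth/run manifest recording the seed and a config hash.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param config The `sim_config` that produced it.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_dataset <- function(dataset, config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_counts(dataset$counts, out_dir)
  write.table(dataset$cells, file.path(out_dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    seed_used = dataset$seed_used,
    config_hash = config_hash(unclass(config)),
    n_genes = nrow(dataset$counts),
    n_cells = ncol(dataset$counts),
    truth = list(
      true_de = dataset$truth$true_de,
      true_active = dataset$truth$true_active,
      true_proportions = as.data.frame(dataset$truth$true_proportions)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' 31-bit polynomial rolling hash of the canonical JSON serialization;
#' changes whenever any configuration field changes.
#'
#' @param x Any jsonlite-serializable object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' The shipped dialysis-stage study configuration
#'
#' A desk-scale emulation of a three-stage peritoneal dialysis cohort:
#' 15 cell types (mesothelial cell, fibroblast, myofibroblast, peritoneal
#' cell and immune populations), 6 healthy-control, 6 short-term and 4
#' long-term samples, 2000 genes, overdispersed counts. Planted structure:
#' fibroblast-hub ligand-receptor circuits in the short-term group at
#' >= 100 CPM against an 8 CPM background, antigen-presentation genes
#' (CD74, HLA-DRA, HLA-DMA, HLA-DQA1) up and PTGDS down in fibroblasts of
#' both dialysis groups, and composition shifts (fibroblast, monocyte and
#' macrophage fall; myofibroblast, T and NK cells rise in long-term
#' dialysis).
#'
#' @param seed Integer seed.
#' @param cells_scale Multiplier on mean cells per sample (1 = ~300
#'   cells/sample).
#' @return A `sim_config`.
#' @export
paper_like_config <- function(seed = 1, cells_scale = 1) {
  types <- data.frame(
    name = c("mesothelial", "fibroblast", "myofibroblast", "peritoneal",
             "monocyte", "macrophage", "T", "B", "NK", "pDC", "cDC",
             "mast", "plasma", "endothelial", "neutrophil"),
    cells_hc = c(60, 40, 15, 25, 25, 30, 30, 20, 15, 15, 15, 15, 15, 20, 15),
    cells_st = c(35, 55, 15, 25, 35, 40, 25, 20, 15, 15, 20, 15, 15, 15, 15),
    cells_lt = c(30, 25, 35, 25, 18, 20, 55, 20, 30, 25, 20, 15, 15, 15, 15))
  types[-1] <- lapply(types[-1], function(v) pmax(15, round(v * cells_scale)))
  markers <- list(
    mesothelial = c("MSLN", "UPK3B", "CALB2", "KRT19"),
    fibroblast = c("COL1A1", "COL1A2", "DCN", "LUM", "PDGFRA"),
    myofibroblast = c("ACTA2", "TAGLN", "MYL9"),
    peritoneal = c("PRG4", "CLDN1"),
    monocyte = c("CD14", "S100A8", "S100A9"),
    macrophage = c("CD68", "MRC1", "MARCO"),
    T = c("CD3D", "CD3E", "TRAC"),
    B = c("CD79A", "MS4A1"),
    NK = c("NKG7", "GNLY", "KLRD1"),
    pDC = c("LILRA4", "IRF7"),
    cDC = c("CD1C", "FCER1A"),
    mast = c("TPSAB1", "CPA3"),
    plasma = c("MZB1", "JCHAIN"),
    endothelial = c("PECAM1", "VWF"),
    neutrophil = c("FCGR3B", "CSF3R"))
  lr_pairs <- data.frame(
    ligand = c("CCL5", "CCL2", "CCL3", "CCL4", "CXCL8", "CXCL8",
               "TNF", "TGFB1", "IL1B", "IL6", "VEGFA", "PDGFB"),
    receptor = c("CCR5", "CCR2", "CCR1", "CCR5", "CXCR1", "CXCR2",
                 "TNFRSF1A", "TGFBR1", "IL1R1", "IL6R", "FLT1", "PDGFRB"),
    stringsAsFactors = FALSE)
  # fibroblast-hub circuits in the short-term group (the stage the study's
  # network view centres on), plus a mesothelial->fibroblast input and one
  # healthy-control circuit so group comparisons have gained/lost edges
  lr_spec <- data.frame(
    sender = c("fibroblast", "fibroblast", "fibroblast", "fibroblast",
               "mesothelial", "fibroblast", "mesothelial"),
    ligand = c("CCL5", "CCL2", "CXCL8", "TGFB1", "IL6", "CCL5", "VEGFA"),
    receiver = c("T", "monocyte", "neutrophil", "mesothelial",
                 "fibroblast", "macrophage", "endothelial"),
    receptor = c("CCR5", "CCR2", "CXCR1", "TGFBR1", "IL6R", "CCR5", "FLT1"),
    group = c("st", "st", "st", "st", "st", "st", "hc"),
    target_cpm = c(150, 130, 160, 120, 110, 150, 120),
    stringsAsFactors = FALSE)
  de_spec <- rbind(
    data.frame(cell_type = "fibroblast",
               gene = rep(c("CD74", "HLA-DRA", "HLA-DMA", "HLA-DQA1"), 2),
               group = rep(c("st", "lt"), each = 4), log2_effect = 1.5,
               stringsAsFactors = FALSE),
    data.frame(cell_type = "fibroblast", gene = "PTGDS",
               group = c("st", "lt"), log2_effect = -1.2,
               stringsAsFactors = FALSE),
    data.frame(cell_type = "mesothelial", gene = "SAA1",
               group = "lt", log2_effect = 1.0, stringsAsFactors = FALSE))
  sim_config(
    n_genes = 2000,
    cell_types = types,
    markers = markers,
    marker_fold = 8,
    samples_per_group = c(hc = 6, st = 6, lt = 4),
    dispersion = 2,
    library_size = c(meanlog = log(4000), sdlog = 0.35),
    de_spec = de_spec,
    lr_spec = lr_spec,
    lr_pairs = lr_pairs,
    lr_background_cpm = 8,
    seed = seed)
}
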