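#' Call active ligand-receptor interactions from pseudobulk CPM
#'
#' Applies the activity rule: a directed interaction sender -> receiver via
#' (ligand, receptor) is active iff the ligand's pseudobulk CPM in the
#' sender cell type AND the receptor's pseudobulk CPM in the receiver cell
#' type both exceed the threshold (strictly "above" by default; `strict =
#' FALSE` uses >=). Every ordered pair of cell types is evaluated,
#' including sender = receiver (autocrine) unless `autocrine = FALSE`.
#' Genes absent from the matrix score CPM 0. For group-stratified profiles
#' (built with `by_group = TRUE`) the rule is applied within each group.
#'
#' @param profiles A `pseudobulk` object from [pseudobulk_cpm()].
#' @param pairs data.frame with `ligand`, `receptor` columns (directed
#'   pairs; see [read_lr_pairs()]).
#' @param threshold CPM activity threshold (> 0; default 50).
#' @param strict Use strict `>` at the threshold (default TRUE).
#' @param autocrine Evaluate sender = receiver pairs (default TRUE).
#' @return data.frame of class `interaction_calls`: `group` (NA when
#'   profiles are unstratified), `sender`, `receiver`, `ligand`,
#'   `receptor`, `ligand_cpm`, `receptor_cpm`, `active`.
#' @export
call_interactions <- function(profiles, pairs, threshold = 50,
                              strict = TRUE, autocrine = TRUE) {
  stopifnot(inherits(profiles, "pseudobulk"))
  if (is.null(pairs) || !nrow(pairs)) stop("empty ligand-receptor pair list")
  if (threshold <= 0) stop("threshold must be positive")
  pairs <- validate_lr_pairs(pairs[c("ligand", "receptor")])
  cpm_of <- function(gene, stratum) {
    if (gene %in% rownames(profiles$cpm)) profiles$cpm[gene, stratum] else 0
  }
  meta <- profiles$meta
  groups <- unique(meta$group)  # NA for unstratified profiles
  out <- list()
  for (g in groups) {
    sel <- if (is.na(g)) is.na(meta$group) else
      !is.na(meta$group) & meta$group == g
    types <- sort(unique(meta$cell_type[sel]))
    strat <- setNames(meta$stratum[sel],
                      meta$cell_type[sel])[types]
    for (sender in types) for (receiver in types) {
      if (!autocrine && sender == receiver) next
      lc <- vapply(pairs$ligand, cpm_of, numeric(1),
                   stratum = strat[[sender]])
      rc <- vapply(pairs$receptor, cpm_of, numeric(1),
                   stratum = strat[[receiver]])
      active <- if (strict) lc > threshold & rc > threshold else
        lc >= threshold & rc >= threshold
      out[[length(out) + 1L]] <- data.frame(
        group = if (is.na(g)) NA_character_ else g,
        sender = sender, receiver = receiver,
        ligand = pairs$ligand, receptor = pairs$receptor,
        ligand_cpm = unname(lc), receptor_cpm = unname(rc),
        active = active, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  class(calls) <- c("interaction_calls", "data.frame")
  attr(calls, "threshold") <- threshold
  calls
}

#' Crosstalk summary matrix over ordered cell-type pairs
#'
#' Per ordered (sender, receiver) pair: the number of active
#' ligand-receptor pairs plus the distinct-ligand and distinct-receptor
#' tallies (the two axes of the interaction-count heatmap). Pairs with no
#' active interaction are reported with zeros.
#'
#' @param calls `interaction_calls` from [call_interactions()] (one group
#'   context: filter by group first for stratified calls).
#' @return data.frame: `sender`, `receiver`, `n_active_pairs`,
#'   `n_ligands`, `n_receptors`, `ligands`, `receptors`
#'   (semicolon-joined distinct active gene symbols).
#' @export
crosstalk_matrix <- function(calls) {
  if (length(unique(calls$group[!is.na(calls$group)])) > 1)
    stop("calls span multiple groups; filter to one group first")
  key <- paste(calls$sender, calls$receiver, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- calls[key == k, , drop = FALSE]
    act <- sub[sub$active, , drop = FALSE]
    data.frame(sender = sub$sender[1], receiver = sub$receiver[1],
               n_active_pairs = nrow(act),
               n_ligands = length(unique(act$ligand)),
               n_receptors = length(unique(act$receptor)),
               ligands = paste(sort(unique(act$ligand)), collapse = ";"),
               receptors = paste(sort(unique(act$receptor)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sender, out$receiver), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Focal-cell-type view of the crosstalk network
#'
#' Splits the active calls touching one focal cell type into incoming
#' edges (partner ligand -> focal receptor) and outgoing edges (focal
#' ligand -> partner receptor); autocrine edges appear in both lists with
#' `autocrine = TRUE`. Partners are ordered by descending edge count.
#'
#' @param calls `interaction_calls` (one group context).
#' @param focal_type Cell type present among the calls.
#' @return `list(focal =, incoming =, outgoing =, partners =)`;
#'   `partners` is a data.frame of partner type and edge count.
#' @export
focal_network <- function(calls, focal_type) {
  if (!focal_type %in% c(calls$sender, calls$receiver))
    stop("unknown focal type: ", focal_type)
  act <- calls[calls$active, , drop = FALSE]
  incoming <- act[act$receiver == focal_type, , drop = FALSE]
  outgoing <- act[act$sender == focal_type, , drop = FALSE]
  incoming$autocrine <- incoming$sender == focal_type
  outgoing$autocrine <- outgoing$receiver == focal_type
  partner <- c(incoming$sender, outgoing$receiver)
  partners <- if (length(partner)) {
    tab <- sort(table(partner), decreasing = TRUE)
    data.frame(partner = names(tab), n_edges = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(partner = character(), n_edges = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(incoming) <- rownames(outgoing) <- NULL
  structure(list(focal = focal_type, incoming = incoming,
                 outgoing = outgoing, partners = partners),
            class = "focal_network")
}

#' @exportS3Method base::print
print.focal_network <- function(x, ...) {
  cat(sprintf("focal crosstalk network for '%s': %d incoming, %d outgoing\n",
              x$focal, nrow(x$incoming), nrow(x$outgoing)))
  print(x$partners)
  invisible(x)
}

#' Edge changes between two groups
#'
#' For calls computed on group-stratified pseudobulks, classifies every
#' (sender, receiver, ligand, receptor) combination from group A to group
#' B as `shared` (active in both), `lost` (active only in A), `gained`
#' (active only in B) or `absent`.
#'
#' @param calls `interaction_calls` computed with group-stratified
#'   profiles.
#' @param group_a,group_b Group labels present in the calls.
#' @return data.frame: `sender`, `receiver`, `ligand`, `receptor`,
#'   `active_a`, `active_b`, `status`.
#' @export
compare_crosstalk <- function(calls, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% calls$group) stop("group absent from calls: ", g)
  }
  a <- calls[calls$group == group_a, , drop = FALSE]
  b <- calls[calls$group == group_b, , drop = FALSE]
  key <- function(d) paste(d$sender, d$receiver, d$ligand, d$receptor,
                           sep = "\r")
  ka <- key(a); kb <- key(b)
  all_keys <- union(ka, kb)
  act_a <- setNames(rep(FALSE, length(all_keys)), all_keys)
  act_b <- act_a
  act_a[ka] <- a$active
  act_b[kb] <- b$active
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- data.frame(sender = parts[, 1], receiver = parts[, 2],
                    ligand = parts[, 3], receptor = parts[, 4],
                    active_a = unname(act_a), active_b = unname(act_b),
                    stringsAsFactors = FALSE)
  out$status <- ifelse(out$active_a & out$active_b, "shared",
                ifelse(out$active_a, "lost",
                ifelse(out$active_b, "gained", "absent")))
  out <- out[order(out$sender, out$receiver, out$ligand, out$receptor), ]
  rownames(out) <- NULL
  out
}

#' Export a crosstalk network or call table
#'
#' `"tsv"` writes a round-trippable edge list (all columns); `"graphml"`
#' writes a directed multigraph with cell types as nodes and one edge per
#' active call carrying ligand/receptor/CPM attributes; `"json"` writes
#' the call records as a JSON array.
#'
#' @param x `interaction_calls`, a [crosstalk_matrix()] table, or a
#'   `focal_network` (its active edges are exported).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"graphml"`, `"json"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(x, path, format = c("tsv", "graphml", "json")) {
  format <- match.arg(format)
  if (inherits(x, "focal_network")) {
    x <- rbind(x$incoming, x$outgoing[!x$outgoing$autocrine, , drop = FALSE])
  }
  df <- as.data.frame(x)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    edges <- if ("active" %in% names(df)) df[df$active, , drop = FALSE] else df
    nodes <- unique(c(edges$sender, edges$receiver, df$sender, df$receiver))
    g <- igraph::graph_from_data_frame(
      cbind(edges[c("sender", "receiver")],
            edges[setdiff(names(edges), c("sender", "receiver"))]),
      directed = TRUE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Parse an exported TSV edge list back into calls
#' @param path TSV written by [export_network()].
#' @return data.frame of calls.
#' @export
read_network_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("active" %in% names(df)) df$active <- as.logical(df$active)
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  df
}
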