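#' @importFrom methods as is
#' @importFrom stats p.adjust phyper rlnorm rnbinom rpois sd t.test
#'   wilcox.test setNames median
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Disease-stage group labels
#'
#' The closed set of sample groups used throughout the pipeline:
#' `"hc"` (healthy control), `"st"` (short-term peritoneal dialysis,
#' < 2 weeks) and `"lt"` (long-term peritoneal dialysis, > 6 years).
#'
#' @format Character vector of length 3.
#' @export
GROUP_LEVELS <- c("hc", "st", "lt")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a UMI count matrix
#'
#' Checks the invariants every downstream stage relies on: a genes x cells
#' sparse (or dense) matrix of non-negative integral UMI counts with unique,
#' non-empty gene symbols as rownames and unique cell barcodes as colnames.
#'
#' @param counts A matrix or `Matrix::dgCMatrix`, genes as rows.
#' @return The matrix, coerced to `dgCMatrix`, invisibly usable downstream.
#' @export
validate_counts <- function(counts) {
  if (!is(counts, "Matrix") && !is.matrix(counts))
    stop("counts must be a matrix or Matrix")
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "dMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell barcode colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated cell barcodes in counts")
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != floor(x))))
    stop("counts must be non-negative integers (UMI counts)")
  counts
}

#' Read a 10x-convention count matrix
#'
#' Reads a Matrix Market coordinate file plus the `features` and `barcodes`
#' sidecar tables (one record per line, optionally gzipped), returning a
#' genes x cells sparse count matrix. Duplicate gene symbols are
#' disambiguated deterministically in file order with `.1`, `.2`, ...
#' suffixes (`make.unique`). When the features table has more than one
#' column the second (the 10x symbol column) is used.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the features/genes table.
#' @param barcodes_path Path to the barcodes table.
#' @return A validated `dgCMatrix` of UMI counts.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- read.delim(features_path, header = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")[[1]]
  if (length(genes) != nrow(m))
    stop(sprintf("features table has %d records but matrix has %d rows",
                 length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes table has %d records but matrix has %d columns",
                 length(barcodes), ncol(m)))
  dimnames(m) <- list(make.unique(genes, sep = "."), barcodes)
  validate_counts(m)
}

#' Write a count matrix in 10x triplet convention
#'
#' @param counts Validated count matrix (see [validate_counts()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths written
#'   (`matrix.mtx`, `features.tsv`, `barcodes.tsv`).
#' @export
write_counts <- function(counts, dir) {
  counts <- validate_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(counts, paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read the per-cell metadata table
#'
#' Expects a delimited table (TSV, or CSV by `.csv` extension) with header
#' columns `cell_id`, `sample_id`, `group` and `cell_type`. `group` must be
#' one of [GROUP_LEVELS]; any other value is a validation error naming the
#' offending value.
#'
#' @param path Path to the table.
#' @return A data.frame with `group` as a factor over [GROUP_LEVELS].
#' @export
read_cell_table <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  validate_cell_table(df)
}

#' Validate a per-cell metadata table
#'
#' @param df A data.frame with columns `cell_id`, `sample_id`, `group`,
#'   `cell_type`.
#' @return The validated data.frame, `group` coerced to a factor.
#' @export
validate_cell_table <- function(df) {
  required <- c("cell_id", "sample_id", "group", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in cell table: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)])[1:3], collapse = ", "))
  bad <- setdiff(unique(as.character(df$group)), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group value(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")")
  df$group <- factor(as.character(df$group), levels = GROUP_LEVELS)
  df[required]
}

#' Align a count matrix with a cell table
#'
#' Restricts both to their common cells (intersection join). Cells present
#' on only one side are dropped with a message reporting the count; a
#' permissive silent join would hide labeling bugs.
#'
#' @param counts Count matrix.
#' @param cells Cell table.
#' @return `list(counts =, cells =)` restricted to common cells, cells in
#'   count-matrix column order.
#' @export
align_cells <- function(counts, cells) {
  counts <- validate_counts(counts)
  cells <- validate_cell_table(cells)
  keep <- intersect(colnames(counts), cells$cell_id)
  if (!length(keep))
    stop("no cells in common between count matrix and cell table")
  dropped <- (ncol(counts) - length(keep)) + (nrow(cells) - length(keep))
  if (dropped > 0)
    message(sprintf("align_cells: dropped %d cell(s) absent from one side",
                    dropped))
  counts <- counts[, keep, drop = FALSE]
  cells <- cells[match(keep, cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  list(counts = counts, cells = cells)
}

#' Read a ligand-receptor pair table
#'
#' Delimited table with header columns `ligand` and `receptor` (optional
#' `source` annotation), as curated from experimentally validated
#' interaction databases. Ordered pairs are deduplicated preserving file
#' order; `(A,B)` and `(B,A)` are distinct directed pairs.
#'
#' @param path Path to the TSV/CSV.
#' @return data.frame with columns `ligand`, `receptor`, `source`.
#' @export
read_lr_pairs <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("ligand-receptor table needs 'ligand' and 'receptor' columns")
  if (!nrow(df)) stop("empty ligand-receptor table: ", path)
  if (!"source" %in% names(df)) df$source <- NA_character_
  validate_lr_pairs(df[c("ligand", "receptor", "source")])
}

#' Validate (and deduplicate) a ligand-receptor pair table
#' @param df data.frame with `ligand` and `receptor` columns.
#' @return Deduplicated data.frame, file order preserved.
#' @export
validate_lr_pairs <- function(df) {
  bad <- is.na(df$ligand) | is.na(df$receptor) |
    !nzchar(df$ligand) | !nzchar(df$receptor)
  if (any(bad))
    stop(sum(bad), " ligand-receptor row(s) with a missing partner")
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicated ligand-receptor pair(s) dropped")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: per line, set name, description, then member gene symbols,
#' tab-separated. Members are deduplicated per set; a set left empty after
#' deduplication is dropped with a warning; a line with fewer than three
#' fields is an error.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character vectors (set name -> members), with the
#'   per-set descriptions in `attr(,"description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3)[1:3], collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  names(desc) <- nm
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropped empty gene set(s): ", paste(nm[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
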