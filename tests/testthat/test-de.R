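test_that("log2 fold change closed forms and sign flip", {
  ds <- simulate_dataset(quick_config(seed = 2, n_genes = 80, cells = 30))
  ab <- log2_fold_change(ds$counts, ds$cells, "fibroblast", "st", "hc")
  ba <- log2_fold_change(ds$counts, ds$cells, "fibroblast", "hc", "st")
  expect_equal(ab, -ba)
  # 3 vs 1.5 with pc = 0 is exactly one doubling
  expect_equal(log2((3 + 0) / (1.5 + 0)), 1)
  # the 0.58 threshold is log2(1.5): a 1.5-fold gene passes
  expect_gte(log2(1.5), 0.58)
  expect_error(log2_fold_change(ds$counts, ds$cells, "nosuchtype",
                                "st", "hc"), "empty stratum")
})

test_that("bonferroni_adjust is min(1, m*p), monotone, validated", {
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni_adjust(1), 1)
  expect_equal(bonferroni_adjust(0.3), 0.3)  # single test unchanged
  p <- runif(20)
  adj <- bonferroni_adjust(p)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("de_test enforces the calling rule on every row", {
  de <- data.frame(cell_type = "fibroblast", gene = c("CD74", "HLA-DRA"),
                   group = "st", log2_effect = 1.5,
                   stringsAsFactors = FALSE)
  ds <- simulate_dataset(quick_config(seed = 31, n_genes = 100, cells = 50,
                                      de_spec = de))
  res <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
  expect_identical(res$significant,
                   abs(res$log2fc) >= 0.58 & res$p_adj < 0.05)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$pct_a >= 0 & res$pct_a <= 1))
  expect_true(all(c("CD74", "HLA-DRA") %in% res$gene[res$significant]))
  # swapping groups negates the fold change and preserves p
  res2 <- de_test(ds$counts, ds$cells, "fibroblast", "hc", "st")
  common <- intersect(res$gene, res2$gene)
  expect_equal(res$log2fc[match(common, res$gene)],
               -res2$log2fc[match(common, res2$gene)])
  expect_equal(res$p_raw[match(common, res$gene)],
               res2$p_raw[match(common, res2$gene)])
})

test_that("de_test is invariant to cell order and skips degenerate genes", {
  ds <- simulate_dataset(quick_config(seed = 12, n_genes = 60, cells = 20))
  res <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
  perm <- sample(ncol(ds$counts))
  res2 <- de_test(ds$counts[, perm], ds$cells[perm, ], "fibroblast",
                  "st", "hc")
  expect_equal(res, res2)
  # a gene never expressed in either stratum is skipped, not an error
  m <- as.matrix(ds$counts)
  m["G0050", ] <- 0L
  res3 <- de_test(Matrix::Matrix(m, sparse = TRUE), ds$cells,
                  "fibroblast", "st", "hc")
  expect_false("G0050" %in% res3$gene)
  expect_error(de_test(ds$counts, ds$cells[1:3, ], "fibroblast",
                       "st", "hc"), ">= 2 cells")
})

test_that("per-gene p-values agree with stats::t.test / wilcox.test", {
  ds <- simulate_dataset(quick_config(seed = 19, n_genes = 40, cells = 25))
  al <- align_cells(ds$counts, ds$cells)
  res <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
  lx <- log_normalize(cpm_per_cell(al$counts))
  ia <- al$cells$cell_type == "fibroblast" & al$cells$group == "st"
  ib <- al$cells$cell_type == "fibroblast" & al$cells$group == "hc"
  for (g in head(res$gene, 5)) {
    expect_equal(res$p_raw[res$gene == g],
                 t.test(lx[g, ia], lx[g, ib])$p.value)
  }
  resw <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc",
                  method = "wilcox")
  g <- resw$gene[1]
  expect_equal(resw$p_raw[1],
               suppressWarnings(wilcox.test(lx[g, ia], lx[g, ib])$p.value))
})

test_that("dotmap_table reports mean expression, pct and both-comparison flags", {
  de <- data.frame(cell_type = "fibroblast", gene = "CD74",
                   group = c("st", "lt"), log2_effect = 2,
                   stringsAsFactors = FALSE)
  ds <- simulate_dataset(quick_config(seed = 23, n_genes = 80, cells = 60,
                                      de_spec = de))
  genes <- c("CD74", "G0030")
  dm <- dotmap_table(ds$counts, ds$cells, genes)
  # counting oracle on one stratum
  al <- align_cells(ds$counts, ds$cells)
  idx <- al$cells$cell_type == "fibroblast" & al$cells$group == "st"
  expect_equal(dm$pct_expr[dm$gene == "CD74" & dm$cell_type == "fibroblast" &
                             dm$group == "st"],
               sum(al$counts["CD74", idx] > 0) / sum(idx))
  # unknown gene: warning, skipped
  expect_warning(dm2 <- dotmap_table(ds$counts, ds$cells,
                                     c("CD74", "NOSUCH")), "NOSUCH")
  expect_false("NOSUCH" %in% dm2$gene)
  # flagged only where significant in both comparisons, fibroblast only
  d1 <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
  d2 <- de_test(ds$counts, ds$cells, "fibroblast", "lt", "hc")
  m1 <- de_test(ds$counts, ds$cells, "mesothelial", "st", "hc")
  m2 <- de_test(ds$counts, ds$cells, "mesothelial", "lt", "hc")
  dm3 <- dotmap_table(ds$counts, ds$cells, genes,
                      de_results = list(rbind(d1, m1), rbind(d2, m2)))
  flagged <- dm3[dm3$flagged, ]
  expect_true(all(flagged$gene == "CD74" & flagged$cell_type == "fibroblast"))
  expect_gt(nrow(flagged), 0)
})

test_that("planted DE genes are recovered with calibrated nulls", {
  # moderate recovery check at unit-test scale (the full 50-seed power
  # sweep lives in the acceptance tests)
  de <- data.frame(cell_type = "fibroblast",
                   gene = sprintf("G%04d", 60:69), group = "st",
                   log2_effect = 1.5, stringsAsFactors = FALSE)
  ds <- simulate_dataset(quick_config(seed = 41, n_genes = 200, cells = 50,
                                      de_spec = de))
  res <- de_test(ds$counts, ds$cells, "fibroblast", "st", "hc")
  called <- res$gene[res$significant]
  expect_gte(sum(de$gene %in% called) / nrow(de), 0.8)
})
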