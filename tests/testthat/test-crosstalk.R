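# A 3-type x 4-pair toy with hand-set pseudobulk CPMs, including values
# exactly at the 50 CPM boundary.
toy_profiles <- function() {
  cpm <- rbind(
    L1 = c(F = 120, M = 10, T = 51),
    L2 = c(F = 50,  M = 200, T = 0),
    R1 = c(F = 60,  M = 49, T = 100),
    R2 = c(F = 50,  M = 51, T = 5),
    L3 = c(F = 0,   M = 0, T = 80),
    R3 = c(F = 30,  M = 70, T = 55))
  make_pseudobulk(cpm)
}

toy_pairs <- data.frame(
  ligand = c("L1", "L2", "L3", "L1"),
  receptor = c("R1", "R2", "R3", "R2"),
  stringsAsFactors = FALSE)

# exhaustive re-evaluation of the rule, written independently of the
# package implementation
enumerate_active <- function(profiles, pairs, threshold, strict = TRUE) {
  types <- colnames(profiles$cpm)
  out <- character()
  for (s in types) for (r in types) for (i in seq_len(nrow(pairs))) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    lc <- if (lg %in% rownames(profiles$cpm)) profiles$cpm[lg, s] else 0
    rcv <- if (rc %in% rownames(profiles$cpm)) profiles$cpm[rc, r] else 0
    hit <- if (strict) lc > threshold && rcv > threshold else
      lc >= threshold && rcv >= threshold
    if (hit) out <- c(out, paste(s, r, lg, rc))
  }
  sort(out)
}

test_that("call_interactions reproduces exhaustive enumeration at 49/50/51", {
  pb <- toy_profiles()
  for (thr in c(49, 50, 51)) {
    calls <- call_interactions(pb, toy_pairs, threshold = thr)
    expect_equal(nrow(calls), 3 * 3 * 4)  # all ordered pairs evaluated
    got <- sort(paste(calls$sender, calls$receiver, calls$ligand,
                      calls$receptor)[calls$active])
    expect_equal(got, enumerate_active(pb, toy_pairs, thr))
  }
  # strict boundary: CPM exactly 50 is inactive at threshold 50
  calls50 <- call_interactions(pb, toy_pairs, threshold = 50)
  l2 <- calls50[calls50$ligand == "L2" & calls50$sender == "F", ]
  expect_false(any(l2$active))
  # >= by flag
  loose <- call_interactions(pb, toy_pairs, threshold = 50, strict = FALSE)
  got <- sort(paste(loose$sender, loose$receiver, loose$ligand,
                    loose$receptor)[loose$active])
  expect_equal(got, enumerate_active(pb, toy_pairs, 50, strict = FALSE))
})

test_that("autocrine handling, absent genes and input order invariance", {
  pb <- toy_profiles()
  calls <- call_interactions(pb, toy_pairs, threshold = 50)
  expect_true(any(calls$sender == calls$receiver))
  no_auto <- call_interactions(pb, toy_pairs, threshold = 50,
                               autocrine = FALSE)
  expect_false(any(no_auto$sender == no_auto$receiver))
  # gene absent from the matrix scores CPM 0
  pairs2 <- rbind(toy_pairs, data.frame(ligand = "GHOST", receptor = "R1"))
  calls2 <- call_interactions(pb, pairs2, threshold = 50)
  ghost <- calls2[calls2$ligand == "GHOST", ]
  expect_true(all(ghost$ligand_cpm == 0) && !any(ghost$active))
  # pair order does not change the active set
  perm <- toy_pairs[c(3, 1, 4, 2), ]
  calls3 <- call_interactions(pb, perm, threshold = 50)
  key <- function(d) sort(paste(d$sender, d$receiver, d$ligand,
                                d$receptor)[d$active])
  expect_equal(key(calls), key(calls3))
  expect_error(call_interactions(pb, toy_pairs[0, ]), "empty")
  expect_error(call_interactions(pb, toy_pairs, threshold = -1), "positive")
})

test_that("raising the threshold never adds an active call", {
  set.seed(55)
  pairs <- data.frame(ligand = sprintf("L%d", 1:6),
                      receptor = sprintf("R%d", 1:6))
  for (i in 1:100) {
    cpm <- matrix(rexp(12 * 4, rate = 1 / 60), 12, 4,
                  dimnames = list(c(pairs$ligand, pairs$receptor),
                                  c("a", "b", "c", "d")))
    pb <- make_pseudobulk(cpm)
    prev <- NULL
    for (thr in c(20, 50, 90)) {
      calls <- call_interactions(pb, pairs, threshold = thr)
      act <- paste(calls$sender, calls$receiver, calls$ligand,
                   calls$receptor)[calls$active]
      if (!is.null(prev)) expect_true(all(act %in% prev))
      prev <- act
    }
  }
})

test_that("crosstalk_matrix tallies match the enumeration oracle", {
  pb <- toy_profiles()
  calls <- call_interactions(pb, toy_pairs, threshold = 50)
  m <- crosstalk_matrix(calls)
  expect_equal(nrow(m), 9)  # all ordered type pairs reported
  expect_equal(sum(m$n_active_pairs), sum(calls$active))
  act <- calls[calls$active, ]
  for (i in seq_len(nrow(m))) {
    sub <- act[act$sender == m$sender[i] & act$receiver == m$receiver[i], ]
    expect_equal(m$n_active_pairs[i], nrow(sub))
    expect_equal(m$n_ligands[i], length(unique(sub$ligand)))
    expect_equal(m$n_receptors[i], length(unique(sub$receptor)))
  }
  # single active call gives a single unit entry
  one <- calls[1, , drop = FALSE]
  one$active <- TRUE
  class(one) <- class(calls)
  m1 <- crosstalk_matrix(one)
  expect_equal(m1$n_active_pairs, 1)
  expect_equal(m1$ligands, one$ligand)
  # no active calls -> all-zero matrix
  none <- calls; none$active <- FALSE
  class(none) <- class(calls)
  expect_true(all(crosstalk_matrix(none)$n_active_pairs == 0))
})

test_that("focal_network splits incoming/outgoing and orders partners", {
  pb <- toy_profiles()
  calls <- call_interactions(pb, toy_pairs, threshold = 50)
  fn <- focal_network(calls, "F")
  expect_true(all(fn$incoming$receiver == "F"))
  expect_true(all(fn$outgoing$sender == "F"))
  act <- calls[calls$active, ]
  expect_equal(nrow(fn$incoming), sum(act$receiver == "F"))
  expect_equal(nrow(fn$outgoing), sum(act$sender == "F"))
  if (nrow(fn$partners) > 1)
    expect_false(is.unsorted(rev(fn$partners$n_edges)))
  # autocrine edges appear in both lists, flagged
  auto <- act[act$sender == "F" & act$receiver == "F", ]
  if (nrow(auto)) {
    expect_true(all(fn$incoming$autocrine[fn$incoming$sender == "F"]))
    expect_true(all(fn$outgoing$autocrine[fn$outgoing$receiver == "F"]))
  }
  # focal type with no active edges -> empty network, not an error
  none <- calls; none$active <- FALSE
  class(none) <- class(calls)
  fn0 <- focal_network(none, "F")
  expect_equal(nrow(fn0$incoming) + nrow(fn0$outgoing), 0)
  expect_error(focal_network(calls, "nosuch"), "unknown focal type")
})

test_that("compare_crosstalk classifies gained/lost/shared edges", {
  cpm <- cbind("F|st" = c(L1 = 100, R1 = 100, L2 = 100, R2 = 10),
               "F|lt" = c(L1 = 100, R1 = 100, L2 = 10, R2 = 100))
  pb <- make_pseudobulk(cpm, groups = c("st", "lt"))
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  calls <- call_interactions(pb, pairs, threshold = 50)
  cmp <- compare_crosstalk(calls, "st", "lt")
  expect_equal(cmp$status[cmp$ligand == "L1"], "shared")
  expect_equal(cmp$status[cmp$ligand == "L2"], "absent")
  # build a toy with one gained and one lost edge
  cpm2 <- cbind("F|st" = c(L1 = 100, R1 = 100, L2 = 10, R2 = 100),
                "F|lt" = c(L1 = 100, R1 = 10, L2 = 100, R2 = 100))
  pb2 <- make_pseudobulk(cpm2, groups = c("st", "lt"))
  calls2 <- call_interactions(pb2, pairs, threshold = 50)
  cmp2 <- compare_crosstalk(calls2, "st", "lt")
  expect_equal(cmp2$status[cmp2$ligand == "L1"], "lost")
  expect_equal(cmp2$status[cmp2$ligand == "L2"], "gained")
  expect_error(compare_crosstalk(calls2, "st", "hc"), "absent")
})

test_that("export round-trips TSV and writes well-formed GraphML/JSON", {
  pb <- toy_profiles()
  calls <- call_interactions(pb, toy_pairs, threshold = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(calls, f, "tsv")
  back <- read_network_tsv(f)
  expect_equal(back$active, calls$active)
  expect_equal(back[c("sender", "receiver", "ligand", "receptor")],
               as.data.frame(calls)[c("sender", "receiver", "ligand",
                                      "receptor")])
  # empty network: header-only file, still parseable
  none <- calls[0, , drop = FALSE]
  export_network(none, f, "tsv")
  expect_equal(nrow(read_network_tsv(f)), 0)
  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(calls, g, "graphml")
  expect_silent(xml <- xml2::read_xml(g))  # well-formed XML
  expect_match(as.character(xml2::xml_name(xml)), "graphml")
  j <- withr::local_tempfile(fileext = ".json")
  export_network(calls, j, "json")
  expect_equal(length(jsonlite::read_json(j)), nrow(calls))
})

test_that("planted circuits around the fibroblast hub are recovered exactly", {
  lr_pairs <- data.frame(ligand = c("CCL5", "TGFB1", "IL6"),
                         receptor = c("CCR5", "TGFBR1", "IL6R"))
  lr_spec <- data.frame(
    sender = c("fibroblast", "fibroblast", "mesothelial"),
    ligand = c("CCL5", "TGFB1", "IL6"),
    receiver = c("mesothelial", "mesothelial", "fibroblast"),
    receptor = c("CCR5", "TGFBR1", "IL6R"),
    group = c("st", "st", "st"),
    target_cpm = c(150, 120, 110), stringsAsFactors = FALSE)
  cfg <- quick_config(seed = 77, n_genes = 150, cells = 60,
                      lr_spec = lr_spec, lr_pairs = lr_pairs)
  ds <- simulate_dataset(cfg)
  pb <- pseudobulk_cpm(ds$counts, ds$cells, by_group = TRUE)
  calls <- call_interactions(pb, lr_pairs, threshold = 50)
  key <- function(d) sort(paste(d$group, d$sender, d$ligand, d$receiver,
                                d$receptor))
  expect_equal(key(calls[calls$active, ]), key(ds$truth$true_active))
  fn <- focal_network(calls[calls$group == "st", ], "fibroblast")
  expect_equal(sort(unique(fn$outgoing$receiver)), "mesothelial")
  expect_equal(sort(unique(fn$incoming$sender)), "mesothelial")
})
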