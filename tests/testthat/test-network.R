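pred_tables <- function() {
  list(
    src1 = tibble::tibble(mirna = c("m1", "m2"), gene = c("g1", "g2")),
    src2 = tibble::tibble(mirna = "m1", gene = "g1"),
    src3 = tibble::tibble(mirna = c("m1", "m3"), gene = c("g1", "g3"))
  )
}

test_that("edges survive the at-least-two-of-three source rule", {
  kept <- intersect_predictions(pred_tables(), min_sources = 2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mirna, "m1")
  expect_equal(kept$sources[[1]], c("src1", "src2", "src3"))
  # two-source edges are retained with their sources recorded
  tabs <- pred_tables()
  tabs$src2 <- dplyr::bind_rows(tabs$src2,
                                tibble::tibble(mirna = "m2", gene = "g2"))
  kept2 <- intersect_predictions(tabs)
  expect_setequal(kept2$mirna, c("m1", "m2"))
  expect_equal(kept2$sources[[which(kept2$mirna == "m2")]], c("src1", "src2"))
  # malformed rows are skipped and counted
  tabs$src1 <- dplyr::bind_rows(tabs$src1,
                                tibble::tibble(mirna = NA, gene = "gX"))
  expect_warning(kept3 <- intersect_predictions(tabs), "malformed")
  expect_equal(attr(kept3, "n_skipped"), 1)
})

test_that("removing a prediction source never grows the retained edge set", {
  set.seed(5)
  tabs <- purrr::map(paste0("src", 1:3), function(s) {
    tibble::tibble(mirna = sample(paste0("m", 1:10), 40, replace = TRUE),
                   gene = sample(paste0("g", 1:10), 40, replace = TRUE))
  })
  names(tabs) <- paste0("src", 1:3)
  full <- intersect_predictions(tabs)
  reduced <- intersect_predictions(tabs[1:2])
  key <- function(x) paste(x$mirna, x$gene)
  expect_true(all(key(reduced) %in% key(full)))
})

test_that("seed grouping pools miRNAs sharing nucleotides 2-8", {
  mirnas <- tibble::tibble(
    mirna = c("miR-b", "miR-a", "miR-c"),
    sequence = c("AUGCUGACGAAUCG",   # seed UGCUGAC
                 "CUGCUGACAAAAAA",   # same seed, different elsewhere
                 "GAAAAAAAGGGGGG")
  )
  grp <- build_seq_groups(mirnas)
  expect_equal(grp$group[grp$mirna %in% c("miR-a", "miR-b")],
               rep("seqgrp-miR-a", 2))   # lexicographically smallest member
  expect_equal(sum(grp$group == "seqgrp-miR-c"), 1)
  # identical sequences under different names share a group
  dup <- build_seq_groups(tibble::tibble(
    mirna = c("x", "y"), sequence = rep("AUGCUGACGAAUCG", 2)))
  expect_equal(dplyr::n_distinct(dup$group), 1)
  # grouping is invariant to input order
  grp_rev <- build_seq_groups(mirnas[3:1, ])
  expect_identical(grp, grp_rev)
  expect_error(build_seq_groups(tibble::tibble(mirna = "z", sequence = "ATGC")),
               "A, C, G, U")
  expect_warning(
    short <- build_seq_groups(tibble::tibble(mirna = "s", sequence = "AUGC")),
    "singleton")
  expect_equal(nrow(short), 1)
})

test_that("a planted seed family yields one group of three plus singletons", {
  family_seed <- "GAGGUAG"
  set.seed(6)
  random_seq <- function() paste(sample(c("A", "C", "G", "U"), 22,
                                        replace = TRUE), collapse = "")
  fam <- paste0("A", family_seed,
                vapply(1:3, function(i) substr(random_seq(), 1, 14), ""))
  mirnas <- tibble::tibble(
    mirna = c(paste0("fam-", 1:3), paste0("solo-", 1:5)),
    sequence = c(fam, vapply(1:5, function(i) random_seq(), ""))
  )
  grp <- build_seq_groups(mirnas)
  sizes <- table(grp$group)
  expect_equal(sort(as.integer(sizes)), c(1, 1, 1, 1, 1, 3))
  expect_equal(as.integer(sizes["seqgrp-fam-1"]), 3)
  # the edit-distance rule also pools near-identical full-length sequences
  near <- tibble::tibble(mirna = c("p", "q"),
                         sequence = c("AUGCUGACGAAUCG", "AUGCUGACGAAUCA"))
  expect_equal(dplyr::n_distinct(build_seq_groups(near, rule = "edit")$group), 1)
})

test_that("the assembled network links associated seqgroups to associated
           mRNAs through retained edges only", {
  assoc_mir <- tibble::tibble(feature = c("m1", "m2"),
                              antibody = "Ago2", passed = c(TRUE, FALSE))
  assoc_mrna <- tibble::tibble(feature = c("g1", "g2"),
                               antibody = "Ago1", passed = c(TRUE, TRUE))
  edges <- intersect_predictions(list(
    src1 = tibble::tibble(mirna = c("m1", "m2"), gene = c("g1", "g2")),
    src2 = tibble::tibble(mirna = c("m1", "m2"), gene = c("g1", "g2")),
    src3 = tibble::tibble(mirna = character(0), gene = character(0))
  ))
  grps <- build_seq_groups(tibble::tibble(
    mirna = c("m1", "m2"),
    sequence = c("AAUGCUGACGAAUC", "CCGGAAUUCCGGAA")))
  g <- assemble_network(assoc_mir, assoc_mrna, edges, grps)
  expect_equal(igraph::vcount(g), 2)   # m2 not associated -> its edge drops
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$type, c("seqgroup", "mrna"))
  # empty case
  g0 <- assemble_network(dplyr::mutate(assoc_mir, passed = FALSE),
                         assoc_mrna, edges, grps)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("a planted association scenario is reconstructed exactly and every
           edge endpoint is associated with two or more sources", {
  set.seed(7)
  mirnas <- sprintf("miR-%02d", 1:10)
  genes <- sprintf("G%03d", 1:20)
  seqs <- tibble::tibble(
    mirna = mirnas,
    sequence = c(rep("AAUGCUGACGAAUC", 3),      # one 3-member family
                 vapply(1:7, function(i)
                   paste(sample(c("A", "C", "G", "U"), 14, replace = TRUE),
                         collapse = ""), ""))
  )
  grps <- build_seq_groups(seqs)
  true_edges <- tidyr::expand_grid(mirna = mirnas, gene = genes) |>
    dplyr::slice_sample(n = 30)
  cfg <- sim_config(prediction_overlap = 1, n_decoys_per_source = 0, seed = 8)
  preds <- simulate_target_predictions(mirnas, genes, true_edges, cfg)
  edges <- intersect_predictions(preds)
  assoc_mir <- tibble::tibble(feature = mirnas, antibody = "Ago2", passed = TRUE)
  assoc_mrna <- tibble::tibble(feature = genes, antibody = "Ago3", passed = TRUE)
  g <- assemble_network(assoc_mir, assoc_mrna, edges, grps)
  # every planted edge appears at the seqgroup level, and nothing else
  expected <- true_edges |>
    dplyr::inner_join(grps, by = "mirna") |>
    dplyr::distinct(group, gene)
  got <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  expect_equal(nrow(got), nrow(expected))
  expect_setequal(paste(got$from, got$to), paste(expected$group, expected$gene))
  # invariant: endpoints associated, >= 2 sources on every edge
  assoc_features <- c(mirnas, genes)
  members <- strsplit(got$member_mirnas, "[+]")
  expect_true(all(unlist(members) %in% mirnas))
  expect_true(all(got$to %in% genes))
  expect_true(all(lengths(strsplit(got$sources, "[+]")) >= 2))
})

test_that("networks export to GraphML, SIF and TSV", {
  assoc_mir <- tibble::tibble(feature = "m1", antibody = "Ago2", passed = TRUE)
  assoc_mrna <- tibble::tibble(feature = "g1", antibody = "Ago1", passed = TRUE)
  edges <- tibble::tibble(mirna = "m1", gene = "g1",
                          sources = list(c("src1", "src2")), n_sources = 2L)
  grps <- build_seq_groups(tibble::tibble(mirna = "m1",
                                          sequence = "AAUGCUGACGAAUC"))
  g <- assemble_network(assoc_mir, assoc_mrna, edges, grps)
  base <- tempfile()
  files <- write_network(g, base)
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_match(readLines(paste0(base, ".sif")), "targets g1")
})
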