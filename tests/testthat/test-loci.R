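test_that("locus clustering follows the fewer-than-two-mismatch rule", {
  set.seed(160)
  p <- random_seq(90)
  sub_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "U"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  p1 <- sub_at(p, 5)            # 1 mismatch from p
  p2 <- sub_at(sub_at(p, 40), 60)  # 2 mismatches from p (and 3 from p1)
  cl <- cluster_loci(c("a", "b"), c(p, p))
  expect_equal(length(unique(cl$locus_id)), 1)
  cl <- cluster_loci(c("a", "b"), c(p, p1))
  expect_equal(length(unique(cl$locus_id)), 1)
  cl <- cluster_loci(c("a", "b"), c(p, p2))
  expect_equal(length(unique(cl$locus_id)), 2)
  # the partition is invariant under input order
  ids <- c("a", "b", "c")
  seqs <- c(p, p1, p2)
  cl1 <- cluster_loci(ids, seqs)
  cl2 <- cluster_loci(rev(ids), rev(seqs))
  part <- function(cl) {
    g <- lapply(split(cl$candidate_id, cl$locus_id), sort)
    unname(g[order(vapply(g, `[[`, character(1), 1))])
  }
  expect_equal(part(cl1), part(cl2))
})

test_that("locus naming follows the reference-stem convention", {
  members <- data.frame(
    candidate_id = c("c1", "c2", "c3", "c4", "c5"),
    locus_id = c("locus_1", "locus_2", "locus_2", "locus_2", "locus_3"),
    reference_hit = c("osa-MIR444d", "osa-MIR444d", "osa-MIR444d",
                      "osa-MIR444d", "osa-MIR169a"),
    tissue = c("root", "bud", "culm", "bud", "leaf"),
    family = c("MIR444", "MIR444", "MIR444", "MIR444", "MIR169"),
    stringsAsFactors = FALSE)
  named <- assign_names(members)
  expect_equal(named$name[named$candidate_id == "c1"], "Ado-MIR444d-1a_r")
  # third allele of the second MIR444d locus, in bud
  expect_equal(named$name[named$candidate_id == "c4"], "Ado-MIR444d-2c_b")
  expect_equal(named$name[named$candidate_id == "c5"], "Ado-MIR169a-1a_l")
  expect_warning(
    assign_names(transform(members, reference_hit = NA_character_)),
    "missing reference hit")
})

test_that("tissue tallies count and normalize correctly", {
  members <- data.frame(tissue = c("bud", "bud", "root", "culm"),
                        family = c("MIR1", "MIR1", "MIR2", "MIR2"),
                        stringsAsFactors = FALSE)
  tt <- tissue_tally(members)
  expect_equal(sum(tt$percent), 100)
  expect_equal(tt$counts[["bud"]], 2)
  expect_equal(unname(rowSums(tt$family_by_tissue)), c(2, 2))
  all_bud <- tissue_tally(data.frame(tissue = rep("bud", 3)))
  expect_equal(all_bud$percent[["bud"]], 100)
})

test_that("tissue sampling tracks the configured weights", {
  counts <- c(bud = 0, culm = 0, leaf = 0, root = 0)
  n <- 0
  for (sd in 171:173) {
    cfg <- simulation_config(seed = sd, n_implants = 0, n_decoys = 400,
                             n_hard_negatives = 0, n_families = 1,
                             family_size_range = c(1, 1))
    sim <- simulate_transcriptome(cfg)
    counts <- counts + table(factor(sim$transcripts$tissue,
                                    levels = names(counts)))
    n <- n + nrow(sim$transcripts)
  }
  for (t in names(counts)) {
    p <- simulation_config()$tissue_weights[[t]]
    expect_lt(abs(counts[[t]] / n - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("composition profiles compute overall and positional percent", {
  cp <- composition_profile(c("UGA", "UGA"))
  expect_equal(unname(cp$positional[1, "U"]), 100)
  expect_equal(cp$overall[["U"]], 100 / 3, tolerance = 1e-12)
  cp <- composition_profile("ACGU")
  expect_true(all(cp$overall == 25))
  # ragged lengths: the longer tail only counts sequences that reach it
  cp <- composition_profile(c("AAA", "AAAAU"))
  expect_equal(unname(cp$positional[5, "U"]), 100)
  expect_equal(sum(cp$positional[5, ]), 100)
  expect_error(composition_profile(character(0)), "no sequences")
})

test_that("profile comparison reports differences and dominant bases", {
  a <- composition_profile(c("UUUU", "UUUU"))
  b <- composition_profile(c("AAAA", "AAAA"))
  cmp_same <- compare_profiles(a, a)
  expect_true(all(cmp_same$overall_diff == 0))
  expect_true(all(cmp_same$positional_diff == 0))
  cmp <- compare_profiles(a, b)
  expect_equal(unname(cmp$positional_diff[1, "U"]), 100)
  expect_equal(cmp$dominant_a[1], "U")
  expect_equal(cmp$dominant_b[1], "A")
})

test_that("locus tables round-trip their bracketed totals", {
  members <- data.frame(
    candidate_id = paste0("c", 1:6),
    locus_id = paste0("locus_", c(1, 1, 2, 3, 4, 5)),
    reference_hit = c("osa-MIR444d", "osa-MIR444d", "osa-MIR444d",
                      "osa-MIR169a", "osa-MIR169a", "osa-MIR169c"),
    tissue = "bud",
    family = c(rep("MIR444", 3), rep("MIR169", 3)),
    stringsAsFactors = FALSE)
  named <- assign_names(members)
  tab <- build_locus_table(named)
  tot <- locus_table_totals(tab)
  expect_equal(tot$total, 5)       # five distinct loci
  expect_true(tot$consistent)
  expect_equal(unname(tot$per_family[tab$family == "MIR169"]), 3)
})
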