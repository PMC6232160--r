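test_that("simulation configs are validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_decoys = -1), "counts")
  expect_error(simulation_config(tissue_weights = c(bud = 0.5, culm = 0.4,
                                                    leaf = 0.05,
                                                    root = 0.04)),
               "sum to 1")
  expect_error(simulation_config(loop_length_range = c(10, 4)), "ordered")
  expect_error(simulation_config(gc_target = 0), "gc_target")
})

test_that("precursor construction honors its contract", {
  set.seed(80)
  mature <- "UGAGGCAGUGCAGUUCAUGGA"
  p0 <- build_precursor(mature, loop_length = 4, duplex_mismatches = 0,
                        lower_stem = 12)
  st <- fold(p0$sequence)
  site <- locate_mature(p0$sequence, st, mature)
  expect_equal(site$duplex_mismatches, 0)   # perfect complement pairs fully
  expect_true(p0$report$c3_arm_ok)
  expect_true(p0$report$c4_duplex_ok)
  expect_equal(unname(p0$mature_interval),
               c(site$start, site$end))
  expect_identical(substr(p0$sequence, p0$mature_interval[1],
                          p0$mature_interval[2]), mature)
  # the designed mismatch count is recovered by the measurement
  for (dm in 1:3) {
    p <- build_precursor(mature, loop_length = 8, duplex_mismatches = dm,
                         lower_stem = 15)
    s <- locate_mature(p$sequence, fold(p$sequence), mature)
    expect_equal(s$duplex_mismatches, dm)
  }
  expect_error(build_precursor(mature, 8, duplex_mismatches = 6),
               "five")
  expect_error(build_precursor("UGAGGCAGUGCAGUUCAUGNA", 8, 0), "ambiguity")
  expect_error(build_precursor(mature, 2, 0), "loop_length")
  expect_error(build_precursor(substr(mature, 1, 15), 8, 0), "19-25")
})

test_that("every generated precursor passes the six criteria", {
  set.seed(81)
  for (i in 1:5) {
    p <- build_precursor(random_seq(21), loop_length = sample(4:15, 1),
                         duplex_mismatches = sample(0:3, 1),
                         lower_stem = sample(5:30, 1))
    expect_true(p$report$accepted)
    expect_lte(p$report$mfei, -0.85)
  }
})

test_that("transcriptome simulation is deterministic and labelled", {
  cfg <- small_sim_config(seed = 123)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$manifest$implanted, b$manifest$implanted)
  expect_identical(a$manifest$hard_negatives, b$manifest$hard_negatives)
  expect_true(all(a$transcripts$tissue %in%
                    c("bud", "culm", "leaf", "root")))
  # implanted intervals lie within their transcript and carry the mature
  for (i in seq_len(nrow(a$manifest$implanted))) {
    im <- a$manifest$implanted[i, ]
    tx <- a$transcripts$sequence[a$transcripts$id == im$transcript_id]
    expect_lte(im$precursor_end, nchar(tx))
    expect_identical(substr(tx, im$mature_start, im$mature_end),
                     im$mature_sequence)
  }
  # no implants requested means an empty implant manifest
  empty <- simulate_transcriptome(
    simulation_config(seed = 5, n_implants = 0, n_decoys = 3,
                      n_hard_negatives = 0, n_families = 2,
                      family_size_range = c(1, 2)))
  expect_equal(nrow(empty$manifest$implanted), 0)
})

test_that("hard negatives fail the filter in their embedded context", {
  cfg <- small_sim_config(seed = 321)
  sim <- simulate_transcriptome(cfg)
  hn <- sim$manifest$hard_negatives
  expect_equal(nrow(hn), cfg$n_hard_negatives)
  for (i in seq_len(nrow(hn))) {
    tx <- sim$transcripts$sequence[sim$transcripts$id ==
                                     hn$transcript_id[i]]
    hp <- extract_hairpin(tx, hn$mature_sequence[i])
    st <- fold(hp$sequence)
    site <- locate_mature(hp$sequence, st, hn$mature_sequence[i])
    rep <- evaluate_criteria(compute_metrics(st), site,
                             nchar(hn$mature_sequence[i]))
    expect_false(rep$accepted, info = hn$class[i])
  }
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(90)
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:10) {
    s <- random_seq(sample(40:120, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(as.list(dinucs(sh)), as.list(dinucs(s)))
  }
})

test_that("designed target sites score exactly as designed", {
  set.seed(100)
  cfg <- small_sim_config(seed = 7)
  mirnas <- c(m1 = fixture_mirna(), m2 = random_seq(21))
  simt <- simulate_targets(mirnas, cfg)
  expect_equal(nrow(simt$mrnas), cfg$n_target_mrnas)
  for (i in seq_len(nrow(simt$target_sites))) {
    ts <- simt$target_sites[i, ]
    site <- substr(simt$mrnas$sequence[simt$mrnas$id == ts$mrna_id],
                   ts$start, ts$end)
    for (mode in c("psrnatarget_like", "targetfinder_like")) {
      dx <- score_duplex(mirnas[[ts$mirna_id]], site, mode)
      expect_equal(dx$expectation, ts$designed_penalty, tolerance = 1e-12)
    }
    dx <- score_duplex(mirnas[[ts$mirna_id]], site, "psrnatarget_like")
    expect_equal(classify_inhibition(dx), ts$designed_inhibition)
  }
  # penalty 0 sites are exact reverse complements
  d0 <- design_target_site(fixture_mirna(), 0)
  expect_identical(d0$site, rna_revcomp(fixture_mirna()))
  # a fractional level no wobble can realize is rejected by name
  expect_error(design_target_site("CCAACCAACCAACCAACCAAC", 0.5),
               "unachievable penalty level 0.5")
  expect_error(design_target_site(fixture_mirna(), 0.3), "unachievable")
  # translation-type sites need a central mismatch worth 2
  expect_error(design_target_site(fixture_mirna(), 1,
                                  translation_type = TRUE),
               "unachievable")
})

test_that("mature sets reproduce the configured length/composition mix", {
  set.seed(110)
  mats <- simulate_mature_set(400)
  len_tab <- table(nchar(mats)) / length(mats)
  expect_equal(unname(len_tab[["21"]]), 0.858, tolerance = 0.08)
  expect_equal(mean(substr(mats, 1, 1) == "U"), 0.851, tolerance = 0.08)
})
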