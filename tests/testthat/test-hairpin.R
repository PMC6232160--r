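test_that("folding engines honor the shared contract", {
  st <- fold(strrep("A", 10), engine = "maxpair")
  expect_equal(st$dotbracket, "..........")
  expect_equal(st$mfe, 0)
  st <- fold("GGGGAAAACCCC", engine = "maxpair")
  expect_equal(st$dotbracket, "((((....))))")
  expect_equal(st$mfe, -4)
  # deterministic
  expect_identical(fold("GGGGAAAACCCC", engine = "maxpair"),
                   fold("GGGGAAAACCCC", engine = "maxpair"))
  expect_error(fold("GGGGNAAACCCC", engine = "maxpair"), "ambiguity")
  expect_error(fold("ACGUA", engine = "maxpair"), ">= 10")
})

test_that("base-pair maximization equals exhaustive enumeration", {
  set.seed(50)
  for (i in 1:25) {
    s <- random_seq(sample(10:14, 1))
    st <- fold(s, engine = "maxpair")
    expect_equal(-st$mfe, oracle_max_pairs(s), info = s)
    # structure is consistent: pairs in the traceback equal the optimum
    pt <- pair_table(st$dotbracket)
    expect_equal(sum(pt > 0) / 2, oracle_max_pairs(s))
  }
})

test_that("thermodynamic engine output parses into valid structures", {
  sts <- fold(c("GGGGAAAACCCC", strrep("A", 12)), engine = "vienna")
  expect_length(sts, 2)
  expect_equal(nchar(sts[[1]]$dotbracket), 12)
  expect_lte(sts[[1]]$mfe, 0)
  expect_equal(sts[[2]]$mfe, 0)
  pt <- pair_table(sts[[1]]$dotbracket)
  expect_equal(length(pt), 12)
})

test_that("hairpin metrics implement AMFE and MFEI exactly", {
  st <- structure(list(sequence = paste0(strrep("GC", 25), strrep("AU", 25)),
                       dotbracket = strrep(".", 100), mfe = -50,
                       engine = "maxpair"), class = "secondary_structure")
  m <- compute_metrics(st)
  expect_equal(m$amfe, -50)
  expect_equal(m$gc_percent, 50)
  expect_equal(m$mfei, -1.0)
  expect_equal(m$gc_percent + m$au_percent, 100)
  # zero energy gives zero AMFE/MFEI
  st$mfe <- 0
  expect_equal(compute_metrics(st)$mfei, 0)
  # scaling the energy scales MFEI linearly
  st$mfe <- -20
  m1 <- compute_metrics(st)
  st$mfe <- -40
  expect_equal(compute_metrics(st)$mfei, 2 * m1$mfei)
  st$sequence <- strrep("AU", 50)
  expect_error(compute_metrics(st), "GC")
})

test_that("mature placement finds arm and duplex mismatches", {
  set.seed(60)
  mature <- "UGAGGCAGUGCAGUUCAUGGA"
  prec <- paste0(mature, "GAAAC", rna_revcomp(mature))
  st <- fold(prec, engine = "maxpair")
  site <- locate_mature(prec, st, mature)
  expect_equal(site$arm, "5p")
  expect_equal(site$start, 1)
  expect_equal(site$mismatches_to_reference, 0)
  expect_equal(site$duplex_mismatches, 0)
  # same hairpin, reference matching the 3' arm
  site3 <- locate_mature(prec, st, rna_revcomp(mature))
  expect_equal(site3$arm, "3p")
  # a reference spanning the terminal loop is called loop_spanning
  span_ref <- substr(prec, 12, 32)
  sitel <- locate_mature(prec, st, span_ref)
  expect_equal(sitel$arm, "loop_spanning")
  # unrelated reference is unmappable
  siteu <- locate_mature(prec, st, random_seq(21))
  expect_true(siteu$unmappable)
})

test_that("the six criteria and their boundaries are enforced", {
  metrics <- data.frame(length = 100, gc_percent = 50, au_percent = 50,
                        mfe = -42.5, amfe = -42.5, mfei = -0.85)
  site <- structure(list(start = 1, end = 21, arm = "5p",
                         mismatches_to_reference = 1,
                         duplex_mismatches = 3, unmappable = FALSE),
                    class = "mature_site")
  rep <- evaluate_criteria(metrics, site, 21)
  expect_true(rep$accepted)
  expect_true(rep$c6_mfei_ok)     # -0.85 is inclusive
  metrics$mfei <- -0.84
  expect_false(evaluate_criteria(metrics, site, 21)$c6_mfei_ok)
  metrics$mfei <- -1
  expect_false(evaluate_criteria(metrics, site, 18)$c1_length_ok)
  site$mismatches_to_reference <- 3
  expect_false(evaluate_criteria(metrics, site, 21)$c2_ref_ok)
  site$mismatches_to_reference <- 1
  site$arm <- "loop_spanning"
  expect_false(evaluate_criteria(metrics, site, 21)$c3_arm_ok)
  site$arm <- "3p"
  site$duplex_mismatches <- 6
  expect_false(evaluate_criteria(metrics, site, 21)$c4_duplex_ok)
  site$duplex_mismatches <- 5
  expect_true(evaluate_criteria(metrics, site, 21)$c4_duplex_ok)
  metrics$au_percent <- 71
  expect_false(evaluate_criteria(metrics, site, 21)$c5_au_ok)
})

test_that("MFEI separates hairpins from unstructured RNA of like length", {
  set.seed(70)
  decoy_mfei <- vapply(1:15, function(i) {
    compute_metrics(fold(random_seq(80), engine = "vienna"))$mfei
  }, numeric(1))
  implant_mfei <- vapply(1:5, function(i) {
    p <- build_precursor(random_seq(21), loop_length = 8,
                         duplex_mismatches = 1, lower_stem = 15,
                         engine = "vienna")
    compute_metrics(fold(p$sequence, engine = "vienna"))$mfei
  }, numeric(1))
  expect_gt(mean(decoy_mfei), -0.85)
  expect_true(all(implant_mfei <= -0.85))
})
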