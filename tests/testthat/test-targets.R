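test_that("duplex scoring applies the plant penalty scheme", {
  mirna <- fixture_mirna()            # UAGGCACUGAAGGACCUGCAU
  L <- nchar(mirna)
  perfect <- rna_revcomp(mirna)
  for (mode in c("psrnatarget_like", "targetfinder_like")) {
    expect_equal(score_duplex(mirna, perfect, mode)$expectation, 0)
  }
  q <- strsplit(mirna, "")[[1]]
  flip_site <- function(pos, to) {
    s <- strsplit(perfect, "")[[1]]
    s[L - pos + 1] <- to
    paste(s, collapse = "")
  }
  # G:U wobble outside the core costs 0.5 (position 15 is G: C -> U)
  expect_equal(q[15], "G")
  expect_equal(score_duplex(mirna, flip_site(15, "U"),
                            "targetfinder_like")$expectation, 0.5)
  # the same wobble inside positions 2-13 is doubled (position 5 is C: no
  # wobble; use position 8 U: A -> G gives U:G)
  expect_equal(q[8], "U")
  expect_equal(score_duplex(mirna, flip_site(8, "G"),
                            "targetfinder_like")$expectation, 1.0)
  # a substitution mismatch at position 5 costs 2 in the doubled region
  expect_equal(q[5], "C")
  expect_equal(score_duplex(mirna, flip_site(5, "A"),
                            "targetfinder_like")$expectation, 2.0)
  # and 1 outside it (position 18, G faces C; A pairs with neither)
  expect_equal(q[18], "G")
  expect_equal(score_duplex(mirna, flip_site(18, "A"),
                            "targetfinder_like")$expectation, 1.0)
})

test_that("gapped duplex alignment equals exhaustive enumeration", {
  set.seed(120)
  for (i in 1:100) {
    m <- sample(8:12, 1)
    q <- random_seq(m)
    s <- random_seq(m + sample(-2:2, 1))
    mine <- mirhunt:::duplex_align(strsplit(q, "")[[1]],
                                   rev(strsplit(s, "")[[1]]))
    expect_equal(mine$expectation, oracle_duplex(q, s), info = paste(q, s))
  }
})

test_that("strand swap preserves the score of gap-free 14-nt duplexes", {
  # for a 14-nt duplex the doubled region 2-13 maps onto itself under
  # reversal; pair states (match / G:U / mismatch) are symmetric in the
  # two strands, so swapping them must not change a gap-free penalty
  # (indel anchoring is miRNA-position based and excluded here)
  set.seed(130)
  for (i in 1:20) {
    a <- random_seq(14)
    b <- rna_revcomp(a)
    ch <- strsplit(b, "")[[1]]
    for (p in sample(c(3, 7, 11), sample(1:3, 1))) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    }
    b <- paste(ch, collapse = "")
    ab <- mirhunt:::duplex_align(strsplit(a, "")[[1]],
                                 rev(strsplit(b, "")[[1]]))$expectation
    ba <- mirhunt:::duplex_align(strsplit(b, "")[[1]],
                                 rev(strsplit(a, "")[[1]]))$expectation
    expect_equal(ab, ba)
  }
})

test_that("transcript scanning recovers designed sites at mode thresholds", {
  set.seed(140)
  mirna <- fixture_mirna()
  for (pen in c(0, 3.0)) {
    d <- design_target_site(mirna, pen)
    tx <- paste0(random_seq(150), d$site, random_seq(150))
    for (mode in c("psrnatarget_like", "targetfinder_like")) {
      hits <- scan_transcript(mirna, tx, mode)
      hit <- hits[abs(hits$start - 151) < 3, ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$expectation, pen)
    }
  }
  # a 3.5 site passes only the targetfinder-like threshold (3.0 vs < 4)
  d <- design_target_site(mirna, 3.5)
  tx <- paste0(random_seq(100), d$site, random_seq(100))
  expect_equal(nrow(scan_transcript(mirna, tx, "psrnatarget_like")), 0)
  expect_equal(nrow(scan_transcript(mirna, tx, "targetfinder_like")), 1)
  # a 4.0 site passes neither (strict "< 4")
  d4 <- design_target_site(mirna, 4)
  tx4 <- paste0(random_seq(100), d4$site, random_seq(100))
  expect_equal(nrow(scan_transcript(mirna, tx4, "targetfinder_like")), 0)
})

test_that("background hit rate on random transcripts is near zero", {
  mirna <- fixture_mirna()
  set.seed(150)
  seeds_with_hits <- 0
  for (i in 1:20) {
    tx <- random_seq(2000)
    h <- scan_transcript(mirna, tx, "psrnatarget_like")
    if (nrow(h) > 0) seeds_with_hits <- seeds_with_hits + 1
  }
  expect_lte(seeds_with_hits, 2)
})

test_that("mode intersection keeps shared overlapping sites only", {
  mk <- function(mirna_id, transcript_id, start, exp, mode) {
    out <- data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
                      start = start, end = start + 20, expectation = exp,
                      mode = mode, stringsAsFactors = FALSE)
    out$duplex <- list(structure(list(expectation = exp,
                                      per_position = rep("match", 21),
                                      site_map = 21:1,
                                      mode = mode),
                                 class = "duplex_score"))
    out
  }
  psr <- rbind(mk("m1", "t1", 100, 1, "psrnatarget_like"),
               mk("m1", "t2", 50, 2, "psrnatarget_like"),
               mk("m2", "t1", 10, 0, "psrnatarget_like"))
  tf <- rbind(mk("m1", "t1", 105, 1.5, "targetfinder_like"),
              mk("m2", "t1", 400, 0, "targetfinder_like"))
  cons <- intersect_modes(psr, tf)
  # m1/t1 overlaps; m1/t2 is psr-only; m2/t1 intervals are disjoint
  expect_equal(nrow(cons), 1)
  expect_equal(cons$mirna_id, "m1")
  expect_equal(cons$expectation_psr, 1)
  expect_equal(cons$score_tf, 1.5)
  expect_true(nrow(intersect_modes(psr, psr[0, ])) == 0)
})

test_that("inhibition typing follows the central mismatch rule", {
  mirna <- fixture_mirna()
  perfect <- rna_revcomp(mirna)
  L <- nchar(mirna)
  flip_site <- function(pos, to) {
    s <- strsplit(perfect, "")[[1]]
    s[L - pos + 1] <- to
    paste(s, collapse = "")
  }
  expect_equal(classify_inhibition(score_duplex(mirna, perfect)),
               "cleavage")
  # mismatch at position 10 -> translation
  q10 <- strsplit(mirna, "")[[1]][10]
  bad10 <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", q10),
                     if (q10 == "G") "U", if (q10 == "U") "G"))[1]
  dx <- score_duplex(mirna, flip_site(10, bad10))
  expect_equal(classify_inhibition(dx), "translation")
  # G:U at position 10 is pairing by default, central mismatch on request
  expect_equal(q10, "A")  # no wobble possible at 10; use position 11 (C)?
  q11 <- strsplit(mirna, "")[[1]][11]
  expect_equal(q11, "A")
  # fall back to a miRNA whose position 10 is G
  mirna2 <- paste0(substr(mirna, 1, 9), "G", substr(mirna, 11, L))
  wob <- score_duplex(mirna2, flip_site(10, "U"))
  expect_equal(classify_inhibition(wob), "cleavage")
  expect_equal(classify_inhibition(wob, gu_central_mismatch = TRUE),
               "translation")
})

test_that("cleavage sites sit opposite the miRNA 10/11 bond", {
  mirna <- fixture_mirna()
  tx <- paste0(random_seq(100), rna_revcomp(mirna), random_seq(100))
  hits <- scan_transcript(mirna, tx, "psrnatarget_like")
  hit <- hits[hits$start == 101, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, 121)
  # cut between transcript positions 111 and 112
  expect_equal(predict_cleavage_site(hit$duplex[[1]], hit$start), 111)
  # translation-type hits have no cleavage coordinate
  d <- design_target_site(mirna, 2, translation_type = TRUE)
  dx <- score_duplex(mirna, d$site)
  expect_error(predict_cleavage_site(dx, 1), "translation")
  ann <- annotate_targets(intersect_modes(
    hits, scan_transcript(mirna, tx, "targetfinder_like")))
  expect_equal(ann$inhibition, "cleavage")
  expect_equal(ann$cleavage_pos, 111)
})
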