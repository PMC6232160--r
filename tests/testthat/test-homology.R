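test_that("self-alignment and strand symmetry behave", {
  q <- "AAAACCCCGGGGAAAACCCC"   # not its own reverse complement
  h <- local_align(q, q)
  expect_equal(h$score, 40)
  expect_equal(h$mismatches, 0)
  expect_equal(h$query_interval, c(1, 20))
  # reverse complement of an embedded copy is found on the minus strand
  set.seed(2)
  subj <- paste0(random_seq(30), rna_revcomp(q), random_seq(30))
  h2 <- local_align(q, subj)
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, 40)
  expect_equal(h2$subject_interval, c(31, 50))
  expect_error(local_align("", q), "empty")
})

test_that("exact aligner equals the independent Smith-Waterman oracle", {
  set.seed(10)
  submat <- blast_submat()
  for (i in 1:200) {
    a <- random_seq(60)
    b <- random_seq(60)
    mine <- local_align(a, b, both_strands = FALSE)$score
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2))
    expect_equal(mine, oracle)
  }
})

test_that("seeded search matches exhaustive alignment on long subjects", {
  set.seed(20)
  for (i in 1:5) {
    q <- random_seq(90)
    core <- substr(q, 20, 75)
    subj <- paste0(random_seq(800), core, random_seq(900))
    full <- local_align(q, subj)
    seeded <- seeded_align(q, subj, word_size = 11, seed_min_subject = 500)
    expect_equal(seeded$score, full$score)
    expect_equal(seeded$subject_interval, full$subject_interval)
    expect_equal(seeded$strand, full$strand)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(evalue_of(20, 100, 100), 0.41 * 1e4 * exp(-12.5))
  # monotone decreasing in score
  e <- evalue_of(c(10, 20, 40), 100, 1e5)
  expect_true(all(diff(e) < 0))
  # linear in database length
  expect_equal(evalue_of(20, 100, 2e5), 2 * evalue_of(20, 100, 1e5))
  expect_error(evalue_of(20, 0, 100), "positive")
  expect_error(evalue_of(20, 100, 100, K = 0), "positive")
})

test_that("best-hit retention applies the E-value cutoff and ties", {
  hits <- data.frame(
    qseqid = c("q1", "q1", "q2", "q3"),
    sseqid = c("s1", "s2", "s1", "s3"),
    pident = 90, length = 21, mismatch = 1, gapopen = 0,
    qstart = 1, qend = 21,
    sstart = c(100, 400, 102, 50), send = c(120, 420, 122, 70),
    evalue = c(1e-5, 2e-3, 3e-4, 12), score = c(40, 30, 35, 40),
    strand = "+", stringsAsFactors = FALSE)
  out <- best_hits(hits, evalue_cutoff = 10)
  expect_equal(out$evalue[out$qseqid == "q1"], 1e-5)
  expect_false("q3" %in% out$qseqid)   # exceeds the E-value cutoff
  # q2's best hit covers 90% of q1's region on s1 -> collapsed as redundant
  expect_false("q2" %in% out$qseqid)
  # but a q2 hit on a distinct region survives the collapse
  hits$sstart[3] <- 300; hits$send[3] <- 320
  expect_true("q2" %in% best_hits(hits)$qseqid)
  expect_equal(nrow(best_hits(hits[0, ])), 0)
})

test_that("whole-length mismatch counts match the global-alignment oracle", {
  expect_equal(whole_length_mismatches("ACGU", "ACGU"), 0)
  expect_equal(whole_length_mismatches("ACGU", "AGGU"), 1)
  expect_equal(whole_length_mismatches("ACGU", "ACG"), 1)  # end overhang
  set.seed(30)
  for (i in 1:200) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    expect_equal(whole_length_mismatches(a, b),
                 as.integer(utils::adist(a, b)))
  }
})

test_that("search_homology reports tabular hits with sane invariants", {
  set.seed(40)
  qs <- c(qA = random_seq(80), qB = random_seq(80))
  subj <- c(s1 = paste0(random_seq(50), qs[["qA"]], random_seq(60)),
            s2 = random_seq(300))
  hits <- search_homology(qs, subj, word_size = 11)
  hA <- hits[hits$qseqid == "qA" & hits$sseqid == "s1", ]
  expect_equal(hA$mismatch, 0)
  expect_equal(hA$length, 80)
  expect_true(hA$evalue < 1e-10)
  out <- best_hits(hits)
  expect_lte(nrow(out), length(unique(hits$qseqid)))
})
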