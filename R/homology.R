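#' Default nucleotide alignment scoring (blastn-like)
#'
#' Match +2, mismatch -3, affine gaps costing open 5 plus 2 per gap
#' position.
#'
#' @return list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
blastn_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
}

#' Optimal local alignment of two sequences
#'
#' Exact affine-gap Smith-Waterman on both strands; the better-scoring
#' strand is reported (ties prefer `+`). Coordinates are 1-based closed
#' intervals on the original (plus-strand) sequences.
#'
#' @param query,subject sequences (RNA alphabet).
#' @param scoring scoring list, see [blastn_scoring()].
#' @param both_strands also search the reverse complement of the subject.
#' @return list with `score`, `query_interval`, `subject_interval`,
#'   `strand`, `identities`, `mismatches`, `gaps`, `aligned_query`,
#'   `aligned_subject`.
#' @export
local_align <- function(query, subject, scoring = blastn_scoring(),
                        both_strands = TRUE) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  fwd <- cpp_sw_align(query, subject, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  hit <- .as_hit(fwd, "+", nchar(subject))
  if (both_strands) {
    rev <- cpp_sw_align(query, rna_revcomp(subject), scoring$match,
                        scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend)
    rhit <- .as_hit(rev, "-", nchar(subject))
    if (rhit$score > hit$score) hit <- rhit
  }
  hit
}

.as_hit <- function(aln, strand, subject_len) {
  si <- c(aln$subject_start, aln$subject_end)
  if (strand == "-" && !is.na(si[1])) {
    si <- c(subject_len - aln$subject_end + 1L,
            subject_len - aln$subject_start + 1L)
  }
  list(score = aln$score,
       query_interval = c(aln$query_start, aln$query_end),
       subject_interval = si,
       strand = strand,
       identities = aln$identities,
       mismatches = aln$mismatches,
       gaps = aln$gaps,
       aligned_query = aln$aligned_query,
       aligned_subject = aln$aligned_subject)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)` for query length `m` and database
#' length `n`.
#'
#' @param score raw alignment score.
#' @param query_length,database_length positive lengths.
#' @param K,lambda Karlin-Altschul parameters (defaults 0.41, 0.625,
#'   appropriate for +2/-3 nucleotide scoring).
#' @return the expected number of chance hits at or above `score`.
#' @export
evalue_of <- function(score, query_length, database_length,
                      K = 0.41, lambda = 0.625) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  if (any(query_length <= 0) || any(database_length <= 0)) {
    stop("lengths must be positive")
  }
  K * query_length * database_length * exp(-lambda * score)
}

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(setNames(list(), character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  split(starts, kmers)
}

#' Search a query against one subject, seeding long subjects
#'
#' For subjects shorter than `seed_min_subject` the search is an exhaustive
#' Smith-Waterman on both strands. Longer subjects are first scanned for
#' exact shared k-mers (`word_size`); alignment is then restricted to
#' subject windows around the seeded region, one window per strand. Without
#' seeds on a strand that strand yields no hit.
#'
#' @inheritParams local_align
#' @param word_size exact-match seed length (default 11; use 7 for short
#'   miRNA-scale queries).
#' @param seed_min_subject subject length below which seeding is skipped.
#' @return as [local_align()], or `NULL` when nothing aligns.
#' @export
seeded_align <- function(query, subject, scoring = blastn_scoring(),
                         word_size = 11, seed_min_subject = 500) {
  n <- nchar(subject)
  if (n <= seed_min_subject) {
    hit <- local_align(query, subject, scoring)
    return(if (hit$score > 0) hit else NULL)
  }
  qlen <- nchar(query)
  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else rna_revcomp(subject)
    idx <- kmer_positions(subj, word_size)
    qk <- unique(names(kmer_positions(query, word_size)))
    hits <- unlist(idx[intersect(qk, names(idx))], use.names = FALSE)
    if (is.null(hits) || length(hits) == 0L) next
    lo <- max(1L, min(hits) - qlen - 10L)
    hi <- min(n, max(hits) + word_size + qlen + 10L)
    aln <- cpp_sw_align(query, substr(subj, lo, hi), scoring$match,
                        scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend)
    if (aln$score <= 0) next
    aln$subject_start <- aln$subject_start + lo - 1L
    aln$subject_end <- aln$subject_end + lo - 1L
    hit <- .as_hit(aln, "+", n)   # coords already on subj orientation
    if (strand == "-") {
      hit$subject_interval <- c(n - hit$subject_interval[2] + 1L,
                                n - hit$subject_interval[1] + 1L)
      hit$strand <- "-"
    }
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  best
}

#' Search many queries against many subjects
#'
#' Produces one row per (query, subject) pair that aligns, in tabular-BLAST
#' column order plus `strand` and the raw `score`. E-values use the total
#' subject length as the database size.
#'
#' @param queries,subjects named character vectors of sequences.
#' @inheritParams seeded_align
#' @param K,lambda Karlin-Altschul parameters for [evalue_of()].
#' @return data.frame: `qseqid`, `sseqid`, `pident`, `length`, `mismatch`,
#'   `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`, `score`,
#'   `strand`.
#' @export
search_homology <- function(queries, subjects, scoring = blastn_scoring(),
                            word_size = 11, seed_min_subject = 500,
                            K = 0.41, lambda = 0.625) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  db_len <- sum(nchar(subjects))
  rows <- list()
  for (qi in seq_along(queries)) {
    for (si in seq_along(subjects)) {
      hit <- seeded_align(queries[[qi]], subjects[[si]], scoring,
                          word_size, seed_min_subject)
      if (is.null(hit) || hit$score <= 0) next
      alen <- nchar(hit$aligned_query)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = names(queries)[qi], sseqid = names(subjects)[si],
        pident = 100 * hit$identities / alen, length = alen,
        mismatch = hit$mismatches, gapopen = hit$gaps,
        qstart = hit$query_interval[1], qend = hit$query_interval[2],
        sstart = hit$subject_interval[1], send = hit$subject_interval[2],
        evalue = evalue_of(hit$score, nchar(queries[[qi]]), db_len,
                           K, lambda),
        score = hit$score, strand = hit$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

interval_overlap_frac <- function(a1, a2, b1, b2) {
  ov <- min(a2, b2) - max(a1, b1) + 1
  if (ov <= 0) return(0)
  ov / min(a2 - a1 + 1, b2 - b1 + 1)
}

#' Retain the best hit per query and drop redundant subject regions
#'
#' Per query the hit with the lowest E-value is kept (ties: highest score,
#' then lexicographically lowest subject id); hits with E-value above the
#' cutoff are discarded. Best hits of different queries that cover the same
#' subject region (interval overlap of at least 80% of the shorter hit, on
#' the same subject) are then collapsed to the single best one.
#'
#' @param hits data.frame from [search_homology()].
#' @param evalue_cutoff E-value cutoff (default 10).
#' @param overlap_frac redundancy-collapse overlap fraction (default 0.8).
#' @return filtered hit data.frame, one row per retained query.
#' @export
best_hits <- function(hits, evalue_cutoff = 10, overlap_frac = 0.8) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$score, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  # redundancy collapse across queries, best (lowest E) first
  hits <- hits[order(hits$evalue, -hits$score, hits$qseqid), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    for (j in seq(i + 1L, nrow(hits))) {
      if (!keep[j] || hits$sseqid[j] != hits$sseqid[i]) next
      f <- interval_overlap_frac(min(hits$sstart[i], hits$send[i]),
                                 max(hits$sstart[i], hits$send[i]),
                                 min(hits$sstart[j], hits$send[j]),
                                 max(hits$sstart[j], hits$send[j]))
      if (f >= overlap_frac) keep[j] <- FALSE
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mismatches of the global alignment of two sequences
#'
#' Substitutions plus gap characters (end overhangs included) of the
#' unit-cost global alignment; used for the "alleles of the same locus"
#' clustering rule.
#'
#' @param a,b sequences.
#' @return integer mismatch count.
#' @export
whole_length_mismatches <- function(a, b) {
  cpp_nw_mismatches(a, b)
}
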