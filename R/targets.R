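duplex_pair_state <- function(q, t) {
  # q: miRNA base; t: the site base it faces (antiparallel duplex)
  if ((q == "A" && t == "U") || (q == "U" && t == "A") ||
      (q == "G" && t == "C") || (q == "C" && t == "G")) "match"
  else if ((q == "G" && t == "U") || (q == "U" && t == "G")) "gu"
  else "mismatch"
}

position_weight <- function(i) ifelse(i >= 2 & i <= 13, 2, 1)

state_cost <- function(state) {
  c(match = 0, gu = 0.5, mismatch = 1, gap = 2)[state]
}

# Global DP of miRNA positions (a..b, absolute numbering) against the
# reversed site. free_site_ends leaves unaligned site bases at either end
# unpenalized (best-window semantics). Minimizes the weighted penalty.
duplex_align <- function(qch, rch, pos_offset = 0L, free_site_ends = FALSE) {
  m <- length(qch); n <- length(rch)
  w <- position_weight(pos_offset + seq_len(m))
  wins <- position_weight(pmin(pos_offset + seq_len(m + 1L),
                               pos_offset + m))
  INF <- 1e18
  d <- matrix(INF, m + 1L, n + 1L)
  d[1L, ] <- if (free_site_ends) 0 else
    c(0, cumsum(rep(2 * wins[1L], n)))
  for (i in seq_len(m)) d[i + 1L, 1L] <- d[i, 1L] + 2 * w[i]
  tb <- matrix(0L, m + 1L, n + 1L)   # 1 diag, 2 up (gap in site), 3 left
  tb[1L, -1L] <- 3L
  tb[-1L, 1L] <- 2L
  for (i in seq_len(m)) {
    ci <- vapply(rch, function(t)
      state_cost(duplex_pair_state(qch[i], t)), numeric(1)) * w[i]
    for (j in seq_len(n)) {
      diag <- d[i, j] + ci[j]
      up <- d[i, j + 1L] + 2 * w[i]
      left <- d[i + 1L, j] + 2 * wins[i + 1L]
      best <- diag; t <- 1L
      if (up < best) { best <- up; t <- 2L }
      if (left < best) { best <- left; t <- 3L }
      d[i + 1L, j + 1L] <- best
      tb[i + 1L, j + 1L] <- t
    }
  }
  jend <- if (free_site_ends) which.min(d[m + 1L, ]) - 1L else n
  expectation <- d[m + 1L, jend + 1L]
  states <- character(m)
  map <- rep(NA_integer_, m)
  i <- m; j <- jend
  while (i > 0L || j > 0L) {
    t <- if (i == 0L) 3L else if (j == 0L) 2L else tb[i + 1L, j + 1L]
    if (free_site_ends && i == 0L) break
    if (t == 1L) {
      states[i] <- duplex_pair_state(qch[i], rch[j])
      map[i] <- j
      i <- i - 1L; j <- j - 1L
    } else if (t == 2L) {
      states[i] <- "gap"
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(expectation = expectation, states = states, rsite_map = map)
}

#' Score a miRNA / target-site duplex
#'
#' The miRNA (5' to 3') is aligned against the site read 3' to 5' under the
#' plant-target penalty scheme: mismatch 1, G:U wobble 0.5, indel 2, all
#' doubled at miRNA positions 2-13; perfect pairing scores 0 and lower is
#' better. `"targetfinder_like"` scores the full miRNA;
#' `"psrnatarget_like"` restricts scoring to the best window of 20 miRNA
#' positions (complementarity scoring length), site overhangs free.
#'
#' @param mirna miRNA sequence, 19-25 nt.
#' @param site target-site sequence in transcript (sense) orientation.
#' @param mode `"psrnatarget_like"` or `"targetfinder_like"`.
#' @return a `duplex_score`: `expectation`, `per_position` (states
#'   `match`/`gu`/`mismatch`/`gap` per miRNA position, `unscored` outside
#'   the chosen window), `site_map` (site coordinate paired with each
#'   miRNA position), `mode`.
#' @export
score_duplex <- function(mirna, site,
                         mode = c("psrnatarget_like", "targetfinder_like")) {
  mode <- match.arg(mode)
  L <- nchar(mirna)
  if (L < 19 || L > 25) stop("miRNA length must be 19-25 nt")
  qch <- seq_chars(mirna)
  rch <- rev(seq_chars(site))
  M <- length(rch)
  if (mode == "targetfinder_like" || L <= 20L) {
    window_starts <- 1L
    win_len <- L
  } else {
    win_len <- 20L
    window_starts <- seq_len(L - win_len + 1L)
  }
  free <- mode == "psrnatarget_like" && L > 20L
  best <- NULL
  for (a in window_starts) {
    al <- duplex_align(qch[a:(a + win_len - 1L)], rch,
                       pos_offset = a - 1L, free_site_ends = free)
    if (is.null(best) || al$expectation < best$expectation) {
      best <- al; best$a <- a
    }
  }
  per_position <- rep("unscored", L)
  site_map <- rep(NA_integer_, L)
  idx <- best$a:(best$a + win_len - 1L)
  per_position[idx] <- best$states
  site_map[idx] <- ifelse(is.na(best$rsite_map), NA_integer_,
                          M - best$rsite_map + 1L)
  structure(list(expectation = best$expectation,
                 per_position = per_position, site_map = site_map,
                 mode = mode), class = "duplex_score")
}

#' @export
print.duplex_score <- function(x, ...) {
  cat("<duplex_score> mode=", x$mode, " expectation=", x$expectation,
      "\n", sep = "")
  invisible(x)
}

mode_threshold <- function(mode) {
  if (mode == "psrnatarget_like") 3.0 else 4.0
}

passes_threshold <- function(expectation, mode, threshold) {
  if (mode == "psrnatarget_like") expectation <= threshold
  else expectation < threshold   # "score lower than 4"
}

#' Scan a transcript for miRNA target sites
#'
#' Reports non-overlapping local score optima passing the mode's
#' threshold: expectation <= 3.0 (psrnatarget_like, inclusive) or < 4.0
#' (targetfinder_like, strict). Windows are pre-screened with an ungapped
#' scorer and refined with the gapped duplex alignment; overlapping windows
#' are resolved best-first, ties to the leftmost site.
#'
#' @param mirna miRNA sequence (19-25 nt).
#' @param transcript transcript sequence, at least as long as the miRNA.
#' @param mode scoring mode, see [score_duplex()].
#' @param threshold override of the mode default.
#' @param mirna_id,transcript_id labels for the output.
#' @return data.frame: `mirna_id`, `transcript_id`, `start`, `end`,
#'   `expectation`, `mode`, plus a `duplex` list-column of `duplex_score`
#'   objects.
#' @export
scan_transcript <- function(mirna, transcript,
                            mode = c("psrnatarget_like",
                                     "targetfinder_like"),
                            threshold = NULL,
                            mirna_id = "mirna",
                            transcript_id = "transcript") {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- mode_threshold(mode)
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (n < L) stop("transcript shorter than miRNA")
  qch <- seq_chars(mirna)
  tch <- seq_chars(transcript)
  starts <- seq_len(n - L + 1L)
  # ungapped per-position penalties: miRNA i faces transcript base s + L - i
  pen <- matrix(0, nrow = L, ncol = length(starts))
  cost_tab <- matrix(0, 4, 4,
                     dimnames = list(c("A", "C", "G", "U"),
                                     c("A", "C", "G", "U")))
  for (q in rownames(cost_tab)) for (t in colnames(cost_tab)) {
    cost_tab[q, t] <- state_cost(duplex_pair_state(q, t))
  }
  for (i in seq_len(L)) {
    faced <- tch[starts + L - i]
    pen[i, ] <- cost_tab[qch[i], faced] * position_weight(i)
  }
  ungapped <- if (mode == "psrnatarget_like" && L > 20L) {
    wins <- vapply(seq_len(L - 19L), function(a)
      colSums(pen[a:(a + 19L), , drop = FALSE]), numeric(length(starts)))
    if (is.matrix(wins)) apply(wins, 1, min) else min(wins)
  } else {
    colSums(pen)
  }
  cand <- starts[ungapped <= threshold + 4]
  if (length(cand) == 0L) return(.empty_hits())
  rows <- list()
  for (s in cand) {
    dx <- score_duplex(mirna, substr(transcript, s, s + L - 1L), mode)
    if (!passes_threshold(dx$expectation, mode, threshold)) next
    rows[[length(rows) + 1L]] <-
      list(start = s, end = s + L - 1L, expectation = dx$expectation,
           duplex = dx)
  }
  if (length(rows) == 0L) return(.empty_hits())
  ord <- order(vapply(rows, `[[`, numeric(1), "expectation"),
               vapply(rows, `[[`, numeric(1), "start"))
  kept <- list()
  for (r in rows[ord]) {
    clash <- any(vapply(kept, function(k)
      r$start <= k$end && r$end >= k$start, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- r
  }
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "start"))]
  out <- data.frame(
    mirna_id = mirna_id, transcript_id = transcript_id,
    start = vapply(kept, `[[`, numeric(1), "start"),
    end = vapply(kept, `[[`, numeric(1), "end"),
    expectation = vapply(kept, `[[`, numeric(1), "expectation"),
    mode = mode, stringsAsFactors = FALSE)
  out$duplex <- lapply(kept, `[[`, "duplex")
  out
}

.empty_hits <- function() {
  out <- data.frame(mirna_id = character(0), transcript_id = character(0),
                    start = numeric(0), end = numeric(0),
                    expectation = numeric(0), mode = character(0),
                    stringsAsFactors = FALSE)
  out$duplex <- list()
  out
}

#' Intersect target predictions of the two scoring modes
#'
#' Keeps (miRNA, transcript) pairs predicted in both modes with overlapping
#' site intervals; the consensus record carries both scores (site interval
#' and duplex from the psRNATarget-like mode, whose report drives the
#' inhibition call).
#'
#' @param hits_psr,hits_tf hit tables from [scan_transcript()] in
#'   `psrnatarget_like` and `targetfinder_like` mode.
#' @return consensus data.frame: `mirna_id`, `transcript_id`, `start`,
#'   `end`, `expectation_psr`, `score_tf`, `duplex` list-column.
#' @export
intersect_modes <- function(hits_psr, hits_tf) {
  rows <- list()
  for (i in seq_len(nrow(hits_psr))) {
    m <- which(hits_tf$mirna_id == hits_psr$mirna_id[i] &
               hits_tf$transcript_id == hits_psr$transcript_id[i] &
               hits_tf$start <= hits_psr$end[i] &
               hits_tf$end >= hits_psr$start[i])
    if (length(m) == 0L) next
    m <- m[which.min(hits_tf$expectation[m])]
    rows[[length(rows) + 1L]] <- list(
      mirna_id = hits_psr$mirna_id[i],
      transcript_id = hits_psr$transcript_id[i],
      start = hits_psr$start[i], end = hits_psr$end[i],
      expectation_psr = hits_psr$expectation[i],
      score_tf = hits_tf$expectation[m],
      duplex = hits_psr$duplex[[i]])
  }
  if (length(rows) == 0L) {
    out <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = numeric(0), end = numeric(0),
                      expectation_psr = numeric(0), score_tf = numeric(0),
                      stringsAsFactors = FALSE)
    out$duplex <- list()
    return(out)
  }
  out <- data.frame(
    mirna_id = vapply(rows, `[[`, character(1), "mirna_id"),
    transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    expectation_psr = vapply(rows, `[[`, numeric(1), "expectation_psr"),
    score_tf = vapply(rows, `[[`, numeric(1), "score_tf"),
    stringsAsFactors = FALSE)
  out$duplex <- lapply(rows, `[[`, "duplex")
  out
}

#' Classify the inhibition type of a target duplex
#'
#' Translation inhibition iff miRNA position 10 or 11 is a mismatch or gap
#' (central mismatch range); by default a G:U wobble counts as pairing
#' (cleavage), switchable with `gu_central_mismatch`.
#'
#' @param duplex a `duplex_score`.
#' @param gu_central_mismatch count central G:U wobbles as mismatches.
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(duplex, gu_central_mismatch = FALSE) {
  stopifnot(inherits(duplex, "duplex_score"))
  bad <- c("mismatch", "gap", if (gu_central_mismatch) "gu")
  central <- duplex$per_position[c(10L, 11L)]
  if (any(central %in% bad)) "translation" else "cleavage"
}

#' Predict the cleavage coordinate of a cleavage-type target hit
#'
#' The slicing position lies opposite the bond between miRNA nucleotides 10
#' and 11 (counted from the miRNA 5' end); the returned transcript
#' coordinate `c` is the base paired with miRNA position 11, with the cut
#' annotated between `c` and `c + 1`.
#'
#' @param duplex a `duplex_score` of the hit.
#' @param site_start transcript coordinate of the site's first base.
#' @param gu_central_mismatch see [classify_inhibition()].
#' @return the transcript coordinate 5' of the cut.
#' @export
predict_cleavage_site <- function(duplex, site_start = 1L,
                                  gu_central_mismatch = FALSE) {
  if (classify_inhibition(duplex, gu_central_mismatch) == "translation") {
    stop("cleavage site undefined for a translation-type hit")
  }
  j <- duplex$site_map[11L]
  if (is.na(j)) stop("miRNA position 11 is unpaired in this duplex")
  j + site_start - 1L
}

#' Annotate consensus targets with inhibition type and cleavage site
#'
#' @param consensus data.frame from [intersect_modes()].
#' @param gu_central_mismatch see [classify_inhibition()].
#' @return `consensus` with `inhibition` and `cleavage_pos` (NA for
#'   translation-type hits) columns added.
#' @export
annotate_targets <- function(consensus, gu_central_mismatch = FALSE) {
  if (nrow(consensus) == 0L) {
    consensus$inhibition <- character(0)
    consensus$cleavage_pos <- numeric(0)
    return(consensus)
  }
  consensus$inhibition <- vapply(consensus$duplex, classify_inhibition,
                                 character(1), gu_central_mismatch)
  consensus$cleavage_pos <- NA_real_
  for (i in seq_len(nrow(consensus))) {
    if (consensus$inhibition[i] == "cleavage") {
      consensus$cleavage_pos[i] <- predict_cleavage_site(
        consensus$duplex[[i]], consensus$start[i], gu_central_mismatch)
    }
  }
  consensus
}
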