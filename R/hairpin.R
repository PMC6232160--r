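default_fold_engine <- function() {
  getOption("mirhunt.fold_engine",
            if (nzchar(Sys.which("RNAfold"))) "vienna" else "maxpair")
}

#' Fold RNA sequences into minimum-energy secondary structures
#'
#' Two engines share one contract: `"vienna"` calls the ViennaRNA `RNAfold`
#' binary (thermodynamic MFE, the default when available); `"maxpair"` is a
#' built-in Nussinov base-pair maximization (pairs AU/GC/GU, minimum loop 3)
#' whose pseudo-energy is -1 kcal/mol per pair, intended for tests and
#' environments without ViennaRNA. Folding is deterministic per engine.
#'
#' @param sequences character vector of RNA sequences (A/C/G/U only, length
#'   >= 10).
#' @param engine `"vienna"` or `"maxpair"`; default taken from
#'   `options(mirhunt.fold_engine=)`, falling back to `"vienna"` when
#'   `RNAfold` is on the PATH.
#' @return for one input a `secondary_structure` (list with `sequence`,
#'   `dotbracket`, `mfe`, `engine`); for several, a list of them.
#' @export
fold <- function(sequences, engine = NULL) {
  if (is.null(engine)) engine <- default_fold_engine()
  engine <- match.arg(engine, c("vienna", "maxpair"))
  if (any(nchar(sequences) < 10L)) stop("sequences must be >= 10 nt")
  if (any(has_ambiguity(sequences))) {
    stop("cannot fold sequences containing ambiguity codes")
  }
  res <- if (engine == "vienna") .fold_vienna(sequences)
         else .fold_maxpair(sequences)
  if (length(sequences) == 1L) res[[1L]] else res
}

.fold_maxpair <- function(sequences) {
  lapply(sequences, function(s) {
    r <- cpp_nussinov(s, 3L)
    structure(list(sequence = s, dotbracket = r$dotbracket,
                   mfe = -as.numeric(r$pairs), engine = "maxpair"),
              class = "secondary_structure")
  })
}

.fold_vienna <- function(sequences) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("fold engine 'vienna' unavailable: RNAfold not on PATH")
  input <- paste0(">s", seq_along(sequences), "\n", sequences,
                  collapse = "\n")
  out <- suppressWarnings(system2(exe, c("--noPS"), input = input,
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("fold engine 'vienna' failed with status ", status)
  }
  out <- out[nzchar(out)]
  heads <- grep("^>", out)
  if (length(heads) != length(sequences)) {
    stop("fold engine 'vienna' returned unexpected output")
  }
  lapply(seq_along(heads), function(i) {
    sline <- out[heads[i] + 2L]
    m <- regmatches(sline, regexpr("\\(\\s*-?[0-9.]+\\)\\s*$", sline))
    if (length(m) == 0L) stop("fold engine 'vienna': cannot parse energy")
    mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    db <- trimws(sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", sline))
    if (nchar(db) != nchar(sequences[i])) {
      stop("fold engine 'vienna': structure/sequence length mismatch")
    }
    structure(list(sequence = sequences[i], dotbracket = db, mfe = mfe,
                   engine = "vienna"), class = "secondary_structure")
  })
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", format(x$mfe), ")  [",
      x$engine, "]\n", sep = "")
  invisible(x)
}

#' Base-pair partner table of a dot-bracket string
#'
#' @param dotbracket dot-bracket string.
#' @return integer vector: `pt[i]` is the 1-based partner of position `i`,
#'   or 0 when unpaired.
#' @export
pair_table <- function(dotbracket) {
  ch <- seq_chars(dotbracket)
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid dot-bracket character: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pt
}

#' Hairpin metrics: MFE, AMFE and MFEI
#'
#' AMFE is the folding energy per 100 nt (`mfe / length * 100`); MFEI is
#' AMFE divided by the GC content expressed as a percentage (50, not 0.5).
#' A+U and G+C percentages are computed over unambiguous bases.
#'
#' @param structure a `secondary_structure` from [fold()].
#' @return one-row data.frame: `length`, `gc_percent`, `au_percent`, `mfe`,
#'   `amfe`, `mfei`.
#' @export
compute_metrics <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  n <- nchar(structure$sequence)
  bc <- base_content(structure$sequence)
  if (is.na(bc["gc"]) || bc["gc"] == 0) {
    stop("MFEI undefined: GC content is zero")
  }
  amfe <- structure$mfe / n * 100
  data.frame(length = n, gc_percent = unname(bc["gc"]),
             au_percent = unname(bc["au"]), mfe = structure$mfe,
             amfe = amfe, mfei = amfe / unname(bc["gc"]))
}

# Hairpin (terminal) loops: maximal unpaired runs closed by a pair.
# Returns a data.frame with loop_start, loop_end and the number of pairs
# enclosing each loop.
find_hairpin_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i && j - i >= 2L && all(pt[(i + 1L):(j - 1L)] == 0L)) {
      enclosing <- sum(pt[seq_len(i)] > j) + 1L
      loops[[length(loops) + 1L]] <-
        data.frame(loop_start = i + 1L, loop_end = j - 1L,
                   enclosing_pairs = enclosing)
    }
  }
  if (length(loops) == 0L) {
    return(data.frame(loop_start = integer(0), loop_end = integer(0),
                      enclosing_pairs = integer(0)))
  }
  do.call(rbind, loops)
}

# Climb the helix chain enclosing [lo, hi] pair by pair, from the inside
# out. The climb stops before the span exceeds max_span or when the next
# enclosing pair sits further than max_bulge unpaired bases away on either
# side (sparse long-range pairings of flanking sequence are not part of
# the hairpin stem; real stems carry only small bulges/internal loops).
enclosing_span <- function(pt, lo, hi, max_span = .Machine$integer.max,
                           max_bulge = 15L) {
  repeat {
    enc <- which(seq_along(pt) < lo & pt > hi)
    if (length(enc) == 0L) break
    a <- max(enc)
    b <- pt[a]
    if (b - a + 1L > max_span) break
    if (lo - a - 1L > max_bulge || b - hi - 1L > max_bulge) break
    lo <- a; hi <- b
  }
  c(lo, hi)
}

#' Locate a reference mature miRNA on a folded precursor
#'
#' Scans every window of the mature's length for the fewest mismatches to
#' the reference mature, then places the best window relative to the
#' terminal loop of the dominant hairpin (the loop with the most enclosing
#' pairs). Ties on reference mismatches are broken by fewer miRNA/miRNA*
#' duplex mismatches, then by the 5'-most window. `duplex_mismatches`
#' counts mature positions not paired to the opposite arm (G:U wobbles
#' count as paired). A candidate whose best window exceeds
#' `max_ref_mismatches` is flagged unmappable; a mature window whose own
#' stem region branches into several hairpin loops is reported as
#' `loop_spanning` (non-hairpin).
#'
#' @param precursor precursor sequence.
#' @param structure its `secondary_structure`.
#' @param mature reference mature sequence (19-25 nt).
#' @param max_ref_mismatches mappability cap (default 5).
#' @return `mature_site` list: `start`, `end`, `arm` (`"5p"`, `"3p"` or
#'   `"loop_spanning"`), `mismatches_to_reference`, `duplex_mismatches`,
#'   `unmappable`.
#' @export
locate_mature <- function(precursor, structure, mature,
                          max_ref_mismatches = 5) {
  L <- nchar(mature)
  if (L < 19 || L > 25) stop("reference mature must be 19-25 nt")
  n <- nchar(precursor)
  if (n < L) stop("precursor shorter than mature")
  pt <- pair_table(structure$dotbracket)
  pch <- seq_chars(precursor)
  mch <- seq_chars(mature)
  starts <- seq_len(n - L + 1L)
  mm <- vapply(starts, function(s)
    sum(pch[s:(s + L - 1L)] != mch), integer(1))
  best_mm <- min(mm)
  cand <- starts[mm == best_mm]
  loops <- find_hairpin_loops(pt)
  place <- lapply(cand, function(s)
    .place_window(pt, loops, s, s + L - 1L))
  dup <- vapply(place, `[[`, numeric(1), "duplex_mismatches")
  pick <- which(dup == min(dup))[1L]
  site <- place[[pick]]
  structure(list(start = cand[pick], end = cand[pick] + L - 1L,
                 arm = site$arm,
                 mismatches_to_reference = best_mm,
                 duplex_mismatches = as.integer(site$duplex_mismatches),
                 unmappable = best_mm > max_ref_mismatches),
            class = "mature_site")
}

.place_window <- function(pt, loops, ms, me) {
  pos <- ms:me
  partners <- pt[pos]
  paired <- partners > 0L
  if (nrow(loops) == 0L || !any(paired)) {
    return(list(arm = "loop_spanning", duplex_mismatches = length(pos)))
  }
  # the mature folds back on its star across exactly one terminal loop;
  # a second hairpin loop inside the duplex span means a branched stem
  span <- range(c(pos, partners[paired]))
  within <- loops$loop_start >= span[1] & loops$loop_end <= span[2]
  if (sum(within) != 1L) {
    return(list(arm = "loop_spanning", duplex_mismatches = sum(!paired)))
  }
  ls <- loops$loop_start[within]; le <- loops$loop_end[within]
  arm <- if (me < ls) "5p" else if (ms > le) "3p" else "loop_spanning"
  ok <- if (arm == "5p") {
    pt[pos] > le
  } else if (arm == "3p") {
    pt[pos] > 0L & pt[pos] < ls
  } else {
    pt[pos] > 0L
  }
  list(arm = arm, duplex_mismatches = sum(!ok))
}

#' Default thresholds of the six-criterion hairpin filter
#'
#' @return list: `mature_len` (19, 25), `ref_mismatch_max` 2,
#'   `duplex_mismatch_max` 5, `au_range` (30, 70), `mfei_cutoff` -0.85.
#' @export
criteria_thresholds <- function() {
  list(mature_len = c(19, 25), ref_mismatch_max = 2,
       duplex_mismatch_max = 5, au_range = c(30, 70), mfei_cutoff = -0.85)
}

#' Apply the six hairpin acceptance criteria
#'
#' (1) mature length 19-25 nt; (2) at most 2 mismatches to the reference
#' mature; (3) mature on a single arm of the stem-loop; (4) at most 5
#' miRNA/miRNA* duplex mismatches; (5) precursor A+U content 30-70%;
#' (6) MFEI at or below -0.85 (inclusive).
#'
#' @param metrics one-row data.frame from [compute_metrics()].
#' @param site `mature_site` from [locate_mature()].
#' @param mature_length length of the predicted mature (nt).
#' @param thresholds see [criteria_thresholds()].
#' @return one-row data.frame with the measured values, `c1_length_ok` ..
#'   `c6_mfei_ok` and `accepted` (the conjunction of all six).
#' @export
evaluate_criteria <- function(metrics, site, mature_length,
                              thresholds = criteria_thresholds()) {
  th <- thresholds
  c1 <- mature_length >= th$mature_len[1] & mature_length <= th$mature_len[2]
  c2 <- !site$unmappable &
    site$mismatches_to_reference <= th$ref_mismatch_max
  c3 <- !site$unmappable & site$arm %in% c("5p", "3p")
  c4 <- site$duplex_mismatches <= th$duplex_mismatch_max
  c5 <- metrics$au_percent >= th$au_range[1] &
    metrics$au_percent <= th$au_range[2]
  c6 <- metrics$mfei <= th$mfei_cutoff
  data.frame(mature_length = mature_length,
             mismatches_to_reference = site$mismatches_to_reference,
             arm = site$arm,
             duplex_mismatches = site$duplex_mismatches,
             au_percent = metrics$au_percent,
             mfei = metrics$mfei,
             c1_length_ok = c1, c2_ref_ok = c2, c3_arm_ok = c3,
             c4_duplex_ok = c4, c5_au_ok = c5, c6_mfei_ok = c6,
             accepted = c1 & c2 & c3 & c4 & c5 & c6,
             stringsAsFactors = FALSE)
}

#' Extract the hairpin around a mature match from a larger region
#'
#' Folds the region once, finds the best mature window, follows its pairing
#' partners to the enclosing helix and returns the padded subsequence
#' spanning that hairpin (to be refolded and filtered as a precursor
#' candidate).
#'
#' @param region candidate region sequence.
#' @param mature reference mature sequence.
#' @param engine folding engine, see [fold()].
#' @param pad padding in nt added on both sides of the hairpin span (kept
#'   small so unpaired flanks do not dilute AMFE/MFEI).
#' @param max_span cap on the extracted hairpin length (nt); the helix
#'   climb stops before exceeding it.
#' @return list: `start`, `end` (1-based on the region), `sequence`.
#' @export
extract_hairpin <- function(region, mature, engine = NULL, pad = 0,
                            max_span = 240L) {
  st <- fold(region, engine = engine)
  pt <- pair_table(st$dotbracket)
  L <- nchar(mature)
  n <- nchar(region)
  rch <- seq_chars(region)
  mch <- seq_chars(mature)
  starts <- seq_len(max(1L, n - L + 1L))
  mm <- vapply(starts, function(s)
    sum(rch[s:min(n, s + L - 1L)] != mch[seq_len(min(L, n - s + 1L))]) +
      max(0L, L - (n - s + 1L)), integer(1))
  ms <- starts[which.min(mm)]
  me <- min(n, ms + L - 1L)
  partners <- pt[ms:me]
  partners <- partners[partners > 0L]
  span <- if (length(partners)) {
    range(c(ms, me, partners))
  } else {
    c(ms, me)
  }
  span <- enclosing_span(pt, span[1], span[2], max_span = max_span)
  lo <- max(1L, span[1] - pad)
  hi <- min(n, span[2] + pad)
  list(start = lo, end = hi, sequence = substr(region, lo, hi))
}
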