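#' Cluster accepted precursor candidates into tentative loci
#'
#' Two candidates are alleles of the same locus when the global alignment
#' of their precursors has fewer than `mismatch_lt` mismatches
#' (substitutions plus end overhangs); clusters are the connected
#' components of that relation (single linkage), so the partition is
#' invariant to input order.
#'
#' @param ids candidate identifiers.
#' @param precursors precursor sequences, parallel to `ids`.
#' @param mismatch_lt candidates with `whole_length_mismatches < this`
#'   share a locus (default 2, i.e. at most one mismatch).
#' @return data.frame `candidate_id`, `locus_id` (`locus_1`, `locus_2`, ...
#'   numbered by first appearance).
#' @export
cluster_loci <- function(ids, precursors, mismatch_lt = 2) {
  n <- length(ids)
  stopifnot(length(precursors) == n)
  if (n == 0L) {
    return(data.frame(candidate_id = character(0),
                      locus_id = character(0), stringsAsFactors = FALSE))
  }
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        adj[i, j] <- adj[j, i] <-
          whole_length_mismatches(precursors[i], precursors[j]) < mismatch_lt
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by first appearance so numbering is deterministic
  first <- match(unique(comp), comp)
  relabel <- match(comp, comp[sort(first)])
  data.frame(candidate_id = ids,
             locus_id = paste0("locus_", relabel),
             stringsAsFactors = FALSE)
}

#' Name locus members after their closest reference locus
#'
#' Names follow `<prefix>-<family+letter>-<locusIndex><alleleLetter>_<tissueInitial>`
#' (e.g. `Ado-MIR444d-2c_b`): the reference locus stem comes from the best
#' reference hit, locus indices number the loci sharing that stem, allele
#' letters enumerate members within a locus, and the suffix is the first
#' letter of the member's tissue. Ordering (and therefore naming) is
#' deterministic given locus ids and member order.
#'
#' @param members data.frame with `candidate_id`, `locus_id`,
#'   `reference_hit` (reference locus name, e.g. `osa-MIR444d`; NA
#'   allowed), `tissue`.
#' @param prefix species prefix of the new names.
#' @return `members` with a `name` column added.
#' @export
assign_names <- function(members, prefix = "Ado") {
  stem <- ifelse(is.na(members$reference_hit),
                 NA_character_,
                 sub("^[A-Za-z]{3,4}-", "", members$reference_hit))
  no_hit <- is.na(stem)
  if (any(no_hit)) {
    warning("missing reference hit for ",
            sum(no_hit), " member(s); naming by family only")
    stem[no_hit] <- vapply(members$candidate_id[no_hit], function(id)
      "MIRna", character(1))
  }
  members$reference_stem <- stem
  # locus index within each reference stem, by order of locus appearance
  loci <- unique(members[, c("locus_id", "reference_stem")])
  loci$locus_index <- stats::ave(seq_len(nrow(loci)), loci$reference_stem,
                                 FUN = seq_along)
  members <- merge(members, loci, by = c("locus_id", "reference_stem"),
                   sort = FALSE)
  members <- members[order(members$locus_id,
                           members$candidate_id), , drop = FALSE]
  allele <- stats::ave(seq_len(nrow(members)), members$locus_id,
                       FUN = seq_along)
  members$name <- paste0(prefix, "-", members$reference_stem, "-",
                         members$locus_index, letters[allele], "_",
                         substr(members$tissue, 1, 1))
  rownames(members) <- NULL
  members
}

#' Tally mature miRNAs and loci by tissue
#'
#' @param members data.frame with `tissue`, optionally `family` and
#'   `locus_id`.
#' @return list: `counts` (per tissue), `percent`, and when `family` is
#'   present a `family_by_tissue` count matrix.
#' @export
tissue_tally <- function(members) {
  tissues <- c("bud", "culm", "leaf", "root")
  counts <- table(factor(members$tissue, levels = tissues))
  pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else counts * 0
  out <- list(counts = as.vector(counts), percent = as.vector(pct))
  names(out$counts) <- names(out$percent) <- tissues
  if (!is.null(members$family)) {
    out$family_by_tissue <- table(members$family,
                                  factor(members$tissue, levels = tissues))
  }
  out
}

#' Overall and position-specific nucleotide composition
#'
#' Frequencies are percentages; a position's denominator counts only the
#' sequences long enough to reach it.
#'
#' @param matures character vector of mature sequences.
#' @return `composition_profile`: `overall` (named % over A/C/G/U),
#'   `positional` (position x base % matrix), `n_sequences`, `max_length`.
#' @export
composition_profile <- function(matures) {
  if (length(matures) == 0L) stop("no sequences")
  bases <- c("A", "C", "G", "U")
  chars <- lapply(matures, seq_chars)
  all_ch <- unlist(chars)
  overall <- 100 * vapply(bases, function(b) mean(all_ch == b), numeric(1))
  maxlen <- max(nchar(matures))
  positional <- matrix(0, nrow = maxlen, ncol = 4,
                       dimnames = list(NULL, bases))
  for (p in seq_len(maxlen)) {
    at <- vapply(chars[nchar(matures) >= p], `[[`, character(1), p)
    positional[p, ] <- 100 * vapply(bases, function(b) mean(at == b),
                                    numeric(1))
  }
  structure(list(overall = overall, positional = positional,
                 n_sequences = length(matures), max_length = maxlen),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$n_sequences, " sequences, up to ",
      x$max_length, " nt\noverall %: ", sep = "")
  print(round(x$overall, 2))
  invisible(x)
}

#' Compare two composition profiles
#'
#' @param a,b `composition_profile` objects.
#' @return list: `overall_diff` (a - b, percentage points),
#'   `positional_diff` over the shared positions, and the dominant base
#'   per position of each profile.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "composition_profile"),
            inherits(b, "composition_profile"))
  shared <- min(a$max_length, b$max_length)
  pd <- a$positional[seq_len(shared), , drop = FALSE] -
    b$positional[seq_len(shared), , drop = FALSE]
  dom <- function(p) colnames(p)[max.col(p, ties.method = "first")]
  list(overall_diff = a$overall - b$overall,
       positional_diff = pd,
       dominant_a = dom(a$positional),
       dominant_b = dom(b$positional))
}

#' Build the per-family locus summary table
#'
#' One row per family: the number of loci, and a breakdown string listing
#' each reference locus letter with the bracketed count of loci assigned
#' to it (e.g. `"a(1), c(3)"`), mirroring the published layout.
#'
#' @param members named data.frame from [assign_names()] (needs `family`,
#'   `locus_id`, `reference_stem`).
#' @return data.frame `family`, `n_loci`, `breakdown`.
#' @export
build_locus_table <- function(members) {
  loci <- unique(members[, c("family", "reference_stem", "locus_id")])
  fams <- sort(unique(loci$family))
  rows <- lapply(fams, function(f) {
    sub <- loci[loci$family == f, , drop = FALSE]
    letter <- sub("^MIR[0-9]+", "", sub$reference_stem)
    letter[!nzchar(letter)] <- "*"
    tab <- table(letter)
    data.frame(family = f, n_loci = nrow(sub),
               breakdown = paste0(names(tab), "(", as.integer(tab), ")",
                                  collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total locus counts of a per-family locus table
#'
#' Sums the bracketed per-reference-locus counts of the breakdown strings
#' and cross-checks them against the numeric per-family column when
#' present.
#'
#' @param tab data.frame with `breakdown` and optionally `n_loci` and
#'   reference-locus count columns.
#' @return list: `total` (sum of bracketed counts), `per_family`, and
#'   `consistent` (breakdown sums match `n_loci` when available).
#' @export
locus_table_totals <- function(tab) {
  per_family <- vapply(tab$breakdown, function(s) {
    m <- regmatches(s, gregexpr("\\(([0-9]+)\\)", s))[[1]]
    sum(as.integer(gsub("[()]", "", m)))
  }, numeric(1))
  names(per_family) <- tab$family
  consistent <- if (!is.null(tab$n_loci)) {
    all(per_family == tab$n_loci)
  } else NA
  list(total = sum(per_family), per_family = per_family,
       consistent = consistent)
}
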