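#' Classify one predicted target as conserved or novel
#'
#' The target is locally aligned against every sequence of every species
#' homolog set; it is conserved iff its best alignment in at least one
#' species has a raw score strictly greater than `score_gt` and covers
#' strictly more than `coverage_gt` percent of the target (query). Both
#' inequalities are strict.
#'
#' @param target_id identifier for the output row.
#' @param target_seq target (query) sequence.
#' @param homolog_sets named list (per species) of named sequence vectors.
#' @param score_gt,coverage_gt strict thresholds (defaults 50 and 50).
#' @param scoring aligner scoring, see [blastn_scoring()].
#' @return one-row data.frame: `target_id`, `status`
#'   (`conserved`/`novel`), `best_species`, `best_score`, `best_coverage`,
#'   plus one logical `conserved_<species>` column per species.
#' @export
classify_conserved <- function(target_id, target_seq, homolog_sets,
                               score_gt = 50, coverage_gt = 50,
                               scoring = blastn_scoring()) {
  if (!nzchar(target_seq)) stop("empty target sequence")
  if (length(homolog_sets) == 0L) stop("no homolog sets supplied")
  qlen <- nchar(target_seq)
  per_species <- lapply(names(homolog_sets), function(sp) {
    best <- list(score = 0, coverage = 0)
    for (s in homolog_sets[[sp]]) {
      hit <- local_align(target_seq, s, scoring)
      if (hit$score > best$score) {
        cov <- 100 * (hit$query_interval[2] - hit$query_interval[1] + 1) /
          qlen
        best <- list(score = hit$score, coverage = cov)
      }
    }
    best$pass <- best$score > score_gt && best$coverage > coverage_gt
    best
  })
  names(per_species) <- names(homolog_sets)
  scores <- vapply(per_species, `[[`, numeric(1), "score")
  pass <- vapply(per_species, `[[`, logical(1), "pass")
  best_i <- if (any(pass)) {
    which(pass)[which.max(scores[pass])]
  } else {
    which.max(scores)
  }
  out <- data.frame(target_id = target_id,
                    status = if (any(pass)) "conserved" else "novel",
                    best_species = names(per_species)[best_i],
                    best_score = per_species[[best_i]]$score,
                    best_coverage = per_species[[best_i]]$coverage,
                    stringsAsFactors = FALSE)
  for (sp in names(per_species)) {
    out[[paste0("conserved_", sp)]] <- per_species[[sp]]$pass
  }
  out
}

#' Classify a set of targets against species homolog sets
#'
#' @param targets named character vector of target sequences.
#' @param families named character vector mapping target id to miRNA
#'   family.
#' @inheritParams classify_conserved
#' @return data.frame, one row per target (see [classify_conserved()]),
#'   with a `family` column.
#' @export
classify_conserved_set <- function(targets, families, homolog_sets,
                                   score_gt = 50, coverage_gt = 50,
                                   scoring = blastn_scoring()) {
  rows <- lapply(names(targets), function(id)
    classify_conserved(id, targets[[id]], homolog_sets, score_gt,
                       coverage_gt, scoring))
  out <- do.call(rbind, rows)
  out$family <- unname(families[out$target_id])
  out
}

#' Per-family conserved/novel summary
#'
#' @param calls data.frame from [classify_conserved_set()].
#' @return data.frame with one row per family plus a `Total` row: number
#'   conserved (any species), per-species conserved counts, novel count;
#'   attribute `percent_conserved` gives
#'   `100 * conserved / (conserved + novel)`.
#' @export
summarize_by_family <- function(calls) {
  sp_cols <- grep("^conserved_", names(calls), value = TRUE)
  fams <- sort(unique(calls$family))
  rows <- lapply(fams, function(f) {
    sub <- calls[calls$family == f, , drop = FALSE]
    row <- data.frame(family = f,
                      conserved = sum(sub$status == "conserved"),
                      stringsAsFactors = FALSE)
    for (sc in sp_cols) row[[sc]] <- sum(sub[[sc]])
    row$novel <- sum(sub$status == "novel")
    row
  })
  out <- do.call(rbind, rows)
  total <- data.frame(family = "Total",
                      conserved = sum(out$conserved),
                      stringsAsFactors = FALSE)
  for (sc in sp_cols) total[[sc]] <- sum(out[[sc]])
  total$novel <- sum(out$novel)
  out <- rbind(out, total)
  attr(out, "percent_conserved") <-
    100 * total$conserved / (total$conserved + total$novel)
  out
}

#' Column totals and conserved percentage of a conserved-target table
#'
#' Works on any Table-2-shaped per-family count table (columns: `family`,
#' `conserved`, per-species counts, `novel`; missing entries NA). Returns
#' each numeric column's total and the overall conserved percentage
#' `100 * conserved_total / (conserved_total + novel_total)`.
#'
#' @param tab data.frame of per-family counts.
#' @return list: `totals` (named numeric), `percent_conserved`.
#' @export
conservation_table_totals <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  totals <- vapply(tab[num], function(x) sum(x, na.rm = TRUE), numeric(1))
  pct <- 100 * totals[["conserved"]] /
    (totals[["conserved"]] + totals[["novel"]])
  list(totals = totals, percent_conserved = pct)
}
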