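#' Full pipeline configuration
#'
#' Aggregates every stage threshold with its published default: E-value
#' cutoff 10, MFEI cutoff -0.85, mature length 19-25 nt, at most 2
#' reference mismatches, at most 5 duplex mismatches, A+U 30-70%, locus
#' rule "fewer than 2 mismatches", expectation <= 3.0 and score < 4.0 for
#' the two target modes, conservation score > 50 and coverage > 50%, 1000
#' bootstrap replicates. [config_self_test()] asserts the defaults.
#'
#' @param simulation a [simulation_config()] describing the synthetic
#'   inputs (the pipeline can equally be fed files, see the analysis
#'   scripts).
#' @param seed master seed (defaults to the simulation seed).
#' @param evalue_cutoff,mfei_cutoff,mature_len,ref_mismatch_max,duplex_mismatch_max,au_range,locus_mismatch_lt,psr_expectation,tf_score_lt,conserve_score_gt,conserve_cov_gt,bootstrap_reps stage thresholds.
#' @param word_size homology seed word size (7: short-query regime).
#' @param region_pad nt added around a homology hit before hairpin
#'   extraction.
#' @param engine folding engine (see [fold()]).
#' @param name_prefix species prefix for locus names.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            seed = simulation$seed,
                            evalue_cutoff = 10,
                            mfei_cutoff = -0.85,
                            mature_len = c(19, 25),
                            ref_mismatch_max = 2,
                            duplex_mismatch_max = 5,
                            au_range = c(30, 70),
                            locus_mismatch_lt = 2,
                            psr_expectation = 3.0,
                            tf_score_lt = 4.0,
                            conserve_score_gt = 50,
                            conserve_cov_gt = 50,
                            bootstrap_reps = 1000,
                            word_size = 7,
                            region_pad = 150,
                            engine = NULL,
                            name_prefix = "Ado") {
  structure(list(simulation = simulation, seed = seed,
                 evalue_cutoff = evalue_cutoff, mfei_cutoff = mfei_cutoff,
                 mature_len = mature_len,
                 ref_mismatch_max = ref_mismatch_max,
                 duplex_mismatch_max = duplex_mismatch_max,
                 au_range = au_range,
                 locus_mismatch_lt = locus_mismatch_lt,
                 psr_expectation = psr_expectation,
                 tf_score_lt = tf_score_lt,
                 conserve_score_gt = conserve_score_gt,
                 conserve_cov_gt = conserve_cov_gt,
                 bootstrap_reps = bootstrap_reps,
                 word_size = word_size, region_pad = region_pad,
                 engine = engine, name_prefix = name_prefix),
            class = "pipeline_config")
}

#' Assert that configuration defaults equal the published thresholds
#'
#' @param config a [pipeline_config()].
#' @return TRUE invisibly; stops when a default was tampered with.
#' @export
config_self_test <- function(config = pipeline_config()) {
  defaults <- list(evalue_cutoff = 10, mfei_cutoff = -0.85,
                   mature_len = c(19, 25), ref_mismatch_max = 2,
                   duplex_mismatch_max = 5, au_range = c(30, 70),
                   locus_mismatch_lt = 2, psr_expectation = 3.0,
                   tf_score_lt = 4.0, conserve_score_gt = 50,
                   conserve_cov_gt = 50, bootstrap_reps = 1000)
  ref <- pipeline_config(simulation = config$simulation)
  for (nm in names(defaults)) {
    if (!isTRUE(all.equal(ref[[nm]], defaults[[nm]]))) {
      stop("configuration self-test failed for ", nm)
    }
  }
  invisible(TRUE)
}

.hairpin_thresholds <- function(config) {
  list(mature_len = config$mature_len,
       ref_mismatch_max = config$ref_mismatch_max,
       duplex_mismatch_max = config$duplex_mismatch_max,
       au_range = config$au_range,
       mfei_cutoff = config$mfei_cutoff)
}

#' Homology + hairpin candidate stage
#'
#' For each retained best hit, extracts a padded region around the hit,
#' trims it to the hairpin enclosing the mature match, refolds and applies
#' the six criteria against the query's reference mature.
#'
#' @param bh best-hit table from [best_hits()].
#' @param transcripts data.frame `id`, `tissue`, `sequence`.
#' @param reference list of `reference_mirna` (the queries).
#' @param config a [pipeline_config()].
#' @return data.frame, one row per candidate, with region coordinates,
#'   precursor/mature sequences, measured criteria values and `accepted`.
#' @export
evaluate_candidates <- function(bh, transcripts, reference, config) {
  ref_by_name <- setNames(reference, vapply(reference, `[[`,
                                            character(1), "name"))
  tx <- setNames(transcripts$sequence, transcripts$id)
  tissue <- setNames(transcripts$tissue, transcripts$id)
  rows <- list()
  for (i in seq_len(nrow(bh))) {
    ref <- ref_by_name[[bh$qseqid[i]]]
    mature <- ref$matures[[1L]]
    subj <- tx[[bh$sseqid[i]]]
    lo <- max(1L, min(bh$sstart[i], bh$send[i]) - config$region_pad)
    hi <- min(nchar(subj), max(bh$sstart[i], bh$send[i]) +
                config$region_pad)
    region_fwd <- substr(subj, lo, hi)
    # a hairpin matches its own reverse complement, so the reported hit
    # strand can be arbitrary; evaluate both orientations and keep the
    # better-supported one (acceptance, then reference mismatches, MFEI)
    best <- NULL
    for (orient in c("+", "-")) {
      region <- if (orient == "+") region_fwd else rna_revcomp(region_fwd)
      hp <- extract_hairpin(region, mature, engine = config$engine)
      st <- fold(hp$sequence, engine = config$engine)
      site <- locate_mature(hp$sequence, st, mature)
      metrics <- compute_metrics(st)
      rep <- evaluate_criteria(metrics, site, nchar(mature),
                               .hairpin_thresholds(config))
      cand <- list(orient = orient, hp = hp, st = st, site = site,
                   metrics = metrics, rep = rep)
      better <- is.null(best) ||
        (cand$rep$accepted && !best$rep$accepted) ||
        (cand$rep$accepted == best$rep$accepted &&
           (cand$site$mismatches_to_reference <
              best$site$mismatches_to_reference ||
            (cand$site$mismatches_to_reference ==
               best$site$mismatches_to_reference &&
             cand$metrics$mfei < best$metrics$mfei)))
      if (better) best <- cand
    }
    hp <- best$hp; st <- best$st; site <- best$site
    metrics <- best$metrics; rep <- best$rep
    # map hairpin span back to transcript (plus-strand) coordinates
    if (best$orient == "-") {
      rl <- nchar(region_fwd)
      prec_tx <- c(lo + (rl - hp$end), lo + (rl - hp$start))
    } else {
      prec_tx <- c(lo + hp$start - 1L, lo + hp$end - 1L)
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(candidate_id = sprintf("cand_%03d", i),
                 transcript_id = bh$sseqid[i],
                 tissue = unname(tissue[bh$sseqid[i]]),
                 query = ref$name, family = ref$family,
                 strand = best$orient,
                 region_start = lo, region_end = hi,
                 precursor = hp$sequence,
                 precursor_start = prec_tx[1], precursor_end = prec_tx[2],
                 mature_seq = substr(hp$sequence, site$start, site$end),
                 mfe = metrics$mfe, amfe = metrics$amfe,
                 stringsAsFactors = FALSE),
      rep)
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full discovery and characterization pipeline on synthetic data
#'
#' Stages: simulate -> homology search -> best hits -> hairpin filter ->
#' locus clustering and naming -> tissue tally and composition -> target
#' prediction (two modes, intersection, inhibition, cleavage sites) ->
#' conservation calls -> family phylogeny with bootstrap -> report.
#' Deterministic: identical config implies identical report.
#'
#' @param config a [pipeline_config()].
#' @param bootstrap_reps override of `config$bootstrap_reps` (the analysis
#'   scripts scale this to the problem at hand).
#' @return a `mirna_run_report` list; see [summarize_run()].
#' @export
run_pipeline <- function(config = pipeline_config(),
                         bootstrap_reps = config$bootstrap_reps) {
  sim <- simulate_transcriptome(config$simulation, engine = config$engine)
  reference <- sim$reference
  queries <- setNames(
    vapply(reference, `[[`, character(1), "precursor"),
    vapply(reference, `[[`, character(1), "name"))
  transcripts <- setNames(sim$transcripts$sequence, sim$transcripts$id)

  hits <- search_homology(queries, transcripts,
                          word_size = config$word_size)
  bh <- best_hits(hits, config$evalue_cutoff)
  candidates <- evaluate_candidates(bh, sim$transcripts, reference, config)
  accepted <- if (nrow(candidates)) {
    candidates[candidates$accepted, , drop = FALSE]
  } else candidates

  drop_log <- if (nrow(candidates)) {
    rej <- candidates[!candidates$accepted, , drop = FALSE]
    crit <- c("c1_length_ok", "c2_ref_ok", "c3_arm_ok", "c4_duplex_ok",
              "c5_au_ok", "c6_mfei_ok")
    data.frame(candidate_id = rej$candidate_id,
               transcript_id = rej$transcript_id,
               reason = apply(!as.matrix(rej[, crit]), 1, function(x)
                 paste(sub("_.*", "", crit)[x], collapse = "+")),
               stringsAsFactors = FALSE)
  } else data.frame()

  # loci, names, tissues, composition
  loci <- members <- locus_table <- NULL
  tissues <- composition <- NULL
  if (nrow(accepted)) {
    loci <- cluster_loci(accepted$candidate_id, accepted$precursor,
                         config$locus_mismatch_lt)
    members <- merge(loci,
                     accepted[, c("candidate_id", "family", "tissue",
                                  "query")],
                     by = "candidate_id", sort = FALSE)
    names(members)[names(members) == "query"] <- "reference_hit"
    members <- assign_names(members, prefix = config$name_prefix)
    locus_table <- build_locus_table(members)
    tissues <- tissue_tally(members)
    composition <- composition_profile(accepted$mature_seq)
  }

  # targets: one representative (family) mature per identified family
  fam_seen <- unique(accepted$family)
  fam_matures <- character(0)
  for (r in reference) {
    if (r$family %in% fam_seen &&
        !(r$family %in% names(fam_matures))) {
      fam_matures[r$family] <- r$matures[[1L]]
    }
  }
  targets <- NULL
  if (length(fam_matures)) {
    simt <- simulate_targets(fam_matures, config$simulation)
    psr <- list(); tf <- list()
    for (mi in names(fam_matures)) {
      for (ti in seq_len(nrow(simt$mrnas))) {
        psr[[length(psr) + 1L]] <- scan_transcript(
          fam_matures[[mi]], simt$mrnas$sequence[ti],
          mode = "psrnatarget_like", threshold = config$psr_expectation,
          mirna_id = mi, transcript_id = simt$mrnas$id[ti])
        tf[[length(tf) + 1L]] <- scan_transcript(
          fam_matures[[mi]], simt$mrnas$sequence[ti],
          mode = "targetfinder_like", threshold = config$tf_score_lt,
          mirna_id = mi, transcript_id = simt$mrnas$id[ti])
      }
    }
    psr <- do.call(rbind, psr)
    tf <- do.call(rbind, tf)
    consensus <- annotate_targets(intersect_modes(psr, tf))
    targets <- list(simulated = simt, psr = psr, tf = tf,
                    consensus = consensus,
                    inhibition_counts = table(consensus$inhibition))
  }

  # conservation of consensus target transcripts
  conservation <- NULL
  if (!is.null(targets) && nrow(targets$consensus)) {
    hom <- simulate_homolog_sets(targets$simulated$mrnas,
                                 config$simulation)
    tids <- unique(targets$consensus$transcript_id)
    seqs <- setNames(
      targets$simulated$mrnas$sequence[
        match(tids, targets$simulated$mrnas$id)], tids)
    fams <- setNames(
      sub("^sim-", "",
          targets$consensus$mirna_id[
            match(tids, targets$consensus$transcript_id)]), tids)
    calls <- classify_conserved_set(seqs, fams, hom$sets,
                                    config$conserve_score_gt,
                                    config$conserve_cov_gt)
    conservation <- list(calls = calls,
                         by_family = summarize_by_family(calls),
                         truth = hom$truth)
  }

  # phylogeny of the largest identified family
  phylo <- NULL
  if (nrow(accepted)) {
    fam_n <- sort(table(accepted$family), decreasing = TRUE)
    fam <- names(fam_n)[1L]
    if (fam_n[1L] >= 3L) {
      sub <- accepted[accepted$family == fam, , drop = FALSE]
      seqs <- setNames(sub$precursor, sub$candidate_id)
      msa <- progressive_align(seqs)
      tree <- nj_bootstrap(msa, replicates = bootstrap_reps,
                           seed = config$seed)
      phylo <- list(family = fam, msa = msa, tree = tree,
                    newick = ape::write.tree(tree))
    }
  }

  funnel <- data.frame(
    stage = c("transcripts", "homology_hits", "best_hits", "candidates",
              "accepted", "loci"),
    count = c(nrow(sim$transcripts), nrow(hits), nrow(bh),
              nrow(candidates), nrow(accepted),
              if (is.null(loci)) 0L else length(unique(loci$locus_id))))

  structure(list(config = config, simulation = sim, hits = hits,
                 best_hits = bh, candidates = candidates,
                 accepted = accepted, drop_log = drop_log, loci = loci,
                 members = members, locus_table = locus_table,
                 tissues = tissues, composition = composition,
                 targets = targets, conservation = conservation,
                 phylo = phylo, funnel = funnel),
            class = "mirna_run_report")
}

#' Recall of implanted precursors and hard-negative acceptances
#'
#' Compares accepted candidates against the simulation truth manifest: an
#' implant counts as recovered when an accepted candidate's precursor
#' interval overlaps its implanted precursor interval on the same
#' transcript.
#'
#' @param report a `mirna_run_report`.
#' @return list: `recall`, `n_implants`, `n_recovered`,
#'   `hard_negative_acceptances`, `decoy_acceptances`.
#' @export
score_against_truth <- function(report) {
  man <- report$simulation$manifest
  acc <- report$accepted
  recovered <- 0L
  if (nrow(man$implanted)) {
    for (i in seq_len(nrow(man$implanted))) {
      im <- man$implanted[i, ]
      hit <- nrow(acc) > 0 && any(
        acc$transcript_id == im$transcript_id &
          acc$precursor_start <= im$precursor_end &
          acc$precursor_end >= im$precursor_start)
      recovered <- recovered + as.integer(hit)
    }
  }
  hard_ids <- if (nrow(man$hard_negatives)) {
    man$hard_negatives$transcript_id
  } else character(0)
  list(recall = if (nrow(man$implanted)) recovered / nrow(man$implanted)
       else NA_real_,
       n_implants = nrow(man$implanted),
       n_recovered = recovered,
       hard_negative_acceptances =
         if (nrow(acc)) sum(acc$transcript_id %in% hard_ids) else 0L,
       decoy_acceptances =
         if (nrow(acc)) sum(acc$transcript_id %in% man$decoy_ids) else 0L)
}

#' Print a human-readable pipeline summary
#'
#' @param report a `mirna_run_report`.
#' @return `report`, invisibly.
#' @export
summarize_run <- function(report) {
  cat("== miRNA discovery run ==\n")
  f <- report$funnel
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-14s %6d\n", f$stage[i], f$count[i]))
  }
  if (!is.null(report$members)) {
    fams <- sort(table(report$members$family), decreasing = TRUE)
    cat("top families:",
        paste(names(fams)[seq_len(min(3, length(fams)))],
              as.integer(fams)[seq_len(min(3, length(fams)))],
              collapse = ", "), "\n")
  }
  if (!is.null(report$targets)) {
    ic <- report$targets$inhibition_counts
    cat("consensus targets:", nrow(report$targets$consensus),
        "( cleavage:", if ("cleavage" %in% names(ic)) ic[["cleavage"]] else 0,
        ", translation:",
        if ("translation" %in% names(ic)) ic[["translation"]] else 0, ")\n")
  }
  if (!is.null(report$conservation)) {
    bf <- report$conservation$by_family
    cat(sprintf("conserved targets: %.2f%%\n",
                attr(bf, "percent_conserved")))
  }
  if (!is.null(report$phylo)) {
    cat("phylogeny of", report$phylo$family, "with",
        length(report$phylo$tree$tip.label), "members\n")
  }
  invisible(report)
}
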