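#' Configuration of the synthetic transcriptome / target generator
#'
#' Defaults encode the study conditions the generator emulates: mature
#' lengths 20/21/22 nt with weights 0.078/0.858/0.064, 5'-terminal uracil in
#' 85.1% of matures, balanced GC, tissue occupancy weighted
#' root > culm > bud > leaf (0.319/0.262/0.228/0.191), precursors built as
#' mature/star duplexes (at most 5 designed duplex mismatches) on an
#' extended stem so that accepted precursors fall in the 60-200 nt band.
#'
#' @param seed integer RNG seed; every simulation is reproducible from it.
#' @param n_decoys number of random background transcripts.
#' @param n_hard_negatives number of decoys carrying a reference mature in a
#'   context designed to fail at least one hairpin criterion.
#' @param n_implants number of transcripts with an implanted true precursor.
#' @param decoy_length_range transcript length range (nt).
#' @param gc_target background GC fraction.
#' @param mature_length_dist named weights over mature lengths.
#' @param loop_length_range terminal loop length range (nt).
#' @param lower_stem_range extension stem length range below the duplex.
#' @param duplex_mismatch_range designed miRNA/miRNA* mismatch range.
#' @param ref_mismatch_range designed mismatches of implanted matures to
#'   their reference mature (0-2 keeps criterion 2 satisfiable).
#' @param tissue_weights sampling weights over bud/culm/leaf/root.
#' @param p_five_prime_u probability that a generated mature starts with U.
#' @param n_families,family_size_range synthetic reference set shape.
#' @param n_target_mrnas,target_mrna_length,target_penalty_levels target
#'   simulation shape: each mRNA carries one site of a designed penalty.
#' @param max_retries rejection-sampling cap per generated object.
#' @return a `simulation_config` list (validated).
#' @export
simulation_config <- function(seed = 1L,
                              n_decoys = 40L,
                              n_hard_negatives = 15L,
                              n_implants = 50L,
                              decoy_length_range = c(200L, 1000L),
                              gc_target = 0.5,
                              mature_length_dist = c("20" = 0.078,
                                                     "21" = 0.858,
                                                     "22" = 0.064),
                              loop_length_range = c(4L, 20L),
                              lower_stem_range = c(3L, 40L),
                              duplex_mismatch_range = c(0L, 3L),
                              ref_mismatch_range = c(0L, 2L),
                              tissue_weights = c(bud = 0.228, culm = 0.262,
                                                 leaf = 0.191, root = 0.319),
                              p_five_prime_u = 0.851,
                              n_families = 14L,
                              family_size_range = c(5L, 6L),
                              n_target_mrnas = 24L,
                              target_mrna_length = 600L,
                              target_penalty_levels = c(0, 0.5, 1, 2, 3, 3.5),
                              max_retries = 100L) {
  cfg <- list(seed = as.integer(seed), n_decoys = as.integer(n_decoys),
              n_hard_negatives = as.integer(n_hard_negatives),
              n_implants = as.integer(n_implants),
              decoy_length_range = decoy_length_range,
              gc_target = gc_target,
              mature_length_dist = mature_length_dist,
              loop_length_range = loop_length_range,
              lower_stem_range = lower_stem_range,
              duplex_mismatch_range = duplex_mismatch_range,
              ref_mismatch_range = ref_mismatch_range,
              tissue_weights = tissue_weights,
              p_five_prime_u = p_five_prime_u,
              n_families = as.integer(n_families),
              family_size_range = family_size_range,
              n_target_mrnas = as.integer(n_target_mrnas),
              target_mrna_length = as.integer(target_mrna_length),
              target_penalty_levels = target_penalty_levels,
              max_retries = as.integer(max_retries))
  counts <- c(cfg$n_decoys, cfg$n_hard_negatives, cfg$n_implants,
              cfg$n_families, cfg$n_target_mrnas)
  if (any(counts < 0)) stop("counts must be >= 0")
  for (w in list(cfg$mature_length_dist, cfg$tissue_weights)) {
    if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  }
  for (r in list(cfg$decoy_length_range, cfg$loop_length_range,
                 cfg$lower_stem_range, cfg$duplex_mismatch_range,
                 cfg$ref_mismatch_range, cfg$family_size_range)) {
    if (length(r) != 2L || r[1] > r[2]) stop("ranges must be ordered (min, max)")
  }
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1) stop("gc_target in (0,1)")
  structure(cfg, class = "simulation_config")
}

sample_range <- function(r) {
  # sample one integer from an inclusive range; robust to r[1] == r[2]
  if (r[1] >= r[2]) return(as.integer(r[1]))
  sample(seq(as.integer(r[1]), as.integer(r[2])), 1L)
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_mature <- function(len, gc = 0.5, p5u = 0.851) {
  body <- random_rna(len - 1L, gc)
  first <- if (stats::runif(1) < p5u) "U"
           else sample(c("A", "G", "C"), 1L)
  paste0(first, body)
}

# bases that neither Watson-Crick pair nor G:U wobble with `base`
non_pairing_bases <- function(base) {
  switch(base,
         A = c("A", "C", "G"),
         C = c("A", "C", "U"),
         G = c("A", "G"),
         U = c("C", "U"),
         stop("ambiguous base: ", base))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson style shuffle by random Eulerian walk over the
#' dinucleotide graph; the output has exactly the dinucleotide counts of
#' the input (hairpin-destroying, composition-preserving decoy material).
#'
#' @param seq a sequence.
#' @return shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 3L) return(seq)
  for (attempt in seq_len(200L)) {
    edges <- split(ch[-1L], ch[-n])
    edges <- lapply(edges, sample)
    out <- character(n)
    out[1L] <- ch[1L]
    ok <- TRUE
    for (i in 2:n) {
      avail <- edges[[out[i - 1L]]]
      if (is.null(avail) || length(avail) == 0L) { ok <- FALSE; break }
      out[i] <- avail[1L]
      edges[[out[i - 1L]]] <- avail[-1L]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  # fall back to a plain composition-preserving shuffle
  paste(sample(ch), collapse = "")
}

#' Sample a set of mature miRNA sequences from the configured distribution
#'
#' Lengths follow `mature_length_dist`, the 5' base is uracil with
#' probability `p_five_prime_u`, remaining positions follow `gc_target`.
#' Used to study length and composition statistics at reference scale.
#'
#' @param n number of matures.
#' @param config a [simulation_config()] (its `seed` is not used; seed the
#'   RNG before calling for reproducibility).
#' @return character vector of mature sequences.
#' @export
simulate_mature_set <- function(n, config = simulation_config()) {
  lens <- as.integer(names(config$mature_length_dist))
  vapply(seq_len(n), function(i) {
    L <- sample(lens, 1L, prob = config$mature_length_dist)
    random_mature(L, config$gc_target, config$p_five_prime_u)
  }, character(1))
}

#' Build a synthetic pre-miRNA around a mature sequence
#'
#' The precursor is 5' flank + one arm + terminal loop + other arm + 3'
#' flank; the arm opposite the mature is its reverse complement with
#' exactly `duplex_mismatches` substitutions to non-pairing bases, and the
#' duplex is extended by a perfectly paired lower stem. Candidates are
#' rejection-sampled (up to `max_retries`) until folding reproduces the
#' design: the mature sits at its designed interval on the designed arm,
#' measured duplex mismatches equal the design, and all six acceptance
#' criteria pass.
#'
#' @param mature mature sequence, 19-25 nt, no ambiguity codes.
#' @param loop_length terminal loop length (>= 3).
#' @param duplex_mismatches designed mismatch count (<= 5).
#' @param arm `"5p"` or `"3p"`: which arm carries the mature.
#' @param lower_stem extension stem length.
#' @param gc_target GC fraction of stem extension and flanks.
#' @param engine folding engine (see [fold()]).
#' @param max_retries rejection-sampling cap.
#' @return list: `sequence`, `mature_interval`, `star_interval`, `arm`,
#'   `retries`, plus the realized `structure` and `report`.
#' @export
build_precursor <- function(mature, loop_length, duplex_mismatches,
                            arm = c("5p", "3p"), lower_stem = 12,
                            gc_target = 0.5, engine = NULL,
                            max_retries = 100L) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  if (L < 19 || L > 25) stop("mature length must be 19-25 nt")
  if (loop_length < 3) stop("loop_length must be >= 3")
  if (duplex_mismatches > 5) {
    stop("no more than five duplex mismatches are allowed")
  }
  if (has_ambiguity(mature)) stop("mature contains ambiguity codes")
  mch <- seq_chars(mature)
  for (try in seq_len(max_retries)) {
    star <- seq_chars(rna_revcomp(mature))
    if (duplex_mismatches > 0) {
      # keep substitutions interior and spread out so folding cannot slip
      ok_pos <- 3:(L - 2)
      pos <- integer(0)
      for (p in sample(ok_pos)) {
        if (all(abs(p - pos) >= 3)) pos <- c(pos, p)
        if (length(pos) == duplex_mismatches) break
      }
      if (length(pos) < duplex_mismatches) next
      for (p in pos) {
        facing <- mch[L - p + 1L]
        star[p] <- sample(non_pairing_bases(facing), 1L)
      }
    }
    star <- paste(star, collapse = "")
    lower <- random_rna(lower_stem, gc_target)
    loop <- random_rna(loop_length, gc = 0.2)
    f5 <- random_rna(sample(3:8, 1L), gc = 0.3)
    f3 <- random_rna(sample(3:8, 1L), gc = 0.3)
    if (arm == "5p") {
      seqs <- c(f5, lower, mature, loop, star, rna_revcomp(lower), f3)
      ms <- nchar(f5) + lower_stem + 1L
    } else {
      seqs <- c(f5, lower, star, loop, mature, rna_revcomp(lower), f3)
      ms <- nchar(f5) + lower_stem + L + loop_length + 1L
    }
    precursor <- paste(seqs, collapse = "")
    st <- fold(precursor, engine = engine)
    site <- locate_mature(precursor, st, mature)
    if (site$start != ms || site$arm != arm ||
        site$mismatches_to_reference != 0L ||
        site$duplex_mismatches != duplex_mismatches) next
    rep <- evaluate_criteria(compute_metrics(st), site, L)
    if (!rep$accepted) next
    star_start <- if (arm == "5p") ms + L + loop_length else
      nchar(f5) + lower_stem + 1L
    return(list(sequence = precursor,
                mature_interval = c(ms, ms + L - 1L),
                star_interval = c(star_start, star_start + L - 1L),
                arm = arm, retries = try - 1L,
                structure = st, report = rep))
  }
  stop("build_precursor: no valid hairpin after ", max_retries, " retries")
}

#' Generate a synthetic reference miRNA set
#'
#' Families `MIR101`, `MIR102`, ... of species code `sim`, each built from
#' a family mature; every member (paralog) carries its own mature variant
#' (four member-specific substitutions away from the family mature, first
#' member unmutated) and one precursor built with [build_precursor()].
#' Distinct member matures keep homology hits member-specific. All
#' sequences are synthetic stand-ins for a real reference set (e.g.
#' miRBase-derived precursors and matures).
#'
#' @param config a [simulation_config()].
#' @param engine folding engine.
#' @return list of `reference_mirna` objects.
#' @export
simulate_reference_set <- function(config, engine = NULL) {
  lens <- as.integer(names(config$mature_length_dist))
  refs <- list()
  for (f in seq_len(config$n_families)) {
    fam <- paste0("MIR", 100L + f)
    L <- sample(lens, 1L, prob = config$mature_length_dist)
    fam_mature <- random_mature(L, config$gc_target, config$p_five_prime_u)
    n_mem <- sample_range(config$family_size_range)
    for (m in seq_len(n_mem)) {
      name <- paste0("sim-", fam, letters[m])
      mature <- if (m == 1L) fam_mature
                else mutate_sequence(fam_mature, 4L)
      prec <- build_precursor(
        mature,
        loop_length = sample_range(config$loop_length_range),
        duplex_mismatches = sample_range(config$duplex_mismatch_range),
        arm = sample(c("5p", "3p"), 1L),
        lower_stem = sample_range(config$lower_stem_range),
        gc_target = config$gc_target, engine = engine,
        max_retries = config$max_retries)
      refs[[name]] <- structure(list(
        name = name, family = fam, species_code = "sim",
        precursor = prec$sequence,
        matures = setNames(mature, sub("MIR", "miR", name)),
        detached = setNames(FALSE, sub("MIR", "miR", name)),
        mature_interval = prec$mature_interval, arm = prec$arm
      ), class = "reference_mirna")
    }
  }
  unname(refs)
}

mutate_sequence <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- seq_chars(seq)
  pos <- sample(seq_along(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

.embed <- function(core, total_min, total_max, gc) {
  extra <- max(0L, sample(total_min:total_max, 1L) - nchar(core))
  left <- sample(0:extra, 1L)
  paste0(random_rna(left, gc), core, random_rna(extra - left, gc))
}

.sample_tissue <- function(w) {
  sample(names(w), 1L, prob = w)
}

#' Simulate a tissue-labelled transcriptome with implanted precursors
#'
#' Produces `n_implants` transcripts each embedding one true precursor
#' (built around a reference mature mutated by the designed number of
#' reference mismatches), `n_decoys` random background transcripts, and
#' `n_hard_negatives` transcripts carrying a reference mature in a context
#' verified at generation time to fail at least one hairpin criterion
#' (classes: dinucleotide-shuffled context, A+U-rich stem, missing star
#' arm). Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param reference optional reference set from [simulate_reference_set()];
#'   generated (from the same seed) when omitted.
#' @param engine folding engine.
#' @return list: `transcripts` (data.frame `id`, `tissue`, `sequence`),
#'   `manifest` (list: `implanted` data.frame, `decoy_ids`,
#'   `hard_negatives` data.frame), `reference`.
#' @export
simulate_transcriptome <- function(config, reference = NULL, engine = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(reference)) reference <- simulate_reference_set(config, engine)
  lens <- config$decoy_length_range
  gc <- config$gc_target
  transcripts <- list()
  implanted <- list()
  hard <- list()

  if (length(reference) < config$n_implants) {
    warning("fewer reference members than implants; references recycled ",
            "(best-hit retention then caps recall)")
  }
  for (i in seq_len(config$n_implants)) {
    ref <- reference[[((i - 1L) %% length(reference)) + 1L]]
    k <- sample_range(config$ref_mismatch_range)
    mature <- mutate_sequence(ref$matures[[1L]], k)
    prec <- build_precursor(
      mature,
      loop_length = sample_range(config$loop_length_range),
      duplex_mismatches = sample_range(config$duplex_mismatch_range),
      arm = sample(c("5p", "3p"), 1L),
      lower_stem = sample_range(config$lower_stem_range),
      gc_target = gc, engine = engine, max_retries = config$max_retries)
    left <- sample(50:300, 1L)
    right <- sample(50:300, 1L)
    seq_full <- paste0(random_rna(left, gc), prec$sequence,
                       random_rna(right, gc))
    id <- sprintf("implant_%03d", i)
    tissue <- .sample_tissue(config$tissue_weights)
    transcripts[[id]] <- data.frame(id = id, tissue = tissue,
                                    sequence = seq_full,
                                    stringsAsFactors = FALSE)
    implanted[[id]] <- data.frame(
      transcript_id = id,
      precursor_start = left + 1L,
      precursor_end = left + nchar(prec$sequence),
      mature_start = left + prec$mature_interval[1],
      mature_end = left + prec$mature_interval[2],
      arm = prec$arm, family = ref$family, reference_name = ref$name,
      tissue = tissue, mature_sequence = mature,
      designed_duplex_mismatches =
        prec$report$duplex_mismatches,
      designed_ref_mismatches = k,
      retries = prec$retries, stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_decoys)) {
    id <- sprintf("decoy_%03d", i)
    transcripts[[id]] <- data.frame(
      id = id, tissue = .sample_tissue(config$tissue_weights),
      sequence = random_rna(sample(lens[1]:lens[2], 1L), gc),
      stringsAsFactors = FALSE)
  }

  classes <- c("shuffled_context", "au_rich_stem", "no_star")
  # hard negatives draw on reference members beyond the implanted ones so
  # that they cannot displace an implant as a query's best hit
  spare <- if (length(reference) > config$n_implants) {
    seq(config$n_implants + 1L, length(reference))
  } else {
    seq_along(reference)
  }
  for (i in seq_len(config$n_hard_negatives)) {
    ref <- reference[[spare[((i - 1L) %% length(spare)) + 1L]]]
    mature <- ref$matures[[1L]]
    cls <- classes[((i - 1L) %% length(classes)) + 1L]
    seq_full <- NULL
    for (try in seq_len(config$max_retries)) {
      core <- .hard_negative_core(cls, mature, config)
      left <- sample(50:300, 1L)
      cand_tx <- paste0(random_rna(left, gc), core,
                        random_rna(sample(50:300, 1L), gc))
      # verify failure the way the pipeline will see it: extract the
      # hairpin around the mature from a padded region and re-filter
      lo <- max(1L, left - 140L)
      hi <- min(nchar(cand_tx), left + nchar(core) + 140L)
      region <- substr(cand_tx, lo, hi)
      hp <- extract_hairpin(region, mature, engine = engine)
      st <- fold(hp$sequence, engine = engine)
      site <- locate_mature(hp$sequence, st, mature)
      rep <- evaluate_criteria(compute_metrics(st), site, nchar(mature))
      if (!rep$accepted) { seq_full <- cand_tx; break }
    }
    if (is.null(seq_full)) {
      stop("could not generate a failing hard negative of class ", cls)
    }
    id <- sprintf("hardneg_%03d", i)
    transcripts[[id]] <- data.frame(
      id = id, tissue = .sample_tissue(config$tissue_weights),
      sequence = seq_full, stringsAsFactors = FALSE)
    hard[[id]] <- data.frame(transcript_id = id, class = cls,
                             reference_name = ref$name,
                             mature_sequence = mature,
                             stringsAsFactors = FALSE)
  }

  list(transcripts = do.call(rbind, c(transcripts,
                                      make.row.names = FALSE)),
       manifest = list(
         implanted = if (length(implanted))
           do.call(rbind, c(implanted, make.row.names = FALSE))
         else data.frame(),
         decoy_ids = grep("^decoy_", names(transcripts), value = TRUE),
         hard_negatives = if (length(hard))
           do.call(rbind, c(hard, make.row.names = FALSE))
         else data.frame()),
       reference = reference)
}

.hard_negative_core <- function(class, mature, config) {
  L <- nchar(mature)
  gc <- config$gc_target
  if (class == "shuffled_context") {
    # a real hairpin whose non-mature context is dinucleotide-shuffled
    prec <- build_precursor(mature, loop_length = 8,
                            duplex_mismatches = 0, lower_stem = 12,
                            gc_target = gc, max_retries = config$max_retries)
    s <- prec$sequence
    ms <- prec$mature_interval[1]; me <- prec$mature_interval[2]
    ctx <- paste0(substr(s, 1, ms - 1), substr(s, me + 1, nchar(s)))
    ctx <- dinucleotide_shuffle(ctx)
    cut <- sample(0:nchar(ctx), 1L)
    paste0(substr(ctx, 1, cut), mature,
           substr(ctx, cut + 1, nchar(ctx)))
  } else if (class == "au_rich_stem") {
    # perfect hairpin, but the extended stem drives A+U far above 70%
    stem <- random_rna(75, gc = 0.06)
    loop <- random_rna(8, gc = 0.1)
    paste0(stem, mature, loop, rna_revcomp(mature), rna_revcomp(stem))
  } else {
    # mature with no star arm at all
    paste0(random_rna(10, gc), mature, random_rna(12, gc = 0.2),
           random_rna(L + 15, gc))
  }
}

pairing_partners <- function(base) {
  switch(base, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
}

#' Design a target site of a given penalty for a miRNA
#'
#' Starting from the exact reverse complement, substitutions are placed on
#' the site to realize the requested expectation penalty under
#' [score_duplex()]: a mismatch costs 1 (2 at miRNA positions 2-13), a G:U
#' wobble 0.5 (1 at positions 2-13). Modifications are confined to miRNA
#' positions 2..min(20, L) so both scoring modes see the same penalty. A
#' translation-type site carries a mismatch at miRNA position 10 or 11
#' (requires penalty >= 2).
#'
#' @param mirna miRNA sequence.
#' @param penalty designed expectation score (multiple of 0.5).
#' @param translation_type force a central mismatch.
#' @return list: `site` (transcript-sense sequence), `penalty`,
#'   `inhibition`, `modifications` (data.frame of position/type).
#' @export
design_target_site <- function(mirna, penalty, translation_type = FALSE) {
  L <- nchar(mirna)
  q <- seq_chars(mirna)
  hi <- min(20L, L)
  inside <- 2:13
  outside <- if (hi >= 14) 14:hi else integer(0)
  free <- rep(TRUE, L)
  mods <- list()
  add <- function(pos, type) {
    mods[[length(mods) + 1L]] <<- data.frame(position = pos, type = type,
                                             stringsAsFactors = FALSE)
    free[pos] <<- FALSE
  }
  rem <- penalty
  if (translation_type) {
    if (rem < 2 - 1e-9) {
      stop("unachievable penalty level ", penalty,
           ": a translation-type site needs a central mismatch (cost 2)")
    }
    add(sample(c(10L, 11L), 1L), "mismatch")
    rem <- rem - 2
  }
  while (rem >= 2 - 1e-9 && any(free[inside])) {
    add(sample(rep(inside[free[inside]], 2L), 1L), "mismatch")
    rem <- rem - 2
  }
  while (rem >= 1 - 1e-9) {
    if (length(outside) && any(free[outside])) {
      add(sample(rep(outside[free[outside]], 2L), 1L), "mismatch")
    } else {
      cand <- inside[free[inside] & q[inside] %in% c("G", "U")]
      if (length(cand) == 0L) stop("unachievable penalty level ", penalty)
      add(sample(rep(cand, 2L), 1L), "gu")
    }
    rem <- rem - 1
  }
  if (rem >= 0.5 - 1e-9) {
    cand <- outside[free[outside] & q[outside] %in% c("G", "U")]
    if (length(cand) == 0L) {
      stop("unachievable penalty level ", penalty,
           ": no free G/U position outside the core for a 0.5 wobble")
    }
    add(sample(rep(cand, 2L), 1L), "gu")
    rem <- rem - 0.5
  }
  if (abs(rem) > 1e-9) stop("unachievable penalty level ", penalty)
  site <- seq_chars(rna_revcomp(mirna))
  for (mod in mods) {
    i <- mod$position
    j <- L - i + 1L        # site position facing miRNA position i
    site[j] <- if (mod$type == "gu") {
      if (q[i] == "G") "U" else "G"     # G:U or U:G wobble
    } else {
      sample(non_pairing_bases(q[i]), 1L)
    }
  }
  mods_df <- if (length(mods)) do.call(rbind, mods)
             else data.frame(position = integer(0), type = character(0))
  inhibition <- if (any(mods_df$type == "mismatch" &
                        mods_df$position %in% c(10L, 11L)))
    "translation" else "cleavage"
  list(site = paste(site, collapse = ""), penalty = penalty,
       inhibition = inhibition, modifications = mods_df)
}

#' Simulate target mRNAs carrying designed miRNA binding sites
#'
#' Each mRNA embeds exactly one site whose [score_duplex()] expectation
#' equals its designed penalty (within 1e-9) in both scoring modes.
#' Designed penalties cycle through `config$target_penalty_levels`;
#' penalties >= 2 alternate between cleavage- and translation-type sites.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param config a [simulation_config()].
#' @return list: `mrnas` (data.frame `id`, `sequence`), `target_sites`
#'   (data.frame `mrna_id`, `mirna_id`, `start`, `end`,
#'   `designed_penalty`, `designed_inhibition`).
#' @export
simulate_targets <- function(mirnas, config) {
  stopifnot(inherits(config, "simulation_config"),
            !is.null(names(mirnas)))
  set.seed(config$seed + 1L)
  levels <- config$target_penalty_levels
  mrnas <- list()
  sites <- list()
  for (i in seq_len(config$n_target_mrnas)) {
    penalty <- levels[((i - 1L) %% length(levels)) + 1L]
    translation <- penalty >= 2 && (i %% 2L == 0L)
    # a fractional level needs a G/U outside the core; cycle to the next
    # miRNA that can realize the designed penalty
    d <- NULL
    for (k in seq_along(mirnas) - 1L) {
      mirna_id <- names(mirnas)[((i - 1L + k) %% length(mirnas)) + 1L]
      d <- tryCatch(
        design_target_site(mirnas[[mirna_id]], penalty, translation),
        error = function(e) NULL)
      if (!is.null(d)) break
    }
    if (is.null(d)) {
      stop("no supplied miRNA can realize penalty level ", penalty)
    }
    len <- config$target_mrna_length
    sl <- nchar(d$site)
    pos <- sample(seq(50L, len - sl - 50L), 1L)
    seq_full <- paste0(random_rna(pos - 1L, config$gc_target), d$site,
                       random_rna(len - pos + 1L - sl, config$gc_target))
    id <- sprintf("mrna_%03d", i)
    mrnas[[id]] <- data.frame(id = id, sequence = seq_full,
                              stringsAsFactors = FALSE)
    sites[[id]] <- data.frame(mrna_id = id, mirna_id = mirna_id,
                              start = pos, end = pos + sl - 1L,
                              designed_penalty = penalty,
                              designed_inhibition = d$inhibition,
                              stringsAsFactors = FALSE)
  }
  list(mrnas = do.call(rbind, c(mrnas, make.row.names = FALSE)),
       target_sites = do.call(rbind, c(sites, make.row.names = FALSE)))
}

#' Simulate cross-species homolog sets for conservation calls
#'
#' A designed fraction of the target mRNAs receives a mutated full-length
#' copy in each simulated species set (conserved); the rest are matched
#' only by unrelated random sequences (novel).
#'
#' @param mrnas data.frame with `id`, `sequence` (from
#'   [simulate_targets()]).
#' @param config a [simulation_config()].
#' @param conserved_fraction fraction of targets with true homologs.
#' @param species species-set names.
#' @param mutation_rate per-base substitution rate of the homolog copies.
#' @return list: `sets` (named list of named sequence vectors), `truth`
#'   (data.frame `mrna_id`, `conserved`).
#' @export
simulate_homolog_sets <- function(mrnas, config, conserved_fraction = 0.7,
                                  species = c("speciesA", "speciesB"),
                                  mutation_rate = 0.05) {
  set.seed(config$seed + 2L)
  n <- nrow(mrnas)
  conserved <- seq_len(n) <= round(conserved_fraction * n)
  sets <- lapply(species, function(sp) {
    seqs <- character(0)
    for (i in seq_len(n)) {
      if (conserved[i]) {
        k <- stats::rbinom(1L, nchar(mrnas$sequence[i]), mutation_rate)
        seqs[paste0(mrnas$id[i], "_", sp)] <-
          mutate_sequence(mrnas$sequence[i], k)
      } else {
        seqs[paste0("bg_", i, "_", sp)] <-
          random_rna(nchar(mrnas$sequence[i]), config$gc_target)
      }
    }
    seqs
  })
  names(sets) <- species
  list(sets = sets,
       truth = data.frame(mrna_id = mrnas$id, conserved = conserved,
                          stringsAsFactors = FALSE))
}
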