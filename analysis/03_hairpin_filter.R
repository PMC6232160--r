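#!/usr/bin/env Rscript
# Stage 3: fold a padded region around every best hit, trim it to the
# hairpin carrying the mature match, and apply the six acceptance
# criteria. Writes the per-candidate filter report and the accepted
# precursors under results/hairpin/.

library(mirhunt)

seed <- as.integer(Sys.getenv("MIRHUNT_SEED", "1"))
bh <- read.delim("results/homology/best_hits.tsv",
                 stringsAsFactors = FALSE)
txf <- read_fasta("results/sim/transcriptome.fa")
tissues <- read.delim("results/sim/tissues.tsv", stringsAsFactors = FALSE)
transcripts <- merge(tissues,
                     data.frame(id = txf$id, sequence = txf$sequence,
                                stringsAsFactors = FALSE), by = "id")
reference <- suppressWarnings(
  parse_reference_set("results/sim/reference_precursors.fa",
                      "results/sim/reference_matures.fa"))
cfg <- pipeline_config(simulation = simulation_config(seed = seed))

cand <- evaluate_candidates(bh, transcripts, reference, cfg)
dir.create("results/hairpin", recursive = TRUE, showWarnings = FALSE)
write.table(cand, "results/hairpin/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
acc <- cand[cand$accepted, , drop = FALSE]
write_fasta(setNames(acc$precursor, acc$candidate_id),
            "results/hairpin/accepted_precursors.fa")
write_fasta(setNames(acc$mature_seq, acc$candidate_id),
            "results/hairpin/accepted_matures.fa")
crit <- c("c1_length_ok", "c2_ref_ok", "c3_arm_ok", "c4_duplex_ok",
          "c5_au_ok", "c6_mfei_ok")
cat(nrow(cand), "candidates folded;", nrow(acc), "accepted\n")
cat("criterion pass rates:",
    paste(sub("_.*", "", crit),
          round(100 * colMeans(cand[, crit])), "%"), "\n")
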