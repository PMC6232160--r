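#!/usr/bin/env Rscript
# Stage 5: simulate target mRNAs with designed binding sites for the
# identified families, predict targets in both scoring modes
# (expectation <= 3.0 and score < 4.0), intersect the modes, classify the
# inhibition type and annotate predicted cleavage sites.
# Writes results/targets/.

library(mirhunt)

seed <- as.integer(Sys.getenv("MIRHUNT_SEED", "1"))
cfg <- simulation_config(seed = seed)
members <- read.delim("results/loci/members.tsv", stringsAsFactors = FALSE)
mat <- read_fasta("results/sim/reference_matures.fa")
# one representative mature per identified family (the family reference)
mat$family <- sub("[a-z]+$", "", sub("^sim-miR", "MIR", mat$id))
fams <- unique(members$family)
mirnas <- setNames(mat$sequence[match(fams, mat$family)], fams)
mirnas <- mirnas[!is.na(mirnas)]

simt <- simulate_targets(mirnas, cfg)
dir.create("results/targets", recursive = TRUE, showWarnings = FALSE)
write_fasta(setNames(simt$mrnas$sequence, simt$mrnas$id),
            "results/targets/mrnas.fa")
write.table(simt$target_sites, "results/targets/designed_sites.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

psr <- list(); tf <- list()
for (mi in names(mirnas)) {
  for (ti in seq_len(nrow(simt$mrnas))) {
    psr[[length(psr) + 1L]] <- scan_transcript(
      mirnas[[mi]], simt$mrnas$sequence[ti], "psrnatarget_like",
      mirna_id = mi, transcript_id = simt$mrnas$id[ti])
    tf[[length(tf) + 1L]] <- scan_transcript(
      mirnas[[mi]], simt$mrnas$sequence[ti], "targetfinder_like",
      mirna_id = mi, transcript_id = simt$mrnas$id[ti])
  }
}
psr <- do.call(rbind, psr); tf <- do.call(rbind, tf)
consensus <- annotate_targets(intersect_modes(psr, tf))
flat <- consensus[, setdiff(names(consensus), "duplex")]
write.table(flat, "results/targets/consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(nrow(psr), "psRNATarget-like and", nrow(tf),
    "TargetFinder-like hits;", nrow(consensus), "consensus targets (",
    sum(flat$inhibition == "cleavage"), "cleavage /",
    sum(flat$inhibition == "translation"), "translation )\n")
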