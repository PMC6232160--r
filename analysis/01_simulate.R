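#!/usr/bin/env Rscript
# Stage 1: generate the ground-truthed synthetic study inputs.
# Writes reference precursor/mature FASTA, the tissue-labelled
# transcriptome, and the truth manifest under results/sim/.

library(mirhunt)

seed <- as.integer(Sys.getenv("MIRHUNT_SEED", "1"))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_transcriptome(cfg)

prec <- setNames(vapply(sim$reference, `[[`, character(1), "precursor"),
                 vapply(sim$reference, `[[`, character(1), "name"))
mat <- unlist(lapply(sim$reference, function(r) r$matures))
write_fasta(prec, file.path(out, "reference_precursors.fa"))
write_fasta(mat, file.path(out, "reference_matures.fa"))

tx <- sim$transcripts
write_fasta(data.frame(id = tx$id, description = tx$tissue,
                       sequence = tx$sequence),
            file.path(out, "transcriptome.fa"))
write.table(tx[, c("id", "tissue")], file.path(out, "tissues.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$manifest$implanted, file.path(out, "manifest_implanted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$manifest$hard_negatives,
            file.path(out, "manifest_hard_negatives.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sim$manifest$decoy_ids, file.path(out, "decoy_ids.txt"))

cat("simulated", nrow(tx), "transcripts:",
    nrow(sim$manifest$implanted), "implants,",
    length(sim$manifest$decoy_ids), "decoys,",
    nrow(sim$manifest$hard_negatives), "hard negatives;",
    length(sim$reference), "reference precursors in",
    length(unique(vapply(sim$reference, `[[`, character(1), "family"))),
    "families\n")
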