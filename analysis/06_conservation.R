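#!/usr/bin/env Rscript
# Stage 6: simulate cross-species homolog sets for the target mRNAs and
# classify each consensus target as conserved (best alignment score > 50
# and query coverage > 50% in at least one species) or novel.
# Writes results/conservation/.

library(mirhunt)

seed <- as.integer(Sys.getenv("MIRHUNT_SEED", "1"))
cfg <- simulation_config(seed = seed)
cons <- read.delim("results/targets/consensus.tsv",
                   stringsAsFactors = FALSE)
mr <- read_fasta("results/targets/mrnas.fa")
mrnas <- data.frame(id = mr$id, sequence = mr$sequence,
                    stringsAsFactors = FALSE)
hom <- simulate_homolog_sets(mrnas, cfg)

tids <- unique(cons$transcript_id)
targets <- setNames(mrnas$sequence[match(tids, mrnas$id)], tids)
fams <- setNames(cons$mirna_id[match(tids, cons$transcript_id)], tids)
calls <- classify_conserved_set(targets, fams, hom$sets)

dir.create("results/conservation", recursive = TRUE, showWarnings = FALSE)
write.table(calls, "results/conservation/calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bf <- summarize_by_family(calls)
write.table(bf, "results/conservation/by_family.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
agree <- merge(calls, hom$truth, by.x = "target_id", by.y = "mrna_id")
cat(nrow(calls), "targets classified;",
    sum(calls$status == "conserved"), "conserved (",
    round(attr(bf, "percent_conserved"), 2), "% );",
    "agreement with simulated truth:",
    round(100 * mean((agree$status == "conserved") == agree$conserved), 1),
    "%\n")
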