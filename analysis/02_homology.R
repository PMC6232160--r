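#!/usr/bin/env Rscript
# Stage 2: homology search of reference precursors against the
# transcriptome; best hit per query at E-value <= 10, redundant subject
# regions collapsed. Writes results/homology/{hits,best_hits}.tsv.

library(mirhunt)

qs <- read_fasta("results/sim/reference_precursors.fa")
tx <- read_fasta("results/sim/transcriptome.fa")
dir.create("results/homology", recursive = TRUE, showWarnings = FALSE)

hits <- search_homology(setNames(qs$sequence, qs$id),
                        setNames(tx$sequence, tx$id), word_size = 7)
bh <- best_hits(hits, evalue_cutoff = 10)
write.table(hits, "results/homology/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(bh, "results/homology/best_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(nrow(hits), "alignments;", nrow(bh),
    "best hits retained at E <= 10\n")
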