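#!/usr/bin/env Rscript
# Stage 4: cluster accepted precursors into tentative loci (alleles share
# a locus below two whole-length mismatches), name members after their
# closest reference locus, tally tissues and profile mature nucleotide
# composition. Writes results/loci/.

library(mirhunt)

cand <- read.delim("results/hairpin/candidates.tsv",
                   stringsAsFactors = FALSE)
acc <- cand[cand$accepted, , drop = FALSE]
dir.create("results/loci", recursive = TRUE, showWarnings = FALSE)

loci <- cluster_loci(acc$candidate_id, acc$precursor)
members <- merge(loci, acc[, c("candidate_id", "family", "tissue",
                               "query")], by = "candidate_id",
                 sort = FALSE)
names(members)[names(members) == "query"] <- "reference_hit"
members <- assign_names(members)
write.table(members, "results/loci/members.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- build_locus_table(members)
write.table(tab, "results/loci/locus_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tt <- tissue_tally(members)
write.table(data.frame(tissue = names(tt$counts), count = tt$counts,
                       percent = tt$percent),
            "results/loci/tissue_tally.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cp <- composition_profile(acc$mature_seq)
write.table(cbind(position = seq_len(nrow(cp$positional)),
                  round(cp$positional, 2)),
            "results/loci/composition_positional.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- locus_table_totals(tab)
cat(nrow(acc), "members in", tot$total, "loci across", nrow(tab),
    "families\n")
cat("tissue % (b/c/l/r):", round(tt$percent, 1), "\n")
cat("overall base % (A/C/G/U):", round(cp$overall, 1), "\n")
cat("5'-U share:", round(cp$positional[1, "U"], 1), "%\n")
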