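#!/usr/bin/env Rscript
# Stage 7: progressively align the precursors of the largest identified
# family and build a neighbor-joining tree with bootstrap supports.
# Writes results/phylo/.

library(mirhunt)

seed <- as.integer(Sys.getenv("MIRHUNT_SEED", "1"))
reps <- as.integer(Sys.getenv("MIRHUNT_BOOTSTRAP", "1000"))
members <- read.delim("results/loci/members.tsv", stringsAsFactors = FALSE)
prec <- read_fasta("results/hairpin/accepted_precursors.fa")

fam_n <- sort(table(members$family), decreasing = TRUE)
fam <- names(fam_n)[1]
stopifnot(fam_n[1] >= 3)
ids <- members$candidate_id[members$family == fam]
seqs <- setNames(prec$sequence[match(ids, prec$id)],
                 members$name[match(ids, members$candidate_id)])

msa <- progressive_align(seqs)
tree <- nj_bootstrap(msa, replicates = reps, seed = seed)

dir.create("results/phylo", recursive = TRUE, showWarnings = FALSE)
write_fasta(setNames(apply(msa, 1, paste, collapse = ""), rownames(msa)),
            "results/phylo/alignment.fa")
write_newick(tree, "results/phylo/tree.nwk")
sup <- attr(tree, "supports")
cat("family", fam, "with", length(seqs), "members;", reps,
    "bootstrap replicates; internal-edge supports:",
    paste(round(sup[!is.na(sup)]), collapse = " "), "\n")
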