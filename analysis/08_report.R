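#!/usr/bin/env Rscript
# Stage 8: assemble the run report: stage funnel, recall against the
# truth manifest, and the per-stage summary tables.
# Writes results/report/.

library(mirhunt)

hits <- read.delim("results/homology/hits.tsv", stringsAsFactors = FALSE)
bh <- read.delim("results/homology/best_hits.tsv",
                 stringsAsFactors = FALSE)
cand <- read.delim("results/hairpin/candidates.tsv",
                   stringsAsFactors = FALSE)
acc <- cand[cand$accepted, , drop = FALSE]
members <- read.delim("results/loci/members.tsv", stringsAsFactors = FALSE)
man <- read.delim("results/sim/manifest_implanted.tsv",
                  stringsAsFactors = FALSE)
hard <- read.delim("results/sim/manifest_hard_negatives.tsv",
                   stringsAsFactors = FALSE)
decoys <- readLines("results/sim/decoy_ids.txt")

recovered <- vapply(seq_len(nrow(man)), function(i) {
  any(acc$transcript_id == man$transcript_id[i] &
        acc$precursor_start <= man$precursor_end[i] &
        acc$precursor_end >= man$precursor_start[i])
}, logical(1))

funnel <- data.frame(
  stage = c("homology_hits", "best_hits", "candidates", "accepted",
            "loci"),
  count = c(nrow(hits), nrow(bh), nrow(cand), nrow(acc),
            length(unique(members$locus_id))))
dir.create("results/report", recursive = TRUE, showWarnings = FALSE)
write.table(funnel, "results/report/funnel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- data.frame(
  metric = c("implants", "recovered", "recall_pct",
             "hard_negative_acceptances", "decoy_acceptances"),
  value = c(nrow(man), sum(recovered), 100 * mean(recovered),
            sum(acc$transcript_id %in% hard$transcript_id),
            sum(acc$transcript_id %in% decoys)))
write.table(truth, "results/report/truth_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("== funnel ==\n")
print(funnel, row.names = FALSE)
cat("== against the truth manifest ==\n")
print(truth, row.names = FALSE)
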