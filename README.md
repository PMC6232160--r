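# mirhunt

Homology-based discovery and characterization of plant microRNAs from
assembled transcriptomes, built for species without a reference genome
(the motivating system is the polyploid giant reed, *Arundo donax*, whose
bud, culm, leaf and root transcriptome assemblies were screened against
rice miRNAs). The package implements the complete in-silico workflow —
candidate detection, stem-loop filtering, locus inference, composition
profiling, target prediction, conservation calls and family phylogenies —
together with a fully ground-truthed synthetic-data generator so that
every stage is testable end to end without external downloads.

## The method

**Candidate detection.** Known precursor miRNAs are aligned against the
transcriptome with an exact affine-gap Smith–Waterman (blastn-like
scoring: match +2, mismatch −3, gap open 5, extend 2; k-mer seeding
accelerates long subjects). Significance uses Karlin–Altschul E-values,
E = K·m·n·e^(−λS), with an E-value cutoff of 10; only the best hit per
query survives, and redundant subject regions are collapsed.

**Six-criterion hairpin filter.** A padded region around each hit is
folded (ViennaRNA `RNAfold` by default, a built-in base-pair-maximization
engine as fallback), trimmed to the hairpin carrying the mature match,
refolded and screened:

1. predicted mature length 19–25 nt;
2. at most 2 mismatches to the known reference mature;
3. mature localized on a single arm of the stem-loop;
4. at most 5 miRNA/miRNA\* duplex mismatches;
5. precursor A+U content 30–70%;
6. MFEI ≤ −0.85 kcal/mol (inclusive), where
   AMFE = MFE/length×100 and MFEI = AMFE/GC%.

**Loci, names, composition.** Accepted precursors with fewer than two
whole-length alignment mismatches are alleles of one locus
(single-linkage). Members are renamed after their closest reference
locus (`Ado-MIR444d-2c_b` = second locus of reference stem MIR444d,
third allele, bud), tallied by tissue, and profiled for overall and
position-specific nucleotide composition.

**Targets.** miRNA–mRNA duplexes are scored with the plant penalty
scheme (mismatch 1, G:U wobble 0.5, indel 2; doubled at miRNA positions
2–13) in two modes — expectation ≤ 3.0 over the best 20-nt window
(psRNATarget-like) and score < 4.0 over the full miRNA
(TargetFinder-like). Sites found by both modes are consensus targets;
a mismatch at miRNA position 10 or 11 marks translational inhibition,
otherwise cleavage is annotated opposite the 10/11 bond. Conservation
against cross-species target sets requires alignment score > 50 and
query coverage > 50% (both strict).

**Phylogenetics.** Family precursors are progressively aligned
(profile–profile Needleman–Wunsch along a k-mer guide tree) and
summarized with canonical Saitou–Nei neighbor joining plus bootstrap
supports (column resampling, default 1000 replicates), serialized as
Newick via `ape`.

## Worked example

```r
library(mirhunt)
set.seed(42)
p  <- build_precursor("UGAGGCAGUGCAGUUCAUGGA", loop_length = 8,
                      duplex_mismatches = 2, lower_stem = 18)
st <- fold(p$sequence)
m  <- compute_metrics(st)
site <- locate_mature(p$sequence, st, "UGAGGCAGUGCAGUUCAUGGA")
cat(sprintf("precursor: %d nt, MFE %.1f kcal/mol, AMFE %.2f, MFEI %.3f\n",
            m$length, m$mfe, m$amfe, m$mfei))
cat(sprintf("mature at %d-%d on the %s arm, %d duplex mismatches\n",
            site$start, site$end, site$arm, site$duplex_mismatches))
evaluate_criteria(m, site, 21)[, c(7:13)]
```

prints

```
precursor: 99 nt, MFE -65.8 kcal/mol, AMFE -66.46, MFEI -1.530
mature at 27-47 on the 5p arm, 2 duplex mismatches
  c1_length_ok c2_ref_ok c3_arm_ok c4_duplex_ok c5_au_ok c6_mfei_ok accepted
1         TRUE      TRUE      TRUE         TRUE     TRUE       TRUE     TRUE
```

A 99-nt synthetic precursor (the published mean precursor length is
99 nt) folds into a stem-loop whose MFEI of −1.53 is well below the
−0.85 acceptance cutoff; the mature sits entirely on the 5' arm with the
two designed duplex mismatches recovered by measurement, so all six
criteria pass. A perfect complementary site then scores expectation 0
and is classified as cleavage-type regulation:

```r
d <- score_duplex("UGAGGCAGUGCAGUUCAUGGA",
                  rna_revcomp("UGAGGCAGUGCAGUUCAUGGA"))
d$expectation            # 0
classify_inhibition(d)   # "cleavage"
```

## The analysis workflow

`analysis/` holds the staged study as numbered drivers over the package
(`MIRHUNT_SEED` selects the seed, default 1):

```sh
Rscript analysis/01_simulate.R        # ground-truthed transcriptome + reference
Rscript analysis/02_homology.R        # seeded search, best hits at E <= 10
Rscript analysis/03_hairpin_filter.R  # fold + six criteria
Rscript analysis/04_loci_composition.R
Rscript analysis/05_targets.R
Rscript analysis/06_conservation.R
Rscript analysis/07_phylogeny.R
Rscript analysis/08_report.R          # funnel + recall vs the truth manifest
```

Each stage reads and writes plain FASTA/TSV under `results/`, so any
stage can be re-run or fed real data in the same formats. At the default
study conditions (50 implanted precursors, 40 decoys, 15 hard-negative
decoys) the run recovers 48/50 implants (96% recall) with zero accepted
hard negatives or decoys.

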