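---
title: "Methods: homology-based plant miRNA discovery and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based plant miRNA discovery and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhunt)
```

# Scope and model

`mirhunt` reconstructs, as a reusable and testable pipeline, the
in-silico route by which plant miRNAs are discovered in an assembled
transcriptome of a species without a reference genome: known precursors
from a well-annotated relative (rice, in the motivating study of the
giant reed *Arundo donax*) serve as homology baits; candidate regions
are folded and screened as pre-miRNA stem-loops; surviving candidates
are grouped into tentative loci, renamed after their closest reference
locus, characterized by tissue occupancy and nucleotide composition;
their targets are predicted by complementarity scoring, classified by
inhibition mode and tested for cross-species conservation; and family
structure is summarized with neighbor-joining trees.

The guiding statistical idea is a cascade of filters, each with an
explicit published threshold, tuned for specificity over sensitivity
(type-I error control at the cost of some false negatives). All
thresholds live in one configuration object whose defaults are asserted
by `config_self_test()`:

| stage | parameter | default | unit |
|---|---|---|---|
| homology | E-value cutoff | 10 | expected chance hits |
| hairpin (1) | mature length | 19–25 | nt |
| hairpin (2) | mismatches to reference mature | ≤ 2 | count |
| hairpin (3) | mature arm | one arm | — |
| hairpin (4) | miRNA/miRNA\* duplex mismatches | ≤ 5 | count |
| hairpin (5) | precursor A+U | 30–70 | % |
| hairpin (6) | MFEI | ≤ −0.85 (inclusive) | kcal/mol convention |
| loci | whole-length mismatches | < 2 | count |
| targets | expectation (best 20-nt window) | ≤ 3.0 | penalty units |
| targets | score (full miRNA) | < 4.0 | penalty units |
| inhibition | central mismatch range | positions 10–11 | miRNA coords |
| conservation | score / query coverage | > 50 / > 50% | strict |
| phylogeny | bootstrap replicates | 1000 | count |

Coordinates are 1-based closed intervals throughout; the internal
alphabet is RNA (DNA input is converted on read).

# Homology stage

`local_align()` is an exact affine-gap Smith–Waterman (Gotoh) with
blastn-like scoring (+2/−3, gap open 5, extend 2), searched on both
strands. Seeding is deliberately *not* allowed to change results:
`seeded_align()` uses exact shared k-mers only to choose subject windows
when the subject exceeds a length threshold, and runs the exact
algorithm inside the window; short subjects are searched exhaustively.
The pipeline's word size is 7 — the short-query regime appropriate for
~21-nt mature homology, where an 11-mer seed can miss a hit carrying two
spread-out mismatches. E-values use the Karlin–Altschul form with
K = 0.41, λ = 0.625 (standard values for +2/−3 nucleotide scoring) and
the total subject length as database size.

Best-hit retention keeps, per query, the lowest E-value (ties: higher
score, then lexicographic subject id); best hits of different queries
covering the same subject region (≥ 80% overlap of the shorter interval)
are collapsed to one. The 80% figure is this package's choice; redundancy
elimination is required but its exact rule is not published.

# Folding and the six criteria

Two interchangeable folding engines implement one contract. The default
calls ViennaRNA's `RNAfold` (thermodynamic MFE); the built-in `maxpair`
engine is a Nussinov base-pair maximization (pairs AU/GC/GU, minimum
loop 3, deterministic traceback) whose pseudo-energy of −1 per pair
makes it useful for structure-logic tests and for environments without
ViennaRNA — its energies are not calibrated, so MFEI-based screening
should use the thermodynamic engine.

A candidate region (hit ± 150 nt) is folded once; the best mature window
(fewest mismatches to the reference mature, ties broken by fewer duplex
mismatches, then 5'-most) anchors a climb along its enclosing helix.
Two guards keep the climb honest: the hairpin span may not exceed
240 nt (the published precursor range tops out at 193 nt), and a single
step may not jump across more than 15 unpaired bases on either side —
real stems carry small bulges and interior loops, whereas sparse
long-range pairings of flanking sequence would otherwise inflate the
"precursor" and dilute its AMFE and A+U content. The trimmed span is
refolded without padding so metrics describe the stem-loop itself.

Arm assignment requires the mature's duplex span to contain exactly one
terminal loop; a branched (multi-loop) span fails criterion 3, as only
hairpin-like structures qualify. Duplex mismatches count mature
positions not paired into the opposite arm; G:U wobbles count as
pairing (a configuration switch can change this; the original tool's
convention is not documented). MFEI is (MFE/length×100)/GC% with GC
expressed as a percentage; the −0.85 cutoff is inclusive because the
published criterion is "≤ −0.85". Because a homologous hairpin aligns
almost equally well to either strand of itself, both orientations of
each region are evaluated and the better-supported one kept.

# Loci, naming, composition

The "alleles of the same locus" relation (global-alignment mismatches,
including end overhangs, fewer than 2) is aggregated by single linkage —
the most permissive reading consistent with the published phrasing — so
the partition is independent of input order. Names follow the observed
pattern `Ado-MIR444d-2c_b`: reference stem, locus index within that
stem, allele letter within the locus, tissue initial; the numeric and
letter parts are an interpretation of the published names (their exact
semantics are never defined) and the convention is configurable.
Composition profiles report overall and position-specific base
percentages, with each position's denominator restricted to sequences
long enough to reach it.

# Target prediction

Both published tools are re-implemented as two modes of one auditable
scorer, since the study fixes their thresholds but not their internals:
penalties are mismatch 1, G:U 0.5, indel 2, doubled at miRNA positions
2–13; the psRNATarget-like mode scores the best window of 20 miRNA
positions (the published complementarity scoring length) with free site
overhangs and accepts expectation ≤ 3.0; the TargetFinder-like mode
scores the full miRNA and accepts < 4.0 (strict, "score lower than 4").
Indel penalties anchor to the next miRNA position — a convention this
package fixes explicitly because any position-weighted scheme must
choose one; as a consequence exact strand-swap symmetry holds only for
gap-free duplexes with a palindromic weight layout, which is what the
test suite asserts. Scanning pre-screens windows with a vectorized
ungapped scorer (margin 4 penalty units) before running the gapped
dynamic program; designed sites carry no indels, so the pre-screen is
exact for them. Consensus targets must be found by both modes with
overlapping intervals. Translation-type inhibition is called iff miRNA
position 10 or 11 is a mismatch or gap (wobble counts as pairing by
default); cleavage sites are annotated opposite the 10/11 bond, i.e. the
returned coordinate `c` means a cut between `c` and `c+1`.

The published workflow's accessibility filter (maximum unpaired energy,
UPE 25, flanks 17 up / 13 down) and its protein-database screen for
non-coding transcripts are not reproducible bit-exactly without the
original server internals and databases; target-site accessibility is
therefore out of the consensus path here, and coding status is left to
the user's transcript selection.

# Conservation

A target is conserved iff its best local alignment in at least one
species set has raw score > 50 *and* query coverage > 50%, both strict —
score 50 or coverage 50.0 is novel. "Score" is interpreted as the raw
alignment score (the published text does not distinguish raw from bit
score; the threshold is configurable). The default comparison is
nucleotide-level with the homology aligner; the published analysis used
protein-level search against curated target sets, whose score scale
differs, so absolute conserved fractions are comparable only in kind.

# Phylogenetics

Family precursors are aligned progressively: profile–profile
Needleman–Wunsch (match 2, mismatch −1, affine gaps open −4 extend −1
per column) along an average-linkage guide tree on shared 5-mer
distances. Distances are p-distances with pairwise deletion of gap
sites (the distance model used in the original analysis is unstated;
p-distance is the simplest defensible default). Neighbor joining is the
canonical Saitou–Nei agglomeration with deterministic tie-breaking by
taxon label order; negative branch lengths are clamped to zero and
counted. Bootstrap resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports the percentage of
replicates containing each internal bipartition of the reference tree;
a resample that leaves some pair without comparable sites is redrawn.
Trees are `ape` `phylo` objects and serialize to Newick with supports
as node labels.

# The synthetic-data generator

The generator's defaults encode the study conditions the package
emulates, and they are not tuning knobs:

* mature lengths 20/21/22 nt with weights 0.078/0.858/0.064 and a
  5'-terminal uracil probability of 0.851, matching the published
  distribution (85.82% of matures 21 nt; 85.11% 5'-U);
* balanced GC (0.5) for background and stems, bracketing the published
  mature GC of 50.15%;
* tissue weights root 0.319, culm 0.262, bud 0.228, leaf 0.191 — the
  published tissue occupancy of mature miRNAs (bud rounded up by 0.001
  so the weights sum to one);
* precursors built as mature/star duplexes (0–3 designed mismatches,
  substitutions placed interior and ≥ 3 nt apart so folding cannot
  slip) over a perfectly paired extension stem of 3–40 nt, terminal
  loops of 4–20 nt and short unpaired flanks, which lands accepted
  precursors in the published 60–200 nt band with a mean near 100 nt;
* 14 reference families (the published family count) of 5–6 members
  each; member matures differ from the family mature by four
  member-specific substitutions so homology hits stay member-specific;
  implanted matures add 0–2 further mismatches, keeping criterion 2
  satisfiable;
* 50 implants, 40 random decoys and 15 hard negatives per run.

Every generated precursor is rejection-sampled (cap 100 tries, retries
recorded) until folding reproduces the design exactly — mature at the
designed interval and arm, measured duplex mismatches equal to the
designed count, all six criteria passed. Hard negatives carry a real
reference mature in three failure-by-construction contexts —
dinucleotide-shuffled hairpin context (Altschul–Erikson random Eulerian
walk), an A+U-rich stem (fails the 30–70% window), and a missing star
arm — and each is verified, in its embedded transcript exactly as the
pipeline will see it, to fail at least one criterion before being
emitted. Designed target sites start from the exact reverse complement
and realize their penalty with substitutions confined to miRNA
positions 2–20, so both scoring modes measure the same designed value;
fractional penalties need a G/U outside the doubled core, and the
simulator cycles to a miRNA that can realize the level (the site
designer itself refuses unachievable levels by name).

What the generator does *not* emulate: expression levels and read
sampling, sequence composition biases of real transcriptomes (decoys
are i.i.d. or shuffled), paralog structure beyond point substitutions,
and genuine cross-species target evolution (homolog sets are mutated
copies). Passing the synthetic suite therefore demonstrates that the
machinery implements its stated rules and recovers planted signal under
realistic scale and noise — not that real-data discovery rates would
match.

# Numerical choices and degenerate inputs

Alignment kernels are exact dynamic programs in C++ (score ties resolve
deterministically: substitution before gap states, 5'-most cells).
`whole_length_mismatches` equals the unit-cost global alignment distance
with end gaps charged. Folding is deterministic per engine; ambiguity
codes are rejected at folding and candidates containing them fail
mapping, because mismatch counting is undefined for them. MFEI is an
error for GC = 0; MFE = 0 gives AMFE = MFEI = 0. Empty hit tables, zero
implants and single-sequence alignments are all defined (empty outputs
or explicit errors, never silent misbehavior).

# Problem sizes used by the test suite and acceptance run

The bundled analysis and the acceptance script use the generator's
default conditions (50 implants, 105 transcripts, 78 reference
precursors); bootstrap is run at 100–300 replicates in the scripted
analyses (the configuration default remains 1000, and the figure is a
choice of the bundled analyses, stated here so they can be scaled up).
Oracle-backed checks run at the sizes where exhaustive enumeration is
exact: 200 random 60-nt pairs against an independent Smith–Waterman,
all unrooted topologies to 6 taxa against least-squares fits, duplex
alignments to 12 nt against exhaustive recursion, and Nussinov folds to
14 nt against interval enumeration.

# Known limitations

Homology discovery cannot find families absent from the reference set;
the per-query best-hit rule bounds discoverable loci by the number of
reference queries; MFEI screening on the trimmed stem is slightly more
permissive than on a flank-padded precursor (trimming removes unpaired
dilution); and the conservation stage's nucleotide-level default is not
score-compatible with protein-level searches. The published study's
wet-lab validation (5'-RACE), GO annotation and network visualization
are intentionally outside this package's scope; only in-silico
cleavage-site annotation is provided.
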