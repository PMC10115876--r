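---
title: "Methods: quantifying HbE base-editing outcomes and off-target effects"
author: "abeprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying HbE base-editing outcomes and off-target effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Haemoglobin E arises from the codon-26 GAG→AAG (E26K) mutation of *HBB*.
An adenine base editor (ABE) targeting this codon can deaminate either or
both of two adenines inside its editing window — the target adenine at
protospacer position 5 (A5) and a bystander at position 6 (A6) — giving
three codon outcomes: GAG (wild type, A5 only), GGG (the benign variant
Hb Aubenas, A5+A6) and AGG (A6 only, a codon of unknown consequence).
`abeprofiler` implements the computational stages by which such an
editing strategy is evaluated:

1. **Amplicon outcome quantification** — per-read codon classification
   from paired amplicon sequencing.
2. **Off-target nomination** — mismatch enumeration over a genome merged
   with CIRCLE-seq evidence, adenine-window filtering, ranking, probe
   design.
3. **Capture quantification** — per-site deamination frequencies and
   statistical calling from ultra-deep targeted capture.
4. **Damage modelling** — sequence-based chromatin-accessibility scoring
   of candidate edits through a pluggable predictor.
5. **Splice and expression statistics** — cryptic-junction counting and
   delta-delta-Ct fold changes.

Every stage is exercised end to end on seeded synthetic data with
machine-readable truth, so all statistical properties are testable
without access to patient sequencing data.

# Coordinate and strand conventions

Coordinates are 0-based half-open internally (BED/BAM convention);
1-based positions appear only in VCF-like output and splice-donor
reporting. Protospacer positions are 1-based from the PAM-distal end, so
A5/A6 keep their usual names. Window positions always refer to the
protospacer strand: for a minus-strand protospacer, the deaminated A
appears as T→C on the reference, and all window logic complements
reference bases first. The splice-donor coordinate is the 1-based
position of the last exonic base before a skip, the convention in which
chr11:5,248,159 (hg19) is the canonical *HBB* exon-1 donor.

# Amplicon classification

Read pairs are merged by an ungapped FLASH-style overlap search
(minimum overlap 10 nt, maximum mismatch fraction 0.25, best =
lowest mismatch fraction, ties to the longer overlap; disagreements take
the higher-quality base). The merge kernel is implemented in C++ because
it is a per-read inner loop. Unmergeable pairs are counted in a QC block
and excluded.

Merged reads are aligned to the amplicon with an affine-gap aligner
(match +2, mismatch −2, gap open −10, gap extend −1 — configurable;
alignment is delegated to `Biostrings::pairwiseAlignment`). A read whose
length equals the amplicon and whose Hamming distance to it is ≤ 5 is
classified without dynamic programming: under these scores an indel pair
costs at least 22 while five mismatches cost 20, so the gapless
alignment is provably optimal. Any gap overlapping the editing window or
the codon yields `INDEL`; otherwise the codon is read out and mapped
AAG/GAG/GGG/AGG to its category, any other codon to
`OTHER_SUBSTITUTION`. Codon bases below Q20 (default) or missing
coverage give `UNCLASSIFIED`.

**Editing efficiency** is defined as the summed frequency of the two
benign outcomes, `WT_CORRECTED + AUBENAS`, over classified reads. This
matches reporting "correction" of the HbE allele as conversion to either
benign codon; whether the AGG bystander outcome should count is
ambiguous, and the default excludes it (the category set is
configurable). Frequencies are over classified reads and sum to one to
1e−9; empty inputs return an all-zero table flagged undefined rather
than NaNs.

Allele phasing between the HbE and trans-thalassaemic alleles is out of
scope unless a discriminating variant position is supplied; outcomes are
otherwise pooled.

# Off-target nomination

`enumerate_offtargets()` finds every 20-nt window on either strand
within a Hamming radius (default 4, maximum 8) of the spacer whose 3'
neighbours match the IUPAC PAM pattern. The search is delegated to
`Biostrings::matchPattern`; bulges are deliberately not modelled
(mismatch-only, as no bulge parameters are defined for this assay).
CIRCLE-seq evidence enters as BED6 plus a numeric read-count column and
is merged by strand-aware interval overlap (union of sources, maximum
read count, minimum mismatch count; representative coordinates from the
lowest-mismatch member).

Sites are filtered to those with at least one protospacer-strand adenine
inside the editing window — the only sites an ABE can edit — and ranked.
The ranking key is CIRCLE-seq read count (descending; absent evidence
counts as zero reads), then mismatch count, then coordinates: in-vitro
cleavage evidence is a direct activity measurement and outranks sequence
similarity. The key is configurable and recorded in the stage run-log.
Capture probes are emitted as fixed 120-bp plus-strand sequences centred
on each protospacer; melting temperature is not optimised.

# Capture quantification

Per-site pileups (`Rsamtools::pileup`) count protospacer-strand A, G and
other bases at each window position, at defaults Q30 base quality and
MAPQ 20. Duplicates are not removed: at capture depths of ~50,000 the
library complexity is legitimately exceeded, and duplicate removal would
discard signal (a documented caveat). Only **editable** positions —
those whose protospacer-strand reference base is A — are eligible for
deamination calling; a window position that is already G on the
protospacer strand has a G frequency near one in both samples and
carries no information about editing.

The caller is this package's explicit re-specification of the "custom
script" class of off-target callers: per editable position, a one-sided
Fisher exact test of G-vs-A counts (edited exceeding control), computed
as the hypergeometric tail (`stats::phyper`), which is numerically
identical to `fisher.test(alternative = "greater")` and is cross-checked
in the tests against both `fisher.test` and an independent `lchoose`
enumeration. The site p-value is the minimum positional p-value
Bonferroni-adjusted by the number of positions tested (a max-frequency
single-test alternative is available). Across sites,
Benjamini–Hochberg adjustment (`stats::p.adjust`) controls the FDR, and
a site is called when q ≤ α (default 0.05) **and** its maximum editable
frequency exceeds the control's. Under null simulations (250 sites,
depth 10,000, error 0.001, 200 replicates) the called fraction stays
within 1.5α; planted 1% editing against 0.1% background at depth 50,000
is called essentially always.

# Damage modelling

The damage statistic is `P(accessible)_control − P(accessible)_edited`
per track, with a site flagged when some track has
`P(accessible)_control > 0.2` and damage `> 0.1`. The accessibility
predictor is a declared contract (input length, track ids, batch
scoring), so any sequence-to-accessibility model can be plugged in,
including large multi-track models trained on real chromatin data. The
flag rule is "any track exceeds" — with many tracks an aggregation must
be chosen, and any-track exceedance is the conservative screen.
Gain-of-function edits (negative damage) are reported with their sign
but flagged only under an optional absolute-damage mode.

The shipped reference predictor is a small one-convolutional-layer
network (8 filters of width 10, leaky-ReLU, global max-pooling, logistic
head) trained by per-sample Adam on a synthetic motif task: accessible
sequences contain a planted 10-bp motif, inaccessible ones do not. The
leaky rectifier matters: with a hard ReLU and per-sample updates the
filters can die irrecoverably early in training, collapsing the model to
a constant. Training is seeded and exactly reproducible; on the default
task (n = 4,000, length 200) held-out AUROC exceeds 0.99.

Edits evaluated per site are each single window adenine plus the
all-adenines edit (configurable). Which bystander combinations an ABE
realises is not knowable from sequence alone; singles-plus-all brackets
the range from minimal to maximal deamination. The model always sees the
protospacer-strand orientation, so a site scores identically under
either strand representation.

# Splice and expression

Junction counting extracts every skipped-region (CIGAR `N`) operation
from alignments (`GenomicAlignments::junctions`); multi-intron reads
contribute one count per skip. The aberrant fraction is the share of
junction counts whose donor differs from the canonical donor; zero
junctions give a flagged undefined value. Relative expression uses the
delta-delta-Ct closed form `2^−ΔΔCt` with replicate Ct values aggregated
by arithmetic mean (triplicates are standard; no outlier handling by
default), plus the β/α-globin expression ratio. Efficiency-corrected
(Pfaffl) quantification is out of scope.

# Synthetic data and what the tests show

Generators draw all randomness through a state-preserving seeded
wrapper, so a fixed seed reproduces byte-identical FASTQ/FASTA/SAM and
JSON truth manifests. Study conditions are fixed at: outcome mix
Aubenas 0.78, WT 0.12, AGG 0.0074, indel 0.0015, remainder unedited;
per-base substitution error 0.001 (Illumina Q30 scale); 150-bp paired
reads over a 240-bp amplicon; capture depth 50,000; accessibility task
n = 4,000 at length 200 with a 10-bp motif; cryptic splice fraction 0.3.
The error model is substitution-only by default (an indel outcome
exercises the INDEL path explicitly), quality strings are constant Q37
unless degraded, and no PCR duplicates or GC bias are simulated.
Off-target genomes are scrubbed of accidental PAM-adjacent near-matches
within the search radius so planted truth is exhaustive.

Problem sizes in the test-suite and acceptance script — 10,000–50,000
read pairs, a 100-kb genome, 250 capture sites, 200 replicates for
error-rate studies — were chosen as the smallest sizes at which the
binomial standard errors of the quantities under test are far below the
effect sizes being verified.

Passing these tests shows the *computations* are correct on data whose
generating process is fully known. It does not show that real patient
data would yield the same headline numbers: real amplicons carry indel
sequencing errors, context-dependent error rates and allele phasing;
real off-target landscapes have repeat-driven near-matches and capture
GC bias; and the reference accessibility model is a stand-in trained on
a synthetic motif task, not on hundreds of real chromatin datasets, so
its flagged-site counts are not comparable to a production model's.

# Degenerate inputs and numerical choices

Empty outcome lists, zero-depth pileups and junction-free alignments
return flagged-undefined results rather than errors; invalid sequences,
windows and configurations fail fast with every violation listed. Site
merging uses union–find over the overlap graph, so it is independent of
input order; ranking ties break deterministically on coordinates.
Frequency sums are checked to 1e−9; Fisher p-values are exact, not
simulated; BH adjustment is clipped to [0, 1].
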