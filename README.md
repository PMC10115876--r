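# abeprofiler

Quantification of adenine base-editing (ABE) outcomes and off-target
effects for correction of the haemoglobin E (HbE) variant, built for
genome-editing groups evaluating an editing strategy from sequencing
data.

HbE β-thalassaemia is driven by the codon-26 GAG→AAG (E26K) mutation of
*HBB*. An ABE guide placing the mutant adenine at protospacer position 5
(A5), with a bystander adenine at position 6 (A6), can deaminate within
its editing window (positions 4–8) to produce three codon outcomes:

| edit        | codon | outcome                         |
|-------------|-------|---------------------------------|
| A5 only     | GAG   | wild-type β-globin              |
| A5 + A6     | GGG   | Hb Aubenas (benign variant)     |
| A6 only     | AGG   | bystander codon                 |

The package implements the full analysis pipeline around this strategy:

- **Amplicon outcomes** — FLASH-style pair merging, affine-gap alignment
  to the amplicon, per-read codon classification
  (AAG/GAG/GGG/AGG/indel), outcome frequencies and editing efficiency
  (the WT + Aubenas fraction of classified reads).
- **Off-target nomination** — Cas-OFFinder-style mismatch enumeration
  (Hamming ≤ k, IUPAC PAM, both strands), merging with CIRCLE-seq site
  lists, filtering to sites with an editing-window adenine, ranking by
  CIRCLE-seq read count then mismatch count, capture-probe design.
- **Capture quantification** — per-site deamination frequencies from
  ultra-deep capture pileups; per-position one-sided Fisher exact tests
  of G excess over matched controls (p = hypergeometric tail),
  Bonferroni-aggregated within the window, Benjamini–Hochberg FDR across
  sites, calling at q ≤ α with a frequency-excess requirement.
- **Damage model** — the damage score
  `P(accessible)_control − P(accessible)_edited` per track through a
  pluggable sequence-based accessibility predictor; sites flagged when
  `P(accessible)_control > 0.2` and damage `> 0.1`. A small seeded
  convolutional reference predictor trained on synthetic motif data is
  included.
- **Splice / expression** — cryptic splice-junction counting against the
  canonical *HBB* exon-1 donor (chr11:5,248,159, hg19) and
  delta-delta-Ct fold changes (`2^−ΔΔCt`) with the β/α-globin ratio.
- **Synthetic data** — seeded generators for every input format
  (paired FASTQ, FASTA genomes with planted off-target sites, capture
  and spliced BAMs, accessibility training sets, Ct tables) with JSON
  truth manifests; byte-identical under a fixed seed.

## Worked example

```r
library(abeprofiler)

spec <- synthetic_hbe_spec()          # synthetic stand-in HbE guide
amp  <- amplicon_testbed(spec)        # 240-bp amplicon, codon at A5-A7

# simulate a patient-like editing outcome mix and quantify it
g <- gen_amplicon_reads(amp$spec, amp$amplicon, amp$codon_interval,
                        c(AUBENAS = 0.78, WT_CORRECTED = 0.12,
                          AGG_VARIANT = 0.0074, INDEL = 0.0015,
                          HBE_UNEDITED = 0.0911),
                        n_reads = 20000, error_rate = 0.001, seed = 2)
res <- quantify_amplicon_sample(g$r1$sequence, g$r2$sequence,
                                amp$amplicon, amp$spec, amp$codon_interval,
                                r1_qual = g$r1$qualities,
                                r2_qual = g$r2$qualities)
res$table
#> Amplicon outcome table (20000 classified reads, 0 unclassified)
#>   HBE_UNEDITED           1855   0.0927
#>   WT_CORRECTED           2393   0.1197
#>   AUBENAS               15513   0.7756
#>   AGG_VARIANT             158   0.0079
#>   INDEL                    32   0.0016
#>   OTHER_SUBSTITUTION       49   0.0024
#>   editing efficiency: 0.8953
```

89.5% of classified alleles carry one of the two benign codons (editing
efficiency), 77.6% are Hb Aubenas, and the AGG bystander codon and
indels stay below 1% — recovering the planted mix to within binomial
noise.

The numbered drivers under `analysis/` run each stage of the study on
synthetic inputs and write their tables under `results/`:
`01_amplicon_outcomes.R`, `02_offtarget_nomination.R`,
`03_capture_calling.R` (prints, at depth 50,000, the called-site count,
the 52.9%-level near-homolog site and the median called frequency),
`04_damage_scores.R` (reference predictor AUROC and the flagged-site
set) and `05_splice_expression.R`.

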