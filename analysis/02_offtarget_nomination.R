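#!/usr/bin/env Rscript
# Off-target nomination funnel: in-silico mismatch enumeration over a
# simulated genome with planted near-matches, merged with CIRCLE-seq-style
# evidence, filtered to sites with an editing-window adenine, ranked, and
# turned into capture probes.

suppressMessages(library(abeprofiler))
dir.create("results", showWarnings = FALSE)
seed <- 1L

spec <- synthetic_hbe_spec()
gg <- gen_genome_with_offtargets(
  100000, spec,
  data.frame(mismatch_count = c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
             strand = c("+", "-", "+", "-", "+", "-", "+", "-")),
  seed = seed, out_dir = "results", prefix = "simulated_genome")

insilico <- enumerate_offtargets(gg$genome, spec, max_mismatches = 4)
message(sprintf("In-silico enumeration: %d candidate sites (planted %d)",
                nrow(insilico), nrow(gg$truth$planted_sites)))

# CIRCLE-seq evidence over a subset of the planted sites
planted <- gg$truth$planted_sites
keep <- seq_len(nrow(planted)) %% 2L == 1L
bed <- "results/simulated_circleseq.bed"
write_bed(data.frame(contig = planted$contig[keep],
                     start = planted$start[keep], end = planted$end[keep],
                     name = sprintf("circle%d", which(keep)),
                     score = withr::with_seed(seed, sample(100:5000,
                                                           sum(keep))),
                     strand = planted$strand[keep]), bed)
circle <- read_circleseq_sites(bed, gg$genome, spec)

merged <- merge_candidates(insilico, circle)
filtered <- filter_adenine_window(merged, spec)
top <- rank_sites(filtered, n = 250)
write_candidate_tsv(merged, "results/offtarget_candidates.tsv")
write_candidate_tsv(top, "results/offtarget_top.tsv")
probes <- design_capture_probes(top, gg$genome)
write_fasta(probes$sequences, "results/capture_probes.fa")

message(sprintf(
  "Funnel: %d merged candidates -> %d with a window adenine -> top %d captured",
  nrow(merged), nrow(filtered), nrow(top)))
message(sprintf("%d candidates carry CIRCLE-seq support",
                sum(grepl("circleseq", merged$sources))))
message("Wrote results/offtarget_candidates.tsv, results/offtarget_top.tsv, results/capture_probes.fa")
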