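#!/usr/bin/env Rscript
# Chromatin-accessibility damage scoring of candidate off-target edits:
# trains the reference convolutional accessibility predictor on the
# synthetic motif task, then scores 30 planted candidate sites (5 of
# which have edits that destroy the accessibility motif) with the damage
# statistic P(accessible)_control - P(accessible)_edited at thresholds
# 0.2 / 0.1.

suppressMessages(library(abeprofiler))
dir.create("results", showWarnings = FALSE)
seed <- 7L
spec <- synthetic_hbe_spec()

ds <- gen_accessibility_dataset(n = 4000, seed = seed)
idx <- withr::with_seed(seed + 1L, sample(length(ds$labels)))
tr <- idx[1:3000]; te <- idx[3001:4000]
model <- train_reference_predictor(
  list(sequences = ds$sequences[tr], labels = ds$labels[tr]), seed = seed)
a <- auroc(predict_accessibility(ds$sequences[te], model)[, 1],
           ds$labels[te])
message(sprintf("Reference predictor held-out AUROC: %.3f (n = %d)",
                a, length(te)))

dg <- gen_damage_genome(spec, n_sites = 30, n_damaging = 5,
                        seed = seed + 2L)
scores <- score_sites(dg$sites, dg$genome, spec, model,
                      p_threshold = 0.2, damage_threshold = 0.1)
scores$planted_damaging <- dg$truth$damaging
write.table(scores, "results/damage_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "Flagged %d/%d sites as likely chromatin-damaging (planted damaging: %d; agreement: %s)",
  sum(scores$flagged), nrow(scores), sum(dg$truth$damaging),
  ifelse(identical(scores$flagged, dg$truth$damaging), "exact", "partial")))
message("Wrote results/damage_scores.tsv")
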