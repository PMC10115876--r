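# Shared fixtures, built in code at test time.

test_spec <- function(...) synthetic_hbe_spec(...)

test_amplicon <- function(spec = test_spec()) amplicon_testbed(spec)

default_outcome_mix <- function() {
  c(AUBENAS = 0.78, WT_CORRECTED = 0.12, AGG_VARIANT = 0.0074,
    HBE_UNEDITED = 0.0926)
}

# a minimal hand-written SAM -> indexed BAM (for splice/capture edge cases)
write_test_bam <- function(lines, contigs, lengths, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "test.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contigs, as.integer(lengths)),
               lines), sam)
  Rsamtools::asBam(sam, destination = file.path(dir, "test"),
                   overwrite = TRUE, indexDestination = TRUE)
}

# one row of a candidate_sites table, by hand
hand_site <- function(contig = "chr_t", start = 100L, strand = "+",
                      protospacer, pam = "TGG", mismatch_count = 0L,
                      circleseq_read_count = NA_real_,
                      sources = "insilico") {
  start <- as.integer(start)
  df <- data.frame(contig = contig, start = start, end = start + 20L,
                   strand = strand, protospacer = protospacer, pam = pam,
                   mismatch_count = mismatch_count, sources = sources,
                   circleseq_read_count = circleseq_read_count,
                   has_adenine_in_window = NA, stringsAsFactors = FALSE)
  class(df) <- c("candidate_sites", "data.frame")
  df
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
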