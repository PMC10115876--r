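#' Merge one paired read (FLASH-style overlap consensus)
#'
#' `r2` is the reverse-strand mate and is reverse-complemented before the
#' ungapped overlap search. Among candidate overlaps of at least
#' `min_overlap` bases the lowest-mismatch-fraction overlap is chosen (ties
#' broken towards the longer overlap); if its mismatch fraction exceeds
#' `max_mismatch_frac` the merge fails, signalled by `merged = FALSE` rather
#' than an error. At overlap disagreements the higher-quality base wins.
#'
#' @param r1_seq,r2_seq Read sequences (r2 as sequenced, reverse strand).
#' @param r1_qual,r2_qual Phred+33 quality strings, same lengths as the reads.
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the overlap.
#' @return List with `sequence`, `qualities` (Phred+33 string) and logical
#'   `merged`; on failure `sequence`/`qualities` are `NA`.
#' @export
merge_read_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                            min_overlap = 10L, max_mismatch_frac = 0.25) {
  m <- merge_read_pairs(r1_seq, r1_qual, r2_seq, r2_qual,
                        min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  list(sequence = m$sequence[1], qualities = m$qualities[1],
       merged = m$merged[1])
}

#' Merge many read pairs at once
#'
#' Vectorised form of [merge_read_pair()].
#'
#' @inheritParams merge_read_pair
#' @return data.frame with columns `sequence`, `qualities`, `merged`.
#' @export
merge_read_pairs <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                             min_overlap = 10L, max_mismatch_frac = 0.25) {
  n <- length(r1_seq)
  stopifnot(length(r2_seq) == n, length(r1_qual) == n, length(r2_qual) == n)
  if (any(!nzchar(r1_seq)) || any(!nzchar(r2_seq))) {
    stop("empty read in pair input", call. = FALSE)
  }
  if (any(nchar(r1_seq) != nchar(r1_qual)) ||
      any(nchar(r2_seq) != nchar(r2_qual))) {
    stop("quality string length differs from read length", call. = FALSE)
  }
  res <- .merge_pairs_cpp(as.character(r1_seq), as.character(r1_qual),
                          as.character(r2_seq), as.character(r2_qual),
                          as.integer(min_overlap), max_mismatch_frac)
  data.frame(sequence = res$sequence, qualities = res$qualities,
             merged = res$merged, stringsAsFactors = FALSE)
}

# Alignment scoring defaults (affine gap); configurable through
# classify_allele()'s `scoring` argument.
default_scoring <- function() {
  list(match = 2, mismatch = -2, gap_open = 10, gap_extend = 1)
}

# Align one read to the amplicon and report, per 0-based reference position,
# the read base and quality, plus whether any gap touches `check_interval`
# (0-based half-open). Insertions are located at the boundary before the
# next reference base and count as overlapping when strictly inside the
# interval. Uses Biostrings' affine-gap aligner; the read is aligned end to
# end, the amplicon locally (merged amplicon reads may span a sub-interval).
align_read_to_ref <- function(seq, qual, amplicon_ref, scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(amplicon_ref),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref0 <- S4Vectors::start(Biostrings::subject(pa)) - 1L  # next ref position
  qvec <- utf8ToInt(qual) - 33L
  ri <- 0L  # read bases consumed
  npos <- length(s)
  pos_ref <- integer(0); pos_base <- character(0); pos_qual <- integer(0)
  del_ref <- integer(0); ins_at <- integer(0)
  for (k in seq_len(npos)) {
    if (s[k] != "-") {
      if (p[k] != "-") {
        ri <- ri + 1L
        pos_ref <- c(pos_ref, ref0); pos_base <- c(pos_base, p[k])
        pos_qual <- c(pos_qual, qvec[ri])
      } else {
        del_ref <- c(del_ref, ref0)
      }
      ref0 <- ref0 + 1L
    } else {
      ri <- ri + 1L
      ins_at <- c(ins_at, ref0)
    }
  }
  list(pos_ref = pos_ref, pos_base = pos_base, pos_qual = pos_qual,
       del_ref = del_ref, ins_at = ins_at)
}

gap_overlaps <- function(aln, lo, hi) {  # [lo, hi) 0-based half-open
  any(aln$del_ref >= lo & aln$del_ref < hi) ||
    any(aln$ins_at > lo & aln$ins_at < hi)
}

#' Classify the editing outcome of one merged amplicon read
#'
#' The read is aligned to the amplicon with an affine-gap aligner
#' (defaults: match +2, mismatch -2, gap open -10, gap extend -1). Any
#' alignment gap overlapping the editing window or the codon yields
#' `INDEL`; otherwise the codon is read out and mapped
#' AAG -> `HBE_UNEDITED`, GAG -> `WT_CORRECTED`, GGG -> `AUBENAS`,
#' AGG -> `AGG_VARIANT`, anything else -> `OTHER_SUBSTITUTION`. Reads not
#' covering the codon, or with any codon base below `min_base_quality`,
#' are `UNCLASSIFIED`.
#'
#' @param sequence Merged read sequence.
#' @param qualities Phred+33 quality string of the same length.
#' @param amplicon_ref Amplicon reference sequence (contains the protospacer).
#' @param spec [protospacer_spec()] whose `locus` gives the protospacer
#'   interval in amplicon coordinates.
#' @param codon_interval [genomic_interval()] of the 3-base codon on the
#'   amplicon (0-based half-open).
#' @param min_base_quality Minimum Phred quality of each codon base.
#' @param scoring Alignment scoring list
#'   (`match`, `mismatch`, `gap_open`, `gap_extend`).
#' @return One of [allele_outcome_levels()].
#' @export
classify_allele <- function(sequence, qualities, amplicon_ref, spec,
                            codon_interval, min_base_quality = 20L,
                            scoring = default_scoring()) {
  classify_alleles(sequence, qualities, amplicon_ref, spec, codon_interval,
                   min_base_quality = min_base_quality, scoring = scoring)[1]
}

#' Classify many merged reads
#'
#' Vectorised [classify_allele()]. Reads whose length equals the amplicon
#' and whose Hamming distance to it is small are classified without dynamic
#' programming (a gapless alignment is then provably optimal under the
#' affine scores); all other reads take the full affine-gap alignment path.
#'
#' @inheritParams classify_allele
#' @param sequences,qualities Character vectors of merged reads/qualities;
#'   `NA` entries (failed merges) come back `UNCLASSIFIED`.
#' @return Character vector of outcome categories.
#' @export
classify_alleles <- function(sequences, qualities, amplicon_ref, spec,
                             codon_interval, min_base_quality = 20L,
                             scoring = default_scoring()) {
  stopifnot(inherits(spec, "protospacer_spec"), !is.null(spec$locus),
            inherits(codon_interval, "genomic_interval"))
  amplicon_ref <- toupper(amplicon_ref)
  L <- nchar(amplicon_ref)
  win_ref <- protospacer_to_ref(spec$locus, spec$editing_window[1]:spec$editing_window[2])
  win_lo <- min(win_ref); win_hi <- max(win_ref) + 1L
  cs <- codon_interval$start; ce <- codon_interval$end
  stopifnot(ce - cs == 3L)
  n <- length(sequences)
  out <- character(n)
  codon_map <- outcome_codons()

  read_codon <- function(bases, quals) {
    if (any(is.na(bases))) return("UNCLASSIFIED")
    if (any(quals < min_base_quality)) return("UNCLASSIFIED")
    codon <- paste(bases, collapse = "")
    if (codon %in% names(codon_map)) unname(codon_map[codon])
    else "OTHER_SUBSTITUTION"
  }

  # Gapless fast path: equal length and few mismatches. With gap penalties
  # open 10 / extend 1 and mismatch -2, any aligned indel pair costs >= 22
  # while <= 5 mismatches cost <= 20, so the gapless alignment is optimal.
  hamming_ok <- rep(FALSE, n)
  eq_len <- !is.na(sequences) & nchar(sequences) == L
  for (i in which(eq_len)) {
    hamming_ok[i] <- .hamming_scan_cpp(sequences[i], amplicon_ref)[1] <= 5L
  }
  for (i in seq_len(n)) {
    if (is.na(sequences[i])) { out[i] <- "UNCLASSIFIED"; next }
    if (hamming_ok[i]) {
      bases <- strsplit(substr(sequences[i], cs + 1L, ce), "")[[1]]
      quals <- utf8ToInt(substr(qualities[i], cs + 1L, ce)) - 33L
      out[i] <- read_codon(bases, quals)
      next
    }
    aln <- align_read_to_ref(sequences[i], qualities[i], amplicon_ref, scoring)
    if (gap_overlaps(aln, win_lo, win_hi) || gap_overlaps(aln, cs, ce)) {
      out[i] <- "INDEL"
      next
    }
    idx <- match((cs):(ce - 1L), aln$pos_ref)
    out[i] <- read_codon(aln$pos_base[idx],
                         if (anyNA(idx)) rep(0L, 3) else aln$pos_qual[idx])
  }
  out
}

#' Summarise classified outcomes into an outcome table
#'
#' Frequencies are over classified reads (everything except
#' `UNCLASSIFIED`); editing efficiency is the corrected fraction,
#' `(WT_CORRECTED + AUBENAS) / total_classified` by default — the sum of
#' the two benign outcomes, mirroring how allele "correction" is reported
#' for this strategy. Which categories count as corrected is configurable.
#'
#' @param outcomes Character vector of [allele_outcome_levels()] values.
#' @param correction_categories Categories counted as corrected alleles.
#' @return An `outcome_table`: list with `counts`, `total_classified`,
#'   `frequencies`, `editing_efficiency`, `indel_frequency`,
#'   `n_unclassified` and `defined` (FALSE when no read classified).
#' @export
summarize_outcomes <- function(outcomes,
                               correction_categories = c("WT_CORRECTED",
                                                         "AUBENAS")) {
  lev <- allele_outcome_levels()
  bad <- setdiff(unique(outcomes), lev)
  if (length(bad)) stop("unknown outcome categories: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(outcomes, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  classified <- setdiff(lev, "UNCLASSIFIED")
  total <- sum(counts[classified])
  defined <- total > 0L
  freqs <- if (defined) counts[classified] / total else
    stats::setNames(rep(0, length(classified)), classified)
  structure(list(
    counts = counts,
    total_classified = total,
    n_unclassified = counts[["UNCLASSIFIED"]],
    frequencies = freqs,
    editing_efficiency = if (defined)
      sum(counts[correction_categories]) / total else NA_real_,
    indel_frequency = if (defined) counts[["INDEL"]] / total else NA_real_,
    defined = defined
  ), class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Amplicon outcome table (", x$total_classified, " classified reads, ",
      x$n_unclassified, " unclassified)\n", sep = "")
  for (k in names(x$frequencies)) {
    cat(sprintf("  %-18s %8d  %7.4f\n", k, x$counts[[k]], x$frequencies[[k]]))
  }
  cat(sprintf("  editing efficiency: %s\n",
              ifelse(x$defined, sprintf("%.4f", x$editing_efficiency), "NA")))
  invisible(x)
}

#' Quantify editing outcomes for one amplicon sample
#'
#' Chains pair merging, per-read classification and outcome summarisation;
#' reads failing the merge are excluded from classification and reported in
#' the QC block.
#'
#' @param r1,r2 Character vectors of paired read sequences (r2 reverse
#'   strand), or paths to FASTQ files.
#' @param r1_qual,r2_qual Quality strings (ignored when FASTQ paths given).
#' @param amplicon_ref Amplicon reference sequence.
#' @inheritParams classify_allele
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @return List with `table` (an `outcome_table`) and `qc`
#'   (`n_pairs`, `n_merged`, `n_merge_failed`).
#' @export
quantify_amplicon_sample <- function(r1, r2, amplicon_ref, spec,
                                     codon_interval,
                                     r1_qual = NULL, r2_qual = NULL,
                                     min_base_quality = 20L,
                                     min_overlap = 10L,
                                     max_mismatch_frac = 0.25,
                                     scoring = default_scoring()) {
  if (length(r1) == 1L && file.exists(r1)) {
    fq1 <- read_fastq(r1); fq2 <- read_fastq(r2)
    r1 <- fq1$sequence; r1_qual <- fq1$qualities
    r2 <- fq2$sequence; r2_qual <- fq2$qualities
  }
  merged <- merge_read_pairs(r1, r1_qual, r2, r2_qual,
                             min_overlap = min_overlap,
                             max_mismatch_frac = max_mismatch_frac)
  keep <- merged$merged
  outcomes <- classify_alleles(merged$sequence[keep], merged$qualities[keep],
                               amplicon_ref, spec, codon_interval,
                               min_base_quality = min_base_quality,
                               scoring = scoring)
  list(table = summarize_outcomes(outcomes),
       qc = list(n_pairs = nrow(merged), n_merged = sum(keep),
                 n_merge_failed = sum(!keep)))
}

#' Write an outcome table row as TSV
#'
#' One row per sample: category counts and frequencies, editing efficiency,
#' indel frequency and QC counts.
#'
#' @param tables Named list of results from [quantify_amplicon_sample()].
#' @param path Output TSV path.
#' @return The data.frame written, invisibly.
#' @export
write_outcome_tsv <- function(tables, path) {
  rows <- lapply(names(tables), function(nm) {
    x <- tables[[nm]]
    tb <- x$table
    row <- c(list(sample = nm),
             as.list(tb$counts),
             stats::setNames(as.list(tb$frequencies),
                             paste0("freq_", names(tb$frequencies))),
             list(editing_efficiency = tb$editing_efficiency,
                  indel_frequency = tb$indel_frequency,
                  n_pairs = x$qc$n_pairs, n_merged = x$qc$n_merged,
                  n_merge_failed = x$qc$n_merge_failed))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
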