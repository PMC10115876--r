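#' Describe a protospacer (guide target)
#'
#' A `protospacer_spec` captures the 20-nt spacer, its PAM pattern, the
#' genomic locus of the on-target protospacer, the deaminase editing window
#' and the protospacer positions of primary interest. Protospacer positions
#' are 1-based counted from the PAM-distal end, so for the HbE guide the
#' target adenine is A5 and the bystander is A6. The editing window is a
#' required, documented configurable; `[4, 8]` is the default span containing
#' both adenines.
#'
#' @param spacer 20-nt spacer sequence, 5'->3', position 1 PAM-distal.
#' @param pam_pattern IUPAC pattern immediately 3' of the protospacer
#'   (e.g. `"NGG"` for SpCas9 editors, `"NG"` for NG-relaxed editors).
#' @param locus Optional [genomic_interval()] of the on-target protospacer.
#' @param editing_window Inclusive 1-based protospacer position range,
#'   length-2 integer vector within `[1, 20]`.
#' @param target_positions Protospacer positions of primary interest; must
#'   lie inside `editing_window`.
#' @return An object of class `protospacer_spec`.
#' @export
protospacer_spec <- function(spacer, pam_pattern = "NGG", locus = NULL,
                             editing_window = c(4L, 8L),
                             target_positions = c(5L, 6L)) {
  spacer <- toupper(as.character(spacer))
  if (nchar(spacer) != 20L) {
    stop("spacer must be exactly 20 nt, got ", nchar(spacer), call. = FALSE)
  }
  check_dna(spacer, allow_iupac = FALSE)
  pam_pattern <- toupper(as.character(pam_pattern))
  if (nchar(pam_pattern) < 1L) stop("pam_pattern must be nonempty", call. = FALSE)
  bad <- !strsplit(pam_pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (any(bad)) stop("pam_pattern contains non-IUPAC symbols", call. = FALSE)
  editing_window <- as.integer(editing_window)
  if (length(editing_window) != 2L || anyNA(editing_window) ||
      editing_window[1] < 1L || editing_window[2] > 20L ||
      editing_window[1] > editing_window[2]) {
    stop("editing_window must be [low, high] within 1..20 with low <= high",
         call. = FALSE)
  }
  target_positions <- sort(unique(as.integer(target_positions)))
  if (!all(target_positions >= editing_window[1] &
           target_positions <= editing_window[2])) {
    stop("target_positions must lie inside editing_window", call. = FALSE)
  }
  if (!is.null(locus)) stopifnot(inherits(locus, "genomic_interval"))
  structure(
    list(spacer = spacer, pam_pattern = pam_pattern, locus = locus,
         editing_window = editing_window, target_positions = target_positions),
    class = "protospacer_spec"
  )
}

#' @export
print.protospacer_spec <- function(x, ...) {
  cat("protospacer_spec\n")
  cat("  spacer:        ", x$spacer, "\n")
  cat("  PAM pattern:   ", x$pam_pattern, "\n")
  cat("  window:        [", x$editing_window[1], ",", x$editing_window[2], "]\n")
  cat("  target pos:    ", paste(x$target_positions, collapse = ", "), "\n")
  if (!is.null(x$locus)) {
    cat("  locus:         ", format_interval(x$locus), "\n")
  }
  invisible(x)
}

#' Synthetic stand-in HbE guide
#'
#' The guide sequence used against the HbE codon is supplementary material
#' of the originating study and is treated as configuration, never
#' hard-coded into analyses. This constructor returns a synthetic
#' stand-in guide with the same geometry — the HbE codon AAG at
#' protospacer positions 5-7, so the target adenine is A5 and the
#' bystander A6, with an NGG PAM — for use by the simulators, examples
#' and tests.
#'
#' @inheritParams protospacer_spec
#' @return A [protospacer_spec()].
#' @export
synthetic_hbe_spec <- function(editing_window = c(4L, 8L),
                               target_positions = c(5L, 6L)) {
  protospacer_spec("CTGTAAGGTCACCTTGCAGC", "NGG",
                   editing_window = editing_window,
                   target_positions = target_positions)
}

#' Genomic interval (0-based half-open)
#'
#' Internal coordinate convention is 0-based half-open, matching BED/BAM;
#' 1-based coordinates appear only at report/VCF boundaries.
#'
#' @param contig Contig/chromosome name.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(c(start, end)) || start < 0L || start >= end) {
    stop("need 0 <= start < end (0-based half-open)", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(contig = as.character(contig), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

format_interval <- function(x) {
  sprintf("%s:%d-%d(%s)", x$contig, x$start, x$end, x$strand)
}

#' Allele outcome categories at the HbE codon
#'
#' The codon-26 AAG (HbE, E26K) can be deaminated to GAG (wild-type,
#' A5 edited), GGG (Hb Aubenas, A5+A6 edited) or AGG (A6-only bystander
#' edit). Classification is mutually exclusive and exhaustive over these
#' plus INDEL, OTHER_SUBSTITUTION and UNCLASSIFIED.
#'
#' @return Character vector of the outcome levels, in canonical order.
#' @export
allele_outcome_levels <- function() {
  c("HBE_UNEDITED", "WT_CORRECTED", "AUBENAS", "AGG_VARIANT",
    "INDEL", "OTHER_SUBSTITUTION", "UNCLASSIFIED")
}

#' Codon strings attached to the codon-level outcome categories
#'
#' @return Named character vector mapping codon to outcome category.
#' @export
outcome_codons <- function() {
  c(AAG = "HBE_UNEDITED", GAG = "WT_CORRECTED",
    GGG = "AUBENAS", AGG = "AGG_VARIANT")
}

check_dna <- function(seq, allow_iupac = TRUE) {
  ok <- if (allow_iupac) {
    c(names(Biostrings::IUPAC_CODE_MAP))
  } else c("A", "C", "G", "T", "N")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop("non-nucleotide character '", chars[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA sequence
#'
#' Accepts IUPAC ambiguity codes; an empty string returns an empty string.
#' Applying the function twice returns the input (involution).
#'
#' @param seq DNA string over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) return("")
  check_dna(seq, allow_iupac = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Match a DNA sequence against an IUPAC pattern
#'
#' `TRUE` iff every base of `seq` belongs to the IUPAC class of the
#' corresponding pattern symbol; used for PAM matching (`"NGG"`, `"NG"`).
#' Ambiguity codes in `seq` itself are compared literally, so an `N` base
#' does not satisfy an `N` pattern class (`N` expands to `ACGT` only).
#'
#' @param pattern IUPAC pattern string.
#' @param seq DNA string of the same length.
#' @return Logical scalar.
#' @export
iupac_match <- function(pattern, seq) {
  pattern <- toupper(as.character(pattern))
  seq <- toupper(as.character(seq))
  if (nchar(pattern) != nchar(seq)) {
    stop("pattern and seq must have equal length (", nchar(pattern), " vs ",
         nchar(seq), ")", call. = FALSE)
  }
  if (!nzchar(pattern)) return(TRUE)
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  classes <- Biostrings::IUPAC_CODE_MAP[p]
  if (anyNA(classes)) stop("pattern contains non-IUPAC symbols", call. = FALSE)
  all(mapply(function(cls, base) {
    grepl(base, cls, fixed = TRUE)
  }, classes, s))
}

#' Map protospacer positions to 0-based reference coordinates
#'
#' Window positions always refer to the protospacer strand; for a
#' minus-strand protospacer the reference base at the returned coordinate is
#' the complement of the protospacer-strand base (the deaminated A appears
#' as T->C on the reference).
#'
#' @param interval [genomic_interval()] of the 20-nt protospacer.
#' @param positions 1-based protospacer positions (PAM-distal end = 1).
#' @return Integer vector of 0-based reference coordinates.
#' @export
protospacer_to_ref <- function(interval, positions) {
  positions <- as.integer(positions)
  stopifnot(all(positions >= 1L & positions <= 20L))
  if (interval$strand == "+") {
    interval$start + positions - 1L
  } else {
    interval$end - positions
  }
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA path (wrapped lines supported).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb")  # binary mode: LF-only, byte-reproducible
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(sprintf(">%s", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a BED6 file of intervals (optionally with extra numeric columns)
#'
#' @param path BED path.
#' @return data.frame with contig, start, end, name, score, strand and any
#'   additional columns (`extra1`, ...). Coordinates stay 0-based half-open.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  base_names <- c("contig", "start", "end", "name", "score", "strand")
  n <- ncol(x)
  names(x) <- c(base_names[seq_len(min(n, 6L))],
                if (n > 6L) paste0("extra", seq_len(n - 6L)))
  x
}

#' Write intervals as BED6
#'
#' @param df data.frame with contig, start, end and optionally name, score,
#'   strand columns (0-based half-open coordinates).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    contig = df$contig,
    start = df$start,
    end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0L,
    strand = if ("strand" %in% names(df)) df$strand else "+"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", out$contig,
                     as.integer(out$start), as.integer(out$end),
                     as.character(out$name), as.character(out$score),
                     as.character(out$strand)), con, sep = "\n")
  invisible(path)
}
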