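#' Candidate off-target site tables
#'
#' Candidate sites are plain data.frames of class `candidate_sites` with
#' columns `contig`, `start`, `end` (0-based half-open, the 20-nt
#' protospacer span), `strand`, `protospacer` (protospacer-strand
#' sequence), `pam` (observed PAM, protospacer strand), `mismatch_count`
#' (vs the spacer), `sources` (comma-joined subset of
#' `insilico`/`circleseq`), `circleseq_read_count` and
#' `has_adenine_in_window`.
#'
#' @name candidate_sites
NULL

new_candidate_sites <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("candidate_sites", "data.frame")
  df
}

site_ids <- function(sites) {
  sprintf("%s:%d-%d(%s)", sites$contig, sites$start, sites$end, sites$strand)
}

# vectorised IUPAC pattern match of many equal-length sequences
iupac_match_many <- function(pattern, seqs) {
  if (!length(seqs)) return(logical(0))
  p <- strsplit(toupper(pattern), "")[[1]]
  ok <- rep(TRUE, length(seqs))
  for (k in seq_along(p)) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[p[k]]], "")[[1]]
    ok <- ok & substr(seqs, k, k) %in% allowed
  }
  ok
}

adenine_in_window <- function(protospacer, editing_window) {
  win <- substr(protospacer, editing_window[1], editing_window[2])
  !is.na(win) & grepl("A", win, fixed = TRUE)
}

#' Enumerate candidate off-target sites by mismatch search
#'
#' Scans both strands of every contig for 20-nt windows within
#' `max_mismatches` Hamming distance of the spacer whose adjacent 3' bases
#' match the PAM pattern (IUPAC). Each qualifying window is returned exactly
#' once with its strand, 0-based coordinates and mismatch count, sorted by
#' (contig, start, strand). Bulges (gapped matches) are not searched.
#'
#' @param genome Named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param spec [protospacer_spec()]; the spacer must be N-free.
#' @param max_mismatches Maximum Hamming distance, at most 8.
#' @return A [candidate_sites] data.frame with `sources = "insilico"`.
#' @export
enumerate_offtargets <- function(genome, spec, max_mismatches = 4L) {
  stopifnot(inherits(spec, "protospacer_spec"))
  if (grepl("N", spec$spacer, fixed = TRUE)) {
    stop("spacer must not contain N for off-target enumeration", call. = FALSE)
  }
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches > 8L) stop("max_mismatches must be <= 8", call. = FALSE)
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  spacer <- Biostrings::DNAString(spec$spacer)
  plen <- nchar(spec$pam_pattern)
  rows <- list()
  for (contig in names(genome)) {
    cseq <- toupper(genome[[contig]])
    L <- nchar(cseq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cseq else reverse_complement(cseq)
      m <- Biostrings::matchPattern(spacer, Biostrings::DNAString(s),
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      st <- S4Vectors::start(m)
      st <- st[st >= 1L & st + 19L + plen <= nchar(s)]
      if (!length(st)) next
      proto <- substring(s, st, st + 19L)
      pam <- substring(s, st + 20L, st + 19L + plen)
      keep <- iupac_match_many(spec$pam_pattern, pam)
      st <- st[keep]; proto <- proto[keep]; pam <- pam[keep]
      if (!length(st)) next
      mm <- vapply(proto, function(p) {
        sum(utf8ToInt(p) != utf8ToInt(spec$spacer))
      }, integer(1), USE.NAMES = FALSE)
      if (strand == "+") {
        start0 <- st - 1L; end0 <- st + 19L
      } else {
        start0 <- L - st - 19L; end0 <- L - st + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = start0, end = end0, strand = strand,
        protospacer = proto, pam = pam, mismatch_count = mm,
        sources = "insilico", circleseq_read_count = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), protospacer = character(0), pam = character(0),
    mismatch_count = integer(0), sources = character(0),
    circleseq_read_count = numeric(0), stringsAsFactors = FALSE)
  df$has_adenine_in_window <- adenine_in_window(df$protospacer,
                                                spec$editing_window)
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  new_candidate_sites(df)
}

#' Read CIRCLE-seq nominated sites
#'
#' Accepts BED6 plus a numeric read-count column (column 7 if present,
#' otherwise the BED score column is used as the read count). When the
#' genome and spec are supplied the protospacer-strand sequence, observed
#' PAM and mismatch count are filled in from the reference.
#'
#' @param path BED path.
#' @param genome Optional named character vector of contig sequences.
#' @param spec Optional [protospacer_spec()].
#' @return A [candidate_sites] data.frame with `sources = "circleseq"`.
#' @export
read_circleseq_sites <- function(path, genome = NULL, spec = NULL) {
  bed <- read_bed(path)
  count <- if ("extra1" %in% names(bed)) as.numeric(bed$extra1)
           else as.numeric(bed$score)
  proto <- rep(NA_character_, nrow(bed))
  pam <- rep(NA_character_, nrow(bed))
  mm <- rep(NA_integer_, nrow(bed))
  if (!is.null(genome) && !is.null(spec)) {
    plen <- nchar(spec$pam_pattern)
    for (i in seq_len(nrow(bed))) {
      cseq <- genome[[bed$contig[i]]]
      if (is.null(cseq)) next
      if (bed$strand[i] == "+") {
        proto[i] <- substr(cseq, bed$start[i] + 1L, bed$end[i])
        pam[i] <- substr(cseq, bed$end[i] + 1L, bed$end[i] + plen)
      } else {
        proto[i] <- reverse_complement(substr(cseq, bed$start[i] + 1L,
                                              bed$end[i]))
        pam[i] <- reverse_complement(substr(cseq, bed$start[i] - plen + 1L,
                                            bed$start[i]))
      }
      if (!is.na(proto[i]) && nchar(proto[i]) == 20L) {
        mm[i] <- sum(utf8ToInt(proto[i]) != utf8ToInt(spec$spacer))
      }
    }
  }
  df <- data.frame(contig = bed$contig, start = bed$start, end = bed$end,
                   strand = bed$strand, protospacer = proto, pam = pam,
                   mismatch_count = mm, sources = "circleseq",
                   circleseq_read_count = count, stringsAsFactors = FALSE)
  df$has_adenine_in_window <- if (is.null(spec)) NA else
    adenine_in_window(df$protospacer, spec$editing_window)
  new_candidate_sites(df[order(df$contig, df$start, df$strand), , drop = FALSE])
}

#' Merge candidate site lists
#'
#' Sites whose intervals share at least one base on the same strand are
#' unified: sources are unioned, the CIRCLE-seq read count is the maximum
#' and the mismatch count the minimum over members; the representative
#' coordinates and protospacer are those of the lowest-mismatch member
#' (ties towards the leftmost). Commutative; the merged list is never
#' larger than the concatenation of the inputs.
#'
#' @param ... One or more [candidate_sites] data.frames.
#' @return A merged [candidate_sites] data.frame.
#' @export
merge_candidates <- function(...) {
  lists <- list(...)
  lists <- lists[vapply(lists, nrow, integer(1)) > 0L]
  if (!length(lists)) {
    return(new_candidate_sites(data.frame(
      contig = character(0), start = integer(0), end = integer(0),
      strand = character(0), protospacer = character(0), pam = character(0),
      mismatch_count = integer(0), sources = character(0),
      circleseq_read_count = numeric(0),
      has_adenine_in_window = logical(0), stringsAsFactors = FALSE)))
  }
  df <- do.call(rbind, lapply(lists, as.data.frame))
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  ov <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  # connected components by union-find over the overlap graph
  parent <- seq_len(nrow(df))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (k in seq_along(qh)) {
    a <- find(qh[k]); b <- find(sh[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nrow(df)), find, integer(1))
  rows <- lapply(unname(split(seq_len(nrow(df)), comp)), function(idx) {
    sub <- df[idx, , drop = FALSE]
    mmv <- sub$mismatch_count
    key <- order(ifelse(is.na(mmv), .Machine$integer.max, mmv), sub$start)
    rep_row <- sub[key[1], , drop = FALSE]
    rep_row$sources <- paste(sort(unique(unlist(
      strsplit(sub$sources, ",", fixed = TRUE)))), collapse = ",")
    rep_row$circleseq_read_count <- if (all(is.na(sub$circleseq_read_count)))
      NA_real_ else max(sub$circleseq_read_count, na.rm = TRUE)
    rep_row$mismatch_count <- if (all(is.na(mmv))) NA_integer_ else
      min(mmv, na.rm = TRUE)
    rep_row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  new_candidate_sites(out)
}

#' Annotate sites with the adenine-in-window flag
#'
#' @param sites A [candidate_sites] data.frame.
#' @param spec [protospacer_spec()].
#' @return `sites` with `has_adenine_in_window` recomputed from the
#'   protospacer-strand sequence and the editing window.
#' @export
annotate_adenine_window <- function(sites, spec) {
  sites$has_adenine_in_window <- adenine_in_window(sites$protospacer,
                                                   spec$editing_window)
  sites
}

#' Keep only sites with an adenine in the editing window
#'
#' A site is retained iff its protospacer-strand sequence carries at least
#' one `A` at a position inside the editing window (minus-strand sites show
#' the adenine as `T` on the reference plus strand). Idempotent.
#'
#' @inheritParams annotate_adenine_window
#' @return The retained subset, flag set.
#' @export
filter_adenine_window <- function(sites, spec) {
  sites <- annotate_adenine_window(sites, spec)
  new_candidate_sites(sites[sites$has_adenine_in_window, , drop = FALSE])
}

#' Rank sites and take the top n
#'
#' Ordering: CIRCLE-seq read count descending (sites without CIRCLE-seq
#' evidence count as zero reads), then mismatch count ascending, then
#' (contig, start, strand). Deterministic under permutation of the input.
#'
#' @param sites A [candidate_sites] data.frame.
#' @param n Number of sites to keep (default 250).
#' @return The first `min(n, nrow)` sites in rank order.
#' @export
rank_sites <- function(sites, n = 250L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  rc <- ifelse(is.na(sites$circleseq_read_count), 0,
               sites$circleseq_read_count)
  mm <- ifelse(is.na(sites$mismatch_count), .Machine$integer.max,
               sites$mismatch_count)
  ord <- order(-rc, mm, sites$contig, sites$start, sites$strand)
  new_candidate_sites(utils::head(sites[ord, , drop = FALSE], n))
}

#' Design capture probes centred on candidate protospacers
#'
#' Emits fixed-width plus-strand probe sequences centred on each
#' protospacer (capture-bait style; melting temperature is not optimised).
#'
#' @param sites A [candidate_sites] data.frame.
#' @param genome Named character vector of contig sequences.
#' @param probe_width Probe length in bp (default 120).
#' @return List with `bed` (probe intervals, 0-based) and `sequences`
#'   (named character vector).
#' @export
design_capture_probes <- function(sites, genome, probe_width = 120L) {
  mid <- (sites$start + sites$end) %/% 2L
  half <- probe_width %/% 2L
  start0 <- pmax(0L, mid - half)
  lens <- nchar(genome[sites$contig])
  start0 <- pmin(start0, pmax(0L, lens - probe_width))
  end0 <- start0 + probe_width
  seqs <- substring(genome[sites$contig], start0 + 1L, end0)
  names(seqs) <- site_ids(sites)
  list(bed = data.frame(contig = sites$contig, start = start0, end = end0,
                        name = site_ids(sites), score = 0L,
                        strand = "+", stringsAsFactors = FALSE),
       sequences = seqs)
}

#' Write a candidate site table as TSV
#'
#' @param sites A [candidate_sites] data.frame.
#' @param path Output path.
#' @export
write_candidate_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
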