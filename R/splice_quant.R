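#' Count splice junctions in a region
#'
#' Extracts every skipped-region (CIGAR `N`) operation from spliced
#' alignments overlapping `region`; each skip in a passing read contributes
#' one count to its (donor, acceptor) key, so multi-intron reads contribute
#' one count per skip. The donor coordinate is the 1-based reference
#' position of the last exonic base before the skip (the convention in
#' which chr11:5,248,159 is the canonical HBB exon-1 donor, hg19); the
#' acceptor is the 1-based first exonic base after it.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param region [genomic_interval()] to read alignments from.
#' @param canonical_donor 1-based reference position of the canonical
#'   donor.
#' @param min_map_quality Minimum mapping quality.
#' @return A `junction_table`: list with `counts` (data.frame `donor`,
#'   `acceptor`, `count`), `canonical_donor`, `total`.
#' @export
count_junctions <- function(bam, region, canonical_donor,
                            min_map_quality = 0L) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!region$contig %in% names(hdr)) {
    stop("contig '", region$contig, "' absent from BAM header",
         call. = FALSE)
  }
  which <- GenomicRanges::GRanges(region$contig,
                                  IRanges::IRanges(region$start + 1L,
                                                   region$end))
  param <- Rsamtools::ScanBamParam(which = which,
                                   mapqFilter = as.integer(min_map_quality))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  introns <- unlist(GenomicAlignments::junctions(gal), use.names = FALSE)
  if (length(introns)) {
    donor <- GenomicRanges::start(introns) - 1L   # last exonic base
    acceptor <- GenomicRanges::end(introns) + 1L  # first exonic base after
    tab <- as.data.frame(table(donor = donor, acceptor = acceptor),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    counts <- data.frame(donor = as.integer(tab$donor),
                         acceptor = as.integer(tab$acceptor),
                         count = as.integer(tab$Freq))
    counts <- counts[order(counts$donor, counts$acceptor), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(donor = integer(0), acceptor = integer(0),
                         count = integer(0))
  }
  structure(list(counts = counts,
                 canonical_donor = as.integer(canonical_donor),
                 total = sum(counts$count)),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat("Junction table:", x$total, "skip operations; canonical donor",
      x$canonical_donor, "\n")
  print(x$counts)
  invisible(x)
}

#' Fraction of aberrantly spliced junctions
#'
#' The fraction of junction counts whose donor differs from the canonical
#' donor. With no junctions the fraction is undefined (`NA` with
#' `attr(, "defined") = FALSE`).
#'
#' @param table A `junction_table` from [count_junctions()].
#' @return Fraction in [0, 1] (or flagged `NA`).
#' @export
aberrant_fraction <- function(table) {
  stopifnot(inherits(table, "junction_table"))
  if (table$total == 0L) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  aberrant <- sum(table$counts$count[table$counts$donor !=
                                       table$canonical_donor])
  out <- aberrant / table$total
  attr(out, "defined") <- TRUE
  out
}

#' Write a junction table as TSV
#'
#' @param table A `junction_table`.
#' @param path Output path.
#' @export
write_junction_tsv <- function(table, path) {
  df <- table$counts
  df$canonical <- df$donor == table$canonical_donor
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
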