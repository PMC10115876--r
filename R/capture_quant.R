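#' Per-position deamination pileup at a candidate site
#'
#' Counts protospacer-strand A, G and other bases at every editing-window
#' position of one captured site, from a coordinate-sorted, indexed BAM.
#' For minus-strand sites the reference shows the deamination as T->C, so
#' reference T counts as protospacer A and reference C as protospacer G.
#' Duplicates are not removed: legitimate capture depth exceeds library
#' complexity at these depths.
#'
#' @param bam Path to an indexed BAM file.
#' @param site One row of a [candidate_sites] data.frame.
#' @param spec [protospacer_spec()].
#' @param min_base_quality Minimum base quality (default Q30).
#' @param min_map_quality Minimum mapping quality (default 20).
#' @return data.frame with `position` (protospacer position), `ref_pos0`
#'   (0-based reference coordinate), `proto_base` (protospacer-strand
#'   reference base), `editable` (TRUE where that base is A), `depth`,
#'   `count_A`, `count_G`, `count_other` and `freq` (G / depth). Depth is
#'   conserved: `count_A + count_G + count_other == depth` everywhere.
#'   Deamination can only occur at editable positions; downstream calling
#'   restricts itself to them.
#' @export
pileup_deamination <- function(bam, site, spec, min_base_quality = 30L,
                               min_map_quality = 20L) {
  stopifnot(inherits(spec, "protospacer_spec"))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!site$contig %in% names(hdr)) {
    stop("contig '", site$contig, "' absent from BAM header", call. = FALSE)
  }
  positions <- spec$editing_window[1]:spec$editing_window[2]
  iv <- genomic_interval(site$contig, site$start, site$end, site$strand)
  ref0 <- protospacer_to_ref(iv, positions)
  which <- GenomicRanges::GRanges(site$contig,
                                  IRanges::IRanges(min(ref0) + 1L,
                                                   max(ref0) + 1L))
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_base_quality),
                               min_mapq = as.integer(min_map_quality),
                               min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  sb <- Rsamtools::ScanBamParam(which = which)
  pu <- Rsamtools::pileup(bam, scanBamParam = sb, pileupParam = pp)
  a_base <- if (site$strand == "+") "A" else "T"
  g_base <- if (site$strand == "+") "G" else "C"
  proto_base <- if (!is.null(site$protospacer) && !is.na(site$protospacer)) {
    strsplit(site$protospacer, "")[[1]][positions]
  } else rep(NA_character_, length(positions))
  out <- data.frame(position = positions, ref_pos0 = ref0,
                    proto_base = proto_base,
                    editable = !is.na(proto_base) & proto_base == "A",
                    depth = 0L, count_A = 0L, count_G = 0L, count_other = 0L)
  for (k in seq_along(ref0)) {
    sub <- pu[pu$pos == ref0[k] + 1L, , drop = FALSE]
    if (!nrow(sub)) next
    cnt <- stats::setNames(sub$count, as.character(sub$nucleotide))
    ca <- sum(cnt[names(cnt) == a_base])
    cg <- sum(cnt[names(cnt) == g_base])
    tot <- sum(cnt)
    out$count_A[k] <- ca
    out$count_G[k] <- cg
    out$count_other[k] <- tot - ca - cg
    out$depth[k] <- tot
  }
  out$freq <- ifelse(out$depth > 0, out$count_G / out$depth, NA_real_)
  out
}

# one-sided exact test for an excess of G in the edited sample at one
# position: hypergeometric tail, identical to fisher.test(alternative =
# "greater") on the 2x2 table (edited/control x G/not-G), vectorised.
fisher_greater_p <- function(g_edit, n_edit, g_ctrl, n_ctrl) {
  stats::phyper(g_edit - 1, m = g_edit + g_ctrl,
                n = (n_edit - g_edit) + (n_ctrl - g_ctrl),
                k = n_edit, lower.tail = FALSE)
}

#' Call off-target editing at one site against a control
#'
#' Per editable window position (protospacer-strand reference base A), a
#' one-sided Fisher exact test for an excess of protospacer-strand G in
#' the edited sample over the control; non-editable positions cannot be
#' deaminated and are excluded. The site p-value is the minimum positional
#' p-value Bonferroni-adjusted by the number of positions tested; a site
#' is called when its (q-)value is at most `alpha`
#' and its maximum per-position frequency exceeds the control's. When used
#' standalone the q-value equals the p-value; across many sites use
#' [call_offtarget_sites()], which applies Benjamini-Hochberg adjustment.
#'
#' @param edited,control Per-position count data.frames from
#'   [pileup_deamination()] (same positions in both).
#' @param alpha Significance level (default 0.05).
#' @param aggregate `"min_p"` (default: minimum Bonferroni-adjusted
#'   positional p) or `"max_freq"` (test only the max-frequency position).
#' @return List with `p_value`, `q_value`, `max_deam_freq`,
#'   `control_max_freq`, `mean_depth`, `called`, `uncallable`.
#' @export
call_offtarget_editing <- function(edited, control, alpha = 0.05,
                                   aggregate = c("min_p", "max_freq")) {
  aggregate <- match.arg(aggregate)
  stopifnot(identical(edited$position, control$position))
  editable <- if ("editable" %in% names(edited)) edited$editable else
    rep(TRUE, nrow(edited))
  editable[is.na(editable)] <- TRUE
  ok <- editable & edited$depth > 0 & control$depth > 0
  if (!any(ok)) {
    return(list(p_value = NA_real_, q_value = NA_real_,
                max_deam_freq = NA_real_, control_max_freq = NA_real_,
                mean_depth = mean(edited$depth), called = FALSE,
                uncallable = TRUE))
  }
  p_pos <- fisher_greater_p(edited$count_G[ok], edited$depth[ok],
                            control$count_G[ok], control$depth[ok])
  w <- sum(ok)
  p_site <- if (aggregate == "min_p") {
    min(pmin(p_pos * w, 1))
  } else {
    i <- which.max(edited$freq[ok])
    min(p_pos[i], 1)
  }
  max_e <- max(edited$freq[ok])
  max_c <- max(control$freq[ok])
  called <- (p_site <= alpha) && (max_e > max_c)
  list(p_value = p_site, q_value = p_site, max_deam_freq = max_e,
       control_max_freq = max_c, mean_depth = mean(edited$depth),
       called = called, uncallable = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, clipped to [0, 1].
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(stats::p.adjust(p_values, method = "BH"), 0), 1)
}

#' Call off-target editing across many sites with FDR control
#'
#' Runs [call_offtarget_editing()] per site, Benjamini-Hochberg-adjusts
#' the site p-values across all callable sites, and re-applies the call
#' rule `q <= alpha` and edited max frequency > control max frequency.
#'
#' @param edited_list,control_list Lists of per-position count data.frames,
#'   one per site, in matching order.
#' @param alpha Significance level.
#' @param aggregate Passed to [call_offtarget_editing()].
#' @return data.frame with one row per site: `p_value`, `q_value`,
#'   `max_deam_freq`, `control_max_freq`, `mean_depth`, `called`,
#'   `uncallable`.
#' @export
call_offtarget_sites <- function(edited_list, control_list, alpha = 0.05,
                                 aggregate = "min_p") {
  stopifnot(length(edited_list) == length(control_list))
  res <- mapply(function(e, c) {
    call_offtarget_editing(e, c, alpha = alpha, aggregate = aggregate)
  }, edited_list, control_list, SIMPLIFY = FALSE)
  df <- do.call(rbind, lapply(res, function(r) {
    data.frame(p_value = r$p_value, q_value = NA_real_,
               max_deam_freq = r$max_deam_freq,
               control_max_freq = r$control_max_freq,
               mean_depth = r$mean_depth, called = FALSE,
               uncallable = r$uncallable)
  }))
  ok <- !df$uncallable
  df$q_value[ok] <- bh_adjust(df$p_value[ok])
  df$called <- ok & !is.na(df$q_value) & df$q_value <= alpha &
    df$max_deam_freq > df$control_max_freq
  rownames(df) <- NULL
  df
}

#' Summarise a capture experiment
#'
#' @param results data.frame from [call_offtarget_sites()] (or a list of
#'   single-site results).
#' @return List with `n_sites`, `n_called`, `median_called_freq` (median of
#'   called sites' maximum deamination frequencies; `NA` when none called),
#'   `mean_depth` (`NA` when no sites).
#' @export
summarize_capture <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  n <- if (is.null(results)) 0L else nrow(results)
  if (n == 0L) {
    return(list(n_sites = 0L, n_called = 0L, median_called_freq = NA_real_,
                mean_depth = NA_real_))
  }
  called <- results[results$called, , drop = FALSE]
  list(n_sites = n,
       n_called = nrow(called),
       median_called_freq = if (nrow(called)) stats::median(called$max_deam_freq)
                            else NA_real_,
       mean_depth = mean(results$mean_depth, na.rm = TRUE))
}

#' Write per-site capture results as TSV and called sites as VCF-like text
#'
#' Positions in the VCF-like stream are 1-based, per convention at report
#' boundaries.
#'
#' @param results data.frame from [call_offtarget_sites()].
#' @param sites The matching [candidate_sites] data.frame.
#' @param tsv_path,vcf_path Output paths (either may be `NULL`).
#' @export
write_capture_results <- function(results, sites, tsv_path = NULL,
                                  vcf_path = NULL) {
  out <- cbind(site = site_ids(sites), as.data.frame(sites), results)
  if (!is.null(tsv_path)) {
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    called <- out[out$called, , drop = FALSE]
    con <- file(vcf_path, "wb")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=DF,Number=1,Type=Float,Description=\"Max deamination frequency\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(called)) {
      ref <- ifelse(called$strand == "+", "A", "T")
      alt <- ifelse(called$strand == "+", "G", "C")
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tDF=%g",
                         called$contig, called$start + 1L, called$site,
                         ref, alt, called$max_deam_freq), con)
    }
  }
  invisible(out)
}
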