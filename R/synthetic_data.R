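#' Synthetic-data generators
#'
#' Every generator is seeded through an RNG-state-preserving wrapper, so a
#' given seed reproduces byte-identical outputs and truth manifests. Each
#' returns its data in memory together with a `truth` manifest (generator
#' name, seed, parameters, per-item planted labels) and optionally writes
#' standard formats (FASTQ/FASTA/SAM+BAM, manifest JSON). The error model
#' is substitution-only by default; quality strings are constant Q37
#' unless a degraded quality is requested.
#'
#' @name synthetic_data
NULL

write_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

phred_char <- function(q) intToUtf8(q + 33L)

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# substitution errors at per-base rate; returns mutated sequences
mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), L, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(L[i], n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Generate paired amplicon reads with planted editing outcomes
#'
#' Each read pair is drawn from the amplicon carrying a planted codon
#' outcome: the codon is replaced by the outcome's codon (AAG/GAG/GGG/AGG),
#' or deleted for `INDEL`. R1 covers the fragment 5' end, R2 is the
#' reverse-complemented 3' end; with `read_length` above half the amplicon
#' length the pair overlaps. Per-base substitution errors are applied to
#' each read independently.
#'
#' @param spec [protospacer_spec()] with amplicon-coordinate locus.
#' @param amplicon_ref Amplicon reference sequence (HbE allele: codon AAG).
#' @param codon_interval [genomic_interval()] of the codon on the amplicon.
#' @param outcome_freqs Named frequencies over
#'   `HBE_UNEDITED`/`WT_CORRECTED`/`AUBENAS`/`AGG_VARIANT`/`INDEL`,
#'   summing to 1 (tolerance 1e-9), none negative.
#' @param n_reads Number of read pairs (>= 1).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @param read_length Read length (default 150).
#' @param quality_phred Constant Phred quality (default 37).
#' @param out_dir If given, writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`
#'   and `<prefix>_truth.json` there.
#' @param prefix File prefix for `out_dir` outputs.
#' @return List with `r1`, `r2` (data.frames id/sequence/qualities) and
#'   `truth` (manifest including the per-read planted outcome).
#' @export
gen_amplicon_reads <- function(spec, amplicon_ref, codon_interval,
                               outcome_freqs, n_reads, error_rate = 0.001,
                               seed = 1L, read_length = 150L,
                               quality_phred = 37L, out_dir = NULL,
                               prefix = "amplicon") {
  if (any(outcome_freqs < 0)) stop("negative outcome frequency", call. = FALSE)
  if (abs(sum(outcome_freqs) - 1) > 1e-9) {
    stop("outcome_freqs must sum to 1", call. = FALSE)
  }
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  lev <- names(outcome_freqs)
  stopifnot(all(lev %in% allele_outcome_levels()))
  cs <- codon_interval$start; ce <- codon_interval$end
  codon_map <- outcome_codons()
  variant_of <- function(outcome) {
    if (outcome == "INDEL") {
      paste0(substr(amplicon_ref, 1L, cs), substr(amplicon_ref, ce + 1L,
                                                  nchar(amplicon_ref)))
    } else {
      codon <- names(codon_map)[codon_map == outcome]
      paste0(substr(amplicon_ref, 1L, cs), codon,
             substr(amplicon_ref, ce + 1L, nchar(amplicon_ref)))
    }
  }
  variants <- stats::setNames(vapply(lev, variant_of, character(1)), lev)
  res <- with_seed(seed, {
    planted <- sample(lev, n_reads, replace = TRUE, prob = outcome_freqs)
    frags <- variants[planted]
    L <- nchar(frags)
    r1 <- substr(frags, 1L, read_length)
    r2 <- vapply(seq_len(n_reads), function(i) {
      reverse_complement(substr(frags[i], L[i] - read_length + 1L, L[i]))
    }, character(1))
    r1 <- mutate_seqs(r1, error_rate)
    r2 <- mutate_seqs(r2, error_rate)
    list(planted = planted, r1 = r1, r2 = r2)
  })
  qual <- strrep(phred_char(quality_phred), read_length)
  ids <- sprintf("read%06d", seq_len(n_reads))
  truth <- list(generator = "gen_amplicon_reads", seed = seed,
                parameters = list(n_reads = n_reads, error_rate = error_rate,
                                  read_length = read_length,
                                  outcome_freqs = as.list(outcome_freqs)),
                planted_outcomes = res$planted)
  out <- list(r1 = data.frame(id = ids, sequence = res$r1, qualities = qual,
                              stringsAsFactors = FALSE),
              r2 = data.frame(id = ids, sequence = res$r2, qualities = qual,
                              stringsAsFactors = FALSE),
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(ids, res$r1, rep(qual, n_reads),
                file.path(out_dir, paste0(prefix, "_R1.fastq")))
    write_fastq(ids, res$r2, rep(qual, n_reads),
                file.path(out_dir, paste0(prefix, "_R2.fastq")))
    write_manifest(truth, file.path(out_dir, paste0(prefix, "_truth.json")))
  }
  out
}

# scan both strands for spacer matches within max_mm that have a matching
# PAM; returns data.frame(start0, strand) (internal, used by the scrubber)
scan_near_matches <- function(genome_seq, spec, max_mm) {
  plen <- nchar(spec$pam_pattern)
  L <- nchar(genome_seq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome_seq else reverse_complement(genome_seq)
    hm <- .hamming_scan_cpp(s, spec$spacer)
    cand <- which(hm <= max_mm)
    cand <- cand[cand + 19L + plen <= L]
    if (!length(cand)) next
    pam <- substring(s, cand + 20L, cand + 19L + plen)
    cand <- cand[iupac_match_many(spec$pam_pattern, pam)]
    if (!length(cand)) next
    start0 <- if (strand == "+") cand - 1L else L - cand - 19L
    hits[[strand]] <- data.frame(start0 = start0, strand = strand,
                                 stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start0 = integer(0), strand = character(0))
}

#' Generate a genome with planted off-target sites
#'
#' A random background genome, scrubbed of accidental PAM-adjacent
#' near-matches within `scrub_radius` mismatches of the spacer, with one
#' protospacer+PAM site planted per requested (mismatch count, strand) at
#' evenly spaced, recorded coordinates.
#'
#' @param length Genome length in bp.
#' @param spec [protospacer_spec()].
#' @param planted data.frame with columns `mismatch_count` and `strand`.
#' @param seed RNG seed.
#' @param scrub_radius Background is cleared of matches within this
#'   Hamming radius (default 4).
#' @param contig Contig name of the simulated sequence.
#' @param out_dir If given, writes `<prefix>.fa` and `<prefix>_truth.json`.
#' @param prefix File prefix.
#' @return List with `genome` (named character vector) and `truth`
#'   (manifest listing each planted site's coordinates, strand, mismatch
#'   count and protospacer sequence).
#' @export
gen_genome_with_offtargets <- function(length, spec, planted, seed = 1L,
                                       scrub_radius = 4L, contig = "chr_sim",
                                       out_dir = NULL, prefix = "genome") {
  n_sites <- nrow(planted)
  plen <- nchar(spec$pam_pattern)
  need <- (n_sites + 1L) * 200L
  if (length < need) {
    stop("genome of length ", length, " too short for ", n_sites,
         " planted sites (need >= ", need, ")", call. = FALSE)
  }
  concrete_pam <- {
    p <- strsplit(spec$pam_pattern, "")[[1]]
    paste(vapply(p, function(sym) {
      substr(Biostrings::IUPAC_CODE_MAP[[sym]], 1L, 1L)
    }, character(1)), collapse = "")
  }
  res <- with_seed(seed, {
    g <- strsplit(random_dna(1L, length), "")[[1]]
    # evenly spaced slots with margins for probe/context extraction
    slot <- as.integer(length %/% (n_sites + 1L))
    starts0 <- slot * seq_len(n_sites) - 10L
    sites <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      mm <- planted$mismatch_count[i]
      proto <- strsplit(spec$spacer, "")[[1]]
      if (mm > 0L) {
        pos <- sample.int(20L, mm)
        for (p in pos) {
          proto[p] <- sample(setdiff(c("A", "C", "G", "T"), proto[p]), 1L)
        }
      }
      proto <- paste(proto, collapse = "")
      cassette <- paste0(proto, concrete_pam)
      if (planted$strand[i] == "-") cassette <- reverse_complement(cassette)
      s0 <- starts0[i]  # 0-based start of the cassette
      g[(s0 + 1L):(s0 + nchar(cassette))] <- strsplit(cassette, "")[[1]]
      # 0-based protospacer interval on the genome
      if (planted$strand[i] == "+") {
        p_start <- s0; p_end <- s0 + 20L
      } else {
        p_start <- s0 + plen; p_end <- s0 + plen + 20L
      }
      sites[[i]] <- data.frame(contig = contig, start = p_start, end = p_end,
                               strand = planted$strand[i],
                               mismatch_count = mm, protospacer = proto,
                               stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites)
    gseq <- paste(g, collapse = "")
    # scrub accidental near-matches not overlapping a planted cassette
    protected_lo <- sites$start - plen  # cassette span regardless of strand
    protected_hi <- sites$end + plen
    for (iter in seq_len(50L)) {
      hits <- scan_near_matches(gseq, spec, scrub_radius)
      acc <- hits[!vapply(seq_len(nrow(hits)), function(k) {
        any(hits$start0[k] < protected_hi & hits$start0[k] + 20L > protected_lo)
      }, logical(1)), , drop = FALSE]
      if (!nrow(acc)) break
      gch <- strsplit(gseq, "")[[1]]
      for (k in seq_len(nrow(acc))) {
        mid <- acc$start0[k] + 10L  # mutate a mid-protospacer base
        gch[mid + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                        gch[mid + 1L]), 1L)
      }
      gseq <- paste(gch, collapse = "")
    }
    list(gseq = gseq, sites = sites)
  })
  genome <- stats::setNames(res$gseq, contig)
  truth <- list(generator = "gen_genome_with_offtargets", seed = seed,
                parameters = list(length = length,
                                  scrub_radius = scrub_radius,
                                  spacer = spec$spacer,
                                  pam_pattern = spec$pam_pattern),
                planted_sites = res$sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, paste0(prefix, ".fa")))
    write_manifest(truth, file.path(out_dir, paste0(prefix, "_truth.json")))
  }
  list(genome = genome, truth = truth)
}

sam_header <- function(contigs, lengths) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contigs, as.integer(lengths)))
}

sam_to_bam <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = sub("\\.sam$", "", sam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

#' Generate a capture-sequencing BAM with planted per-site editing
#'
#' Emits `depth` single-end reads spanning each candidate site. Each read
#' is planted as edited with the site's editing frequency; an edited read
#' carries every editing-window adenine converted A->G on the protospacer
#' strand (T->C on the reference for minus-strand sites). Background
#' substitution errors are applied on top. Reads are written as
#' coordinate-sorted SAM (kept alongside for byte-level reproducibility
#' checks) and converted to indexed BAM.
#'
#' @param sites A [candidate_sites] data.frame.
#' @param editing_freqs Per-site editing frequencies in [0, 1].
#' @param depth Reads per site (>= 1).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @param genome Named character vector of contig sequences.
#' @param spec [protospacer_spec()].
#' @param out_dir Output directory (required; BAM is a file format).
#' @param prefix File prefix.
#' @param read_length Read length (default 120).
#' @return List with `bam`, `sam` paths and `truth` (per-site planted
#'   frequency and realised edited-read count).
#' @export
gen_capture_bam <- function(sites, editing_freqs, depth, error_rate = 0.001,
                            seed = 1L, genome, spec, out_dir,
                            prefix = "capture", read_length = 120L) {
  stopifnot(nrow(sites) == length(editing_freqs),
            all(editing_freqs >= 0 & editing_freqs <= 1), depth >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  win <- spec$editing_window[1]:spec$editing_window[2]
  res <- with_seed(seed, {
    recs <- list(); n_edited <- integer(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      site <- sites[i, ]
      cseq <- genome[[site$contig]]
      iv <- genomic_interval(site$contig, site$start, site$end, site$strand)
      win_ref0 <- protospacer_to_ref(iv, win)
      proto_bases <- strsplit(site$protospacer, "")[[1]]
      a_ref0 <- win_ref0[proto_bases[win] == "A"]
      mid <- (site$start + site$end) %/% 2L
      r_start0 <- max(0L, mid - read_length %/% 2L)
      r_start0 <- min(r_start0, nchar(cseq) - read_length)
      ref_read <- substr(cseq, r_start0 + 1L, r_start0 + read_length)
      edited_read <- {
        ch <- strsplit(ref_read, "")[[1]]
        for (r0 in a_ref0) {
          j <- r0 - r_start0 + 1L
          if (j >= 1L && j <= read_length) {
            ch[j] <- if (site$strand == "+") "G" else "C"
          }
        }
        paste(ch, collapse = "")
      }
      is_edited <- stats::runif(depth) < editing_freqs[i]
      n_edited[i] <- sum(is_edited)
      reads <- ifelse(is_edited, edited_read, ref_read)
      reads <- mutate_seqs(reads, error_rate)
      recs[[i]] <- data.frame(
        qname = sprintf("site%03d_read%06d", i, seq_len(depth)),
        contig = site$contig, pos1 = r_start0 + 1L, seq = reads,
        stringsAsFactors = FALSE)
    }
    list(recs = do.call(rbind, recs), n_edited = n_edited)
  })
  recs <- res$recs[order(res$recs$contig, res$recs$pos1), , drop = FALSE]
  qual <- strrep(phred_char(37L), read_length)
  sam_path <- file.path(out_dir, paste0(prefix, ".sam"))
  con <- file(sam_path, "wb")
  writeLines(sam_header(names(genome), nchar(genome)), con, sep = "\n")
  writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                     recs$qname, recs$contig, recs$pos1, read_length,
                     recs$seq, qual), con, sep = "\n")
  close(con)
  bam <- sam_to_bam(sam_path)
  truth <- list(generator = "gen_capture_bam", seed = seed,
                parameters = list(depth = depth, error_rate = error_rate,
                                  read_length = read_length),
                sites = data.frame(site = site_ids(sites),
                                   editing_freq = editing_freqs,
                                   n_edited = res$n_edited,
                                   stringsAsFactors = FALSE))
  write_manifest(truth, file.path(out_dir, paste0(prefix, "_truth.json")))
  list(bam = bam, sam = sam_path, truth = truth)
}

#' Simulate per-position pileup count tables for one site
#'
#' Count-level counterpart of [gen_capture_bam()] for replicate-scale
#' simulations (type-I error and power studies): per-read editing at
#' `freq` converts every window adenine; substitution errors at
#' `error_rate` are distributed uniformly over the three non-ref bases.
#' Positions whose protospacer base is not A cannot be edited.
#'
#' @param spec [protospacer_spec()].
#' @param protospacer 20-nt protospacer-strand sequence of the site.
#' @param freq Per-read editing frequency.
#' @param depth Read depth.
#' @param error_rate Per-base substitution error rate.
#' @return data.frame in the [pileup_deamination()] layout (positions are
#'   editing-window protospacer positions; `ref_pos0` is the window
#'   offset). Draws from the current RNG stream; wrap in a seeded context
#'   for reproducibility.
#' @export
gen_capture_counts <- function(spec, protospacer, freq, depth,
                               error_rate = 0.001) {
  win <- spec$editing_window[1]:spec$editing_window[2]
  bases <- strsplit(protospacer, "")[[1]][win]
  n_edited <- stats::rbinom(1L, depth, freq)
  out <- data.frame(position = win, ref_pos0 = win - 1L,
                    proto_base = bases, editable = bases == "A",
                    depth = depth,
                    count_A = 0L, count_G = 0L, count_other = 0L)
  e3 <- error_rate / 3
  for (k in seq_along(win)) {
    if (bases[k] == "A") {
      g_from_edit <- stats::rbinom(1L, n_edited, 1 - 2 * e3)
      g_from_err <- stats::rbinom(1L, depth - n_edited, e3)
      g <- g_from_edit + g_from_err
      oth <- stats::rbinom(1L, depth - g, 2 * e3)
    } else if (bases[k] == "G") {
      g <- stats::rbinom(1L, depth, 1 - 3 * e3)
      oth <- stats::rbinom(1L, depth - g, 2 * e3)
    } else {
      g <- stats::rbinom(1L, depth, e3)
      oth <- depth - g - stats::rbinom(1L, depth - g, e3)
    }
    out$count_G[k] <- g
    out$count_other[k] <- oth
    out$count_A[k] <- depth - g - oth
  }
  out$freq <- out$count_G / out$depth
  attr(out, "n_edited") <- n_edited
  out
}

#' Generate a labeled accessibility training set
#'
#' Positives embed the accessibility motif once at a uniformly random
#' offset in a random background; negatives are random sequences rejection
#' -sampled to be motif-free. Classes are exactly balanced.
#'
#' @param n Total sequences (even).
#' @param motif Motif string (shorter than `input_length`).
#' @param input_length Sequence length.
#' @param seed RNG seed.
#' @param out_dir If given, writes a FASTA (labels in headers) and a truth
#'   manifest.
#' @param prefix File prefix.
#' @return List with `sequences`, `labels` (1 = accessible), `offsets`
#'   (1-based motif offset, NA for negatives) and `truth`.
#' @export
gen_accessibility_dataset <- function(n = 4000L, motif = "GGTAATGACC",
                                      input_length = 200L, seed = 7L,
                                      out_dir = NULL, prefix = "access") {
  stopifnot(nchar(motif) < input_length, n %% 2L == 0L)
  res <- with_seed(seed, {
    n_pos <- n %/% 2L
    w <- nchar(motif)
    pos_seqs <- random_dna(n_pos, input_length)
    offsets <- sample.int(input_length - w + 1L, n_pos, replace = TRUE)
    for (i in seq_len(n_pos)) {
      substr(pos_seqs[i], offsets[i], offsets[i] + w - 1L) <- motif
    }
    neg_seqs <- character(n - n_pos)
    for (i in seq_len(n - n_pos)) {
      repeat {
        s <- random_dna(1L, input_length)
        if (!grepl(motif, s, fixed = TRUE) &&
            !grepl(reverse_complement(motif), s, fixed = TRUE)) break
      }
      neg_seqs[i] <- s
    }
    list(sequences = c(pos_seqs, neg_seqs),
         labels = c(rep(1L, n_pos), rep(0L, n - n_pos)),
         offsets = c(offsets, rep(NA_integer_, n - n_pos)))
  })
  truth <- list(generator = "gen_accessibility_dataset", seed = seed,
                parameters = list(n = n, motif = motif,
                                  input_length = input_length),
                labels = res$labels, motif_offsets = res$offsets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(res$sequences,
                                sprintf("seq%05d_label%d",
                                        seq_along(res$sequences),
                                        res$labels)),
                file.path(out_dir, paste0(prefix, ".fa")))
    write_manifest(truth, file.path(out_dir, paste0(prefix, "_truth.json")))
  }
  c(res, list(truth = truth))
}

#' Generate a genome of candidate sites with planted damaging edits
#'
#' Builds a genome carrying `n_sites` plus-strand candidate protospacer
#' sites (each with a matching PAM). For `n_damaging` of them the
#' accessibility motif is written over the protospacer such that the
#' motif's central adenines (positions 4 and 5 of the default motif) fall
#' on the spec's target positions, so converting the window adenines
#' destroys the motif. Half of the remaining benign sites carry the motif
#' elsewhere in their context (accessible but undamaged by the edit); the
#' rest are motif-free (inaccessible). Sites are spaced widely enough for
#' model-length context extraction.
#'
#' @param spec [protospacer_spec()].
#' @param n_sites Total candidate sites.
#' @param n_damaging Number of motif-destroying sites.
#' @param motif Accessibility motif (must contain `AA` at positions 4-5,
#'   as the default does).
#' @param seed RNG seed.
#' @param contig Contig name.
#' @return List with `genome`, `sites` (a [candidate_sites] data.frame)
#'   and `truth` (per-site `damaging` and `has_motif` labels).
#' @export
gen_damage_genome <- function(spec, n_sites = 30L, n_damaging = 5L,
                              motif = "GGTAATGACC", seed = 1L,
                              contig = "chr_dmg") {
  stopifnot(n_damaging <= n_sites, substr(motif, 4L, 5L) == "AA")
  slot <- 400L
  length <- (n_sites + 1L) * slot
  t1 <- spec$target_positions[1]
  # motif start (1-based protospacer position) aligning motif AA at
  # positions 4-5 onto the target adenines
  m_start <- t1 - 3L
  stopifnot(m_start >= 1L, m_start + nchar(motif) - 1L <= 20L)
  res <- with_seed(seed, {
    g <- strsplit(random_dna(1L, length), "")[[1]]
    damaging <- c(rep(TRUE, n_damaging), rep(FALSE, n_sites - n_damaging))
    n_benign <- n_sites - n_damaging
    motif_benign <- c(rep(FALSE, n_damaging),
                      rep(c(TRUE, FALSE), length.out = n_benign))
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      s0 <- slot * i  # 0-based protospacer start
      proto <- spec$spacer
      if (damaging[i]) {
        substr(proto, m_start, m_start + nchar(motif) - 1L) <- motif
      }
      cassette <- paste0(proto, "TGG")
      g[(s0 + 1L):(s0 + nchar(cassette))] <- strsplit(cassette, "")[[1]]
      if (motif_benign[i]) {
        # motif 40 bp downstream of the PAM: inside the model context,
        # outside the reach of any window edit
        off0 <- s0 + 23L + 40L
        g[(off0 + 1L):(off0 + nchar(motif))] <- strsplit(motif, "")[[1]]
      }
      mm <- sum(utf8ToInt(proto) != utf8ToInt(spec$spacer))
      rows[[i]] <- data.frame(contig = contig, start = s0, end = s0 + 20L,
                              strand = "+", protospacer = proto, pam = "TGG",
                              mismatch_count = mm, sources = "insilico",
                              circleseq_read_count = NA_real_,
                              stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    # scrub accidental motif copies outside the planted ones
    gseq <- paste(g, collapse = "")
    planted_motif0 <- c(slot * seq_len(n_sites)[damaging] + m_start - 1L,
                        slot * seq_len(n_sites)[motif_benign] + 63L)
    for (iter in seq_len(20L)) {
      hit0 <- c(gregexpr(motif, gseq, fixed = TRUE)[[1]],
                gregexpr(reverse_complement(motif), gseq,
                         fixed = TRUE)[[1]])
      hit0 <- hit0[hit0 > 0L] - 1L
      acc <- setdiff(hit0, planted_motif0)
      if (!length(acc)) break
      gch <- strsplit(gseq, "")[[1]]
      for (h in acc) {
        gch[h + 5L] <- sample(setdiff(c("A", "C", "G", "T"), gch[h + 5L]), 1L)
      }
      gseq <- paste(gch, collapse = "")
    }
    list(gseq = gseq, sites = sites, damaging = damaging,
         has_motif = damaging | motif_benign)
  })
  sites <- annotate_adenine_window(new_candidate_sites(res$sites), spec)
  truth <- list(generator = "gen_damage_genome", seed = seed,
                parameters = list(n_sites = n_sites,
                                  n_damaging = n_damaging, motif = motif),
                damaging = res$damaging, has_motif = res$has_motif)
  list(genome = stats::setNames(res$gseq, contig), sites = sites,
       truth = truth)
}

#' Generate spliced alignments mixing canonical and cryptic donors
#'
#' Reads carry one skipped-region operation from the chosen donor to the
#' acceptor; a planted fraction uses the cryptic donor. Donor/acceptor are
#' 1-based positions of the last/first exonic bases.
#'
#' @param canonical_donor,cryptic_donor,acceptor 1-based positions.
#' @param cryptic_fraction Fraction of reads using the cryptic donor.
#' @param n_reads Number of spliced reads.
#' @param seed RNG seed.
#' @param contig Contig name.
#' @param out_dir Output directory.
#' @param prefix File prefix.
#' @param exon_len Aligned bases on each side of the skip.
#' @return List with `bam`, `sam` paths and `truth` (per-read donor and
#'   planted cryptic fraction).
#' @export
gen_spliced_bam <- function(canonical_donor, cryptic_donor, acceptor,
                            cryptic_fraction, n_reads, seed = 1L,
                            contig = "chr11", out_dir, prefix = "spliced",
                            exon_len = 50L) {
  stopifnot(cryptic_fraction >= 0, cryptic_fraction <= 1,
            acceptor > max(canonical_donor, cryptic_donor) + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- with_seed(seed, {
    cryptic <- stats::runif(n_reads) < cryptic_fraction
    donors <- ifelse(cryptic, cryptic_donor, canonical_donor)
    seqs <- random_dna(n_reads, 2L * exon_len)
    list(donors = donors, cryptic = cryptic, seqs = seqs)
  })
  pos1 <- res$donors - exon_len + 1L
  gap <- acceptor - res$donors - 1L
  cigar <- sprintf("%dM%dN%dM", exon_len, gap, exon_len)
  qual <- strrep(phred_char(37L), 2L * exon_len)
  ord <- order(pos1)
  contig_len <- acceptor + exon_len + 100L
  sam_path <- file.path(out_dir, paste0(prefix, ".sam"))
  con <- file(sam_path, "wb")
  writeLines(sam_header(contig, contig_len), con, sep = "\n")
  writeLines(sprintf("read%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     seq_len(n_reads)[ord], contig, pos1[ord], cigar[ord],
                     res$seqs[ord], qual), con, sep = "\n")
  close(con)
  bam <- sam_to_bam(sam_path)
  truth <- list(generator = "gen_spliced_bam", seed = seed,
                parameters = list(canonical_donor = canonical_donor,
                                  cryptic_donor = cryptic_donor,
                                  acceptor = acceptor,
                                  cryptic_fraction = cryptic_fraction,
                                  n_reads = n_reads),
                planted_donors = res$donors)
  write_manifest(truth, file.path(out_dir, paste0(prefix, "_truth.json")))
  list(bam = bam, sam = sam_path, truth = truth)
}
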