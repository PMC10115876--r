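# Independent oracles, deliberately implemented by different mechanisms
# than the package code paths they check.

# Brute-force off-target scan: embed() windows + rowSums Hamming distance,
# regex-based PAM matching. Minus-strand sites are found directly on the
# plus strand as windows whose reverse complement matches the spacer, with
# the reverse-complemented PAM pattern on their 5' side.
oracle_offtargets <- function(genome, spacer, pam_pattern, max_mm) {
  iupac_regex <- function(pattern) {
    map <- Biostrings::IUPAC_CODE_MAP
    paste0(vapply(strsplit(pattern, "")[[1]], function(s) {
      cls <- map[[s]]
      if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
    }, character(1)), collapse = "")
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  plen <- nchar(pam_pattern)
  pam_re <- paste0("^", iupac_regex(pam_pattern), "$")
  # reverse complement of an IUPAC pattern, as a regex
  rc_pat <- paste(rev(vapply(strsplit(pam_pattern, "")[[1]], function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    comp[[s]]
  }, character(1))), collapse = "")
  rc_pam_re <- paste0("^", iupac_regex(rc_pat), "$")
  sp_code <- utf8ToInt(spacer)
  rc_sp_code <- utf8ToInt(rc(spacer))
  out <- list()
  for (contig in names(genome)) {
    g <- toupper(genome[[contig]])
    L <- nchar(g)
    code <- utf8ToInt(g)
    if (L < 20L + plen) next
    W <- t(vapply(seq_len(20L), function(j) code[j:(L - 20L + j)],
                  integer(L - 19L)))  # 20 x n_windows
    n_win <- ncol(W)
    mm_plus <- colSums(W != sp_code)
    # minus strand: window's revcomp vs spacer == window vs revcomp complement?
    # hamming(revcomp(w), spacer) == hamming(w, revcomp(spacer))
    mm_minus <- colSums(W != rc_sp_code)
    for (i in seq_len(n_win)) {
      s0 <- i - 1L
      if (mm_plus[i] <= max_mm && i + 19L + plen <= L) {
        pam <- substr(g, i + 20L, i + 19L + plen)
        if (grepl(pam_re, pam)) {
          out[[length(out) + 1L]] <- data.frame(
            contig = contig, start = s0, end = s0 + 20L, strand = "+",
            mismatch_count = mm_plus[i], stringsAsFactors = FALSE)
        }
      }
      if (mm_minus[i] <= max_mm && i - plen >= 1L) {
        pam_left <- substr(g, i - plen, i - 1L)
        if (grepl(rc_pam_re, pam_left)) {
          out[[length(out) + 1L]] <- data.frame(
            contig = contig, start = s0, end = s0 + 20L, strand = "-",
            mismatch_count = mm_minus[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatch_count = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

# exact one-sided hypergeometric tail by direct enumeration over lchoose
oracle_fisher_greater <- function(g_edit, n_edit, g_ctrl, n_ctrl) {
  m <- g_edit + g_ctrl          # total G
  N <- n_edit + n_ctrl          # total reads
  ks <- g_edit:min(m, n_edit)   # as or more extreme in the edited sample
  ks <- ks[N - m - (n_edit - ks) >= 0]
  sum(exp(lchoose(m, ks) + lchoose(N - m, n_edit - ks) - lchoose(N, n_edit)))
}

# hand BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# count skip (N) operations in a SAM file by walking CIGARs directly
oracle_sam_skips <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  skips <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    pos <- as.integer(f[4]); cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    ref <- pos
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type == "N") {
        skips[[length(skips) + 1L]] <- c(donor = ref - 1L,
                                         acceptor = ref + n)
      }
      if (type %in% c("M", "D", "N", "=", "X")) ref <- ref + n
    }
  }
  if (!length(skips)) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  as.data.frame(do.call(rbind, skips))
}

# closed-form delta-delta-Ct, written independently of the package
oracle_ddct <- function(t, r, tc, rc) {
  2^-((mean(t) - mean(r)) - (mean(tc) - mean(rc)))
}
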