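#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// FLASH-style ungapped overlap merge of read pairs.
// r2 is the reverse-strand mate: it is reverse-complemented (and its quality
// string reversed) before the overlap search. Among overlaps >= min_overlap
// the one with the lowest mismatch fraction wins (ties -> longest overlap);
// pairs whose best overlap exceeds max_mismatch_frac are flagged unmerged.
// At overlap disagreements the higher-quality base is taken.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1_seq, CharacterVector r1_qual,
                     CharacterVector r2_seq, CharacterVector r2_qual,
                     int min_overlap, double max_mismatch_frac) {
  int n = r1_seq.size();
  CharacterVector out_seq(n), out_qual(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    std::string a  = as<std::string>(r1_seq[i]);
    std::string aq = as<std::string>(r1_qual[i]);
    std::string b0 = as<std::string>(r2_seq[i]);
    std::string bq = as<std::string>(r2_qual[i]);
    int L1 = a.size(), L2 = b0.size();
    // reverse complement r2, reverse its qualities
    std::string b(L2, 'N');
    for (int j = 0; j < L2; ++j) b[j] = comp_base(b0[L2 - 1 - j]);
    std::reverse(bq.begin(), bq.end());

    int max_o = std::min(L1, L2);
    int best_o = -1, best_mm = 0;
    double best_frac = 2.0;
    for (int o = min_overlap; o <= max_o; ++o) {
      int mm = 0;
      const char *pa = a.data() + (L1 - o);
      for (int j = 0; j < o; ++j) if (pa[j] != b[j]) ++mm;
      double frac = (double)mm / o;
      if (frac < best_frac - 1e-12 ||
          (std::abs(frac - best_frac) <= 1e-12 && o > best_o)) {
        best_frac = frac; best_o = o; best_mm = mm;
      }
    }
    if (best_o < 0 || best_frac > max_mismatch_frac) {
      out_seq[i] = NA_STRING; out_qual[i] = NA_STRING; ok[i] = false;
      continue;
    }
    int o = best_o;
    std::string ms = a.substr(0, L1 - o);
    std::string mq = aq.substr(0, L1 - o);
    for (int j = 0; j < o; ++j) {
      char ca = a[L1 - o + j], cb = b[j];
      char qa = aq[L1 - o + j], qb = bq[j];
      if (ca == cb) { ms += ca; mq += std::max(qa, qb); }
      else if (qa >= qb) { ms += ca; mq += qa; }
      else { ms += cb; mq += qb; }
    }
    ms += b.substr(o);
    mq += bq.substr(o);
    out_seq[i] = ms; out_qual[i] = mq; ok[i] = true;
  }
  return List::create(_["sequence"] = out_seq, _["qualities"] = out_qual,
                      _["merged"] = ok);
}

// Hamming distance of a query against every window of equal length on one
// strand of a subject, used by the off-target scan's planted-site scrubber.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
IntegerVector hamming_scan_cpp(std::string subject, std::string query) {
  int L = subject.size(), w = query.size();
  int n = L - w + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int mm = 0;
    for (int j = 0; j < w; ++j) if (subject[i + j] != query[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
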