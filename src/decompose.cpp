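#include <Rcpp.h>
using namespace Rcpp;

// Status codes shared with the R wrapper (R/genotyper.R keeps the mapping).
static const int STATUS_PASS = 0;
static const int STATUS_NO_ANCHOR = 1;
static const int STATUS_AMBIGUOUS = 2;

// Leftmost occurrence of `a` in `s` at or after `from`, allowing up to
// max_mm mismatches and no indels. Returns -1 if absent.
static int find_anchor(const std::string& s, const std::string& a,
                       int max_mm, int from) {
  const int n = (int)s.size(), m = (int)a.size();
  if (m == 0) return -1;
  for (int i = from; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (s[i + j] != a[j] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) return i;
  }
  return -1;
}

// Greedily consume repeats of `motif` at `pos`; returns the count.
static int count_motif(const std::string& s, size_t& pos,
                       const char* motif, size_t mlen) {
  int c = 0;
  while (pos + mlen <= s.size() && s.compare(pos, mlen, motif, mlen) == 0) {
    pos += mlen;
    ++c;
  }
  return c;
}

// Anchor a batch of reads between the 5'/3' flank sequences and greedily
// decompose the inter-anchor segment left-to-right into
// (CAG)n (CAACAG)m (CCGCCA)k (CCG)p (CCT)q.
// [[Rcpp::export]]
DataFrame anchor_decompose_cpp(CharacterVector reads, std::string anchor5,
                               std::string anchor3, int max_mismatch) {
  const int n = reads.size();
  IntegerVector status(n), cag(n, NA_INTEGER), caacag(n, NA_INTEGER),
      ccgcca(n, NA_INTEGER), ccg(n, NA_INTEGER), cct(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) {
      status[r] = STATUS_NO_ANCHOR;
      continue;
    }
    const std::string s = as<std::string>(reads[r]);
    const int i5 = find_anchor(s, anchor5, max_mismatch, 0);
    if (i5 < 0) {
      status[r] = STATUS_NO_ANCHOR;
      continue;
    }
    const int seg_start = i5 + (int)anchor5.size();
    const int i3 = find_anchor(s, anchor3, max_mismatch, seg_start);
    if (i3 < 0) {
      status[r] = STATUS_NO_ANCHOR;
      continue;
    }
    const std::string seg = s.substr(seg_start, i3 - seg_start);
    size_t pos = 0;
    const int n_cag = count_motif(seg, pos, "CAG", 3);
    const int n_caacag = count_motif(seg, pos, "CAACAG", 6);
    const int n_ccgcca = count_motif(seg, pos, "CCGCCA", 6);
    const int n_ccg = count_motif(seg, pos, "CCG", 3);
    const int n_cct = count_motif(seg, pos, "CCT", 3);
    if (pos != seg.size() || n_cag < 1) {
      status[r] = STATUS_AMBIGUOUS;
      continue;
    }
    status[r] = STATUS_PASS;
    cag[r] = n_cag;
    caacag[r] = n_caacag;
    ccgcca[r] = n_ccgcca;
    ccg[r] = n_ccg;
    cct[r] = n_cct;
  }
  return DataFrame::create(_["status"] = status, _["cag"] = cag,
                           _["caacag"] = caacag, _["ccgcca"] = ccgcca,
                           _["ccg"] = ccg, _["cct"] = cct);
}
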