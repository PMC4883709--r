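#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, T=3, N=4.
// N never matches any base (including another N).

static const double FACT[17] = {
  1.0, 1.0, 2.0, 6.0, 24.0, 120.0, 720.0, 5040.0, 40320.0,
  362880.0, 3628800.0, 39916800.0, 479001600.0, 6227020800.0,
  87178291200.0, 1307674368000.0, 20922789888000.0
};

// Similarity of one ungapped window to a candidate, at exponent nu = 1:
// sum of factorials of maximal exact-match run lengths, plus for every run
// pair (x < y) the cross term h_x*h_y divided by the product of all
// intervening gap factors (a_hat * d + 1), d = number of mismatch positions
// between consecutive runs. Leading/trailing mismatches carry no penalty
// term of their own (they separate no runs).
static double mask_score(unsigned int mask, int len, double a_hat) {
  int runs[17], gaps[17], nrun = 0;
  int pos = 0, last_end = -1;
  while (pos < len) {
    if (mask & (1u << pos)) {
      if (nrun > 0) gaps[nrun - 1] = pos - last_end;
      int h = 0;
      while (pos < len && (mask & (1u << pos))) { ++h; ++pos; }
      runs[nrun++] = h;
      last_end = pos;
    } else ++pos;
  }
  if (nrun == 0) return 0.0;
  double s = 0.0;
  for (int a = 0; a < nrun; ++a) s += FACT[runs[a]];
  for (int a = 0; a < nrun; ++a) {
    double denom = 1.0;
    for (int b = a + 1; b < nrun; ++b) {
      denom *= a_hat * (double)gaps[b - 1] + 1.0;
      s += (double)runs[a] * (double)runs[b] / denom;
    }
  }
  return s;
}

// [[Rcpp::export]]
double cpp_mask_score(int mask, int len, double a_hat) {
  return mask_score((unsigned int)mask, len, a_hat);
}

// Max window similarity (nu = 1) of each candidate against each promoter,
// scanning every ungapped window on both strands. proms: list of integer
// vectors (encoded promoters); cands: n_cand x len integer matrix.
// Returns n_gene x n_cand matrix of maxima.
// [[Rcpp::export]]
NumericMatrix cpp_scan_max(List proms, IntegerMatrix cands, double a_hat) {
  const int len = cands.ncol();
  const int n_cand = cands.nrow();
  const int n_gene = proms.size();
  if (len < 1 || len > 16) stop("candidate length must be in 1..16");
  NumericMatrix out(n_gene, n_cand);

  const bool use_table = (len <= 10);
  std::vector<double> table;
  const unsigned int even_mask = [&]{
    unsigned int m = 0;
    for (int i = 0; i < len; ++i) m |= (1u << (2 * i));
    return m;
  }();
  if (use_table) {
    table.assign(1u << (2 * len), 0.0);
    for (unsigned int c = 0; c < (1u << len); ++c) {
      unsigned int spread = 0;
      for (int i = 0; i < len; ++i) if (c & (1u << i)) spread |= (1u << (2 * i));
      table[spread] = mask_score(c, len, a_hat);
    }
  }

  // candidate codes (2 bits per position) + N masks, forward and revcomp
  std::vector<unsigned int> ccode(n_cand), rcode(n_cand), cnmask(n_cand), rnmask(n_cand);
  for (int c = 0; c < n_cand; ++c) {
    unsigned int fc = 0, rc = 0, fn = 0, rn = 0;
    for (int i = 0; i < len; ++i) {
      int b = cands(c, i);
      if (b < 0 || b > 4) stop("bad base code in candidate");
      unsigned int fb = (b == 4) ? 0u : (unsigned int)b;
      if (b == 4) fn |= (1u << (2 * i));
      fc |= fb << (2 * i);
      int j = len - 1 - i;                     // reverse complement
      unsigned int rb = (b == 4) ? 0u : (unsigned int)(3 - b);
      if (b == 4) rn |= (1u << (2 * j));
      rc |= rb << (2 * j);
    }
    ccode[c] = fc; rcode[c] = rc; cnmask[c] = fn; rnmask[c] = rn;
  }

  std::vector<unsigned int> wcode, wnmask;
  for (int g = 0; g < n_gene; ++g) {
    IntegerVector p = proms[g];
    const int plen = p.size();
    const int n_win = plen - len + 1;
    if (n_win < 1) continue;                   // promoter shorter than candidate -> 0
    wcode.assign(n_win, 0u); wnmask.assign(n_win, 0u);
    unsigned int code = 0, nm = 0;
    const unsigned int keep = (len >= 16) ? 0xFFFFFFFFu : ((1u << (2 * len)) - 1u);
    for (int i = 0; i < plen; ++i) {
      int b = p[i];
      if (b < 0 || b > 4) stop("bad base code in promoter");
      unsigned int bb = (b == 4) ? 0u : (unsigned int)b;
      code = ((code >> 2) | (bb << (2 * (len - 1)))) & keep;
      nm = ((nm >> 2) | (((b == 4) ? 1u : 0u) << (2 * (len - 1)))) & keep;
      if (i >= len - 1) { wcode[i - len + 1] = code; wnmask[i - len + 1] = nm; }
    }
    for (int c = 0; c < n_cand; ++c) {
      const unsigned int fc = ccode[c], rc = rcode[c];
      const unsigned int fn = cnmask[c], rn = rnmask[c];
      double best = 0.0;
      for (int w = 0; w < n_win; ++w) {
        unsigned int x = wcode[w] ^ fc;
        unsigned int mm = ((x | (x >> 1)) & even_mask) | wnmask[w] | fn;
        unsigned int match = even_mask & ~mm;
        double s;
        if (use_table) s = table[match];
        else {
          unsigned int compact = 0;
          for (int i = 0; i < len; ++i) if (match & (1u << (2 * i))) compact |= (1u << i);
          s = mask_score(compact, len, a_hat);
        }
        if (s > best) best = s;
        x = wcode[w] ^ rc;
        mm = ((x | (x >> 1)) & even_mask) | wnmask[w] | rn;
        match = even_mask & ~mm;
        if (use_table) s = table[match];
        else {
          unsigned int compact = 0;
          for (int i = 0; i < len; ++i) if (match & (1u << (2 * i))) compact |= (1u << i);
          s = mask_score(compact, len, a_hat);
        }
        if (s > best) best = s;
      }
      out(g, c) = best;
    }
  }
  return out;
}
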