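#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty.
// Sequences arrive as integer codes (byte values); only equality is used,
// so the same kernel serves nucleotide and protein alphabets.
//
// Tie-break among equal-scoring alignments: smallest (q_start, s_start),
// then shortest alignment. Spans are 0-based half-open.
//
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s,
                  double match, double mismatch, double gap) {
  const int m = q.size(), n = s.size();
  const int w = n + 1;
  std::vector<double> Hv((size_t)(m + 1) * w, 0.0);
  double* H0 = Hv.data();
  const int* qp = INTEGER(q);
  const int* sp = INTEGER(s);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const double* up = H0 + (size_t)(i - 1) * w;
    double* cur = H0 + (size_t)i * w;
    const int qi = qp[i - 1];
    for (int j = 1; j <= n; ++j) {
      double h = up[j - 1] + ((qi == sp[j - 1]) ? match : mismatch);
      const double hu = up[j] + gap;
      if (hu > h) h = hu;
      const double hl = cur[j - 1] + gap;
      if (hl > h) h = hl;
      if (h < 0.0) h = 0.0;
      cur[j] = h;
      if (h > best) best = h;
    }
  }
#define H(i, j) H0[(size_t)(i) * w + (j)]

  int qs = 0, qe = 0, ss = 0, se = 0;
  int b_matches = 0, b_diag = 0, b_gapcols = 0, b_gapopens = 0, b_len = 0;
  bool have = false;

  if (best > 0.0) {
    const double eps = 1e-9;
    for (int ie = 1; ie <= m; ++ie) {
      for (int je = 1; je <= n; ++je) {
        if (std::abs(H(ie, je) - best) > eps) continue;
        // traceback: prefer diagonal, then up (gap in subject), then left
        int i = ie, j = je;
        int matches = 0, diag = 0, gapcols = 0, gapopens = 0, len = 0;
        int lastmove = 0; // 1 diag, 2 up, 3 left
        while (i > 0 && j > 0 && H(i, j) > eps) {
          double v = H(i, j);
          double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
          if (std::abs(H(i - 1, j - 1) + sub - v) <= eps) {
            if (q[i - 1] == s[j - 1]) ++matches;
            ++diag; ++len; --i; --j; lastmove = 1;
          } else if (std::abs(H(i - 1, j) + gap - v) <= eps) {
            ++gapcols; ++len;
            if (lastmove != 2) ++gapopens;
            --i; lastmove = 2;
          } else {
            ++gapcols; ++len;
            if (lastmove != 3) ++gapopens;
            --j; lastmove = 3;
          }
        }
        bool better = false;
        if (!have) better = true;
        else if (i < qs) better = true;
        else if (i == qs && j < ss) better = true;
        else if (i == qs && j == ss && len < b_len) better = true;
        if (better) {
          have = true;
          qs = i; ss = j; qe = ie; se = je;
          b_matches = matches; b_diag = diag; b_gapcols = gapcols;
          b_gapopens = gapopens; b_len = len;
        }
      }
    }
  }

#undef H

  return List::create(
    _["score"] = best,
    _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["matches"] = b_matches, _["diag"] = b_diag,
    _["gap_cols"] = b_gapcols, _["gap_opens"] = b_gapopens,
    _["aln_len"] = b_len);
}
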