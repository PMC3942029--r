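#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of a position-specific scoring matrix
// (rows = 20 aa in a fixed order, cols = profile positions) against an
// integer-encoded sequence (1-based residue indices; 0 = unknown, scored
// as the column minimum). Affine gaps with positive costs gap_open /
// gap_extend (a gap of length 1 costs gap_open + gap_extend).
// Returns the best score and the aligned coordinate ranges (1-based).
// [[Rcpp::export(name = ".pssm_sw")]]
List pssm_sw(NumericMatrix pssm, IntegerVector seq,
             double gap_open, double gap_extend) {
  const int L = pssm.ncol();   // profile length
  const int n = seq.size();
  const double NEG = -1e30;

  std::vector<double> H((L + 1) * (n + 1), 0.0);
  std::vector<double> E(n + 1, NEG);          // gap in profile (consume seq)
  std::vector<unsigned char> tb((L + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    double colmin = pssm(0, i - 1);
    for (int a = 1; a < 20; ++a) colmin = std::min(colmin, pssm(a, i - 1));
    double F = NEG;                            // gap in seq (consume profile)
    for (int j = 1; j <= n; ++j) {
      int aa = seq[j - 1];
      double sub = (aa >= 1 && aa <= 20) ? pssm(aa - 1, i - 1) : colmin;
      E[j] = std::max(E[j] - gap_extend, H[idx(i - 1, j)] - gap_open - gap_extend);
      F = std::max(F - gap_extend, H[idx(i, j - 1)] - gap_open - gap_extend);
      double h = H[idx(i - 1, j - 1)] + sub;
      unsigned char t = 1;                     // 1 = diagonal
      if (E[j] > h) { h = E[j]; t = 2; }       // 2 = from (i-1, j)
      if (F > h)    { h = F;    t = 3; }       // 3 = from (i, j-1)
      if (h <= 0.0) { h = 0.0;  t = 0; }
      H[idx(i, j)] = h;
      tb[idx(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // greedy single-step traceback (exact for matches, approximate inside
  // long affine gaps; used only for aligned-range coordinates)
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tb[idx(i, j)] != 0) {
    unsigned char t = tb[idx(i, j)];
    if (t == 1) { --i; --j; }
    else if (t == 2) { --i; }
    else { --j; }
  }
  int qstart = i + 1, sstart = j + 1, qend = bi, send = bj;
  if (best <= 0.0) { qstart = qend = sstart = send = 0; }

  return List::create(_["score"] = best,
                      _["profile_start"] = qstart, _["profile_end"] = qend,
                      _["seq_start"] = sstart, _["seq_end"] = send);
}
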