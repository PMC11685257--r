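// Affine-gap global alignment (Gotoh) with deterministic tie-breaking:
// diagonal (match/mismatch) is preferred over a gap in the query
// (deletion from the reference), which is preferred over a gap in the
// reference (insertion).  A gap of length L scores
// gap_open + (L - 1) * gap_extend, i.e. gap_open is the cost of the first
// gapped base.  Scores are kept in two rolling rows; per-state traceback
// codes are packed one byte per cell.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG = -1e18;

// state codes: 0 = M (diagonal), 1 = X (gap in query), 2 = Y (gap in ref)
// [[Rcpp::export(name = ".affineAlignCpp")]]
List affine_align_cpp(std::string ref, std::string query,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const size_t n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)n * (double)m > 4.5e8) stop("sequences too long to align");

  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  // tb[(i*(m+1))+j]: bits 0-1 from-state of M, 2-3 of X, 4-5 of Y
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (size_t j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = gap_open + (double)(j - 1) * gap_extend;
    tb[j] |= (unsigned char)((j == 1 ? 0 : 2) << 4);
  }

  for (size_t i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    Xcur[0] = gap_open + (double)(i - 1) * gap_extend;
    tb[i * (m + 1)] |= (unsigned char)((i == 1 ? 0 : 1) << 2);
    for (size_t j = 1; j <= m; ++j) {
      unsigned char code = 0;
      // M: diagonal from (i-1, j-1); prefer M, then X, then Y
      double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
      double bm = Mprev[j - 1]; int fm = 0;
      if (Xprev[j - 1] > bm) { bm = Xprev[j - 1]; fm = 1; }
      if (Yprev[j - 1] > bm) { bm = Yprev[j - 1]; fm = 2; }
      Mcur[j] = bm + s;
      code |= (unsigned char)fm;
      // X: vertical from (i-1, j)
      double bx = Mprev[j] + gap_open; int fx = 0;
      if (Xprev[j] + gap_extend > bx) { bx = Xprev[j] + gap_extend; fx = 1; }
      if (Yprev[j] + gap_open > bx) { bx = Yprev[j] + gap_open; fx = 2; }
      Xcur[j] = bx;
      code |= (unsigned char)(fx << 2);
      // Y: horizontal from (i, j-1)
      double by = Mcur[j - 1] + gap_open; int fy = 0;
      if (Xcur[j - 1] + gap_open > by) { by = Xcur[j - 1] + gap_open; fy = 1; }
      if (Ycur[j - 1] + gap_extend > by) { by = Ycur[j - 1] + gap_extend; fy = 2; }
      Ycur[j] = by;
      code |= (unsigned char)(fy << 4);
      tb[i * (m + 1) + j] = code;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  double best = Mprev[m]; int state = 0;
  if (Xprev[m] > best) { best = Xprev[m]; state = 1; }
  if (Yprev[m] > best) { best = Yprev[m]; state = 2; }

  std::string ar, aq;
  ar.reserve(n + m); aq.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[i * (m + 1) + j];
    if (state == 0) {
      ar.push_back(ref[i - 1]);
      aq.push_back(query[j - 1]);
      state = code & 3;
      --i; --j;
    } else if (state == 1) {
      ar.push_back(ref[i - 1]);
      aq.push_back('-');
      state = (code >> 2) & 3;
      --i;
    } else {
      ar.push_back('-');
      aq.push_back(query[j - 1]);
      state = (code >> 4) & 3;
      --j;
    }
  }
  std::string arf(ar.rbegin(), ar.rend());
  std::string aqf(aq.rbegin(), aq.rend());
  return List::create(_["alignedRef"] = arf, _["alignedQuery"] = aqf,
                      _["score"] = best);
}
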