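#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh, three-state) with deterministic
// tie-breaking: diagonal (M) is preferred over a gap in the second sequence
// (X, consumes the first/reference sequence) over a gap in the first
// sequence (Y, consumes the second/haplotype sequence).
//
// A gap of length L costs gap_open + (L - 1) * gap_extend.
// Characters listed in `ambiguous` never count as a match (always scored as
// mismatch), and never count as identity matches either.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State { SM = 0, SX = 1, SY = 2 };

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     std::string ambiguous) {
  const int n = (int)a.size();
  const int m = (int)b.size();

  bool amb[256];
  std::memset(amb, 0, sizeof(amb));
  for (char c : ambiguous) amb[(unsigned char)c] = true;

  // traceback: predecessor state of each cell, one byte per state matrix
  RawMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  std::vector<double> pM(m + 1), pX(m + 1), pY(m + 1);
  std::vector<double> cM(m + 1), cX(m + 1), cY(m + 1);

  pM[0] = 0.0; pX[0] = NEG_INF; pY[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    pM[j] = NEG_INF;
    pX[j] = NEG_INF;
    pY[j] = gap_open + (j - 1) * gap_extend;
    tbY(0, j) = (j == 1) ? SM : SY;
  }

  for (int i = 1; i <= n; ++i) {
    cM[0] = NEG_INF;
    cY[0] = NEG_INF;
    cX[0] = gap_open + (i - 1) * gap_extend;
    tbX(i, 0) = (i == 1) ? SM : SX;
    const unsigned char ai = (unsigned char)a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const unsigned char bj = (unsigned char)b[j - 1];
      const double s = (ai == bj && !amb[ai] && !amb[bj]) ? match : mismatch;

      // M: from diagonal of any state, preference M > X > Y on ties
      double best = pM[j - 1]; int bs = SM;
      if (pX[j - 1] > best) { best = pX[j - 1]; bs = SX; }
      if (pY[j - 1] > best) { best = pY[j - 1]; bs = SY; }
      cM[j] = best + s;
      tbM(i, j) = (Rbyte)bs;

      // X: gap in b (consume a_i), vertical move
      double vM = pM[j] + gap_open;
      double vX = pX[j] + gap_extend;
      double vY = pY[j] + gap_open;
      best = vM; bs = SM;
      if (vX > best) { best = vX; bs = SX; }
      if (vY > best) { best = vY; bs = SY; }
      cX[j] = best;
      tbX(i, j) = (Rbyte)bs;

      // Y: gap in a (consume b_j), horizontal move
      double hM = cM[j - 1] + gap_open;
      double hX = cX[j - 1] + gap_open;
      double hY = cY[j - 1] + gap_extend;
      best = hM; bs = SM;
      if (hX > best) { best = hX; bs = SX; }
      if (hY > best) { best = hY; bs = SY; }
      cY[j] = best;
      tbY(i, j) = (Rbyte)bs;
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }

  double score = pM[m]; int state = SM;
  if (pX[m] > score) { score = pX[m]; state = SX; }
  if (pY[m] > score) { score = pY[m]; state = SY; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == SM) {
      prev = tbM(i, j);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == SX) {
      prev = tbX(i, j);
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      prev = tbY(i, j);
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    unsigned char ca = (unsigned char)ra[k], cb = (unsigned char)rb[k];
    if (ca == cb && ca != '-' && !amb[ca]) ++matches;
  }

  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score,
                      _["matches"] = matches,
                      _["columns"] = (int)ra.size());
}
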