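#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Global pairwise alignment with affine gap costs (Gotoh three-state DP).
// A gap run of length L costs gap_open + L * gap_extend (both negative).
// 'N' against anything scores 0 (neither match nor mismatch).
// Ties are broken deterministically: diagonal state first, then a gap in
// the second sequence, then a gap in the first.
//
// Scores use two rolling rows per state; the traceback keeps one byte per
// cell packing the predecessor state of all three states (2 bits each).

static inline double subst_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;

  std::vector<double> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  // packed traceback: bits 0-1 = pred of M, 2-3 = pred of X, 4-5 = pred of Y
  std::vector<unsigned char> trace((size_t)(n + 1) * W, 0);

  // row 0
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = gap_open + j * gap_extend;
    trace[j] = (unsigned char)(((j == 1 ? 0 : 2) & 3) << 4);
  }

  for (int i = 1; i <= n; ++i) {
    unsigned char *tr = &trace[(size_t)i * W];
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + i * gap_extend;
    tr[0] = (unsigned char)(((i == 1 ? 0 : 1) & 3) << 2);
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: from any state at (i-1, j-1)
      double best = Mp[j - 1]; unsigned char argM = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; argM = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; argM = 2; }
      const double Mv = best + subst_score(ai, b[j - 1], match, mismatch);
      // X: gap in b (consumes a); opening from M/Y above, extending from X
      best = Mp[j] + gap_open + gap_extend; unsigned char argX = 0;
      if (Xp[j] + gap_extend > best) { best = Xp[j] + gap_extend; argX = 1; }
      if (Yp[j] + gap_open + gap_extend > best) {
        best = Yp[j] + gap_open + gap_extend; argX = 2;
      }
      const double Xv = best;
      // Y: gap in a (consumes b); opening from M/X on the left
      best = Mc[j - 1] + gap_open + gap_extend; unsigned char argY = 0;
      if (Xc[j - 1] + gap_open + gap_extend > best) {
        best = Xc[j - 1] + gap_open + gap_extend; argY = 1;
      }
      if (Yc[j - 1] + gap_extend > best) {
        best = Yc[j - 1] + gap_extend; argY = 2;
      }
      Mc[j] = Mv; Xc[j] = Xv; Yc[j] = best;
      tr[j] = (unsigned char)(argM | (argX << 2) | (argY << 4));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score = Mp[m]; int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  std::string out_a, out_b;
  out_a.reserve(n + m); out_b.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char t = trace[(size_t)i * W + j];
    if (state == 0) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
      state = t & 3; --i; --j;
    } else if (state == 1) {
      out_a.push_back(a[i - 1]); out_b.push_back('-');
      state = (t >> 2) & 3; --i;
    } else {
      out_a.push_back('-'); out_b.push_back(b[j - 1]);
      state = (t >> 4) & 3; --j;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());

  return List::create(_["aligned1"] = out_a, _["aligned2"] = out_b,
                      _["score"] = score);
}
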