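#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh), deterministic traceback.
//
// Scoring: match / mismatch per aligned pair; a gap of length L costs
// gap_open + (L - 1) * gap_extend (gap_open covers the first gap base).
// 'N' never matches anything (scored as mismatch, not counted as identity).
//
// States: M = diagonal, X = gap in b (a base over '-'), Y = gap in a.
// Tie-break everywhere: M before X before Y, i.e. match/mismatch preferred
// over a gap in b, preferred over a gap in a.  With a = center and
// b = member this is the documented match > mismatch > gap-in-member >
// gap-in-center order.
//
// end_free: end gaps in either sequence are free (overlap-style alignment,
// used for the identity computation); the returned score excludes them.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool end_free) {
  const int n = a.size(), m = b.size();
  const size_t W = (size_t)m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  auto idx = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[idx(i, 0)] = end_free ? 0.0 : gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j)
    Y[idx(0, j)] = end_free ? 0.0 : gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      double s = (ai == bj && ai != 'N') ? match : mismatch;
      size_t d = idx(i - 1, j - 1), u = idx(i - 1, j), l = idx(i, j - 1),
             c = idx(i, j);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + s;
      double xo = (M[u] > Y[u] ? M[u] : Y[u]) + gap_open;
      double xe = X[u] + gap_extend;
      X[c] = xo > xe ? xo : xe;
      double yo = (M[l] > X[l] ? M[l] : X[l]) + gap_open;
      double ye = Y[l] + gap_extend;
      Y[c] = yo > ye ? yo : ye;
    }
  }

  // Endpoint: full corner for global; best last-row/last-col cell when end
  // gaps are free.  Scan order makes the choice deterministic: the corner
  // first, then last column bottom-up, then last row right-to-left;
  // replacement only on strictly greater score.
  int ei = n, ej = m;
  auto cell = [&](int i, int j) {
    double v = M[idx(i, j)];
    if (X[idx(i, j)] > v) v = X[idx(i, j)];
    if (Y[idx(i, j)] > v) v = Y[idx(i, j)];
    return v;
  };
  double best_score = cell(n, m);
  if (end_free) {
    for (int i = n - 1; i >= 0; --i)
      if (cell(i, m) > best_score) { best_score = cell(i, m); ei = i; ej = m; }
    for (int j = m - 1; j >= 0; --j)
      if (cell(n, j) > best_score) { best_score = cell(n, j); ei = n; ej = j; }
  }

  // Traceback from (ei, ej); state preference M > X > Y at every step.
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  // trailing free end gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej;
  double v = cell(ei, ej);
  int state; // 0 = M, 1 = X, 2 = Y
  const double eps = 1e-9;
  if (std::abs(M[idx(i, j)] - v) < eps) state = 0;
  else if (std::abs(X[idx(i, j)] - v) < eps) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (i == 0) {
      --j; ra.push_back('-'); rb.push_back(b[j]);
      continue;
    }
    if (j == 0) {
      --i; ra.push_back(a[i]); rb.push_back('-');
      continue;
    }
    if (state == 0) {
      const char ai = a[i - 1], bj = b[j - 1];
      double s = (ai == bj && ai != 'N') ? match : mismatch;
      double need = M[idx(i, j)] - s;
      size_t d = idx(i - 1, j - 1);
      ra.push_back(ai); rb.push_back(bj);
      --i; --j;
      if (std::abs(M[d] - need) < eps) state = 0;
      else if (std::abs(X[d] - need) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      size_t u = idx(i - 1, j);
      double cur = X[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (i == 0) { state = 0; continue; } // rest handled by the i==0 branch
      if (std::abs(M[u] + gap_open - cur) < eps) state = 0;
      else if (std::abs(X[u] + gap_extend - cur) < eps) state = 1;
      else state = 2;
    } else {
      size_t l = idx(i, j - 1);
      double cur = Y[idx(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (j == 0) { state = 0; continue; }
      if (std::abs(M[l] + gap_open - cur) < eps) state = 0;
      else if (std::abs(Y[l] + gap_extend - cur) < eps) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int n_match = 0, n_cols = ra.size();
  for (int k = 0; k < n_cols; ++k)
    if (ra[k] == rb[k] && ra[k] != '-' && ra[k] != 'N') ++n_match;

  return List::create(_["score"] = best_score, _["a"] = ra, _["b"] = rb,
                      _["n_match"] = n_match);
}

// Count of positions at which two equal-length strings differ ('N' always
// counts as a difference).  Used for flanking-anchor comparison.
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  int n = a.size() < b.size() ? a.size() : b.size();
  int d = 0;
  for (int k = 0; k < n; ++k)
    if (a[k] != b[k] || a[k] == 'N') ++d;
  return d;
}
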