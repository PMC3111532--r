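// Needleman-Wunsch global alignment with affine gaps (Gotoh three-state
// dynamic program). A gap of length L costs open + L * extend, terminal
// gaps included. Traceback ties are broken deterministically: diagonal
// first, then up (gap in the second sequence), then left.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, NumericMatrix sub,
              CharacterVector alphabet, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // char -> substitution matrix index
  std::vector<int> idx(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    idx[(unsigned char) Rcpp::as<std::string>(alphabet[k])[0]] = k;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char) a[i]];
    if (ai[i] < 0) stop("character not in alphabet: %c", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char) b[j]];
    if (bi[j] < 0) stop("character not in alphabet: %c", b[j]);
  }

  const int W = m + 1;
  // M: a[i] aligned to b[j]; X: a[i] aligned to gap; Y: b[j] aligned to gap
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      const int d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j;
      const int l = i * W + (j - 1);
      double s = sub(ai[i - 1], bi[j - 1]);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + s;
      double xo = M[u] - (gap_open + gap_extend);
      double xe = X[u] - gap_extend;
      X[c] = xo >= xe ? xo : xe;
      double yo = M[l] - (gap_open + gap_extend);
      double ye = Y[l] - gap_extend;
      Y[c] = yo >= ye ? yo : ye;
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;  // 0 = M, 1 = X, 2 = Y; preference M > X > Y
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const int d = (i - 1) * W + (j - 1);
      double need = M[c] - sub(ai[i - 1], bi[j - 1]);
      --i; --j;
      // diagonal predecessor preference: M, then X, then Y
      if (std::abs(M[d] - need) < eps) state = 0;
      else if (std::abs(X[d] - need) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      const int u = (i - 1) * W + j;
      // gap-open preferred over gap-extend on ties (shorter gap runs)
      state = (std::abs(X[c] - (M[u] - (gap_open + gap_extend))) < eps) ? 0 : 1;
      --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const int l = i * W + (j - 1);
      state = (std::abs(Y[c] - (M[l] - (gap_open + gap_extend))) < eps) ? 0 : 2;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == rb[k] && ra[k] != '-') ++matches;
  }
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["matches"] = matches,
                      _["length"] = (int) ra.size());
}
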