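// Needleman-Wunsch-Gotoh three-state global alignment with affine gap
// penalties and free (unpenalized) end gaps.
//
// Gap cost convention: a gap run of length L costs gap_open for its first
// column and gap_extend for each subsequent column, i.e.
// gap_open + (L - 1) * gap_extend. End gap runs (touching either end of the
// alignment) cost 0.
//
// Deterministic tie-breaking during traceback: diagonal (match state M) is
// preferred over up (gap in B, state X) over left (gap in A, state Y).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align(std::string a, std::string b, NumericMatrix submat,
                 std::string alphabet, double gap_open, double gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  // residue -> matrix index
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> ai(m), bi(n);
  for (int i = 0; i < m; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("illegal residue '%c' at position %d of first sequence", a[i], i + 1);
  }
  for (int j = 0; j < n; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("illegal residue '%c' at position %d of second sequence", b[j], j + 1);
  }

  // DP matrices, (m+1) x (n+1), flattened.
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) X[i * W] = 0.0;   // free leading gap in B
  for (int j = 1; j <= n; ++j) Y[j] = 0.0;       // free leading gap in A

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = submat(ai[i - 1], bi[j - 1]);
      double dm = M[d], dx = X[d], dy = Y[d];
      double best = dm >= dx ? (dm >= dy ? dm : dy) : (dx >= dy ? dx : dy);
      M[c] = s + best;
      double x1 = M[u] - gap_open, x2 = X[u] - gap_extend, x3 = Y[u] - gap_open;
      X[c] = x1 >= x2 ? (x1 >= x3 ? x1 : x3) : (x2 >= x3 ? x2 : x3);
      double y1 = M[l] - gap_open, y2 = Y[l] - gap_extend, y3 = X[l] - gap_open;
      Y[c] = y1 >= y2 ? (y1 >= y3 ? y1 : y3) : (y2 >= y3 ? y2 : y3);
    }
  }

  // Best end point with free trailing gaps: any cell in the last row or last
  // column; the remaining residues of the other sequence become a free gap.
  // Candidate order implements the tie-break (corner first, then last column
  // bottom-up, then last row right-to-left; state order M > X > Y).
  double score = NEG;
  int ei = m, ej = n, estate = 0;  // 0 = M, 1 = X, 2 = Y
  {
    std::vector<double> cand;
    // pass 1: find max
    for (int i = m; i >= 1; --i) {
      const int c = i * W + n;
      if (M[c] > score) score = M[c];
      if (X[c] > score) score = X[c];
      if (Y[c] > score) score = Y[c];
    }
    for (int j = n; j >= 1; --j) {
      const int c = m * W + j;
      if (M[c] > score) score = M[c];
      if (X[c] > score) score = X[c];
      if (Y[c] > score) score = Y[c];
    }
    // pass 2: first candidate attaining max, in preference order
    bool found = false;
    const int corner = m * W + n;
    const double states_eps = 0.0; (void)states_eps;
    if (M[corner] == score) { ei = m; ej = n; estate = 0; found = true; }
    else if (X[corner] == score) { ei = m; ej = n; estate = 1; found = true; }
    else if (Y[corner] == score) { ei = m; ej = n; estate = 2; found = true; }
    if (!found) {
      for (int i = m - 1; i >= 1 && !found; --i) {
        const int c = i * W + n;
        if (M[c] == score) { ei = i; ej = n; estate = 0; found = true; }
        else if (X[c] == score) { ei = i; ej = n; estate = 1; found = true; }
        else if (Y[c] == score) { ei = i; ej = n; estate = 2; found = true; }
      }
    }
    if (!found) {
      for (int j = n - 1; j >= 1 && !found; --j) {
        const int c = m * W + j;
        if (M[c] == score) { ei = m; ej = j; estate = 0; found = true; }
        else if (X[c] == score) { ei = m; ej = j; estate = 1; found = true; }
        else if (Y[c] == score) { ei = m; ej = j; estate = 2; found = true; }
      }
    }
  }

  // The fully staggered alignment (all of A against a leading gap, all of B
  // against a trailing gap) has two free end runs and score 0; the DP above
  // cannot represent it because it has no aligned column. It wins only when
  // strictly better than every DP path.
  if (0.0 > score) {
    std::string sa = a + std::string(n, '-');
    std::string sb = std::string(m, '-') + b;
    return List::create(_["aligned_A"] = sa, _["aligned_B"] = sb,
                        _["score"] = 0.0);
  }

  std::string ra, rb;  // built reversed
  // trailing free gaps from (m, n) down to the chosen end point
  for (int i = m; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = n; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej, st = estate;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (st == 0) {  // M
      if (i == 0 || j == 0) stop("traceback error (M at boundary)");
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const int d = (i - 1) * W + (j - 1);
      double target = M[i * W + j] - submat(ai[i - 1], bi[j - 1]);
      if (i == 1 && j == 1) { st = 0; }
      else if (std::abs(M[d] - target) < tol) st = 0;
      else if (std::abs(X[d] - target) < tol) st = 1;
      else st = 2;
      --i; --j;
      if (i == 0 && j == 0) break;
      // boundary states: X[i][0] / Y[0][j] represent free leading gaps
      if (j == 0 && st == 0 && i > 0) st = 1;
      if (i == 0 && st == 0 && j > 0) st = 2;
    } else if (st == 1) {  // X: gap in B, consumes a_i
      if (j == 0) {  // free leading gap in B
        while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
        break;
      }
      ra.push_back(a[i - 1]); rb.push_back('-');
      const int u = (i - 1) * W + j;
      double cur = X[i * W + j];
      if (i - 1 == 0) {
        // came from row 0: only Y[0][j] (leading gap in A) or start
        --i;
        if (j > 0) st = 2; else break;
        continue;
      }
      if (std::abs(M[u] - gap_open - cur) < tol) st = 0;
      else if (std::abs(X[u] - gap_extend - cur) < tol) st = 1;
      else st = 2;
      --i;
      if (j == 0 && st == 0) st = 1;
    } else {  // Y: gap in A, consumes b_j
      if (i == 0) {  // free leading gap in A
        while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
        break;
      }
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const int l = i * W + (j - 1);
      double cur = Y[i * W + j];
      if (j - 1 == 0) {
        --j;
        if (i > 0) st = 1; else break;
        continue;
      }
      if (std::abs(M[l] - gap_open - cur) < tol) st = 0;
      else if (std::abs(Y[l] - gap_extend - cur) < tol) st = 2;
      else st = 1;
      --j;
    }
  }

  std::string outa(ra.rbegin(), ra.rend()), outb(rb.rbegin(), rb.rend());
  return List::create(_["aligned_A"] = outa, _["aligned_B"] = outb,
                      _["score"] = score);
}
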