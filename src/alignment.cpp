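#include <Rcpp.h>
using namespace Rcpp;

// Affine gap convention used package-wide: a gap of length k costs
// open + (k-1) * ext.

static const double NEG_INF = -1e18;
static const double EPS = 1e-9;

// Global affine-gap (Gotoh) alignment over a precomputed pair-score
// matrix C (n1 x n2). Tie-breaking in traceback: prefer match (M) over
// gap-in-first (Y, consumes the second sequence) over gap-in-second (X).
// Returns aligned 1-based index vectors (0 = gap) and the optimal score.
static List gotoh_core(const NumericMatrix& C, double open, double ext) {
  int n1 = C.nrow(), n2 = C.ncol();
  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) { M(i,j) = X(i,j) = Y(i,j) = NEG_INF; }
  M(0,0) = 0.0;
  for (int i = 1; i <= n1; ++i) X(i,0) = -(open + (i - 1) * ext);
  for (int j = 1; j <= n2; ++j) Y(0,j) = -(open + (j - 1) * ext);
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double prev = std::max(M(i-1,j-1), std::max(X(i-1,j-1), Y(i-1,j-1)));
      M(i,j) = C(i-1,j-1) + prev;
      X(i,j) = std::max(M(i-1,j) - open,
                        std::max(X(i-1,j) - ext, Y(i-1,j) - open));
      Y(i,j) = std::max(M(i,j-1) - open,
                        std::max(X(i,j-1) - open, Y(i,j-1) - ext));
    }
  }
  double best = std::max(M(n1,n2), std::max(X(n1,n2), Y(n1,n2)));
  // traceback
  std::vector<int> ai, bi;
  int i = n1, j = n2;
  int state; // 0 = M, 1 = Y (gap in first), 2 = X (gap in second)
  if (M(i,j) >= best - EPS) state = 0;
  else if (Y(i,j) >= best - EPS) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double tgt = M(i,j) - C(i-1,j-1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i,j) >= tgt - EPS) state = 0;
      else if (Y(i,j) >= tgt - EPS) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in first, consumes second
      ai.push_back(0); bi.push_back(j);
      double tgt = Y(i,j);
      if (M(i,j-1) - open >= tgt - EPS) { state = 0; }
      else if (Y(i,j-1) - ext >= tgt - EPS) { state = 1; }
      else { state = 2; }
      --j;
    } else { // gap in second, consumes first
      ai.push_back(i); bi.push_back(0);
      double tgt = X(i,j);
      if (M(i-1,j) - open >= tgt - EPS) { state = 0; }
      else if (Y(i-1,j) - open >= tgt - EPS) { state = 1; }
      else { state = 2; }
      --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}

// [[Rcpp::export]]
List cpp_gotoh(IntegerVector a, IntegerVector b, NumericMatrix sub,
               double open, double ext) {
  int n1 = a.size(), n2 = b.size();
  NumericMatrix C(n1, n2);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      C(i,j) = sub(a[i], b[j]);
  return gotoh_core(C, open, ext);
}

// Profile-profile global alignment: fa, fb are residue-count matrices
// (alphabet x ncol, gaps excluded); the column-pair score is the
// count-weighted mean substitution score.
// [[Rcpp::export]]
List cpp_profile_nw(NumericMatrix fa, NumericMatrix fb, NumericMatrix sub,
                    double open, double ext) {
  int n1 = fa.ncol(), n2 = fb.ncol(), A = sub.nrow();
  NumericMatrix C(n1, n2);
  NumericVector wa(n1), wb(n2);
  for (int i = 0; i < n1; ++i)
    for (int r = 0; r < A; ++r) wa[i] += fa(r, i);
  for (int j = 0; j < n2; ++j)
    for (int r = 0; r < A; ++r) wb[j] += fb(r, j);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      if (wa[i] <= 0 || wb[j] <= 0) { C(i,j) = 0.0; continue; }
      double s = 0.0;
      for (int r = 0; r < A; ++r) {
        if (fa(r, i) <= 0) continue;
        for (int q = 0; q < A; ++q) {
          if (fb(q, j) <= 0) continue;
          s += fa(r, i) * fb(q, j) * sub(r, q);
        }
      }
      C(i,j) = s / (wa[i] * wb[j]);
    }
  }
  return gotoh_core(C, open, ext);
}

// Glocal scan: the whole profile (rows of S) is aligned against a local
// region of the target (columns of S); target overhangs are free,
// internal gaps on both sides are affine. S(i-1, j-1) is the log-odds
// score of profile column i against target residue j.
// Returns the optimal score and, per profile column, the matched target
// position (0 if the column was deleted).
// [[Rcpp::export]]
List cpp_glocal(NumericMatrix S, double open, double ext) {
  int m = S.nrow(), L = S.ncol();
  // states: M match, D profile-column deletion, I target insertion
  NumericMatrix M(m + 1, L + 1), D(m + 1, L + 1), I(m + 1, L + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= L; ++j) { M(i,j) = D(i,j) = I(i,j) = NEG_INF; }
  for (int j = 1; j <= L; ++j) M(1, j) = S(0, j - 1); // free leading overhang
  for (int j = 0; j <= L; ++j) D(1, j) = -open;
  for (int j = 1; j <= L; ++j) { // insertions following profile column 1
    double ins = std::max(M(1,j-1) - open,
                          std::max(I(1,j-1) - ext, D(1,j-1) - open));
    if (ins > NEG_INF / 2) I(1, j) = ins;
  }
  for (int i = 2; i <= m; ++i) {
    for (int j = 0; j <= L; ++j) {
      if (j >= 1) {
        double prev = std::max(M(i-1,j-1), std::max(D(i-1,j-1), I(i-1,j-1)));
        if (prev > NEG_INF / 2) M(i,j) = S(i - 1, j - 1) + prev;
      }
      double d = std::max(M(i-1,j) - open,
                          std::max(D(i-1,j) - ext, I(i-1,j) - open));
      if (d > NEG_INF / 2) D(i,j) = d;
      if (j >= 1) {
        double ins = std::max(M(i,j-1) - open,
                              std::max(I(i,j-1) - ext, D(i,j-1) - open));
        if (ins > NEG_INF / 2) I(i,j) = ins;
      }
    }
  }
  // insertions within row 1 (between free start and column 1) are useless;
  // omitted. Find the best end: any target position, free trailing overhang.
  double best = NEG_INF;
  int bj = 0, bstate = 0; // 0 = M, 1 = D
  for (int j = 0; j <= L; ++j) {
    if (M(m, j) > best + EPS) { best = M(m, j); bj = j; bstate = 0; }
    if (D(m, j) > best + EPS) { best = D(m, j); bj = j; bstate = 1; }
  }
  IntegerVector matched(m);
  int i = m, j = bj, state = bstate;
  while (i >= 1) {
    if (state == 0) { // M
      matched[i - 1] = j;
      if (i == 1) break;
      double tgt = M(i,j) - S(i - 1, j - 1);
      --i; --j;
      if (M(i,j) >= tgt - EPS) state = 0;
      else if (D(i,j) >= tgt - EPS) state = 1;
      else state = 2;
    } else if (state == 1) { // D
      matched[i - 1] = 0;
      if (i == 1) break;
      double tgt = D(i,j);
      if (M(i-1,j) - open >= tgt - EPS) state = 0;
      else if (D(i-1,j) - ext >= tgt - EPS) state = 1;
      else state = 2;
      --i;
    } else { // I: stays on row i, consumes target only
      double tgt = I(i,j);
      int next;
      if (M(i,j-1) - open >= tgt - EPS) next = 0;
      else if (I(i,j-1) - ext >= tgt - EPS) next = 2;
      else next = 1;
      --j;
      state = next;
    }
  }
  return List::create(_["score"] = best, _["matched"] = matched);
}
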