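#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion.  A gap of length L costs gap_open + gap_extend * L.  States:
// M = residues paired (diagonal), X = gap in b (move down / "up" in
// traceback), Y = gap in a (move left).  All tie-breaks, both inside the
// recursion and at traceback, prefer M over X over Y (diagonal > up > left)
// so the traceback is deterministic.

static const double NEG = -1e18;

static inline int arg3(double m, double x, double y) {
  // priority M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + gap_extend * i);
    PX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + gap_extend * j);
    PY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double om = M(i - 1, j) - gap_open - gap_extend;
      double ox = X(i - 1, j) - gap_extend;
      double oy = Y(i - 1, j) - gap_open - gap_extend;
      PX(i, j) = arg3(om, ox, oy);
      X(i, j) = std::max(om, std::max(ox, oy));

      double pm = M(i, j - 1) - gap_open - gap_extend;
      double px = X(i, j - 1) - gap_open - gap_extend;
      double py = Y(i, j - 1) - gap_extend;
      PY(i, j) = arg3(pm, px, py);
      Y(i, j) = std::max(pm, std::max(px, py));

      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      PM(i, j) = arg3(dm, dx, dy);
      M(i, j) = sub(a[i - 1], b[j - 1]) + std::max(dm, std::max(dx, dy));
    }
  }
  int state = arg3(M(n, m), X(n, m), Y(n, m));
  double score = (state == 0) ? M(n, m) : (state == 1 ? X(n, m) : Y(n, m));

  std::vector<int> pa, pb;  // 1-based positions, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = PM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = PX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; state = prev;
    } else {
      int prev = PY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = wrap(pa),
                      _["path_b"] = wrap(pb));
}

// Score-only variant (rolling rows), used for all-against-all RBH scoring.
// [[Rcpp::export]]
double nw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1),
                      M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = 0.0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; X0[j] = NEG;
    Y0[j] = -(gap_open + gap_extend * j);
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = -(gap_open + gap_extend * i);
    for (int j = 1; j <= m; ++j) {
      X1[j] = std::max(M0[j] - gap_open - gap_extend,
               std::max(X0[j] - gap_extend,
                        Y0[j] - gap_open - gap_extend));
      Y1[j] = std::max(M1[j - 1] - gap_open - gap_extend,
               std::max(X1[j - 1] - gap_open - gap_extend,
                        Y1[j - 1] - gap_extend));
      M1[j] = sub(a[i - 1], b[j - 1]) +
              std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return std::max(M0[m], std::max(X0[m], Y0[m]));
}

// [[Rcpp::export]]
NumericMatrix nw_score_matrix_cpp(List a_codes, List b_codes,
                                  NumericMatrix sub, double gap_open,
                                  double gap_extend) {
  const int na = a_codes.size(), nb = b_codes.size();
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    IntegerVector ai = a_codes[i];
    for (int j = 0; j < nb; ++j) {
      IntegerVector bj = b_codes[j];
      out(i, j) = nw_score_cpp(ai, bj, sub, gap_open, gap_extend);
    }
  }
  return out;
}

// Exhaustive enumeration oracle: walks every monotone alignment path,
// accumulating the affine score move by move, and keeps the maximum.  It is
// independent of the dynamic-programming recursion above (no tables, no
// optimal-substructure assumption) and only feasible for short sequences.
static void bf_rec(const IntegerVector& a, const IntegerVector& b,
                   const NumericMatrix& sub, double go, double ge,
                   int i, int j, int last, double score, double& best) {
  const int n = a.size(), m = b.size();
  if (i == n && j == m) {
    if (score > best) best = score;
    return;
  }
  if (i < n && j < m)
    bf_rec(a, b, sub, go, ge, i + 1, j + 1, 0,
           score + sub(a[i], b[j]), best);
  if (i < n) {
    double cost = (last == 1) ? ge : go + ge;
    bf_rec(a, b, sub, go, ge, i + 1, j, 1, score - cost, best);
  }
  if (j < m) {
    double cost = (last == 2) ? ge : go + ge;
    bf_rec(a, b, sub, go, ge, i, j + 1, 2, score - cost, best);
  }
}

// [[Rcpp::export]]
double nw_score_bruteforce_cpp(IntegerVector a, IntegerVector b,
                               NumericMatrix sub, double gap_open,
                               double gap_extend) {
  if (a.size() > 10 || b.size() > 10)
    stop("brute-force oracle limited to sequences of length <= 10");
  double best = NEG;
  bf_rec(a, b, sub, gap_open, gap_extend, 0, 0, -1, 0.0, best);
  return best;
}
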