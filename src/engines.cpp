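// Nearest-neighbor dynamic programming engines:
//  - duplex_dp: minimum-free-energy intermolecular miRNA/target hybrid
//    (no intramolecular pairs, no multibranch loops)
//  - fold_dp: Zuker-style intramolecular MFE fold of a target window
//    (hairpins, stacks, bulges, internal loops, linear multibranch model)
//
// Bases are encoded 0=A 1=C 2=G 3=U 4=N. Pair types follow the R-side
// PAIR_TYPES order: 1=CG 2=GC 3=GU 4=UG 5=AU 6=UA, 0 = not pairable.
// Loop tables are passed from R with extrapolation / disallowed sizes
// already resolved (+Inf where a size is not admissible).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const double INF = R_PosInf;
static const double TOL = 1e-9;

static inline int pair_code(int a, int b) {
  if (a == 1 && b == 2) return 1;  // CG
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 2 && b == 3) return 3;  // GU
  if (a == 3 && b == 2) return 4;  // UG
  if (a == 0 && b == 3) return 5;  // AU
  if (a == 3 && b == 0) return 6;  // UA
  return 0;
}

struct NNModel {
  NumericMatrix stack;          // 6x6, [outer-1, inner_reversed-1]
  NumericVector bulge;          // index size-1
  NumericVector internal_init;  // index size-1
  NumericVector hairpin;        // index size-1 (pre-extrapolated)
  double ml_close, ml_branch, ml_unpaired;
  double ninio, ninio_max, terminal_au;
  int max_loop;

  inline double au(int pt) const { return pt >= 3 ? terminal_au : 0.0; }
  inline double stk(int pt_outer, int pt_inner_rev) const {
    return stack(pt_outer - 1, pt_inner_rev - 1);
  }
  inline double loop(int l1, int l2) const {  // internal/bulge between pairs
    int sz = l1 + l2;
    if (sz < 1 || sz > max_loop) return INF;
    if (l1 == 0 || l2 == 0) return bulge[sz - 1];
    double e = internal_init[sz - 1];
    double asym = std::abs(l1 - l2) * ninio;
    return e + (asym > ninio_max ? ninio_max : asym);
  }
  inline double hp(int sz) const {
    if (sz < 3 || sz > hairpin.size()) return INF;
    return hairpin[sz - 1];
  }
};

// ---------------------------------------------------------------------------
// Intermolecular duplex
// ---------------------------------------------------------------------------

// V[i][j]: min energy of a sub-duplex whose 5'(miRNA)-most pair is
// (i on miRNA, j on window), including everything 3'-ward of it (loops,
// stacks, the far helix-end AU penalty) but neither the initiation term nor
// the AU penalty on the near side of (i, j).
// [[Rcpp::export(name = ".duplex_dp")]]
List duplex_dp(IntegerVector m, IntegerVector w, NumericMatrix stack,
               NumericVector bulge, NumericVector internal_init,
               double ninio, double ninio_max, double terminal_au,
               double duplex_init, int max_loop) {
  NNModel nn{stack, bulge, internal_init, NumericVector(0),
             0, 0, 0, ninio, ninio_max, terminal_au, max_loop};
  const int M = m.size(), W = w.size();
  std::vector<std::vector<double>> V(M, std::vector<double>(W, INF));
  std::vector<std::vector<int>> PT(M, std::vector<int>(W, 0));
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < W; ++j) PT[i][j] = pair_code(m[i], w[j]);

  for (int i = M - 1; i >= 0; --i) {
    for (int j = 0; j < W; ++j) {
      int pt = PT[i][j];
      if (!pt) continue;
      double best = nn.au(pt);  // terminate the duplex here
      int kmax = std::min(M - 1, i + 1 + nn.max_loop);
      for (int k = i + 1; k <= kmax; ++k) {
        int l1 = k - i - 1;
        int lmin = std::max(0, j - 1 - (nn.max_loop - l1));
        for (int l = j - 1; l >= lmin; --l) {
          int qt = PT[k][l];
          if (!qt || !R_finite(V[k][l])) continue;
          int l2 = j - l - 1;
          double e;
          if (l1 == 0 && l2 == 0) {
            e = nn.stk(pt, pair_code(w[l], m[k]));
          } else {
            e = nn.loop(l1, l2) + nn.au(pt) + nn.au(qt);
          }
          double cand = e + V[k][l];
          if (cand < best) best = cand;
        }
      }
      V[i][j] = best;
    }
  }

  double mfe = INF;
  int si = -1, sj = -1;
  for (int i = 0; i < M; ++i)
    for (int j = W - 1; j >= 0; --j) {
      if (!PT[i][j] || !R_finite(V[i][j])) continue;
      double e = duplex_init + nn.au(PT[i][j]) + V[i][j];
      if (e < mfe - TOL) { mfe = e; si = i; sj = j; }
    }
  if (si < 0) {
    return List::create(_["mfe"] = INF,
                        _["pairs"] = IntegerMatrix(0, 2));
  }

  // traceback: at each pair, prefer terminating, then transitions scanned
  // k ascending / l descending (stacks come first on each diagonal step)
  std::vector<std::array<int, 2>> pairs;
  int i = si, j = sj;
  while (true) {
    pairs.push_back({i, j});
    int pt = PT[i][j];
    double v = V[i][j];
    if (std::fabs(nn.au(pt) - v) < TOL) break;
    bool moved = false;
    int kmax = std::min(M - 1, i + 1 + nn.max_loop);
    for (int k = i + 1; k <= kmax && !moved; ++k) {
      int l1 = k - i - 1;
      int lmin = std::max(0, j - 1 - (nn.max_loop - l1));
      for (int l = j - 1; l >= lmin; --l) {
        int qt = PT[k][l];
        if (!qt || !R_finite(V[k][l])) continue;
        int l2 = j - l - 1;
        double e = (l1 == 0 && l2 == 0)
          ? nn.stk(pt, pair_code(w[l], m[k]))
          : nn.loop(l1, l2) + nn.au(pt) + nn.au(qt);
        if (std::fabs(e + V[k][l] - v) < TOL) {
          i = k; j = l; moved = true; break;
        }
      }
    }
    if (!moved) stop("duplex traceback failed (internal error)");
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    pm(p, 0) = pairs[p][0];
    pm(p, 1) = pairs[p][1];
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = pm);
}

// ---------------------------------------------------------------------------
// Intramolecular fold (Zuker MFE with linear multiloop model)
// ---------------------------------------------------------------------------

struct FoldArrays {
  int n;
  std::vector<double> V, WM;
  double& v(int i, int j) { return V[(size_t)i * n + j]; }
  double& wm(int i, int j) { return WM[(size_t)i * n + j]; }
};

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector s, NumericMatrix stack, NumericVector bulge,
             NumericVector internal_init, NumericVector hairpin,
             double ml_close, double ml_branch, double ml_unpaired,
             double ninio, double ninio_max, double terminal_au,
             int max_loop) {
  NNModel nn{stack, bulge, internal_init, hairpin,
             ml_close, ml_branch, ml_unpaired,
             ninio, ninio_max, terminal_au, max_loop};
  const int n = s.size();
  if (n < 5) {
    return List::create(_["mfe"] = 0.0, _["pairs"] = IntegerMatrix(0, 2));
  }
  FoldArrays A;
  A.n = n;
  A.V.assign((size_t)n * n, INF);
  A.WM.assign((size_t)n * n, INF);
  std::vector<int> PT((size_t)n * n, 0);
  auto pt = [&](int i, int j) { return PT[(size_t)i * n + j]; };
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) PT[(size_t)i * n + j] = pair_code(s[i], s[j]);

  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // ---- V(i,j): (i,j) paired
      if (pt(i, j)) {
        double auij = nn.au(pt(i, j));
        double best = nn.hp(j - i - 1) + auij;  // hairpin
        // stack + interior/bulge
        int kmax = std::min(j - 1, i + 1 + nn.max_loop);
        for (int k = i + 1; k <= kmax; ++k) {
          int l1 = k - i - 1;
          int lmin = std::max(k + 1, j - 1 - (nn.max_loop - l1));
          for (int l = j - 1; l >= lmin; --l) {
            if (!pt(k, l) || !R_finite(A.v(k, l))) continue;
            int l2 = j - l - 1;
            double e;
            if (l1 == 0 && l2 == 0) {
              e = nn.stk(pt(i, j), pair_code(s[l], s[k]));
            } else {
              e = nn.loop(l1, l2) + auij + nn.au(pt(k, l));
            }
            double cand = e + A.v(k, l);
            if (cand < best) best = cand;
          }
        }
        // multibranch closing
        for (int h = i + 2; h <= j - 2; ++h) {
          double a = A.wm(i + 1, h - 1), b = A.wm(h, j - 1);
          if (!R_finite(a) || !R_finite(b)) continue;
          double cand = nn.ml_close + nn.ml_branch + auij + a + b;
          if (cand < best) best = cand;
        }
        A.v(i, j) = best;
      }
      // ---- WM(i,j): part of a multiloop, >= 1 branch
      double best = INF;
      if (R_finite(A.v(i, j)))
        best = A.v(i, j) + nn.ml_branch + nn.au(pt(i, j));
      if (R_finite(A.wm(i + 1, j)))
        best = std::min(best, A.wm(i + 1, j) + nn.ml_unpaired);
      if (R_finite(A.wm(i, j - 1)))
        best = std::min(best, A.wm(i, j - 1) + nn.ml_unpaired);
      for (int k = i + 1; k <= j; ++k) {
        double a = A.wm(i, k - 1), b = (k <= j) ? A.wm(k, j) : INF;
        if (!R_finite(a) || !R_finite(b)) continue;
        best = std::min(best, a + b);
      }
      A.wm(i, j) = best;
    }
  }

  // external loop
  std::vector<double> W(n + 1, 0.0);  // W[j+1] = min energy over s[0..j]
  for (int j = 0; j < n; ++j) {
    double best = W[j];  // j unpaired
    for (int i = 0; i + 4 <= j; ++i) {
      if (!pt(i, j) || !R_finite(A.v(i, j))) continue;
      double cand = W[i] + A.v(i, j) + nn.au(pt(i, j));
      if (cand < best) best = cand;
    }
    W[j + 1] = best;
  }
  double mfe = W[n];

  // traceback
  std::vector<std::array<int, 2>> pairs;
  // work items: {0=external segment [0..j], 1=V(i,j), 2=WM(i,j)}
  std::vector<std::array<int, 3>> work;
  work.push_back({0, 0, n - 1});
  while (!work.empty()) {
    auto it = work.back();
    work.pop_back();
    int ty = it[0], i = it[1], j = it[2];
    if (ty == 0) {  // external [0..j]
      while (j >= 0) {
        if (std::fabs(W[j + 1] - W[j]) < TOL) { --j; continue; }
        bool moved = false;
        for (int i2 = 0; i2 + 4 <= j; ++i2) {
          if (!pt(i2, j) || !R_finite(A.v(i2, j))) continue;
          if (std::fabs(W[i2] + A.v(i2, j) + nn.au(pt(i2, j)) - W[j + 1]) < TOL) {
            work.push_back({1, i2, j});
            j = i2 - 1;
            moved = true;
            break;
          }
        }
        if (!moved) stop("fold traceback failed in exterior loop");
      }
    } else if (ty == 1) {  // V(i,j)
      pairs.push_back({i, j});
      double v = A.v(i, j);
      double auij = nn.au(pt(i, j));
      bool moved = false;
      // order: stack / interior (k asc, l desc), hairpin, multiloop (h asc)
      int kmax = std::min(j - 1, i + 1 + nn.max_loop);
      for (int k = i + 1; k <= kmax && !moved; ++k) {
        int l1 = k - i - 1;
        int lmin = std::max(k + 1, j - 1 - (nn.max_loop - l1));
        for (int l = j - 1; l >= lmin; --l) {
          if (!pt(k, l) || !R_finite(A.v(k, l))) continue;
          int l2 = j - l - 1;
          double e = (l1 == 0 && l2 == 0)
            ? nn.stk(pt(i, j), pair_code(s[l], s[k]))
            : nn.loop(l1, l2) + auij + nn.au(pt(k, l));
          if (std::fabs(e + A.v(k, l) - v) < TOL) {
            work.push_back({1, k, l});
            moved = true;
            break;
          }
        }
      }
      if (!moved && std::fabs(nn.hp(j - i - 1) + auij - v) < TOL) moved = true;
      if (!moved) {
        for (int h = i + 2; h <= j - 2; ++h) {
          double a = A.wm(i + 1, h - 1), b = A.wm(h, j - 1);
          if (!R_finite(a) || !R_finite(b)) continue;
          if (std::fabs(nn.ml_close + nn.ml_branch + auij + a + b - v) < TOL) {
            work.push_back({2, i + 1, h - 1});
            work.push_back({2, h, j - 1});
            moved = true;
            break;
          }
        }
      }
      if (!moved) stop("fold traceback failed in V");
    } else {  // WM(i,j)
      double v = A.wm(i, j);
      if (R_finite(A.v(i, j)) &&
          std::fabs(A.v(i, j) + nn.ml_branch + nn.au(pt(i, j)) - v) < TOL) {
        work.push_back({1, i, j});
        continue;
      }
      if (R_finite(A.wm(i + 1, j)) &&
          std::fabs(A.wm(i + 1, j) + nn.ml_unpaired - v) < TOL) {
        work.push_back({2, i + 1, j});
        continue;
      }
      if (R_finite(A.wm(i, j - 1)) &&
          std::fabs(A.wm(i, j - 1) + nn.ml_unpaired - v) < TOL) {
        work.push_back({2, i, j - 1});
        continue;
      }
      bool moved = false;
      for (int k = i + 1; k <= j; ++k) {
        double a = A.wm(i, k - 1), b = A.wm(k, j);
        if (!R_finite(a) || !R_finite(b)) continue;
        if (std::fabs(a + b - v) < TOL) {
          work.push_back({2, i, k - 1});
          work.push_back({2, k, j});
          moved = true;
          break;
        }
      }
      if (!moved) stop("fold traceback failed in WM");
    }
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    pm(p, 0) = pairs[p][0];
    pm(p, 1) = pairs[p][1];
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = pm);
}
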