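// Affine-gap pairwise DP engine shared by all alignment-facing modules.
//
// Bases are encoded 0=A 1=C 2=G 3=T 4=N; the 5x5 score matrix is supplied by
// the caller (row = first sequence, col = second). Gap convention: the first
// gap character of a run costs gap_open, each further character gap_extend.
// Coordinates in the returned hits are 0-based half-open.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// "unreachable" floor: far below any legitimate score, but with enough
// headroom that saturating arithmetic (no per-cell guards, which cost more
// than the DP itself) can never overflow or climb back into the legitimate
// score range: per-step drift is <= ~240 and paths are <= ~10^5 steps.
static const int NEG = -100000000;

// op codes in the returned run-length encoded path
static const int OP_M = 1; // seq1 base aligned to seq2 base
static const int OP_I = 2; // seq1 base aligned to gap
static const int OP_D = 3; // gap aligned to seq2 base

struct Hit {
  int score, gs, ge, cs, ce;
  std::vector<int> ops, lens;
};

static inline int max2(int a, int b) { return a > b ? a : b; }

// traceback byte layout: bits 0-1 = M predecessor (0 start, 1 M, 2 X, 3 Y),
// bit 2 = X predecessor (0 M, 1 X), bit 3 = Y predecessor (0 M, 1 Y)
static Hit traceback(int bi, int bj, int state, int score,
                     const std::vector<uint8_t>& tb, int m1) {
  std::vector<int> rops;
  int i = bi, j = bj, st = state;
  while (true) {
    uint8_t t = tb[(size_t)i * m1 + j];
    if (st == 0) { // M
      rops.push_back(OP_M);
      int pred = t & 3;
      --i; --j;
      if (pred == 0) break;
      st = pred - 1; // 1->M(0), 2->X(1), 3->Y(2)
    } else if (st == 1) { // X: seq1 base vs gap
      rops.push_back(OP_I);
      int pred = (t >> 2) & 1;
      --i;
      st = pred == 0 ? 0 : 1;
    } else { // Y: gap vs seq2 base
      rops.push_back(OP_D);
      int pred = (t >> 3) & 1;
      --j;
      st = pred == 0 ? 0 : 2;
    }
  }
  Hit h;
  h.score = score;
  h.gs = i; h.ge = bi;
  h.cs = j; h.ce = bj;
  // run-length encode reversed path
  for (int k = (int)rops.size() - 1; k >= 0;) {
    int op = rops[k], len = 0;
    while (k >= 0 && rops[k] == op) { ++len; --k; }
    h.ops.push_back(op);
    h.lens.push_back(len);
  }
  return h;
}

// One full DP pass. mode 0 = local (best cell), mode 1 = overlap/semi-global
// (free end gaps on both sequences: zero-cost start on either edge, best end
// on either far edge). masked rows of seq1 cannot be passed through.
static bool dp_pass(const std::vector<int>& g, const std::vector<int>& c,
                    const int* sub, int gap_open, int gap_extend,
                    int mode, const std::vector<uint8_t>& masked,
                    std::vector<uint8_t>& tb, Hit& out) {
  const int n = (int)g.size(), m = (int)c.size(), m1 = m + 1;
  std::vector<int> M((size_t)(n + 1) * m1, NEG), X(M), Y(M);
  int best = NEG, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const bool mk = masked[i - 1] != 0;
    const int* srow = sub + 5 * g[i - 1];
    size_t ro = (size_t)i * m1, po = (size_t)(i - 1) * m1;
    const bool edge_row = (i == 1);
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      int mv, xv;
      if (mk) {
        mv = NEG;
        xv = NEG;
      } else {
        // M state: fresh start allowed in local mode everywhere, in
        // semi-global mode on the top/left edges only
        int pv = NEG, pred = 0;
        if (mode == 0 || edge_row || j == 1) pv = 0;
        int d = M[po + j - 1];
        if (d > pv) { pv = d; pred = 1; }
        d = X[po + j - 1];
        if (d > pv) { pv = d; pred = 2; }
        d = Y[po + j - 1];
        if (d > pv) { pv = d; pred = 3; }
        mv = pv + srow[c[j - 1]];
        t |= pred;
        // X state (consume seq1 base i)
        int fromM = M[po + j] - gap_open;
        int fromX = X[po + j] - gap_extend;
        if (fromX > fromM) { xv = fromX; t |= 4; } else xv = fromM;
      }
      M[ro + j] = mv;
      X[ro + j] = xv;
      // Y state (consume seq2 base j)
      int fromM = M[ro + j - 1] - gap_open;
      int fromY = Y[ro + j - 1] - gap_extend;
      int yv;
      if (fromY > fromM) { yv = fromY; t |= 8; } else yv = fromM;
      Y[ro + j] = yv;
      tb[ro + j] = t;
      if (mode == 0) {
        if (mv > best) { best = mv; bi = i; bj = j; }
      } else if (i == n || j == m) {
        if (mv > best) { best = mv; bi = i; bj = j; }
      }
    }
  }
  if (bi < 0 || best <= NEG / 2) return false;
  out = traceback(bi, bj, 0, best, tb, m1);
  return true;
}

// Best local alignment score only: rolling rows, no traceback storage.
// Used for all-vs-all comparisons where only the score matters.
// [[Rcpp::export(name = ".align_score")]]
int align_score(IntegerVector g, IntegerVector c, IntegerMatrix sub,
                int gap_open, int gap_extend) {
  const int n = g.size(), m = c.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> subv(25);
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) subv[5 * i + j] = sub(i, j);
  std::vector<int> M(m + 1, NEG), X(m + 1, NEG), Y(m + 1, NEG);
  std::vector<int> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    M.swap(Mp); X.swap(Xp); Y.swap(Yp);
    M[0] = X[0] = Y[0] = NEG;
    const int* srow = subv.data() + 5 * g[i - 1];
    const int* mp = Mp.data(); const int* xp = Xp.data();
    const int* yp = Yp.data();
    int* Md = M.data(); int* Xd = X.data(); int* Yd = Y.data();
    for (int j = 1; j <= m; ++j) {
      int pv = mp[j - 1];
      if (xp[j - 1] > pv) pv = xp[j - 1];
      if (yp[j - 1] > pv) pv = yp[j - 1];
      if (pv < 0) pv = 0;
      int mv = pv + srow[c[j - 1]];
      Md[j] = mv;
      if (mv > best) best = mv;
      int a = mp[j] - gap_open, b = xp[j] - gap_extend;
      Xd[j] = a > b ? a : b;
      a = Md[j - 1] - gap_open; b = Yd[j - 1] - gap_extend;
      Yd[j] = a > b ? a : b;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".align_core")]]
List align_core(IntegerVector g, IntegerVector c, IntegerMatrix sub,
                int gap_open, int gap_extend, int min_score, int mode,
                int max_hits) {
  const int n = g.size(), m = c.size();
  std::vector<int> gv(g.begin(), g.end()), cv(c.begin(), c.end());
  std::vector<int> subv(25);
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) subv[5 * i + j] = sub(i, j);
  std::vector<uint8_t> masked(n, 0), tb((size_t)(n + 1) * (m + 1), 0);
  List hits;
  if (n == 0 || m == 0) return hits;
  int nhit = 0;
  while (nhit < max_hits) {
    Hit h;
    if (!dp_pass(gv, cv, subv.data(), gap_open, gap_extend, mode, masked, tb, h))
      break;
    if (h.score < min_score) break;
    hits.push_back(List::create(
      _["score"] = h.score,
      _["s1_start"] = h.gs, _["s1_end"] = h.ge,
      _["s2_start"] = h.cs, _["s2_end"] = h.ce,
      _["ops"] = IntegerVector(h.ops.begin(), h.ops.end()),
      _["lens"] = IntegerVector(h.lens.begin(), h.lens.end())));
    ++nhit;
    if (mode != 0) break; // semi-global: single best
    for (int i = h.gs; i < h.ge; ++i) masked[i] = 1;
    if (h.ge <= h.gs) break; // safety: zero-length footprint cannot recur
  }
  return hits;
}
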