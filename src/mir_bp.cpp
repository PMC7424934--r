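// Max-sum (min-cost) belief propagation, ICM polish, exhaustive search and
// energy evaluation for the 2x2-patch cluster graph.
//
// Layout (0-based in C++; R passes 0-based states):
//   cells:   idx = col * H + row                      (column-major)
//   patches: p   = j * (H-1) + i   for top-left (i, j)
//   patch cells: A=(i,j) B=(i,j+1) C=(i+1,j) D=(i+1,j+1)
//   slot tables [n x n x 4 x nP]: 0:AB 1:CD 2:AC 3:BD; first index is the
//     state of the first-named cell
//   incoming message directions per patch:
//     0: from above on (A,B); 1: from below on (C,D);
//     2: from left on (A,C); 3: from right on (B,D)
//
// The corner penalty applies when a patch has both a horizontal step
// (A!=B or C!=D) and a vertical step (A!=C or B!=D). Messages and
// min-marginals handle it exactly by case decomposition: the unrestricted
// minimum plus the penalty, against the two restricted families (no
// vertical step / no horizontal step) that provably avoid it.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstring>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Graph {
  int H, W, n, nP;
  const double *tab;
  const double *unary;
  double wc;

  const double *T(int p, int slot) const {
    return tab + ((size_t)p * 4 + slot) * n * n;
  }
  const double *U(int row, int col) const {
    return unary + (size_t)(col * H + row) * n;
  }
  int pid(int i, int j) const { return j * (H - 1) + i; }

  double patch_cost(int p, int a, int b, int c, int d) const {
    double v = T(p, 0)[a + n * b] + T(p, 1)[c + n * d] +
               T(p, 2)[a + n * c] + T(p, 3)[b + n * d];
    if (((a != b) || (c != d)) && ((a != c) || (b != d))) v += wc;
    return v;
  }

  double energy(const int *st) const {
    double e = 0.0;
    for (int j = 0; j < W - 1; ++j)
      for (int i = 0; i < H - 1; ++i) {
        int a = st[j * H + i], b = st[(j + 1) * H + i];
        int c = st[j * H + i + 1], d = st[(j + 1) * H + i + 1];
        e += patch_cost(pid(i, j), a, b, c, d);
        e += U(i, j)[a] + U(i, j + 1)[b] + U(i + 1, j)[c] + U(i + 1, j + 1)[d];
      }
    return e;
  }
};

static Graph make_graph(const NumericVector &tables, const NumericMatrix &unary,
                        int H, int W, int n, double w_corner) {
  Graph g;
  g.H = H; g.W = W; g.n = n; g.nP = (H - 1) * (W - 1);
  g.tab = REAL(tables);
  g.unary = REAL(unary);
  g.wc = w_corner;
  return g;
}

// [[Rcpp::export]]
double mir_energy_cpp(NumericVector tables, NumericMatrix unary,
                      IntegerVector states, int H, int W, int n,
                      double w_corner) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  return g.energy(INTEGER(states));
}

// Augmented pair tables of one patch (factor costs + incoming messages).
struct Ctx {
  int n;
  std::vector<double> gAB, gCD, gAC, gBD;
  std::vector<double> uA, uB, uC, uD;
};

static std::vector<double> transposed(const std::vector<double> &m, int n) {
  std::vector<double> t((size_t)n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) t[j + n * i] = m[i + n * j];
  return t;
}

// exclude_dir: incoming message left out (the link being sent on), or -1.
static Ctx load_ctx(const Graph &g, int i, int j,
                    const std::vector<std::vector<double>> &inmsg,
                    int exclude_dir) {
  int n = g.n, p = g.pid(i, j);
  Ctx c;
  c.n = n;
  c.gAB.assign(g.T(p, 0), g.T(p, 0) + n * n);
  c.gCD.assign(g.T(p, 1), g.T(p, 1) + n * n);
  c.gAC.assign(g.T(p, 2), g.T(p, 2) + n * n);
  c.gBD.assign(g.T(p, 3), g.T(p, 3) + n * n);
  std::vector<double> *slots[4] = {&c.gAB, &c.gCD, &c.gAC, &c.gBD};
  for (int d = 0; d < 4; ++d) {
    if (d == exclude_dir) continue;
    const std::vector<double> &m = inmsg[(size_t)p * 4 + d];
    if (m.empty()) continue;
    for (int k = 0; k < n * n; ++k) (*slots[d])[k] += m[k];
  }
  c.uA.assign(g.U(i, j), g.U(i, j) + n);
  c.uB.assign(g.U(i, j + 1), g.U(i, j + 1) + n);
  c.uC.assign(g.U(i + 1, j), g.U(i + 1, j) + n);
  c.uD.assign(g.U(i + 1, j + 1), g.U(i + 1, j + 1) + n);
  return c;
}

// Relabelling helpers: each returns a Ctx in which the requested pair plays
// the role of (A, B) / the requested cell plays the role of A.
static Ctx remap_rowswap(const Ctx &c) {            // (A,B,C,D) -> (C,D,A,B)
  Ctx r; r.n = c.n;
  r.gAB = c.gCD; r.gCD = c.gAB;
  r.gAC = transposed(c.gAC, c.n); r.gBD = transposed(c.gBD, c.n);
  r.uA = c.uC; r.uB = c.uD; r.uC = c.uA; r.uD = c.uB;
  return r;
}
static Ctx remap_colswap(const Ctx &c) {            // (A,B,C,D) -> (B,A,D,C)
  Ctx r; r.n = c.n;
  r.gAB = transposed(c.gAB, c.n); r.gCD = transposed(c.gCD, c.n);
  r.gAC = c.gBD; r.gBD = c.gAC;
  r.uA = c.uB; r.uB = c.uA; r.uC = c.uD; r.uD = c.uC;
  return r;
}
static Ctx remap_bcswap(const Ctx &c) {             // (A,B,C,D) -> (A,C,B,D)
  Ctx r; r.n = c.n;
  r.gAB = c.gAC; r.gAC = c.gAB;
  r.gCD = c.gBD; r.gBD = c.gCD;
  r.uA = c.uA; r.uB = c.uC; r.uC = c.uB; r.uD = c.uD;
  return r;
}

// Message over the (A,B) pair: out[a + n*b] = min over (C,D) of the full
// patch cost (with unaries of the eliminated cells), exact corner handling.
static void msg_over_AB(const Ctx &c, double wc, std::vector<double> &out) {
  int n = c.n;
  std::vector<double> q((size_t)n * n), M1((size_t)n * n);
  for (int d = 0; d < n; ++d)
    for (int cc = 0; cc < n; ++cc)
      q[cc + n * d] = c.uC[cc] + c.uD[d] + c.gCD[cc + n * d];
  for (int b = 0; b < n; ++b)
    for (int cc = 0; cc < n; ++cc) {
      double best = INF;
      const double *qr = &q[cc], *bd = &c.gBD[b];
      for (int d = 0; d < n; ++d) {
        double v = qr[(size_t)n * d] + bd[(size_t)n * d];
        if (v < best) best = v;
      }
      M1[cc + n * b] = best;
    }
  for (int b = 0; b < n; ++b)
    for (int a = 0; a < n; ++a) {
      double unr = INF;
      const double *ac = &c.gAC[a], *m1 = &M1[n * b];
      for (int cc = 0; cc < n; ++cc) {
        double v = ac[(size_t)n * cc] + m1[cc];
        if (v < unr) unr = v;
      }
      double v0 = q[a + n * b] + c.gAC[a + n * a] + c.gBD[b + n * b];
      double best = std::min(unr + wc, v0);
      if (a == b) {
        for (int cc = 0; cc < n; ++cc) {
          double v = q[cc + n * cc] + c.gAC[a + n * cc] + c.gBD[a + n * cc];
          if (v < best) best = v;
        }
      }
      out[a + n * b] = c.gAB[a + n * b] + c.uA[a] + c.uB[b] + best;
    }
}

// Min-marginal of cell A: mm[a] = min over (B,C,D), exact corner handling.
static void marg_A(const Ctx &c, double wc, std::vector<double> &mm) {
  int n = c.n;
  std::vector<double> q((size_t)n * n), X((size_t)n * n);
  for (int d = 0; d < n; ++d)
    for (int cc = 0; cc < n; ++cc)
      q[cc + n * d] = c.uC[cc] + c.uD[d] + c.gCD[cc + n * d];
  for (int b = 0; b < n; ++b)
    for (int cc = 0; cc < n; ++cc) {
      double best = INF;
      for (int d = 0; d < n; ++d) {
        double v = q[cc + n * d] + c.gBD[b + n * d];
        if (v < best) best = v;
      }
      X[cc + n * b] = best;
    }
  for (int a = 0; a < n; ++a) {
    double unr = INF;
    for (int b = 0; b < n; ++b) {
      double gab = c.gAB[a + n * b] + c.uB[b];
      for (int cc = 0; cc < n; ++cc) {
        double v = gab + c.gAC[a + n * cc] + X[cc + n * b];
        if (v < unr) unr = v;
      }
    }
    double v0 = INF;   // no vertical step: C=A, D=B
    for (int b = 0; b < n; ++b) {
      double v = c.gAB[a + n * b] + c.uB[b] + q[a + n * b] +
                 c.gAC[a + n * a] + c.gBD[b + n * b];
      if (v < v0) v0 = v;
    }
    double h0 = INF;   // no horizontal step: B=A, D=C
    for (int cc = 0; cc < n; ++cc) {
      double v = c.gAB[a + n * a] + c.uB[a] + q[cc + n * cc] +
                 c.gAC[a + n * cc] + c.gBD[a + n * cc];
      if (v < h0) h0 = v;
    }
    mm[a] = c.uA[a] + std::min(std::min(unr + wc, v0), h0);
  }
}

// Decode: per-cell argmin of summed cluster min-marginals (ties -> lowest,
// i.e. darkest, level).
static void decode_states(const Graph &g,
                          const std::vector<std::vector<double>> &inmsg,
                          std::vector<int> &states) {
  int H = g.H, W = g.W, n = g.n, pH = H - 1, pW = W - 1;
  std::vector<double> belief((size_t)n * H * W, 0.0);
  std::vector<double> mm(n);
  for (int j = 0; j < pW; ++j)
    for (int i = 0; i < pH; ++i) {
      Ctx c = load_ctx(g, i, j, inmsg, -1);
      marg_A(c, g.wc, mm);
      for (int t = 0; t < n; ++t) belief[(size_t)(j * H + i) * n + t] += mm[t];
      marg_A(remap_colswap(c), g.wc, mm);
      for (int t = 0; t < n; ++t)
        belief[(size_t)((j + 1) * H + i) * n + t] += mm[t];
      marg_A(remap_rowswap(c), g.wc, mm);
      for (int t = 0; t < n; ++t)
        belief[(size_t)(j * H + i + 1) * n + t] += mm[t];
      marg_A(remap_rowswap(remap_colswap(c)), g.wc, mm);
      for (int t = 0; t < n; ++t)
        belief[(size_t)((j + 1) * H + i + 1) * n + t] += mm[t];
    }
  states.assign(H * W, 0);
  for (int cell = 0; cell < H * W; ++cell) {
    int best = 0;
    double bv = belief[(size_t)cell * n];
    for (int t = 1; t < n; ++t)
      if (belief[(size_t)cell * n + t] < bv) {
        bv = belief[(size_t)cell * n + t];
        best = t;
      }
    states[cell] = best;
  }
}

// [[Rcpp::export]]
List mir_bp_cpp(NumericVector tables, NumericMatrix unary, int H, int W,
                int n, double w_corner, double damping, int max_iter,
                double tol) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  int nP = g.nP, pH = H - 1, pW = W - 1;
  std::vector<std::vector<double>> inmsg((size_t)nP * 4), newmsg((size_t)nP * 4);
  for (int j = 0; j < pW; ++j)
    for (int i = 0; i < pH; ++i) {
      int p = g.pid(i, j);
      if (i > 0)      inmsg[(size_t)p * 4 + 0].assign((size_t)n * n, 0.0);
      if (i < pH - 1) inmsg[(size_t)p * 4 + 1].assign((size_t)n * n, 0.0);
      if (j > 0)      inmsg[(size_t)p * 4 + 2].assign((size_t)n * n, 0.0);
      if (j < pW - 1) inmsg[(size_t)p * 4 + 3].assign((size_t)n * n, 0.0);
    }
  for (size_t k = 0; k < inmsg.size(); ++k) newmsg[k] = inmsg[k];

  std::vector<double> out((size_t)n * n);
  std::vector<int> prev_decode, cur_decode;
  bool have_decode = false;
  int iter = 0;
  bool converged = false;
  double delta = INF;
  for (iter = 1; iter <= max_iter; ++iter) {
    // synchronous round: all messages from the old message set
    for (int j = 0; j < pW; ++j)
      for (int i = 0; i < pH; ++i) {
        // send up (over AB) -> receiver (i-1, j), direction 1
        if (i > 0) {
          Ctx c = load_ctx(g, i, j, inmsg, 0);
          msg_over_AB(c, w_corner, out);
          newmsg[(size_t)g.pid(i - 1, j) * 4 + 1] = out;
        }
        // send down (over CD) -> receiver (i+1, j), direction 0
        if (i < pH - 1) {
          Ctx c = remap_rowswap(load_ctx(g, i, j, inmsg, 1));
          msg_over_AB(c, w_corner, out);
          newmsg[(size_t)g.pid(i + 1, j) * 4 + 0] = out;
        }
        // send left (over AC) -> receiver (i, j-1), direction 3
        if (j > 0) {
          Ctx c = remap_bcswap(load_ctx(g, i, j, inmsg, 2));
          msg_over_AB(c, w_corner, out);
          newmsg[(size_t)g.pid(i, j - 1) * 4 + 3] = out;
        }
        // send right (over BD) -> receiver (i, j+1), direction 2
        if (j < pW - 1) {
          Ctx c = remap_bcswap(remap_colswap(load_ctx(g, i, j, inmsg, 3)));
          msg_over_AB(c, w_corner, out);
          newmsg[(size_t)g.pid(i, j + 1) * 4 + 2] = out;
        }
      }
    // normalise, damp, measure change
    delta = 0.0;
    for (size_t k = 0; k < newmsg.size(); ++k) {
      if (newmsg[k].empty()) continue;
      std::vector<double> &nm = newmsg[k];
      std::vector<double> &om = inmsg[k];
      double mn = INF;
      for (int t = 0; t < n * n; ++t) mn = std::min(mn, nm[t]);
      for (int t = 0; t < n * n; ++t) {
        double v = damping * om[t] + (1.0 - damping) * (nm[t] - mn);
        double ch = std::abs(v - om[t]);
        if (ch > delta) delta = ch;
        om[t] = v;
      }
    }
    if (delta < tol) { converged = true; break; }
    // messages on loopy graphs may keep translating while the decoded
    // assignment is already stable; check the decode periodically
    if (iter % 10 == 0) {
      decode_states(g, inmsg, cur_decode);
      if (have_decode && cur_decode == prev_decode) { converged = true; break; }
      prev_decode = cur_decode;
      have_decode = true;
      Rcpp::checkUserInterrupt();
    }
  }
  if (iter > max_iter) iter = max_iter;

  std::vector<int> st;
  decode_states(g, inmsg, st);
  IntegerVector states(st.begin(), st.end());
  return List::create(_["states"] = states,
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged,
                      _["delta"] = delta);
}

// [[Rcpp::export]]
List mir_icm_cpp(NumericVector tables, NumericMatrix unary,
                 IntegerVector states, int H, int W, int n, double w_corner,
                 int max_sweeps) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  std::vector<int> st(INTEGER(states), INTEGER(states) + H * W);
  int sweeps = 0;
  bool changed = true;
  while (changed && sweeps < max_sweeps) {
    changed = false;
    ++sweeps;
    for (int col = 0; col < W; ++col)
      for (int row = 0; row < H; ++row) {
        int cell = col * H + row;
        int cur = st[cell];
        double base = 0.0;
        int bi0 = std::max(0, row - 1), bi1 = std::min(H - 2, row);
        int bj0 = std::max(0, col - 1), bj1 = std::min(W - 2, col);
        double bestv = INF; int best = cur;
        for (int s = 0; s < n; ++s) {
          st[cell] = s;
          double v = g.U(row, col)[s];
          for (int j = bj0; j <= bj1; ++j)
            for (int i = bi0; i <= bi1; ++i)
              v += g.patch_cost(g.pid(i, j), st[j * H + i],
                                st[(j + 1) * H + i], st[j * H + i + 1],
                                st[(j + 1) * H + i + 1]);
          if (s == cur) base = v;
          if (v < bestv - 1e-12) { bestv = v; best = s; }
        }
        st[cell] = (bestv < base - 1e-12) ? best : cur;
        if (st[cell] != cur) changed = true;
      }
  }
  IntegerVector out(st.begin(), st.end());
  return List::create(_["states"] = out, _["sweeps"] = sweeps);
}

// Coordinate descent over uniform luminance regions: repeatedly try moving
// every cell of one region to a common level (coordinated move), keeping
// strict improvements. Complements single-cell ICM, which cannot discover
// coordinated lighting splits.
// [[Rcpp::export]]
List mir_region_icm_cpp(NumericVector tables, NumericMatrix unary,
                        IntegerVector states, IntegerVector labels0,
                        int H, int W, int n, double w_corner,
                        int max_sweeps) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  std::vector<int> st(INTEGER(states), INTEGER(states) + H * W);
  const int *lab = INTEGER(labels0);
  int n_reg = 0;
  for (int k = 0; k < H * W; ++k) n_reg = std::max(n_reg, lab[k] + 1);
  // patches touching each region (patch indices, unique)
  std::vector<std::vector<int>> rpatch(n_reg);
  std::vector<std::vector<int>> rcells(n_reg);
  for (int col = 0; col < W; ++col)
    for (int row = 0; row < H; ++row) {
      int r = lab[col * H + row];
      rcells[r].push_back(col * H + row);
      for (int j = std::max(0, col - 1); j <= std::min(W - 2, col); ++j)
        for (int i = std::max(0, row - 1); i <= std::min(H - 2, row); ++i) {
          int p = g.pid(i, j);
          if (rpatch[r].empty() || rpatch[r].back() != p) rpatch[r].push_back(p);
        }
    }
  for (int r = 0; r < n_reg; ++r) {
    std::sort(rpatch[r].begin(), rpatch[r].end());
    rpatch[r].erase(std::unique(rpatch[r].begin(), rpatch[r].end()),
                    rpatch[r].end());
  }
  auto local_energy = [&](int r) {
    double e = 0.0;
    for (int p : rpatch[r]) {
      int i = p % (H - 1), j = p / (H - 1);
      e += g.patch_cost(p, st[j * H + i], st[(j + 1) * H + i],
                        st[j * H + i + 1], st[(j + 1) * H + i + 1]);
      e += g.U(i, j)[st[j * H + i]] + g.U(i, j + 1)[st[(j + 1) * H + i]] +
           g.U(i + 1, j)[st[j * H + i + 1]] +
           g.U(i + 1, j + 1)[st[(j + 1) * H + i + 1]];
    }
    return e;
  };
  int sweeps = 0;
  bool changed = true;
  std::vector<int> saved;
  while (changed && sweeps < max_sweeps) {
    changed = false;
    ++sweeps;
    for (int r = 0; r < n_reg; ++r) {
      double cur = local_energy(r);
      saved.assign(rcells[r].size(), 0);
      for (size_t k = 0; k < rcells[r].size(); ++k) saved[k] = st[rcells[r][k]];
      double bestv = cur;
      int best = -1;
      for (int s = 0; s < n; ++s) {
        for (int cell : rcells[r]) st[cell] = s;
        double v = local_energy(r);
        if (v < bestv - 1e-12) { bestv = v; best = s; }
      }
      if (best >= 0) {
        for (int cell : rcells[r]) st[cell] = best;
        changed = true;
      } else {
        for (size_t k = 0; k < rcells[r].size(); ++k)
          st[rcells[r][k]] = saved[k];
      }
    }
  }
  IntegerVector out(st.begin(), st.end());
  return List::create(_["states"] = out, _["sweeps"] = sweeps);
}

// Coordinated shift moves: (a) half-plane shifts at every grid line (the
// natural lighting-split move on these stimuli) and (b) shifts of a region
// together with the regions it encloses (a target patch moves with its
// surround). Greedy strict-improvement sweeps until stable.
// [[Rcpp::export]]
List mir_shift_icm_cpp(NumericVector tables, NumericMatrix unary,
                       IntegerVector states, IntegerVector labels0,
                       int H, int W, int n, double w_corner, int max_shift,
                       int max_sweeps) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  std::vector<int> st(INTEGER(states), INTEGER(states) + H * W);
  const int *lab = INTEGER(labels0);
  int n_reg = 0;
  for (int k = 0; k < H * W; ++k) n_reg = std::max(n_reg, lab[k] + 1);

  // region cells and adjacency (for enclosed-region groups)
  std::vector<std::vector<int>> rcells(n_reg);
  std::vector<std::vector<int>> rneigh(n_reg);
  for (int col = 0; col < W; ++col)
    for (int row = 0; row < H; ++row) {
      int cell = col * H + row, r = lab[cell];
      rcells[r].push_back(cell);
      if (col + 1 < W && lab[cell + H] != r) {
        rneigh[r].push_back(lab[cell + H]);
        rneigh[lab[cell + H]].push_back(r);
      }
      if (row + 1 < H && lab[cell + 1] != r) {
        rneigh[r].push_back(lab[cell + 1]);
        rneigh[lab[cell + 1]].push_back(r);
      }
    }
  for (int r = 0; r < n_reg; ++r) {
    std::sort(rneigh[r].begin(), rneigh[r].end());
    rneigh[r].erase(std::unique(rneigh[r].begin(), rneigh[r].end()),
                    rneigh[r].end());
  }
  // group = region plus every region whose only neighbour it is
  std::vector<std::vector<int>> groups(n_reg);
  for (int r = 0; r < n_reg; ++r) {
    groups[r] = rcells[r];
    for (int t = 0; t < n_reg; ++t)
      if (t != r && rneigh[t].size() == 1 && rneigh[t][0] == r)
        groups[r].insert(groups[r].end(), rcells[t].begin(), rcells[t].end());
  }

  double curE = g.energy(st.data());
  std::vector<int> trial(H * W);
  auto try_shift = [&](const std::vector<int> &cells, int d) {
    for (int cell : cells) {
      int s = st[cell] + d;
      if (s < 0 || s >= n) return false;  // skip clipped moves
    }
    std::copy(st.begin(), st.end(), trial.begin());
    for (int cell : cells) trial[cell] += d;
    double e = g.energy(trial.data());
    if (e < curE - 1e-12) {
      std::copy(trial.begin(), trial.end(), st.begin());
      curE = e;
      return true;
    }
    return false;
  };

  std::vector<int> half;
  int sweeps = 0;
  bool changed = true;
  while (changed && sweeps < max_sweeps) {
    changed = false;
    ++sweeps;
    for (int c0 = 0; c0 < W; ++c0)           // column-interval shifts
      for (int c1 = c0; c1 < W; ++c1) {
        half.clear();
        for (int col = c0; col <= c1; ++col)
          for (int row = 0; row < H; ++row) half.push_back(col * H + row);
        for (int d = -max_shift; d <= max_shift; ++d)
          if (d != 0 && try_shift(half, d)) changed = true;
      }
    for (int r0 = 0; r0 < H; ++r0)           // row-interval shifts
      for (int r1 = r0; r1 < H; ++r1) {
        half.clear();
        for (int col = 0; col < W; ++col)
          for (int row = r0; row <= r1; ++row) half.push_back(col * H + row);
        for (int d = -max_shift; d <= max_shift; ++d)
          if (d != 0 && try_shift(half, d)) changed = true;
      }
    for (int r = 0; r < n_reg; ++r)          // region(+enclosed) shifts
      for (int d = -max_shift; d <= max_shift; ++d)
        if (d != 0 && try_shift(groups[r], d)) changed = true;
    Rcpp::checkUserInterrupt();
  }
  IntegerVector out(st.begin(), st.end());
  return List::create(_["states"] = out, _["sweeps"] = sweeps,
                      _["energy"] = curE);
}

// [[Rcpp::export]]
List mir_exhaustive_cpp(NumericVector tables, NumericMatrix unary, int H,
                        int W, int n, double w_corner) {
  Graph g = make_graph(tables, unary, H, W, n, w_corner);
  int nc = H * W;
  double total = std::pow((double)n, (double)nc);
  if (total > 1e7)
    stop("state space too large for exhaustive enumeration (> 1e7)");
  std::vector<int> st(nc, 0), best(nc, 0);
  double bestE = g.energy(st.data());
  // odometer with the last cell fastest: earlier configurations are
  // lexicographically smaller in raster-major order, and strict improvement
  // keeps the first (lowest-index) minimiser
  while (true) {
    int k = nc - 1;
    while (k >= 0 && st[k] == n - 1) { st[k] = 0; --k; }
    if (k < 0) break;
    ++st[k];
    double e = g.energy(st.data());
    if (e < bestE - 1e-12) { bestE = e; best = st; }
  }
  IntegerVector out(best.begin(), best.end());
  return List::create(_["states"] = out, _["energy"] = bestE);
}
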