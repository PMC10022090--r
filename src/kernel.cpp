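// Five-matrix global alignment kernel with context-dependent n-polymer
// copy-number penalties.
//
// Matrices D, I, M, S, L hold the states Deleting, Inserting, Matching,
// Shortening and Lengthening. D/I implement the usual affine (Gotoh)
// recurrences; S and L consume whole repeat units of an annotated
// n-polymer (n reference bases for S, n matching read bases for L) and are
// written *forward* from the current cell, gated by the reference
// annotation:
//   c1: l > 0              (current reference column starts a repeat unit)
//   c2: l > 0 && idx == 0  (current column starts the polymer)
//   c3: next n read bases equal the reference unit (lengthening only)
// A shortening/lengthening run of k units is charged the single lookup
// N[n, l, l -+ k], replacing (not adding to) the previous lookup: each S/L
// cell stores the value at the run's entry point ("base") in addition to
// its own value and run length (in bases). S and L keep one slot per
// repeat-unit length n, because runs of different unit length through the
// same cell are distinct continuation states; for S this makes the
// program exact (at a given column the annotation index pins the run
// length of any continuable candidate, so minimising the value per slot
// is sufficient).
//
// Traceback happens entirely within M via predecessor and run-length
// information; S-runs emit deletions, L-runs emit insertions.
//
// Encoding: bases are 0..3 = ACGT, >=4 is unknown (never eligible for S/L,
// substitution charged at the maximum entry of P). Annotation matrices are
// n_max x m (row n-1 = unit length n, column j = 0-based reference offset).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

namespace {

struct Model {
  const double* P;      // 4x4 column-major
  double g_open, g_extend;
  const double* N;      // n_max x l_max x l_max column-major, may be null
  int n_max, l_max;
  bool use_npoly;
  double p_max;

  double subst(int rb, int qb) const {
    if (rb > 3 || qb > 3 || rb < 0 || qb < 0) return p_max;
    return P[rb + 4 * qb];
  }
  // expected copies l, observed copies obs (true counts; clamped here)
  double n_pen(int n, int l, int obs) const {
    int li = l < l_max ? l : l_max - 1;
    int oi = obs < 0 ? 0 : (obs < l_max ? obs : l_max - 1);
    return N[(n - 1) + n_max * (li + l_max * oi)];
  }
};

// predecessor codes stored in M; FROM_S/FROM_L also record the slot
enum Pred { NONE = -1, DIAG = 0, FROM_S = 1, FROM_L = 2, FROM_D = 3,
            FROM_I = 4 };

// per-slot forward state for S or L at one cell
struct Slot {
  double val, base;
  int run;
};

} // namespace

// ---------------------------------------------------------------- unbanded

// [[Rcpp::export(name = ".align_kernel")]]
List align_kernel(IntegerVector read, IntegerVector ref,
                  IntegerMatrix ann_l, IntegerMatrix ann_idx,
                  NumericMatrix P, double g_open, double g_extend,
                  SEXP N_, IntegerVector N_dim, bool use_npoly) {
  const int nr = read.size();   // read length
  const int m  = ref.size();    // window length
  Model mod;
  mod.P = REAL(P); mod.g_open = g_open; mod.g_extend = g_extend;
  mod.p_max = Rcpp::max(P);
  mod.use_npoly = use_npoly && !Rf_isNull(N_);
  mod.N = mod.use_npoly ? REAL(N_) : nullptr;
  mod.n_max = mod.use_npoly ? N_dim[0] : 0;
  mod.l_max = mod.use_npoly ? N_dim[1] : 0;
  if (mod.use_npoly && mod.n_max > ann_l.nrow())
    stop("annotation has fewer unit lengths than the penalty tensor");
  const int n_max = mod.n_max;

  const int ncol = m + 1;
  const size_t sz = (size_t)(nr + 1) * ncol;
  std::vector<double> Mv(sz, INF), Dv(sz, INF), Iv(sz, INF);
  std::vector<int> Mp(sz, NONE), Msl(sz, 0), Dr(sz, 0), Ir(sz, 0);
  std::vector<Slot> S, L;
  if (mod.use_npoly) {
    S.assign(sz * n_max, Slot{INF, 0.0, 0});
    L.assign(sz * n_max, Slot{INF, 0.0, 0});
  }
  auto at = [ncol](int i, int j) { return (size_t)i * ncol + j; };
  auto slot = [n_max](size_t cell, int n) { return cell * n_max + (n - 1); };
  Mv[at(0, 0)] = 0.0; // anchored global alignment

  for (int i = 0; i <= nr; ++i) {
    for (int j = 0; j <= m; ++j) {
      const size_t c = at(i, j);
      if (i > 0 || j > 0) {
        if (j > 0) {
          double open = Mv[at(i, j - 1)] + g_open;
          double ext  = Dv[at(i, j - 1)] + g_extend;
          if (open <= ext) { Dv[c] = open; Dr[c] = 1; }
          else             { Dv[c] = ext;  Dr[c] = Dr[at(i, j - 1)] + 1; }
        }
        if (i > 0) {
          double open = Mv[at(i - 1, j)] + g_open;
          double ext  = Iv[at(i - 1, j)] + g_extend;
          if (open <= ext) { Iv[c] = open; Ir[c] = 1; }
          else             { Iv[c] = ext;  Ir[c] = Ir[at(i - 1, j)] + 1; }
        }
        double best = INF; int pred = NONE; int psl = 0;
        if (i > 0 && j > 0) {
          double diag = Mv[at(i - 1, j - 1)] +
            mod.subst(ref[j - 1], read[i - 1]);
          if (diag < best) { best = diag; pred = DIAG; }
        }
        if (mod.use_npoly) {
          for (int n = 1; n <= n_max; ++n) {
            const Slot &s = S[slot(c, n)];
            if (s.val < best) { best = s.val; pred = FROM_S; psl = n; }
          }
          for (int n = 1; n <= n_max; ++n) {
            const Slot &s = L[slot(c, n)];
            if (s.val < best) { best = s.val; pred = FROM_L; psl = n; }
          }
        }
        if (Dv[c] < best) { best = Dv[c]; pred = FROM_D; }
        if (Iv[c] < best) { best = Iv[c]; pred = FROM_I; }
        Mv[c] = best; Mp[c] = pred; Msl[c] = psl;
      }
      // forward writes into S (column j+n) and L (row i+n)
      if (mod.use_npoly && j < m) {
        for (int n = 1; n <= n_max; ++n) {
          const int l   = ann_l(n - 1, j);
          if (l <= 0) continue;
          const int idx = ann_idx(n - 1, j);
          // --- shortening: delete one unit (n reference bases)
          if (j + n <= m) {
            Slot &tgt = S[slot(at(i, j + n), n)];
            if (idx == 0 && Mv[c] < INF) {
              double cand = Mv[c] + mod.n_pen(n, l, l - 1);
              if (cand < tgt.val) { tgt = Slot{cand, Mv[c], n}; }
            }
            const Slot &cur = S[slot(c, n)];
            if (cur.val < INF && idx == cur.run / n) {
              int k = cur.run / n + 1;
              if (l - k >= 0) {
                double cand = cur.base + mod.n_pen(n, l, l - k);
                if (cand < tgt.val) {
                  tgt = Slot{cand, cur.base, cur.run + n};
                }
              }
            }
          }
          // --- lengthening: insert one unit matching R[j..j+n)
          if (idx == 0 && i + n <= nr && j + n <= m) {
            bool c3 = true;
            for (int t = 0; t < n; ++t) {
              int qb = read[i + t], rb = ref[j + t];
              if (qb > 3 || rb > 3 || qb != rb) { c3 = false; break; }
            }
            if (c3) {
              Slot &tgt = L[slot(at(i + n, j), n)];
              if (Mv[c] < INF) {
                double cand = Mv[c] + mod.n_pen(n, l, l + 1);
                if (cand < tgt.val) { tgt = Slot{cand, Mv[c], n}; }
              }
              const Slot &cur = L[slot(c, n)];
              if (cur.val < INF) {
                int k = cur.run / n + 1;
                double cand = cur.base + mod.n_pen(n, l, l + k);
                if (cand < tgt.val) {
                  tgt = Slot{cand, cur.base, cur.run + n};
                }
              }
            }
          }
        }
      }
    }
  }

  const size_t end = at(nr, m);
  if (!std::isfinite(Mv[end]))
    stop("alignment terminal cell unreachable");
  // traceback within M
  std::string ops;
  int i = nr, j = m;
  while (i > 0 || j > 0) {
    const size_t c = at(i, j);
    int run;
    switch (Mp[c]) {
    case DIAG:   ops.push_back('M'); --i; --j; break;
    case FROM_S:
      run = S[slot(c, Msl[c])].run;
      ops.append(run, 'D'); j -= run; break;
    case FROM_L:
      run = L[slot(c, Msl[c])].run;
      ops.append(run, 'I'); i -= run; break;
    case FROM_D: ops.append(Dr[c], 'D'); j -= Dr[c]; break;
    case FROM_I: ops.append(Ir[c], 'I'); i -= Ir[c]; break;
    default: stop("traceback reached a cell with no predecessor");
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = ops, _["score"] = Mv[end]);
}

// ------------------------------------------------------------------ banded

// [[Rcpp::export(name = ".banded_kernel")]]
List banded_kernel(IntegerVector read, IntegerVector ref,
                   IntegerMatrix ann_l, IntegerMatrix ann_idx,
                   NumericMatrix P, double g_open, double g_extend,
                   SEXP N_, IntegerVector N_dim, bool use_npoly,
                   IntegerVector id_path, int b) {
  const int nr = read.size();
  const int m  = ref.size();
  const int T  = id_path.size();          // anti-diagonals 1..T
  if (T != nr + m)
    stop("ID path length must equal read length + window length");
  Model mod;
  mod.P = REAL(P); mod.g_open = g_open; mod.g_extend = g_extend;
  mod.p_max = Rcpp::max(P);
  mod.use_npoly = use_npoly && !Rf_isNull(N_);
  mod.N = mod.use_npoly ? REAL(N_) : nullptr;
  mod.n_max = mod.use_npoly ? N_dim[0] : 0;
  mod.l_max = mod.use_npoly ? N_dim[1] : 0;
  const int n_max = mod.n_max;

  // prefix insertion counts along the supplemented path; INSs[t] = number
  // of I ops among the first t ops (id_path: 0 = I, 1 = D)
  std::vector<int> INSs(T + 1, 0), DELs(T + 1, 0);
  for (int t = 1; t <= T; ++t) {
    INSs[t] = INSs[t - 1] + (id_path[t - 1] == 0 ? 1 : 0);
    DELs[t] = DELs[t - 1] + (id_path[t - 1] == 1 ? 1 : 0);
  }
  if (INSs[T] != nr || DELs[T] != m)
    stop("ID path inconsistent with read/window lengths");

  const int W = 2 * b + 1;
  const size_t sz = (size_t)W * T;        // workspace B: anti-diagonals 1..T
  std::vector<double> Mv(sz, INF), Dv(sz, INF), Iv(sz, INF);
  std::vector<int> Mp(sz, NONE), Msl(sz, 0), Dr(sz, 0), Ir(sz, 0);
  std::vector<Slot> S, L;
  if (mod.use_npoly) {
    S.assign(sz * n_max, Slot{INF, 0.0, 0});
    L.assign(sz * n_max, Slot{INF, 0.0, 0});
  }
  auto slot = [n_max](long cell, int n) {
    return (size_t)cell * n_max + (n - 1);
  };

  // cell (row r, col c) of the full matrix -> linear index in B, or -1
  auto bidx = [&](int r, int c) -> long {
    if (r < 0 || r > nr || c < 0 || c > m) return -1;
    int t = r + c;
    if (t < 1 || t > T) return -1;
    int jb = INSs[t] + b - r;
    if (jb < 0 || jb >= W) return -1;
    return (long)(t - 1) * W + jb;
  };
  auto getM = [&](int r, int c) -> double {
    if (r == 0 && c == 0) return 0.0;
    long k = bidx(r, c); return k < 0 ? INF : Mv[k];
  };
  auto getD = [&](int r, int c) -> double {
    long k = bidx(r, c); return k < 0 ? INF : Dv[k];
  };
  auto getDr = [&](int r, int c) -> int {
    long k = bidx(r, c); return k < 0 ? 0 : Dr[k];
  };
  auto getI = [&](int r, int c) -> double {
    long k = bidx(r, c); return k < 0 ? INF : Iv[k];
  };
  auto getIr = [&](int r, int c) -> int {
    long k = bidx(r, c); return k < 0 ? 0 : Ir[k];
  };

  // forward writes from cell (r,c); cell == -1 marks the origin, whose
  // S/L slots are all empty
  auto forward_writes = [&](int r, int c, double mval, long cell) {
    if (!mod.use_npoly || c >= m) return;
    for (int n = 1; n <= n_max; ++n) {
      const int l = ann_l(n - 1, c);
      if (l <= 0) continue;
      const int idx = ann_idx(n - 1, c);
      if (c + n <= m) {
        long tcell = bidx(r, c + n);
        if (tcell >= 0) {
          Slot &tgt = S[slot(tcell, n)];
          if (idx == 0 && mval < INF) {
            double cand = mval + mod.n_pen(n, l, l - 1);
            if (cand < tgt.val) tgt = Slot{cand, mval, n};
          }
          if (cell >= 0) {
            const Slot &cur = S[slot(cell, n)];
            if (cur.val < INF && idx == cur.run / n) {
              int k = cur.run / n + 1;
              if (l - k >= 0) {
                double cand = cur.base + mod.n_pen(n, l, l - k);
                if (cand < tgt.val) tgt = Slot{cand, cur.base, cur.run + n};
              }
            }
          }
        }
      }
      if (idx == 0 && r + n <= nr && c + n <= m) {
        bool c3 = true;
        for (int t = 0; t < n; ++t) {
          int qb = read[r + t], rb = ref[c + t];
          if (qb > 3 || rb > 3 || qb != rb) { c3 = false; break; }
        }
        if (c3) {
          long tcell = bidx(r + n, c);
          if (tcell >= 0) {
            Slot &tgt = L[slot(tcell, n)];
            if (mval < INF) {
              double cand = mval + mod.n_pen(n, l, l + 1);
              if (cand < tgt.val) tgt = Slot{cand, mval, n};
            }
            if (cell >= 0) {
              const Slot &cur = L[slot(cell, n)];
              if (cur.val < INF) {
                int k = cur.run / n + 1;
                double cand = cur.base + mod.n_pen(n, l, l + k);
                if (cand < tgt.val) tgt = Slot{cand, cur.base, cur.run + n};
              }
            }
          }
        }
      }
    }
  };

  forward_writes(0, 0, 0.0, -1); // origin

  for (int t = 1; t <= T; ++t) {
    for (int jb = 0; jb < W; ++jb) {
      const int r = INSs[t] + b - jb;
      const int c = DELs[t] - b + jb;
      if (r < 0 || r > nr || c < 0 || c > m) continue;
      const long cc = (long)(t - 1) * W + jb;
      if (c > 0) {
        double open = getM(r, c - 1) + g_open;
        double ext  = getD(r, c - 1) + g_extend;
        if (open <= ext) { Dv[cc] = open; Dr[cc] = 1; }
        else             { Dv[cc] = ext;  Dr[cc] = getDr(r, c - 1) + 1; }
      }
      if (r > 0) {
        double open = getM(r - 1, c) + g_open;
        double ext  = getI(r - 1, c) + g_extend;
        if (open <= ext) { Iv[cc] = open; Ir[cc] = 1; }
        else             { Iv[cc] = ext;  Ir[cc] = getIr(r - 1, c) + 1; }
      }
      double best = INF; int pred = NONE; int psl = 0;
      if (r > 0 && c > 0) {
        double diag = getM(r - 1, c - 1) + mod.subst(ref[c - 1], read[r - 1]);
        if (diag < best) { best = diag; pred = DIAG; }
      }
      if (mod.use_npoly) {
        for (int n = 1; n <= n_max; ++n) {
          const Slot &s = S[slot(cc, n)];
          if (s.val < best) { best = s.val; pred = FROM_S; psl = n; }
        }
        for (int n = 1; n <= n_max; ++n) {
          const Slot &s = L[slot(cc, n)];
          if (s.val < best) { best = s.val; pred = FROM_L; psl = n; }
        }
      }
      if (Dv[cc] < best) { best = Dv[cc]; pred = FROM_D; }
      if (Iv[cc] < best) { best = Iv[cc]; pred = FROM_I; }
      Mv[cc] = best; Mp[cc] = pred; Msl[cc] = psl;
      forward_writes(r, c, Mv[cc], cc);
    }
  }

  long end = (nr == 0 && m == 0) ? -2 : bidx(nr, m);
  double final_score;
  if (end == -2) {
    final_score = 0.0;
  } else {
    if (end < 0 || !std::isfinite(Mv[end]))
      stop("banded alignment could not reach the terminal cell; widen the band");
    final_score = Mv[end];
  }

  std::string ops;
  int r = nr, c = m;
  while (r > 0 || c > 0) {
    long k = bidx(r, c);
    if (k < 0) stop("banded traceback left the band; widen the band");
    int run;
    switch (Mp[k]) {
    case DIAG:   ops.push_back('M'); --r; --c; break;
    case FROM_S:
      run = S[slot(k, Msl[k])].run;
      ops.append(run, 'D'); c -= run; break;
    case FROM_L:
      run = L[slot(k, Msl[k])].run;
      ops.append(run, 'I'); r -= run; break;
    case FROM_D: ops.append(Dr[k], 'D'); c -= Dr[k]; break;
    case FROM_I: ops.append(Ir[k], 'I'); r -= Ir[k]; break;
    default: stop("banded traceback reached a cell with no predecessor");
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = ops, _["score"] = final_score,
                      _["cells"] = (double)((size_t)W * T));
}
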