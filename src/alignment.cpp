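#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise alignment engine.
//
// States: M = aligned residue pair, X = gap in the second sequence
// (consumes a residue of `a`; "up" in the DP table), Y = gap in the first
// sequence (consumes a residue of `b`; "left"). A gap of length k costs
// gap_open + k * gap_extend. Gaps in the two sequences may abut (X <-> Y
// transitions are allowed), which makes the model identical to the cubic
// "jump" formulation max_k S[i-k][j] - open - k*extend.
//
// Determinism: preference order M > X > Y both when choosing the state of a
// cell and when choosing the predecessor of a gap state; the local maximum
// is the first best cell in row-major order (smallest i, then j).

namespace {

const int NEG_INF = INT_MIN / 4;

struct AlnResult {
  int score;
  int q_start, q_end, s_start, s_end;  // 0-based half-open
  int identities, columns;
};

struct Workspace {
  std::vector<int> Mp, Xp, Yp, Mc, Xc, Yc;   // rolling value rows
  std::vector<unsigned char> trace;          // packed: tM | tX<<2 | tY<<4
  void ensure_rows(size_t w) {
    if (Mp.size() < w) {
      Mp.resize(w); Xp.resize(w); Yp.resize(w);
      Mc.resize(w); Xc.resize(w); Yc.resize(w);
    }
  }
  void ensure_trace(size_t n) { if (trace.size() < n) trace.resize(n); }
};

// Packed trace codes per state: predecessor 0=M, 1=X, 2=Y, 3=start.
AlnResult align_core(const int* a, int n, const int* b, int m,
                     const int* S, int nS, int go, int ge,
                     bool local, Workspace& ws) {
  const int W = m + 1;
  ws.ensure_rows(W);
  ws.ensure_trace((size_t)(n + 1) * W);
  int* Mp = ws.Mp.data(); int* Xp = ws.Xp.data(); int* Yp = ws.Yp.data();
  int* Mc = ws.Mc.data(); int* Xc = ws.Xc.data(); int* Yc = ws.Yc.data();
  unsigned char* tr = ws.trace.data();
  const int goe = go + ge;

  // row 0
  Mp[0] = 0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  tr[0] = 3;
  for (int j = 1; j <= m; ++j) {
    if (local) {
      Mp[j] = 0; Xp[j] = NEG_INF; Yp[j] = NEG_INF;
      tr[j] = 3;
    } else {
      Mp[j] = NEG_INF; Xp[j] = NEG_INF;
      Yp[j] = -(go + j * ge);
      tr[j] = (unsigned char)(3 | (3 << 2) | (((j == 1) ? 0 : 2) << 4));
    }
  }

  int best = 0, bi = 0, bj = 0;
  // track final-row values for the global score
  for (int i = 1; i <= n; ++i) {
    unsigned char* trow = tr + (size_t)i * W;
    if (local) {
      Mc[0] = 0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
      trow[0] = 3;
    } else {
      Mc[0] = NEG_INF; Yc[0] = NEG_INF;
      Xc[0] = -(go + i * ge);
      trow[0] = (unsigned char)(3 | (((i == 1) ? 0 : 1) << 2) | (3 << 4));
    }
    const int* Srow = S + (size_t)a[i - 1] * nS;
    // branchless max chains (ties resolve to the earlier state in the
    // M > X > Y preference order); the left-neighbour cell is carried in
    // registers to keep the serial Y recurrence off the store/load path
    int mleft = Mc[0], xleft = Xc[0], yleft = Yc[0];
    for (int j = 1; j <= m; ++j) {
      const int bjv = b[j - 1];
      // M from the diagonal (prefer M > X > Y)
      const int dm = Mp[j - 1], dx = Xp[j - 1], dy = Yp[j - 1];
      int bd = (dx > dm) ? dx : dm;
      bd = (dy > bd) ? dy : bd;
      int td = (bd == dm) ? 0 : ((bd == dx) ? 1 : 2);
      int mv = bd + Srow[bjv];
      if (local) {
        td = (mv <= 0) ? 3 : td;
        mv = (mv <= 0) ? 0 : mv;
        if (mv > best) { best = mv; bi = i; bj = j; }
      }
      Mc[j] = mv;
      // X from above (gap in b)
      const int xo = Mp[j] - goe, xe = Xp[j] - ge, xy = Yp[j] - goe;
      int xv = (xe > xo) ? xe : xo;
      xv = (xy > xv) ? xy : xv;
      const int tx = (xv == xo) ? 0 : ((xv == xe) ? 1 : 2);
      Xc[j] = xv;
      // Y from the left (gap in a)
      const int yo = mleft - goe, yx = xleft - goe, ye = yleft - ge;
      int yv = (yx > yo) ? yx : yo;
      yv = (ye > yv) ? ye : yv;
      const int ty = (yv == yo) ? 0 : ((yv == yx) ? 1 : 2);
      Yc[j] = yv;
      trow[j] = (unsigned char)(td | (tx << 2) | (ty << 4));
      mleft = mv; xleft = xv; yleft = yv;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnResult res;
  res.identities = 0; res.columns = 0;
  int i, j, st;
  if (local) {
    res.score = best;
    if (best <= 0) {
      res.q_start = res.q_end = res.s_start = res.s_end = 0;
      return res;
    }
    i = bi; j = bj; st = 0;
  } else {
    int fm = Mp[m], fx = Xp[m], fy = Yp[m];  // Mp holds row n after swap
    res.score = fm; st = 0;
    if (fx > res.score) { res.score = fx; st = 1; }
    if (fy > res.score) { res.score = fy; st = 2; }
    i = n; j = m;
    bi = n; bj = m;
  }

  while (true) {
    const unsigned char t = tr[(size_t)i * W + j];
    if (!local && i == 0 && j == 0) break;
    if (st == 0) {
      const int td = t & 3;
      if (local && td == 3) {
        // M here is a zero start cell reached without consuming it
        break;
      }
      ++res.columns;
      if (a[i - 1] == b[j - 1]) ++res.identities;
      st = td; --i; --j;
    } else if (st == 1) {
      ++res.columns;
      st = (t >> 2) & 3; --i;
    } else {
      ++res.columns;
      st = (t >> 4) & 3; --j;
    }
  }
  res.q_start = i; res.q_end = bi;
  res.s_start = j; res.s_end = bj;
  return res;
}

std::vector<std::vector<int> > as_int_seqs(const List& xs) {
  std::vector<std::vector<int> > out(xs.size());
  for (R_xlen_t k = 0; k < xs.size(); ++k) {
    IntegerVector v = xs[k];
    out[k].assign(v.begin(), v.end());
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                    int gap_open, int gap_extend, bool local) {
  std::vector<int> flat(S.begin(), S.end());
  // IntegerMatrix is column-major; align_core indexes S[a*nS + b], so
  // transpose-free access relies on the matrix being symmetric (validated
  // on the R side).
  Workspace ws;
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  AlnResult r = align_core(av.data(), av.size(), bv.data(), bv.size(),
                           flat.data(), S.nrow(), gap_open, gap_extend,
                           local, ws);
  return List::create(
      _["score"] = r.score,
      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["s_start"] = r.s_start, _["s_end"] = r.s_end,
      _["identities"] = r.identities, _["columns"] = r.columns);
}

// Score-only Smith-Waterman over all query x subject pairs (rolling rows).
// [[Rcpp::export]]
IntegerMatrix sw_scores_cpp(List queries, List subjects, IntegerMatrix S,
                            int gap_open, int gap_extend) {
  std::vector<std::vector<int> > qs = as_int_seqs(queries);
  std::vector<std::vector<int> > ss = as_int_seqs(subjects);
  std::vector<int> flat(S.begin(), S.end());
  const int nS = S.nrow();
  IntegerMatrix out(qs.size(), ss.size());
  size_t maxm = 1;
  for (size_t k = 0; k < ss.size(); ++k) maxm = std::max(maxm, ss[k].size() + 1);
  std::vector<int> Mp(maxm), Xp(maxm), Yp(maxm), Mc(maxm), Xc(maxm), Yc(maxm);
  for (size_t qi = 0; qi < qs.size(); ++qi) {
    const std::vector<int>& a = qs[qi];
    const int n = a.size();
    for (size_t si = 0; si < ss.size(); ++si) {
      const std::vector<int>& b = ss[si];
      const int m = b.size();
      int best = 0;
      for (int j = 0; j <= m; ++j) { Mp[j] = 0; Xp[j] = NEG_INF; Yp[j] = NEG_INF; }
      for (int i = 1; i <= n; ++i) {
        Mc[0] = 0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
        const int* Srow = flat.data() + (size_t)a[i - 1] * nS;
        for (int j = 1; j <= m; ++j) {
          int bd = Mp[j - 1];
          if (Xp[j - 1] > bd) bd = Xp[j - 1];
          if (Yp[j - 1] > bd) bd = Yp[j - 1];
          int mv = (bd <= NEG_INF / 2) ? NEG_INF : bd + Srow[b[j - 1]];
          if (mv <= 0) mv = 0;
          Mc[j] = mv;
          if (mv > best) best = mv;
          int xv = Mp[j] - gap_open - gap_extend;
          if (Xp[j] - gap_extend > xv) xv = Xp[j] - gap_extend;
          if (Yp[j] - gap_open - gap_extend > xv) xv = Yp[j] - gap_open - gap_extend;
          if (xv < NEG_INF / 2) xv = NEG_INF;
          Xc[j] = xv;
          int yv = Mc[j - 1] - gap_open - gap_extend;
          if (Xc[j - 1] - gap_open - gap_extend > yv) yv = Xc[j - 1] - gap_open - gap_extend;
          if (Yc[j - 1] - gap_extend > yv) yv = Yc[j - 1] - gap_extend;
          if (yv < NEG_INF / 2) yv = NEG_INF;
          Yc[j] = yv;
        }
        Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
      }
      out(qi, si) = best;
    }
  }
  return out;
}

// Global (end-to-end) alignment for all pairs of `as` x `bs`: percent
// identity, raw score, identities and columns.
// [[Rcpp::export]]
List nw_pid_cpp(List as, List bs, IntegerMatrix S, int gap_open,
                int gap_extend) {
  std::vector<std::vector<int> > av = as_int_seqs(as);
  std::vector<std::vector<int> > bv = as_int_seqs(bs);
  std::vector<int> flat(S.begin(), S.end());
  const int nS = S.nrow();
  const size_t nA = av.size(), nB = bv.size();
  NumericMatrix pid(nA, nB);
  IntegerMatrix score(nA, nB), ident(nA, nB), cols(nA, nB);
  Workspace ws;
  for (size_t i = 0; i < nA; ++i) {
    for (size_t j = 0; j < nB; ++j) {
      AlnResult r = align_core(av[i].data(), av[i].size(),
                               bv[j].data(), bv[j].size(),
                               flat.data(), nS, gap_open, gap_extend,
                               false, ws);
      score(i, j) = r.score;
      ident(i, j) = r.identities;
      cols(i, j) = r.columns;
      pid(i, j) = r.columns > 0 ? 100.0 * r.identities / r.columns : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["pid"] = pid, _["score"] = score,
                      _["identities"] = ident, _["columns"] = cols);
}
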