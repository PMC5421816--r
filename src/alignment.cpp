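// Global (Needleman-Wunsch) alignment between cluster profiles.
//
// Scoring: expected column mismatch cost + unit gap cost, minimized; the
// distance is total cost divided by the minimal alignment length among the
// minimum-cost alignments (a symmetric functional of the two profiles, so
// d(a,b) = d(b,a) exactly), giving a value in [0,1].  Residual ties in the
// traceback prefer diagonal > up > left.
//
// The DP is computed inside an expanding diagonal corridor.  A corridor of
// half-width k is exact whenever the optimal cost C satisfies
// C <= gap * (|la-lb| + 2k): any path leaving the corridor contains at least
// |la-lb| + 2(k+1) gap steps.  The corridor is doubled until this certificate
// holds, so the result is identical to the full matrix.  When a caller
// supplies a cutoff, the search may stop early once a certified lower bound
// on the distance reaches the cutoff (2C/(la+lb+C/gap) is a lower bound on
// C/len because len <= (la+lb+C/gap)/2).

#include "core.h"

#include <cctype>
#include <cstring>

namespace pbp {

namespace {

const double kPure[4][5] = {{1, 0, 0, 0, 0},
                            {0, 1, 0, 0, 0},
                            {0, 0, 1, 0, 0},
                            {0, 0, 0, 1, 0}};

// Per-rep dense view of column pointers; pure columns point into kPure.
inline void col_view(const Rep& r, std::vector<const double*>& out) {
  out.resize(r.len);
  for (int i = 0; i < r.len; ++i) out[i] = kPure[r.code[i] == 255 ? 0 : r.code[i]];
  for (size_t m = 0; m < r.mixed_idx.size(); ++m)
    out[r.mixed_idx[m]] = r.mixed_col[m].p.data();
}

inline double sub_cost(const Rep& A, const Rep& B, int i, int j,
                       const std::vector<const double*>& ca,
                       const std::vector<const double*>& cb,
                       const AlignParams& par) {
  uint8_t x = A.code[i], y = B.code[j];
  if (x != 255 && y != 255) return x == y ? 0.0 : par.mismatch;
  const double* p = ca[i];
  const double* q = cb[j];
  double m = p[0] * q[0] + p[1] * q[1] + p[2] * q[2] + p[3] * q[3];
  double gg = p[4] * q[4];
  double og = p[4] + q[4] - 2.0 * gg;
  return par.mismatch * (1.0 - m - gg - og) + par.gap * og;
}

struct DPResult {
  double cost;
  long len;
  bool done;                 // corridor certificate held
  std::vector<uint8_t> mv;   // moves (1 diag, 2 up, 3 left) if traced
  int W, loD;
};

// One corridor pass with half-width k.  Returns done=false if the band
// certificate fails.  row_lb (out): min cost over the last completed row.
DPResult corridor_pass(const Rep& A, const Rep& B,
                       const std::vector<const double*>& ca,
                       const std::vector<const double*>& cb,
                       const AlignParams& par, long k, bool trace,
                       double cutoff, double* reached_lb) {
  const int la = A.len, lb = B.len;
  const int delta = lb - la;
  const long loD = std::min(0, delta) - k;
  const long hiD = std::max(0, delta) + k;
  const int W = static_cast<int>(hiD - loD + 1);
  const double g = par.gap;

  thread_local std::vector<double> gapA, gapB, cprev, ccur;
  thread_local std::vector<long> lprev, lcur;
  gapA.resize(la);
  gapB.resize(lb);
  for (int i = 0; i < la; ++i) gapA[i] = g * (1.0 - ca[i][4]);
  for (int j = 0; j < lb; ++j) gapB[j] = g * (1.0 - cb[j][4]);
  cprev.assign(W, INF);
  ccur.assign(W, INF);
  lprev.assign(W, 0);
  lcur.assign(W, 0);
  DPResult res;
  res.W = W;
  res.loD = static_cast<int>(loD);
  if (trace) res.mv.assign(static_cast<size_t>(la + 1) * W, 0);

  // escape bound: any path outside the corridor costs at least this
  const double escape =
      (g > 0) ? g * (std::abs(delta) + 2.0 * (k + 1)) : INF;
  auto dist_lb = [&](double C) {
    if (g > 0) return 2.0 * C / (la + lb + C / g);
    return (la + lb) > 0 ? C / (la + lb) : 0.0;
  };

  // row 0
  {
    double acc = 0.0;
    for (long j = 0; j <= std::min<long>(lb, hiD); ++j) {
      if (j > 0) acc += gapB[j - 1];
      long w = j - loD;
      if (w >= 0 && w < W) {
        cprev[w] = acc;
        lprev[w] = j;
        if (trace && j > 0) res.mv[w] = 3;
      }
    }
  }

  for (int i = 1; i <= la; ++i) {
    std::fill(ccur.begin(), ccur.end(), INF);
    long jmin = std::max<long>(0, i + loD);
    long jmax = std::min<long>(lb, i + hiD);
    double rowmin = INF;
    const double* cp = cprev.data();
    const long* lp = lprev.data();
    double* cc = ccur.data();
    long* lc = lcur.data();
    const double gA = gapA[i - 1];
    const uint8_t ai = A.code[i - 1];
    const double* pa = ca[i - 1];
    const bool a_pure = (ai != 255);
    uint8_t* mvrow = trace ? res.mv.data() + static_cast<size_t>(i) * W
                           : nullptr;
    for (long j = jmin; j <= jmax; ++j) {
      long w = j - i - loD;
      double cd = INF, cu = INF, cl = INF;
      if (j > 0 && cp[w] < INF) {
        const uint8_t bj = B.code[j - 1];
        double sc;
        if (a_pure && bj != 255) {
          sc = (ai == bj) ? 0.0 : par.mismatch;
        } else {
          const double* p = pa;
          const double* q = cb[j - 1];
          double mm = p[0] * q[0] + p[1] * q[1] + p[2] * q[2] + p[3] * q[3];
          double gg = p[4] * q[4];
          double og = p[4] + q[4] - 2.0 * gg;
          sc = par.mismatch * (1.0 - mm - gg - og) + par.gap * og;
        }
        cd = cp[w] + sc;
      }
      long lu = 0, ll = 0;
      if (w + 1 < W && cp[w + 1] < INF) {
        cu = cp[w + 1] + gA;
        lu = lp[w + 1] + 1;
      }
      if (w - 1 >= 0 && cc[w - 1] < INF) {
        cl = cc[w - 1] + gapB[j - 1];
        ll = lc[w - 1] + 1;
      }
      // lexicographic (cost, length): the distance divides by the minimal
      // alignment length among minimum-cost paths, which is symmetric in
      // the two profiles; residual ties prefer diagonal > up > left
      uint8_t mv = 1;
      double c = cd;
      long ln = lp[w] + 1;
      if (cu < c || (cu == c && cu < INF && lu < ln)) {
        c = cu; ln = lu; mv = 2;
      }
      if (cl < c || (cl == c && cl < INF && ll < ln)) {
        c = cl; ln = ll; mv = 3;
      }
      cc[w] = c;
      lc[w] = ln;
      if (c < rowmin) rowmin = c;
      if (mvrow) mvrow[w] = mv;
    }
    std::swap(cprev, ccur);
    std::swap(lprev, lcur);
    // certified lower bound on the final distance so far
    double clb = std::min(rowmin, escape);
    *reached_lb = dist_lb(clb);
    if (!trace && *reached_lb >= cutoff) {
      res.done = false;
      res.cost = INF;
      res.len = 0;
      return res;
    }
  }
  long wfin = lb - la - loD;
  res.cost = cprev[wfin];
  res.len = lprev[wfin];
  res.done = (g <= 0) || (res.cost <= g * (std::abs(delta) + 2.0 * k)) ||
             (k >= std::max(la, lb));
  *reached_lb = dist_lb(std::min(res.cost, escape));
  return res;
}

DPResult align_core(const Rep& a, const Rep& b, const AlignParams& par,
                    double cutoff, bool trace, double* lb_out) {
  if (a.len == 0 || b.len == 0)
    Rcpp::stop("cannot align an empty profile");
  thread_local std::vector<const double*> ca, cb;
  col_view(a, ca);
  col_view(b, cb);
  long kmax = std::max(a.len, b.len);
  long k = (par.gap > 0) ? 4 : kmax;
  // corridor width at which escaping paths alone certify the cutoff, so a
  // failed narrow pass can jump straight to the decisive width
  long k_cut = kmax;
  if (!trace && par.gap > 0 && cutoff < 2.0 * par.gap && cutoff > 0 &&
      std::isfinite(cutoff)) {
    double c_need =
        cutoff * (a.len + b.len) / (2.0 - cutoff / par.gap);
    k_cut = static_cast<long>(
        std::ceil(std::max(0.0, c_need / par.gap -
                                std::abs(a.len - b.len)) / 2.0)) + 1;
  }
  for (;;) {
    DPResult r = corridor_pass(a, b, ca, cb, par, k, trace, cutoff, lb_out);
    if (r.done) return r;
    if (!trace && *lb_out >= cutoff) {
      r.done = false;
      return r;
    }
    if (k >= kmax) return r;  // full-width pass is always exact
    k = std::min(kmax, std::max(k * 2, std::min(k_cut, kmax)));
  }
}

}  // namespace

AlignResult align_dist(const Rep& a, const Rep& b, const AlignParams& par,
                       double cutoff) {
  double lb = 0.0;
  DPResult r = align_core(a, b, par, cutoff, false, &lb);
  AlignResult out;
  if (!r.done) {
    out.truncated = true;
    out.dist = lb;
    out.cost = INF;
    out.len = 0;
    return out;
  }
  out.cost = r.cost;
  out.len = r.len;
  out.dist = (r.len > 0) ? r.cost / r.len : 0.0;
  return out;
}

Rep align_merge(const Rep& a, const Rep& b, const AlignParams& par) {
  double lb = 0.0;
  DPResult r = align_core(a, b, par, INF, true, &lb);
  thread_local std::vector<const double*> ca, cb;
  col_view(a, ca);
  col_view(b, cb);
  const double wa = a.weight, wb = b.weight, wt = wa + wb;

  // traceback from (la, lb)
  std::vector<Col> cols;
  cols.reserve(r.len);
  int i = a.len;
  long j = b.len;
  while (i > 0 || j > 0) {
    long w = j - i - r.loD;
    uint8_t mv = r.mv[static_cast<size_t>(i) * r.W + w];
    Col c{};
    if (mv == 1) {
      const double* p = ca[i - 1];
      const double* q = cb[j - 1];
      for (int t = 0; t < 5; ++t) c.p[t] = (wa * p[t] + wb * q[t]) / wt;
      --i; --j;
    } else if (mv == 2) {
      const double* p = ca[i - 1];
      for (int t = 0; t < 4; ++t) c.p[t] = wa * p[t] / wt;
      c.p[4] = (wa * p[4] + wb) / wt;
      --i;
    } else {
      const double* q = cb[j - 1];
      for (int t = 0; t < 4; ++t) c.p[t] = wb * q[t] / wt;
      c.p[4] = (wb * q[4] + wa) / wt;
      --j;
    }
    cols.push_back(c);
  }

  Rep m;
  m.weight = wt;
  m.len = static_cast<int>(cols.size());
  m.code.resize(m.len);
  for (int t = 0; t < m.len; ++t) {
    const Col& c = cols[m.len - 1 - t];  // reverse
    int pure = -1;
    for (int bbase = 0; bbase < 4; ++bbase)
      if (c.p[bbase] == 1.0) pure = bbase;
    if (pure >= 0 && c.p[4] == 0.0) {
      m.code[t] = static_cast<uint8_t>(pure);
    } else {
      m.code[t] = 255;
      m.mixed_idx.push_back(t);
      m.mixed_col.push_back(c);
    }
  }
  return m;
}

Rep rep_from_string(const std::string& s, double weight) {
  Rep r;
  r.weight = weight;
  r.len = static_cast<int>(s.size());
  r.code.resize(r.len);
  for (int i = 0; i < r.len; ++i) {
    char ch = std::toupper(static_cast<unsigned char>(s[i]));
    int b = -1;
    switch (ch) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': case 'U': b = 3; break;
      default: b = -1;
    }
    if (b >= 0) {
      r.code[i] = static_cast<uint8_t>(b);
      continue;
    }
    // IUPAC ambiguity: uniform mass over the coded base set
    const char* set = nullptr;
    switch (ch) {
      case 'N': set = "ACGT"; break;
      case 'R': set = "AG"; break;
      case 'Y': set = "CT"; break;
      case 'S': set = "CG"; break;
      case 'W': set = "AT"; break;
      case 'K': set = "GT"; break;
      case 'M': set = "AC"; break;
      case 'B': set = "CGT"; break;
      case 'D': set = "AGT"; break;
      case 'H': set = "ACT"; break;
      case 'V': set = "ACG"; break;
      default:
        Rcpp::stop("invalid base '%c' at position %d", ch, i + 1);
    }
    Col c{};
    double mass = 1.0 / std::strlen(set);
    for (const char* p = set; *p; ++p) {
      int bb = (*p == 'A') ? 0 : (*p == 'C') ? 1 : (*p == 'G') ? 2 : 3;
      c.p[bb] = mass;
    }
    r.code[i] = 255;
    r.mixed_idx.push_back(i);
    r.mixed_col.push_back(c);
  }
  return r;
}

Rcpp::NumericMatrix rep_to_matrix(const Rep& r) {
  Rcpp::NumericMatrix m(5, r.len);
  for (int i = 0; i < r.len; ++i)
    if (r.code[i] != 255) m(r.code[i], i) = 1.0;
  for (size_t k = 0; k < r.mixed_idx.size(); ++k)
    for (int t = 0; t < 5; ++t) m(t, r.mixed_idx[k]) = r.mixed_col[k].p[t];
  Rcpp::rownames(m) =
      Rcpp::CharacterVector::create("A", "C", "G", "T", "gap");
  return m;
}

Rep rep_from_matrix(const Rcpp::NumericMatrix& m, double weight) {
  if (m.nrow() != 5) Rcpp::stop("profile matrix must have 5 rows (A,C,G,T,gap)");
  Rep r;
  r.weight = weight;
  r.len = m.ncol();
  r.code.resize(r.len);
  for (int i = 0; i < r.len; ++i) {
    double s = 0;
    int pure = -1;
    for (int t = 0; t < 5; ++t) {
      if (m(t, i) < -1e-12) Rcpp::stop("negative probability in profile column %d", i + 1);
      s += m(t, i);
      if (t < 4 && m(t, i) == 1.0) pure = t;
    }
    if (std::abs(s - 1.0) > 1e-9)
      Rcpp::stop("profile column %d does not sum to 1", i + 1);
    if (pure >= 0 && m(4, i) == 0.0) {
      r.code[i] = static_cast<uint8_t>(pure);
    } else {
      r.code[i] = 255;
      Col c{};
      for (int t = 0; t < 5; ++t) c.p[t] = m(t, i);
      r.mixed_idx.push_back(i);
      r.mixed_col.push_back(c);
    }
  }
  return r;
}

}  // namespace pbp
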