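#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <climits>
#include <algorithm>
using namespace Rcpp;

static const int NAA = 20;       // standard amino acids
static const int NXX = 21;       // + X at index 20
static const double LN2 = 0.6931471805599453;

// ---------------------------------------------------------------------------
// Sinkhorn projection of a positive kernel onto given row/column marginals.
// Returns the projected matrix; used both as a public primitive and as the
// robust fallback inside the entropy-constrained adjustment.
// ---------------------------------------------------------------------------
static bool sinkhorn_core(std::vector<double>& q, const double* c1,
                          const double* c2, double tol, int maxit,
                          int* iters_out) {
  std::vector<double> rs(NAA), cs(NAA);
  double resid = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    for (int a = 0; a < NAA; ++a) {
      double s = 0.0;
      for (int b = 0; b < NAA; ++b) s += q[a * NAA + b];
      rs[a] = c1[a] / s;
    }
    for (int a = 0; a < NAA; ++a)
      for (int b = 0; b < NAA; ++b) q[a * NAA + b] *= rs[a];
    resid = 0.0;
    for (int b = 0; b < NAA; ++b) {
      double s = 0.0;
      for (int a = 0; a < NAA; ++a) s += q[a * NAA + b];
      cs[b] = c2[b] / s;
      resid = std::max(resid, std::fabs(s - c2[b]));
    }
    for (int a = 0; a < NAA; ++a)
      for (int b = 0; b < NAA; ++b) q[a * NAA + b] *= cs[b];
    if (resid < tol) { ++it; break; }
  }
  if (iters_out) *iters_out = it;
  return resid < tol;
}

static double rel_entropy_bits(const std::vector<double>& q,
                               const double* c1, const double* c2) {
  double h = 0.0;
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) {
      double v = q[a * NAA + b];
      if (v > 0.0) h += v * std::log(v / (c1[a] * c2[b]));
    }
  return h / LN2;
}

// [[Rcpp::export]]
List cpp_sinkhorn(NumericMatrix q0, NumericVector c1, NumericVector c2,
                  double tol, int maxit) {
  std::vector<double> q(q0.begin(), q0.end());
  // NumericMatrix is column-major; the kernel is symmetric in layout use:
  // we treat q[a*NAA+b]; transpose in, transpose out for consistency.
  std::vector<double> qr(NAA * NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) qr[a * NAA + b] = q0(a, b);
  int iters = 0;
  bool ok = sinkhorn_core(qr, c1.begin(), c2.begin(), tol, maxit, &iters);
  NumericMatrix out(NAA, NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) out(a, b) = qr[a * NAA + b];
  return List::create(_["q"] = out, _["iters"] = iters,
                      _["converged"] = ok);
}

// ---------------------------------------------------------------------------
// Entropy-constrained compositional adjustment.
//
// Find Q minimising KL(Q || Q0) subject to row marginals c1, column
// marginals c2 and relative entropy D(Q || c1 x c2) = h.  Stationarity of
// the Lagrangian confines Q to the family
//     q_ab = exp( alpha*log q0_ab + (1-alpha)*log(c1_a c2_b)
//                 + rho_a + sigma_b ),
// so we run a damped Newton iteration on the 40 free variables
// (rho_1..20, sigma_1..19, alpha; sigma_20 fixed, last column equation
// dropped as redundant).  If Newton fails, a monotone bisection on alpha
// with an inner Sinkhorn projection is used; if the target entropy is
// unreachable for these compositions the call reports non-convergence.
// ---------------------------------------------------------------------------

struct AdjustWork {
  std::vector<double> L0;   // log q0
  std::vector<double> lc;   // log(c1_a c2_b)
  std::vector<double> G;    // L0 - lc
  const double* c1;
  const double* c2;
  double h;                 // target entropy, bits
};

static void build_q(const AdjustWork& w, const double* rho,
                    const double* sigma, double alpha,
                    std::vector<double>& q) {
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) {
      int i = a * NAA + b;
      q[i] = std::exp(alpha * w.L0[i] + (1.0 - alpha) * w.lc[i] +
                      rho[a] + sigma[b]);
    }
}

// residuals: F[0..19] = rowsum - c1; F[20..38] = colsum(0..18) - c2;
// F[39] = D - h (bits)
static double residuals(const AdjustWork& w, const std::vector<double>& q,
                        const double* rho, const double* sigma, double alpha,
                        double* F) {
  double worst = 0.0;
  for (int a = 0; a < NAA; ++a) {
    double s = 0.0;
    for (int b = 0; b < NAA; ++b) s += q[a * NAA + b];
    F[a] = s - w.c1[a];
    worst = std::max(worst, std::fabs(F[a]));
  }
  for (int b = 0; b < NAA - 1; ++b) {
    double s = 0.0;
    for (int a = 0; a < NAA; ++a) s += q[a * NAA + b];
    F[NAA + b] = s - w.c2[b];
    worst = std::max(worst, std::fabs(F[NAA + b]));
  }
  double D = 0.0;
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) {
      int i = a * NAA + b;
      D += q[i] * (alpha * w.G[i] + rho[a] + sigma[b]);
    }
  D /= LN2;
  F[39] = D - w.h;
  worst = std::max(worst, std::fabs(F[39]));
  return worst;
}

static bool solve_dense(std::vector<double>& A, double* x, int n) {
  // Gaussian elimination with partial pivoting; A is n x n row-major,
  // x holds the RHS on entry and the solution on exit.
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double best = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-14) return false;
    if (piv != k) {
      for (int j = k; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(x[k], x[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = A[i * n + k] / A[k * n + k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      x[i] -= f * x[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = x[i];
    for (int j = i + 1; j < n; ++j) s -= A[i * n + j] * x[j];
    x[i] = s / A[i * n + i];
  }
  return true;
}

// warm[0..19] = rho, warm[20..39] = sigma, warm[40] = alpha
static bool newton_adjust(const AdjustWork& w, std::vector<double>& q,
                          double tol, int maxit, double* warm,
                          int* niter = nullptr) {
  const int NV = 40;
  double rho[NAA] = {0.0}, sigma[NAA] = {0.0};
  double alpha = 1.0;
  if (warm && warm[40] > 0.0) {
    std::copy(warm, warm + NAA, rho);
    std::copy(warm + NAA, warm + 2 * NAA, sigma);
    alpha = warm[40];
  } else {
    // precondition rho/sigma with a few Sinkhorn sweeps at alpha = 1
    std::vector<double> k0(NAA * NAA);
    for (int i = 0; i < NAA * NAA; ++i) k0[i] = std::exp(w.L0[i]);
    std::vector<double> kk = k0;
    sinkhorn_core(kk, w.c1, w.c2, 1e-4, 20, nullptr);
    for (int a = 0; a < NAA; ++a) {
      double s0 = 0.0, s1 = 0.0;
      for (int b = 0; b < NAA; ++b) { s0 += k0[a * NAA + b];
                                      s1 += kk[a * NAA + b]; }
      rho[a] = std::log(s1 / s0);
    }
  }
  std::vector<double> J(NV * NV);
  double F[NV], step[NV];
  build_q(w, rho, sigma, alpha, q);
  double worst = residuals(w, q, rho, sigma, alpha, F);
  int it = 0;
  for (; it < maxit && worst >= tol; ++it) {
    // assemble Jacobian: variables x = (rho_0..19, sigma_0..18, alpha)
    std::fill(J.begin(), J.end(), 0.0);
    double T, qab;
    for (int a = 0; a < NAA; ++a) {
      double rowsum = 0.0, ga = 0.0, dd = 0.0;
      for (int b = 0; b < NAA; ++b) {
        int i = a * NAA + b;
        qab = q[i];
        rowsum += qab;
        ga += qab * w.G[i];
        T = (alpha * w.G[i] + rho[a] + sigma[b]) / LN2;
        dd += qab * (T + 1.0 / LN2);
        if (b < NAA - 1) {
          J[a * NV + NAA + b] = qab;                    // dR_a/dsigma_b
          J[(NAA + b) * NV + a] = qab;                  // dC_b/drho_a
        }
      }
      J[a * NV + a] = rowsum;                           // dR_a/drho_a
      J[a * NV + NV - 1] = ga;                          // dR_a/dalpha
      J[(NV - 1) * NV + a] = dd;                        // dD/drho_a
    }
    for (int b = 0; b < NAA - 1; ++b) {
      double colsum = 0.0, gb = 0.0, dd = 0.0;
      for (int a = 0; a < NAA; ++a) {
        int i = a * NAA + b;
        qab = q[i];
        colsum += qab;
        gb += qab * w.G[i];
        T = (alpha * w.G[i] + rho[a] + sigma[b]) / LN2;
        dd += qab * (T + 1.0 / LN2);
      }
      J[(NAA + b) * NV + NAA + b] = colsum;
      J[(NAA + b) * NV + NV - 1] = gb;
      J[(NV - 1) * NV + NAA + b] = dd;
    }
    double dalpha = 0.0;
    for (int a = 0; a < NAA; ++a)
      for (int b = 0; b < NAA; ++b) {
        int i = a * NAA + b;
        T = (alpha * w.G[i] + rho[a] + sigma[b]) / LN2;
        dalpha += q[i] * w.G[i] * (T + 1.0 / LN2);
      }
    J[(NV - 1) * NV + NV - 1] = dalpha;
    for (int i = 0; i < NV; ++i) step[i] = -F[i];
    std::vector<double> Jcopy = J;
    if (!solve_dense(Jcopy, step, NV)) return false;
    // damped update
    double lam = 1.0;
    bool improved = false;
    for (int half = 0; half < 12; ++half, lam *= 0.5) {
      double r2[NAA], s2[NAA], a2;
      for (int a = 0; a < NAA; ++a) r2[a] = rho[a] + lam * step[a];
      for (int b = 0; b < NAA - 1; ++b) s2[b] = sigma[b] + lam * step[NAA + b];
      s2[NAA - 1] = 0.0;
      a2 = alpha + lam * step[NV - 1];
      build_q(w, r2, s2, a2, q);
      double w2 = residuals(w, q, r2, s2, a2, F);
      if (w2 < worst || w2 < tol) {
        std::copy(r2, r2 + NAA, rho);
        std::copy(s2, s2 + NAA, sigma);
        alpha = a2;
        worst = w2;
        improved = true;
        break;
      }
    }
    if (!improved) { if (niter) *niter = it + 1; return false; }
  }
  if (niter) *niter = it;
  if (worst < tol) {
    if (warm) {
      std::copy(rho, rho + NAA, warm);
      std::copy(sigma, sigma + NAA, warm + NAA);
      warm[40] = alpha;
    }
    return true;
  }
  return false;
}

// monotone-in-alpha fallback: Sinkhorn projection of the alpha-kernel,
// bisection on the resulting entropy
static bool bisect_adjust(const AdjustWork& w, std::vector<double>& q,
                          double tol, int maxit) {
  std::vector<double> kern(NAA * NAA);
  auto evalD = [&](double alpha, std::vector<double>& out) {
    for (int i = 0; i < NAA * NAA; ++i)
      out[i] = std::exp(alpha * w.L0[i] + (1.0 - alpha) * w.lc[i]);
    if (!sinkhorn_core(out, w.c1, w.c2, 1e-13, 20000, nullptr)) return -1.0;
    return rel_entropy_bits(out, w.c1, w.c2);
  };
  double lo = 0.0, hi = 1.0;
  double dhi = evalD(hi, kern);
  int grow = 0;
  while (dhi >= 0.0 && dhi < w.h && grow++ < 12) {
    hi *= 1.5;
    dhi = evalD(hi, kern);
  }
  if (dhi < w.h) return false;  // entropy target unreachable
  for (int it = 0; it < maxit; ++it) {
    double mid = 0.5 * (lo + hi);
    double d = evalD(mid, kern);
    if (d < 0.0) return false;
    if (std::fabs(d - w.h) < tol) { q = kern; return true; }
    if (d < w.h) lo = mid; else hi = mid;
  }
  q = kern;
  return std::fabs(rel_entropy_bits(q, w.c1, w.c2) - w.h) < tol * 10;
}

static bool adjust_core(const double* q0, const double* c1, const double* c2,
                        double h, double tol, int maxit,
                        std::vector<double>& q, bool* noop,
                        double* warm = nullptr) {
  // no-op fast path: constraints already satisfied by q0
  double worst = 0.0;
  for (int a = 0; a < NAA; ++a) {
    double rs = 0.0, cs = 0.0;
    for (int b = 0; b < NAA; ++b) { rs += q0[a * NAA + b];
                                    cs += q0[b * NAA + a]; }
    worst = std::max(worst, std::fabs(rs - c1[a]));
    worst = std::max(worst, std::fabs(cs - c2[a]));
  }
  std::vector<double> qv(q0, q0 + NAA * NAA);
  if (worst < tol && std::fabs(rel_entropy_bits(qv, c1, c2) - h) < tol) {
    q = qv;
    if (noop) *noop = true;
    return true;
  }
  if (noop) *noop = false;
  AdjustWork w;
  w.L0.resize(NAA * NAA);
  w.lc.resize(NAA * NAA);
  w.G.resize(NAA * NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) {
      int i = a * NAA + b;
      w.L0[i] = std::log(q0[i]);
      w.lc[i] = std::log(c1[a] * c2[b]);
      w.G[i] = w.L0[i] - w.lc[i];
    }
  w.c1 = c1; w.c2 = c2; w.h = h;
  q.resize(NAA * NAA);
  if (newton_adjust(w, q, tol, maxit, warm)) return true;
  if (warm && warm[40] > 0.0 &&
      newton_adjust(w, q, tol, maxit, nullptr))  // retry cold
    return true;
  return bisect_adjust(w, q, tol, maxit);
}

// [[Rcpp::export]]
List cpp_adjust_q(NumericMatrix q0, NumericVector c1, NumericVector c2,
                  double h, double tol, int maxit) {
  std::vector<double> q0r(NAA * NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) q0r[a * NAA + b] = q0(a, b);
  std::vector<double> q;
  bool noop = false;
  bool ok = adjust_core(q0r.data(), c1.begin(), c2.begin(), h, tol, maxit,
                        q, &noop);
  // (diagnostic iteration counts available via newton_adjust's niter)
  NumericMatrix out(NAA, NAA);
  if (ok)
    for (int a = 0; a < NAA; ++a)
      for (int b = 0; b < NAA; ++b) out(a, b) = q[a * NAA + b];
  return List::create(_["q"] = out, _["converged"] = ok, _["noop"] = noop);
}

// ---------------------------------------------------------------------------
// Matrix-switching Smith-Waterman-Gotoh.
//
// The matrix bank has 10 slots:
//   0 full, 1 noncc, 2 cc (unweighted), 3..9 cc copies for registers a..g
//   (weight-scaled; for the ccalignx mode these are the register-group
//   matrices of the respective register).
// Pair selection: both coiled-coil -> register of the more confident
// prediction picks slot 2+r (slot 2 if no register); exactly one -> full;
// neither -> noncc.
// ---------------------------------------------------------------------------

struct SeqAnno {
  std::vector<int> seq, state, group, reg;
  std::vector<double> prob;
  int n;
};

static SeqAnno list_to_anno(const List& l) {
  SeqAnno s;
  IntegerVector a = l["seq"], b = l["state"], g = l["group"], r = l["reg"];
  NumericVector p = l["prob"];
  s.seq.assign(a.begin(), a.end());
  s.state.assign(b.begin(), b.end());
  s.group.assign(g.begin(), g.end());
  s.reg.assign(r.begin(), r.end());
  s.prob.assign(p.begin(), p.end());
  s.n = s.seq.size();
  return s;
}

struct Bank {
  // 10 matrices, each NXX*NXX int, row-major [a*NXX+b]
  std::vector<int> m;
  const int* mat(int k) const { return m.data() + k * NXX * NXX; }
};

static inline int pair_slot(const SeqAnno& A, const SeqAnno& B, int i, int j,
                            int conf_rule) {
  if (A.state[i]) {
    if (B.state[j]) {
      int r;
      if (conf_rule == 0) {           // query wins ties
        r = (A.prob[i] >= B.prob[j]) ? A.reg[i] : B.reg[j];
      } else {                        // symmetric: max prob, tie -> smaller
        if (A.prob[i] > B.prob[j]) r = A.reg[i];
        else if (B.prob[j] > A.prob[i]) r = B.reg[j];
        else r = std::min(A.reg[i], B.reg[j]);
      }
      return (r > 0) ? 2 + r : 2;
    }
    return 0;                         // mixed
  }
  return B.state[j] ? 0 : 1;          // mixed : noncc
}

// score-only local DP
static int gotoh_score(const SeqAnno& A, const SeqAnno& B, const Bank& bank,
                       int beta, bool use_bonus, int conf_rule,
                       int gap_open, int gap_ext) {
  const int oe = gap_open + gap_ext, ge = gap_ext;
  const int m = A.n, n = B.n;
  const int NEG = INT_MIN / 4;
  std::vector<int> H(n + 1, 0), E(n + 1, NEG);
  // runs of constant coiled-coil state along the subject: within a run
  // the matrix slot is fixed unless both residues are coiled-coil, so
  // most cells take a branch-free inner loop
  std::vector<int> segStart, segEnd, segState;
  {
    int j = 0;
    while (j < n) {
      int k = j;
      while (k < n && B.state[k] == B.state[j]) ++k;
      segStart.push_back(j);
      segEnd.push_back(k);
      segState.push_back(B.state[j]);
      j = k;
    }
  }
  int best = 0;
  int* Hp = H.data();
  int* Ep = E.data();
  for (int i = 1; i <= m; ++i) {
    const int ai = A.seq[i - 1];
    const bool cci = A.state[i - 1] != 0;
    const int regi = A.reg[i - 1];
    const double probi = A.prob[i - 1];
    const int* rowMix = bank.mat(0) + ai * NXX;
    const int* rowNon = bank.mat(1) + ai * NXX;
    const int* rowSelf = bank.mat(regi > 0 ? 2 + regi : 2) + ai * NXX;
    int diag = 0, F = NEG, Hij = 0;
    for (size_t s = 0; s < segStart.size(); ++s) {
      const int j0 = segStart[s], j1 = segEnd[s];
      if (!cci || !segState[s]) {
        const int* row = (cci || segState[s]) ? rowMix : rowNon;
        for (int j = j0 + 1; j <= j1; ++j) {
          int e = std::max(Hp[j] - oe, Ep[j] - ge);
          Ep[j] = e;
          F = std::max(Hij - oe, F - ge);
          int h = diag + row[B.seq[j - 1]];
          if (h < 0) h = 0;
          if (e > h) h = e;
          if (F > h) h = F;
          diag = Hp[j];
          Hp[j] = h;
          Hij = h;
          if (h > best) best = h;
        }
      } else {
        for (int j = j0 + 1; j <= j1; ++j) {
          int e = std::max(Hp[j] - oe, Ep[j] - ge);
          Ep[j] = e;
          F = std::max(Hij - oe, F - ge);
          const int regj = B.reg[j - 1];
          int r;
          if (conf_rule == 0) {
            r = (probi >= B.prob[j - 1]) ? regi : regj;
          } else {
            if (probi > B.prob[j - 1]) r = regi;
            else if (B.prob[j - 1] > probi) r = regj;
            else r = std::min(regi, regj);
          }
          const int* row = (r == regi) ? rowSelf
                           : bank.mat(r > 0 ? 2 + r : 2) + ai * NXX;
          int sub = row[B.seq[j - 1]];
          if (use_bonus && regi > 0 && regi == regj) sub += beta;
          int h = diag + sub;
          if (h < 0) h = 0;
          if (e > h) h = e;
          if (F > h) h = F;
          diag = Hp[j];
          Hp[j] = h;
          Hij = h;
          if (h > best) best = h;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_align_score(List qa, List sa, List bankList, int beta,
                    bool use_bonus, int conf_rule, int gap_open,
                    int gap_ext) {
  SeqAnno A = list_to_anno(qa), B = list_to_anno(sa);
  Bank bank;
  bank.m.resize(10 * NXX * NXX);
  for (int k = 0; k < 10; ++k) {
    IntegerMatrix M = bankList[k];
    for (int a = 0; a < NXX; ++a)
      for (int b = 0; b < NXX; ++b)
        bank.m[k * NXX * NXX + a * NXX + b] = M(a, b);
  }
  return gotoh_score(A, B, bank, beta, use_bonus, conf_rule, gap_open,
                     gap_ext);
}

// full DP with traceback; tie-break diagonal > up (gap in subject) > left
// [[Rcpp::export]]
List cpp_align_full(List qa, List sa, List bankList, int beta,
                    bool use_bonus, int conf_rule, int gap_open,
                    int gap_ext) {
  SeqAnno A = list_to_anno(qa), B = list_to_anno(sa);
  Bank bank;
  bank.m.resize(10 * NXX * NXX);
  for (int k = 0; k < 10; ++k) {
    IntegerMatrix M = bankList[k];
    for (int a = 0; a < NXX; ++a)
      for (int b = 0; b < NXX; ++b)
        bank.m[k * NXX * NXX + a * NXX + b] = M(a, b);
  }
  const int oe = gap_open + gap_ext, ge = gap_ext;
  const int m = A.n, n = B.n;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  // pointers: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<unsigned char> P((m + 1) * (n + 1), 0);
  std::vector<unsigned char> PE((m + 1) * (n + 1), 0),
      PF((m + 1) * (n + 1), 0);  // 1 = extend
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int ai = A.seq[i - 1];
    const bool cci = A.state[i - 1] != 0;
    const int regi = A.reg[i - 1];
    for (int j = 1; j <= n; ++j) {
      int id = i * (n + 1) + j, up = (i - 1) * (n + 1) + j, lf = id - 1,
          dg = up - 1;
      int eo = H[up] - oe, ee = E[up] - ge;
      E[id] = std::max(eo, ee);
      PE[id] = (ee > eo) ? 1 : 0;
      int fo = H[lf] - oe, fe = F[lf] - ge;
      F[id] = std::max(fo, fe);
      PF[id] = (fe > fo) ? 1 : 0;
      int slot = pair_slot(A, B, i - 1, j - 1, conf_rule);
      int sub = bank.mat(slot)[ai * NXX + B.seq[j - 1]];
      if (use_bonus && cci && regi > 0 && regi == B.reg[j - 1] &&
          B.state[j - 1])
        sub += beta;
      int cand = H[dg] + sub;
      int h = 0;
      unsigned char p = 0;
      if (cand >= h && cand > 0) { h = cand; p = 1; }
      if (E[id] > h) { h = E[id]; p = 2; }
      if (F[id] > h) { h = F[id]; p = 3; }
      H[id] = h;
      P[id] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> qpos, spos, slots;
  std::vector<bool> bonusv;
  int i = bi, j = bj;
  unsigned char state = 0;  // 0 from H, 1 from E, 2 from F
  while (i > 0 && j > 0) {
    int id = i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = P[id];
      if (p == 0) break;
      if (p == 1) {
        int slot = pair_slot(A, B, i - 1, j - 1, conf_rule);
        bool bon = use_bonus && A.state[i - 1] && B.state[j - 1] &&
                   A.reg[i - 1] > 0 && A.reg[i - 1] == B.reg[j - 1];
        qpos.push_back(i); spos.push_back(j);
        slots.push_back(slot); bonusv.push_back(bon);
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in subject, consume query residue
      qpos.push_back(i); spos.push_back(0);
      slots.push_back(-1); bonusv.push_back(false);
      if (PE[id] == 0) state = 0;
      --i;
    } else {                  // gap in query, consume subject residue
      qpos.push_back(0); spos.push_back(j);
      slots.push_back(-1); bonusv.push_back(false);
      if (PF[id] == 0) state = 0;
      --j;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(spos.begin(), spos.end());
  std::reverse(slots.begin(), slots.end());
  std::reverse(bonusv.begin(), bonusv.end());
  int qs = 0, qe = 0, ss = 0, se = 0;
  for (size_t k = 0; k < qpos.size(); ++k) {
    if (qpos[k] > 0) { if (qs == 0) qs = qpos[k]; qe = qpos[k]; }
    if (spos[k] > 0) { if (ss == 0) ss = spos[k]; se = spos[k]; }
  }
  return List::create(_["score"] = best, _["qstart"] = qs, _["qend"] = qe,
                      _["sstart"] = ss, _["send"] = se,
                      _["qpos"] = qpos, _["spos"] = spos,
                      _["slot"] = slots, _["bonus"] = bonusv);
}

// ---------------------------------------------------------------------------
// Batch best-hit search: replicates the per-pair pipeline (compositions ->
// entropy-constrained adjustment -> matrix bank -> score-only DP) entirely
// in C++ for all query x subject pairs.
// ---------------------------------------------------------------------------

static void composition(const int* counts, double pseudo, const double* bg,
                        double* out, int* nobs) {
  int n = 0;
  for (int a = 0; a < NAA; ++a) n += counts[a];
  for (int a = 0; a < NAA; ++a)
    out[a] = (counts[a] + pseudo * bg[a]) / (n + pseudo);
  *nobs = n;
}

// derive half-bit integer scores (round half away from zero) into slot
static void scores_from_q(const std::vector<double>& q, const double* c1,
                          const double* c2, double wgt, const int* base,
                          int* out) {
  for (int a = 0; a < NXX; ++a)
    for (int b = 0; b < NXX; ++b) out[a * NXX + b] = base[a * NXX + b];
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) {
      double lo = wgt * 2.0 * std::log2(q[a * NAA + b] / (c1[a] * c2[b]));
      out[a * NXX + b] = (int)(lo >= 0 ? std::floor(lo + 0.5)
                                       : -std::floor(-lo + 0.5));
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_best_hits(List queries, List subjects, int mode,
                            NumericMatrix q0m, NumericVector bg, double h0,
                            IntegerMatrix baseScores, NumericVector wreg,
                            int beta, int conf_rule, int gap_open,
                            int gap_ext, double pseudo, int min_region,
                            double tol, int maxit) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<SeqAnno> Q(nq), S(ns);
  std::vector<std::vector<int>> Qcnt(nq), Scnt(ns);
  for (int i = 0; i < nq; ++i) {
    List l = queries[i];
    Q[i] = list_to_anno(l);
    IntegerMatrix cm = l["counts"];
    Qcnt[i].assign(cm.begin(), cm.end());  // 20 x 6 column-major
  }
  for (int j = 0; j < ns; ++j) {
    List l = subjects[j];
    S[j] = list_to_anno(l);
    IntegerMatrix cm = l["counts"];
    Scnt[j].assign(cm.begin(), cm.end());
  }
  std::vector<double> q0(NAA * NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b) q0[a * NAA + b] = q0m(a, b);
  std::vector<int> base(NXX * NXX);
  for (int a = 0; a < NXX; ++a)
    for (int b = 0; b < NXX; ++b) base[a * NXX + b] = baseScores(a, b);
  NumericMatrix out(nq, ns);
  const int MSZ = NXX * NXX;
  Bank bank;
  bank.m.resize(10 * MSZ);
  std::vector<double> qfull, qcc, qnoncc, qgrp;
  // region order in counts: full, cc, noncc, AD, EG, BCF
  std::vector<std::array<std::array<double, NAA>, 6>> subComp(ns);
  std::vector<std::array<int, 6>> subObs(ns);
  for (int j = 0; j < ns; ++j)
    for (int r = 0; r < 6; ++r)
      composition(Scnt[j].data() + r * NAA, pseudo, bg.begin(),
                  subComp[j][r].data(), &subObs[j][r]);
  double warmBuf[6][41];
  for (int i = 0; i < nq; ++i) {
    double cq[6][NAA];
    int nqueryobs[6];
    for (int r = 0; r < 6; ++r) {
      composition(Qcnt[i].data() + r * NAA, pseudo, bg.begin(), cq[r],
                  &nqueryobs[r]);
      warmBuf[r][40] = -1.0;  // invalidate warm starts per query
    }
    for (int j = 0; j < ns; ++j) {
      double cs[6][NAA];
      int nsubobs[6];
      for (int r = 0; r < 6; ++r) {
        std::copy(subComp[j][r].begin(), subComp[j][r].end(), cs[r]);
        nsubobs[r] = subObs[j][r];
      }
      if (mode == 0) {
        for (int k = 0; k < 10; ++k)
          std::copy(base.begin(), base.end(), bank.m.begin() + k * MSZ);
      } else {
        // "governing" joint distribution per level; a no-op adjustment
        // (compositions equal the base background) keeps the base
        // matrix, exactly like the R path
        struct Gov {
          const std::vector<double>* q;
          const double* c1;
          const double* c2;
          bool isBase;   // unweighted integer scores are the base scores
          int slot;      // slot carrying the unweighted integers (-1 none)
        };
        bool noop = false;
        Gov govBase = {&q0, bg.begin(), bg.begin(), true, -1};
        // full-length
        Gov govFull = govBase;
        bool okF = nqueryobs[0] >= min_region && nsubobs[0] >= min_region &&
                   adjust_core(q0.data(), cq[0], cs[0], h0, tol, maxit,
                               qfull, &noop, warmBuf[0]);
        if (okF && !noop) {
          scores_from_q(qfull, cq[0], cs[0], 1.0, base.data(),
                        bank.m.data() + 0 * MSZ);
          govFull = {&qfull, cq[0], cs[0], false, 0};
        } else {
          std::copy(base.begin(), base.end(), bank.m.begin());
          govFull.slot = 0;
        }
        // non-coiled-coil (falls back to full)
        bool okN = nqueryobs[2] >= min_region && nsubobs[2] >= min_region &&
                   adjust_core(q0.data(), cq[2], cs[2], h0, tol, maxit,
                               qnoncc, &noop, warmBuf[2]);
        if (okN && !noop)
          scores_from_q(qnoncc, cq[2], cs[2], 1.0, base.data(),
                        bank.m.data() + 1 * MSZ);
        else
          std::copy(bank.m.begin(), bank.m.begin() + MSZ,
                    bank.m.begin() + 1 * MSZ);
        // coiled-coil (falls back to full)
        Gov govCC = govFull;
        bool okC = nqueryobs[1] >= min_region && nsubobs[1] >= min_region &&
                   adjust_core(q0.data(), cq[1], cs[1], h0, tol, maxit,
                               qcc, &noop, warmBuf[1]);
        if (okC && !noop) {
          scores_from_q(qcc, cq[1], cs[1], 1.0, base.data(),
                        bank.m.data() + 2 * MSZ);
          govCC = {&qcc, cq[1], cs[1], false, 2};
        } else {
          std::copy(bank.m.begin() + 0 * MSZ, bank.m.begin() + 1 * MSZ,
                    bank.m.begin() + 2 * MSZ);
          govCC.slot = 2;
        }
        // register-group adjustments (ccalignx only; fall back to cc)
        std::vector<double> qg[3];
        Gov govG[3] = {govCC, govCC, govCC};
        if (mode == 2) {
          for (int g = 0; g < 3; ++g) {
            int r6 = 3 + g;  // counts column: AD, EG, BCF
            if (nqueryobs[r6] >= min_region && nsubobs[r6] >= min_region &&
                adjust_core(q0.data(), cq[r6], cs[r6], h0, tol, maxit,
                            qg[g], &noop, warmBuf[r6]) && !noop)
              govG[g] = {&qg[g], cq[r6], cs[r6], false, -1};
          }
        }
        // register slots 3..9: weight-scaled copies of the governing
        // matrix; weight 1 reuses its unweighted integer scores
        static const int reg2grp[7] = {0, 2, 2, 0, 1, 2, 1};  // a..g
        for (int r = 1; r <= 7; ++r) {
          int slot = 2 + r;
          double wg = wreg[r - 1];
          int g = reg2grp[r - 1];
          int dup = -1;
          for (int r2 = 1; r2 < r; ++r2)
            if (reg2grp[r2 - 1] == g && wreg[r2 - 1] == wg) { dup = r2; break; }
          if (dup > 0) {
            std::copy(bank.m.begin() + (2 + dup) * MSZ,
                      bank.m.begin() + (3 + dup) * MSZ,
                      bank.m.begin() + slot * MSZ);
            continue;
          }
          const Gov& gov = (mode == 2) ? govG[g] : govCC;
          if (wg == 1.0 && gov.slot >= 0)
            std::copy(bank.m.begin() + gov.slot * MSZ,
                      bank.m.begin() + (gov.slot + 1) * MSZ,
                      bank.m.begin() + slot * MSZ);
          else if (wg == 1.0 && gov.isBase)
            std::copy(base.begin(), base.end(),
                      bank.m.begin() + slot * MSZ);
          else
            scores_from_q(*gov.q, gov.c1, gov.c2, wg, base.data(),
                          bank.m.data() + slot * MSZ);
        }
      }
      out(i, j) = gotoh_score(Q[i], S[j], bank, beta, mode == 2, conf_rule,
                              gap_open, gap_ext);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
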