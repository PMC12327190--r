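// Inheritance-kernel mixing engine for the discrete (L_inf, k) trait grid.
//
// The larvae trait distribution is a mixture, over all parent-cell pairs, of
// bivariate normal kernels centred at the pair midpoint with covariance
// Sigma = Omega^{1/2} Lambda Omega^{1/2}, Omega = Omega_G + Omega_A,
// Omega_G = cV * diag((dL^2)/2, (dk^2)/2) (two-point pair variances),
// Omega_A = diag(sA2L, sA2K), Lambda the correlation matrix with off-diagonal
// rho. Each kernel is truncated to the grid and renormalized to its in-grid
// mass; cell masses come from the bivariate normal CDF over cell rectangles.
//
// Because Omega is diagonal, every kernel shares the same correlation rho, and
// the kernel shape depends on the pair only through the absolute cell lags
// (|di|, |dj|). Cell masses for a kernel are translation-invariant up to the
// parity of the midpoint on the half-cell lattice, so per (lag, parity) the
// engine caches a windowed template of cell masses; the yearly mixing then
// reduces to weighted template additions. The cache is exposed to R as an
// external pointer so repeated spawns in a simulation reuse the templates.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double phid(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// Port of A. Genz's BVND: P(X > dh, Y > dk) for the standard bivariate
// normal with correlation r. Double-precision accurate (~1e-15).
static double bvnu(double dh, double dk, double r) {
  if (!std::isfinite(dh) && dh > 0) return 0.0;
  if (!std::isfinite(dk) && dk > 0) return 0.0;
  if (!std::isfinite(dh) && dh < 0)
    return (!std::isfinite(dk) && dk < 0) ? 1.0 : phid(-dk);
  if (!std::isfinite(dk) && dk < 0) return phid(-dh);
  static const double w6[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
  static const double x6[3] = {0.9324695142031522, 0.6612093864662647,
                               0.2386191860831970};
  static const double w12[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464,  0.2031674267230659,
                                0.2334925365383547,  0.2491470458134029};
  static const double x12[6] = {0.9815606342467191, 0.9041172563704750,
                                0.7699026741943050, 0.5873179542866171,
                                0.3678314989981802, 0.1252334085114692};
  static const double w20[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};
  static const double x20[10] = {0.9931285991850949,  0.9639719272779138,
                                 0.9122344282513259,  0.8391169718222188,
                                 0.7463319064601508,  0.6360536807265150,
                                 0.5108670019508271,  0.3737060887154196,
                                 0.2277858511416451,  0.07652652113349733};
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { lg = 3;  w = w6;  x = x6; }
  else if (ar < 0.75) { lg = 6;  w = w12; x = x12; }
  else                { lg = 10; w = w20; x = x20; }
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  const double twopi = 2.0 * M_PI;
  if (ar < 0.925) {
    if (ar > 0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0)
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::max(0.0, std::min(1.0, bvn));
}

// CDF: P(X < x, Y < y) with correlation r
static inline double bvncdf(double x, double y, double r) {
  return bvnu(-x, -y, r);
}

// [[Rcpp::export]]
double cpp_bvnu(double dh, double dk, double r) { return bvnu(dh, dk, r); }

// Rectangle masses of one bivariate normal over an edge-defined grid.
// Requires sL > 0 and sK > 0 (non-degenerate); used for kernels and for
// the initial trait distribution.
// [[Rcpp::export]]
NumericMatrix cpp_bvn_cell_masses(NumericVector edgesL, NumericVector edgesK,
                                  double muL, double muK, double sL, double sK,
                                  double rho) {
  if (sL <= 0 || sK <= 0) stop("cpp_bvn_cell_masses requires sL, sK > 0");
  int nL = edgesL.size() - 1, nK = edgesK.size() - 1;
  std::vector<double> F((nL + 1) * (nK + 1));
  for (int j = 0; j <= nK; j++) {
    double zk = (edgesK[j] - muK) / sK;
    for (int i = 0; i <= nL; i++) {
      double zl = (edgesL[i] - muL) / sL;
      F[i + j * (nL + 1)] = bvncdf(zl, zk, rho);
    }
  }
  NumericMatrix out(nL, nK);
  for (int j = 0; j < nK; j++)
    for (int i = 0; i < nL; i++) {
      double m = F[(i + 1) + (j + 1) * (nL + 1)] - F[i + (j + 1) * (nL + 1)] -
                 F[(i + 1) + j * (nL + 1)] + F[i + j * (nL + 1)];
      out(i, j) = std::max(0.0, m);
    }
  return out;
}

struct Tmpl {
  int cl0 = 0, ncl = 0, ck0 = 0, nck = 0;  // window in shift coordinates
  std::vector<double> m;                   // col-major ncl x nck
  bool built = false;
};

struct Group {
  double sL = 0, sK = 0;
  Tmpl t[4];                   // parity combo pL + 2*pK
  std::vector<double> ingrid;  // lazily filled canvas (2nL-1)x(2nK-1)
};

struct MixCache {
  bool init = false;
  int nL = 0, nK = 0;
  double hL = 0, hK = 0, cV = 0, sA2L = 0, sA2K = 0, rho = 0;
  std::map<int, Group> groups;
};

// 1-D cell masses along a degenerate (s == 0) axis for midpoint parity p:
// parity 0 puts the point mass inside cell c = 0; parity 1 places the
// midpoint on a cell edge and splits it evenly between cells 0 and 1.
static void degenerate_axis(int p, int &c0, int &nc, std::vector<double> &mass) {
  if (p == 0) { c0 = 0; nc = 1; mass.assign(1, 1.0); }
  else        { c0 = 0; nc = 2; mass.assign(2, 0.5); }
}

// 1-D normal cell masses along shift coordinate for parity p, scale s, cell h
static void normal_axis(int p, double s, double h, int n, int &c0, int &nc,
                        std::vector<double> &mass) {
  // cell c spans standardized edges z(tau), tau = 2c - p -/+ 1
  int cmax = (int)std::ceil((6.0 * s / h) + 1.0) + 1;
  int lo = std::max(-(n - 1), -cmax), hi = std::min(n - 1, cmax);
  c0 = lo; nc = hi - lo + 1;
  mass.resize(nc);
  double prev = phid(((2.0 * lo - p - 1.0) * h / 2.0) / s);
  for (int c = lo; c <= hi; c++) {
    double cur = phid(((2.0 * c - p + 1.0) * h / 2.0) / s);
    mass[c - lo] = std::max(0.0, cur - prev);
    prev = cur;
  }
}

static void build_template(Tmpl &T, int pL, int pK, const MixCache &mc,
                           const Group &g) {
  double sL = g.sL, sK = g.sK;
  int nL = mc.nL, nK = mc.nK;
  if (sL <= 0 || sK <= 0) {
    int cl0, ncl, ck0, nck;
    std::vector<double> mL, mK;
    if (sL <= 0) degenerate_axis(pL, cl0, ncl, mL);
    else normal_axis(pL, sL, mc.hL, nL, cl0, ncl, mL);
    if (sK <= 0) degenerate_axis(pK, ck0, nck, mK);
    else normal_axis(pK, sK, mc.hK, nK, ck0, nck, mK);
    T.cl0 = cl0; T.ncl = ncl; T.ck0 = ck0; T.nck = nck;
    T.m.resize((size_t)ncl * nck);
    for (int j = 0; j < nck; j++)
      for (int i = 0; i < ncl; i++) T.m[i + (size_t)j * ncl] = mL[i] * mK[j];
    T.built = true;
    return;
  }
  // On small grids (<= 1024 cells) templates span the whole grid: cell
  // masses are exact to CDF precision. On larger grids the support is
  // truncated at 4.5 SD (+1 cell), excluding < 4e-6 of a kernel's mass;
  // the final renormalization restores the total.
  int clmax, ckmax;
  if (nL * nK <= 1024) {
    clmax = nL; ckmax = nK;
  } else {
    clmax = (int)std::ceil(4.5 * sL / mc.hL + 1.0) + 1;
    ckmax = (int)std::ceil(4.5 * sK / mc.hK + 1.0) + 1;
  }
  int cl0 = std::max(-(nL - 1), -clmax), cl1 = std::min(nL - 1, clmax);
  int ck0 = std::max(-(nK - 1), -ckmax), ck1 = std::min(nK - 1, ckmax);
  int ncl = cl1 - cl0 + 1, nck = ck1 - ck0 + 1;
  std::vector<double> F((size_t)(ncl + 1) * (nck + 1));
  for (int j = 0; j <= nck; j++) {
    double zk = ((2.0 * (ck0 + j) - pK - 1.0) * mc.hK / 2.0) / sK;
    for (int i = 0; i <= ncl; i++) {
      double zl = ((2.0 * (cl0 + i) - pL - 1.0) * mc.hL / 2.0) / sL;
      F[i + (size_t)j * (ncl + 1)] = bvncdf(zl, zk, mc.rho);
    }
  }
  T.cl0 = cl0; T.ncl = ncl; T.ck0 = ck0; T.nck = nck;
  T.m.resize((size_t)ncl * nck);
  for (int j = 0; j < nck; j++)
    for (int i = 0; i < ncl; i++) {
      double v = F[(i + 1) + (size_t)(j + 1) * (ncl + 1)] -
                 F[i + (size_t)(j + 1) * (ncl + 1)] -
                 F[(i + 1) + (size_t)j * (ncl + 1)] +
                 F[i + (size_t)j * (ncl + 1)];
      T.m[i + (size_t)j * ncl] = std::max(0.0, v);
    }
  T.built = true;
}

// In-grid probability mass for the kernel with midpoint index (m2L, m2K).
// A degenerate axis (s == 0) contributes factor 1: midpoints always lie
// inside the grid rectangle. Values are cached on the midpoint canvas.
static double ingrid_mass(const MixCache &mc, Group &g, int m2L, int m2K) {
  int W = 2 * mc.nL - 1;
  size_t idx = (size_t)m2L + (size_t)m2K * W;
  if (g.ingrid.empty())
    g.ingrid.assign((size_t)W * (2 * mc.nK - 1),
                    std::numeric_limits<double>::quiet_NaN());
  double v = g.ingrid[idx];
  if (!std::isnan(v)) return v;
  double zll = 0, zlh = 0, zkl = 0, zkh = 0;
  if (g.sL > 0) {
    zll = ((-m2L - 1.0) * mc.hL / 2.0) / g.sL;
    zlh = ((2.0 * mc.nL - m2L - 1.0) * mc.hL / 2.0) / g.sL;
  }
  if (g.sK > 0) {
    zkl = ((-m2K - 1.0) * mc.hK / 2.0) / g.sK;
    zkh = ((2.0 * mc.nK - m2K - 1.0) * mc.hK / 2.0) / g.sK;
  }
  if (g.sL <= 0 && g.sK <= 0)      v = 1.0;
  else if (g.sL <= 0)              v = phid(zkh) - phid(zkl);
  else if (g.sK <= 0)              v = phid(zlh) - phid(zll);
  else
    v = bvncdf(zlh, zkh, mc.rho) - bvncdf(zll, zkh, mc.rho) -
        bvncdf(zlh, zkl, mc.rho) + bvncdf(zll, zkl, mc.rho);
  v = std::max(v, 0.0);
  g.ingrid[idx] = v;
  return v;
}

// [[Rcpp::export]]
SEXP cpp_mix_cache_new() {
  XPtr<MixCache> p(new MixCache(), true);
  return p;
}

// Accumulate one directed lag (u, v) into the midpoint-weight canvas.
static void accumulate_lag(const NumericMatrix &P, int u, int v, double mult,
                           double epsP, std::vector<double> &canvas,
                           std::vector<int> &nz, int W) {
  int nL = P.nrow(), nK = P.ncol();
  int j1lo = std::max(0, -v), j1hi = nK - 1 - std::max(0, v);
  for (int j1 = j1lo; j1 <= j1hi; j1++) {
    int m2K = 2 * j1 + v;
    for (int i1 = 0; i1 + u <= nL - 1; i1++) {
      double p1 = P(i1, j1);
      if (p1 <= 0) continue;
      double p2 = P(i1 + u, j1 + v);
      if (p2 <= 0) continue;
      double wgt = mult * p1 * p2;
      if (wgt < epsP) continue;
      size_t idx = (size_t)(2 * i1 + u) + (size_t)m2K * W;
      if (canvas[idx] == 0.0) nz.push_back((int)idx);
      canvas[idx] += wgt;
    }
  }
}

// The larvae trait distribution: truncated-MVN mixture over parent pairs,
// discretized to the grid. P is the parent distribution (sums to 1).
// Returns the renormalized larvae distribution (sums to 1).
// [[Rcpp::export]]
NumericMatrix cpp_larvae_mix(NumericMatrix P, double hL, double hK, double cV,
                             double sA2L, double sA2K, double rho, double epsP,
                             SEXP cacheSEXP) {
  int nL = P.nrow(), nK = P.ncol();
  XPtr<MixCache> cache(cacheSEXP);
  MixCache &mc = *cache;
  if (!mc.init) {
    mc.init = true;
    mc.nL = nL; mc.nK = nK; mc.hL = hL; mc.hK = hK;
    mc.cV = cV; mc.sA2L = sA2L; mc.sA2K = sA2K; mc.rho = rho;
  } else if (mc.nL != nL || mc.nK != nK || mc.hL != hL || mc.hK != hK ||
             mc.cV != cV || mc.sA2L != sA2L || mc.sA2K != sA2K ||
             mc.rho != rho) {
    stop("kernel cache was created for different grid or kernel parameters");
  }
  int W = 2 * nL - 1;
  NumericMatrix out(nL, nK);
  std::vector<double> canvas((size_t)W * (2 * nK - 1), 0.0);
  std::vector<int> nz;
  nz.reserve(4096);

  for (int u = 0; u < nL; u++) {
    for (int av = 0; av < nK; av++) {
      nz.clear();
      if (u == 0 && av == 0) {
        accumulate_lag(P, 0, 0, 1.0, epsP, canvas, nz, W);  // self-pairs
      } else if (u == 0) {
        accumulate_lag(P, 0, av, 2.0, epsP, canvas, nz, W);
      } else if (av == 0) {
        accumulate_lag(P, u, 0, 2.0, epsP, canvas, nz, W);
      } else {
        accumulate_lag(P, u, av, 2.0, epsP, canvas, nz, W);
        accumulate_lag(P, u, -av, 2.0, epsP, canvas, nz, W);
      }
      if (nz.empty()) continue;
      int key = u * 4096 + av;
      Group &g = mc.groups[key];
      if (g.t[0].m.empty() && !g.t[0].built) {
        g.sL = std::sqrt(cV * (u * hL) * (u * hL) / 2.0 + sA2L);
        g.sK = std::sqrt(cV * (av * hK) * (av * hK) / 2.0 + sA2K);
      }
      for (size_t z = 0; z < nz.size(); z++) {
        size_t idx = (size_t)nz[z];
        double wgt = canvas[idx];
        canvas[idx] = 0.0;
        int m2K = (int)(idx / W), m2L = (int)(idx % W);
        int pL = m2L & 1, pK = m2K & 1;
        int qL = (m2L - pL) / 2, qK = (m2K - pK) / 2;
        Tmpl &T = g.t[pL + 2 * pK];
        if (!T.built) build_template(T, pL, pK, mc, g);
        double ig = ingrid_mass(mc, g, m2L, m2K);
        if (ig <= 0) continue;  // kernel entirely outside the grid (cannot
                                // happen for midpoints inside the grid)
        double wr = wgt / ig;
        int ilo = std::max(0, qL + T.cl0);
        int ihi = std::min(nL - 1, qL + T.cl0 + T.ncl - 1);
        int jlo = std::max(0, qK + T.ck0);
        int jhi = std::min(nK - 1, qK + T.ck0 + T.nck - 1);
        int off = -qL - T.cl0;
        int len = ihi - ilo + 1;
        for (int j = jlo; j <= jhi; j++) {
          double *__restrict__ oc = &out(0, j) + ilo;
          const double *__restrict__ tc =
              &T.m[(size_t)(j - qK - T.ck0) * T.ncl] + ilo + off;
          for (int i = 0; i < len; i++) oc[i] += wr * tc[i];
        }
      }
    }
  }
  double tot = 0.0;
  for (int j = 0; j < nK; j++)
    for (int i = 0; i < nL; i++) tot += out(i, j);
  if (tot <= 0) stop("all parent pairs were pruned; no larvae mass left");
  for (int j = 0; j < nK; j++)
    for (int i = 0; i < nL; i++) out(i, j) /= tot;
  return out;
}
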