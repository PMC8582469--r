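// Photon Monte Carlo core: cross-section interpolation, seed ray tracing,
// analytic and Woodcock (delta) tracking, TLE / analog scoring with
// history-by-history variance.  Energies keV, lengths mm unless noted;
// mass coefficients cm^2/g.  Kerma approximation throughout: secondary
// electrons deposit locally, no radiative transport.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double MEC2 = 510.99895;            // keV
static const double KEV_TO_J = 1.602176634e-16;
// TLE: Gy per (keV * cm2/g * mm / mm^3)
static const double K_TLE = 1.602176634e-11;
// analog: Gy per (keV / (mm^3 * g/cm3))
static const double K_DEP = 1.602176634e-10;

// ---------------------------------------------------------------- RNG -----
// xoroshiro128++ seeded per history through splitmix64 so that results are
// independent of batching order.
struct Rng {
  uint64_t s0, s1;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t stream, uint64_t hist) {
    uint64_t x = stream ^ (0xD1B54A32D192ED03ULL * (hist + 1));
    s0 = splitmix(x); s1 = splitmix(x);
    if (!(s0 | s1)) s1 = 1;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t a = s0, b = s1, r = rotl(a + b, 17) + a;
    b ^= a;
    s0 = rotl(a, 49) ^ b ^ (b << 21);
    s1 = rotl(b, 28);
    return r;
  }
  double u01() { return (next() >> 11) * 1.1102230246251565e-16; }
  // uniform unit vector
  void isotropic(double *u) {
    double c = 2.0 * u01() - 1.0, ph = 6.283185307179586 * u01();
    double s = std::sqrt(std::max(0.0, 1.0 - c * c));
    u[0] = s * std::cos(ph); u[1] = s * std::sin(ph); u[2] = c;
  }
};

// ------------------------------------------------------- cross sections ---
struct ElemXS {
  double A;
  std::vector<double> logE, lph, linc, lcoh, lmuen;
  double kedge = -1.0, kfrac = 0.0, kyield = 0.0;
  std::vector<double> klineE, klineCdf;
  std::vector<double> ffx2;     // (sin(th/2)/lambda)^2 grid, 1/A^2
  std::vector<double> ff2;      // F^2 at grid
  std::vector<double> ffcum;    // cumulative integral of F^2 d(x^2)
  std::vector<double> sf;       // incoherent scattering function S at grid
  double sfAt(double x2) const {
    size_t n = ffx2.size();
    if (x2 <= ffx2[0]) return sf[0];
    if (x2 >= ffx2[n - 1]) return sf[n - 1];
    size_t hi = std::upper_bound(ffx2.begin(), ffx2.end(), x2) - ffx2.begin();
    size_t lo = hi - 1;
    double f = (x2 - ffx2[lo]) / (ffx2[hi] - ffx2[lo]);
    return sf[lo] + f * (sf[hi] - sf[lo]);
  }
};

static double loginterp(const std::vector<double> &lx,
                        const std::vector<double> &ly, double xlog) {
  size_t n = lx.size();
  if (xlog <= lx[0]) return std::exp(ly[0]);
  if (xlog >= lx[n - 1]) return std::exp(ly[n - 1]);
  size_t hi = std::upper_bound(lx.begin(), lx.end(), xlog) - lx.begin();
  size_t lo = hi - 1;
  double f = (xlog - lx[lo]) / (lx[hi] - lx[lo]);
  return std::exp(ly[lo] + f * (ly[hi] - ly[lo]));
}

struct MatXS {
  double density;
  std::vector<int> elem;
  std::vector<double> wfrac;
  // merged log-log tables for speed
  std::vector<double> logE, lph, linc, lcoh, lmuen;
  double ph(double E) const { return loginterp(logE, lph, std::log(E)); }
  double inc(double E) const { return loginterp(logE, linc, std::log(E)); }
  double coh(double E) const { return loginterp(logE, lcoh, std::log(E)); }
  double muen(double E) const { return loginterp(logE, lmuen, std::log(E)); }
  double tot(double E) const { return ph(E) + inc(E) + coh(E); }
};

struct Physics {
  std::vector<ElemXS> el;
  std::vector<MatXS> mat;
};

static Physics buildPhysics(List phys) {
  Physics P;
  List els = phys["elements"];
  for (int i = 0; i < els.size(); ++i) {
    List e = els[i];
    ElemXS x;
    x.A = as<double>(e["A"]);
    NumericVector E = e["E"], ph = e["photo"], in = e["incoh"],
                  co = e["coh"], mu = e["muen"];
    for (int j = 0; j < E.size(); ++j) {
      x.logE.push_back(std::log(E[j]));
      x.lph.push_back(std::log(std::max<double>(ph[j], 1e-300)));
      x.linc.push_back(std::log(std::max<double>(in[j], 1e-300)));
      x.lcoh.push_back(std::log(std::max<double>(co[j], 1e-300)));
      x.lmuen.push_back(std::log(std::max<double>(mu[j], 1e-300)));
    }
    x.kedge = as<double>(e["kedge"]);
    x.kfrac = as<double>(e["kfrac"]);
    x.kyield = as<double>(e["kyield"]);
    NumericVector kE = e["klineE"], kW = e["klineW"];
    double wsum = 0.0;
    for (int j = 0; j < kW.size(); ++j) wsum += kW[j];
    double c = 0.0;
    for (int j = 0; j < kE.size(); ++j) {
      x.klineE.push_back(kE[j]);
      c += kW[j] / (wsum > 0 ? wsum : 1.0);
      x.klineCdf.push_back(c);
    }
    NumericVector fx = e["ffx"], fF = e["ffF"], fS = e["ffS"];
    double cum = 0.0;
    for (int j = 0; j < fx.size(); ++j) {
      x.ffx2.push_back(fx[j] * fx[j]);
      x.ff2.push_back(fF[j] * fF[j]);
      x.sf.push_back(fS[j]);
      if (j > 0)
        cum += 0.5 * (x.ff2[j] + x.ff2[j - 1]) * (x.ffx2[j] - x.ffx2[j - 1]);
      x.ffcum.push_back(cum);
    }
    P.el.push_back(x);
  }
  List mats = phys["materials"];
  for (int i = 0; i < mats.size(); ++i) {
    List m = mats[i];
    MatXS mx;
    mx.density = as<double>(m["density"]);
    IntegerVector ei = m["elem"];     // 1-based element indices
    NumericVector wf = m["wfrac"];
    std::vector<double> grid;
    for (int j = 0; j < ei.size(); ++j) {
      mx.elem.push_back(ei[j] - 1);
      mx.wfrac.push_back(wf[j]);
      const ElemXS &e = P.el[ei[j] - 1];
      grid.insert(grid.end(), e.logE.begin(), e.logE.end());
    }
    std::sort(grid.begin(), grid.end());
    grid.erase(std::unique(grid.begin(), grid.end(),
                           [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
               grid.end());
    for (double lg : grid) {
      double sph = 0, sin_ = 0, sco = 0, smu = 0;
      for (size_t j = 0; j < mx.elem.size(); ++j) {
        const ElemXS &e = P.el[mx.elem[j]];
        sph += mx.wfrac[j] * loginterp(e.logE, e.lph, lg);
        sin_ += mx.wfrac[j] * loginterp(e.logE, e.linc, lg);
        sco += mx.wfrac[j] * loginterp(e.logE, e.lcoh, lg);
        smu += mx.wfrac[j] * loginterp(e.logE, e.lmuen, lg);
      }
      mx.logE.push_back(lg);
      mx.lph.push_back(std::log(std::max(sph, 1e-300)));
      mx.linc.push_back(std::log(std::max(sin_, 1e-300)));
      mx.lcoh.push_back(std::log(std::max(sco, 1e-300)));
      mx.lmuen.push_back(std::log(std::max(smu, 1e-300)));
    }
    P.mat.push_back(mx);
  }
  return P;
}

// --------------------------------------------------------- interactions ---
// Kahn's rejection method for the Klein-Nishina distribution.
// Returns x = E/E' >= 1; cos(theta) = 1 - (x-1)/alpha.
static double kahn_x(double alpha, Rng &rng) {
  for (;;) {
    double u1 = rng.u01(), u2 = rng.u01(), u3 = rng.u01();
    if (u1 <= (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha)) {
      double x = 1.0 + 2.0 * alpha * u2;
      if (u3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * u2);
      double c = 1.0 - (x - 1.0) / alpha;
      if (u3 <= 0.5 * (c * c + 1.0 / x)) return x;
    }
  }
}

static void compton(double E, Rng &rng, double &Eout, double &cost) {
  double a = E / MEC2;
  double x = kahn_x(a, rng);
  cost = 1.0 - (x - 1.0) / a;
  Eout = E / x;
}

// Incoherent scattering on a bound atomic electron cloud: Klein-Nishina
// (Kahn) with rejection on the incoherent scattering function S(x)/S(x_max).
static void compton_bound(const ElemXS &e, double E, Rng &rng, double &Eout,
                          double &cost) {
  double a = E / MEC2;
  double x2max = (E / 12.398419843) * (E / 12.398419843);
  double smax = e.sfAt(x2max);
  for (int it = 0; it < 10000; ++it) {
    double x = kahn_x(a, rng);
    double c = 1.0 - (x - 1.0) / a;
    double x2 = x2max * 0.5 * (1.0 - c);
    if (smax <= 0 || rng.u01() <= e.sfAt(x2) / smax) {
      cost = c; Eout = E / x;
      return;
    }
  }
  compton(E, rng, Eout, cost);
}

// Rayleigh: sample x^2 from piecewise-linear F^2(x^2), then Thomson rejection.
static double rayleigh_cost(const ElemXS &e, double E, Rng &rng) {
  double HCkevA = 12.398419843;
  double xmax = E / HCkevA;            // sin(th/2)/lambda at theta = pi
  double x2max = xmax * xmax;
  // cumulative at x2max
  size_t n = e.ffx2.size();
  double cmax;
  if (x2max >= e.ffx2[n - 1]) cmax = e.ffcum[n - 1];
  else {
    size_t hi = std::upper_bound(e.ffx2.begin(), e.ffx2.end(), x2max) - e.ffx2.begin();
    size_t lo = hi - 1;
    double du = x2max - e.ffx2[lo];
    double slope = (e.ff2[hi] - e.ff2[lo]) / (e.ffx2[hi] - e.ffx2[lo]);
    double Fa = e.ff2[lo];
    cmax = e.ffcum[lo] + Fa * du + 0.5 * slope * du * du;
  }
  for (int iter = 0; iter < 10000; ++iter) {
    double c = rng.u01() * cmax;
    size_t hi = std::upper_bound(e.ffcum.begin(), e.ffcum.end(), c) - e.ffcum.begin();
    if (hi == 0) hi = 1;
    if (hi > n - 1) hi = n - 1;
    size_t lo = hi - 1;
    double Fa = e.ff2[lo];
    double slope = (e.ff2[hi] - e.ff2[lo]) / (e.ffx2[hi] - e.ffx2[lo]);
    double dc = c - e.ffcum[lo];
    double du;
    if (std::fabs(slope) < 1e-30 * std::max(Fa, 1.0)) du = (Fa > 0 ? dc / Fa : 0.0);
    else {
      double disc = Fa * Fa + 2.0 * slope * dc;
      du = (std::sqrt(std::max(disc, 0.0)) - Fa) / slope;
    }
    double x2 = e.ffx2[lo] + du;
    if (x2 > x2max) continue;
    double cost = 1.0 - 2.0 * x2 / x2max;
    if (rng.u01() <= 0.5 * (1.0 + cost * cost)) return cost;
  }
  return 1.0;
}

// rotate direction u by polar angle with cos c and uniform azimuth
static void deflect(double *u, double c, Rng &rng) {
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double ph = 6.283185307179586 * rng.u01();
  double sp = std::sin(ph), cp = std::cos(ph);
  double ux = u[0], uy = u[1], uz = u[2];
  double r = std::sqrt(std::max(1e-30, 1.0 - uz * uz));
  double nx, ny, nz;
  if (r > 1e-10) {
    nx = ux * c + s * (ux * uz * cp - uy * sp) / r;
    ny = uy * c + s * (uy * uz * cp + ux * sp) / r;
    nz = uz * c - s * r * cp;
  } else {
    nx = s * cp; ny = s * sp; nz = (uz > 0 ? c : -c);
  }
  double nrm = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  u[0] = nx * nrm; u[1] = ny * nrm; u[2] = nz * nrm;
}

// --------------------------------------------------------------- solids ---
struct Solid {
  int kind;            // 0 cylinder, 1 capsule, 2 sphere, 3 cone frustum
  double r, h, r2;     // mm
  double tr[3];
  bool rotated;
  double rot[9];       // row-major, local->seed: p_seed = R p_local + tr

  void toLocal(const double *p, double *q) const {
    double d[3] = {p[0] - tr[0], p[1] - tr[1], p[2] - tr[2]};
    if (!rotated) { q[0] = d[0]; q[1] = d[1]; q[2] = d[2]; return; }
    // R^T d
    q[0] = rot[0] * d[0] + rot[3] * d[1] + rot[6] * d[2];
    q[1] = rot[1] * d[0] + rot[4] * d[1] + rot[7] * d[2];
    q[2] = rot[2] * d[0] + rot[5] * d[1] + rot[8] * d[2];
  }
  void dirLocal(const double *u, double *v) const {
    if (!rotated) { v[0] = u[0]; v[1] = u[1]; v[2] = u[2]; return; }
    v[0] = rot[0] * u[0] + rot[3] * u[1] + rot[6] * u[2];
    v[1] = rot[1] * u[0] + rot[4] * u[1] + rot[7] * u[2];
    v[2] = rot[2] * u[0] + rot[5] * u[1] + rot[8] * u[2];
  }
  bool inside(const double *p) const {
    double q[3]; toLocal(p, q);
    double rr = q[0] * q[0] + q[1] * q[1];
    switch (kind) {
    case 0: return rr <= r * r && std::fabs(q[2]) <= h;
    case 1:
      if (std::fabs(q[2]) <= h) return rr <= r * r;
      if (q[2] > h)  { double dz = q[2] - h; return rr + dz * dz <= r * r; }
      { double dz = q[2] + h; return rr + dz * dz <= r * r; }
    case 2: return rr + q[2] * q[2] <= r * r;
    case 3: {
      if (std::fabs(q[2]) > h) return false;
      double rc = r + (r2 - r) * (q[2] + h) / (2.0 * h);
      return rr <= rc * rc;
    }
    }
    return false;
  }
  // signed-ish distance to the surface (exact for kinds 0-2), used to verify
  // phase-space capture positions
  double surfdist(const double *p) const {
    double q[3]; toLocal(p, q);
    double rad = std::sqrt(q[0] * q[0] + q[1] * q[1]);
    switch (kind) {
    case 0: {
      double dr = rad - r, dz = std::fabs(q[2]) - h;
      if (dr <= 0 && dz <= 0) return std::max(dr, dz);
      double ddr = std::max(dr, 0.0), ddz = std::max(dz, 0.0);
      return std::sqrt(ddr * ddr + ddz * ddz);
    }
    case 1: {
      double az = std::fabs(q[2]);
      if (az <= h) return rad - r;
      double dz = az - h;
      return std::sqrt(rad * rad + dz * dz) - r;
    }
    case 2: return std::sqrt(rad * rad + q[2] * q[2]) - r;
    default: return 1e30;
    }
  }
  // append all surface-crossing ray parameters (p + t u, t > tmin)
  void roots(const double *pw, const double *uw, std::vector<double> &ts) const {
    double p[3], u[3];
    toLocal(pw, p); dirLocal(uw, u);
    double a2 = u[0] * u[0] + u[1] * u[1];
    double b2 = p[0] * u[0] + p[1] * u[1];
    double c2 = p[0] * p[0] + p[1] * p[1];
    auto quad = [&](double A, double B, double C, double *out) -> int {
      if (std::fabs(A) < 1e-300) return 0;
      double D = B * B - A * C;
      if (D < 0) return 0;
      double sD = std::sqrt(D);
      out[0] = (-B - sD) / A; out[1] = (-B + sD) / A;
      return 2;
    };
    double tt[2];
    switch (kind) {
    case 0: {
      int n = quad(a2, b2, c2 - r * r, tt);
      for (int i = 0; i < n; ++i) {
        double z = p[2] + tt[i] * u[2];
        if (std::fabs(z) <= h) ts.push_back(tt[i]);
      }
      if (std::fabs(u[2]) > 1e-300) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          double t = (sgn * h - p[2]) / u[2];
          double x = p[0] + t * u[0], y = p[1] + t * u[1];
          if (x * x + y * y <= r * r) ts.push_back(t);
        }
      }
      break;
    }
    case 1: {
      int n = quad(a2, b2, c2 - r * r, tt);
      for (int i = 0; i < n; ++i) {
        double z = p[2] + tt[i] * u[2];
        if (std::fabs(z) <= h) ts.push_back(tt[i]);
      }
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double zc = sgn * h;
        double pz = p[2] - zc;
        int m = quad(1.0, b2 + pz * u[2], c2 + pz * pz - r * r, tt);
        for (int i = 0; i < m; ++i) {
          double z = p[2] + tt[i] * u[2];
          if ((sgn > 0 && z > h) || (sgn < 0 && z < -h)) ts.push_back(tt[i]);
        }
      }
      break;
    }
    case 2: {
      int n = quad(1.0, b2 + p[2] * u[2], c2 + p[2] * p[2] - r * r, tt);
      for (int i = 0; i < n; ++i) ts.push_back(tt[i]);
      break;
    }
    case 3: {
      double k = (r2 - r) / (2.0 * h);       // dr/dz
      double r0 = r + k * (0.0 + h);          // radius at z=0 (local)
      // radius(z) = r0 + k z ; surface: x^2+y^2 = (r0 + k z)^2
      double A = a2 - k * k * u[2] * u[2];
      double B = b2 - k * u[2] * (r0 + k * p[2]);
      double C = c2 - (r0 + k * p[2]) * (r0 + k * p[2]);
      int n;
      if (std::fabs(A) > 1e-14) n = quad(A, B, C, tt);
      else { n = 0; if (std::fabs(B) > 1e-300) { tt[0] = -C / (2.0 * B); n = 1; } }
      for (int i = 0; i < n; ++i) {
        double z = p[2] + tt[i] * u[2];
        if (std::fabs(z) <= h && (r0 + k * z) >= 0) ts.push_back(tt[i]);
      }
      if (std::fabs(u[2]) > 1e-300) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          double t = (sgn * h - p[2]) / u[2];
          double x = p[0] + t * u[0], y = p[1] + t * u[1];
          double rc = r0 + k * (sgn * h);
          if (x * x + y * y <= rc * rc) ts.push_back(t);
        }
      }
      break;
    }
    }
  }
};

struct Seed {
  std::vector<Solid> solids;     // innermost -> outermost; last = capture surface
  std::vector<int> mat;          // material index, -1 = vacuum
  int active = 0;                // index into solids
  int active_mode = 0;           // 0 volume, 1 surface
  std::vector<double> lineE, lineCdf;
  double L = 0.0;

  int materialAt(const double *p) const {
    for (size_t i = 0; i < solids.size(); ++i)
      if (solids[i].inside(p)) return mat[i];
    return -2;                   // outside all components
  }
  bool insideOuter(const double *p) const {
    for (size_t i = 0; i < solids.size(); ++i)
      if (solids[i].inside(p)) return true;
    return false;
  }
  double sampleLine(Rng &rng) const {
    double u = rng.u01();
    size_t i = std::lower_bound(lineCdf.begin(), lineCdf.end(), u) - lineCdf.begin();
    if (i >= lineE.size()) i = lineE.size() - 1;
    return lineE[i];
  }
  void sampleEmission(Rng &rng, double *p, double *u, double &E) const {
    const Solid &s = solids[active];
    rng.isotropic(u);
    if (active_mode == 1) {
      // uniform over the lateral (cylindrical) surface of the active solid;
      // the point starts on the side of the surface the direction points
      // into (standard surface tie-break), via a small nudge along u
      double ph = 6.283185307179586 * rng.u01();
      double z = (2.0 * rng.u01() - 1.0) * s.h;
      double q[3] = {s.r * std::cos(ph), s.r * std::sin(ph), z};
      if (s.rotated) {
        p[0] = s.rot[0] * q[0] + s.rot[1] * q[1] + s.rot[2] * q[2] + s.tr[0];
        p[1] = s.rot[3] * q[0] + s.rot[4] * q[1] + s.rot[5] * q[2] + s.tr[1];
        p[2] = s.rot[6] * q[0] + s.rot[7] * q[1] + s.rot[8] * q[2] + s.tr[2];
      } else {
        p[0] = q[0] + s.tr[0]; p[1] = q[1] + s.tr[1]; p[2] = q[2] + s.tr[2];
      }
      for (int a = 0; a < 3; ++a) p[a] += 1e-6 * u[a];
    } else {
      // rejection sample the bounding box of the solid
      double ext = (s.kind == 1) ? s.h + s.r : s.h;
      if (s.kind == 2) ext = s.r;
      double rmax = std::max(s.r, s.r2);
      for (;;) {
        double q[3] = {(2.0 * rng.u01() - 1.0) * rmax,
                       (2.0 * rng.u01() - 1.0) * rmax,
                       (2.0 * rng.u01() - 1.0) * ext};
        double w[3];
        if (s.rotated) {
          w[0] = s.rot[0] * q[0] + s.rot[1] * q[1] + s.rot[2] * q[2] + s.tr[0];
          w[1] = s.rot[3] * q[0] + s.rot[4] * q[1] + s.rot[5] * q[2] + s.tr[1];
          w[2] = s.rot[6] * q[0] + s.rot[7] * q[1] + s.rot[8] * q[2] + s.tr[2];
        } else {
          w[0] = q[0] + s.tr[0]; w[1] = q[1] + s.tr[1]; w[2] = q[2] + s.tr[2];
        }
        if (s.inside(w)) {
          // the active region is this component only: points falling inside
          // a nested inner component (e.g. an X-ray marker) are rejected
          bool in_inner = false;
          for (int j = 0; j < active; ++j)
            if (solids[j].inside(w)) { in_inner = true; break; }
          if (!in_inner) { p[0] = w[0]; p[1] = w[1]; p[2] = w[2]; break; }
        }
      }
    }
    E = sampleLine(rng);
  }
};

static Seed buildSeed(List sl) {
  Seed sd;
  List solids = sl["solids"];
  IntegerVector mats = sl["mat"];
  for (int i = 0; i < solids.size(); ++i) {
    List s = solids[i];
    Solid so;
    std::string kind = as<std::string>(s["kind"]);
    so.kind = (kind == "cylinder") ? 0 : (kind == "capsule") ? 1
              : (kind == "sphere") ? 2 : 3;
    so.r = as<double>(s["r"]);
    so.h = as<double>(s["h"]);
    so.r2 = s.containsElementNamed("r2") ? as<double>(s["r2"]) : so.r;
    NumericVector tr = s["tr"];
    so.tr[0] = tr[0]; so.tr[1] = tr[1]; so.tr[2] = tr[2];
    so.rotated = false;
    if (s.containsElementNamed("rot") && !Rf_isNull(s["rot"])) {
      NumericMatrix R = s["rot"];
      so.rotated = true;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) so.rot[3 * a + b] = R(a, b);
    }
    sd.solids.push_back(so);
    sd.mat.push_back(mats[i]);       // already 0-based or -1
  }
  sd.active = as<int>(sl["active"]);
  sd.active_mode = as<int>(sl["active_mode"]);
  NumericVector lE = sl["lineE"], lW = sl["lineW"];
  double wsum = 0.0;
  for (int i = 0; i < lW.size(); ++i) wsum += lW[i];
  double c = 0.0;
  for (int i = 0; i < lE.size(); ++i) {
    sd.lineE.push_back(lE[i]);
    c += lW[i] / wsum;
    sd.lineCdf.push_back(c);
  }
  sd.L = as<double>(sl["L"]);
  return sd;
}

// --------------------------------------------------------------- tallies ---
struct Tally {
  std::vector<double> sum, sum2, pend;
  std::vector<int64_t> tag;
  void init(size_t n) {
    sum.assign(n, 0.0); sum2.assign(n, 0.0);
    pend.assign(n, 0.0); tag.assign(n, -1);
  }
  inline void add(size_t i, double v, int64_t h) {
    if (tag[i] != h) {
      if (tag[i] >= 0) { sum[i] += pend[i]; sum2[i] += pend[i] * pend[i]; }
      pend[i] = 0.0; tag[i] = h;
    }
    pend[i] += v;
  }
  void flush() {
    for (size_t i = 0; i < sum.size(); ++i)
      if (tag[i] >= 0) { sum[i] += pend[i]; sum2[i] += pend[i] * pend[i];
                         pend[i] = 0.0; tag[i] = -1; }
  }
};

struct AnnularScorer {
  std::vector<double> rlo, rhi;        // mm, disjoint ascending shells
  std::vector<double> costh;           // cos(theta edges), descending in cos
  int ntheta = 0;
  int quantity = 0;                    // 0 kerma, 1 fluence
  int medium = -1;                     // scoring medium (kerma)
  double delta_cut = 0.0;
  std::vector<double> vol;             // mm^3 per cell (nr x ntheta)
  Tally tal;

  void init() {
    ntheta = (int)costh.size() - 1;
    size_t n = rlo.size() * ntheta;
    vol.assign(n, 0.0);
    for (size_t i = 0; i < rlo.size(); ++i)
      for (int j = 0; j < ntheta; ++j) {
        double dcos = costh[j] - costh[j + 1];
        vol[i * ntheta + j] = 2.0943951023931953 *    // 2*pi/3
          (rhi[i]*rhi[i]*rhi[i] - rlo[i]*rlo[i]*rlo[i]) * dcos;
      }
    tal.init(n);
  }
  // score a straight segment from p along u of length s
  void segment(const Physics &P, const double *p, const double *u, double s,
               double E, double w, int64_t h) {
    if (E < delta_cut) return;
    double Rout = rhi.back();
    // clip to |p + t u| <= Rout
    double b = p[0]*u[0] + p[1]*u[1] + p[2]*u[2];
    double c = p[0]*p[0] + p[1]*p[1] + p[2]*p[2] - Rout*Rout;
    double D = b*b - c;
    if (D <= 0) return;
    double sD = std::sqrt(D);
    double ta = std::max(0.0, -b - sD), tb = std::min(s, -b + sD);
    if (tb <= ta) return;
    std::vector<double> ts;
    ts.push_back(ta); ts.push_back(tb);
    auto sphere_hits = [&](double R) {
      double cc = p[0]*p[0] + p[1]*p[1] + p[2]*p[2] - R*R;
      double DD = b*b - cc;
      if (DD <= 0) return;
      double sd = std::sqrt(DD);
      double t1 = -b - sd, t2 = -b + sd;
      if (t1 > ta && t1 < tb) ts.push_back(t1);
      if (t2 > ta && t2 < tb) ts.push_back(t2);
    };
    for (size_t i = 0; i < rlo.size(); ++i) { sphere_hits(rlo[i]); sphere_hits(rhi[i]); }
    // theta-cone crossings: z = cth * |p|, skip poles
    for (size_t j = 1; j + 1 < costh.size(); ++j) {
      double cth = costh[j];
      if (std::fabs(cth) < 1e-12) {          // plane z = 0
        if (std::fabs(u[2]) > 1e-300) {
          double t = -p[2] / u[2];
          if (t > ta && t < tb) ts.push_back(t);
        }
        continue;
      }
      double c2 = cth * cth;
      double A = u[2]*u[2] - c2;
      double B = p[2]*u[2] - c2*b;
      double C = p[2]*p[2] - c2*(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
      double tt[2]; int n = 0;
      if (std::fabs(A) > 1e-14) {
        double DD = B*B - A*C;
        if (DD >= 0) { double sd = std::sqrt(DD);
          tt[0] = (-B - sd)/A; tt[1] = (-B + sd)/A; n = 2; }
      } else if (std::fabs(B) > 1e-300) { tt[0] = -C/(2.0*B); n = 1; }
      for (int i = 0; i < n; ++i) {
        if (tt[i] <= ta || tt[i] >= tb) continue;
        double z = p[2] + tt[i]*u[2];
        if (z * cth > 0) ts.push_back(tt[i]);
      }
    }
    std::sort(ts.begin(), ts.end());
    double coef;
    if (quantity == 0)
      coef = w * E * P.mat[medium].muen(E) * K_TLE;
    else
      coef = w * 0.1;                        // fluence: cm per mm... handled below
    for (size_t i = 0; i + 1 < ts.size(); ++i) {
      double len = ts[i + 1] - ts[i];
      if (len <= 1e-12) continue;
      double tm = 0.5 * (ts[i] + ts[i + 1]);
      double q[3] = {p[0] + tm*u[0], p[1] + tm*u[1], p[2] + tm*u[2]};
      double rr = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2]);
      // shell bin
      size_t k = std::upper_bound(rlo.begin(), rlo.end(), rr) - rlo.begin();
      if (k == 0) continue;
      k -= 1;
      if (rr >= rhi[k]) continue;
      double ct = (rr > 0) ? q[2] / rr : 1.0;
      if (ct > costh[0] + 1e-12 || ct < costh[ntheta] - 1e-12) continue;
      int j = 0;
      while (j < ntheta - 1 && ct <= costh[j + 1]) ++j;
      size_t idx = k * ntheta + j;
      if (quantity == 0)
        tal.add(idx, coef * len / vol[idx], h);
      else // track length density: cm / cm^3 = 100 * mm/mm^3
        tal.add(idx, w * len / vol[idx] * 100.0, h);
    }
  }
};

struct CartScorer {
  double org[3], sp[3];
  int dim[3];
  int mode = 0;                 // 0 TLE, 1 analog deposition
  int medium = -1;              // fixed scoring medium; -1 = local (voxel world)
  double delta_cut = 0.0;
  Tally tal;
  void init() { tal.init((size_t)dim[0] * dim[1] * dim[2]); }
  inline bool voxelOf(const double *p, int *ijk) const {
    for (int a = 0; a < 3; ++a) {
      double f = (p[a] - org[a]) / sp[a];
      if (f < 0 || f >= dim[a]) return false;
      ijk[a] = (int)f;
    }
    return true;
  }
  inline size_t idx(const int *ijk) const {
    return ((size_t)ijk[2] * dim[1] + ijk[1]) * dim[0] + ijk[0];
  }
};

// voxel phantom
struct Phantom {
  double org[3], sp[3];
  int dim[3];
  const int *mat;                 // per voxel, 0-based material index
  std::vector<double> rho;        // per material
  inline bool voxelIndex(const double *p, int *ijk) const {
    for (int a = 0; a < 3; ++a) {
      double f = (p[a] - org[a]) / sp[a];
      if (f < 0 || f >= dim[a]) return false;
      ijk[a] = (int)f;
    }
    return true;
  }
  inline int matAt(const int *ijk) const {
    return mat[((size_t)ijk[2] * dim[1] + ijk[1]) * dim[0] + ijk[0]];
  }
};

// DDA traversal of a Cartesian grid along a segment; calls fn(voxel ijk, chord)
template <typename F>
static void dda(const double *org, const double *sp, const int *dim,
                const double *p, const double *u, double s, F fn) {
  // clip segment to grid box
  double t0 = 0.0, t1 = s;
  for (int a = 0; a < 3; ++a) {
    double lo = org[a], hi = org[a] + sp[a] * dim[a];
    if (std::fabs(u[a]) < 1e-300) {
      if (p[a] < lo || p[a] >= hi) return;
    } else {
      double ta = (lo - p[a]) / u[a], tb = (hi - p[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return;
  double start[3];
  for (int a = 0; a < 3; ++a) start[a] = p[a] + (t0 + 1e-9) * u[a];
  int ijk[3];
  for (int a = 0; a < 3; ++a) {
    double f = (start[a] - org[a]) / sp[a];
    ijk[a] = (int)std::floor(f);
    if (ijk[a] < 0) ijk[a] = 0;
    if (ijk[a] >= dim[a]) ijk[a] = dim[a] - 1;
  }
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (u[a] > 1e-300) {
      step[a] = 1;
      tMax[a] = ((org[a] + (ijk[a] + 1) * sp[a]) - p[a]) / u[a];
      tDelta[a] = sp[a] / u[a];
    } else if (u[a] < -1e-300) {
      step[a] = -1;
      tMax[a] = ((org[a] + ijk[a] * sp[a]) - p[a]) / u[a];
      tDelta[a] = -sp[a] / u[a];
    } else {
      step[a] = 0; tMax[a] = 1e300; tDelta[a] = 1e300;
    }
  }
  double tcur = t0;
  for (;;) {
    int axis = 0;
    if (tMax[1] < tMax[axis]) axis = 1;
    if (tMax[2] < tMax[axis]) axis = 2;
    double tnext = std::min(tMax[axis], t1);
    if (tnext > tcur) fn(ijk, tnext - tcur);
    if (tMax[axis] >= t1) break;
    tcur = tMax[axis];
    tMax[axis] += tDelta[axis];
    ijk[axis] += step[axis];
    if (ijk[axis] < 0 || ijk[axis] >= dim[axis]) break;
  }
}

// --------------------------------------------------------------- worlds ---
struct RunTotals {
  double emitted = 0, deposited = 0, escaped = 0;
  int64_t n_escape = 0, n_escape_uncollided = 0, n_primary = 0;
};

struct PhotonState {
  double p[3], u[3], E, w;
  int ncoll;
  bool secondary;
};

// element choice proportional to w_i * channel_i(E)
static int pickElement(const Physics &P, const MatXS &m, double E, int channel,
                       Rng &rng) {
  double tot = 0.0;
  double vals[32];
  for (size_t i = 0; i < m.elem.size(); ++i) {
    const ElemXS &e = P.el[m.elem[i]];
    double lg = std::log(E);
    double v = (channel == 0) ? loginterp(e.logE, e.lph, lg)
             : (channel == 2) ? loginterp(e.logE, e.lcoh, lg)
                              : loginterp(e.logE, e.linc, lg);
    vals[i] = m.wfrac[i] * v;
    tot += vals[i];
  }
  double u = rng.u01() * tot;
  for (size_t i = 0; i < m.elem.size(); ++i) {
    u -= vals[i];
    if (u <= 0) return m.elem[i];
  }
  return m.elem[m.elem.size() - 1];
}

// ---------------------------------------------------------------- main run --
// Flexible single-threaded driver.  See R wrappers for the configuration
// list layout.
// [[Rcpp::export]]
List cpp_run(List phys, List world, List source, List config, List scorers) {
  Physics P = buildPhysics(phys);
  std::string wtype = as<std::string>(world["type"]);
  int64_t nhist = (int64_t)as<double>(config["n_histories"]);
  uint64_t stream = (uint64_t)as<double>(config["rng_seed"]);
  double cutoff = as<double>(config["cutoff_keV"]);
  bool fluor_on = as<bool>(config["fluorescence"]);

  // world
  bool isVoxel = (wtype == "voxel");
  int bg = -1;
  double Rb = 0.0;
  Seed seed;
  bool hasSeed = false;
  Phantom ph;
  IntegerVector pmat;
  if (!isVoxel) {
    bg = as<int>(world["background"]);        // 0-based, -1 vacuum
    Rb = as<double>(world["radius_mm"]);
    if (world.containsElementNamed("seed") && !Rf_isNull(world["seed"])) {
      seed = buildSeed(world["seed"]);
      hasSeed = true;
    }
  } else {
    List pl = world["phantom"];
    NumericVector o = pl["origin"], s = pl["spacing"];
    IntegerVector d = pl["dims"];
    pmat = pl["mat"];                          // 0-based per voxel
    NumericVector rho = pl["rho"];             // per material
    for (int a = 0; a < 3; ++a) { ph.org[a] = o[a]; ph.sp[a] = s[a]; ph.dim[a] = d[a]; }
    ph.mat = INTEGER(pmat);
    ph.rho = as<std::vector<double>>(rho);
  }

  // source
  std::string stype = as<std::string>(source["type"]);
  NumericMatrix srec;
  std::vector<double> planCdf;
  std::vector<std::vector<double>> poseR, poseT;
  NumericVector s_pos, s_dir, s_lineE, s_lineW;
  std::vector<double> srcCdf;
  if (stype == "phsp") {
    srec = as<NumericMatrix>(source["records"]);  // cols E x y z ux uy uz w
    NumericVector pc = source["entry_cdf"];
    planCdf = as<std::vector<double>>(pc);
    List pr = source["poseR"], pt = source["poseT"];
    for (int i = 0; i < pr.size(); ++i) {
      NumericMatrix R = pr[i]; NumericVector t = pt[i];
      std::vector<double> rr(9), tt(3);
      for (int a = 0; a < 3; ++a) { tt[a] = t[a];
        for (int b = 0; b < 3; ++b) rr[3 * a + b] = R(a, b); }
      poseR.push_back(rr); poseT.push_back(tt);
    }
  } else if (stype == "point" || stype == "pencil") {
    s_pos = source["position"];
    if (stype == "pencil") s_dir = source["direction"];
    s_lineE = source["lineE"]; s_lineW = source["lineW"];
    double c = 0, wsum = 0;
    for (int i = 0; i < s_lineW.size(); ++i) wsum += s_lineW[i];
    for (int i = 0; i < s_lineW.size(); ++i) { c += s_lineW[i] / wsum; srcCdf.push_back(c); }
  }

  // scorers
  std::vector<AnnularScorer> ann;
  std::vector<CartScorer> cart;
  std::vector<int> order_type, order_idx;
  for (int i = 0; i < scorers.size(); ++i) {
    List sc = scorers[i];
    std::string t = as<std::string>(sc["type"]);
    if (t == "annular") {
      AnnularScorer a;
      a.rlo = as<std::vector<double>>(sc["r_lo_mm"]);
      a.rhi = as<std::vector<double>>(sc["r_hi_mm"]);
      NumericVector th = sc["theta_deg"];
      for (int j = 0; j < th.size(); ++j)
        a.costh.push_back(std::cos(th[j] * 0.017453292519943295));
      a.quantity = as<std::string>(sc["quantity"]) == "fluence" ? 1 : 0;
      a.medium = as<int>(sc["medium"]);
      a.delta_cut = as<double>(sc["delta_cut"]);
      a.init();
      ann.push_back(a); order_type.push_back(0); order_idx.push_back(ann.size() - 1);
    } else {
      CartScorer cs;
      NumericVector o = sc["origin"], s = sc["spacing"];
      IntegerVector d = sc["dims"];
      for (int a = 0; a < 3; ++a) { cs.org[a] = o[a]; cs.sp[a] = s[a]; cs.dim[a] = d[a]; }
      cs.mode = (t == "cart_analog") ? 1 : 0;
      cs.medium = as<int>(sc["medium"]);
      cs.delta_cut = as<double>(sc["delta_cut"]);
      cs.init();
      cart.push_back(cs); order_type.push_back(1); order_idx.push_back(cart.size() - 1);
    }
  }

  RunTotals tot;
  Rng rng;
  std::vector<PhotonState> stack;

  auto scoreSegment = [&](const double *p, const double *u, double s, double E,
                          double w, int64_t h, bool in_bg) {
    if (!in_bg) return;
    for (auto &a : ann) a.segment(P, p, u, s, E, w, h);
    for (auto &cs : cart) {
      if (cs.mode != 0 || E < cs.delta_cut) continue;
      if (isVoxel) {
        dda(cs.org, cs.sp, cs.dim, p, u, s, [&](const int *ijk, double len) {
          // material of the phantom voxel containing this scorer cell
          double c[3] = {cs.org[0] + (ijk[0] + 0.5) * cs.sp[0],
                         cs.org[1] + (ijk[1] + 0.5) * cs.sp[1],
                         cs.org[2] + (ijk[2] + 0.5) * cs.sp[2]};
          int pijk[3];
          if (!ph.voxelIndex(c, pijk)) return;
          int m = ph.matAt(pijk);
          double mu = P.mat[m].muen(E);
          cs.tal.add(cs.idx(ijk), w * E * mu * K_TLE * len /
                     (cs.sp[0] * cs.sp[1] * cs.sp[2]), h);
        });
      } else {
        double mu = P.mat[cs.medium].muen(E);
        double coef = w * E * mu * K_TLE / (cs.sp[0] * cs.sp[1] * cs.sp[2]);
        dda(cs.org, cs.sp, cs.dim, p, u, s, [&](const int *ijk, double len) {
          cs.tal.add(cs.idx(ijk), coef * len, h);
        });
      }
    }
  };
  auto scoreDeposit = [&](const double *p, double edep, double w, int64_t h,
                          double rho_local) {
    tot.deposited += w * edep;
    for (auto &cs : cart) {
      if (cs.mode != 1) continue;
      int ijk[3];
      if (!cs.voxelOf(p, ijk)) continue;
      double vol = cs.sp[0] * cs.sp[1] * cs.sp[2];
      cs.tal.add(cs.idx(ijk), w * edep * K_DEP / (vol * rho_local), h);
    }
  };

  for (int64_t hist = 0; hist < nhist; ++hist) {
    if ((hist & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed(stream, hist);
    stack.clear();
    PhotonState s0;
    s0.w = 1.0; s0.ncoll = 0; s0.secondary = false;
    if (stype == "seed") {
      seed.sampleEmission(rng, s0.p, s0.u, s0.E);
      tot.n_primary++;
    } else if (stype == "phsp") {
      double u = rng.u01();
      size_t e = std::lower_bound(planCdf.begin(), planCdf.end(), u) - planCdf.begin();
      if (e >= poseR.size()) e = poseR.size() - 1;
      int irec = (int)(rng.u01() * srec.nrow());
      if (irec >= srec.nrow()) irec = srec.nrow() - 1;
      double lp[3] = {srec(irec, 1), srec(irec, 2), srec(irec, 3)};
      double lu[3] = {srec(irec, 4), srec(irec, 5), srec(irec, 6)};
      const std::vector<double> &R = poseR[e], &T = poseT[e];
      for (int a = 0; a < 3; ++a) {
        s0.p[a] = R[3*a]*lp[0] + R[3*a+1]*lp[1] + R[3*a+2]*lp[2] + T[a];
        s0.u[a] = R[3*a]*lu[0] + R[3*a+1]*lu[1] + R[3*a+2]*lu[2];
      }
      s0.E = srec(irec, 0); s0.w = srec(irec, 7);
      tot.n_primary++;
    } else {
      s0.p[0] = s_pos[0]; s0.p[1] = s_pos[1]; s0.p[2] = s_pos[2];
      if (stype == "pencil") { s0.u[0] = s_dir[0]; s0.u[1] = s_dir[1]; s0.u[2] = s_dir[2]; }
      else rng.isotropic(s0.u);
      double u = rng.u01();
      size_t i = std::lower_bound(srcCdf.begin(), srcCdf.end(), u) - srcCdf.begin();
      if (i >= (size_t)s_lineE.size()) i = s_lineE.size() - 1;
      s0.E = s_lineE[i];
      tot.n_primary++;
    }
    tot.emitted += s0.w * s0.E;
    stack.push_back(s0);

    while (!stack.empty()) {
      PhotonState st = stack.back();
      stack.pop_back();
      bool alive = true;
      while (alive) {
        if (!isVoxel) {
          // ------- analytic tracking (homogeneous background + seed solids)
          int m = hasSeed ? seed.materialAt(st.p) : -2;
          int cur = (m == -2) ? bg : m;
          // distance to next boundary
          std::vector<double> ts;
          if (hasSeed)
            for (auto &so : seed.solids) so.roots(st.p, st.u, ts);
          {
            double b = st.p[0]*st.u[0] + st.p[1]*st.u[1] + st.p[2]*st.u[2];
            double c = st.p[0]*st.p[0] + st.p[1]*st.p[1] + st.p[2]*st.p[2] - Rb*Rb;
            double D = b*b - c;
            if (D > 0) { double sd = std::sqrt(D);
              ts.push_back(-b - sd); ts.push_back(-b + sd); }
          }
          double tb = 1e300;
          for (double t : ts) if (t > 1e-7 && t < tb) tb = t;
          if (tb >= 1e300) { // outside everything moving away
            tot.escaped += st.w * st.E; tot.n_escape++;
            if (st.ncoll == 0 && !st.secondary) tot.n_escape_uncollided++;
            alive = false; break;
          }
          double mu = 0.0;
          if (cur >= 0) mu = P.mat[cur].tot(st.E) * P.mat[cur].density * 0.1; // 1/mm
          double sflight;
          if (mu <= 0.0) sflight = tb;
          else {
            sflight = -std::log(std::max(rng.u01(), 1e-300)) / mu;
            if (sflight > tb) sflight = tb;
          }
          bool at_boundary = (sflight >= tb);
          scoreSegment(st.p, st.u, sflight, st.E, st.w, hist, cur == bg);
          for (int a = 0; a < 3; ++a) st.p[a] += sflight * st.u[a];
          if (at_boundary) {
            // nudge through surface
            for (int a = 0; a < 3; ++a) st.p[a] += 1e-6 * st.u[a];
            double r2 = st.p[0]*st.p[0] + st.p[1]*st.p[1] + st.p[2]*st.p[2];
            if (r2 >= Rb * Rb) {
              tot.escaped += st.w * st.E; tot.n_escape++;
              if (st.ncoll == 0 && !st.secondary) tot.n_escape_uncollided++;
              alive = false;
            }
            continue;
          }
          // interaction in material `cur`
          const MatXS &M = P.mat[cur];
          double pph = M.ph(st.E), pin = M.inc(st.E), pco = M.coh(st.E);
          double x = rng.u01() * (pph + pin + pco);
          if (x < pph) {
            // photoelectric
            int ei = pickElement(P, M, st.E, 0, rng);
            const ElemXS &e = P.el[ei];
            double edep = st.E;
            if (fluor_on && e.kedge > 0 && st.E > e.kedge &&
                rng.u01() < e.kfrac * e.kyield) {
              double uu = rng.u01();
              size_t li = std::lower_bound(e.klineCdf.begin(), e.klineCdf.end(), uu)
                          - e.klineCdf.begin();
              if (li >= e.klineE.size()) li = e.klineE.size() - 1;
              double Ef = e.klineE[li];
              if (Ef < st.E) {
                edep = st.E - Ef;
                PhotonState fs = st;
                fs.E = Ef; fs.ncoll = 0; fs.secondary = true;
                rng.isotropic(fs.u);
                if (Ef >= cutoff) stack.push_back(fs);
                else { scoreDeposit(st.p, Ef, st.w, hist,
                                    cur >= 0 ? P.mat[cur].density : 1.0); }
              }
            }
            scoreDeposit(st.p, edep, st.w, hist, cur >= 0 ? P.mat[cur].density : 1.0);
            alive = false;
          } else if (x < pph + pin) {
            double Ep, ct;
            int sei = pickElement(P, M, st.E, 1, rng);
            compton_bound(P.el[sei], st.E, rng, Ep, ct);
            scoreDeposit(st.p, st.E - Ep, st.w, hist, P.mat[cur].density);
            deflect(st.u, ct, rng);
            st.E = Ep; st.ncoll++;
            if (st.E < cutoff) { scoreDeposit(st.p, st.E, st.w, hist, P.mat[cur].density);
                                 alive = false; }
          } else {
            int ei = pickElement(P, M, st.E, 2, rng);
            double ct = rayleigh_cost(P.el[ei], st.E, rng);
            deflect(st.u, ct, rng);
            st.ncoll++;
          }
        } else {
          // ------------------------------- Woodcock tracking in the phantom
          int ijk[3];
          if (!ph.voxelIndex(st.p, ijk)) {
            // fly to the box or escape
            double t0 = 1e300;
            {
              double ta = 0.0, tb2 = 1e300;
              bool ok = true;
              for (int a = 0; a < 3; ++a) {
                double lo = ph.org[a], hi2 = ph.org[a] + ph.sp[a] * ph.dim[a];
                if (std::fabs(st.u[a]) < 1e-300) {
                  if (st.p[a] < lo || st.p[a] >= hi2) { ok = false; break; }
                } else {
                  double u1 = (lo - st.p[a]) / st.u[a], u2 = (hi2 - st.p[a]) / st.u[a];
                  if (u1 > u2) std::swap(u1, u2);
                  ta = std::max(ta, u1); tb2 = std::min(tb2, u2);
                }
              }
              if (ok && tb2 > ta && ta > 0) t0 = ta;
            }
            if (t0 >= 1e300) {
              tot.escaped += st.w * st.E; tot.n_escape++;
              alive = false; break;
            }
            for (int a = 0; a < 3; ++a) st.p[a] += (t0 + 1e-6) * st.u[a];
            continue;
          }
          // majorant at current energy
          double mumax = 0.0;
          for (size_t mi = 0; mi < P.mat.size(); ++mi) {
            if (ph.rho[mi] <= 0) continue;
            double v = P.mat[mi].tot(st.E) * ph.rho[mi] * 0.1;
            if (v > mumax) mumax = v;
          }
          double sflight = -std::log(std::max(rng.u01(), 1e-300)) / mumax;
          // does it leave the box?
          double tbox = 1e300;
          for (int a = 0; a < 3; ++a) {
            if (std::fabs(st.u[a]) < 1e-300) continue;
            double lo = ph.org[a], hi2 = ph.org[a] + ph.sp[a] * ph.dim[a];
            double t = (st.u[a] > 0 ? hi2 - st.p[a] : lo - st.p[a]) / st.u[a];
            tbox = std::min(tbox, t);
          }
          if (sflight >= tbox) {
            scoreSegment(st.p, st.u, tbox, st.E, st.w, hist, true);
            tot.escaped += st.w * st.E; tot.n_escape++;
            if (st.ncoll == 0 && !st.secondary) tot.n_escape_uncollided++;
            alive = false; break;
          }
          scoreSegment(st.p, st.u, sflight, st.E, st.w, hist, true);
          for (int a = 0; a < 3; ++a) st.p[a] += sflight * st.u[a];
          if (!ph.voxelIndex(st.p, ijk)) { continue; }
          int m = ph.matAt(ijk);
          double mulocal = P.mat[m].tot(st.E) * ph.rho[m] * 0.1;
          if (rng.u01() * mumax > mulocal) continue;       // null collision
          const MatXS &M = P.mat[m];
          double pph = M.ph(st.E), pin = M.inc(st.E), pco = M.coh(st.E);
          double x = rng.u01() * (pph + pin + pco);
          if (x < pph) {
            int ei = pickElement(P, M, st.E, 0, rng);
            const ElemXS &e = P.el[ei];
            double edep = st.E;
            if (fluor_on && e.kedge > 0 && st.E > e.kedge &&
                rng.u01() < e.kfrac * e.kyield) {
              double uu = rng.u01();
              size_t li = std::lower_bound(e.klineCdf.begin(), e.klineCdf.end(), uu)
                          - e.klineCdf.begin();
              if (li >= e.klineE.size()) li = e.klineE.size() - 1;
              double Ef = e.klineE[li];
              if (Ef < st.E) {
                edep = st.E - Ef;
                PhotonState fs = st;
                fs.E = Ef; fs.ncoll = 0; fs.secondary = true;
                rng.isotropic(fs.u);
                if (Ef >= cutoff) stack.push_back(fs);
                else scoreDeposit(st.p, Ef, st.w, hist, ph.rho[m]);
              }
            }
            scoreDeposit(st.p, edep, st.w, hist, ph.rho[m]);
            alive = false;
          } else if (x < pph + pin) {
            double Ep, ct;
            int sei = pickElement(P, M, st.E, 1, rng);
            compton_bound(P.el[sei], st.E, rng, Ep, ct);
            scoreDeposit(st.p, st.E - Ep, st.w, hist, ph.rho[m]);
            deflect(st.u, ct, rng);
            st.E = Ep; st.ncoll++;
            if (st.E < cutoff) { scoreDeposit(st.p, st.E, st.w, hist, ph.rho[m]);
                                 alive = false; }
          } else {
            int ei = pickElement(P, M, st.E, 2, rng);
            double ct = rayleigh_cost(P.el[ei], st.E, rng);
            deflect(st.u, ct, rng);
            st.ncoll++;
          }
        }
      }
    }
  }

  // collect
  List out_sc(scorers.size());
  for (int i = 0; i < scorers.size(); ++i) {
    if (order_type[i] == 0) {
      AnnularScorer &a = ann[order_idx[i]];
      a.tal.flush();
      out_sc[i] = List::create(_["sum"] = wrap(a.tal.sum),
                               _["sum2"] = wrap(a.tal.sum2),
                               _["vol_mm3"] = wrap(a.vol));
    } else {
      CartScorer &cs = cart[order_idx[i]];
      cs.tal.flush();
      out_sc[i] = List::create(_["sum"] = wrap(cs.tal.sum),
                               _["sum2"] = wrap(cs.tal.sum2));
    }
  }
  return List::create(
    _["scorers"] = out_sc,
    _["totals"] = List::create(
      _["emitted_keV"] = tot.emitted,
      _["deposited_keV"] = tot.deposited,
      _["escaped_keV"] = tot.escaped,
      _["n_escape"] = (double)tot.n_escape,
      _["n_escape_uncollided"] = (double)tot.n_escape_uncollided,
      _["n_primary"] = (double)tot.n_primary,
      _["n_histories"] = (double)nhist));
}

// ------------------------------------------------- phase-space generation --
// Transports decay photons through the seed's own materials (vacuum outside)
// and records every photon crossing the outer surface outward.  All photons
// are recorded (including K fluorescence born in the source, which is a
// substantial part of the emission of silver-rod seeds); electrons are never
// tracked (kerma approximation).  Setting fluorescence = false suppresses
// fluorescence generation entirely, leaving primary-line photons only.
// [[Rcpp::export]]
List cpp_generate_phsp(List phys, List seed_spec, double n_records,
                       double rng_seed, double max_factor, bool fluorescence) {
  Physics P = buildPhysics(phys);
  Seed sd = buildSeed(seed_spec);
  int64_t want = (int64_t)n_records;
  NumericMatrix rec(want, 8);
  int64_t got = 0, prim = 0;
  int64_t maxprim = (int64_t)(max_factor * (double)want) + 1000;
  Rng rng;
  std::vector<PhotonState> stack;
  while (got < want) {
    if (prim > maxprim)
      stop("phase-space generation stalled: %d records after %d primaries",
           (int)got, (int)prim);
    if ((prim & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed((uint64_t)rng_seed, prim);
    prim++;
    PhotonState s0;
    s0.w = 1.0; s0.ncoll = 0; s0.secondary = false;
    sd.sampleEmission(rng, s0.p, s0.u, s0.E);
    stack.clear();
    stack.push_back(s0);
    while (!stack.empty() && got < want) {
      PhotonState st = stack.back();
      stack.pop_back();
      bool alive = true;
      while (alive && got < want) {
        int cur = sd.materialAt(st.p);
        if (cur == -2) { alive = false; break; }   // outside (shouldn't happen)
        std::vector<double> ts;
        for (auto &so : sd.solids) so.roots(st.p, st.u, ts);
        double tb = 1e300;
        for (double t : ts) if (t > 1e-7 && t < tb) tb = t;
        if (tb >= 1e300) { alive = false; break; }
        double mu = 0.0;
        if (cur >= 0) mu = P.mat[cur].tot(st.E) * P.mat[cur].density * 0.1;
        double sflight = (mu <= 0) ? tb
                       : -std::log(std::max(rng.u01(), 1e-300)) / mu;
        if (sflight >= tb) {
          double qn[3] = {st.p[0] + (tb + 1e-6) * st.u[0],
                          st.p[1] + (tb + 1e-6) * st.u[1],
                          st.p[2] + (tb + 1e-6) * st.u[2]};
          if (!sd.insideOuter(qn)) {
            // tb is itself a surface-crossing root of the union boundary:
            // record at the precise exit point
            double tx = tb;
            rec(got, 0) = st.E;
            rec(got, 1) = st.p[0] + tx * st.u[0];
            rec(got, 2) = st.p[1] + tx * st.u[1];
            rec(got, 3) = st.p[2] + tx * st.u[2];
            rec(got, 4) = st.u[0]; rec(got, 5) = st.u[1]; rec(got, 6) = st.u[2];
            rec(got, 7) = st.w;
            got++;
            alive = false;
          } else {
            st.p[0] = qn[0]; st.p[1] = qn[1]; st.p[2] = qn[2];
          }
          continue;
        }
        for (int a = 0; a < 3; ++a) st.p[a] += sflight * st.u[a];
        const MatXS &M = P.mat[cur];
        double pph = M.ph(st.E), pin = M.inc(st.E), pco = M.coh(st.E);
        double x = rng.u01() * (pph + pin + pco);
        if (x < pph) {
          if (fluorescence) {
            int ei = pickElement(P, M, st.E, 0, rng);
            const ElemXS &e = P.el[ei];
            if (e.kedge > 0 && st.E > e.kedge &&
                rng.u01() < e.kfrac * e.kyield) {
              double uu = rng.u01();
              size_t li = std::lower_bound(e.klineCdf.begin(), e.klineCdf.end(),
                                           uu) - e.klineCdf.begin();
              if (li >= e.klineE.size()) li = e.klineE.size() - 1;
              if (e.klineE[li] < st.E) {
                PhotonState fs = st;
                fs.E = e.klineE[li]; fs.ncoll = 0; fs.secondary = true;
                rng.isotropic(fs.u);
                stack.push_back(fs);
              }
            }
          }
          alive = false;
        } else if (x < pph + pin) {
          double Ep, ct;
          int sei = pickElement(P, M, st.E, 1, rng);
          compton_bound(P.el[sei], st.E, rng, Ep, ct);
          deflect(st.u, ct, rng);
          st.E = Ep;
          if (st.E < 1.0) alive = false;
        } else {
          int ei = pickElement(P, M, st.E, 2, rng);
          double ct = rayleigh_cost(P.el[ei], st.E, rng);
          deflect(st.u, ct, rng);
        }
      }
    }
  }
  return List::create(_["records"] = rec, _["n_primary"] = (double)prim);
}

// ------------------------------------------------------------ utilities ---
// [[Rcpp::export]]
NumericMatrix cpp_sample_emission(List seed_spec, double n, double rng_seed) {
  Seed sd = buildSeed(seed_spec);
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 7);
  Rng rng;
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    double p[3], u[3], E;
    sd.sampleEmission(rng, p, u, E);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    out(i, 3) = u[0]; out(i, 4) = u[1]; out(i, 5) = u[2];
    out(i, 6) = E;
  }
  return out;
}

// material segments a ray crosses through a seed, from start to outer exit
// [[Rcpp::export]]
NumericMatrix cpp_trace(List seed_spec, NumericVector origin, NumericVector dir) {
  Seed sd = buildSeed(seed_spec);
  double p[3] = {origin[0], origin[1], origin[2]};
  double u[3] = {dir[0], dir[1], dir[2]};
  std::vector<double> ts;
  for (auto &so : sd.solids) so.roots(p, u, ts);
  std::vector<double> pos;
  for (double t : ts) if (t > 1e-9) pos.push_back(t);
  std::sort(pos.begin(), pos.end());
  std::vector<std::pair<double, int>> segs;    // length, material
  double tcur = 0.0;
  // if starting outside, advance to first entry
  if (!sd.insideOuter(p)) {
    bool entered = false;
    for (double t : pos) {
      double q[3] = {p[0] + (t + 1e-9) * u[0], p[1] + (t + 1e-9) * u[1],
                     p[2] + (t + 1e-9) * u[2]};
      if (sd.insideOuter(q)) { tcur = t; entered = true; break; }
    }
    if (!entered) return NumericMatrix(0, 2);
  }
  for (double t : pos) {
    if (t <= tcur + 1e-9) continue;
    double tm = 0.5 * (tcur + t);
    double q[3] = {p[0] + tm * u[0], p[1] + tm * u[1], p[2] + tm * u[2]};
    if (!sd.insideOuter(q)) break;
    int m = sd.materialAt(q);
    segs.push_back({t - tcur, m});
    tcur = t;
  }
  NumericMatrix out(segs.size(), 2);
  for (size_t i = 0; i < segs.size(); ++i) {
    out(i, 0) = segs[i].first;
    out(i, 1) = segs[i].second;    // 0-based material, -1 vacuum
  }
  return out;
}

// component index containing each point (1-based; 0 = outside)
// [[Rcpp::export]]
IntegerVector cpp_component_at(List seed_spec, NumericMatrix pts) {
  Seed sd = buildSeed(seed_spec);
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int comp = 0;
    for (size_t j = 0; j < sd.solids.size(); ++j)
      if (sd.solids[j].inside(p)) { comp = (int)j + 1; break; }
    out[i] = comp;
  }
  return out;
}

// distance of points from the capture surface, i.e. the boundary of the
// union of all component solids (|.| small = on surface, < 0 inside)
// [[Rcpp::export]]
NumericVector cpp_outer_surface_distance(List seed_spec, NumericMatrix pts) {
  Seed sd = buildSeed(seed_spec);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double d = 1e30;
    for (auto &so : sd.solids) d = std::min(d, so.surfdist(p));
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_compton(double E, double n, double rng_seed) {
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 2);
  Rng rng;
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    double Ep, ct;
    compton(E, rng, Ep, ct);
    out(i, 0) = Ep; out(i, 1) = ct;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rayleigh(List phys, int material, double E, double n,
                           double rng_seed) {
  Physics P = buildPhysics(phys);
  int64_t nn = (int64_t)n;
  NumericVector out(nn);
  Rng rng;
  const MatXS &M = P.mat[material];
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    int ei = pickElement(P, M, E, 2, rng);
    out[i] = rayleigh_cost(P.el[ei], E, rng);
  }
  return out;
}

// photoelectric events: returns fluorescence photon energy or 0
// [[Rcpp::export]]
NumericVector cpp_photo(List phys, int material, double E, double n,
                        double rng_seed, bool fluor_on) {
  Physics P = buildPhysics(phys);
  int64_t nn = (int64_t)n;
  NumericVector out(nn);
  Rng rng;
  const MatXS &M = P.mat[material];
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    int ei = pickElement(P, M, E, 0, rng);
    const ElemXS &e = P.el[ei];
    double Ef = 0.0;
    if (fluor_on && e.kedge > 0 && E > e.kedge &&
        rng.u01() < e.kfrac * e.kyield) {
      double uu = rng.u01();
      size_t li = std::lower_bound(e.klineCdf.begin(), e.klineCdf.end(), uu)
                  - e.klineCdf.begin();
      if (li >= e.klineE.size()) li = e.klineE.size() - 1;
      if (e.klineE[li] < E) Ef = e.klineE[li];
    }
    out[i] = Ef;
  }
  return out;
}

// interaction channel frequencies: 1 photo, 2 compton, 3 rayleigh
// [[Rcpp::export]]
IntegerVector cpp_sample_channel(List phys, int material, double E, double n,
                                 double rng_seed) {
  Physics P = buildPhysics(phys);
  int64_t nn = (int64_t)n;
  IntegerVector out(nn);
  Rng rng;
  const MatXS &M = P.mat[material];
  double pph = M.ph(E), pin = M.inc(E), pco = M.coh(E);
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    double x = rng.u01() * (pph + pin + pco);
    out[i] = (x < pph) ? 1 : (x < pph + pin) ? 2 : 3;
  }
  return out;
}

// incoherent (bound-electron) scattering samples for a material
// [[Rcpp::export]]
NumericMatrix cpp_incoh(List phys, int material, double E, double n,
                        double rng_seed) {
  Physics P = buildPhysics(phys);
  int64_t nn = (int64_t)n;
  NumericMatrix out(nn, 2);
  Rng rng;
  const MatXS &M = P.mat[material];
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed((uint64_t)rng_seed, i);
    int ei = pickElement(P, M, E, 1, rng);
    double Ep, ct;
    compton_bound(P.el[ei], E, rng, Ep, ct);
    out(i, 0) = Ep; out(i, 1) = ct;
  }
  return out;
}
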