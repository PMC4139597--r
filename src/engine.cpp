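// Compiled kernels for the chain energy/force engine: a unified per-row
// evaluator for every slow (nonbonded / mean-field / correlation / rotamer
// / double-torsion) term class, batch energy evaluation, a central-
// difference gradient driver over the defining points of each class (using
// translation invariance for the last point), and the analytic gradient of
// the stiff local terms. These mirror the package's R reference
// implementations exactly (same frame conventions, same capping); the R
// versions remain the oracles in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double COUL = 332.0637;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator-(const V3 &a, const V3 &b) {
  return V3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline V3 operator+(const V3 &a, const V3 &b) {
  return V3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline V3 operator*(double s, const V3 &a) {
  return V3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) {
  double n = norm(a);
  return V3(a.x / n, a.y / n, a.z / n);
}

// axis of b - a with a dummy +x axis for zero-offset (isotropic) sites
static inline V3 axis_of(const V3 &a, const V3 &b) {
  V3 v = b - a;
  double n = norm(v);
  if (n < 1e-9) return V3(1, 0, 0);
  return V3(v.x / n, v.y / n, v.z / n);
}

// orthonormal completion of u: reference axis = first coordinate axis with
// the smallest |component| (matches the R engine's ties.method = "first")
static inline void perp_frame(const V3 &u, V3 &e1, V3 &e2) {
  double ax = std::fabs(u.x), ay = std::fabs(u.y), az = std::fabs(u.z);
  V3 ref(0, 0, 0);
  if (ax <= ay && ax <= az) ref.x = 1;
  else if (ay <= az) ref.y = 1;
  else ref.z = 1;
  double p = dot(ref, u);
  e1 = unit(ref - p * u);
  e2 = cross(u, e1);
}

// IUPAC dihedral (cis = 0), matching the R dihedral_angle()
static inline double dihedral(const V3 &p1, const V3 &p2, const V3 &p3,
                              const V3 &p4) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  V3 m1 = cross(n1, unit(b2));
  return std::atan2(dot(m1, n2), dot(n1, n2));
}

// second-order-cumulant mean-field dipole energy of one site pair
static double dip2_pair(const V3 &si, const V3 &sj, const V3 &ui,
                        const V3 &uj, double mpi, double msi, double mpj,
                        double msj, double eps_r, double rt0, double cap,
                        double rcore = 0) {
  V3 rv = sj - si;
  double r = norm(rv);
  V3 rh(rv.x / r, rv.y / r, rv.z / r);
  // short-range softening: the point-dipole kernel saturates below rcore
  double reff = std::sqrt(r * r + rcore * rcore);
  double k = COUL / (eps_r * reff * reff * reff);
  V3 e1i, e2i, e1j, e2j;
  perp_frame(ui, e1i, e2i);
  perp_frame(uj, e1j, e2j);
  const V3 Ei[3] = {ui, e1i, e2i};
  const V3 Ej[3] = {uj, e1j, e2j};
  const double mi[3] = {mpi, msi, msi};
  const double mj[3] = {mpj, msj, msj};
  const double w[3] = {1.0, 0.5, 0.5};
  double ai[3], aj[3];
  for (int p = 0; p < 3; ++p) {
    ai[p] = dot(Ei[p], rh);
    aj[p] = dot(Ej[p], rh);
  }
  double mean_e = 0, second = 0;
  for (int p = 0; p < 3; ++p) {
    for (int q = 0; q < 3; ++q) {
      double cpq =
          k * mi[p] * mj[q] * (dot(Ei[p], Ej[q]) - 3 * ai[p] * aj[q]);
      if (p == 0 && q == 0) mean_e = cpq;
      second += w[p] * w[q] * cpq * cpq;
    }
  }
  double u = mean_e - (second - mean_e * mean_e) / (2 * rt0);
  if (u > cap) u = cap;
  if (u < -cap) u = -cap;
  return u;
}

static double gb_pair(const V3 &si, const V3 &sj, const V3 &ui, const V3 &uj,
                      double eps0, double sig0, double chi, double chip,
                      double cap) {
  V3 rv = sj - si;
  double r = norm(rv);
  V3 rh(rv.x / r, rv.y / r, rv.z / r);
  double a = dot(rh, ui), b = dot(rh, uj), cc = dot(ui, uj);
  double hp = (a + b) * (a + b) / (1 + chi * cc) +
              (a - b) * (a - b) / (1 - chi * cc);
  double s2 = 1 - 0.5 * chi * hp;
  if (s2 < 1e-12) s2 = 1e-12;
  double sig = sig0 / std::sqrt(s2);
  double d1 = 1 - chi * chi * cc * cc;
  if (d1 < 1e-12) d1 = 1e-12;
  double e1 = 1 / std::sqrt(d1);
  double hpp = (a + b) * (a + b) / (1 + chip * cc) +
               (a - b) * (a - b) / (1 - chip * cc);
  double e2 = 1 - 0.5 * chip * hpp;
  if (e2 < 0) e2 = 0;
  double eps = eps0 * e1 * e2 * e2;
  double rr = r - sig + sig0;
  double u;
  if (rr <= sig0 * 0.1) {
    u = cap;
  } else {
    double rho6 = std::pow(sig0 / rr, 6);
    u = 4 * eps * (rho6 * rho6 - rho6);
  }
  return u > cap ? cap : u;
}

// ---------------------------------------------------------------------------
// unified class evaluator

enum ClassId {
  GB_BRANCH = 1, GB_MID = 2, DIP_BRANCH = 3, DIP_MID = 4, DH = 5,
  LJ_PM = 6, TORD = 7, ROT = 8, CORR3 = 9, TURN3 = 10, TURN4 = 11
};

struct Ctx {
  int id;
  double cap, eps_r, rt0, c, eps, sigma, pref, kappa, ev_eps, ev_sigma, rcore;
  std::vector<double> fa, fb, beta_cos, beta_sin;
  // per-row parameter vectors (may be empty)
  const double *eps0, *sig0, *chi, *chip;
  const double *mpi, *msi, *mpj, *msj;
  const double *k_alpha, *alpha0;
  const int *two;
};

static double getd(const List &par, const char *nm, double dflt = 0) {
  if (!par.containsElementNamed(nm)) return dflt;
  return as<double>(par[nm]);
}
static std::vector<double> getv(const List &par, const char *nm) {
  if (!par.containsElementNamed(nm)) return std::vector<double>();
  return as<std::vector<double>>(par[nm]);
}

// keep NumericVectors alive while Ctx holds raw pointers
struct CtxStore {
  NumericVector eps0, sig0, chi, chip, mpi, msi, mpj, msj, k_alpha, alpha0;
  IntegerVector two;
};

static Ctx make_ctx(int id, const List &par, CtxStore &st) {
  Ctx c;
  c.id = id;
  c.cap = getd(par, "cap", 1e4);
  c.eps_r = getd(par, "eps_r", 1);
  c.rt0 = getd(par, "rt0", 0.59616);
  c.c = getd(par, "c", 0);
  c.eps = getd(par, "eps", 0);
  c.sigma = getd(par, "sigma", 0);
  c.pref = getd(par, "pref", 0);
  c.kappa = getd(par, "kappa", 0);
  c.ev_eps = getd(par, "ev_eps", 0);
  c.ev_sigma = getd(par, "ev_sigma", 0);
  c.rcore = getd(par, "rcore", 0);
  c.fa = getv(par, "a");
  c.fb = getv(par, "b");
  c.beta_cos = getv(par, "beta_cos");
  c.beta_sin = getv(par, "beta_sin");
  c.eps0 = c.sig0 = c.chi = c.chip = c.mpi = c.msi = c.mpj = c.msj =
      c.k_alpha = c.alpha0 = nullptr;
  c.two = nullptr;
  if (par.containsElementNamed("eps0")) {
    st.eps0 = par["eps0"]; c.eps0 = st.eps0.begin();
    st.sig0 = par["sig0"]; c.sig0 = st.sig0.begin();
    st.chi = par["chi"]; c.chi = st.chi.begin();
    st.chip = par["chip"]; c.chip = st.chip.begin();
  }
  if (par.containsElementNamed("mpi")) {
    st.mpi = par["mpi"]; c.mpi = st.mpi.begin();
    st.msi = par["msi"]; c.msi = st.msi.begin();
    st.mpj = par["mpj"]; c.mpj = st.mpj.begin();
    st.msj = par["msj"]; c.msj = st.msj.begin();
  }
  if (par.containsElementNamed("k_alpha")) {
    st.k_alpha = par["k_alpha"]; c.k_alpha = st.k_alpha.begin();
    st.alpha0 = par["alpha0"]; c.alpha0 = st.alpha0.begin();
    st.two = as<IntegerVector>(par["two"]); c.two = st.two.begin();
  }
  return c;
}

// energy of row i, with P = the row's defining points
static double row_energy(const Ctx &c, int i, const V3 *P) {
  switch (c.id) {
  case GB_BRANCH:
    return gb_pair(P[1], P[3], axis_of(P[0], P[1]), axis_of(P[2], P[3]),
                   c.eps0[i], c.sig0[i], c.chi[i], c.chip[i], c.cap);
  case GB_MID:
    return gb_pair(0.5 * (P[0] + P[1]), 0.5 * (P[2] + P[3]),
                   axis_of(P[0], P[1]), axis_of(P[2], P[3]), c.eps0[i],
                   c.sig0[i], c.chi[i], c.chip[i], c.cap);
  case DIP_BRANCH:
  case DIP_MID: {
    V3 si = (c.id == DIP_MID) ? 0.5 * (P[0] + P[1]) : P[1];
    V3 sj = (c.id == DIP_MID) ? 0.5 * (P[2] + P[3]) : P[3];
    double u = dip2_pair(si, sj, axis_of(P[0], P[1]), axis_of(P[2], P[3]),
                         c.mpi[i], c.msi[i], c.mpj[i], c.msj[i], c.eps_r,
                         c.rt0, c.cap, c.rcore);
    if (c.ev_eps > 0) {
      // repulsive excluded-volume core of the polar site
      double s12 = std::pow(c.ev_sigma / norm(sj - si), 12);
      u += 4 * c.ev_eps * s12;
      if (u > c.cap) u = c.cap;
    }
    return u;
  }
  case DH: {
    double r = norm(0.5 * (P[2] + P[3]) - 0.5 * (P[0] + P[1]));
    double u = c.pref * std::exp(-c.kappa * r) / r;
    return u > c.cap ? c.cap : u;
  }
  case LJ_PM: {
    double r = norm(0.5 * (P[1] + P[2]) - P[0]);
    double s6 = std::pow(c.sigma / r, 6);
    double u = 4 * c.eps * (s6 * s6 - s6);
    return u > c.cap ? c.cap : u;
  }
  case TORD: {
    double g1 = dihedral(P[0], P[1], P[2], P[3]);
    double g2 = dihedral(P[1], P[2], P[3], P[4]);
    double u = 0;
    for (size_t k = 0; k < c.fa.size(); ++k) {
      u += c.fa[k] * std::cos((k + 1) * g1) * std::cos((k + 1) * g2) +
           c.fb[k] * std::sin((k + 1) * g1) * std::sin((k + 1) * g2);
    }
    return u;
  }
  case ROT: {
    V3 e1, e2, e3;
    if (c.two[i]) {
      V3 u = unit(P[1] - P[0]);
      V3 tmp;
      perp_frame(u, e1, tmp);
      e2 = u;
      e3 = cross(e1, e2);
    } else {
      V3 u = unit(P[1] - P[0]);
      V3 v = unit(P[2] - P[1]);
      e1 = unit(u - v);
      e2 = unit(u + v);
      e3 = cross(e1, e2);
    }
    V3 wu = unit(P[4] - P[3]);
    double ca = dot(wu, e1);
    if (ca > 1) ca = 1;
    if (ca < -1) ca = -1;
    double al = std::acos(ca);
    double be = std::atan2(dot(wu, e3), dot(wu, e2));
    double u = c.k_alpha[i] * (al - c.alpha0[i]) * (al - c.alpha0[i]);
    for (size_t k = 0; k < c.beta_cos.size(); ++k) {
      u += c.beta_cos[k] * std::cos((k + 1) * be) +
           c.beta_sin[k] * std::sin((k + 1) * be);
    }
    return u;
  }
  case CORR3: {
    double d = dip2_pair(0.5 * (P[1] + P[2]), 0.5 * (P[5] + P[6]),
                         axis_of(P[1], P[2]), axis_of(P[5], P[6]), c.mpi[i],
                         c.msi[i], c.mpj[i], c.msj[i], c.eps_r, c.rt0,
                         c.cap, c.rcore);
    double g1 = dihedral(P[0], P[1], P[2], P[3]);
    double g2 = dihedral(P[4], P[5], P[6], P[7]);
    return c.c * d * std::cos(g1) * std::cos(g2);
  }
  case TURN3:
    return c.c * dip2_pair(0.5 * (P[0] + P[1]), 0.5 * (P[1] + P[2]),
                           axis_of(P[0], P[1]), axis_of(P[1], P[2]),
                           c.mpi[i], c.msi[i], c.mpj[i], c.msj[i], c.eps_r,
                           c.rt0, c.cap, c.rcore);
  case TURN4: {
    double d = dip2_pair(0.5 * (P[0] + P[1]), 0.5 * (P[2] + P[3]),
                         axis_of(P[0], P[1]), axis_of(P[2], P[3]), c.mpi[i],
                         c.msi[i], c.mpj[i], c.msj[i], c.eps_r, c.rt0,
                         c.cap, c.rcore);
    return c.c * d * std::cos(dihedral(P[0], P[1], P[2], P[3]));
  }
  }
  stop("unknown class id");
  return 0;
}

// gather the defining points of row i from the stacked coordinates
static inline void gather(const NumericMatrix &X, const IntegerMatrix &idx,
                          int i, V3 *P, int k) {
  for (int p = 0; p < k; ++p) {
    int s = idx(i, p) - 1;
    P[p] = V3(X(s, 0), X(s, 1), X(s, 2));
  }
}

// [[Rcpp::export(name = ".cpp_class_energy")]]
NumericVector cpp_class_energy(int id, NumericMatrix X, IntegerMatrix idx,
                               List par) {
  int m = idx.nrow(), k = idx.ncol();
  CtxStore st;
  Ctx c = make_ctx(id, par, st);
  NumericVector out(m);
  std::vector<V3> P(k);
  for (int i = 0; i < m; ++i) {
    gather(X, idx, i, P.data(), k);
    out[i] = row_energy(c, i, P.data());
  }
  return out;
}

// central-difference gradient of one class, scatter-added into an n x 3
// gradient matrix; the last defining point uses translation invariance
// [[Rcpp::export(name = ".cpp_class_grad")]]
void cpp_class_grad(int id, NumericMatrix X, IntegerMatrix idx, List par,
                    double weight, double h, NumericMatrix G) {
  int m = idx.nrow(), k = idx.ncol();
  CtxStore st;
  Ctx c = make_ctx(id, par, st);
  std::vector<V3> P(k);
  std::vector<double> glast(3);
  for (int i = 0; i < m; ++i) {
    gather(X, idx, i, P.data(), k);
    glast[0] = glast[1] = glast[2] = 0;
    for (int p = 0; p < k - 1; ++p) {
      int s = idx(i, p) - 1;
      for (int cc = 0; cc < 3; ++cc) {
        double *coord = (cc == 0) ? &P[p].x : (cc == 1) ? &P[p].y : &P[p].z;
        double orig = *coord;
        *coord = orig + h;
        double ep = row_energy(c, i, P.data());
        *coord = orig - h;
        double em = row_energy(c, i, P.data());
        *coord = orig;
        double g = (ep - em) / (2 * h);
        G(s, cc) += weight * g;
        glast[cc] -= weight * g;
      }
    }
    int s = idx(i, k - 1) - 1;
    G(s, 0) += glast[0];
    G(s, 1) += glast[1];
    G(s, 2) += glast[2];
  }
}

// analytic gradient of the stiff local terms (bond + angle + torsion),
// identical formulas to the R reference implementation
// [[Rcpp::export(name = ".cpp_fast_grad")]]
NumericMatrix cpp_fast_grad(NumericMatrix X, IntegerVector bi,
                            IntegerVector bj, NumericVector d0,
                            NumericVector kb, IntegerVector ai,
                            IntegerVector aj, IntegerVector ak,
                            NumericVector th0, NumericVector kth,
                            IntegerVector ti, IntegerVector tj,
                            IntegerVector tk, IntegerVector tl,
                            NumericMatrix ta, NumericMatrix tb) {
  int n = X.nrow();
  NumericMatrix G(n, 3);
  for (int b = 0; b < bi.size(); ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    V3 rv = V3(X(j, 0), X(j, 1), X(j, 2)) - V3(X(i, 0), X(i, 1), X(i, 2));
    double d = norm(rv);
    if (d < 1e-9) stop("coincident bonded sites");
    double coef = 2 * kb[b] * (d - d0[b]) / d;
    G(j, 0) += coef * rv.x; G(j, 1) += coef * rv.y; G(j, 2) += coef * rv.z;
    G(i, 0) -= coef * rv.x; G(i, 1) -= coef * rv.y; G(i, 2) -= coef * rv.z;
  }
  for (int a = 0; a < ai.size(); ++a) {
    int i = ai[a] - 1, j = aj[a] - 1, k = ak[a] - 1;
    V3 u = V3(X(i, 0), X(i, 1), X(i, 2)) - V3(X(j, 0), X(j, 1), X(j, 2));
    V3 v = V3(X(k, 0), X(k, 1), X(k, 2)) - V3(X(j, 0), X(j, 1), X(j, 2));
    double nu = norm(u), nv = norm(v);
    V3 uh(u.x / nu, u.y / nu, u.z / nu), vh(v.x / nv, v.y / nv, v.z / nv);
    double ct = dot(uh, vh);
    if (ct > 1) ct = 1;
    if (ct < -1) ct = -1;
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1 - ct * ct, 1e-12));
    double dE = 2 * kth[a] * (th - th0[a]);
    V3 g1 = (dE / (nu * st)) * (ct * uh - vh);
    V3 g3 = (dE / (nv * st)) * (ct * vh - uh);
    G(i, 0) += g1.x; G(i, 1) += g1.y; G(i, 2) += g1.z;
    G(k, 0) += g3.x; G(k, 1) += g3.y; G(k, 2) += g3.z;
    G(j, 0) -= g1.x + g3.x; G(j, 1) -= g1.y + g3.y; G(j, 2) -= g1.z + g3.z;
  }
  int nf = ta.ncol();
  for (int t = 0; t < ti.size(); ++t) {
    int i = ti[t] - 1, j = tj[t] - 1, k = tk[t] - 1, l = tl[t] - 1;
    V3 p1(X(i, 0), X(i, 1), X(i, 2)), p2(X(j, 0), X(j, 1), X(j, 2));
    V3 p3(X(k, 0), X(k, 1), X(k, 2)), p4(X(l, 0), X(l, 1), X(l, 2));
    V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
    V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double n1s = dot(n1, n1), n2s = dot(n2, n2);
    if (n1s < 1e-16 || n2s < 1e-16)
      stop("degenerate torsion geometry at anchors %d-%d-%d-%d", i + 1,
           j + 1, k + 1, l + 1);
    double nb2 = norm(b2);
    double g = dihedral(p1, p2, p3, p4);
    double dE = 0;
    for (int f = 0; f < nf; ++f) {
      dE += -ta(t, f) * (f + 1) * std::sin((f + 1) * g) +
            tb(t, f) * (f + 1) * std::cos((f + 1) * g);
    }
    V3 g1 = (nb2 / n1s) * n1;
    V3 g4 = (-nb2 / n2s) * n2;
    double f1 = dot(b1, b2) / (nb2 * nb2);
    double f2 = dot(b3, b2) / (nb2 * nb2);
    V3 g2 = (-(1 + f1)) * g1 + f2 * g4;
    V3 g3 = f1 * g1 + (-(1 + f2)) * g4;
    G(i, 0) += dE * g1.x; G(i, 1) += dE * g1.y; G(i, 2) += dE * g1.z;
    G(j, 0) += dE * g2.x; G(j, 1) += dE * g2.y; G(j, 2) += dE * g2.z;
    G(k, 0) += dE * g3.x; G(k, 1) += dE * g3.y; G(k, 2) += dE * g3.z;
    G(l, 0) += dE * g4.x; G(l, 1) += dE * g4.y; G(l, 2) += dE * g4.z;
  }
  return G;
}
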