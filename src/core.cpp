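// Core numerics: toy bead force field, restraint penalties with exact
// gradients, exponential-memory time averaging (block ring buffer), and the
// MD integrators.  Units: kcal/mol, Angstrom, amu, fs, degrees at the API.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 1 kcal/mol expressed in amu*A^2/fs^2 (4184 J/mol / 1e7)
static const double KCAL = 4.184e-4;
static const double KB = 0.001987204259;   // kcal/mol/K
static const double R2DEG = 57.29577951308232;
static const double D2RAD = 0.017453292519943295;

// ---------------------------------------------------------------------------
// small vector helpers on raw coordinate arrays (n x 3, column major from R)
struct V3 { double x, y, z; };
static inline V3 getv(const NumericMatrix &X, int i) {
  return V3{X(i, 0), X(i, 1), X(i, 2)};
}
static inline V3 sub(V3 a, V3 b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 scale3(V3 a, double s) { return V3{a.x * s, a.y * s, a.z * s}; }
static inline void addto(NumericMatrix &F, int i, V3 g, double s) {
  F(i, 0) += s * g.x; F(i, 1) += s * g.y; F(i, 2) += s * g.z;
}

// virtual-bond angle (radians) at vertex b; gradients wrt a, b, c (per rad)
static double angle_rad(V3 a, V3 b, V3 c, V3 &ga, V3 &gb, V3 &gc, bool &ok) {
  V3 u = sub(a, b), v = sub(c, b);
  double nu = norm3(u), nv = norm3(v);
  if (nu < 1e-10 || nv < 1e-10) { ok = false; ga = gb = gc = V3{0, 0, 0}; return 0.0; }
  double ct = dot(u, v) / (nu * nv);
  if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  double th = std::acos(ct);
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-8) { ok = false; ga = gb = gc = V3{0, 0, 0}; return th; }
  // d(theta)/da = (cos(theta)*u_hat - v_hat) / (|u| sin(theta))
  V3 uh = scale3(u, 1.0 / nu), vh = scale3(v, 1.0 / nv);
  ga = scale3(sub(scale3(uh, ct), vh), 1.0 / (nu * st));
  gc = scale3(sub(scale3(vh, ct), uh), 1.0 / (nv * st));
  gb = V3{-(ga.x + gc.x), -(ga.y + gc.y), -(ga.z + gc.z)};
  ok = true;
  return th;
}

// signed dihedral (radians) about b--c; gradients wrt the four beads
static double dihedral_rad(V3 a, V3 b, V3 c, V3 d,
                           V3 &ga, V3 &gb, V3 &gc, V3 &gd, bool &ok) {
  V3 b1 = sub(b, a), b2 = sub(c, b), b3 = sub(d, c);
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  double nb2 = norm3(b2), n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  if (nb2 < 1e-10 || n1sq < 1e-16 || n2sq < 1e-16) {
    ok = false; ga = gb = gc = gd = V3{0, 0, 0}; return 0.0;
  }
  double x = dot(n1, n2);
  double y = dot(cross(n1, n2), scale3(b2, 1.0 / nb2));
  double phi = std::atan2(y, x);
  ga = scale3(n1, -nb2 / n1sq);
  gd = scale3(n2,  nb2 / n2sq);
  // with b1 = b - a, b2 = c - b, b3 = d - c:
  //   d(phi)/db = -(1 + c12) d(phi)/da + c32 d(phi)/dd
  //   d(phi)/dc =       c12  d(phi)/da - (1 + c32) d(phi)/dd
  double c12 = dot(b1, b2) / (nb2 * nb2), c32 = dot(b3, b2) / (nb2 * nb2);
  gb = V3{-(1.0 + c12) * ga.x + c32 * gd.x,
          -(1.0 + c12) * ga.y + c32 * gd.y,
          -(1.0 + c12) * ga.z + c32 * gd.z};
  gc = V3{c12 * ga.x - (1.0 + c32) * gd.x,
          c12 * ga.y - (1.0 + c32) * gd.y,
          c12 * ga.z - (1.0 + c32) * gd.z};
  ok = true;
  return phi;
}

// ---------------------------------------------------------------------------
// restraint penalty wells (flat bottom, Gaussian walls); degrees for angles

// distance penalty with linear kappa tail above the upper bound
static inline void pen_dist(double d, double dl, double du, double A,
                            double sig, double kap, double &V, double &dV) {
  if (d < dl) {
    double x = dl - d, e = std::exp(-x * x / (2.0 * sig * sig));
    V = -A * e; dV = -A * e * x / (sig * sig);
  } else if (d <= du) {
    V = -A; dV = 0.0;
  } else {
    double x = d - du, e = std::exp(-x * x / (2.0 * sig * sig));
    V = -A * e + kap * x; dV = A * e * x / (sig * sig) + kap;
  }
}

// flat-bottom well on a linear coordinate (virtual-bond angle theta)
static inline void pen_flat(double v, double lo, double hi, double A,
                            double sig, double &V, double &dV) {
  if (v < lo) {
    double x = lo - v, e = std::exp(-x * x / (2.0 * sig * sig));
    V = -A * e; dV = -A * e * x / (sig * sig);
  } else if (v <= hi) {
    V = -A; dV = 0.0;
  } else {
    double x = v - hi, e = std::exp(-x * x / (2.0 * sig * sig));
    V = -A * e; dV = A * e * x / (sig * sig);
  }
}

static inline double wrap360(double x) {
  double r = x - 360.0 * std::floor(x / 360.0);
  if (r >= 360.0) r -= 360.0;
  if (r < 0) r += 360.0;
  return r;
}

// periodic flat-bottom well for the virtual-bond dihedral gamma; the wall on
// each side uses the wrapped angular distance to the nearer boundary
static inline void pen_gamma(double g, double gl, double gu, double A,
                             double sig, double &V, double &dV) {
  double span = wrap360(gu - gl);
  double rel = wrap360(g - gl);
  if (rel <= span) { V = -A; dV = 0.0; return; }
  double above = rel - span;      // ccw distance past the upper bound
  double below = 360.0 - rel;     // cw distance below the lower bound
  if (above <= below) {
    double e = std::exp(-above * above / (2.0 * sig * sig));
    V = -A * e; dV = A * e * above / (sig * sig);
  } else {
    double e = std::exp(-below * below / (2.0 * sig * sig));
    V = -A * e; dV = -A * e * below / (sig * sig);
  }
}

// [[Rcpp::export]]
List cpp_pen_dist(NumericVector d, double dl, double du, double A, double sig,
                  double kap) {
  int n = d.size();
  NumericVector V(n), dV(n);
  for (int i = 0; i < n; ++i) pen_dist(d[i], dl, du, A, sig, kap, V[i], dV[i]);
  return List::create(_["V"] = V, _["dV"] = dV);
}

// [[Rcpp::export]]
List cpp_pen_theta(NumericVector th, double lo, double hi, double A, double sig) {
  int n = th.size();
  NumericVector V(n), dV(n);
  for (int i = 0; i < n; ++i) pen_flat(th[i], lo, hi, A, sig, V[i], dV[i]);
  return List::create(_["V"] = V, _["dV"] = dV);
}

// [[Rcpp::export]]
List cpp_pen_gamma(NumericVector g, double gl, double gu, double A, double sig) {
  int n = g.size();
  NumericVector V(n), dV(n);
  for (int i = 0; i < n; ++i) pen_gamma(g[i], gl, gu, A, sig, V[i], dV[i]);
  return List::create(_["V"] = V, _["dV"] = dV);
}

// ---------------------------------------------------------------------------
// toy force field: harmonic virtual bonds, harmonic virtual-bond angles (deg),
// cosine dihedral series, WCA excluded volume for |i-j| >= 2

// [[Rcpp::export]]
List cpp_toy_energy_forces(NumericMatrix X, List ff) {
  int n = X.nrow();
  double b0 = ff["b0"], kb = ff["k_bond"], th0 = ff["theta0"],
         kth = ff["k_theta"], eps = ff["eps_ev"], sev = ff["sigma_ev"];
  NumericVector cd = ff["dihedral_coef"];
  NumericMatrix F(n, 3);
  double E = 0.0, Eb = 0.0, Ea = 0.0, Ed = 0.0, Ev = 0.0;
  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    V3 r = sub(getv(X, i + 1), getv(X, i));
    double d = norm3(r);
    if (d < 1e-8) stop("coincident bonded beads %d and %d", i + 1, i + 2);
    double dd = d - b0;
    Eb += 0.5 * kb * dd * dd;
    double pref = kb * dd / d;   // dV/dd * d(d)/dr
    addto(F, i + 1, r, -pref);
    addto(F, i, r, pref);
  }
  // angles (degrees)
  for (int i = 1; i + 1 < n; ++i) {
    V3 ga, gb, gc; bool ok;
    double th = angle_rad(getv(X, i - 1), getv(X, i), getv(X, i + 1), ga, gb, gc, ok) * R2DEG;
    double dd = th - th0;
    Ea += 0.5 * kth * dd * dd;
    if (ok) {
      double pref = kth * dd * R2DEG;  // gradient vectors are per radian
      addto(F, i - 1, ga, -pref);
      addto(F, i, gb, -pref);
      addto(F, i + 1, gc, -pref);
    }
  }
  // dihedral cosine series sum_k c_k (1 + cos(k * gamma))
  for (int i = 1; i + 2 < n; ++i) {
    V3 ga, gb, gc, gd; bool ok;
    double phi = dihedral_rad(getv(X, i - 1), getv(X, i), getv(X, i + 1), getv(X, i + 2),
                              ga, gb, gc, gd, ok);
    double dVdphi = 0.0;
    for (int k = 0; k < cd.size(); ++k) {
      double kk = k + 1.0;
      Ed += cd[k] * (1.0 + std::cos(kk * phi));
      dVdphi += -cd[k] * kk * std::sin(kk * phi);
    }
    if (ok) {
      addto(F, i - 1, ga, -dVdphi);
      addto(F, i, gb, -dVdphi);
      addto(F, i + 1, gc, -dVdphi);
      addto(F, i + 2, gd, -dVdphi);
    }
  }
  // WCA excluded volume, cutoff 2^(1/6) sigma
  double rc = std::pow(2.0, 1.0 / 6.0) * sev, rc2 = rc * rc;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      V3 r = sub(getv(X, j), getv(X, i));
      double r2 = dot(r, r);
      if (r2 >= rc2 || eps <= 0) continue;
      double s2 = sev * sev / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
      Ev += 4.0 * eps * (s12 - s6) + eps;
      double pref = 4.0 * eps * (-12.0 * s12 + 6.0 * s6) / r2; // dV/dr / r
      addto(F, j, r, -pref);
      addto(F, i, r, pref);
    }
  }
  E = Eb + Ea + Ed + Ev;
  return List::create(_["energy"] = E, _["forces"] = F,
                      _["terms"] = NumericVector::create(
                          _["bond"] = Eb, _["angle"] = Ea,
                          _["dihedral"] = Ed, _["excluded"] = Ev));
}

// ---------------------------------------------------------------------------
// flattened restraint set (built in R): group index vectors are 0-based

struct RSet {
  IntegerVector gi, gip, gj, gjp;            // distance groups + offsets
  NumericVector dl, du, A, sig, kap;
  IntegerVector tv; NumericVector tl, tu, At, sigt;
  IntegerVector gb; NumericVector gl, gu, Ag, sigg;
  int nd, nt, ng;
};

static RSet unpack(List rf) {
  RSet s;
  s.gi = rf["gi"]; s.gip = rf["gip"]; s.gj = rf["gj"]; s.gjp = rf["gjp"];
  s.dl = rf["dl"]; s.du = rf["du"]; s.A = rf["A"]; s.sig = rf["sig"]; s.kap = rf["kap"];
  s.tv = rf["tv"]; s.tl = rf["tl"]; s.tu = rf["tu"]; s.At = rf["At"]; s.sigt = rf["sigt"];
  s.gb = rf["gb"]; s.gl = rf["gl"]; s.gu = rf["gu"]; s.Ag = rf["Ag"]; s.sigg = rf["sigg"];
  s.nd = s.dl.size(); s.nt = s.tl.size(); s.ng = s.gl.size();
  return s;
}

// r^-6 combined group distance for restraint k; if pref != 0 accumulates
// -pref * dD/dx into F
static double group_dist(const NumericMatrix &X, const RSet &s, int k,
                         double pref, NumericMatrix *F) {
  int a0 = s.gip[k], a1 = s.gip[k + 1], b0 = s.gjp[k], b1 = s.gjp[k + 1];
  int P = (a1 - a0) * (b1 - b0);
  if (P == 1) {
    int i = s.gi[a0], j = s.gj[b0];
    V3 r = sub(getv(X, j), getv(X, i));
    double d = norm3(r);
    if (F && pref != 0.0) {
      addto(*F, j, r, -pref / d);
      addto(*F, i, r, pref / d);
    }
    return d;
  }
  double S = 0.0;
  for (int a = a0; a < a1; ++a)
    for (int b = b0; b < b1; ++b) {
      V3 r = sub(getv(X, s.gj[b]), getv(X, s.gi[a]));
      double d = norm3(r);
      S += std::pow(d, -6.0) / P;
    }
  double D = std::pow(S, -1.0 / 6.0);
  if (F && pref != 0.0) {
    for (int a = a0; a < a1; ++a)
      for (int b = b0; b < b1; ++b) {
        int i = s.gi[a], j = s.gj[b];
        V3 r = sub(getv(X, j), getv(X, i));
        double d = norm3(r);
        double dDdd = std::pow(D / d, 7.0) / P;
        addto(*F, j, r, -pref * dDdd / d);
        addto(*F, i, r, pref * dDdd / d);
      }
  }
  return D;
}

// instantaneous values of all restrained quantities
// [[Rcpp::export]]
List cpp_measure(NumericMatrix X, List rf) {
  RSet s = unpack(rf);
  NumericVector d(s.nd), th(s.nt), g(s.ng);
  LogicalVector thok(s.nt), gok(s.ng);
  for (int k = 0; k < s.nd; ++k) d[k] = group_dist(X, s, k, 0.0, nullptr);
  for (int k = 0; k < s.nt; ++k) {
    V3 ga, gb, gc; bool ok;
    int v = s.tv[k];
    th[k] = angle_rad(getv(X, v - 1), getv(X, v), getv(X, v + 1), ga, gb, gc, ok) * R2DEG;
    thok[k] = ok;
  }
  for (int k = 0; k < s.ng; ++k) {
    V3 ga, gb, gc, gd; bool ok;
    int b = s.gb[k];
    g[k] = dihedral_rad(getv(X, b - 1), getv(X, b), getv(X, b + 1), getv(X, b + 2),
                        ga, gb, gc, gd, ok) * R2DEG;
    gok[k] = ok;
  }
  return List::create(_["dist"] = d, _["theta"] = th, _["theta_ok"] = thok,
                      _["gamma"] = g, _["gamma_ok"] = gok);
}

// dense gradients of every restrained quantity (for the R-level chain rule);
// distance rows in A^-1 units... actually d(value)/d(coord): dist per A,
// angles in deg per A
// [[Rcpp::export]]
List cpp_measure_grad(NumericMatrix X, List rf) {
  RSet s = unpack(rf);
  int n = X.nrow();
  List mv = cpp_measure(X, rf);
  NumericMatrix Gd(s.nd, 3 * n), Gt(s.nt, 3 * n), Gg(s.ng, 3 * n);
  for (int k = 0; k < s.nd; ++k) {
    NumericMatrix F(n, 3);
    group_dist(X, s, k, -1.0, &F);      // F holds +dD/dx
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) Gd(k, 3 * i + c) = F(i, c);
  }
  for (int k = 0; k < s.nt; ++k) {
    V3 ga, gb, gc; bool ok;
    int v = s.tv[k];
    angle_rad(getv(X, v - 1), getv(X, v), getv(X, v + 1), ga, gb, gc, ok);
    if (!ok) continue;
    V3 gr[3] = {ga, gb, gc};
    int ids[3] = {v - 1, v, v + 1};
    for (int q = 0; q < 3; ++q) {
      Gt(k, 3 * ids[q] + 0) = gr[q].x * R2DEG;
      Gt(k, 3 * ids[q] + 1) = gr[q].y * R2DEG;
      Gt(k, 3 * ids[q] + 2) = gr[q].z * R2DEG;
    }
  }
  for (int k = 0; k < s.ng; ++k) {
    V3 ga, gb, gc, gd; bool ok;
    int b = s.gb[k];
    dihedral_rad(getv(X, b - 1), getv(X, b), getv(X, b + 1), getv(X, b + 2),
                 ga, gb, gc, gd, ok);
    if (!ok) continue;
    V3 gr[4] = {ga, gb, gc, gd};
    int ids[4] = {b - 1, b, b + 1, b + 2};
    for (int q = 0; q < 4; ++q) {
      Gg(k, 3 * ids[q] + 0) = gr[q].x * R2DEG;
      Gg(k, 3 * ids[q] + 1) = gr[q].y * R2DEG;
      Gg(k, 3 * ids[q] + 2) = gr[q].z * R2DEG;
    }
  }
  return List::create(_["values"] = mv, _["dist"] = Gd, _["theta"] = Gt,
                      _["gamma"] = Gg);
}

// instantaneous restraint energy and forces
// [[Rcpp::export]]
List cpp_inst_restraint(NumericMatrix X, List rf) {
  RSet s = unpack(rf);
  int n = X.nrow();
  NumericMatrix F(n, 3);
  double E = 0.0;
  for (int k = 0; k < s.nd; ++k) {
    double d = group_dist(X, s, k, 0.0, nullptr);
    double V, dV;
    pen_dist(d, s.dl[k], s.du[k], s.A[k], s.sig[k], s.kap[k], V, dV);
    E += V;
    if (dV != 0.0) group_dist(X, s, k, dV, &F);
  }
  for (int k = 0; k < s.nt; ++k) {
    V3 ga, gb, gc; bool ok;
    int v = s.tv[k];
    double th = angle_rad(getv(X, v - 1), getv(X, v), getv(X, v + 1), ga, gb, gc, ok) * R2DEG;
    if (!ok) continue;                  // degenerate angle: restraint skipped
    double V, dV;
    pen_flat(th, s.tl[k], s.tu[k], s.At[k], s.sigt[k], V, dV);
    E += V;
    double pref = dV * R2DEG;
    addto(F, v - 1, ga, -pref); addto(F, v, gb, -pref); addto(F, v + 1, gc, -pref);
  }
  for (int k = 0; k < s.ng; ++k) {
    V3 ga, gb, gc, gd; bool ok;
    int b = s.gb[k];
    double gm = dihedral_rad(getv(X, b - 1), getv(X, b), getv(X, b + 1), getv(X, b + 2),
                             ga, gb, gc, gd, ok) * R2DEG;
    if (!ok) continue;
    double V, dV;
    pen_gamma(gm, s.gl[k], s.gu[k], s.Ag[k], s.sigg[k], V, dV);
    E += V;
    double pref = dV * R2DEG;
    addto(F, b - 1, ga, -pref); addto(F, b, gb, -pref);
    addto(F, b + 1, gc, -pref); addto(F, b + 2, gd, -pref);
  }
  return List::create(_["energy"] = E, _["forces"] = F);
}

// ---------------------------------------------------------------------------
// time-averaging state (internal ring-buffer mirror of the R list state)

struct TavgCore {
  double tau, dt, a, w_evict;   // a = n_ave*dt/tau
  int n_ave, N_tau, K_max;
  long long i; long long I;
  double f_max;
  int nd, nt, ng;
  // ring buffers of committed block averages, newest at (head-1)
  std::vector<double> rd, rt, rg_s, rg_c, rt_frac, rg_frac;
  int head, count;
  // recursive weighted sums (numerators) and weights (denominators)
  std::vector<double> Nd, Nt, Ns, Nc, Wt, Wg;
  double Wd;
  // current-block accumulators
  std::vector<double> ad, at, as, ac;
  std::vector<int> ant, ang;
  int acc_steps;
  int commits_since_refresh;

  double &R(std::vector<double> &buf, int nr, int k, int r) {
    // k = 1..count blocks back
    int col = head - k; if (col < 0) col += K_max;
    return buf[(size_t)col * nr + r];
  }

  void refresh() {
    // exact recompute of the recursive sums from the ring (fp-drift control)
    Wd = 0.0;
    std::fill(Nd.begin(), Nd.end(), 0.0);
    std::fill(Nt.begin(), Nt.end(), 0.0);
    std::fill(Ns.begin(), Ns.end(), 0.0);
    std::fill(Nc.begin(), Nc.end(), 0.0);
    std::fill(Wt.begin(), Wt.end(), 0.0);
    std::fill(Wg.begin(), Wg.end(), 0.0);
    for (int k = 1; k <= count; ++k) {
      double w = std::exp(-a * k);
      Wd += w;
      for (int r = 0; r < nd; ++r) Nd[r] += w * R(rd, nd, k, r);
      for (int r = 0; r < nt; ++r) {
        double f = R(rt_frac, nt, k, r);
        Wt[r] += w * f; Nt[r] += w * f * R(rt, nt, k, r);
      }
      for (int r = 0; r < ng; ++r) {
        double f = R(rg_frac, ng, k, r);
        Wg[r] += w * f;
        Ns[r] += w * f * R(rg_s, ng, k, r);
        Nc[r] += w * f * R(rg_c, ng, k, r);
      }
    }
    commits_since_refresh = 0;
  }

  // The weighted window sums are recomputed exactly from the ring at every
  // commit (instead of a decay-and-subtract recursion) so that a run resumed
  // from a checkpoint is bit-identical to an uninterrupted one.
  void commit() {
    // block simple averages
    std::vector<double> bd(nd), bt(nt, 0.0), bs(ng, 0.0), bc(ng, 0.0),
        ft(nt, 0.0), fg(ng, 0.0);
    for (int r = 0; r < nd; ++r) bd[r] = ad[r] / n_ave;
    for (int r = 0; r < nt; ++r)
      if (ant[r] > 0) { bt[r] = at[r] / ant[r]; ft[r] = (double)ant[r] / n_ave; }
    for (int r = 0; r < ng; ++r)
      if (ang[r] > 0) {
        bs[r] = as[r] / ang[r]; bc[r] = ac[r] / ang[r];
        fg[r] = (double)ang[r] / n_ave;
      }
    // evict the block that leaves the window, push the new one into the ring
    if (count == K_max) count--;
    for (int r = 0; r < nd; ++r) rd[(size_t)head * nd + r] = bd[r];
    for (int r = 0; r < nt; ++r) {
      rt[(size_t)head * nt + r] = bt[r];
      rt_frac[(size_t)head * nt + r] = ft[r];
    }
    for (int r = 0; r < ng; ++r) {
      rg_s[(size_t)head * ng + r] = bs[r];
      rg_c[(size_t)head * ng + r] = bc[r];
      rg_frac[(size_t)head * ng + r] = fg[r];
    }
    head = (head + 1) % K_max;
    count++;
    I++;
    std::fill(ad.begin(), ad.end(), 0.0);
    std::fill(at.begin(), at.end(), 0.0);
    std::fill(as.begin(), as.end(), 0.0);
    std::fill(ac.begin(), ac.end(), 0.0);
    std::fill(ant.begin(), ant.end(), 0);
    std::fill(ang.begin(), ang.end(), 0);
    acc_steps = 0;
    refresh();
  }

  double f_at(long long step) const {
    if (N_tau <= 0 || step >= N_tau) return f_max;
    return 1.0 + (f_max - 1.0) * ((double)step / (double)N_tau);
  }
};

static TavgCore tavg_from_r(List st) {
  TavgCore c;
  c.tau = st["tau"]; c.dt = st["dt"]; c.n_ave = st["n_ave"];
  c.N_tau = st["N_tau"]; c.K_max = st["K_max"]; c.f_max = st["f_max"];
  c.a = c.n_ave * c.dt / c.tau;
  c.i = (long long)as<double>(st["i"]); c.I = (long long)as<double>(st["I"]);
  NumericMatrix hd = st["hist_d"], ht = st["hist_theta"], hs = st["hist_sin"],
      hc = st["hist_cos"], hft = st["hist_frac_theta"], hfg = st["hist_frac_gamma"];
  c.nd = hd.nrow(); c.nt = ht.nrow(); c.ng = hs.nrow();
  int nb = hd.ncol();  // committed blocks, newest first
  c.count = nb;
  c.head = nb % c.K_max;
  size_t K = (size_t)c.K_max;
  c.rd.assign(K * c.nd, 0.0); c.rt.assign(K * c.nt, 0.0);
  c.rg_s.assign(K * c.ng, 0.0); c.rg_c.assign(K * c.ng, 0.0);
  c.rt_frac.assign(K * c.nt, 0.0); c.rg_frac.assign(K * c.ng, 0.0);
  // column j (0-based) of hist = block j+1 back => ring col head-1-j
  for (int j = 0; j < nb; ++j) {
    int col = c.head - 1 - j; if (col < 0) col += c.K_max;
    for (int r = 0; r < c.nd; ++r) c.rd[(size_t)col * c.nd + r] = hd(r, j);
    for (int r = 0; r < c.nt; ++r) {
      c.rt[(size_t)col * c.nt + r] = ht(r, j);
      c.rt_frac[(size_t)col * c.nt + r] = hft(r, j);
    }
    for (int r = 0; r < c.ng; ++r) {
      c.rg_s[(size_t)col * c.ng + r] = hs(r, j);
      c.rg_c[(size_t)col * c.ng + r] = hc(r, j);
      c.rg_frac[(size_t)col * c.ng + r] = hfg(r, j);
    }
  }
  c.Nd.assign(c.nd, 0.0); c.Nt.assign(c.nt, 0.0);
  c.Ns.assign(c.ng, 0.0); c.Nc.assign(c.ng, 0.0);
  c.Wt.assign(c.nt, 0.0); c.Wg.assign(c.ng, 0.0);
  c.refresh();
  NumericVector ad = st["acc_d"], at = st["acc_theta"], as_ = st["acc_sin"],
      ac = st["acc_cos"];
  IntegerVector ant = st["acc_n_theta"], ang = st["acc_n_gamma"];
  c.ad.assign(ad.begin(), ad.end()); c.at.assign(at.begin(), at.end());
  c.as.assign(as_.begin(), as_.end()); c.ac.assign(ac.begin(), ac.end());
  c.ant.assign(ant.begin(), ant.end()); c.ang.assign(ang.begin(), ang.end());
  c.acc_steps = st["acc_steps"];
  return c;
}

static List tavg_to_r(const TavgCore &c, List proto) {
  List st = clone(proto);
  st["i"] = (double)c.i; st["I"] = (double)c.I;
  int nb = c.count;
  NumericMatrix hd(c.nd, nb), ht(c.nt, nb), hs(c.ng, nb), hc(c.ng, nb),
      hft(c.nt, nb), hfg(c.ng, nb);
  TavgCore &cc = const_cast<TavgCore &>(c);
  for (int j = 0; j < nb; ++j) {
    for (int r = 0; r < c.nd; ++r) hd(r, j) = cc.R(cc.rd, c.nd, j + 1, r);
    for (int r = 0; r < c.nt; ++r) {
      ht(r, j) = cc.R(cc.rt, c.nt, j + 1, r);
      hft(r, j) = cc.R(cc.rt_frac, c.nt, j + 1, r);
    }
    for (int r = 0; r < c.ng; ++r) {
      hs(r, j) = cc.R(cc.rg_s, c.ng, j + 1, r);
      hc(r, j) = cc.R(cc.rg_c, c.ng, j + 1, r);
      hfg(r, j) = cc.R(cc.rg_frac, c.ng, j + 1, r);
    }
  }
  st["hist_d"] = hd; st["hist_theta"] = ht; st["hist_sin"] = hs;
  st["hist_cos"] = hc; st["hist_frac_theta"] = hft; st["hist_frac_gamma"] = hfg;
  st["acc_d"] = NumericVector(c.ad.begin(), c.ad.end());
  st["acc_theta"] = NumericVector(c.at.begin(), c.at.end());
  st["acc_sin"] = NumericVector(c.as.begin(), c.as.end());
  st["acc_cos"] = NumericVector(c.ac.begin(), c.ac.end());
  st["acc_n_theta"] = IntegerVector(c.ant.begin(), c.ant.end());
  st["acc_n_gamma"] = IntegerVector(c.ang.begin(), c.ang.end());
  st["acc_steps"] = c.acc_steps;
  return st;
}

// time-averaged restraint energy (unscaled) and scaled forces at the current
// coordinates, given the committed history in the state
static double tavg_energy_forces(const NumericMatrix &X, const RSet &s,
                                 TavgCore &c, double f_i, NumericMatrix &F,
                                 bool add_forces) {
  double E = 0.0;
  for (int k = 0; k < s.nd; ++k) {
    double y = group_dist(X, s, k, 0.0, nullptr);
    if (y <= 0) stop("non-positive restrained distance");
    double w0 = 1.0, W = c.Wd + w0;
    // distances average y^{-m} with m = 3; ybar = <y^-3>^{-1/3}
    double S = (c.Nd[k] + w0 * std::pow(y, -3.0)) / W;
    double ybar = std::pow(S, -1.0 / 3.0);
    double V, dV;
    pen_dist(ybar, s.dl[k], s.du[k], s.A[k], s.sig[k], s.kap[k], V, dV);
    E += V;
    if (add_forces && dV != 0.0) {
      // dybar/dy = (w0/W) * (ybar/y)^4  (momentary-term weight, Eq-14 form)
      double dybar_dy = (w0 / W) * std::pow(ybar / y, 4.0);
      group_dist(X, s, k, f_i * dV * dybar_dy, &F);
    }
  }
  for (int k = 0; k < s.nt; ++k) {
    V3 ga, gb, gc; bool ok;
    int v = s.tv[k];
    double y = angle_rad(getv(X, v - 1), getv(X, v), getv(X, v + 1), ga, gb, gc, ok) * R2DEG;
    double w0 = ok ? 1.0 : 0.0;
    double W = c.Wt[k] + w0;
    if (W <= 0) continue;
    double ybar = (c.Nt[k] + w0 * y) / W;
    double V, dV;
    pen_flat(ybar, s.tl[k], s.tu[k], s.At[k], s.sigt[k], V, dV);
    E += V;
    if (add_forces && ok && dV != 0.0) {
      double pref = f_i * dV * (w0 / W) * R2DEG;
      addto(F, v - 1, ga, -pref); addto(F, v, gb, -pref); addto(F, v + 1, gc, -pref);
    }
  }
  for (int k = 0; k < s.ng; ++k) {
    V3 ga, gb, gc, gd; bool ok;
    int b = s.gb[k];
    double yrad = dihedral_rad(getv(X, b - 1), getv(X, b), getv(X, b + 1),
                               getv(X, b + 2), ga, gb, gc, gd, ok);
    double w0 = ok ? 1.0 : 0.0;
    double W = c.Wg[k] + w0;
    if (W <= 0) continue;
    double Sbar = (c.Ns[k] + w0 * std::sin(yrad)) / W;
    double Cbar = (c.Nc[k] + w0 * std::cos(yrad)) / W;
    if (Sbar == 0 && Cbar == 0) continue;
    double ybar = std::atan2(Sbar, Cbar) * R2DEG;
    double V, dV;
    pen_gamma(ybar, s.gl[k], s.gu[k], s.Ag[k], s.sigg[k], V, dV);
    E += V;
    if (add_forces && ok && dV != 0.0) {
      // d(ybar)/d(y) with ybar, y in the same angular unit
      double dyb = (w0 / W) * (Cbar * std::cos(yrad) + Sbar * std::sin(yrad)) /
                   (Sbar * Sbar + Cbar * Cbar);
      double pref = f_i * dV * dyb * R2DEG;
      addto(F, b - 1, ga, -pref); addto(F, b, gb, -pref);
      addto(F, b + 1, gc, -pref); addto(F, b + 2, gd, -pref);
    }
  }
  return E;
}

static void tavg_accumulate(const NumericMatrix &X, const RSet &s, TavgCore &c) {
  for (int k = 0; k < s.nd; ++k) {
    double y = group_dist(X, s, k, 0.0, nullptr);
    if (y <= 0) stop("non-positive restrained distance in accumulation");
    c.ad[k] += 1.0 / (y * y * y);
  }
  for (int k = 0; k < s.nt; ++k) {
    V3 ga, gb, gc; bool ok;
    int v = s.tv[k];
    double y = angle_rad(getv(X, v - 1), getv(X, v), getv(X, v + 1), ga, gb, gc, ok) * R2DEG;
    if (ok) { c.at[k] += y; c.ant[k]++; }
  }
  for (int k = 0; k < s.ng; ++k) {
    V3 ga, gb, gc, gd; bool ok;
    int b = s.gb[k];
    double y = dihedral_rad(getv(X, b - 1), getv(X, b), getv(X, b + 1),
                            getv(X, b + 2), ga, gb, gc, gd, ok);
    if (ok) { c.as[k] += std::sin(y); c.ac[k] += std::cos(y); c.ang[k]++; }
  }
  c.acc_steps++;
  c.i++;
  if (c.acc_steps == c.n_ave) c.commit();
}

// ---------------------------------------------------------------------------
// MD driver.  thermostat: 0 none (NVE), 1 Langevin (BAOAB), 2 Berendsen.
// restraint mode: 0 none, 1 instantaneous, 2 time-averaged.

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix coords0, NumericMatrix vel0, List ff, List rf,
                List cfg, List tstate) {
  int n = coords0.nrow();
  NumericMatrix X = clone(coords0), Vl = clone(vel0);
  NumericVector masses = cfg["masses"];
  double dt = cfg["dt"];
  int n_steps = cfg["n_steps"], save_every = cfg["save_every"],
      energy_every = cfg["energy_every"];
  int mode = cfg["mode"], thermo = cfg["thermo"];
  double T_bath = cfg["T_bath"], gamma_fs = cfg["gamma"], tau_b = cfg["tau_b"];
  bool scale_energy = cfg["scale_energy"];
  double blowup = cfg["blowup"];
  int ndof = cfg["ndof"];

  RSet s{};
  bool have_r = mode > 0;
  if (have_r) s = unpack(rf);
  bool tavg = (mode == 2);
  TavgCore tc;
  if (tavg) tc = tavg_from_r(tstate);

  // Langevin OU coefficients
  double c1 = 1.0, c2k = 0.0;
  bool do_ou = (thermo == 1 && gamma_fs > 0);
  if (do_ou) {
    c1 = std::exp(-gamma_fs * dt);
    c2k = KB * T_bath * KCAL * (1.0 - c1 * c1);  // * 1/m later
  }

  int n_esave = (energy_every > 0) ? n_steps / energy_every : 0;
  int n_xsave = (save_every > 0) ? n_steps / save_every : 0;
  NumericMatrix Eser(n_esave, 7);  // E_pot E_restr E_kin E_total T_kin f_i time_ps
  NumericVector traj(n_xsave > 0 ? (size_t)n_xsave * n * 3 : 0);
  IntegerVector traj_steps(n_xsave), e_steps(n_esave);

  NumericMatrix F(n, 3);
  double E_toy = 0.0, E_r = 0.0, f_i = 1.0;

  // force evaluation at current X
  auto eval_forces = [&](void) {
    std::fill(F.begin(), F.end(), 0.0);
    List tf = cpp_toy_energy_forces(X, ff);
    E_toy = tf["energy"];
    NumericMatrix Ft = tf["forces"];
    for (int q = 0; q < 3 * n; ++q) F[q] += Ft[q];
    E_r = 0.0;
    if (mode == 1) {
      List rr = cpp_inst_restraint(X, rf);
      E_r = rr["energy"];
      NumericMatrix Fr = rr["forces"];
      for (int q = 0; q < 3 * n; ++q) F[q] += Fr[q];
    } else if (mode == 2) {
      f_i = tc.f_at(tc.i);
      E_r = tavg_energy_forces(X, s, tc, f_i, F, true);
    }
  };

  // seed the averaging with the initial configuration of a fresh run
  if (tavg && tc.i == 0) tavg_accumulate(X, s, tc);

  eval_forces();
  int ei = 0, xi = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int b = 0; b < n; ++b) {
      double am = KCAL / masses[b] * 0.5 * dt;
      Vl(b, 0) += am * F(b, 0); Vl(b, 1) += am * F(b, 1); Vl(b, 2) += am * F(b, 2);
    }
    if (do_ou) {
      // A: half drift, O: OU velocity update, A: half drift
      for (int b = 0; b < n; ++b)
        for (int q = 0; q < 3; ++q) X(b, q) += 0.5 * dt * Vl(b, q);
      for (int b = 0; b < n; ++b) {
        double c2 = std::sqrt(c2k / masses[b]);
        for (int q = 0; q < 3; ++q)
          Vl(b, q) = c1 * Vl(b, q) + c2 * R::norm_rand();
      }
      for (int b = 0; b < n; ++b)
        for (int q = 0; q < 3; ++q) X(b, q) += 0.5 * dt * Vl(b, q);
    } else {
      for (int b = 0; b < n; ++b)
        for (int q = 0; q < 3; ++q) X(b, q) += dt * Vl(b, q);
    }
    eval_forces();
    for (int b = 0; b < n; ++b) {
      double am = KCAL / masses[b] * 0.5 * dt;
      Vl(b, 0) += am * F(b, 0); Vl(b, 1) += am * F(b, 1); Vl(b, 2) += am * F(b, 2);
    }
    // kinetic energy / temperature
    double ke = 0.0;
    for (int b = 0; b < n; ++b)
      ke += 0.5 * masses[b] * (Vl(b, 0) * Vl(b, 0) + Vl(b, 1) * Vl(b, 1) + Vl(b, 2) * Vl(b, 2));
    ke /= KCAL;
    double T_kin = 2.0 * ke / (KB * ndof);
    if (thermo == 2 && T_kin > 0) {
      double lam = std::sqrt(1.0 + (dt / tau_b) * (T_bath / T_kin - 1.0));
      for (int q = 0; q < 3 * n; ++q) Vl[q] *= lam;
      ke *= lam * lam;
      T_kin = 2.0 * ke / (KB * ndof);
    }
    // accumulate the restrained quantities at the new configuration
    if (tavg) {
      tavg_accumulate(X, s, tc);
      // committed history may have changed; the next force evaluation at the
      // start of the following step uses it (forces here already consistent)
      if (tc.acc_steps == 0) eval_forces();  // just committed: refresh E_r/F
    }
    // blow-up detection
    bool bad = !std::isfinite(E_toy) || !std::isfinite(E_r) || !std::isfinite(ke);
    if (!bad)
      for (int q = 0; q < 3 * n && !bad; ++q)
        if (!std::isfinite(X[q]) || std::fabs(X[q]) > blowup) bad = true;
    if (bad) stop("trajectory blew up at step %d (non-finite or |coordinate| > %g A)",
                  step, blowup);
    if (energy_every > 0 && step % energy_every == 0 && ei < n_esave) {
      double er_rep = (mode == 2 && scale_energy) ? f_i * E_r : E_r;
      Eser(ei, 0) = E_toy; Eser(ei, 1) = E_r; Eser(ei, 2) = ke;
      Eser(ei, 3) = E_toy + er_rep + ke; Eser(ei, 4) = T_kin;
      Eser(ei, 5) = (mode == 2) ? f_i : 1.0; Eser(ei, 6) = step * dt * 1e-3;
      e_steps[ei] = step;
      ei++;
    }
    if (save_every > 0 && step % save_every == 0 && xi < n_xsave) {
      for (int b = 0; b < n; ++b)
        for (int q = 0; q < 3; ++q) traj[(size_t)xi * n * 3 + (size_t)q * n + b] = X(b, q);
      traj_steps[xi] = step;
      xi++;
    }
  }

  List out = List::create(
      _["coords"] = X, _["velocities"] = Vl,
      _["energies"] = Eser, _["energy_steps"] = e_steps,
      _["traj"] = traj, _["traj_steps"] = traj_steps, _["n_saved"] = xi);
  if (tavg) out["tavg_state"] = tavg_to_r(tc, tstate);
  return out;
}

// single-point time-averaged forces/energy for the R-level wrapper
// [[Rcpp::export]]
List cpp_tavg_forces(NumericMatrix X, List rf, List tstate, bool scale_energy) {
  RSet s = unpack(rf);
  TavgCore tc = tavg_from_r(tstate);
  int n = X.nrow();
  NumericMatrix F(n, 3);
  double f_i = tc.f_at(tc.i);
  double E = tavg_energy_forces(X, s, tc, f_i, F, true);
  return List::create(_["energy"] = E, _["forces"] = F, _["f"] = f_i,
                      _["energy_scaled"] = scale_energy ? f_i * E : E);
}
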