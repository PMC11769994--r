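// Core numerics for the planar walking model:
//  - 7-segment / 9-DOF skeleton equations of motion (Jacobian assembly)
//  - Hill-type muscle-tendon geometry and contraction dynamics
//  - heel/toe ground contact (damped quadratic spring + smoothed Coulomb)
//  - fixed-step RK4 forward simulation of the coupled system
//
// Generalized coordinates q (9):
//   0: x of hip joint [m]   1: y of hip joint [m]   2: HAT angle phi [rad, CCW]
//   3: hip R   4: knee R   5: ankle R   6: hip L   7: knee L   8: ankle L
// Joint angles are distal-minus-proximal segment angles (hip flexion +,
// knee extension +, ankle dorsiflexion +). Segment angles are CCW from
// vertical; x is the direction of travel, y is up, ground at y = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NQ = 9;
static const int NM = 18;

// dependency masks: which q-coords each segment angle depends on
// segments: 0 HAT, 1 thighR, 2 shankR, 3 footR, 4 thighL, 5 shankL, 6 footL
static const int DEP[7] = {
  1 << 2,
  (1 << 2) | (1 << 3),
  (1 << 2) | (1 << 3) | (1 << 4),
  (1 << 2) | (1 << 3) | (1 << 4) | (1 << 5),
  (1 << 2) | (1 << 6),
  (1 << 2) | (1 << 6) | (1 << 7),
  (1 << 2) | (1 << 6) | (1 << 7) | (1 << 8)
};

struct Skel {
  double m[7], I[7];
  double Lt, Ls, cH, ct, cs;
  double heelx, heely, toex, toey, fcomx, fcomy;
  double g;
};

static Skel parse_skel(const List& sk) {
  Skel S;
  NumericVector m = sk["m"], I = sk["I"];
  for (int i = 0; i < 7; i++) { S.m[i] = m[i]; S.I[i] = I[i]; }
  S.Lt = sk["Lt"]; S.Ls = sk["Ls"];
  S.cH = sk["cH"]; S.ct = sk["ct"]; S.cs = sk["cs"];
  NumericVector h = sk["heel"], t = sk["toe"], fc = sk["footcom"];
  S.heelx = h[0]; S.heely = h[1]; S.toex = t[0]; S.toey = t[1];
  S.fcomx = fc[0]; S.fcomy = fc[1];
  S.g = sk["g"];
  return S;
}

static inline void seg_angles(const double* q, double* th) {
  th[0] = q[2];
  th[1] = q[2] + q[3]; th[2] = th[1] + q[4]; th[3] = th[2] + q[5];
  th[4] = q[2] + q[6]; th[5] = th[4] + q[7]; th[6] = th[5] + q[8];
}
static inline void seg_omegas(const double* qd, double* om) {
  om[0] = qd[2];
  om[1] = qd[2] + qd[3]; om[2] = om[1] + qd[4]; om[3] = om[2] + qd[5];
  om[4] = qd[2] + qd[6]; om[5] = om[4] + qd[7]; om[6] = om[5] + qd[8];
}

// chain of (segment-angle index, local vector) from hip to a point on seg s
struct Chain { int n; int seg[3]; double vx[3], vy[3]; };

static Chain point_chain(const Skel& S, int s, double lx, double ly) {
  Chain c; c.n = 0;
  auto add = [&](int a, double x, double y) {
    c.seg[c.n] = a; c.vx[c.n] = x; c.vy[c.n] = y; c.n++;
  };
  switch (s) {
  case 0: add(0, lx, ly); break;
  case 1: add(1, lx, ly); break;
  case 2: add(1, 0, -S.Lt); add(2, lx, ly); break;
  case 3: add(1, 0, -S.Lt); add(2, 0, -S.Ls); add(3, lx, ly); break;
  case 4: add(4, lx, ly); break;
  case 5: add(4, 0, -S.Lt); add(5, lx, ly); break;
  case 6: add(4, 0, -S.Lt); add(5, 0, -S.Ls); add(6, lx, ly); break;
  }
  return c;
}

// position, 2x9 jacobian and acceleration bias (Jdot*qd) of a chain point;
// velocity is J * qd, computed by callers
static void point_eval(const Chain& c, const double* q, const double* th,
                       const double* om, double* pos, arma::mat* J,
                       double* ab) {
  double px = q[0], py = q[1];
  double ax = 0, ay = 0;
  if (J) { J->zeros(); (*J)(0, 0) = 1.0; (*J)(1, 1) = 1.0; }
  for (int k = 0; k < c.n; k++) {
    int a = c.seg[k];
    double ct = std::cos(th[a]), st = std::sin(th[a]);
    double rx = ct * c.vx[k] - st * c.vy[k];
    double ry = st * c.vx[k] + ct * c.vy[k];
    px += rx; py += ry;
    double wx = -ry, wy = rx;            // perp(r)
    if (ab)  { ax -= om[a] * om[a] * rx; ay -= om[a] * om[a] * ry; }
    if (J) {
      int dep = DEP[a];
      for (int cc = 2; cc < NQ; cc++)
        if (dep & (1 << cc)) { (*J)(0, cc) += wx; (*J)(1, cc) += wy; }
    }
  }
  pos[0] = px; pos[1] = py;
  if (ab) { ab[0] = ax; ab[1] = ay; }
}

// segment CoM local vectors
static void com_local(const Skel& S, int s, double* lx, double* ly) {
  switch (s) {
  case 0: *lx = 0; *ly = S.cH; break;
  case 1: case 4: *lx = 0; *ly = -S.ct; break;
  case 2: case 5: *lx = 0; *ly = -S.cs; break;
  case 3: case 6: *lx = S.fcomx; *ly = S.fcomy; break;
  }
}

struct ExtForce { int seg; double lx, ly, fx, fy; };

// M(q) qdd = Q  -> qdd.  Qjoint: applied moments on coords 3..8.
static arma::vec eom_solve(const Skel& S, const double* q, const double* qd,
                           const double* Qjoint,
                           const std::vector<ExtForce>& ext) {
  double th[7], om[7];
  seg_angles(q, th); seg_omegas(qd, om);
  arma::mat M(NQ, NQ, arma::fill::zeros);
  arma::vec rhs(NQ, arma::fill::zeros);
  arma::mat J(2, NQ);
  double pos[2], ab[2];
  for (int s = 0; s < 7; s++) {
    double lx, ly; com_local(S, s, &lx, &ly);
    Chain c = point_chain(S, s, lx, ly);
    point_eval(c, q, th, om, pos, &J, ab);
    M += S.m[s] * (J.t() * J);
    int dep = DEP[s];
    for (int i = 2; i < NQ; i++)
      if (dep & (1 << i))
        for (int j = 2; j < NQ; j++)
          if (dep & (1 << j)) M(i, j) += S.I[s];
    arma::vec f(2);
    f(0) = -S.m[s] * ab[0];
    f(1) = -S.m[s] * (ab[1] + S.g);   // gravity enters as force (0, -m g)
    rhs += J.t() * f;
  }
  for (int j = 0; j < 6; j++) rhs(3 + j) += Qjoint[j];
  for (size_t k = 0; k < ext.size(); k++) {
    Chain c = point_chain(S, ext[k].seg, ext[k].lx, ext[k].ly);
    point_eval(c, q, th, om, pos, &J, nullptr);
    arma::vec f(2); f(0) = ext[k].fx; f(1) = ext[k].fy;
    rhs += J.t() * f;
  }
  arma::vec qdd;
  bool ok = arma::solve(qdd, M, rhs, arma::solve_opts::likely_sympd);
  if (!ok) stop("singular mass matrix");
  return qdd;
}

// ---------------------------------------------------------------- contact ---

struct ContactP { double kz, cd, mu, vs; };

static inline void contact_f(const ContactP& C, double pen, double pend,
                             double vt, double* fx, double* fy) {
  double Fy = 0.0;
  if (pen > 0.0) {
    Fy = C.kz * pen * pen * (1.0 + C.cd * pend);
    if (Fy < 0.0) Fy = 0.0;
  }
  *fy = Fy;
  *fx = -C.mu * Fy * std::tanh(vt / C.vs);
}

// ----------------------------------------------------------------- curves ---

struct CurveP {
  double gw;                 // active fl gaussian width
  double kpe, e0;            // passive fl
  double eps0, Ftoe, ktoe, epstoe, klin;   // tendon
  double af, fecc, gecc;     // force-velocity
  double vclo, vchi;         // normalized CE velocity clamp [lopt/s units of vmax]
};

static CurveP parse_curves(const NumericVector& cc) {
  CurveP P;
  P.gw = cc["gw"]; P.kpe = cc["kpe"]; P.e0 = cc["e0"];
  P.eps0 = cc["eps0"]; P.Ftoe = cc["Ftoe"]; P.ktoe = cc["ktoe"];
  P.epstoe = cc["epstoe"]; P.klin = cc["klin"];
  P.af = cc["af"]; P.fecc = cc["fecc"]; P.gecc = cc["gecc"];
  P.vclo = cc["vclo"]; P.vchi = cc["vchi"];
  return P;
}

static inline double fl_act(const CurveP& P, double lt) {
  double z = (lt - 1.0) / P.gw; return std::exp(-z * z);
}
static inline double fl_pas(const CurveP& P, double lt) {
  if (lt <= 1.0) return 0.0;
  return (std::exp(P.kpe * (lt - 1.0) / P.e0) - 1.0) / (std::exp(P.kpe) - 1.0);
}
static inline double f_ten(const CurveP& P, double eps) {
  if (eps <= 0.0) return 0.0;
  if (eps < P.epstoe)
    return P.Ftoe * (std::exp(P.ktoe * eps / P.epstoe) - 1.0) /
           (std::exp(P.ktoe) - 1.0);
  return P.klin * (eps - P.epstoe) + P.Ftoe;
}
static inline double fv_fwd(const CurveP& P, double vt) {
  // vt = ce velocity / (vmax * lopt), lengthening positive
  if (vt <= -1.0) return 0.0;
  if (vt <= 0.0) return (1.0 + vt) / (1.0 - vt / P.af);
  return 1.0 + (P.fecc - 1.0) * vt / (vt + P.gecc);
}
static inline double fv_inv(const CurveP& P, double phi, bool* clamped) {
  double vt;
  if (phi < 0.0) { vt = -1.0; if (clamped) *clamped = true; }
  else if (phi < 1.0) vt = (phi - 1.0) / (1.0 + phi / P.af);
  else {
    double ph = phi, cap = P.fecc - 0.01;
    if (ph > cap) { ph = cap; if (clamped) *clamped = true; }
    vt = P.gecc * (ph - 1.0) / (P.fecc - ph);
  }
  if (vt < P.vclo) { vt = P.vclo; if (clamped) *clamped = true; }
  if (vt > P.vchi) { vt = P.vchi; if (clamped) *clamped = true; }
  return vt;
}

// --------------------------------------------------------------- muscles ----

struct MusP {
  double fmax, lopt, penn, slack, vmax, tact, tdeact, mass, ftfrac;
};

struct MusPath { int n; int seg[3]; double lx[3], ly[3]; int span; };

struct MuscleSet {
  int n;
  std::vector<MusP> p;
  std::vector<MusPath> path;
};

static MuscleSet parse_muscles(const List& mus) {
  MuscleSet M;
  NumericMatrix par = mus["par"];   // n x 9
  List paths = mus["paths"];
  M.n = par.nrow();
  M.p.resize(M.n); M.path.resize(M.n);
  for (int i = 0; i < M.n; i++) {
    M.p[i].fmax = par(i, 0); M.p[i].lopt = par(i, 1); M.p[i].penn = par(i, 2);
    M.p[i].slack = par(i, 3); M.p[i].vmax = par(i, 4);
    M.p[i].tact = par(i, 5); M.p[i].tdeact = par(i, 6);
    M.p[i].mass = par(i, 7); M.p[i].ftfrac = par(i, 8);
    NumericMatrix pm = paths[i];    // npts x 3 (seg, lx, ly)
    M.path[i].n = pm.nrow();
    if (M.path[i].n < 2 || M.path[i].n > 3) stop("muscle path must have 2 or 3 points");
    for (int k = 0; k < M.path[i].n; k++) {
      M.path[i].seg[k] = (int) pm(k, 0);
      M.path[i].lx[k] = pm(k, 1); M.path[i].ly[k] = pm(k, 2);
    }
    int s0 = M.path[i].seg[0], s1 = M.path[i].seg[M.path[i].n - 1];
    M.path[i].span = (DEP[s1] & ~DEP[s0]) & ~(1 << 2);
    if ((DEP[s0] & ~DEP[s1]) & ~(1 << 2)) stop("muscle path must run proximal to distal");
  }
  return M;
}

// MTU length from joint angles only (independent of x, y, phi)
static double mtu_len(const Skel& S, const MusPath& mp, const double* q) {
  double th[7]; seg_angles(q, th);
  double L = 0.0, px = 0, py = 0, qx = 0, qy = 0, pos[2];
  double qq[NQ]; for (int i = 0; i < NQ; i++) qq[i] = q[i];
  qq[0] = 0; qq[1] = 0;
  for (int k = 0; k < mp.n; k++) {
    Chain c = point_chain(S, mp.seg[k], mp.lx[k], mp.ly[k]);
    point_eval(c, qq, th, nullptr, pos, nullptr, nullptr);
    qx = pos[0]; qy = pos[1];
    if (k > 0) {
      double d = std::sqrt((qx - px) * (qx - px) + (qy - py) * (qy - py));
      if (d < 1e-9) stop("degenerate (zero-length) muscle path segment");
      L += d;
    }
    px = qx; py = qy;
  }
  return L;
}

// lengths (n) and moment arms (n x 6, coords 3..8), central FD step h
static void muscle_geom(const Skel& S, const MuscleSet& M, const double* q,
                        double* len, double* arms /* n x 6 col-major */,
                        double h) {
  double qq[NQ]; for (int i = 0; i < NQ; i++) qq[i] = q[i];
  for (int i = 0; i < M.n; i++) {
    len[i] = mtu_len(S, M.path[i], qq);
    for (int j = 0; j < 6; j++) {
      int cc = 3 + j;
      double a = 0.0;
      if (M.path[i].span & (1 << cc)) {
        double keep = qq[cc];
        qq[cc] = keep + h; double lp = mtu_len(S, M.path[i], qq);
        qq[cc] = keep - h; double lm = mtu_len(S, M.path[i], qq);
        qq[cc] = keep;
        a = -(lp - lm) / (2.0 * h);
      }
      arms[i + M.n * j] = a;
    }
  }
}

// tendon force [N] and CE velocity [m/s] from the force-velocity inversion
static void mtu_dyn(const MusP& m, const CurveP& P, double a, double lce,
                    double lmtu, double* fsee, double* vce, bool* clamped) {
  double cosp = std::cos(m.penn);
  double lt = lce / m.lopt;
  if (lt < 0.2) lt = 0.2;
  if (lt > 1.9) lt = 1.9;
  double lse = lmtu - lce * cosp;
  double eps = lse / m.slack - 1.0;
  double ftn = f_ten(P, eps);              // tendon force / fmax
  double fla = fl_act(P, lt), flp = fl_pas(P, lt);
  double aa = a < 0.005 ? 0.005 : a;
  double denom = aa * fla;
  if (denom < 1e-4) denom = 1e-4;
  double phi = (ftn / cosp - flp) / denom;
  double vt = fv_inv(P, phi, clamped);
  *fsee = ftn * m.fmax;
  *vce = vt * m.vmax * m.lopt;
}

// isometric CE length: bisection on force balance at fixed lmtu, activation a
static double init_lce(const MusP& m, const CurveP& P, double a, double lmtu) {
  double cosp = std::cos(m.penn);
  auto resid = [&](double lce) {
    double lse = lmtu - lce * cosp;
    double ftn = f_ten(P, lse / m.slack - 1.0);
    double lt = lce / m.lopt;
    return ftn / cosp - (a * fl_act(P, lt) + fl_pas(P, lt));
  };
  double lo = 0.3 * m.lopt, hi = 1.7 * m.lopt;
  double flo = resid(lo), fhi = resid(hi);
  if (flo <= 0.0) {
    // tendon slack even at shortest CE: set CE to take up the slack
    double lce = (lmtu - m.slack) / cosp;
    if (lce < 0.5 * m.lopt) lce = 0.5 * m.lopt;
    if (lce > 1.6 * m.lopt) lce = 1.6 * m.lopt;
    return lce;
  }
  if (fhi >= 0.0) return hi;
  for (int it = 0; it < 70; it++) {
    double mid = 0.5 * (lo + hi), fm = resid(mid);
    if (fm > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ------------------------------------------------------ passive moments -----

struct PassiveP { double e1, s1, t1, e2, s2, t2, damp; };

static inline double passive_m(const PassiveP& p, double th, double thd) {
  return p.e1 * std::exp(-p.s1 * (th - p.t1))
       - p.e2 * std::exp(p.s2 * (th - p.t2))
       - p.damp * thd;
}

static void parse_passive(const NumericMatrix& pm, PassiveP* out) {
  // rows: hip, knee, ankle; cols: e1 s1 t1 e2 s2 t2 damp
  for (int i = 0; i < 3; i++) {
    out[i].e1 = pm(i, 0); out[i].s1 = pm(i, 1); out[i].t1 = pm(i, 2);
    out[i].e2 = pm(i, 3); out[i].s2 = pm(i, 4); out[i].t2 = pm(i, 5);
    out[i].damp = pm(i, 6);
  }
}

// ----------------------------------------------------------------- energy ---

// Umberger-flavored heat + positive CE work rate, W (>= 0)
static double energy_rate(const MusP& m, double u, double a, double lce,
                          double vce, double fsee, const CurveP& P) {
  double A = (u > a) ? u : 0.5 * (u + a);
  if (A <= 0.0) return 0.0;
  double am = std::pow(A, 0.6);
  double lt = lce / m.lopt;
  double fla = fl_act(P, lt);
  double f = m.ftfrac;
  double h_am = (128.0 * f + 25.0) * am;
  double vnorm = vce / m.lopt;              // lopt/s, lengthening +
  double vmax_st = m.vmax / 2.5;
  double a_st = 100.0 / vmax_st, a_ft = 153.0 / m.vmax;
  double h_sl;
  if (vnorm <= 0.0)
    h_sl = (a_st * (1.0 - f) + a_ft * f) * (-vnorm) * A * A * fla;
  else
    h_sl = a_st * vnorm * A * fla;
  double fce = fsee / std::cos(m.penn);
  double w = -fce * vce;                    // concentric work rate
  if (w < 0.0) w = 0.0;
  double hw = h_am + h_sl;
  if (hw < 0.0) hw = 0.0;
  return m.mass * hw + w;
}

// ------------------------------------------------------------- controller ---

struct Ctrl {
  double onset[9], offset[9], amp[9];
  double stride, baseline;
};

static Ctrl parse_ctrl(const List& pr) {
  Ctrl C;
  NumericVector on = pr["onset"], off = pr["offset"], am = pr["amplitude"];
  for (int i = 0; i < 9; i++) { C.onset[i] = on[i]; C.offset[i] = off[i]; C.amp[i] = am[i]; }
  C.stride = pr["stride_period"]; C.baseline = pr["baseline"];
  return C;
}

static inline double stim_right(const Ctrl& C, int i, double t) {
  double tt = t - C.stride * std::floor(t / C.stride);
  if (tt < 0) tt += C.stride;
  bool in;
  if (C.onset[i] <= C.offset[i]) in = (tt >= C.onset[i] && tt < C.offset[i]);
  else in = (tt >= C.onset[i] || tt < C.offset[i]);
  return in ? C.amp[i] : C.baseline;
}
static inline double stim_at(const Ctrl& C, int i, double t) {
  if (i < 9) return stim_right(C, i, t);
  return stim_right(C, i - 9, t - 0.5 * C.stride);
}

// ------------------------------------------------------------ Rcpp exports --

// [[Rcpp::export]]
arma::vec cpp_eom(const List& skel, const NumericVector& q,
                  const NumericVector& qd, const NumericVector& joint_moments,
                  const NumericMatrix& ext_forces) {
  Skel S = parse_skel(skel);
  std::vector<ExtForce> ext;
  for (int i = 0; i < ext_forces.nrow(); i++) {
    ExtForce e;
    e.seg = (int) ext_forces(i, 0);
    e.lx = ext_forces(i, 1); e.ly = ext_forces(i, 2);
    e.fx = ext_forces(i, 3); e.fy = ext_forces(i, 4);
    ext.push_back(e);
  }
  double Qj[6]; for (int j = 0; j < 6; j++) Qj[j] = joint_moments[j];
  return eom_solve(S, q.begin(), qd.begin(), Qj, ext);
}

// [[Rcpp::export]]
List cpp_kinematics(const List& skel, const NumericVector& q,
                    const NumericVector& qd) {
  Skel S = parse_skel(skel);
  double th[7], om[7];
  seg_angles(q.begin(), th); seg_omegas(qd.begin(), om);
  CharacterVector nm = CharacterVector::create(
    "hip", "kneeR", "ankleR", "heelR", "toeR",
    "kneeL", "ankleL", "heelL", "toeL",
    "comHAT", "comThighR", "comShankR", "comFootR",
    "comThighL", "comShankL", "comFootL", "head");
  int segid[17] = {0, 1, 2, 3, 3, 4, 5, 6, 6, 0, 1, 2, 3, 4, 5, 6, 0};
  double lxv[17], lyv[17];
  lxv[0] = 0; lyv[0] = 0;
  lxv[1] = 0; lyv[1] = -S.Lt; lxv[2] = 0; lyv[2] = -S.Ls;
  lxv[3] = S.heelx; lyv[3] = S.heely; lxv[4] = S.toex; lyv[4] = S.toey;
  lxv[5] = 0; lyv[5] = -S.Lt; lxv[6] = 0; lyv[6] = -S.Ls;
  lxv[7] = S.heelx; lyv[7] = S.heely; lxv[8] = S.toex; lyv[8] = S.toey;
  for (int s = 0; s < 7; s++) com_local(S, s, &lxv[9 + s], &lyv[9 + s]);
  lxv[16] = 0; lyv[16] = 2.0 * S.cH;   // head marker for plotting
  // special-case: hip point itself
  NumericMatrix pts(2, 17), vts(2, 17);
  double pos[2];
  arma::mat J(2, NQ);
  arma::vec qdv(const_cast<double*>(qd.begin()), NQ, false);
  for (int k = 0; k < 17; k++) {
    Chain c = (k == 0) ? point_chain(S, 0, 0, 0) : point_chain(S, segid[k], lxv[k], lyv[k]);
    if (k == 0) { c.n = 0; }
    point_eval(c, q.begin(), th, om, pos, &J, nullptr);
    pts(0, k) = pos[0]; pts(1, k) = pos[1];
    arma::vec v = J * qdv;
    vts(0, k) = v(0); vts(1, k) = v(1);
  }
  colnames(pts) = nm; colnames(vts) = nm;
  // whole-body CoM
  double M = 0, cx = 0, cy = 0, cvx = 0, cvy = 0;
  for (int s = 0; s < 7; s++) {
    M += S.m[s];
    cx += S.m[s] * pts(0, 9 + s); cy += S.m[s] * pts(1, 9 + s);
    cvx += S.m[s] * vts(0, 9 + s); cvy += S.m[s] * vts(1, 9 + s);
  }
  NumericVector segang(7);
  for (int s = 0; s < 7; s++) segang[s] = th[s];
  return List::create(_["points"] = pts, _["velocities"] = vts,
                      _["segment_angles"] = segang,
                      _["com"] = NumericVector::create(cx / M, cy / M),
                      _["vcom"] = NumericVector::create(cvx / M, cvy / M));
}

// [[Rcpp::export]]
List cpp_muscle_geometry(const List& skel, const List& muscles,
                         const NumericVector& q, double fd_step = 1e-5) {
  Skel S = parse_skel(skel);
  MuscleSet M = parse_muscles(muscles);
  std::vector<double> len(M.n), arms(M.n * 6);
  muscle_geom(S, M, q.begin(), len.data(), arms.data(), fd_step);
  NumericVector L(M.n);
  NumericMatrix A(M.n, 6);
  for (int i = 0; i < M.n; i++) {
    L[i] = len[i];
    for (int j = 0; j < 6; j++) A(i, j) = arms[i + M.n * j];
  }
  colnames(A) = CharacterVector::create("hip_R", "knee_R", "ankle_R",
                                        "hip_L", "knee_L", "ankle_L");
  return List::create(_["length"] = L, _["moment_arms"] = A);
}

// [[Rcpp::export]]
List cpp_mtu_dynamics(const NumericVector& mpar, const NumericVector& curves,
                      double activation, double ce_length, double mtu_length) {
  MusP m;
  m.fmax = mpar["fmax"]; m.lopt = mpar["lopt"]; m.penn = mpar["pennation"];
  m.slack = mpar["tendon_slack"]; m.vmax = mpar["vmax"];
  CurveP P = parse_curves(curves);
  double fsee, vce; bool cl = false;
  mtu_dyn(m, P, activation, ce_length, mtu_length, &fsee, &vce, &cl);
  return List::create(_["see_force"] = fsee, _["ce_velocity"] = vce,
                      _["clamped"] = cl);
}

// [[Rcpp::export]]
double cpp_init_lce(const NumericVector& mpar, const NumericVector& curves,
                    double activation, double mtu_length) {
  MusP m;
  m.fmax = mpar["fmax"]; m.lopt = mpar["lopt"]; m.penn = mpar["pennation"];
  m.slack = mpar["tendon_slack"]; m.vmax = mpar["vmax"];
  CurveP P = parse_curves(curves);
  return init_lce(m, P, activation, mtu_length);
}

// ------------------------------------------------------------- simulation ---

struct SimCtx {
  Skel S;
  MuscleSet M;
  ContactP C;
  CurveP P;
  PassiveP pass[3];
  Ctrl ctrl;
  double fd_step;
  // scratch/log
  double grf[8], epow, fsee_log[NM], stim_log[NM];
  int n_clamped;
};

// y layout: q(9) qd(9) a(18) lce(18)  => 54 states
static const int NY = 54;

static void derivs(SimCtx& X, double t, const double* y, double* dy,
                   bool record) {
  const double* q = y;
  const double* qd = y + 9;
  const double* a = y + 18;
  const double* lce = y + 36;
  // muscle geometry
  double len[NM], arms[NM * 6];
  muscle_geom(X.S, X.M, q, len, arms, X.fd_step);
  // stimulation + activation dynamics
  double Qj[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < X.M.n; i++) {
    double u = stim_at(X.ctrl, i, t);
    double ai = a[i]; if (ai < 0) ai = 0; if (ai > 1) ai = 1;
    double tau = (u >= ai) ? X.M.p[i].tact : X.M.p[i].tdeact;
    dy[18 + i] = (u - ai) / tau;
    double fsee, vce; bool cl = false;
    mtu_dyn(X.M.p[i], X.P, ai, lce[i], len[i], &fsee, &vce, &cl);
    dy[36 + i] = vce;
    for (int j = 0; j < 6; j++) {
      double r = arms[i + X.M.n * j];
      if (r != 0.0) Qj[j] += fsee * r;
    }
    if (record) {
      X.fsee_log[i] = fsee;
      X.stim_log[i] = u;
      X.epow += energy_rate(X.M.p[i], u, ai, lce[i], vce, fsee, X.P);
      if (cl) X.n_clamped++;
    }
  }
  // passive joint moments (hip, knee, ankle per side)
  for (int side = 0; side < 2; side++) {
    for (int j = 0; j < 3; j++) {
      int cc = 3 + 3 * side + j;
      Qj[3 * side + j] += passive_m(X.pass[j], q[cc], qd[cc]);
    }
  }
  // contact at heel/toe of each foot
  std::vector<ExtForce> ext;
  double th[7], om[7];
  seg_angles(q, th); seg_omegas(qd, om);
  int csegs[4] = {3, 3, 6, 6};
  double clx[4] = {X.S.heelx, X.S.toex, X.S.heelx, X.S.toex};
  double cly[4] = {X.S.heely, X.S.toey, X.S.heely, X.S.toey};
  for (int k = 0; k < 4; k++) {
    Chain c = point_chain(X.S, csegs[k], clx[k], cly[k]);
    double pos[2]; arma::mat J(2, NQ);
    point_eval(c, q, th, om, pos, &J, nullptr);
    arma::vec qdv(const_cast<double*>(qd), NQ, false);
    arma::vec v = J * qdv;
    double fx, fy;
    contact_f(X.C, -pos[1], -v(1), v(0), &fx, &fy);
    if (fx != 0.0 || fy != 0.0) {
      ExtForce e; e.seg = csegs[k]; e.lx = clx[k]; e.ly = cly[k];
      e.fx = fx; e.fy = fy;
      ext.push_back(e);
    }
    if (record) { X.grf[2 * k] = fx; X.grf[2 * k + 1] = fy; }
  }
  arma::vec qdd = eom_solve(X.S, q, qd, Qj, ext);
  for (int i = 0; i < 9; i++) { dy[i] = qd[i]; dy[9 + i] = qdd(i); }
}

// [[Rcpp::export]]
List cpp_simulate(const List& skel, const List& muscles,
                  const NumericVector& contact, const NumericMatrix& passive,
                  const List& profile, const NumericVector& curves,
                  const NumericVector& q0, const NumericVector& qd0,
                  const NumericVector& a0, const NumericVector& lce0,
                  double duration, double dt, double fall_height,
                  double fd_step = 1e-5) {
  SimCtx X;
  X.S = parse_skel(skel);
  X.M = parse_muscles(muscles);
  X.C.kz = contact["stiffness"]; X.C.cd = contact["damping_coefficient"];
  X.C.mu = contact["friction_coefficient"]; X.C.vs = contact["velocity_smoothing"];
  X.P = parse_curves(curves);
  parse_passive(passive, X.pass);
  X.ctrl = parse_ctrl(profile);
  X.fd_step = fd_step;
  X.n_clamped = 0;

  int nstep = (int) std::floor(duration / dt + 0.5);
  int nsamp = nstep + 1;
  double y[NY], k1[NY], k2[NY], k3[NY], k4[NY], yt[NY];
  for (int i = 0; i < 9; i++) { y[i] = q0[i]; y[9 + i] = qd0[i]; }
  for (int i = 0; i < NM; i++) { y[18 + i] = a0[i]; y[36 + i] = lce0[i]; }

  NumericVector time(nsamp);
  NumericMatrix Q(nsamp, 9), Qd(nsamp, 9), Act(nsamp, NM), Lce(nsamp, NM),
                Fsee(nsamp, NM), Grf(nsamp, 8), Stim(nsamp, NM);
  NumericVector Epow(nsamp);
  int status = 0;     // 0 completed, 1 fell, 2 diverged
  int ndone = 0;

  for (int s = 0; s < nsamp; s++) {
    double t = s * dt;
    // record state + instantaneous outputs (k1 evaluation)
    X.epow = 0.0;
    for (int k = 0; k < 8; k++) X.grf[k] = 0.0;
    bool finite = true;
    for (int i = 0; i < NY; i++) if (!std::isfinite(y[i])) finite = false;
    if (!finite) { status = 2; break; }
    derivs(X, t, y, k1, true);
    time[s] = t;
    for (int i = 0; i < 9; i++) { Q(s, i) = y[i]; Qd(s, i) = y[9 + i]; }
    for (int i = 0; i < NM; i++) {
      Act(s, i) = y[18 + i]; Lce(s, i) = y[36 + i];
      Fsee(s, i) = X.fsee_log[i]; Stim(s, i) = X.stim_log[i];
    }
    for (int k = 0; k < 8; k++) Grf(s, k) = X.grf[k];
    Epow[s] = X.epow;
    ndone = s + 1;
    // fall check: HAT CoM height
    double hat_y = y[1] + X.S.cH * std::cos(y[2]);
    if (hat_y < fall_height) { status = 1; break; }
    if (s == nstep) break;
    // RK4 step
    for (int i = 0; i < NY; i++) yt[i] = y[i] + 0.5 * dt * k1[i];
    derivs(X, t + 0.5 * dt, yt, k2, false);
    for (int i = 0; i < NY; i++) yt[i] = y[i] + 0.5 * dt * k2[i];
    derivs(X, t + 0.5 * dt, yt, k3, false);
    for (int i = 0; i < NY; i++) yt[i] = y[i] + dt * k3[i];
    derivs(X, t + dt, yt, k4, false);
    for (int i = 0; i < NY; i++)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < NM; i++) {   // keep activations in [0, 1]
      if (y[18 + i] < 0.0) y[18 + i] = 0.0;
      if (y[18 + i] > 1.0) y[18 + i] = 1.0;
      double lmin = 0.25 * X.M.p[i].lopt, lmax = 1.85 * X.M.p[i].lopt;
      if (y[36 + i] < lmin) y[36 + i] = lmin;
      if (y[36 + i] > lmax) y[36 + i] = lmax;
    }
  }

  auto crop = [&](NumericMatrix m) {
    if (ndone == nsamp) return m;
    NumericMatrix out(ndone, m.ncol());
    for (int i = 0; i < ndone; i++)
      for (int j = 0; j < m.ncol(); j++) out(i, j) = m(i, j);
    return out;
  };
  NumericVector tt(ndone), ee(ndone);
  for (int i = 0; i < ndone; i++) { tt[i] = time[i]; ee[i] = Epow[i]; }
  return List::create(
    _["time"] = tt, _["q"] = crop(Q), _["qdot"] = crop(Qd),
    _["activation"] = crop(Act), _["ce_length"] = crop(Lce),
    _["see_force"] = crop(Fsee), _["stimulation"] = crop(Stim),
    _["grf"] = crop(Grf), _["metabolic_power"] = ee,
    _["status"] = status, _["n_fv_clamped"] = X.n_clamped);
}

// batch landmark traces for a whole trial (rows of Q/Qd are samples)
// [[Rcpp::export]]
List cpp_landmark_traces(const List& skel, const NumericMatrix& Q,
                         const NumericMatrix& Qd) {
  Skel S = parse_skel(skel);
  int n = Q.nrow();
  NumericMatrix com(n, 2), vcom(n, 2), toeR(n, 2), toeL(n, 2),
                ankR(n, 2), ankL(n, 2);
  double th[7], om[7], q[NQ], qd[NQ], pos[2];
  arma::mat J(2, NQ);
  struct Item { int seg; double lx, ly; NumericMatrix* out; };
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < NQ; j++) { q[j] = Q(i, j); qd[j] = Qd(i, j); }
    seg_angles(q, th); seg_omegas(qd, om);
    arma::vec qdv(qd, NQ, false);
    double M = 0, cx = 0, cy = 0, cvx = 0, cvy = 0;
    for (int s = 0; s < 7; s++) {
      double lx, ly; com_local(S, s, &lx, &ly);
      Chain c = point_chain(S, s, lx, ly);
      point_eval(c, q, th, om, pos, &J, nullptr);
      arma::vec v = J * qdv;
      M += S.m[s];
      cx += S.m[s] * pos[0]; cy += S.m[s] * pos[1];
      cvx += S.m[s] * v(0); cvy += S.m[s] * v(1);
    }
    com(i, 0) = cx / M; com(i, 1) = cy / M;
    vcom(i, 0) = cvx / M; vcom(i, 1) = cvy / M;
    Item items[4] = {
      {3, S.toex, S.toey, &toeR}, {6, S.toex, S.toey, &toeL},
      {2, 0.0, -S.Ls, &ankR}, {5, 0.0, -S.Ls, &ankL}};
    for (int k = 0; k < 4; k++) {
      Chain c = point_chain(S, items[k].seg, items[k].lx, items[k].ly);
      point_eval(c, q, th, om, pos, nullptr, nullptr);
      (*items[k].out)(i, 0) = pos[0]; (*items[k].out)(i, 1) = pos[1];
    }
  }
  return List::create(_["com"] = com, _["vcom"] = vcom,
                      _["toe_R"] = toeR, _["toe_L"] = toeL,
                      _["ankle_R"] = ankR, _["ankle_L"] = ankL);
}
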