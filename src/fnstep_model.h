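#ifndef FNSTEP_MODEL_H
#define FNSTEP_MODEL_H

#include <RcppArmadillo.h>

// ---------------------------------------------------------------------------
// Hill-type muscle curves (smooth de-Groote-style parameterization).
// Curves are normalized so that f_L(1) = 1 and f_V(0) = 1 exactly: the
// identity point (a = 1, ltilde = 1, vtilde = 0) yields the maximum
// isometric force.
// ---------------------------------------------------------------------------

namespace fnstep {

inline double fl_active_raw(double l) {
  static const double b1[3] = {0.814483478343008, 0.433004984392647, 0.100};
  static const double b2[3] = {1.055033428970575, 0.716775413397760, 1.000};
  static const double b3[3] = {0.162384573599574, -0.029947116970696,
                               0.353553390593274};
  static const double b4[3] = {0.063303448465465, 0.200356847296188, 0.000};
  double f = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = b3[i] + b4[i] * l;
    double z = (l - b2[i]) / den;
    f += b1[i] * std::exp(-0.5 * z * z);
  }
  return f;
}

inline double fl_active(double l) {
  static const double norm = fl_active_raw(1.0);
  return fl_active_raw(l) / norm;
}

inline double fv_raw(double v) {
  static const double d1 = -0.318323436899127;
  static const double d2 = -8.149156043475250;
  static const double d3 = -0.374121508647863;
  static const double d4 = 0.885644059915004;
  double z = d2 * v + d3;
  return d1 * std::log(z + std::sqrt(z * z + 1.0)) + d4;
}

inline double fv_curve(double v) {
  static const double norm = fv_raw(0.0);
  return fv_raw(v) / norm;
}

// Passive fiber force; zero at optimal length, exponential beyond.
inline double fp_passive(double l) {
  static const double kpe = 4.0, e0 = 0.6;
  return (std::exp(kpe * (l - 1.0) / e0) - 1.0) / (std::exp(kpe) - 1.0);
}

// Tendon force-length (normalized force vs normalized tendon length);
// exponential and analytically invertible, used in compliant-tendon mode.
static const double kT_c1 = 0.2, kT_c2 = 0.995, kT_c3 = 0.25, kT_k = 35.0;

inline double ft_tendon(double lt_norm) {
  return kT_c1 * std::exp(kT_k * (lt_norm - kT_c2)) - kT_c3;
}

inline double ft_tendon_inv(double f) {
  return kT_c2 + std::log((f + kT_c3) / kT_c1) / kT_k;
}

inline double muscle_force_norm(double a, double l, double v) {
  return a * fl_active(l) * fv_curve(v) + fp_passive(l);
}

// First-order activation dynamics with a smooth blend between the
// activation and deactivation time constants; exact (e - a)/tau in either
// saturated regime.
inline double activation_rate(double e, double a, double tact, double tdeact) {
  const double ksm = 0.05;
  double s = 1.0 / (1.0 + std::exp(-(e - a) / ksm));
  double tau = tdeact + (tact - tdeact) * s;
  return (e - a) / tau;
}

// ---------------------------------------------------------------------------
// Smoothed Hunt-Crossley sphere-on-plane contact (planar). The penetration
// and the Hunt-Crossley velocity factor are smoothed with a
// sqrt-softplus so the force is C-infinity in all arguments; friction uses a
// tanh slip law plus a viscous term.
// ---------------------------------------------------------------------------

inline double smooth_pos(double x, double eps) {
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}

// normal (y) and tangential (x) force on the body owning the sphere
inline void hc_force(double pen, double penrate, double slipv,
                     double stiff, double diss, double mud, double muv,
                     double eps, double vs, double &fx, double &fy) {
  double d = smooth_pos(pen, eps);
  double vfac = smooth_pos(1.0 + 1.5 * diss * penrate, 1e-3);
  fy = stiff * std::pow(d, 1.5) * vfac;
  fx = -fy * mud * std::tanh(slipv / vs) - muv * slipv * (d / (d + eps));
}

// contact elastic potential energy stored at smoothed penetration d
inline double hc_potential(double pen, double stiff, double eps) {
  double d = smooth_pos(pen, eps);
  return 0.4 * stiff * std::pow(d, 2.5);
}

// ---------------------------------------------------------------------------
// Flattened planar model (parsed once per batch call from an R list built
// by compile_model() on the R side).
// ---------------------------------------------------------------------------

struct Model {
  int nseg, ncoord, nmus, nsph, nres;
  // base coordinate indices (tx, ty, rot), -1 when that DOF is absent
  int base_tx, base_ty, base_rot;
  arma::ivec seg_parent;  // -1 for base segment 0
  arma::ivec seg_coord;   // coordinate driving segment's revolute joint
  arma::vec seg_qsign;
  arma::mat seg_dloc;     // 2 x nseg joint position in parent frame
  arma::mat seg_com;      // 2 x nseg
  arma::vec seg_mass, seg_inertia;
  double gravity;
  // muscles
  arma::vec mus_fmax, mus_lopt, mus_lslack, mus_tact, mus_tdeact, mus_vmax,
      mus_lmt0;
  arma::mat R_ma;  // ncoord x nmus moment arms
  // contact spheres
  arma::ivec sph_seg, sph_foot;  // sph_foot: 1 = left, 2 = right, 0 = none
  arma::mat sph_loc;             // 2 x nsph
  arma::vec sph_radius, sph_stiff, sph_diss, sph_mud, sph_muv, sph_eps,
      sph_vs;
  // reserve actuators
  arma::ivec res_coord;
  arma::vec res_max;
  bool rigid_tendon;
};

inline Model parse_model(const Rcpp::List &cm) {
  Model m;
  m.nseg = Rcpp::as<int>(cm["nseg"]);
  m.ncoord = Rcpp::as<int>(cm["ncoord"]);
  m.nmus = Rcpp::as<int>(cm["nmus"]);
  m.nsph = Rcpp::as<int>(cm["nsph"]);
  m.nres = Rcpp::as<int>(cm["nres"]);
  Rcpp::IntegerVector bc = cm["base_coords"];
  m.base_tx = bc[0];
  m.base_ty = bc[1];
  m.base_rot = bc[2];
  m.seg_parent = Rcpp::as<arma::ivec>(cm["seg_parent"]);
  m.seg_coord = Rcpp::as<arma::ivec>(cm["seg_coord"]);
  m.seg_qsign = Rcpp::as<arma::vec>(cm["seg_qsign"]);
  m.seg_dloc = Rcpp::as<arma::mat>(cm["seg_dloc"]);
  m.seg_com = Rcpp::as<arma::mat>(cm["seg_com"]);
  m.seg_mass = Rcpp::as<arma::vec>(cm["seg_mass"]);
  m.seg_inertia = Rcpp::as<arma::vec>(cm["seg_inertia"]);
  m.gravity = Rcpp::as<double>(cm["gravity"]);
  if (m.nmus > 0) {
    m.mus_fmax = Rcpp::as<arma::vec>(cm["mus_fmax"]);
    m.mus_lopt = Rcpp::as<arma::vec>(cm["mus_lopt"]);
    m.mus_lslack = Rcpp::as<arma::vec>(cm["mus_lslack"]);
    m.mus_tact = Rcpp::as<arma::vec>(cm["mus_tact"]);
    m.mus_tdeact = Rcpp::as<arma::vec>(cm["mus_tdeact"]);
    m.mus_vmax = Rcpp::as<arma::vec>(cm["mus_vmax"]);
    m.mus_lmt0 = Rcpp::as<arma::vec>(cm["mus_lmt0"]);
    m.R_ma = Rcpp::as<arma::mat>(cm["R_ma"]);
  }
  if (m.nsph > 0) {
    m.sph_seg = Rcpp::as<arma::ivec>(cm["sph_seg"]);
    m.sph_foot = Rcpp::as<arma::ivec>(cm["sph_foot"]);
    m.sph_loc = Rcpp::as<arma::mat>(cm["sph_loc"]);
    m.sph_radius = Rcpp::as<arma::vec>(cm["sph_radius"]);
    m.sph_stiff = Rcpp::as<arma::vec>(cm["sph_stiff"]);
    m.sph_diss = Rcpp::as<arma::vec>(cm["sph_diss"]);
    m.sph_mud = Rcpp::as<arma::vec>(cm["sph_mud"]);
    m.sph_muv = Rcpp::as<arma::vec>(cm["sph_muv"]);
    m.sph_eps = Rcpp::as<arma::vec>(cm["sph_eps"]);
    m.sph_vs = Rcpp::as<arma::vec>(cm["sph_vs"]);
  }
  if (m.nres > 0) {
    m.res_coord = Rcpp::as<arma::ivec>(cm["res_coord"]);
    m.res_max = Rcpp::as<arma::vec>(cm["res_max"]);
  }
  m.rigid_tendon = Rcpp::as<bool>(cm["rigid_tendon"]);
  return m;
}

// Per-segment kinematic state computed in a forward pass.
struct Kin {
  arma::vec phi, w, al;     // angle, angular velocity/acceleration
  arma::mat O, vO, aO;      // 2 x nseg origin pos/vel/acc
  arma::mat cw;             // 2 x nseg world com offset from origin
  arma::mat pcom, vcom, acom;
};

inline void fwd_kinematics(const Model &m, const arma::vec &q,
                           const arma::vec &u, const arma::vec &ud, Kin &k) {
  int n = m.nseg;
  k.phi.zeros(n); k.w.zeros(n); k.al.zeros(n);
  k.O.zeros(2, n); k.vO.zeros(2, n); k.aO.zeros(2, n);
  k.cw.zeros(2, n); k.pcom.zeros(2, n); k.vcom.zeros(2, n);
  k.acom.zeros(2, n);
  for (int s = 0; s < n; ++s) {
    if (s == 0) {
      if (m.base_tx >= 0) {
        k.O(0, 0) = q(m.base_tx); k.vO(0, 0) = u(m.base_tx);
        k.aO(0, 0) = ud(m.base_tx);
      }
      if (m.base_ty >= 0) {
        k.O(1, 0) = q(m.base_ty); k.vO(1, 0) = u(m.base_ty);
        k.aO(1, 0) = ud(m.base_ty);
      }
      if (m.base_rot >= 0) {
        k.phi(0) = q(m.base_rot); k.w(0) = u(m.base_rot);
        k.al(0) = ud(m.base_rot);
      }
    } else {
      int p = m.seg_parent(s);
      int c = m.seg_coord(s);
      double sgn = m.seg_qsign(s);
      k.phi(s) = k.phi(p) + sgn * q(c);
      k.w(s) = k.w(p) + sgn * u(c);
      k.al(s) = k.al(p) + sgn * ud(c);
      double cp = std::cos(k.phi(p)), sp = std::sin(k.phi(p));
      double rx = cp * m.seg_dloc(0, s) - sp * m.seg_dloc(1, s);
      double ry = sp * m.seg_dloc(0, s) + cp * m.seg_dloc(1, s);
      k.O(0, s) = k.O(0, p) + rx;
      k.O(1, s) = k.O(1, p) + ry;
      // omega x r = w * perp(r), perp(r) = (-ry, rx)
      k.vO(0, s) = k.vO(0, p) - k.w(p) * ry;
      k.vO(1, s) = k.vO(1, p) + k.w(p) * rx;
      k.aO(0, s) = k.aO(0, p) - k.al(p) * ry - k.w(p) * k.w(p) * rx;
      k.aO(1, s) = k.aO(1, p) + k.al(p) * rx - k.w(p) * k.w(p) * ry;
    }
    double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
    double cx = cs * m.seg_com(0, s) - ss * m.seg_com(1, s);
    double cy = ss * m.seg_com(0, s) + cs * m.seg_com(1, s);
    k.cw(0, s) = cx; k.cw(1, s) = cy;
    k.pcom(0, s) = k.O(0, s) + cx;
    k.pcom(1, s) = k.O(1, s) + cy;
    k.vcom(0, s) = k.vO(0, s) - k.w(s) * cy;
    k.vcom(1, s) = k.vO(1, s) + k.w(s) * cx;
    k.acom(0, s) = k.aO(0, s) - k.al(s) * cy - k.w(s) * k.w(s) * cx;
    k.acom(1, s) = k.aO(1, s) + k.al(s) * cx - k.w(s) * k.w(s) * cy;
  }
}

inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Contact forces for all spheres at the given kinematic state.
// out: 4 x nsph (px, py, fx, fy in world frame).
inline void contact_all(const Model &m, const Kin &k, arma::mat &out) {
  out.zeros(4, m.nsph);
  for (int i = 0; i < m.nsph; ++i) {
    int s = m.sph_seg(i);
    double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
    double lx = cs * m.sph_loc(0, i) - ss * m.sph_loc(1, i);
    double ly = ss * m.sph_loc(0, i) + cs * m.sph_loc(1, i);
    double px = k.O(0, s) + lx, py = k.O(1, s) + ly;
    double vx = k.vO(0, s) - k.w(s) * ly;
    double vy = k.vO(1, s) + k.w(s) * lx;
    double pen = m.sph_radius(i) - py;
    double fx, fy;
    hc_force(pen, -vy, vx, m.sph_stiff(i), m.sph_diss(i), m.sph_mud(i),
             m.sph_muv(i), m.sph_eps(i), m.sph_vs(i), fx, fy);
    out(0, i) = px; out(1, i) = py; out(2, i) = fx; out(3, i) = fy;
  }
}

// Rigid-tendon muscle forces along the tendon (N); lengths from the
// moment-arm map l_mt(q) = lmt0 - R_ma^T q.
inline void muscle_forces_rigid(const Model &m, const arma::vec &q,
                                const arma::vec &u, const arma::vec &act,
                                arma::vec &fmus) {
  fmus.zeros(m.nmus);
  if (m.nmus == 0) return;
  arma::vec lmt = m.mus_lmt0 - m.R_ma.t() * q;
  arma::vec vmt = -m.R_ma.t() * u;
  for (int i = 0; i < m.nmus; ++i) {
    double ln = (lmt(i) - m.mus_lslack(i)) / m.mus_lopt(i);
    double vn = vmt(i) / (m.mus_vmax(i) * m.mus_lopt(i));
    fmus(i) = m.mus_fmax(i) * muscle_force_norm(act(i), ln, vn);
  }
}

// Inverse dynamics (RNEA) generalized forces for given motion and external
// contact forces; gravity can be disabled for mass-matrix extraction.
inline arma::vec rnea(const Model &m, const Kin &k, const arma::mat &cforce,
                      bool with_gravity, bool with_contact) {
  int n = m.nseg;
  arma::mat f(2, n, arma::fill::zeros);
  arma::vec nn(n, arma::fill::zeros);
  double gy = with_gravity ? -m.gravity : 0.0;
  for (int s = 0; s < n; ++s) {
    double Fx = m.seg_mass(s) * k.acom(0, s);
    double Fy = m.seg_mass(s) * (k.acom(1, s) - gy);
    f(0, s) = Fx; f(1, s) = Fy;
    nn(s) = m.seg_inertia(s) * k.al(s) +
            cross2(k.cw(0, s), k.cw(1, s), Fx, Fy);
  }
  if (with_contact) {
    for (int i = 0; i < m.nsph; ++i) {
      int s = m.sph_seg(i);
      f(0, s) -= cforce(2, i);
      f(1, s) -= cforce(3, i);
      nn(s) -= cross2(cforce(0, i) - k.O(0, s), cforce(1, i) - k.O(1, s),
                      cforce(2, i), cforce(3, i));
    }
  }
  for (int s = n - 1; s >= 1; --s) {
    int p = m.seg_parent(s);
    f(0, p) += f(0, s);
    f(1, p) += f(1, s);
    nn(p) += nn(s) + cross2(k.O(0, s) - k.O(0, p), k.O(1, s) - k.O(1, p),
                            f(0, s), f(1, s));
  }
  arma::vec tau(m.ncoord, arma::fill::zeros);
  if (m.base_tx >= 0) tau(m.base_tx) = f(0, 0);
  if (m.base_ty >= 0) tau(m.base_ty) = f(1, 0);
  if (m.base_rot >= 0) tau(m.base_rot) = nn(0);
  for (int s = 1; s < n; ++s) tau(m.seg_coord(s)) = m.seg_qsign(s) * nn(s);
  return tau;
}

}  // namespace fnstep

#endif
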