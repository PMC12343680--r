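#include "fnstep_model.h"

using namespace Rcpp;
using namespace arma;
using namespace fnstep;

// Muscle-tendon unit force for vectors of (activation, normalized fiber
// length, normalized fiber velocity); force along the tendon in N.
// [[Rcpp::export]]
NumericVector cpp_muscle_force(NumericVector a, NumericVector lnorm,
                               NumericVector vnorm, double fmax,
                               double pennation) {
  int n = a.size();
  NumericVector out(n);
  double cp = std::cos(pennation);
  for (int i = 0; i < n; ++i)
    out[i] = fmax * muscle_force_norm(a[i], lnorm[i], vnorm[i]) * cp;
  return out;
}

// [[Rcpp::export]]
List cpp_hill_curves(NumericVector lnorm, NumericVector vnorm) {
  int n = lnorm.size();
  NumericVector fl(n), fp(n), fv(vnorm.size());
  for (int i = 0; i < n; ++i) {
    fl[i] = fl_active(lnorm[i]);
    fp[i] = fp_passive(lnorm[i]);
  }
  for (int i = 0; i < vnorm.size(); ++i) fv[i] = fv_curve(vnorm[i]);
  return List::create(_["fl"] = fl, _["fp"] = fp, _["fv"] = fv);
}

// [[Rcpp::export]]
NumericVector cpp_activation_rate(NumericVector e, NumericVector a,
                                  NumericVector tact, NumericVector tdeact) {
  int n = e.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = activation_rate(e[i], a[i], tact[i], tdeact[i]);
  return out;
}

// Smoothed Hunt-Crossley contact force (normal fy, tangential fx).
// [[Rcpp::export]]
List cpp_contact_force(NumericVector pen, NumericVector penrate,
                       NumericVector slipv, double stiff, double diss,
                       double mud, double muv, double eps, double vs) {
  int n = pen.size();
  NumericVector fx(n), fy(n);
  for (int i = 0; i < n; ++i)
    hc_force(pen[i], penrate[i], slipv[i], stiff, diss, mud, muv, eps, vs,
             fx[i], fy[i]);
  return List::create(_["tangential"] = fx, _["normal"] = fy);
}

// [[Rcpp::export]]
NumericVector cpp_contact_potential(NumericVector pen, double stiff,
                                    double eps) {
  int n = pen.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hc_potential(pen[i], stiff, eps);
  return out;
}

static void mtu_torques(const Model &m, const vec &q, const vec &u,
                        const vec &act, const vec &ftilde, vec &tau_mus,
                        vec &fmus) {
  if (m.nmus == 0) {
    tau_mus.zeros(m.ncoord);
    fmus.zeros(0);
    return;
  }
  if (m.rigid_tendon) {
    muscle_forces_rigid(m, q, u, act, fmus);
  } else {
    fmus = m.mus_fmax % ftilde;  // tendon force from normalized-force state
  }
  tau_mus = m.R_ma * fmus;
}

// Implicit dynamics residual for a batch of collocation points.
// Q,U,UD: ncoord x P; ACT,E: nmus x P; RES: nres x P; FT: nmus x P
// (normalized tendon force states, compliant mode only; pass 0 x P when
// rigid). Returns residual matrix ncoord x P (units N / Nm).
// [[Rcpp::export]]
arma::mat cpp_dyn_residual_batch(List cm, arma::mat Q, arma::mat U,
                                 arma::mat UD, arma::mat ACT, arma::mat RES,
                                 arma::mat FT) {
  Model m = parse_model(cm);
  int P = Q.n_cols;
  mat out(m.ncoord, P);
  Kin k;
  mat cf;
  vec tau_mus, fmus;
  for (int p = 0; p < P; ++p) {
    vec q = Q.col(p), u = U.col(p), ud = UD.col(p);
    fwd_kinematics(m, q, u, ud, k);
    contact_all(m, k, cf);
    vec tau = rnea(m, k, cf, true, true);
    vec ft = (m.nmus > 0 && !m.rigid_tendon) ? vec(FT.col(p))
                                             : vec(m.nmus, fill::zeros);
    mtu_torques(m, q, u, m.nmus > 0 ? vec(ACT.col(p)) : vec(),
                ft, tau_mus, fmus);
    tau -= tau_mus;
    for (int r = 0; r < m.nres; ++r)
      tau(m.res_coord(r)) -= m.res_max(r) * RES(r, p);
    out.col(p) = tau;
  }
  return out;
}

// Hill equilibrium residual in compliant-tendon mode: normalized fiber
// force minus normalized tendon force at each point. FT / DFT are the
// normalized tendon-force states and their time derivatives.
// [[Rcpp::export]]
arma::mat cpp_tendon_equilibrium_batch(List cm, arma::mat Q, arma::mat U,
                                       arma::mat ACT, arma::mat FT,
                                       arma::mat DFT) {
  Model m = parse_model(cm);
  int P = Q.n_cols;
  mat out(m.nmus, P, fill::zeros);
  for (int p = 0; p < P; ++p) {
    vec q = Q.col(p), u = U.col(p);
    vec lmt = m.mus_lmt0 - m.R_ma.t() * q;
    vec vmt = -m.R_ma.t() * u;
    for (int i = 0; i < m.nmus; ++i) {
      double ft = FT(i, p);
      double ltn = ft_tendon_inv(ft);
      double lt = m.mus_lslack(i) * ltn;
      double lf = lmt(i) - lt;
      double ln = lf / m.mus_lopt(i);
      // tendon lengthening rate from dF/dt through the tendon curve slope
      double dlt = m.mus_lslack(i) * DFT(i, p) / (kT_k * (ft + kT_c3));
      double vf = vmt(i) - dlt;
      double vn = vf / (m.mus_vmax(i) * m.mus_lopt(i));
      out(i, p) = muscle_force_norm(ACT(i, p), ln, vn) - ft;
    }
  }
  return out;
}

// Forward kinematics of arbitrary body-fixed points over a batch of
// configurations. segs: 0-based segment indices; offsets: 2 x npts.
// Returns (2*npts) x P stacked (x, y) rows per point.
// [[Rcpp::export]]
arma::mat cpp_point_positions(List cm, arma::mat Q, IntegerVector segs,
                              arma::mat offsets) {
  Model m = parse_model(cm);
  int P = Q.n_cols, np = segs.size();
  mat out(2 * np, P);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  for (int p = 0; p < P; ++p) {
    fwd_kinematics(m, Q.col(p), zero, zero, k);
    for (int j = 0; j < np; ++j) {
      int s = segs[j];
      double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
      out(2 * j, p) =
          k.O(0, s) + cs * offsets(0, j) - ss * offsets(1, j);
      out(2 * j + 1, p) =
          k.O(1, s) + ss * offsets(0, j) + cs * offsets(1, j);
    }
  }
  return out;
}

// Whole-body center of mass (and its velocity) over a batch.
// Returns 4 x P: (x, y, vx, vy).
// [[Rcpp::export]]
arma::mat cpp_com_batch(List cm, arma::mat Q, arma::mat U) {
  Model m = parse_model(cm);
  int P = Q.n_cols;
  mat out(4, P);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  double mt = accu(m.seg_mass);
  for (int p = 0; p < P; ++p) {
    fwd_kinematics(m, Q.col(p), U.col(p), zero, k);
    vec2 c = zeros<vec>(2), v = zeros<vec>(2);
    for (int s = 0; s < m.nseg; ++s) {
      c += m.seg_mass(s) * k.pcom.col(s);
      v += m.seg_mass(s) * k.vcom.col(s);
    }
    out(0, p) = c(0) / mt; out(1, p) = c(1) / mt;
    out(2, p) = v(0) / mt; out(3, p) = v(1) / mt;
  }
  return out;
}

// Per-foot resultant contact force over a batch: 4 x P rows
// (left fx, left fy, right fx, right fy).
// [[Rcpp::export]]
arma::mat cpp_foot_forces_batch(List cm, arma::mat Q, arma::mat U) {
  Model m = parse_model(cm);
  int P = Q.n_cols;
  mat out(4, P, fill::zeros);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  mat cf;
  for (int p = 0; p < P; ++p) {
    fwd_kinematics(m, Q.col(p), U.col(p), zero, k);
    contact_all(m, k, cf);
    for (int i = 0; i < m.nsph; ++i) {
      if (m.sph_foot(i) == 1) {
        out(0, p) += cf(2, i); out(1, p) += cf(3, i);
      } else if (m.sph_foot(i) == 2) {
        out(2, p) += cf(2, i); out(3, p) += cf(3, i);
      }
    }
  }
  return out;
}

// Per-sphere world positions and forces at a single state.
// [[Rcpp::export]]
arma::mat cpp_sphere_state(List cm, arma::vec q, arma::vec u) {
  Model m = parse_model(cm);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  fwd_kinematics(m, q, u, zero, k);
  mat cf;
  contact_all(m, k, cf);
  return cf;
}

// Mass matrix via RNEA with unit accelerations (gravity and contact off).
// [[Rcpp::export]]
arma::mat cpp_mass_matrix(List cm, arma::vec q) {
  Model m = parse_model(cm);
  mat M(m.ncoord, m.ncoord);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  mat cf(4, std::max(m.nsph, 1), fill::zeros);
  for (int j = 0; j < m.ncoord; ++j) {
    vec e(m.ncoord, fill::zeros);
    e(j) = 1.0;
    fwd_kinematics(m, q, zero, e, k);
    M.col(j) = rnea(m, k, cf, false, false);
  }
  return M;
}

// Forward dynamics: generalized accelerations given state and controls.
// [[Rcpp::export]]
arma::vec cpp_fd_accel(List cm, arma::vec q, arma::vec u, arma::vec act,
                       arma::vec res, arma::vec ftilde) {
  Model m = parse_model(cm);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  fwd_kinematics(m, q, u, zero, k);
  mat cf;
  contact_all(m, k, cf);
  vec bias = rnea(m, k, cf, true, true);
  vec tau_mus, fmus;
  mtu_torques(m, q, u, act, ftilde, tau_mus, fmus);
  vec tau_app = tau_mus;
  for (int r = 0; r < m.nres; ++r)
    tau_app(m.res_coord(r)) += m.res_max(r) * res(r);
  mat M(m.ncoord, m.ncoord);
  mat cf0(4, std::max(m.nsph, 1), fill::zeros);
  for (int j = 0; j < m.ncoord; ++j) {
    vec e(m.ncoord, fill::zeros);
    e(j) = 1.0;
    fwd_kinematics(m, q, zero, e, k);
    M.col(j) = rnea(m, k, cf0, false, false);
  }
  return solve(M, tau_app - bias, solve_opts::likely_sympd);
}

// Muscle-tendon forces (rigid tendon) over a batch: nmus x P.
// [[Rcpp::export]]
arma::mat cpp_muscle_forces_batch(List cm, arma::mat Q, arma::mat U,
                                  arma::mat ACT) {
  Model m = parse_model(cm);
  int P = Q.n_cols;
  mat out(m.nmus, P);
  vec fmus;
  for (int p = 0; p < P; ++p) {
    muscle_forces_rigid(m, Q.col(p), U.col(p), ACT.col(p), fmus);
    out.col(p) = fmus;
  }
  return out;
}

// Kinetic + gravitational + contact elastic energy of a state.
// [[Rcpp::export]]
List cpp_energy(List cm, arma::vec q, arma::vec u) {
  Model m = parse_model(cm);
  Kin k;
  vec zero(m.ncoord, fill::zeros);
  fwd_kinematics(m, q, u, zero, k);
  double ke = 0, pe = 0, ce = 0;
  for (int s = 0; s < m.nseg; ++s) {
    ke += 0.5 * m.seg_mass(s) *
              (k.vcom(0, s) * k.vcom(0, s) + k.vcom(1, s) * k.vcom(1, s)) +
          0.5 * m.seg_inertia(s) * k.w(s) * k.w(s);
    pe += m.seg_mass(s) * m.gravity * k.pcom(1, s);
  }
  for (int i = 0; i < m.nsph; ++i) {
    int s = m.sph_seg(i);
    double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
    double py = k.O(1, s) + ss * m.sph_loc(0, i) + cs * m.sph_loc(1, i);
    ce += hc_potential(m.sph_radius(i) - py, m.sph_stiff(i), m.sph_eps(i));
  }
  return List::create(_["kinetic"] = ke, _["gravitational"] = pe,
                      _["contact"] = ce, _["total"] = ke + pe + ce);
}
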