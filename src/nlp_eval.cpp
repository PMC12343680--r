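// Fast evaluation of the transcribed NLP residual stack (cost rows,
// equality constraints, inequality constraints) for one decision vector.
// A single forward-kinematics pass per collocation point serves the
// dynamics residual, marker tracking, foot forces, leg clearance and the
// center of mass. Row ordering must match the bookkeeping in the R
// transcription (ocp.R / build_sparsity).

#include "fnstep_model.h"

using namespace Rcpp;
using namespace arma;
using namespace fnstep;

// [[Rcpp::export]]
arma::vec cpp_nlp_eval(List cm, List su, arma::vec x,
                       arma::imat knee_events) {
  Model m = parse_model(cm);
  const int nq = as<int>(su["nq"]), nmus = as<int>(su["nmus"]),
            nres = as<int>(su["nres"]), nx = as<int>(su["nx"]),
            nu = as<int>(su["nu"]), b = as<int>(su["b"]),
            P = as<int>(su["P"]), N = as<int>(su["N"]);
  const bool tf_free = as<bool>(su["tf_free"]),
             track = as<bool>(su["track"]),
             predictive = as<bool>(su["predictive"]),
             compliant = as<bool>(su["compliant"]),
             has_sym = as<bool>(su["has_sym"]),
             has_rest = as<bool>(su["has_rest"]),
             has_avg = as<bool>(su["has_avg"]),
             has_inter = as<bool>(su["has_inter"]),
             has_knees = as<bool>(su["has_knees"]),
             wad_on = as<bool>(su["wad_on"]);
  const double mg = as<double>(su["mg"]);
  const vec sx = as<vec>(su["sx"]);
  const vec qw_pat = as<vec>(su["qw_pat"]);

  double tf = tf_free ? x(P * b) : as<double>(su["tf_fixed"]);
  double h = tf / N;

  // unpack states/controls
  mat X(nx, P), U(nu, P);
  for (int p = 0; p < P; ++p) {
    for (int s = 0; s < nx; ++s) X(s, p) = x(p * b + s);
    for (int s = 0; s < nu; ++s) U(s, p) = x(p * b + nx + s);
  }
  mat Q = X.rows(0, nq - 1);
  mat Uq = X.rows(nq, 2 * nq - 1);
  mat ACT = nmus > 0 ? mat(X.rows(2 * nq, 2 * nq + nmus - 1))
                     : mat(0, P);
  mat FT = compliant ? mat(X.rows(2 * nq + nmus, 2 * nq + 2 * nmus - 1))
                     : mat(nmus, P, fill::zeros);
  mat EXC = nmus > 0 ? mat(U.rows(0, nmus - 1)) : mat(0, P);
  mat RES = nres > 0 ? mat(U.rows(nmus, nmus + nres - 1)) : mat(0, P);
  mat ACC = U.rows(nmus + nres, nmus + nres + nq - 1);
  mat DFT = compliant
                ? mat(U.rows(nmus + nres + nq, nmus + nres + nq + nmus - 1))
                : mat(0, P);

  // per-point kinematics pass
  mat DYN(nq, P);
  mat ARATE(nmus, P);
  const ivec mark_segs = track ? as<ivec>(su["mark_segs"]) : ivec();
  const mat mark_off = track ? as<mat>(su["mark_off"]) : mat();
  int M = track ? mark_segs.n_elem : 0;
  mat MPOS(2 * M, P);
  mat FOOT(4, P, fill::zeros);
  const ivec cp_segs = has_inter ? as<ivec>(su["cp_segs"]) : ivec();
  const mat cp_off = has_inter ? as<mat>(su["cp_off"]) : mat();
  const imat cp_pairs = has_inter ? as<imat>(su["cp_pairs"]) : imat();
  int ncp = has_inter ? cp_segs.n_elem : 0;
  mat CPOS(2 * ncp, P);
  double com_x0 = 0, com_x1 = 0;
  double mt = accu(m.seg_mass);

  Kin k;
  mat cf;
  vec tau_mus, fmus;
  for (int p = 0; p < P; ++p) {
    vec q = Q.col(p), u = Uq.col(p), ud = ACC.col(p);
    fwd_kinematics(m, q, u, ud, k);
    contact_all(m, k, cf);
    vec tau = rnea(m, k, cf, true, true);
    if (nmus > 0) {
      vec act = ACT.col(p);
      if (m.rigid_tendon) {
        muscle_forces_rigid(m, q, u, act, fmus);
      } else {
        fmus = m.mus_fmax % vec(FT.col(p));
      }
      tau -= m.R_ma * fmus;
      for (int i = 0; i < nmus; ++i) {
        ARATE(i, p) = activation_rate(EXC(i, p), act(i), m.mus_tact(i),
                                      m.mus_tdeact(i));
      }
    }
    for (int r = 0; r < m.nres; ++r)
      tau(m.res_coord(r)) -= m.res_max(r) * RES(r, p);
    DYN.col(p) = tau / mg;
    for (int j = 0; j < M; ++j) {
      int s = mark_segs(j);
      double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
      MPOS(2 * j, p) = k.O(0, s) + cs * mark_off(0, j) -
                       ss * mark_off(1, j);
      MPOS(2 * j + 1, p) = k.O(1, s) + ss * mark_off(0, j) +
                           cs * mark_off(1, j);
    }
    if (track) {
      for (int i = 0; i < m.nsph; ++i) {
        if (m.sph_foot(i) == 1) {
          FOOT(0, p) += cf(2, i);
          FOOT(1, p) += cf(3, i);
        } else if (m.sph_foot(i) == 2) {
          FOOT(2, p) += cf(2, i);
          FOOT(3, p) += cf(3, i);
        }
      }
    }
    for (int j = 0; j < ncp; ++j) {
      int s = cp_segs(j);
      double cs = std::cos(k.phi(s)), ss = std::sin(k.phi(s));
      CPOS(2 * j, p) = k.O(0, s) + cs * cp_off(0, j) - ss * cp_off(1, j);
      CPOS(2 * j + 1, p) = k.O(1, s) + ss * cp_off(0, j) +
                           cs * cp_off(1, j);
    }
    if (p == 0 || p == P - 1) {
      double cx = 0;
      for (int s = 0; s < m.nseg; ++s)
        cx += m.seg_mass(s) * k.pcom(0, s);
      if (p == 0) com_x0 = cx / mt; else com_x1 = cx / mt;
    }
  }

  // state-derivative stack and Hermite-Simpson defects
  mat F(nx, P);
  F.rows(0, nq - 1) = Uq;
  F.rows(nq, 2 * nq - 1) = ACC;
  if (nmus > 0) F.rows(2 * nq, 2 * nq + nmus - 1) = ARATE;
  if (compliant) F.rows(2 * nq + nmus, 2 * nq + 2 * nmus - 1) = DFT;

  mat DH(nx, N), DS(nx, N);
  for (int i = 0; i < N; ++i) {
    int i0 = 2 * i, im = 2 * i + 1, i1 = 2 * i + 2;
    DH.col(i) = (X.col(im) - 0.5 * (X.col(i0) + X.col(i1)) -
                 (h / 8) * (F.col(i0) - F.col(i1))) / sx;
    DS.col(i) = (X.col(i1) - X.col(i0) -
                 (h / 6) * (F.col(i0) + 4 * F.col(im) + F.col(i1))) / sx;
  }

  mat TEN;
  if (compliant) {
    TEN.set_size(nmus, P);
    for (int p = 0; p < P; ++p) {
      vec q = Q.col(p), u = Uq.col(p);
      vec lmt = m.mus_lmt0 - m.R_ma.t() * q;
      vec vmt = -m.R_ma.t() * u;
      for (int i = 0; i < nmus; ++i) {
        double ft = FT(i, p);
        double lt = m.mus_lslack(i) * ft_tendon_inv(ft);
        double ln = (lmt(i) - lt) / m.mus_lopt(i);
        double dlt = m.mus_lslack(i) * DFT(i, p) / (kT_k * (ft + kT_c3));
        double vn = (vmt(i) - dlt) / (m.mus_vmax(i) * m.mus_lopt(i));
        TEN(i, p) = muscle_force_norm(ACT(i, p), ln, vn) - ft;
      }
    }
  }

  // ----- assemble output ---------------------------------------------------
  std::vector<double> out;
  out.reserve(6000);

  vec sqw = sqrt(qw_pat * tf);
  if (track) {
    const mat ref_mark = as<mat>(su["ref_mark"]);
    const vec mark_w = as<vec>(su["mark_w"]);
    const double fsc = as<double>(su["foot_scale"]);
    const mat ref_foot = as<mat>(su["ref_foot"]);
    for (int p = 0; p < P; ++p)
      for (int r = 0; r < 2 * M; ++r)
        out.push_back((MPOS(r, p) - ref_mark(r, p)) * mark_w(r) * sqw(p));
    for (int p = 0; p < P; ++p)
      for (int r = 0; r < 4; ++r)
        out.push_back((FOOT(r, p) - ref_foot(r, p)) * fsc * sqw(p));
  }
  const ivec syn_a = as<ivec>(su["syn_a"]), syn_b = as<ivec>(su["syn_b"]);
  const double sqrt_ws = as<double>(su["sqrt_ws"]);
  if (syn_a.n_elem > 0) {
    for (int p = 0; p < P; ++p)
      for (unsigned r = 0; r < syn_a.n_elem; ++r)
        out.push_back((EXC(syn_a(r), p) - EXC(syn_b(r), p)) * sqrt_ws *
                      sqw(p));
  }
  const vec eff_w_sqrt = as<vec>(su["eff_w_sqrt"]);
  int nctl = nmus + nres;
  if (nctl > 0) {
    double dfac = 1.0;
    if (predictive) {
      double d = std::abs(com_x1 - com_x0);
      double dmin = as<double>(su["min_distance"]);
      if (d < dmin) d = dmin;
      dfac = 1.0 / std::sqrt(d);
    }
    for (int p = 0; p < P; ++p) {
      for (int r = 0; r < nmus; ++r)
        out.push_back(EXC(r, p) * eff_w_sqrt(r) * dfac * sqw(p));
      for (int r = 0; r < nres; ++r)
        out.push_back(RES(r, p) * eff_w_sqrt(nmus + r) * dfac * sqw(p));
    }
  }
  const ivec jp_rows = as<ivec>(su["jp_rows"]);
  if (jp_rows.n_elem > 0) {
    const double jp_scale = as<double>(su["jp_scale"]);
    for (int p = 0; p < P; ++p)
      for (unsigned r = 0; r < jp_rows.n_elem; ++r)
        out.push_back(EXC(jp_rows(r), p) * jp_scale * sqw(p));
  }
  if (compliant && wad_on) {
    const double sqrt_wad = as<double>(su["sqrt_wad"]);
    for (int p = 0; p < P; ++p)
      for (int r = 0; r < nmus; ++r)
        out.push_back(DFT(r, p) * m.mus_fmax(r) * sqrt_wad * sqw(p));
  }

  // equalities
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < nx; ++s) out.push_back(DH(s, i));
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < nx; ++s) out.push_back(DS(s, i));
  for (int p = 0; p < P; ++p)
    for (int s = 0; s < nq; ++s) out.push_back(DYN(s, p));
  if (compliant)
    for (int p = 0; p < P; ++p)
      for (int s = 0; s < nmus; ++s) out.push_back(TEN(s, p));
  if (has_sym) {
    const ivec sperm = as<ivec>(su["sperm"]), cperm = as<ivec>(su["cperm"]);
    const ivec skeep = as<ivec>(su["skeep"]), ckeep = as<ivec>(su["ckeep"]);
    for (unsigned i = 0; i < skeep.n_elem; ++i) {
      int s = skeep(i);
      out.push_back((X(s, P - 1) - X(sperm(s), 0)) / sx(s));
    }
    for (unsigned i = 0; i < ckeep.n_elem; ++i) {
      int s = ckeep(i);
      out.push_back(U(s, P - 1) - U(cperm(s), 0));
    }
  }
  if (has_rest)
    for (int s = 0; s < nq; ++s) out.push_back(Uq(s, 0));
  if (has_avg) {
    const double tgt = as<double>(su["avg_target"]);
    out.push_back((com_x1 - com_x0) / tf - tgt);
  }
  const ivec epi_idx = as<ivec>(su["ep_init_idx"]);
  const vec epi_val = as<vec>(su["ep_init_val"]);
  for (unsigned i = 0; i < epi_idx.n_elem; ++i) {
    int s = epi_idx(i);
    out.push_back((X(s, 0) - epi_val(i)) / sx(s));
  }
  const ivec epf_idx = as<ivec>(su["ep_final_idx"]);
  const vec epf_val = as<vec>(su["ep_final_val"]);
  for (unsigned i = 0; i < epf_idx.n_elem; ++i) {
    int s = epf_idx(i);
    out.push_back((X(s, P - 1) - epf_val(i)) / sx(s));
  }

  // inequalities
  if (has_inter) {
    // clearance as smooth equality rows: gap - floor - slack, with the
    // bounded slack variables stored after t_f in the decision vector
    const double min_gap = as<double>(su["inter_min_gap"]);
    const int slack_off = as<int>(su["slack_off"]);
    int srow = 0;
    for (unsigned kk = 0; kk < cp_pairs.n_cols; ++kk) {
      int i = cp_pairs(0, kk), j = cp_pairs(1, kk);
      for (int p = 0; p < P; ++p) {
        double dx = CPOS(2 * i, p) - CPOS(2 * j, p);
        double dy = CPOS(2 * i + 1, p) - CPOS(2 * j + 1, p);
        out.push_back(std::sqrt(dx * dx + dy * dy + 1e-12) - min_gap -
                      x(slack_off + srow));
        ++srow;
      }
    }
  }
  if (has_knees && knee_events.n_rows > 0) {
    // rows of knee_events: (state row of the knee coordinate, node),
    // both 0-based; two hinge rows per event
    const double tol = as<double>(su["knee_tol"]);
    for (unsigned k = 0; k < knee_events.n_rows; ++k) {
      int kc = knee_events(k, 0), nd = knee_events(k, 1);
      out.push_back(tol - X(kc, nd));
      out.push_back(X(kc, nd) + tol);
    }
  }

  return vec(out);
}
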