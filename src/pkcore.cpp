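// Closed-form compartment model predictions and the FO / FOCE-I marginal
// likelihood kernel.  Structural kinds are coded as integers:
//   1 onecpt_iv   params CL, V
//   2 onecpt_oral params CL, V, KA
//   3 twocpt_iv   params CL, V, Q, V2
//   4 twocpt_oral params CL, V, KA, Q, V2
//   5 linear_test params CL (prediction is the eta-carrying parameter itself)
// IIV codes: 1 exponential, 2 additive.  Residual codes: 1 additive,
// 2 proportional, 3 combined (pred^2*s1 + s2, variances).
//
// Subject data arrive as concatenated arrays with 0-based offset vectors.
// The marginal covariance R + G Omega G' is handled by the Woodbury
// identity (R diagonal, rank = number of etas), and dF/deta is analytic
// for the IV-bolus/infusion and linear-test kinds (finite differences
// otherwise).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double VAR_FLOOR = 1e-12;

static void biexp_rates_cpp(double k10, double k12, double k21,
                            double &alpha, double &beta) {
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0) disc = 0;
  double r = std::sqrt(disc);
  alpha = 0.5 * (s + r);
  beta  = 0.5 * (s - r);
  if (beta < 0) beta = 0;
}

// single-dose contribution at time-after-dose tau >= 0
static double conc_one_dose(int kind, const double *pp, double amt,
                            double dur, double tau) {
  switch (kind) {
  case 1: { // one-compartment IV
    double CL = pp[0], V = pp[1], k = CL / V;
    if (dur <= 0.0) return amt / V * std::exp(-k * tau);
    double rate = amt / dur;
    if (tau <= dur) return rate / CL * (1.0 - std::exp(-k * tau));
    return rate / CL * (1.0 - std::exp(-k * dur)) * std::exp(-k * (tau - dur));
  }
  case 2: { // one-compartment first-order absorption (bolus into gut)
    double CL = pp[0], V = pp[1], ka = pp[2], k = CL / V;
    if (std::fabs(ka - k) < 1e-8 * k)  // analytic KA -> k limit
      return amt / V * k * tau * std::exp(-k * tau);
    return amt * ka / (V * (ka - k)) *
           (std::exp(-k * tau) - std::exp(-ka * tau));
  }
  case 3: { // two-compartment IV
    double CL = pp[0], V = pp[1], Q = pp[2], V2 = pp[3];
    double k10 = CL / V, k12 = Q / V, k21 = Q / V2, alpha, beta;
    biexp_rates_cpp(k10, k12, k21, alpha, beta);
    double den = alpha - beta, A, B;
    if (den < 1e-12 * std::max(alpha, 1.0)) { A = 1.0; B = 0.0; }
    else { A = (alpha - k21) / den; B = (k21 - beta) / den; }
    if (dur <= 0.0) {
      double c = A * std::exp(-alpha * tau);
      if (beta > 1e-300) c += B * std::exp(-beta * tau);
      else c += B;
      return amt / V * c;
    }
    double rate = amt / dur;
    double c;
    if (tau <= dur) {
      c = A / alpha * (1.0 - std::exp(-alpha * tau));
      if (beta > 1e-300) c += B / beta * (1.0 - std::exp(-beta * tau));
      else c += B * tau;
    } else {
      double rest = tau - dur;
      c = A / alpha * (1.0 - std::exp(-alpha * dur)) *
          std::exp(-alpha * rest);
      if (beta > 1e-300)
        c += B / beta * (1.0 - std::exp(-beta * dur)) * std::exp(-beta * rest);
      else c += B * dur;
    }
    return rate / V * c;
  }
  case 4: { // two-compartment first-order absorption
    double CL = pp[0], V = pp[1], ka = pp[2], Q = pp[3], V2 = pp[4];
    double k10 = CL / V, k12 = Q / V, k21 = Q / V2, alpha, beta;
    biexp_rates_cpp(k10, k12, k21, alpha, beta);
    // keep ka away from the alpha/beta poles
    if (std::fabs(ka - alpha) < 1e-8 * std::max(alpha, 1e-12))
      ka = alpha * (1.0 + 1e-7);
    if (std::fabs(ka - beta) < 1e-8 * std::max(beta, 1e-12))
      ka = beta * (1.0 + 1e-7) + 1e-12;
    double c = (k21 - alpha) / ((ka - alpha) * (beta - alpha)) *
               std::exp(-alpha * tau);
    if (beta > 1e-300)
      c += (k21 - beta) / ((ka - beta) * (alpha - beta)) * std::exp(-beta * tau);
    else
      c += k21 / (ka * alpha);
    c += (k21 - ka) / ((alpha - ka) * (beta - ka)) * std::exp(-ka * tau);
    return amt * ka / V * c;
  }
  case 5: // linear test model: prediction equals the parameter
    return pp[0];
  default:
    return NA_REAL;
  }
}

static void predict_subject(int kind, const double *p, const double *doses,
                            int nd, const double *times, int nt,
                            double *out) {
  if (kind == 5) {
    for (int j = 0; j < nt; ++j) out[j] = p[0];
    return;
  }
  for (int j = 0; j < nt; ++j) out[j] = 0.0;
  for (int d = 0; d < nd; ++d) {
    double td = doses[3 * d], amt = doses[3 * d + 1], dur = doses[3 * d + 2];
    for (int j = 0; j < nt; ++j) {
      double tau = times[j] - td;
      if (tau >= 0) out[j] += conc_one_dose(kind, p, amt, dur, tau);
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_predict_conc(int kind, const arma::vec &params,
                           const arma::mat &doses, const arma::vec &times) {
  vec out(times.n_elem);
  std::vector<double> dflat(3 * doses.n_rows);
  for (uword d = 0; d < doses.n_rows; ++d)
    for (int c = 0; c < 3; ++c) dflat[3 * d + c] = doses(d, c);
  predict_subject(kind, params.memptr(), dflat.data(), doses.n_rows,
                  times.memptr(), times.n_elem, out.memptr());
  return out;
}

static inline double resvar(int code, double f, double s1, double s2) {
  double v;
  if (code == 1) v = s1;
  else if (code == 2) v = f * f * s1;
  else v = f * f * s1 + s2;
  return v < VAR_FLOOR ? VAR_FLOOR : v;
}

// Reusable per-call scratch space: one allocation set for all subjects.
struct Work {
  std::vector<double> pbuf, dbuf, fwork, f0, jwork, G;
  std::vector<double> grad, step, enew, eta, b, z, H, A;
  void ensure(int np, int no, int ne) {
    if ((int)pbuf.size() < np) pbuf.resize(np);
    if ((int)dbuf.size() < 2 * no) dbuf.resize(2 * no);
    if ((int)fwork.size() < no) fwork.resize(no);
    if ((int)f0.size() < no) f0.resize(no);
    if ((int)jwork.size() < 2 * no + ne + 1) jwork.resize(2 * no + ne + 1);
    if ((int)G.size() < no * ne) G.resize(no * ne);
    int m = ne > 0 ? ne : 1;
    if ((int)grad.size() < m) {
      grad.resize(m); step.resize(m); enew.resize(m); eta.resize(m);
      b.resize(m); z.resize(m);
    }
    if ((int)H.size() < m * m) { H.resize(m * m); A.resize(m * m); }
  }
};

// Solve the SPD system M x = rhs (column-major, n x n).  Returns false
// when M is not positive definite.  Hand-coded for n <= 2 (the common
// eta dimensions), Armadillo otherwise.
static bool solve_spd(int n, const double *M, const double *rhs,
                      double *x) {
  if (n == 1) {
    if (!(M[0] > 0)) return false;
    x[0] = rhs[0] / M[0];
    return true;
  }
  if (n == 2) {
    double a = M[0], b = M[1], d = M[3];
    double det = a * d - b * b;
    if (!(a > 0) || !(det > 0)) return false;
    x[0] = (d * rhs[0] - b * rhs[1]) / det;
    x[1] = (a * rhs[1] - b * rhs[0]) / det;
    return true;
  }
  mat Mm(const_cast<double *>(M), n, n, false, true);
  vec rv(const_cast<double *>(rhs), n, false, true);
  vec xv(x, n, false, true);
  return solve(xv, Mm, rv, solve_opts::likely_sympd + solve_opts::no_approx);
}

// log-determinant of an SPD matrix, with PD check; n <= 2 closed form.
static bool logdet_spd(int n, const double *M, double &ld) {
  if (n == 1) {
    if (!(M[0] > 0)) return false;
    ld = std::log(M[0]);
    return true;
  }
  if (n == 2) {
    double det = M[0] * M[3] - M[1] * M[1];
    if (!(M[0] > 0) || !(det > 0)) return false;
    ld = std::log(det);
    return true;
  }
  mat Mm(const_cast<double *>(M), n, n, false, true);
  mat C;
  if (!chol(C, Mm, "lower")) return false;
  ld = 0;
  for (int i = 0; i < n; ++i) ld += 2.0 * std::log(C(i, i));
  return true;
}

struct SubjProblem {
  int kind, resid;
  int np, ne, no, nd;
  const double *tv;      // typical values (length np)
  const uword *iiv_idx;  // 0-based indices of params carrying eta
  const int *iiv_code;   // 1 exp, 2 add, aligned with iiv_idx
  const double *omega;   // SDs, aligned with iiv_idx
  double s1, s2;
  const double *doses;   // nd x (time, amount, duration), row-packed
  const double *times, *dv;
  bool positive_kind;

  bool indiv(const double *eta, double *p) const {
    for (int k = 0; k < np; ++k) p[k] = tv[k];
    for (int j = 0; j < ne; ++j) {
      uword ix = iiv_idx[j];
      p[ix] = (iiv_code[j] == 1) ? tv[ix] * std::exp(eta[j])
                                 : tv[ix] + eta[j];
    }
    if (positive_kind)
      for (int k = 0; k < np; ++k)
        if (!(p[k] > 0) || !std::isfinite(p[k])) return false;
    return true;
  }

  bool pred(const double *eta, double *f, Work &w) const {
    if (!indiv(eta, w.pbuf.data())) return false;
    predict_subject(kind, w.pbuf.data(), doses, nd, times, no, f);
    for (int j = 0; j < no; ++j) if (!std::isfinite(f[j])) return false;
    return true;
  }

  // conditional -2 log density (up to 2*pi constants)
  double cond_obj(const double *eta, Work &w) const {
    if (!pred(eta, w.fwork.data(), w)) return datum::inf;
    const double *f = w.fwork.data();
    double g = 0;
    for (int j = 0; j < no; ++j) {
      double v = resvar(resid, f[j], s1, s2);
      double r = dv[j] - f[j];
      g += std::log(v) + r * r / v;
    }
    for (int j = 0; j < ne; ++j)
      g += eta[j] * eta[j] / (omega[j] * omega[j]);
    return g;
  }

  // dF/d(CL, V) for the one-compartment IV model, accumulated over doses
  void dpred_onecpt_iv(const double *p, double *dcl, double *dv_) const {
    double CL = p[0], V = p[1], k = CL / V;
    for (int j = 0; j < no; ++j) { dcl[j] = 0.0; dv_[j] = 0.0; }
    for (int d = 0; d < nd; ++d) {
      double td = doses[3 * d], amt = doses[3 * d + 1],
             dur = doses[3 * d + 2];
      for (int j = 0; j < no; ++j) {
        double tau = times[j] - td;
        if (tau < 0) continue;
        if (dur <= 0.0) {
          double c = amt / V * std::exp(-k * tau);
          dcl[j] += -c * tau / V;
          dv_[j] += c * (k * tau - 1.0) / V;
        } else {
          double rate = amt / dur, dc_dk;
          if (tau <= dur) {
            double E = std::exp(-k * tau);
            double c = rate / CL * (1.0 - E);
            dc_dk = rate / CL * tau * E;
            dcl[j] += -c / CL + dc_dk / V;
            dv_[j] += -dc_dk * k / V;
          } else {
            double ET = std::exp(-k * dur), Er = std::exp(-k * (tau - dur));
            double c = rate / CL * (1.0 - ET) * Er;
            dc_dk = rate / CL *
                    (dur * ET * Er - (1.0 - ET) * (tau - dur) * Er);
            dcl[j] += -c / CL + dc_dk / V;
            dv_[j] += -dc_dk * k / V;
          }
        }
      }
    }
  }

  // G = dF/deta (no x ne, column-major in w.G): analytic for kinds 1
  // and 5, central finite differences otherwise
  bool jac(const double *eta, Work &w) const {
    double *G = w.G.data();
    if (kind == 1 || kind == 5) {
      if (!indiv(eta, w.pbuf.data())) return false;
      const double *p = w.pbuf.data();
      if (kind == 5) {
        for (int a = 0; a < ne; ++a) {
          double chain = (iiv_code[a] == 1) ? p[iiv_idx[a]] : 1.0;
          for (int j = 0; j < no; ++j)
            G[a * no + j] = (iiv_idx[a] == 0) ? chain : 0.0;
        }
        return true;
      }
      double *dcl = w.dbuf.data(), *dvv = dcl + no;
      dpred_onecpt_iv(p, dcl, dvv);
      for (int a = 0; a < ne; ++a) {
        uword ix = iiv_idx[a];
        double chain = (iiv_code[a] == 1) ? p[ix] : 1.0;
        const double *dp = (ix == 0) ? dcl : dvv;
        for (int j = 0; j < no; ++j) G[a * no + j] = dp[j] * chain;
      }
      return true;
    }
    double *fp = w.jwork.data(), *fm = fp + no, *e = fm + no;
    for (int j = 0; j < ne; ++j) e[j] = eta[j];
    for (int j = 0; j < ne; ++j) {
      double h = 1e-5 * (1.0 + std::fabs(eta[j]));
      e[j] = eta[j] + h;
      if (!pred(e, fp, w)) return false;
      e[j] = eta[j] - h;
      if (!pred(e, fm, w)) return false;
      e[j] = eta[j];
      for (int o = 0; o < no; ++o)
        G[j * no + o] = (fp[o] - fm[o]) / (2.0 * h);
    }
    return true;
  }
};

// Gauss-Newton search for the conditional mode eta-hat (in w.eta).
static bool inner_mode(const SubjProblem &sp, double *eta, double tol,
                       int max_iter, Work &w) {
  const int ne = sp.ne, no = sp.no;
  double g0 = sp.cond_obj(eta, w);
  if (!std::isfinite(g0)) {
    for (int j = 0; j < ne; ++j) eta[j] = 0.0;
    g0 = sp.cond_obj(eta, w);
  }
  if (!std::isfinite(g0)) return false;
  double *grad = w.grad.data(), *H = w.H.data(), *step = w.step.data(),
         *enew = w.enew.data();
  for (int it = 0; it < max_iter; ++it) {
    if (!sp.pred(eta, w.f0.data(), w)) return false;
    if (!sp.jac(eta, w)) return false;
    const double *f = w.f0.data(), *G = w.G.data();
    for (int a = 0; a < ne; ++a) {
      grad[a] = 0.0;
      for (int c = 0; c < ne; ++c) H[c * ne + a] = 0.0;
    }
    for (int j = 0; j < no; ++j) {
      double v = resvar(sp.resid, f[j], sp.s1, sp.s2);
      double r = sp.dv[j] - f[j];
      double dvdf = (sp.resid == 1) ? 0.0 : 2.0 * f[j] * sp.s1;
      for (int a = 0; a < ne; ++a) {
        double Ga = G[a * no + j];
        grad[a] += dvdf * Ga / v - 2.0 * r * Ga / v -
                   r * r * dvdf * Ga / (v * v);
        for (int c = 0; c <= a; ++c)
          H[c * ne + a] += 2.0 * Ga * G[c * no + j] / v +
                           0.5 * dvdf * dvdf * Ga * G[c * no + j] /
                               (v * v);
      }
    }
    double gmax = 0.0;
    for (int a = 0; a < ne; ++a) {
      grad[a] += 2.0 * eta[a] / (sp.omega[a] * sp.omega[a]);
      H[a * ne + a] += 2.0 / (sp.omega[a] * sp.omega[a]);
      for (int c = a + 1; c < ne; ++c) H[c * ne + a] = H[a * ne + c];
      if (std::fabs(grad[a]) > gmax) gmax = std::fabs(grad[a]);
    }
    if (gmax < tol) return true;
    for (int a = 0; a < ne; ++a) grad[a] = -grad[a];
    if (!solve_spd(ne, H, grad, step)) return false;
    double t = 1.0, gnew = datum::inf;
    for (int ls = 0; ls < 25; ++ls) {
      for (int a = 0; a < ne; ++a) enew[a] = eta[a] + t * step[a];
      gnew = sp.cond_obj(enew, w);
      if (std::isfinite(gnew) && gnew <= g0 + 1e-12) break;
      t *= 0.5;
    }
    if (!std::isfinite(gnew) || gnew > g0) return true;  // stalled
    double smax = 0.0;
    for (int a = 0; a < ne; ++a)
      if (std::fabs(t * step[a]) > smax) smax = std::fabs(t * step[a]);
    bool tiny = (g0 - gnew < 1e-12 * (1.0 + std::fabs(g0))) &&
                smax < 1e-10;
    for (int a = 0; a < ne; ++a) eta[a] = enew[a];
    g0 = gnew;
    if (tiny) return true;
  }
  return true;  // iteration cap reached with a usable point
}

static SubjProblem make_subj(int i, int kind, int resid, const mat &tv,
                             const uvec &iiv_idx, const ivec &iiv_code,
                             const vec &omega, double s1, double s2,
                             const vec &times, const vec &dv,
                             const ivec &obs_off, const vec &dose_flat,
                             const ivec &dose_off, double *tvrow) {
  SubjProblem sp;
  sp.kind = kind; sp.resid = resid;
  sp.np = tv.n_cols; sp.ne = iiv_idx.n_elem;
  for (int k = 0; k < sp.np; ++k) tvrow[k] = tv(i, k);
  sp.tv = tvrow;
  sp.iiv_idx = iiv_idx.memptr();
  sp.iiv_code = iiv_code.memptr();
  sp.omega = omega.memptr();
  sp.s1 = s1; sp.s2 = s2;
  sp.no = obs_off[i + 1] - obs_off[i];
  sp.times = times.memptr() + obs_off[i];
  sp.dv = dv.memptr() + obs_off[i];
  sp.nd = dose_off[i + 1] - dose_off[i];
  sp.doses = dose_flat.memptr() + 3 * dose_off[i];
  sp.positive_kind = (kind != 5);
  return sp;
}

// Marginal -2 log likelihood contribution of one subject at its eta via
// the Woodbury identity on Sigma = R + G Omega G' (R diagonal, G in
// w.G, predictions in w.f0).  Returns false on a non-PD factorization.
static bool subject_obv(const SubjProblem &sp, const double *eta,
                        Work &w, double &out) {
  const int ne = sp.ne, no = sp.no;
  const double *f = w.f0.data();
  double ld_R = 0.0, quad = 0.0;
  if (ne == 0) {
    for (int j = 0; j < no; ++j) {
      double v = resvar(sp.resid, f[j], sp.s1, sp.s2);
      double r = sp.dv[j] - f[j];
      ld_R += std::log(v);
      quad += r * r / v;
    }
    out = ld_R + quad;
    return true;
  }
  const double *G = w.G.data();
  double *A = w.A.data(), *b = w.b.data(), *z = w.z.data();
  double ld_Om = 0.0;
  for (int a = 0; a < ne; ++a) {
    b[a] = 0.0;
    for (int c = 0; c < ne; ++c) A[c * ne + a] = 0.0;
    double w2 = sp.omega[a] * sp.omega[a];
    A[a * ne + a] = 1.0 / w2;
    ld_Om += std::log(w2);
  }
  for (int j = 0; j < no; ++j) {
    double v = resvar(sp.resid, f[j], sp.s1, sp.s2);
    ld_R += std::log(v);
    // linearized residual y - F(eta) + G eta
    double rr = sp.dv[j] - f[j];
    for (int a = 0; a < ne; ++a) rr += G[a * no + j] * eta[a];
    quad += rr * rr / v;
    for (int a = 0; a < ne; ++a) {
      double gw = G[a * no + j] / v;
      b[a] += gw * rr;
      for (int c = 0; c <= a; ++c) A[c * ne + a] += gw * G[c * no + j];
    }
  }
  for (int a = 0; a < ne; ++a)
    for (int c = a + 1; c < ne; ++c) A[c * ne + a] = A[a * ne + c];
  double ld_A;
  if (!logdet_spd(ne, A, ld_A)) return false;
  if (!solve_spd(ne, A, b, z)) return false;
  double bz = 0.0;
  for (int a = 0; a < ne; ++a) bz += b[a] * z[a];
  out = ld_R + ld_Om + ld_A + quad - bz;
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_neg2ll(int kind, int method, const arma::mat &tv,
                      const arma::uvec &iiv_idx, const arma::ivec &iiv_code,
                      const arma::vec &omega, int resid_code,
                      const arma::vec &sigma, const arma::vec &times,
                      const arma::vec &dv, const arma::ivec &obs_off,
                      const arma::vec &dose_flat, const arma::ivec &dose_off,
                      double inner_tol, int inner_max,
                      const arma::mat &eta_start) {
  const int ns = tv.n_rows;
  const int ne = iiv_idx.n_elem;
  const int np = tv.n_cols;
  const bool foce = (method == 1) && ne > 0;
  double s1 = sigma[0], s2 = sigma.n_elem > 1 ? sigma[1] : 0.0;

  double obv = 0.0;
  bool ok = true;
  mat etas(ns, ne, fill::zeros);
  if (eta_start.n_rows == (uword)ns && eta_start.n_cols == (uword)ne)
    etas = eta_start;
  Work w;
  int max_no = 0;
  for (int i = 0; i < ns; ++i)
    if (obs_off[i + 1] - obs_off[i] > max_no)
      max_no = obs_off[i + 1] - obs_off[i];
  w.ensure(np, max_no, ne);
  std::vector<double> tvrow(np);

  for (int i = 0; i < ns && ok; ++i) {
    SubjProblem sp = make_subj(i, kind, resid_code, tv, iiv_idx, iiv_code,
                               omega, s1, s2, times, dv, obs_off,
                               dose_flat, dose_off, tvrow.data());
    if (sp.no == 0) continue;

    double *eta = w.eta.data();
    for (int a = 0; a < ne; ++a) eta[a] = 0.0;
    if (foce) {
      for (int a = 0; a < ne; ++a) eta[a] = etas(i, a);
      if (!inner_mode(sp, eta, inner_tol, inner_max, w)) {
        ok = false; break;
      }
      for (int a = 0; a < ne; ++a) etas(i, a) = eta[a];
    }

    if (!sp.pred(eta, w.f0.data(), w)) { ok = false; break; }
    if (ne > 0 && !sp.jac(eta, w)) { ok = false; break; }
    double contrib;
    if (!subject_obv(sp, eta, w, contrib)) { ok = false; break; }
    obv += contrib;
  }

  if (!ok || !std::isfinite(obv))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("obv") = NA_REAL);
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("obv") = obv,
                            Rcpp::Named("etas") = etas);
}

// Per-subject conditional mode at fixed population parameters (EBE pass)
// with individual predictions at the mode.
// [[Rcpp::export]]
Rcpp::List cpp_ebe(int kind, const arma::mat &tv, const arma::uvec &iiv_idx,
                   const arma::ivec &iiv_code, const arma::vec &omega,
                   int resid_code, const arma::vec &sigma,
                   const arma::vec &times, const arma::vec &dv,
                   const arma::ivec &obs_off, const arma::vec &dose_flat,
                   const arma::ivec &dose_off, double inner_tol,
                   int inner_max) {
  const int ns = tv.n_rows;
  const int ne = iiv_idx.n_elem;
  const int np = tv.n_cols;
  double s1 = sigma[0], s2 = sigma.n_elem > 1 ? sigma[1] : 0.0;
  mat etas(ns, ne, fill::zeros);
  Rcpp::LogicalVector flagged(ns);
  vec ipred(times.n_elem, fill::value(NA_REAL));
  Work w;
  int max_no = 0;
  for (int i = 0; i < ns; ++i)
    if (obs_off[i + 1] - obs_off[i] > max_no)
      max_no = obs_off[i + 1] - obs_off[i];
  w.ensure(np, max_no, ne);
  std::vector<double> tvrow(np);

  for (int i = 0; i < ns; ++i) {
    SubjProblem sp = make_subj(i, kind, resid_code, tv, iiv_idx, iiv_code,
                               omega, s1, s2, times, dv, obs_off,
                               dose_flat, dose_off, tvrow.data());
    double *eta = w.eta.data();
    for (int a = 0; a < ne; ++a) eta[a] = 0.0;
    bool okk = true;
    if (ne > 0 && sp.no > 0)
      okk = inner_mode(sp, eta, inner_tol, inner_max, w);
    if (!okk) for (int a = 0; a < ne; ++a) eta[a] = 0.0;
    if (!okk) flagged[i] = true;
    for (int a = 0; a < ne; ++a) etas(i, a) = eta[a];
    if (sp.no > 0) {
      if (sp.pred(eta, w.f0.data(), w)) {
        for (int j = 0; j < sp.no; ++j) ipred[obs_off[i] + j] = w.f0[j];
      } else flagged[i] = true;
    }
  }
  return Rcpp::List::create(Rcpp::Named("etas") = etas,
                            Rcpp::Named("ipred") = ipred,
                            Rcpp::Named("flagged") = flagged);
}
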