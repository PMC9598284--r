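// Core linear-system machinery for the minimal CNS PBPK model.
//
// States are amounts (mg), ordered:
//   0 blood, 1 tissue, 2 brain vasculature, 3 brain ECF, 4 CSF,
//   5 EVD collection bag (absorbing),
//   6 cumulative integral of blood amount      (mg*h)
//   7 cumulative integral of ECF amount        (mg*h)
//   8 cumulative integral of CSF amount        (mg*h)
// The three cumulative states make interval-averaged observations
// (microdialysis fractions, EVD bag concentrations, AUCs) exact:
// they are propagated through the same matrix exponential as the
// physical states, never through grid quadrature.
//
// Parameter vector layout (see .pack_pars() on the R side):
//   0 V_B, 1 V_tissue, 2 V_brain_vasc, 3 V_ECF, 4 V_CSF,
//   5 fd*CO, 6 Q_brain, 7 CL, 8 Kp, 9 PS_ECF, 10 PS_CSF,
//   11 Q_bulk, 12 Q_sink_physio

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NPHYS = 6;   // physical states
static const int NAUG  = 9;   // physical + cumulative-integral states

// Effective sink flow: drain flow is assumed to replace physiological
// CSF reabsorption, floored at zero when the drain exceeds it.
static double sink_flow(double q_sink_physio, double q_evd) {
  double q = q_sink_physio - q_evd;
  return q > 0.0 ? q : 0.0;
}

// Amount-space rate matrix of the six physical compartments.
static mat rate_matrix(const vec& p, double q_evd) {
  const double VB = p[0], VT = p[1], VV = p[2], VE = p[3], VC = p[4];
  const double fdCO = p[5], Qbr = p[6], CL = p[7], Kp = p[8];
  const double PSE = p[9], PSC = p[10], Qbulk = p[11];
  const double Qsink = sink_flow(p[12], q_evd);

  mat A(NPHYS, NPHYS, fill::zeros);
  // blood
  A(0, 0) = -(fdCO + Qbr + CL) / VB;
  A(0, 1) = fdCO / (Kp * VT);
  A(0, 2) = Qbr / VV;
  // lumped tissue
  A(1, 0) = fdCO / VB;
  A(1, 1) = -fdCO / (Kp * VT);
  // brain vasculature
  A(2, 0) = Qbr / VB;
  A(2, 2) = -(Qbr + PSE + PSC) / VV;
  A(2, 3) = PSE / VE;
  A(2, 4) = (PSC + Qsink) / VC;
  // brain ECF
  A(3, 2) = PSE / VV;
  A(3, 3) = -(PSE + Qbulk) / VE;
  // CSF
  A(4, 2) = PSC / VV;
  A(4, 3) = Qbulk / VE;
  A(4, 4) = -(PSC + Qsink + q_evd) / VC;
  // EVD bag (absorbing)
  A(5, 4) = q_evd / VC;
  return A;
}

static mat augmented_matrix(const vec& p, double q_evd) {
  mat A(NAUG, NAUG, fill::zeros);
  A.submat(0, 0, NPHYS - 1, NPHYS - 1) = rate_matrix(p, q_evd);
  A(6, 0) = 1.0;  // d/dt cum_B   = A_B
  A(7, 3) = 1.0;  // d/dt cum_ECF = A_ECF
  A(8, 4) = 1.0;  // d/dt cum_CSF = A_CSF
  return A;
}

// Compact system for the estimation path: the five circulating states
// plus the two cumulative integrals the observation models need
// (ECF for dialysate fractions, CSF for the drained amount). The EVD
// bag and blood integral are not tracked: the drain only removes mass,
// so dropping the absorbing state does not change the dynamics.
static const int NCMP = 7;

static mat compact_matrix(const vec& p, double q_evd) {
  mat A6 = rate_matrix(p, q_evd);
  mat A(NCMP, NCMP, fill::zeros);
  A.submat(0, 0, 4, 4) = A6.submat(0, 0, 4, 4);
  A(5, 3) = 1.0;  // d/dt cum_ECF = A_ECF
  A(6, 4) = 1.0;  // d/dt cum_CSF = A_CSF
  return A;
}

static void compact_propagator(const vec& p, double q_evd, double rate,
                               double dt, mat& E, vec& f) {
  mat M(NCMP + 1, NCMP + 1, fill::zeros);
  M.submat(0, 0, NCMP - 1, NCMP - 1) = compact_matrix(p, q_evd);
  M(0, NCMP) = rate;
  mat EM = expmat(M * dt);
  E = EM.submat(0, 0, NCMP - 1, NCMP - 1);
  f = EM.submat(0, NCMP, NCMP - 1, NCMP);
}

// Exact transition over one constant-coefficient segment: returns the
// pair (E, f) with x(dt) = E x(0) + f, via the standard augmentation
// exp([[A, u], [0, 0]] dt) = [[E, f], [0, 1]].
static void segment_propagator(const vec& p, double q_evd, double rate,
                               double dt, mat& E, vec& f) {
  mat M(NAUG + 1, NAUG + 1, fill::zeros);
  M.submat(0, 0, NAUG - 1, NAUG - 1) = augmented_matrix(p, q_evd);
  M(0, NAUG) = rate;  // infusion into blood, mg/h
  mat EM = expmat(M * dt);
  E = EM.submat(0, 0, NAUG - 1, NAUG - 1);
  f = EM.submat(0, NAUG, NAUG - 1, NAUG);
}

// [[Rcpp::export(name = ".rate_matrix_cpp")]]
arma::mat rate_matrix_cpp(const arma::vec& pars, double q_evd) {
  return rate_matrix(pars, q_evd);
}

// Propagate an initial augmented state through a piecewise-constant
// segment schedule; returns states at every break (row 0 = x0).
// [[Rcpp::export(name = ".propagate_cpp")]]
arma::mat propagate_cpp(const arma::vec& pars, const arma::vec& x0,
                        const arma::vec& seg_dt, const arma::vec& seg_rate,
                        const arma::vec& seg_qevd) {
  const uword n = seg_dt.n_elem;
  mat out(n + 1, NAUG);
  vec x = x0;
  out.row(0) = x.t();
  mat E; vec f;
  double last_dt = datum::nan, last_rate = datum::nan, last_q = datum::nan;
  for (uword k = 0; k < n; ++k) {
    if (seg_dt[k] != last_dt || seg_rate[k] != last_rate ||
        seg_qevd[k] != last_q) {
      segment_propagator(pars, seg_qevd[k], seg_rate[k], seg_dt[k], E, f);
      last_dt = seg_dt[k]; last_rate = seg_rate[k]; last_q = seg_qevd[k];
    }
    x = E * x + f;
    out.row(k + 1) = x.t();
  }
  return out;
}

// Periodic (steady-state) augmented state at the start of a dosing
// interval, for the segment schedule covering exactly one interval.
// Only the five circulating states are periodic; the EVD bag and the
// cumulative integrals restart at zero each interval.
// [[Rcpp::export(name = ".steady_state_cpp")]]
Rcpp::List steady_state_cpp(const arma::vec& pars, const arma::vec& seg_dt,
                            const arma::vec& seg_rate,
                            const arma::vec& seg_qevd) {
  const uword n = seg_dt.n_elem;
  mat P(NAUG, NAUG, fill::eye);
  vec q(NAUG, fill::zeros);
  mat E; vec f;
  double last_dt = datum::nan, last_rate = datum::nan, last_q = datum::nan;
  for (uword k = 0; k < n; ++k) {
    if (seg_dt[k] != last_dt || seg_rate[k] != last_rate ||
        seg_qevd[k] != last_q) {
      segment_propagator(pars, seg_qevd[k], seg_rate[k], seg_dt[k], E, f);
      last_dt = seg_dt[k]; last_rate = seg_rate[k]; last_q = seg_qevd[k];
    }
    P = E * P;
    q = E * q + f;
  }
  // circulating block: states 0..4
  mat P5 = P.submat(0, 0, 4, 4);
  vec q5 = q.subvec(0, 4);
  mat I5(5, 5, fill::eye);
  vec x5;
  bool ok = solve(x5, I5 - P5, q5, solve_opts::no_approx);
  vec x0(NAUG, fill::zeros);
  double resid = datum::inf;
  if (ok) {
    x0.subvec(0, 4) = x5;
    resid = norm((I5 - P5) * x5 - q5) / std::max(norm(q5), 1e-300);
  }
  return Rcpp::List::create(Rcpp::Named("x0") = x0,
                            Rcpp::Named("ok") = ok,
                            Rcpp::Named("residual") = resid);
}

// ---------------------------------------------------------------------
// Population-likelihood machinery
// ---------------------------------------------------------------------

struct SubjectDesign {
  vec seg_dt, seg_rate, seg_qevd;
  ivec obs_type;          // 0 plasma, 1 dialysate, 2 evd
  uvec i1, i2;            // break-row indices into the state matrix
  vec dt_obs;             // interval length (h) for interval streams
  vec qevd_obs, vevd_obs; // per-observation EVD flow / sample volume
  vec dv;                 // observed values (mg/L)
  vec pars;               // subject-specific parameter vector
};

static SubjectDesign unpack_subject(const Rcpp::List& s) {
  SubjectDesign d;
  d.seg_dt   = Rcpp::as<vec>(s["seg_dt"]);
  d.seg_rate = Rcpp::as<vec>(s["seg_rate"]);
  d.seg_qevd = Rcpp::as<vec>(s["seg_qevd"]);
  d.obs_type = Rcpp::as<ivec>(s["obs_type"]);
  d.i1       = Rcpp::as<uvec>(s["i1"]);
  d.i2       = Rcpp::as<uvec>(s["i2"]);
  d.dt_obs   = Rcpp::as<vec>(s["dt_obs"]);
  d.qevd_obs = Rcpp::as<vec>(s["qevd_obs"]);
  d.vevd_obs = Rcpp::as<vec>(s["vevd_obs"]);
  d.dv       = Rcpp::as<vec>(s["dv"]);
  d.pars     = Rcpp::as<vec>(s["pars"]);
  return d;
}

// Steady-state predictions for every observation of one subject
// (compact 7-state system).
static vec subject_predictions(const SubjectDesign& d, const vec& pars) {
  const uword n = d.seg_dt.n_elem;
  mat P(NCMP, NCMP, fill::eye);
  vec q(NCMP, fill::zeros);
  mat E; vec f;
  std::vector<mat> Es(n);
  std::vector<vec> fs(n);
  double last_dt = datum::nan, last_rate = datum::nan, last_q = datum::nan;
  for (uword k = 0; k < n; ++k) {
    if (d.seg_dt[k] != last_dt || d.seg_rate[k] != last_rate ||
        d.seg_qevd[k] != last_q) {
      compact_propagator(pars, d.seg_qevd[k], d.seg_rate[k], d.seg_dt[k],
                         E, f);
      last_dt = d.seg_dt[k]; last_rate = d.seg_rate[k];
      last_q = d.seg_qevd[k];
    }
    Es[k] = E; fs[k] = f;
    P = E * P;
    q = E * q + f;
  }
  mat P5 = P.submat(0, 0, 4, 4);
  vec q5 = q.subvec(0, 4);
  mat I5(5, 5, fill::eye);
  vec x5;
  if (!solve(x5, I5 - P5, q5, solve_opts::no_approx))
    Rcpp::stop("steady-state periodicity system is singular");
  vec x(NCMP, fill::zeros);
  x.subvec(0, 4) = x5;
  mat X(n + 1, NCMP);
  X.row(0) = x.t();
  for (uword k = 0; k < n; ++k) {
    x = Es[k] * x + fs[k];
    X.row(k + 1) = x.t();
  }
  const double VB = pars[0], VE = pars[3], VC = pars[4];
  const uword m = d.dv.n_elem;
  vec pred(m);
  for (uword j = 0; j < m; ++j) {
    switch (d.obs_type[j]) {
    case 0:  // plasma: point concentration in blood
      pred[j] = X(d.i1[j], 0) / VB;
      break;
    case 1:  // dialysate: time-average of C_ECF over the interval
      pred[j] = (X(d.i2[j], 5) - X(d.i1[j], 5)) / (VE * d.dt_obs[j]);
      break;
    default: // evd: amount drained over the interval / sample volume
      pred[j] = d.qevd_obs[j] * (X(d.i2[j], 6) - X(d.i1[j], 6)) /
                (VC * d.vevd_obs[j]);
    }
  }
  return pred;
}

// -log p(y | eta) with combined (proportional + additive) error for
// plasma and proportional-only error for the CNS streams.
static double subject_nll(const SubjectDesign& d, const vec& pred,
                          double s_pp, double s_ap, double s_pE,
                          double s_pC) {
  const double LOG2PI = 1.8378770664093453;
  double nll = 0.0;
  for (uword j = 0; j < pred.n_elem; ++j) {
    double v;
    switch (d.obs_type[j]) {
    case 0:  v = s_pp * s_pp * pred[j] * pred[j] + s_ap * s_ap; break;
    case 1:  v = s_pE * s_pE * pred[j] * pred[j]; break;
    default: v = s_pC * s_pC * pred[j] * pred[j];
    }
    if (!(v > 1e-12)) v = 1e-12;
    double r = d.dv[j] - pred[j];
    nll += 0.5 * (LOG2PI + std::log(v) + r * r / v);
  }
  return nll;
}

// theta layout: 0 CL, 1 Kp, 2 PS_ECF, 3 PS_CSF, 4 omega_CL,
//               5 s_prop_plasma, 6 s_add_plasma, 7 s_prop_ECF, 8 s_prop_CSF
static double eta_objective(const SubjectDesign& d, const vec& theta,
                            double eta) {
  vec pars = d.pars;
  pars[7] = theta[0] * std::exp(eta);  // CL_i
  pars[8] = theta[1];                  // Kp
  pars[9] = theta[2];                  // PS_ECF
  pars[10] = theta[3];                 // PS_CSF
  vec pred = subject_predictions(d, pars);
  double omega = theta[4];
  return subject_nll(d, pred, theta[5], theta[6], theta[7], theta[8]) +
         0.5 * eta * eta / (omega * omega);
}

// -log p(y | eta) alone (no shrinkage penalty) — exposed for tests
// and empirical-Bayes diagnostics.
// [[Rcpp::export(name = ".subject_cond_nll_cpp")]]
double subject_cond_nll_cpp(const Rcpp::List& subject,
                            const arma::vec& theta, double eta) {
  SubjectDesign d = unpack_subject(subject);
  vec pars = d.pars;
  pars[7] = theta[0] * std::exp(eta);
  pars[8] = theta[1];
  pars[9] = theta[2];
  pars[10] = theta[3];
  vec pred = subject_predictions(d, pars);
  return subject_nll(d, pred, theta[5], theta[6], theta[7], theta[8]);
}

// [[Rcpp::export(name = ".subject_pred_cpp")]]
arma::vec subject_pred_cpp(const Rcpp::List& subject, const arma::vec& theta,
                           double eta) {
  SubjectDesign d = unpack_subject(subject);
  vec pars = d.pars;
  pars[7] = theta[0] * std::exp(eta);
  pars[8] = theta[1];
  pars[9] = theta[2];
  pars[10] = theta[3];
  return subject_predictions(d, pars);
}

// Laplace-approximated marginal -log-likelihood, with a safeguarded
// Newton search for the per-subject empirical-Bayes mode.
// [[Rcpp::export(name = ".laplace_nll_cpp")]]
Rcpp::List laplace_nll_cpp(const Rcpp::List& subjects,
                           const arma::vec& theta,
                           const arma::vec& eta_start) {
  const int S = subjects.size();
  vec etas(S), nll_i(S);
  double total = 0.0;
  const double h = 1e-4, eta_lo = -6.0, eta_hi = 6.0;
  const double omega = theta[4];

  for (int s = 0; s < S; ++s) {
    SubjectDesign d = unpack_subject(subjects[s]);
    double eta = eta_start[s];
    if (!std::isfinite(eta)) eta = 0.0;
    double f0 = eta_objective(d, theta, eta);
    double H = 1.0 / (omega * omega);
    for (int it = 0; it < 15; ++it) {
      double fp = eta_objective(d, theta, eta + h);
      double fm = eta_objective(d, theta, eta - h);
      double g1 = (fp - fm) / (2.0 * h);
      double g2 = (fp - 2.0 * f0 + fm) / (h * h);
      if (g2 > 1e-8) H = g2;
      if (std::abs(g1) < 1e-8) break;
      double step;
      if (g2 > 1e-8) step = -g1 / g2;
      else step = (g1 > 0 ? -0.2 : 0.2);
      if (step > 1.0) step = 1.0;
      if (step < -1.0) step = -1.0;
      double eta_new = eta + step;
      if (eta_new < eta_lo) eta_new = eta_lo;
      if (eta_new > eta_hi) eta_new = eta_hi;
      double f_new = eta_objective(d, theta, eta_new);
      // backtrack if the Newton step overshoots
      int bt = 0;
      while (f_new > f0 + 1e-12 && bt < 8) {
        eta_new = eta + (eta_new - eta) * 0.5;
        f_new = eta_objective(d, theta, eta_new);
        ++bt;
      }
      double moved = std::abs(eta_new - eta);
      if (f_new <= f0) { eta = eta_new; f0 = f_new; }
      if (moved < 1e-7) break;
    }
    double li = f0 + std::log(omega) + 0.5 * std::log(H);
    etas[s] = eta;
    nll_i[s] = li;
    total += li;
  }
  return Rcpp::List::create(Rcpp::Named("nll") = total,
                            Rcpp::Named("etas") = etas,
                            Rcpp::Named("nll_subject") = nll_i);
}
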