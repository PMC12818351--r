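// MCMC core for replica-averaged forward-model inference.
//
// The sampler walks over (replica states, sigma_B, phi, theta) with one
// composite sweep per step: one replica state move, then per observable type
// a log-space sigma_B move, a log-space phi move (Good-Bad only), and a
// theta move (gradient-informed during burn-in, plain random walk after).
// Predictions are linear in theta through per-state cos^2/cos basis matrices
// plus an arbitrary offset matrix, so replica-averaged means and SEMs are
// maintained with O(n_obs) running sums.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static const double LOG_2PI = 1.837877066409345483560659472811;

struct LikePars {
  int code;                    // 0 gaussian, 1 good-bad, 2 multi-severity
  std::vector<double> levels;  // severity inflators phi_m (code 2)
};

// H(x) = 1 for x > 0, H(0) = 0: gates stay open at sigma_B -> 0.
static inline bool gate_open(double x) { return !(x > 0.0); }

// -log likelihood for one observable given residual d - g.
static double obs_nll(double resid, double sem, double sigB, double phi,
                      const LikePars &lp) {
  const double s0sq = sigB * sigB + sem * sem;
  const double r2 = resid * resid;
  if (lp.code == 0) {
    return 0.5 * (LOG_2PI + std::log(s0sq)) + r2 / (2.0 * s0sq);
  } else if (lp.code == 1) {
    const double s0 = std::sqrt(s0sq);
    const double p2 = phi * phi;
    double l1 = gate_open(sem - s0)
                    ? std::log(0.5) - 0.5 * (LOG_2PI + std::log(s0sq)) -
                          r2 / (2.0 * s0sq)
                    : R_NegInf;
    double l2 = gate_open(sem - phi * s0)
                    ? std::log(0.5) - 0.5 * (LOG_2PI + std::log(p2 * s0sq)) -
                          r2 / (2.0 * p2 * s0sq)
                    : R_NegInf;
    double m = std::max(l1, l2);
    if (!R_finite(m)) return R_PosInf;
    double dlt = std::fabs(l1 - l2);
    if (dlt > 34.0) return -m;           // the other component is negligible
    return -(m + std::log1p(std::exp(-dlt)));
  }
  const int M = (int)lp.levels.size();
  const double s0 = std::sqrt(s0sq);
  double m = R_NegInf;
  std::vector<double> ls(M, R_NegInf);
  for (int i = 0; i < M; ++i) {
    const double pm = lp.levels[i];
    if (pm * s0 - sem > 0.0) {
      ls[i] = -std::log((double)M) - 0.5 * (LOG_2PI + std::log(pm * pm * s0sq)) -
              r2 / (2.0 * pm * pm * s0sq);
      if (ls[i] > m) m = ls[i];
    }
  }
  if (!R_finite(m)) return R_PosInf;
  double s = 0.0;
  for (int i = 0; i < M; ++i) s += std::exp(ls[i] - m);
  return -(m + std::log(s));
}

// Mixture weight multiplying (d-g)/s0^2 in du/dtheta; 1 for Gaussian,
// reduces the pull of observables parked in the wide ("bad") component.
static double obs_gradweight(double resid, double sem, double sigB, double phi,
                             const LikePars &lp) {
  const double s0sq = sigB * sigB + sem * sem;
  const double r2 = resid * resid;
  if (lp.code == 0) return 1.0;
  if (lp.code == 1) {
    const double s0 = std::sqrt(s0sq);
    const double p2 = phi * phi;
    double l1 = gate_open(sem - s0)
                    ? std::log(0.5) - 0.5 * std::log(s0sq) - r2 / (2.0 * s0sq)
                    : R_NegInf;
    double l2 = gate_open(sem - phi * s0)
                    ? std::log(0.5) - 0.5 * std::log(p2 * s0sq) -
                          r2 / (2.0 * p2 * s0sq)
                    : R_NegInf;
    double m = std::max(l1, l2);
    if (!R_finite(m)) return 1.0;
    double w1 = R_finite(l1) ? std::exp(l1 - m) : 0.0;
    double w2 = R_finite(l2) ? std::exp(l2 - m) : 0.0;
    return (w1 + w2 / p2) / (w1 + w2);
  }
  const int M = (int)lp.levels.size();
  const double s0 = std::sqrt(s0sq);
  double m = R_NegInf;
  std::vector<double> ls(M, R_NegInf);
  for (int i = 0; i < M; ++i) {
    const double pm = lp.levels[i];
    if (pm * s0 - sem > 0.0) {
      ls[i] = -0.5 * std::log(pm * pm * s0sq) - r2 / (2.0 * pm * pm * s0sq);
      if (ls[i] > m) m = ls[i];
    }
  }
  if (!R_finite(m)) return 1.0;
  double num = 0.0, den = 0.0;
  for (int i = 0; i < M; ++i) {
    if (!R_finite(ls[i])) continue;
    double w = std::exp(ls[i] - m);
    den += w;
    num += w / (lp.levels[i] * lp.levels[i]);
  }
  return den > 0.0 ? num / den : 1.0;
}

class ReplicaSampler {
 public:
  // basis matrices (n_states x n_obs): prediction for replica in state s is
  // A*c2(s,j) + B*c1(s,j) + C + j0(s,j) with (A,B,C) of the observable's type
  NumericMatrix c2, c1, j0;
  IntegerVector type;   // 0-based type per observable
  NumericVector d;      // experimental couplings
  NumericVector logp;   // log prior populations per state
  int S, J, N, K;
  LikePars lp;
  double xi;
  bool sample_theta;
  double lrate, eta, step_sigma, step_phi, step_theta, step_trade;
  int sem_mode;  // 0: sd/sqrt(N), 1: sd/N, 2: sd
  double sig_lo, sig_hi, phi_lo, phi_hi, th_lo, th_hi;

  std::vector<int> rep;                      // replica states, 0-based
  std::vector<double> A, B, C, sigB, phiv;   // per type
  // running sums over replicas, per observable
  std::vector<double> S2, S1, S0, Q22, Q11, Q00, Q21, Q20, Q10;
  std::vector<double> gmean, sem, nll;       // caches per observable
  std::vector<std::vector<int> > obs_of;     // observables per type
  double u_repprior, u_nuis;

  // reusable scratch buffers (avoid per-move heap churn)
  std::vector<double> scr_sv, scr_g, scr_sem, scr_nll, scr_vec;

  long prop_rep = 0, acc_rep = 0, prop_sig = 0, acc_sig = 0;
  long prop_phi = 0, acc_phi = 0, prop_th = 0, acc_th = 0;
  long prop_trade = 0, acc_trade = 0;

  void init_sums() {
    S2.assign(J, 0.0); S1.assign(J, 0.0); S0.assign(J, 0.0);
    Q22.assign(J, 0.0); Q11.assign(J, 0.0); Q00.assign(J, 0.0);
    Q21.assign(J, 0.0); Q20.assign(J, 0.0); Q10.assign(J, 0.0);
    for (int r = 0; r < N; ++r) {
      int s = rep[r];
      for (int j = 0; j < J; ++j) {
        double a = c2(s, j), b = c1(s, j), o = j0(s, j);
        S2[j] += a; S1[j] += b; S0[j] += o;
        Q22[j] += a * a; Q11[j] += b * b; Q00[j] += o * o;
        Q21[j] += a * b; Q20[j] += a * o; Q10[j] += b * o;
      }
    }
    u_repprior = 0.0;
    for (int r = 0; r < N; ++r) u_repprior -= logp[rep[r]];
  }

  void refresh_obs(int j) {
    int k = type[j];
    double a = A[k], b = B[k], cc = C[k];
    double sp = a * S2[j] + b * S1[j] + N * cc + S0[j];
    double sp2 = a * a * Q22[j] + b * b * Q11[j] + Q00[j] + N * cc * cc +
                 2.0 * a * b * Q21[j] + 2.0 * a * Q20[j] + 2.0 * b * Q10[j] +
                 2.0 * cc * (a * S2[j] + b * S1[j] + S0[j]);
    double m = sp / N;
    double v = sp2 / N - m * m;
    if (v < 0.0) v = 0.0;
    gmean[j] = m;
    double sd = std::sqrt(v);
    sem[j] = sem_mode == 0 ? sd / std::sqrt((double)N)
                           : (sem_mode == 1 ? sd / N : sd);
    nll[j] = obs_nll(d[j] - m, sem[j], sigB[k], phiv[k], lp);
  }

  void refresh_all() {
    for (int j = 0; j < J; ++j) refresh_obs(j);
  }

  double nuis_energy() const {
    // truncated Jeffreys priors: uniform density in log sigma / log phi
    double u = 0.0;
    for (int k = 0; k < K; ++k) {
      u += std::log(sigB[k]);
      if (sig_hi > sig_lo) u += std::log(std::log(sig_hi / sig_lo));
      if (lp.code == 1) {
        u += std::log(phiv[k]);
        if (phi_hi > phi_lo) u += std::log(std::log(phi_hi / phi_lo));
      }
    }
    return u;
  }

  double u_data() const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += nll[j];
    return N * s;
  }

  void grad_theta(int k, double *g3) const {
    double gA = 0.0, gB = 0.0, gC = 0.0;
    const std::vector<int> &oj = obs_of[k];
    for (size_t t = 0; t < oj.size(); ++t) {
      int j = oj[t];
      double s0sq = sigB[k] * sigB[k] + sem[j] * sem[j];
      double resid = d[j] - gmean[j];
      double w = obs_gradweight(resid, sem[j], sigB[k], phiv[k], lp);
      double common = w * resid / s0sq;
      gA -= S2[j] * common;  // N * dg/dA = S2
      gB -= S1[j] * common;
      gC -= N * common;
    }
    g3[0] = gA; g3[1] = gB; g3[2] = gC;
  }

  void move_replica() {
    ++prop_rep;
    int r = (int)std::floor(unif_rand() * N);
    if (r >= N) r = N - 1;
    int snew = (int)std::floor(unif_rand() * S);
    if (snew >= S) snew = S - 1;
    int sold = rep[r];
    if (snew == sold) { ++acc_rep; return; }
    double old_nll_sum = 0.0;
    scr_sv.resize(9 * (size_t)J);
    scr_g.resize(J); scr_sem.resize(J); scr_nll.resize(J);
    std::vector<double> &sv = scr_sv, &gold = scr_g, &semold = scr_sem,
                        &nllold = scr_nll;
    for (int j = 0; j < J; ++j) {
      old_nll_sum += nll[j];
      sv[9 * j + 0] = S2[j]; sv[9 * j + 1] = S1[j]; sv[9 * j + 2] = S0[j];
      sv[9 * j + 3] = Q22[j]; sv[9 * j + 4] = Q11[j]; sv[9 * j + 5] = Q00[j];
      sv[9 * j + 6] = Q21[j]; sv[9 * j + 7] = Q20[j]; sv[9 * j + 8] = Q10[j];
      gold[j] = gmean[j]; semold[j] = sem[j]; nllold[j] = nll[j];
      double a_n = c2(snew, j), b_n = c1(snew, j), o_n = j0(snew, j);
      double a_o = c2(sold, j), b_o = c1(sold, j), o_o = j0(sold, j);
      S2[j] += a_n - a_o; S1[j] += b_n - b_o; S0[j] += o_n - o_o;
      Q22[j] += a_n * a_n - a_o * a_o;
      Q11[j] += b_n * b_n - b_o * b_o;
      Q00[j] += o_n * o_n - o_o * o_o;
      Q21[j] += a_n * b_n - a_o * b_o;
      Q20[j] += a_n * o_n - a_o * o_o;
      Q10[j] += b_n * o_n - b_o * o_o;
      refresh_obs(j);
    }
    double new_nll_sum = 0.0;
    for (int j = 0; j < J; ++j) new_nll_sum += nll[j];
    double dU = (logp[sold] - logp[snew]) + xi * N * (new_nll_sum - old_nll_sum);
    if (std::log(unif_rand()) < -dU) {
      rep[r] = snew;
      u_repprior += logp[sold] - logp[snew];
      ++acc_rep;
    } else {
      for (int j = 0; j < J; ++j) {
        S2[j] = sv[9 * j + 0]; S1[j] = sv[9 * j + 1]; S0[j] = sv[9 * j + 2];
        Q22[j] = sv[9 * j + 3]; Q11[j] = sv[9 * j + 4]; Q00[j] = sv[9 * j + 5];
        Q21[j] = sv[9 * j + 6]; Q20[j] = sv[9 * j + 7]; Q10[j] = sv[9 * j + 8];
        gmean[j] = gold[j]; sem[j] = semold[j]; nll[j] = nllold[j];
      }
    }
  }

  // log-space random walk; Jacobian cancels the Jeffreys prior term, so the
  // acceptance ratio carries only the data term.
  void move_sigma(int k) {
    ++prop_sig;
    double cand = sigB[k] * std::exp(step_sigma * norm_rand());
    if (cand < sig_lo || cand > sig_hi) return;
    const std::vector<int> &oj = obs_of[k];
    double dnll = 0.0;
    std::vector<double> nl(oj.size());
    for (size_t t = 0; t < oj.size(); ++t) {
      int j = oj[t];
      nl[t] = obs_nll(d[j] - gmean[j], sem[j], cand, phiv[k], lp);
      dnll += nl[t] - nll[j];
    }
    if (std::log(unif_rand()) < -xi * N * dnll) {
      sigB[k] = cand;
      for (size_t t = 0; t < oj.size(); ++t) nll[oj[t]] = nl[t];
      ++acc_sig;
    }
  }

  void move_phi(int k) {
    if (lp.code != 1) return;
    ++prop_phi;
    double cand = phiv[k] * std::exp(step_phi * norm_rand());
    if (cand < phi_lo || cand > phi_hi) return;
    const std::vector<int> &oj = obs_of[k];
    double dnll = 0.0;
    std::vector<double> nl(oj.size());
    for (size_t t = 0; t < oj.size(); ++t) {
      int j = oj[t];
      nl[t] = obs_nll(d[j] - gmean[j], sem[j], sigB[k], cand, lp);
      dnll += nl[t] - nll[j];
    }
    if (std::log(unif_rand()) < -xi * N * dnll) {
      phiv[k] = cand;
      for (size_t t = 0; t < oj.size(); ++t) nll[oj[t]] = nl[t];
      ++acc_phi;
    }
  }

  // correlated (sigma_B down, phi up) proposal along the near-degenerate
  // direction separating the "sloppy Gaussian" and "tight + wide outlier"
  // basins; symmetric in (log sigma, log phi), so the truncated Jeffreys
  // priors cancel as in the single-coordinate moves.
  void move_trade(int k) {
    if (lp.code != 1) return;
    ++prop_trade;
    double z = step_trade * norm_rand();
    double sig_c = sigB[k] * std::exp(-z);
    double phi_c = phiv[k] * std::exp(z);
    if (sig_c < sig_lo || sig_c > sig_hi || phi_c < phi_lo || phi_c > phi_hi)
      return;
    const std::vector<int> &oj = obs_of[k];
    double dnll = 0.0;
    std::vector<double> nl(oj.size());
    for (size_t t = 0; t < oj.size(); ++t) {
      int j = oj[t];
      nl[t] = obs_nll(d[j] - gmean[j], sem[j], sig_c, phi_c, lp);
      dnll += nl[t] - nll[j];
    }
    if (std::log(unif_rand()) < -xi * N * dnll) {
      sigB[k] = sig_c;
      phiv[k] = phi_c;
      for (size_t t = 0; t < oj.size(); ++t) nll[oj[t]] = nl[t];
      ++acc_trade;
    }
  }

  void robust_nuisances() {
    for (int k = 0; k < K; ++k) {
      const std::vector<int> &oj = obs_of[k];
      std::vector<double> ar(oj.size());
      for (size_t t = 0; t < oj.size(); ++t)
        ar[t] = std::fabs(d[oj[t]] - gmean[oj[t]]);
      std::sort(ar.begin(), ar.end());
      double med = ar[ar.size() / 2];
      double s = 1.4826 * med;
      if (s < sig_lo) s = sig_lo;
      if (s > sig_hi) s = sig_hi;
      sigB[k] = s;
      double p = 0.75 * phi_hi;
      if (p < phi_lo) p = phi_lo;
      phiv[k] = (lp.code == 1) ? p : phiv[k];
      for (size_t t = 0; t < oj.size(); ++t) refresh_obs(oj[t]);
    }
  }

  void move_theta(int k, bool burnin) {
    ++prop_th;
    double An, Bn, Cn;
    if (burnin && (lrate > 0.0 || eta > 0.0)) {
      double g3[3];
      grad_theta(k, g3);
      An = A[k] - lrate * g3[0] + eta * norm_rand();
      Bn = B[k] - lrate * g3[1] + eta * norm_rand();
      Cn = C[k] - lrate * g3[2] + eta * norm_rand();
    } else {
      // 10% of proposals take a 5x stride to hop between nearby sub-modes
      double st = (unif_rand() < 0.1) ? 5.0 * step_theta : step_theta;
      An = A[k] + st * norm_rand();
      Bn = B[k] + st * norm_rand();
      Cn = C[k] + st * norm_rand();
    }
    if (An < th_lo || An > th_hi || Bn < th_lo || Bn > th_hi ||
        Cn < th_lo || Cn > th_hi)
      return;
    // sigma_SEM is recomputed only after replica moves and cached here:
    // theta moves see a fixed sem (matching the analytic gradient's
    // fixed-finite-sampling-error convention), which closes
    // the degenerate channel of inflating the coefficients to inflate the
    // replica spread and thereby the error bars.
    const std::vector<int> &oj = obs_of[k];
    double dnll = 0.0;
    std::vector<double> gm(oj.size()), nl(oj.size());
    for (size_t t = 0; t < oj.size(); ++t) {
      int j = oj[t];
      double sp = An * S2[j] + Bn * S1[j] + N * Cn + S0[j];
      double m = sp / N;
      gm[t] = m;
      nl[t] = obs_nll(d[j] - m, sem[j], sigB[k], phiv[k], lp);
      dnll += nl[t] - nll[j];
    }
    if (std::log(unif_rand()) < -xi * N * dnll) {
      A[k] = An; B[k] = Bn; C[k] = Cn;
      for (size_t t = 0; t < oj.size(); ++t) {
        int j = oj[t];
        gmean[j] = gm[t]; nll[j] = nl[t];
      }
      ++acc_th;
    }
  }
};

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericMatrix c2, NumericMatrix c1, NumericMatrix j0,
                   IntegerVector obs_type, NumericVector d,
                   NumericVector log_prior_pop, List cfg) {
  ReplicaSampler sm;
  sm.c2 = c2; sm.c1 = c1; sm.j0 = j0;
  sm.type = obs_type; sm.d = d; sm.logp = log_prior_pop;
  sm.S = c2.nrow(); sm.J = c2.ncol();
  sm.N = as<int>(cfg["n_replicas"]);
  sm.K = as<int>(cfg["n_types"]);
  sm.lp.code = as<int>(cfg["likelihood_code"]);
  if (sm.lp.code == 2) sm.lp.levels = as<std::vector<double> >(cfg["severity_levels"]);
  sm.xi = as<double>(cfg["xi"]);
  sm.sample_theta = as<bool>(cfg["sample_theta"]);
  sm.lrate = as<double>(cfg["lrate"]);
  sm.eta = as<double>(cfg["eta"]);
  sm.step_sigma = as<double>(cfg["step_sigma"]);
  sm.step_phi = as<double>(cfg["step_phi"]);
  sm.step_theta = as<double>(cfg["step_theta"]);
  sm.step_trade = as<double>(cfg["step_trade"]);
  sm.sem_mode = as<int>(cfg["sem_mode"]);
  NumericVector sb = cfg["sigma_bounds"], pb = cfg["phi_bounds"],
                tb = cfg["theta_bounds"];
  sm.sig_lo = sb[0]; sm.sig_hi = sb[1];
  sm.phi_lo = pb[0]; sm.phi_hi = pb[1];
  sm.th_lo = tb[0]; sm.th_hi = tb[1];
  const int n_burn = as<int>(cfg["n_burn"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int n_anneal = as<int>(cfg["n_anneal"]);
  const int thin = as<int>(cfg["thin"]);
  sm.A = as<std::vector<double> >(cfg["init_A"]);
  sm.B = as<std::vector<double> >(cfg["init_B"]);
  sm.C = as<std::vector<double> >(cfg["init_C"]);
  sm.sigB = as<std::vector<double> >(cfg["init_sigma"]);
  sm.phiv = as<std::vector<double> >(cfg["init_phi"]);
  sm.rep = as<std::vector<int> >(cfg["init_states"]);  // 0-based

  sm.obs_of.assign(sm.K, std::vector<int>());
  for (int j = 0; j < sm.J; ++j) sm.obs_of[obs_type[j]].push_back(j);
  sm.gmean.assign(sm.J, 0.0);
  sm.sem.assign(sm.J, 0.0);
  sm.nll.assign(sm.J, 0.0);

  GetRNGstate();
  sm.init_sums();
  sm.refresh_all();
  sm.u_nuis = sm.nuis_energy();
  {
    double u0 = sm.u_repprior + sm.u_nuis + sm.xi * sm.u_data();
    if (!R_finite(u0)) {
      PutRNGstate();
      stop("non-finite initial energy (u = %g); check data, predictions and bounds",
           u0);
    }
  }

  const int n_rec = n_steps / thin;
  const bool record_states = as<bool>(cfg["record_states"]);
  const int K = sm.K;
  IntegerMatrix tr_states(record_states ? n_rec : 0, record_states ? sm.N : 0);
  NumericVector tr_u(n_rec), tr_uprior(n_rec), tr_udata(n_rec);
  NumericMatrix tr_A(n_rec, K), tr_B(n_rec, K), tr_C(n_rec, K);
  NumericMatrix tr_sig(n_rec, K), tr_phi(n_rec, K);
  NumericMatrix tr_gA(n_rec, K), tr_gB(n_rec, K), tr_gC(n_rec, K);
  NumericVector occ(sm.S);

  int rec = 0;
  const int total = n_burn + n_steps;
  const int rep_moves = as<int>(cfg["replica_moves_per_sweep"]);
  for (int step = 0; step < total; ++step) {
    const bool burnin = step < n_burn;
    const bool anneal = step < n_anneal;
    for (int r = 0; r < rep_moves; ++r) sm.move_replica();
    if (anneal) {
      // robust warm start: outlier component held wide open, sigma_B pinned
      // to a median-absolute-residual scale while theta descends; the
      // warm-start steps are part of burn-in and are discarded
      if (step % 200 == 0) sm.robust_nuisances();
    } else {
      for (int k = 0; k < K; ++k) sm.move_sigma(k);
      for (int k = 0; k < K; ++k) sm.move_phi(k);
      for (int k = 0; k < K; ++k) sm.move_trade(k);
    }
    if (sm.sample_theta)
      for (int k = 0; k < K; ++k) sm.move_theta(k, burnin);
    if ((step + 1) % 5000 == 0) {  // guard against running-sum drift
      sm.init_sums();
      sm.refresh_all();
    }
    if (!burnin) {
      for (int r = 0; r < sm.N; ++r) occ[sm.rep[r]] += 1.0;
      int pstep = step - n_burn;
      if ((pstep + 1) % thin == 0 && rec < n_rec) {
        double ud = sm.u_data();
        double up = sm.u_repprior + sm.nuis_energy();
        tr_u[rec] = up + sm.xi * ud;
        tr_uprior[rec] = up;
        tr_udata[rec] = ud;
        if (record_states)
          for (int r = 0; r < sm.N; ++r) tr_states(rec, r) = sm.rep[r] + 1;
        for (int k = 0; k < K; ++k) {
          tr_A(rec, k) = sm.A[k]; tr_B(rec, k) = sm.B[k]; tr_C(rec, k) = sm.C[k];
          tr_sig(rec, k) = sm.sigB[k]; tr_phi(rec, k) = sm.phiv[k];
          double g3[3];
          sm.grad_theta(k, g3);
          tr_gA(rec, k) = g3[0]; tr_gB(rec, k) = g3[1]; tr_gC(rec, k) = g3[2];
        }
        ++rec;
      }
    }
  }
  PutRNGstate();

  IntegerVector final_states(sm.N);
  for (int r = 0; r < sm.N; ++r) final_states[r] = sm.rep[r] + 1;
  return List::create(
      _["u"] = tr_u, _["u_prior"] = tr_uprior, _["u_data"] = tr_udata,
      _["A"] = tr_A, _["B"] = tr_B, _["C"] = tr_C,
      _["sigma_B"] = tr_sig, _["phi"] = tr_phi,
      _["grad_A"] = tr_gA, _["grad_B"] = tr_gB, _["grad_C"] = tr_gC,
      _["occupancy"] = occ,
      _["replica_states"] = tr_states,
      _["final_states"] = final_states,
      _["acceptance"] = List::create(
          _["replica"] = NumericVector::create((double)sm.acc_rep, (double)sm.prop_rep),
          _["sigma"] = NumericVector::create((double)sm.acc_sig, (double)sm.prop_sig),
          _["phi"] = NumericVector::create((double)sm.acc_phi, (double)sm.prop_phi),
          _["trade"] = NumericVector::create((double)sm.acc_trade, (double)sm.prop_trade),
          _["theta"] = NumericVector::create((double)sm.acc_th, (double)sm.prop_th)));
}
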