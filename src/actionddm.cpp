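#include <Rcpp.h>
#include <vector>
#include <array>
#include "rng.h"
#include "wfpt.h"

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// parameter order used throughout: alpha, b_v, b_z, v_intercept, a, t

// ---------------------------------------------------------------------------
// WFPT density exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector wfpt_logpdf_cpp(NumericVector rt, IntegerVector boundary,
                              NumericVector v, NumericVector a,
                              NumericVector z, NumericVector t0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = rt[i] - t0[i];
    if (!(u > 0.0)) { out[i] = NEG_INF; continue; }
    out[i] = (boundary[i] > 0)
      ? wfpt_logpdf_upper(u, v[i], a[i], z[i])
      : wfpt_logpdf_lower(u, v[i], a[i], z[i]);
  }
  return out;
}

// [[Rcpp::export]]
double ddm_prob_upper_cpp(double v, double a, double z) {
  return ddm_prob_upper(v, a, z);
}

// ---------------------------------------------------------------------------
// First-passage sampling: Euler-Maruyama with Brownian-bridge crossing checks
// ---------------------------------------------------------------------------

// Simulate one first passage. Writes decision rt (including t0) and boundary
// (+1 upper, -1 lower, 0 censored at the deadline).
static void em_first_passage(double v, double a, double z, double t0,
                             double dt, double deadline, Rng& rng,
                             double& rt, int& boundary) {
  double x = z * a;
  double max_dec = deadline - t0;
  double sdt = std::sqrt(dt);
  double tt = 0.0;
  // guard against pathological t0 >= deadline
  if (!(max_dec > 0.0)) { boundary = 0; rt = NA_REAL; return; }
  while (tt < max_dec) {
    double xn = x + v * dt + sdt * rng.norm();
    tt += dt;
    if (xn >= a) { boundary = 1;  rt = t0 + tt; return; }
    if (xn <= 0.0) { boundary = -1; rt = t0 + tt; return; }
    // within-step boundary crossing via Brownian-bridge probabilities;
    // exp() only evaluated when the path came close to a boundary
    double du = (a - x) * (a - xn);
    double dl = x * xn;
    double pu = (du < 10.0 * dt) ? std::exp(-2.0 * du / dt) : 0.0;
    double pl = (dl < 10.0 * dt) ? std::exp(-2.0 * dl / dt) : 0.0;
    if (pu > 0.0 || pl > 0.0) {
      double uu = rng.unif();
      if (uu < pu) { boundary = 1;  rt = t0 + tt; return; }
      if (uu < pu + pl) { boundary = -1; rt = t0 + tt; return; }
    }
    x = xn;
  }
  boundary = 0;
  rt = NA_REAL;
}

// [[Rcpp::export]]
List wfpt_sample_cpp(int n, double v, double a, double z, double t0,
                     double dt, double deadline, double seed) {
  Rng rng((uint64_t)seed);
  NumericVector rt(n);
  IntegerVector boundary(n);
  for (int i = 0; i < n; ++i) {
    double r; int b;
    em_first_passage(v, a, z, t0, dt, deadline, rng, r, b);
    rt[i] = r; boundary[i] = b;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}

// ---------------------------------------------------------------------------
// Sequential Action-DDM likelihood
// ---------------------------------------------------------------------------

struct SubjData {
  std::vector<int> stim;    // +1 rich, -1 lean
  std::vector<int> resp;    // +1 rich, -1 lean, 0 none
  std::vector<int> reward;  // 0/1
  std::vector<int> valid;   // contributes to likelihood
  std::vector<int> updq;    // feedback updates Q
  std::vector<double> rt;   // seconds (NA allowed when resp == 0)
  int n;
};

static SubjData as_subjdata(List s) {
  SubjData d;
  IntegerVector stim = s["stim"], resp = s["resp"], reward = s["reward"],
    valid = s["valid"], updq = s["updq"];
  NumericVector rt = s["rt"];
  d.n = stim.size();
  d.stim.assign(stim.begin(), stim.end());
  d.resp.assign(resp.begin(), resp.end());
  d.reward.assign(reward.begin(), reward.end());
  d.valid.assign(valid.begin(), valid.end());
  d.updq.assign(updq.begin(), updq.end());
  d.rt.assign(rt.begin(), rt.end());
  return d;
}

// Core sequential likelihood. If trial_lp is non-null it receives the
// per-trial log density (0 for trials outside the likelihood). If latents is
// non-null it receives columns q_rich, q_lean, delta_q, v_t, z_t (pre-choice).
static double subj_loglik(const SubjData& d, const double* p, int sign_whole,
                          double* trial_lp = 0, double* latents = 0) {
  double alpha = p[0], bv = p[1], bz = p[2], vint = p[3], a = p[4], t0 = p[5];
  double qr = 0.0, ql = 0.0, ll = 0.0;
  bool dead = false;
  for (int i = 0; i < d.n; ++i) {
    double dq = qr - ql;
    double z = 1.0 / (1.0 + std::exp(-bz * dq));
    double s = (double)d.stim[i];
    double vt = sign_whole ? s * (vint + bv * dq) : s * vint + bv * dq;
    if (latents) {
      latents[i] = qr; latents[d.n + i] = ql; latents[2 * d.n + i] = dq;
      latents[3 * d.n + i] = vt; latents[4 * d.n + i] = z;
    }
    double lp = 0.0;
    if (!dead && d.valid[i] && d.resp[i] != 0) {
      double u = d.rt[i] - t0;
      lp = (d.resp[i] == 1) ? wfpt_logpdf_upper(u, vt, a, z)
                            : wfpt_logpdf_lower(u, vt, a, z);
      ll += lp;
      if (!std::isfinite(ll)) { dead = true; ll = NEG_INF; }
    }
    if (trial_lp) trial_lp[i] = lp;
    if (d.resp[i] != 0 && d.updq[i]) {
      if (d.resp[i] == 1) qr += alpha * ((double)d.reward[i] - qr);
      else                ql += alpha * ((double)d.reward[i] - ql);
    }
  }
  return ll;
}

// [[Rcpp::export]]
List subject_loglik_cpp(List subj, NumericVector params, int sign_whole,
                        bool return_latents) {
  SubjData d = as_subjdata(subj);
  double p[6];
  for (int j = 0; j < 6; ++j) p[j] = params[j];
  if (return_latents) {
    NumericMatrix lat(d.n, 5);
    double ll = subj_loglik(d, p, sign_whole, 0, lat.begin());
    colnames(lat) = CharacterVector::create("q_rich", "q_lean", "delta_q",
                                            "v_t", "z_t");
    return List::create(_["loglik"] = ll, _["latents"] = lat);
  }
  double ll = subj_loglik(d, p, sign_whole);
  return List::create(_["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// Forward simulation of one subject on a schedule
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_subject_cpp(IntegerVector stim, IntegerVector reward_sched,
                          int queued, NumericVector params, int sign_whole,
                          double dt, double deadline, double seed,
                          IntegerVector block) {
  int n = stim.size();
  double p[6];
  for (int j = 0; j < 6; ++j) p[j] = params[j];
  double alpha = p[0], bv = p[1], bz = p[2], vint = p[3], a = p[4], t0 = p[5];
  Rng rng((uint64_t)seed);
  IntegerVector resp(n), reward(n);
  NumericVector rt(n);
  NumericMatrix lat(n, 5);
  double qr = 0.0, ql = 0.0;
  int pending_rich = 0, pending_lean = 0, cur_block = block.size() ? block[0] : 1;
  for (int i = 0; i < n; ++i) {
    if (block.size() && block[i] != cur_block) {
      // queued rewards do not carry across blocks
      cur_block = block[i];
      pending_rich = 0; pending_lean = 0;
    }
    double dq = qr - ql;
    double z = 1.0 / (1.0 + std::exp(-bz * dq));
    double s = (double)stim[i];
    double vt = sign_whole ? s * (vint + bv * dq) : s * vint + bv * dq;
    lat(i, 0) = qr; lat(i, 1) = ql; lat(i, 2) = dq; lat(i, 3) = vt; lat(i, 4) = z;
    double rti; int bnd;
    em_first_passage(vt, a, z, t0, dt, deadline, rng, rti, bnd);
    resp[i] = bnd;
    rt[i] = rti;
    int correct = (bnd != 0 && bnd == stim[i]) ? 1 : 0;
    int r = 0;
    if (queued) {
      if (reward_sched[i]) {
        if (stim[i] == 1) ++pending_rich; else ++pending_lean;
      }
      if (correct) {
        if (stim[i] == 1 && pending_rich > 0) { r = 1; --pending_rich; }
        if (stim[i] == -1 && pending_lean > 0) { r = 1; --pending_lean; }
      }
    } else {
      r = (correct && reward_sched[i]) ? 1 : 0;
    }
    reward[i] = r;
    if (bnd != 0) {
      if (bnd == 1) qr += alpha * ((double)r - qr);
      else          ql += alpha * ((double)r - ql);
    }
  }
  colnames(lat) = CharacterVector::create("q_rich", "q_lean", "delta_q",
                                          "v_t", "z_t");
  return List::create(_["resp"] = resp, _["rt"] = rt, _["reward"] = reward,
                      _["latents"] = lat);
}

// ---------------------------------------------------------------------------
// Hierarchical adaptive Metropolis-within-Gibbs sampler
// ---------------------------------------------------------------------------

// unconstrained -> natural scale, honoring variant restrictions
static void transform_params(const double* u, const int* active,
                             const double* fixed_nat, int shared_b,
                             double* p) {
  p[0] = 1.0 / (1.0 + std::exp(-u[0]));
  p[1] = u[1];
  p[2] = u[2];
  p[3] = u[3];
  p[4] = std::exp(u[4]);
  p[5] = std::exp(u[5]);
  for (int j = 0; j < 6; ++j) if (!active[j]) p[j] = fixed_nat[j];
  if (shared_b) p[2] = p[1];
}

static inline double dnorm_log(double x, double m, double s) {
  double zz = (x - m) / s;
  return -0.918938533204672742 - std::log(s) - 0.5 * zz * zz;
}

// [[Rcpp::export]]
List mcmc_hier_cpp(List subj_list, IntegerVector active_, NumericVector fixed_nat_,
                   int shared_b, int sign_whole,
                   NumericVector prior_mu_mean, NumericVector prior_mu_sd,
                   NumericVector prior_sigma_sd,
                   int n_chains, int n_iter, int n_warmup, int thin,
                   double seed, int hierarchical, NumericMatrix init_theta) {
  int nsub = subj_list.size();
  std::vector<SubjData> data(nsub);
  for (int s = 0; s < nsub; ++s) data[s] = as_subjdata(subj_list[s]);

  int active[6];
  double fixed_nat[6], pm[6], psd[6], hsd[6];
  for (int j = 0; j < 6; ++j) {
    active[j] = active_[j];
    fixed_nat[j] = fixed_nat_[j];
    pm[j] = prior_mu_mean[j];
    psd[j] = prior_mu_sd[j];
    hsd[j] = prior_sigma_sd[j];
  }
  // under shared_B the b_z slot is not sampled
  if (shared_b) active[2] = 0;

  int n_keep = (n_iter - n_warmup) / thin;
  List chains(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    Rng rng((uint64_t)seed + 0x9E3779B97F4A7C15ULL * (uint64_t)(c + 1));

    // state
    std::vector<std::array<double, 6> > theta(nsub);
    std::vector<double> cur_ll(nsub);
    double mu[6], sig[6];
    for (int s = 0; s < nsub; ++s)
      for (int j = 0; j < 6; ++j) {
        theta[s][j] = init_theta(s, j);
        if (active[j]) theta[s][j] += 0.15 * rng.norm();
      }
    // repair any initializations with impossible likelihood (t0 >= min rt)
    for (int s = 0; s < nsub; ++s) {
      double p[6];
      transform_params(theta[s].data(), active, fixed_nat, shared_b, p);
      cur_ll[s] = subj_loglik(data[s], p, sign_whole);
      int tries = 0;
      while (!std::isfinite(cur_ll[s]) && tries < 200) {
        if (active[5]) theta[s][5] -= 0.05;  // shrink non-decision time
        if (active[4]) theta[s][4] += 0.01;  // widen threshold slightly
        transform_params(theta[s].data(), active, fixed_nat, shared_b, p);
        cur_ll[s] = subj_loglik(data[s], p, sign_whole);
        ++tries;
      }
    }
    for (int j = 0; j < 6; ++j) {
      double m = 0.0, ss = 0.0;
      for (int s = 0; s < nsub; ++s) m += theta[s][j];
      m /= nsub;
      for (int s = 0; s < nsub; ++s) ss += (theta[s][j] - m) * (theta[s][j] - m);
      mu[j] = m;
      sig[j] = std::max(nsub > 1 ? std::sqrt(ss / (nsub - 1)) : 0.3, 0.1);
    }

    // adaptation state
    std::vector<std::array<double, 6> > lstep(nsub);
    for (int s = 0; s < nsub; ++s) lstep[s].fill(std::log(0.25));
    double lstep_sig[6], lstep_nc[6];
    for (int j = 0; j < 6; ++j) lstep_sig[j] = std::log(0.3);
    for (int j = 0; j < 6; ++j) lstep_nc[j] = std::log(0.1);
    std::vector<std::array<double, 6> > acc_sum(nsub), acc_n(nsub);
    for (int s = 0; s < nsub; ++s) { acc_sum[s].fill(0.0); acc_n[s].fill(0.0); }

    NumericMatrix mu_out(n_keep, 6), sig_out(n_keep, 6),
      theta_out(n_keep, nsub * 6);
    NumericVector ll_out(n_keep);
    int keep_i = 0;

    for (int iter = 1; iter <= n_iter; ++iter) {
      bool warm = iter <= n_warmup;
      // subject-level componentwise Metropolis
      for (int s = 0; s < nsub; ++s) {
        for (int j = 0; j < 6; ++j) {
          if (!active[j]) continue;
          double old = theta[s][j];
          double prop = old + std::exp(lstep[s][j]) * rng.norm();
          double p[6];
          std::array<double, 6> th = theta[s];
          th[j] = prop;
          transform_params(th.data(), active, fixed_nat, shared_b, p);
          double ll_new = subj_loglik(data[s], p, sign_whole);
          double lprior_new, lprior_old;
          if (hierarchical) {
            lprior_new = dnorm_log(prop, mu[j], sig[j]);
            lprior_old = dnorm_log(old, mu[j], sig[j]);
          } else {
            lprior_new = dnorm_log(prop, pm[j], psd[j]);
            lprior_old = dnorm_log(old, pm[j], psd[j]);
          }
          double logr = ll_new - cur_ll[s] + lprior_new - lprior_old;
          double ap = std::isfinite(logr) ? std::min(1.0, std::exp(logr)) : 0.0;
          if (rng.unif() < ap) { theta[s][j] = prop; cur_ll[s] = ll_new; }
          if (warm) {
            double gamma = 1.0 / std::pow((double)iter, 0.6);
            lstep[s][j] += gamma * (ap - 0.44);
          } else {
            acc_sum[s][j] += ap; acc_n[s][j] += 1.0;
          }
        }
      }
      // group level
      if (hierarchical) {
        for (int j = 0; j < 6; ++j) {
          if (!active[j]) continue;
          // Gibbs for mu_j (normal prior)
          double sum = 0.0;
          for (int s = 0; s < nsub; ++s) sum += theta[s][j];
          double prec = nsub / (sig[j] * sig[j]) + 1.0 / (psd[j] * psd[j]);
          double mean = (sum / (sig[j] * sig[j]) + pm[j] / (psd[j] * psd[j])) / prec;
          mu[j] = mean + rng.norm() / std::sqrt(prec);
          // Metropolis on log sigma_j with half-normal prior
          double ls_old = std::log(sig[j]);
          double ls_new = ls_old + std::exp(lstep_sig[j]) * rng.norm();
          double s_new = std::exp(ls_new);
          double ssq = 0.0;
          for (int s = 0; s < nsub; ++s) {
            double dlt = theta[s][j] - mu[j];
            ssq += dlt * dlt;
          }
          double lp_old = -nsub * ls_old - ssq / (2.0 * sig[j] * sig[j])
            - sig[j] * sig[j] / (2.0 * hsd[j] * hsd[j]) + ls_old;
          double lp_new = -nsub * ls_new - ssq / (2.0 * s_new * s_new)
            - s_new * s_new / (2.0 * hsd[j] * hsd[j]) + ls_new;
          double ap = std::min(1.0, std::exp(lp_new - lp_old));
          if (rng.unif() < ap) sig[j] = s_new;
          if (warm) {
            double gamma = 1.0 / std::pow((double)iter, 0.6);
            lstep_sig[j] += gamma * (ap - 0.44);
          }
        }
        // interweaved non-centered move: holding each subject's standardized
        // deviate eps_sj = (theta_sj - mu_j) / sigma_j fixed, propose
        // (mu_j, log sigma_j) jointly and translate/rescale all subjects.
        // This breaks the funnel coupling between the group scale and the
        // subject-level values that the centered updates mix slowly through.
        for (int j = 0; j < 6; ++j) {
          if (!active[j]) continue;
          double ls_old = std::log(sig[j]);
          double step = std::exp(lstep_nc[j]);
          double mu_new = mu[j] + step * rng.norm();
          double ls_new = ls_old + 0.5 * step * rng.norm();
          double s_new = std::exp(ls_new);
          double lp = dnorm_log(mu_new, pm[j], psd[j]) - dnorm_log(mu[j], pm[j], psd[j])
            - s_new * s_new / (2.0 * hsd[j] * hsd[j])
            + sig[j] * sig[j] / (2.0 * hsd[j] * hsd[j])
            + ls_new - ls_old;  // Jacobian of the log-scale proposal
          std::vector<double> ll_new(nsub);
          std::vector<std::array<double, 6> > th_new(nsub);
          bool ok = true;
          for (int s = 0; s < nsub && ok; ++s) {
            double eps = (theta[s][j] - mu[j]) / sig[j];
            th_new[s] = theta[s];
            th_new[s][j] = mu_new + s_new * eps;
            double p[6];
            transform_params(th_new[s].data(), active, fixed_nat, shared_b, p);
            ll_new[s] = subj_loglik(data[s], p, sign_whole);
            lp += ll_new[s] - cur_ll[s];
            if (!std::isfinite(lp)) ok = false;
          }
          double ap = ok ? std::min(1.0, std::exp(lp)) : 0.0;
          if (rng.unif() < ap) {
            mu[j] = mu_new; sig[j] = s_new;
            for (int s = 0; s < nsub; ++s) {
              theta[s][j] = th_new[s][j];
              cur_ll[s] = ll_new[s];
            }
          }
          if (warm) {
            double gamma = 1.0 / std::pow((double)iter, 0.6);
            lstep_nc[j] += gamma * (ap - 0.234);
          }
        }
      }
      // store
      if (!warm && ((iter - n_warmup) % thin == 0)) {
        double lltot = 0.0;
        for (int s = 0; s < nsub; ++s) lltot += cur_ll[s];
        ll_out[keep_i] = lltot;
        for (int j = 0; j < 6; ++j) {
          mu_out(keep_i, j) = active[j] ? mu[j] : NA_REAL;
          sig_out(keep_i, j) = active[j] ? sig[j] : NA_REAL;
        }
        for (int s = 0; s < nsub; ++s)
          for (int j = 0; j < 6; ++j)
            theta_out(keep_i, s * 6 + j) = active[j] ? theta[s][j] : NA_REAL;
        ++keep_i;
      }
    }

    NumericMatrix acc(nsub, 6);
    for (int s = 0; s < nsub; ++s)
      for (int j = 0; j < 6; ++j)
        acc(s, j) = acc_n[s][j] > 0 ? acc_sum[s][j] / acc_n[s][j] : NA_REAL;

    chains[c] = List::create(_["mu"] = mu_out, _["sigma"] = sig_out,
                             _["theta"] = theta_out, _["loglik"] = ll_out,
                             _["accept"] = acc);
  }
  return chains;
}

// ---------------------------------------------------------------------------
// Pointwise per-trial log likelihood over posterior draws (for WAIC)
// ---------------------------------------------------------------------------

// theta_nat: n_draws x (nsub * 6) on the natural scale
// [[Rcpp::export]]
NumericMatrix pointwise_loglik_cpp(List subj_list, NumericMatrix theta_nat,
                                   int sign_whole) {
  int nsub = subj_list.size();
  std::vector<SubjData> data(nsub);
  int ntot = 0;
  std::vector<int> offset(nsub);
  for (int s = 0; s < nsub; ++s) {
    data[s] = as_subjdata(subj_list[s]);
    offset[s] = ntot;
    ntot += data[s].n;
  }
  int nd = theta_nat.nrow();
  NumericMatrix out(nd, ntot);
  std::vector<double> buf;
  for (int d = 0; d < nd; ++d) {
    for (int s = 0; s < nsub; ++s) {
      double p[6];
      for (int j = 0; j < 6; ++j) p[j] = theta_nat(d, s * 6 + j);
      buf.assign(data[s].n, 0.0);
      subj_loglik(data[s], p, sign_whole, buf.data());
      for (int i = 0; i < data[s].n; ++i) out(d, offset[s] + i) = buf[i];
    }
  }
  return out;
}
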