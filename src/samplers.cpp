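// Metropolis-within-Gibbs samplers for Poisson log-linear random-effect
// models on areal lattices: the BYM (ICAR + exchangeable) model and the
// two-outcome shared component model.  Single-site random-walk updates
// for all non-conjugate effects, conjugate Gibbs draws for gamma-prior
// precisions, Robbins-Monro proposal adaptation during burn-in only.
// Uses R's RNG throughout so chains are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Adapter {
  double base, ls, scale;
  long acc, att;
  explicit Adapter(double s0) : base(s0), ls(0.0), scale(s0),
                                acc(0), att(0) {}
  void window(int k) {          // Robbins-Monro step toward 0.4 acceptance
    if (att == 0) return;
    double rate = static_cast<double>(acc) / att;
    ls += (rate - 0.4) / std::sqrt(static_cast<double>(k));
    scale = base * std::exp(ls);
    acc = 0; att = 0;
  }
  void reset() { acc = 0; att = 0; }
  double rate() const {
    return att ? static_cast<double>(acc) / att : NA_REAL;
  }
};

inline bool mh_accept(double log_ratio) {
  if (!std::isfinite(log_ratio)) return false;
  return std::log(unif_rand()) < log_ratio;
}

// ICAR pairwise quadratic form (each edge once) plus squared terms for
// isolated areas, which carry an exchangeable prior with the same
// precision.
double icar_quad(const std::vector<double>& u, const IntegerVector& adj,
                 const IntegerVector& adj_ptr, const LogicalVector& iso) {
  int n = u.size();
  double q = 0.0;
  for (int i = 0; i < n; ++i) {
    if (iso[i]) { q += 2.0 * u[i] * u[i]; continue; }
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
      double d = u[i] - u[adj[k]];
      q += d * d;
    }
  }
  return 0.5 * q;   // each edge (and isolated square) counted twice above
}

double pois_dev(const NumericVector& o, const std::vector<double>& mu) {
  double d = 0.0;
  for (int i = 0; i < (int)mu.size(); ++i)
    d += o[i] * std::log(mu[i]) - mu[i] - std::lgamma(o[i] + 1.0);
  return -2.0 * d;
}

// precision update shared by both samplers.
// prec_type: 0 = Gamma(pa, pb) prior on tau (conjugate Gibbs);
//            1 = Uniform(0, pb) prior on sd (random-walk MH on log tau);
//            2 = half-Normal(0, precision pa) prior on sd (MH).
double update_precision(double tau, double quad, double n_eff,
                        int prec_type, double pa, double pb,
                        Adapter& ad, bool adapting) {
  if (prec_type == 0)
    return R::rgamma(pa + n_eff / 2.0, 1.0 / (pb + quad / 2.0));
  double lt = std::log(tau);
  double ltp = lt + norm_rand() * ad.scale;
  double taup = std::exp(ltp);
  double lr = (n_eff / 2.0 - 0.5) * (ltp - lt) - quad / 2.0 * (taup - tau);
  if (prec_type == 1) {                     // sd must lie in (0, pb)
    if (std::exp(-ltp / 2.0) >= pb) lr = R_NegInf;
  } else {                                  // half-normal on sd
    lr += -pa / 2.0 * (1.0 / taup - 1.0 / tau);
  }
  ++ad.att;
  if (mh_accept(lr)) { ++ad.acc; return taup; }
  return tau;
}

} // namespace

// [[Rcpp::export]]
List bym_chain_cpp(NumericVector o, NumericVector e,
                   IntegerVector adj, IntegerVector adj_ptr,
                   IntegerVector igrp, int n_grp, int n_center_grp,
                   LogicalVector isolated, double n_eff_u,
                   double a_u, double b_u, double a_v, double b_v,
                   int n_burn, int n_sample, int thin,
                   double prop_sd, bool adapt,
                   NumericVector u0, NumericVector v0,
                   NumericVector alpha0, double tau_u0, double tau_v0) {
  int n = o.size();
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  double tau_u = tau_u0, tau_v = tau_v0;

  int n_keep = n_sample / thin;
  NumericMatrix keep_u(n_keep, n), keep_v(n_keep, n),
                keep_alpha(n_keep, n_grp);
  NumericVector keep_tau_u(n_keep), keep_tau_v(n_keep), keep_dev(n_keep);

  Adapter ad_u(prop_sd), ad_v(prop_sd), ad_a(prop_sd), ad_s(prop_sd);
  int win = 0, kept = 0, total = n_burn + n_sample;
  std::vector<double> gsum(n_grp), gcnt(n_grp), go(n_grp, 0.0);
  for (int i = 0; i < n; ++i) go[igrp[i]] += o[i];

  for (int it = 0; it < total; ++it) {
    bool burn = it < n_burn;
    if (it == n_burn) {
      ad_u.reset(); ad_v.reset(); ad_a.reset(); ad_s.reset();
    }

    // --- spatial field u ---
    for (int i = 0; i < n; ++i) {
      double cur = u[i], prop = cur + norm_rand() * ad_u.scale;
      double lik = o[i] * (prop - cur) -
        e[i] * std::exp(alpha[igrp[i]] + v[i]) *
        (std::exp(prop) - std::exp(cur));
      double pr;
      if (isolated[i]) {
        pr = -0.5 * tau_u * (prop * prop - cur * cur);
      } else {
        double s = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double uj = u[adj[k]];
          s += (prop - uj) * (prop - uj) - (cur - uj) * (cur - uj);
        }
        pr = -0.5 * tau_u * s;
      }
      ++ad_u.att;
      if (mh_accept(lik + pr)) { u[i] = prop; ++ad_u.acc; }
    }
    // per-component sum-to-zero centering, absorbed by the intercepts
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gcnt.begin(), gcnt.end(), 0.0);
    for (int i = 0; i < n; ++i)
      if (igrp[i] < n_center_grp) { gsum[igrp[i]] += u[i]; gcnt[igrp[i]]++; }
    for (int g = 0; g < n_center_grp; ++g)
      if (gcnt[g] > 0) gsum[g] /= gcnt[g];
    for (int i = 0; i < n; ++i)
      if (igrp[i] < n_center_grp) u[i] -= gsum[igrp[i]];
    for (int g = 0; g < n_center_grp; ++g) alpha[g] += gsum[g];

    // --- exchangeable field v ---
    for (int i = 0; i < n; ++i) {
      double cur = v[i], prop = cur + norm_rand() * ad_v.scale;
      double lik = o[i] * (prop - cur) -
        e[i] * std::exp(alpha[igrp[i]] + u[i]) *
        (std::exp(prop) - std::exp(cur));
      double pr = -0.5 * tau_v * (prop * prop - cur * cur);
      ++ad_v.att;
      if (mh_accept(lik + pr)) { v[i] = prop; ++ad_v.acc; }
    }

    // --- exchange move along the unidentified direction ---
    // the likelihood depends on u + v only; proposing (u_i + d, v_i - d)
    // and accepting on the prior ratio alone mixes the spatial vs
    // unstructured split far faster than the site updates can
    for (int i = 0; i < n; ++i) {
      double d = norm_rand() * ad_s.scale;
      double up = u[i] + d, vp = v[i] - d;
      double pr;
      if (isolated[i]) {
        pr = -0.5 * tau_u * (up * up - u[i] * u[i]);
      } else {
        double s = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double uj = u[adj[k]];
          s += (up - uj) * (up - uj) - (u[i] - uj) * (u[i] - uj);
        }
        pr = -0.5 * tau_u * s;
      }
      pr += -0.5 * tau_v * (vp * vp - v[i] * v[i]);
      ++ad_s.att;
      if (mh_accept(pr)) { u[i] = up; v[i] = vp; ++ad_s.acc; }
    }
    // re-center after the exchange sweep
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gcnt.begin(), gcnt.end(), 0.0);
    for (int i = 0; i < n; ++i)
      if (igrp[i] < n_center_grp) { gsum[igrp[i]] += u[i]; gcnt[igrp[i]]++; }
    for (int g = 0; g < n_center_grp; ++g)
      if (gcnt[g] > 0) gsum[g] /= gcnt[g];
    for (int i = 0; i < n; ++i)
      if (igrp[i] < n_center_grp) u[i] -= gsum[igrp[i]];
    for (int g = 0; g < n_center_grp; ++g) alpha[g] += gsum[g];

    // --- flat intercepts, one per group ---
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int i = 0; i < n; ++i)
      gsum[igrp[i]] += e[i] * std::exp(alpha[igrp[i]] + u[i] + v[i]);
    for (int g = 0; g < n_grp; ++g) {
      double d = norm_rand() * ad_a.scale;
      double lr = go[g] * d - gsum[g] * (std::exp(d) - 1.0);
      ++ad_a.att;
      if (mh_accept(lr)) { alpha[g] += d; ++ad_a.acc; }
    }

    // --- conjugate precision draws ---
    double qu = icar_quad(u, adj, adj_ptr, isolated);
    tau_u = R::rgamma(a_u + n_eff_u / 2.0, 1.0 / (b_u + qu / 2.0));
    double sv = 0.0;
    for (int i = 0; i < n; ++i) sv += v[i] * v[i];
    tau_v = R::rgamma(a_v + n / 2.0, 1.0 / (b_v + sv / 2.0));

    if (adapt && burn && (it + 1) % 100 == 0) {
      ++win;
      ad_u.window(win); ad_v.window(win); ad_a.window(win);
      ad_s.window(win);
    }

    if (!burn && ((it - n_burn) % thin == thin - 1) && kept < n_keep) {
      std::vector<double> mu(n);
      for (int i = 0; i < n; ++i) {
        keep_u(kept, i) = u[i];
        keep_v(kept, i) = v[i];
        mu[i] = e[i] * std::exp(alpha[igrp[i]] + u[i] + v[i]);
      }
      for (int g = 0; g < n_grp; ++g) keep_alpha(kept, g) = alpha[g];
      keep_tau_u[kept] = tau_u;
      keep_tau_v[kept] = tau_v;
      keep_dev[kept] = pois_dev(o, mu);
      ++kept;
    }
  }

  return List::create(
    _["u"] = keep_u, _["v"] = keep_v, _["alpha"] = keep_alpha,
    _["tau_u"] = keep_tau_u, _["tau_v"] = keep_tau_v,
    _["deviance"] = keep_dev,
    _["accept"] = NumericVector::create(
      _["u"] = ad_u.rate(), _["v"] = ad_v.rate(), _["alpha"] = ad_a.rate(),
      _["exchange"] = ad_s.rate()),
    _["proposal_sd"] = NumericVector::create(
      _["u"] = ad_u.scale, _["v"] = ad_v.scale, _["alpha"] = ad_a.scale,
      _["exchange"] = ad_s.scale));
}

// [[Rcpp::export]]
List scm_chain_cpp(NumericVector o1, NumericVector e1,
                   NumericVector o2, NumericVector e2,
                   IntegerVector adj, IntegerVector adj_ptr,
                   IntegerVector igrp, int n_grp, int n_center_grp,
                   LogicalVector isolated,
                   bool lambda_icar, bool beta_icar,
                   double n_eff_l, double n_eff_b,
                   int prec_type, double pa, double pb,
                   int delta_type, double d_p1, double d_p2,
                   int n_burn, int n_sample, int thin,
                   double prop_sd, bool adapt,
                   NumericVector lam0, NumericVector bet0,
                   NumericVector p10, NumericVector p20,
                   NumericVector a10, NumericVector a20, double delta0,
                   NumericVector tau0) {
  int n = o1.size();
  std::vector<double> lam(lam0.begin(), lam0.end());
  std::vector<double> bet(bet0.begin(), bet0.end());
  std::vector<double> p1(p10.begin(), p10.end());
  std::vector<double> p2(p20.begin(), p20.end());
  std::vector<double> a1(a10.begin(), a10.end());
  std::vector<double> a2(a20.begin(), a20.end());
  double delta = delta0;
  double tau_l = tau0[0], tau_b = tau0[1], tau_p1 = tau0[2],
         tau_p2 = tau0[3];

  int n_keep = n_sample / thin;
  NumericMatrix keep_lam(n_keep, n), keep_bet(n_keep, n),
      keep_p1(n_keep, n), keep_p2(n_keep, n),
      keep_a1(n_keep, n_grp), keep_a2(n_keep, n_grp),
      keep_tau(n_keep, 4);
  NumericVector keep_delta(n_keep), keep_dev(n_keep);

  Adapter ad_l(prop_sd), ad_b(prop_sd), ad_p(prop_sd), ad_a(prop_sd),
      ad_d(prop_sd * 0.5), ad_t(0.5);
  int win = 0, kept = 0, total = n_burn + n_sample;
  std::vector<double> gsum(n_grp), gcnt(n_grp),
      go1(n_grp, 0.0), go2(n_grp, 0.0);
  for (int i = 0; i < n; ++i) { go1[igrp[i]] += o1[i]; go2[igrp[i]] += o2[i]; }

  for (int it = 0; it < total; ++it) {
    bool burn = it < n_burn;
    if (it == n_burn) {
      ad_l.reset(); ad_b.reset(); ad_p.reset();
      ad_a.reset(); ad_d.reset(); ad_t.reset();
    }
    double id = 1.0 / delta;

    // --- shared field lambda (enters both likelihoods) ---
    for (int i = 0; i < n; ++i) {
      double cur = lam[i], prop = cur + norm_rand() * ad_l.scale;
      double b1 = e1[i] * std::exp(a1[igrp[i]] + p1[i]);
      double b2 = e2[i] * std::exp(a2[igrp[i]] + bet[i] + p2[i]);
      double lik =
        o1[i] * delta * (prop - cur) + o2[i] * id * (prop - cur)
        - b1 * (std::exp(delta * prop) - std::exp(delta * cur))
        - b2 * (std::exp(id * prop) - std::exp(id * cur));
      double pr;
      if (!lambda_icar || isolated[i]) {
        pr = -0.5 * tau_l * (prop * prop - cur * cur);
      } else {
        double s = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double lj = lam[adj[k]];
          s += (prop - lj) * (prop - lj) - (cur - lj) * (cur - lj);
        }
        pr = -0.5 * tau_l * s;
      }
      ++ad_l.att;
      if (mh_accept(lik + pr)) { lam[i] = prop; ++ad_l.acc; }
    }
    if (lambda_icar) {        // centering absorbed into both intercepts
      std::fill(gsum.begin(), gsum.end(), 0.0);
      std::fill(gcnt.begin(), gcnt.end(), 0.0);
      for (int i = 0; i < n; ++i)
        if (igrp[i] < n_center_grp) { gsum[igrp[i]] += lam[i]; gcnt[igrp[i]]++; }
      for (int g = 0; g < n_center_grp; ++g)
        if (gcnt[g] > 0) gsum[g] /= gcnt[g];
      for (int i = 0; i < n; ++i)
        if (igrp[i] < n_center_grp) lam[i] -= gsum[igrp[i]];
      for (int g = 0; g < n_center_grp; ++g) {
        a1[g] += delta * gsum[g];
        a2[g] += id * gsum[g];
      }
    }

    // --- outcome-2-specific spatial field beta ---
    for (int i = 0; i < n; ++i) {
      double cur = bet[i], prop = cur + norm_rand() * ad_b.scale;
      double b2 = e2[i] * std::exp(a2[igrp[i]] + id * lam[i] + p2[i]);
      double lik = o2[i] * (prop - cur) -
        b2 * (std::exp(prop) - std::exp(cur));
      double pr;
      if (!beta_icar || isolated[i]) {
        pr = -0.5 * tau_b * (prop * prop - cur * cur);
      } else {
        double s = 0.0;
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double bj = bet[adj[k]];
          s += (prop - bj) * (prop - bj) - (cur - bj) * (cur - bj);
        }
        pr = -0.5 * tau_b * s;
      }
      ++ad_b.att;
      if (mh_accept(lik + pr)) { bet[i] = prop; ++ad_b.acc; }
    }
    if (beta_icar) {
      std::fill(gsum.begin(), gsum.end(), 0.0);
      std::fill(gcnt.begin(), gcnt.end(), 0.0);
      for (int i = 0; i < n; ++i)
        if (igrp[i] < n_center_grp) { gsum[igrp[i]] += bet[i]; gcnt[igrp[i]]++; }
      for (int g = 0; g < n_center_grp; ++g)
        if (gcnt[g] > 0) gsum[g] /= gcnt[g];
      for (int i = 0; i < n; ++i)
        if (igrp[i] < n_center_grp) bet[i] -= gsum[igrp[i]];
      for (int g = 0; g < n_center_grp; ++g) a2[g] += gsum[g];
    }

    // --- unstructured residual fields ---
    for (int i = 0; i < n; ++i) {
      double cur = p1[i], prop = cur + norm_rand() * ad_p.scale;
      double b1 = e1[i] * std::exp(a1[igrp[i]] + delta * lam[i]);
      double lik = o1[i] * (prop - cur) -
        b1 * (std::exp(prop) - std::exp(cur));
      double pr = -0.5 * tau_p1 * (prop * prop - cur * cur);
      ++ad_p.att;
      if (mh_accept(lik + pr)) { p1[i] = prop; ++ad_p.acc; }
    }
    for (int i = 0; i < n; ++i) {
      double cur = p2[i], prop = cur + norm_rand() * ad_p.scale;
      double b2 = e2[i] * std::exp(a2[igrp[i]] + id * lam[i] + bet[i]);
      double lik = o2[i] * (prop - cur) -
        b2 * (std::exp(prop) - std::exp(cur));
      double pr = -0.5 * tau_p2 * (prop * prop - cur * cur);
      ++ad_p.att;
      if (mh_accept(lik + pr)) { p2[i] = prop; ++ad_p.acc; }
    }

    // --- flat intercepts ---
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int i = 0; i < n; ++i)
      gsum[igrp[i]] += e1[i] *
        std::exp(a1[igrp[i]] + delta * lam[i] + p1[i]);
    for (int g = 0; g < n_grp; ++g) {
      double d = norm_rand() * ad_a.scale;
      double lr = go1[g] * d - gsum[g] * (std::exp(d) - 1.0);
      ++ad_a.att;
      if (mh_accept(lr)) { a1[g] += d; ++ad_a.acc; }
    }
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int i = 0; i < n; ++i)
      gsum[igrp[i]] += e2[i] *
        std::exp(a2[igrp[i]] + id * lam[i] + bet[i] + p2[i]);
    for (int g = 0; g < n_grp; ++g) {
      double d = norm_rand() * ad_a.scale;
      double lr = go2[g] * d - gsum[g] * (std::exp(d) - 1.0);
      ++ad_a.att;
      if (mh_accept(lr)) { a2[g] += d; ++ad_a.acc; }
    }

    // --- scaling parameter delta ---
    {
      double dp, lr_prior = 0.0;
      bool ok = true;
      if (delta_type == 0) {                 // log-normal prior on delta
        double ld = std::log(delta);
        double ldp = ld + norm_rand() * ad_d.scale;
        dp = std::exp(ldp);
        lr_prior = -d_p2 / 2.0 *
          ((ldp - d_p1) * (ldp - d_p1) - (ld - d_p1) * (ld - d_p1));
      } else {                               // uniform(d_p1, d_p2) on delta
        dp = delta + norm_rand() * ad_d.scale;
        if (dp < d_p1 || dp > d_p2) ok = false;
      }
      ++ad_d.att;
      if (ok) {
        double idp = 1.0 / dp, lik = 0.0;
        for (int i = 0; i < n; ++i) {
          double b1 = e1[i] * std::exp(a1[igrp[i]] + p1[i]);
          double b2 = e2[i] * std::exp(a2[igrp[i]] + bet[i] + p2[i]);
          lik += o1[i] * lam[i] * (dp - delta)
               + o2[i] * lam[i] * (idp - id)
               - b1 * (std::exp(dp * lam[i]) - std::exp(delta * lam[i]))
               - b2 * (std::exp(idp * lam[i]) - std::exp(id * lam[i]));
        }
        if (mh_accept(lik + lr_prior)) {
          delta = dp; id = idp; ++ad_d.acc;
        }
      }
    }

    // --- precisions ---
    {
      double ql = lambda_icar ? icar_quad(lam, adj, adj_ptr, isolated)
                              : [&]{ double s = 0; for (double x : lam)
                                     s += x * x; return s; }();
      tau_l = update_precision(tau_l, ql, n_eff_l, prec_type, pa, pb,
                               ad_t, burn);
      double qb = beta_icar ? icar_quad(bet, adj, adj_ptr, isolated)
                            : [&]{ double s = 0; for (double x : bet)
                                   s += x * x; return s; }();
      tau_b = update_precision(tau_b, qb, n_eff_b, prec_type, pa, pb,
                               ad_t, burn);
      double s1 = 0, s2 = 0;
      for (int i = 0; i < n; ++i) { s1 += p1[i] * p1[i]; s2 += p2[i] * p2[i]; }
      tau_p1 = update_precision(tau_p1, s1, n, prec_type, pa, pb,
                                ad_t, burn);
      tau_p2 = update_precision(tau_p2, s2, n, prec_type, pa, pb,
                                ad_t, burn);
    }

    if (adapt && burn && (it + 1) % 100 == 0) {
      ++win;
      ad_l.window(win); ad_b.window(win); ad_p.window(win);
      ad_a.window(win); ad_d.window(win); ad_t.window(win);
    }

    if (!burn && ((it - n_burn) % thin == thin - 1) && kept < n_keep) {
      std::vector<double> mu(2 * n);
      NumericVector oo(2 * n);
      for (int i = 0; i < n; ++i) {
        keep_lam(kept, i) = lam[i];
        keep_bet(kept, i) = bet[i];
        keep_p1(kept, i) = p1[i];
        keep_p2(kept, i) = p2[i];
        mu[i] = e1[i] * std::exp(a1[igrp[i]] + delta * lam[i] + p1[i]);
        mu[n + i] = e2[i] *
          std::exp(a2[igrp[i]] + id * lam[i] + bet[i] + p2[i]);
        oo[i] = o1[i]; oo[n + i] = o2[i];
      }
      for (int g = 0; g < n_grp; ++g) {
        keep_a1(kept, g) = a1[g];
        keep_a2(kept, g) = a2[g];
      }
      keep_delta[kept] = delta;
      keep_tau(kept, 0) = tau_l; keep_tau(kept, 1) = tau_b;
      keep_tau(kept, 2) = tau_p1; keep_tau(kept, 3) = tau_p2;
      keep_dev[kept] = pois_dev(oo, mu);
      ++kept;
    }
  }

  return List::create(
    _["lambda"] = keep_lam, _["beta"] = keep_bet,
    _["phi1"] = keep_p1, _["phi2"] = keep_p2,
    _["alpha1"] = keep_a1, _["alpha2"] = keep_a2,
    _["delta"] = keep_delta, _["tau"] = keep_tau,
    _["deviance"] = keep_dev,
    _["accept"] = NumericVector::create(
      _["lambda"] = ad_l.rate(), _["beta"] = ad_b.rate(),
      _["phi"] = ad_p.rate(), _["alpha"] = ad_a.rate(),
      _["delta"] = ad_d.rate(), _["tau"] = ad_t.rate()));
}
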