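// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// spatially-explicit binomial logistic model:
//   logit(p_i) = alpha[c,r] + beta[c,r] * (t - t0) + u[admin2] + v[admin1]
// with intrinsic CAR prior on u (per-country scale, islands fixed at 0,
// per-component sum-to-zero re-imposed after every u sweep), Gaussian
// priors on v / alpha / beta, Gibbs updates for the grand means, and
// log-scale random-walk updates for all standard deviations.
// Record weights enter as powers on the binomial likelihood contributions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double log1pexp_c(double x) {
  if (x > 35.0) return x;
  return std::log1p(std::exp(x));
}

struct ModelDat {
  IntegerVector k, n, r, ci, a1i, a2i;   // r,ci,a1i,a2i are 0-based here
  NumericVector w, tt;
  int N, C, K, J;
  IntegerMatrix edges;                    // 0-based admin2 pairs
  IntegerVector a2_country, comp, icar_rank;
  LogicalVector island;
  std::vector<std::vector<int>> recs_cr, recs_a2, recs_a1, nbr;
  std::vector<std::vector<int>> edges_by_country, comp_members;
  std::vector<bool> comp_active;          // size >= 2 (recentred, updated)
  std::vector<std::vector<int>> a1_by_country;
};

static ModelDat unpack(const List& dat) {
  ModelDat d;
  d.k = dat["k"]; d.n = dat["n"]; d.w = dat["w"]; d.tt = dat["tt"];
  IntegerVector r1 = dat["r"], c1 = dat["c_idx"], a11 = dat["a1_idx"],
    a21 = dat["a2_idx"];
  d.N = d.k.size();
  d.r = clone(r1); d.ci = clone(c1); d.a1i = clone(a11); d.a2i = clone(a21);
  for (int i = 0; i < d.N; ++i) {
    d.r[i] -= 1; d.ci[i] -= 1; d.a1i[i] -= 1; d.a2i[i] -= 1;
  }
  d.C = as<int>(dat["C"]); d.K = as<int>(dat["K"]); d.J = as<int>(dat["J"]);
  IntegerMatrix e1 = dat["edges"];
  d.edges = IntegerMatrix(e1.nrow(), 2);
  for (int i = 0; i < e1.nrow(); ++i) {
    d.edges(i, 0) = e1(i, 0) - 1; d.edges(i, 1) = e1(i, 1) - 1;
  }
  IntegerVector a2c = dat["a2_country"], cmp = dat["comp"];
  d.a2_country = clone(a2c); d.comp = clone(cmp);
  for (int j = 0; j < d.J; ++j) { d.a2_country[j] -= 1; d.comp[j] -= 1; }
  d.icar_rank = dat["icar_rank"];
  d.island = dat["island"];

  d.recs_cr.assign(d.C * 2, {});
  d.recs_a2.assign(d.J, {});
  d.recs_a1.assign(d.K, {});
  for (int i = 0; i < d.N; ++i) {
    d.recs_cr[d.ci[i] * 2 + d.r[i]].push_back(i);
    d.recs_a2[d.a2i[i]].push_back(i);
    d.recs_a1[d.a1i[i]].push_back(i);
  }
  d.nbr.assign(d.J, {});
  d.edges_by_country.assign(d.C, {});
  for (int e = 0; e < d.edges.nrow(); ++e) {
    int a = d.edges(e, 0), b = d.edges(e, 1);
    d.nbr[a].push_back(b); d.nbr[b].push_back(a);
    d.edges_by_country[d.a2_country[a]].push_back(e);
  }
  int ncomp = 0;
  for (int j = 0; j < d.J; ++j) ncomp = std::max(ncomp, d.comp[j] + 1);
  d.comp_members.assign(ncomp, {});
  for (int j = 0; j < d.J; ++j) d.comp_members[d.comp[j]].push_back(j);
  d.comp_active.assign(ncomp, false);
  for (int c = 0; c < ncomp; ++c)
    d.comp_active[c] = d.comp_members[c].size() >= 2;
  d.a1_by_country.assign(d.C, {});
  {
    std::vector<int> a1_country(d.K, -1);
    for (int i = 0; i < d.N; ++i) a1_country[d.a1i[i]] = d.ci[i];
    for (int kk = 0; kk < d.K; ++kk)
      if (a1_country[kk] >= 0) d.a1_by_country[a1_country[kk]].push_back(kk);
  }
  return d;
}

struct State {
  std::vector<double> mu_a, mu_b, al, be, s_a, s_b, s_u, u, v;
  double s_v;
  std::vector<double> eta;
};

static void refresh_eta(const ModelDat& d, State& s) {
  s.eta.assign(d.N, 0.0);
  for (int i = 0; i < d.N; ++i) {
    int cr = d.ci[i] * 2 + d.r[i];
    s.eta[i] = s.al[cr] + s.be[cr] * d.tt[i] + s.u[d.a2i[i]] +
      s.v[d.a1i[i]];
  }
}

static double loglik_full(const ModelDat& d, const State& s,
                          bool with_const) {
  double ll = 0.0;
  for (int i = 0; i < d.N; ++i) {
    double e = s.eta[i];
    double c0 = with_const ? R::lchoose(d.n[i], d.k[i]) : 0.0;
    ll += d.w[i] * (c0 + d.k[i] * e - d.n[i] * log1pexp_c(e));
  }
  return ll;
}

static double dhalfnorm_log_c(double x, double scale) {
  return 0.5 * std::log(2.0 / M_PI) - std::log(scale) -
    x * x / (2.0 * scale * scale);
}

static double logpost_full(const ModelDat& d, const State& s,
                           const List& hyper) {
  double mu_sd = as<double>(hyper["mu_sd"]);
  double h_sa = as<double>(hyper["sigma_alpha_scale"]);
  double h_sb = as<double>(hyper["sigma_beta_scale"]);
  double h_su = as<double>(hyper["sigma_u_scale"]);
  double h_sv = as<double>(hyper["sigma_v_scale"]);
  double lp = loglik_full(d, s, true);
  // ICAR
  std::vector<double> ss(d.C, 0.0);
  for (int e = 0; e < d.edges.nrow(); ++e) {
    double diff = s.u[d.edges(e, 0)] - s.u[d.edges(e, 1)];
    ss[d.a2_country[d.edges(e, 0)]] += diff * diff;
  }
  for (int c = 0; c < d.C; ++c) {
    if (d.icar_rank[c] > 0)
      lp += -d.icar_rank[c] * std::log(s.s_u[c]) -
        ss[c] / (2.0 * s.s_u[c] * s.s_u[c]);
  }
  for (int kk = 0; kk < d.K; ++kk)
    lp += R::dnorm(s.v[kk], 0.0, s.s_v, 1);
  for (int r = 0; r < 2; ++r) {
    for (int c = 0; c < d.C; ++c) {
      lp += R::dnorm(s.al[c * 2 + r], s.mu_a[r], s.s_a[r], 1);
      lp += R::dnorm(s.be[c * 2 + r], s.mu_b[r], s.s_b[r], 1);
    }
    lp += R::dnorm(s.mu_a[r], 0.0, mu_sd, 1) +
      R::dnorm(s.mu_b[r], 0.0, mu_sd, 1);
    lp += dhalfnorm_log_c(s.s_a[r], h_sa) + dhalfnorm_log_c(s.s_b[r], h_sb);
  }
  for (int c = 0; c < d.C; ++c) lp += dhalfnorm_log_c(s.s_u[c], h_su);
  lp += dhalfnorm_log_c(s.s_v, h_sv);
  return lp;
}

// likelihood change when eta of records idx shifts by delta (constant)
static double dlik_shift(const ModelDat& d, const State& s,
                         const std::vector<int>& idx, double delta) {
  double dl = 0.0;
  for (int i : idx) {
    double e0 = s.eta[i], e1 = e0 + delta;
    dl += d.w[i] * (d.k[i] * delta -
                    d.n[i] * (log1pexp_c(e1) - log1pexp_c(e0)));
  }
  return dl;
}

static State make_state(const ModelDat& d, const List& init) {
  State s;
  NumericVector mu_a = init["mu_alpha"], mu_b = init["mu_beta"],
    al = init["alpha"], be = init["beta"], s_a = init["sigma_alpha"],
    s_b = init["sigma_beta"], s_u = init["sigma_u"], u = init["u"],
    v = init["v"];
  s.mu_a = as<std::vector<double>>(mu_a);
  s.mu_b = as<std::vector<double>>(mu_b);
  s.al = as<std::vector<double>>(al);    // length C*2, index c*2+r
  s.be = as<std::vector<double>>(be);
  s.s_a = as<std::vector<double>>(s_a);
  s.s_b = as<std::vector<double>>(s_b);
  s.s_u = as<std::vector<double>>(s_u);
  s.s_v = as<double>(init["sigma_v"]);
  s.u = as<std::vector<double>>(u);
  s.v = as<std::vector<double>>(v);
  refresh_eta(d, s);
  return s;
}

// [[Rcpp::export]]
double logpost_cpp(List dat, List params, List hyper) {
  ModelDat d = unpack(dat);
  // flatten C x 2 matrices into c*2+r order
  NumericMatrix alm = params["alpha"], bem = params["beta"];
  NumericVector alf(d.C * 2), bef(d.C * 2);
  for (int c = 0; c < d.C; ++c) for (int r = 0; r < 2; ++r) {
    alf[c * 2 + r] = alm(c, r); bef[c * 2 + r] = bem(c, r);
  }
  List init = List::create(
    _["mu_alpha"] = params["mu_alpha"], _["mu_beta"] = params["mu_beta"],
    _["alpha"] = alf, _["beta"] = bef,
    _["sigma_alpha"] = params["sigma_alpha"],
    _["sigma_beta"] = params["sigma_beta"],
    _["sigma_u"] = params["sigma_u"], _["sigma_v"] = params["sigma_v"],
    _["u"] = params["u"], _["v"] = params["v"]);
  NumericVector sa = params["sigma_alpha"], sb = params["sigma_beta"],
    su = params["sigma_u"];
  double sv = as<double>(params["sigma_v"]);
  for (int r = 0; r < 2; ++r)
    if (sa[r] <= 0 || sb[r] <= 0) return R_NegInf;
  for (int c = 0; c < d.C; ++c) if (su[c] <= 0) return R_NegInf;
  if (sv <= 0) return R_NegInf;
  State s = make_state(d, init);
  return logpost_full(d, s, hyper);
}

struct Adapt {
  std::vector<double> ls;  // log step sizes
  double target = 0.38;
  void init(int n, double step0) { ls.assign(n, std::log(step0)); }
  void tune(int i, double acc, double gam) {
    ls[i] += gam * (acc - target);
    if (ls[i] < -10) ls[i] = -10;
    if (ls[i] > 3) ls[i] = 3;
  }
  double step(int i) const { return std::exp(ls[i]); }
};

// [[Rcpp::export]]
List run_mcmc_cpp(List dat, List hyper, List init, int n_iter, int n_warmup,
                  int thin) {
  ModelDat d = unpack(dat);
  State s = make_state(d, init);
  double lp0 = logpost_full(d, s, hyper);
  if (!std::isfinite(lp0))
    stop("non-finite posterior at initialization; jitter inits or re-seed");

  double mu_sd = as<double>(hyper["mu_sd"]);
  double h_sa = as<double>(hyper["sigma_alpha_scale"]);
  double h_sb = as<double>(hyper["sigma_beta_scale"]);
  double h_su = as<double>(hyper["sigma_u_scale"]);
  double h_sv = as<double>(hyper["sigma_v_scale"]);

  Adapt ad_al, ad_be, ad_u, ad_v, ad_sa, ad_sb, ad_su, ad_sv;
  ad_al.init(d.C * 2, 0.2); ad_be.init(d.C * 2, 0.02);
  ad_u.init(d.J, 0.3); ad_v.init(d.K, 0.2);
  ad_sa.init(2, 0.3); ad_sb.init(2, 0.3); ad_su.init(d.C, 0.3);
  ad_sv.init(1, 0.3);

  int n_keep = (n_iter - n_warmup + thin - 1) / thin;
  NumericMatrix out_mu_a(n_keep, 2), out_mu_b(n_keep, 2),
    out_al(n_keep, d.C * 2), out_be(n_keep, d.C * 2),
    out_sa(n_keep, 2), out_sb(n_keep, 2), out_su(n_keep, d.C),
    out_sv(n_keep, 1), out_u(n_keep, d.J), out_v(n_keep, d.K);

  double acc_al = 0, acc_be = 0, acc_u = 0, acc_v = 0, acc_s = 0;
  double n_al = 0, n_be = 0, n_u = 0, n_v = 0, n_s = 0;
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;
    double gam = std::pow(it + 1.0, -0.6);

    // --- alpha, beta (per country x stratum) ---
    for (int c = 0; c < d.C; ++c) for (int r = 0; r < 2; ++r) {
      int cr = c * 2 + r;
      const std::vector<int>& idx = d.recs_cr[cr];
      // alpha
      {
        double delta = ad_al.step(cr) * R::norm_rand();
        double a0 = s.al[cr], a1 = a0 + delta;
        double dl = dlik_shift(d, s, idx, delta);
        double dp = (-(a1 - s.mu_a[r]) * (a1 - s.mu_a[r]) +
                     (a0 - s.mu_a[r]) * (a0 - s.mu_a[r])) /
          (2.0 * s.s_a[r] * s.s_a[r]);
        double lr = dl + dp;
        double accp = std::min(1.0, std::exp(lr));
        if (R::unif_rand() < accp) {
          s.al[cr] = a1;
          for (int i : idx) s.eta[i] += delta;
          if (!warm) acc_al += 1;
        }
        if (warm) ad_al.tune(cr, accp, gam); else n_al += 1;
      }
      // beta (record-specific shift delta * tt)
      {
        double delta = ad_be.step(cr) * R::norm_rand();
        double b0 = s.be[cr], b1 = b0 + delta;
        double dl = 0.0;
        for (int i : idx) {
          double e0 = s.eta[i], e1 = e0 + delta * d.tt[i];
          dl += d.w[i] * (d.k[i] * (e1 - e0) -
                          d.n[i] * (log1pexp_c(e1) - log1pexp_c(e0)));
        }
        double dp = (-(b1 - s.mu_b[r]) * (b1 - s.mu_b[r]) +
                     (b0 - s.mu_b[r]) * (b0 - s.mu_b[r])) /
          (2.0 * s.s_b[r] * s.s_b[r]);
        double accp = std::min(1.0, std::exp(dl + dp));
        if (R::unif_rand() < accp) {
          s.be[cr] = b1;
          for (int i : idx) s.eta[i] += delta * d.tt[i];
          if (!warm) acc_be += 1;
        }
        if (warm) ad_be.tune(cr, accp, gam); else n_be += 1;
      }
    }

    // --- grand means: conjugate Gibbs ---
    for (int r = 0; r < 2; ++r) {
      double sum_a = 0, sum_b = 0;
      for (int c = 0; c < d.C; ++c) {
        sum_a += s.al[c * 2 + r]; sum_b += s.be[c * 2 + r];
      }
      double prec_a = d.C / (s.s_a[r] * s.s_a[r]) + 1.0 / (mu_sd * mu_sd);
      double mean_a = (sum_a / (s.s_a[r] * s.s_a[r])) / prec_a;
      s.mu_a[r] = R::rnorm(mean_a, 1.0 / std::sqrt(prec_a));
      double prec_b = d.C / (s.s_b[r] * s.s_b[r]) + 1.0 / (mu_sd * mu_sd);
      double mean_b = (sum_b / (s.s_b[r] * s.s_b[r])) / prec_b;
      s.mu_b[r] = R::rnorm(mean_b, 1.0 / std::sqrt(prec_b));
    }

    // --- sigma_alpha, sigma_beta: log-scale random walk ---
    for (int r = 0; r < 2; ++r) {
      {
        double t0 = std::log(s.s_a[r]);
        double t1 = t0 + ad_sa.step(r) * R::norm_rand();
        double s0 = s.s_a[r], s1 = std::exp(t1);
        double ssq = 0;
        for (int c = 0; c < d.C; ++c) {
          double dd = s.al[c * 2 + r] - s.mu_a[r]; ssq += dd * dd;
        }
        double lt1 = -d.C * t1 - ssq / (2 * s1 * s1) +
          dhalfnorm_log_c(s1, h_sa) + t1;
        double lt0 = -d.C * t0 - ssq / (2 * s0 * s0) +
          dhalfnorm_log_c(s0, h_sa) + t0;
        double accp = std::min(1.0, std::exp(lt1 - lt0));
        if (R::unif_rand() < accp) { s.s_a[r] = s1; if (!warm) acc_s += 1; }
        if (warm) ad_sa.tune(r, accp, gam); else n_s += 1;
      }
      {
        double t0 = std::log(s.s_b[r]);
        double t1 = t0 + ad_sb.step(r) * R::norm_rand();
        double s0 = s.s_b[r], s1 = std::exp(t1);
        double ssq = 0;
        for (int c = 0; c < d.C; ++c) {
          double dd = s.be[c * 2 + r] - s.mu_b[r]; ssq += dd * dd;
        }
        double lt1 = -d.C * t1 - ssq / (2 * s1 * s1) +
          dhalfnorm_log_c(s1, h_sb) + t1;
        double lt0 = -d.C * t0 - ssq / (2 * s0 * s0) +
          dhalfnorm_log_c(s0, h_sb) + t0;
        double accp = std::min(1.0, std::exp(lt1 - lt0));
        if (R::unif_rand() < accp) { s.s_b[r] = s1; if (!warm) acc_s += 1; }
        if (warm) ad_sb.tune(r, accp, gam); else n_s += 1;
      }
    }

    // --- u: single-site updates, islands fixed at 0 ---
    for (int j = 0; j < d.J; ++j) {
      if (d.island[j]) continue;
      double delta = ad_u.step(j) * R::norm_rand();
      double u0 = s.u[j], u1 = u0 + delta;
      double dl = dlik_shift(d, s, d.recs_a2[j], delta);
      double su2 = s.s_u[d.a2_country[j]]; su2 *= su2;
      double dp = 0;
      for (int nb : d.nbr[j]) {
        double d1 = u1 - s.u[nb], d0 = u0 - s.u[nb];
        dp += d0 * d0 - d1 * d1;
      }
      dp /= (2.0 * su2);
      double accp = std::min(1.0, std::exp(dl + dp));
      if (R::unif_rand() < accp) {
        s.u[j] = u1;
        for (int i : d.recs_a2[j]) s.eta[i] += delta;
        if (!warm) acc_u += 1;
      }
      if (warm) ad_u.tune(j, accp, gam); else n_u += 1;
    }
    // re-impose per-component sum-to-zero
    for (size_t cc = 0; cc < d.comp_members.size(); ++cc) {
      if (!d.comp_active[cc]) continue;
      double m = 0;
      for (int j : d.comp_members[cc]) m += s.u[j];
      m /= d.comp_members[cc].size();
      if (m != 0) {
        for (int j : d.comp_members[cc]) {
          s.u[j] -= m;
          for (int i : d.recs_a2[j]) s.eta[i] -= m;
        }
      }
    }

    // --- sigma_u per country ---
    for (int c = 0; c < d.C; ++c) {
      double ssq = 0;
      for (int e : d.edges_by_country[c]) {
        double dd = s.u[d.edges(e, 0)] - s.u[d.edges(e, 1)];
        ssq += dd * dd;
      }
      double rank = d.icar_rank[c];
      double t0 = std::log(s.s_u[c]);
      double t1 = t0 + ad_su.step(c) * R::norm_rand();
      double s0 = s.s_u[c], s1 = std::exp(t1);
      double lt1 = -rank * t1 - ssq / (2 * s1 * s1) +
        dhalfnorm_log_c(s1, h_su) + t1;
      double lt0 = -rank * t0 - ssq / (2 * s0 * s0) +
        dhalfnorm_log_c(s0, h_su) + t0;
      double accp = std::min(1.0, std::exp(lt1 - lt0));
      if (R::unif_rand() < accp) { s.s_u[c] = s1; if (!warm) acc_s += 1; }
      if (warm) ad_su.tune(c, accp, gam); else n_s += 1;
    }

    // --- v ---
    for (int kk = 0; kk < d.K; ++kk) {
      double delta = ad_v.step(kk) * R::norm_rand();
      double v0 = s.v[kk], v1 = v0 + delta;
      double dl = dlik_shift(d, s, d.recs_a1[kk], delta);
      double dp = (v0 * v0 - v1 * v1) / (2.0 * s.s_v * s.s_v);
      double accp = std::min(1.0, std::exp(dl + dp));
      if (R::unif_rand() < accp) {
        s.v[kk] = v1;
        for (int i : d.recs_a1[kk]) s.eta[i] += delta;
        if (!warm) acc_v += 1;
      }
      if (warm) ad_v.tune(kk, accp, gam); else n_v += 1;
    }

    // --- exact shift move: alpha[c,.] + d, v[k in c] - d ---
    // the likelihood is invariant along this direction (eta unchanged);
    // the Gaussian priors make the conditional of d Gaussian, so this is a
    // Gibbs update that breaks the intercept/province-effect confounding
    for (int c = 0; c < d.C; ++c) {
      int Kc = (int) d.a1_by_country[c].size();
      if (Kc == 0) continue;
      double prec = Kc / (s.s_v * s.s_v);
      double lin = 0.0;
      for (int r = 0; r < 2; ++r) {
        double sa2 = s.s_a[r] * s.s_a[r];
        prec += 1.0 / sa2;
        lin += (s.mu_a[r] - s.al[c * 2 + r]) / sa2;
      }
      for (int kk : d.a1_by_country[c]) lin += s.v[kk] / (s.s_v * s.s_v);
      double dshift = R::rnorm(lin / prec, 1.0 / std::sqrt(prec));
      s.al[c * 2 + 0] += dshift; s.al[c * 2 + 1] += dshift;
      for (int kk : d.a1_by_country[c]) s.v[kk] -= dshift;
    }

    // --- sigma_v ---
    {
      double ssq = 0;
      for (int kk = 0; kk < d.K; ++kk) ssq += s.v[kk] * s.v[kk];
      double t0 = std::log(s.s_v);
      double t1 = t0 + ad_sv.step(0) * R::norm_rand();
      double s0 = s.s_v, s1 = std::exp(t1);
      double lt1 = -d.K * t1 - ssq / (2 * s1 * s1) +
        dhalfnorm_log_c(s1, h_sv) + t1;
      double lt0 = -d.K * t0 - ssq / (2 * s0 * s0) +
        dhalfnorm_log_c(s0, h_sv) + t0;
      double accp = std::min(1.0, std::exp(lt1 - lt0));
      if (R::unif_rand() < accp) { s.s_v = s1; if (!warm) acc_s += 1; }
      if (warm) ad_sv.tune(0, accp, gam); else n_s += 1;
    }

    if (!warm && ((it - n_warmup) % thin == 0)) {
      for (int r = 0; r < 2; ++r) {
        out_mu_a(row, r) = s.mu_a[r]; out_mu_b(row, r) = s.mu_b[r];
        out_sa(row, r) = s.s_a[r]; out_sb(row, r) = s.s_b[r];
      }
      for (int cr = 0; cr < d.C * 2; ++cr) {
        out_al(row, cr) = s.al[cr]; out_be(row, cr) = s.be[cr];
      }
      for (int c = 0; c < d.C; ++c) out_su(row, c) = s.s_u[c];
      out_sv(row, 0) = s.s_v;
      for (int j = 0; j < d.J; ++j) out_u(row, j) = s.u[j];
      for (int kk = 0; kk < d.K; ++kk) out_v(row, kk) = s.v[kk];
      ++row;
    }
  }

  NumericVector acc = NumericVector::create(
    _["alpha"] = n_al > 0 ? acc_al / n_al : NA_REAL,
    _["beta"] = n_be > 0 ? acc_be / n_be : NA_REAL,
    _["u"] = n_u > 0 ? acc_u / n_u : NA_REAL,
    _["v"] = n_v > 0 ? acc_v / n_v : NA_REAL,
    _["sigma"] = n_s > 0 ? acc_s / n_s : NA_REAL);

  return List::create(
    _["mu_alpha"] = out_mu_a, _["mu_beta"] = out_mu_b,
    _["alpha"] = out_al, _["beta"] = out_be,
    _["sigma_alpha"] = out_sa, _["sigma_beta"] = out_sb,
    _["sigma_u"] = out_su, _["sigma_v"] = out_sv,
    _["u"] = out_u, _["v"] = out_v, _["accept"] = acc);
}
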