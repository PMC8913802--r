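// Metropolis-within-Gibbs core for the data-augmented spatial count model.
// One call runs one chain; R owns the RNG seed (set.seed before .Call), so
// chains are bit-reproducible. Conditionals mirror the reference R updates:
// exact Bernoulli full conditionals for z, uniform-on-S random walks for
// activity centres, log-scale Metropolis for lambda0 and sigma, conjugate
// beta for psi.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SigmaPrior {
  int dist;        // 0 = uniform(lo, hi), 1 = gamma(shape, rate)
  double p1, p2;   // lo/hi or shape/rate
  double logdens(double sigma) const {
    if (dist == 0) {
      return (sigma <= p1 || sigma >= p2) ? R_NegInf : 0.0;
    }
    return R::dgamma(sigma, p1, 1.0 / p2, 1);
  }
};

// Poisson log-likelihood (factorial constants dropped) from per-detector
// totals; rate at detector j is lambda0 * sumg[j], constant across nights.
double loglik(const std::vector<double>& sumg, double lambda0,
              const NumericVector& n_total, const NumericVector& k_obs) {
  double ll = 0.0;
  const int J = sumg.size();
  for (int j = 0; j < J; ++j) {
    if (k_obs[j] <= 0) continue;
    const double lam = lambda0 * sumg[j];
    if (n_total[j] > 0) {
      if (lam <= 0) return R_NegInf;
      ll += n_total[j] * std::log(lam);
    }
    ll -= k_obs[j] * lam;
  }
  return ll;
}

} // namespace

// [[Rcpp::export]]
List run_chain_cpp(NumericVector n_total, NumericVector k_obs,
                   NumericMatrix traps, NumericVector bounds,
                   double area_ha, List prior,
                   int M, int n_iter, int n_burnin, int n_adapt, int thin,
                   int snapshot_every, NumericVector init_steps,
                   double init_lambda0, double init_sigma) {
  const int J = traps.nrow();
  const double xmin = bounds[0], xmax = bounds[1];
  const double ymin = bounds[2], ymax = bounds[3];

  const double l0_lo = prior["lambda0_lo"], l0_hi = prior["lambda0_hi"];
  const double psi_a = prior["psi_a"], psi_b = prior["psi_b"];
  SigmaPrior sp;
  sp.dist = as<int>(prior["sigma_dist"]);
  sp.p1 = prior["sigma_p1"];
  sp.p2 = prior["sigma_p2"];

  double step_s = init_steps[0];
  double step_l0 = init_steps[1];
  double step_sig = init_steps[2];

  // --- initial state ---
  double psi = R::rbeta(psi_a, psi_b);
  double lambda0 = std::min(std::max(init_lambda0, l0_lo + 1e-6 * (l0_hi - l0_lo)),
                            l0_hi - 1e-6 * (l0_hi - l0_lo));
  double sigma = init_sigma;
  if (sp.dist == 0) {
    sigma = std::min(std::max(sigma, sp.p1 + 1e-6 * (sp.p2 - sp.p1)),
                     sp.p2 - 1e-6 * (sp.p2 - sp.p1));
  }
  std::vector<int> z(M);
  std::vector<double> sx(M), sy(M);
  std::vector<double> d2(static_cast<size_t>(M) * J);
  std::vector<double> g(static_cast<size_t>(M) * J);
  std::vector<double> sumg(J, 0.0);

  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < M; ++i) {
    z[i] = (R::unif_rand() < psi) ? 1 : 0;
    sx[i] = R::runif(xmin, xmax);
    sy[i] = R::runif(ymin, ymax);
    for (int j = 0; j < J; ++j) {
      const double dx = sx[i] - traps(j, 0), dy = sy[i] - traps(j, 1);
      const double dd = dx * dx + dy * dy;
      d2[static_cast<size_t>(i) * J + j] = dd;
      const double gg = std::exp(-dd * inv2s2);
      g[static_cast<size_t>(i) * J + j] = gg;
      if (z[i]) sumg[j] += gg;
    }
  }

  const int n_ret = (n_iter - n_burnin) / thin;
  const int n_snap = (n_ret + snapshot_every - 1) / snapshot_every;
  NumericMatrix draws(n_ret, 5);
  IntegerVector snap_iter(n_snap);
  IntegerMatrix snap_z(n_snap, M);
  NumericMatrix snap_x(n_snap, M), snap_y(n_snap, M);

  // adaptation bookkeeping (Robbins-Monro-style batches, adapt phase only)
  const int batch = 50;
  int try_s = 0, acc_s = 0, try_l0 = 0, acc_l0 = 0, try_sig = 0, acc_sig = 0;
  int n_batches = 0;

  std::vector<double> gtmp(J), sumg_p(J);
  int ret = 0, snap = 0;
  const int total_iter = n_adapt + n_iter;

  for (int iter = 1; iter <= total_iter; ++iter) {
    const bool adapting = iter <= n_adapt;

    // --- z: exact Bernoulli full conditionals, sequential sweep ---
    const double lpsi = std::log(psi), l1mpsi = std::log1p(-psi);
    for (int i = 0; i < M; ++i) {
      const double* gi = &g[static_cast<size_t>(i) * J];
      double logit = lpsi - l1mpsi;
      bool without_impossible = false;
      for (int j = 0; j < J; ++j) {
        if (k_obs[j] <= 0) continue;
        const double base = sumg[j] - z[i] * gi[j];
        logit -= k_obs[j] * lambda0 * gi[j];
        if (n_total[j] > 0) {
          if (base <= 0) { without_impossible = true; }
          else logit += n_total[j] * (std::log(base + gi[j]) - std::log(base));
        }
      }
      int znew;
      if (psi <= 0.0) znew = 0;
      else if (psi >= 1.0 || without_impossible) znew = 1;
      else znew = (R::unif_rand() < 1.0 / (1.0 + std::exp(-logit))) ? 1 : 0;
      if (znew != z[i]) {
        const double sgn = znew ? 1.0 : -1.0;
        for (int j = 0; j < J; ++j) sumg[j] += sgn * gi[j];
        z[i] = znew;
      }
    }

    // --- s: random walk for included, uniform redraw for excluded ---
    for (int i = 0; i < M; ++i) {
      double* gi = &g[static_cast<size_t>(i) * J];
      double* d2i = &d2[static_cast<size_t>(i) * J];
      if (!z[i]) {
        sx[i] = R::runif(xmin, xmax);
        sy[i] = R::runif(ymin, ymax);
        for (int j = 0; j < J; ++j) {
          const double dx = sx[i] - traps(j, 0), dy = sy[i] - traps(j, 1);
          d2i[j] = dx * dx + dy * dy;
          gi[j] = std::exp(-d2i[j] * inv2s2);
        }
        continue;
      }
      const double px = sx[i] + R::norm_rand() * step_s;
      const double py = sy[i] + R::norm_rand() * step_s;
      ++try_s;
      if (px < xmin || px > xmax || py < ymin || py > ymax) continue;
      double delta = 0.0;
      bool cur_impossible = false, new_impossible = false;
      for (int j = 0; j < J; ++j) {
        const double dx = px - traps(j, 0), dy = py - traps(j, 1);
        const double dd = dx * dx + dy * dy;
        gtmp[j] = std::exp(-dd * inv2s2);
        if (k_obs[j] <= 0) continue;
        delta -= k_obs[j] * lambda0 * (gtmp[j] - gi[j]);
        if (n_total[j] > 0) {
          const double cur = sumg[j], prop = sumg[j] - gi[j] + gtmp[j];
          if (cur <= 0) cur_impossible = true;
          if (prop <= 0) new_impossible = true;
          if (cur > 0 && prop > 0) {
            delta += n_total[j] * (std::log(prop) - std::log(cur));
          }
        }
      }
      bool accept;
      if (new_impossible) accept = false;
      else if (cur_impossible) accept = true;
      else accept = std::log(R::unif_rand()) < delta;
      if (accept) {
        ++acc_s;
        for (int j = 0; j < J; ++j) {
          sumg[j] += gtmp[j] - gi[j];
          gi[j] = gtmp[j];
          const double dx = px - traps(j, 0), dy = py - traps(j, 1);
          d2i[j] = dx * dx + dy * dy;
        }
        sx[i] = px; sy[i] = py;
      }
    }

    // --- lambda0: log-scale Metropolis, uniform prior ---
    {
      const double prop = lambda0 * std::exp(R::norm_rand() * step_l0);
      ++try_l0;
      if (prop > l0_lo && prop < l0_hi) {
        const double ll_new = loglik(sumg, prop, n_total, k_obs);
        const double ll_cur = loglik(sumg, lambda0, n_total, k_obs);
        double lr;
        if (!std::isfinite(ll_new)) lr = R_NegInf;
        else if (!std::isfinite(ll_cur)) lr = R_PosInf;
        else lr = ll_new - ll_cur + std::log(prop) - std::log(lambda0);
        if (std::log(R::unif_rand()) < lr) { lambda0 = prop; ++acc_l0; }
      }
    }

    // --- sigma: log-scale Metropolis against likelihood x prior ---
    {
      const double prop = sigma * std::exp(R::norm_rand() * step_sig);
      ++try_sig;
      const double lp_new = sp.logdens(prop);
      if (std::isfinite(lp_new)) {
        const double inv_new = 1.0 / (2.0 * prop * prop);
        std::fill(sumg_p.begin(), sumg_p.end(), 0.0);
        for (int i = 0; i < M; ++i) {
          if (!z[i]) continue;
          const double* d2i = &d2[static_cast<size_t>(i) * J];
          for (int j = 0; j < J; ++j) sumg_p[j] += std::exp(-d2i[j] * inv_new);
        }
        const double ll_new = loglik(sumg_p, lambda0, n_total, k_obs);
        const double ll_cur = loglik(sumg, lambda0, n_total, k_obs);
        double lr;
        if (!std::isfinite(ll_new)) lr = R_NegInf;
        else if (!std::isfinite(ll_cur)) lr = R_PosInf;
        else {
          lr = ll_new - ll_cur + lp_new - sp.logdens(sigma) +
            std::log(prop) - std::log(sigma);
        }
        if (std::log(R::unif_rand()) < lr) {
          sigma = prop;
          inv2s2 = inv_new;
          ++acc_sig;
          for (int i = 0; i < M; ++i) {
            double* gi = &g[static_cast<size_t>(i) * J];
            const double* d2i = &d2[static_cast<size_t>(i) * J];
            for (int j = 0; j < J; ++j) gi[j] = std::exp(-d2i[j] * inv2s2);
          }
          sumg = sumg_p;
        }
      }
    }

    // --- psi: conjugate beta ---
    int N = 0;
    for (int i = 0; i < M; ++i) N += z[i];
    psi = R::rbeta(psi_a + N, psi_b + M - N);

    // --- adapt proposal scales toward acceptance in [0.2, 0.45] ---
    if (adapting && iter % batch == 0) {
      ++n_batches;
      const double del = 1.0 / std::sqrt(static_cast<double>(n_batches));
      if (try_s > 0) {
        const double r = static_cast<double>(acc_s) / try_s;
        if (r < 0.2) step_s *= std::exp(-del);
        else if (r > 0.45) step_s *= std::exp(del);
        step_s = std::min(std::max(step_s, 1.0),
                          std::max(xmax - xmin, ymax - ymin));
      }
      const double r0 = static_cast<double>(acc_l0) / try_l0;
      if (r0 < 0.2) step_l0 *= std::exp(-del);
      else if (r0 > 0.45) step_l0 *= std::exp(del);
      step_l0 = std::min(std::max(step_l0, 0.01), 2.0);
      const double rs = static_cast<double>(acc_sig) / try_sig;
      if (rs < 0.2) step_sig *= std::exp(-del);
      else if (rs > 0.45) step_sig *= std::exp(del);
      step_sig = std::min(std::max(step_sig, 0.01), 2.0);
      try_s = acc_s = try_l0 = acc_l0 = try_sig = acc_sig = 0;
    }

    // --- record ---
    if (!adapting) {
      const int post = iter - n_adapt;
      if (post > n_burnin && (post - n_burnin) % thin == 0) {
        draws(ret, 0) = N;
        draws(ret, 1) = N / area_ha;
        draws(ret, 2) = lambda0;
        draws(ret, 3) = sigma;
        draws(ret, 4) = psi;
        if (ret % snapshot_every == 0 && snap < n_snap) {
          snap_iter[snap] = ret + 1;
          for (int i = 0; i < M; ++i) {
            snap_z(snap, i) = z[i];
            snap_x(snap, i) = sx[i];
            snap_y(snap, i) = sy[i];
          }
          ++snap;
        }
        ++ret;
      }
    }
  }

  colnames(draws) = CharacterVector::create("N", "D", "lambda0", "sigma", "psi");
  return List::create(
    _["draws"] = draws,
    _["snap_iter"] = snap_iter,
    _["snap_z"] = snap_z,
    _["snap_x"] = snap_x,
    _["snap_y"] = snap_y,
    _["steps"] = NumericVector::create(step_s, step_l0, step_sig),
    _["accept"] = NumericVector::create(
      try_s > 0 ? static_cast<double>(acc_s) / try_s : NA_REAL,
      try_l0 > 0 ? static_cast<double>(acc_l0) / try_l0 : NA_REAL,
      try_sig > 0 ? static_cast<double>(acc_sig) / try_sig : NA_REAL)
  );
}
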