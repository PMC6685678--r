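// MCMC core for the zero-inflated Poisson model with BYM (ICAR + iid)
// spatial random effects. The R wrapper (fit_zip_car) standardises the
// covariates, builds the adjacency structures and back-transforms the
// output; this file only runs the chain. All randomness goes through R's
// RNG, so a set.seed() before the call makes the chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log_plogis(double x) { // log(1/(1+exp(-x))), stable
  return x > 0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".zip_car_mcmc")]]
List zip_car_mcmc(const arma::ivec& y,
                  const arma::mat& Xs,        // n x M, standardised
                  const arma::imat& edges,    // E x 2, 0-based, i < j
                  const arma::ivec& nbr,      // flat neighbour list, 0-based
                  const arma::ivec& nbr_ptr,  // CSR offsets, length n + 1
                  const arma::ivec& colour,   // 1-based colour per cell
                  const arma::mat& Qx,        // (D - W) %*% Xs
                  const arma::vec& xQx,       // diag(Xs' Q Xs)
                  const arma::vec& xnorm2,    // colSums(Xs^2)
                  const arma::vec& b_init,
                  double theta_mean, double theta_var, double sd_b,
                  double a_u, double b_u, double a_v, double b_v,
                  int n_iter, int n_burn, int thin, bool demand_zip) {
  const int n = y.n_elem;
  const int M = Xs.n_cols;
  const int n_colours = colour.max();
  const int n_keep = (n_iter - n_burn) / thin;

  // state
  double theta = theta_mean;
  arma::vec b = b_init;                     // (beta0, beta) standardised scale
  arma::vec u(n, arma::fill::zeros), v(n, arma::fill::zeros);
  double tau_u = 1.0, tau_v = 1.0;
  arma::ivec z(n, arma::fill::zeros);
  arma::vec eta_fix(n);
  eta_fix.fill(b(0));
  if (M > 0) eta_fix += Xs * b.subvec(1, M);
  arma::vec lambda = arma::exp(eta_fix + u + v);

  // degrees
  arma::vec deg(n);
  for (int i = 0; i < n; ++i) deg(i) = nbr_ptr(i + 1) - nbr_ptr(i);

  // adaptation state
  double ls_theta = std::log(0.5), ls_v = std::log(0.1), ls_b = std::log(0.1);
  arma::vec ls_u(n_colours, arma::fill::value(std::log(0.1)));
  arma::vec ls_s(M + 1, arma::fill::value(std::log(0.5)));
  arma::vec ls_w(std::max(M, 1), arma::fill::value(std::log(0.5)));
  double acc_theta = 0, acc_b = 0, acc_v = 0, bat = 0;
  double ls_cu = std::log(0.3), ls_cv = std::log(0.3), acc_cu = 0, acc_cv = 0;
  arma::vec acc_u(n_colours, arma::fill::zeros);
  arma::vec acc_s(M + 1, arma::fill::zeros), acc_w(std::max(M, 1), arma::fill::zeros);
  double acc_theta_all = 0, acc_b_all = 0; int n_all = 0;

  // running covariance of the regression block (Welford)
  arma::vec b_mean(M + 1, arma::fill::zeros);
  arma::mat b_cov_acc(M + 1, M + 1, arma::fill::zeros);
  int b_count = 0;
  arma::mat prop_chol = arma::eye(M + 1, M + 1);
  bool use_cov = false;

  // storage
  arma::mat keep_beta(n_keep, M + 1);
  arma::vec keep_theta(n_keep), keep_tau_u(n_keep), keep_tau_v(n_keep);
  arma::mat keep_u(n_keep, n), keep_v(n_keep, n);
  arma::vec pred_sum(n, arma::fill::zeros), pred_sq(n, arma::fill::zeros),
            lam_sum(n, arma::fill::zeros);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double p = 1.0 / (1.0 + std::exp(-theta));

    // -- structural zeros
    int n1 = 0;
    for (int i = 0; i < n; ++i) {
      if (y(i) == 0) {
        double pr1 = p / (p + (1.0 - p) * std::exp(-lambda(i)));
        z(i) = (unif_rand() < pr1) ? 1 : 0;
        n1 += z(i);
      } else z(i) = 0;
    }

    // -- theta
    {
      double th_new = theta + std::exp(ls_theta) * norm_rand();
      double lp_old = R::dnorm(theta, theta_mean, std::sqrt(theta_var), 1) +
        n1 * log_plogis(theta) + (n - n1) * log_plogis(-theta);
      double lp_new = R::dnorm(th_new, theta_mean, std::sqrt(theta_var), 1) +
        n1 * log_plogis(th_new) + (n - n1) * log_plogis(-th_new);
      if (std::log(unif_rand()) < lp_new - lp_old) {
        theta = th_new; acc_theta += 1; acc_theta_all += 1;
      }
      bat += 1; n_all += 1;
    }

    // -- regression block
    {
      arma::vec step(M + 1);
      for (int j = 0; j <= M; ++j) step(j) = norm_rand();
      arma::vec prop = b + std::exp(ls_b) * (use_cov ? arma::vec(prop_chol.t() * step) : step);
      arma::vec eta_new(n, arma::fill::value(prop(0)));
      if (M > 0) eta_new += Xs * prop.subvec(1, M);
      double dll = 0;
      for (int i = 0; i < n; ++i) {
        if (z(i) == 0) {
          double lam_new = std::exp(eta_new(i) + u(i) + v(i));
          dll += y(i) * (eta_new(i) - eta_fix(i)) - (lam_new - lambda(i));
        }
      }
      for (int j = 0; j <= M; ++j) {
        dll += R::dnorm(prop(j), 0, sd_b, 1) - R::dnorm(b(j), 0, sd_b, 1);
      }
      if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
        b = prop; eta_fix = eta_new;
        lambda = arma::exp(eta_fix + u + v);
        acc_b += 1; acc_b_all += 1;
      }
    }

    // -- ICAR field by colour class
    for (int c = 1; c <= n_colours; ++c) {
      double s = std::exp(ls_u(c - 1));
      int n_c = 0, n_acc = 0;
      for (int i = 0; i < n; ++i) {
        if (colour(i) != c) continue;
        ++n_c;
        double du = s * norm_rand();
        double nbr_sum = 0;
        for (int k = nbr_ptr(i); k < nbr_ptr(i + 1); ++k) nbr_sum += u(nbr(k));
        double dprior = -tau_u / 2.0 * deg(i) * du * du -
          tau_u * du * (deg(i) * u(i) - nbr_sum);
        double dll = dprior;
        if (z(i) == 0) dll += y(i) * du - lambda(i) * (std::exp(du) - 1.0);
        if (std::log(unif_rand()) < dll) {
          u(i) += du;
          lambda(i) *= std::exp(du);
          ++n_acc;
        }
      }
      acc_u(c - 1) += n_c > 0 ? (double)n_acc / n_c : 0;
    }

    // -- deconfounding swaps (likelihood-invariant; see fit_zip_car docs)
    {
      // intercept vs v
      double dd = std::exp(ls_s(0)) * norm_rand();
      double dlp = -tau_v / 2.0 * (dd * dd * n - 2.0 * dd * arma::accu(v)) +
        R::dnorm(b(0) + dd, 0, sd_b, 1) - R::dnorm(b(0), 0, sd_b, 1);
      if (std::log(unif_rand()) < dlp) {
        b(0) += dd; v -= dd; eta_fix += dd;
        acc_s(0) += 1;
      }
      for (int m = 0; m < M; ++m) {
        // beta_m vs the ICAR field (keeps sum(u) = 0: Xs has mean zero)
        dd = std::exp(ls_s(m + 1)) * norm_rand();
        double cross = arma::dot(Qx.col(m), u);
        dlp = -tau_u / 2.0 * (dd * dd * xQx(m) - 2.0 * dd * cross) +
          R::dnorm(b(m + 1) + dd, 0, sd_b, 1) - R::dnorm(b(m + 1), 0, sd_b, 1);
        if (std::log(unif_rand()) < dlp) {
          b(m + 1) += dd;
          u -= dd * Xs.col(m);
          eta_fix += dd * Xs.col(m);
          acc_s(m + 1) += 1;
        }
        // beta_m vs the unstructured field
        dd = std::exp(ls_w(m)) * norm_rand();
        dlp = -tau_v / 2.0 * (dd * dd * xnorm2(m) - 2.0 * dd * arma::dot(Xs.col(m), v)) +
          R::dnorm(b(m + 1) + dd, 0, sd_b, 1) - R::dnorm(b(m + 1), 0, sd_b, 1);
        if (std::log(unif_rand()) < dlp) {
          b(m + 1) += dd;
          v -= dd * Xs.col(m);
          eta_fix += dd * Xs.col(m);
          acc_w(m) += 1;
        }
      }
    }

    // -- recentre u (sum-to-zero), absorb the mean into the intercept
    {
      double mu = arma::mean(u);
      u -= mu; b(0) += mu; eta_fix += mu;
    }

    // -- unstructured effect
    {
      double s = std::exp(ls_v);
      int n_acc = 0;
      for (int i = 0; i < n; ++i) {
        double dv = s * norm_rand();
        double dll = -tau_v / 2.0 * ((v(i) + dv) * (v(i) + dv) - v(i) * v(i));
        if (z(i) == 0) dll += y(i) * dv - lambda(i) * (std::exp(dv) - 1.0);
        if (std::log(unif_rand()) < dll) {
          v(i) += dv;
          lambda(i) *= std::exp(dv);
          ++n_acc;
        }
      }
      acc_v += (double)n_acc / n;
    }

    // -- field rescaling moves: u -> c u (and v -> c v) with log-normal
    //    proposals; these mix the amplitude of each random-effect field,
    //    which single-site updates traverse very slowly (the collapsed
    //    field / huge precision state is otherwise nearly absorbing)
    {
      double ss_u = 0;
      for (unsigned int e = 0; e < edges.n_rows; ++e) {
        double d = u(edges(e, 0)) - u(edges(e, 1));
        ss_u += d * d;
      }
      double lc = std::exp(ls_cu) * norm_rand();
      double c = std::exp(lc);
      double dll = -tau_u / 2.0 * (c * c - 1.0) * ss_u + (n - 1) * lc;
      for (int i = 0; i < n; ++i) {
        if (z(i) == 0) {
          double du = (c - 1.0) * u(i);
          dll += y(i) * du - lambda(i) * (std::exp(du) - 1.0);
        }
      }
      if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
        for (int i = 0; i < n; ++i) lambda(i) *= std::exp((c - 1.0) * u(i));
        u *= c;
        ss_u *= c * c;
        acc_cu += 1;
      }

      lc = std::exp(ls_cv) * norm_rand();
      c = std::exp(lc);
      dll = -tau_v / 2.0 * (c * c - 1.0) * arma::dot(v, v) + n * lc;
      for (int i = 0; i < n; ++i) {
        if (z(i) == 0) {
          double dv = (c - 1.0) * v(i);
          dll += y(i) * dv - lambda(i) * (std::exp(dv) - 1.0);
        }
      }
      if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
        for (int i = 0; i < n; ++i) lambda(i) *= std::exp((c - 1.0) * v(i));
        v *= c;
        acc_cv += 1;
      }

      // -- precisions (conjugate)
      tau_u = R::rgamma(a_u + (n - 1) / 2.0, 1.0 / (b_u + ss_u / 2.0));
      tau_v = R::rgamma(a_v + n / 2.0, 1.0 / (b_v + arma::dot(v, v) / 2.0));
    }

    // -- adaptation during burn-in
    if (it <= n_burn) {
      ++b_count;
      arma::vec delta = b - b_mean;
      b_mean += delta / b_count;
      b_cov_acc += delta * (b - b_mean).t();
      if (it % 50 == 0) {
        double step = std::min(0.1, 5.0 / std::sqrt((double)it));
        ls_theta += step * (acc_theta / bat - 0.44);
        ls_cu += step * (acc_cu / bat - 0.44);
        ls_cv += step * (acc_cv / bat - 0.44);
        acc_cu = acc_cv = 0;
        ls_b += step * (acc_b / bat - 0.234);
        ls_v += step * (acc_v / bat - 0.44);
        for (int c = 0; c < n_colours; ++c) ls_u(c) += step * (acc_u(c) / bat - 0.44);
        for (int j = 0; j <= M; ++j) ls_s(j) += step * (acc_s(j) / bat - 0.44);
        for (int m = 0; m < M; ++m) ls_w(m) += step * (acc_w(m) / bat - 0.44);
        acc_theta = acc_b = acc_v = 0; bat = 0;
        acc_u.zeros(); acc_s.zeros(); acc_w.zeros();
        if (it >= 200 && b_count > (M + 2)) {
          arma::mat cv = b_cov_acc / (b_count - 1) * (2.38 * 2.38 / (M + 1));
          cv.diag() += 1e-8;
          arma::mat R_;
          if (arma::chol(R_, cv)) { prop_chol = R_; use_cov = true; }
        }
      }
    }

    // -- store
    if (it > n_burn && (it - n_burn) % thin == 0) {
      keep_beta.row(kept) = b.t();
      keep_theta(kept) = theta;
      keep_tau_u(kept) = tau_u;
      keep_tau_v(kept) = tau_v;
      keep_u.row(kept) = u.t();
      keep_v.row(kept) = v.t();
      double p_now = 1.0 / (1.0 + std::exp(-theta));
      arma::vec mean_now = demand_zip ? arma::vec((1.0 - p_now) * lambda) : lambda;
      pred_sum += mean_now;
      pred_sq += arma::square(mean_now);
      lam_sum += lambda;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = keep_beta, _["theta"] = keep_theta,
    _["tau_u"] = keep_tau_u, _["tau_v"] = keep_tau_v,
    _["u"] = keep_u, _["v"] = keep_v,
    _["pred_sum"] = pred_sum, _["pred_sq"] = pred_sq,
    _["lam_sum"] = lam_sum, _["kept"] = kept,
    _["acc"] = List::create(_["theta"] = acc_theta_all / n_all,
                            _["b"] = acc_b_all / n_all)
  );
}
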