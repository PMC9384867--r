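// Proximal-Newton core of the penalized maximum-entropy solver.
//
// Minimizes  -mean_presence(eta) + logsumexp_background(eta)
//            + sum_j lambda_j |beta_j|
// over beta, eta = F beta, by Newton steps on a working set with an
// L1-penalized quadratic subproblem solved by coordinate descent and
// an Armijo line search on the true objective.  The objective is
// convex, so the stationary point is the global optimum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logsumexp_vec(const vec& x) {
  double m = x.max();
  return m + std::log(accu(exp(x - m)));
}

static vec softmax_vec(const vec& x) {
  vec w = exp(x - x.max());
  return w / accu(w);
}

// KKT stationarity residual with box constraints |beta| <= bmax:
// at a bound only the inward pull counts as a violation.
static double kkt_res(const vec& beta, const vec& g, const vec& lam,
                      double bmax) {
  double r = 0.0;
  for (uword j = 0; j < beta.n_elem; ++j) {
    double rj;
    if (beta[j] >= bmax)
      rj = std::max(0.0, g[j] + lam[j]);
    else if (beta[j] <= -bmax)
      rj = std::max(0.0, -(g[j] - lam[j]));
    else if (beta[j] != 0.0)
      rj = std::fabs(g[j] + lam[j] * (beta[j] > 0 ? 1.0 : -1.0));
    else
      rj = std::max(std::fabs(g[j]) - lam[j], 0.0);
    if (rj > r) r = rj;
  }
  return r;
}

// Coordinate descent on 1/2 (z-b0)' H (z-b0) + g'(z-b0) + sum lam|z|.
// Returns d = z - b0.
static vec cd_lasso_quad(const mat& H, const vec& g, const vec& b0,
                         const vec& lam, double bmax,
                         int max_cycles = 300, double ztol = 1e-11) {
  const uword n = b0.n_elem;
  vec z = b0;
  vec Hd(n, fill::zeros);       // H * (z - b0)
  vec hdiag = H.diag();
  hdiag.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
  std::vector<uword> sweep(n);
  for (uword j = 0; j < n; ++j) sweep[j] = j;
  bool full_next = true;
  for (int cycle = 0; cycle < max_cycles; ++cycle) {
    double maxdel = 0.0;
    for (uword idx = 0; idx < sweep.size(); ++idx) {
      uword j = sweep[idx];
      double u = hdiag[j] * z[j] - (g[j] + Hd[j]);
      double au = std::fabs(u) - lam[j];
      double znew = au > 0 ? (u > 0 ? au : -au) / hdiag[j] : 0.0;
      if (znew > bmax) znew = bmax; else if (znew < -bmax) znew = -bmax;
      double del = znew - z[j];
      if (del != 0.0) {
        Hd += H.col(j) * del;
        z[j] = znew;
        double adel = std::fabs(del);
        if (adel > maxdel) maxdel = adel;
      }
    }
    if (full_next) {
      sweep.clear();
      for (uword j = 0; j < n; ++j) if (z[j] != 0.0) sweep.push_back(j);
      full_next = false;
      if (maxdel < ztol) break;
    } else if (maxdel < ztol) {
      sweep.resize(n);
      for (uword j = 0; j < n; ++j) sweep[j] = j;
      full_next = true;
    }
  }
  return z - b0;
}

static uvec top_violators(const vec& g, const vec& beta, const vec& lam,
                          uword cap) {
  vec vs = abs(g) - lam;
  for (uword j = 0; j < beta.n_elem; ++j) if (beta[j] != 0.0) vs[j] = 0.0;
  uvec cand = find(vs > 0);
  if (cand.n_elem <= cap) return cand;
  vec vals = vs.elem(cand);
  uvec ord = sort_index(vals, "descend");
  return cand.elem(ord.head(cap));
}

// [[Rcpp::export]]
Rcpp::List enm_solve_cpp(const arma::mat& Fp, const arma::mat& Fbg,
                         const arma::vec& lambda, const arma::vec& beta0,
                         double tol, int max_iter, double kkt_tol,
                         double beta_max) {
  const uword N = Fbg.n_rows;
  vec Fp_means = mean(Fp, 0).t();
  vec beta = beta0;
  uvec nz0 = find(beta != 0.0);
  vec eta(N, fill::zeros);
  if (nz0.n_elem > 0) eta = Fbg.cols(nz0) * beta.elem(nz0);

  auto penalty = [&](const vec& b) { return accu(lambda % abs(b)); };
  double obj = logsumexp_vec(eta) - dot(Fp_means, beta) + penalty(beta);

  vec q = softmax_vec(eta);
  vec g_full = Fbg.t() * q - Fp_means;
  uvec active = find(beta != 0.0);
  active = unique(join_cols(active, top_violators(g_full, beta, lambda, 100)));

  int total_iters = 0;
  bool converged = false;
  int stalled_rounds = 0;
  uvec prev_viol;
  for (int round = 0; round < 60; ++round) {
    double obj_round_start = obj;
    if (active.n_elem > 0) {
      mat A = Fbg.cols(active);
      vec lam_a = lambda.elem(active);
      vec pm_a = Fp_means.elem(active);
      int stall = 0;
      for (int inner = 0; inner < 80; ++inner) {
        double obj_prev = obj;
        ++total_iters;
        if (total_iters > max_iter)
          Rcpp::stop("maxent solver failed to converge in %d iterations",
                     total_iters);
        q = softmax_vec(eta);
        vec g_a = A.t() * q - pm_a;
        vec b_a = beta.elem(active);
        if (kkt_res(b_a, g_a, lam_a, beta_max) < tol) break;
        // exact Hessian of logsumexp on the active set
        mat B = A.each_col() % sqrt(q);
        vec mu = A.t() * q;
        mat H = B.t() * B - mu * mu.t();
        H.diag() += 1e-9;
        vec d = cd_lasso_quad(H, g_a, b_a, lam_a, beta_max);
        bool moved = false;
        if (!d.is_zero()) {
          double model_dec = dot(g_a, d) +
            accu(lam_a % abs(b_a + d)) - accu(lam_a % abs(b_a));
          vec Ad = A * d;
          double tstep = 1.0;
          while (tstep >= 1e-8) {
            vec cand = b_a + tstep * d;
            vec eta_c = eta + tstep * Ad;
            double pen_c = penalty(beta) - accu(lam_a % abs(b_a)) +
              accu(lam_a % abs(cand));
            double obj_c = logsumexp_vec(eta_c) -
              (dot(Fp_means, beta) + tstep * dot(pm_a, d)) + pen_c;
            if (obj_c <= obj + 1e-4 * tstep * model_dec + 1e-12) {
              beta.elem(active) = cand;
              eta = eta_c;
              obj = obj_c;
              moved = true;
              break;
            }
            tstep *= 0.5;
          }
        }
        if (!moved) {
          // guaranteed-progress fallback: backtracking proximal
          // gradient step (handles near-degenerate curvature)
          double L = 1.0;
          for (int bt = 0; bt < 60 && !moved; ++bt) {
            vec cand = b_a - g_a / L;
            for (uword j = 0; j < cand.n_elem; ++j) {
              double u = cand[j];
              double au = std::fabs(u) - lam_a[j] / L;
              double zj = au > 0 ? (u > 0 ? au : -au) : 0.0;
              if (zj > beta_max) zj = beta_max;
              else if (zj < -beta_max) zj = -beta_max;
              cand[j] = zj;
            }
            vec dd = cand - b_a;
            if (dd.is_zero()) break;
            vec eta_c = eta + A * dd;
            double pen_c = penalty(beta) - accu(lam_a % abs(b_a)) +
              accu(lam_a % abs(cand));
            double obj_c = logsumexp_vec(eta_c) -
              (dot(Fp_means, beta) + dot(pm_a, dd)) + pen_c;
            double quad = dot(g_a, dd) + 0.5 * L * dot(dd, dd) +
              accu(lam_a % abs(cand)) - accu(lam_a % abs(b_a));
            if (obj_c <= obj + quad + 1e-12 && obj_c <= obj + 1e-15) {
              beta.elem(active) = cand;
              eta = eta_c;
              obj = obj_c;
              moved = true;
            } else {
              L *= 2.0;
            }
          }
          if (!moved) break;   // no measurable progress possible
        }
        // numerical floor: steps that no longer move the objective
        if (obj_prev - obj < 1e-13) { if (++stall >= 2) break; }
        else stall = 0;
      }
    }
    q = softmax_vec(eta);
    g_full = Fbg.t() * q - Fp_means;
    uvec viol = find((abs(g_full) > lambda + kkt_tol) % (beta == 0.0));
    if (viol.n_elem == 0) { converged = true; break; }
    // at the numerical floor no descent is measurable; if the same
    // violators were already in the working set and nothing moved,
    // residual violations of order kkt_tol are numerically meaningless
    bool same_viol = prev_viol.n_elem == viol.n_elem &&
      (prev_viol.n_elem == 0 || all(prev_viol == viol));
    if (obj_round_start - obj < 1e-12) ++stalled_rounds;
    else stalled_rounds = 0;
    if ((same_viol && obj_round_start - obj < 1e-13) ||
        stalled_rounds >= 2) {
      converged = true;
      break;
    }
    prev_viol = viol;
    if (round == 59)
      Rcpp::stop("maxent solver: KKT violations remain after 60 working-set rounds");
    uvec supp = find(beta != 0.0);
    active = unique(join_cols(supp, top_violators(g_full, beta, lambda, 100)));
  }
  if (!converged)
    Rcpp::stop("maxent solver failed to converge");
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("eta_bg") = eta,
    Rcpp::Named("iters") = total_iters);
}
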