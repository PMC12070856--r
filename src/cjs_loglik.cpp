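#include <Rcpp.h>
using namespace Rcpp;

// Cormack-Jolly-Seber log-likelihood with a transience mixture, conditional
// on first capture. For each history the resident branch is a forward
// recursion over the latent alive state; the transient branch (prob 1-rho)
// contributes only when the bird is never re-encountered after release.
// `mult` carries multiplicities of collapsed identical histories.
// [[Rcpp::export]]
double cjs_loglik_cpp(IntegerMatrix ch, IntegerVector first,
                      NumericVector phi, double p, double rho,
                      NumericVector mult) {
  int n = ch.nrow(), K = ch.ncol();
  if (phi.size() != K - 1) stop("phi must have length n_occasions - 1");
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    int f = first[i] - 1;
    double a = 1.0;    // P(data since release, alive at current occasion)
    double dead = 0.0; // P(data since release, dead by current occasion)
    bool seen_after = false;
    for (int t = f + 1; t < K; t++) {
      double surv = a * phi[t - 1];
      double died = a * (1.0 - phi[t - 1]);
      if (ch(i, t) == 1) {
        seen_after = true;
        a = surv * p;
        dead = 0.0; // dead birds cannot be detected
      } else {
        a = surv * (1.0 - p);
        dead += died;
      }
    }
    double lik = rho * (a + dead);
    if (!seen_after) lik += 1.0 - rho;
    ll += mult[i] * std::log(lik);
  }
  return ll;
}

static double logpost(const IntegerMatrix& ch, const IntegerVector& first,
                      const NumericVector& mult, const NumericVector& x,
                      double rho_fixed) {
  int K = ch.ncol();
  NumericVector theta(x.size());
  double jac = 0.0;
  for (int j = 0; j < x.size(); j++) {
    theta[j] = 1.0 / (1.0 + std::exp(-x[j]));
    jac += std::log(theta[j]) + std::log1p(-theta[j]);
  }
  NumericVector phi(theta.begin(), theta.begin() + (K - 1));
  double rho = rho_fixed > 0 ? rho_fixed : theta[K];
  return cjs_loglik_cpp(ch, first, phi, theta[K - 1], rho, mult) + jac;
}

// One chain of single-site random-walk Metropolis on the logit scale for
// the transient-CJS posterior under Uniform(0,1) priors. Uses R's RNG, so
// a set.seed() in the caller makes the chain reproducible. Returns the
// kept draws on the probability scale.
// [[Rcpp::export]]
NumericMatrix cjs_metropolis_cpp(IntegerMatrix ch, IntegerVector first,
                                 NumericVector mult, int n_iter, int n_burn,
                                 int thin, double step, NumericVector init_x,
                                 double rho_fixed = -1.0) {
  int npar = init_x.size();
  int nkeep = (n_iter - n_burn) / thin;
  NumericMatrix out(nkeep, npar);
  NumericVector x = clone(init_x);
  double lp = logpost(ch, first, mult, x, rho_fixed);
  int kept = 0;
  for (int it = 1; it <= n_iter; it++) {
    for (int j = 0; j < npar; j++) {
      double old = x[j];
      x[j] = old + R::rnorm(0.0, step);
      double lp_new = logpost(ch, first, mult, x, rho_fixed);
      if (std::log(R::runif(0.0, 1.0)) < lp_new - lp) {
        lp = lp_new;
      } else {
        x[j] = old;
      }
    }
    if (it > n_burn && (it - n_burn) % thin == 0) {
      for (int j = 0; j < npar; j++) {
        out(kept, j) = 1.0 / (1.0 + std::exp(-x[j]));
      }
      kept++;
    }
  }
  return out;
}
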