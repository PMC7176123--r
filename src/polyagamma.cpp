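// Exact sampler for the Polya-Gamma distribution PG(1, z), used to augment
// the Bernoulli-logit likelihood into conditionally Gaussian form.
//
// Alternating-series rejection sampler (Devroye-type) on the Jacobi
// representation PG(1, z) = J*(1, z/2) / 4, with the proposal a mixture of a
// truncated exponential (x > t) and a truncated inverse-Gaussian (x <= t) at
// the standard switch point t = 0.64. Uses R's RNG so draws are reproducible
// under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// Coefficients a_n(x) of the alternating series for the J*(1, .) density.
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > TRUNC) {
    return M_PI * d * std::exp(-0.5 * d * d * M_PI * M_PI * x);
  } else {
    return M_PI * d * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * d * d / x);
  }
}

// Probability that the proposal draws from the exponential (x > t) branch.
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian IG(1/z, 1) truncated to (0, t).
static double rtigauss(double z, double t) {
  z = std::fabs(z);
  double x = t + 1.0;
  if (z < 1.0 / t) { // mu = 1/z > t: one-sided rejection from the boundary
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double mu_y = mu * y;
      x = mu + 0.5 * mu * mu_y -
          0.5 * mu * std::sqrt(4.0 * mu_y + mu_y * mu_y);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  for (;;) {
    double x;
    if (R::unif_rand() < mass_texpon(z)) {
      x = TRUNC + R::exp_rand() / fz;
    } else {
      x = rtigauss(z, TRUNC);
    }
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x; // accept
      } else {
        s += a_coef(n, x);
        if (y > s) break; // reject, propose again
      }
    }
  }
}

// [[Rcpp::export(rpg_devroye)]]
NumericVector rpg_devroye(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(z[i])) stop("non-finite tilting parameter in PG draw");
    out[i] = rpg1(z[i]);
  }
  return out;
}
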