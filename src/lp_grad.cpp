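// Log joint density and gradient of the four count-regression families on
// the unconstrained scale, for the Hamiltonian sampler.
//
// Parameter layout in q:
//   [0]                gamma (intercept, log rate per AE)
//   [1 .. p]           fixed effects (design-column order)
//   if school effects: [p+1 .. p+S] zeta, then log(sigma_zeta)
//   if NB/ZINB:        log(kappa_nb)
//   if ZINB:           logit(theta) per event level
//
// Families: 0 poisson, 1 poisson_school, 2 nb_school, 3 zinb_school.
// Priors: Cauchy(0, scaleFixed) on intercept+effects (or Gamma(shape,rate)
// on exp(gamma)); Normal(0, sigma) on zeta; half-Cauchy(0, scaleSigma) on
// sigma and kappa; Uniform(0,1) on theta. Log-Jacobians of the log/logit
// transforms are included.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List lpGradCpp(NumericVector q, IntegerVector x, NumericMatrix X,
               NumericVector offset, IntegerVector school, int nschool,
               IntegerVector event, int nevent, int family,
               double scaleFixed, double scaleSigma, int interceptPrior,
               double ipShape, double ipRate) {
  const int n = x.size();
  const int p = X.ncol();
  const int d = q.size();
  const bool hasSchool = family >= 1;
  const bool hasKappa = family >= 2;
  const bool hasTheta = family == 3;

  int pos = 1 + p;
  const int zOff = pos;
  if (hasSchool) pos += nschool;
  const int lsOff = hasSchool ? pos++ : -1;
  const int lkOff = hasKappa ? pos++ : -1;
  const int thOff = hasTheta ? pos : -1;
  if (hasTheta) pos += nevent;
  if (pos != d) stop("parameter vector length mismatch");

  const double g = q[0];
  const double lsig = hasSchool ? q[lsOff] : 0.0;
  const double sigma = std::exp(lsig);
  const double lk = hasKappa ? q[lkOff] : 0.0;
  const double k = std::exp(lk);

  std::vector<double> theta(hasTheta ? nevent : 0);
  if (hasTheta)
    for (int e = 0; e < nevent; ++e)
      theta[e] = 1.0 / (1.0 + std::exp(-q[thOff + e]));

  NumericVector grad(d);
  double lp = 0.0, dk = 0.0;
  bool bad = false;

  for (int i = 0; i < n && !bad; ++i) {
    double eta = g + offset[i];
    for (int j = 0; j < p; ++j)
      if (X(i, j) != 0.0) eta += X(i, j) * q[1 + j];
    if (hasSchool) eta += q[zOff + school[i] - 1];
    if (eta > 45.0) { bad = true; break; }
    const double mu = std::exp(eta);
    const double xi = (double)x[i];
    double r;  // d loglik / d eta for this row
    if (family <= 1) {
      lp += xi * eta - mu - std::lgamma(xi + 1.0);
      r = xi - mu;
    } else {
      const double km = k + mu;
      const double lkm = std::log(km);
      if (family == 2 || x[i] > 0) {
        double ll = std::lgamma(xi + k) - std::lgamma(k) -
          std::lgamma(xi + 1.0) + k * (lk - lkm) + xi * (eta - lkm);
        double rr = xi - mu * (xi + k) / km;
        double dki = R::digamma(xi + k) - R::digamma(k) + lk + 1.0 -
          lkm - (xi + k) / km;
        if (family == 3) {
          const double th = theta[event[i] - 1];
          ll += std::log1p(-th);
          grad[thOff + event[i] - 1] += -th;  // dll/dtheta * theta(1-theta)
        }
        lp += ll;
        r = rr;
        dk += dki;
      } else {
        // ZINB zero cell: log(theta + (1 - theta) * NB(0))
        const double th = theta[event[i] - 1];
        const double a0 = k * (lk - lkm);
        const double p0 = std::exp(a0);
        const double L = th + (1.0 - th) * p0;
        lp += std::log(L);
        r = -(1.0 - th) * p0 * k * mu / (km * L);
        dk += (1.0 - th) * p0 * (lk + 1.0 - lkm - k / km) / L;
        grad[thOff + event[i] - 1] += (1.0 - p0) / L * th * (1.0 - th);
      }
    }
    grad[0] += r;
    for (int j = 0; j < p; ++j)
      if (X(i, j) != 0.0) grad[1 + j] += X(i, j) * r;
    if (hasSchool) grad[zOff + school[i] - 1] += r;
  }

  if (bad || !std::isfinite(lp))
    return List::create(_["lp"] = R_NegInf,
                        _["grad"] = NumericVector(d));

  // priors
  const double s2f = scaleFixed * scaleFixed;
  if (interceptPrior == 1) {
    lp += ipShape * g - ipRate * std::exp(g) + ipShape * std::log(ipRate) -
      std::lgamma(ipShape);
    grad[0] += ipShape - ipRate * std::exp(g);
  } else {
    lp += -std::log(M_PI * scaleFixed) - std::log1p(g * g / s2f);
    grad[0] += -2.0 * g / (s2f + g * g);
  }
  for (int j = 0; j < p; ++j) {
    const double b = q[1 + j];
    lp += -std::log(M_PI * scaleFixed) - std::log1p(b * b / s2f);
    grad[1 + j] += -2.0 * b / (s2f + b * b);
  }
  if (hasSchool) {
    const double s2 = sigma * sigma;
    double ssq = 0.0;
    for (int s = 0; s < nschool; ++s) {
      const double z = q[zOff + s];
      ssq += z * z;
      grad[zOff + s] += -z / s2;
    }
    lp += -nschool * (lsig + 0.5 * std::log(2.0 * M_PI)) -
      ssq / (2.0 * s2);
    const double ss2 = scaleSigma * scaleSigma;
    lp += std::log(2.0 / (M_PI * scaleSigma)) -
      std::log1p(s2 / ss2) + lsig;  // half-Cauchy + log-Jacobian
    grad[lsOff] += -nschool + ssq / s2 - 2.0 * s2 / (ss2 + s2) + 1.0;
  }
  if (hasKappa) {
    const double ss2 = scaleSigma * scaleSigma;
    lp += std::log(2.0 / (M_PI * scaleSigma)) -
      std::log1p(k * k / ss2) + lk;
    grad[lkOff] = k * dk - 2.0 * k * k / (ss2 + k * k) + 1.0;
  }
  if (hasTheta)
    for (int e = 0; e < nevent; ++e) {
      lp += std::log(theta[e]) + std::log1p(-theta[e]);  // uniform + Jacobian
      grad[thOff + e] += 1.0 - 2.0 * theta[e];
    }

  if (!std::isfinite(lp))
    return List::create(_["lp"] = R_NegInf,
                        _["grad"] = NumericVector(d));
  return List::create(_["lp"] = lp, _["grad"] = grad);
}
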