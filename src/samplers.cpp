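// Single-site Gibbs samplers with residual updating for whole-genome
// regression (BayesA / BayesB / BayesCpi / Bayesian LASSO) and GBLUP.
// All randomness goes through R's RNG so set.seed() in R gives
// bit-reproducible chains.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// scaled-inverse-chi-square(df, scale): df*scale / chisq(df)
static inline double rscinv(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// inverse-Gaussian(mu, lambda), Michael-Schucany-Haas.  The textbook
// form mu + mu^2 y/(2 lambda) - (mu/2lambda) sqrt(4 mu lambda y + ...)
// cancels catastrophically when mu >> lambda; this algebraically equal
// form is stable for all mu:  x = mu (1 - 2 / (1 + sqrt(1 + 4/u))),
// u = y mu / lambda.
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x;
  if (y <= 0.0) {
    x = mu;
  } else {
    double u = y * mu / lambda;
    x = mu * (1.0 - 2.0 / (1.0 + std::sqrt(1.0 + 4.0 / u)));
  }
  if (x <= 0.0) x = 1e-300;  // numerical underflow guard
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static inline double vec_var(const std::vector<double>& g) {
  const int n = (int)g.size();
  if (n < 2) return 0.0;
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += g[i];
  m /= n;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += (g[i] - m) * (g[i] - m);
  return s / (n - 1);
}

// models: 0 = bayesA, 1 = bayesB, 2 = bayesCpi (pi = 0 gives ridge),
//         3 = blasso
// [[Rcpp::export(name = ".wgr_mcmc")]]
List wgr_mcmc(NumericVector y0, LogicalVector yMiss, NumericMatrix X,
              NumericMatrix W, int model, List hyper, int nIter,
              int burnIn, int thin, bool saveEffects, bool debug) {
  const int n = y0.size();
  const int p = X.ncol();
  const int m = W.ncol();
  const double nu = as<double>(hyper["nu"]);
  const double S = as<double>(hyper["S"]);
  const double nuE = as<double>(hyper["nuE"]);
  const double SE = as<double>(hyper["SE"]);
  double piZero = as<double>(hyper["pi"]);
  const bool piEstimate = as<bool>(hyper["piEstimate"]);
  double lambda2 = as<double>(hyper["lambda2"]);
  const bool lambdaFixed = as<bool>(hyper["lambdaFixed"]);
  const double lambdaShape = as<double>(hyper["lambdaShape"]);
  const double lambdaRate = as<double>(hyper["lambdaRate"]);
  const bool fixVarE = as<bool>(hyper["fixVarE"]);
  double S_ = S;
  const bool SEstimate = as<bool>(hyper["SEstimate"]);
  const double SShape = as<double>(hyper["SShape"]);
  const double SRate = as<double>(hyper["SRate"]);

  std::vector<double> yw(n), e(n), g(n, 0.0);
  double yObsMean = 0.0;
  int nObs = 0;
  for (int i = 0; i < n; ++i)
    if (!yMiss[i]) { yObsMean += y0[i]; ++nObs; }
  yObsMean = (nObs > 0) ? yObsMean / nObs : 0.0;
  for (int i = 0; i < n; ++i) {
    yw[i] = yMiss[i] ? yObsMean : y0[i];
    e[i] = yw[i];
  }

  std::vector<double> b(p, 0.0), xtx(p), alpha(m, 0.0), wtw(m);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }

  std::vector<double> varJ(m, S > 0 ? S : 1.0);  // bayesA/B per-marker var
  double varAlpha = S > 0 ? S : 1.0;             // bayesCpi common var
  std::vector<double> tau2(m, 1.0);              // blasso
  std::vector<int> delta(m, model == 1 ? 0 : 1); // inclusion indicators
  double varE = fixVarE ? as<double>(hyper["varEFixed"])
                        : (SE > 0 ? SE : 1.0);

  const int nStore = (nIter - burnIn) / thin;
  NumericMatrix bDraws(nStore, p), scalar(nStore, 4);
  colnames(scalar) = CharacterVector::create("varE", "varG", "pi",
                                             "lambda2");
  NumericMatrix alphaDraws(saveEffects ? nStore : 0, saveEffects ? m : 0);
  std::vector<double> aSum(m, 0.0), aSq(m, 0.0), gSum(n, 0.0);
  double residDev = 0.0;
  int stored = 0;

  for (int it = 0; it < nIter; ++it) {
    // data augmentation: redraw missing phenotypes from the model
    for (int i = 0; i < n; ++i) if (yMiss[i]) {
      double fitted = yw[i] - e[i];
      e[i] = R::norm_rand() * std::sqrt(varE);
      yw[i] = fitted + e[i];
    }
    // fixed effects, flat prior
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0) continue;
      double rhs = xtx[k] * b[k];
      for (int i = 0; i < n; ++i) rhs += X(i, k) * e[i];
      double bn = rhs / xtx[k] +
        R::norm_rand() * std::sqrt(varE / xtx[k]);
      double d_ = bn - b[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * d_;
      b[k] = bn;
    }
    // marker effects
    int mZero = 0, mIn = 0;
    double sumA2in = 0.0;
    for (int j = 0; j < m; ++j) {
      const double c = wtw[j];
      if (c <= 1e-12) { continue; }
      double* wj = &W(0, j);
      double r = c * alpha[j];
      for (int i = 0; i < n; ++i) r += wj[i] * e[i];
      double aOld = alpha[j], aNew = 0.0;
      if (model == 0) {                       // bayesA
        double lhs = c + varE / varJ[j];
        aNew = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
        varJ[j] = rscinv(nu + 1.0, (nu * S_ + aNew * aNew) / (nu + 1.0));
      } else if (model == 1 || model == 2) {  // bayesB / bayesCpi
        double vj = (model == 1) ? varJ[j] : varAlpha;
        int incl;
        if (piZero <= 0.0) incl = 1;
        else if (piZero >= 1.0) incl = 0;
        else {
          double v0 = c * varE;
          double v1 = c * varE + c * c * vj;
          double lo = std::log(1.0 - piZero) - std::log(piZero) +
            0.5 * (std::log(v0 / v1) + r * r * (1.0 / v0 - 1.0 / v1));
          double pr1 = 1.0 / (1.0 + std::exp(-lo));
          incl = (R::unif_rand() < pr1) ? 1 : 0;
        }
        delta[j] = incl;
        if (incl) {
          double lhs = c + varE / vj;
          aNew = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
          ++mIn;
          sumA2in += aNew * aNew;
        } else {
          aNew = 0.0;
          ++mZero;
        }
        if (model == 1)
          varJ[j] = incl
            ? rscinv(nu + 1.0, (nu * S_ + aNew * aNew) / (nu + 1.0))
            : rscinv(nu, S_);                 // prior draw when excluded
      } else {                                // blasso (Park-Casella)
        double lhs = c + 1.0 / tau2[j];
        aNew = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
        double a2 = aNew * aNew;
        double mu = (a2 > 1e-16 * lambda2 * varE)
          ? std::sqrt(lambda2 * varE / a2) : 1e8;
        tau2[j] = 1.0 / rinvgauss(mu, lambda2);
      }
      if (aNew != aOld) {
        double d_ = aNew - aOld;
        for (int i = 0; i < n; ++i) e[i] -= wj[i] * d_;
        alpha[j] = aNew;
      }
    }
    // hyper updates
    if (SEstimate && (model == 0 || model == 1)) {
      double sumInv = 0.0;
      for (int j = 0; j < m; ++j) sumInv += 1.0 / varJ[j];
      S_ = R::rgamma(SShape + 0.5 * m * nu,
                     1.0 / (SRate + 0.5 * nu * sumInv));
    }
    if (model == 2)
      varAlpha = rscinv(nu + mIn, (nu * S_ + sumA2in) / (nu + mIn));
    if ((model == 1 || model == 2) && piEstimate)
      piZero = R::rbeta(mZero + 1.0, (m - mZero) + 1.0);
    if (model == 3 && !lambdaFixed) {
      double st = 0.0;
      for (int j = 0; j < m; ++j) st += tau2[j];
      lambda2 = R::rgamma(lambdaShape + m, 1.0 / (lambdaRate + st / 2.0));
    }
    // residual variance
    if (!fixVarE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = (sse + nuE * SE) / R::rchisq(nuE + n);
    }
    // storage
    if (it >= burnIn && (it - burnIn) % thin == 0 && stored < nStore) {
      // genetic values from the maintained residual: g = yw - Xb - e
      for (int i = 0; i < n; ++i) {
        double fit = 0.0;
        for (int k = 0; k < p; ++k) fit += X(i, k) * b[k];
        g[i] = yw[i] - fit - e[i];
      }
      scalar(stored, 0) = varE;
      scalar(stored, 1) = vec_var(g);
      scalar(stored, 2) = piZero;
      scalar(stored, 3) = lambda2;
      for (int k = 0; k < p; ++k) bDraws(stored, k) = b[k];
      for (int j = 0; j < m; ++j) {
        aSum[j] += alpha[j];
        aSq[j] += alpha[j] * alpha[j];
        if (saveEffects) alphaDraws(stored, j) = alpha[j];
      }
      for (int i = 0; i < n; ++i) gSum[i] += g[i];
      if (debug) {
        // residual-update consistency: recompute W alpha from scratch
        std::vector<double> gt(n, 0.0);
        for (int j = 0; j < m; ++j) {
          double* wj = &W(0, j);
          for (int i = 0; i < n; ++i) gt[i] += wj[i] * alpha[j];
        }
        double mx = 0.0;
        for (int i = 0; i < n; ++i) {
          double dev = std::fabs(gt[i] - g[i]);
          if (dev > mx) mx = dev;
        }
        if (mx > residDev) residDev = mx;
      }
      ++stored;
    }
  }

  NumericVector aMean(m), aSD(m), gMean(n);
  for (int j = 0; j < m; ++j) {
    aMean[j] = aSum[j] / nStore;
    double v = aSq[j] / nStore - aMean[j] * aMean[j];
    aSD[j] = v > 0 ? std::sqrt(v) : 0.0;
  }
  for (int i = 0; i < n; ++i) gMean[i] = gSum[i] / nStore;
  return List::create(_["scalar"] = scalar, _["b"] = bDraws,
                      _["alphaMean"] = aMean, _["alphaSD"] = aSD,
                      _["gMean"] = gMean, _["alphaDraws"] = alphaDraws,
                      _["residDev"] = residDev);
}

// GBLUP via one-time eigendecomposition of G: u = U gamma with
// gamma_k ~ N(0, d_k * varA); coordinates updated singly.
// [[Rcpp::export(name = ".gblup_mcmc")]]
List gblup_mcmc(NumericVector y0, LogicalVector yMiss, NumericMatrix X,
                NumericMatrix U, NumericVector d, List hyper, int nIter,
                int burnIn, int thin, bool saveEffects, bool debug) {
  const int n = y0.size();
  const int p = X.ncol();
  const int K = U.ncol();
  const double nu = as<double>(hyper["nu"]);
  const double S = as<double>(hyper["S"]);
  const double nuE = as<double>(hyper["nuE"]);
  const double SE = as<double>(hyper["SE"]);
  const bool fixVarE = as<bool>(hyper["fixVarE"]);

  std::vector<double> yw(n), e(n), g(n, 0.0), b(p, 0.0), xtx(p);
  double yObsMean = 0.0;
  int nObs = 0;
  for (int i = 0; i < n; ++i)
    if (!yMiss[i]) { yObsMean += y0[i]; ++nObs; }
  yObsMean = (nObs > 0) ? yObsMean / nObs : 0.0;
  for (int i = 0; i < n; ++i) {
    yw[i] = yMiss[i] ? yObsMean : y0[i];
    e[i] = yw[i];
  }
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  std::vector<double> gamma(K, 0.0);
  double varA = S > 0 ? S : 1.0;
  double varE = fixVarE ? as<double>(hyper["varEFixed"])
                        : (SE > 0 ? SE : 1.0);

  const int nStore = (nIter - burnIn) / thin;
  NumericMatrix bDraws(nStore, p), scalar(nStore, 2);
  colnames(scalar) = CharacterVector::create("varE", "varG");
  NumericMatrix uDraws(saveEffects ? nStore : 0, saveEffects ? n : 0);
  std::vector<double> uSum(n, 0.0), uSq(n, 0.0);
  double residDev = 0.0;
  int stored = 0;

  for (int it = 0; it < nIter; ++it) {
    for (int i = 0; i < n; ++i) if (yMiss[i]) {
      double fitted = yw[i] - e[i];
      e[i] = R::norm_rand() * std::sqrt(varE);
      yw[i] = fitted + e[i];
    }
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0) continue;
      double rhs = xtx[k] * b[k];
      for (int i = 0; i < n; ++i) rhs += X(i, k) * e[i];
      double bn = rhs / xtx[k] +
        R::norm_rand() * std::sqrt(varE / xtx[k]);
      double d_ = bn - b[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * d_;
      b[k] = bn;
    }
    double sgam = 0.0;  // sum gamma_k^2 / d_k
    for (int k = 0; k < K; ++k) {
      double* uk = &U(0, k);
      double r = gamma[k];                 // u_k'u_k = 1 (orthonormal)
      for (int i = 0; i < n; ++i) r += uk[i] * e[i];
      double lhs = 1.0 + varE / (d[k] * varA);
      double gn = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
      double d_ = gn - gamma[k];
      for (int i = 0; i < n; ++i) {
        e[i] -= uk[i] * d_;
        g[i] += uk[i] * d_;
      }
      gamma[k] = gn;
      sgam += gn * gn / d[k];
    }
    varA = rscinv(nu + K, (nu * S + sgam) / (nu + K));
    if (!fixVarE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = (sse + nuE * SE) / R::rchisq(nuE + n);
    }
    if (it >= burnIn && (it - burnIn) % thin == 0 && stored < nStore) {
      scalar(stored, 0) = varE;
      scalar(stored, 1) = varA;
      for (int k = 0; k < p; ++k) bDraws(stored, k) = b[k];
      for (int i = 0; i < n; ++i) {
        uSum[i] += g[i];
        uSq[i] += g[i] * g[i];
        if (saveEffects) uDraws(stored, i) = g[i];
      }
      if (debug) {
        double mx = 0.0;
        for (int i = 0; i < n; ++i) {
          double fit = 0.0;
          for (int k = 0; k < p; ++k) fit += X(i, k) * b[k];
          double dev = std::fabs(yw[i] - fit - g[i] - e[i]);
          if (dev > mx) mx = dev;
        }
        if (mx > residDev) residDev = mx;
      }
      ++stored;
    }
  }
  NumericVector uMean(n), uSD(n);
  for (int i = 0; i < n; ++i) {
    uMean[i] = uSum[i] / nStore;
    double v = uSq[i] / nStore - uMean[i] * uMean[i];
    uSD[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["scalar"] = scalar, _["b"] = bDraws,
                      _["uMean"] = uMean, _["uSD"] = uSD,
                      _["uDraws"] = uDraws, _["residDev"] = residDev);
}
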