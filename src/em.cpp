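#include <Rcpp.h>
using namespace Rcpp;

// EM fit of the two-class discrete-time hazard mixture.
//
// Inputs are prepared in R: pos[i] = number of grid ages <= t_i,
// j[i] = 1-based grid position of t_i (0 when t_i is off-grid),
// event[i] in {0,1}, p[i] = carrier mixing weight, K = grid length.
//
// Each iteration evaluates the per-individual class likelihoods
//   L_g(i) = lambda_g[j_i]^d_i * prod_{k < pos*_i} (1 - lambda_g[k])
//            * (1 - lambda_g[j_i])^{(1-d_i) [t_i on grid]}
// (pos* excludes t_i itself), takes the posterior carrier probability
// pi_i, and updates each hazard as the pi-weighted occurrence/exposure
// ratio over the risk set {t_i >= t_k}. Stops when the marginal
// log-likelihood improves by less than tol.
// [[Rcpp::export(name = ".em_mml_fit_cpp")]]
List em_mml_fit(IntegerVector pos, IntegerVector j, IntegerVector event,
                NumericVector p, int K, double tol, int max_iter) {
  const int n = pos.size();
  std::vector<double> lam1(K), lam0(K);
  std::vector<double> cum1(K + 1), cum0(K + 1);
  std::vector<double> s1(K + 1), s0(K + 1);   // bucket sums by pos
  std::vector<double> num1(K + 1), num0(K + 1); // event sums by j
  NumericVector pi_hat(n);

  // pooled occurrence/exposure initialisation (pi = 1 for everyone)
  {
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(num1.begin(), num1.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      s1[pos[i]] += 1.0;
      if (event[i] == 1) num1[j[i]] += 1.0;
    }
    double risk = 0.0;
    for (int k = K; k >= 1; --k) {
      risk += s1[k];
      double lam = risk > 0.0 ? num1[k] / risk : 0.0;
      lam1[k - 1] = lam0[k - 1] = lam;
    }
  }

  double loglik = R_NegInf;
  bool converged = false, empty_risk = false;
  int it = 0;
  std::vector<double> trace;
  trace.reserve(64);

  for (it = 1; it <= max_iter; ++it) {
    // cumulative survival products; cum[m] = prod_{k <= m} (1 - lambda[k])
    cum1[0] = cum0[0] = 1.0;
    for (int k = 1; k <= K; ++k) {
      cum1[k] = cum1[k - 1] * (1.0 - lam1[k - 1]);
      cum0[k] = cum0[k - 1] * (1.0 - lam0[k - 1]);
    }

    double new_loglik = 0.0;
    for (int i = 0; i < n; ++i) {
      const int ji = j[i];
      const int nlt = pos[i] - (ji > 0 ? 1 : 0);
      double L1 = cum1[nlt], L0 = cum0[nlt];
      if (ji > 0) {
        if (event[i] == 1) {
          L1 *= lam1[ji - 1];
          L0 *= lam0[ji - 1];
        } else {
          L1 *= 1.0 - lam1[ji - 1];
          L0 *= 1.0 - lam0[ji - 1];
        }
      }
      const double a = p[i] * L1, b = (1.0 - p[i]) * L0, den = a + b;
      pi_hat[i] = den > 0.0 ? a / den : p[i];
      new_loglik += std::log(den);
    }

    trace.push_back(new_loglik);
    if (R_finite(new_loglik) && it > 1 && new_loglik - loglik < tol) {
      loglik = std::max(loglik, new_loglik);
      converged = true;
      break;
    }
    loglik = new_loglik;

    // M-step: weighted occurrence/exposure per class
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s0.begin(), s0.end(), 0.0);
    std::fill(num1.begin(), num1.end(), 0.0);
    std::fill(num0.begin(), num0.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      s1[pos[i]] += pi_hat[i];
      s0[pos[i]] += 1.0 - pi_hat[i];
      if (event[i] == 1) {
        num1[j[i]] += pi_hat[i];
        num0[j[i]] += 1.0 - pi_hat[i];
      }
    }
    double risk1 = 0.0, risk0 = 0.0;
    for (int k = K; k >= 1; --k) {
      risk1 += s1[k];
      risk0 += s0[k];
      if (risk1 <= 0.0 || risk0 <= 0.0) empty_risk = true;
      double l1 = risk1 > 0.0 ? num1[k] / risk1 : 0.0;
      double l0 = risk0 > 0.0 ? num0[k] / risk0 : 0.0;
      lam1[k - 1] = std::min(std::max(l1, 0.0), 1.0);
      lam0[k - 1] = std::min(std::max(l0, 0.0), 1.0);
    }
  }
  if (it > max_iter) it = max_iter;

  return List::create(
    _["lambda_carrier"] = NumericVector(lam1.begin(), lam1.end()),
    _["lambda_noncarrier"] = NumericVector(lam0.begin(), lam0.end()),
    _["posterior"] = pi_hat,
    _["loglik"] = loglik,
    _["iterations"] = it,
    _["converged"] = converged,
    _["empty_risk"] = empty_risk,
    _["trace"] = NumericVector(trace.begin(), trace.end())
  );
}
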