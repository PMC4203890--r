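// Gibbs sampler for a 1-D Dirichlet-process mixture of normals with a
// normal/inverse-gamma base measure (Neal's collapsed algorithm for the
// assignments, explicit parameter draws for the k0 and density updates).

#include <Rcpp.h>
using namespace Rcpp;

// log Student-t density with location m, scale s, df v
static double dt_ls(double y, double m, double s, double v) {
  double z = (y - m) / s;
  return R::lgammafn((v + 1.0) / 2.0) - R::lgammafn(v / 2.0) -
         0.5 * std::log(v * M_PI) - std::log(s) -
         (v + 1.0) / 2.0 * std::log1p(z * z / v);
}

// [[Rcpp::export(name = ".dpGibbsCpp")]]
List dpGibbsCpp(NumericVector y, double mu1, double k0init, double nu1,
                double psi1, double tau1, double tau2, double a0, double b0,
                int nIter, int nBurn, int nThin, double alphaFix) {
  int n = y.size();
  double a = nu1 / 2.0, b = psi1 / 2.0;  // IG prior on sigma^2
  double k0 = k0init;
  double alpha = (alphaFix > 0.0) ? alphaFix : 1.0;

  std::vector<int> z(n, 0);               // cluster labels
  std::vector<double> csum, csum2;        // per-cluster sums
  std::vector<int> cn;                    // per-cluster sizes
  csum.push_back(0.0); csum2.push_back(0.0); cn.push_back(0);
  for (int i = 0; i < n; ++i) {
    cn[0]++; csum[0] += y[i]; csum2[0] += y[i] * y[i];
  }

  int nKeep = 0;
  std::map<int, int> kCount;              // occupied-cluster histogram
  std::map<int, double> bestLoglik;       // best joint loglik per K
  std::map<int, List> bestState;
  std::vector<int> kTrace;                // occupied K per retained sample

  for (int iter = 0; iter < nIter; ++iter) {
    // --- resample assignments (collapsed) ---
    for (int i = 0; i < n; ++i) {
      int zi = z[i];
      cn[zi]--; csum[zi] -= y[i]; csum2[zi] -= y[i] * y[i];
      int K = cn.size();
      std::vector<double> logw(K + 1);
      for (int c = 0; c < K; ++c) {
        if (cn[c] == 0) { logw[c] = R_NegInf; continue; }
        double m = cn[c];
        double ybar = csum[c] / m;
        double ssq = csum2[c] - m * ybar * ybar;
        double kn = k0 + m;
        double mn = (k0 * mu1 + m * ybar) / kn;
        double an = a + m / 2.0;
        double bn = b + 0.5 * ssq +
                    k0 * m * (ybar - mu1) * (ybar - mu1) / (2.0 * kn);
        double scale = std::sqrt(bn * (kn + 1.0) / (an * kn));
        logw[c] = std::log(m) + dt_ls(y[i], mn, scale, 2.0 * an);
      }
      double scale0 = std::sqrt(b * (k0 + 1.0) / (a * k0));
      logw[K] = std::log(alpha) + dt_ls(y[i], mu1, scale0, 2.0 * a);
      double mx = *std::max_element(logw.begin(), logw.end());
      std::vector<double> w(K + 1);
      double tot = 0.0;
      for (int c = 0; c <= K; ++c) { w[c] = std::exp(logw[c] - mx); tot += w[c]; }
      double u = R::runif(0.0, tot), acc = 0.0;
      int pick = K;
      for (int c = 0; c <= K; ++c) { acc += w[c]; if (u <= acc) { pick = c; break; } }
      if (pick == K) { csum.push_back(0.0); csum2.push_back(0.0); cn.push_back(0); }
      z[i] = pick;
      cn[pick]++; csum[pick] += y[i]; csum2[pick] += y[i] * y[i];
    }
    // drop empty clusters, relabel
    {
      std::vector<int> map(cn.size(), -1);
      std::vector<double> s2, q2; std::vector<int> c2;
      for (size_t c = 0; c < cn.size(); ++c)
        if (cn[c] > 0) {
          map[c] = c2.size();
          c2.push_back(cn[c]); s2.push_back(csum[c]); q2.push_back(csum2[c]);
        }
      for (int i = 0; i < n; ++i) z[i] = map[z[i]];
      cn = c2; csum = s2; csum2 = q2;
    }
    int K = cn.size();

    // --- draw cluster parameters from conjugate posteriors ---
    std::vector<double> muC(K), sdC(K);
    double sumDev = 0.0;
    for (int c = 0; c < K; ++c) {
      double m = cn[c];
      double ybar = csum[c] / m;
      double ssq = csum2[c] - m * ybar * ybar;
      double kn = k0 + m;
      double mn = (k0 * mu1 + m * ybar) / kn;
      double an = a + m / 2.0;
      double bn = b + 0.5 * ssq +
                  k0 * m * (ybar - mu1) * (ybar - mu1) / (2.0 * kn);
      double sig2 = bn / R::rgamma(an, 1.0);
      muC[c] = R::rnorm(mn, std::sqrt(sig2 / kn));
      sdC[c] = std::sqrt(sig2);
      sumDev += (muC[c] - mu1) * (muC[c] - mu1) / sig2;
    }
    // --- k0 from its Gamma posterior ---
    k0 = R::rgamma(tau1 / 2.0 + K / 2.0, 1.0 / (tau2 / 2.0 + sumDev / 2.0));
    if (k0 < 1e-8) k0 = 1e-8;
    // --- alpha: Escobar-West auxiliary update ---
    if (alphaFix <= 0.0) {
      double eta = R::rbeta(alpha + 1.0, (double)n);
      double odds = (a0 + K - 1.0) / (n * (b0 - std::log(eta)));
      double pi1 = odds / (1.0 + odds);
      double shape = (R::runif(0.0, 1.0) < pi1) ? (a0 + K) : (a0 + K - 1.0);
      alpha = R::rgamma(shape, 1.0 / (b0 - std::log(eta)));
      if (alpha < 1e-8) alpha = 1e-8;
    }

    if (iter >= nBurn && ((iter - nBurn) % nThin == 0)) {
      ++nKeep;
      // joint log density of the sampled state: classification likelihood
      // plus parameter priors (NIG base measure) plus the CRP partition
      double jll = 0.0;
      for (int i = 0; i < n; ++i)
        jll += R::dnorm(y[i], muC[z[i]], sdC[z[i]], 1);
      for (int c = 0; c < K; ++c) {
        double s2 = sdC[c] * sdC[c];
        jll += a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(s2) -
               b / s2;                                   // InvGamma(s2; a, b)
        jll += R::dnorm(muC[c], mu1, std::sqrt(s2 / k0), 1);
        jll += std::log(alpha) + R::lgammafn((double)cn[c]);
      }
      jll += R::lgammafn(alpha) - R::lgammafn(alpha + n);
      kCount[K]++;
      kTrace.push_back(K);
      if (bestLoglik.find(K) == bestLoglik.end() || jll > bestLoglik[K]) {
        bestLoglik[K] = jll;
        NumericVector w(K), mu(K), sd(K);
        for (int c = 0; c < K; ++c) {
          w[c] = (double)cn[c] / n; mu[c] = muC[c]; sd[c] = sdC[c];
        }
        bestState[K] = List::create(_["weight"] = w, _["mean"] = mu,
                                    _["sd"] = sd, _["joint"] = jll);
      }
    }
  }

  // posterior-mode K, then its best state
  int kMode = -1, cMax = -1;
  for (std::map<int, int>::iterator it = kCount.begin(); it != kCount.end(); ++it)
    if (it->second > cMax) { cMax = it->second; kMode = it->first; }
  IntegerVector kTr(kTrace.begin(), kTrace.end());
  return List::create(_["kMode"] = kMode, _["state"] = bestState[kMode],
                      _["kTrace"] = kTr, _["nKeep"] = nKeep);
}
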