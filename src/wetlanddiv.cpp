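#include <Rcpp.h>
using namespace Rcpp;

// Sequential urn sampler for a log-series community: individual i starts a
// new species with probability alpha/(alpha + i - 1), otherwise copies the
// species of a uniformly chosen earlier individual.  E[S] =
// alpha * (digamma(alpha + N) - digamma(alpha)) ~= alpha * log(1 + N/alpha),
// so alpha is the true diversity parameter of the generated site.
// Uses R's RNG: seeding via set.seed() on the R side.
// [[Rcpp::export]]
IntegerVector hoppe_urn_sample(double alpha, int n_individuals) {
  if (alpha <= 0.0) stop("alpha must be > 0");
  if (n_individuals < 1) stop("n_individuals must be >= 1");
  std::vector<int> lab(n_individuals);
  int n_species = 0;
  for (int i = 0; i < n_individuals; ++i) {
    double u = unif_rand() * (alpha + i);
    if (u < alpha) {
      lab[i] = n_species++;
    } else {
      int j = (int)(unif_rand() * i);
      if (j >= i) j = i - 1;  // guard against unif_rand() == 1
      lab[i] = lab[j];
    }
  }
  IntegerVector counts(n_species);
  for (int i = 0; i < n_individuals; ++i) counts[lab[i]]++;
  return counts;
}

// Exact single-covariate quantile regression by vertex enumeration: an
// optimal solution of min sum rho_tau(y - b0 - b1 x) interpolates at least
// two data points, so all O(n^2) candidate lines through point pairs are
// scored.  The positive/negative residual sums of each candidate do not
// depend on tau, so the per-tau scan is O(n^2) after an O(n^3) setup.
// Returns a (n_tau x 3) matrix: b0, b1, loss.
// [[Rcpp::export]]
NumericMatrix qr_enumerate(NumericVector y, NumericVector x,
                           NumericVector taus) {
  int n = y.size();
  if (x.size() != n) stop("y and x lengths differ");
  if (n < 2) stop("need at least 2 observations");
  std::vector<double> b0s, b1s, possum, negsum;
  b0s.reserve(n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i];
      if (dx == 0.0) continue;
      double b1 = (y[j] - y[i]) / dx;
      double b0 = y[i] - b1 * x[i];
      double P = 0.0, N = 0.0;
      for (int k = 0; k < n; ++k) {
        double r = y[k] - b0 - b1 * x[k];
        if (r > 0) P += r; else N -= r;
      }
      b0s.push_back(b0); b1s.push_back(b1);
      possum.push_back(P); negsum.push_back(N);
    }
  }
  int m = b0s.size();
  if (m == 0) stop("covariate is constant: quantile fit undefined");
  int nt = taus.size();
  NumericMatrix out(nt, 3);
  for (int t = 0; t < nt; ++t) {
    double tau = taus[t];
    if (tau <= 0.0 || tau >= 1.0) stop("tau must be in (0,1)");
    double best = R_PosInf; int bi = 0;
    for (int c = 0; c < m; ++c) {
      double loss = tau * possum[c] + (1.0 - tau) * negsum[c];
      if (loss < best) { best = loss; bi = c; }
    }
    out(t, 0) = b0s[bi]; out(t, 1) = b1s[bi]; out(t, 2) = best;
  }
  colnames(out) = CharacterVector::create("b0", "b1", "loss");
  return out;
}

// xy-pair bootstrap of the exact quantile fit.  Degenerate resamples
// (constant covariate) are redrawn; the redraw count is returned in the
// attribute "n_redrawn".  Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix qr_pair_bootstrap(NumericVector y, NumericVector x,
                                double tau, int B) {
  int n = y.size();
  NumericMatrix out(B, 2);
  NumericVector yb(n), xb(n);
  NumericVector tv = NumericVector::create(tau);
  int redrawn = 0;
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    while (!ok) {
      for (int k = 0; k < n; ++k) {
        int idx = (int)(unif_rand() * n);
        if (idx >= n) idx = n - 1;
        yb[k] = y[idx]; xb[k] = x[idx];
      }
      double x0 = xb[0];
      for (int k = 1; k < n; ++k) if (xb[k] != x0) { ok = true; break; }
      if (!ok) {
        ++redrawn;
        if (redrawn > 10000) stop("covariate nearly constant: bootstrap failed");
      }
    }
    NumericMatrix fit = qr_enumerate(yb, xb, tv);
    out(b, 0) = fit(0, 0); out(b, 1) = fit(0, 1);
  }
  colnames(out) = CharacterVector::create("b0", "b1");
  out.attr("n_redrawn") = redrawn;
  return out;
}
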