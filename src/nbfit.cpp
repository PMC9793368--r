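#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial log pmf under the mean/dispersion parametrization
// Var = m + phi * m^2; phi -> 0 is the Poisson limit.
static double nb_lpmf(double x, double m, double phi) {
  if (m <= 0.0) return (x == 0.0) ? 0.0 : R_NegInf;
  if (phi < 1e-8) {
    if (x == 0.0) return -m;
    return x * std::log(m) - m - std::lgamma(x + 1.0);
  }
  double a = 1.0 / phi;
  double lp = std::log1p(phi * m); // log(1 + phi m)
  if (x == 0.0) return -a * lp;    // gamma terms cancel; dominant case in UMI data
  return std::lgamma(x + a) - std::lgamma(a) - std::lgamma(x + 1.0)
       - a * lp + x * (std::log(phi * m) - lp);
}

// [[Rcpp::export]]
double cpp_nb_loglik(NumericVector x, NumericVector s, double mu, double phi) {
  double ll = 0.0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    ll += nb_lpmf(x[i], s[i] * mu, phi);
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

// Solve the mean score equation sum(x)/mu = sum s(1 + phi x)/(1 + phi s mu)
// by safeguarded Newton; the score is strictly decreasing in mu so the root
// is unique whenever sum(x) > 0.
static double solve_mu(const double* x, const double* s, R_xlen_t n,
                       double phi, double mu0, bool* ok) {
  double sx = 0.0, ss = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) { sx += x[i]; ss += s[i]; }
  if (sx <= 0.0) { *ok = true; return 0.0; }
  if (phi < 1e-8) { *ok = true; return sx / ss; }
  double mu = (mu0 > 0.0) ? mu0 : sx / ss;
  *ok = false;
  for (int it = 0; it < 100; ++it) {
    double g = 0.0, gp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double den = 1.0 + phi * s[i] * mu;
      double num = s[i] * (1.0 + phi * x[i]);
      g  += num / den;
      gp += num * phi * s[i] / (den * den);
    }
    // score = sx/mu - g ; derivative = -sx/mu^2 + gp
    double score = sx / mu - g;
    if (std::fabs(score) <= 1e-10 * (sx / mu + 1.0)) { *ok = true; break; }
    double d     = -sx / (mu * mu) + gp;
    double step  = (d != 0.0) ? score / d : 0.0;
    double mu_new = mu - step;
    if (!R_finite(mu_new) || mu_new <= 0.0) mu_new = mu / 2.0;
    if (std::fabs(mu_new - mu) <= 1e-10 * (mu + 1e-300)) { mu = mu_new; *ok = true; break; }
    mu = mu_new;
  }
  return mu;
}

struct ProfRes { double mu; double ll; bool ok; };

static ProfRes profile_at_phi(const double* x, const double* s, R_xlen_t n,
                              double phi, double mu_init) {
  ProfRes r;
  bool ok = true;
  r.mu = solve_mu(x, s, n, phi, mu_init, &ok);
  r.ok = ok;
  double ll = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) ll += nb_lpmf(x[i], s[i] * r.mu, phi);
  r.ll = ll;
  return r;
}

// Profile-likelihood NB fit: golden-section over log(phi) on top of the exact
// inner mean solve; phi = 0 (Poisson boundary) always considered.
// Returns (mu, phi, loglik, converged).
static void fit_nb_core(const double* x, const double* s, R_xlen_t n,
                        double* out) {
  double sx = 0.0, ss = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) { sx += x[i]; ss += s[i]; }
  if (sx <= 0.0) { out[0] = 0.0; out[1] = 0.0; out[2] = 0.0; out[3] = 1.0; return; }

  const double phi_max = 1e6;
  bool all_ok = true;

  // Poisson boundary
  double mu_pois = sx / ss;
  double ll_pois = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) ll_pois += nb_lpmf(x[i], s[i] * mu_pois, 0.0);

  // coarse grid on log10(phi)
  const int ngrid = 17;
  double best_ll = ll_pois, best_mu = mu_pois, best_phi = 0.0;
  int best_idx = -1;
  double lphi_lo = -6.0, lphi_hi = std::log10(phi_max);
  double lgrid[ngrid];
  for (int j = 0; j < ngrid; ++j) {
    lgrid[j] = lphi_lo + (lphi_hi - lphi_lo) * j / (ngrid - 1);
    double phi = std::pow(10.0, lgrid[j]);
    ProfRes r = profile_at_phi(x, s, n, phi, best_mu > 0 ? best_mu : mu_pois);
    if (!r.ok) all_ok = false;
    if (r.ll > best_ll) { best_ll = r.ll; best_mu = r.mu; best_phi = phi; best_idx = j; }
  }

  if (best_idx >= 0) {
    // golden-section refine on log(phi) between grid neighbours
    double a = (best_idx > 0) ? lgrid[best_idx - 1] : lphi_lo - 1.0;
    double b = (best_idx < ngrid - 1) ? lgrid[best_idx + 1] : lphi_hi;
    const double gr = 0.61803398874989484;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    ProfRes rc = profile_at_phi(x, s, n, std::pow(10.0, c), best_mu);
    ProfRes rd = profile_at_phi(x, s, n, std::pow(10.0, d), best_mu);
    int iter = 0;
    while (std::fabs(b - a) > 3e-5 && iter < 200) {
      if (rc.ll >= rd.ll) { b = d; d = c; rd = rc; c = b - gr * (b - a);
        rc = profile_at_phi(x, s, n, std::pow(10.0, c), rd.mu); }
      else { a = c; c = d; rc = rd; d = a + gr * (b - a);
        rd = profile_at_phi(x, s, n, std::pow(10.0, d), rc.mu); }
      ++iter;
    }
    ProfRes rbest = (rc.ll >= rd.ll) ? rc : rd;
    double lbest = (rc.ll >= rd.ll) ? c : d;
    if (rbest.ll > best_ll) { best_ll = rbest.ll; best_mu = rbest.mu;
      best_phi = std::pow(10.0, lbest); }
    if (iter >= 200) all_ok = false;
  }

  out[0] = best_mu; out[1] = best_phi; out[2] = best_ll;
  out[3] = all_ok ? 1.0 : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_fit_nb(NumericVector x, NumericVector s) {
  NumericVector out(4);
  fit_nb_core(REAL(x), REAL(s), x.size(), REAL(out));
  return out;
}

// Fit every (gene, cluster) cell of a genes x cells matrix independently.
// labels are 1-based cluster ids. Returns G x K matrices mu, phi, loglik, conv.
// [[Rcpp::export]]
List cpp_fit_nb_by_cluster(NumericMatrix X, NumericVector s, IntegerVector labels,
                           int K) {
  R_xlen_t G = X.nrow(), N = X.ncol();
  // index cells per cluster
  std::vector< std::vector<int> > idx(K);
  for (R_xlen_t c = 0; c < N; ++c) idx[labels[c] - 1].push_back((int)c);
  NumericMatrix mu(G, K), phi(G, K), ll(G, K), conv(G, K);
  std::vector<double> xs, sv;
  for (int k = 0; k < K; ++k) {
    const std::vector<int>& cells = idx[k];
    R_xlen_t n = cells.size();
    xs.resize(n); sv.resize(n);
    for (R_xlen_t i = 0; i < n; ++i) sv[i] = s[cells[i]];
    for (R_xlen_t g = 0; g < G; ++g) {
      for (R_xlen_t i = 0; i < n; ++i) xs[i] = X(g, cells[i]);
      double out[4];
      fit_nb_core(xs.data(), sv.data(), n, out);
      mu(g, k) = out[0]; phi(g, k) = out[1]; ll(g, k) = out[2]; conv(g, k) = out[3];
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["mu"] = mu, _["phi"] = phi, _["loglik"] = ll,
                      _["converged"] = conv);
}

// Per-gene mean solve at a shared dispersion (profile step of the gene-common
// families). Returns per-gene mu and loglik.
// [[Rcpp::export]]
List cpp_nb_mu_given_phi(NumericMatrix X, NumericVector s, double phi) {
  R_xlen_t G = X.nrow(), N = X.ncol();
  NumericVector mu(G), ll(G);
  std::vector<double> xs(N);
  const double* sv = REAL(s);
  for (R_xlen_t g = 0; g < G; ++g) {
    for (R_xlen_t c = 0; c < N; ++c) xs[c] = X(g, c);
    bool ok = true;
    double m = solve_mu(xs.data(), sv, N, phi, -1.0, &ok);
    double l = 0.0;
    for (R_xlen_t c = 0; c < N; ++c) l += nb_lpmf(xs[c], sv[c] * m, phi);
    mu[g] = m; ll[g] = l;
  }
  return List::create(_["mu"] = mu, _["loglik"] = ll);
}

// Vectorized NB log pmf (recycled scalar parameters handled in R wrapper).
// [[Rcpp::export]]
NumericVector cpp_nb_lpmf(NumericVector x, NumericVector m, NumericVector phi) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = nb_lpmf(x[i], m[i], phi[i]);
  return out;
}
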