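#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Gauss-Legendre nodes/weights on [-1, 1], computed once per order by
// Newton iteration on the Legendre polynomial (Golub-Welsch not needed
// at the small fixed order used here).
static void gauss_legendre(int n, std::vector<double> &x, std::vector<double> &w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; i++) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1, pp = 0.0;
    do {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; j++) {
        double p2 = p1;
        p1 = p0;
        p0 = ((2.0 * j + 1.0) * z * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (z * p0 - p1) / (z * z - 1.0);
      z1 = z;
      z = z1 - p0 / pp;
    } while (std::fabs(z - z1) > 1e-15);
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

static const int GL_ORDER = 16;
static std::vector<double> gl_x, gl_w;

static inline double sigmoid(double m, double s, double m50) {
  return 1.0 / (1.0 + std::exp(-s * (m - m50)));
}

struct ValenceProbs {
  double p_att;      // P(m0 > beta)
  double p_corr_imm; // E[1(m0>beta) g(m0)]
  double p_corr_del;
  double p_err_del;
};

// Integrand terms at one abscissa for the delayed-phase expectations.
// A word attempted (m > beta) succeeds w.p. g(m); success boosts its
// strength by c before the delay multiplier gamma, failure (or no
// attempt) leaves it un-boosted.
static inline void delayed_terms(double m, double beta, double gamma, double c,
                                 double s, double m50,
                                 double &corr, double &err) {
  double md = gamma * m;
  double p_del_plain = 0.0, e_del_plain = 0.0;
  if (md > beta) {
    double g2 = sigmoid(md, s, m50);
    p_del_plain = g2;
    e_del_plain = 1.0 - g2;
  }
  if (m > beta) {
    double g = sigmoid(m, s, m50);
    double mc = gamma * c * m;
    double p_del_boost = 0.0, e_del_boost = 0.0;
    if (mc > beta) {
      double g2c = sigmoid(mc, s, m50);
      p_del_boost = g2c;
      e_del_boost = 1.0 - g2c;
    }
    corr = g * p_del_boost + (1.0 - g) * p_del_plain;
    err = g * e_del_boost + (1.0 - g) * e_del_plain;
  } else {
    corr = p_del_plain;
    err = e_del_plain;
  }
}

// Composite Gauss-Legendre over [a, b] with npan equal panels; fills
// three integrals (corr_imm, corr_del, err_del) of integrand * phi.
static void segment_integrals(double a, double b, int npan, double mu, double sd,
                              double beta, double gamma, double c, double s,
                              double m50, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  double h = (b - a) / npan;
  for (int p = 0; p < npan; p++) {
    double lo = a + p * h;
    double mid = lo + 0.5 * h, half = 0.5 * h;
    for (int i = 0; i < GL_ORDER; i++) {
      double m = mid + half * gl_x[i];
      double wgt = half * gl_w[i] * R::dnorm(m, mu, sd, 0);
      double corr, err;
      if (m > beta) out[0] += wgt * sigmoid(m, s, m50);
      delayed_terms(m, beta, gamma, c, s, m50, corr, err);
      out[1] += wgt * corr;
      out[2] += wgt * err;
    }
  }
}

static ValenceProbs valence_probs(double mu, double sd, double beta,
                                  double gamma, double c, double s, double m50) {
  if (gl_x.empty()) gauss_legendre(GL_ORDER, gl_x, gl_w);
  ValenceProbs vp;
  vp.p_att = R::pnorm(beta, mu, sd, 0, 0); // upper tail, strict vs non-strict is measure zero
  double lo = mu - 8.0 * sd, hi = mu + 8.0 * sd;
  // split at the discontinuities of the indicator functions
  std::vector<double> cuts;
  cuts.push_back(lo);
  double br[3] = {beta, beta / gamma, beta / (gamma * c)};
  for (int k = 0; k < 3; k++)
    if (br[k] > lo && br[k] < hi) cuts.push_back(br[k]);
  cuts.push_back(hi);
  std::sort(cuts.begin(), cuts.end());

  double tot[3] = {0.0, 0.0, 0.0};
  for (size_t seg = 0; seg + 1 < cuts.size(); seg++) {
    double a = cuts[seg], b = cuts[seg + 1];
    if (b - a < 1e-14) continue;
    double prev[3], cur[3];
    segment_integrals(a, b, 1, mu, sd, beta, gamma, c, s, m50, prev);
    int npan = 2;
    bool converged = false;
    while (npan <= 1024) {
      segment_integrals(a, b, npan, mu, sd, beta, gamma, c, s, m50, cur);
      double d = 0.0;
      for (int k = 0; k < 3; k++) d = std::max(d, std::fabs(cur[k] - prev[k]));
      if (d < 1e-7) { converged = true; break; }
      for (int k = 0; k < 3; k++) prev[k] = cur[k];
      npan *= 2;
    }
    if (!converged)
      stop("quadrature did not converge on [%g, %g] (mu=%g sd=%g beta=%g gamma=%g c=%g s=%g)",
           a, b, mu, sd, beta, gamma, c, s);
    for (int k = 0; k < 3; k++) tot[k] += cur[k];
  }
  vp.p_corr_imm = tot[0];
  vp.p_corr_del = tot[1];
  vp.p_err_del = tot[2];
  return vp;
}

// theta: alpha, beta, gamma, eps_pos, eps_neg, sigma, c, s
// PM order: pm1 pos imm, pm2 neg imm, pm3 neu imm, pm4 err imm,
//           pm5 pos del, pm6 neg del, pm7 neu del, pm8 err del
static void expected_one(const double *theta, double n_pos, double n_neg,
                         double n_neu, double m50, int additive_noise,
                         double *pm) {
  double alpha = theta[0], beta = theta[1], gamma = theta[2];
  double eps_pos = theta[3], eps_neg = theta[4], sigma = theta[5];
  double c = theta[6], s = theta[7];
  double eps[3] = {eps_pos, eps_neg, 1.0};
  double n[3] = {n_pos, n_neg, n_neu};
  double err_imm = 0.0, err_del = 0.0;
  for (int v = 0; v < 3; v++) {
    double mu = eps[v] * alpha;
    double sd = additive_noise ? sigma : eps[v] * sigma;
    ValenceProbs vp = valence_probs(mu, sd, beta, gamma, c, s, m50);
    pm[v] = n[v] * vp.p_corr_imm;
    pm[4 + v] = n[v] * vp.p_corr_del;
    err_imm += n[v] * (vp.p_att - vp.p_corr_imm);
    err_del += n[v] * vp.p_err_del;
  }
  // reorder: slots computed as pos, neg, neu in 0..2 / 4..6 already match
  pm[3] = err_imm;
  pm[7] = err_del;
}

// [[Rcpp::export]]
NumericVector expected_pms_cpp(NumericVector theta, double n_pos, double n_neg,
                               double n_neu, double m50, int additive_noise) {
  if (theta.size() != 8) stop("theta must have length 8");
  NumericVector pm(8);
  expected_one(theta.begin(), n_pos, n_neg, n_neu, m50, additive_noise, pm.begin());
  return pm;
}

// [[Rcpp::export]]
NumericMatrix expected_pms_batch_cpp(NumericMatrix theta, double n_pos,
                                     double n_neg, double n_neu, double m50,
                                     int additive_noise) {
  if (theta.ncol() != 8) stop("theta must have 8 columns");
  int n = theta.nrow();
  NumericMatrix pm(n, 8);
  std::vector<double> row(8), out(8);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < 8; j++) row[j] = theta(i, j);
    expected_one(row.data(), n_pos, n_neg, n_neu, m50, additive_noise, out.data());
    for (int j = 0; j < 8; j++) pm(i, j) = out[j];
  }
  return pm;
}
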