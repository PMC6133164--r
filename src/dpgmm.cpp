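#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sufficient statistics of one mixture component: count, coordinate sums
// and the upper triangle of the sum of outer products.
struct GroupStats {
  int n = 0;
  double s1 = 0.0, s2 = 0.0;
  double q11 = 0.0, q12 = 0.0, q22 = 0.0;
};

// Log posterior-predictive density of y under a group with the conjugate
// normal-inverse-Wishart base measure (2-D closed form): the predictive is
// a bivariate Student-t with nu + n - 1 degrees of freedom.
static double log_predictive(const GroupStats &g, double y1, double y2,
                             double a, double nu, double u) {
  const double kap = a + g.n;
  const double df = nu + g.n - 1.0;  // nu_n - d + 1 with d = 2
  const double mu1 = g.s1 / kap;
  const double mu2 = g.s2 / kap;
  // Lambda_n = u*nu*I + Q - s s^T / kap  (prior mean zero)
  const double l11 = u * nu + g.q11 - g.s1 * g.s1 / kap;
  const double l12 = g.q12 - g.s1 * g.s2 / kap;
  const double l22 = u * nu + g.q22 - g.s2 * g.s2 / kap;
  const double sc = (kap + 1.0) / (kap * df);  // scale multiplier
  const double s11 = l11 * sc, s12 = l12 * sc, s22 = l22 * sc;
  const double det = s11 * s22 - s12 * s12;
  const double d1 = y1 - mu1, d2 = y2 - mu2;
  const double quad = (d1 * d1 * s22 - 2.0 * d1 * d2 * s12 + d2 * d2 * s11) / det;
  return R::lgammafn(0.5 * (df + 2.0)) - R::lgammafn(0.5 * df) -
         std::log(df) - std::log(M_PI) - 0.5 * std::log(det) -
         0.5 * (df + 2.0) * std::log1p(quad / df);
}

// Exposed for testing: log predictive density of (y1, y2) given a group
// holding the n observations with coordinate sums s and outer-product sums
// (q11, q12, q22).
// [[Rcpp::export]]
double dpgmm_log_predictive_cpp(int n, double s1, double s2, double q11,
                                double q12, double q22, double y1, double y2,
                                double a, double nu, double u) {
  GroupStats g;
  g.n = n; g.s1 = s1; g.s2 = s2; g.q11 = q11; g.q12 = q12; g.q22 = q22;
  return log_predictive(g, y1, y2, a, nu, u);
}

// Collapsed Gibbs sweep over allocations of a Dirichlet-process Gaussian
// mixture; returns the retained thinned draws as 1-based label rows.
// [[Rcpp::export]]
IntegerMatrix dpgmm_gibbs_cpp(NumericMatrix Y, double alpha, double a,
                              double nu, double u, int n_draws, int burn_in,
                              int thin, bool use_likelihood) {
  const int N = Y.nrow();
  std::vector<int> z(N, 0);
  std::vector<GroupStats> gr(1);
  gr[0].n = N;
  for (int i = 0; i < N; ++i) {
    gr[0].s1 += Y(i, 0);
    gr[0].s2 += Y(i, 1);
    gr[0].q11 += Y(i, 0) * Y(i, 0);
    gr[0].q12 += Y(i, 0) * Y(i, 1);
    gr[0].q22 += Y(i, 1) * Y(i, 1);
  }
  const GroupStats empty_group;
  IntegerMatrix out(n_draws, N);
  std::vector<double> logp;
  const int total = burn_in + n_draws * thin;
  int stored = 0;

  for (int sweep = 1; sweep <= total; ++sweep) {
    for (int i = 0; i < N; ++i) {
      const double y1 = Y(i, 0), y2 = Y(i, 1);
      const int cur = z[i];
      // downdate the item's group
      GroupStats &gc = gr[cur];
      gc.n -= 1;
      gc.s1 -= y1; gc.s2 -= y2;
      gc.q11 -= y1 * y1; gc.q12 -= y1 * y2; gc.q22 -= y2 * y2;
      if (gc.n == 0) {
        // drop the emptied group: swap with the last one
        const int last = (int)gr.size() - 1;
        if (cur != last) {
          gr[cur] = gr[last];
          for (int j = 0; j < N; ++j) if (z[j] == last) z[j] = cur;
        }
        gr.pop_back();
      }
      const int K = (int)gr.size();
      logp.assign(K + 1, 0.0);
      for (int g = 0; g < K; ++g) {
        logp[g] = std::log((double)gr[g].n);
        if (use_likelihood) logp[g] += log_predictive(gr[g], y1, y2, a, nu, u);
      }
      logp[K] = std::log(alpha);
      if (use_likelihood) logp[K] += log_predictive(empty_group, y1, y2, a, nu, u);
      double mx = logp[0];
      for (int g = 1; g <= K; ++g) if (logp[g] > mx) mx = logp[g];
      double tot = 0.0;
      for (int g = 0; g <= K; ++g) { logp[g] = std::exp(logp[g] - mx); tot += logp[g]; }
      const double udraw = unif_rand() * tot;
      double acc = 0.0;
      int pick = K;
      for (int g = 0; g <= K; ++g) {
        acc += logp[g];
        if (udraw <= acc) { pick = g; break; }
      }
      if (pick == K) gr.push_back(GroupStats());
      GroupStats &gn = gr[pick];
      gn.n += 1;
      gn.s1 += y1; gn.s2 += y2;
      gn.q11 += y1 * y1; gn.q12 += y1 * y2; gn.q22 += y2 * y2;
      z[i] = pick;
    }
    if (sweep > burn_in && (sweep - burn_in) % thin == 0 && stored < n_draws) {
      for (int j = 0; j < N; ++j) out(stored, j) = z[j] + 1;
      ++stored;
    }
  }
  return out;
}
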