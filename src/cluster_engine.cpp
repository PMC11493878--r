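#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pooled-variance two-sample t per bin (column of X). g[i] == 1 -> first group.
// Bins with (near-)zero pooled variance get t = 0 and therefore never enter a
// cluster: degenerate-variance bins are excluded from cluster formation.
static void tstats(const NumericMatrix& X, const std::vector<int>& g,
                   int n1, int n2, std::vector<double>& t) {
  const int n = X.nrow(), B = X.ncol();
  const double df = (double)n1 + n2 - 2.0;
  for (int b = 0; b < B; ++b) {
    double s1 = 0.0, s2 = 0.0, q1 = 0.0, q2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double v = X(i, b);
      if (g[i]) { s1 += v; q1 += v * v; } else { s2 += v; q2 += v * v; }
    }
    const double m1 = s1 / n1, m2 = s2 / n2;
    double ss = (q1 - n1 * m1 * m1) + (q2 - n2 * m2 * m2);
    if (ss < 0) ss = 0;
    const double se = std::sqrt((ss / df) * (1.0 / n1 + 1.0 / n2));
    t[b] = (se > 1e-12) ? (m1 - m2) / se : 0.0;
  }
}

// Connected components of suprathreshold bins on a channel x freq x time grid.
// Bin linear index b = ch + nchan * (f + nfreq * tt) (R column-major for an
// array with dim = c(nchan, nfreq, ntime)). Positive and negative clusters are
// formed separately (sign-consistent components). Returns max |cluster mass|;
// optionally fills per-bin labels and per-cluster masses.
static double cluster_pass(const std::vector<double>& t, double thr,
                           int nchan, int nfreq, int ntime,
                           const std::vector< std::vector<int> >& adj,
                           std::vector<int>* labels_out,
                           std::vector<double>* masses_out) {
  const int B = nchan * nfreq * ntime;
  std::vector<int> lab(B, 0);
  std::vector<double> masses;
  std::vector<int> stack;
  int nextlab = 0;
  double maxmass = 0.0;

  for (int b0 = 0; b0 < B; ++b0) {
    if (lab[b0] != 0) continue;
    const double tb = t[b0];
    if (tb <= thr && tb >= -thr) continue;
    const int sgn = (tb > 0.0) ? 1 : -1;
    ++nextlab;
    double mass = 0.0;
    stack.clear();
    stack.push_back(b0);
    lab[b0] = nextlab;
    while (!stack.empty()) {
      const int b = stack.back();
      stack.pop_back();
      mass += t[b];
      const int ch = b % nchan;
      const int rest = b / nchan;
      const int f = rest % nfreq;
      const int tt = rest / nfreq;
      // neighbour visitor: same-sign suprathreshold, unlabelled
      #define VISIT(nb) do {                                            \
        const int nb_ = (nb);                                           \
        if (lab[nb_] == 0) {                                            \
          const double tn = t[nb_];                                     \
          if ((sgn > 0 && tn > thr) || (sgn < 0 && tn < -thr)) {        \
            lab[nb_] = nextlab; stack.push_back(nb_);                   \
          }                                                             \
        }                                                               \
      } while (0)
      const std::vector<int>& nbch = adj[ch];
      for (size_t k = 0; k < nbch.size(); ++k)
        VISIT(nbch[k] + nchan * (f + nfreq * tt));
      if (f > 0)          VISIT(b - nchan);
      if (f < nfreq - 1)  VISIT(b + nchan);
      if (tt > 0)         VISIT(b - nchan * nfreq);
      if (tt < ntime - 1) VISIT(b + nchan * nfreq);
      #undef VISIT
    }
    masses.push_back(mass);
    if (std::fabs(mass) > maxmass) maxmass = std::fabs(mass);
  }
  if (labels_out) *labels_out = lab;
  if (masses_out) *masses_out = masses;
  return maxmass;
}

//' @noRd
// [[Rcpp::export(name = ".cluster_perm_engine")]]
List cluster_perm_engine(NumericMatrix X, IntegerVector g, int nperm,
                         int nchan, int nfreq, int ntime, List adj_r,
                         double tthr) {
  const int n = X.nrow();
  const int B = X.ncol();
  if (B != nchan * nfreq * ntime)
    stop("bin count does not match nchan * nfreq * ntime");
  if ((int)g.size() != n) stop("label length does not match rows of X");

  std::vector<int> gv(n);
  int n1 = 0;
  for (int i = 0; i < n; ++i) { gv[i] = (g[i] == 1) ? 1 : 0; n1 += gv[i]; }
  const int n2 = n - n1;
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations");

  // adjacency: 1-based channel neighbour lists from R -> 0-based
  if ((int)adj_r.size() != nchan) stop("adjacency list length must equal nchan");
  std::vector< std::vector<int> > adj(nchan);
  for (int c = 0; c < nchan; ++c) {
    IntegerVector v = adj_r[c];
    adj[c].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) {
      const int nb = v[k] - 1;
      if (nb < 0 || nb >= nchan) stop("adjacency index out of range");
      if (nb != c) adj[c].push_back(nb);
    }
  }

  std::vector<double> tobs(B);
  tstats(X, gv, n1, n2, tobs);
  std::vector<int> labels;
  std::vector<double> masses;
  cluster_pass(tobs, tthr, nchan, nfreq, ntime, adj, &labels, &masses);

  NumericVector nullmax(nperm);
  IntegerVector idx = seq_len(n);
  std::vector<int> gp(n);
  std::vector<double> tp(B);
  for (int p = 0; p < nperm; ++p) {
    IntegerVector sh = sample(idx, n, false); // uses R's RNG (seedable from R)
    for (int i = 0; i < n; ++i) gp[i] = gv[sh[i] - 1];
    tstats(X, gp, n1, n2, tp);
    nullmax[p] = cluster_pass(tp, tthr, nchan, nfreq, ntime, adj, NULL, NULL);
  }

  return List::create(_["t"] = NumericVector(tobs.begin(), tobs.end()),
                      _["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["masses"] = NumericVector(masses.begin(), masses.end()),
                      _["null_max"] = nullmax);
}
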