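#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// midranks (average ranks on ties) of v into out
static void midranks(const std::vector<double>& v, std::vector<int>& ord,
                     std::vector<double>& out) {
  int n = v.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average of 1-based ranks i+1..j+1
    for (int k = i; k <= j; ++k) out[ord[k]] = r;
    i = j + 1;
  }
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  int n = a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  return sab / std::sqrt(saa * sbb);
}

// Variogram-matched surrogate ensemble (parcellated maps).
// Each surrogate: permute the map, smooth it with a distance-decay kernel on
// each unit's k nearest neighbours at ncand candidate scales, fit
// gamma_emp ~ alpha + beta * gamma_smoothed by least squares, keep the best
// scale, and return sqrt(|beta|)*smoothed + sqrt(|alpha|)*N(0,1) noise,
// optionally rank-remapped onto the source value distribution.
//
// knn: n x k 1-based neighbour indices; wflat: per-scale row-normalised
// kernel weights, laid out [scale][unit][neighbour]; pair_*: 0-based pair
// indices and bin ids for the empirical variogram bins (only nonempty bins).
// [[Rcpp::export]]
List surrogates_core(NumericVector x, IntegerMatrix knn, NumericVector wflat,
                     int ncand, IntegerVector pair_i, IntegerVector pair_j,
                     IntegerVector pair_bin, int nbins,
                     NumericVector gamma_emp, int nsurr, bool rank_remap,
                     NumericVector ref, bool alpha_clamp,
                     NumericVector lag_centers, double smooth_bw) {
  const int n = x.size();
  const int k = knn.ncol();
  const int npair = pair_i.size();
  const bool want_rho = ref.size() == n;

  NumericMatrix out(nsurr, n);
  NumericVector rhos(want_rho ? nsurr : 0);

  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> x_sorted(xs);
  std::sort(x_sorted.begin(), x_sorted.end());

  std::vector<double> ref_rank(n);
  std::vector<int> ord(n);
  if (want_rho) {
    std::vector<double> rv(ref.begin(), ref.end());
    std::vector<double> rr(n);
    midranks(rv, ord, rr);
    ref_rank = rr;
  }

  std::vector<int> perm(n);
  std::vector<double> xp(n), y(n), ybest(n), eps(n), surr(n), srank(n);
  std::vector<double> gam(nbins), gs(nbins);
  std::vector<int> bin_n(nbins, 0);
  for (int p = 0; p < npair; ++p) bin_n[pair_bin[p]]++;

  // gaussian kernel smoothing of a binned variogram across lag centers,
  // weighted by per-bin pair counts; stabilizes per-lag estimates so the
  // amplitude fit is not attenuated by sampling noise
  std::vector<double> kw((size_t)nbins * nbins);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double u = (lag_centers[a] - lag_centers[b]) / smooth_bw;
      kw[(size_t)a * nbins + b] = std::exp(-0.5 * u * u) * bin_n[b];
    }
  auto smooth_gamma = [&](const std::vector<double>& raw,
                          std::vector<double>& out) {
    for (int a = 0; a < nbins; ++a) {
      double num = 0, den = 0;
      const double* wa = &kw[(size_t)a * nbins];
      for (int b = 0; b < nbins; ++b) { num += wa[b] * raw[b]; den += wa[b]; }
      out[a] = num / den;
    }
  };
  std::vector<double> emp_raw(gamma_emp.begin(), gamma_emp.end());
  std::vector<double> emp_s(nbins);
  smooth_gamma(emp_raw, emp_s);

  // flattened knn (0-based) for speed
  std::vector<int> nb(n * k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) nb[i * k + j] = knn(i, j) - 1;

  const double* w = wflat.begin();

  for (int s = 0; s < nsurr; ++s) {
    // Fisher-Yates permutation using R's RNG (deterministic under set.seed)
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < n; ++i) xp[i] = xs[perm[i]];

    double best_sse = R_PosInf, best_alpha = 0, best_beta = 1;
    for (int c = 0; c < ncand; ++c) {
      const double* wc = w + (size_t)c * n * k;
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        const int* nbi = &nb[i * k];
        const double* wci = wc + (size_t)i * k;
        for (int j = 0; j < k; ++j) acc += wci[j] * xp[nbi[j]];
        y[i] = acc;
      }
      std::fill(gam.begin(), gam.end(), 0.0);
      for (int p = 0; p < npair; ++p) {
        double d = y[pair_i[p]] - y[pair_j[p]];
        gam[pair_bin[p]] += d * d;
      }
      for (int b = 0; b < nbins; ++b) gam[b] = 0.5 * gam[b] / bin_n[b];
      smooth_gamma(gam, gs);
      // least-squares fit smoothed emp = alpha + beta * smoothed gamma_y
      double mx = 0, my = 0;
      for (int b = 0; b < nbins; ++b) { mx += gs[b]; my += emp_s[b]; }
      mx /= nbins; my /= nbins;
      double sxy = 0, sxx = 0;
      for (int b = 0; b < nbins; ++b) {
        sxy += (gs[b] - mx) * (emp_s[b] - my);
        sxx += (gs[b] - mx) * (gs[b] - mx);
      }
      double beta = sxx > 0 ? sxy / sxx : 0.0;
      double alpha = my - beta * mx;
      double sse = 0;
      for (int b = 0; b < nbins; ++b) {
        double r = emp_s[b] - (alpha + beta * gs[b]);
        sse += r * r;
      }
      if (sse < best_sse) {
        best_sse = sse; best_alpha = alpha; best_beta = beta;
        std::copy(y.begin(), y.end(), ybest.begin());
      }
    }
    double sb = std::sqrt(std::fabs(best_beta));
    double sa = alpha_clamp ? std::sqrt(std::max(best_alpha, 0.0))
                            : std::sqrt(std::fabs(best_alpha));
    for (int i = 0; i < n; ++i) surr[i] = sb * ybest[i] + sa * norm_rand();

    if (rank_remap) {
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return surr[a] < surr[b]; });
      for (int i = 0; i < n; ++i) surr[ord[i]] = x_sorted[i];
    }
    for (int i = 0; i < n; ++i) out(s, i) = surr[i];
    if (want_rho) {
      midranks(surr, ord, srank);
      rhos[s] = pearson(ref_rank, srank);
    }
  }
  return List::create(_["surrogates"] = out, _["rho"] = rhos);
}
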