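#include <Rcpp.h>

// Exact permutation count for the Spearman statistic. With the rank marginals
// fixed, |r_s| >= |r_obs| is equivalent to |sum(rx_perm * ry) - n*mean(rx)*
// mean(ry)| >= threshold, so it suffices to count permutations whose centred
// cross-product clears the observed one. All n! permutations are enumerated
// with Heap's algorithm (n <= 10, i.e. <= 3,628,800 permutations).

// [[Rcpp::export]]
double spearman_perm_count(Rcpp::NumericVector rx, Rcpp::NumericVector ry,
                           double threshold) {
  const int n = rx.size();
  if (n != ry.size()) Rcpp::stop("rank vectors must have equal length");
  if (n > 10) Rcpp::stop("exact enumeration limited to n <= 10");
  std::vector<double> a(rx.begin(), rx.end());
  const double mx = std::accumulate(a.begin(), a.end(), 0.0) / n;
  double my = 0.0;
  for (int i = 0; i < n; ++i) my += ry[i];
  my /= n;
  const double centre = n * mx * my;

  double hits = 0.0;
  std::vector<int> c(n, 0);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * ry[i];
  if (std::fabs(s - centre) >= threshold) hits += 1.0;

  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(a[0], a[i]);
      else std::swap(a[c[i]], a[i]);
      s = 0.0;
      for (int k = 0; k < n; ++k) s += a[k] * ry[k];
      if (std::fabs(s - centre) >= threshold) hits += 1.0;
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return hits;
}
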