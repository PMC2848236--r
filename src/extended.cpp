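// Extended-precision (80-bit long double) evaluation of the binomial
// redistribution table and the sequential correct/contaminate
// transforms.  Double precision handles molecules up to 269 atoms of
// the labeled element; the wider exponent range and 64-bit mantissa of
// long double push the limit far past that without any change to the
// algebra.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// B(n,k) = choose(m-n, k-n) * na^(k-n) * (1-na)^(m-k), accumulated in
// log space via lgamma so no intermediate ever overflows.
static long double bterm_ld(int n, int k, int m, long double na) {
  if (na <= 0.0L) return (k == n) ? 1.0L : 0.0L;
  long double lcoef = lgammal((long double)(m - n) + 1.0L)
                    - lgammal((long double)(k - n) + 1.0L)
                    - lgammal((long double)(m - k) + 1.0L);
  return expl(lcoef + (long double)(k - n) * logl(na)
                    + (long double)(m - k) * log1pl(-na));
}

static std::vector<long double> build_table_ld(int m, long double na) {
  std::vector<long double> B((size_t)(m + 1) * (size_t)(m + 1), 0.0L);
  for (int n = 0; n <= m; ++n)
    for (int k = n; k <= m; ++k)
      B[(size_t)n * (m + 1) + k] = bterm_ld(n, k, m, na);
  return B;
}

// [[Rcpp::export]]
List ext_binomial_table(int element_max, double na) {
  const int m = element_max;
  std::vector<long double> B = build_table_ld(m, (long double)na);
  NumericMatrix terms(m + 1, m + 1);
  NumericVector loss(m + 1);
  for (int n = 0; n <= m; ++n) {
    for (int k = n; k <= m; ++k)
      terms(n, k) = (double)B[(size_t)n * (m + 1) + k];
    // closed form 1 - (1-na)^(m-n)
    loss[n] = (na <= 0.0) ? 0.0
      : (double)(-expm1l((long double)(m - n) * log1pl(-(long double)na)));
  }
  return List::create(_["terms"] = terms, _["loss_sums"] = loss);
}

// Spectra cross the R boundary as doubles; an optional low-order
// compensation vector (value - double(value)) restores the full
// extended-precision value, so chained extended-mode transforms do not
// round through 53-bit doubles.  That matters: the sequential solve
// amplifies input rounding by roughly (1 + na/(1-na))^element_max, which
// at 500 carbons turns double rounding into ~1e-12 round-trip error.
static std::vector<long double> join_hi_lo(NumericVector hi,
                                           Nullable<NumericVector> lo) {
  std::vector<long double> x(hi.size());
  for (int i = 0; i < hi.size(); ++i) x[i] = (long double)hi[i];
  if (lo.isNotNull()) {
    NumericVector l(lo);
    for (int i = 0; i < hi.size(); ++i) x[i] += (long double)l[i];
  }
  return x;
}

static List split_hi_lo(const std::vector<long double>& x) {
  const int n = (int)x.size();
  NumericVector hi(n), lo(n);
  for (int i = 0; i < n; ++i) {
    hi[i] = (double)x[i];
    lo[i] = (double)(x[i] - (long double)hi[i]);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// [[Rcpp::export]]
List ext_contaminate(NumericVector x, Nullable<NumericVector> x_lo,
                     double na) {
  const int m = x.size() - 1;
  std::vector<long double> B = build_table_ld(m, (long double)na);
  std::vector<long double> in = join_hi_lo(x, x_lo);
  std::vector<long double> out(m + 1, 0.0L);
  for (int k = 0; k <= m; ++k)
    for (int n = 0; n <= k; ++n)
      out[k] += in[n] * B[(size_t)n * (m + 1) + k];
  return split_hi_lo(out);
}

// [[Rcpp::export]]
List ext_correct(NumericVector observed, Nullable<NumericVector> observed_lo,
                 double na) {
  const int m = observed.size() - 1;
  std::vector<long double> B = build_table_ld(m, (long double)na);
  std::vector<long double> obs = join_hi_lo(observed, observed_lo);
  std::vector<long double> corrected(m + 1, 0.0L);
  for (int i = 0; i <= m; ++i) {
    long double spill = 0.0L;
    for (int x = 0; x < i; ++x)
      spill += corrected[x] * B[(size_t)x * (m + 1) + i];
    // 1 - B_sum(i) == B(i,i)
    corrected[i] = (obs[i] - spill) / B[(size_t)i * (m + 1) + i];
  }
  return split_hi_lo(corrected);
}
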