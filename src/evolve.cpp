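#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher evolution of a haploid genome pool.
//
// haps: 2N x K matrix of 0/1 alleles; rows 2i, 2i+1 form diploid i.
// lambda: K-1 Poisson crossover intensities per interval, chosen so that the
//   marginal switch probability per interval equals the requested
//   recombination fraction (Haldane inverse: lambda = -log(1 - 2r) / 2); a
//   Poisson number of crossovers with these interval intensities makes
//   switches in disjoint intervals independent Bernoulli events with no
//   interference.
// sel: 0-based selected column, or -1 for neutrality.  Genotype fitnesses at
//   the selected site are 1, 1+h*s, 1+s for 0, 1, 2 copies of the derived
//   allele.
// record: sorted 1-based generations at which allele frequencies are stored.
//
// Returns a T x K matrix of population allele frequencies.  Uses R's RNG so
// set.seed() in R makes runs reproducible.
// [[Rcpp::export(rng = true)]]
NumericMatrix evolve_pool_cpp(IntegerMatrix haps, NumericVector lambda,
                              int sel, double s, double h,
                              IntegerVector record) {
  const int n_hap = haps.nrow();
  const int K = haps.ncol();
  const int N = n_hap / 2;
  if (n_hap == 0 || N * 2 != n_hap)
    stop("population must contain an even, positive number of haplotypes");
  if (sel >= K) stop("selected site index out of range");
  const int n_gen = record[record.size() - 1];

  // row-major internal layout: each haplotype is contiguous, so the common
  // no-crossover case copies a parent haplotype with one memcpy
  std::vector<int> cur((size_t)n_hap * K), nxt((size_t)n_hap * K);
  for (int i = 0; i < n_hap; ++i)
    for (int j = 0; j < K; ++j)
      cur[(size_t)i * K + j] = haps(i, j);
  std::vector<double> cumw(N);
  double lam_tot = 0.0;
  std::vector<double> cumlam(K > 1 ? K - 1 : 0);
  for (int i = 0; i + 1 < K; ++i) {
    lam_tot += lambda[i];
    cumlam[i] = lam_tot;
  }

  NumericMatrix out(record.size(), K);
  int rec_i = 0;
  std::vector<int> xpos;

  for (int gen = 1; gen <= n_gen; ++gen) {
    // fitness-weighted cumulative distribution over diploid parents
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      if (sel >= 0) {
        int g = cur[(size_t)(2 * i) * K + sel] +
                cur[(size_t)(2 * i + 1) * K + sel];
        w = (g == 2) ? 1.0 + s : (g == 1 ? 1.0 + h * s : 1.0);
      }
      tot += w;
      cumw[i] = tot;
    }
    for (int off = 0; off < n_hap; ++off) {
      // choose parent proportional to fitness
      double u = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumw[mid] < u) lo = mid + 1; else hi = mid;
      }
      const int p = lo;
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      int nx = (lam_tot > 0) ? (int)R::rpois(lam_tot) : 0;
      if (nx == 0) {
        // no crossover: copy one parental haplotype wholesale
        std::memcpy(&nxt[(size_t)off * K],
                    &cur[(size_t)(2 * p + strand) * K],
                    (size_t)K * sizeof(int));
      } else {
        // crossover intervals via inversion on the cumulative intensity
        xpos.clear();
        for (int e = 0; e < nx; ++e) {
          double v = unif_rand() * lam_tot;
          int lo2 = 0, hi2 = K - 2;
          while (lo2 < hi2) {
            int mid = (lo2 + hi2) / 2;
            if (cumlam[mid] < v) lo2 = mid + 1; else hi2 = mid;
          }
          xpos.push_back(lo2);   // crossover between sites lo2 and lo2+1
        }
        std::sort(xpos.begin(), xpos.end());
        size_t e = 0;
        const int *p0 = &cur[(size_t)(2 * p) * K];
        const int *p1 = &cur[(size_t)(2 * p + 1) * K];
        int *dst = &nxt[(size_t)off * K];
        for (int j = 0; j < K; ++j) {
          while (e < xpos.size() && xpos[e] < j) {
            strand ^= 1;
            ++e;
          }
          dst[j] = strand ? p1[j] : p0[j];
        }
      }
    }
    cur.swap(nxt);
    if (rec_i < record.size() && gen == record[rec_i]) {
      std::vector<long> acc(K, 0);
      for (int i = 0; i < n_hap; ++i) {
        const int *row = &cur[(size_t)i * K];
        for (int j = 0; j < K; ++j) acc[j] += row[j];
      }
      for (int j = 0; j < K; ++j) out(rec_i, j) = (double)acc[j] / n_hap;
      ++rec_i;
    }
  }
  return out;
}
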