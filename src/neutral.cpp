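#include <Rcpp.h>
using namespace Rcpp;

// Weighted index draw from cumulative walk over w (sum given), using u ~ U(0, total).
static int pick(const std::vector<double> &w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  return n - 1;
}

// Moran-type neutral community with immigration. One update step: a random
// resident dies; with probability m it is replaced by an immigrant drawn from
// the fixed source pool, otherwise by the offspring of a resident drawn
// proportional to local abundance. Each sample is an independent local
// community initialized by a multinomial draw from the source pool and run
// for `steps` updates.
// [[Rcpp::export(name = ".simulate_neutral_cpp")]]
IntegerMatrix simulate_neutral_cpp(int S, int N, double m, int n_samples,
                                   int steps, NumericVector pool) {
  RNGScope scope;
  IntegerMatrix out(n_samples, S);
  std::vector<double> p(pool.begin(), pool.end());
  for (int s = 0; s < n_samples; ++s) {
    // multinomial initialization from the source pool
    std::vector<double> counts(S, 0.0);
    {
      IntegerVector init(S);
      rmultinom(N, &p[0], S, &init[0]);
      for (int i = 0; i < S; ++i) counts[i] = init[i];
    }
    for (int t = 0; t < steps; ++t) {
      int dead = pick(counts, (double)N);
      counts[dead] -= 1.0;
      int born;
      if (unif_rand() < m) {
        born = pick(p, 1.0);
      } else {
        born = pick(counts, (double)(N - 1));
      }
      counts[born] += 1.0;
    }
    for (int i = 0; i < S; ++i) out(s, i) = (int)counts[i];
  }
  return out;
}
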