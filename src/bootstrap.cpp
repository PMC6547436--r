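#include <Rcpp.h>
using namespace Rcpp;

// Per bootstrap trial, repartition every genome's proteins uniformly at
// random into pseudo-new/pseudo-old sets of the original sizes (partial
// Fisher-Yates over an index array) and count the genomes whose pseudo-new
// observed/expected ratio strictly exceeds the pseudo-old ratio. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector bootstrap_trial_counts(List obs, List expd, IntegerVector n_new,
                                     int n_trials) {
  const int G = obs.size();
  std::vector<std::vector<double> > O(G), E(G);
  std::vector<std::vector<int> > idx(G);
  std::vector<double> Otot(G), Etot(G);
  for (int g = 0; g < G; ++g) {
    NumericVector o = obs[g], e = expd[g];
    if (o.size() != e.size())
      stop("observed/expected length mismatch in genome %d", g + 1);
    if (n_new[g] < 1 || n_new[g] >= o.size())
      stop("n_new must be in [1, n_proteins - 1] (genome %d)", g + 1);
    O[g].assign(o.begin(), o.end());
    E[g].assign(e.begin(), e.end());
    idx[g].resize(o.size());
    for (int i = 0; i < o.size(); ++i) idx[g][i] = i;
    Otot[g] = std::accumulate(O[g].begin(), O[g].end(), 0.0);
    Etot[g] = std::accumulate(E[g].begin(), E[g].end(), 0.0);
  }

  IntegerVector out(n_trials);
  RNGScope scope;
  for (int t = 0; t < n_trials; ++t) {
    int cnt = 0;
    for (int g = 0; g < G; ++g) {
      const int n = (int)O[g].size();
      const int k = n_new[g];
      std::vector<int> &id = idx[g];
      double On = 0.0, En = 0.0;
      for (int i = 0; i < k; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(id[i], id[j]);
        On += O[g][id[i]];
        En += E[g][id[i]];
      }
      const double Oo = Otot[g] - On, Eo = Etot[g] - En;
      // strict inequality; ties and zero-expected denominators do not count
      if (En > 0.0 && Eo > 0.0 && On * Eo > Oo * En) ++cnt;
    }
    out[t] = cnt;
  }
  return out;
}
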