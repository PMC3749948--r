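#include <Rcpp.h>
using namespace Rcpp;

// Single-chain heat-bath sampler for the Potts model
//   P(a) ~ exp( sum_{i<j} e_ij(a_i, a_j) + sum_i h_i(a_i) ).
// e is the dense Lq x Lq site-major coupling matrix (symmetric, zero
// diagonal blocks); ht is the q x L transpose of the field matrix so
// that fields of one site are contiguous.  Uses R's RNG so results are
// reproducible via set.seed().

// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix e, NumericMatrix ht,
                               int L, int q, int n, int burn_in, int thin,
                               IntegerVector start) {
  IntegerMatrix out(n, L);
  std::vector<int> a(L);
  for (int i = 0; i < L; ++i) a[i] = start[i] - 1;  // 0-based states
  std::vector<double> logp(q), p(q);

  RNGScope scope;
  long total_sweeps = (long)burn_in + (long)n * thin;
  int emitted = 0;
  for (long sweep = 0; sweep < total_sweeps && emitted < n; ++sweep) {
    for (int i = 0; i < L; ++i) {
      int ri = i * q;
      for (int s = 0; s < q; ++s) logp[s] = ht(s, i);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        int cj = j * q + a[j];
        for (int s = 0; s < q; ++s) logp[s] += e(ri + s, cj);
      }
      double mx = logp[0];
      for (int s = 1; s < q; ++s) if (logp[s] > mx) mx = logp[s];
      double Z = 0.0;
      for (int s = 0; s < q; ++s) { p[s] = std::exp(logp[s] - mx); Z += p[s]; }
      double u = unif_rand() * Z, cum = 0.0;
      int pick = q - 1;
      for (int s = 0; s < q; ++s) {
        cum += p[s];
        if (u <= cum) { pick = s; break; }
      }
      a[i] = pick;
    }
    long after = sweep + 1 - burn_in;
    if (after > 0 && after % thin == 0) {
      for (int i = 0; i < L; ++i) out(emitted, i) = a[i] + 1;
      ++emitted;
    }
  }
  return out;
}
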