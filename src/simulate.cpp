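#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov nucleotide sequence generator. `trans` is a 4x4
// row-stochastic matrix over A,C,G,T; `init` the start distribution.
// Draws come from R's RNG, so set.seed() in R makes output deterministic.
// [[Rcpp::export]]
std::string markov_seq_cpp(int len, NumericMatrix trans, NumericVector init) {
  static const char bases[] = "ACGT";
  std::string out(len, 'A');
  if (len <= 0) return out;
  auto draw = [](const double* p) {
    double u = unif_rand(), c = 0.0;
    for (int k = 0; k < 4; ++k) { c += p[k]; if (u <= c) return k; }
    return 3;
  };
  double p0[4];
  for (int k = 0; k < 4; ++k) p0[k] = init[k];
  int s = draw(p0);
  out[0] = bases[s];
  double T[4][4];
  for (int i = 0; i < 4; ++i)
    for (int k = 0; k < 4; ++k) T[i][k] = trans(i, k);
  for (int i = 1; i < len; ++i) {
    s = draw(T[s]);
    out[i] = bases[s];
  }
  return out;
}
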