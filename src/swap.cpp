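#include <Rcpp.h>
using namespace Rcpp;

// Margin-preserving unit-move chain on a non-negative integer count matrix.
// One accepted move picks two distinct rows (i, j) and two distinct columns
// (a, b) uniformly and transfers one unit: (i,a)-1, (i,b)+1, (j,a)+1, (j,b)-1.
// Moves that would drive a cell negative are rejected and do not count.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix swap_randomize_cpp(IntegerMatrix m, double n_swaps,
                                 double max_proposals) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  double accepted = 0, proposals = 0;
  while (accepted < n_swaps && proposals < max_proposals) {
    proposals += 1;
    int i = (int)std::floor(unif_rand() * nr);
    int j = (int)std::floor(unif_rand() * nr);
    if (i >= nr) i = nr - 1;
    if (j >= nr) j = nr - 1;
    if (i == j) continue;
    int a = (int)std::floor(unif_rand() * nc);
    int b = (int)std::floor(unif_rand() * nc);
    if (a >= nc) a = nc - 1;
    if (b >= nc) b = nc - 1;
    if (a == b) continue;
    if (out(i, a) < 1 || out(j, b) < 1) continue;
    out(i, a) -= 1;
    out(i, b) += 1;
    out(j, a) += 1;
    out(j, b) -= 1;
    accepted += 1;
  }
  out.attr("accepted") = accepted;
  out.attr("proposals") = proposals;
  return out;
}
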