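#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard-swap chain on a 0/1 matrix: each attempt draws two distinct
// rows and two distinct columns with R's RNG; if the 2x2 submatrix is a
// diagonal or anti-diagonal checkerboard it is flipped. Attempted (not
// successful) swaps are counted, so chain cost is predictable. Row and
// column sums are invariant by construction. Modifies `m` in place; callers
// pass a private copy.
// [[Rcpp::export]]
void swap_chain_inplace(IntegerMatrix m, int n_swaps) {
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return;
  for (int s = 0; s < n_swaps; ++s) {
    int r1 = static_cast<int>(unif_rand() * nr);
    int r2 = static_cast<int>(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = static_cast<int>(unif_rand() * nc);
    int c2 = static_cast<int>(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a == d && b == c && a != b) {
      m(r1, c1) = b; m(r1, c2) = a;
      m(r2, c1) = d; m(r2, c2) = c;
    }
  }
}
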