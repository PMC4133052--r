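// Thomas-algorithm solver for the tri-diagonal systems of the
// deme-exchange chain, carried out in long double so the linear-solve
// route stays meaningful as an independent cross-check of the closed
// forms up to D = 200.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Solve (I - Q') x = b for each column of b, where Q' is the embedded
// jump chain with constant up/down probabilities: sub-diagonal -down_p,
// diagonal 1, super-diagonal -up_p.
// [[Rcpp::export]]
NumericMatrix tridiag_jump_solve(int n, double up_p, double down_p,
                                 NumericMatrix b) {
  std::vector<long double> diag(n, 1.0L), rhs(n);
  NumericMatrix out(n, b.ncol());
  const long double lo = -(long double)down_p;
  const long double up = -(long double)up_p;
  std::vector<long double> cp(n);   // modified super-diagonal
  for (int col = 0; col < b.ncol(); ++col) {
    for (int i = 0; i < n; ++i) rhs[i] = b(i, col);
    // forward sweep
    cp[0] = up / 1.0L;
    rhs[0] = rhs[0] / 1.0L;
    for (int i = 1; i < n; ++i) {
      long double m = 1.0L - lo * cp[i - 1];
      cp[i] = up / m;
      rhs[i] = (rhs[i] - lo * rhs[i - 1]) / m;
    }
    // back substitution
    for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
    for (int i = 0; i < n; ++i) out(i, col) = (double)rhs[i];
  }
  return out;
}
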