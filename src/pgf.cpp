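#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-point oracle for the lineage extinction probabilities: iterate the
// offspring PGF map from q = 0 with Steffensen (Aitken delta-squared)
// acceleration. Evaluated in extended (long double) precision because the
// residual g(q) - q suffers cancellation near criticality, where double
// arithmetic caps the attainable root accuracy near 1e-10.

typedef long double ld;

template <class G>
static ld solve_fixed_point(G g, ld tol, long max_iter) {
  ld q = 0.0L;
  for (long k = 0; k < max_iter; ++k) {
    ld q1 = g(q);
    ld q2 = g(q1);
    ld denom = q2 - 2.0L * q1 + q;
    ld qn;
    if (std::fabs((double)denom) > 0.0) {
      qn = q - (q1 - q) * (q1 - q) / denom;
      if (!std::isfinite((double)qn) || qn < 0.0L || qn > 1.0L) qn = q2;
    } else {
      qn = q2;
    }
    if (std::fabs((double)(qn - q)) < (double)tol) return qn;
    q = qn;
  }
  return q;
}

// [[Rcpp::export]]
NumericVector pgf_iterate_cpp(double lambda_s, double mu_s, double lambda_a,
                              double mu_a, double lambda_m, double mu_m,
                              double u, double v, double v_a,
                              double tol, double max_iter) {
  ld ls = lambda_s, ms = mu_s, la = lambda_a, ma = mu_a, lm = lambda_m,
     mm = mu_m, uu = u, vv = v, va = v_a;
  ld tl = tol;
  long mi = (long)max_iter;

  ld tot_m = lm + mm, tot_a = la + ma, tot_s = ls + ms;
  ld q_m = (tot_m == 0.0L) ? 1.0L
    : solve_fixed_point([&](ld q) { return (lm * q * q + mm) / tot_m; },
                        tl, mi);
  ld q_a = (tot_a == 0.0L) ? 1.0L
    : solve_fixed_point([&](ld q) {
        return (la * (1.0L - va) * q * q + va * la * q * q_m + ma) / tot_a;
      }, tl, mi);
  ld q_s = (tot_s == 0.0L) ? 1.0L
    : solve_fixed_point([&](ld q) {
        return (ls * (1.0L - uu - vv) * q * q + uu * ls * q * q_a +
                vv * ls * q * q_m + ms) / tot_s;
      }, tl, mi);
  return NumericVector::create((double)q_s, (double)q_a, (double)q_m);
}
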