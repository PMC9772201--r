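#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage simulation of a Wiener diffusion with unit
// noise between absorbing boundaries 0 and a. Start point z*a, per-trial
// drift v. Paths not absorbed by max_t are flagged (upper = NA, rt = NA).
// Uses the R RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List ddm_sim_cpp(int n, double a, NumericVector v, NumericVector z,
                 double dt, double max_t) {
  NumericVector rt(n);
  LogicalVector upper(n);
  double sdt = std::sqrt(dt);
  int max_steps = (int)(max_t / dt) + 1;
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double x = a * z[z.size() == 1 ? 0 : i];
    int step = 0;
    bool done = false;
    while (step < max_steps) {
      x += vi * dt + sdt * norm_rand();
      ++step;
      if (x >= a) { upper[i] = true; done = true; break; }
      if (x <= 0.0) { upper[i] = false; done = true; break; }
    }
    if (done) {
      rt[i] = step * dt;
    } else {
      rt[i] = NA_REAL;
      upper[i] = NA_LOGICAL;
    }
  }
  return List::create(_["upper"] = upper, _["rt"] = rt);
}
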