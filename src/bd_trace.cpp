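#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian-dynamics photon-rate trace for a mixture of freely diffusing
// emitters in a periodic box with a 3D Gaussian molecular detection
// function centred in the box. Uses R's RNG (unif_rand/norm_rand) so a
// trace is bit-reproducible under set.seed().
//
// Units: lengths um, dt s, brightness/background kHz; the returned vector
// is the instantaneous detected rate in kHz at each step.
//
// counts[i], D_um2s[i], brightness[i] describe species i; particles with
// init_center[i] true start at the focus centre (otherwise uniform).
// [[Rcpp::export]]
NumericVector bd_trace_cpp(int n_steps, IntegerVector counts,
                           NumericVector D_um2s, NumericVector brightness,
                           LogicalVector init_center, double dt,
                           NumericVector box, double w_xy, double w_z,
                           double background) {
  NumericVector rate(n_steps, background);
  const double lx = box[0], ly = box[1], lz = box[2];
  const double cx = lx / 2.0, cy = ly / 2.0, cz = lz / 2.0;
  const double ax = -2.0 / (w_xy * w_xy), az = -2.0 / (w_z * w_z);
  RNGScope scope;
  for (int s = 0; s < counts.size(); ++s) {
    const double sig = std::sqrt(2.0 * D_um2s[s] * dt);
    const double B = brightness[s];
    for (int p = 0; p < counts[s]; ++p) {
      double x, y, z;
      if (init_center[s]) {
        x = cx; y = cy; z = cz;
      } else {
        x = unif_rand() * lx; y = unif_rand() * ly; z = unif_rand() * lz;
      }
      for (int t = 0; t < n_steps; ++t) {
        if (sig > 0.0) {
          x += sig * norm_rand(); y += sig * norm_rand(); z += sig * norm_rand();
          x -= lx * std::floor(x / lx);
          y -= ly * std::floor(y / ly);
          z -= lz * std::floor(z / lz);
        }
        const double dx = x - cx, dy = y - cy, dz = z - cz;
        rate[t] += B * std::exp(ax * (dx * dx + dy * dy) + az * dz * dz);
      }
    }
  }
  return rate;
}
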