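#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Coordinates and radii in the same length unit; returned areas in unit^2.
// Test points are placed on a golden-section spiral on each solvent-expanded
// sphere; a point is accessible if it lies outside every neighbour's
// expanded sphere.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  // golden spiral unit sphere points
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    sx[k] = rk * std::cos(th);
    sy[k] = rk * std::sin(th);
    sz[k] = zk;
  }
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radius[i] + probe;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double ri = er[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double lim = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * sx[k], py = yi + ri * sy[k], pz = zi + ri * sz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double)acc / n_points);
  }
  return area;
}
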