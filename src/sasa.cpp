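#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley quadrature: for each atom in `which` (1-based), count probe
// points on the solvent-expanded sphere not inside any other atom's expanded
// sphere. ASA_i = exposed_fraction * 4*pi*(r_i + probe)^2.
// [[Rcpp::export]]
NumericVector cpp_atom_asa(NumericMatrix xyz, NumericVector radius,
                           double probe, NumericMatrix pts,
                           IntegerVector which) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radius[i] + probe;

  // coincident atoms make the surface undefined
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < 1e-12)
        stop("coincident atoms at rows %d and %d", i + 1, j + 1);
    }
  }

  NumericVector out(which.size());
  std::vector<int> nb;
  for (int w = 0; w < which.size(); ++w) {
    const int i = which[w] - 1;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double s = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < s * s) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xyz(i, 0) + R[i] * pts(k, 0);
      const double py = xyz(i, 1) + R[i] * pts(k, 1);
      const double pz = xyz(i, 2) + R[i] * pts(k, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    out[w] = (double)exposed / m * 4.0 * M_PI * R[i] * R[i];
  }
  return out;
}
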