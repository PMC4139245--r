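#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley accessible surface area with a deterministic generalized
// spiral point set on the probe-expanded sphere of each atom.  An atom's
// accessible area is the fraction of its surface points lying inside no
// other probe-expanded sphere, times 4*pi*(r+p)^2.  Only atoms listed in
// `subset` (1-based indices) are evaluated; every atom occludes.
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radius,
                          double probe, int n_points,
                          IntegerVector subset) {
  const int n = xyz.nrow();
  const int m = subset.size();
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = r * std::cos(golden * k);
    py[k] = r * std::sin(golden * k);
    pz[k] = z;
  }
  std::vector<double> er(n);
  for (int j = 0; j < n; ++j) er[j] = radius[j] + probe;
  NumericVector out(m);
  std::vector<int> nb;
  nb.reserve(128);
  for (int s = 0; s < m; ++s) {
    const int i = subset[s] - 1;
    const double ri = er[i];
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double rr = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < rr * rr) nb.push_back(j);
    }
    int nfree = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xi + ri * px[k], qy = yi + ri * py[k],
                   qz = zi + ri * pz[k];
      bool occluded = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        const int j = nb[t];
        const double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1),
                     dz = qz - xyz(j, 2);
        // strict interior test with a small guard so a point lying
        // exactly on a neighbouring sphere's surface is not occluded
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j] - 1e-9) {
          occluded = true;
          break;
        }
      }
      if (!occluded) ++nfree;
    }
    out[s] = 4.0 * M_PI * ri * ri * nfree / n_points;
  }
  return out;
}

// All inter-copy atom pairs closer than frac * (r_i + r_j); `copy` labels
// which rigid copy each atom belongs to.  Returns a 3-column matrix
// (i, j, distance) with 1-based indices.
// [[Rcpp::export(name = ".clash_kernel")]]
NumericMatrix clash_kernel(NumericMatrix xyz, NumericVector radius,
                           IntegerVector copy, double frac) {
  const int n = xyz.nrow();
  std::vector<double> vi, vj, vd;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (copy[i] == copy[j]) continue;
      const double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
                   dz = xyz(j, 2) - xyz(i, 2);
      const double lim = frac * (radius[i] + radius[j]);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  }
  NumericMatrix out(vi.size(), 3);
  for (size_t k = 0; k < vi.size(); ++k) {
    out(k, 0) = vi[k];
    out(k, 1) = vj[k];
    out(k, 2) = vd[k];
  }
  return out;
}
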