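// Solvent-accessible surface area cores.
//
// Two independent algorithms over the same expanded-sphere model
// (radius_i + probe): Shrake-Rupley test-point quadrature on a
// deterministic Fibonacci lattice, and Lee-Richards accessible-arc
// integration over z-slices. Areas are returned per atom; callers may
// restrict the set of atoms whose area is accumulated (occluders always
// include every atom).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".sasa_shrake_cpp")]]
NumericVector sasa_shrake_cpp(NumericMatrix coords, NumericVector radii,
                              double probe, NumericMatrix points,
                              IntegerVector subset) {
  const int n = coords.nrow();
  const int np = points.nrow();
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  for (int s = 0; s < subset.size(); ++s) {
    const int i = subset[s] - 1;  // 1-based from R
    const double Ri = R[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    // neighbour list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double lim = Ri + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      const double px = xi + Ri * points(p, 0);
      const double py = yi + Ri * points(p, 1);
      const double pz = zi + Ri * points(p, 2);
      bool buried = false;
      for (size_t k = 0; k < nb.size(); ++k) {
        const int j = nb[k];
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)np;
  }
  return area;
}

// Accessible-arc length (radians) on a circle of radius r centred at the
// origin, occluded by intervals [start, end] (already wrapped to [0, 2pi)).
static double accessible_angle(std::vector<std::pair<double, double> >& arcs) {
  if (arcs.empty()) return 2.0 * M_PI;
  std::sort(arcs.begin(), arcs.end());
  double covered = 0.0, cur_s = arcs[0].first, cur_e = arcs[0].second;
  for (size_t k = 1; k < arcs.size(); ++k) {
    if (arcs[k].first > cur_e) {
      covered += cur_e - cur_s;
      cur_s = arcs[k].first;
      cur_e = arcs[k].second;
    } else if (arcs[k].second > cur_e) {
      cur_e = arcs[k].second;
    }
  }
  covered += cur_e - cur_s;
  double acc = 2.0 * M_PI - covered;
  return acc < 0.0 ? 0.0 : acc;
}

// [[Rcpp::export(name = ".sasa_lee_richards_cpp")]]
NumericVector sasa_lee_richards_cpp(NumericMatrix coords, NumericVector radii,
                                    double probe, double slice_width,
                                    IntegerVector subset) {
  const int n = coords.nrow();
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  for (int s = 0; s < subset.size(); ++s) {
    const int i = subset[s] - 1;
    const double Ri = R[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double lim = Ri + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    const int nslice = std::max(1, (int)std::ceil(2.0 * Ri / slice_width));
    const double dz_step = 2.0 * Ri / nslice;
    double a = 0.0;
    for (int sl = 0; sl < nslice; ++sl) {
      const double z = zi - Ri + (sl + 0.5) * dz_step;
      const double dz_i = z - zi;
      const double ri2 = Ri * Ri - dz_i * dz_i;
      if (ri2 <= 0.0) continue;
      const double ri = std::sqrt(ri2);
      bool full_occl = false;
      std::vector<std::pair<double, double> > arcs;
      for (size_t k = 0; k < nb.size() && !full_occl; ++k) {
        const int j = nb[k];
        const double dz_j = z - coords(j, 2);
        const double rj2 = R[j] * R[j] - dz_j * dz_j;
        if (rj2 <= 0.0) continue;  // neighbour sphere misses this slice
        const double rj = std::sqrt(rj2);
        const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d >= ri + rj) continue;        // circles disjoint in the plane
        if (d + ri <= rj) { full_occl = true; break; }  // fully inside j
        if (d + rj <= ri) continue;        // j's circle inside ours: no arc
        double cosa = (d * d + ri2 - rj2) / (2.0 * d * ri);
        cosa = std::max(-1.0, std::min(1.0, cosa));
        const double half = std::acos(cosa);
        const double centre = std::atan2(dy, dx);
        double lo = centre - half, hi = centre + half;
        // wrap into [0, 2pi); avoids fmod (not builtin-expanded)
        const double tau = 2.0 * M_PI;
        lo -= tau * std::floor(lo / tau);
        hi -= tau * std::floor(hi / tau);
        if (lo <= hi) {
          arcs.push_back(std::make_pair(lo, hi));
        } else {
          arcs.push_back(std::make_pair(0.0, hi));
          arcs.push_back(std::make_pair(lo, tau));
        }
      }
      if (full_occl) continue;
      const double acc = accessible_angle(arcs);
      // lateral area of a sphere slab of thickness dz is 2*pi*R*dz
      // (Archimedes), scaled by the accessible fraction of the circle.
      a += acc / (2.0 * M_PI) * 2.0 * M_PI * Ri * dz_step;
    }
    area[i] = a;
  }
  return area;
}
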