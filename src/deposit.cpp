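// Exact deposition of straight segments into cylindrical (r, z) bins.
// Each segment is split at its crossings of the ring boundaries r = k*dr
// (roots of the quadratic r^2(t) = R^2) and of the slab boundaries
// z = z_min + m*dz; every sub-piece's full length is credited to the bin
// containing its midpoint.  Deposition therefore conserves total length
// exactly and depends on a segment only through (r(t), z(t)), so it is
// exactly invariant under rotations about the z axis.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

namespace {

// orientation channel: index of canonical axis maximizing |u_local . c_i|
inline int best_axis(const double* axes, int n_axes, double ur, double uf,
                     double uz) {
  int best = 0;
  double bv = -1.0;
  for (int i = 0; i < n_axes; ++i) {
    double d = std::fabs(ur * axes[i] + uf * axes[i + n_axes] +
                         uz * axes[i + 2 * n_axes]);
    if (d > bv) {
      bv = d;
      best = i;
    }
  }
  return best;
}

}  // namespace

// segs: n x >=10 matrix with columns x0,y0,z0,x1,y1,z1 at the given column
// offsets (0-based c0).  axes: 7 x 3 matrix (rows = axes in local
// (e_r, e_phi, e_z) frame) or 0 x 0 for plain single-channel deposition.
// Returns list(length_sums = nr x nz x nchan array, clipped, total).
// [[Rcpp::export]]
List deposit_cylindrical_cpp(NumericMatrix segs, IntegerVector col0,
                             double dr, double dz, int nr, int nz,
                             double zmin, NumericMatrix axes) {
  int c0 = col0[0];  // 0-based index of x0 column
  int n_axes = axes.nrow();
  int nchan = n_axes > 0 ? n_axes : 1;
  NumericVector vals(Dimension(nr, nz, nchan));
  double clipped = 0.0, total = 0.0;
  int n = segs.nrow();
  std::vector<double> ts;
  ts.reserve(64);
  const double* axp = n_axes > 0 ? &axes(0, 0) : nullptr;

  for (int i = 0; i < n; ++i) {
    double x0 = segs(i, c0), y0 = segs(i, c0 + 1), z0 = segs(i, c0 + 2);
    double x1 = segs(i, c0 + 3), y1 = segs(i, c0 + 4), z1 = segs(i, c0 + 5);
    double ddx = x1 - x0, ddy = y1 - y0, ddz = z1 - z0;
    double L = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    if (L <= 0) continue;
    total += L;
    // r^2(t) = qa t^2 + qb t + qc
    double qa = ddx * ddx + ddy * ddy;
    double qb = 2.0 * (x0 * ddx + y0 * ddy);
    double qc = x0 * x0 + y0 * y0;
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    // z-plane crossings
    if (ddz != 0.0) {
      double zlo = std::min(z0, z1), zhi = std::max(z0, z1);
      int m0 = (int)std::ceil((zlo - zmin) / dz);
      int m1 = (int)std::floor((zhi - zmin) / dz);
      for (int m = m0; m <= m1; ++m) {
        double t = (zmin + m * dz - z0) / ddz;
        if (t > 0.0 && t < 1.0) ts.push_back(t);
      }
    }
    // ring crossings
    double r2min, r2max;
    {
      double e0 = qc, e1 = qa + qb + qc;
      r2min = std::min(e0, e1);
      r2max = std::max(e0, e1);
      if (qa > 0.0) {
        double tv = -qb / (2.0 * qa);
        if (tv > 0.0 && tv < 1.0) {
          double rv = qa * tv * tv + qb * tv + qc;
          r2min = std::min(r2min, rv);
        }
      }
    }
    int k0 = (int)std::ceil(std::sqrt(std::max(0.0, r2min)) / dr);
    if (k0 < 1) k0 = 1;
    int k1 = (int)std::floor(std::sqrt(r2max) / dr);
    if (qa > 0.0) {
      for (int k = k0; k <= k1; ++k) {
        double R2 = (double)k * dr * (double)k * dr;
        double disc = qb * qb - 4.0 * qa * (qc - R2);
        if (disc < 0) continue;
        double sq = std::sqrt(disc);
        double t1 = (-qb - sq) / (2.0 * qa), t2 = (-qb + sq) / (2.0 * qa);
        if (t1 > 0.0 && t1 < 1.0) ts.push_back(t1);
        if (t2 > 0.0 && t2 < 1.0) ts.push_back(t2);
      }
    }
    std::sort(ts.begin(), ts.end());
    double ux = ddx / L, uy = ddy / L, uz = ddz / L;
    for (size_t s = 0; s + 1 < ts.size(); ++s) {
      double t0 = ts[s], t1 = ts[s + 1];
      double w = (t1 - t0) * L;
      if (w <= 0) continue;
      double tm = 0.5 * (t0 + t1);
      double xm = x0 + tm * ddx, ym = y0 + tm * ddy, zm = z0 + tm * ddz;
      double r = std::sqrt(xm * xm + ym * ym);
      int kr = (int)std::floor(r / dr);
      int kz = (int)std::floor((zm - zmin) / dz);
      if (kr < 0 || kr >= nr || kz < 0 || kz >= nz) {
        clipped += w;
        continue;
      }
      int ch = 0;
      if (n_axes > 0) {
        // local cylindrical frame at the sub-piece midpoint azimuth
        double ir = (r > 1e-12) ? 1.0 / r : 0.0;
        double cph = (r > 1e-12) ? xm * ir : 1.0;
        double sph = (r > 1e-12) ? ym * ir : 0.0;
        double ur = ux * cph + uy * sph;
        double uf = -ux * sph + uy * cph;
        ch = best_axis(axp, n_axes, ur, uf, uz);
      }
      vals[kr + nr * (kz + nz * ch)] += w;
    }
  }
  return List::create(_["length_sums"] = vals, _["clipped"] = clipped,
                      _["total"] = total);
}
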