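// Expected potential-synapse estimators: overlap integrals over a 3-D
// lattice sampling two cylindrically stored density fields (uniform and
// 7-axis orientation-template variants), the Gaussian-kernel pairwise sum
// over raw segment inventories, and the brute-force counting oracle with
// exact clamped segment-segment distances.
#include <Rcpp.h>
#include <algorithm>
#include <functional>
using namespace Rcpp;

#ifndef M_PI_4
#define M_PI_4 0.78539816339744830962
#endif

namespace {

struct Grid {
  const double* v;  // nr x nz (x nchan)
  int nr, nz, nchan;
  double dr, dz, zmin;
};

// Bilinear interpolation on (r, z) bin centers.  Radially the field is
// clamped to the innermost bin value for r below the first center and
// tapers linearly to 0 beyond the last center (reaching 0 at one bin width
// past it); in z it tapers to 0 beyond the outermost centers.
inline void rz_weights(const Grid& g, double r, double z, int idx[4],
                       double w[4]) {
  double fr = r / g.dr - 0.5;
  double fz = (z - g.zmin) / g.dz - 0.5;
  int i0 = (int)std::floor(fr), j0 = (int)std::floor(fz);
  double wi = fr - i0, wj = fz - j0;
  int ii[2] = {i0, i0 + 1};
  int jj[2] = {j0, j0 + 1};
  double wri[2] = {1.0 - wi, wi};
  double wzj[2] = {1.0 - wj, wj};
  int n = 0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) {
      int i = ii[a], j = jj[b];
      if (i < 0) i = 0;  // clamp at the axis
      if (i >= g.nr || j < 0 || j >= g.nz) {
        idx[n] = -1;
        w[n] = 0.0;
      } else {
        idx[n] = i + g.nr * j;
        w[n] = wri[a] * wzj[b];
      }
      ++n;
    }
}

inline double sample_rz(const Grid& g, double r, double z, int chan = 0) {
  int idx[4];
  double w[4];
  rz_weights(g, r, z, idx, w);
  const double* v = g.v + (size_t)chan * g.nr * g.nz;
  double s = 0.0;
  for (int k = 0; k < 4; ++k)
    if (idx[k] >= 0) s += w[k] * v[idx[k]];
  return s;
}

Grid as_grid(NumericVector vals, NumericVector meta) {
  // meta: nr, nz, nchan, dr, dz, zmin
  Grid g;
  g.v = &vals[0];
  g.nr = (int)meta[0];
  g.nz = (int)meta[1];
  g.nchan = (int)meta[2];
  g.dr = meta[3];
  g.dz = meta[4];
  g.zmin = meta[5];
  return g;
}

}  // namespace

// [[Rcpp::export]]
NumericVector sample_density_cpp(NumericVector vals, NumericVector meta,
                                 NumericVector r, NumericVector z) {
  Grid g = as_grid(vals, meta);
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_rz(g, r[i], z[i]);
  return out;
}

// K_U = (pi/4) * 2s * sum_v rho_a(x_v) rho_d(x_v - d) * step^3 over a
// lattice restricted to the overlap box [lims = xlo,xhi,ylo,yhi,zlo,zhi].
// [[Rcpp::export]]
double k_uniform_cpp(NumericVector va, NumericVector ma, NumericVector vd,
                     NumericVector md, double rho, double zeta, double s,
                     double step, NumericVector lims) {
  Grid A = as_grid(va, ma), D = as_grid(vd, md);
  double xlo = lims[0], xhi = lims[1], ylo = lims[2], yhi = lims[3],
         zlo = lims[4], zhi = lims[5];
  if (xhi <= xlo || yhi <= ylo || zhi <= zlo) return 0.0;
  int nx = (int)std::ceil((xhi - xlo) / step);
  int ny = (int)std::ceil((yhi - ylo) / step);
  int nzq = (int)std::ceil((zhi - zlo) / step);
  double acc = 0.0;
  for (int iz = 0; iz < nzq; ++iz) {
    double z = zlo + (iz + 0.5) * step;
    for (int ix = 0; ix < nx; ++ix) {
      double x = xlo + (ix + 0.5) * step;
      for (int iy = 0; iy < ny; ++iy) {
        double y = ylo + (iy + 0.5) * step;
        double ra = std::sqrt(x * x + y * y);
        double da = sample_rz(A, ra, z);
        if (da <= 0.0) continue;
        double xd = x - rho;
        double rd = std::sqrt(xd * xd + y * y);
        double dd = sample_rz(D, rd, z - zeta);
        acc += da * dd;
      }
    }
  }
  return M_PI_4 * 2.0 * s * acc * step * step * step;
}

// K_O = 2s * sum_v sum_ij |sin theta_ij| T_a(x_v, i) T_d(x_v - d, j) dV with
// the canonical axes rotated into the global frame by each field's local
// azimuth.  axes: n_axes x 3 in the local (e_r, e_phi, e_z) frame.
// [[Rcpp::export]]
double k_template_cpp(NumericVector va, NumericVector ma, NumericVector vd,
                      NumericVector md, NumericMatrix axes, double rho,
                      double zeta, double s, double step, NumericVector lims) {
  Grid A = as_grid(va, ma), D = as_grid(vd, md);
  int nax = axes.nrow();
  double xlo = lims[0], xhi = lims[1], ylo = lims[2], yhi = lims[3],
         zlo = lims[4], zhi = lims[5];
  if (xhi <= xlo || yhi <= ylo || zhi <= zlo) return 0.0;
  int nx = (int)std::ceil((xhi - xlo) / step);
  int ny = (int)std::ceil((yhi - ylo) / step);
  int nzq = (int)std::ceil((zhi - zlo) / step);
  std::vector<double> ga(3 * nax), gd(3 * nax), ta(nax), td(nax);
  size_t plane = (size_t)A.nr * A.nz, planeD = (size_t)D.nr * D.nz;
  double acc = 0.0;
  for (int iz = 0; iz < nzq; ++iz) {
    double z = zlo + (iz + 0.5) * step;
    for (int ix = 0; ix < nx; ++ix) {
      double x = xlo + (ix + 0.5) * step;
      for (int iy = 0; iy < ny; ++iy) {
        double y = ylo + (iy + 0.5) * step;
        double ra = std::sqrt(x * x + y * y);
        int ia[4];
        double wa[4];
        rz_weights(A, ra, z, ia, wa);
        double suma = 0.0;
        for (int c = 0; c < nax; ++c) {
          double sv = 0.0;
          for (int k = 0; k < 4; ++k)
            if (ia[k] >= 0) sv += wa[k] * A.v[ia[k] + plane * c];
          ta[c] = sv;
          suma += sv;
        }
        if (suma <= 0.0) continue;
        double xd = x - rho;
        double rd = std::sqrt(xd * xd + y * y);
        int id[4];
        double wd[4];
        rz_weights(D, rd, z - zeta, id, wd);
        double sumd = 0.0;
        for (int c = 0; c < nax; ++c) {
          double sv = 0.0;
          for (int k = 0; k < 4; ++k)
            if (id[k] >= 0) sv += wd[k] * D.v[id[k] + planeD * c];
          td[c] = sv;
          sumd += sv;
        }
        if (sumd <= 0.0) continue;
        // rotate axes to global frame by each local azimuth
        double ca = (ra > 1e-12) ? x / ra : 1.0, sa = (ra > 1e-12) ? y / ra : 0.0;
        double cd = (rd > 1e-12) ? xd / rd : 1.0, sd = (rd > 1e-12) ? y / rd : 0.0;
        for (int c = 0; c < nax; ++c) {
          double cr = axes(c, 0), cf = axes(c, 1), cz = axes(c, 2);
          ga[3 * c] = cr * ca - cf * sa;
          ga[3 * c + 1] = cr * sa + cf * ca;
          ga[3 * c + 2] = cz;
          gd[3 * c] = cr * cd - cf * sd;
          gd[3 * c + 1] = cr * sd + cf * cd;
          gd[3 * c + 2] = cz;
        }
        for (int i = 0; i < nax; ++i) {
          if (ta[i] <= 0.0) continue;
          for (int j = 0; j < nax; ++j) {
            if (td[j] <= 0.0) continue;
            double dot = ga[3 * i] * gd[3 * j] + ga[3 * i + 1] * gd[3 * j + 1] +
                         ga[3 * i + 2] * gd[3 * j + 2];
            double s2 = 1.0 - dot * dot;
            if (s2 <= 0.0) continue;
            acc += std::sqrt(s2) * ta[i] * td[j];
          }
        }
      }
    }
  }
  return 2.0 * s * acc * step * step * step;
}

// K_S = 2s * sum_i sum_j l_a,i l_d,j |sin theta_ij| g(m_a,i - m_d,j - d)
// with g an isotropic trivariate normal of per-axis sd sqrt(2)*sigma.
// ma/md: n x 3 midpoints; ua/ud: n x 3 unit orientations; la/ld lengths.
// [[Rcpp::export]]
double k_kernel_cpp(NumericMatrix ma, NumericVector la, NumericMatrix ua,
                    NumericMatrix md, NumericVector ld, NumericMatrix ud,
                    NumericVector dvec, double s, double sigma) {
  int na = ma.nrow(), nd = md.nrow();
  double v2 = 2.0 * sigma * sigma;        // per-axis variance
  double norm = std::pow(2.0 * M_PI * v2, -1.5);
  double cut2 = 2.0 * v2 * 80.0;          // exp(-40) ~ 4e-18: negligible
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    double ax = ma(i, 0) - dvec[0], ay = ma(i, 1) - dvec[1],
           az = ma(i, 2) - dvec[2];
    for (int j = 0; j < nd; ++j) {
      double dx = ax - md(j, 0), dy = ay - md(j, 1), dz = az - md(j, 2);
      double q2 = dx * dx + dy * dy + dz * dz;
      if (q2 > cut2) continue;
      double dot = ua(i, 0) * ud(j, 0) + ua(i, 1) * ud(j, 1) +
                   ua(i, 2) * ud(j, 2);
      double s2 = 1.0 - dot * dot;
      if (s2 <= 0.0) continue;
      acc += la[i] * ld[j] * std::sqrt(s2) * norm * std::exp(-q2 / (2.0 * v2));
    }
  }
  return 2.0 * s * acc;
}

namespace {

// minimum distance between segments p0-p1 and q0-q1 (Ericson, clamped),
// also returns the midpoint of the closest-point pair
double seg_seg_dist(const double* p, const double* q, double* contact) {
  double d1x = p[3] - p[0], d1y = p[4] - p[1], d1z = p[5] - p[2];
  double d2x = q[3] - q[0], d2y = q[4] - q[1], d2z = q[5] - q[2];
  double rx = p[0] - q[0], ry = p[1] - q[1], rz = p[2] - q[2];
  double a = d1x * d1x + d1y * d1y + d1z * d1z;
  double e = d2x * d2x + d2y * d2y + d2z * d2z;
  double f = d2x * rx + d2y * ry + d2z * rz;
  double s = 0.0, t = 0.0;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = d1x * rx + d1y * ry + d1z * rz;
    if (e <= EPS) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = d1x * d2x + d1y * d2y + d1z * d2z;
      double denom = a * e - b * b;
      if (denom > EPS)
        s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  double c1x = p[0] + s * d1x, c1y = p[1] + s * d1y, c1z = p[2] + s * d1z;
  double c2x = q[0] + t * d2x, c2y = q[1] + t * d2y, c2z = q[2] + t * d2z;
  double dx = c1x - c2x, dy = c1y - c2y, dz = c1z - c2z;
  contact[0] = 0.5 * (c1x + c2x);
  contact[1] = 0.5 * (c1y + c2y);
  contact[2] = 0.5 * (c1z + c2z);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

}  // namespace

namespace {
// segments share a tree node: identical, parent-child, or siblings
inline bool tree_adjacent(int i, int j, const int* par) {
  return i == j || par[i] == j + 1 || par[j] == i + 1 ||
         (par[i] != 0 && par[i] == par[j]);
}
}  // namespace

// Counts (axonal segment, dendritic segment) pairs with minimum distance
// <= s after translating the dendritic morphology by dvec.  If cluster,
// qualifying pairs representing one geometric close approach are merged
// into a single contact site: two pairs merge when their axonal segments
// share a tree node AND their dendritic segments share a tree node AND
// their closest-approach midpoints lie within link_r (transitively).
// Approaches by unrelated branch pairs remain distinct sites.
// sa/sd: n x 6 (x0..z1); pa/pd: 1-based parent row (0 = arbor root).
// Returns c(n_sites_or_pairs, n_raw_pairs).
// [[Rcpp::export]]
IntegerVector count_pairs_cpp(NumericMatrix sa, NumericMatrix sd,
                              IntegerVector pa, IntegerVector pd,
                              NumericVector dvec, double s, bool cluster,
                              double link_r) {
  int na = sa.nrow(), nd = sd.nrow();
  // precompute midpoints + half lengths for pruning, dendrite translated
  std::vector<double> A(6 * na), D(6 * nd), amx(na), amy(na), amz(na),
      ah(na), dmx(nd), dmy(nd), dmz(nd), dh(nd);
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < 6; ++k) A[6 * i + k] = sa(i, k);
    amx[i] = 0.5 * (sa(i, 0) + sa(i, 3));
    amy[i] = 0.5 * (sa(i, 1) + sa(i, 4));
    amz[i] = 0.5 * (sa(i, 2) + sa(i, 5));
    double dx = sa(i, 3) - sa(i, 0), dy = sa(i, 4) - sa(i, 1),
           dz = sa(i, 5) - sa(i, 2);
    ah[i] = 0.5 * std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  for (int j = 0; j < nd; ++j) {
    D[6 * j] = sd(j, 0) + dvec[0];
    D[6 * j + 1] = sd(j, 1) + dvec[1];
    D[6 * j + 2] = sd(j, 2) + dvec[2];
    D[6 * j + 3] = sd(j, 3) + dvec[0];
    D[6 * j + 4] = sd(j, 4) + dvec[1];
    D[6 * j + 5] = sd(j, 5) + dvec[2];
    dmx[j] = 0.5 * (D[6 * j] + D[6 * j + 3]);
    dmy[j] = 0.5 * (D[6 * j + 1] + D[6 * j + 4]);
    dmz[j] = 0.5 * (D[6 * j + 2] + D[6 * j + 5]);
    double dx = D[6 * j + 3] - D[6 * j], dy = D[6 * j + 4] - D[6 * j + 1],
           dz = D[6 * j + 5] - D[6 * j + 2];
    dh[j] = 0.5 * std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  std::vector<double> cx, cy, cz;
  std::vector<int> qa, qd;
  double contact[3];
  int raw = 0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nd; ++j) {
      double bx = amx[i] - dmx[j], by = amy[i] - dmy[j], bz = amz[i] - dmz[j];
      double bound = s + ah[i] + dh[j];
      if (bx * bx + by * by + bz * bz > bound * bound) continue;
      if (seg_seg_dist(&A[6 * i], &D[6 * j], contact) <= s) {
        ++raw;
        if (cluster) {
          cx.push_back(contact[0]);
          cy.push_back(contact[1]);
          cz.push_back(contact[2]);
          qa.push_back(i);
          qd.push_back(j);
        }
      }
    }
  }
  if (!cluster) return IntegerVector::create(raw, raw);
  // union-find over qualifying pairs
  int q = raw;
  std::vector<int> parent(q);
  for (int i = 0; i < q; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  double l2 = link_r * link_r;
  const int* pap = &pa[0];
  const int* pdp = &pd[0];
  for (int i = 0; i < q; ++i)
    for (int j = i + 1; j < q; ++j) {
      double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
      if (dx * dx + dy * dy + dz * dz > l2) continue;
      if (!tree_adjacent(qa[i], qa[j], pap) ||
          !tree_adjacent(qd[i], qd[j], pdp))
        continue;
      int ri = find(i), rj = find(j);
      if (ri != rj) parent[ri] = rj;
    }
  int sites = 0;
  for (int i = 0; i < q; ++i)
    if (find(i) == i) ++sites;
  return IntegerVector::create(sites, raw);
}
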