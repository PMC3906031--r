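// Stochastic neurite outgrowth: at each of n_steps fixed increments every
// active growth cone elongates by step_length along a von Mises-Fisher
// perturbation of its current direction and may split into two daughters
// with probability branch_prob * 2^(-branch_decay * centrifugal_order).
// All randomness goes through R's RNG so results are reproducible from
// set.seed() on the R side.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }

// Direction drawn from a vMF density with mean mu (unit) and concentration
// kappa; kappa -> 0 degenerates to the uniform sphere.
Vec3 rvmf(const Vec3& mu, double kappa) {
  double u1 = unif_rand(), u2 = unif_rand();
  double w;
  if (kappa < 1e-8) {
    w = 2.0 * u1 - 1.0;
  } else {
    w = 1.0 + std::log(u1 + (1.0 - u1) * std::exp(-2.0 * kappa)) / kappa;
    if (w < -1.0) w = -1.0;
    if (w > 1.0) w = 1.0;
  }
  // orthonormal basis around mu
  Vec3 a = (std::fabs(mu.x) < 0.9) ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  // e1 = normalize(a - (a.mu) mu)
  double d = a.x * mu.x + a.y * mu.y + a.z * mu.z;
  Vec3 e1 = {a.x - d * mu.x, a.y - d * mu.y, a.z - d * mu.z};
  double n1 = std::sqrt(e1.x * e1.x + e1.y * e1.y + e1.z * e1.z);
  e1 = (1.0 / n1) * e1;
  Vec3 e2 = {mu.y * e1.z - mu.z * e1.y, mu.z * e1.x - mu.x * e1.z,
             mu.x * e1.y - mu.y * e1.x};
  double st = std::sqrt(std::max(0.0, 1.0 - w * w));
  double th = 2.0 * M_PI * u2;
  return {st * (std::cos(th) * e1.x + std::sin(th) * e2.x) + w * mu.x,
          st * (std::cos(th) * e1.y + std::sin(th) * e2.y) + w * mu.y,
          st * (std::cos(th) * e1.z + std::sin(th) * e2.z) + w * mu.z};
}

// Area-uniform direction within the polar band [pol_lo, pol_hi] (radians,
// measured from +z), azimuth uniform on [0, 2pi).
Vec3 rdir_band(double pol_lo, double pol_hi) {
  double c_hi = std::cos(pol_lo), c_lo = std::cos(pol_hi);  // cos decreasing
  double c = c_lo + (c_hi - c_lo) * unif_rand();
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  return {s * std::cos(phi), s * std::sin(phi), c};
}

struct Cone {
  Vec3 pos, dir;
  int order, kind, arbor, parent;  // parent: 1-based segment row, 0 = none
  bool fresh;                      // first step uses dir unperturbed
};

}  // namespace

// Segment table columns: kind (1 axon, 2 apical, 3 basal), arbor, parent,
// order, x0, y0, z0, x1, y1, z1.
// [[Rcpp::export]]
NumericMatrix grow_neuron_cpp(int n_steps, double step_length,
                              double branch_prob, double branch_decay,
                              double kappa, double kappa_branch, int n_basal,
                              double soma_radius, NumericVector axon_polar,
                              NumericVector apical_polar,
                              NumericVector basal_polar) {
  RNGScope rng;
  std::vector<Cone> cones;
  cones.reserve(64);
  int arbor = 0;
  auto seed_arbor = [&](int kind, double lo, double hi) {
    Vec3 u = rdir_band(lo, hi);
    Cone c;
    c.pos = soma_radius * u;
    c.dir = u;
    c.order = 0;
    c.kind = kind;
    c.arbor = ++arbor;
    c.parent = 0;
    c.fresh = true;
    cones.push_back(c);
  };
  seed_arbor(1, axon_polar[0], axon_polar[1]);
  seed_arbor(2, apical_polar[0], apical_polar[1]);
  for (int b = 0; b < n_basal; ++b) seed_arbor(3, basal_polar[0], basal_polar[1]);

  std::vector<double> rows;  // flat, 10 per segment
  rows.reserve(10 * 2048);
  int n_seg = 0;

  for (int t = 0; t < n_steps; ++t) {
    size_t n_active = cones.size();
    std::vector<Cone> born;
    for (size_t i = 0; i < n_active; ++i) {
      Cone& c = cones[i];
      Vec3 d = c.fresh ? c.dir : rvmf(c.dir, kappa);
      c.fresh = false;
      Vec3 p1 = c.pos + step_length * d;
      rows.push_back((double)c.kind);
      rows.push_back((double)c.arbor);
      rows.push_back((double)c.parent);
      rows.push_back((double)c.order);
      rows.push_back(c.pos.x);
      rows.push_back(c.pos.y);
      rows.push_back(c.pos.z);
      rows.push_back(p1.x);
      rows.push_back(p1.y);
      rows.push_back(p1.z);
      ++n_seg;
      c.pos = p1;
      c.dir = d;
      c.parent = n_seg;
      double pb = branch_prob * std::pow(2.0, -branch_decay * c.order);
      if (t + 1 < n_steps && unif_rand() < pb) {
        Cone d1 = c, d2 = c;
        d1.order = d2.order = c.order + 1;
        d1.dir = rvmf(c.dir, kappa_branch);
        d2.dir = rvmf(c.dir, kappa_branch);
        d1.fresh = d2.fresh = true;
        born.push_back(d1);
        born.push_back(d2);
        c.order = -1;  // mark dead
      }
    }
    // drop split cones, append daughters (stable order => reproducible RNG use)
    std::vector<Cone> next;
    next.reserve(cones.size() + born.size());
    for (auto& c : cones)
      if (c.order >= 0) next.push_back(c);
    for (auto& c : born) next.push_back(c);
    cones.swap(next);
  }

  NumericMatrix out(n_seg, 10);
  for (int i = 0; i < n_seg; ++i)
    for (int j = 0; j < 10; ++j) out(i, j) = rows[10 * i + j];
  colnames(out) = CharacterVector::create("kind", "arbor", "parent", "order",
                                          "x0", "y0", "z0", "x1", "y1", "z1");
  return out;
}
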