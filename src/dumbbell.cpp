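#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coarse-grained FP-linker-FP dumbbell chain.
// Sites 0 and N-1 are the fluorescent-protein spheres; sites 1..N-2 are
// linker beads (one per residue).  Bonds have fixed length; conformational
// moves are pivot rotations of a chain arm and single-bead crankshaft
// rotations, both of which preserve all bond lengths exactly.  Excluded
// volume is hard-core (overlapping proposals are rejected); non-adjacent
// linker beads within contact_range attract with a square well of depth
// eps (in kT).  FP spheres carry no attraction.

static inline double dist3(const std::vector<double> &x,
                           const std::vector<double> &y,
                           const std::vector<double> &z, int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// rotate point p about axis (unit vector u) through origin by angle a
static inline void rotate_about(double ux, double uy, double uz, double ca,
                                double sa, double &px, double &py,
                                double &pz) {
  double dot = ux * px + uy * py + uz * pz;
  double cx = uy * pz - uz * py;
  double cy = uz * px - ux * pz;
  double cz = ux * py - uy * px;
  double nx = px * ca + cx * sa + ux * dot * (1.0 - ca);
  double ny = py * ca + cy * sa + uy * dot * (1.0 - ca);
  double nz = pz * ca + cz * sa + uz * dot * (1.0 - ca);
  px = nx; py = ny; pz = nz;
}

struct ChainModel {
  int N;                 // total sites (linker + 2 FP)
  double bead_radius, fp_radius, contact_range, eps;
  std::vector<double> radius;   // per-site hard radius

  bool overlaps(const std::vector<double> &x, const std::vector<double> &y,
                const std::vector<double> &z) const {
    for (int i = 0; i < N; ++i)
      for (int j = i + 2; j < N; ++j) {
        double lim = radius[i] + radius[j];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < lim * lim * (1.0 - 1e-12))
          return true;
      }
    return false;
  }

  // square-well attraction between non-adjacent linker beads only
  double energy(const std::vector<double> &x, const std::vector<double> &y,
                const std::vector<double> &z) const {
    if (eps <= 0.0) return 0.0;
    double e = 0.0;
    double cr2 = contact_range * contact_range;
    for (int i = 1; i < N - 1; ++i)
      for (int j = i + 2; j < N - 1; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (dx * dx + dy * dy + dz * dz < cr2) e -= eps;
      }
    return e;
  }
};

// [[Rcpp::export(name = ".dumbbell_mc")]]
List dumbbell_mc(int n_linker, double attraction_scale, double epsilon0,
                 double bond_length, double bead_radius, double fp_radius,
                 double contact_range, double fp_mass, int n_conformers,
                 int mc_steps, int equilibration_steps, bool keep_coords) {
  ChainModel m;
  m.N = n_linker + 2;
  m.bead_radius = bead_radius;
  m.fp_radius = fp_radius;
  m.contact_range = contact_range;
  m.eps = attraction_scale * epsilon0;
  m.radius.assign(m.N, bead_radius);
  m.radius[0] = fp_radius;
  m.radius[m.N - 1] = fp_radius;

  // bond lengths: FP-bead bonds put the sphere surface at the bead surface
  std::vector<double> bond(m.N - 1, bond_length);
  if (n_linker > 0) {
    bond[0] = fp_radius + bead_radius;
    bond[m.N - 2] = fp_radius + bead_radius;
  } else {
    bond[0] = 2.0 * fp_radius;  // bare FP-FP dumbbell
  }

  // straight initial chain along x
  std::vector<double> x(m.N, 0.0), y(m.N, 0.0), z(m.N, 0.0);
  for (int i = 1; i < m.N; ++i) x[i] = x[i - 1] + bond[i - 1];
  if (m.overlaps(x, y, z)) stop("unsatisfiable dumbbell geometry");

  double E = m.energy(x, y, z);
  std::vector<double> px = x, py = y, pz = z;

  NumericVector out_re(n_conformers), out_rg(n_conformers),
      out_re_linker(n_conformers);
  NumericVector coords(keep_coords ? n_conformers * m.N * 3 : 0);

  long total = (long)equilibration_steps + (long)n_conformers * mc_steps;
  int taken = 0;
  long accepted = 0;

  for (long step = 1; step <= total; ++step) {
    px = x; py = y; pz = z;
    double u = unif_rand();
    if (u < 0.5 || m.N < 3) {
      // pivot: rotate one arm about a random axis through a random joint
      int k = 1 + (int)(unif_rand() * (m.N - 2));
      if (k > m.N - 2) k = m.N - 2;
      double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
      double nn = std::sqrt(ax * ax + ay * ay + az * az);
      if (nn < 1e-12) continue;
      ax /= nn; ay /= nn; az /= nn;
      double ang = (unif_rand() * 2.0 - 1.0) * M_PI;
      double ca = std::cos(ang), sa = std::sin(ang);
      bool tail = unif_rand() < 0.5;
      int lo = tail ? k + 1 : 0;
      int hi = tail ? m.N - 1 : k - 1;
      for (int i = lo; i <= hi; ++i) {
        double qx = px[i] - px[k], qy = py[i] - py[k], qz = pz[i] - pz[k];
        rotate_about(ax, ay, az, ca, sa, qx, qy, qz);
        px[i] = px[k] + qx; py[i] = py[k] + qy; pz[i] = pz[k] + qz;
      }
    } else {
      // crankshaft: rotate interior site about the axis of its neighbours
      int k = 1 + (int)(unif_rand() * (m.N - 2));
      if (k > m.N - 2) k = m.N - 2;
      double ax = px[k + 1] - px[k - 1], ay = py[k + 1] - py[k - 1],
             az = pz[k + 1] - pz[k - 1];
      double nn = std::sqrt(ax * ax + ay * ay + az * az);
      if (nn < 1e-9) continue;  // neighbours coincide; skip
      ax /= nn; ay /= nn; az /= nn;
      double ang = (unif_rand() * 2.0 - 1.0) * M_PI;
      double ca = std::cos(ang), sa = std::sin(ang);
      double qx = px[k] - px[k - 1], qy = py[k] - py[k - 1],
             qz = pz[k] - pz[k - 1];
      rotate_about(ax, ay, az, ca, sa, qx, qy, qz);
      px[k] = px[k - 1] + qx; py[k] = py[k - 1] + qy; pz[k] = pz[k - 1] + qz;
    }

    if (!m.overlaps(px, py, pz)) {
      double Enew = m.energy(px, py, pz);
      if (Enew <= E || unif_rand() < std::exp(E - Enew)) {
        x = px; y = py; z = pz;
        E = Enew;
        ++accepted;
      }
    }

    if (step > equilibration_steps &&
        (step - equilibration_steps) % mc_steps == 0 &&
        taken < n_conformers) {
      out_re[taken] = dist3(x, y, z, 0, m.N - 1);
      out_re_linker[taken] =
          n_linker > 1 ? dist3(x, y, z, 1, m.N - 2) : NA_REAL;
      // mass-weighted Rg; FP spheres enter as uniform spheres (2/5 R^2 term)
      double msum = n_linker + 2.0 * fp_mass;
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < m.N; ++i) {
        double w = (i == 0 || i == m.N - 1) ? fp_mass : 1.0;
        cx += w * x[i]; cy += w * y[i]; cz += w * z[i];
      }
      cx /= msum; cy /= msum; cz /= msum;
      double s2 = 0;
      for (int i = 0; i < m.N; ++i) {
        double w = (i == 0 || i == m.N - 1) ? fp_mass : 1.0;
        double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
        s2 += w * (dx * dx + dy * dy + dz * dz);
        if (i == 0 || i == m.N - 1) s2 += w * 0.4 * fp_radius * fp_radius;
      }
      out_rg[taken] = std::sqrt(s2 / msum);
      if (keep_coords) {
        long off = (long)taken * m.N * 3;
        for (int i = 0; i < m.N; ++i) {
          coords[off + i] = x[i];
          coords[off + m.N + i] = y[i];
          coords[off + 2 * m.N + i] = z[i];
        }
      }
      ++taken;
    }
  }

  List out = List::create(
      _["re"] = out_re, _["rg"] = out_rg, _["re_linker"] = out_re_linker,
      _["acceptance"] = (double)accepted / (double)total,
      _["n_sites"] = m.N);
  if (keep_coords) {
    coords.attr("dim") = IntegerVector::create(m.N, 3, n_conformers);
    out["coords"] = coords;
  }
  return out;
}

// Debye scattering for a set of conformers.  Each site has a scattering
// mass and a hard radius; radius 0 sites are point scatterers, radius > 0
// sites use the uniform-sphere form factor.  I(0) = (sum of masses)^2.
// [[Rcpp::export(name = ".debye_profiles")]]
NumericMatrix debye_profiles(NumericVector coords, NumericVector masses,
                             NumericVector radii, NumericVector q) {
  IntegerVector dim = coords.attr("dim");
  int N = dim[0], nc = dim[2], nq = q.size();
  NumericMatrix I(nc, nq);

  // per-site form factors on the q grid
  NumericMatrix ff(N, nq);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < nq; ++k) {
      double u = q[k] * radii[i];
      double f = 1.0;
      if (u > 1e-8)
        f = 3.0 * (std::sin(u) - u * std::cos(u)) / (u * u * u);
      ff(i, k) = masses[i] * f;
    }

  for (int c = 0; c < nc; ++c) {
    long off = (long)c * N * 3;
    for (int k = 0; k < nq; ++k) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += ff(i, k) * ff(i, k);
      I(c, k) = s;
    }
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = coords[off + i] - coords[off + j];
        double dy = coords[off + N + i] - coords[off + N + j];
        double dz = coords[off + 2 * N + i] - coords[off + 2 * N + j];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int k = 0; k < nq; ++k) {
          double qd = q[k] * d;
          double sinc = qd > 1e-8 ? std::sin(qd) / qd : 1.0;
          I(c, k) += 2.0 * ff(i, k) * ff(j, k) * sinc;
        }
      }
  }
  return I;
}
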