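#include <Rcpp.h>
using namespace Rcpp;

// Photon random walk through a scattering slab, binned into a backprojected
// source-plane kernel. Geometry: isotropic point emitter at the origin (the
// focal plane), tissue slab occupying 0 <= z <= z_h (um), free space beyond
// the surface at z = z_h. Photons are launched toward the surface with an
// elevation inside the collection cone, take exponential free paths
// (rate mu, um^-1), deflect by Henyey-Greenstein angles with uniform
// azimuthal spin while inside the slab, and are collected when they cross
// z = z_h. A collected photon is traced backwards along its final direction
// to its apparent (x, y) origin on the z = 0 plane and binned on a square
// grid centred on the true source. Photons crossing z = 0 backwards never
// reach the epi-collection optics and are dropped.
//
// Uses R's RNG (unif_rand) so that set.seed() in R makes runs bit-identical.

static inline double hg_cos(double g) {
  double u = unif_rand();
  if (g <= 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// rotate unit vector d by polar angle (ct, st) about itself with azimuth phi
static inline void deflect(double &dx, double &dy, double &dz,
                           double ct, double st, double phi) {
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(dz) > 0.99999) {
    // near-vertical: use the standard degenerate-frame formula
    nx = st * cp;
    ny = st * sp;
    nz = ct * (dz > 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - dz * dz);
    nx = st * (dx * dz * cp - dy * sp) / denom + dx * ct;
    ny = st * (dy * dz * cp + dx * sp) / denom + dy * ct;
    nz = -st * cp * denom + dz * ct;
  }
  // renormalise against drift
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx / nrm; dy = ny / nrm; dz = nz / nrm;
}

// [[Rcpp::export(name = ".mc_sample_kernel")]]
List mc_sample_kernel(double n_photons, double mu_um, double g, double z_h,
                      double theta_max, int elevation_solid_angle,
                      double pixel_pitch, int halfwidth, double max_events) {
  const int side = 2 * halfwidth + 1;
  NumericMatrix counts(side, side);
  double n_collected = 0.0, n_lost = 0.0, n_binned = 0.0, total_events = 0.0;
  const double two_pi = 2.0 * M_PI;
  const double cos_max = std::cos(theta_max);
  const R_xlen_t n = (R_xlen_t) n_photons;

  for (R_xlen_t i = 0; i < n; ++i) {
    // launch toward the surface (+z) inside the NA cone
    double ct0;
    if (elevation_solid_angle) {
      ct0 = cos_max + (1.0 - cos_max) * unif_rand();
    } else {
      ct0 = std::cos(theta_max * unif_rand());
    }
    double st0 = std::sqrt(1.0 - ct0 * ct0);
    double phi0 = two_pi * unif_rand();
    double dx = st0 * std::cos(phi0), dy = st0 * std::sin(phi0), dz = ct0;
    double x = 0.0, y = 0.0, z = 0.0;
    double events = 0.0;
    bool collected = false;

    if (z_h <= 0.0) {
      collected = true;  // empty slab: exits immediately at the origin
    } else {
      for (;;) {
        double step = -std::log(1.0 - unif_rand()) / mu_um;
        double zn = z + dz * step;
        if (dz > 0.0 && zn >= z_h) {     // crosses the surface: truncate, collect
          double t = (z_h - z) / dz;
          x += dx * t; y += dy * t; z = z_h;
          collected = true;
          break;
        }
        if (dz < 0.0 && zn < 0.0) {      // crosses z = 0 backwards: lost
          break;
        }
        x += dx * step; y += dy * step; z = zn;
        double ct = hg_cos(g);
        double st = std::sqrt(1.0 - ct * ct);
        deflect(dx, dy, dz, ct, st, two_pi * unif_rand());
        events += 1.0;
        if (events >= max_events) break;  // pathological walk guard
      }
    }

    if (!collected) { n_lost += 1.0; continue; }
    n_collected += 1.0;
    total_events += events;
    // backproject along the final direction to the z = 0 plane
    double ax, ay;
    if (z <= 0.0) {            // exited at the source plane itself
      ax = x; ay = y;
    } else {
      if (dz <= 0.0) continue; // cannot happen for surface exits; guard anyway
      double t = z / dz;
      ax = x - dx * t; ay = y - dy * t;
    }
    long ix = std::lround(ax / pixel_pitch);
    long iy = std::lround(ay / pixel_pitch);
    if (std::labs(ix) <= halfwidth && std::labs(iy) <= halfwidth) {
      counts(iy + halfwidth, ix + halfwidth) += 1.0;
      n_binned += 1.0;
    }
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["counts"] = counts,
                      _["n_collected"] = n_collected,
                      _["n_lost"] = n_lost,
                      _["n_binned"] = n_binned,
                      _["mean_events"] = n_collected > 0 ?
                        total_events / n_collected : NA_REAL);
}
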