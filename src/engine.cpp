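// Weighted Monte Carlo photon transport in layered turbid slabs.
//
// Conventions: z = 0 at the illuminated surface, increasing into the
// tissue; pencil beam launched at the origin along +z; lengths in mm.
// Absorption is handled by weighting (at each collision the weight is
// multiplied by the single-scattering albedo and the complement is
// deposited as absorbed), scattering angles are Henyey-Greenstein,
// boundaries are planar with unpolarized Fresnel reflection/refraction.
// Detection is by exit radius on the top surface, binned into annuli.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding.  Each photon gets its own
// stream derived from (global seed, photon index), so tallies are
// invariant to batching and adding photons extends rather than reshuffles
// the sequence.
struct Xoshiro256 {
  uint64_t s[4];

  static inline uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed_stream(uint64_t global_seed, uint64_t stream) {
    uint64_t x = global_seed ^ (stream * 0xD2B74407B1CE6E93ULL);
    x += 0x9E3779B97F4A7C15ULL * (stream + 1);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x1ULL;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1]: safe for -log(u)
  inline double unif_pos() {
    return (double)((next() >> 11) + 1) * 0x1.0p-53;
  }
  // uniform on [0, 1)
  inline double unif() {
    return (double)(next() >> 11) * 0x1.0p-53;
  }
};

// Kahan-compensated accumulator for the global weight ledger.
struct Kahan {
  double s = 0.0, c = 0.0;
  inline void add(double v) {
    double y = v - c;
    double t = s + y;
    c = (t - s) - y;
    s = t;
  }
};

struct Slab {
  double z0, z1;        // top/bottom interface depth, mm
  double mus, mua, g, n;
  double mut;           // mus + mua
  double inv_mut;       // 1 / mut (0 if mut == 0)
  double albedo;        // mus / mut (1 if mut == 0)
  double absfrac;       // mua / mut (0 if mut == 0)
  // Henyey-Greenstein sampling constants
  double g2, inv2g, one_m_g2, one_m_g;
};

// Henyey-Greenstein deflection cosine.  g == 0 degenerates to isotropic.
inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Same, with the layer constants precomputed (hot path).
inline double hg_cosine_fast(const Slab& L, double u) {
  if (L.g == 0.0) return 2.0 * u - 1.0;
  const double f = L.one_m_g2 / (L.one_m_g + 2.0 * L.g * u);
  double c = (1.0 + L.g2 - f * f) * L.inv2g;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Random azimuth by rejection (Marsaglia polar trick): returns
// (cos phi, sin phi) uniform on the circle without trig calls.
inline void random_azimuth(Xoshiro256& rng, double& cp, double& sp) {
  double a, b, r2;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    r2 = a * a + b * b;
  } while (r2 > 1.0 || r2 == 0.0);
  cp = (a * a - b * b) / r2;
  sp = 2.0 * a * b / r2;
}

// Update direction after scattering by (cos theta, azimuth).  The
// update is exact for a unit input vector; rounding drift accumulates
// at ~1e-16 per step and stays far below 1e-9 over any photon lifetime,
// so no per-step renormalization is done.
inline void spin_direction(double& ux, double& uy, double& uz,
                           double ct, double cp, double sp) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0) ? ct : -ct;
  } else {
    const double tmp = std::sqrt((1.0 - uz) * (1.0 + uz));
    const double stt = st / tmp;
    const double nux = stt * (ux * uz * cp - uy * sp) + ux * ct;
    const double nuy = stt * (uy * uz * cp + ux * sp) + uy * ct;
    const double nuz = -st * cp * tmp + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
}

// Unpolarized Fresnel reflectance for |cos(th_i)| = ci crossing from
// index ni to nt; ct receives |cos(th_t)|.  Returns 1 on total internal
// reflection.
inline double fresnel_reflectance(double ni, double nt, double ci,
                                  double& ct) {
  if (ni == nt) { ct = ci; return 0.0; }
  if (ci > 1.0) ci = 1.0;
  const double si2 = 1.0 - ci * ci;
  const double st2 = (ni / nt) * (ni / nt) * si2;
  if (st2 >= 1.0) { ct = 0.0; return 1.0; }
  ct = std::sqrt(1.0 - st2);
  if (ci > 0.999999) {  // normal incidence limit
    const double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  const double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  const double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Deposit a straight free flight of length `len` starting at depth z0
// with direction cosine uz into per-depth-slab path buffer `buf`
// (slab k covers [k*vox, (k+1)*vox)).  The remainder trick keeps the
// total deposited exactly equal to len.
inline void deposit_depth(std::vector<double>& buf, int nz, double vox,
                          double z0, double uz, double len,
                          int& tmin, int& tmax) {
  if (len <= 0.0) return;
  // depths are always within [0, ztot], so integer truncation == floor
  auto clampi = [nz](int k) { return k < 0 ? 0 : (k >= nz ? nz - 1 : k); };
  if (std::fabs(uz) < 1e-12) {
    int k = clampi((int)(z0 / vox));
    buf[k] += len;
    if (k < tmin) tmin = k;
    if (k > tmax) tmax = k;
    return;
  }
  const double z1 = z0 + uz * len;
  int ka = clampi((int)(z0 / vox));
  int kb = clampi((int)(z1 / vox));
  if (ka == kb) {
    buf[ka] += len;
  } else if (uz > 0.0) {
    const double inv = 1.0 / uz;
    double used = ((double)(ka + 1) * vox - z0) * inv;
    buf[ka] += used;
    const double per = vox * inv;
    for (int k = ka + 1; k < kb; ++k) { buf[k] += per; used += per; }
    buf[kb] += len - used;
  } else {
    const double inv = -1.0 / uz;
    double used = (z0 - (double)ka * vox) * inv;
    buf[ka] += used;
    const double per = vox * inv;
    for (int k = ka - 1; k > kb; --k) { buf[k] += per; used += per; }
    buf[kb] += len - used;
  }
  if (std::min(ka, kb) < tmin) tmin = std::min(ka, kb);
  if (std::max(ka, kb) > tmax) tmax = std::max(ka, kb);
}

// 3-D voxel traversal (Amanatides & Woo) of the segment p0 -> p1 with
// geometric-length deposition, clipped to the grid box.  Used only for
// detected photons after rotation into the exit plane.
struct Grid3D {
  double xmin, ymin, vox;
  int nx, ny, nz;
  std::vector<double> v;  // nx * ny * nz, x fastest

  inline void deposit(double x0, double y0, double z0,
                      double x1, double y1, double z1, double w) {
    const double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0.0 || w == 0.0) return;
    // clip parameter range to the box (Liang-Barsky)
    double t0 = 0.0, t1 = 1.0;
    const double lo[3] = { xmin, ymin, 0.0 };
    const double hi[3] = { xmin + nx * vox, ymin + ny * vox, nz * vox };
    const double p0[3] = { x0, y0, z0 };
    const double d[3] = { dx, dy, dz };
    for (int a = 0; a < 3; ++a) {
      if (d[a] == 0.0) {
        if (p0[a] < lo[a] || p0[a] >= hi[a]) return;
      } else {
        double ta = (lo[a] - p0[a]) / d[a];
        double tb = (hi[a] - p0[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) return;
      }
    }
    // entry point nudged inwards so floor() lands inside
    const double eps = 1e-12;
    double t = t0;
    double px = x0 + dx * t, py = y0 + dy * t, pz = z0 + dz * t;
    int ix = (int)((px - xmin) / vox + (dx >= 0 ? eps : -eps) + 1.0) - 1;
    int iy = (int)((py - ymin) / vox + (dy >= 0 ? eps : -eps) + 1.0) - 1;
    int iz = (int)(pz / vox + (dz >= 0 ? eps : -eps) + 1.0) - 1;
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);
    const double inf = std::numeric_limits<double>::infinity();
    int sx = dx > 0 ? 1 : -1, sy = dy > 0 ? 1 : -1, sz = dz > 0 ? 1 : -1;
    double tdx = dx != 0 ? std::fabs(vox / dx) : inf;
    double tdy = dy != 0 ? std::fabs(vox / dy) : inf;
    double tdz = dz != 0 ? std::fabs(vox / dz) : inf;
    double tmx = dx != 0
      ? ((xmin + (ix + (dx > 0 ? 1 : 0)) * vox) - x0) / dx : inf;
    double tmy = dy != 0
      ? ((ymin + (iy + (dy > 0 ? 1 : 0)) * vox) - y0) / dy : inf;
    double tmz = dz != 0
      ? (((iz + (dz > 0 ? 1 : 0)) * vox) - z0) / dz : inf;
    while (t < t1) {
      double tn = std::min(std::min(tmx, tmy), std::min(tmz, t1));
      if (tn > t) {
        v[(size_t)iz * nx * ny + (size_t)iy * nx + ix] += w * L * (tn - t);
        t = tn;
      }
      if (t >= t1) break;
      if (tmx <= tmy && tmx <= tmz) {
        ix += sx; tmx += tdx;
        if (ix < 0 || ix >= nx) break;
      } else if (tmy <= tmz) {
        iy += sy; tmy += tdy;
        if (iy < 0 || iy >= ny) break;
      } else {
        iz += sz; tmz += tdz;
        if (iz < 0 || iz >= nz) break;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix layers,  // cols: thickness, mus, mua, g, n
                        double n_ambient_top, double n_ambient_bottom,
                        double n_photons, double seed, double voxel_size,
                        NumericVector ring_edges,
                        int tally_mode,        // 0 = depth_profile, 1 = full_3d
                        bool roulette_on, double roulette_threshold,
                        double roulette_survival, double max_total_path,
                        NumericVector grid_spec,   // xmin, xmax, ymin, ymax (full_3d)
                        IntegerVector grid_rings,  // 0-based rings carrying a 3-D grid
                        int n_records,
                        bool path_hist, double hist_bin, double hist_max) {
  const int nlay = layers.nrow();
  if (nlay < 1) stop("model must have at least one layer");
  std::vector<Slab> lay(nlay);
  double ztot = 0.0;
  for (int i = 0; i < nlay; ++i) {
    Slab& L = lay[i];
    L.z0 = ztot;
    ztot += layers(i, 0);
    L.z1 = ztot;
    L.mus = layers(i, 1);
    L.mua = layers(i, 2);
    L.g = layers(i, 3);
    L.n = layers(i, 4);
    L.mut = L.mus + L.mua;
    L.inv_mut = L.mut > 0.0 ? 1.0 / L.mut : 0.0;
    L.albedo = L.mut > 0.0 ? L.mus / L.mut : 1.0;
    L.absfrac = L.mut > 0.0 ? L.mua / L.mut : 0.0;
    L.g2 = L.g * L.g;
    L.inv2g = L.g > 0.0 ? 0.5 / L.g : 0.0;
    L.one_m_g2 = 1.0 - L.g * L.g;
    L.one_m_g = 1.0 - L.g;
  }
  const int nrings = ring_edges.size() - 1;
  if (nrings < 1) stop("need at least two ring edges");
  const int nz = (int)std::ceil(ztot / voxel_size - 1e-9);
  const int64_t nph = (int64_t)n_photons;

  std::vector<double> detected(nrings, 0.0);
  std::vector<double> pathw((size_t)nrings * nz, 0.0);
  Kahan acc_detected, acc_absorbed, acc_transmitted, acc_escaped,
        acc_specular, acc_lost, acc_roulette;

  // optional 3-D grids (full_3d mode, detected photons only)
  std::vector<Grid3D> grids;
  std::vector<int> ring_grid(nrings, -1);
  if (tally_mode == 1) {
    if (grid_spec.size() != 4) stop("grid_spec must be xmin,xmax,ymin,ymax");
    for (int j = 0; j < grid_rings.size(); ++j) {
      int r = grid_rings[j];
      if (r < 0 || r >= nrings) stop("grid ring index out of range");
      Grid3D g;
      g.xmin = grid_spec[0];
      g.ymin = grid_spec[2];
      g.vox = voxel_size;
      g.nx = (int)std::ceil((grid_spec[1] - grid_spec[0]) / voxel_size - 1e-9);
      g.ny = (int)std::ceil((grid_spec[3] - grid_spec[2]) / voxel_size - 1e-9);
      g.nz = nz;
      g.v.assign((size_t)g.nx * g.ny * g.nz, 0.0);
      ring_grid[r] = (int)grids.size();
      grids.push_back(std::move(g));
    }
  }

  // optional total-path histograms per ring (for absorption reweighting)
  int nbins = 0;
  std::vector<double> hist;
  if (path_hist) {
    nbins = (int)std::ceil(hist_max / hist_bin);
    hist.assign((size_t)nrings * nbins, 0.0);
  }

  // per-photon scratch
  std::vector<double> slab(nz, 0.0);
  std::vector<double> segs;  // x0,y0,z0,x1,y1,z1 per free flight (full_3d)
  if (tally_mode == 1) segs.reserve(6 * 4096);

  // per-photon records (debugging / oracles)
  List records(std::max(n_records, 0));
  const double* edges = REAL(ring_edges);

  Xoshiro256 rng;
  const uint64_t useed = (uint64_t)seed;
  uint64_t n_steps = 0;  // free flights, for performance diagnostics

  for (int64_t ip = 0; ip < nph; ++ip) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed_stream(useed, (uint64_t)ip);

    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int il = 0;
    double w = 1.0;
    double total_path = 0.0;
    double photon_absorbed = 0.0;
    int tmin = nz, tmax = -1;
    if (tally_mode == 1) segs.clear();

    // specular loss at normal incidence on the top surface
    if (n_ambient_top != lay[0].n) {
      const double r0 = (n_ambient_top - lay[0].n) / (n_ambient_top + lay[0].n);
      const double rsp = r0 * r0;
      acc_specular.add(rsp);
      w -= rsp;
    }

    int outcome = -1;       // 0 detected, 1 absorbed-to-roulette, 2 transmitted,
                            // 3 escaped outside rings, 4 path-capped
    double exit_r = NA_REAL;
    int exit_ring = -1;

    for (;;) {
      const Slab& L = lay[il];
      double step;
      if (L.mut > 0.0) {
        step = -std::log(rng.unif_pos()) / L.mut;
      } else {
        step = std::numeric_limits<double>::infinity();
      }
      // distance to the layer interface along uz
      double db;
      if (uz > 1e-15) db = (L.z1 - z) / uz;
      else if (uz < -1e-15) db = (L.z0 - z) / uz;
      else db = std::numeric_limits<double>::infinity();
      ++n_steps;
      const bool hit_boundary = db <= step;
      double travel = hit_boundary ? db : step;
      if (!std::isfinite(travel)) {  // non-interacting medium, no boundary
        outcome = 4;
        acc_lost.add(w);
        break;
      }

      if (total_path + travel > max_total_path) {
        outcome = 4;
        acc_lost.add(w);
        break;
      }

      deposit_depth(slab, nz, voxel_size, z, uz, travel, tmin, tmax);
      if (tally_mode == 1) {
        segs.push_back(x); segs.push_back(y); segs.push_back(z);
        segs.push_back(x + ux * travel);
        segs.push_back(y + uy * travel);
        segs.push_back(z + uz * travel);
      }
      x += ux * travel;
      y += uy * travel;
      z += uz * travel;
      total_path += travel;

      if (hit_boundary) {
        if (uz < 0.0) {
          z = L.z0;  // snap to interface
          const double n_out = (il == 0) ? n_ambient_top : lay[il - 1].n;
          double ct;
          const double R = fresnel_reflectance(L.n, n_out, -uz, ct);
          if (R >= 1.0 || rng.unif() < R) {
            uz = -uz;  // internal reflection
          } else if (il == 0) {
            // exits the top surface: detect by radius
            exit_r = std::sqrt(x * x + y * y);
            const double* hi = std::upper_bound(edges, edges + nrings + 1, exit_r);
            int k = (int)(hi - edges) - 1;
            if (k >= 0 && k < nrings && exit_r >= edges[0]) {
              outcome = 0;
              exit_ring = k;
              detected[k] += w;
              acc_detected.add(w);
              for (int j = tmin; j <= tmax; ++j)
                pathw[(size_t)k * nz + j] += w * slab[j];
              if (path_hist) {
                int b = (int)(total_path / hist_bin);
                if (b >= nbins) b = nbins - 1;
                hist[(size_t)k * nbins + b] += w;
              }
              if (tally_mode == 1 && ring_grid[k] >= 0) {
                Grid3D& G = grids[ring_grid[k]];
                double cphi = 1.0, sphi = 0.0;
                if (exit_r > 1e-12) {
                  cphi = x / exit_r;
                  sphi = y / exit_r;
                }
                for (size_t s = 0; s + 5 < segs.size(); s += 6) {
                  const double ax = segs[s] * cphi + segs[s + 1] * sphi;
                  const double ay = -segs[s] * sphi + segs[s + 1] * cphi;
                  const double bx = segs[s + 3] * cphi + segs[s + 4] * sphi;
                  const double by = -segs[s + 3] * sphi + segs[s + 4] * cphi;
                  G.deposit(ax, ay, segs[s + 2], bx, by, segs[s + 5], w);
                }
              }
            } else {
              outcome = 3;
              acc_escaped.add(w);
            }
            break;
          } else {
            // refract into the layer above
            const double scale = L.n / n_out;
            ux *= scale; uy *= scale;
            uz = ct > 0 ? -ct : -std::fabs(ct);
            const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm; uy /= norm; uz /= norm;
            --il;
          }
        } else {
          z = L.z1;
          const double n_out = (il == nlay - 1) ? n_ambient_bottom : lay[il + 1].n;
          double ct;
          const double R = fresnel_reflectance(L.n, n_out, uz, ct);
          if (R >= 1.0 || rng.unif() < R) {
            uz = -uz;
          } else if (il == nlay - 1) {
            outcome = 2;
            acc_transmitted.add(w);
            break;
          } else {
            const double scale = L.n / n_out;
            ux *= scale; uy *= scale;
            uz = ct;
            const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm; uy /= norm; uz /= norm;
            ++il;
          }
        }
        continue;  // resample free path (memoryless)
      }

      // collision: deposit absorption, survive with the albedo, scatter
      if (L.mua > 0.0) {
        photon_absorbed += w * L.absfrac;
        w *= L.albedo;
      }
      if (roulette_on && w < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          acc_roulette.add(-w * (1.0 - roulette_survival) / roulette_survival);
          w /= roulette_survival;
        } else {
          acc_roulette.add(w);
          outcome = 1;
          break;
        }
      }
      double cp, sp;
      const double ct = hg_cosine_fast(L, rng.unif());
      random_azimuth(rng, cp, sp);
      spin_direction(ux, uy, uz, ct, cp, sp);
    }

    acc_absorbed.add(photon_absorbed);

    if (ip < n_records) {
      NumericVector path(slab.begin(), slab.end());
      records[(R_xlen_t)ip] = List::create(
        _["outcome"] = outcome,
        _["weight"] = w,
        _["exit_radius"] = exit_r,
        _["exit_ring"] = exit_ring >= 0 ? exit_ring + 1 : NA_INTEGER,
        _["total_path"] = total_path,
        _["path_by_slab"] = path);
    }

    // reset scratch
    for (int j = tmin; j <= tmax; ++j) slab[j] = 0.0;
  }

  NumericMatrix pw(nz, nrings);
  for (int k = 0; k < nrings; ++k)
    for (int j = 0; j < nz; ++j)
      pw(j, k) = pathw[(size_t)k * nz + j];

  List out = List::create(
    _["detected_weight_by_ring"] = NumericVector(detected.begin(), detected.end()),
    _["path_weight_by_ring"] = pw,
    _["launched"] = (double)nph,
    _["absorbed_weight"] = acc_absorbed.s,
    _["transmitted_weight"] = acc_transmitted.s,
    _["escaped_outside_weight"] = acc_escaped.s,
    _["specular_weight"] = acc_specular.s,
    _["lost_weight"] = acc_lost.s,
    _["roulette_net_weight"] = acc_roulette.s,
    _["detected_total"] = acc_detected.s,
    _["n_steps"] = (double)n_steps,
    _["n_slabs"] = nz,
    _["total_thickness"] = ztot);

  if (tally_mode == 1) {
    List gl(grids.size());
    IntegerVector gr(grids.size());
    int gi = 0;
    for (int k = 0; k < nrings; ++k) {
      if (ring_grid[k] >= 0) {
        const Grid3D& G = grids[ring_grid[k]];
        NumericVector a(G.v.begin(), G.v.end());
        a.attr("dim") = IntegerVector::create(G.nx, G.ny, G.nz);
        gl[gi] = a;
        gr[gi] = k + 1;
        ++gi;
      }
    }
    out["grid3d_by_ring"] = gl;
    out["grid3d_rings"] = gr;
    out["grid3d_origin"] = NumericVector::create(grid_spec[0], grid_spec[2], 0.0);
  }
  if (path_hist) {
    NumericMatrix hm(nbins, nrings);
    for (int k = 0; k < nrings; ++k)
      for (int b = 0; b < nbins; ++b)
        hm(b, k) = hist[(size_t)k * nbins + b];
    out["path_hist_by_ring"] = hm;
    out["path_hist_bin"] = hist_bin;
  }
  if (n_records > 0) out["photon_records"] = records;
  return out;
}

// [[Rcpp::export]]
List cpp_sample_hg(double n, double g, double seed) {
  const int64_t nn = (int64_t)n;
  NumericVector ct((R_xlen_t)nn), phi((R_xlen_t)nn);
  Xoshiro256 rng;
  for (int64_t i = 0; i < nn; ++i) {
    rng.seed_stream((uint64_t)seed, (uint64_t)i);
    ct[(R_xlen_t)i] = hg_cosine(g, rng.unif());
    double cp, sp;
    random_azimuth(rng, cp, sp);
    double a = std::atan2(sp, cp);
    if (a < 0) a += 2.0 * M_PI;
    phi[(R_xlen_t)i] = a;
  }
  return List::create(_["cos_theta"] = ct, _["azimuth"] = phi);
}
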