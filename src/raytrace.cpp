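#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Voxel grid geometry shared by traversal, simulation and accumulation.
// Voxel (i,j,k) (0-based here, 1-based in R) spans the half-open box
// [x0 + i*v, x0 + (i+1)*v) x ... ; a point on a shared face belongs to the
// voxel being entered.
struct GridGeom {
  double x0, y0, z0, v;
  int nx, ny, nz;
};

struct Seg {
  int ix, iy, iz;   // 0-based
  double t0, t1;    // distances along the ray from the pulse origin
};

static inline bool finite3(double a, double b, double c) {
  return R_finite(a) && R_finite(b) && R_finite(c);
}

// Amanatides & Woo style incremental traversal, clipped to [0, tmax_ray].
static void traverse_core(const GridGeom &g,
                          double ox, double oy, double oz,
                          double dx, double dy, double dz,
                          double tmax_ray,
                          std::vector<Seg> &out) {
  out.clear();
  const double eps = 1e-12;
  double lox = g.x0, hix = g.x0 + g.nx * g.v;
  double loy = g.y0, hiy = g.y0 + g.ny * g.v;
  double loz = g.z0, hiz = g.z0 + g.nz * g.v;

  // Clip the ray to the grid AABB.
  double tmin = 0.0, tmax = tmax_ray;
  const double o[3] = {ox, oy, oz};
  const double d[3] = {dx, dy, dz};
  const double lo[3] = {lox, loy, loz};
  const double hi[3] = {hix, hiy, hiz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < eps) {
      if (o[a] < lo[a] || o[a] >= hi[a]) return;  // parallel and outside slab
    } else {
      double t1 = (lo[a] - o[a]) / d[a];
      double t2 = (hi[a] - o[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  if (tmax <= tmin) return;

  // Start voxel: nudge slightly inside to resolve boundary starts.
  double tstart = tmin;
  double px = ox + (tstart + eps) * dx;
  double py = oy + (tstart + eps) * dy;
  double pz = oz + (tstart + eps) * dz;
  int ix = (int)std::floor((px - g.x0) / g.v);
  int iy = (int)std::floor((py - g.y0) / g.v);
  int iz = (int)std::floor((pz - g.z0) / g.v);
  ix = std::min(std::max(ix, 0), g.nx - 1);
  iy = std::min(std::max(iy, 0), g.ny - 1);
  iz = std::min(std::max(iz, 0), g.nz - 1);

  int step[3];
  double tDelta[3], tNext[3];
  int idx[3] = {ix, iy, iz};
  const int n[3] = {g.nx, g.ny, g.nz};
  const double g0[3] = {g.x0, g.y0, g.z0};
  for (int a = 0; a < 3; ++a) {
    if (d[a] > eps) {
      step[a] = 1;
      tDelta[a] = g.v / d[a];
      tNext[a] = ((g0[a] + (idx[a] + 1) * g.v) - o[a]) / d[a];
    } else if (d[a] < -eps) {
      step[a] = -1;
      tDelta[a] = -g.v / d[a];
      tNext[a] = ((g0[a] + idx[a] * g.v) - o[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = R_PosInf;
      tNext[a] = R_PosInf;
    }
  }

  double t = tstart;
  while (t < tmax - eps) {
    int amin = 0;
    if (tNext[1] < tNext[amin]) amin = 1;
    if (tNext[2] < tNext[amin]) amin = 2;
    double texit = std::min(tNext[amin], tmax);
    if (texit > t + eps) {
      Seg s;
      s.ix = idx[0]; s.iy = idx[1]; s.iz = idx[2];
      s.t0 = t; s.t1 = texit;
      out.push_back(s);
    }
    t = tNext[amin];
    if (t >= tmax - eps) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= n[amin]) break;
    tNext[amin] += tDelta[amin];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_traverse(NumericVector origin, NumericVector direction,
                           NumericVector grid_origin, double voxel_size,
                           IntegerVector dims, double max_range) {
  GridGeom g = {grid_origin[0], grid_origin[1], grid_origin[2], voxel_size,
                dims[0], dims[1], dims[2]};
  std::vector<Seg> segs;
  traverse_core(g, origin[0], origin[1], origin[2],
                direction[0], direction[1], direction[2], max_range, segs);
  NumericMatrix out(segs.size(), 5);
  for (size_t i = 0; i < segs.size(); ++i) {
    out(i, 0) = segs[i].ix + 1;
    out(i, 1) = segs[i].iy + 1;
    out(i, 2) = segs[i].iz + 1;
    out(i, 3) = segs[i].t0;
    out(i, 4) = segs[i].t1;
  }
  colnames(out) = CharacterVector::create("ix", "iy", "iz", "entry", "exit");
  return out;
}

static inline int lin_idx(const GridGeom &g, int ix, int iy, int iz) {
  return ix + g.nx * (iy + g.ny * iz);
}

// Simulate returns for a set of pulses through an attenuation field
// lambda = PAD * G (m^-1). Uses R's RNG so set.seed() governs everything.
// mode: 1 = single return, 2 = multiple returns with continuation prob.
// Ground: analytic plane z = gr0 + grx*x + gry*y; a pulse reaching the plane
// within max_range gets a terminal ground return.
// [[Rcpp::export]]
List cpp_simulate_pulses(NumericMatrix origins, NumericMatrix dirs,
                         NumericVector lambda, NumericVector grid_origin,
                         double voxel_size, IntegerVector dims,
                         double max_range, int mode, double p_continue,
                         int max_returns, NumericVector ground_plane) {
  GridGeom g = {grid_origin[0], grid_origin[1], grid_origin[2], voxel_size,
                dims[0], dims[1], dims[2]};
  const int npulse = origins.nrow();
  const double gr0 = ground_plane[0], grx = ground_plane[1], gry = ground_plane[2];
  std::vector<int> r_pulse, r_index;
  std::vector<double> r_range;
  std::vector<int> r_ground;
  std::vector<Seg> segs;
  int rejected = 0;

  RNGScope scope;
  for (int p = 0; p < npulse; ++p) {
    double ox = origins(p, 0), oy = origins(p, 1), oz = origins(p, 2);
    double dx = dirs(p, 0), dy = dirs(p, 1), dz = dirs(p, 2);
    if (!finite3(ox, oy, oz) || !finite3(dx, dy, dz)) { ++rejected; continue; }
    // Origins must lie inside the scene footprint (x, y); z may be anywhere.
    if (ox < g.x0 || ox >= g.x0 + g.nx * g.v ||
        oy < g.y0 || oy >= g.y0 + g.ny * g.v) { ++rejected; continue; }

    // Ground intersection distance (exact, plane may be tilted).
    double tg = R_PosInf;
    double denom = dz - grx * dx - gry * dy;
    double znum = (gr0 + grx * ox + gry * oy) - oz;
    if (std::fabs(denom) > 1e-12) {
      double tcand = znum / denom;
      if (tcand > 1e-9) tg = tcand;
    }
    double tstop = std::min(tg, max_range);

    traverse_core(g, ox, oy, oz, dx, dy, dz, tstop, segs);

    int nhit = 0;
    double tau_target = -std::log(unif_rand());
    double tau_cum = 0.0;
    bool tracking = true;
    for (size_t s = 0; s < segs.size() && tracking; ++s) {
      double lam = lambda[lin_idx(g, segs[s].ix, segs[s].iy, segs[s].iz)];
      double t0 = segs[s].t0;
      double t1 = segs[s].t1;
      while (tracking) {
        double dtau = lam * (t1 - t0);
        if (tau_cum + dtau < tau_target || lam <= 0.0) {
          tau_cum += dtau;
          break;  // interception not reached inside this stretch
        }
        // Hit inside [t0, t1).
        double thit = t0 + (tau_target - tau_cum) / lam;
        ++nhit;
        r_pulse.push_back(p + 1);
        r_index.push_back(nhit);
        r_range.push_back(thit);
        r_ground.push_back(0);
        if (mode == 1 || nhit >= max_returns || unif_rand() > p_continue) {
          tracking = false;
          break;
        }
        // Continue past the hit with a fresh target depth.
        tau_target = -std::log(unif_rand());
        tau_cum = 0.0;
        t0 = thit;
      }
    }
    if (tracking) {
      // Beam still travelling: ground return if the ray reaches ground.
      if (tg <= max_range) {
        ++nhit;
        r_pulse.push_back(p + 1);
        r_index.push_back(nhit);
        r_range.push_back(tg);
        r_ground.push_back(1);
      } else if (nhit == 0) {
        // no return at all; keep the pulse with a zero marker row
        r_pulse.push_back(p + 1);
        r_index.push_back(0);
        r_range.push_back(NA_REAL);
        r_ground.push_back(0);
      }
    }
  }

  return List::create(_["pulse_id"] = wrap(r_pulse),
                      _["return_index"] = wrap(r_index),
                      _["range_m"] = wrap(r_range),
                      _["is_ground"] = wrap(r_ground),
                      _["n_rejected"] = rejected);
}

// Accumulate per-voxel attenuation statistics from pulse records.
// Pulses are passed as unique-pulse geometry plus a ragged return list
// indexed by offsets (0-based, length npulse+1). Returns must be ordered by
// range within a pulse; a ground return, if present, is last. A pulse with no
// returns has offset[i] == offset[i+1].
// [[Rcpp::export]]
List cpp_accumulate(NumericMatrix origins, NumericMatrix dirs,
                    IntegerVector offsets, NumericVector ret_range,
                    NumericVector ret_fraction, IntegerVector ret_ground,
                    NumericVector grid_origin, double voxel_size,
                    IntegerVector dims, double max_range,
                    bool exclude_ground) {
  GridGeom g = {grid_origin[0], grid_origin[1], grid_origin[2], voxel_size,
                dims[0], dims[1], dims[2]};
  const int npulse = origins.nrow();
  const int nvox = g.nx * g.ny * g.nz;
  NumericVector entering(nvox), intercepted(nvox), free_path(nvox),
      survivor_path(nvox), potential_path(nvox);
  IntegerVector ray_count(nvox);
  int skipped_returns = 0;
  std::vector<Seg> segs;

  for (int p = 0; p < npulse; ++p) {
    double ox = origins(p, 0), oy = origins(p, 1), oz = origins(p, 2);
    double dx = dirs(p, 0), dy = dirs(p, 1), dz = dirs(p, 2);
    int rbeg = offsets[p], rend = offsets[p + 1];

    // Ground return (terminal) truncates the tracked path.
    double tstop = max_range;
    int last_veg = rend;  // exclusive
    bool has_ground = false;
    if (rend > rbeg && ret_ground[rend - 1] == 1) {
      has_ground = true;
      tstop = std::min(tstop, ret_range[rend - 1]);
      last_veg = rend - 1;
    }
    traverse_core(g, ox, oy, oz, dx, dy, dz, tstop, segs);
    if (segs.empty()) continue;
    double t_grid_exit = segs.back().t1;

    double w = 1.0;  // beam fraction still travelling
    int r = rbeg;    // next vegetation return to deposit
    for (size_t s = 0; s < segs.size(); ++s) {
      if (w <= 1e-12) break;
      double t0 = segs[s].t0, t1 = segs[s].t1;
      int vi = lin_idx(g, segs[s].ix, segs[s].iy, segs[s].iz);
      entering[vi] += w;
      ray_count[vi] += 1;
      potential_path[vi] += w * (t1 - t0);
      double w_seg = w;
      // vegetation hits inside [t0, t1)
      while (r < last_veg && ret_range[r] < t1) {
        if (ret_range[r] < t0 - 1e-9) { ++skipped_returns; ++r; continue; }
        double f = ret_fraction[r];
        if (!exclude_ground || ret_ground[r] == 0) {
          intercepted[vi] += f;
          free_path[vi] += f * (ret_range[r] - t0);
        }
        w_seg -= f;
        ++r;
      }
      if (w_seg < 0) w_seg = 0;
      // surviving fraction travels the full (possibly truncated) segment
      survivor_path[vi] += w_seg * (t1 - t0);
      w = w_seg;
    }
    // returns beyond the traversed extent
    while (r < last_veg) {
      if (ret_range[r] > t_grid_exit + 1e-9) ++skipped_returns;
      ++r;
    }
    (void)has_ground;
  }

  return List::create(_["entering_weight"] = entering,
                      _["intercepted_weight"] = intercepted,
                      _["weighted_free_path"] = free_path,
                      _["weighted_survivor_path"] = survivor_path,
                      _["weighted_potential_path"] = potential_path,
                      _["ray_count"] = ray_count,
                      _["skipped_returns"] = skipped_returns);
}

// k-nearest-neighbour inverse distance weighting onto raster cell centres.
// Exact-hit points (distance < 1e-9) are returned verbatim.
// [[Rcpp::export]]
NumericVector cpp_idw(NumericVector cx, NumericVector cy,
                      NumericVector px, NumericVector py, NumericVector pz,
                      int k, double power) {
  const int ncell = cx.size();
  const int npt = px.size();
  const int kk = std::min(k, npt);
  NumericVector out(ncell);
  std::vector<std::pair<double, int> > d(npt);
  for (int c = 0; c < ncell; ++c) {
    for (int i = 0; i < npt; ++i) {
      double ddx = px[i] - cx[c], ddy = py[i] - cy[c];
      d[i] = std::make_pair(ddx * ddx + ddy * ddy, i);
    }
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    if (d[0].first < 1e-18) {
      out[c] = pz[d[0].second];
      continue;
    }
    double wsum = 0.0, zsum = 0.0;
    for (int j = 0; j < kk; ++j) {
      double w = 1.0 / std::pow(std::sqrt(d[j].first), power);
      wsum += w;
      zsum += w * pz[d[j].second];
    }
    out[c] = zsum / wsum;
  }
  return out;
}
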