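#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Spatial hash with cubic cells of side >= 2*(r_max + probe), so that any
// pair of atoms whose extended spheres intersect lies in the same or an
// adjacent cell.  Gives O(N) contact detection for bounded-density systems.
struct CellGrid {
  double side;
  double origin[3];
  int shape[3];
  std::vector<std::vector<int> > cells; // atom indices (0-based) per cell

  int cell_of(double x, double y, double z) const {
    int ix = (int)std::floor((x - origin[0]) / side);
    int iy = (int)std::floor((y - origin[1]) / side);
    int iz = (int)std::floor((z - origin[2]) / side);
    if (ix < 0) ix = 0; if (ix >= shape[0]) ix = shape[0] - 1;
    if (iy < 0) iy = 0; if (iy >= shape[1]) iy = shape[1] - 1;
    if (iz < 0) iz = 0; if (iz >= shape[2]) iz = shape[2] - 1;
    return ix + shape[0] * (iy + shape[1] * iz);
  }
};

static void build_grid(const NumericMatrix &xyz, const NumericVector &radii,
                       double probe, CellGrid &g) {
  const int n = xyz.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (radii[i] > rmax) rmax = radii[i];
  double side = 2.0 * (rmax + probe);
  if (side < 1e-10) side = 1e-10;
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = xyz(0, k); hi[k] = xyz(0, k); }
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (xyz(i, k) < lo[k]) lo[k] = xyz(i, k);
      if (xyz(i, k) > hi[k]) hi[k] = xyz(i, k);
    }
  g.side = side;
  int ncell = 1;
  for (int k = 0; k < 3; ++k) {
    g.origin[k] = lo[k];
    g.shape[k] = (int)std::floor((hi[k] - lo[k]) / side) + 1;
    if (g.shape[k] < 1) g.shape[k] = 1;
    ncell *= g.shape[k];
  }
  g.cells.assign(ncell, std::vector<int>());
  for (int i = 0; i < n; ++i)
    g.cells[g.cell_of(xyz(i, 0), xyz(i, 1), xyz(i, 2))].push_back(i);
}

// Neighbors of atom i: all j != i with ||x_i - x_j|| < r_i + r_j + 2*probe
// (strict: tangent spheres do not occlude).  Ascending index order.
static void grid_neighbors(const CellGrid &g, const NumericMatrix &xyz,
                           const NumericVector &radii, double probe, int i,
                           std::vector<int> &out) {
  out.clear();
  double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
  int ix = (int)std::floor((xi - g.origin[0]) / g.side);
  int iy = (int)std::floor((yi - g.origin[1]) / g.side);
  int iz = (int)std::floor((zi - g.origin[2]) / g.side);
  for (int dx = -1; dx <= 1; ++dx) {
    int cx = ix + dx; if (cx < 0 || cx >= g.shape[0]) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      int cy = iy + dy; if (cy < 0 || cy >= g.shape[1]) continue;
      for (int dz = -1; dz <= 1; ++dz) {
        int cz = iz + dz; if (cz < 0 || cz >= g.shape[2]) continue;
        const std::vector<int> &cell =
          g.cells[cx + g.shape[0] * (cy + g.shape[1] * cz)];
        for (size_t m = 0; m < cell.size(); ++m) {
          int j = cell[m];
          if (j == i) continue;
          double ddx = xi - xyz(j, 0), ddy = yi - xyz(j, 1),
                 ddz = zi - xyz(j, 2);
          double cut = radii[i] + radii[j] + 2.0 * probe;
          if (ddx * ddx + ddy * ddy + ddz * ddz < cut * cut)
            out.push_back(j);
        }
      }
    }
  }
  std::sort(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_cell_list(NumericMatrix xyz, NumericVector radii, double probe) {
  CellGrid g;
  build_grid(xyz, radii, probe, g);
  List membership(g.cells.size());
  for (size_t c = 0; c < g.cells.size(); ++c) {
    IntegerVector v(g.cells[c].size());
    for (size_t m = 0; m < g.cells[c].size(); ++m) v[m] = g.cells[c][m] + 1;
    membership[c] = v;
  }
  return List::create(
    _["cell_side"] = g.side,
    _["origin"] = NumericVector::create(g.origin[0], g.origin[1], g.origin[2]),
    _["grid_shape"] = IntegerVector::create(g.shape[0], g.shape[1], g.shape[2]),
    _["cell_membership"] = membership);
}

// [[Rcpp::export]]
List cpp_neighbor_lists(NumericMatrix xyz, NumericVector radii, double probe) {
  const int n = xyz.nrow();
  CellGrid g;
  build_grid(xyz, radii, probe, g);
  List out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    grid_neighbors(g, xyz, radii, probe, i, nb);
    IntegerVector v(nb.size());
    for (size_t m = 0; m < nb.size(); ++m) v[m] = nb[m] + 1;
    out[i] = v;
  }
  return out;
}

// Coincident-center resolution: the atom with the smaller extended sphere is
// fully buried; on an exact tie the higher-index atom is buried.  Returns
// true if atom i is fully buried by a coincident neighbor, and removes
// coincident neighbors it wins against from nb.
static bool resolve_coincident(const NumericMatrix &xyz,
                               const std::vector<double> &R, int i,
                               std::vector<int> &nb) {
  std::vector<int> kept;
  bool buried = false;
  for (size_t m = 0; m < nb.size(); ++m) {
    int j = nb[m];
    double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
           dz = xyz(i, 2) - xyz(j, 2);
    if (dx == 0.0 && dy == 0.0 && dz == 0.0) {
      if (R[j] > R[i] || (R[j] == R[i] && j < i)) { buried = true; break; }
      // i wins: coincident j cannot occlude any of i's surface
      continue;
    }
    kept.push_back(j);
  }
  if (!buried) nb.swap(kept);
  return buried;
}

// Shrake & Rupley: unit test points (Fibonacci lattice, supplied by caller)
// are scaled to the extended sphere R_i = r_i + probe; a point is accessible
// iff it lies strictly outside every neighbor's extended sphere.
// area_i = (accessible / n_points) * 4 * pi * R_i^2.
// [[Rcpp::export]]
NumericVector cpp_sasa_sr(NumericMatrix xyz, NumericVector radii, double probe,
                          NumericMatrix points) {
  const int n = xyz.nrow(), np = points.nrow();
  NumericVector area(n);
  CellGrid g;
  build_grid(xyz, radii, probe, g);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    grid_neighbors(g, xyz, radii, probe, i, nb);
    if (resolve_coincident(xyz, R, i, nb)) { area[i] = 0.0; continue; }
    const double Ri = R[i];
    // atom-local frame: only center differences enter, so a rigid
    // translation that is exact in floating point leaves results bitwise
    // identical
    const size_t nnb = nb.size();
    std::vector<double> ox(nnb), oy(nnb), oz(nnb), R2(nnb);
    for (size_t m = 0; m < nnb; ++m) {
      int j = nb[m];
      ox[m] = xyz(i, 0) - xyz(j, 0);
      oy[m] = xyz(i, 1) - xyz(j, 1);
      oz[m] = xyz(i, 2) - xyz(j, 2);
      R2[m] = R[j] * R[j];
    }
    int acc = 0;
    for (int k = 0; k < np; ++k) {
      double rx = Ri * points(k, 0);
      double ry = Ri * points(k, 1);
      double rz = Ri * points(k, 2);
      bool ok = true;
      for (size_t m = 0; m < nnb; ++m) {
        double dx = ox[m] + rx, dy = oy[m] + ry, dz = oz[m] + rz;
        if (dx * dx + dy * dy + dz * dz <= R2[m]) { ok = false; break; }
      }
      if (ok) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * ((double)acc / (double)np);
  }
  return area;
}

// Lee & Richards: each atom's extended sphere is sliced individually into
// n_slices slabs; at each slab midpoint the exposed arc of the atom's circle
// is found by merging the angular intervals buried by neighbor circles in
// that plane; the exposed fraction contributes an Archimedes strip
// f * 2 * pi * R_i * dz.  Exact for an isolated sphere at any slice count.
// [[Rcpp::export]]
NumericVector cpp_sasa_lr(NumericMatrix xyz, NumericVector radii, double probe,
                          int n_slices) {
  const int n = xyz.nrow();
  NumericVector area(n);
  CellGrid g;
  build_grid(xyz, radii, probe, g);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  std::vector<int> nb;
  std::vector<std::pair<double, double> > arcs;
  const double TWOPI = 2.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    grid_neighbors(g, xyz, radii, probe, i, nb);
    if (resolve_coincident(xyz, R, i, nb)) { area[i] = 0.0; continue; }
    const double Ri = R[i];
    const double dz = 2.0 * Ri / n_slices;
    // atom-local frame (see S&R above): slab heights are relative to the
    // atom center and neighbors enter through center differences only
    const size_t nnb = nb.size();
    std::vector<double> ndx(nnb), ndy(nnb), ndz(nnb), nd(nnb);
    for (size_t m = 0; m < nnb; ++m) {
      int j = nb[m];
      ndx[m] = xyz(j, 0) - xyz(i, 0);
      ndy[m] = xyz(j, 1) - xyz(i, 1);
      ndz[m] = xyz(j, 2) - xyz(i, 2);
      nd[m] = std::sqrt(ndx[m] * ndx[m] + ndy[m] * ndy[m]);
    }
    double a = 0.0;
    for (int s = 0; s < n_slices; ++s) {
      double zi = -Ri + (s + 0.5) * dz;                  // slab midpoint, local
      double rho2_i = Ri * Ri - zi * zi;
      if (rho2_i <= 0.0) continue;                       // cannot happen at midpoints
      double rho_i = std::sqrt(rho2_i);
      arcs.clear();
      bool full_buried = false;
      for (size_t m = 0; m < nnb; ++m) {
        int j = nb[m];
        double zj = zi - ndz[m];
        if (std::fabs(zj) >= R[j]) continue;             // neighbor misses this plane
        double rho_j = std::sqrt(R[j] * R[j] - zj * zj);
        double dx = ndx[m], dy = ndy[m];
        double d = nd[m];
        if (d >= rho_i + rho_j) continue;                // disjoint circles
        if (d + rho_i <= rho_j) { full_buried = true; break; } // circle swallowed
        if (d + rho_j <= rho_i) continue;                // inner circle, boundary free
        double carg = (d * d + rho2_i - rho_j * rho_j) / (2.0 * d * rho_i);
        if (carg > 1.0) carg = 1.0;
        if (carg < -1.0) carg = -1.0;
        double alpha = std::acos(carg);                  // buried half-width
        double mid = std::atan2(dy, dx);
        double lo = mid - alpha, hi = mid + alpha;
        // normalize to [0, 2*pi), split wrap-around intervals
        while (lo < 0.0) { lo += TWOPI; hi += TWOPI; }
        if (hi > TWOPI) {
          arcs.push_back(std::make_pair(lo, TWOPI));
          arcs.push_back(std::make_pair(0.0, hi - TWOPI));
        } else {
          arcs.push_back(std::make_pair(lo, hi));
        }
      }
      if (full_buried) continue;
      double buried = 0.0;
      if (!arcs.empty()) {
        std::sort(arcs.begin(), arcs.end());
        double cur_lo = arcs[0].first, cur_hi = arcs[0].second;
        for (size_t m = 1; m < arcs.size(); ++m) {
          if (arcs[m].first <= cur_hi) {
            if (arcs[m].second > cur_hi) cur_hi = arcs[m].second;
          } else {
            buried += cur_hi - cur_lo;
            cur_lo = arcs[m].first;
            cur_hi = arcs[m].second;
          }
        }
        buried += cur_hi - cur_lo;
        if (buried > TWOPI) buried = TWOPI;
      }
      a += (TWOPI - buried) * Ri * dz;
    }
    area[i] = a;
  }
  return area;
}
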