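#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list neighbor search for orthorhombic (or absent) boxes.
// Distances use the minimum-image convention when a box is supplied;
// callers must guarantee cutoff < min(box)/2 (checked on the R side).

namespace {

struct CellGrid {
  // Bins reference points into a 3D grid with cell edge >= cutoff.
  std::vector<std::vector<int>> cells;
  int nx, ny, nz;
  double ox, oy, oz;      // origin (non-periodic) -- unused for PBC
  double cx, cy, cz;      // cell edge lengths
  bool periodic;
  double bx, by, bz;      // box edges (periodic only)

  CellGrid(const NumericMatrix& pts, double cutoff,
           const NumericVector& box) {
    periodic = box.size() == 3;
    if (periodic) {
      bx = box[0]; by = box[1]; bz = box[2];
      nx = std::max(1, (int)std::floor(bx / cutoff));
      ny = std::max(1, (int)std::floor(by / cutoff));
      nz = std::max(1, (int)std::floor(bz / cutoff));
      cx = bx / nx; cy = by / ny; cz = bz / nz;
      ox = oy = oz = 0.0;
    } else {
      double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
      double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
      for (int i = 0; i < pts.nrow(); ++i) {
        xmin = std::min(xmin, pts(i,0)); xmax = std::max(xmax, pts(i,0));
        ymin = std::min(ymin, pts(i,1)); ymax = std::max(ymax, pts(i,1));
        zmin = std::min(zmin, pts(i,2)); zmax = std::max(zmax, pts(i,2));
      }
      ox = xmin; oy = ymin; oz = zmin;
      nx = std::max(1, (int)std::floor((xmax - xmin) / cutoff) + 1);
      ny = std::max(1, (int)std::floor((ymax - ymin) / cutoff) + 1);
      nz = std::max(1, (int)std::floor((zmax - zmin) / cutoff) + 1);
      cx = cy = cz = cutoff;
      bx = by = bz = 0.0;
    }
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < pts.nrow(); ++i)
      cells[index_of(pts(i,0), pts(i,1), pts(i,2))].push_back(i);
  }

  inline int wrap(int k, int n) const { return ((k % n) + n) % n; }

  inline size_t index_of(double x, double y, double z) const {
    int ix, iy, iz;
    if (periodic) {
      ix = wrap((int)std::floor(x / cx), nx);
      iy = wrap((int)std::floor(y / cy), ny);
      iz = wrap((int)std::floor(z / cz), nz);
    } else {
      ix = std::min(nx - 1, std::max(0, (int)std::floor((x - ox) / cx)));
      iy = std::min(ny - 1, std::max(0, (int)std::floor((y - oy) / cy)));
      iz = std::min(nz - 1, std::max(0, (int)std::floor((z - oz) / cz)));
    }
    return ((size_t)ix * ny + iy) * nz + iz;
  }

  inline double dist2(double x1, double y1, double z1,
                      double x2, double y2, double z2) const {
    double dx = x1 - x2, dy = y1 - y2, dz = z1 - z2;
    if (periodic) {
      dx -= bx * std::round(dx / bx);
      dy -= by * std::round(dy / by);
      dz -= bz * std::round(dz / bz);
    }
    return dx * dx + dy * dy + dz * dz;
  }

  // Visit all reference points in the 27 cells around (x, y, z).
  template <typename F>
  void visit_neighbors(double x, double y, double z, F fn) const {
    int ix0, iy0, iz0;
    if (periodic) {
      ix0 = wrap((int)std::floor(x / cx), nx);
      iy0 = wrap((int)std::floor(y / cy), ny);
      iz0 = wrap((int)std::floor(z / cz), nz);
    } else {
      ix0 = (int)std::floor((x - ox) / cx);
      iy0 = (int)std::floor((y - oy) / cy);
      iz0 = (int)std::floor((z - oz) / cz);
    }
    // With few cells along an axis the 27-stencil would revisit the same
    // wrapped cell; clamp the stencil width to the cell count.
    int wx = std::min(1, nx - 1), wy = std::min(1, ny - 1), wz = std::min(1, nz - 1);
    if (periodic && nx <= 2) wx = nx - 1;
    if (periodic && ny <= 2) wy = ny - 1;
    if (periodic && nz <= 2) wz = nz - 1;
    std::unordered_set<size_t> seen;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int ix = ix0 + dx, iy = iy0 + dy, iz = iz0 + dz;
          if (periodic) {
            ix = wrap(ix, nx); iy = wrap(iy, ny); iz = wrap(iz, nz);
          } else {
            if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
              continue;
          }
          size_t ci = ((size_t)ix * ny + iy) * nz + iz;
          if (!seen.insert(ci).second) continue;
          for (int j : cells[ci]) fn(j);
        }
  }
};

} // namespace

//' @name cpp_water_counts
//' @noRd
// [[Rcpp::export]]
List cpp_water_counts(NumericMatrix solute, IntegerVector solute_res,
                      NumericMatrix water, IntegerVector water_mol,
                      double cutoff, NumericVector box, int n_res) {
  CellGrid grid(solute, cutoff, box);
  double cut2 = cutoff * cutoff;

  int n_mol = 0;
  for (int i = 0; i < water_mol.size(); ++i)
    n_mol = std::max(n_mol, water_mol[i] + 1);

  // residue sets per water molecule, as flat flags: n_mol x n_res is too big
  // in general; use a per-molecule set.
  std::vector<std::unordered_set<int>> mol_res(n_mol);

  for (int w = 0; w < water.nrow(); ++w) {
    double x = water(w,0), y = water(w,1), z = water(w,2);
    int m = water_mol[w];
    grid.visit_neighbors(x, y, z, [&](int j) {
      if (grid.dist2(x, y, z, solute(j,0), solute(j,1), solute(j,2)) < cut2)
        mol_res[m].insert(solute_res[j]);
    });
  }

  int chain = 0;
  IntegerVector per_res(n_res);
  for (int m = 0; m < n_mol; ++m) {
    if (!mol_res[m].empty()) ++chain;
    for (int r : mol_res[m])
      if (r >= 0 && r < n_res) per_res[r] += 1;  // r < 0: chain-only atoms
  }
  return List::create(_["chain"] = chain, _["per_residue"] = per_res);
}

//' @name cpp_contact_count
//' @noRd
// [[Rcpp::export]]
int cpp_contact_count(NumericMatrix xyz, IntegerVector res,
                      double cutoff, int min_sep, NumericVector box) {
  CellGrid grid(xyz, cutoff, box);
  double cut2 = cutoff * cutoff;
  std::unordered_set<long long> pairs;
  int n = xyz.nrow();
  for (int i = 0; i < n; ++i) {
    double x = xyz(i,0), y = xyz(i,1), z = xyz(i,2);
    int ri = res[i];
    grid.visit_neighbors(x, y, z, [&](int j) {
      if (j <= i) return;
      int rj = res[j];
      int sep = ri > rj ? ri - rj : rj - ri;
      if (sep < min_sep) return;
      if (grid.dist2(x, y, z, xyz(j,0), xyz(j,1), xyz(j,2)) < cut2) {
        int lo = std::min(ri, rj), hi = std::max(ri, rj);
        pairs.insert((long long)lo * 1000000LL + hi);
      }
    });
  }
  return (int)pairs.size();
}
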