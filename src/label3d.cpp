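#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass 26-connected (8-connected when nz == 1) component labelling of a
// logical (y, x, z) array stored column-major. Returns integer labels 1..K in
// scan order, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask size does not match dims");

  IntegerVector labels(n, 0);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // Half neighbourhood: offsets (dy, dx, dz) that precede the current voxel
  // in scan order (dz<0, or dz==0 && dx<0, or dz==0 && dx==0 && dy<0).
  int offs[13][3]; int noff = 0;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dz > 0) continue;
        if (dz == 0 && (dx > 0 || (dx == 0 && dy >= 0))) continue;
        offs[noff][0] = dy; offs[noff][1] = dx; offs[noff][2] = dz; ++noff;
      }

  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t idx = (R_xlen_t)y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
        if (!mask[idx]) continue;
        int lab = 0;
        for (int k = 0; k < noff; ++k) {
          int yy = y + offs[k][0], xx = x + offs[k][1], zz = z + offs[k][2];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0) continue;
          R_xlen_t nidx = (R_xlen_t)yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
          int nl = labels[nidx];
          if (nl > 0) {
            if (lab == 0) lab = nl;
            else uf_union(parent, lab, nl);
          }
        }
        if (lab == 0) {
          parent.push_back(next);
          lab = next++;
        }
        labels[idx] = lab;
      }
    }
  }

  // Compact to 1..K in order of first appearance of each root.
  std::vector<int> compact(next, 0);
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = labels[i];
    if (l == 0) continue;
    int r = uf_find(parent, l);
    if (compact[r] == 0) compact[r] = ++k;
    labels[i] = compact[r];
  }
  return labels;
}
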