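// 3D curve thinning by sequential simple-point removal.
//
// A foreground voxel is "simple" when its removal preserves topology:
//  (1) exactly one 26-connected foreground component in the 3x3x3
//      neighbourhood (centre excluded), and
//  (2) exactly one 6-connected background component within the
//      18-neighbourhood that touches the centre's 6-neighbours.
// Curve endpoints (<= 1 foreground neighbour) are never removed, so vessel
// centrelines survive. Voxels are peeled in order of increasing city-block
// distance to the background, so the surviving curve lies on the medial
// axis; removal is sequential, re-checking topology as the surface erodes.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-neighbourhood occupancy of (x,y,z); nb[dz+1][dy+1][dx+1]
void neighbourhood(const LogicalVector &img, int x, int y, int z,
                   int nx, int ny, int nz, int nb[3][3][3]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = img[idx3(xx, yy, zz, nx, ny)];
        nb[dz + 1][dy + 1][dx + 1] = v ? 1 : 0;
      }
  nb[1][1][1] = 0; // centre excluded
}

int count_neighbours(const int nb[3][3][3]) {
  int n = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) n += nb[a][b][c];
  return n;
}

// label 26-connected foreground components in the 3x3x3 neighbourhood
int fg_components(const int nb[3][3][3]) {
  int lab[27]; for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    int z = i / 9, y = (i / 3) % 3, x = i % 3;
    if (!nb[z][y][x] || lab[i]) continue;
    ++ncomp;
    int top = 0; stack[top++] = i; lab[i] = ncomp;
    while (top) {
      int j = stack[--top];
      int zj = j / 9, yj = (j / 3) % 3, xj = j % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = zj + dz, yy = yj + dy, xx = xj + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            int k = xx + 3 * yy + 9 * zz;
            if (nb[zz][yy][xx] && !lab[k]) { lab[k] = ncomp; stack[top++] = k; }
          }
    }
  }
  return ncomp;
}

// 6-connected background components within the 18-neighbourhood that touch
// a 6-neighbour of the centre
int bg_components(const int nb[3][3][3]) {
  // 18-neighbourhood: positions with |dx|+|dy|+|dz| <= 2, excluding centre
  // and corners
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int z = i / 9 - 1, y = (i / 3) % 3 - 1, x = i % 3 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m >= 1 && m <= 2);
  }
  int lab[27]; for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 6; ++s) {
    int x = d6[s][0] + 1, y = d6[s][1] + 1, z = d6[s][2] + 1;
    int i = x + 3 * y + 9 * z;
    if (nb[z][y][x] || lab[i]) continue;   // foreground or already labelled
    ++ncomp;
    int top = 0; stack[top++] = i; lab[i] = ncomp;
    while (top) {
      int j = stack[--top];
      int zj = j / 9, yj = (j / 3) % 3, xj = j % 3;
      for (int s2 = 0; s2 < 6; ++s2) {
        int xx = xj + d6[s2][0], yy = yj + d6[s2][1], zz = zj + d6[s2][2];
        if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
        int k = xx + 3 * yy + 9 * zz;
        if (!in18[k] || nb[zz][yy][xx] || lab[k]) continue;
        lab[k] = ncomp; stack[top++] = k;
      }
    }
  }
  return ncomp;
}

inline bool is_simple(const LogicalVector &img, int x, int y, int z,
                      int nx, int ny, int nz) {
  int nb[3][3][3];
  neighbourhood(img, x, y, z, nx, ny, nz, nb);
  return fg_components(nb) == 1 && bg_components(nb) == 1;
}

} // namespace

// [[Rcpp::export(name = ".skeleton3d_cpp")]]
LogicalVector skeleton3d_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  LogicalVector img = clone(mask);
  // city-block distance to background by BFS (6-connectivity)
  std::vector<int> dist(n, -1);
  std::vector<int> frontier, next;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!img[i]) { dist[i] = 0; continue; }
        bool border = (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
                       z == 0 || z == nz - 1);
        if (!border)
          for (int s = 0; s < 6 && !border; ++s)
            border = !img[idx3(x + d6[s][0], y + d6[s][1], z + d6[s][2],
                               nx, ny)];
        if (border) { dist[i] = 1; frontier.push_back(i); }
      }
  int level = 1;
  while (!frontier.empty()) {
    next.clear();
    for (size_t q = 0; q < frontier.size(); ++q) {
      int i = frontier[q];
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (int s = 0; s < 6; ++s) {
        int xx = x + d6[s][0], yy = y + d6[s][1], zz = z + d6[s][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (img[j] && dist[j] < 0) { dist[j] = level + 1; next.push_back(j); }
      }
    }
    frontier.swap(next);
    ++level;
  }
  // distance-ordered sequential thinning: peel simple, non-endpoint voxels
  // from the outside in so the surviving curve sits on the medial axis
  int maxd = 1;
  for (int i = 0; i < n; ++i) if (dist[i] > maxd) maxd = dist[i];
  std::vector< std::vector<int> > buckets(maxd + 1);
  for (int i = 0; i < n; ++i) if (img[i]) buckets[dist[i]].push_back(i);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dlev = 1; dlev <= maxd; ++dlev) {
      std::vector<int> &bk = buckets[dlev];
      for (size_t q = 0; q < bk.size(); ++q) {
        int i = bk[q];
        if (!img[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        int nb[3][3][3];
        neighbourhood(img, x, y, z, nx, ny, nz, nb);
        if (count_neighbours(nb) <= 1) continue;      // endpoint: keep
        if (fg_components(nb) == 1 && bg_components(nb) == 1) {
          img[i] = false;
          changed = true;
        }
      }
    }
  }
  return img;
}
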