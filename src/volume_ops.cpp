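#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Voxel layout throughout: x fastest, idx = x + nx*(y + ny*z), 0-based.

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long long)ny * z);
}

// ---------------------------------------------------------------------------
// Tube rasterization: paint capsules (segments with radius) into an intensity
// volume (max-composited) and a class label volume with fixed priority
// fiber(1) > appendage(3) > epidermal_af(2) > background(0).
// ---------------------------------------------------------------------------

static inline int label_prio(int lab) {
  switch (lab) {
    case 1: return 3;
    case 3: return 2;
    case 2: return 1;
    default: return 0;
  }
}

// [[Rcpp::export]]
void cpp_paint_capsules(NumericVector vol, IntegerVector labels,
                        IntegerVector dims, NumericVector voxel,
                        NumericMatrix a, NumericMatrix b,
                        NumericVector radius, NumericVector value,
                        IntegerVector cls) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const int nseg = a.nrow();
  for (int s = 0; s < nseg; ++s) {
    const double ax = a(s,0), ay = a(s,1), az = a(s,2);
    const double bx = b(s,0), by = b(s,1), bz = b(s,2);
    const double r = radius[s];
    const double lox = std::min(ax,bx) - r, hix = std::max(ax,bx) + r;
    const double loy = std::min(ay,by) - r, hiy = std::max(ay,by) + r;
    const double loz = std::min(az,bz) - r, hiz = std::max(az,bz) + r;
    int x0 = std::max(0, (int)std::floor(lox / vx));
    int x1 = std::min(nx - 1, (int)std::ceil(hix / vx));
    int y0 = std::max(0, (int)std::floor(loy / vy));
    int y1 = std::min(ny - 1, (int)std::ceil(hiy / vy));
    int z0 = std::max(0, (int)std::floor(loz / vz));
    int z1 = std::min(nz - 1, (int)std::ceil(hiz / vz));
    const double dx = bx - ax, dy = by - ay, dz = bz - az;
    const double len2 = dx*dx + dy*dy + dz*dz;
    const double r2 = r * r;
    for (int z = z0; z <= z1; ++z) {
      const double pz = z * vz;
      for (int y = y0; y <= y1; ++y) {
        const double py = y * vy;
        for (int x = x0; x <= x1; ++x) {
          const double px = x * vx;
          double t = 0.0;
          if (len2 > 0) {
            t = ((px-ax)*dx + (py-ay)*dy + (pz-az)*dz) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          const double qx = ax + t*dx - px, qy = ay + t*dy - py,
                       qz = az + t*dz - pz;
          if (qx*qx + qy*qy + qz*qz <= r2) {
            const int id = vidx(x, y, z, nx, ny);
            if (value[s] > vol[id]) vol[id] = value[s];
            if (label_prio(cls[s]) > label_prio(labels[id]))
              labels[id] = cls[s];
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma in voxels per axis, truncated at 3 sigma.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int half = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * half + 1);
  double ksum = 0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + half];
  }
  for (double &w : k) w /= ksum;
  const int n[3] = {nx, ny, nz};
  const long long stride[3] = {1, nx, (long long)nx * ny};
  const int len = n[axis];
  const long long st = stride[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[o2]; ++j2) {
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      long long base = stride[o1] * j1 + stride[o2] * j2;
      for (int i = 0; i < len; ++i) line[i] = v[base + st * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -half; t <= half; ++t) {
          int ii = i + t;
          if (ii < 0) ii = 0;
          if (ii >= len) ii = len - 1;
          acc += k[t + half] * line[ii];
        }
        v[base + st * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dims,
                               NumericVector sigma_vox) {
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, dims[0], dims[1], dims[2], 0, sigma_vox[0]);
  blur_axis(v, dims[0], dims[1], dims[2], 1, sigma_vox[1]);
  blur_axis(v, dims[0], dims[1], dims[2], 2, sigma_vox[2]);
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// Anisotropic chamfer distance transform: distance (um) from each foreground
// voxel to the nearest background voxel, two-pass over the 26-neighbourhood.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_chamfer3d(IntegerVector mask, IntegerVector dims,
                            NumericVector voxel, bool outside_bg = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double BIG = 1e18;
  const long long n = (long long)nx * ny * nz;
  NumericVector d(n);
  for (long long i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;
  // neighbour offsets with negative lexicographic order (forward pass set)
  std::vector<std::array<int,3>> fwd;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        fwd.push_back({dx, dy, dz});
      }
  std::vector<double> w(fwd.size());
  for (size_t k = 0; k < fwd.size(); ++k) {
    double ddx = fwd[k][0]*voxel[0], ddy = fwd[k][1]*voxel[1],
           ddz = fwd[k][2]*voxel[2];
    w[k] = std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
  }
  // half-voxel offset so surface voxels get ~half a voxel of distance
  const double surf = 0.5 * std::min(voxel[0], std::min(voxel[1], voxel[2]));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int id = vidx(x,y,z,nx,ny);
        if (!mask[id]) continue;
        double best = d[id];
        for (size_t k = 0; k < fwd.size(); ++k) {
          int xx = x + fwd[k][0], yy = y + fwd[k][1], zz = z + fwd[k][2];
          double nb;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            nb = outside_bg ? 0.0 : BIG;
          else
            nb = d[vidx(xx,yy,zz,nx,ny)];
          if (nb + w[k] < best) best = nb + w[k];
        }
        d[id] = best;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        const int id = vidx(x,y,z,nx,ny);
        if (!mask[id]) continue;
        double best = d[id];
        for (size_t k = 0; k < fwd.size(); ++k) {
          int xx = x - fwd[k][0], yy = y - fwd[k][1], zz = z - fwd[k][2];
          double nb;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            nb = outside_bg ? 0.0 : BIG;
          else
            nb = d[vidx(xx,yy,zz,nx,ny)];
          if (nb + w[k] < best) best = nb + w[k];
        }
        d[id] = best;
      }
  for (long long i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    if (d[i] >= BIG / 2) d[i] = R_PosInf; else d[i] += surf;
  }
  return d;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_cc26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long long> stack;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((long long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x+dx, yy = y+dy, zz = z+dz;
            if (xx < 0 || yy < 0 || zz < 0 ||
                xx >= nx || yy >= ny || zz >= nz) continue;
            long long id = vidx(xx,yy,zz,nx,ny);
            if (mask[id] && !lab[id]) { lab[id] = next; stack.push_back(id); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 3D curve thinning: sequential deletion of simple border points, six
// directional sub-iterations, preserving curve endpoints, until stable.
// Simplicity via the topological-number criterion: exactly one 26-connected
// foreground component in the punctured 26-neighbourhood and exactly one
// 6-connected background component in the 18-neighbourhood touching the
// centre by a 6-face.
// ---------------------------------------------------------------------------

static int n26_offsets[26][3];
static bool n26_init_done = false;
static void init_n26() {
  if (n26_init_done) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        n26_offsets[k][0] = dx; n26_offsets[k][1] = dy; n26_offsets[k][2] = dz;
        ++k;
      }
  n26_init_done = true;
}

// neighbourhood cube nb[3][3][3], centre at [1][1][1]
static bool is_simple(const int nb[27]) {
  // nb indexed (dx+1) + 3*(dy+1) + 9*(dz+1)
  // --- foreground 26-components in punctured neighbourhood ---
  int compF[27];
  for (int i = 0; i < 27; ++i) compF[i] = 0;
  int ncf = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || compF[i]) continue;
    ++ncf;
    std::vector<int> st{i};
    compF[i] = ncf;
    while (!st.empty()) {
      int cur = st.back(); st.pop_back();
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int k = 0; k < 26; ++k) {
        int xx = cx + n26_offsets[k][0], yy = cy + n26_offsets[k][1],
            zz = cz + n26_offsets[k][2];
        if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1)
          continue;
        int j = (xx+1) + 3*(yy+1) + 9*(zz+1);
        if (j == 13 || !nb[j] || compF[j]) continue;
        compF[j] = ncf;
        st.push_back(j);
      }
    }
  }
  if (ncf != 1) return false;
  // --- background 6-components within N18, seeded from 6-neighbours ---
  auto in18 = [](int dx, int dy, int dz) {
    return std::abs(dx) + std::abs(dy) + std::abs(dz) <= 2 &&
           !(dx == 0 && dy == 0 && dz == 0);
  };
  int compB[27];
  for (int i = 0; i < 27; ++i) compB[i] = 0;
  int ncb = 0;
  const int six[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int s = 0; s < 6; ++s) {
    int i = (six[s][0]+1) + 3*(six[s][1]+1) + 9*(six[s][2]+1);
    if (nb[i] || compB[i]) continue;
    ++ncb;
    std::vector<int> st{i};
    compB[i] = ncb;
    while (!st.empty()) {
      int cur = st.back(); st.pop_back();
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int s2 = 0; s2 < 6; ++s2) {
        int xx = cx + six[s2][0], yy = cy + six[s2][1], zz = cz + six[s2][2];
        if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1)
          continue;
        if (!in18(xx, yy, zz)) continue;
        int j = (xx+1) + 3*(yy+1) + 9*(zz+1);
        if (nb[j] || compB[j]) continue;
        compB[j] = ncb;
        st.push_back(j);
      }
    }
  }
  return ncb == 1;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask_in, IntegerVector dims) {
  init_n26();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector mask = clone(mask_in);
  auto get = [&](int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return mask[vidx(x,y,z,nx,ny)];
  };
  auto fill_nb = [&](int x, int y, int z, int nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[(dx+1) + 3*(dy+1) + 9*(dz+1)] = get(x+dx, y+dy, z+dz);
  };
  auto count26 = [&](int x, int y, int z) {
    int c = 0;
    for (int k = 0; k < 26; ++k)
      c += get(x + n26_offsets[k][0], y + n26_offsets[k][1],
               z + n26_offsets[k][2]);
    return c;
  };
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  std::vector<long long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const long long id = vidx(x,y,z,nx,ny);
            if (!mask[id]) continue;
            if (get(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            int nc = count26(x, y, z);
            if (nc <= 1) continue;  // endpoint or isolated: keep
            cand.push_back(id);
          }
      for (long long id : cand) {
        int x = id % nx, y = (id / nx) % ny, z = id / ((long long)nx * ny);
        if (count26(x, y, z) <= 1) continue;
        int nb[27];
        fill_nb(x, y, z, nb);
        if (is_simple(nb)) {
          mask[id] = 0;
          changed = true;
        }
      }
    }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Uniform-grid nearest neighbour: for each query point, index (1-based) and
// distance of the nearest reference point.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_grid_nn(NumericMatrix ref, NumericMatrix query, double cell) {
  const int nr = ref.nrow(), nq = query.nrow();
  IntegerVector out_idx(nq, NA_INTEGER);
  NumericVector out_dist(nq, R_PosInf);
  if (nr == 0 || nq == 0) return List::create(_["idx"] = out_idx,
                                              _["dist"] = out_dist);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i,d));
      hi[d] = std::max(hi[d], ref(i,d));
    }
  int gd[3];
  for (int d = 0; d < 3; ++d)
    gd[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  auto cell_of = [&](double v, int d) {
    int c = (int)std::floor((v - lo[d]) / cell);
    return std::max(0, std::min(gd[d] - 1, c));
  };
  std::vector<std::vector<int>> buckets((size_t)gd[0] * gd[1] * gd[2]);
  auto bidx = [&](int cx, int cy, int cz) {
    return (size_t)cx + (size_t)gd[0] * (cy + (size_t)gd[1] * cz);
  };
  for (int i = 0; i < nr; ++i)
    buckets[bidx(cell_of(ref(i,0),0), cell_of(ref(i,1),1),
                 cell_of(ref(i,2),2))].push_back(i);
  const int maxring = std::max(gd[0], std::max(gd[1], gd[2]));
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    const int cx = cell_of(qx,0), cy = cell_of(qy,1), cz = cell_of(qz,2);
    double best = R_PosInf;
    int besti = -1;
    for (int ring = 0; ring <= maxring; ++ring) {
      if (besti >= 0 && best <= (ring - 1) * cell) break;
      for (int dz = -ring; dz <= ring; ++dz) {
        int zz = cz + dz;
        if (zz < 0 || zz >= gd[2]) continue;
        for (int dy = -ring; dy <= ring; ++dy) {
          int yy = cy + dy;
          if (yy < 0 || yy >= gd[1]) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)))
                != ring) continue;
            int xx = cx + dx;
            if (xx < 0 || xx >= gd[0]) continue;
            for (int i : buckets[bidx(xx,yy,zz)]) {
              double ddx = ref(i,0)-qx, ddy = ref(i,1)-qy, ddz = ref(i,2)-qz;
              double dd = std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
              if (dd < best) { best = dd; besti = i; }
            }
          }
        }
      }
    }
    out_idx[q] = besti + 1;
    out_dist[q] = best;
  }
  return List::create(_["idx"] = out_idx, _["dist"] = out_dist);
}

// ---------------------------------------------------------------------------
// Trilinear sampling at continuous 0-based voxel coordinates; outside -> fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = std::min((int)std::floor(x), nx - 2 < 0 ? 0 : nx - 2);
    int y0 = std::min((int)std::floor(y), ny - 2 < 0 ? 0 : ny - 2);
    int z0 = std::min((int)std::floor(z), nz - 2 < 0 ? 0 : nz - 2);
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    auto V = [&](int a, int b, int c) {
      return vol[vidx(std::min(a, nx-1), std::min(b, ny-1),
                      std::min(c, nz-1), nx, ny)];
    };
    double c00 = V(x0,y0,z0)*(1-fx) + V(x0+1,y0,z0)*fx;
    double c10 = V(x0,y0+1,z0)*(1-fx) + V(x0+1,y0+1,z0)*fx;
    double c01 = V(x0,y0,z0+1)*(1-fx) + V(x0+1,y0,z0+1)*fx;
    double c11 = V(x0,y0+1,z0+1)*(1-fx) + V(x0+1,y0+1,z0+1)*fx;
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    out[i] = c0*(1-fz) + c1*fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Perona-Malik diffusion, 6-neighbour explicit scheme, g = 1/(1+(|du|/K)^2).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_perona_malik3d(NumericVector vol, IntegerVector dims,
                                 int iters, double K, double dt) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<double> u(vol.begin(), vol.end()), u2(n);
  const int six[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const long long id = vidx(x,y,z,nx,ny);
          double acc = 0;
          for (int s = 0; s < 6; ++s) {
            int xx = x + six[s][0], yy = y + six[s][1], zz = z + six[s][2];
            if (xx < 0 || yy < 0 || zz < 0 ||
                xx >= nx || yy >= ny || zz >= nz) continue;
            double du = u[vidx(xx,yy,zz,nx,ny)] - u[id];
            double g = 1.0 / (1.0 + (du / K) * (du / K));
            acc += g * du;
          }
          u2[id] = u[id] + dt * acc;
        }
    std::swap(u, u2);
  }
  return NumericVector(u.begin(), u.end());
}

// ---------------------------------------------------------------------------
// Box mean and variance over an odd window (wx, wy, wz), clamped borders.
// ---------------------------------------------------------------------------

static void box_axis(std::vector<double> &v, int nx, int ny, int nz,
                     int axis, int half) {
  if (half <= 0) return;
  const int n[3] = {nx, ny, nz};
  const long long stride[3] = {1, nx, (long long)nx * ny};
  const int len = n[axis];
  const long long st = stride[axis];
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(len);
  const double w = 1.0 / (2 * half + 1);
  for (int j2 = 0; j2 < n[o2]; ++j2)
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      long long base = stride[o1] * j1 + stride[o2] * j2;
      for (int i = 0; i < len; ++i) line[i] = v[base + st * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -half; t <= half; ++t) {
          int ii = std::max(0, std::min(len - 1, i + t));
          acc += line[ii];
        }
        v[base + st * i] = acc * w;
      }
    }
}

static void boxmax_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, int half) {
  if (half <= 0) return;
  const int n[3] = {nx, ny, nz};
  const long long stride[3] = {1, nx, (long long)nx * ny};
  const int len = n[axis];
  const long long st = stride[axis];
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(len);
  for (int j2 = 0; j2 < n[o2]; ++j2)
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      long long base = stride[o1] * j1 + stride[o2] * j2;
      for (int i = 0; i < len; ++i) line[i] = v[base + st * i];
      for (int i = 0; i < len; ++i) {
        double m = line[i];
        for (int t = -half; t <= half; ++t) {
          int ii = i + t;
          if (ii < 0 || ii >= len) continue;
          if (line[ii] > m) m = line[ii];
        }
        v[base + st * i] = m;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_box_max(NumericVector vol, IntegerVector dims,
                          IntegerVector win) {
  std::vector<double> v(vol.begin(), vol.end());
  for (int ax = 0; ax < 3; ++ax)
    boxmax_axis(v, dims[0], dims[1], dims[2], ax, win[ax] / 2);
  return NumericVector(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_box_meanvar(NumericVector vol, IntegerVector dims,
                     IntegerVector win) {
  const long long n = (long long)dims[0] * dims[1] * dims[2];
  std::vector<double> m(vol.begin(), vol.end()), s(n);
  for (long long i = 0; i < n; ++i) s[i] = m[i] * m[i];
  for (int ax = 0; ax < 3; ++ax) {
    int half = win[ax] / 2;
    box_axis(m, dims[0], dims[1], dims[2], ax, half);
    box_axis(s, dims[0], dims[1], dims[2], ax, half);
  }
  NumericVector mean(n), var(n);
  for (long long i = 0; i < n; ++i) {
    mean[i] = m[i];
    var[i] = std::max(0.0, s[i] - m[i] * m[i]);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// ---------------------------------------------------------------------------
// Mean-pooling downsample by integer factors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_downsample_mean(NumericVector vol, IntegerVector dims,
                                  IntegerVector f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = (nx + fx - 1) / fx, oy = (ny + fy - 1) / fy,
            oz = (nz + fz - 1) / fz;
  NumericVector out((long long)ox * oy * oz);
  out.attr("odims") = IntegerVector::create(ox, oy, oz);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double acc = 0; int cnt = 0;
        for (int dz = 0; dz < fz; ++dz) {
          int zz = z * fz + dz; if (zz >= nz) break;
          for (int dy = 0; dy < fy; ++dy) {
            int yy = y * fy + dy; if (yy >= ny) break;
            for (int dx = 0; dx < fx; ++dx) {
              int xx = x * fx + dx; if (xx >= nx) break;
              acc += vol[vidx(xx,yy,zz,nx,ny)];
              ++cnt;
            }
          }
        }
        out[x + (long long)ox * (y + (long long)oy * z)] = acc / cnt;
      }
  return out;
}
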