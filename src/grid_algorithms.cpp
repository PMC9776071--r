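#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Single-source Dijkstra on a 3D voxel grid with 26-connectivity.
// Edge weight between voxels u, v: 0.5 * (cost[u] + cost[v]) * ||step in mm||.
// Non-finite cost marks a blocked voxel. Ties resolved deterministically:
// the priority queue pops the smallest linear index among equal distances and
// on equal tentative distance the smaller predecessor index is kept.
// [[Rcpp::export]]
List grid_dijkstra_cpp(NumericVector cost, IntegerVector dims,
                       NumericVector spacing, int src) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();

  if (src < 0 || src >= n) stop("source index out of range");
  if (!R_finite(cost[src])) stop("source voxel has non-finite cost");

  std::vector<double> dist(n, INF);
  std::vector<int> pred(n, -1);
  std::vector<char> done(n, 0);

  // precompute the 26 neighbour offsets and metric step lengths
  int off[26];
  double slen[26];
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off[m] = dx + nx * (dy + ny * dz);
        slen[m] = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                            dy * dy * spacing[1] * spacing[1] +
                            dz * dz * spacing[2] * spacing[2]);
        ++m;
      }

  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  dist[src] = 0.0;
  pq.push(QN(0.0, src));

  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    const double du = top.first;
    const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
    const double cu = cost[u];
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int vx = ux + dx, vy = uy + dy, vz = uz + dz;
          const int kk = k++;
          if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
            continue;
          const int v = u + off[kk];
          if (done[v]) continue;
          const double cv = cost[v];
          if (!R_finite(cv)) continue;
          const double nd = du + 0.5 * (cu + cv) * slen[kk];
          if (nd < dist[v]) {
            dist[v] = nd;
            pred[v] = u;
            pq.push(QN(nd, v));
          } else if (nd == dist[v] && pred[v] >= 0 && u < pred[v]) {
            pred[v] = u;  // deterministic lexicographic tie-break
          }
        }
  }

  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}

// 1D squared distance transform (lower envelope of parabolas), physical
// sample spacing w. Parabolas with infinite offset are skipped.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // index of last parabola in the envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    const double xq = q * w;
    double s = 0.0;
    while (k >= 0) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // no finite parabola at all
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[j + 1] < xq) ++j;
    const double xv = v[j] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Exact Euclidean distance transform of a 3D binary mask: for every voxel,
// the distance (mm) to the nearest TRUE voxel centre, with anisotropic
// spacing. Returns +Inf where the mask is empty.
// [[Rcpp::export]]
NumericVector grid_edt_cpp(LogicalVector mask, IntegerVector dims,
                           NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int z = 0; z < nz; ++z) f[z] = g[base + stride * z];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + stride * z] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
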