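// Voxel-grid utilities for the carved volume: 6-connected component
// labelling, chamfer (3-4-5) distance-to-background transform, and Dijkstra
// shortest paths on the 26-connected occupied-voxel graph (used for
// centerline extraction).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export(name = ".largest_component")]]
LogicalVector largest_component(LogicalVector occ, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<int> label(n, 0);
  int best_label = 0, best_size = 0, cur = 0;
  std::queue<int> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  for (int s = 0; s < n; ++s) {
    if (!occ[s] || label[s]) continue;
    ++cur;
    int size = 0;
    label[s] = cur;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (occ[w] && !label[w]) { label[w] = cur; q.push(w); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (label[i] == best_label && best_label);
  out.attr("dim") = dim;
  return out;
}

// chamfer 3-4-5 distance to the nearest background voxel, in voxel units
// [[Rcpp::export(name = ".chamfer_dt")]]
NumericVector chamfer_dt(LogicalVector occ, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double BIG = 1e18;
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = occ[i] ? BIG : 0.0;

  // forward/backward passes over the half-neighbourhoods
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = lin(x, y, z, nx, ny);
        if (d[v] == 0.0) continue;
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
                // outside the grid counts as background
                double w = std::abs(dx) + std::abs(dy) + std::abs(dz);
                double c = w == 1 ? 3 : (w == 2 ? 4 : 5);
                if (c < d[v]) d[v] = c;
                continue;
              }
              int u = lin(xx, yy, zz, nx, ny);
              int w = std::abs(dx) + std::abs(dy) + std::abs(dz);
              double c = (w == 1 ? 3 : (w == 2 ? 4 : 5)) + d[u];
              if (c < d[v]) d[v] = c;
            }
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int v = lin(x, y, z, nx, ny);
        if (d[v] == 0.0) continue;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
                double w = std::abs(dx) + std::abs(dy) + std::abs(dz);
                double c = w == 1 ? 3 : (w == 2 ? 4 : 5);
                if (c < d[v]) d[v] = c;
                continue;
              }
              int u = lin(xx, yy, zz, nx, ny);
              int w = std::abs(dx) + std::abs(dy) + std::abs(dz);
              double c = (w == 1 ? 3 : (w == 2 ? 4 : 5)) + d[u];
              if (c < d[v]) d[v] = c;
            }
      }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = occ[i] ? d[i] / 3.0 : 0.0;
  out.attr("dim") = dim;
  return out;
}

// Dijkstra over occupied voxels, 26-connectivity; edge cost =
// euclidean step length * mean node cost of its endpoints.
// start0 is a 0-based linear index. Returns distances (Inf where
// unreachable) and 0-based parent indices (-1 at roots/unreached).
// [[Rcpp::export(name = ".voxel_dijkstra")]]
List voxel_dijkstra(LogicalVector occ, IntegerVector dim, int start0,
                    NumericVector node_cost) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<int> parent(n, -1);
  typedef std::pair<double, int> DN;
  std::priority_queue<DN, std::vector<DN>, std::greater<DN> > pq;

  if (start0 < 0 || start0 >= n || !occ[start0])
    stop("start voxel is not occupied");
  dist[start0] = 0.0;
  pq.push(DN(0.0, start0));

  while (!pq.empty()) {
    DN top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v]) continue;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int u = lin(xx, yy, zz, nx, ny);
          if (!occ[u]) continue;
          double step = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          double w = step * 0.5 * (node_cost[v] + node_cost[u]);
          if (dist[v] + w < dist[u]) {
            dist[u] = dist[v] + w;
            parent[u] = v;
            pq.push(DN(dist[u], u));
          }
        }
  }

  NumericVector dd(dist.begin(), dist.end());
  IntegerVector pp(parent.begin(), parent.end());
  dd.attr("dim") = dim;
  return List::create(_["dist"] = dd, _["parent"] = pp);
}

// Bilinear splat of weighted points into an image raster; rows/cols are
// fractional 1-based pixel coordinates. Used by the phantom renderer to
// accumulate projected optical thickness.
// [[Rcpp::export(name = ".splat_project")]]
NumericMatrix splat_project(NumericVector row, NumericVector col,
                            NumericVector w, int nrow, int ncol) {
  NumericMatrix img(nrow, ncol);
  const int n = row.size();
  for (int i = 0; i < n; ++i) {
    double r = row[i] - 1.0, c = col[i] - 1.0;  // 0-based
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double fr = r - r0, fc = c - c0;
    for (int dr = 0; dr <= 1; ++dr)
      for (int dc = 0; dc <= 1; ++dc) {
        int rr = r0 + dr, cc = c0 + dc;
        if (rr < 0 || cc < 0 || rr >= nrow || cc >= ncol) continue;
        double wt = (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc);
        img(rr, cc) += w[i] * wt;
      }
  }
  return img;
}

// 3x3 median filter (replicated borders); edge-preserving denoise step
// [[Rcpp::export(name = ".median3x3")]]
NumericMatrix median3x3(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0) rr = 0; if (rr >= nr) rr = nr - 1;
          if (cc < 0) cc = 0; if (cc >= nc) cc = nc - 1;
          v[k++] = img(rr, cc);
        }
      // insertion sort and take the middle element
      for (int i = 1; i < 9; ++i) {
        double key = v[i]; int j = i - 1;
        while (j >= 0 && v[j] > key) { v[j + 1] = v[j]; --j; }
        v[j + 1] = key;
      }
      out(r, c) = v[4];
    }
  return out;
}

// accumulate strip-constraint satisfaction counts for one frame:
// ok[cell, col] += (lo[col] <= p[cell] <= hi[col]) over contributing
// columns; modifies ok in place
// [[Rcpp::export(name = ".carve_accum")]]
void carve_accum(IntegerMatrix ok, NumericVector p, NumericVector lo,
                 NumericVector hi, LogicalVector use) {
  const int ncell = ok.nrow(), ncol = ok.ncol();
  for (int j = 0; j < ncol; ++j) {
    if (!use[j] || NumericVector::is_na(lo[j])) continue;
    const double l = lo[j], h = hi[j];
    int *col = &ok(0, j);
    const double *pp = p.begin();
    for (int c = 0; c < ncell; ++c)
      if (pp[c] >= l && pp[c] <= h) ++col[c];
  }
}
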