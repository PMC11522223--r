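// Iso-surface extraction from a scalar field on a regular grid by marching
// tetrahedra (Kuhn 6-tetrahedron cube decomposition). Table-free: every cube
// is split into the six tetrahedra that share the main diagonal, so shared
// cube faces are cut along the same diagonal in neighbouring cubes and the
// resulting surface is watertight by construction. Triangle winding is fixed
// at emission time so normals point from high field values (inside) to low.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based vertex ids, 3 per triangle
  std::unordered_map<uint64_t, int> edge_vertex;
};

// vertex on the segment between lattice nodes a and b (0-based linear ids),
// interpolated to the iso level; deduplicated per undirected lattice edge
static int edge_point(MeshAcc &m, uint64_t ia, uint64_t ib,
                      const double *pa, const double *pb,
                      double va, double vb, double iso) {
  uint64_t key = ia < ib ? (ia << 32 | ib) : (ib << 32 | ia);
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  int id = (int)m.vx.size();
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  m.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MeshAcc &m, int a, int b, int c, const double *inward) {
  // inward = a point on the inside of the surface element; orient the
  // triangle so its normal points away from it
  double e1x = m.vx[b] - m.vx[a], e1y = m.vy[b] - m.vy[a], e1z = m.vz[b] - m.vz[a];
  double e2x = m.vx[c] - m.vx[a], e2y = m.vy[c] - m.vy[a], e2z = m.vz[c] - m.vz[a];
  double nx = e1y * e2z - e1z * e2y;
  double ny = e1z * e2x - e1x * e2z;
  double nz = e1x * e2y - e1y * e2x;
  double cx = (m.vx[a] + m.vx[b] + m.vx[c]) / 3.0 - inward[0];
  double cy = (m.vy[a] + m.vy[b] + m.vy[c]) / 3.0 - inward[1];
  double cz = (m.vz[a] + m.vz[b] + m.vz[c]) / 3.0 - inward[2];
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
}

// the six tetrahedra of the Kuhn decomposition, as cube-corner indices
// (corner bit order: x + 2y + 4z); all contain corners 0 and 7
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

} // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, double iso) {
  IntegerVector dims = field.attr("dim");
  if (dims.size() != 3) stop("field must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = field.begin();
  MeshAcc m;

  double corner_pos[8][3];
  double corner_val[8];
  uint64_t corner_id[8];

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          uint64_t id = (uint64_t)cx + (uint64_t)nx * (cy + (uint64_t)ny * cz);
          corner_id[c] = id;
          corner_pos[c][0] = cx; corner_pos[c][1] = cy; corner_pos[c][2] = cz;
          corner_val[c] = f[id];
          (corner_val[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (corner_val[T[k]] > iso) in_idx[nin++] = T[k];
            else out_idx[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;

          if (nin == 1 || nin == 3) {
            // single separated vertex A (inside if nin==1, outside if nin==3)
            int A = (nin == 1) ? in_idx[0] : out_idx[0];
            const int *others = (nin == 1) ? out_idx : in_idx;
            int p[3];
            for (int k = 0; k < 3; ++k)
              p[k] = edge_point(m, corner_id[A], corner_id[others[k]],
                                corner_pos[A], corner_pos[others[k]],
                                corner_val[A], corner_val[others[k]], iso);
            // inward reference: the inside vertex (nin==1: A itself;
            // nin==3: any inside corner)
            const double *inw = (nin == 1) ? corner_pos[A] : corner_pos[others[0]];
            emit_tri(m, p[0], p[1], p[2], inw);
          } else {
            // two inside (A,B), two outside (C,D): quad AC-AD-BD-BC
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int pAC = edge_point(m, corner_id[A], corner_id[C], corner_pos[A],
                                 corner_pos[C], corner_val[A], corner_val[C], iso);
            int pAD = edge_point(m, corner_id[A], corner_id[D], corner_pos[A],
                                 corner_pos[D], corner_val[A], corner_val[D], iso);
            int pBD = edge_point(m, corner_id[B], corner_id[D], corner_pos[B],
                                 corner_pos[D], corner_val[B], corner_val[D], iso);
            int pBC = edge_point(m, corner_id[B], corner_id[C], corner_pos[B],
                                 corner_pos[C], corner_val[B], corner_val[C], iso);
            double inw[3] = {
              (corner_pos[A][0] + corner_pos[B][0]) / 2.0,
              (corner_pos[A][1] + corner_pos[B][1]) / 2.0,
              (corner_pos[A][2] + corner_pos[B][2]) / 2.0 };
            emit_tri(m, pAC, pAD, pBD, inw);
            emit_tri(m, pAC, pBD, pBC, inw);
          }
        }
      }

  int nv = (int)m.vx.size(), nt = (int)m.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = m.vx[i]; V(i, 1) = m.vy[i]; V(i, 2) = m.vz[i];
  }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = m.tri[3 * i] + 1;
    F(i, 1) = m.tri[3 * i + 1] + 1;
    F(i, 2) = m.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
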