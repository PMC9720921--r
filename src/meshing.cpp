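#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Separable Gaussian blur of a 3D array with zero boundary conditions.
// sigma is per-axis, in voxel units; a sigma of 0 skips that axis.
// [[Rcpp::export(name = ".gaussian_blur3")]]
NumericVector gaussian_blur3(NumericVector field, IntegerVector dim,
                             NumericVector sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> cur(field.begin(), field.end());
  std::vector<double> nxt(ntot);
  const int strides[3] = {1, n1, n1 * n2};
  const int sizes[3] = {n1, n2, n3};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * rad + 1);
    double tot = 0.0;
    for (int k = -rad; k <= rad; ++k) {
      w[k + rad] = std::exp(-0.5 * k * k / (s * s));
      tot += w[k + rad];
    }
    for (double &x : w) x /= tot;

    const int stride = strides[ax];
    const int len = sizes[ax];
    // iterate over all lines along axis ax
    const int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < sizes[ob]; ++b) {
      for (int a = 0; a < sizes[oa]; ++a) {
        R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          int lo = std::max(0, i - rad), hi = std::min(len - 1, i + rad);
          for (int k = lo; k <= hi; ++k)
            acc += w[k - i + rad] * cur[base + (R_xlen_t)k * stride];
          nxt[base + (R_xlen_t)i * stride] = acc;
        }
      }
    }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// corner offsets of a cell, axis order (1,2,3)
static const int CRN[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
// 6-tetrahedra decomposition sharing the 0-6 body diagonal; face diagonals
// depend only on direction, so the split is consistent across adjacent cells
// and the extracted surface is watertight.
static const int TET[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

struct MeshAcc {
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  uint64_t ntot;
};

static int edge_vertex(MeshAcc &m, uint64_t na, uint64_t nb,
                       const double *pa, const double *pb,
                       double fa, double fb, double level) {
  uint64_t a = na, b = nb;
  if (a > b) { std::swap(a, b); std::swap(pa, pb); std::swap(fa, fb); }
  uint64_t key = a * m.ntot + b;
  auto it = m.vmap.find(key);
  if (it != m.vmap.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  if (t < 0) t = 0; if (t > 1) t = 1;
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)m.vx.size() - 1;
  m.vmap.emplace(key, id);
  return id;
}

static void push_tri(MeshAcc &m, int a, int b, int c,
                     const double ref[3]) {
  // orient so the normal points away from the inside reference point
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double dx = m.vx[a] - ref[0], dy = m.vy[a] - ref[1], dz = m.vz[a] - ref[2];
  if (nx * dx + ny * dy + nz * dz < 0) std::swap(b, c);
  m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c);
}

// Marching tetrahedra isosurface of a 3D scalar field.
// Returns physical-coordinate vertices (spacing/origin applied) and 1-based
// face indices with consistent outward orientation.
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dim, double level,
                NumericVector spacing, NumericVector origin) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *F = field.begin();
  MeshAcc m;
  m.ntot = (uint64_t)n1 * n2 * n3;

  double fv[8]; double pv[8][3]; uint64_t nid[8];
  for (int k = 0; k < n3 - 1; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CRN[c][0], cj = j + CRN[c][1], ck = k + CRN[c][2];
          uint64_t id = (uint64_t)ci + (uint64_t)n1 * (cj + (uint64_t)n2 * ck);
          nid[c] = id;
          fv[c] = F[id];
          pv[c][0] = origin[0] + ci * spacing[0];
          pv[c][1] = origin[1] + cj * spacing[1];
          pv[c][2] = origin[2] + ck * spacing[2];
          if (fv[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            int c = TET[t][v];
            if (fv[c] >= level) vin[nin++] = c; else vout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double ref[3] = {0, 0, 0};
          for (int v = 0; v < nin; ++v)
            for (int d = 0; d < 3; ++d) ref[d] += pv[vin[v]][d] / nin;
          if (nin == 1) {
            int a = edge_vertex(m, nid[vin[0]], nid[vout[0]], pv[vin[0]], pv[vout[0]], fv[vin[0]], fv[vout[0]], level);
            int b = edge_vertex(m, nid[vin[0]], nid[vout[1]], pv[vin[0]], pv[vout[1]], fv[vin[0]], fv[vout[1]], level);
            int c = edge_vertex(m, nid[vin[0]], nid[vout[2]], pv[vin[0]], pv[vout[2]], fv[vin[0]], fv[vout[2]], level);
            push_tri(m, a, b, c, ref);
          } else if (nin == 3) {
            int a = edge_vertex(m, nid[vin[0]], nid[vout[0]], pv[vin[0]], pv[vout[0]], fv[vin[0]], fv[vout[0]], level);
            int b = edge_vertex(m, nid[vin[1]], nid[vout[0]], pv[vin[1]], pv[vout[0]], fv[vin[1]], fv[vout[0]], level);
            int c = edge_vertex(m, nid[vin[2]], nid[vout[0]], pv[vin[2]], pv[vout[0]], fv[vin[2]], fv[vout[0]], level);
            push_tri(m, a, b, c, ref);
          } else { // 2 in, 2 out -> quad split into two triangles
            int p1 = edge_vertex(m, nid[vin[0]], nid[vout[0]], pv[vin[0]], pv[vout[0]], fv[vin[0]], fv[vout[0]], level);
            int p2 = edge_vertex(m, nid[vin[0]], nid[vout[1]], pv[vin[0]], pv[vout[1]], fv[vin[0]], fv[vout[1]], level);
            int p3 = edge_vertex(m, nid[vin[1]], nid[vout[1]], pv[vin[1]], pv[vout[1]], fv[vin[1]], fv[vout[1]], level);
            int p4 = edge_vertex(m, nid[vin[1]], nid[vout[0]], pv[vin[1]], pv[vout[0]], fv[vin[1]], fv[vout[0]], level);
            push_tri(m, p1, p2, p3, ref);
            push_tri(m, p1, p3, p4, ref);
          }
        }
      }

  int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0)=m.vx[i]; V(i,1)=m.vy[i]; V(i,2)=m.vz[i]; }
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; ++i) { Fc(i,0)=m.f0[i]+1; Fc(i,1)=m.f1[i]+1; Fc(i,2)=m.f2[i]+1; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// 26-connected component labeling of a {0,1} 3D array.
// Returns an integer array: 0 background, 1..n component labels
// (labels ordered by first-encountered voxel in column-major order).
// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(IntegerVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(ntot, 0);
  lab.attr("dim") = dim;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % n1), j = (int)((cur / n1) % n2), k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            R_xlen_t q = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("n_components") = IntegerVector::create(next);
  return lab;
}

// Taubin lambda/mu smoothing with uniform (umbrella) weights.
// [[Rcpp::export(name = ".taubin_smooth")]]
NumericMatrix taubin_smooth(NumericMatrix verts, IntegerMatrix faces,
                            int iterations, double lambda, double mu) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> adj(nv);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int i = 0; i < nf; ++i) {
    int a = faces(i,0) - 1, b = faces(i,1) - 1, c = faces(i,2) - 1;
    add_edge(a, b); add_edge(b, c); add_edge(c, a);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  std::vector<double> x(nv), y(nv), z(nv), dx(nv), dy(nv), dz(nv);
  for (int i = 0; i < nv; ++i) { x[i]=verts(i,0); y[i]=verts(i,1); z[i]=verts(i,2); }
  auto pass = [&](double factor) {
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) { dx[i]=dy[i]=dz[i]=0; continue; }
      double mx=0, my=0, mz=0;
      for (int j : adj[i]) { mx+=x[j]; my+=y[j]; mz+=z[j]; }
      double n = (double)adj[i].size();
      dx[i]=mx/n - x[i]; dy[i]=my/n - y[i]; dz[i]=mz/n - z[i];
    }
    for (int i = 0; i < nv; ++i) { x[i]+=factor*dx[i]; y[i]+=factor*dy[i]; z[i]+=factor*dz[i]; }
  };
  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return out;
}
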