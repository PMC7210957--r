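// Mesh geometry kernels: marching-tetrahedra isosurface extraction with
// edge-keyed vertex welding, face-connectivity components, uniform-grid
// nearest-neighbour queries, point-to-triangle distances, ray casting for
// ambient-occlusion accessibility, and parity inside/outside tests.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra
// ---------------------------------------------------------------------------

// 6-tetrahedron decomposition of a cube around the main diagonal 0-7,
// corner id = dx + 2*dy + 4*dz.  Face diagonals agree between neighbouring
// cubes, so welded meshes are watertight away from the volume boundary.
static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 p; p.x=x; p.y=y; p.z=z; return p; }
static inline V3 sub(const V3&a, const V3&b){ return v3(a.x-b.x,a.y-b.y,a.z-b.z); }
static inline V3 add(const V3&a, const V3&b){ return v3(a.x+b.x,a.y+b.y,a.z+b.z); }
static inline V3 mul(const V3&a, double s){ return v3(a.x*s,a.y*s,a.z*s); }
static inline double dot(const V3&a, const V3&b){ return a.x*b.x+a.y*b.y+a.z*b.z; }
static inline V3 cross(const V3&a, const V3&b){
  return v3(a.y*b.z-a.z*b.y, a.z*b.x-a.x*b.z, a.x*b.y-a.y*b.x);
}
static inline double norm(const V3&a){ return std::sqrt(dot(a,a)); }

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector vol, IntegerVector dim, NumericVector spacing,
                   double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *v = REAL(vol);
  const int64_t nxy = (int64_t)nx * ny;

  std::unordered_map<uint64_t, int> edge2vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  edge2vert.reserve(1 << 16);

  // corner linear index (0-based, column-major as stored by R)
  auto lin = [&](int ix, int iy, int iz) -> int64_t {
    return (int64_t)ix + (int64_t)nx * iy + nxy * iz;
  };

  auto edgeVertex = [&](int64_t ia, int64_t ib, double va, double vb,
                        const V3 &pa, const V3 &pb) -> int {
    uint64_t lo = (uint64_t)std::min(ia, ib), hi = (uint64_t)std::max(ia, ib);
    uint64_t key = lo * (uint64_t)(nxy * nz) + hi;
    auto it = edge2vert.find(key);
    if (it != edge2vert.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    V3 p = add(pa, mul(sub(pb, pa), t));
    int id = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    edge2vert.emplace(key, id);
    return id;
  };

  auto addTri = [&](int a, int b, int c, const V3 &outDir) {
    // orient so the normal has positive dot with outDir (inside -> outside)
    V3 pa = v3(vx[a], vy[a], vz[a]), pb = v3(vx[b], vy[b], vz[b]),
       pc = v3(vx[c], vy[c], vz[c]);
    V3 n = cross(sub(pb, pa), sub(pc, pa));
    if (dot(n, outDir) < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  double cval[8];
  int64_t cidx[8];
  V3 cpos[8];

  for (int iz = 0; iz + 1 < nz; ++iz) {
    for (int iy = 0; iy + 1 < ny; ++iy) {
      for (int ix = 0; ix + 1 < nx; ++ix) {
        double vmin = 1e300, vmax = -1e300;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          int64_t id = lin(ix + dx, iy + dy, iz + dz);
          double val = v[id];
          cidx[c] = id; cval[c] = val;
          cpos[c] = v3((ix + dx) * sx, (iy + dy) * sy, (iz + dz) * sz);
          if (val < vmin) vmin = val;
          if (val > vmax) vmax = val;
        }
        if (vmin > iso || vmax <= iso) continue;
        for (int t = 0; t < 6; ++t) {
          int id4[4]; bool in[4]; int nin = 0;
          for (int k = 0; k < 4; ++k) {
            id4[k] = TETS[t][k];
            in[k] = cval[id4[k]] > iso;
            if (in[k]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int insideIdx[4], outsideIdx[4]; int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (in[k]) insideIdx[ni++] = id4[k]; else outsideIdx[no++] = id4[k];
          }
          if (nin == 1) {
            int a = insideIdx[0];
            int e0 = edgeVertex(cidx[a], cidx[outsideIdx[0]], cval[a], cval[outsideIdx[0]], cpos[a], cpos[outsideIdx[0]]);
            int e1 = edgeVertex(cidx[a], cidx[outsideIdx[1]], cval[a], cval[outsideIdx[1]], cpos[a], cpos[outsideIdx[1]]);
            int e2 = edgeVertex(cidx[a], cidx[outsideIdx[2]], cval[a], cval[outsideIdx[2]], cpos[a], cpos[outsideIdx[2]]);
            V3 ctr = mul(add(add(v3(vx[e0],vy[e0],vz[e0]), v3(vx[e1],vy[e1],vz[e1])), v3(vx[e2],vy[e2],vz[e2])), 1.0/3.0);
            addTri(e0, e1, e2, sub(ctr, cpos[a]));
          } else if (nin == 3) {
            int d = outsideIdx[0];
            int e0 = edgeVertex(cidx[d], cidx[insideIdx[0]], cval[d], cval[insideIdx[0]], cpos[d], cpos[insideIdx[0]]);
            int e1 = edgeVertex(cidx[d], cidx[insideIdx[1]], cval[d], cval[insideIdx[1]], cpos[d], cpos[insideIdx[1]]);
            int e2 = edgeVertex(cidx[d], cidx[insideIdx[2]], cval[d], cval[insideIdx[2]], cpos[d], cpos[insideIdx[2]]);
            V3 ctr = mul(add(add(v3(vx[e0],vy[e0],vz[e0]), v3(vx[e1],vy[e1],vz[e1])), v3(vx[e2],vy[e2],vz[e2])), 1.0/3.0);
            addTri(e0, e1, e2, sub(cpos[d], ctr));
          } else { // nin == 2
            int a = insideIdx[0], b = insideIdx[1];
            int c = outsideIdx[0], d = outsideIdx[1];
            int eac = edgeVertex(cidx[a], cidx[c], cval[a], cval[c], cpos[a], cpos[c]);
            int ead = edgeVertex(cidx[a], cidx[d], cval[a], cval[d], cpos[a], cpos[d]);
            int ebc = edgeVertex(cidx[b], cidx[c], cval[b], cval[c], cpos[b], cpos[c]);
            int ebd = edgeVertex(cidx[b], cidx[d], cval[b], cval[d], cpos[b], cpos[d]);
            V3 outDir = sub(mul(add(cpos[c], cpos[d]), 0.5), mul(add(cpos[a], cpos[b]), 0.5));
            addTri(eac, ead, ebd, outDir);
            addTri(eac, ebd, ebc, outDir);
          }
        }
      }
    }
  }

  int nV = (int)vx.size(), nF = (int)f0.size();
  NumericMatrix verts(nV, 3);
  for (int i = 0; i < nV; ++i) { verts(i,0)=vx[i]; verts(i,1)=vy[i]; verts(i,2)=vz[i]; }
  IntegerMatrix faces(nF, 3);
  for (int i = 0; i < nF; ++i) { faces(i,0)=f0[i]+1; faces(i,1)=f1[i]+1; faces(i,2)=f2[i]+1; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Connected components of faces via shared vertices (union-find)
// ---------------------------------------------------------------------------

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
};

// [[Rcpp::export(name = ".mesh_face_components")]]
IntegerVector mesh_face_components(IntegerMatrix faces, int nverts) {
  int nF = faces.nrow();
  UF uf(nverts);
  for (int i = 0; i < nF; ++i) {
    uf.unite(faces(i,0)-1, faces(i,1)-1);
    uf.unite(faces(i,0)-1, faces(i,2)-1);
  }
  std::unordered_map<int,int> relab;
  IntegerVector comp(nF);
  int next = 1;
  for (int i = 0; i < nF; ++i) {
    int r = uf.find(faces(i,0)-1);
    auto it = relab.find(r);
    if (it == relab.end()) { relab.emplace(r, next); comp[i] = next; ++next; }
    else comp[i] = it->second;
  }
  return comp;
}

// ---------------------------------------------------------------------------
// Uniform grid over points: nearest-neighbour distances
// ---------------------------------------------------------------------------

struct PointGrid {
  double ox, oy, oz, cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> bins;
  const double *px, *py, *pz;
  int n;

  void build(const NumericMatrix &P) {
    n = P.nrow();
    px = &P(0,0); py = &P(0,1); pz = &P(0,2);
    double mnx=1e300, mny=1e300, mnz=1e300, mxx=-1e300, mxy=-1e300, mxz=-1e300;
    for (int i = 0; i < n; ++i) {
      mnx=std::min(mnx,px[i]); mny=std::min(mny,py[i]); mnz=std::min(mnz,pz[i]);
      mxx=std::max(mxx,px[i]); mxy=std::max(mxy,py[i]); mxz=std::max(mxz,pz[i]);
    }
    double ext = std::max({mxx-mnx, mxy-mny, mxz-mnz, 1e-12});
    double target = std::cbrt((double)std::max(n,1));
    cell = std::max(ext / std::max(target, 1.0), 1e-9);
    ox = mnx; oy = mny; oz = mnz;
    gx = std::max(1, (int)std::floor((mxx-mnx)/cell) + 1);
    gy = std::max(1, (int)std::floor((mxy-mny)/cell) + 1);
    gz = std::max(1, (int)std::floor((mxz-mnz)/cell) + 1);
    bins.assign((size_t)gx*gy*gz, {});
    for (int i = 0; i < n; ++i) {
      int cx = std::min(gx-1, std::max(0, (int)((px[i]-ox)/cell)));
      int cy = std::min(gy-1, std::max(0, (int)((py[i]-oy)/cell)));
      int cz = std::min(gz-1, std::max(0, (int)((pz[i]-oz)/cell)));
      bins[(size_t)cx + (size_t)gx*(cy + (size_t)gy*cz)].push_back(i);
    }
  }

  // nearest point index and squared distance, expanding-shell search
  void nearest(double qx, double qy, double qz, int &best, double &bestd2) const {
    int cx = std::min(gx-1, std::max(0, (int)((qx-ox)/cell)));
    int cy = std::min(gy-1, std::max(0, (int)((qy-oy)/cell)));
    int cz = std::min(gz-1, std::max(0, (int)((qz-oz)/cell)));
    best = -1; bestd2 = 1e300;
    int maxr = std::max({gx, gy, gz});
    for (int r = 0; r <= maxr; ++r) {
      // once we have a candidate, stop when the shell cannot contain closer pts
      if (best >= 0) {
        double safe = (double)(r - 1) * cell;
        if (safe > 0 && safe * safe > bestd2) break;
      }
      int x0 = std::max(0, cx-r), x1 = std::min(gx-1, cx+r);
      int y0 = std::max(0, cy-r), y1 = std::min(gy-1, cy+r);
      int z0 = std::max(0, cz-r), z1 = std::min(gz-1, cz+r);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            if (r > 0 && std::abs(x-cx) != r && std::abs(y-cy) != r && std::abs(z-cz) != r)
              continue; // only the shell
            const auto &b = bins[(size_t)x + (size_t)gx*(y + (size_t)gy*z)];
            for (int id : b) {
              double dx=px[id]-qx, dy=py[id]-qy, dz=pz[id]-qz;
              double d2 = dx*dx+dy*dy+dz*dz;
              if (d2 < bestd2) { bestd2 = d2; best = id; }
            }
          }
    }
  }
};

// [[Rcpp::export(name = ".nn_dist")]]
NumericVector nn_dist(NumericMatrix query, NumericMatrix ref) {
  PointGrid g; g.build(ref);
  int n = query.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int best; double d2;
    g.nearest(query(i,0), query(i,1), query(i,2), best, d2);
    out[i] = std::sqrt(d2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Point-triangle distance (Ericson) and grid over triangles
// ---------------------------------------------------------------------------

static double pointTriDist2(const V3 &p, const V3 &a, const V3 &b, const V3 &c,
                            V3 *closest = nullptr) {
  V3 ab = sub(b,a), ac = sub(c,a), ap = sub(p,a);
  double d1 = dot(ab,ap), d2 = dot(ac,ap);
  V3 q;
  if (d1 <= 0 && d2 <= 0) q = a;
  else {
    V3 bp = sub(p,b);
    double d3 = dot(ab,bp), d4 = dot(ac,bp);
    if (d3 >= 0 && d4 <= d3) q = b;
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) q = add(a, mul(ab, d1/(d1-d3)));
      else {
        V3 cp = sub(p,c);
        double d5 = dot(ab,cp), d6 = dot(ac,cp);
        if (d6 >= 0 && d5 <= d6) q = c;
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) q = add(a, mul(ac, d2/(d2-d6)));
          else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0)
              q = add(b, mul(sub(c,b), (d4-d3)/((d4-d3)+(d5-d6))));
            else {
              double denom = 1.0/(va+vb+vc);
              q = add(a, add(mul(ab, vb*denom), mul(ac, vc*denom)));
            }
          }
        }
      }
    }
  }
  if (closest) *closest = q;
  V3 d = sub(p,q);
  return dot(d,d);
}

struct TriGrid {
  double ox, oy, oz, cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> bins;
  std::vector<V3> A, B, C;
  int nF;

  void build(const NumericMatrix &V, const IntegerMatrix &F) {
    nF = F.nrow();
    A.resize(nF); B.resize(nF); C.resize(nF);
    double mnx=1e300,mny=1e300,mnz=1e300,mxx=-1e300,mxy=-1e300,mxz=-1e300;
    for (int i = 0; i < nF; ++i) {
      A[i] = v3(V(F(i,0)-1,0), V(F(i,0)-1,1), V(F(i,0)-1,2));
      B[i] = v3(V(F(i,1)-1,0), V(F(i,1)-1,1), V(F(i,1)-1,2));
      C[i] = v3(V(F(i,2)-1,0), V(F(i,2)-1,1), V(F(i,2)-1,2));
      for (const V3 *p : {&A[i],&B[i],&C[i]}) {
        mnx=std::min(mnx,p->x); mny=std::min(mny,p->y); mnz=std::min(mnz,p->z);
        mxx=std::max(mxx,p->x); mxy=std::max(mxy,p->y); mxz=std::max(mxz,p->z);
      }
    }
    double ext = std::max({mxx-mnx, mxy-mny, mxz-mnz, 1e-12});
    double target = std::cbrt((double)std::max(nF,1));
    cell = std::max(ext / std::max(target, 1.0), 1e-9);
    ox=mnx; oy=mny; oz=mnz;
    gx = std::max(1, (int)std::floor((mxx-mnx)/cell)+1);
    gy = std::max(1, (int)std::floor((mxy-mny)/cell)+1);
    gz = std::max(1, (int)std::floor((mxz-mnz)/cell)+1);
    bins.assign((size_t)gx*gy*gz, {});
    for (int i = 0; i < nF; ++i) {
      double bx0 = std::min({A[i].x,B[i].x,C[i].x}), bx1 = std::max({A[i].x,B[i].x,C[i].x});
      double by0 = std::min({A[i].y,B[i].y,C[i].y}), by1 = std::max({A[i].y,B[i].y,C[i].y});
      double bz0 = std::min({A[i].z,B[i].z,C[i].z}), bz1 = std::max({A[i].z,B[i].z,C[i].z});
      int x0 = std::max(0,(int)((bx0-ox)/cell)), x1 = std::min(gx-1,(int)((bx1-ox)/cell));
      int y0 = std::max(0,(int)((by0-oy)/cell)), y1 = std::min(gy-1,(int)((by1-oy)/cell));
      int z0 = std::max(0,(int)((bz0-oz)/cell)), z1 = std::min(gz-1,(int)((bz1-oz)/cell));
      for (int z=z0; z<=z1; ++z) for (int y=y0; y<=y1; ++y) for (int x=x0; x<=x1; ++x)
        bins[(size_t)x + (size_t)gx*(y + (size_t)gy*z)].push_back(i);
    }
  }

  double nearestDist(const V3 &p, int *bestTri = nullptr) const {
    int cx = std::min(gx-1, std::max(0, (int)((p.x-ox)/cell)));
    int cy = std::min(gy-1, std::max(0, (int)((p.y-oy)/cell)));
    int cz = std::min(gz-1, std::max(0, (int)((p.z-oz)/cell)));
    double bestd2 = 1e300; int best = -1;
    int maxr = std::max({gx, gy, gz}) + 1;
    for (int r = 0; r <= maxr; ++r) {
      if (best >= 0) {
        double safe = (double)(r-1) * cell;
        if (safe > 0 && safe*safe > bestd2) break;
      }
      int x0 = std::max(0, cx-r), x1 = std::min(gx-1, cx+r);
      int y0 = std::max(0, cy-r), y1 = std::min(gy-1, cy+r);
      int z0 = std::max(0, cz-r), z1 = std::min(gz-1, cz+r);
      for (int z=z0; z<=z1; ++z) for (int y=y0; y<=y1; ++y) for (int x=x0; x<=x1; ++x) {
        if (r > 0 && std::abs(x-cx) != r && std::abs(y-cy) != r && std::abs(z-cz) != r)
          continue;
        for (int id : bins[(size_t)x + (size_t)gx*(y + (size_t)gy*z)]) {
          double d2 = pointTriDist2(p, A[id], B[id], C[id]);
          if (d2 < bestd2) { bestd2 = d2; best = id; }
        }
      }
    }
    if (bestTri) *bestTri = best;
    return std::sqrt(bestd2);
  }

  // Moeller-Trumbore; returns smallest positive hit distance or -1
  double rayHit(const V3 &o, const V3 &d, double tmin) const {
    // DDA traversal
    double t = 0.0;
    // clip ray to grid bounds
    double bx0 = ox, bx1 = ox + gx*cell, by0 = oy, by1 = oy + gy*cell,
           bz0 = oz, bz1 = oz + gz*cell;
    double tEnter = 0.0, tExit = std::numeric_limits<double>::infinity();
    const double big = 1e30;
    double inv[3] = { d.x!=0 ? 1.0/d.x : big, d.y!=0 ? 1.0/d.y : big, d.z!=0 ? 1.0/d.z : big };
    double t1 = (bx0-o.x)*inv[0], t2 = (bx1-o.x)*inv[0];
    tEnter = std::max(tEnter, std::min(t1,t2)); tExit = std::min(tExit, std::max(t1,t2));
    t1 = (by0-o.y)*inv[1]; t2 = (by1-o.y)*inv[1];
    tEnter = std::max(tEnter, std::min(t1,t2)); tExit = std::min(tExit, std::max(t1,t2));
    t1 = (bz0-o.z)*inv[2]; t2 = (bz1-o.z)*inv[2];
    tEnter = std::max(tEnter, std::min(t1,t2)); tExit = std::min(tExit, std::max(t1,t2));
    if (d.x == 0 && (o.x < bx0 || o.x > bx1)) return -1;
    if (d.y == 0 && (o.y < by0 || o.y > by1)) return -1;
    if (d.z == 0 && (o.z < bz0 || o.z > bz1)) return -1;
    if (tEnter > tExit) return -1;
    t = tEnter;
    V3 p = add(o, mul(d, t + 1e-12));
    int cx = std::min(gx-1, std::max(0, (int)((p.x-ox)/cell)));
    int cy = std::min(gy-1, std::max(0, (int)((p.y-oy)/cell)));
    int cz = std::min(gz-1, std::max(0, (int)((p.z-oz)/cell)));
    int sxd = d.x > 0 ? 1 : (d.x < 0 ? -1 : 0);
    int syd = d.y > 0 ? 1 : (d.y < 0 ? -1 : 0);
    int szd = d.z > 0 ? 1 : (d.z < 0 ? -1 : 0);
    double nbx = ox + (cx + (sxd > 0 ? 1 : 0)) * cell;
    double nby = oy + (cy + (syd > 0 ? 1 : 0)) * cell;
    double nbz = oz + (cz + (szd > 0 ? 1 : 0)) * cell;
    double tmx = sxd != 0 ? (nbx - o.x) * inv[0] : big;
    double tmy = syd != 0 ? (nby - o.y) * inv[1] : big;
    double tmz = szd != 0 ? (nbz - o.z) * inv[2] : big;
    double tdx = sxd != 0 ? cell * std::abs(inv[0]) : big;
    double tdy = syd != 0 ? cell * std::abs(inv[1]) : big;
    double tdz = szd != 0 ? cell * std::abs(inv[2]) : big;
    double bestT = -1;
    while (true) {
      double cellExit = std::min({tmx, tmy, tmz, tExit});
      for (int id : bins[(size_t)cx + (size_t)gx*(cy + (size_t)gy*cz)]) {
        // Moeller-Trumbore
        V3 e1 = sub(B[id], A[id]), e2 = sub(C[id], A[id]);
        V3 pv = cross(d, e2);
        double det = dot(e1, pv);
        if (std::abs(det) < 1e-14) continue;
        double invDet = 1.0/det;
        V3 tv = sub(o, A[id]);
        double u = dot(tv, pv) * invDet;
        if (u < -1e-9 || u > 1 + 1e-9) continue;
        V3 qv = cross(tv, e1);
        double vv = dot(d, qv) * invDet;
        if (vv < -1e-9 || u + vv > 1 + 1e-9) continue;
        double th = dot(e2, qv) * invDet;
        if (th > tmin && th <= cellExit + 1e-9) {
          if (bestT < 0 || th < bestT) bestT = th;
        }
      }
      if (bestT > 0) return bestT;
      if (tmx <= tmy && tmx <= tmz) {
        if (tmx > tExit) break; cx += sxd; if (cx < 0 || cx >= gx) break; tmx += tdx;
      } else if (tmy <= tmz) {
        if (tmy > tExit) break; cy += syd; if (cy < 0 || cy >= gy) break; tmy += tdy;
      } else {
        if (tmz > tExit) break; cz += szd; if (cz < 0 || cz >= gz) break; tmz += tdz;
      }
    }
    return -1;
  }
};

// [[Rcpp::export(name = ".point_mesh_dist")]]
NumericVector point_mesh_dist(NumericMatrix points, NumericMatrix verts,
                              IntegerMatrix faces) {
  TriGrid g; g.build(verts, faces);
  int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = g.nearestDist(v3(points(i,0), points(i,1), points(i,2)));
  return out;
}

// Per-face accessibility: fraction of given unit directions whose ray from the
// face centroid (offset eps along the face normal) escapes without hitting the
// mesh.  Directions are supplied by the caller (seeded in R).
// [[Rcpp::export(name = ".ao_accessibility")]]
NumericVector ao_accessibility(NumericMatrix verts, IntegerMatrix faces,
                               NumericMatrix dirs, double eps) {
  TriGrid g; g.build(verts, faces);
  int nF = faces.nrow(), nD = dirs.nrow();
  NumericVector out(nF);
  for (int i = 0; i < nF; ++i) {
    V3 a = g.A[i], b = g.B[i], c = g.C[i];
    V3 ctr = mul(add(add(a,b),c), 1.0/3.0);
    V3 n = cross(sub(b,a), sub(c,a));
    double nn = norm(n);
    if (nn > 0) n = mul(n, 1.0/nn);
    V3 o = add(ctr, mul(n, eps));
    int freeCount = 0;
    for (int k = 0; k < nD; ++k) {
      V3 d = v3(dirs(k,0), dirs(k,1), dirs(k,2));
      if (g.rayHit(o, d, 1e-9) < 0) ++freeCount;
    }
    out[i] = (double)freeCount / (double)nD;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Parity inside test along +x rays (meshes assumed closed for this query).
// [[Rcpp::export(name = ".points_in_mesh")]]
LogicalVector points_in_mesh(NumericMatrix points, NumericMatrix verts,
                             IntegerMatrix faces) {
  TriGrid g; g.build(verts, faces);
  int n = points.nrow();
  LogicalVector out(n);
  // jittered direction avoids edge-grazing degeneracies
  V3 d = v3(0.577350269189626, 0.577350269189626 + 1.23e-4, 0.577350269189626 - 3.1e-5);
  double dn = norm(d); d = mul(d, 1.0/dn);
  for (int i = 0; i < n; ++i) {
    V3 o = v3(points(i,0), points(i,1), points(i,2));
    // count all crossings by marching past each hit
    int crossings = 0;
    double t0 = 1e-9;
    for (int guard = 0; guard < 1000; ++guard) {
      double t = g.rayHit(o, d, t0);
      if (t < 0) break;
      ++crossings;
      t0 = t + 1e-7;
    }
    out[i] = (crossings % 2) == 1;
  }
  return out;
}

// Depth-map visibility: per-face fraction of directions from which the face
// centroid is not occluded by nearer geometry in the same screen pixel.
// A face is visible along a direction when its depth is within `bias` of the
// nearest centroid depth in its pixel (the bias keeps coplanar neighbours
// from shadowing each other).  O(nDirs * nFaces).
// [[Rcpp::export(name = ".ao_depthmap")]]
NumericVector ao_depthmap(NumericMatrix verts, IntegerMatrix faces,
                          NumericMatrix dirs, double pixel, double bias) {
  const int nF = faces.nrow(), nD = dirs.nrow();
  std::vector<double> cx(nF), cy(nF), cz(nF);
  for (int i = 0; i < nF; ++i) {
    const int a = faces(i,0)-1, b = faces(i,1)-1, c = faces(i,2)-1;
    cx[i] = (verts(a,0)+verts(b,0)+verts(c,0)) / 3.0;
    cy[i] = (verts(a,1)+verts(b,1)+verts(c,1)) / 3.0;
    cz[i] = (verts(a,2)+verts(b,2)+verts(c,2)) / 3.0;
  }
  std::vector<int> visCount(nF, 0);
  std::vector<double> ua(nF), ub(nF), ut(nF);
  std::vector<int> pix(nF);
  for (int k = 0; k < nD; ++k) {
    V3 d = v3(dirs(k,0), dirs(k,1), dirs(k,2));
    // orthonormal screen basis perpendicular to d
    V3 ref = std::abs(d.x) < 0.9 ? v3(1,0,0) : v3(0,1,0);
    V3 u = cross(d, ref);
    u = mul(u, 1.0/norm(u));
    V3 w = cross(d, u);
    double amin = 1e300, bmin = 1e300, amax = -1e300, bmax = -1e300;
    for (int i = 0; i < nF; ++i) {
      ua[i] = cx[i]*u.x + cy[i]*u.y + cz[i]*u.z;
      ub[i] = cx[i]*w.x + cy[i]*w.y + cz[i]*w.z;
      ut[i] = cx[i]*d.x + cy[i]*d.y + cz[i]*d.z;
      amin = std::min(amin, ua[i]); amax = std::max(amax, ua[i]);
      bmin = std::min(bmin, ub[i]); bmax = std::max(bmax, ub[i]);
    }
    int na = std::max(1, (int)((amax - amin)/pixel) + 1);
    int nb = std::max(1, (int)((bmax - bmin)/pixel) + 1);
    std::vector<double> zmin((size_t)na*nb, 1e300);
    for (int i = 0; i < nF; ++i) {
      int pa = std::min(na-1, (int)((ua[i]-amin)/pixel));
      int pb = std::min(nb-1, (int)((ub[i]-bmin)/pixel));
      pix[i] = pa + na*pb;
      if (ut[i] < zmin[pix[i]]) zmin[pix[i]] = ut[i];
    }
    for (int i = 0; i < nF; ++i)
      if (ut[i] <= zmin[pix[i]] + bias) ++visCount[i];
    Rcpp::checkUserInterrupt();
  }
  NumericVector out(nF);
  for (int i = 0; i < nF; ++i) out[i] = (double)visCount[i] / nD;
  return out;
}
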