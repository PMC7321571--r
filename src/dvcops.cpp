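#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel coordinates are 1-based (R convention). A volume of dims (n1,n2,n3)
// is addressed as v[i + n1*(j + n2*k)] with 0-based i,j,k internally.

static inline double lanczos3(double d) {
  if (d == 0.0) return 1.0;
  double ad = std::fabs(d);
  if (ad >= 3.0) return 0.0;
  double pd = M_PI * d;
  return 3.0 * std::sin(pd) * std::sin(pd / 3.0) / (pd * pd);
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Resample `vol` under the affine map y = A (x - c) + c + t: the output at
// voxel y takes the value of the input at x = Ainv (y - c - t) + c.
// method: 0 = trilinear, 1 = Lanczos a=3 (per-axis weights renormalized).
// Source points outside [1, n] on any axis are zeroed and flagged.
// [[Rcpp::export]]
List cpp_affine_resample(NumericVector vol, IntegerVector dim,
                         NumericMatrix Ainv, NumericVector center,
                         NumericVector shift, int method) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  LogicalVector inside(n);
  const double a11 = Ainv(0,0), a12 = Ainv(0,1), a13 = Ainv(0,2);
  const double a21 = Ainv(1,0), a22 = Ainv(1,1), a23 = Ainv(1,2);
  const double a31 = Ainv(2,0), a32 = Ainv(2,1), a33 = Ainv(2,2);
  const double c1 = center[0], c2 = center[1], c3 = center[2];
  const double t1 = shift[0], t2 = shift[1], t3 = shift[2];
  const double *v = REAL(vol);

  double wx[6], wy[6], wz[6];
  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k) {
    const double dz = (k + 1) - c3 - t3;
    for (int j = 0; j < n2; ++j) {
      const double dy = (j + 1) - c2 - t2;
      for (int i = 0; i < n1; ++i, ++idx) {
        const double dx = (i + 1) - c1 - t1;
        const double sx = a11*dx + a12*dy + a13*dz + c1;
        const double sy = a21*dx + a22*dy + a23*dz + c2;
        const double sz = a31*dx + a32*dy + a33*dz + c3;
        if (sx < 1.0 || sx > n1 || sy < 1.0 || sy > n2 ||
            sz < 1.0 || sz > n3) {
          out[idx] = 0.0; inside[idx] = false; continue;
        }
        inside[idx] = true;
        if (method == 0) {
          int i0 = (int)std::floor(sx) - 1, j0 = (int)std::floor(sy) - 1,
              k0 = (int)std::floor(sz) - 1;
          double fx = sx - (i0 + 1), fy = sy - (j0 + 1), fz = sz - (k0 + 1);
          int i1 = clampi(i0 + 1, 0, n1 - 1), j1 = clampi(j0 + 1, 0, n2 - 1),
              k1 = clampi(k0 + 1, 0, n3 - 1);
          i0 = clampi(i0, 0, n1 - 1); j0 = clampi(j0, 0, n2 - 1);
          k0 = clampi(k0, 0, n3 - 1);
          #define V(ii,jj,kk) v[(R_xlen_t)(ii) + (R_xlen_t)n1*((jj) + (R_xlen_t)n2*(kk))]
          double c00 = V(i0,j0,k0)*(1-fx) + V(i1,j0,k0)*fx;
          double c10 = V(i0,j1,k0)*(1-fx) + V(i1,j1,k0)*fx;
          double c01 = V(i0,j0,k1)*(1-fx) + V(i1,j0,k1)*fx;
          double c11 = V(i0,j1,k1)*(1-fx) + V(i1,j1,k1)*fx;
          double c0 = c00*(1-fy) + c10*fy;
          double c1v = c01*(1-fy) + c11*fy;
          out[idx] = c0*(1-fz) + c1v*fz;
        } else {
          // Lanczos-3: 6 taps per axis around the source point
          int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
              iz = (int)std::floor(sz);
          double swx = 0, swy = 0, swz = 0;
          for (int m = 0; m < 6; ++m) {
            wx[m] = lanczos3(sx - (ix - 2 + m)); swx += wx[m];
            wy[m] = lanczos3(sy - (iy - 2 + m)); swy += wy[m];
            wz[m] = lanczos3(sz - (iz - 2 + m)); swz += wz[m];
          }
          double acc = 0.0;
          for (int mz = 0; mz < 6; ++mz) {
            if (wz[mz] == 0.0) continue;
            int kk = clampi(iz - 3 + mz, 0, n3 - 1);
            double accy = 0.0;
            for (int my = 0; my < 6; ++my) {
              if (wy[my] == 0.0) continue;
              int jj = clampi(iy - 3 + my, 0, n2 - 1);
              double accx = 0.0;
              const double *row = v + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
              for (int mx = 0; mx < 6; ++mx) {
                if (wx[mx] == 0.0) continue;
                int ii = clampi(ix - 3 + mx, 0, n1 - 1);
                accx += wx[mx] * row[ii];
              }
              accy += wy[my] * accx;
            }
            acc += wz[mz] * accy;
          }
          out[idx] = acc / (swx * swy * swz);
          #undef V
        }
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

struct WsNode {
  double prio;
  R_xlen_t order;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled watershed by priority flooding (6-connectivity):
// marker voxels keep their labels; unlabeled voxels are flooded in order of
// increasing `priority` (typically gradient magnitude).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(clone(markers));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t order = 0;
  const int *mk = INTEGER(markers);
  const double *pr = REAL(priority);
  int *lb = INTEGER(labels);

  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (mk[idx] > 0) pq.push(WsNode{pr[idx], order++, idx, mk[idx]});
  }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t idx = nd.idx;
    if (lb[idx] > 0 && lb[idx] != nd.label && mk[idx] == 0) continue;
    if (lb[idx] == 0) lb[idx] = nd.label;
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / s3);
    R_xlen_t nb[6]; int nn = 0;
    if (i > 0)      nb[nn++] = idx - s1;
    if (i < n1 - 1) nb[nn++] = idx + s1;
    if (j > 0)      nb[nn++] = idx - s2;
    if (j < n2 - 1) nb[nn++] = idx + s2;
    if (k > 0)      nb[nn++] = idx - s3;
    if (k < n3 - 1) nb[nn++] = idx + s3;
    for (int q = 0; q < nn; ++q) {
      R_xlen_t v = nb[q];
      if (lb[v] == 0) {
        lb[v] = lb[idx];
        pq.push(WsNode{pr[v], order++, v, lb[idx]});
      }
    }
  }
  return labels;
}
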