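#include <Rcpp.h>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection, no backface culling.
// All rays originate at the origin of the current frame. `dirs` is n x 3
// (unit direction per ray), `V` is m x 3 vertices, `F` is k x 3 zero-based
// triangle indices. Returns the nearest hit distance per ray (NA if the ray
// misses every triangle) and the 1-based index of the hit triangle.
// [[Rcpp::export]]
List cpp_cast_rays(NumericMatrix dirs, NumericMatrix V, IntegerMatrix F) {
  const int n = dirs.nrow(), k = F.nrow();
  const double eps = 1e-12, tol = 1e-9;
  NumericVector tout(n, R_PosInf);
  IntegerVector tri(n, NA_INTEGER);
  for (int j = 0; j < k; ++j) {
    const int ia = F(j, 0), ib = F(j, 1), ic = F(j, 2);
    const double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    const double e1x = V(ib, 0) - ax, e1y = V(ib, 1) - ay, e1z = V(ib, 2) - az;
    const double e2x = V(ic, 0) - ax, e2y = V(ic, 1) - ay, e2z = V(ic, 2) - az;
    for (int i = 0; i < n; ++i) {
      const double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
      const double px = dy * e2z - dz * e2y;
      const double py = dz * e2x - dx * e2z;
      const double pz = dx * e2y - dy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      const double inv = 1.0 / det;
      // origin - vertex a
      const double sx = -ax, sy = -ay, sz = -az;
      const double u = (sx * px + sy * py + sz * pz) * inv;
      if (u < -tol || u > 1.0 + tol) continue;
      const double qx = sy * e1z - sz * e1y;
      const double qy = sz * e1x - sx * e1z;
      const double qz = sx * e1y - sy * e1x;
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -tol || u + v > 1.0 + tol) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t > tol && t < tout[i]) {
        tout[i] = t;
        tri[i] = j + 1;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    if (tri[i] == NA_INTEGER) tout[i] = NA_REAL;
  return List::create(_["t"] = tout, _["tri"] = tri);
}

// Unsigned distance from each point to the nearest triangle of a mesh.
// Used as the geometric oracle for round-trip scan tests.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  const int n = P.nrow(), k = F.nrow();
  NumericVector out(n, R_PosInf);
  for (int j = 0; j < k; ++j) {
    const int ia = F(j, 0), ib = F(j, 1), ic = F(j, 2);
    const double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    const double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    const double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);
    const double abx = bx - ax, aby = by - ay, abz = bz - az;
    const double acx = cx - ax, acy = cy - ay, acz = cz - az;
    for (int i = 0; i < n; ++i) {
      const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
      // closest point on triangle (Ericson, Real-Time Collision Detection)
      const double apx = px - ax, apy = py - ay, apz = pz - az;
      const double d1 = abx * apx + aby * apy + abz * apz;
      const double d2 = acx * apx + acy * apy + acz * apz;
      double qx, qy, qz;
      if (d1 <= 0.0 && d2 <= 0.0) {
        qx = ax; qy = ay; qz = az;
      } else {
        const double bpx = px - bx, bpy = py - by, bpz = pz - bz;
        const double d3 = abx * bpx + aby * bpy + abz * bpz;
        const double d4 = acx * bpx + acy * bpy + acz * bpz;
        if (d3 >= 0.0 && d4 <= d3) {
          qx = bx; qy = by; qz = bz;
        } else {
          const double vc = d1 * d4 - d3 * d2;
          if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
            const double w = d1 / (d1 - d3);
            qx = ax + w * abx; qy = ay + w * aby; qz = az + w * abz;
          } else {
            const double cpx = px - cx, cpy = py - cy, cpz = pz - cz;
            const double d5 = abx * cpx + aby * cpy + abz * cpz;
            const double d6 = acx * cpx + acy * cpy + acz * cpz;
            if (d6 >= 0.0 && d5 <= d6) {
              qx = cx; qy = cy; qz = cz;
            } else {
              const double vb = d5 * d2 - d1 * d6;
              if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
                const double w = d2 / (d2 - d6);
                qx = ax + w * acx; qy = ay + w * acy; qz = az + w * acz;
              } else {
                const double va = d3 * d6 - d5 * d4;
                if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
                  const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                  qx = bx + w * (cx - bx);
                  qy = by + w * (cy - by);
                  qz = bz + w * (cz - bz);
                } else {
                  const double denom = 1.0 / (va + vb + vc);
                  const double v = vb * denom, w = vc * denom;
                  qx = ax + abx * v + acx * w;
                  qy = ay + aby * v + acy * w;
                  qz = az + abz * v + acz * w;
                }
              }
            }
          }
        }
      }
      const double ddx = px - qx, ddy = py - qy, ddz = pz - qz;
      const double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < out[i]) out[i] = d;
    }
  }
  return out;
}
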