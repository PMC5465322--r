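// Numerical core of the three-force epiboly model: spring forces on the EVL
// vertex network, geodesic point-to-arc distances, and the overdamped Euler
// integrator that advances EVL vertices and DCL particles on the egg sphere.
#include <Rcpp.h>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double angv(const double* a, const double* b) {
  double c[3];
  cross3(a, b, c);
  return std::atan2(norm3(c), dot3(a, b));
}

// Geodesic angle from unit point p to the great-circle arc (a, b); if
// closest != NULL the closest unit point on the arc is written there.
static double point_arc_angle(const double* p, const double* a,
                              const double* b, double* closest) {
  double n[3];
  cross3(a, b, n);
  double nn = norm3(n);
  double ab = angv(a, b);
  if (nn < 1e-14) {  // degenerate (coincident or antipodal endpoints)
    double da = angv(p, a), db = angv(p, b);
    const double* e = (da <= db) ? a : b;
    if (closest) { closest[0] = e[0]; closest[1] = e[1]; closest[2] = e[2]; }
    return std::min(da, db);
  }
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  double pn = dot3(p, n);
  double s[3] = {p[0] - pn * n[0], p[1] - pn * n[1], p[2] - pn * n[2]};
  double sn = norm3(s);
  bool inside = false;
  double f[3];
  if (sn > 1e-14) {
    for (int k = 0; k < 3; ++k) f[k] = s[k] / sn;
    inside = (angv(a, f) + angv(f, b)) <= ab + 1e-10;
  }
  if (inside) {
    if (closest) { closest[0] = f[0]; closest[1] = f[1]; closest[2] = f[2]; }
    return angv(p, f);
  }
  double da = angv(p, a), db = angv(p, b);
  const double* e = (da <= db) ? a : b;
  if (closest) { closest[0] = e[0]; closest[1] = e[1]; closest[2] = e[2]; }
  return std::min(da, db);
}

// [[Rcpp::export]]
NumericVector point_segments_min_angle(NumericMatrix P, NumericMatrix V,
                                       IntegerVector segA, IntegerVector segB) {
  int np = P.nrow(), ns = segA.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      double a[3] = {V(segA[s], 0), V(segA[s], 1), V(segA[s], 2)};
      double b[3] = {V(segB[s], 0), V(segB[s], 1), V(segB[s], 2)};
      double d = point_arc_angle(p, a, b, nullptr);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Hookean spring forces on the EVL vertex network, optionally projected to
// the local tangent plane of the sphere.
// [[Rcpp::export]]
NumericMatrix evl_forces_cpp(NumericMatrix vert, IntegerVector si,
                             IntegerVector sj, NumericVector rest,
                             NumericVector stiff, double U0, bool project) {
  int nv = vert.nrow(), ns = si.size();
  NumericMatrix F(nv, 3);
  for (int s = 0; s < ns; ++s) {
    int i = si[s], j = sj[s];
    double d[3] = {vert(j, 0) - vert(i, 0), vert(j, 1) - vert(i, 1),
                   vert(j, 2) - vert(i, 2)};
    double len = norm3(d);
    if (len < 1e-12) stop("coincident spring endpoints");
    double f = U0 * stiff[s] * (len - rest[s]) / len;
    for (int k = 0; k < 3; ++k) {
      F(i, k) += f * d[k];
      F(j, k) -= f * d[k];
    }
  }
  if (project) {
    for (int i = 0; i < nv; ++i) {
      double r[3] = {vert(i, 0), vert(i, 1), vert(i, 2)};
      double rn = norm3(r);
      if (rn < 1e-12) stop("vertex at the sphere centre");
      for (int k = 0; k < 3; ++k) r[k] /= rn;
      double fr = F(i, 0) * r[0] + F(i, 1) * r[1] + F(i, 2) * r[2];
      for (int k = 0; k < 3; ++k) F(i, k) -= fr * r[k];
    }
  }
  return F;
}

// Barycentric-style weights of p with respect to 3 points (least squares
// with sum-to-one constraint); falls back to inverse-distance weights for
// degenerate triangles.
static void bary3(const double* p, const double* v1, const double* v2,
                  const double* v3, double* w) {
  double e1[3] = {v2[0] - v1[0], v2[1] - v1[1], v2[2] - v1[2]};
  double e2[3] = {v3[0] - v1[0], v3[1] - v1[1], v3[2] - v1[2]};
  double q[3] = {p[0] - v1[0], p[1] - v1[1], p[2] - v1[2]};
  double a = dot3(e1, e1), b = dot3(e1, e2), c = dot3(e2, e2);
  double det = a * c - b * b;
  double scale = std::max(a, c);
  if (scale < 1e-20 || det < 1e-10 * scale * scale) {
    double d1 = std::max(1e-9, std::sqrt(dot3(q, q)));
    double q2[3] = {p[0] - v2[0], p[1] - v2[1], p[2] - v2[2]};
    double q3[3] = {p[0] - v3[0], p[1] - v3[1], p[2] - v3[2]};
    double d2 = std::max(1e-9, norm3(q2)), d3 = std::max(1e-9, norm3(q3));
    double s = 1 / d1 + 1 / d2 + 1 / d3;
    w[0] = (1 / d1) / s; w[1] = (1 / d2) / s; w[2] = (1 / d3) / s;
    return;
  }
  double r1 = dot3(e1, q), r2 = dot3(e2, q);
  w[1] = (c * r1 - b * r2) / det;
  w[2] = (a * r2 - b * r1) / det;
  w[0] = 1.0 - w[1] - w[2];
}

// [[Rcpp::export]]
NumericVector bary3_weights_cpp(NumericVector p, NumericMatrix tri) {
  double w[3];
  double pp[3] = {p[0], p[1], p[2]};
  double v1[3] = {tri(0, 0), tri(0, 1), tri(0, 2)};
  double v2[3] = {tri(1, 0), tri(1, 1), tri(1, 2)};
  double v3[3] = {tri(2, 0), tri(2, 1), tri(2, 2)};
  bary3(pp, v1, v2, v3, w);
  return NumericVector::create(w[0], w[1], w[2]);
}

static inline void reproject(double* p, double R) {
  double n = norm3(p);
  for (int k = 0; k < 3; ++k) p[k] *= R / n;
}

// Forward-Euler overdamped integration of the full three-force model.
// Returns recorded frames for EVL vertices and DCL particles.
// [[Rcpp::export]]
List simulate_core(NumericMatrix vert0, LogicalVector isBorder,
                   IntegerVector si, IntegerVector sj, NumericVector rest,
                   NumericVector stiff,
                   IntegerVector edgeA, IntegerVector edgeB,
                   NumericMatrix dcl0, NumericVector radius0,
                   IntegerVector divStep, double U0, double V0, double U1,
                   double U2, double a2, double noiseSdStep, double drag,
                   double dt, double R, int nSteps, int recordEvery,
                   double attractionScale) {
  int nv = vert0.nrow();
  int n0 = dcl0.nrow();
  int maxn = 2 * n0;
  int nFrames = nSteps / recordEvery + 1;
  int nEdges = edgeA.size();

  std::vector<double> vert(nv * 3), vvel(nv * 3, 0.0);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) vert[3 * i + k] = vert0(i, k);

  std::vector<double> dcl(maxn * 3, NA_REAL), rad(maxn, NA_REAL);
  std::vector<int> parent(maxn, -1);
  std::vector<bool> alive(maxn, false), divided(maxn, false);
  for (int i = 0; i < n0; ++i) {
    for (int k = 0; k < 3; ++k) dcl[3 * i + k] = dcl0(i, k);
    rad[i] = radius0[i];
    alive[i] = true;
  }
  int nAlive = n0;

  NumericVector evlRec(nFrames * nv * 3);
  NumericVector dclRec(nFrames * maxn * 3, NA_REAL);
  NumericMatrix radRec(maxn, nFrames);
  std::fill(radRec.begin(), radRec.end(), NA_REAL);

  double cutoff = (a2 > 0) ? 6.0 * a2 : 0.0;  // force support of the Gaussian
  double maxDisp = 0.1 * R;
  int frame = 0;
  auto record = [&](int f) {
    for (int i = 0; i < nv; ++i)
      for (int k = 0; k < 3; ++k)
        evlRec[f * nv * 3 + 3 * i + k] = vert[3 * i + k];
    for (int i = 0; i < maxn; ++i) {
      if (alive[i]) {
        for (int k = 0; k < 3; ++k)
          dclRec[f * maxn * 3 + 3 * i + k] = dcl[3 * i + k];
        radRec(i, f) = rad[i];
      }
    }
  };
  record(frame++);

  std::vector<double> newv(nv * 3), force(nv * 3);
  std::vector<double> uvert(nv * 3);

  for (int step = 0; step < nSteps; ++step) {
    // --- EVL vertices: springs on bulk, imposed meridian velocity on margin
    std::fill(force.begin(), force.end(), 0.0);
    for (int s = 0; s < (int)si.size(); ++s) {
      int i = si[s], j = sj[s];
      double d[3] = {vert[3 * j] - vert[3 * i],
                     vert[3 * j + 1] - vert[3 * i + 1],
                     vert[3 * j + 2] - vert[3 * i + 2]};
      double len = norm3(d);
      if (len < 1e-12) stop("coincident spring endpoints at step %d", step);
      double f = U0 * stiff[s] * (len - rest[s]) / len;
      for (int k = 0; k < 3; ++k) {
        force[3 * i + k] += f * d[k];
        force[3 * j + k] -= f * d[k];
      }
    }
    for (int i = 0; i < nv; ++i) {
      double p[3] = {vert[3 * i], vert[3 * i + 1], vert[3 * i + 2]};
      double vel[3];
      if (isBorder[i]) {
        double rho = std::sqrt(p[0] * p[0] + p[1] * p[1]);
        if (rho < 1e-9 * R) {
          vel[0] = vel[1] = vel[2] = 0.0;  // clamped at a pole
        } else {
          // unit vector of increasing polar angle (toward the vegetal pole)
          vel[0] = V0 * p[2] * p[0] / (R * rho);
          vel[1] = V0 * p[2] * p[1] / (R * rho);
          vel[2] = -V0 * rho / R;
        }
      } else {
        double rn = norm3(p);
        double rh[3] = {p[0] / rn, p[1] / rn, p[2] / rn};
        double fr = dot3(&force[3 * i], rh);
        for (int k = 0; k < 3; ++k)
          vel[k] = force[3 * i + k] - fr * rh[k];
      }
      double q[3];
      for (int k = 0; k < 3; ++k) q[k] = p[k] + vel[k] * dt;
      reproject(q, R);
      for (int k = 0; k < 3; ++k) {
        newv[3 * i + k] = q[k];
        vvel[3 * i + k] = (q[k] - p[k]) / dt;
      }
    }
    std::copy(newv.begin(), newv.end(), vert.begin());
    for (int i = 0; i < nv; ++i)
      for (int k = 0; k < 3; ++k) uvert[3 * i + k] = vert[3 * i + k] / R;

    // --- DCL particles
    std::vector<double> disp(maxn * 3, 0.0);
    for (int i = 0; i < maxn; ++i) {
      if (!alive[i]) continue;
      double p[3] = {dcl[3 * i], dcl[3 * i + 1], dcl[3 * i + 2]};
      double rn = norm3(p);
      double rh[3] = {p[0] / rn, p[1] / rn, p[2] / rn};
      double f[3] = {0, 0, 0};
      // soft-sphere repulsion
      if (U1 > 0) {
        for (int j = 0; j < maxn; ++j) {
          if (j == i || !alive[j]) continue;
          double d[3] = {p[0] - dcl[3 * j], p[1] - dcl[3 * j + 1],
                         p[2] - dcl[3 * j + 2]};
          double len = norm3(d);
          double touch = rad[i] + rad[j];
          if (len < touch && len > 1e-9) {
            double fm = U1 * (touch - len) / len;
            for (int k = 0; k < 3; ++k) f[k] += fm * d[k];
          }
        }
      }
      // Gaussian attraction to the nearest EVL cell border
      if (U2 > 0 && nEdges > 0) {
        double up[3] = {rh[0], rh[1], rh[2]};
        double bestAng = R_PosInf, bestPt[3] = {0, 0, 0};
        for (int s = 0; s < nEdges; ++s) {
          const double* a = &uvert[3 * edgeA[s]];
          const double* b = &uvert[3 * edgeB[s]];
          // quick reject: chord lower bound on the distance
          double ca[3] = {up[0] - a[0], up[1] - a[1], up[2] - a[2]};
          double abv[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
          double lb = (norm3(ca) - norm3(abv)) * R;  // chord <= arc
          if (lb > cutoff && lb > bestAng * R) continue;
          double cp[3];
          double ang = point_arc_angle(up, a, b, cp);
          if (ang < bestAng) {
            bestAng = ang;
            for (int k = 0; k < 3; ++k) bestPt[k] = cp[k];
          }
        }
        double dgeo = bestAng * R;
        if (R_finite(dgeo) && dgeo < cutoff && dgeo > 1e-9) {
          double dir[3] = {bestPt[0] * R - p[0], bestPt[1] * R - p[1],
                           bestPt[2] * R - p[2]};
          double dn = norm3(dir);
          if (dn > 1e-12) {
            double fm = U2 * attractionScale * (dgeo / (a2 * a2)) *
                        std::exp(-dgeo * dgeo / (2 * a2 * a2)) / dn;
            for (int k = 0; k < 3; ++k) f[k] += fm * dir[k];
          }
        }
      }
      // drag: barycentric blend of the 3 nearest EVL vertex velocities
      if (drag > 0 && nv >= 3) {
        int b1 = -1, b2 = -1, b3 = -1;
        double d1 = R_PosInf, d2 = R_PosInf, d3 = R_PosInf;
        for (int v = 0; v < nv; ++v) {
          double d[3] = {p[0] - vert[3 * v], p[1] - vert[3 * v + 1],
                         p[2] - vert[3 * v + 2]};
          double dd = dot3(d, d);
          if (dd < d1) {
            d3 = d2; b3 = b2; d2 = d1; b2 = b1; d1 = dd; b1 = v;
          } else if (dd < d2) {
            d3 = d2; b3 = b2; d2 = dd; b2 = v;
          } else if (dd < d3) {
            d3 = dd; b3 = v;
          }
        }
        double w[3];
        bary3(p, &vert[3 * b1], &vert[3 * b2], &vert[3 * b3], w);
        for (int k = 0; k < 3; ++k)
          f[k] += drag * (w[0] * vvel[3 * b1 + k] + w[1] * vvel[3 * b2 + k] +
                          w[2] * vvel[3 * b3 + k]);
      }
      // tangent projection of the deterministic displacement
      double fr = dot3(f, rh);
      for (int k = 0; k < 3; ++k) disp[3 * i + k] = (f[k] - fr * rh[k]) * dt;
      // tangential Gaussian noise
      if (noiseSdStep > 0) {
        double e1[3], e2[3];
        double ax[3] = {1, 0, 0};
        if (std::fabs(rh[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
        cross3(rh, ax, e1);
        double n1 = norm3(e1);
        for (int k = 0; k < 3; ++k) e1[k] /= n1;
        cross3(rh, e1, e2);
        double g1 = R::rnorm(0.0, noiseSdStep);
        double g2 = R::rnorm(0.0, noiseSdStep);
        for (int k = 0; k < 3; ++k)
          disp[3 * i + k] += g1 * e1[k] + g2 * e2[k];
      }
      double dnorm = norm3(&disp[3 * i]);
      if (dnorm > maxDisp)
        stop("integration instability: particle displacement %.1f um exceeds 0.1 R in one step",
             dnorm);
    }
    for (int i = 0; i < maxn; ++i) {
      if (!alive[i]) continue;
      double q[3] = {dcl[3 * i] + disp[3 * i], dcl[3 * i + 1] + disp[3 * i + 1],
                     dcl[3 * i + 2] + disp[3 * i + 2]};
      reproject(q, R);
      for (int k = 0; k < 3; ++k) dcl[3 * i + k] = q[k];
    }

    // --- divisions scheduled for this step
    for (int i = 0; i < n0; ++i) {
      if (divStep[i] == step && alive[i]) {
        if (divided[i])
          stop("schedule validation: cell %d scheduled to divide twice", i + 1);
        double p[3] = {dcl[3 * i], dcl[3 * i + 1], dcl[3 * i + 2]};
        double rn = norm3(p);
        double rh[3] = {p[0] / rn, p[1] / rn, p[2] / rn};
        double e1[3], e2[3];
        double ax[3] = {1, 0, 0};
        if (std::fabs(rh[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
        cross3(rh, ax, e1);
        double n1 = norm3(e1);
        for (int k = 0; k < 3; ++k) e1[k] /= n1;
        cross3(rh, e1, e2);
        double phi = R::runif(0.0, 2.0 * M_PI);
        double dir[3];
        for (int k = 0; k < 3; ++k)
          dir[k] = std::cos(phi) * e1[k] + std::sin(phi) * e2[k];
        double half = rad[i] / 2.0;
        double rdaughter = rad[i] * std::pow(0.5, 1.0 / 3.0);
        int j = nAlive;  // new slot
        if (j >= maxn) stop("division overflow");
        for (int k = 0; k < 3; ++k) {
          double q1 = p[k] + half * dir[k];
          double q2 = p[k] - half * dir[k];
          dcl[3 * i + k] = q1;
          dcl[3 * j + k] = q2;
        }
        reproject(&dcl[3 * i], R);
        reproject(&dcl[3 * j], R);
        rad[i] = rdaughter;
        rad[j] = rdaughter;
        divided[i] = true;
        divided[j] = true;
        alive[j] = true;
        parent[j] = i;
        ++nAlive;
      }
    }

    if ((step + 1) % recordEvery == 0) record(frame++);
  }

  evlRec.attr("dim") = IntegerVector::create(3, nv, nFrames);
  dclRec.attr("dim") = IntegerVector::create(3, maxn, nFrames);
  IntegerVector par(maxn);
  for (int i = 0; i < maxn; ++i) par[i] = parent[i] + 1;  // 1-based, 0 = none
  return List::create(_["evl"] = evlRec, _["dcl"] = dclRec,
                      _["radius"] = radRec, _["parent"] = par,
                      _["nParticles"] = nAlive, _["nFrames"] = nFrames);
}
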