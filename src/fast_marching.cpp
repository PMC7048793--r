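// Fast-marching solver for the Eikonal equation |grad T| = 1/f on a regular
// anisotropic 3D grid, plus geodesic backtracing on the arrival-time field
// and brute-force nearest-point queries used for distance transforms.
//
// Grid convention: arrays are column-major (R layout), voxel (i,j,k) 0-based,
// physical center of voxel i along axis a is (i + 0.5) * h[a] mm.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Grid {
  int n[3];
  double h[3];
  inline int idx(int i, int j, int k) const {
    return i + n[0] * (j + n[1] * k);
  }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < n[0] && j < n[1] && k < n[2];
  }
};

// Solve sum_a (a_i t + b_i)^2 = rhs2 for the largest root t, where each term
// is the upwind difference operator of one axis (first- or second-order).
// `v` holds the one-step upwind values used for the causality check.
static double eikonal_update(const double acoef[3], const double bcoef[3],
                             const double v[3], double rhs2) {
  int ord[3] = {0, 1, 2};
  for (int a = 0; a < 3; ++a)
    for (int b = a + 1; b < 3; ++b)
      if (v[ord[b]] < v[ord[a]]) std::swap(ord[a], ord[b]);

  double best = INF;
  double A = 0.0, B = 0.0, C = -rhs2;
  for (int m = 0; m < 3; ++m) {
    int ax = ord[m];
    double vm = v[ax];
    if (!std::isfinite(vm)) break;
    A += acoef[ax] * acoef[ax];
    B += 2.0 * acoef[ax] * bcoef[ax];
    C += bcoef[ax] * bcoef[ax];
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) continue;
    double t = (-B + std::sqrt(disc)) / (2.0 * A);
    // causality: t must exceed every one-step value used
    if (t >= vm) best = t;
  }
  return best;
}

// [[Rcpp::export(name = ".cw_fmm")]]
NumericVector cw_fmm(NumericVector speed, NumericVector spacing,
                     IntegerVector seed_vox) {
  IntegerVector dims = speed.attr("dim");
  if (dims.size() != 3) stop("speed must be a 3D array");
  Grid g;
  for (int a = 0; a < 3; ++a) { g.n[a] = dims[a]; g.h[a] = spacing[a]; }
  const int ntot = g.n[0] * g.n[1] * g.n[2];

  NumericVector T(ntot, R_PosInf);
  std::vector<char> alive(ntot, 0);

  const int si = seed_vox[0], sj = seed_vox[1], sk = seed_vox[2];
  if (!g.inside(si, sj, sk)) stop("seed voxel outside grid");
  const int sidx = g.idx(si, sj, sk);
  if (speed[sidx] <= 0) stop("seed voxel has zero speed");

  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  T[sidx] = 0.0;
  alive[sidx] = 1;

  // Analytic initialisation in a small ball around the seed tempers the
  // source-point singularity of the upwind scheme: voxels with an unbroken
  // line of sight through medium of the seed's speed get their exact
  // arrival time; heterogeneous face neighbours get a trapezoidal estimate.
  const int R = 3;
  const double fs = speed[sidx];
  for (int dk = -R; dk <= R; ++dk)
    for (int dj = -R; dj <= R; ++dj)
      for (int di = -R; di <= R; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int i = si + di, j = sj + dj, k = sk + dk;
        if (!g.inside(i, j, k)) continue;
        int id = g.idx(i, j, k);
        if (speed[id] <= 0) continue;
        double dist = std::sqrt(di * di * g.h[0] * g.h[0] +
                                dj * dj * g.h[1] * g.h[1] +
                                dk * dk * g.h[2] * g.h[2]);
        bool clear = true;
        int nsmp = 2 * R + 2;
        for (int s = 1; s < nsmp && clear; ++s) {
          double fr = (double)s / nsmp;
          int ii = si + (int)std::lround(fr * di);
          int jj = sj + (int)std::lround(fr * dj);
          int kk = sk + (int)std::lround(fr * dk);
          if (speed[g.idx(ii, jj, kk)] != fs) clear = false;
        }
        double t;
        if (clear && speed[id] == fs) {
          t = dist / fs;
        } else if (std::abs(di) + std::abs(dj) + std::abs(dk) == 1) {
          t = dist * 0.5 * (1.0 / fs + 1.0 / speed[id]);
        } else {
          continue;
        }
        if (t < T[id]) { T[id] = t; heap.push(Node(t, id)); }
      }

  const int off[3] = {1, g.n[0], g.n[0] * g.n[1]};

  while (!heap.empty()) {
    Node nd = heap.top(); heap.pop();
    int id = nd.second;
    if (alive[id]) continue;
    if (nd.first > T[id]) continue; // stale entry
    alive[id] = 1;

    int k = id / (g.n[0] * g.n[1]);
    int j = (id / g.n[0]) % g.n[1];
    int i = id % g.n[0];

    // relax the 6 face neighbours
    for (int a = 0; a < 3; ++a) {
      for (int s = -1; s <= 1; s += 2) {
        int ii = i + (a == 0 ? s : 0);
        int jj = j + (a == 1 ? s : 0);
        int kk = k + (a == 2 ? s : 0);
        if (!g.inside(ii, jj, kk)) continue;
        int nid = g.idx(ii, jj, kk);
        if (alive[nid] || speed[nid] <= 0) continue;

        // per-axis upwind operator (a t + b); a second-order difference is
        // used when two consecutive upstream values are available, causal,
        // and the stencil does not straddle a speed interface (where the
        // wide difference would be inconsistent)
        double v[3], acoef[3], bcoef[3];
        for (int b = 0; b < 3; ++b) {
          v[b] = INF; acoef[b] = 0; bcoef[b] = 0;
          double hb = g.h[b];
          for (int s = -1; s <= 1; s += 2) {
            int p1[3] = {ii, jj, kk}; p1[b] += s;
            if (!g.inside(p1[0], p1[1], p1[2])) continue;
            int q1 = g.idx(p1[0], p1[1], p1[2]);
            if (!alive[q1]) continue;
            double T1 = T[q1];
            if (T1 >= v[b]) continue;
            v[b] = T1;
            acoef[b] = 1.0 / hb;
            bcoef[b] = -T1 / hb;
            int p2[3] = {ii, jj, kk}; p2[b] += 2 * s;
            if (g.inside(p2[0], p2[1], p2[2])) {
              int q2 = g.idx(p2[0], p2[1], p2[2]);
              if (alive[q2] && T[q2] <= T1 &&
                  speed[q1] == speed[nid] && speed[q2] == speed[nid]) {
                acoef[b] = 1.5 / hb;
                bcoef[b] = (-2.0 * T1 + 0.5 * T[q2]) / hb;
              }
            }
          }
        }
        double rhs2 = 1.0 / (speed[nid] * speed[nid]);
        double t = eikonal_update(acoef, bcoef, v, rhs2);
        if (t < T[nid]) { T[nid] = t; heap.push(Node(t, nid)); }
      }
    }
  }

  T.attr("dim") = dims;
  return T;
}

// trilinear interpolation of T at continuous voxel coordinates (0-based,
// voxel centers at integers); infinities are clamped to a large finite value
// so the gradient pushes trajectories away from forbidden regions.
static double interp_T(const NumericVector &T, const Grid &g, const double u[3]) {
  const double BIG = 1e30;
  double c[3]; int i0[3];
  for (int a = 0; a < 3; ++a) {
    double x = u[a];
    if (x < 0) x = 0;
    if (x > g.n[a] - 1) x = g.n[a] - 1;
    i0[a] = (int)std::floor(x);
    if (i0[a] > g.n[a] - 2) i0[a] = g.n[a] - 2;
    if (i0[a] < 0) i0[a] = 0;
    c[a] = x - i0[a];
  }
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        double w = (di ? c[0] : 1 - c[0]) * (dj ? c[1] : 1 - c[1]) * (dk ? c[2] : 1 - c[2]);
        if (w == 0) continue;
        double val = T[g.idx(i0[0] + di, i0[1] + dj, i0[2] + dk)];
        if (!std::isfinite(val) || val > BIG) val = BIG;
        acc += w * val;
      }
  return acc;
}

// Arclength of a polyline after moving-average smoothing with a window of
// `win` points (endpoint runs are kept raw); suppresses the sub-voxel
// zigzag that steepest descent accumulates where the arrival field is flat.
static double smoothed_length(const std::vector<double> &path, int win) {
  int n = (int)path.size() / 3;
  if (n < 2) return 0.0;
  if (win < 3 || n <= win) {
    double L = 0;
    for (int r = 1; r < n; ++r) {
      double s = 0;
      for (int a = 0; a < 3; ++a) {
        double d = path[3 * r + a] - path[3 * (r - 1) + a];
        s += d * d;
      }
      L += std::sqrt(s);
    }
    return L;
  }
  int k = win / 2;
  std::vector<double> sm(path.size());
  for (int r = 0; r < n; ++r) {
    if (r < k || r >= n - k) {
      for (int a = 0; a < 3; ++a) sm[3 * r + a] = path[3 * r + a];
    } else {
      for (int a = 0; a < 3; ++a) {
        double acc = 0;
        for (int q = r - k; q <= r + k; ++q) acc += path[3 * q + a];
        sm[3 * r + a] = acc / (2 * k + 1);
      }
    }
  }
  double L = 0;
  for (int r = 1; r < n; ++r) {
    double s = 0;
    for (int a = 0; a < 3; ++a) {
      double d = sm[3 * r + a] - sm[3 * (r - 1) + a];
      s += d * d;
    }
    L += std::sqrt(s);
  }
  return L;
}

// Single steepest-descent trace on T from `start` (mm) to the seed (mm).
// Returns the arclength (mm); optionally records the polyline.
static double trace_one(const NumericVector &T, const Grid &g,
                        const double start[3], const double seed[3],
                        double step, double stop_radius, double smooth_mm,
                        std::vector<double> *path, bool &ok) {
  std::vector<double> own;
  std::vector<double> *pts = path ? path : &own;
  double p[3] = {start[0], start[1], start[2]};
  ok = true;

  double d2seed = 0;
  for (int a = 0; a < 3; ++a) d2seed += (p[a] - seed[a]) * (p[a] - seed[a]);

  double diag = 0;
  for (int a = 0; a < 3; ++a) diag += g.n[a] * g.h[a] * g.n[a] * g.h[a];
  const long max_steps = (long)(20.0 * std::sqrt(diag) / step) + 100;

  pts->push_back(p[0]); pts->push_back(p[1]); pts->push_back(p[2]);

  long stall = 0;
  for (long it = 0; it < max_steps; ++it) {
    if (std::sqrt(d2seed) <= stop_radius) break;

    double u[3];
    for (int a = 0; a < 3; ++a) u[a] = p[a] / g.h[a] - 0.5;

    // gradient by central differences of the interpolated field
    double gvec[3];
    for (int a = 0; a < 3; ++a) {
      double up[3] = {u[0], u[1], u[2]}, um[3] = {u[0], u[1], u[2]};
      double del = 0.5; // half a voxel in index units
      up[a] += del; um[a] -= del;
      gvec[a] = (interp_T(T, g, up) - interp_T(T, g, um)) / (2 * del * g.h[a]);
    }
    double norm = std::sqrt(gvec[0] * gvec[0] + gvec[1] * gvec[1] + gvec[2] * gvec[2]);

    double pn[3];
    bool moved = false;
    if (norm > 0 && std::isfinite(norm)) {
      for (int a = 0; a < 3; ++a) pn[a] = p[a] - step * gvec[a] / norm;
      double t_old = interp_T(T, g, u);
      double un[3];
      for (int a = 0; a < 3; ++a) un[a] = pn[a] / g.h[a] - 0.5;
      if (interp_T(T, g, un) < t_old) moved = true;
    }
    if (!moved) {
      // discrete fallback: hop to the 26-neighbour voxel center with lowest T
      int iv[3];
      for (int a = 0; a < 3; ++a) {
        iv[a] = (int)std::lround(p[a] / g.h[a] - 0.5);
        if (iv[a] < 0) iv[a] = 0;
        if (iv[a] > g.n[a] - 1) iv[a] = g.n[a] - 1;
      }
      double bestT = T[g.idx(iv[0], iv[1], iv[2])];
      int best[3] = {iv[0], iv[1], iv[2]};
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int i = iv[0] + di, j = iv[1] + dj, k = iv[2] + dk;
            if (!g.inside(i, j, k)) continue;
            double t = T[g.idx(i, j, k)];
            if (t < bestT) { bestT = t; best[0] = i; best[1] = j; best[2] = k; }
          }
      if (best[0] == iv[0] && best[1] == iv[1] && best[2] == iv[2]) {
        if (++stall > 3) { ok = false; break; }
        // jitter towards the seed as a last resort
        double dvec[3], dn = std::sqrt(d2seed);
        for (int a = 0; a < 3; ++a) dvec[a] = (seed[a] - p[a]) / (dn > 0 ? dn : 1);
        for (int a = 0; a < 3; ++a) pn[a] = p[a] + step * dvec[a];
      } else {
        stall = 0;
        for (int a = 0; a < 3; ++a) pn[a] = (best[a] + 0.5) * g.h[a];
      }
    } else {
      stall = 0;
    }

    for (int a = 0; a < 3; ++a) p[a] = pn[a];
    d2seed = 0;
    for (int a = 0; a < 3; ++a) d2seed += (p[a] - seed[a]) * (p[a] - seed[a]);
    pts->push_back(p[0]); pts->push_back(p[1]); pts->push_back(p[2]);
  }

  // close the final straight segment to the seed
  double tail = std::sqrt(d2seed);
  if (tail > stop_radius * 4) ok = false; // never converged
  pts->push_back(seed[0]); pts->push_back(seed[1]); pts->push_back(seed[2]);

  int win = (int)std::lround(smooth_mm / step);
  if (win % 2 == 0) ++win;
  return smoothed_length(*pts, win);
}

// [[Rcpp::export(name = ".cw_trace")]]
List cw_trace(NumericVector T, NumericVector spacing, NumericVector start,
              NumericVector seed, double step, double stop_radius,
              double smooth_mm, bool keep_path) {
  IntegerVector dims = T.attr("dim");
  Grid g;
  for (int a = 0; a < 3; ++a) { g.n[a] = dims[a]; g.h[a] = spacing[a]; }
  double st[3] = {start[0], start[1], start[2]};
  double sd[3] = {seed[0], seed[1], seed[2]};
  std::vector<double> path;
  bool ok;
  double len = trace_one(T, g, st, sd, step, stop_radius, smooth_mm,
                         keep_path ? &path : 0, ok);
  List out = List::create(_["length"] = len, _["converged"] = ok);
  if (keep_path) {
    int np = path.size() / 3;
    NumericMatrix pm(np, 3);
    for (int r = 0; r < np; ++r)
      for (int a = 0; a < 3; ++a) pm(r, a) = path[3 * r + a];
    out["path"] = pm;
  }
  return out;
}

// [[Rcpp::export(name = ".cw_trace_lengths")]]
List cw_trace_lengths(NumericVector T, NumericVector spacing,
                      NumericMatrix starts, NumericVector seed,
                      double step, double stop_radius, double smooth_mm) {
  IntegerVector dims = T.attr("dim");
  Grid g;
  for (int a = 0; a < 3; ++a) { g.n[a] = dims[a]; g.h[a] = spacing[a]; }
  double sd[3] = {seed[0], seed[1], seed[2]};
  int n = starts.nrow();
  NumericVector len(n);
  LogicalVector conv(n);
  for (int r = 0; r < n; ++r) {
    double st[3] = {starts(r, 0), starts(r, 1), starts(r, 2)};
    bool ok;
    len[r] = trace_one(T, g, st, sd, step, stop_radius, smooth_mm, 0, ok);
    conv[r] = ok;
  }
  return List::create(_["length"] = len, _["converged"] = conv);
}

// For each query point, the minimum Euclidean distance to the target set and
// the (1-based) index of the nearest target; ties broken by lowest index.
// [[Rcpp::export(name = ".cw_nearest")]]
List cw_nearest(NumericMatrix query, NumericMatrix target) {
  int nq = query.nrow(), nt = target.nrow();
  if (nt == 0) stop("empty target set");
  NumericVector dist(nq);
  IntegerVector which(nq);
  for (int q = 0; q < nq; ++q) {
    double best = INF;
    int bi = 0;
    for (int t = 0; t < nt; ++t) {
      double d2 = 0;
      for (int a = 0; a < 3; ++a) {
        double d = query(q, a) - target(t, a);
        d2 += d * d;
      }
      if (d2 < best) { best = d2; bi = t; }
    }
    dist[q] = std::sqrt(best);
    which[q] = bi + 1;
  }
  return List::create(_["dist"] = dist, _["which"] = which);
}
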