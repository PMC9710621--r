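#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Position-based contact resolution for a monolayer of capsule-shaped cells.
//
// Each cell is represented by a short centerline polyline in its body frame
// (1 point for coccoids, 2 for straight rods/ellipsoids, several for bent
// rods) plus a contact radius; the outline used for rendering/annotations is
// contained in the capsule hull of that polyline, so driving the capsule
// penetration below a per-pair allowance bounds the exact polygon overlap.
//
// The solver performs damped Gauss-Seidel sweeps: contacts are visited in a
// fixed pair order and both bodies are corrected immediately (translation +
// a small rotation about the centroid), which propagates pressure through
// dense packings far faster than a simultaneous update. The summed
// penetration depth over all pairs is required to be non-increasing from
// sweep to sweep; a sweep that would increase it is retried from the
// previous state with half the step (up to a fixed number of halvings), so
// the logged convergence series is monotone by construction. Fully
// deterministic: no randomness, fixed sweep order.

struct V2 { double x, y; };

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// closest points between segments a0-a1 and b0-b1
static void seg_seg(const V2 &a0, const V2 &a1, const V2 &b0, const V2 &b1,
                    V2 &pa, V2 &pb, double &d2) {
  double ux = a1.x - a0.x, uy = a1.y - a0.y;
  double vx = b1.x - b0.x, vy = b1.y - b0.y;
  double wx = a0.x - b0.x, wy = a0.y - b0.y;
  double a = ux * ux + uy * uy;
  double b = ux * vx + uy * vy;
  double c = vx * vx + vy * vy;
  double d = ux * wx + uy * wy;
  double e = vx * wx + vy * wy;
  double s;
  double denom = a * c - b * b;
  if (denom > 1e-14) s = clamp01((b * e - c * d) / denom);
  else s = 0.0; // nearly parallel: refine from an endpoint
  double t = (c > 1e-14) ? clamp01((b * s + e) / c) : 0.0;
  s = (a > 1e-14) ? clamp01((b * t - d) / a) : 0.0;
  t = (c > 1e-14) ? clamp01((b * s + e) / c) : 0.0;
  pa.x = a0.x + s * ux; pa.y = a0.y + s * uy;
  pb.x = b0.x + t * vx; pb.y = b0.y + t * vy;
  double dx = pb.x - pa.x, dy = pb.y - pa.y;
  d2 = dx * dx + dy * dy;
}

struct State { std::vector<double> x, y, ang; };

static void cell_points(const State &st, const NumericMatrix &body,
                        const IntegerVector &off, int i, std::vector<V2> &wp) {
  double ca = std::cos(st.ang[i]), sa = std::sin(st.ang[i]);
  for (int k = off[i]; k < off[i + 1]; ++k) {
    wp[k].x = body(k, 0) * ca - body(k, 1) * sa + st.x[i];
    wp[k].y = body(k, 0) * sa + body(k, 1) * ca + st.y[i];
  }
}

static void world_points(const State &st, const NumericMatrix &body,
                         const IntegerVector &off, std::vector<V2> &wp) {
  int n = st.x.size();
  for (int i = 0; i < n; ++i) cell_points(st, body, off, i, wp);
}

// closest points between the polylines of cells i and j
static double pair_dist(const std::vector<V2> &wp, const IntegerVector &off,
                        int i, int j, V2 &pi, V2 &pj) {
  double best = R_PosInf;
  int ai0 = off[i], ai1 = off[i + 1], bj0 = off[j], bj1 = off[j + 1];
  for (int a = ai0; a < std::max(ai1 - 1, ai0 + 1); ++a) {
    int a2 = (a + 1 < ai1) ? a + 1 : a;
    for (int b = bj0; b < std::max(bj1 - 1, bj0 + 1); ++b) {
      int b2 = (b + 1 < bj1) ? b + 1 : b;
      V2 pa, pb; double d2;
      seg_seg(wp[a], wp[a2], wp[b], wp[b2], pa, pb, d2);
      if (d2 < best) { best = d2; pi = pa; pj = pb; }
    }
  }
  return std::sqrt(best);
}

struct Pair { int i, j; };

// candidate pairs by bounding-circle prefilter
static void candidates(const State &st, const std::vector<double> &breach,
                       std::vector<Pair> &out) {
  out.clear();
  int n = st.x.size();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = st.x[j] - st.x[i], dy = st.y[j] - st.y[i];
      double reach = breach[i] + breach[j];
      if (dx * dx + dy * dy <= reach * reach) { Pair p = {i, j}; out.push_back(p); }
    }
}

// total penetration depth and worst allowance violation over candidate pairs
static double measure(const State &st, const std::vector<V2> &wp,
                      const IntegerVector &off, const NumericVector &radius,
                      const std::vector<Pair> &cand,
                      const std::vector<double> &allow, bool &within) {
  double total = 0.0;
  within = true;
  for (size_t c = 0; c < cand.size(); ++c) {
    int i = cand[c].i, j = cand[c].j;
    V2 pi, pj;
    double d = pair_dist(wp, off, i, j, pi, pj);
    double pen = radius[i] + radius[j] - d;
    if (pen > 0.0) {
      total += pen;
      size_t key = c;
      if (pen > allow[key]) within = false;
    }
  }
  return total;
}

// [[Rcpp::export]]
List resolve_overlaps_cpp(NumericMatrix body, IntegerVector offsets,
                          NumericVector radius, NumericVector area,
                          NumericVector clen,
                          NumericVector x0, NumericVector y0,
                          NumericVector ang0,
                          double tol, int max_iter, double damping,
                          double rot_strength, NumericVector boundary) {
  int n = x0.size();
  State st;
  st.x.assign(x0.begin(), x0.end());
  st.y.assign(y0.begin(), y0.end());
  st.ang.assign(ang0.begin(), ang0.end());

  std::vector<double> breach(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double m = 0.0;
    for (int k = offsets[i]; k < offsets[i + 1]; ++k) {
      double v = std::sqrt(body(k, 0) * body(k, 0) + body(k, 1) * body(k, 1));
      if (v > m) m = v;
    }
    breach[i] = m + radius[i] + 1e-9;
  }

  bool has_wall = boundary.size() == 4;
  std::vector<V2> wp(body.nrow());
  std::vector<Pair> cand;
  std::vector<double> allow;
  std::vector<double> log_pen;

  world_points(st, body, offsets, wp);
  candidates(st, breach, cand);
  allow.resize(cand.size());
  for (size_t c = 0; c < cand.size(); ++c) {
    int i = cand[c].i, j = cand[c].j;
    double amin = std::min(area[i], area[j]);
    double lmin = std::min(clen[i], clen[j]);
    allow[c] = tol * amin / std::max(lmin, 1e-9);
  }
  bool within;
  double total = measure(st, wp, offsets, radius, cand, allow, within);
  log_pen.push_back(total);

  bool wall_ok = true;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // wall violation check
    wall_ok = true;
    if (has_wall) {
      for (int i = 0; i < n && wall_ok; ++i)
        for (int k = offsets[i]; k < offsets[i + 1]; ++k)
          if (wp[k].x - radius[i] < boundary[0] - 1e-6 ||
              wp[k].y - radius[i] < boundary[1] - 1e-6 ||
              wp[k].x + radius[i] > boundary[2] + 1e-6 ||
              wp[k].y + radius[i] > boundary[3] + 1e-6) { wall_ok = false; break; }
    }
    if (within && wall_ok) { converged = true; break; }

    State prev = st;
    double scale = damping;
    bool improved = false;
    double trial_total = total;
    for (int h = 0; h < 6; ++h) {
      st = prev;
      world_points(st, body, offsets, wp);
      // one Gauss-Seidel sweep over candidate pairs, immediate updates
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c].i, j = cand[c].j;
        V2 pi, pj;
        double d = pair_dist(wp, offsets, i, j, pi, pj);
        double pen = radius[i] + radius[j] - d;
        if (pen <= 0.0) continue;
        double nx, ny;
        if (d > 1e-12) { nx = (pj.x - pi.x) / d; ny = (pj.y - pi.y) / d; }
        else { nx = std::cos(st.ang[i] + 1.0); ny = std::sin(st.ang[i] + 1.0); }
        double half = 0.5 * pen * scale;
        // translations
        st.x[i] -= nx * half; st.y[i] -= ny * half;
        st.x[j] += nx * half; st.y[j] += ny * half;
        // small rotations from the moment of the correction about centroid
        if (rot_strength > 0.0) {
          double rix = pi.x - st.x[i], riy = pi.y - st.y[i];
          double rjx = pj.x - st.x[j], rjy = pj.y - st.y[j];
          double li2 = rix * rix + riy * riy + radius[i] * radius[i];
          double lj2 = rjx * rjx + rjy * rjy + radius[j] * radius[j];
          st.ang[i] += rot_strength * (rix * (-ny * half) - riy * (-nx * half)) / li2;
          st.ang[j] += rot_strength * (rjx * (ny * half) - rjy * (nx * half)) / lj2;
        }
        cell_points(st, body, offsets, i, wp);
        cell_points(st, body, offsets, j, wp);
      }
      if (has_wall) {
        for (int i = 0; i < n; ++i) {
          double bx = 0.0, by = 0.0;
          for (int k = offsets[i]; k < offsets[i + 1]; ++k) {
            double px = wp[k].x, py = wp[k].y, r = radius[i];
            if (px - r < boundary[0]) bx = std::max(bx, boundary[0] - (px - r));
            if (px + r > boundary[2]) by = std::min(by, 0.0), bx = std::min(bx, boundary[2] - (px + r));
            if (py - r < boundary[1]) by = std::max(by, boundary[1] - (py - r));
            if (py + r > boundary[3]) by = std::min(by, boundary[3] - (py + r));
          }
          if (bx != 0.0 || by != 0.0) {
            st.x[i] += bx * scale; st.y[i] += by * scale;
            cell_points(st, body, offsets, i, wp);
          }
        }
      }
      trial_total = measure(st, wp, offsets, radius, cand, allow, within);
      if (trial_total <= total + 1e-15) { improved = true; break; }
      scale *= 0.5;
    }
    if (!improved) {
      st = prev;
      world_points(st, body, offsets, wp);
      total = measure(st, wp, offsets, radius, cand, allow, within);
      break;
    }
    total = trial_total;
    log_pen.push_back(total);
    // refresh the candidate set as cells move
    candidates(st, breach, cand);
    allow.resize(cand.size());
    for (size_t c = 0; c < cand.size(); ++c) {
      int i = cand[c].i, j = cand[c].j;
      double amin = std::min(area[i], area[j]);
      double lmin = std::min(clen[i], clen[j]);
      allow[c] = tol * amin / std::max(lmin, 1e-9);
    }
    total = measure(st, wp, offsets, radius, cand, allow, within);
  }

  return List::create(
    _["x"] = NumericVector(st.x.begin(), st.x.end()),
    _["y"] = NumericVector(st.y.begin(), st.y.end()),
    _["angle"] = NumericVector(st.ang.begin(), st.ang.end()),
    _["iterations"] = iter,
    _["converged"] = converged,
    _["penetration_log"] = NumericVector(log_pen.begin(), log_pen.end()));
}
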