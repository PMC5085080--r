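#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ray / segment / circle intersection utilities shared by the raycasting,
// trajectory and filter code. Walls are rows (x1, y1, x2, y2, transparent).

static const double GEOM_EPS = 1e-12;

static inline double wrap_pi_g(double a) {
  return a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
}

// distance along ray (origin ox,oy; direction dx,dy, unit) to segment, or -1
static double ray_segment(double ox, double oy, double dx, double dy,
                          double x1, double y1, double x2, double y2) {
  double ex = x2 - x1, ey = y2 - y1;
  double denom = dx * ey - dy * ex;
  if (std::fabs(denom) < GEOM_EPS) return -1.0; // parallel
  double qx = x1 - ox, qy = y1 - oy;
  double t = (qx * ey - qy * ex) / denom;       // along ray
  double s = (qx * dy - qy * dx) / denom;       // along segment
  if (t > GEOM_EPS && s >= -1e-9 && s <= 1.0 + 1e-9) return t;
  return -1.0;
}

// first positive distance to circle |p + t d - c| = r, or -1
static double ray_circle(double ox, double oy, double dx, double dy,
                         double cx, double cy, double r) {
  double fx = ox - cx, fy = oy - cy;
  double b = fx * dx + fy * dy;
  double c = fx * fx + fy * fy - r * r;
  double disc = b * b - c;
  if (disc < 0) return -1.0;
  double sq = std::sqrt(disc);
  double t1 = -b - sq, t2 = -b + sq;
  if (t1 > GEOM_EPS) return t1;
  if (t2 > GEOM_EPS) return t2;
  return -1.0;
}

struct Geom {
  NumericMatrix walls; // K x 5
  int n_perimeter;
  bool circle;
  double cx, cy, r;
};

static Geom as_geom(const List& g) {
  Geom out{as<NumericMatrix>(g["walls"]), as<int>(g["n_perimeter"]),
           as<bool>(g["is_circle"]), as<double>(g["cx"]), as<double>(g["cy"]),
           as<double>(g["radius"])};
  return out;
}

// first hit distance; which = 0 all walls, 1 opaque only
static double first_hit(const Geom& g, double ox, double oy, double ang,
                        int which) {
  double dx = std::cos(ang), dy = std::sin(ang);
  double best = R_PosInf;
  int K = g.walls.nrow();
  for (int k = 0; k < K; ++k) {
    if (which == 1 && g.walls(k, 4) > 0.5) continue; // skip transparent
    double t = ray_segment(ox, oy, dx, dy, g.walls(k, 0), g.walls(k, 1),
                           g.walls(k, 2), g.walls(k, 3));
    if (t > 0 && t < best) best = t;
  }
  if (g.circle) {
    double t = ray_circle(ox, oy, dx, dy, g.cx, g.cy, g.r);
    if (t > 0 && t < best) best = t;
  }
  return best;
}

static bool point_inside(const Geom& g, double x, double y) {
  if (g.circle) {
    double dx = x - g.cx, dy = y - g.cy;
    return dx * dx + dy * dy < g.r * g.r;
  }
  // crossing number against perimeter walls, ray towards +x with an
  // irrational-slope nudge to dodge vertex degeneracies
  int cross = 0;
  double dy0 = 1e-7;
  for (int k = 0; k < g.n_perimeter; ++k) {
    double t = ray_segment(x, y, 1.0, dy0, g.walls(k, 0), g.walls(k, 1),
                           g.walls(k, 2), g.walls(k, 3));
    if (t > 0) ++cross;
  }
  return (cross % 2) == 1;
}

static double seg_point_dist(double px, double py, double x1, double y1,
                             double x2, double y2) {
  double ex = x2 - x1, ey = y2 - y1;
  double L2 = ex * ex + ey * ey;
  double t = L2 > 0 ? ((px - x1) * ex + (py - y1) * ey) / L2 : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dx = px - (x1 + t * ex), dy = py - (y1 + t * ey);
  return std::sqrt(dx * dx + dy * dy);
}

static double min_wall_dist(const Geom& g, double x, double y) {
  double best = R_PosInf;
  int K = g.walls.nrow();
  for (int k = 0; k < K; ++k) {
    double d = seg_point_dist(x, y, g.walls(k, 0), g.walls(k, 1),
                              g.walls(k, 2), g.walls(k, 3));
    if (d < best) best = d;
  }
  if (g.circle) {
    double d = std::fabs(g.r - std::sqrt((x - g.cx) * (x - g.cx) +
                                         (y - g.cy) * (y - g.cy)));
    if (d < best) best = d;
  }
  return best;
}

static bool segments_cross(double ax, double ay, double bx, double by,
                           double x1, double y1, double x2, double y2) {
  double dx = bx - ax, dy = by - ay;
  double ex = x2 - x1, ey = y2 - y1;
  double denom = dx * ey - dy * ex;
  if (std::fabs(denom) < GEOM_EPS) return false;
  double qx = x1 - ax, qy = y1 - ay;
  double t = (qx * ey - qy * ex) / denom;
  double s = (qx * dy - qy * dx) / denom;
  return t > 1e-9 && t < 1 - 1e-9 && s > -1e-9 && s < 1 + 1e-9;
}

static bool step_blocked(const Geom& g, double ax, double ay, double bx,
                         double by) {
  int K = g.walls.nrow();
  for (int k = 0; k < K; ++k)
    if (segments_cross(ax, ay, bx, by, g.walls(k, 0), g.walls(k, 1),
                       g.walls(k, 2), g.walls(k, 3)))
      return true;
  if (g.circle) {
    double dx = bx - g.cx, dy = by - g.cy;
    if (dx * dx + dy * dy >= g.r * g.r) return true;
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector inside_cpp(List geom, NumericMatrix pts) {
  Geom g = as_geom(geom);
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_inside(g, pts(i, 0), pts(i, 1));
  return out;
}

// Raycast from one pose. mode: 0 vision, 1 dark (contact), 2 semi-transparent.
// Returns n x 2 (dist, hit) for modes 0/1; n x 4 (d_near, hit, d_opaque, hit)
// for mode 2 (union of nearest-wall and opaque-wall hits).
// [[Rcpp::export]]
NumericMatrix raycast_cpp(List geom, double x, double y, NumericVector angles,
                          int mode, double contact_range) {
  Geom g = as_geom(geom);
  int n = angles.size();
  if (mode == 2) {
    NumericMatrix out(n, 4);
    for (int i = 0; i < n; ++i) {
      double da = first_hit(g, x, y, angles[i], 0);
      double dop = first_hit(g, x, y, angles[i], 1);
      out(i, 0) = R_finite(da) ? da : NA_REAL;
      out(i, 1) = R_finite(da) ? 1.0 : 0.0;
      out(i, 2) = R_finite(dop) ? dop : NA_REAL;
      out(i, 3) = R_finite(dop) ? 1.0 : 0.0;
    }
    return out;
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    // vision sees opaque walls only; darkness senses any wall by contact
    double d = first_hit(g, x, y, angles[i], mode == 0 ? 1 : 0);
    bool hit = R_finite(d);
    if (mode == 1 && (!hit || d > contact_range)) hit = false;
    out(i, 0) = hit ? d : NA_REAL;
    out(i, 1) = hit ? 1.0 : 0.0;
  }
  return out;
}

// Vision-regime raycast for many points sharing one angle set (classifier
// reconstruction; heading-independent allocentric directions).
// [[Rcpp::export]]
NumericMatrix raycast_batch_cpp(List geom, NumericMatrix pts,
                                NumericVector angles) {
  Geom g = as_geom(geom);
  int n = pts.nrow(), m = angles.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    if (!point_inside(g, pts(i, 0), pts(i, 1))) {
      for (int j = 0; j < m; ++j) out(i, j) = NA_REAL;
      continue;
    }
    for (int j = 0; j < m; ++j) {
      double d = first_hit(g, pts(i, 0), pts(i, 1), angles[j], 1);
      out(i, j) = R_finite(d) ? d : NA_REAL;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wall_distance_cpp(List geom, NumericMatrix pts) {
  Geom g = as_geom(geom);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = min_wall_dist(g, pts(i, 0), pts(i, 1));
  return out;
}

// [[Rcpp::export]]
LogicalVector step_blocked_cpp(List geom, NumericMatrix from, NumericMatrix to) {
  Geom g = as_geom(geom);
  int n = from.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = step_blocked(g, from(i, 0), from(i, 1), to(i, 0), to(i, 1));
  return out;
}

// Correlated random walk forager with wall avoidance. Returns (n+1) x 3
// matrix (x, y, heading); heading[k+1] is the movement direction of step k,
// so dead-reckoning from noise-free cues reproduces the path exactly.
// [[Rcpp::export]]
NumericMatrix forage_cpp(List geom, int n_steps, double dt, double mean_speed,
                         double sd_speed, double max_speed, double turn_sd,
                         double avoid_dist, double x0, double y0, double h0) {
  Geom g = as_geom(geom);
  RNGScope scope;
  NumericMatrix out(n_steps + 1, 3);
  double x = x0, y = y0, h = h0, v = mean_speed, dh_prev = 0;
  const double rho = 0.8;   // speed AR(1) persistence
  const double rho_t = 0.05; // turning AR(1) persistence
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = h;
  for (int k = 0; k < n_steps; ++k) {
    v = mean_speed + rho * (v - mean_speed) +
        norm_rand() * sd_speed * std::sqrt(1 - rho * rho);
    if (v < 0) v = 0;
    if (v > max_speed) v = max_speed;
    double dh = rho_t * dh_prev +
                norm_rand() * turn_sd * std::sqrt(dt) *
                std::sqrt(1 - rho_t * rho_t);
    // steer away from walls when the look-ahead is short
    double look = avoid_dist + v * dt * 8.0;
    double da = first_hit(g, x, y, h, 0);
    if (da < look) {
      double dl = first_hit(g, x, y, h + 0.7, 0);
      double dr = first_hit(g, x, y, h - 0.7, 0);
      double steer = 3.0 * dt * (1.0 + avoid_dist / (da + 1.0));
      dh += (dl > dr ? steer : -steer);
    }
    bool ok = false;
    double hn = h, xn = x, yn = y;
    for (int tries = 0; tries < 40 && !ok; ++tries) {
      hn = h + dh;
      xn = x + v * dt * std::cos(hn);
      yn = y + v * dt * std::sin(hn);
      if (point_inside(g, xn, yn) && !step_blocked(g, x, y, xn, yn) &&
          min_wall_dist(g, xn, yn) > 1.0) {
        ok = true;
      } else {
        dh = norm_rand() * (0.8 + 0.15 * tries);
        if (tries > 25) v *= 0.5;
      }
    }
    if (!ok) { xn = x; yn = y; hn = h; v = 0; } // stay put this step
    dh_prev = wrap_pi_g(hn - h);
    x = xn; y = yn; h = hn;
    out(k + 1, 0) = x; out(k + 1, 1) = y; out(k + 1, 2) = h;
  }
  return out;
}
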