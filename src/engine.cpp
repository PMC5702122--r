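#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic per-particle RNG: splitmix64-seeded xoshiro256+.
// Particles get independent streams derived from (master seed, index), so
// results do not depend on simulation order and are platform-stable.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256p {
  uint64_t s[4];
  explicit Xoshiro256p(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

static inline uint64_t particle_seed(double master, int i) {
  uint64_t s = (uint64_t)master;
  s ^= 0xD1B54A32D192ED03ULL * (uint64_t)(i + 1);
  return s;
}

// ---------------------------------------------------------------------------
// Velocity field: either uniform (vx0, vy0) or bilinear interpolation on a
// regular grid (node values computed once from the Stokeslet superposition).
// ---------------------------------------------------------------------------

struct VelField {
  bool uniform;
  double vx0, vy0;
  int nx, ny;             // number of nodes in x / y
  double x0, y0, dx, dy;  // grid origin and spacing
  const double *vx, *vy;  // nx * ny, column j = y index (R matrix layout)

  inline void eval(double x, double y, double &ux, double &uy) const {
    if (uniform) { ux = vx0; uy = vy0; return; }
    double fx = (x - x0) / dx, fy = (y - y0) / dy;
    if (fx < 0) fx = 0;
    if (fx > nx - 1.0) fx = nx - 1.0;
    if (fy < 0) fy = 0;
    if (fy > ny - 1.0) fy = ny - 1.0;
    int ix = (int)fx, iy = (int)fy;
    if (ix > nx - 2) ix = nx - 2;
    if (iy > ny - 2) iy = ny - 2;
    double tx = fx - ix, ty = fy - iy;
    const int i00 = ix + nx * iy, i10 = i00 + 1, i01 = i00 + nx, i11 = i01 + 1;
    double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty),
           w01 = (1 - tx) * ty,       w11 = tx * ty;
    ux = w00 * vx[i00] + w10 * vx[i10] + w01 * vx[i01] + w11 * vx[i11];
    uy = w00 * vy[i00] + w10 * vy[i10] + w01 * vy[i01] + w11 * vy[i11];
  }

  double max_speed(double width, double height) const {
    if (uniform) return std::sqrt(vx0 * vx0 + vy0 * vy0);
    double m = 0.0;
    for (int i = 0; i < nx * ny; ++i) {
      double s = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
      if (s > m) m = s;
    }
    (void)width; (void)height;
    return m;
  }
};

static VelField make_field(List field) {
  VelField f;
  if (field.size() == 0 || !field.containsElementNamed("vx")) {
    f.uniform = true;
    NumericVector v = field["v"];
    f.vx0 = v[0]; f.vy0 = v[1];
    f.nx = f.ny = 0; f.x0 = f.y0 = f.dx = f.dy = 0;
    f.vx = f.vy = nullptr;
  } else {
    f.uniform = false;
    NumericVector xs = field["x"], ys = field["y"];
    NumericMatrix vx = field["vx"], vy = field["vy"];
    f.nx = xs.size(); f.ny = ys.size();
    f.x0 = xs[0]; f.y0 = ys[0];
    f.dx = (f.nx > 1) ? xs[1] - xs[0] : 1.0;
    f.dy = (f.ny > 1) ? ys[1] - ys[0] : 1.0;
    f.vx = vx.begin(); f.vy = vy.begin();
    f.vx0 = f.vy0 = 0;
  }
  return f;
}

// ---------------------------------------------------------------------------
// Cell lookup: uniform spatial bins over cell centers. A query returns the
// exact nearest cell-boundary distance whenever it is below `cap`; distances
// beyond cap are reported as cap (sufficient for the step-size logic, which
// only needs exact distances within one maximal jump of the particle).
// ---------------------------------------------------------------------------

struct CellLookup {
  int n;
  std::vector<double> cx, cy;
  double r, cap, binsize, width, height;
  int nbx, nby;
  std::vector<int> head, nxt;

  CellLookup(NumericMatrix centers, double r_, double cap_,
             double width_, double height_)
      : n(centers.nrow()), r(r_), cap(cap_), width(width_), height(height_) {
    cx.resize(n); cy.resize(n);
    for (int i = 0; i < n; ++i) { cx[i] = centers(i, 0); cy[i] = centers(i, 1); }
    binsize = r + cap + 1e-9;
    nbx = std::max(1, (int)std::ceil(width / binsize));
    nby = std::max(1, (int)std::ceil(height / binsize));
    head.assign((size_t)nbx * nby, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int bx = clampi((int)(cx[i] / binsize), nbx);
      int by = clampi((int)(cy[i] / binsize), nby);
      int b = bx + nbx * by;
      nxt[i] = head[b];
      head[b] = i;
    }
  }

  static inline int clampi(int v, int nmax) {
    if (v < 0) return 0;
    if (v >= nmax) return nmax - 1;
    return v;
  }

  // nearest cell-boundary distance (capped); idx is 0-based, -1 if none found
  inline double nearest(double x, double y, int &idx) const {
    idx = -1;
    if (n == 0) return cap;
    double best = cap;
    int bx = clampi((int)(x / binsize), nbx);
    int by = clampi((int)(y / binsize), nby);
    for (int jy = by - 1; jy <= by + 1; ++jy) {
      if (jy < 0 || jy >= nby) continue;
      for (int jx = bx - 1; jx <= bx + 1; ++jx) {
        if (jx < 0 || jx >= nbx) continue;
        for (int i = head[jx + nbx * jy]; i != -1; i = nxt[i]) {
          double ddx = x - cx[i], ddy = y - cy[i];
          double d = std::sqrt(ddx * ddx + ddy * ddy) - r;
          if (d < best) { best = d; idx = i; }
        }
      }
    }
    return best;
  }
};

// intermediate step size: positive root of |v| t + sqrt(4 D t) = gap
static inline double intermediate_dt(double gap, double speed, double D) {
  if (speed <= 0.0) return gap * gap / (4.0 * D);
  if (D <= 0.0) return gap / speed;
  double s = std::sqrt(4.0 * D);
  double u = (-s + std::sqrt(s * s + 4.0 * speed * gap)) / (2.0 * speed);
  return u * u;
}

// ---------------------------------------------------------------------------
// Three-tier adaptive engine.
// Status codes: 0 mobile, 1 captured, 2 exited right edge.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_adaptive(int n_particles, double t_end, double seed,
                           double width, double height,
                           NumericMatrix centers, double cell_r,
                           double a, double D, double rho,
                           double dt_max, double dt_min, List field,
                           int record_id = -1) {
  VelField vf = make_field(field);
  const double vmax = vf.max_speed(width, height);
  // exact-distance horizon: one maximal tier-1 jump plus the contact shell
  const double cap = vmax * dt_max + std::sqrt(4.0 * D * dt_max) + 5.0 * a + 1.0;
  CellLookup cells(centers, cell_r, cap, width, height);

  NumericMatrix out(n_particles, 7);  // x, y, status, cell, collisions, t, y0
  double tier_counts[3] = {0, 0, 0};
  double n_rejected = 0;
  std::vector<double> traj;  // x, y, t, tier for the recorded particle

  const double contact = cell_r + a;  // center distance at particle-cell contact

  for (int ip = 0; ip < n_particles; ++ip) {
    Xoshiro256p rng(particle_seed(seed, ip));
    double x = 0.0, y = rng.unif() * height;
    const double y_entry = y;
    double t = 0.0;
    int status = 0, cell_hit = 0;
    long collisions = 0;
    bool record = (ip == record_id);
    if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(0); }

    while (status == 0 && t < t_end - 1e-12) {
      double rem = t_end - t;
      int ic;
      double Rcell = cells.nearest(x, y, ic);
      double R = std::min(std::min(x, y), std::min(height - y, Rcell));
      double vx, vy;
      vf.eval(x, y, vx, vy);
      double gap = R - a;

      // tier 1: largest permissible step
      double dt1 = std::min(dt_max, rem);
      double theta = 2.0 * M_PI * rng.unif();
      double sd = std::sqrt(4.0 * D * dt1);
      double sx = vx * dt1 + sd * std::cos(theta);
      double sy = vy * dt1 + sd * std::sin(theta);
      if (std::sqrt(sx * sx + sy * sy) < gap) {
        x += sx; y += sy; t += dt1;
        tier_counts[0] += 1;
        if (x >= width) { status = 2; x = width; }
        if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(1); }
        continue;
      }

      // tier 2: step sized so the jump cannot cross the nearest boundary
      if (gap > 0.0) {
        double speed = std::sqrt(vx * vx + vy * vy);
        double dta = intermediate_dt(gap, speed, D);
        if (dta > rem) dta = rem;
        theta = 2.0 * M_PI * rng.unif();
        sd = std::sqrt(4.0 * D * dta);
        sx = vx * dta + sd * std::cos(theta);
        sy = vy * dta + sd * std::sin(theta);
        if (std::sqrt(sx * sx + sy * sy) > 4.0 * a) {
          x += sx; y += sy; t += dta;
          tier_counts[1] += 1;
          if (x >= width) { status = 2; x = width; }
          if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(2); }
          continue;
        }
      }

      // tier 3: finest step; collisions resolved here
      double dt3 = std::min(dt_min, rem);
      theta = 2.0 * M_PI * rng.unif();
      sd = std::sqrt(4.0 * D * dt3);
      double nxp = x + vx * dt3 + sd * std::cos(theta);
      double nyp = y + vy * dt3 + sd * std::sin(theta);
      t += dt3;  // the clock advances whether the move is accepted or not
      tier_counts[2] += 1;

      // specular reflection at the inlet and the no-slip walls
      if (nxp < 0) nxp = -nxp;
      if (nyp < 0) nyp = -nyp;
      if (nyp > height) nyp = 2.0 * height - nyp;

      if (nxp >= width) {
        status = 2; x = width; y = nyp;
        if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(3); }
        break;
      }

      int jc;
      double d = cells.nearest(nxp, nyp, jc);
      if (jc >= 0 && d < a) {
        // contact with cell jc: capture with probability rho, else reflect
        ++collisions;
        double ddx = nxp - cells.cx[jc], ddy = nyp - cells.cy[jc];
        double dist = std::sqrt(ddx * ddx + ddy * ddy);
        if (dist < 1e-12) { // degenerate: reject the move
          n_rejected += 1;
          if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(3); }
          continue;
        }
        double nhx = ddx / dist, nhy = ddy / dist;
        if (rng.unif() < rho) {
          status = 1; cell_hit = jc + 1;
          x = cells.cx[jc] + contact * nhx;
          y = cells.cy[jc] + contact * nhy;
          if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(3); }
          break;
        }
        // flat-wall specular reflection: mirror the penetrating normal component
        double pen = contact - dist;
        double rx = nxp + 2.0 * pen * nhx;
        double ry = nyp + 2.0 * pen * nhy;
        int kc;
        double dref = cells.nearest(rx, ry, kc);
        bool ok = rx >= 0 && rx < width && ry >= 0 && ry <= height && dref >= a;
        if (ok) { x = rx; y = ry; } else { n_rejected += 1; }
      } else {
        x = nxp; y = nyp;
      }
      if (record) { traj.push_back(x); traj.push_back(y); traj.push_back(t); traj.push_back(3); }
    }

    out(ip, 0) = x; out(ip, 1) = y; out(ip, 2) = status;
    out(ip, 3) = cell_hit; out(ip, 4) = (double)collisions; out(ip, 5) = t;
    out(ip, 6) = y_entry;
  }

  List res = List::create(
      _["result"] = out,
      _["tier_counts"] = NumericVector::create(tier_counts[0], tier_counts[1],
                                               tier_counts[2]),
      _["rejected"] = n_rejected);
  if (record_id >= 0) {
    int m = traj.size() / 4;
    NumericMatrix tm(m, 4);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < 4; ++j) tm(i, j) = traj[4 * i + j];
    res["trajectory"] = tm;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Fixed-step comparison engine: constant time step, rejection of moves that
// overlap cell interiors, capture attempted while inside a thin interaction
// layer around each cell periphery.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_fixed(int n_particles, double t_end, double seed,
                        double width, double height,
                        NumericMatrix centers, double cell_r,
                        double a, double D, double rho,
                        double dt, double layer, List field) {
  VelField vf = make_field(field);
  const double vmax = vf.max_speed(width, height);
  const double cap = vmax * dt + std::sqrt(4.0 * D * dt) + layer + 5.0 * a + 1.0;
  CellLookup cells(centers, cell_r, cap, width, height);

  NumericMatrix out(n_particles, 7);
  double n_rejected = 0;

  for (int ip = 0; ip < n_particles; ++ip) {
    Xoshiro256p rng(particle_seed(seed, ip));
    double x = 0.0, y = rng.unif() * height;
    const double y_entry = y;
    double t = 0.0;
    int status = 0, cell_hit = 0;
    long collisions = 0;

    while (status == 0 && t < t_end - 1e-12) {
      double rem = t_end - t;
      double dtc = std::min(dt, rem);
      double vx, vy;
      vf.eval(x, y, vx, vy);
      double theta = 2.0 * M_PI * rng.unif();
      double sd = std::sqrt(4.0 * D * dtc);
      double nxp = x + vx * dtc + sd * std::cos(theta);
      double nyp = y + vy * dtc + sd * std::sin(theta);
      t += dtc;

      if (nxp < 0) nxp = -nxp;
      if (nyp < 0) nyp = -nyp;
      if (nyp > height) nyp = 2.0 * height - nyp;
      if (nxp >= width) { status = 2; x = width; y = nyp; break; }

      int jc;
      double d = cells.nearest(nxp, nyp, jc);
      if (jc >= 0 && d < a) {   // overlap with a cell: move rejected
        n_rejected += 1;
        continue;
      }
      x = nxp; y = nyp;
      if (jc >= 0 && d <= layer) {  // inside the interaction layer
        ++collisions;
        if (rng.unif() < rho) { status = 1; cell_hit = jc + 1; break; }
      }
    }

    out(ip, 0) = x; out(ip, 1) = y; out(ip, 2) = status;
    out(ip, 3) = cell_hit; out(ip, 4) = (double)collisions; out(ip, 5) = t;
    out(ip, 6) = y_entry;
  }

  return List::create(_["result"] = out, _["rejected"] = n_rejected);
}

// ---------------------------------------------------------------------------
// Regularized-Stokeslet velocity superposition (2D kernel with the quartic
// blob): velocity at each query point from N point forces.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_velocity_eval(NumericMatrix points, NumericMatrix forces,
                                double eps, double mu, NumericMatrix queries) {
  const int n = points.nrow(), m = queries.nrow();
  const double e2 = eps * eps;
  const double c8 = 1.0 / (8.0 * M_PI * mu);
  const double c4 = 1.0 / (4.0 * M_PI * mu);
  NumericMatrix out(m, 2);
  for (int q = 0; q < m; ++q) {
    const double qx = queries(q, 0), qy = queries(q, 1);
    double ux = 0.0, uy = 0.0;
    for (int k = 0; k < n; ++k) {
      const double dx = qx - points(k, 0);
      const double dy = qy - points(k, 1);
      const double r2 = dx * dx + dy * dy;
      const double s = r2 + e2;
      const double fx = forces(k, 0), fy = forces(k, 1);
      const double A = -c8 * (std::log(s) - 2.0 * e2 / s);
      const double B = c4 * (fx * dx + fy * dy) / s;
      ux += fx * A + dx * B;
      uy += fy * A + dy * B;
    }
    out(q, 0) = ux;
    out(q, 1) = uy;
  }
  return out;
}
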