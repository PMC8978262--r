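// Photon-packet transport kernel for tetrahedral meshes.
//
// Geometry convention: local face f of a tetrahedron is the face opposite
// local vertex f. Face planes are precomputed as outward unit normals with
// offsets; ray exit uses plane intersections. All lengths in mm.
//
// RNG: xoshiro256++ seeded per packet through splitmix64 from
// (seed, packet index), so runs are bitwise reproducible and independent of
// how packets are batched.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  void seed(uint64_t seed_val) {
    uint64_t x = seed_val;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: never 0, so -log(u) is finite
  inline double unif_pos() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

// ------------------------------------------------------- small physics ----

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  if (u <= 0.0) return -1.0;
  if (u >= 1.0) return 1.0;
  double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - frac * frac) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  double R = 0.5 * (rs * rs + rp * rp);
  if (R > 1.0) R = 1.0;
  return R;
}

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// spin the direction by (cos theta, phi) in the local frame (MCML style)
static inline Vec3 spin(Vec3 u, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(u.z) > 0.99999) {
    return {st * cp, st * sp, ct * (u.z >= 0 ? 1.0 : -1.0)};
  }
  double den = std::sqrt(1.0 - u.z * u.z);
  Vec3 out;
  out.x = st * (u.x * u.z * cp - u.y * sp) / den + u.x * ct;
  out.y = st * (u.y * u.z * cp + u.x * sp) / den + u.y * ct;
  out.z = -st * cp * den + u.z * ct;
  double nn = norm(out);
  return (1.0 / nn) * out;
}

// ----------------------------------------------------- mesh precompute ----

struct MeshGeom {
  int n_tet;
  const int *tets;      // 4 x n_tet column-major (R matrix n_tet x 4 transposed access)
  int n_tet_rows;       // stride helper
  std::vector<double> fn;   // 12 * n_tet face normals (outward, unit)
  std::vector<double> fd;   // 4 * n_tet plane offsets: n . x = d on face
};

// tets: IntegerMatrix n x 4 (0-based vertex ids), verts: NumericMatrix m x 3
static void precompute_faces(const NumericMatrix &verts, const IntegerMatrix &tets,
                             std::vector<double> &fn, std::vector<double> &fd) {
  int n = tets.nrow();
  fn.assign(12 * (size_t)n, 0.0);
  fd.assign(4 * (size_t)n, 0.0);
  for (int t = 0; t < n; ++t) {
    Vec3 P[4];
    for (int k = 0; k < 4; ++k) {
      int v = tets(t, k);
      P[k] = v3(verts(v, 0), verts(v, 1), verts(v, 2));
    }
    for (int f = 0; f < 4; ++f) {
      // face f: the three vertices != f
      int a = (f + 1) & 3, b = (f + 2) & 3, c = (f + 3) & 3;
      Vec3 nrm = cross(P[b] - P[a], P[c] - P[a]);
      double nn = norm(nrm);
      if (nn > 0) nrm = (1.0 / nn) * nrm;
      // orient outward: away from opposite vertex f
      if (dot(nrm, P[f] - P[a]) > 0) nrm = -1.0 * nrm;
      fn[12 * (size_t)t + 3 * f + 0] = nrm.x;
      fn[12 * (size_t)t + 3 * f + 1] = nrm.y;
      fn[12 * (size_t)t + 3 * f + 2] = nrm.z;
      fd[4 * (size_t)t + f] = dot(nrm, P[a]);
    }
  }
}

static const double KFACE_TOL = 1e-9;   // plane-distance snap (mm)
static const double KNUDGE = 1e-7;      // post-crossing nudge (mm)

// first face crossed by ray (pos, dir) within tet t; returns face id or -1,
// distance in *dist
static inline int exit_face_geom(const std::vector<double> &fn,
                                 const std::vector<double> &fd, int t,
                                 Vec3 pos, Vec3 dir, double *dist) {
  int best = -1;
  double bestd = HUGE_VAL;
  for (int f = 0; f < 4; ++f) {
    Vec3 nrm = v3(fn[12 * (size_t)t + 3 * f], fn[12 * (size_t)t + 3 * f + 1],
                  fn[12 * (size_t)t + 3 * f + 2]);
    double den = dot(nrm, dir);
    if (den <= 0) continue;  // moving away from or parallel to this plane
    double d = (fd[4 * (size_t)t + f] - dot(nrm, pos)) / den;
    if (d < -KFACE_TOL) continue;  // behind (numerically outside)
    if (d < 0) d = 0.0;
    if (d < bestd) {
      bestd = d;
      best = f;
    }
  }
  *dist = bestd;
  return best;
}

static inline bool in_tet(const std::vector<double> &fn, const std::vector<double> &fd,
                          int t, Vec3 p, double tol) {
  for (int f = 0; f < 4; ++f) {
    Vec3 nrm = v3(fn[12 * (size_t)t + 3 * f], fn[12 * (size_t)t + 3 * f + 1],
                  fn[12 * (size_t)t + 3 * f + 2]);
    if (dot(nrm, p) > fd[4 * (size_t)t + f] + tol) return false;
  }
  return true;
}

// -------------------------------------------------------- R interface ----

// [[Rcpp::export]]
IntegerMatrix cpp_build_adjacency(IntegerMatrix tets) {
  // tets: n x 4, 0-based vertex indices. Returns n x 4 with the neighbor
  // tet (0-based) across local face f, or -1 on the mesh boundary.
  int n = tets.nrow();
  IntegerMatrix adj(n, 4);
  std::fill(adj.begin(), adj.end(), -1);
  std::unordered_map<uint64_t, std::pair<int, int>> open;  // face key -> (tet, face)
  open.reserve((size_t)n * 2);
  auto key_of = [](int a, int b, int c) -> uint64_t {
    // sort three vertex ids, pack into 64 bits (supports < 2^21 vertices)
    int lo = a, mid = b, hi = c, tswap;
    if (lo > mid) { tswap = lo; lo = mid; mid = tswap; }
    if (mid > hi) { tswap = mid; mid = hi; hi = tswap; }
    if (lo > mid) { tswap = lo; lo = mid; mid = tswap; }
    return ((uint64_t)lo << 42) | ((uint64_t)mid << 21) | (uint64_t)hi;
  };
  for (int t = 0; t < n; ++t) {
    for (int f = 0; f < 4; ++f) {
      int a = tets(t, (f + 1) & 3), b = tets(t, (f + 2) & 3), c = tets(t, (f + 3) & 3);
      uint64_t k = key_of(a, b, c);
      auto it = open.find(k);
      if (it == open.end()) {
        open.emplace(k, std::make_pair(t, f));
      } else {
        int t2 = it->second.first, f2 = it->second.second;
        if (adj(t2, f2) != -1)
          stop("face shared by more than two tetrahedra (non-manifold mesh)");
        adj(t, f) = t2;
        adj(t2, f2) = t;
        open.erase(it);
      }
    }
  }
  return adj;
}

// [[Rcpp::export]]
NumericVector cpp_tet_volumes(NumericMatrix verts, IntegerMatrix tets) {
  int n = tets.nrow();
  NumericVector vol(n);
  for (int t = 0; t < n; ++t) {
    Vec3 P[4];
    for (int k = 0; k < 4; ++k) {
      int v = tets(t, k);
      P[k] = v3(verts(v, 0), verts(v, 1), verts(v, 2));
    }
    vol[t] = dot(P[1] - P[0], cross(P[2] - P[0], P[3] - P[0])) / 6.0;
  }
  return vol;
}

// [[Rcpp::export]]
List cpp_exit_face(NumericMatrix verts, IntegerMatrix tets, int tet,
                   NumericVector pos, NumericVector dir) {
  std::vector<double> fn, fd;
  precompute_faces(verts, tets, fn, fd);
  double dist;
  int f = exit_face_geom(fn, fd, tet, v3(pos[0], pos[1], pos[2]),
                         v3(dir[0], dir[1], dir[2]), &dist);
  return List::create(_["face"] = f, _["distance"] = dist);
}

// walk from tet toward the tet containing p; returns containing tet,
// or ~(tet,face) boundary encoding -2 - (4*tet + face) when the walk leaves
// the mesh, or -1 when it fails to converge
static inline int walk_locate(const IntegerMatrix &adj,
                              const std::vector<double> &fn,
                              const std::vector<double> &fd, int start, Vec3 p,
                              int max_hops) {
  int t = start;
  const double tol = 1e-9;
  for (int hop = 0; hop < max_hops; ++hop) {
    int worstf = -1;
    double worst = tol;
    for (int f = 0; f < 4; ++f) {
      Vec3 nrm = v3(fn[12 * (size_t)t + 3 * f], fn[12 * (size_t)t + 3 * f + 1],
                    fn[12 * (size_t)t + 3 * f + 2]);
      double excess = dot(nrm, p) - fd[4 * (size_t)t + f];
      if (excess > worst) {
        worst = excess;
        worstf = f;
      }
    }
    if (worstf < 0) return t;  // contained
    int nb = adj(t, worstf);
    if (nb < 0) return -2 - (4 * t + worstf);  // left the mesh through (t, face)
    t = nb;
  }
  return -1;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(NumericMatrix verts, IntegerMatrix tets, IntegerMatrix adj,
                         NumericMatrix points, int hint) {
  // Walking point location with brute-force fallback; returns 0-based tet
  // index or -1 for points outside the mesh.
  int n = tets.nrow(), m = points.nrow();
  std::vector<double> fn, fd;
  precompute_faces(verts, tets, fn, fd);
  IntegerVector out(m);
  int cur = (hint >= 0 && hint < n) ? hint : 0;
  const double tol = 1e-9;
  for (int i = 0; i < m; ++i) {
    Vec3 p = v3(points(i, 0), points(i, 1), points(i, 2));
    int t = cur, found = -1;
    for (int step = 0; step < 4 * n + 8; ++step) {
      if (in_tet(fn, fd, t, p, tol)) {
        found = t;
        break;
      }
      // walk through the most violated face
      int worstf = -1;
      double worst = tol;
      for (int f = 0; f < 4; ++f) {
        Vec3 nrm = v3(fn[12 * (size_t)t + 3 * f], fn[12 * (size_t)t + 3 * f + 1],
                      fn[12 * (size_t)t + 3 * f + 2]);
        double excess = dot(nrm, p) - fd[4 * (size_t)t + f];
        if (excess > worst) {
          worst = excess;
          worstf = f;
        }
      }
      if (worstf < 0) break;
      int nb = adj(t, worstf);
      if (nb < 0) break;  // walked off the mesh
      t = nb;
    }
    if (found < 0) {
      // fallback: exhaustive scan (handles walks trapped at boundary notches)
      for (int t2 = 0; t2 < n; ++t2) {
        if (in_tet(fn, fd, t2, p, tol)) {
          found = t2;
          break;
        }
      }
    }
    out[i] = found;
    if (found >= 0) cur = found;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_hg_cos(double g, double u) { return hg_cos(g, u); }

// [[Rcpp::export]]
double cpp_fresnel_R(double n1, double n2, double cos_incident) {
  return fresnel_R(n1, n2, cos_incident);
}

// [[Rcpp::export]]
List cpp_transport(NumericMatrix verts, IntegerMatrix tets, IntegerMatrix adj,
                   IntegerVector mat_row, NumericMatrix mat,
                   NumericMatrix p0, NumericMatrix d0, IntegerVector tet0,
                   NumericVector w0, double seed,
                   double roulette_threshold, double roulette_survival,
                   int max_steps, bool score_tracklen) {
  // mat_row: per-tet 0-based row into mat; mat columns: mu_a, mu_s, g, n
  // p0/d0/tet0/w0: initial packet states (tet0 0-based, must be valid)
  int n_tet = tets.nrow();
  int n_pkt = p0.nrow();

  std::vector<double> fn, fd;
  precompute_faces(verts, tets, fn, fd);

  std::vector<double> absorbed(n_tet, 0.0), tracklen(n_tet, 0.0);
  NumericMatrix exited(n_tet, 4);  // boundary exit weight per (tet, local face)

  long double led_emitted = 0.0L, led_absorbed = 0.0L, led_exited = 0.0L;
  long double led_roul_killed = 0.0L, led_roul_created = 0.0L, led_lost = 0.0L;
  long long n_geom_lost = 0;

  uint64_t base = (uint64_t)seed;
  Xoshiro256pp rng;

  for (int k = 0; k < n_pkt; ++k) {
    uint64_t sm = base ^ (0x5851F42D4C957F2DULL * (uint64_t)(k + 1));
    rng.seed(sm);

    Vec3 pos = v3(p0(k, 0), p0(k, 1), p0(k, 2));
    Vec3 dir = v3(d0(k, 0), d0(k, 1), d0(k, 2));
    int tet = tet0[k];
    double w = w0[k];
    led_emitted += w;

    double s_left = -std::log(rng.unif_pos());  // dimensionless step
    int steps = 0;
    bool alive = true;

    while (alive && steps < max_steps) {
      ++steps;
      int mrow = mat_row[tet];
      double mu_a = mat(mrow, 0), mu_s = mat(mrow, 1);
      double g = mat(mrow, 2), n1 = mat(mrow, 3);
      double mu_t = mu_a + mu_s;

      double dface;
      int face = exit_face_geom(fn, fd, tet, pos, dir, &dface);
      if (face < 0) {
        // wedged at a shared vertex/edge: re-seat by walking to the tet that
        // actually contains a slightly advanced probe point
        Vec3 probe = pos + (10.0 * KNUDGE) * dir;
        int found = walk_locate(adj, fn, fd, tet, probe, 64);
        if (found >= 0) {
          tet = found;
          pos = probe;
          continue;
        }
        if (found <= -2) {
          // walked off the mesh: the packet is exiting at a boundary corner
          int enc = -found - 2;
          exited(enc / 4, enc % 4) += w;
          led_exited += w;
          break;
        }
        led_lost += w;
        ++n_geom_lost;
        break;
      }
      double dstep = (mu_t > 0.0) ? s_left / mu_t : HUGE_VAL;

      if (dstep < dface) {
        // interaction inside this tet
        pos = pos + dstep * dir;
        if (score_tracklen) tracklen[tet] += w * dstep;
        double dep = w * (mu_a / mu_t);
        absorbed[tet] += dep;
        led_absorbed += dep;
        w -= dep;
        double ct = hg_cos(g, rng.unif());
        double phi = 2.0 * M_PI * rng.unif();
        dir = spin(dir, ct, phi);
        s_left = -std::log(rng.unif_pos());
        if (w < roulette_threshold) {
          if (rng.unif() < roulette_survival) {
            double w_new = w / roulette_survival;
            led_roul_created += (w_new - w);
            w = w_new;
          } else {
            led_roul_killed += w;
            alive = false;
          }
        }
      } else {
        // advance to the face
        pos = pos + dface * dir;
        if (score_tracklen) tracklen[tet] += w * dface;
        if (mu_t > 0.0) s_left -= dface * mu_t;
        int nb = adj(tet, face);
        if (nb < 0) {
          // external boundary: score exitance, terminate
          exited(tet, face) += w;
          led_exited += w;
          alive = false;
        } else {
          double n2 = mat(mat_row[nb], 3);
          if (n1 != n2) {
            Vec3 nrm = v3(fn[12 * (size_t)tet + 3 * face],
                          fn[12 * (size_t)tet + 3 * face + 1],
                          fn[12 * (size_t)tet + 3 * face + 2]);
            double ci = dot(dir, nrm);  // > 0: exiting through the face
            if (ci < 0) ci = -ci;
            double R = fresnel_R(n1, n2, ci);
            if (rng.unif() < R) {
              // specular reflection, stay in this tet
              double dn = dot(dir, nrm);
              dir = dir - (2.0 * dn) * nrm;
              pos = pos + KNUDGE * dir;
            } else {
              // refract (below critical angle by construction: R = 1 at TIR)
              double eta = n1 / n2;
              double st2 = eta * eta * (1.0 - ci * ci);
              double ct = std::sqrt(std::max(0.0, 1.0 - st2));
              dir = eta * dir + (ct - eta * ci) * nrm;
              double nn = norm(dir);
              dir = (1.0 / nn) * dir;
              tet = nb;
              pos = pos + KNUDGE * dir;
            }
          } else {
            tet = nb;
            pos = pos + KNUDGE * dir;
          }
        }
      }
    }
    if (alive && steps >= max_steps) {
      // truncated packet: book its weight with the lost bucket
      led_lost += w;
    }
  }

  double roulette_net = (double)(led_roul_killed - led_roul_created + led_lost);
  double emitted = (double)led_emitted;
  double absorbed_total = (double)led_absorbed;
  double exited_total = (double)led_exited;
  double residual = emitted - absorbed_total - exited_total - roulette_net;

  return List::create(
      _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
      _["tracklen"] = NumericVector(tracklen.begin(), tracklen.end()),
      _["exited"] = exited,
      _["emitted"] = emitted, _["absorbed_total"] = absorbed_total,
      _["exited_total"] = exited_total, _["roulette_net"] = roulette_net,
      _["residual"] = residual, _["n_geom_lost"] = (double)n_geom_lost);
}
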