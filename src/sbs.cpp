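// Lattice strings-and-binders-switch (SBS) polymer Monte Carlo.
//
// A self-avoiding chain of beads on a cubic lattice (bond length 1, at
// most one particle per site, hard walls) carries colour-typed binding
// sites; diffusing binders of matching colour gain energy -E[colour] for
// every 6-neighbourhood contact with a matching bead.  Metropolis moves:
// single-bead corner flips, end-bead pivots, and binder steps.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cstdint>
using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Sim {
  int L, n, nb;                    // box, beads, binders
  std::vector<int> col;            // bead colours (0 neutral, 1..3 typed)
  std::vector<int> bcol;           // binder colours
  std::vector<double> eng;         // binding energy per colour (kT), idx 1..3
  std::vector<int> x, y, z;        // bead coords
  std::vector<int> bx, by, bz;     // binder coords
  std::vector<int> grid;           // site -> 0 empty, 1..n bead, n+1.. binder
  std::mt19937_64 rng;
  std::uniform_int_distribution<int> dist_particle, dist_dir;
  std::uniform_real_distribution<double> dist_u01{0.0, 1.0};
  double E = 0.0;                  // running energy (kT)

  int idx(int a, int b, int c) const { return (a * L + b) * L + c; }
  bool inbox(int a, int b, int c) const {
    return a >= 0 && a < L && b >= 0 && b < L && c >= 0 && c < L;
  }

  // energy of a binder at (a,b,c) with colour cc against adjacent beads
  double binder_site_energy(int a, int b, int c, int cc) const {
    double e = 0;
    for (int d = 0; d < 6; ++d) {
      int aa = a + DX[d], bb = b + DY[d], cz = c + DZ[d];
      if (!inbox(aa, bb, cz)) continue;
      int g = grid[idx(aa, bb, cz)];
      if (g >= 1 && g <= n && col[g - 1] == cc) e -= eng[cc];
    }
    return e;
  }
  // energy of a bead at (a,b,c) with colour cc against adjacent binders
  double bead_site_energy(int a, int b, int c, int cc) const {
    if (cc == 0) return 0;
    double e = 0;
    for (int d = 0; d < 6; ++d) {
      int aa = a + DX[d], bb = b + DY[d], cz = c + DZ[d];
      if (!inbox(aa, bb, cz)) continue;
      int g = grid[idx(aa, bb, cz)];
      if (g > n && bcol[g - n - 1] == cc) e -= eng[cc];
    }
    return e;
  }

  double full_energy() const {
    double e = 0;
    for (int i = 0; i < nb; ++i)
      e += binder_site_energy(bx[i], by[i], bz[i], bcol[i]);
    return e;
  }

  // deterministic compact start: boustrophedon filling of a near-cubic
  // block centred in the box
  void init_compact() {
    int side = (int)std::ceil(std::cbrt((double)n));
    if (side >= L) stop("box too small for compact start");
    int off = (L - side) / 2;
    int a = 0, b = 0, c = 0, db = 1, dc = 1;
    for (int i = 0; i < n; ++i) {
      x[i] = off + a; y[i] = off + b; z[i] = off + c;
      grid[idx(x[i], y[i], z[i])] = i + 1;
      if (c + dc >= 0 && c + dc < side) {
        c += dc;
      } else if (b + db >= 0 && b + db < side) {
        b += db; dc = -dc;
      } else {
        a += 1; db = -db; dc = -dc;
      }
    }
  }

  void init(unsigned long seed, bool compact) {
    rng.seed(seed);
    grid.assign((size_t)L * L * L, 0);
    x.resize(n); y.resize(n); z.resize(n);
    if (compact) {
      init_compact();
      place_binders();
      E = full_energy();
      return;
    }
    // grow a random self-avoiding walk from the box centre, restarting on
    // dead ends
    std::uniform_int_distribution<int> d6(0, 5);
    for (int attempt = 0; attempt < 10000; ++attempt) {
      std::fill(grid.begin(), grid.end(), 0);
      int cx = L / 2, cy = L / 2, cz = L / 2;
      x[0] = cx; y[0] = cy; z[0] = cz;
      grid[idx(cx, cy, cz)] = 1;
      bool ok = true;
      for (int i = 1; i < n; ++i) {
        int perm[6] = {0, 1, 2, 3, 4, 5};
        for (int k = 5; k > 0; --k) {
          std::uniform_int_distribution<int> dk(0, k);
          std::swap(perm[k], perm[dk(rng)]);
        }
        bool placed = false;
        for (int k = 0; k < 6 && !placed; ++k) {
          int d = perm[k];
          int aa = x[i-1] + DX[d], bb = y[i-1] + DY[d], cc2 = z[i-1] + DZ[d];
          if (inbox(aa, bb, cc2) && grid[idx(aa, bb, cc2)] == 0) {
            x[i] = aa; y[i] = bb; z[i] = cc2;
            grid[idx(aa, bb, cc2)] = i + 1;
            placed = true;
          }
        }
        if (!placed) { ok = false; break; }
      }
      if (ok) break;
      if (attempt == 9999) stop("could not grow initial chain; box too small");
    }
    place_binders();
    E = full_energy();
  }

  // binders at uniform random empty sites
  void place_binders() {
    bx.resize(nb); by.resize(nb); bz.resize(nb);
    std::uniform_int_distribution<int> dL(0, L - 1);
    for (int i = 0; i < nb; ++i) {
      for (int tries = 0; ; ++tries) {
        if (tries > 1000000) stop("box too crowded for binders");
        int a = dL(rng), b = dL(rng), c = dL(rng);
        if (grid[idx(a, b, c)] == 0) {
          bx[i] = a; by[i] = b; bz[i] = c;
          grid[idx(a, b, c)] = n + i + 1;
          break;
        }
      }
    }
  }

  void step() {
    int p = dist_particle(rng);
    if (p < n) {  // bead move
      int i = p;
      int nx2, ny2, nz2;
      if (i == 0 || i == n - 1) {
        int j = (i == 0) ? 1 : n - 2;  // bonded neighbour
        int d = dist_dir(rng);
        nx2 = x[j] + DX[d]; ny2 = y[j] + DY[d]; nz2 = z[j] + DZ[d];
      } else {
        // corner flip: only if neighbours are at a right angle
        int ax = x[i-1] - x[i], ay = y[i-1] - y[i], az = z[i-1] - z[i];
        int bx2 = x[i+1] - x[i], by2 = y[i+1] - y[i], bz2 = z[i+1] - z[i];
        if (ax + bx2 == 0 && ay + by2 == 0 && az + bz2 == 0) return; // straight
        nx2 = x[i-1] + x[i+1] - x[i];
        ny2 = y[i-1] + y[i+1] - y[i];
        nz2 = z[i-1] + z[i+1] - z[i];
      }
      if (!inbox(nx2, ny2, nz2)) return;
      if (nx2 == x[i] && ny2 == y[i] && nz2 == z[i]) return;  // no-op
      if (grid[idx(nx2, ny2, nz2)] != 0) return;              // occupied
      double dE = 0;
      if (col[i] != 0) {
        dE -= bead_site_energy(x[i], y[i], z[i], col[i]);
        // temporarily vacate so the new-site scan cannot see the bead
        grid[idx(x[i], y[i], z[i])] = 0;
        dE += bead_site_energy(nx2, ny2, nz2, col[i]);
        grid[idx(x[i], y[i], z[i])] = i + 1;
      }
      if (dE <= 0 || dist_u01(rng) < std::exp(-dE)) {
        grid[idx(x[i], y[i], z[i])] = 0;
        x[i] = nx2; y[i] = ny2; z[i] = nz2;
        grid[idx(nx2, ny2, nz2)] = i + 1;
        E += dE;
      }
    } else {  // binder step
      int i = p - n;
      int d = dist_dir(rng);
      int a = bx[i] + DX[d], b = by[i] + DY[d], c = bz[i] + DZ[d];
      if (!inbox(a, b, c) || grid[idx(a, b, c)] != 0) return;
      double dE = -binder_site_energy(bx[i], by[i], bz[i], bcol[i])
                  + binder_site_energy(a, b, c, bcol[i]);
      if (dE <= 0 || dist_u01(rng) < std::exp(-dE)) {
        grid[idx(bx[i], by[i], bz[i])] = 0;
        bx[i] = a; by[i] = b; bz[i] = c;
        grid[idx(a, b, c)] = n + i + 1;
        E += dE;
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_sbs_run(IntegerVector pattern, int box, IntegerVector binder_counts,
                 NumericVector energies, double n_steps, int sample_every,
                 int trace_every, int seed, bool compact_init) {
  Sim s;
  s.L = box;
  s.n = pattern.size();
  s.col.assign(pattern.begin(), pattern.end());
  s.eng.assign(4, 0.0);
  for (int c = 1; c <= 3 && c <= energies.size(); ++c)
    s.eng[c] = energies[c - 1];
  s.nb = 0;
  for (int c = 0; c < binder_counts.size(); ++c) s.nb += binder_counts[c];
  s.bcol.resize(s.nb);
  int k = 0;
  for (int c = 0; c < binder_counts.size(); ++c)
    for (int i = 0; i < binder_counts[c]; ++i) s.bcol[k++] = c + 1;
  s.dist_particle = std::uniform_int_distribution<int>(0, s.n + s.nb - 1);
  s.dist_dir = std::uniform_int_distribution<int>(0, 5);
  s.init((unsigned long)seed, compact_init);

  long long steps = (long long)n_steps;
  int n_samples = sample_every > 0 ? (int)(steps / sample_every) : 0;
  int n_trace = trace_every > 0 ? (int)(steps / trace_every) : 0;
  List bead_samples(n_samples), binder_samples(n_samples);
  NumericVector sample_energy(n_samples), trace(n_trace);
  int si = 0, ti = 0;
  for (long long t = 1; t <= steps; ++t) {
    s.step();
    if (trace_every > 0 && t % trace_every == 0 && ti < n_trace)
      trace[ti++] = s.E;
    if (sample_every > 0 && t % sample_every == 0 && si < n_samples) {
      IntegerMatrix bm(s.n, 3), qm(s.nb, 3);
      for (int i = 0; i < s.n; ++i) {
        bm(i, 0) = s.x[i]; bm(i, 1) = s.y[i]; bm(i, 2) = s.z[i];
      }
      for (int i = 0; i < s.nb; ++i) {
        qm(i, 0) = s.bx[i]; qm(i, 1) = s.by[i]; qm(i, 2) = s.bz[i];
      }
      bead_samples[si] = bm;
      binder_samples[si] = qm;
      sample_energy[si] = s.E;
      ++si;
    }
  }
  return List::create(
    _["beads"] = bead_samples, _["binders"] = binder_samples,
    _["sample_energy"] = sample_energy, _["energy_trace"] = trace,
    _["final_energy_incremental"] = s.E,
    _["final_energy_recomputed"] = s.full_energy(),
    _["binder_colours"] = wrap(s.bcol));
}

// Full-state energy recomputation (bookkeeping oracle): every adjacent
// (binder, matching-colour bead) pair contributes -E[colour].
// [[Rcpp::export]]
double cpp_energy_full(IntegerMatrix beads, IntegerVector colours,
                       IntegerMatrix binders, IntegerVector bcolours,
                       NumericVector energies) {
  double e = 0;
  for (int i = 0; i < binders.nrow(); ++i) {
    int cc = bcolours[i];
    for (int j = 0; j < beads.nrow(); ++j) {
      if (colours[j] != cc) continue;
      int man = std::abs(beads(j,0) - binders(i,0)) +
                std::abs(beads(j,1) - binders(i,1)) +
                std::abs(beads(j,2) - binders(i,2));
      if (man == 1) e -= energies[cc - 1];
    }
  }
  return e;
}

// ---- exact lattice convex hull volume --------------------------------
//
// Incremental (beneath-beyond) 3D convex hull with exact int64
// orientation predicates, followed by a half-space membership count of
// lattice sites inside the hull.  Degenerate inputs (rank < 3) fall back
// to the number of distinct occupied sites.

struct Face { int a, b, c; bool alive; };

static inline int64_t orient3d(const std::array<int64_t,3>& p,
                               const std::array<int64_t,3>& q,
                               const std::array<int64_t,3>& r,
                               const std::array<int64_t,3>& s) {
  int64_t ax = q[0]-p[0], ay = q[1]-p[1], az = q[2]-p[2];
  int64_t bx = r[0]-p[0], by = r[1]-p[1], bz = r[2]-p[2];
  int64_t cx = s[0]-p[0], cy = s[1]-p[1], cz = s[2]-p[2];
  return ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx);
}

// [[Rcpp::export]]
double cpp_hull_sites(IntegerMatrix pts) {
  int n = pts.nrow();
  std::vector<std::array<int64_t,3>> P;
  P.reserve(n);
  for (int i = 0; i < n; ++i)
    P.push_back({(int64_t)pts(i,0), (int64_t)pts(i,1), (int64_t)pts(i,2)});
  std::sort(P.begin(), P.end());
  P.erase(std::unique(P.begin(), P.end()), P.end());
  n = (int)P.size();
  if (n < 4) return (double)n;

  // find an affinely independent quadruple
  int i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i)
    if (P[i] != P[0]) i1 = i;
  for (int i = 1; i < n && i2 < 0; ++i) {
    // non-collinear with (0, i1): cross product nonzero
    int64_t ux = P[i1][0]-P[0][0], uy = P[i1][1]-P[0][1], uz = P[i1][2]-P[0][2];
    int64_t vx = P[i][0]-P[0][0], vy = P[i][1]-P[0][1], vz = P[i][2]-P[0][2];
    int64_t cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
    if (cx || cy || cz) i2 = i;
  }
  if (i2 < 0) return (double)n;  // collinear set
  for (int i = 1; i < n && i3 < 0; ++i)
    if (orient3d(P[0], P[i1], P[i2], P[i]) != 0) i3 = i;
  if (i3 < 0) return (double)n;  // coplanar set

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c, int opp) {
    if (orient3d(P[a], P[b], P[c], P[opp]) > 0) std::swap(b, c);
    faces.push_back({a, b, c, true});
  };
  add_face(0, i1, i2, i3);
  add_face(0, i1, i3, i2);
  add_face(0, i2, i3, i1);
  add_face(i1, i2, i3, 0);

  for (int rep = 0; rep < 3; ++rep) {  // re-insertion passes catch
    bool changed = false;               // degenerate misses
    for (int p = 0; p < n; ++p) {
      std::vector<int> vis;
      for (int f = 0; f < (int)faces.size(); ++f) {
        if (!faces[f].alive) continue;
        if (orient3d(P[faces[f].a], P[faces[f].b], P[faces[f].c], P[p]) > 0)
          vis.push_back(f);
      }
      if (vis.empty()) continue;
      changed = true;
      // horizon: directed edges of visible faces appearing exactly once
      std::vector<std::pair<int,int>> edges;
      for (int f : vis) {
        edges.push_back({faces[f].a, faces[f].b});
        edges.push_back({faces[f].b, faces[f].c});
        edges.push_back({faces[f].c, faces[f].a});
        faces[f].alive = false;
      }
      for (auto& e : edges) {
        bool twin = false;
        for (auto& e2 : edges)
          if (e2.first == e.second && e2.second == e.first) { twin = true; break; }
        if (!twin) {
          // keep visible-face winding; skip zero-area faces (p collinear
          // with the horizon edge)
          int64_t ux = P[e.second][0]-P[e.first][0],
                  uy = P[e.second][1]-P[e.first][1],
                  uz = P[e.second][2]-P[e.first][2];
          int64_t vx = P[p][0]-P[e.first][0],
                  vy = P[p][1]-P[e.first][1],
                  vz = P[p][2]-P[e.first][2];
          if (!(uy*vz-uz*vy) && !(uz*vx-ux*vz) && !(ux*vy-uy*vx)) continue;
          faces.push_back({e.first, e.second, p, true});
        }
      }
    }
    if (!changed) break;
  }

  // compact alive faces
  std::vector<Face> hull;
  for (auto& f : faces) if (f.alive) hull.push_back(f);

  // count lattice sites inside all half-spaces
  int64_t xmin = P[0][0], xmax = P[0][0], ymin = P[0][1], ymax = P[0][1],
          zmin = P[0][2], zmax = P[0][2];
  for (auto& p : P) {
    xmin = std::min(xmin, p[0]); xmax = std::max(xmax, p[0]);
    ymin = std::min(ymin, p[1]); ymax = std::max(ymax, p[1]);
    zmin = std::min(zmin, p[2]); zmax = std::max(zmax, p[2]);
  }
  // precompute face plane normals/offsets
  struct Plane { int64_t nx, ny, nz, d; };
  std::vector<Plane> planes;
  for (auto& f : hull) {
    int64_t ax = P[f.b][0]-P[f.a][0], ay = P[f.b][1]-P[f.a][1],
            az = P[f.b][2]-P[f.a][2];
    int64_t bx2 = P[f.c][0]-P[f.a][0], by2 = P[f.c][1]-P[f.a][1],
            bz2 = P[f.c][2]-P[f.a][2];
    int64_t nx2 = ay*bz2 - az*by2, ny2 = az*bx2 - ax*bz2,
            nz2 = ax*by2 - ay*bx2;
    if (!nx2 && !ny2 && !nz2) continue;
    int64_t d = nx2*P[f.a][0] + ny2*P[f.a][1] + nz2*P[f.a][2];
    planes.push_back({nx2, ny2, nz2, d});
  }
  double count = 0;
  for (int64_t a = xmin; a <= xmax; ++a)
    for (int64_t b = ymin; b <= ymax; ++b)
      for (int64_t c = zmin; c <= zmax; ++c) {
        bool inside = true;
        for (auto& pl : planes) {
          if (pl.nx*a + pl.ny*b + pl.nz*c > pl.d) { inside = false; break; }
        }
        if (inside) count += 1;
      }
  return count;
}

// Bead-pair contact matrix: 1 if squared Euclidean distance <= thresh2.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_matrix(IntegerMatrix beads, double thresh2) {
  int n = beads.nrow();
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double dx = beads(i,0)-beads(j,0), dy = beads(i,1)-beads(j,1),
             dz = beads(i,2)-beads(j,2);
      int v = (dx*dx + dy*dy + dz*dz <= thresh2) ? 1 : 0;
      out(i, j) = out(j, i) = v;
    }
  return out;
}
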