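#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Diffusion-limited aggregation of rigid, axis-parallel rods on a 3D
// hexagonal lattice: hexagonal close packing in x-y (6 lateral neighbours,
// axial coordinates q,r with x = q + r/2, y = r*sqrt(3)/2) and +/-1 steps
// in z. A rod occupies L consecutive z sites of one column. Walkers are
// launched on a circle outside the aggregate, take axial steps with
// probability p_axial (4L/(pi D) more likely than lateral, from the viscous
// resistance of a cylinder) and stick when adhesive spheres of compatible
// type meet laterally in register (base offset == 0 mod period).

static inline int64_t pack3(int q, int r, int z) {
  const int64_t OFF = 1 << 20;
  return (((int64_t)(q + OFF)) << 42) | (((int64_t)(r + OFF)) << 21) |
         ((int64_t)(z + OFF));
}
static inline int64_t pack2(int q, int r) {
  const int64_t OFF = 1 << 20;
  return (((int64_t)(q + OFF)) << 21) | ((int64_t)(r + OFF));
}

static const int DQ[6] = {1, -1, 0, 0, 1, -1};
static const int DR[6] = {0, 0, 1, -1, -1, 1};

// [[Rcpp::export]]
List cpp_run_dla(IntegerVector sphere_type, int period, int n_rods,
                 double p_axial, double launch_margin, double kill_factor,
                 double max_steps, int min_contacts, LogicalMatrix allow) {
  const int L = sphere_type.size();
  // adhesive sphere indices (type >= 0; drivers are -1)
  std::vector<int> adh;
  for (int i = 0; i < L; ++i) if (sphere_type[i] >= 0) adh.push_back(i);

  std::unordered_map<int64_t, std::pair<int, int>> sites; // -> (rod, sphere)
  std::unordered_map<int64_t, int> cols;                  // column -> rod count

  std::vector<int> bq(n_rods), br(n_rods), bz(n_rods);
  std::vector<std::pair<int, int>> edges;

  const double SQ3 = std::sqrt(3.0);
  auto colx = [&](int q, int r) { return q + 0.5 * r; };
  auto coly = [&](int r) { return 0.5 * SQ3 * r; };

  // seed rod at the origin
  bq[0] = 0; br[0] = 0; bz[0] = 0;
  for (int i = 0; i < L; ++i) sites[pack3(0, 0, i)] = {0, i};
  cols[pack2(0, 0)] = 1;
  double max_rad = 0.0;
  int zmin = 0, zmax = L - 1;

  GetRNGstate();
  double total_steps = 0.0, n_ax = 0.0, n_lat = 0.0;
  int relaunches = 0;

  for (int rod = 1; rod < n_rods; ++rod) {
    bool placed = false;
    while (!placed) {
      // launch
      const double Rl = max_rad + launch_margin;
      const double ang = 2.0 * M_PI * unif_rand();
      const double x = Rl * std::cos(ang), y = Rl * std::sin(ang);
      int r = (int)std::lround(2.0 * y / SQ3);
      int q = (int)std::lround(x - 0.5 * r);
      const int zlo = zmin - L - (int)launch_margin;
      const int zhi = zmax + (int)launch_margin;
      int z0 = zlo + (int)std::floor(unif_rand() * (zhi - zlo + 1));
      const double kill_r2 = (kill_factor * Rl) * (kill_factor * Rl);
      const int kill_z = (int)(kill_factor * (L + launch_margin));

      double steps = 0.0;
      while (true) {
        // contact check (after launch and after every move)
        int contacts = 0, touch_rod = -1;
        bool multi = false;
        for (int d = 0; d < 6 && contacts < min_contacts; ++d) {
          const int nq = q + DQ[d], nr = r + DR[d];
          if (cols.find(pack2(nq, nr)) == cols.end()) continue;
          for (size_t a = 0; a < adh.size(); ++a) {
            const int ia = adh[a];
            auto it = sites.find(pack3(nq, nr, z0 + ia));
            if (it == sites.end()) continue;
            const int ib = it->second.second;
            const int tb = sphere_type[ib];
            if (tb < 0) continue;
            if (!allow(sphere_type[ia], tb)) continue;
            const int off = ((ia - ib) % period + period) % period;
            if (off != 0) continue;
            ++contacts;
            if (touch_rod == -1) touch_rod = it->second.first;
            else if (touch_rod != it->second.first) multi = true;
            if (contacts >= min_contacts) break;
          }
        }
        if (contacts >= min_contacts) {
          // stick: record all contacted rods as edges
          for (int d = 0; d < 6; ++d) {
            const int nq = q + DQ[d], nr = r + DR[d];
            if (cols.find(pack2(nq, nr)) == cols.end()) continue;
            for (size_t a = 0; a < adh.size(); ++a) {
              const int ia = adh[a];
              auto it = sites.find(pack3(nq, nr, z0 + ia));
              if (it == sites.end()) continue;
              const int ib = it->second.second;
              if (sphere_type[ib] < 0) continue;
              if (!allow(sphere_type[ia], sphere_type[ib])) continue;
              if (((ia - ib) % period + period) % period != 0) continue;
              const int other = it->second.first;
              bool seen = false;
              for (size_t e = edges.size(); e-- > 0;) {
                if (edges[e].first != rod) break;
                if (edges[e].second == other) { seen = true; break; }
              }
              if (!seen) edges.push_back({rod, other});
            }
          }
          bq[rod] = q; br[rod] = r; bz[rod] = z0;
          for (int i = 0; i < L; ++i) sites[pack3(q, r, z0 + i)] = {rod, i};
          cols[pack2(q, r)] += 1;
          const double cx = colx(q, r), cy = coly(r);
          const double rad = std::sqrt(cx * cx + cy * cy);
          if (rad > max_rad) max_rad = rad;
          if (z0 < zmin) zmin = z0;
          if (z0 + L - 1 > zmax) zmax = z0 + L - 1;
          placed = true;
          (void)multi;
          break;
        }

        // step
        steps += 1.0; total_steps += 1.0;
        if (steps > max_steps) { ++relaunches; break; }
        if (unif_rand() < p_axial) {
          n_ax += 1.0;
          const int dz = unif_rand() < 0.5 ? -1 : 1;
          bool blocked = false;
          if (cols.find(pack2(q, r)) != cols.end()) {
            const int lead = dz > 0 ? z0 + L : z0 - 1;
            blocked = sites.find(pack3(q, r, lead)) != sites.end();
          }
          if (!blocked) z0 += dz;
        } else {
          n_lat += 1.0;
          const int d = (int)std::floor(unif_rand() * 6.0);
          const int nq = q + DQ[d], nr = r + DR[d];
          bool blocked = false;
          if (cols.find(pack2(nq, nr)) != cols.end()) {
            for (int i = 0; i < L; ++i) {
              if (sites.find(pack3(nq, nr, z0 + i)) != sites.end()) {
                blocked = true; break;
              }
            }
          }
          if (!blocked) { q = nq; r = nr; }
        }
        // kill
        const double cx = colx(q, r), cy = coly(r);
        if (cx * cx + cy * cy > kill_r2 || z0 < zmin - kill_z ||
            z0 > zmax + kill_z) {
          ++relaunches; break;
        }
      }
    }
  }
  PutRNGstate();

  IntegerMatrix bases(n_rods, 3);
  for (int i = 0; i < n_rods; ++i) {
    bases(i, 0) = bq[i]; bases(i, 1) = br[i]; bases(i, 2) = bz[i];
  }
  IntegerMatrix em(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    em(e, 0) = edges[e].first + 1; em(e, 1) = edges[e].second + 1;
  }
  return List::create(_["bases"] = bases, _["edges"] = em,
                      _["total_steps"] = total_steps,
                      _["axial_steps"] = n_ax, _["lateral_steps"] = n_lat,
                      _["relaunches"] = relaunches);
}

// Draw n diffusion steps with the walker's axial/lateral decision rule and
// return the class counts (for checking the 4L/(pi D) anisotropy).
// [[Rcpp::export]]
NumericVector cpp_step_counts(double p_axial, double n) {
  GetRNGstate();
  double ax = 0.0;
  for (double i = 0; i < n; ++i) if (unif_rand() < p_axial) ax += 1.0;
  PutRNGstate();
  return NumericVector::create(ax, n - ax);
}
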