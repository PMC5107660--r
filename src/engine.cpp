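// Stepping engine for the scaffold-engraftment agent-based model.
//
// A 3D cubic lattice of patches carries a radial substrate field; agents are
// motile or engrafted cells. Within each time step, agents act once each in
// a freshly randomized order: move (motile), attach (motile), age/die
// (engrafted), proliferate (engrafted). All randomness flows through R's RNG
// so set.seed() makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "voronoi.h"
using namespace Rcpp;

static int DIRS[26][3];
static double DIRN[26][3];  // normalized
static bool dirs_ready = false;

static void init_dirs() {
  if (dirs_ready) return;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        DIRS[k][0] = dx;
        DIRS[k][1] = dy;
        DIRS[k][2] = dz;
        double nrm = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        DIRN[k][0] = dx / nrm;
        DIRN[k][1] = dy / nrm;
        DIRN[k][2] = dz / nrm;
        ++k;
      }
  dirs_ready = true;
}

// nearest of the 26 lattice directions (max cosine; first wins ties)
static int quantize_dir(double vx, double vy, double vz) {
  init_dirs();
  int best = 0;
  double bdot = -2.0;
  double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (nrm < 1e-12) return 0;
  vx /= nrm; vy /= nrm; vz /= nrm;
  for (int k = 0; k < 26; ++k) {
    double d = vx * DIRN[k][0] + vy * DIRN[k][1] + vz * DIRN[k][2];
    if (d > bdot) {
      bdot = d;
      best = k;
    }
  }
  return best;
}

// Rodrigues rotation of v around unit axis a by angle theta
static void rotate_about(const double v[3], const double a[3], double theta,
                         double out[3]) {
  double c = std::cos(theta), s = std::sin(theta);
  double cross[3] = {a[1] * v[2] - a[2] * v[1], a[2] * v[0] - a[0] * v[2],
                     a[0] * v[1] - a[1] * v[0]};
  double dot = a[0] * v[0] + a[1] * v[1] + a[2] * v[2];
  for (int i = 0; i < 3; ++i)
    out[i] = v[i] * c + cross[i] * s + a[i] * dot * (1.0 - c);
}

// the "ahead", "ahead-left", "ahead-right" lattice directions for a heading:
// quantize the heading, then rotate it +/- 45 degrees about the axis
// perpendicular to it within the plane of the heading and an up-reference.
static void ahead_dirs(double hx, double hy, double hz, int out[3]) {
  init_dirs();
  int k0 = quantize_dir(hx, hy, hz);
  out[0] = k0;
  double h[3] = {DIRN[k0][0], DIRN[k0][1], DIRN[k0][2]};
  double up[3] = {0.0, 0.0, 1.0};
  if (std::fabs(h[2]) > 0.999) {
    up[0] = 1.0;
    up[2] = 0.0;
  }
  double ax[3] = {h[1] * up[2] - h[2] * up[1], h[2] * up[0] - h[0] * up[2],
                  h[0] * up[1] - h[1] * up[0]};
  double an = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  for (int i = 0; i < 3; ++i) ax[i] /= an;
  double r[3];
  const double q = M_PI / 4.0;
  rotate_about(h, ax, q, r);
  out[1] = quantize_dir(r[0], r[1], r[2]);
  rotate_about(h, ax, -q, r);
  out[2] = quantize_dir(r[0], r[1], r[2]);
}

// [[Rcpp::export(name = ".cpp_quantize_direction")]]
IntegerVector cpp_quantize_direction(NumericVector v) {
  if (v.size() != 3) stop("v must have length 3");
  init_dirs();
  int k = quantize_dir(v[0], v[1], v[2]);
  return IntegerVector::create(DIRS[k][0], DIRS[k][1], DIRS[k][2]);
}

// [[Rcpp::export(name = ".cpp_ahead_directions")]]
IntegerMatrix cpp_ahead_directions(NumericVector heading) {
  if (heading.size() != 3) stop("heading must have length 3");
  init_dirs();
  int ks[3];
  ahead_dirs(heading[0], heading[1], heading[2], ks);
  IntegerMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = DIRS[ks[i]][j];
  return out;
}

// uniform draw on the integer lattice of [lo, hi] (inclusive endpoints)
static int unif_int(double lo, double hi) {
  int a = (int)std::ceil(lo - 1e-9);
  int b = (int)std::floor(hi + 1e-9);
  if (b < a) b = a;
  int k = a + (int)(unif_rand() * (double)(b - a + 1));
  if (k > b) k = b;
  return k;
}

struct DrawSpec {     // one of T_life / T_prol under one engraftment mode
  int kind;           // 0 = uniform interval, 1 = environment-coupled
  double lo, hi;      // uniform interval, or noise interval when coupled
  double base, sign;  // coupled: round(scale*(base + sign*c/envf)) + n
  double scale;
};

static DrawSpec read_spec(List s) {
  DrawSpec d;
  d.kind = as<int>(s["kind"]);
  d.lo = as<double>(s["lo"]);
  d.hi = as<double>(s["hi"]);
  d.base = s.containsElementNamed("base") ? as<double>(s["base"]) : 0.0;
  d.sign = s.containsElementNamed("sign") ? as<double>(s["sign"]) : 0.0;
  d.scale = s.containsElementNamed("scale") ? as<double>(s["scale"]) : 1.0;
  return d;
}

static int draw_T(const DrawSpec &d, double cp, double envf) {
  if (d.kind == 0) return unif_int(d.lo, d.hi);
  double det = d.scale * (d.base + d.sign * cp / envf);
  int v = (int)std::lround(det) + unif_int(d.lo, d.hi);
  return v < 1 ? 1 : v;  // negative formula values floored at 1
}

struct Engine {
  int G, lo, hi, P;
  std::vector<double> conc;
  std::vector<int> occ;  // -1 empty, else cell id
  std::vector<int> cx, cy, cz, Tl, Tp, Nl, Np;
  std::vector<signed char> st;  // 0 motile, 1 engrafted, 2 gone
  double n_crit, envf, c_amount, move_thresh;
  bool per_step_deposit, prolif_on;
  int max_tgt;
  DrawSpec init_life, init_prol, off_life, off_prol;

  int idx(int x, int y, int z) const {
    return (x - lo) + G * ((y - lo) + G * (z - lo));
  }
  bool inb(int x, int y, int z) const {
    return x >= lo && x <= hi && y >= lo && y <= hi && z >= lo && z <= hi;
  }

  int occupied_neighbours(int x, int y, int z) const {
    int n = 0;
    for (int k = 0; k < 26; ++k) {
      int xx = x + DIRS[k][0], yy = y + DIRS[k][1], zz = z + DIRS[k][2];
      if (inb(xx, yy, zz) && occ[idx(xx, yy, zz)] >= 0) ++n;
    }
    return n;
  }

  void engraft(int id, bool offspring) {
    int p = idx(cx[id], cy[id], cz[id]);
    double cp = conc[p];
    if (offspring) {
      Tl[id] = draw_T(off_life, cp, envf);
      Tp[id] = draw_T(off_prol, cp, envf);
    } else {
      Tl[id] = draw_T(init_life, cp, envf);
      Tp[id] = draw_T(init_prol, cp, envf);
    }
    Nl[id] = 0;
    Np[id] = 0;
    st[id] = 1;
    if (!per_step_deposit) conc[p] += c_amount;
  }

  void die(int id) {
    int p = idx(cx[id], cy[id], cz[id]);
    occ[p] = -1;
    st[id] = 2;
    conc[p] -= c_amount;
    if (conc[p] < 0.0) conc[p] = 0.0;
  }
};

// [[Rcpp::export(name = ".cpp_run_engine")]]
List cpp_run_engine(List cfg) {
  init_dirs();
  Engine E;
  E.G = as<int>(cfg["grid_size"]);
  E.lo = -E.G / 2;
  E.hi = E.G / 2 - 1;
  E.P = E.G * E.G * E.G;
  const int n_cells = as<int>(cfg["n_cells"]);
  const double engraft_prob = as<double>(cfg["engraft_prob"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const IntegerVector record_steps = cfg["record_steps"];
  const IntegerVector slice_z = cfg["slice_z"];
  const bool grace = as<bool>(cfg["seeding_grace"]);
  const bool want_cvhv = as<bool>(cfg["compute_cvhv"]);
  const bool keep_pos = as<bool>(cfg["keep_positions"]);
  const double c_scale = as<double>(cfg["c_formula_scale"]);
  const double c_div = as<double>(cfg["c_formula_divisor"]);
  E.n_crit = as<double>(cfg["n_crit"]);
  E.envf = as<double>(cfg["c_envfactor"]);
  E.c_amount = as<double>(cfg["c_amount"]);
  E.move_thresh = as<double>(cfg["movement_threshold"]);
  E.per_step_deposit = as<bool>(cfg["per_step_deposit"]);
  E.prolif_on = as<bool>(cfg["proliferation"]);
  E.max_tgt = as<int>(cfg["max_target_neighbors"]);
  E.init_life = read_spec(cfg["init_life"]);
  E.init_prol = read_spec(cfg["init_prol"]);
  E.off_life = read_spec(cfg["off_life"]);
  E.off_prol = read_spec(cfg["off_prol"]);

  if (n_cells > E.P) stop("n_cells exceeds the number of patches");

  // baseline radial substrate field (no z term)
  E.conc.resize(E.P);
  for (int z = E.lo; z <= E.hi; ++z)
    for (int y = E.lo; y <= E.hi; ++y)
      for (int x = E.lo; x <= E.hi; ++x)
        E.conc[E.idx(x, y, z)] =
            c_scale * std::sqrt((double)(x * x + y * y)) / c_div;
  E.occ.assign(E.P, -1);

  // --- seeding: n_cells distinct random patches (partial Fisher-Yates)
  std::vector<int> pool(E.P);
  for (int i = 0; i < E.P; ++i) pool[i] = i;
  int engrafted_t0 = 0;
  for (int i = 0; i < n_cells; ++i) {
    int j = i + (int)(unif_rand() * (double)(E.P - i));
    if (j > E.P - 1) j = E.P - 1;
    std::swap(pool[i], pool[j]);
    int p = pool[i];
    int x = E.lo + p % E.G, y = E.lo + (p / E.G) % E.G,
        z = E.lo + p / (E.G * E.G);
    bool attach = unif_rand() < engraft_prob;
    if (!attach && !grace) continue;  // eliminated at seeding
    int id = (int)E.cx.size();
    E.cx.push_back(x);
    E.cy.push_back(y);
    E.cz.push_back(z);
    E.Tl.push_back(0);
    E.Tp.push_back(0);
    E.Nl.push_back(0);
    E.Np.push_back(0);
    E.st.push_back(0);
    E.occ[p] = id;
    if (attach) {
      E.engraft(id, false);
      ++engrafted_t0;
    }
  }

  const int n_rec = record_steps.size(), n_sl = slice_z.size();
  NumericMatrix rec_counts(n_rec, n_sl), rec_cvhv(n_rec, n_sl);
  std::fill(rec_cvhv.begin(), rec_cvhv.end(), NA_REAL);
  List rec_pos(keep_pos ? n_rec : 0);
  IntegerMatrix totals(n_steps, 6);  // engrafted, motile, attach, birth, death, culled
  const double half = 0.5;
  double vb[4] = {E.lo - half, E.hi + half, E.lo - half, E.hi + half};

  std::vector<int> order;
  for (int step = 1; step <= n_steps; ++step) {
    // randomized sequential order over cells alive at step start
    order.clear();
    const int n_now = (int)E.cx.size();
    for (int i = 0; i < n_now; ++i)
      if (E.st[i] != 2) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (double)(i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    int attach = 0, birth = 0, death = 0, culled = 0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int id = order[oi];
      if (E.st[id] == 2) continue;

      if (E.st[id] == 0) {
        // Rule 1: movement along a re-randomized forward vector
        double hx = norm_rand(), hy = norm_rand(), hz = norm_rand();
        int ks[3];
        ahead_dirs(hx, hy, hz, ks);
        double S = 0.0;
        double cahead[3];
        bool okahead[3];
        for (int a = 0; a < 3; ++a) {
          int xx = E.cx[id] + DIRS[ks[a]][0], yy = E.cy[id] + DIRS[ks[a]][1],
              zz = E.cz[id] + DIRS[ks[a]][2];
          okahead[a] = E.inb(xx, yy, zz);
          cahead[a] = okahead[a] ? E.conc[E.idx(xx, yy, zz)] : 0.0;
          S += unif_rand() * cahead[a];
        }
        int mx = E.cx[id], my = E.cy[id], mz = E.cz[id];
        bool moved = false;
        if (S > E.move_thresh) {
          // toward the strongest in-bounds, unoccupied ahead patch
          double bestc = -1.0;
          for (int a = 0; a < 3; ++a) {
            if (!okahead[a]) continue;
            int xx = E.cx[id] + DIRS[ks[a]][0], yy = E.cy[id] + DIRS[ks[a]][1],
                zz = E.cz[id] + DIRS[ks[a]][2];
            if (E.occ[E.idx(xx, yy, zz)] >= 0) continue;
            if (cahead[a] > bestc) {
              bestc = cahead[a];
              mx = xx; my = yy; mz = zz;
              moved = true;
            }
          }
        } else {
          // random unoccupied adjacent patch
          int cand[26], nc = 0;
          for (int k = 0; k < 26; ++k) {
            int xx = E.cx[id] + DIRS[k][0], yy = E.cy[id] + DIRS[k][1],
                zz = E.cz[id] + DIRS[k][2];
            if (E.inb(xx, yy, zz) && E.occ[E.idx(xx, yy, zz)] < 0)
              cand[nc++] = k;
          }
          if (nc > 0) {
            int pick = (int)(unif_rand() * (double)nc);
            if (pick >= nc) pick = nc - 1;
            mx = E.cx[id] + DIRS[cand[pick]][0];
            my = E.cy[id] + DIRS[cand[pick]][1];
            mz = E.cz[id] + DIRS[cand[pick]][2];
            moved = true;
          }
        }
        if (moved) {
          E.occ[E.idx(E.cx[id], E.cy[id], E.cz[id])] = -1;
          E.cx[id] = mx; E.cy[id] = my; E.cz[id] = mz;
          E.occ[E.idx(mx, my, mz)] = id;
        }
        // Rule 2: attachment
        double N = unif_rand() * 100.0;
        if (N > E.n_crit) {
          E.engraft(id, false);
          ++attach;
        }
      }

      if (E.st[id] == 1) {
        if (E.per_step_deposit)
          E.conc[E.idx(E.cx[id], E.cy[id], E.cz[id])] += E.c_amount;
        // Rule 3: ageing and death
        E.Nl[id] += 1;
        if (E.Nl[id] >= E.Tl[id]) {
          E.die(id);
          ++death;
          continue;
        }
        // Rule 4: proliferation
        if (E.prolif_on) {
          if (E.Np[id] < E.Tp[id]) E.Np[id] += 1;
          if (E.Np[id] >= E.Tp[id]) {
            int cand[26], nc = 0;
            for (int k = 0; k < 26; ++k) {
              int xx = E.cx[id] + DIRS[k][0], yy = E.cy[id] + DIRS[k][1],
                  zz = E.cz[id] + DIRS[k][2];
              if (!E.inb(xx, yy, zz)) continue;
              if (E.occ[E.idx(xx, yy, zz)] >= 0) continue;
              if (E.occupied_neighbours(xx, yy, zz) > E.max_tgt) continue;
              cand[nc++] = k;
            }
            if (nc > 0) {
              int pick = (int)(unif_rand() * (double)nc);
              if (pick >= nc) pick = nc - 1;
              int xx = E.cx[id] + DIRS[cand[pick]][0],
                  yy = E.cy[id] + DIRS[cand[pick]][1],
                  zz = E.cz[id] + DIRS[cand[pick]][2];
              int nid = (int)E.cx.size();
              E.cx.push_back(xx); E.cy.push_back(yy); E.cz.push_back(zz);
              E.Tl.push_back(0); E.Tp.push_back(0);
              E.Nl.push_back(0); E.Np.push_back(0);
              E.st.push_back(0);
              E.occ[E.idx(xx, yy, zz)] = nid;
              E.engraft(nid, true);  // offspring acts from the next step
              E.Np[id] = 0;
              ++birth;
            }  // else: defer, counter held at T_prol, retried next step
          }
        }
      }
    }

    // one-step-grace seeding: unattached motile cells are eliminated
    if (grace && step == 1) {
      for (size_t i = 0; i < E.st.size(); ++i)
        if (E.st[i] == 0) {
          E.occ[E.idx(E.cx[i], E.cy[i], E.cz[i])] = -1;
          E.st[i] = 2;
          ++culled;
        }
    }

    int n_eng = 0, n_mot = 0;
    for (size_t i = 0; i < E.st.size(); ++i) {
      if (E.st[i] == 1) ++n_eng;
      else if (E.st[i] == 0) ++n_mot;
    }
    totals(step - 1, 0) = n_eng;
    totals(step - 1, 1) = n_mot;
    totals(step - 1, 2) = attach;
    totals(step - 1, 3) = birth;
    totals(step - 1, 4) = death;
    totals(step - 1, 5) = culled;

    // recording
    for (int r = 0; r < n_rec; ++r) {
      if (record_steps[r] != step) continue;
      for (int s = 0; s < n_sl; ++s) {
        int zz = slice_z[s];
        std::vector<double> sx, sy;
        for (size_t i = 0; i < E.st.size(); ++i)
          if (E.st[i] == 1 && E.cz[i] == zz) {
            sx.push_back((double)E.cx[i]);
            sy.push_back((double)E.cy[i]);
          }
        rec_counts(r, s) = (double)sx.size();
        if (want_cvhv && sx.size() >= 2) {
          std::vector<double> ar = voronoi_areas_core(sx, sy, vb);
          double m = 0.0;
          for (double a : ar) m += a;
          m /= ar.size();
          double v = 0.0;
          for (double a : ar) v += (a - m) * (a - m);
          v /= (ar.size() - 1.0);
          rec_cvhv(r, s) = v * (double)ar.size();
        }
      }
      if (keep_pos) {
        int na = 0;
        for (size_t i = 0; i < E.st.size(); ++i)
          if (E.st[i] == 1) ++na;
        IntegerMatrix pos(na, 3);
        int rI = 0;
        for (size_t i = 0; i < E.st.size(); ++i)
          if (E.st[i] == 1) {
            pos(rI, 0) = E.cx[i];
            pos(rI, 1) = E.cy[i];
            pos(rI, 2) = E.cz[i];
            ++rI;
          }
        rec_pos[r] = pos;
      }
    }
  }

  // occupancy sanity: each occupied patch points at a live cell on it
  int occ_bad = 0;
  for (int p = 0; p < E.P; ++p) {
    int id = E.occ[p];
    if (id < 0) continue;
    if (E.st[id] == 2 || E.idx(E.cx[id], E.cy[id], E.cz[id]) != p) ++occ_bad;
  }

  colnames(totals) = CharacterVector::create("engrafted", "motile", "attachments",
                                             "births", "deaths", "culled");
  List out = List::create(
      _["engrafted_t0"] = engrafted_t0, _["totals"] = totals,
      _["record_steps"] = record_steps, _["slice_z"] = slice_z,
      _["slice_counts"] = rec_counts, _["slice_cvhv"] = rec_cvhv,
      _["occupancy_violations"] = occ_bad,
      _["substrate"] = NumericVector(E.conc.begin(), E.conc.end()));
  if (keep_pos) out["positions"] = rec_pos;
  return out;
}
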