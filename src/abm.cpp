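#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Agent ids are 1-based: citizens 1..n_cit, cops n_cit+1..n_cit+n_cops.
// Cells are 1-based 1..side*side; 0 in a position slot means "off grid" (Jailed).
// occupancy holds the agent id on a cell, 0 when empty.
// Citizen states: 0 Quiet, 1 Active, 2 Jailed.
// All randomness goes through R's RNG so set.seed() gives full determinism.
//
// The tick maintains two per-cell count fields -- cops within vision and
// Active citizens within vision -- updated incrementally on every move,
// state flip, arrest and release, so each citizen's decision is O(1) instead
// of an O(vision^2) rescan. Movement draws candidate cells by rejection
// sampling (uniform over the vision box, accept the first empty cell), which
// is exactly uniform over empty cells; a full enumeration fallback preserves
// the "stay put only when no empty cell is visible" contract.

namespace {

struct Params {
  int n_cit, n_cops, side, ncell, vision, max_jail, jail_cap;
  double k;
};

Params read_params(const List& world) {
  List p = world["params"];
  Params q;
  q.n_cit    = as<int>(p["n_citizens"]);
  q.n_cops   = as<int>(p["n_cops"]);
  q.side     = as<int>(p["grid_side"]);
  q.ncell    = q.side * q.side;
  q.vision   = as<int>(p["vision"]);
  q.max_jail = as<int>(p["max_jail_term"]);
  q.jail_cap = as<int>(p["jail_capacity"]);
  q.k        = as<double>(p["arrest_k"]);
  return q;
}

inline int wrap(int a, int side) { a %= side; return a < 0 ? a + side : a; }
inline int cell_x(int c, int side) { return (c - 1) / side; }
inline int cell_y(int c, int side) { return (c - 1) % side; }

inline int unif_index(int n) {
  int i = static_cast<int>(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

struct World {
  NumericVector ra, ph;
  IntegerVector state, jail, cit_pos, cop_pos, occ;
  Params p;
  std::vector<int> cop_field;  // cops within vision of each cell
  std::vector<int> act_field;  // Active citizens within vision of each cell
};

// Visit every cell of the Chebyshev vision box around cell c exactly once.
template <typename F>
void for_vision(const Params& p, int c, F fn) {
  int span = std::min(2 * p.vision + 1, p.side);
  int x = cell_x(c, p.side), y = cell_y(c, p.side);
  static thread_local std::vector<int> xs, ys;
  xs.resize(span);
  ys.resize(span);
  for (int i = 0; i < span; ++i) {
    xs[i] = wrap(x - p.vision + i, p.side);
    ys[i] = wrap(y - p.vision + i, p.side);
  }
  for (int i = 0; i < span; ++i) {
    int base = xs[i] * p.side + 1;
    for (int j = 0; j < span; ++j) fn(base + ys[j]);
  }
}

inline void bump_field(World& w, std::vector<int>& field, int c, int delta) {
  for_vision(w.p, c, [&](int cc) { field[cc - 1] += delta; });
}

void build_fields(World& w) {
  w.cop_field.assign(w.p.ncell, 0);
  w.act_field.assign(w.p.ncell, 0);
  for (int i = 0; i < w.p.n_cops; ++i) bump_field(w, w.cop_field, w.cop_pos[i], 1);
  for (int i = 0; i < w.p.n_cit; ++i)
    if (w.state[i] == 1) bump_field(w, w.act_field, w.cit_pos[i], 1);
}

World clone_world(const List& world, bool with_fields) {
  World w;
  w.ra      = clone(as<NumericVector>(world["risk_aversion"]));
  w.ph      = clone(as<NumericVector>(world["perceived_hardship"]));
  w.state   = clone(as<IntegerVector>(world["state"]));
  w.jail    = clone(as<IntegerVector>(world["jail_remaining"]));
  w.cit_pos = clone(as<IntegerVector>(world["citizen_pos"]));
  w.cop_pos = clone(as<IntegerVector>(world["cop_pos"]));
  w.occ     = clone(as<IntegerVector>(world["occupancy"]));
  w.p       = read_params(world);
  if (with_fields) build_fields(w);
  return w;
}

List pack_world(const World& w, const List& old, int t) {
  List out = List::create(
    _["risk_aversion"]      = w.ra,
    _["perceived_hardship"] = w.ph,
    _["state"]              = w.state,
    _["jail_remaining"]     = w.jail,
    _["citizen_pos"]        = w.cit_pos,
    _["cop_pos"]            = w.cop_pos,
    _["occupancy"]          = w.occ,
    _["t"]                  = t,
    _["params"]             = old["params"]);
  out.attr("class") = old.attr("class");
  return out;
}

// Uniformly chosen empty cell in the vision box of `pos`, or 0 if none.
int pick_empty_cell(const World& w, int pos, std::vector<int>& buf) {
  int span = std::min(2 * w.p.vision + 1, w.p.side);
  int x = cell_x(pos, w.p.side), y = cell_y(pos, w.p.side);
  int tries = 3 * span * span;
  for (int i = 0; i < tries; ++i) {
    int xx = wrap(x - w.p.vision + unif_index(span), w.p.side);
    int yy = wrap(y - w.p.vision + unif_index(span), w.p.side);
    int cc = xx * w.p.side + yy + 1;
    if (w.occ[cc - 1] == 0) return cc;
  }
  buf.clear();
  for_vision(w.p, pos, [&](int cc) { if (w.occ[cc - 1] == 0) buf.push_back(cc); });
  if (buf.empty()) return 0;
  return buf[unif_index(static_cast<int>(buf.size()))];
}

// Relocate agent gid to a uniformly chosen empty cell within its vision
// radius; no move when no empty cell is visible or vision is zero.
// `use_fields` is false for the standalone single-agent entry points.
void move_agent_impl(World& w, int gid, std::vector<int>& buf, bool use_fields) {
  bool is_cop = gid > w.p.n_cit;
  int pos = is_cop ? w.cop_pos[gid - w.p.n_cit - 1] : w.cit_pos[gid - 1];
  if (pos == 0 || w.p.vision <= 0) return;
  int dest = pick_empty_cell(w, pos, buf);
  if (dest == 0) return;
  w.occ[pos - 1] = 0;
  w.occ[dest - 1] = gid;
  if (is_cop) {
    w.cop_pos[gid - w.p.n_cit - 1] = dest;
    if (use_fields) {
      bump_field(w, w.cop_field, pos, -1);
      bump_field(w, w.cop_field, dest, 1);
    }
  } else {
    w.cit_pos[gid - 1] = dest;
    if (use_fields && w.state[gid - 1] == 1) {
      bump_field(w, w.act_field, pos, -1);
      bump_field(w, w.act_field, dest, 1);
    }
  }
}

// Count cops and other Active citizens visible from cell c by direct scan
// (used by the standalone decision entry point; the tick uses the fields).
void scan_vision(const World& w, int c, int self_id, int& n_cops, int& n_act) {
  n_cops = 0; n_act = 0;
  for_vision(w.p, c, [&](int cc) {
    int id = w.occ[cc - 1];
    if (id == 0) return;
    if (id > w.p.n_cit) ++n_cops;
    else if (id != self_id && w.state[id - 1] == 1) ++n_act;
  });
}

// Threshold rule: Active iff grievance - risk_aversion * arrest_probability
// strictly exceeds the propaganda level. The cop-to-active ratio counts the
// evaluating citizen as active (the +1 in the denominator) and is floored to
// an integer (Epstein's estimated arrest likelihood); the discontinuity at
// ratios below one is what lets local rebellion cascades ignite.
inline bool threshold_rule(const World& w, int cid, int ncops, int nact_others,
                           double L, double P) {
  double r = static_cast<double>(ncops / (nact_others + 1));  // integer division
  double parr = 1.0 - std::exp(-w.p.k * r);
  double g = w.ph[cid - 1] * (1.0 - L);
  return (g - w.ra[cid - 1] * parr) > P;
}

bool decide_active_scan(const World& w, int cid, double L, double P) {
  int ncops, nact;
  scan_vision(w, w.cit_pos[cid - 1], cid, ncops, nact);
  return threshold_rule(w, cid, ncops, nact, L, P);
}

// One cop sweep: jail one uniformly chosen visible Active citizen, if any and
// if jail capacity allows. Returns the arrested citizen id, 0 when none.
int enforce_impl(World& w, int cop_i, int& jailed_count, std::vector<int>& buf,
                 bool use_fields) {
  if (jailed_count >= w.p.jail_cap) return 0;
  int pos = w.cop_pos[cop_i - 1];
  if (use_fields && w.act_field[pos - 1] == 0) return 0;
  buf.clear();
  for_vision(w.p, pos, [&](int cc) {
    int id = w.occ[cc - 1];
    if (id >= 1 && id <= w.p.n_cit && w.state[id - 1] == 1) buf.push_back(id);
  });
  if (buf.empty()) return 0;
  int cid = buf[unif_index(static_cast<int>(buf.size()))];
  int cpos = w.cit_pos[cid - 1];
  w.state[cid - 1] = 2;
  w.jail[cid - 1] = 1 + unif_index(w.p.max_jail);  // jail term ~ U{1..max_jail}
  w.occ[cpos - 1] = 0;
  w.cit_pos[cid - 1] = 0;
  if (use_fields) bump_field(w, w.act_field, cpos, -1);
  ++jailed_count;
  return cid;
}

}  // namespace

// [[Rcpp::export]]
List abm_step_cpp(List world, double legitimacy, double propaganda) {
  World w = clone_world(world, true);
  const int n_cit = w.p.n_cit, n_cops = w.p.n_cops;

  int jailed_count = 0;
  for (int i = 0; i < n_cit; ++i) if (w.state[i] == 2) ++jailed_count;

  // Uniformly shuffled activation order over all mobile agents.
  std::vector<int> order;
  order.reserve(n_cit + n_cops);
  for (int i = 1; i <= n_cit; ++i) if (w.state[i - 1] != 2) order.push_back(i);
  for (int i = n_cit + 1; i <= n_cit + n_cops; ++i) order.push_back(i);
  for (int i = static_cast<int>(order.size()) - 1; i > 0; --i) {
    int j = unif_index(i + 1);
    std::swap(order[i], order[j]);
  }

  std::vector<int> buf;
  buf.reserve(w.p.ncell);
  for (int gid : order) {
    if (gid <= n_cit) {
      if (w.state[gid - 1] == 2) continue;  // jailed earlier in this tick
      move_agent_impl(w, gid, buf, true);
      int pos = w.cit_pos[gid - 1];
      int self_act = w.state[gid - 1] == 1 ? 1 : 0;
      int nact = w.act_field[pos - 1] - self_act;
      int newstate =
          threshold_rule(w, gid, w.cop_field[pos - 1], nact, legitimacy, propaganda)
              ? 1 : 0;
      if (newstate != w.state[gid - 1]) {
        w.state[gid - 1] = newstate;
        bump_field(w, w.act_field, pos, newstate == 1 ? 1 : -1);
      }
    } else {
      move_agent_impl(w, gid, buf, true);
      enforce_impl(w, gid - n_cit, jailed_count, buf, true);
    }
  }

  // Jail countdown; release to Quiet on a uniformly chosen empty cell.
  for (int i = 0; i < n_cit; ++i) {
    if (w.state[i] != 2) continue;
    w.jail[i] -= 1;
    if (w.jail[i] <= 0) {
      buf.clear();
      for (int c = 1; c <= w.p.ncell; ++c) if (w.occ[c - 1] == 0) buf.push_back(c);
      if (buf.empty()) { w.jail[i] = 1; continue; }  // grid full: retry next tick
      int dest = buf[unif_index(static_cast<int>(buf.size()))];
      w.state[i] = 0;
      w.jail[i] = 0;
      w.cit_pos[i] = dest;
      w.occ[dest - 1] = i + 1;
    }
  }

  return pack_world(w, world, as<int>(world["t"]) + 1);
}

// Would-be Active decision for every citizen at current positions, with no
// movement and no RNG use; NA for Jailed citizens. Used for monotonicity
// checks of the decision rule in legitimacy and propaganda.
// [[Rcpp::export]]
IntegerVector abm_decisions_cpp(List world, double legitimacy, double propaganda) {
  World w = clone_world(world, false);
  IntegerVector out(w.p.n_cit, NA_INTEGER);
  for (int i = 1; i <= w.p.n_cit; ++i)
    if (w.state[i - 1] != 2)
      out[i - 1] = decide_active_scan(w, i, legitimacy, propaganda) ? 1 : 0;
  return out;
}

// Local cop and other-active counts plus the floored cop ratio for one
// citizen, by direct scan; exposes the decision inputs for unit tests.
// [[Rcpp::export]]
List abm_local_view_cpp(List world, int cid) {
  World w = clone_world(world, false);
  int ncops, nact;
  scan_vision(w, w.cit_pos[cid - 1], cid, ncops, nact);
  return List::create(_["cops_in_vision"] = ncops,
                      _["actives_in_vision"] = nact,
                      _["cop_ratio"] = ncops / (nact + 1));
}

// [[Rcpp::export]]
List abm_move_one_cpp(List world, int gid) {
  World w = clone_world(world, false);
  std::vector<int> buf;
  move_agent_impl(w, gid, buf, false);
  int pos = gid > w.p.n_cit ? w.cop_pos[gid - w.p.n_cit - 1] : w.cit_pos[gid - 1];
  return List::create(_["world"] = pack_world(w, world, as<int>(world["t"])),
                      _["pos"] = pos);
}

// [[Rcpp::export]]
List abm_enforce_one_cpp(List world, int cop) {
  World w = clone_world(world, false);
  int jailed_count = 0;
  for (int i = 0; i < w.p.n_cit; ++i) if (w.state[i] == 2) ++jailed_count;
  std::vector<int> buf;
  int cid = enforce_impl(w, cop, jailed_count, buf, false);
  return List::create(_["world"] = pack_world(w, world, as<int>(world["t"])),
                      _["arrested"] = cid);
}
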