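// Core stochastic engine: multi-lane, multi-section TASEP with
// Langmuir-kinetics reservoirs, multi-site hops, lateral lane changes and
// staggered (blocked) regions.  All randomness draws from R's RNG so that
// set.seed() at the R level makes a run fully reproducible.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

enum Status {
  ST_QUEUED = 0,
  ST_LATTICE = 1,
  ST_RESERVOIR = 2,
  ST_DELIVERED = 3,
  ST_LEAKED = 4,
  ST_JUNCTION = 5,
  ST_DROPPED = 6
};
const int N_STATUS = 7;

enum Cause { CAUSE_CROWD = 0, CAUSE_PROC = 1 };

struct Motor {
  int species;     // 0 = fast (a), 1 = slow (b)
  int section;     // 0-based
  int lane, site;  // 0-based while on lattice / anchored in a reservoir
  int run;         // forward displacement (sites) since last (re)attachment
  int status;
  int entry_iter;  // iteration of reservoir entry
};

struct Section {
  int T, N;
  std::vector<int> acc;   // T*N accessibility mask (1 = bindable)
  std::vector<int> occ;   // T*N occupancy: motor index + 1, or 0
  std::vector<int> atp;   // T*N minimum reservoir residence (iterations)
  bool lateral;
  int cap;                // reservoir capacity per site
  std::vector<std::deque<int> > res;  // per-site FIFO reservoirs
  std::deque<int> inq;       // motors waiting to load at site 1
  std::deque<int> junction;  // motors delivered from this section's plus end
  // accumulators
  std::vector<int> detach_cnt;    // T*N*2 species*2 cause
  std::vector<int> reattach_cnt;  // T*N*2 species
  std::vector<int> outflow;       // horizon*T*2 species
  std::vector<int> detach_series; // horizon*2 species*2 cause
  std::vector<double> dens;       // T*N*2 species occupancy accumulator
  double loaded = 0, delivered = 0, leaked = 0, transferred_in = 0;
  inline int idx(int l, int j) const { return l * N + j; }
};

inline int pick(int k) {  // uniform integer in [0, k)
  int u = (int)std::floor(unif_rand() * k);
  return u >= k ? k - 1 : u;
}

struct Engine {
  std::vector<Section> sec;
  std::vector<Motor> motors;
  std::vector<int> stepped;  // iteration stamp guard (ascending order)
  int horizon;
  int v_sp[2], p_sp[2], lt_sp[2];
  bool crowding_detach, drop_blocked, stop_when_empty, record_density;
  double exit_prob;
  int update_order;   // 0 = descending site, 1 = random shuffle
  int lateral_target; // 0 = displaced (site + v), 1 = nearest (site +/- 1)
  int snapshot_every, burn_in;
  long n_active = 0;
  long created[2] = {0, 0};
  long dropped = 0;
  int clearance_iter = -1;
  int iters_run = 0;

  bool accessible(const Section& s, int l, int j) const {
    return s.acc[s.idx(l, j)] != 0;
  }
  bool empty_cell(const Section& s, int l, int j) const {
    return s.occ[s.idx(l, j)] == 0;
  }

  int gap_ahead(const Section& s, int l, int j) const {
    int g = 0;
    for (int jj = j + 1; jj < s.N; ++jj) {
      if (s.acc[s.idx(l, jj)] && s.occ[s.idx(l, jj)] == 0) ++g; else break;
    }
    return g;
  }

  void record_detach(Section& s, int t, const Motor& m, int cause) {
    s.detach_cnt[(s.idx(m.lane, m.site)) * 4 + m.species * 2 + cause]++;
    s.detach_series[(t - 1) * 4 + m.species * 2 + cause]++;
  }

  // returns true if the motor left the lattice
  bool try_detach(int mi, int t, int cause) {
    Motor& m = motors[mi];
    Section& s = sec[m.section];
    if (cause == CAUSE_CROWD && !crowding_detach) return false;  // stall
    std::deque<int>& q = s.res[s.idx(m.lane, m.site)];
    if ((int)q.size() >= s.cap) return false;  // reservoir full: stall
    s.occ[s.idx(m.lane, m.site)] = 0;
    m.status = ST_RESERVOIR;
    m.entry_iter = t;
    q.push_back(mi);
    record_detach(s, t, m, cause);
    return true;
  }

  void deliver(int mi, int t) {
    Motor& m = motors[mi];
    Section& s = sec[m.section];
    s.occ[s.idx(m.lane, m.site)] = 0;
    s.outflow[(t - 1) * s.T * 2 + m.lane * 2 + m.species]++;
    s.delivered += 1;
    s.junction.push_back(mi);
    if (m.section == (int)sec.size() - 1) {
      m.status = ST_DELIVERED;
      --n_active;
    } else {
      m.status = ST_JUNCTION;
    }
  }

  void step_motor(int mi, int t) {
    Motor& m = motors[mi];
    Section& s = sec[m.section];
    const int v = v_sp[m.species], p = p_sp[m.species];
    // processivity limit reached earlier but reservoir was full: retry
    if (m.run >= p) { try_detach(mi, t, CAUSE_PROC); return; }
    // delivery: hop would overshoot the plus end and the path out is clear
    if (m.site + v >= s.N) {
      bool clear = true;
      for (int jj = m.site + 1; jj < s.N; ++jj)
        if (!s.acc[s.idx(m.lane, jj)] || s.occ[s.idx(m.lane, jj)] != 0) {
          clear = false; break;
        }
      if (clear) {
        if (exit_prob >= 1.0 || unif_rand() < exit_prob) deliver(mi, t);
        return;  // stall if the exit itself is stochastically blocked
      }
    }
    const int g = gap_ahead(s, m.lane, m.site);
    if (g >= v) {
      s.occ[s.idx(m.lane, m.site)] = 0;
      m.site += v;
      m.run += v;
      s.occ[s.idx(m.lane, m.site)] = mi + 1;
      if (m.run >= p) try_detach(mi, t, CAUSE_PROC);
      return;
    }
    if (s.lateral) {
      int cand_l[4], cand_j[4], nc = 0;
      for (int dl = -1; dl <= 1; dl += 2) {
        int ll = m.lane + dl;
        if (ll < 0 || ll >= s.T) continue;
        if (lateral_target == 0) {
          int jj = m.site + v;
          if (jj < s.N && s.acc[s.idx(ll, jj)] && s.occ[s.idx(ll, jj)] == 0) {
            cand_l[nc] = ll; cand_j[nc] = jj; ++nc;
          }
        } else {
          for (int dj = -1; dj <= 1; dj += 2) {
            int jj = m.site + dj;
            if (jj >= 0 && jj < s.N && s.acc[s.idx(ll, jj)] &&
                s.occ[s.idx(ll, jj)] == 0) {
              cand_l[nc] = ll; cand_j[nc] = jj; ++nc;
            }
          }
        }
      }
      if (nc > 0) {
        int k = (nc == 1) ? 0 : pick(nc);
        s.occ[s.idx(m.lane, m.site)] = 0;
        int adv = cand_j[k] - m.site;
        m.lane = cand_l[k];
        m.site = cand_j[k];
        if (adv > 0) m.run += adv;
        s.occ[s.idx(m.lane, m.site)] = mi + 1;
        if (m.run >= p) try_detach(mi, t, CAUSE_PROC);
        return;
      }
    }
    try_detach(mi, t, CAUSE_CROWD);
  }

  void sweep_section(int si, int t) {
    Section& s = sec[si];
    if (update_order == 0) {
      for (int j = s.N - 1; j >= 0; --j)
        for (int l = 0; l < s.T; ++l) {
          int o = s.occ[s.idx(l, j)];
          // only step the motor if it is still at (l, j); motors move
          // forward, so a cell can only have been vacated, never re-stepped
          if (o > 0 && motors[o - 1].site == j && motors[o - 1].lane == l)
            step_motor(o - 1, t);
        }
    } else if (update_order == 2) {
      // minus-end-first traversal with a once-per-iteration guard: a motor
      // that hopped forward is not stepped again when its new site is reached
      for (int j = 0; j < s.N; ++j)
        for (int l = 0; l < s.T; ++l) {
          int o = s.occ[s.idx(l, j)];
          if (o > 0 && stepped[o - 1] != t) {
            stepped[o - 1] = t;
            step_motor(o - 1, t);
          }
        }
    } else {
      std::vector<int> ids;
      for (int c = 0; c < s.T * s.N; ++c)
        if (s.occ[c] > 0) ids.push_back(s.occ[c] - 1);
      for (int i = (int)ids.size() - 1; i > 0; --i)
        std::swap(ids[i], ids[pick(i + 1)]);
      for (size_t i = 0; i < ids.size(); ++i) step_motor(ids[i], t);
    }
  }

  void load_section(int si) {
    Section& s = sec[si];
    while (!s.inq.empty()) {
      int lanes[16], nl = 0;
      for (int l = 0; l < s.T; ++l)
        if (s.acc[s.idx(l, 0)] && s.occ[s.idx(l, 0)] == 0) lanes[nl++] = l;
      if (nl == 0) break;
      int mi = s.inq.front();
      s.inq.pop_front();
      Motor& m = motors[mi];
      m.lane = lanes[nl == 1 ? 0 : pick(nl)];
      m.site = 0;
      m.run = 0;
      m.status = ST_LATTICE;
      s.occ[s.idx(m.lane, 0)] = mi + 1;
      s.loaded += 1;
    }
    if (drop_blocked) {
      while (!s.inq.empty()) {
        int mi = s.inq.front();
        s.inq.pop_front();
        motors[mi].status = ST_DROPPED;
        --n_active;
        ++dropped;
      }
    }
  }

  void reservoir_update(int si, int t) {
    Section& s = sec[si];
    for (int l = 0; l < s.T; ++l)
      for (int j = 0; j < s.N; ++j) {
        std::deque<int>& q = s.res[s.idx(l, j)];
        if (q.empty()) continue;
        int mi = q.front();
        Motor& m = motors[mi];
        int residence = t - m.entry_iter;
        if (residence >= lt_sp[m.species]) {  // leakage
          q.pop_front();
          m.status = ST_LEAKED;
          --n_active;
          s.leaked += 1;
          continue;
        }
        if (residence < s.atp[s.idx(l, j)]) continue;  // ATP waiting rule
        int cand_l[9], cand_j[9], nc = 0;
        for (int ll = l - 1; ll <= l + 1; ++ll) {
          if (ll < 0 || ll >= s.T) continue;
          for (int jj = j - 1; jj <= j + 1; ++jj) {
            if (jj < 0 || jj >= s.N) continue;
            if (s.acc[s.idx(ll, jj)] && s.occ[s.idx(ll, jj)] == 0) {
              cand_l[nc] = ll; cand_j[nc] = jj; ++nc;
            }
          }
        }
        if (nc == 0) continue;
        int k = (nc == 1) ? 0 : pick(nc);
        q.pop_front();
        m.lane = cand_l[k];
        m.site = cand_j[k];
        m.run = 0;
        m.status = ST_LATTICE;
        s.occ[s.idx(m.lane, m.site)] = mi + 1;
        s.reattach_cnt[(s.idx(l, j)) * 2 + m.species]++;  // anchor site
      }
  }
};

}  // namespace

// [[Rcpp::export]]
List engine_run(List sections_cfg, IntegerMatrix species_tbl,
                IntegerVector sched_a, IntegerVector sched_b,
                List transfer_scheds, List initial, int horizon, List opts) {
  Engine E;
  const int S = sections_cfg.size();
  E.horizon = horizon;
  for (int k = 0; k < 2; ++k) {
    E.v_sp[k] = species_tbl(k, 0);
    E.p_sp[k] = species_tbl(k, 1);
    E.lt_sp[k] = species_tbl(k, 2);
  }
  E.crowding_detach = as<bool>(opts["crowding_detach"]);
  E.drop_blocked = as<bool>(opts["drop_blocked"]);
  E.stop_when_empty = as<bool>(opts["stop_when_empty"]);
  E.record_density = as<bool>(opts["record_density"]);
  E.exit_prob = as<double>(opts["exit_prob"]);
  E.update_order = as<int>(opts["update_order"]);
  E.lateral_target = as<int>(opts["lateral_target"]);
  E.snapshot_every = as<int>(opts["snapshot_every"]);
  E.burn_in = as<int>(opts["burn_in"]);

  E.sec.resize(S);
  for (int si = 0; si < S; ++si) {
    List cfg = sections_cfg[si];
    IntegerMatrix acc = cfg["accessible"];
    Section& s = E.sec[si];
    s.T = acc.nrow();
    s.N = acc.ncol();
    s.acc.assign(s.T * s.N, 1);
    for (int l = 0; l < s.T; ++l)
      for (int j = 0; j < s.N; ++j) s.acc[s.idx(l, j)] = acc(l, j);
    s.occ.assign(s.T * s.N, 0);
    s.atp.assign(s.T * s.N, 0);
    if (!Rf_isNull(cfg["atp_wait"])) {
      IntegerMatrix aw = cfg["atp_wait"];
      for (int l = 0; l < s.T; ++l)
        for (int j = 0; j < s.N; ++j) s.atp[s.idx(l, j)] = aw(l, j);
    }
    s.lateral = as<bool>(cfg["lateral"]);
    s.cap = as<int>(cfg["capacity"]);
    s.res.resize(s.T * s.N);
    s.detach_cnt.assign(s.T * s.N * 4, 0);
    s.reattach_cnt.assign(s.T * s.N * 2, 0);
    s.outflow.assign((size_t)horizon * s.T * 2, 0);
    s.detach_series.assign((size_t)horizon * 4, 0);
    s.dens.assign(s.T * s.N * 2, 0.0);
  }

  // pre-seeded ("sprinkled") occupancy
  for (int si = 0; si < S; ++si) {
    if (Rf_isNull(initial[si])) continue;
    IntegerMatrix ini = initial[si];
    Section& s = E.sec[si];
    for (int r = 0; r < ini.nrow(); ++r) {
      int l = ini(r, 0) - 1, j = ini(r, 1) - 1, sp = ini(r, 2) - 1;
      if (l < 0 || l >= s.T || j < 0 || j >= s.N)
        stop("initial occupancy out of bounds");
      if (!s.acc[s.idx(l, j)]) stop("initial occupancy on a blocked site");
      if (s.occ[s.idx(l, j)] != 0) stop("initial occupancy collision");
      Motor m;
      m.species = sp; m.section = si; m.lane = l; m.site = j;
      m.run = 0; m.status = ST_LATTICE; m.entry_iter = 0;
      E.motors.push_back(m);
      s.occ[s.idx(l, j)] = (int)E.motors.size();
      ++E.n_active;
      ++E.created[sp];
    }
  }

  int last_arrival = 0;
  if (sched_a.size() > 0) last_arrival = std::max(last_arrival, sched_a[sched_a.size() - 1]);
  if (sched_b.size() > 0) last_arrival = std::max(last_arrival, sched_b[sched_b.size() - 1]);

  std::vector<IntegerVector> transfers(S);
  std::vector<int> tptr(S, 0);
  for (int si = 1; si < S; ++si)
    if (!Rf_isNull(transfer_scheds[si])) transfers[si] = transfer_scheds[si];

  int n_snap = (E.snapshot_every > 0) ? horizon / E.snapshot_every : 0;
  NumericMatrix snapshots(n_snap, 2 + N_STATUS);
  LogicalVector snapshot_ok(n_snap);
  int snap_row = 0;

  int pa = 0, pb = 0;
  const int na = sched_a.size(), nb = sched_b.size();

  for (int t = 1; t <= horizon; ++t) {
    E.iters_run = t;
    // -- arrivals: external influx into section 1 --
    while (pa < na && sched_a[pa] == t) {
      Motor m; m.species = 0; m.section = 0; m.lane = -1; m.site = -1;
      m.run = 0; m.status = ST_QUEUED; m.entry_iter = 0;
      E.motors.push_back(m);
      E.sec[0].inq.push_back((int)E.motors.size() - 1);
      ++E.n_active; ++E.created[0]; ++pa;
    }
    while (pb < nb && sched_b[pb] == t) {
      Motor m; m.species = 1; m.section = 0; m.lane = -1; m.site = -1;
      m.run = 0; m.status = ST_QUEUED; m.entry_iter = 0;
      E.motors.push_back(m);
      E.sec[0].inq.push_back((int)E.motors.size() - 1);
      ++E.n_active; ++E.created[1]; ++pb;
    }
    // -- junction transfer into downstream sections --
    for (int si = 1; si < S; ++si) {
      IntegerVector& tr = transfers[si];
      while (tptr[si] < tr.size() && tr[tptr[si]] == t) {
        ++tptr[si];
        std::deque<int>& up = E.sec[si - 1].junction;
        if (up.empty()) continue;
        int mi = up.front();
        up.pop_front();
        Motor& m = E.motors[mi];
        m.section = si; m.run = 0; m.status = ST_QUEUED;
        E.sec[si].inq.push_back(mi);
        E.sec[si].transferred_in += 1;
      }
    }
    // -- loading, sweep, reservoir kinetics --
    for (int si = 0; si < S; ++si) E.load_section(si);
    if (E.update_order == 2) E.stepped.resize(E.motors.size(), 0);
    for (int si = 0; si < S; ++si) E.sweep_section(si, t);
    for (int si = 0; si < S; ++si) E.reservoir_update(si, t);
    // -- density accumulation --
    if (E.record_density && t > E.burn_in) {
      for (int si = 0; si < S; ++si) {
        Section& s = E.sec[si];
        for (int c = 0; c < s.T * s.N; ++c)
          if (s.occ[c] > 0) s.dens[c * 2 + E.motors[s.occ[c] - 1].species] += 1.0;
      }
    }
    // -- snapshot ledger + invariant audit --
    if (E.snapshot_every > 0 && t % E.snapshot_every == 0 && snap_row < n_snap) {
      long by_status[N_STATUS] = {0};
      for (size_t i = 0; i < E.motors.size(); ++i) by_status[E.motors[i].status]++;
      bool ok = true;
      long on_grid = 0;
      for (int si = 0; si < S; ++si) {
        Section& s = E.sec[si];
        for (int l = 0; l < s.T; ++l)
          for (int j = 0; j < s.N; ++j) {
            int o = s.occ[s.idx(l, j)];
            if (o > 0) {
              ++on_grid;
              const Motor& m = E.motors[o - 1];
              if (!s.acc[s.idx(l, j)] || m.status != ST_LATTICE ||
                  m.section != si || m.lane != l || m.site != j)
                ok = false;
            }
          }
      }
      if (on_grid != by_status[ST_LATTICE]) ok = false;
      snapshots(snap_row, 0) = t;
      snapshots(snap_row, 1) = (double)(E.created[0] + E.created[1]);
      for (int k = 0; k < N_STATUS; ++k) snapshots(snap_row, 2 + k) = (double)by_status[k];
      snapshot_ok[snap_row] = ok;
      ++snap_row;
    }
    if (E.stop_when_empty && t >= last_arrival && E.n_active == 0) {
      E.clearance_iter = t;
      break;
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // -- assemble results --
  List out_sections(S);
  for (int si = 0; si < S; ++si) {
    Section& s = E.sec[si];
    IntegerVector detach(s.detach_cnt.begin(), s.detach_cnt.end());
    detach.attr("dim") = IntegerVector::create(4, s.N, s.T);  // (sp,cause) x site x lane
    IntegerVector reatt(s.reattach_cnt.begin(), s.reattach_cnt.end());
    reatt.attr("dim") = IntegerVector::create(2, s.N, s.T);
    IntegerVector ofl(s.outflow.begin(), s.outflow.end());
    ofl.attr("dim") = IntegerVector::create(2, s.T, horizon);
    IntegerVector dser(s.detach_series.begin(), s.detach_series.end());
    dser.attr("dim") = IntegerVector::create(4, horizon);
    NumericVector dens(s.dens.begin(), s.dens.end());
    dens.attr("dim") = IntegerVector::create(2, s.N, s.T);
    long res_tot = 0;
    for (size_t c = 0; c < s.res.size(); ++c) res_tot += s.res[c].size();
    out_sections[si] = List::create(
        _["detach_counts"] = detach, _["reattach_counts"] = reatt,
        _["outflow"] = ofl, _["detach_series"] = dser, _["density_sum"] = dens,
        _["loaded"] = s.loaded, _["delivered"] = s.delivered,
        _["leaked"] = s.leaked, _["transferred_in"] = s.transferred_in,
        _["queued"] = (double)s.inq.size(), _["junction"] = (double)s.junction.size(),
        _["in_reservoirs"] = (double)res_tot);
  }
  const size_t M = E.motors.size();
  IntegerVector m_sp(M), m_sec(M), m_lane(M), m_site(M), m_run(M), m_status(M);
  for (size_t i = 0; i < M; ++i) {
    m_sp[i] = E.motors[i].species + 1;
    m_sec[i] = E.motors[i].section + 1;
    m_lane[i] = E.motors[i].lane + 1;
    m_site[i] = E.motors[i].site + 1;
    m_run[i] = E.motors[i].run;
    m_status[i] = E.motors[i].status;
  }
  if (snap_row < n_snap) {
    snapshots = snapshots(Range(0, std::max(snap_row - 1, 0)), _);
    snapshot_ok = snapshot_ok[Range(0, std::max(snap_row - 1, 0))];
    if (snap_row == 0) {
      snapshots = NumericMatrix(0, 2 + N_STATUS);
      snapshot_ok = LogicalVector(0);
    }
  }
  return List::create(
      _["sections"] = out_sections,
      _["created"] = NumericVector::create(E.created[0], E.created[1]),
      _["dropped"] = (double)E.dropped,
      _["clearance_iter"] = E.clearance_iter,
      _["iters_run"] = E.iters_run,
      _["snapshots"] = snapshots, _["snapshot_ok"] = snapshot_ok,
      _["motors"] = DataFrame::create(
          _["species"] = m_sp, _["section"] = m_sec, _["lane"] = m_lane,
          _["site"] = m_site, _["run_sites"] = m_run, _["status"] = m_status));
}
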