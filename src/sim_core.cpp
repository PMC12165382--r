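#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event type codes shared with the R side (see events_df in R/simulate.R):
// 1 = origin firing, 2 = fork step (bin replicated), 3 = fork termination,
// 4 = origin passivation, 5 = firing-factor recycling.

namespace {

struct ActiveFork {
  int chrom;      // 1-based chromosome index
  int bin;        // last bin replicated by this fork
  int dir;        // -1 leftward, +1 rightward
  int parent;     // 0-based origin index
  int rec;        // index into the fork record vectors
  double next_t;  // next scheduled step (deterministic mode only)
};

} // namespace

// Kinetic Monte Carlo simulation of one S phase.
//
// Origins fire by mass action against the pool of free firing factors
// (propensity f_i * F_free); each firing spawns two divergent forks and
// moves one factor into a recycling state; forks advance one 1-kb bin at a
// time (exponential waits at rate v, or clocked steps every 1/v minutes in
// deterministic mode) and terminate on chromosome ends or already-replicated
// DNA; a pending origin overrun by a fork is passivated; recycling factors
// return to the free pool at rate r each.
//
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List sim_core(IntegerVector chrom_len, IntegerVector ori_chrom,
              IntegerVector ori_bin, NumericVector ori_rate,
              int n_factors, double recycle_rate, double fork_speed,
              bool stochastic_forks, double max_time, bool keep_events) {
  const int n_chrom = chrom_len.size();
  const int n_ori = ori_chrom.size();

  std::vector<int> offset(n_chrom + 1, 0);
  for (int c = 0; c < n_chrom; ++c) offset[c + 1] = offset[c] + chrom_len[c];
  const int n_bins = offset[n_chrom];

  NumericVector rep_time(n_bins, NA_REAL);
  IntegerVector rep_dir(n_bins, NA_INTEGER);
  IntegerVector rep_parent(n_bins, NA_INTEGER); // 1-based origin index

  // origin fate: 0 pending, 1 fired, 2 passivated
  IntegerVector ori_state(n_ori, 0);
  NumericVector ori_time(n_ori, NA_REAL);

  std::vector<int> bin2ori(n_bins, -1);
  for (int i = 0; i < n_ori; ++i) {
    int g = offset[ori_chrom[i] - 1] + ori_bin[i] - 1;
    if (bin2ori[g] >= 0) stop("duplicate origin bins");
    bin2ori[g] = i;
  }

  std::vector<ActiveFork> forks;
  // per-fork records (all forks ever created)
  std::vector<int> fk_parent, fk_dir, fk_last;
  std::vector<double> fk_born, fk_term;

  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_chrom, ev_bin, ev_id;
  auto log_ev = [&](double t, int type, int chrom, int bin, int id) {
    if (!keep_events) return;
    ev_time.push_back(t); ev_type.push_back(type);
    ev_chrom.push_back(chrom); ev_bin.push_back(bin); ev_id.push_back(id);
  };

  double sum_pending = 0.0;
  for (int i = 0; i < n_ori; ++i) {
    if (ori_rate[i] <= 0) stop("origin firing rates must be > 0");
    sum_pending += ori_rate[i];
  }
  int free_f = n_factors, n_rec = 0, n_replicated = 0;
  double t = 0.0, completion = NA_REAL;
  bool completed = false, stalled = false;
  const double step_dt = 1.0 / fork_speed;
  long iter = 0;

  auto terminate_fork = [&](ActiveFork &f, double at) {
    fk_term[f.rec] = at;
    fk_last[f.rec] = f.bin;
    log_ev(at, 3, f.chrom, f.bin, f.parent + 1);
  };

  // replicate one bin via a fork that has just stepped onto it
  auto spawn_forks = [&](int oi, double at) {
    for (int d = -1; d <= 1; d += 2) {
      ActiveFork f;
      f.chrom = ori_chrom[oi]; f.bin = ori_bin[oi]; f.dir = d;
      f.parent = oi; f.rec = (int)fk_parent.size();
      f.next_t = at + step_dt;
      fk_parent.push_back(oi + 1); fk_dir.push_back(d);
      fk_born.push_back(at); fk_term.push_back(NA_REAL);
      fk_last.push_back(ori_bin[oi]);
      forks.push_back(f);
    }
  };

  while (true) {
    if (++iter % 4096 == 0) { // refresh against incremental float drift
      sum_pending = 0.0;
      for (int i = 0; i < n_ori; ++i)
        if (ori_state[i] == 0) sum_pending += ori_rate[i];
    }
    if (sum_pending < 0) sum_pending = 0;
    double a_fire = (free_f > 0) ? free_f * sum_pending : 0.0;
    double a_rec = recycle_rate * n_rec;

    int ev = 0;          // 1 fire, 2 fork step, 3 recycle
    int fork_idx = -1;
    double t_next;

    if (stochastic_forks) {
      double a_fork = fork_speed * forks.size();
      double total = a_fire + a_fork + a_rec;
      if (total <= 0) { stalled = true; break; }
      t_next = t + exp_rand() / total;
      if (t_next > max_time) { t = max_time; break; }
      double u = unif_rand() * total;
      if (u < a_fire) ev = 1;
      else if (u < a_fire + a_fork) {
        ev = 2;
        fork_idx = (int)((u - a_fire) / fork_speed);
        if (fork_idx >= (int)forks.size()) fork_idx = (int)forks.size() - 1;
      } else ev = 3;
    } else {
      double a_gil = a_fire + a_rec;
      double t_gil = (a_gil > 0) ? t + exp_rand() / a_gil : R_PosInf;
      double t_fork = R_PosInf;
      for (int k = 0; k < (int)forks.size(); ++k)
        if (forks[k].next_t < t_fork) { t_fork = forks[k].next_t; fork_idx = k; }
      if (!R_FINITE(t_gil) && !R_FINITE(t_fork)) { stalled = true; break; }
      if (t_fork <= t_gil) { ev = 2; t_next = t_fork; }
      else {
        t_next = t_gil;
        ev = (unif_rand() * a_gil < a_fire) ? 1 : 3;
      }
      if (t_next > max_time) { t = max_time; break; }
    }
    t = t_next;

    if (ev == 1) { // origin firing
      double u = unif_rand() * sum_pending, acc = 0.0;
      int oi = -1;
      for (int i = 0; i < n_ori; ++i) {
        if (ori_state[i] != 0) continue;
        acc += ori_rate[i];
        oi = i;
        if (u <= acc) break;
      }
      if (oi < 0) { stalled = true; break; } // float drift, no origin pending
      ori_state[oi] = 1; ori_time[oi] = t;
      sum_pending -= ori_rate[oi];
      --free_f; ++n_rec;
      int g = offset[ori_chrom[oi] - 1] + ori_bin[oi] - 1;
      rep_time[g] = t; rep_dir[g] = 0; rep_parent[g] = oi + 1;
      ++n_replicated;
      log_ev(t, 1, ori_chrom[oi], ori_bin[oi], oi + 1);
      spawn_forks(oi, t);
    } else if (ev == 2) { // fork step
      ActiveFork &f = forks[fork_idx];
      int target = f.bin + f.dir;
      int g = offset[f.chrom - 1] + target - 1;
      bool off_end = target < 1 || target > chrom_len[f.chrom - 1];
      if (off_end || !ISNA(rep_time[g])) {
        terminate_fork(f, t);
        forks.erase(forks.begin() + fork_idx);
      } else {
        f.bin = target;
        f.next_t = t + step_dt;
        fk_last[f.rec] = target;
        rep_time[g] = t; rep_dir[g] = f.dir; rep_parent[g] = f.parent + 1;
        ++n_replicated;
        log_ev(t, 2, f.chrom, target, f.parent + 1);
        int oi = bin2ori[g];
        if (oi >= 0 && ori_state[oi] == 0) {
          ori_state[oi] = 2; ori_time[oi] = t;
          sum_pending -= ori_rate[oi];
          log_ev(t, 4, f.chrom, target, oi + 1);
        }
        if (n_replicated == n_bins) {
          completed = true; completion = t;
          for (auto &fa : forks) terminate_fork(fa, t);
          forks.clear();
          break;
        }
      }
    } else { // recycling
      --n_rec; ++free_f;
      log_ev(t, 5, NA_INTEGER, NA_INTEGER, NA_INTEGER);
    }
  }

  List forks_out = List::create(
      _["parent"] = wrap(fk_parent), _["dir"] = wrap(fk_dir),
      _["born"] = wrap(fk_born), _["terminated"] = wrap(fk_term),
      _["last_bin"] = wrap(fk_last));
  List events_out = R_NilValue;
  if (keep_events)
    events_out = List::create(_["time"] = wrap(ev_time), _["type"] = wrap(ev_type),
                              _["chrom"] = wrap(ev_chrom), _["bin"] = wrap(ev_bin),
                              _["id"] = wrap(ev_id));
  return List::create(
      _["rep_time"] = rep_time, _["rep_dir"] = rep_dir, _["rep_parent"] = rep_parent,
      _["ori_state"] = ori_state, _["ori_time"] = ori_time,
      _["completed"] = completed, _["completion_time"] = completion,
      _["stalled"] = stalled, _["t_end"] = t,
      _["forks"] = forks_out, _["events"] = events_out);
}
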