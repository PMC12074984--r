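#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-cell Gillespie simulation of a bounded linear birth-death process.
//
// Epochs: matrix with columns (duration_weeks, lambda, nu, cap); rates are
// per cell per week. A birth replaces the dividing cell by two daughter
// cells (so every cell record marks one division); a death removes the cell.
// Births are suppressed while the population sits at the epoch cap.
//
// Returns parent pointers and birth times for every cell ever created,
// which is sufficient to extract the genealogy of any subset of survivors.
// [[Rcpp::export(name = ".sim_pop_cpp")]]
List sim_pop_cpp(NumericMatrix epochs, double t_end, double count_dt,
                 double max_events) {
  RNGScope scope;
  std::vector<int> parent;
  std::vector<double> t_birth;
  parent.reserve(1 << 16);
  t_birth.reserve(1 << 16);

  // founder cell (the zygote), id 0
  parent.push_back(-1);
  t_birth.push_back(0.0);
  std::vector<int> alive;
  alive.push_back(0);

  int n_epochs = epochs.nrow();
  std::vector<double> ep_end(n_epochs);
  double acc = 0.0;
  for (int e = 0; e < n_epochs; ++e) {
    acc += epochs(e, 0);
    ep_end[e] = acc;
  }
  ep_end[n_epochs - 1] = std::max(ep_end[n_epochs - 1], t_end);

  std::vector<double> grid_t, grid_n;
  double next_grid = 0.0;

  double t = 0.0;
  int epoch = 0;
  double n_events = 0.0;
  bool extinct = false;

  while (t < t_end) {
    while (epoch < n_epochs - 1 && t >= ep_end[epoch]) ++epoch;
    double lambda = epochs(epoch, 1), nu = epochs(epoch, 2);
    double cap = epochs(epoch, 3);
    double n = (double)alive.size();
    if (n == 0.0) { extinct = true; break; }
    double b_rate = (n < cap) ? lambda * n : 0.0;
    double d_rate = nu * n;
    double tot = b_rate + d_rate;
    double t_next;
    if (tot <= 0.0) {
      t_next = std::min(ep_end[epoch], t_end); // quiescent until rates change
      if (t_next <= t) t_next = t_end;
    } else {
      t_next = t + R::exp_rand() / tot;
    }
    double t_stop = std::min(ep_end[epoch], t_end);
    if (t_next > t_stop) { // epoch boundary or end reached without an event
      while (next_grid <= t_stop + 1e-12 && next_grid <= t_end + 1e-12) {
        grid_t.push_back(next_grid); grid_n.push_back(n);
        next_grid += count_dt;
      }
      t = t_stop;
      if (t >= t_end) break;
      continue;
    }
    while (next_grid <= t_next) {
      grid_t.push_back(next_grid); grid_n.push_back(n);
      next_grid += count_dt;
    }
    t = t_next;
    if (++n_events > max_events)
      stop("event budget exceeded (%.0f events); reduce cap or t_end",
           max_events);
    if (R::unif_rand() * tot < b_rate) {
      // division: pick a cell, replace it with two daughters
      int idx = (int)(R::unif_rand() * alive.size());
      if (idx == (int)alive.size()) idx--;
      int par = alive[idx];
      int id1 = (int)parent.size();
      parent.push_back(par); t_birth.push_back(t);
      parent.push_back(par); t_birth.push_back(t);
      alive[idx] = id1;
      alive.push_back(id1 + 1);
    } else {
      int idx = (int)(R::unif_rand() * alive.size());
      if (idx == (int)alive.size()) idx--;
      alive[idx] = alive.back();
      alive.pop_back();
    }
  }
  while (!extinct && next_grid <= t_end + 1e-12) {
    grid_t.push_back(next_grid); grid_n.push_back((double)alive.size());
    next_grid += count_dt;
  }

  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["t_birth"] = NumericVector(t_birth.begin(), t_birth.end()),
    _["alive"] = IntegerVector(alive.begin(), alive.end()),
    _["grid_t"] = NumericVector(grid_t.begin(), grid_t.end()),
    _["grid_n"] = NumericVector(grid_n.begin(), grid_n.end()),
    _["extinct"] = extinct,
    _["n_events"] = n_events,
    _["t_final"] = t);
}

// Fast genealogy sampler for the same bounded birth-death model.
//
// Forward pass: count-level Gillespie while N is below `stoch_n`, then a
// deterministic exponential segment up to the cap, constant at the cap
// (births balancing deaths). Backward pass: exact pair-merge probability
// k(k-1)/(n(n-1)) at each recorded stochastic birth event, and the
// continuum coalescent rate k(k-1)*b(t)/N(t) in the smooth segments, where
// b(t) is the per-capita birth rate (lambda below the cap, nu at the cap).
//
// Returns merge times/pairs for n_tips lineages sampled at t_end plus the
// integral of b(t) over each branch (expected divisions per unit is b).
// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(NumericMatrix epochs, double t_end, int n_tips,
                       double stoch_n, double max_events) {
  RNGScope scope;
  int n_epochs = epochs.nrow();
  std::vector<double> ep_end(n_epochs);
  double acc = 0.0;
  for (int e = 0; e < n_epochs; ++e) { acc += epochs(e, 0); ep_end[e] = acc; }
  ep_end[n_epochs - 1] = std::max(ep_end[n_epochs - 1], t_end);

  // ---- forward pass: piecewise description of N(t) ----
  // segment: t0, t1, type (0 stoch, 1 det-exp, 2 cap), N0, growth g, bpc
  std::vector<double> seg_t0, seg_t1, seg_n0, seg_g, seg_b;
  std::vector<int> seg_type;
  // stochastic events: time, N just after (forward), birth flag
  std::vector<double> ev_t; std::vector<int> ev_n, ev_birth;

  double t = 0.0, n = 1.0;
  int epoch = 0;
  double n_events = 0.0;
  bool extinct = false;

  while (t < t_end) {
    while (epoch < n_epochs - 1 && t >= ep_end[epoch]) ++epoch;
    double lambda = epochs(epoch, 1), nu = epochs(epoch, 2);
    double cap = epochs(epoch, 3);
    double t_stop = std::min(ep_end[epoch], t_end);
    if (n <= 0.0) { extinct = true; break; }
    if (n < stoch_n && n < cap) {
      // exact count-level Gillespie
      double seg_start = t;
      seg_t0.push_back(t); seg_type.push_back(0);
      seg_n0.push_back(n); seg_g.push_back(0.0); seg_b.push_back(lambda);
      while (t < t_stop && n > 0.0 && n < stoch_n && n < cap) {
        double b_rate = lambda * n, d_rate = nu * n;
        double tot = b_rate + d_rate;
        if (tot <= 0.0) { t = t_stop; break; }
        double t_next = t + R::exp_rand() / tot;
        if (t_next > t_stop) { t = t_stop; break; }
        t = t_next;
        if (++n_events > max_events) stop("event budget exceeded");
        if (R::unif_rand() * tot < b_rate) {
          n += 1.0;
          ev_t.push_back(t); ev_n.push_back((int)n); ev_birth.push_back(1);
        } else {
          n -= 1.0;
          ev_t.push_back(t); ev_n.push_back((int)n); ev_birth.push_back(0);
        }
      }
      seg_t1.push_back(t);
      if (n <= 0.0) { extinct = true; break; }
      (void)seg_start;
    } else if (n < cap) {
      // deterministic exponential growth at rate g = lambda - nu
      double g = lambda - nu;
      double t1;
      if (g > 1e-12) {
        double t_cap = t + std::log(cap / n) / g;
        t1 = std::min(t_cap, t_stop);
      } else {
        t1 = t_stop;
      }
      seg_t0.push_back(t); seg_t1.push_back(t1); seg_type.push_back(1);
      seg_n0.push_back(n); seg_g.push_back(g); seg_b.push_back(lambda);
      n = n * std::exp(g * (t1 - t));
      if (n > cap - 0.5) n = cap;
      t = t1;
    } else {
      // at cap: constant size, turnover at per-capita rate nu
      n = cap;
      seg_t0.push_back(t); seg_t1.push_back(t_stop); seg_type.push_back(2);
      seg_n0.push_back(cap); seg_g.push_back(0.0); seg_b.push_back(nu);
      t = t_stop;
    }
  }

  if (extinct || n < (double)n_tips) {
    return List::create(_["ok"] = false, _["extinct"] = extinct,
                        _["final_n"] = n);
  }

  // ---- backward pass ----
  int n_seg = (int)seg_t0.size();
  int k = n_tips;
  std::vector<int> active(k);
  for (int i = 0; i < k; ++i) active[i] = i + 1; // tip ids 1..n
  int next_id = n_tips + 1;
  std::vector<double> m_time; std::vector<int> m_a, m_b, m_new;
  // per-branch integral of b(t): accumulate per active lineage
  std::vector<double> node_bint(2 * n_tips, 0.0); // index by node id
  int ev_idx = (int)ev_t.size() - 1;

  for (int s = n_seg - 1; s >= 0 && k > 1; --s) {
    double t1 = seg_t1[s], t0 = seg_t0[s];
    double bpc = seg_b[s];
    double tcur = t1;
    if (seg_type[s] == 0) {
      // replay recorded events backwards
      while (ev_idx >= 0 && ev_t[ev_idx] > t0 - 1e-12 && k > 1) {
        double te = ev_t[ev_idx];
        if (te > t1 + 1e-12) { ev_idx--; continue; }
        double dt = tcur - te;
        for (int i = 0; i < k; ++i) node_bint[active[i]] += bpc * dt;
        int n_after = ev_n[ev_idx];
        if (ev_birth[ev_idx]) {
          // forward birth: n_after cells after; backward merge prob
          double p = (double)k * (k - 1) / ((double)n_after * (n_after - 1));
          if (R::unif_rand() < p) {
            int i = (int)(R::unif_rand() * k); if (i == k) i--;
            int j = (int)(R::unif_rand() * (k - 1)); if (j == k - 1) j--;
            if (j >= i) j++;
            m_time.push_back(te);
            m_a.push_back(active[i]); m_b.push_back(active[j]);
            m_new.push_back(next_id);
            active[i] = next_id++;
            active[j] = active[k - 1];
            k--;
          }
        }
        tcur = te;
        ev_idx--;
      }
      double dt = tcur - t0;
      if (dt > 0) for (int i = 0; i < k; ++i) node_bint[active[i]] += bpc * dt;
    } else {
      // continuum coalescent: rate(t) = k(k-1) * bpc / N(t)
      while (k > 1 && tcur > t0 + 1e-12) {
        double kk = (double)k * (k - 1);
        double wait;
        if (seg_type[s] == 2) {
          wait = R::exp_rand() / (kk * bpc / seg_n0[s]);
        } else {
          // N(t) = N0 * exp(g (t - t0)); backwards from tcur
          double g = seg_g[s];
          double N_tcur = seg_n0[s] * std::exp(g * (tcur - t0));
          if (g <= 1e-12) {
            wait = R::exp_rand() / (kk * bpc / N_tcur);
          } else {
            // hazard h(u) = kk*bpc/N(tcur-u) = (kk*bpc/N_tcur) e^{g u}
            double E = R::exp_rand();
            double a = kk * bpc / N_tcur;
            wait = std::log(1.0 + g * E / a) / g;
          }
        }
        double te = tcur - wait;
        if (te <= t0) {
          for (int i = 0; i < k; ++i)
            node_bint[active[i]] += bpc * (tcur - t0);
          tcur = t0;
          break;
        }
        for (int i = 0; i < k; ++i) node_bint[active[i]] += bpc * wait;
        int i = (int)(R::unif_rand() * k); if (i == k) i--;
        int j = (int)(R::unif_rand() * (k - 1)); if (j == k - 1) j--;
        if (j >= i) j++;
        m_time.push_back(te);
        m_a.push_back(active[i]); m_b.push_back(active[j]);
        m_new.push_back(next_id);
        active[i] = next_id++;
        active[j] = active[k - 1];
        k--;
        tcur = te;
      }
      if (k > 1 && tcur > t0) {
        for (int i = 0; i < k; ++i) node_bint[active[i]] += bpc * (tcur - t0);
      }
    }
  }
  // by construction the founder phase forces full coalescence by t = 0
  double t_mrca = (k == 1) ? m_time.back() : 0.0;
  // root stem: integral of b(t) from the zygote (t = 0) to the MRCA
  double root_bint = 0.0;
  for (int s = 0; s < n_seg; ++s) {
    double lo = seg_t0[s], hi = std::min(seg_t1[s], t_mrca);
    if (hi <= lo) continue;
    root_bint += seg_b[s] * (hi - lo);
  }

  return List::create(
    _["ok"] = (k == 1),
    _["extinct"] = false,
    _["final_n"] = n,
    _["merge_time"] = NumericVector(m_time.begin(), m_time.end()),
    _["merge_a"] = IntegerVector(m_a.begin(), m_a.end()),
    _["merge_b"] = IntegerVector(m_b.begin(), m_b.end()),
    _["merge_new"] = IntegerVector(m_new.begin(), m_new.end()),
    _["branch_bint"] = NumericVector(node_bint.begin(), node_bint.end()),
    _["t_mrca"] = t_mrca,
    _["root_bint"] = root_bint);
}
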