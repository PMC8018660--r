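#include <Rcpp.h>
#include <vector>
#include "dynamics.h"

using namespace Rcpp;
using emobook::Dyn;

Dyn dyn_from_list(const List& p); // dynamics.cpp

namespace {

struct World {
  double w, h;
  double delta(double a, double b, double span) const {
    double d = b - a;
    d -= span * std::round(d / span);
    return d;
  }
  double dist(double x1, double y1, double x2, double y2) const {
    double dx = delta(x1, x2, w), dy = delta(y1, y2, h);
    return std::sqrt(dx * dx + dy * dy);
  }
  double wrap(double v, double span) const {
    return v - span * std::floor(v / span);
  }
};

inline double half_decay(double v, double dt, double hl) {
  return v * std::pow(0.5, dt / hl);
}

} // namespace

// Event-driven group simulation. Individuals carry their own activation
// clocks (minutes); the individual with the smallest clock acts next, ties
// broken by index. LIKE values are stored with per-dyad last-update
// timestamps and decayed lazily on read; the decay semigroup law makes this
// exactly equivalent to eager per-minute decay.
// [[Rcpp::export]]
List run_engine_cpp(List params, List cfg) {
  Dyn dyn = dyn_from_list(params);

  const int    n         = as<int>(cfg["n"]);
  const double lps       = as<double>(cfg["lps"]);
  const double stab      = as<double>(cfg["stabilization"]);
  const double rec       = as<double>(cfg["recording"]);
  NumericVector snap_rel = cfg["snapshot_times"]; // relative to record start
  const double like_int  = as<double>(cfg["like_sample_interval"]);
  const double prox_int  = as<double>(cfg["proximity_sample_interval"]);
  const double prox_rad  = as<double>(cfg["proximity_radius"]);
  const double wspan     = as<double>(cfg["width"]);
  const double hspan     = as<double>(cfg["height"]);
  const double percep_r  = as<double>(cfg["perception_radius"]);
  const double view_deg  = as<double>(cfg["view_angle"]);
  const double pscan     = as<double>(cfg["pscan"]);
  const double reach     = as<double>(cfg["grooming_reach"]);
  const double cont      = as<double>(cfg["groom_continue_p"]);
  const double sat_gain  = as<double>(cfg["satisfaction_gain"]);
  const double sat_hl    = as<double>(cfg["satisfaction_halflife"]);
  const double anx_gain  = as<double>(cfg["anxiety_gain"]);
  const double anx_hl    = as<double>(cfg["anxiety_halflife"]);
  const double aro_base  = as<double>(cfg["arousal_baseline"]);
  const double aro_hl    = as<double>(cfg["arousal_halflife"]);
  const double aro_bump  = as<double>(cfg["arousal_bump"]);
  const double agon_p    = as<double>(cfg["agonism_p"]);
  const double leave_radius = as<double>(cfg["leave_radius"]);
  const double cohesion_radius = as<double>(cfg["cohesion_radius"]);
  const double step_len  = as<double>(cfg["step_length"]);
  NumericVector dom      = cfg["dominance"];
  NumericMatrix fear     = cfg["fear"];
  NumericMatrix like0    = cfg["like0"];

  const double T_end = stab + rec;
  const double half_view = view_deg * M_PI / 360.0;
  World world{wspan, hspan};

  // agent state
  std::vector<double> px(n), py(n), heading(n), clock(n), last_emo(n, 0.0);
  std::vector<double> arousal(n, aro_base), anxiety(n, 0.0), satisfaction(n, 0.0);
  std::vector<int> last_aggressor(n, -1);
  std::vector<int> goal(n, -1); // committed approach target
  const double giveup_p = 0.03; // per-minute chance to abandon a chase
  std::vector<double> accounted(n, 0.0);

  // dyadic state (row-major i*n+j: attitude of i toward j)
  std::vector<double> like(n * n), like_ts(n * n, 0.0);
  std::vector<double> groom_min(n * n, 0.0), prox_cnt(n * n, 0.0);

  for (int i = 0; i < n; ++i) {
    px[i] = unif_rand() * wspan;
    py[i] = unif_rand() * hspan;
    heading[i] = unif_rand() * 2.0 * M_PI;
    clock[i] = unif_rand(); // desynchronize first activations within minute 0-1
    for (int j = 0; j < n; ++j) like[i * n + j] = like0(i, j);
  }

  std::vector<double> clock0(clock); // first scheduled activations

  // sampling schedule (absolute times)
  const int n_snap = snap_rel.size();
  NumericVector snap_abs(n_snap);
  for (int s = 0; s < n_snap; ++s) snap_abs[s] = stab + snap_rel[s];
  int snap_idx = 0;
  double next_like = stab, next_prox = stab;
  int n_prox_samples = 0;

  std::vector<NumericMatrix> snapshots;
  std::vector<std::vector<double> > like_samples;
  std::vector<double> like_sample_times;

  // counters
  long n_bouts = 0, n_like_writes = 0, n_attacks = 0, n_submissive = 0;
  long n_rest = 0, n_groom_min = 0, n_approach = 0, n_avoid = 0, n_walk = 0;
  long n_leave = 0, n_signal = 0;
  double sum_visible = 0.0; long n_activations = 0;
  long n_enc = 0, n_pass_low = 0, n_pass_high = 0, n_chase_start = 0,
       n_chase_drop = 0, n_satiated = 0, n_refuse = 0;

  std::vector<int> visible; visible.reserve(n);
  std::vector<double> weights(n);

  auto like_read = [&](int i, int j, double now) -> double {
    return emobook::idle_decay(like[i * n + j], now - like_ts[i * n + j], dyn);
  };

  auto realize_matrix = [&](double t) -> NumericMatrix {
    NumericMatrix m(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        m(i, j) = (i == j) ? NA_REAL : like_read(i, j, t);
    return m;
  };

  auto process_samples = [&](double horizon) {
    for (;;) {
      double t_snap = (snap_idx < n_snap) ? snap_abs[snap_idx] : R_PosInf;
      double t_like = (next_like <= stab + rec) ? next_like : R_PosInf;
      double t_prox = (next_prox <= stab + rec) ? next_prox : R_PosInf;
      double t = std::min(t_snap, std::min(t_like, t_prox));
      if (t > horizon) break;
      if (t == t_like) {
        std::vector<double> samp(n * n);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j)
            samp[i * n + j] = (i == j) ? NA_REAL : like_read(i, j, t);
        like_samples.push_back(samp);
        like_sample_times.push_back(t - stab);
        next_like += like_int;
      }
      if (t == t_prox) {
        for (int i = 0; i < n; ++i)
          for (int j = i + 1; j < n; ++j)
            if (world.dist(px[i], py[i], px[j], py[j]) <= prox_rad) {
              prox_cnt[i * n + j] += 1.0;
              prox_cnt[j * n + i] += 1.0;
            }
        ++n_prox_samples;
        next_prox += prox_int;
      }
      if (t == t_snap) {
        snapshots.push_back(realize_matrix(t));
        ++snap_idx;
      }
    }
  };

  auto move_relative = [&](int i, int j, double sign) {
    // sign +1: toward j (stop at reach); sign -1: directly away
    double dx = world.delta(px[i], px[j], wspan), dy = world.delta(py[i], py[j], hspan);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-9) { dx = 1.0; dy = 0.0; d = 1.0; }
    double step = step_len;
    if (sign > 0) step = std::min(step, std::max(0.0, d - 0.5 * reach));
    heading[i] = std::atan2(sign * dy, sign * dx);
    px[i] = world.wrap(px[i] + sign * step * dx / d, wspan);
    py[i] = world.wrap(py[i] + sign * step * dy / d, hspan);
  };

  // group centroid via circular means (well-defined on the torus)
  auto centroid = [&](double& cx, double& cy) {
    double sx = 0, sy = 0, tx = 0, ty = 0;
    for (int i = 0; i < n; ++i) {
      sx += std::sin(px[i] * 2.0 * M_PI / wspan);
      tx += std::cos(px[i] * 2.0 * M_PI / wspan);
      sy += std::sin(py[i] * 2.0 * M_PI / hspan);
      ty += std::cos(py[i] * 2.0 * M_PI / hspan);
    }
    cx = world.wrap(std::atan2(sx, tx) * wspan / (2.0 * M_PI), wspan);
    cy = world.wrap(std::atan2(sy, ty) * hspan / (2.0 * M_PI), hspan);
  };

  // step toward the group centroid when drifted beyond the cohesion radius;
  // returns true if a cohesion step was taken
  auto cohere = [&](int i) -> bool {
    double cx, cy;
    centroid(cx, cy);
    double dx = world.delta(px[i], cx, wspan), dy = world.delta(py[i], cy, hspan);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d <= cohesion_radius) return false;
    heading[i] = std::atan2(dy, dx);
    px[i] = world.wrap(px[i] + step_len * dx / d, wspan);
    py[i] = world.wrap(py[i] + step_len * dy / d, hspan);
    return true;
  };

  auto touch_emotions = [&](int i, double now) {
    double dt = now - last_emo[i];
    if (dt > 0) {
      satisfaction[i] = half_decay(satisfaction[i], dt, sat_hl);
      anxiety[i]      = half_decay(anxiety[i], dt, anx_hl);
      arousal[i]      = aro_base + half_decay(arousal[i] - aro_base, dt, aro_hl);
      last_emo[i] = now;
    }
  };

  // grooming bout: geometric minute-by-minute continuation, occupies both
  // partners; returns the bout length (the actor's clock advance)
  // reciprocal return bouts do not themselves prime a further return, so a
  // grooming session is at most one bout each way
  std::vector<char> goal_is_return(n, 0);

  auto do_groom = [&](int me, int target, double now, bool allow_return) -> double {
    // geometric continuation, truncated: receivers end long bouts, so a
    // single bout cannot silently traverse the whole slow increase curve
    int L = 1;
    while (unif_rand() < cont && L < 15) ++L;
    double t_done = now + L;
    // receiver's LIKE toward the groomer: lazy decay to bout start, then
    // the calibrated increase over the bout
    int idx = target * n + me;
    double v0 = emobook::idle_decay(like[idx], now - like_ts[idx], dyn);
    like[idx] = emobook::groom_increase(v0, (double)L, dyn);
    like_ts[idx] = t_done;
    ++n_like_writes;
    ++n_bouts;
    n_groom_min += L;
    // grooming-minutes matrix counts the recording window only
    double ov = std::min(t_done, T_end) - std::max(now, stab);
    if (ov > 0) groom_min[me * n + target] += ov;
    touch_emotions(target, now);
    satisfaction[target] = std::min(1.0, satisfaction[target] + sat_gain * L);
    arousal[target] = std::min(1.0, arousal[target] + aro_bump);
    arousal[me] = std::min(1.0, arousal[me] + aro_bump);
    accounted[target] += t_done - clock[target];
    clock[target] = t_done;
    last_emo[target] = t_done;
    // grooming partners end the bout facing each other; the receiver is
    // primed to return the grooming with a probability equal to its own
    // (just-updated) valuation of the groomer, so session reciprocity is
    // itself bookkeeping-driven
    double dx = world.delta(px[me], px[target], wspan);
    double dy = world.delta(py[me], py[target], hspan);
    heading[me] = std::atan2(dy, dx);
    heading[target] = std::atan2(-dy, -dx);
    if (allow_return && unif_rand() < like[idx]) {
      goal[target] = me;
      goal_is_return[target] = 1;
    }
    return (double)L;
  };

  while (true) {
    int imin = 0;
    for (int i = 1; i < n; ++i) if (clock[i] < clock[imin]) imin = i;
    double now = clock[imin];
    process_samples(std::min(now, T_end));
    if (now >= T_end) break;

    int me = imin;
    touch_emotions(me, now);

    // perception: ordinary vision is a forward cone of limited radius; a
    // scheduled scan event (probability myPscan) is a full-circle,
    // unlimited-range scan of the group
    bool scan = unif_rand() < pscan;
    visible.clear();
    for (int j = 0; j < n; ++j) {
      if (j == me) continue;
      if (scan) { visible.push_back(j); continue; }
      double dx = world.delta(px[me], px[j], wspan), dy = world.delta(py[me], py[j], hspan);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > percep_r) continue;
      double bearing = std::atan2(dy, dx);
      double diff = std::fabs(std::remainder(bearing - heading[me], 2.0 * M_PI));
      if (diff > half_view) continue;
      visible.push_back(j);
    }

    sum_visible += (double)visible.size();
    ++n_activations;

    double advance = 1.0;

    // recent aggression elevates the chance of an avoid response
    if (last_aggressor[me] >= 0) {
      int agg = last_aggressor[me];
      last_aggressor[me] = -1;
      if (unif_rand() < anxiety[me]) {
        move_relative(me, agg, -1.0);
        ++n_avoid;
        accounted[me] += advance;
        clock[me] = now + advance;
        continue;
      }
    }

    if (unif_rand() >= arousal[me]) {
      ++n_rest; // rest: stay put (a committed approach survives a pause)
    } else {
      bool acted = false;
      // a committed approach is pursued until the partner is reached or
      // the chase is abandoned; satiation gates initiation, not pursuit
      if (goal[me] >= 0) {
        if (unif_rand() < giveup_p) {
          goal[me] = -1;
          goal_is_return[me] = 0;
          ++n_chase_drop;
        } else {
          int target = goal[me];
          if (world.dist(px[me], py[me], px[target], py[target]) <= reach) {
            // a satiated receiver declines a fresh bout (returns are never
            // refused: the partner just groomed and is being repaid)
            if (!goal_is_return[me] &&
                unif_rand() < satisfaction[target]) {
              ++n_signal; // affiliative signal only
            } else {
              advance = do_groom(me, target, now, !goal_is_return[me]);
            }
            goal[me] = -1;
            goal_is_return[me] = 0;
          } else {
            move_relative(me, target, +1.0);
            ++n_approach;
          }
          acted = true;
        }
      }
      if (!acted && visible.empty()) {
        heading[me] += (unif_rand() * 2.0 - 1.0) * M_PI / 3.0;
        px[me] = world.wrap(px[me] + step_len * std::cos(heading[me]), wspan);
        py[me] = world.wrap(py[me] + step_len * std::sin(heading[me]), hspan);
        ++n_walk;
        acted = true;
      }
      // agonism: directed down-hierarchy, small fixed probability
      if (!acted && unif_rand() < agon_p) {
        int lower_cnt = 0;
        for (size_t v = 0; v < visible.size(); ++v)
          if (dom[visible[v]] < dom[me]) ++lower_cnt;
        if (lower_cnt > 0) {
          int pick = (int)(unif_rand() * lower_cnt);
          int target = -1;
          for (size_t v = 0; v < visible.size(); ++v) {
            if (dom[visible[v]] < dom[me] && pick-- == 0) { target = visible[v]; break; }
          }
          touch_emotions(target, now);
          anxiety[target] = std::min(1.0, anxiety[target] + anx_gain);
          last_aggressor[target] = me;
          arousal[target] = std::min(1.0, arousal[target] + aro_bump);
          ++n_attacks;
          ++n_submissive; // the lower-ranked receiver signals submission
          acted = true;
        }
      }
      if (!acted && unif_rand() >= 1.0 - satisfaction[me]) {
        ++n_satiated;
        // satiated: no grooming motivation; put distance between self and
        // the nearest group member if crowded, else rest
        int nearest = -1;
        double dmin = R_PosInf;
        for (size_t v = 0; v < visible.size(); ++v) {
          double d = world.dist(px[me], py[me], px[visible[v]], py[visible[v]]);
          if (d < dmin) { dmin = d; nearest = visible[v]; }
        }
        if (nearest >= 0 && dmin <= leave_radius) {
          move_relative(me, nearest, -1.0);
          ++n_leave;
        } else if (cohere(me)) {
          ++n_approach; // drift back toward the troupe
        } else {
          ++n_rest;
        }
        acted = true;
      }
      if (!acted) {
        // affiliative partner choice under LIKE-partner selectivity: a
        // candidate is encountered uniformly at random among the visible —
        // preferring those within ordinary perception range, since grooming
        // is a proximity behaviour — and the affiliative act toward it
        // proceeds with probability (1 - lps) + lps * LIKE, so realized
        // grooming partners follow the normalized LPS mixture while the
        // overall grooming rate itself rises as valuations build up
        int n_near = 0;
        for (size_t v = 0; v < visible.size(); ++v) {
          if (world.dist(px[me], py[me], px[visible[v]], py[visible[v]]) <= percep_r)
            weights[n_near++] = (double)visible[v];
        }
        int target;
        if (n_near > 0) target = (int)weights[(int)(unif_rand() * n_near)];
        else target = visible[(int)(unif_rand() * visible.size())];
        ++n_enc;
        double lk = like_read(me, target, now);
        bool pass = unif_rand() < (1.0 - lps) + lps * lk;
        if (pass) { if (lk < 0.25) ++n_pass_low; else ++n_pass_high; }
        if (!pass) {
          // declined encounter; keep the troupe coherent instead
          if (cohere(me)) ++n_approach; else ++n_rest;
        } else
        // fear-driven avoidance of the chosen partner, strongest when the
        // actor is anxious; a mild baseline keeps rank assortment without
        // categorically blocking up-hierarchy affiliation
        if (unif_rand() < fear(me, target) * (0.2 + 0.8 * anxiety[me])) {
          move_relative(me, target, -1.0);
          ++n_avoid;
        } else if (world.dist(px[me], py[me], px[target], py[target]) <= reach) {
          if (unif_rand() < satisfaction[target]) {
            ++n_signal; ++n_refuse; // satiated receiver declines
          } else {
            advance = do_groom(me, target, now, true);
          }
        } else {
          move_relative(me, target, +1.0);
          ++n_approach;
          goal[me] = target; // commit to the chosen partner
          goal_is_return[me] = 0;
          ++n_chase_start;
        }
      }
    }

    accounted[me] += advance;
    clock[me] = now + advance;
  }
  process_samples(T_end);

  // package outputs
  List snaps(snapshots.size());
  for (size_t s = 0; s < snapshots.size(); ++s) snaps[s] = snapshots[s];

  NumericMatrix groom(n, n), prox(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      groom(i, j) = groom_min[i * n + j];
      prox(i, j) = n_prox_samples > 0 ? prox_cnt[i * n + j] / n_prox_samples : NA_REAL;
    }

  int ns = (int)like_samples.size();
  NumericVector samp_arr(Dimension(n, n, ns));
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        samp_arr[s * n * n + j * n + i] = like_samples[s][i * n + j];

  return List::create(
    _["snapshots"] = snaps,
    _["snapshot_times"] = snap_rel,
    _["like_samples"] = samp_arr,
    _["like_sample_times"] = NumericVector(like_sample_times.begin(), like_sample_times.end()),
    _["grooming_minutes"] = groom,
    _["proximity_rate"] = prox,
    _["n_proximity_samples"] = n_prox_samples,
    _["final_like"] = realize_matrix(T_end),
    _["accounted_minutes"] = NumericVector(accounted.begin(), accounted.end()),
    _["initial_clock"] = NumericVector(clock0.begin(), clock0.end()),
    _["final_clock"] = NumericVector(clock.begin(), clock.end()),
    _["counters"] = List::create(
      _["bouts"] = (double)n_bouts,
      _["like_writes"] = (double)n_like_writes,
      _["grooming_minutes_total"] = (double)n_groom_min,
      _["attacks"] = (double)n_attacks,
      _["submissive_signals"] = (double)n_submissive,
      _["rest"] = (double)n_rest,
      _["approach"] = (double)n_approach,
      _["avoid"] = (double)n_avoid,
      _["leave"] = (double)n_leave,
      _["affiliative_signals"] = (double)n_signal,
      _["encounters"] = (double)n_enc,
      _["gate_pass_low"] = (double)n_pass_low,
      _["gate_pass_high"] = (double)n_pass_high,
      _["chases_started"] = (double)n_chase_start,
      _["chases_abandoned"] = (double)n_chase_drop,
      _["satiated_decisions"] = (double)n_satiated,
      _["bouts_refused"] = (double)n_refuse,
      _["random_walk"] = (double)n_walk,
      _["mean_visible"] = n_activations > 0 ? sum_visible / n_activations : NA_REAL,
      _["activations"] = (double)n_activations)
  );
}
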