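// Event-driven kinetic Monte Carlo core for the three-process
// failure-recovery dynamics.  Node states: 0 = A (active),
// 1 = X (internally failed), 2 = Y (externally failed).
//
// Transitions:
//   A -> X  rate p                 (spontaneous internal failure)
//   A -> Y  rate r, only in a CDN  (induced external failure)
//   X -> A  rate q                 (internal recovery)
//   Y -> A  rate q'                (external recovery)
// A node is in a critically damaged neighborhood (CDN) iff its number of
// active neighbors is <= m.
//
// Uses R's RNG (unif_rand / exp_rand) so that set.seed() on the R side
// makes whole runs reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Fenwick (binary indexed) tree over per-node total exit rates; rates
// change only locally after an event, so updates are O(log N).
struct RateTree {
  int n;
  std::vector<double> tree;  // 1-based
  std::vector<double> rate;  // current per-node rate, 0-based

  explicit RateTree(int n_) : n(n_), tree(n_ + 1, 0.0), rate(n_, 0.0) {}

  void add(int i, double delta) {
    rate[i] += delta;
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += delta;
  }
  void set(int i, double value) { add(i, value - rate[i]); }

  double total() const {
    double s = 0.0;
    for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  // smallest i with prefix_sum(i) > u
  int find(double u) const {
    int pos = 0, mask = 1;
    while ((mask << 1) <= n) mask <<= 1;
    for (; mask > 0; mask >>= 1) {
      int nxt = pos + mask;
      if (nxt <= n && tree[nxt] <= u) {
        u -= tree[nxt];
        pos = nxt;
      }
    }
    return pos;  // 0-based node index
  }
  // recompute internal sums from `rate` (kills floating-point drift)
  void rebuild() {
    std::fill(tree.begin(), tree.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += rate[i];
  }
};

inline double node_rate(int state, int n_act, double p, double r, double q,
                        double qp, int m) {
  switch (state) {
    case 0: return p + (n_act <= m ? r : 0.0);
    case 1: return q;
    default: return qp;
  }
}

}  // namespace

// [[Rcpp::export(name = ".gillespie_core")]]
List gillespie_core(IntegerVector adj_ptr, IntegerVector adj_nbr,
                    IntegerVector init_state, double p, double r, double q,
                    double qp, int m, double t_max, double sample_dt,
                    NumericVector snapshot_times) {
  const int N = init_state.size();
  std::vector<int> state(init_state.begin(), init_state.end());
  std::vector<int> n_act(N, 0);

  for (int i = 0; i < N; ++i)
    for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e)
      if (state[adj_nbr[e]] == 0) ++n_act[i];

  RateTree rates(N);
  for (int i = 0; i < N; ++i)
    rates.set(i, node_rate(state[i], n_act[i], p, r, q, qp, m));

  int cA = 0, cX = 0, cY = 0;
  for (int i = 0; i < N; ++i) {
    if (state[i] == 0) ++cA;
    else if (state[i] == 1) ++cX;
    else ++cY;
  }

  const int n_samples = (int)std::floor(t_max / sample_dt + 1e-9) + 1;
  NumericVector s_time(n_samples), s_z(n_samples), s_uint(n_samples),
      s_uext(n_samples);
  int samp = 0;

  const int n_snap = snapshot_times.size();
  List snaps(n_snap);
  int snap_idx = 0;

  double t = 0.0, event_count = 0.0;
  long long since_rebuild = 0;
  RNGScope rng;

  for (;;) {
    double total = rates.total();
    double t_next;
    if (total <= 0.0) {
      t_next = t_max + 1.0;  // frozen: fast-forward through samples
    } else {
      t_next = t + exp_rand() / total;
    }

    // record samples / snapshots on the uniform grid crossed by this wait
    // (piecewise-constant interpolation between events)
    while (samp < n_samples && samp * sample_dt <= t_next + 1e-12) {
      double ts = samp * sample_dt;
      if (ts > t_max + 1e-12) break;
      s_time[samp] = ts;
      s_z[samp] = (double)cA / N;
      s_uint[samp] = (double)cX / N;
      s_uext[samp] = (double)cY / N;
      ++samp;
    }
    while (snap_idx < n_snap && snapshot_times[snap_idx] <= t_next + 1e-12) {
      IntegerVector sv(N);
      std::copy(state.begin(), state.end(), sv.begin());
      snaps[snap_idx] = List::create(_["time"] = snapshot_times[snap_idx],
                                     _["state"] = sv);
      ++snap_idx;
    }

    if (t_next > t_max || total <= 0.0) break;
    t = t_next;

    // pick node proportionally to its exit rate, then the channel
    int i = rates.find(unif_rand() * total);
    if (i >= N) i = N - 1;  // guard against rounding at the top end
    int old = state[i], neu;
    if (old == 0) {
      double ri = rates.rate[i];
      neu = (unif_rand() * ri < p) ? 1 : 2;
      --cA;
      if (neu == 1) ++cX; else ++cY;
    } else {
      neu = 0;
      ++cA;
      if (old == 1) --cX; else --cY;
    }
    state[i] = neu;
    rates.set(i, node_rate(neu, n_act[i], p, r, q, qp, m));

    // only the flipped node's neighbors change CDN status
    int d = (neu == 0) ? 1 : -1;
    for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
      int w = adj_nbr[e];
      n_act[w] += d;
      if (state[w] == 0)
        rates.set(w, node_rate(0, n_act[w], p, r, q, qp, m));
    }

    event_count += 1.0;
    if (++since_rebuild >= 4000000LL) {  // cure float drift in the sum tree
      rates.rebuild();
      since_rebuild = 0;
    }
    if (((long long)event_count & 0xFFFFF) == 0) checkUserInterrupt();
  }

  IntegerVector fin(N);
  std::copy(state.begin(), state.end(), fin.begin());
  return List::create(
      _["time"] = s_time[Range(0, samp - 1)],
      _["z"] = s_z[Range(0, samp - 1)],
      _["u_int"] = s_uint[Range(0, samp - 1)],
      _["u_ext"] = s_uext[Range(0, samp - 1)],
      _["final_state"] = fin, _["event_count"] = event_count,
      _["snapshots"] = snaps);
}
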