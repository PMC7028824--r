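#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step (tau-leaping) sampler for the irreversible two-state lattice
// process. Hazards are frozen at the start of each step, every susceptible
// node flips independently with probability 1 - exp(-rate * tau), flipped
// nodes are stamped with the end-of-step time.
//
// Adjacency is CSR: neighbours of node i (0-based) are nbr_idx[nbr_ptr[i]
// .. nbr_ptr[i+1]-1] with reciprocal distances nbr_invd at the same slots.
//
// rate_i = lambda * W_i + uv_rate_i with W_i = sum_j S_j / d_ij, except in
// uniform mode where rate_i = lambda for every susceptible node (the
// neighbour-independent validation mode).
//
// An active set (susceptible nodes with positive rate) avoids full-lattice
// scans when growth is frontier-limited. Nodes enter the set when a
// neighbour flips (W becomes positive) or when they start with positive UV
// hazard; they leave when they flip.
//
// tau per step: tau_fixed if > 0, else min(tau_max, c_tau / max active rate).
//
// status: 1 = stop count reached, 2 = stagnated (zero total hazard),
//         3 = step budget exhausted.

// [[Rcpp::export]]
List cpp_simulate_fixed(IntegerVector nbr_ptr, IntegerVector nbr_idx,
                        NumericVector nbr_invd, NumericVector uv_rate,
                        double lambda, IntegerVector state0, int stop_count,
                        double c_tau, double tau_max, double tau_fixed,
                        int max_steps, bool uniform) {
  const int n = state0.size();
  std::vector<int> S(state0.begin(), state0.end());
  std::vector<double> W(n, 0.0);
  std::vector<char> in_active(n, 0);
  std::vector<int> active;
  active.reserve(n);

  int count = 0;
  for (int i = 0; i < n; ++i)
    if (S[i]) ++count;

  // neighbour weights from the initial cancerous set
  for (int i = 0; i < n; ++i) {
    if (!S[i]) continue;
    for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; ++k)
      W[nbr_idx[k] - 1] += nbr_invd[k];
  }
  for (int i = 0; i < n; ++i) {
    if (S[i]) continue;
    double r = uniform ? lambda : lambda * W[i] + uv_rate[i];
    if (uniform || r > 0.0) {
      active.push_back(i);
      in_active[i] = 1;
    }
  }

  std::vector<double> ev_time;
  std::vector<int> ev_node;
  std::vector<double> step_time;
  std::vector<int> step_count;
  ev_time.reserve(std::min(n, stop_count + 256));
  ev_node.reserve(std::min(n, stop_count + 256));

  double t = 0.0;
  int status = 3;
  std::vector<int> flips;

  if (count >= stop_count) status = 1;

  int step = 0;
  while (status == 3 && step < max_steps) {
    ++step;
    // compact the active set and find the maximal rate
    double rmax = 0.0;
    size_t w = 0;
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      if (S[i]) { in_active[i] = 0; continue; }
      active[w++] = i;
      double r = uniform ? lambda : lambda * W[i] + uv_rate[i];
      if (r > rmax) rmax = r;
    }
    active.resize(w);
    if (rmax <= 0.0 || active.empty()) { status = 2; break; }

    double tau = tau_fixed > 0.0 ? tau_fixed : c_tau / rmax;
    if (tau > tau_max) tau = tau_max;

    flips.clear();
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      double r = uniform ? lambda : lambda * W[i] + uv_rate[i];
      if (r <= 0.0) continue;
      double p = -expm1(-r * tau);
      if (R::unif_rand() < p) flips.push_back(i);
    }
    t += tau;

    for (size_t f = 0; f < flips.size(); ++f) {
      int i = flips[f];
      S[i] = 1;
      ++count;
      ev_time.push_back(t);
      ev_node.push_back(i + 1);
      for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; ++k) {
        int j = nbr_idx[k] - 1;
        W[j] += nbr_invd[k];
        if (!S[j] && !in_active[j]) {
          in_active[j] = 1;
          active.push_back(j);
        }
      }
    }

    step_time.push_back(t);
    step_count.push_back(count);
    if (count >= stop_count) status = 1;
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = ev_time, _["nodes"] = ev_node,
                      _["step_times"] = step_time,
                      _["step_counts"] = step_count, _["t_end"] = t,
                      _["n_steps"] = step, _["status"] = status,
                      _["count"] = count);
}
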