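// Compiled inner loop of the learning simulation.
//
// The R wrapper pre-draws the training stimulus stream and the frozen test
// set (so environment sampling stays in R and is shared across strategies);
// this engine perceives each sequence under the configured representation,
// chooses go/no-go by the softmax rule (consuming exactly one R uniform per
// training step), applies the normalized delta-rule update to the chosen
// behavior's strengths, and scores the frozen test set at each checkpoint.
//
// Subsequences are encoded as base-(n_symbols + 1) integers; since stimulus
// ids are >= 1 the encoding is prefix-free across lengths, so keys of
// different lengths never collide.

#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Elem {
  uint64_t key;
  double x;
};

enum Strategy { TRACE = 0, DEPTH = 1, FLEXIBLE = 2 };

void build_percept(const int* seq, int L, int strategy, int depth,
                   double theta, bool merge_recent, uint64_t base,
                   std::vector<Elem>& out) {
  out.clear();
  if (strategy == TRACE) {
    for (int i = 0; i < L; ++i) {
      double x = std::pow(theta, L - 1 - i);
      uint64_t key = (uint64_t)seq[i];
      bool found = false;
      for (Elem& e : out) {
        if (e.key == key) {
          if (merge_recent) {
            if (x > e.x) e.x = x;
          } else {
            e.x += x;
          }
          found = true;
          break;
        }
      }
      if (!found) out.push_back({key, x});
    }
  } else if (strategy == DEPTH) {
    uint64_t key = 0;
    for (int i = L - depth; i < L; ++i) key = key * base + (uint64_t)seq[i];
    out.push_back({key, 1.0});
  } else {  // FLEXIBLE: all contiguous subsequences of the last `depth`
    for (int s = L - depth; s < L; ++s) {
      uint64_t key = 0;
      for (int e = s; e < L; ++e) {
        key = key * base + (uint64_t)seq[e];
        bool found = false;
        for (Elem& el : out) {
          if (el.key == key) {
            el.x += 1.0;
            found = true;
            break;
          }
        }
        if (!found) out.push_back({key, 1.0});
      }
    }
  }
}

typedef std::unordered_map<uint64_t, std::array<double, 2> > WeightMap;

inline void values(const WeightMap& w, const std::vector<Elem>& percept,
                   double& v_go, double& v_nogo) {
  v_go = 0.0;
  v_nogo = 0.0;
  for (const Elem& e : percept) {
    WeightMap::const_iterator it = w.find(e.key);
    if (it != w.end()) {
      v_go += it->second[0] * e.x;
      v_nogo += it->second[1] * e.x;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List run_engine_cpp(IntegerMatrix train_seq, LogicalVector train_reward,
                    IntegerMatrix test_seq, LogicalVector test_reward,
                    int n_symbols, int strategy, int depth, double theta,
                    int trace_merge_recent, double alpha, double beta,
                    int measure_every, int greedy_test) {
  const int steps = train_seq.nrow();
  const int L = train_seq.ncol();
  const int n_test = test_seq.nrow();
  const uint64_t base = (uint64_t)n_symbols + 1;
  if (strategy == DEPTH || strategy == FLEXIBLE) {
    if (depth < 1 || depth > L) stop("invalid strategy depth");
  }

  // frozen test percepts, built once
  std::vector<std::vector<Elem> > test_percepts(n_test);
  std::vector<int> row(L);
  for (int j = 0; j < n_test; ++j) {
    for (int c = 0; c < L; ++c) row[c] = test_seq(j, c);
    build_percept(row.data(), L, strategy, depth, theta,
                  trace_merge_recent != 0, base, test_percepts[j]);
  }

  WeightMap weights;
  const int n_checks = steps / measure_every;
  NumericVector performance(n_checks);
  std::vector<Elem> percept;
  percept.reserve(16);
  int check = 0;
  double v_go, v_nogo;

  for (int t = 0; t < steps; ++t) {
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    for (int c = 0; c < L; ++c) row[c] = train_seq(t, c);
    build_percept(row.data(), L, strategy, depth, theta,
                  trace_merge_recent != 0, base, percept);
    values(weights, percept, v_go, v_nogo);
    const double p_go = 1.0 / (1.0 + std::exp(-beta * (v_go - v_nogo)));
    const int b = (unif_rand() < p_go) ? 0 : 1;  // 0 = go, 1 = no-go
    const double reinf = (b == 0) ? (train_reward[t] ? 5.0 : -4.0) : 0.0;
    const double delta = reinf - (b == 0 ? v_go : v_nogo);
    if (delta != 0.0) {
      double sumx = 0.0;
      for (const Elem& e : percept) sumx += e.x;
      const double step = alpha * delta / (sumx * sumx);
      for (const Elem& e : percept) {
        std::array<double, 2>& w = weights[e.key];
        w[b] += step * e.x;
        if (!std::isfinite(w[b]) || std::fabs(w[b]) > 1e6) {
          stop("associative strength diverged (|w| > 1e6); "
               "check alpha and beta");
        }
      }
    }
    if ((t + 1) % measure_every == 0) {
      double total = 0.0;
      for (int j = 0; j < n_test; ++j) {
        values(weights, test_percepts[j], v_go, v_nogo);
        if (greedy_test != 0) {
          const bool go = v_go > v_nogo;  // tie -> no-go
          total += (go == (bool)test_reward[j]) ? 1.0 : 0.0;
        } else {
          const double p = 1.0 / (1.0 + std::exp(-beta * (v_go - v_nogo)));
          total += test_reward[j] ? p : 1.0 - p;
        }
      }
      performance[check++] = total / n_test;
    }
  }

  // export learned weights (decode keys back into id sequences)
  const size_t n_keys = weights.size();
  List keys(n_keys);
  NumericVector go(n_keys), nogo(n_keys);
  size_t j = 0;
  for (WeightMap::const_iterator it = weights.begin(); it != weights.end();
       ++it, ++j) {
    uint64_t key = it->first;
    std::vector<int> ids;
    while (key > 0) {
      ids.push_back((int)(key % base));
      key /= base;
    }
    IntegerVector sub(ids.rbegin(), ids.rend());
    keys[j] = sub;
    go[j] = it->second[0];
    nogo[j] = it->second[1];
  }
  return List::create(_["performance"] = performance, _["keys"] = keys,
                      _["go"] = go, _["nogo"] = nogo);
}
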