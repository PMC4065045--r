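#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Calibrated score of the best connected component of the included set,
// and that component's members.  muK/sigmaK are indexed by component size
// k (position k-1); sigma is floored at 1e-9 to survive degenerate
// (constant) score fields.
static double bestComponentScore(const std::vector<int>& adjPtr,
                                 const std::vector<int>& adjIdx,
                                 const std::vector<double>& z,
                                 const std::vector<double>& muK,
                                 const std::vector<double>& sigmaK,
                                 const std::vector<char>& included,
                                 std::vector<int>& visitStamp,
                                 int stamp,
                                 std::vector<int>& stack,
                                 std::vector<int>& comp,
                                 std::vector<int>& bestComp) {
  const int V = (int)z.size();
  double best = -1e30;
  bestComp.clear();
  for (int v = 0; v < V; ++v) {
    if (!included[v] || visitStamp[v] == stamp) continue;
    double sum = 0.0;
    comp.clear();
    stack.clear();
    stack.push_back(v);
    visitStamp[v] = stamp;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      sum += z[u];
      comp.push_back(u);
      for (int e = adjPtr[u]; e < adjPtr[u + 1]; ++e) {
        int w = adjIdx[e];
        if (included[w] && visitStamp[w] != stamp) {
          visitStamp[w] = stamp;
          stack.push_back(w);
        }
      }
    }
    int k = (int)comp.size();
    double zA = sum / std::sqrt((double)k);
    double sig = sigmaK[k - 1];
    if (sig < 1e-9) sig = 1e-9;
    double s = (zA - muK[k - 1]) / sig;
    if (s > best) {
      best = s;
      bestComp = comp;
    }
  }
  return best;
}

// Simulated annealing over node inclusion states.  Objective: calibrated
// score of the best connected component of the included set.  Single-node
// toggle proposals: half uniform over all nodes, half targeted at the
// current best component and its neighbourhood (informed proposals; the
// uniform half keeps the chain ergodic).  Improvements always accepted,
// worsenings with probability exp(delta/T) under geometric cooling.
// Each run ends with greedy single-toggle sweeps to a local optimum.
// Uses R's RNG so runs are reproducible from set.seed().
// [[Rcpp::export]]
List anneal_kernel(IntegerVector adjPtrR, IntegerVector adjIdxR,
                   NumericVector zR, NumericVector muKR, NumericVector sigmaKR,
                   LogicalVector includedInit, int iterations,
                   double tStart, double tEnd) {
  const int V = zR.size();
  std::vector<int> adjPtr(adjPtrR.begin(), adjPtrR.end());
  std::vector<int> adjIdx(adjIdxR.begin(), adjIdxR.end());
  std::vector<double> z(zR.begin(), zR.end());
  std::vector<double> muK(muKR.begin(), muKR.end());
  std::vector<double> sigmaK(sigmaKR.begin(), sigmaKR.end());
  std::vector<char> included(V);
  for (int i = 0; i < V; ++i) included[i] = includedInit[i] ? 1 : 0;

  std::vector<int> visitStamp(V, 0), stack, comp, bestComp, cand;
  std::vector<int> candStamp(V, 0);
  int stamp = 0, cstamp = 0;
  stack.reserve(V);

  double cur = bestComponentScore(adjPtr, adjIdx, z, muK, sigmaK, included,
                                  visitStamp, ++stamp, stack, comp, bestComp);
  double best = cur;
  std::vector<char> bestState = included;
  long acceptedWorse = 0;
  const double coolBase = (iterations > 1)
      ? std::pow(tEnd / tStart, 1.0 / (iterations - 1)) : 1.0;
  double T = tStart;

  for (int it = 0; it < iterations; ++it) {
    int v;
    if (!bestComp.empty() && unif_rand() < 0.5) {
      // targeted proposal: best component plus its neighbourhood
      cand.clear();
      ++cstamp;
      for (size_t i = 0; i < bestComp.size(); ++i) {
        int u = bestComp[i];
        if (candStamp[u] != cstamp) { candStamp[u] = cstamp; cand.push_back(u); }
        for (int e = adjPtr[u]; e < adjPtr[u + 1]; ++e) {
          int w = adjIdx[e];
          if (candStamp[w] != cstamp) { candStamp[w] = cstamp; cand.push_back(w); }
        }
      }
      v = cand[(int)(unif_rand() * cand.size())];
    } else {
      v = (int)(unif_rand() * V);
      if (v >= V) v = V - 1;
    }
    included[v] = !included[v];
    double prop = bestComponentScore(adjPtr, adjIdx, z, muK, sigmaK,
                                     included, visitStamp, ++stamp, stack,
                                     comp, bestComp);
    double delta = prop - cur;
    bool accept = delta >= 0.0 || unif_rand() < std::exp(delta / T);
    if (accept) {
      if (delta < 0.0) ++acceptedWorse;
      cur = prop;
      if (cur > best) {
        best = cur;
        bestState = included;
      }
    } else {
      included[v] = !included[v];
      // restore bestComp for the next targeted proposal
      bestComponentScore(adjPtr, adjIdx, z, muK, sigmaK, included,
                         visitStamp, ++stamp, stack, comp, bestComp);
    }
    T *= coolBase;
  }

  // greedy polish: sweep single-node toggles to a local optimum
  included = bestState;
  double cur2 = best;
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps < 50) {
    improved = false;
    ++sweeps;
    for (int v = 0; v < V; ++v) {
      included[v] = !included[v];
      double prop = bestComponentScore(adjPtr, adjIdx, z, muK, sigmaK,
                                       included, visitStamp, ++stamp, stack,
                                       comp, bestComp);
      if (prop > cur2 + 1e-12) {
        cur2 = prop;
        improved = true;
      } else {
        included[v] = !included[v];
      }
    }
  }
  best = cur2;
  bestState = included;

  LogicalVector out(V);
  for (int i = 0; i < V; ++i) out[i] = bestState[i] != 0;
  return List::create(_["included"] = out, _["bestScore"] = best,
                      _["acceptedWorse"] = (double)acceptedWorse);
}
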