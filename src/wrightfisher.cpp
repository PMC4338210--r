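// Forward Wright-Fisher machinery for synthetic haplotype panels.
//
// Two pieces: (1) scalar allele-count trajectories under additive
// selection (genotype fitnesses 1, 1 + s/2, 1 + s), used both raw (for
// fixation-probability checks) and conditioned on first reaching a target
// frequency; (2) a trajectory-conditioned haplotype population: children
// inherit the focal allele dictated by the trajectory, pick a base parent
// from the matching focal class, and copy flanking sites from the base
// parent with per-interval donor switches (crossovers) to uniformly chosen
// parents of either class. All draws use R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double selNext(double p, double s) {
  // deterministic post-selection frequency under additive selection
  return p * (1.0 + s / 2.0 + s * p / 2.0) / (1.0 + s * p);
}

// One unconditioned trajectory; returns final count after absorption or
// maxGen generations.
// [[Rcpp::export]]
IntegerVector cpp_wf_fate(int nReps, int n2, double s, int initCount,
                          int maxGen) {
  IntegerVector out(nReps);
  for (int r = 0; r < nReps; r++) {
    int k = initCount;
    for (int g = 0; g < maxGen && k > 0 && k < n2; g++) {
      double p = selNext((double)k / n2, s);
      k = (int)R::rbinom(n2, p);
    }
    out[r] = k;
  }
  return out;
}

// Trajectory from initCount conditioned on first reaching targetCount
// before loss; re-drawn on loss, error after maxTries attempts.
// [[Rcpp::export]]
IntegerVector cpp_wf_trajectory(int n2, double s, int initCount,
                                int targetCount, int maxGen, int maxTries) {
  for (int tries = 0; tries < maxTries; tries++) {
    std::vector<int> traj;
    traj.push_back(initCount);
    int k = initCount;
    bool ok = false;
    for (int g = 0; g < maxGen; g++) {
      double p = selNext((double)k / n2, s);
      k = (int)R::rbinom(n2, p);
      traj.push_back(k);
      if (k >= targetCount) { ok = true; break; }
      if (k == 0) break;
    }
    if (ok) return wrap(traj);
  }
  stop("focal-allele trajectory failed to reach the target frequency in %d "
       "attempts of at most %d generations each", maxTries, maxGen);
}

// Evolve a haplotype population along a fixed focal trajectory.
// init: n2 x S starting population (row-major via IntegerMatrix), with the
// first traj[0] rows carrying the derived focal allele. recProb[j] is the
// crossover probability of the interval between sites j and j+1 (0-based).
// Returns the final-generation population, derived rows first.
// [[Rcpp::export]]
IntegerMatrix cpp_wf_panel(IntegerMatrix init, IntegerVector traj,
                           int focal, NumericVector recProb) {
  int n2 = init.nrow(), S = init.ncol();
  int G = traj.size() - 1;
  std::vector<int> cur(init.begin(), init.end());  // column-major
  std::vector<int> nxt(cur.size());
  auto at = [&](std::vector<int> &m, int i, int j) -> int & {
    return m[(size_t)j * n2 + i];
  };
  for (int g = 1; g <= G; g++) {
    int kPrev = traj[g - 1], kNow = traj[g];
    for (int i = 0; i < n2; i++) {
      bool derived = i < kNow;
      int base;
      if (derived)
        base = (int)(unif_rand() * kPrev);
      else
        base = kPrev + (int)(unif_rand() * (n2 - kPrev));
      if (base < 0) base = 0;
      if (base >= n2) base = n2 - 1;
      at(nxt, i, focal) = derived ? 1 : 0;
      int donor = base;
      for (int j = focal; j + 1 < S; j++) {      // rightward
        if (unif_rand() < recProb[j]) donor = (int)(unif_rand() * n2);
        at(nxt, i, j + 1) = at(cur, donor, j + 1);
      }
      donor = base;
      for (int j = focal; j > 0; j--) {          // leftward
        if (unif_rand() < recProb[j - 1]) donor = (int)(unif_rand() * n2);
        at(nxt, i, j - 1) = at(cur, donor, j - 1);
      }
    }
    std::swap(cur, nxt);
  }
  IntegerMatrix out(n2, S);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}
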