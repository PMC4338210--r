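// Structured-coalescent simulator of two-continent demographies with
// optional deme substructure, island / ring stepping-stone migration,
// circumarctic deme-pair gene flow, and exponential growth of the American
// population. One segregating site per replicate: after the genealogy
// fully coalesces, a single mutation is placed uniformly on the total
// branch length (fixed-S convention, as in ms -s 1), so every replicate
// segregates in the combined sample by construction.
//
// Time runs backward in generations. Epochs:
//   [0, T1)   continental demes with migration (T1 = 0 when unstructured)
//   [T1, T2)  two panmictic continents, no gene flow
//   [T2, inf) one panmictic ancestral population
// Within an epoch, waiting times are exact: the constant-rate event pool
// (coalescence in constant-size demes, migration) competes with the
// time-inhomogeneous American coalescence pool (rate growing as
// exp(alpha * t) backward under growth), sampled by closed-form inversion
// of its integrated rate. Event rates are maintained incrementally.
// All random draws use R's RNG, so set.seed() in R governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lineage {
  int deme;
  int nAsia;     // sampled Asian chromosomes beneath this lineage
  int nAmer;     // sampled American chromosomes beneath
  double birth;  // time (backward) the lineage became active
};

inline double pairs(int k) { return 0.5 * k * (k - 1); }

struct Sim {
  // resolved demography
  double T1, T2;
  int A, M;                 // deme counts in the structured epoch
  double asiaN, amerNPresent, alpha, ancestralN;
  int topology;             // 0 none, 1 island, 2 stepping-stone (ring)
  bool circ;
  double migFrac, circRate;

  // state
  std::vector<Lineage> lin;
  std::vector<double> bLen;
  std::vector<int> bAsia, bAmer;
  double t;
  int phase;  // 1 demes, 2 two continents, 3 ancestral

  int nDemes() const { return phase == 1 ? A + M : (phase == 2 ? 2 : 1); }
  bool isAsianDeme(int d) const {
    if (phase == 1) return d < A;
    if (phase == 2) return d == 0;
    return true;  // ancestral pool behaves as a constant-size deme
  }
  bool isCircDeme(int d) const {
    return phase == 1 && circ && (d == 0 || d == A);
  }
  // constant-size deme N (Asian demes, the ancestral population, and
  // American demes when there is no growth)
  double constDemeSize(int d) const {
    if (phase == 3) return ancestralN;
    if (phase == 2) return d == 0 ? asiaN : amerNPresent;
    return d < A ? asiaN / A : amerNPresent / M;
  }

  // migration destination for a lineage currently in deme d
  int migrate(int d) const {
    if (isCircDeme(d)) return d == 0 ? A : 0;
    bool asia = d < A;
    int lo = asia ? 0 : A;
    int n = asia ? A : M;
    int start = lo + (circ ? 1 : 0);   // circumarctic deme is out of the pool
    int size = n - (circ ? 1 : 0);
    if (size < 2) return d;
    if (topology == 1) {               // island: uniform other pool deme
      int pick = start + (int)(unif_rand() * (size - 1));
      if (pick >= d) pick++;
      return pick;
    }
    // stepping stone: ring over the pool demes, step to a random neighbour
    int pos = d - start;
    int step = unif_rand() < 0.5 ? -1 : 1;
    return start + (pos + step + size) % size;
  }

  // per-lineage migration out-rate by deme
  double migRate(int d) const {
    if (phase != 1 || topology == 0) return 0.0;
    if (isCircDeme(d)) return circRate;
    int size = (d < A ? A : M) - (circ ? 1 : 0);
    return size >= 2 ? migFrac : 0.0;
  }

  void recordAndMerge(int i, int j, double tt) {
    bLen.push_back(tt - lin[i].birth);
    bAsia.push_back(lin[i].nAsia);
    bAmer.push_back(lin[i].nAmer);
    bLen.push_back(tt - lin[j].birth);
    bAsia.push_back(lin[j].nAsia);
    bAmer.push_back(lin[j].nAmer);
    lin[i].nAsia += lin[j].nAsia;
    lin[i].nAmer += lin[j].nAmer;
    lin[i].birth = tt;
    lin.erase(lin.begin() + j);
  }

  // coalesce a uniform pair within deme d at the current time
  void coalescePair(int d) {
    int k = 0;
    for (auto &l : lin) if (l.deme == d) k++;
    int a = (int)(unif_rand() * k);
    int b = (int)(unif_rand() * (k - 1));
    if (b >= a) b++;
    if (a > b) std::swap(a, b);
    int i = -1, j = -1, seen = 0;
    for (size_t x = 0; x < lin.size(); x++) {
      if (lin[x].deme != d) continue;
      if (seen == a) i = (int)x;
      if (seen == b) { j = (int)x; break; }
      seen++;
    }
    recordAndMerge(i, j, t);
  }

  // move a uniformly chosen lineage out of deme d; returns its destination
  int migrateLineage(int d) {
    int k = 0;
    for (auto &l : lin) if (l.deme == d) k++;
    int pick = (int)(unif_rand() * k), seen = 0;
    for (auto &l : lin) {
      if (l.deme != d) continue;
      if (seen == pick) { l.deme = migrate(d); return l.deme; }
      seen++;
    }
    return d;
  }

  // run one epoch; returns when the epoch ends or the MRCA is reached
  void runEpoch(double phaseEnd) {
    int nd = nDemes();
    std::vector<int> kd(nd, 0);
    for (auto &l : lin) kd[l.deme]++;

    bool amerGrows = alpha > 0 && phase != 3;
    double rConstCoal = 0;     // summed coal rate of constant-size demes
    double sumPairsGrow = 0;   // pair count over growing American demes
    double migSum = 0;
    for (int d = 0; d < nd; d++) {
      if (amerGrows && !isAsianDeme(d)) sumPairsGrow += pairs(kd[d]);
      else rConstCoal += pairs(kd[d]) / (2.0 * constDemeSize(d));
      migSum += kd[d] * migRate(d);
    }
    // American coalescence rate at time tt: sumPairsGrow / growDenom * e^(alpha tt)
    double growDenom = 2.0 * amerNPresent / (phase == 1 ? M : 1);

    while (lin.size() > 1) {
      if (rConstCoal < 0) rConstCoal = 0;   // guard incremental round-off
      if (migSum < 0) migSum = 0;
      double rConst = rConstCoal + migSum;
      double dtC = rConst > 0 ? exp_rand() / rConst : R_PosInf;
      double dtG = R_PosInf;
      if (amerGrows && sumPairsGrow > 0) {
        double a0 = sumPairsGrow / growDenom * std::exp(alpha * t);
        dtG = std::log1p(alpha * exp_rand() / a0) / alpha;
      }
      double dt = std::min(dtC, dtG);
      if (t + dt >= phaseEnd) { t = phaseEnd; return; }
      t += dt;

      if (dtG < dtC) {
        // American coalescence in the growth pool: deme by pair count
        double u = unif_rand() * sumPairsGrow;
        int deme = nd - 1;
        for (int d = 0; d < nd; d++) {
          if (isAsianDeme(d) || kd[d] < 2) continue;
          u -= pairs(kd[d]);
          if (u <= 0) { deme = d; break; }
        }
        coalescePair(deme);
        sumPairsGrow -= kd[deme] - 1;
        migSum -= migRate(deme);
        kd[deme]--;
      } else {
        double u = unif_rand() * rConst;
        int deme = -1;
        for (int d = 0; d < nd && u > 0; d++) {
          if (kd[d] < 2 || (amerGrows && !isAsianDeme(d))) continue;
          u -= pairs(kd[d]) / (2.0 * constDemeSize(d));
          if (u <= 0) deme = d;
        }
        if (deme >= 0) {
          coalescePair(deme);
          rConstCoal -= (kd[deme] - 1) / (2.0 * constDemeSize(deme));
          migSum -= migRate(deme);
          kd[deme]--;
        } else {
          // migration: pick source deme by its total out-rate
          int from = -1;
          for (int d = 0; d < nd; d++) {
            if (kd[d] == 0) continue;
            u -= kd[d] * migRate(d);
            if (u <= 0) { from = d; break; }
          }
          if (from < 0) {  // float slack: last occupied mobile deme
            for (int d = nd - 1; d >= 0; d--)
              if (kd[d] > 0 && migRate(d) > 0) { from = d; break; }
          }
          if (from >= 0) {
            int dto = migrateLineage(from);
            if (dto != from) {
              if (amerGrows && !isAsianDeme(from))
                sumPairsGrow -= kd[from] - 1;
              else
                rConstCoal -= (kd[from] - 1) / (2.0 * constDemeSize(from));
              if (amerGrows && !isAsianDeme(dto))
                sumPairsGrow += kd[dto];
              else
                rConstCoal += kd[dto] / (2.0 * constDemeSize(dto));
              migSum += migRate(dto) - migRate(from);
              kd[from]--; kd[dto]++;
            }
          }
        }
      }
    }
  }

  void run() {
    t = 0.0;
    if (T1 > 0) {
      phase = 1;
      runEpoch(T1);
    }
    if (lin.size() > 1) {
      phase = 2;
      for (auto &l : lin) l.deme = l.deme < A ? 0 : 1;
      if (T2 > t) runEpoch(T2);
    }
    if (lin.size() > 1) {
      phase = 3;
      for (auto &l : lin) l.deme = 0;
      runEpoch(R_PosInf);
    }
  }

  // drop one mutation uniformly on total branch length
  void mutate(int &dAsia, int &dAmer, double &totalLen) {
    double L = 0.0;
    for (double x : bLen) L += x;
    totalLen = L;
    double u = unif_rand() * L;
    for (size_t i = 0; i < bLen.size(); i++) {
      u -= bLen[i];
      if (u <= 0) { dAsia = bAsia[i]; dAmer = bAmer[i]; return; }
    }
    dAsia = bAsia.back(); dAmer = bAmer.back();
  }

  void seedSamples(const IntegerVector &samplesAsia,
                   const IntegerVector &samplesAmerica) {
    for (int d = 0; d < A; d++)
      for (int s = 0; s < samplesAsia[d]; s++)
        lin.push_back({d, 1, 0, 0.0});
    for (int d = 0; d < M; d++)
      for (int s = 0; s < samplesAmerica[d]; s++)
        lin.push_back({A + d, 0, 1, 0.0});
  }
};

Sim makeSim(const IntegerVector &samplesAsia,
            const IntegerVector &samplesAmerica,
            double T1, double T2, double asiaN, double amerNPresent,
            double alpha, double ancestralN, int topology,
            bool circumarctic, double migFrac, double circRate) {
  Sim sim;
  sim.T1 = T1; sim.T2 = T2;
  sim.A = samplesAsia.size(); sim.M = samplesAmerica.size();
  sim.asiaN = asiaN; sim.amerNPresent = amerNPresent;
  sim.alpha = alpha; sim.ancestralN = ancestralN;
  sim.topology = topology; sim.circ = circumarctic;
  sim.migFrac = migFrac; sim.circRate = circRate;
  sim.seedSamples(samplesAsia, samplesAmerica);
  return sim;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_simulate_snps(int nSnps,
                                IntegerVector samplesAsia,
                                IntegerVector samplesAmerica,
                                double T1, double T2,
                                double asiaN, double amerNPresent,
                                double alpha, double ancestralN,
                                int topology, bool circumarctic,
                                double migFrac, double circRate) {
  NumericMatrix out(nSnps, 3);
  for (int r = 0; r < nSnps; r++) {
    Sim sim = makeSim(samplesAsia, samplesAmerica, T1, T2, asiaN,
                      amerNPresent, alpha, ancestralN, topology,
                      circumarctic, migFrac, circRate);
    sim.run();
    int dAsia = 0, dAmer = 0;
    double L = 0;
    sim.mutate(dAsia, dAmer, L);
    out(r, 0) = dAsia;
    out(r, 1) = dAmer;
    out(r, 2) = L;
  }
  return out;
}

// Per-replicate time to the most recent common ancestor, for analytic
// cross-checks (Kingman: E[TMRCA] = 2N for n = 2 in one constant-size
// population).
// [[Rcpp::export]]
NumericVector cpp_tmrca(int nReps,
                        IntegerVector samplesAsia,
                        IntegerVector samplesAmerica,
                        double T1, double T2,
                        double asiaN, double amerNPresent,
                        double alpha, double ancestralN,
                        int topology, bool circumarctic,
                        double migFrac, double circRate) {
  NumericVector out(nReps);
  for (int r = 0; r < nReps; r++) {
    Sim sim = makeSim(samplesAsia, samplesAmerica, T1, T2, asiaN,
                      amerNPresent, alpha, ancestralN, topology,
                      circumarctic, migFrac, circRate);
    sim.run();
    out[r] = sim.t;
  }
  return out;
}
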