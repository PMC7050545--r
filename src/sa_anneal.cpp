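#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing maximization of Barber bipartite modularity Q_B on a
// binary plant x ant matrix. Single-species relocation moves (to an existing
// module or to one fresh empty module), geometric cooling, best-ever
// partition returned. Uses R's RNG so set.seed() on the R side makes runs
// reproducible.
//
// Nodes are indexed 0..P-1 (plants) then P..P+A-1 (ants). Module "slots" are
// fixed ids 0..P+A-1; at most one empty slot is offered as a relocation
// target per proposal, which is how new modules are created.

// [[Rcpp::export]]
List sa_anneal_cpp(IntegerMatrix B, double t0, double cooling,
                   int steps_per_t, double tmin) {
  const int P = B.nrow(), A = B.ncol(), n = P + A;

  std::vector< std::vector<int> > nbr(n);
  std::vector<double> deg(n, 0.0);
  double F = 0.0;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < A; ++j)
      if (B(i, j) > 0) {
        nbr[i].push_back(P + j);
        nbr[P + j].push_back(i);
        deg[i] += 1.0;
        deg[P + j] += 1.0;
        F += 1.0;
      }

  // start from singletons: node v in module v
  std::vector<int> mem(n), size(n, 1);
  std::vector<double> sumKp(n, 0.0), sumKa(n, 0.0);
  for (int v = 0; v < n; ++v) {
    mem[v] = v;
    if (v < P) sumKp[v] = deg[v]; else sumKa[v] = deg[v];
  }
  std::vector<int> active(n), pos(n), freeSlots;
  for (int m = 0; m < n; ++m) { active[m] = m; pos[m] = m; }
  int nActive = n;

  // Q of the singleton start is exactly 0: every module holds one node, so
  // it has neither within-module links nor a degree-product expectation.
  double Q = 0.0;

  double bestQ = Q;
  std::vector<int> bestMem(mem);

  int nTemps = 0;
  for (double T = t0; T >= tmin; T *= cooling) ++nTemps;
  NumericMatrix trace(nTemps, 2);

  int ti = 0;
  for (double T = t0; T >= tmin; T *= cooling, ++ti) {
    for (int step = 0; step < steps_per_t; ++step) {
      int v = (int)(unif_rand() * n);
      if (v >= n) v = n - 1;
      int a = mem[v];
      bool haveSpare = nActive < n;
      int nTargets = nActive + (haveSpare ? 1 : 0);
      int t = (int)(unif_rand() * nTargets);
      if (t >= nTargets) t = nTargets - 1;
      int b;
      if (t == nActive) { // spare empty slot: create a new module
        b = freeSlots.empty() ? -1 : freeSlots.back();
        if (b < 0) continue;
      } else {
        b = active[t];
      }
      if (b == a) continue;

      double La = 0.0, Lb = 0.0;
      for (size_t k = 0; k < nbr[v].size(); ++k) {
        int m = mem[nbr[v][k]];
        if (m == a) La += 1.0;
        else if (m == b) Lb += 1.0;
      }
      double oppA = (v < P) ? sumKa[a] : sumKp[a];
      double oppB = (v < P) ? sumKa[b] : sumKp[b];
      double dq = ((Lb - La) - deg[v] * (oppB - oppA) / F) / F;

      if (dq > 0.0 || unif_rand() < std::exp(dq / T)) {
        mem[v] = b;
        size[a] -= 1; size[b] += 1;
        if (v < P) { sumKp[a] -= deg[v]; sumKp[b] += deg[v]; }
        else       { sumKa[a] -= deg[v]; sumKa[b] += deg[v]; }
        Q += dq;
        if (size[b] == 1) { // b was the spare: activate it
          freeSlots.pop_back();
          active[nActive] = b; pos[b] = nActive; ++nActive;
        }
        if (size[a] == 0) { // a emptied: deactivate
          int last = active[nActive - 1];
          active[pos[a]] = last; pos[last] = pos[a];
          --nActive;
          freeSlots.push_back(a);
        }
        if (Q > bestQ) { bestQ = Q; bestMem = mem; }
      }
    }
    trace(ti, 0) = T;
    trace(ti, 1) = bestQ;
  }

  return List::create(_["membership"] = IntegerVector(bestMem.begin(), bestMem.end()),
                      _["qb"] = bestQ,
                      _["trace"] = trace);
}
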