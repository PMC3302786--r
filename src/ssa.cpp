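// Generic mass-action Gillespie direct-method engine.
//
// The reaction network is supplied from R as a rate vector, a reactant-index
// matrix (up to two distinct reactant species per channel; all channels in
// this package are unimolecular or hetero-bimolecular, so propensities are
// plain products k * x1 [* x2]) and a dense stoichiometry matrix.  Running
// maxima are tracked at event resolution because the downstream decision rule
// compares the maximum of a trajectory, not grid samples, to a threshold.
//
// RNG: std::mt19937_64, whose raw output sequence is fully specified by the
// C++ standard, with hand-written uniform/exponential transforms, so
// trajectories are bit-reproducible across platforms.  A trajectory seed s is
// whitened through splitmix64 before seeding the engine.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform on the open interval (0, 1), 53-bit resolution
static inline double runif01(std::mt19937_64& eng) {
  return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector init,
                 NumericVector rates,
                 IntegerMatrix reactants,  // nchan x 2, 1-based; 0 = no second reactant
                 IntegerMatrix stoich,     // nspecies x nchan
                 NumericVector grid,       // strictly increasing record times (may be empty)
                 double t_end,
                 double seed,
                 bool record) {
  const int ns = init.size();
  const int nc = rates.size();
  if (reactants.nrow() != nc || stoich.ncol() != nc || stoich.nrow() != ns)
    stop("inconsistent network dimensions");

  std::vector<double> state(init.begin(), init.end());
  std::vector<double> smax(state);

  // per-channel changed-species lists, and species -> dependent channels
  std::vector<std::vector<int>> changed(nc);
  std::vector<std::vector<int>> dep_of_species(ns);
  for (int j = 0; j < nc; ++j)
    for (int s = 0; s < ns; ++s)
      if (stoich(s, j) != 0) changed[j].push_back(s);
  for (int j = 0; j < nc; ++j) {
    if (reactants(j, 0) > 0) dep_of_species[reactants(j, 0) - 1].push_back(j);
    if (reactants(j, 1) > 0) dep_of_species[reactants(j, 1) - 1].push_back(j);
  }

  std::vector<double> a(nc);
  auto prop = [&](int j) -> double {
    double p = rates[j];
    int r1 = reactants(j, 0), r2 = reactants(j, 1);
    if (r1 > 0) p *= state[r1 - 1];
    if (r2 > 0) p *= state[r2 - 1];
    return p;
  };
  double a0 = 0.0;
  for (int j = 0; j < nc; ++j) { a[j] = prop(j); a0 += a[j]; }

  const int ng = grid.size();
  NumericMatrix out = record ? NumericMatrix(ng, ns) : NumericMatrix(0, 0);
  int gi = 0;

  std::mt19937_64 eng(splitmix64(static_cast<uint64_t>(seed)));

  double t = 0.0;
  long long n_events = 0;
  long long resync = 0;

  for (;;) {
    if (a0 <= 1e-12) {
      // exhausted: freeze the state out to t_end
      if (record) for (; gi < ng; ++gi)
        for (int s = 0; s < ns; ++s) out(gi, s) = state[s];
      break;
    }
    double tau = -std::log(runif01(eng)) / a0;
    double tnext = t + tau;
    if (record) {
      while (gi < ng && grid[gi] < tnext && grid[gi] <= t_end) {
        for (int s = 0; s < ns; ++s) out(gi, s) = state[s];
        ++gi;
      }
    }
    if (tnext > t_end) {
      if (record) for (; gi < ng; ++gi)
        for (int s = 0; s < ns; ++s) out(gi, s) = state[s];
      break;
    }
    t = tnext;

    // select channel proportional to propensity
    double r = runif01(eng) * a0;
    int j = 0;
    double cum = a[0];
    while (cum < r && j < nc - 1) cum += a[++j];
    // guard against fp round-off selecting a zero-propensity channel
    while (a[j] <= 0.0 && j > 0) --j;

    // apply stoichiometry, update maxima
    for (int s : changed[j]) {
      state[s] += stoich(s, j);
      if (state[s] < 0) stop("negative count (corrupt network)");
      if (state[s] > smax[s]) smax[s] = state[s];
    }
    // update dependent propensities incrementally
    for (int s : changed[j])
      for (int k : dep_of_species[s]) {
        double anew = prop(k);
        a0 += anew - a[k];
        a[k] = anew;
      }
    ++n_events;
    if (++resync == 16384) {  // kill accumulated fp drift in a0
      resync = 0;
      a0 = 0.0;
      for (int k = 0; k < nc; ++k) a0 += a[k];
    }
  }

  return List::create(_["counts"] = out,
                      _["max"] = NumericVector(smax.begin(), smax.end()),
                      _["final"] = NumericVector(state.begin(), state.end()),
                      _["final_time"] = t,
                      _["n_events"] = static_cast<double>(n_events));
}
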