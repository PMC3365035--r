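#include <Rcpp.h>
using namespace Rcpp;

// Individual-based resource-mediated community simulator.
//
// Organisms are (trait bit-vector, neutral tag) genotypes competing for a
// cascade of depletable resources.  All stochastic draws go through R's RNG,
// so a single set.seed() in R makes whole runs reproducible.
//
// Time is discrete ("updates").  One update:
//   1. resources decay by (1 - decay) and receive exogenous inflow;
//   2. every viable organism bearing function j takes an equal share of the
//      alpha-fraction of resource j; consumed units are converted into
//      by-product resources one level down the cascade;
//   3. fitness = (base_merit + resource merit) / (1 + trait_cost * n_traits);
//      Poisson(birth_rate * n_organisms) birth events occur, parents sampled
//      fitness-proportionally, each offspring filling an empty slot if the
//      population is below capacity, else replacing a uniform random organism;
//   4. each birth mutates trait bits / neutral tag / lethality; any mutation
//      founds a new genotype and a genealogy record;
//   5. genotypes whose organism count reaches zero are stamped extinct.

namespace {

struct GenoTable {
  std::vector<int> parent;   // 0 = founder (no parent)
  std::vector<int> origin;
  std::vector<int> extinct;  // -1 while extant
  std::vector<int> traits;   // bitmask over functions
  std::vector<int> tag;
  std::vector<int> viable;   // 0/1
  std::vector<int> count;    // living organisms of this genotype
  std::vector<int> ntraits;
};

int popcount_int(int x) {
  int n = 0;
  while (x) { n += x & 1; x >>= 1; }
  return n;
}

} // namespace

// [[Rcpp::export]]
List sim_steps_cpp(List state, int n_updates, NumericVector inflow, List cfg,
                   IntegerVector capture_at) {
  const int pop_size  = as<int>(cfg["population_size"]);
  const int n_fun     = as<int>(cfg["n_functions"]);
  const NumericVector rewards = cfg["rewards"];
  const double decay      = as<double>(cfg["decay"]);
  const double uptake     = as<double>(cfg["uptake_fraction"]);
  const double conversion = as<double>(cfg["conversion_factor"]);
  const double base_merit = as<double>(cfg["base_merit"]);
  const double trait_cost = as<double>(cfg["trait_cost"]);
  const double birth_rate = as<double>(cfg["birth_rate"]);
  const double mu_trait   = as<double>(cfg["mu_trait"]);
  const double mu_tag     = as<double>(cfg["mu_tag"]);
  const double mu_lethal  = as<double>(cfg["mu_lethal"]);
  const List downstream   = cfg["downstream"]; // per function: 1-based targets

  // unpack state
  IntegerVector org_in = state["organisms"];
  std::vector<int> org(org_in.begin(), org_in.end()); // 1-based genotype ids
  NumericVector res = clone(as<NumericVector>(state["resources"]));
  int t = as<int>(state["update"]);
  int next_tag = as<int>(state["next_tag"]);

  List gl = state["genealogy"];
  GenoTable g;
  {
    IntegerVector p = gl["parent"], o = gl["origin"], e = gl["extinct"],
      tr = gl["traits"], tg = gl["tag"], vi = gl["viable"], ct = gl["count"],
      nt = gl["ntraits"];
    g.parent.assign(p.begin(), p.end());
    g.origin.assign(o.begin(), o.end());
    g.extinct.assign(e.begin(), e.end());
    g.traits.assign(tr.begin(), tr.end());
    g.tag.assign(tg.begin(), tg.end());
    g.viable.assign(vi.begin(), vi.end());
    g.count.assign(ct.begin(), ct.end());
    g.ntraits.assign(nt.begin(), nt.end());
  }
  size_t reserve_n = g.parent.size() + (size_t)(n_updates * birth_rate * pop_size * 0.3) + 64;
  g.parent.reserve(reserve_n); g.origin.reserve(reserve_n); g.extinct.reserve(reserve_n);
  g.traits.reserve(reserve_n); g.tag.reserve(reserve_n); g.viable.reserve(reserve_n);
  g.count.reserve(reserve_n); g.ntraits.reserve(reserve_n);

  std::vector<int> cap_times(capture_at.begin(), capture_at.end());
  List captures(cap_times.size());
  IntegerVector capture_update(cap_times.size());

  std::vector<int> perf(n_fun);
  std::vector<double> merit_fun(n_fun);
  std::vector<double> cumfit;
  bool failed = false;
  const int t_end = t + n_updates;

  while (t < t_end) {
    ++t;
    const int norg = (int)org.size();

    // 1. decay then inflow
    for (int r = 0; r < n_fun; ++r)
      res[r] = (1.0 - decay) * res[r] + inflow[r];

    // 2. performer census and uptake
    std::fill(perf.begin(), perf.end(), 0);
    for (int i = 0; i < norg; ++i) {
      const int gi = org[i] - 1;
      if (!g.viable[gi]) continue;
      int tr = g.traits[gi];
      for (int j = 0; tr; ++j, tr >>= 1)
        if (tr & 1) ++perf[j];
    }
    for (int j = 0; j < n_fun; ++j) {
      if (perf[j] == 0) { merit_fun[j] = 0.0; continue; }
      const double consumed = uptake * res[j];
      res[j] -= consumed;                    // never negative: uptake <= 1
      merit_fun[j] = rewards[j] * consumed / perf[j];
      IntegerVector ds = downstream[j];
      for (int d = 0; d < ds.size(); ++d)
        res[ds[d] - 1] += consumed / conversion;
    }

    // 3. fitness
    cumfit.resize(norg);
    double tot = 0.0;
    for (int i = 0; i < norg; ++i) {
      const int gi = org[i] - 1;
      double f = 0.0;
      if (g.viable[gi]) {
        double m = base_merit;
        int tr = g.traits[gi];
        for (int j = 0; tr; ++j, tr >>= 1)
          if (tr & 1) m += merit_fun[j];
        f = m / (1.0 + trait_cost * g.ntraits[gi]);
      }
      tot += f;
      cumfit[i] = tot;
    }
    if (tot <= 0.0) {            // no viable replicator left: failed replicate
      failed = true;
      for (size_t c = 0; c < cap_times.size(); ++c)
        if (cap_times[c] >= t) {  // frozen population: later snapshots identical
          captures[c] = IntegerVector(org.begin(), org.end());
          capture_update[c] = cap_times[c];
        }
      t = t_end;
      break;
    }

    // 4. births; parents come from the update-start pool (fitness and
    // membership frozen at the update boundary), so a child never reproduces
    // within its own birth update and origins are strictly ordered
    const int nb = (int)R::rpois(birth_rate * norg);
    const std::vector<int> org0(org.begin(), org.begin() + norg);
    for (int b = 0; b < nb; ++b) {
      const double u = R::runif(0.0, tot);
      int lo = 0, hi = norg - 1;
      while (lo < hi) {
        const int mid = (lo + hi) / 2;
        if (cumfit[mid] < u) lo = mid + 1; else hi = mid;
      }
      const int pg = org0[lo] - 1;           // parent genotype index (0-based)
      if (!g.viable[pg]) continue;           // can't happen (fitness 0), guard

      // mutate
      int tr = g.traits[pg];
      bool mutated = false;
      for (int j = 0; j < n_fun; ++j)
        if (R::runif(0.0, 1.0) < mu_trait) { tr ^= (1 << j); mutated = true; }
      int tg = g.tag[pg];
      if (R::runif(0.0, 1.0) < mu_tag) { tg = next_tag++; mutated = true; }
      int viable_child = 1;
      if (R::runif(0.0, 1.0) < mu_lethal) { viable_child = 0; mutated = true; }

      int child_id;
      if (mutated) {
        g.parent.push_back(pg + 1);
        g.origin.push_back(t);
        g.extinct.push_back(-1);
        g.traits.push_back(tr);
        g.tag.push_back(tg);
        g.viable.push_back(viable_child);
        g.count.push_back(1);
        g.ntraits.push_back(popcount_int(tr));
        child_id = (int)g.parent.size();     // 1-based
      } else {
        child_id = pg + 1;
        // the parent's last organism may have been replaced earlier in this
        // same update; it was never absent at an update boundary, so undo
        // the provisional extinction stamp
        if (g.count[pg] == 0 && g.extinct[pg] == t) g.extinct[pg] = -1;
        ++g.count[pg];
      }

      // place offspring
      if ((int)org.size() < pop_size) {
        org.push_back(child_id);
      } else {
        const int victim = (int)(R::runif(0.0, 1.0) * org.size());
        const int vg = org[victim] - 1;
        if (--g.count[vg] == 0) g.extinct[vg] = t;
        org[victim] = child_id;
      }
    }

    // captures at end of update t
    for (size_t c = 0; c < cap_times.size(); ++c)
      if (cap_times[c] == t) {
        captures[c] = IntegerVector(org.begin(), org.end());
        capture_update[c] = t;
      }
  }

  List gen = List::create(
    _["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
    _["origin"] = IntegerVector(g.origin.begin(), g.origin.end()),
    _["extinct"] = IntegerVector(g.extinct.begin(), g.extinct.end()),
    _["traits"] = IntegerVector(g.traits.begin(), g.traits.end()),
    _["tag"] = IntegerVector(g.tag.begin(), g.tag.end()),
    _["viable"] = IntegerVector(g.viable.begin(), g.viable.end()),
    _["count"] = IntegerVector(g.count.begin(), g.count.end()),
    _["ntraits"] = IntegerVector(g.ntraits.begin(), g.ntraits.end()));

  return List::create(
    _["organisms"] = IntegerVector(org.begin(), org.end()),
    _["resources"] = res,
    _["update"] = t,
    _["next_tag"] = next_tag,
    _["genealogy"] = gen,
    _["captures"] = captures,
    _["capture_update"] = capture_update,
    _["failed"] = failed);
}
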