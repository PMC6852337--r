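// Backwards-in-time spatially explicit neutral coalescent.
//
// One lineage per sampled individual; events pick an active lineage
// uniformly at random. With probability nu the lineage speciates and its
// descendants receive a fresh species id; otherwise it moves to a parent
// slot drawn via a fat-tailed dispersal kernel (rejection-resampled until
// inside the closed landscape; in aware mode cross-forest-type proposals
// are accepted with probability m) and coalesces with any active lineage
// already occupying that slot. All randomness flows through R's RNG so a
// single set.seed() in R reproduces the census bit-for-bit.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Radial inverse-CDF draw for the 2D Student-t-type kernel:
// F(r) = 1 - (1 + r^2/(tau sigma^2))^(-tau/2).
static inline double draw_radius(double sigma, double tau) {
  double u = unif_rand();
  return sigma * std::sqrt(tau * std::expm1((-2.0 / tau) * std::log1p(-u)));
}

// [[Rcpp::export]]
List coalesce_cpp(IntegerMatrix forest_type, IntegerMatrix density,
                  NumericVector sigma, NumericVector tau,
                  double nu, double m, int mode, // 0 naive, 1 aware, 2 global
                  IntegerMatrix samples, double max_events,
                  double max_tries) {
  const int h = forest_type.nrow(), w = forest_type.ncol();

  // linear slot indexing for the global (well-mixed) mode
  std::vector<double> cell_offset(static_cast<size_t>(h) * w + 1, 0.0);
  double J = 0.0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      size_t cid = static_cast<size_t>(c) * h + r;
      cell_offset[cid] = J;
      J += density(r, c);
    }
  cell_offset[static_cast<size_t>(h) * w] = J;

  long long maxD = 1;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (density(r, c) > maxD) maxD = density(r, c);

  // lineage state
  const int n_samples_rows = samples.nrow();
  std::vector<int> lin_r, lin_c, lin_idx;
  std::vector<std::vector<int> > desc;
  int sample_id = 0;
  for (int i = 0; i < n_samples_rows; ++i) {
    int r = samples(i, 0) - 1, c = samples(i, 1) - 1, n = samples(i, 2);
    if (density(r, c) < 1) stop("sampled cell has density < 1");
    for (int k = 0; k < n; ++k) {
      lin_r.push_back(r); lin_c.push_back(c); lin_idx.push_back(k);
      desc.push_back(std::vector<int>(1, sample_id++));
    }
  }
  const int n_total = sample_id;
  std::vector<int> species(n_total, 0);

  // occupancy: slot key -> lineage id
  std::unordered_map<long long, int> occ;
  occ.reserve(n_total * 2);
  auto slot_key = [&](int r, int c, int idx) -> long long {
    return (static_cast<long long>(c) * h + r) * maxD + idx;
  };
  std::vector<int> active; // lineage ids, swap-removed
  std::vector<int> pos_in_active(n_total, -1);
  for (int i = 0; i < n_total; ++i) {
    long long key = slot_key(lin_r[i], lin_c[i], lin_idx[i]);
    if (occ.count(key)) stop("duplicate sampled slot in sample map");
    occ[key] = i;
    pos_in_active[i] = active.size();
    active.push_back(i);
  }

  auto deactivate = [&](int id) {
    int p = pos_in_active[id];
    int last = active.back();
    active[p] = last;
    pos_in_active[last] = p;
    active.pop_back();
    pos_in_active[id] = -1;
  };

  int next_species = 0;
  double events = 0.0, cross_prop = 0.0, cross_acc = 0.0;

  while (!active.empty()) {
    // a sole surviving lineage is the MRCA of its descendants: founding
    // species assignment is the same whether it speciates now or later
    if (active.size() == 1) {
      int a = active[0];
      ++next_species;
      for (size_t k = 0; k < desc[a].size(); ++k)
        species[desc[a][k]] = next_species;
      occ.erase(slot_key(lin_r[a], lin_c[a], lin_idx[a]));
      deactivate(a);
      break;
    }
    if (++events > max_events)
      stop("coalescent did not terminate within max_events = %g", max_events);
    if (((long long)events & 0xFFFFF) == 0) checkUserInterrupt();

    int a = active[static_cast<int>(unif_rand() * active.size()) %
                   static_cast<int>(active.size())];

    if (unif_rand() < nu) { // speciation
      ++next_species;
      for (size_t k = 0; k < desc[a].size(); ++k)
        species[desc[a][k]] = next_species;
      occ.erase(slot_key(lin_r[a], lin_c[a], lin_idx[a]));
      deactivate(a);
      continue;
    }

    // dispersal to a parent slot
    int nr = lin_r[a], nc = lin_c[a], ni = lin_idx[a];
    if (mode == 2) { // global: uniform over the other J - 1 individuals
      double own = cell_offset[static_cast<size_t>(nc) * h + nr] + ni;
      double t = std::floor(unif_rand() * (J - 1.0));
      if (t >= J - 1.0) t = J - 2.0;
      if (t >= own) t += 1.0;
      // invert the linear index: binary search over cell offsets
      size_t lo = 0, hi = static_cast<size_t>(h) * w;
      while (hi - lo > 1) {
        size_t mid = (lo + hi) / 2;
        if (cell_offset[mid] <= t) lo = mid; else hi = mid;
      }
      nr = static_cast<int>(lo % h);
      nc = static_cast<int>(lo / h);
      ni = static_cast<int>(t - cell_offset[lo]);
    } else {
      const int own_type = forest_type(lin_r[a], lin_c[a]);
      const int ki = (mode == 1 && sigma.size() > 1) ? (own_type - 1) : 0;
      const double sg = sigma[ki], tu = tau[ki];
      double tries = 0.0;
      for (;;) {
        if (++tries > max_tries)
          stop("dispersal rejection loop exceeded max_tries (mixing starvation?)");
        double r_dist = draw_radius(sg, tu);
        double th = 2.0 * M_PI * unif_rand();
        int pr = lin_r[a] + static_cast<int>(std::lround(r_dist * std::sin(th)));
        int pc = lin_c[a] + static_cast<int>(std::lround(r_dist * std::cos(th)));
        if (pr < 0 || pr >= h || pc < 0 || pc >= w) continue;
        if (mode == 1 && forest_type(pr, pc) != own_type) {
          cross_prop += 1.0;
          if (m <= 0.0) continue;       // never cross
          if (m < 1.0) {                // Bernoulli(m) acceptance
            if (unif_rand() >= m) continue;
          }                              // m == 1: accept, no draw consumed
          cross_acc += 1.0;
        }
        nr = pr; nc = pc;
        int d = density(nr, nc);
        ni = static_cast<int>(unif_rand() * d);
        if (ni >= d) ni = d - 1;
        break;
      }
    }

    // move (or coalesce) into the parent slot
    occ.erase(slot_key(lin_r[a], lin_c[a], lin_idx[a]));
    long long key = slot_key(nr, nc, ni);
    std::unordered_map<long long, int>::iterator it = occ.find(key);
    if (it != occ.end()) { // coalescence: a joins the occupant
      int b = it->second;
      desc[b].insert(desc[b].end(), desc[a].begin(), desc[a].end());
      deactivate(a);
    } else {
      occ[key] = a;
      lin_r[a] = nr; lin_c[a] = nc; lin_idx[a] = ni;
    }
  }

  return List::create(_["species"] = wrap(species),
                      _["n_species"] = next_species,
                      _["events"] = events,
                      _["cross_proposals"] = cross_prop,
                      _["cross_accepts"] = cross_acc);
}
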