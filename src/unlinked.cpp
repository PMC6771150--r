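// Fast unlinked-sites simulator: one independent coalescent genealogy per
// SNP under the four two-deme scenarios, with each site's derived allele
// placed on a branch chosen proportionally to branch length (infinite
// sites). Lineages carry their descendant-tip sets as 32-bit masks, so a
// 26-tip genealogy costs a few microseconds and a 1661-site dataset a few
// milliseconds. Time is in units of 4*Ne generations; deme sizes are
// relative to Ne (the colonized deme shrinks backward in time from
// growth_ratio to founder_ratio at ct, rate alpha).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

namespace {

struct Branch { uint32_t mask; double len; };

struct DemeState {
  std::vector<uint32_t> active;
};

// coalesce `active` lineages from t0 to tmax in a deme of relative size
// x(t) = x0 * exp(-alpha * t); records (mask, length) for both children of
// every coalescence; returns the time reached
double coalesce_span(std::vector<uint32_t>& active,
                     std::vector<double>& born, double t0, double tmax,
                     double x0, double alpha,
                     std::vector<Branch>& branches, std::mt19937_64& rng) {
  std::exponential_distribution<double> Exp(1.0);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double t = t0;
  while (active.size() > 1) {
    const double k = (double) active.size();
    const double rate = k * (k - 1.0);
    const double e = Exp(rng);
    double s;
    if (alpha == 0.0) {
      s = e * x0 / rate;
    } else {
      s = std::log1p(e * alpha * x0 * std::exp(-alpha * t) / rate) / alpha;
    }
    if (t + s > tmax) return tmax;
    t += s;
    // pick an unordered pair
    const size_t i = (size_t)(U(rng) * active.size());
    size_t j = (size_t)(U(rng) * (active.size() - 1));
    if (j >= i) ++j;
    branches.push_back({active[i], t - born[i]});
    branches.push_back({active[j], t - born[j]});
    const uint32_t merged = active[i] | active[j];
    const size_t hi = std::max(i, j), lo = std::min(i, j);
    active.erase(active.begin() + hi);
    born.erase(born.begin() + hi);
    active[lo] = merged;
    born[lo] = t;
  }
  return t;
}

// one genealogy; fills `branches` (cleared first)
void one_genealogy(int model, double ct, double fr, double gr,
                   int n1h, int n2h, std::vector<Branch>& branches,
                   std::mt19937_64& rng) {
  branches.clear();
  std::vector<uint32_t> d1, d2;
  std::vector<double> b1, b2;
  for (int i = 0; i < n1h; ++i) { d1.push_back(1u << i); b1.push_back(0.0); }
  for (int i = 0; i < n2h; ++i) { d2.push_back(1u << (n1h + i));
                                  b2.push_back(0.0); }
  const double eps = 1e-12;
  if (model == 1 || ct <= eps) {
    d1.insert(d1.end(), d2.begin(), d2.end());
    b1.insert(b1.end(), b2.begin(), b2.end());
    coalesce_span(d1, b1, 0.0, 1e300, 1.0, 0.0, branches, rng);
    return;
  }
  if (model == 2) {
    coalesce_span(d1, b1, 0.0, ct, 1.0, 0.0, branches, rng);
    coalesce_span(d2, b2, 0.0, ct, 1.0, 0.0, branches, rng);
  } else {
    const double alpha = std::log(gr / fr) / ct;
    if (model == 3) {
      coalesce_span(d1, b1, 0.0, ct, gr, alpha, branches, rng);
      coalesce_span(d2, b2, 0.0, ct, 1.0, 0.0, branches, rng);
    } else {
      coalesce_span(d1, b1, 0.0, ct, 1.0, 0.0, branches, rng);
      coalesce_span(d2, b2, 0.0, ct, gr, alpha, branches, rng);
    }
  }
  d1.insert(d1.end(), d2.begin(), d2.end());
  b1.insert(b1.end(), b2.begin(), b2.end());
  coalesce_span(d1, b1, ct, 1e300, 1.0, 0.0, branches, rng);
}

} // namespace

// [[Rcpp::export(name = ".sim_unlinked")]]
Rcpp::IntegerMatrix sim_unlinked_cpp(int model, double ct, double fr,
                                     double gr, int n1h, int n2h, int s,
                                     double seed) {
  const int ntips = n1h + n2h;
  if (ntips > 31) Rcpp::stop("unlinked mode supports at most 31 haploids");
  Rcpp::IntegerMatrix m(ntips, s);
  std::mt19937_64 rng((uint64_t) seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::vector<Branch> branches;
  branches.reserve(2 * ntips);
  for (int j = 0; j < s; ++j) {
    one_genealogy(model, ct, fr, gr, n1h, n2h, branches, rng);
    double total = 0;
    for (const Branch& b : branches) total += b.len;
    double u = U(rng) * total;
    uint32_t mask = branches.back().mask;
    for (const Branch& b : branches) {
      u -= b.len;
      if (u <= 0) { mask = b.mask; break; }
    }
    for (int i = 0; i < ntips; ++i) {
      if (mask & (1u << i)) m(i, j) = 1;
    }
  }
  return m;
}
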