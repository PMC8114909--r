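// Coalescent machinery: Hudson-style ancestral recombination graph over a
// continuous region with piecewise-linear recombination intensity taken from
// a genetic map, a two-locus sampler used to build composite-likelihood
// lookup tables, and a vectorised composite-likelihood scan.
//
// All randomness comes from a seeded mt19937_64 with hand-rolled transforms
// (uniform -> exponential / poisson) so that streams are reproducible across
// platforms independent of the C++ standard library's distributions.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  int unif_int(int n) {  // 0 .. n-1
    return (int)std::min((double)n - 1.0, std::floor(unif() * n));
  }
};

typedef std::vector<uint64_t> Bits;

inline int popcount_bits(const Bits &b) {
  int c = 0;
  for (uint64_t w : b) {
#if defined(__GNUC__) || defined(__clang__)
    c += __builtin_popcountll(w);
#else
    while (w) { c += (int)(w & 1); w >>= 1; }
#endif
  }
  return c;
}

struct Seg {
  double l, r;   // physical, half-open [l, r)
  Bits bits;     // samples this segment is ancestral to
  int cnt;
};

// piecewise-linear map between physical position and cumulative rho
struct RhoMap {
  std::vector<double> pos, rho;  // same length, pos increasing, rho nondecr.
  double phys_to_rho(double x) const {
    size_t i = std::upper_bound(pos.begin(), pos.end(), x) - pos.begin();
    if (i == 0) return rho.front();
    if (i >= pos.size()) return rho.back();
    double w = (x - pos[i - 1]) / (pos[i] - pos[i - 1]);
    return rho[i - 1] + w * (rho[i] - rho[i - 1]);
  }
  double rho_to_phys(double g) const {
    size_t i = std::upper_bound(rho.begin(), rho.end(), g) - rho.begin();
    if (i == 0) return pos.front();
    if (i >= rho.size()) return pos.back();
    double dr = rho[i] - rho[i - 1];
    if (dr <= 0.0) return pos[i - 1];
    double w = (g - rho[i - 1]) / dr;
    return pos[i - 1] + w * (pos[i] - pos[i - 1]);
  }
};

struct Lineage {
  std::vector<Seg> segs;  // sorted, disjoint
  double rho_span, bp;
};

void refresh_cache(Lineage &ln, const RhoMap &m) {
  ln.bp = 0.0;
  for (const Seg &s : ln.segs) ln.bp += s.r - s.l;
  if (ln.segs.empty()) {
    ln.rho_span = 0.0;
  } else {
    ln.rho_span = m.phys_to_rho(ln.segs.back().r) -
                  m.phys_to_rho(ln.segs.front().l);
  }
}

// merge two sorted disjoint segment lists; union bit sets on overlap; drop
// parts whose sample set is complete (local MRCA reached)
std::vector<Seg> merge_lineages(const std::vector<Seg> &a,
                                const std::vector<Seg> &b,
                                int n_samples, int words) {
  std::vector<double> cuts;
  for (const Seg &s : a) { cuts.push_back(s.l); cuts.push_back(s.r); }
  for (const Seg &s : b) { cuts.push_back(s.l); cuts.push_back(s.r); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());

  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double l = cuts[c], r = cuts[c + 1];
    double mid = 0.5 * (l + r);
    while (ia < a.size() && a[ia].r <= l) ++ia;
    while (ib < b.size() && b[ib].r <= l) ++ib;
    bool ina = ia < a.size() && a[ia].l <= mid && mid < a[ia].r;
    bool inb = ib < b.size() && b[ib].l <= mid && mid < b[ib].r;
    if (!ina && !inb) continue;
    Bits bits(words, 0);
    int cnt;
    if (ina && inb) {
      for (int w = 0; w < words; ++w) bits[w] = a[ia].bits[w] | b[ib].bits[w];
      cnt = popcount_bits(bits);
      if (cnt == n_samples) continue;  // locally coalesced everywhere
    } else if (ina) {
      bits = a[ia].bits; cnt = a[ia].cnt;
    } else {
      bits = b[ib].bits; cnt = b[ib].cnt;
    }
    if (!out.empty() && out.back().r == l && out.back().bits == bits) {
      out.back().r = r;  // coalesce contiguous equal-set pieces
    } else {
      Seg s; s.l = l; s.r = r; s.bits = std::move(bits); s.cnt = cnt;
      out.push_back(std::move(s));
    }
  }
  return out;
}

}  // namespace

// Simulate a haplotype panel under the coalescent with recombination.
// map_pos / map_rho give cumulative scaled recombination (rho = 4*Ne*r,
// dimensionless) as a piecewise-linear function of physical position;
// theta is the scaled mutation rate per bp.  Returns continuous mutation
// positions (ascending) and an n_hap x S 0/1 matrix.
// [[Rcpp::export(name = ".arg_simulate")]]
List arg_simulate(int n_hap, double region_length,
                  NumericVector map_pos, NumericVector map_rho,
                  double theta, double seed) {
  if (n_hap < 2) stop("n_hap must be >= 2");
  RhoMap m;
  m.pos.assign(map_pos.begin(), map_pos.end());
  m.rho.assign(map_rho.begin(), map_rho.end());
  Rng rng((uint64_t)seed);
  const int words = (n_hap + 63) / 64;

  std::vector<Lineage> L(n_hap);
  for (int i = 0; i < n_hap; ++i) {
    Seg s;
    s.l = 0.0; s.r = region_length;
    s.bits.assign(words, 0);
    s.bits[i / 64] |= (uint64_t)1 << (i % 64);
    s.cnt = 1;
    L[i].segs.push_back(std::move(s));
    refresh_cache(L[i], m);
  }

  std::vector<std::pair<double, Bits> > muts;

  long guard = 0;
  while (!L.empty()) {
    if (++guard > 100000000L) stop("ARG simulation failed to terminate");
    size_t k = L.size();
    double coal = k > 1 ? 0.5 * (double)k * (double)(k - 1) : 0.0;
    double rho_tot = 0.0, bp_tot = 0.0;
    for (const Lineage &ln : L) { rho_tot += ln.rho_span; bp_tot += ln.bp; }
    double rec = 0.5 * rho_tot;
    double mut = 0.5 * theta * bp_tot;
    double total = coal + rec + mut;
    if (total <= 0.0) break;  // single lineage w/o material (cannot occur)
    double u = rng.unif() * total;

    if (u < coal) {
      int i = rng.unif_int((int)k);
      int j = rng.unif_int((int)k - 1);
      if (j >= i) ++j;
      std::vector<Seg> merged = merge_lineages(L[i].segs, L[j].segs,
                                               n_hap, words);
      if (i > j) std::swap(i, j);
      L.erase(L.begin() + j);
      if (merged.empty()) {
        L.erase(L.begin() + i);
      } else {
        L[i].segs = std::move(merged);
        refresh_cache(L[i], m);
      }
    } else if (u < coal + rec) {
      double target = (u - coal) * 2.0;  // point within cumulative rho spans
      size_t i = 0;
      double acc = 0.0;
      for (; i < k; ++i) {
        if (target < acc + L[i].rho_span || i == k - 1) break;
        acc += L[i].rho_span;
      }
      Lineage &ln = L[i];
      double gl = m.phys_to_rho(ln.segs.front().l);
      double g = gl + rng.unif_pos() * ln.rho_span;
      double x = m.rho_to_phys(g);
      std::vector<Seg> left, right;
      for (Seg &s : ln.segs) {
        if (s.r <= x) left.push_back(std::move(s));
        else if (s.l >= x) right.push_back(std::move(s));
        else {
          Seg sl = s, sr = s;
          sl.r = x; sr.l = x;
          left.push_back(std::move(sl));
          right.push_back(std::move(sr));
        }
      }
      if (left.empty() || right.empty()) {
        // breakpoint fell on the boundary of the span: no-op
        continue;
      }
      ln.segs = std::move(left);
      refresh_cache(ln, m);
      Lineage nl;
      nl.segs = std::move(right);
      refresh_cache(nl, m);
      L.push_back(std::move(nl));
    } else {
      double target = (u - coal - rec) / (0.5 * theta);
      size_t i = 0;
      double acc = 0.0;
      for (; i < k; ++i) {
        if (target < acc + L[i].bp || i == k - 1) break;
        acc += L[i].bp;
      }
      double off = rng.unif() * L[i].bp;
      for (const Seg &s : L[i].segs) {
        double len = s.r - s.l;
        if (off < len) {
          muts.push_back(std::make_pair(s.l + off, s.bits));
          break;
        }
        off -= len;
      }
    }
  }

  std::sort(muts.begin(), muts.end(),
            [](const std::pair<double, Bits> &x,
               const std::pair<double, Bits> &y) { return x.first < y.first; });
  int S = (int)muts.size();
  NumericVector pos(S);
  IntegerMatrix hap(n_hap, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].first;
    const Bits &b = muts[s].second;
    for (int i = 0; i < n_hap; ++i)
      hap(i, s) = (b[i / 64] >> (i % 64)) & 1;
  }
  return List::create(_["positions"] = pos, _["haplotypes"] = hap);
}

// Two-locus coalescent sampler: n_reps replicates of a two-site ARG with
// scaled recombination rho between the sites and per-locus mutation rate
// theta_locus; replicates are retained only when each locus receives
// exactly one mutation (biallelic under infinite sites).  Returns a matrix
// of derived-allele two-locus configurations (n00, n01, n10, n11).
// [[Rcpp::export(name = ".two_locus_sim")]]
IntegerMatrix two_locus_sim(int n_hap, double rho, double theta_locus,
                            int n_reps, double seed) {
  if (n_hap < 2) stop("n_hap must be >= 2");
  Rng rng((uint64_t)seed);
  const int words = (n_hap + 63) / 64;
  std::vector<std::array<int, 4> > keep;

  struct TL {
    Bits a, b;
    int ca, cb;  // 0 = absent; full (== n) segments are dropped
  };

  for (int rep = 0; rep < n_reps; ++rep) {
    std::vector<TL> L(n_hap);
    for (int i = 0; i < n_hap; ++i) {
      L[i].a.assign(words, 0); L[i].b.assign(words, 0);
      L[i].a[i / 64] |= (uint64_t)1 << (i % 64);
      L[i].b[i / 64] |= (uint64_t)1 << (i % 64);
      L[i].ca = 1; L[i].cb = 1;
    }
    bool mutA = false, mutB = false, bad = false;
    Bits DA, DB;

    while (!L.empty() && !bad) {
      size_t k = L.size();
      int nab = 0, na = 0, nb = 0;
      for (const TL &t : L) {
        if (t.ca > 0) ++na;
        if (t.cb > 0) ++nb;
        if (t.ca > 0 && t.cb > 0) ++nab;
      }
      double coal = k > 1 ? 0.5 * (double)k * (double)(k - 1) : 0.0;
      double rec = 0.5 * rho * nab;
      double mut = 0.5 * theta_locus * (na + nb);
      double total = coal + rec + mut;
      if (total <= 0.0) break;
      double u = rng.unif() * total;
      if (u < coal) {
        int i = rng.unif_int((int)k);
        int j = rng.unif_int((int)k - 1);
        if (j >= i) ++j;
        TL merged;
        merged.a.assign(words, 0); merged.b.assign(words, 0);
        for (int w = 0; w < words; ++w) {
          merged.a[w] = L[i].a[w] | L[j].a[w];
          merged.b[w] = L[i].b[w] | L[j].b[w];
        }
        merged.ca = (L[i].ca || L[j].ca) ? popcount_bits(merged.a) : 0;
        merged.cb = (L[i].cb || L[j].cb) ? popcount_bits(merged.b) : 0;
        if (merged.ca == n_hap) merged.ca = 0;  // locus A done on this line
        if (merged.cb == n_hap) merged.cb = 0;
        if (i > j) std::swap(i, j);
        L.erase(L.begin() + j);
        if (merged.ca == 0 && merged.cb == 0) {
          L.erase(L.begin() + i);
        } else {
          if (merged.ca == 0) merged.a.assign(words, 0);
          if (merged.cb == 0) merged.b.assign(words, 0);
          L[i] = std::move(merged);
        }
      } else if (u < coal + rec) {
        int pick = (int)((u - coal) / (0.5 * rho));
        int i = 0, seen = 0;
        for (; i < (int)k; ++i) {
          if (L[i].ca > 0 && L[i].cb > 0) {
            if (seen == pick || i == (int)k - 1) break;
            ++seen;
          }
        }
        TL nb_;
        nb_.b = L[i].b; nb_.cb = L[i].cb;
        nb_.a.assign(words, 0); nb_.ca = 0;
        L[i].b.assign(words, 0); L[i].cb = 0;
        L.push_back(std::move(nb_));
      } else {
        int pick = (int)((u - coal - rec) / (0.5 * theta_locus));
        // enumerate carriers: first the A-carriers, then the B-carriers
        int i = 0, seen = 0; bool locusA = true;
        bool done = false;
        for (int pass = 0; pass < 2 && !done; ++pass) {
          for (i = 0; i < (int)k; ++i) {
            bool carries = pass == 0 ? L[i].ca > 0 : L[i].cb > 0;
            if (carries) {
              if (seen == pick) { locusA = (pass == 0); done = true; break; }
              ++seen;
            }
          }
        }
        if (!done) { i = (int)k - 1; locusA = L[i].ca > 0; }
        if (locusA) {
          if (mutA) { bad = true; break; }
          mutA = true; DA = L[i].a;
        } else {
          if (mutB) { bad = true; break; }
          mutB = true; DB = L[i].b;
        }
      }
    }

    if (bad || !mutA || !mutB) continue;
    Bits inter(words, 0);
    for (int w = 0; w < words; ++w) inter[w] = DA[w] & DB[w];
    int n11 = popcount_bits(inter);
    int n10 = popcount_bits(DA) - n11;
    int n01 = popcount_bits(DB) - n11;
    int n00 = n_hap - n11 - n10 - n01;
    keep.push_back({{n00, n01, n10, n11}});
  }

  IntegerMatrix out((int)keep.size(), 4);
  for (int r = 0; r < (int)keep.size(); ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = keep[r][c];
  return out;
}

// Composite log-likelihood scan.  key_idx: 1-based row of lik_mat for each
// site pair (0 = configuration unseen in the lookup -> floor_log);
// dist: physical bp between the pair's sites; lik_mat: log-likelihood per
// (configuration, grid rho); grid_rho ascending (first entry may be 0).
// Interpolation is linear in log1p(rho); beyond the grid ends the
// log-likelihood is clamped.  Returns the summed log-likelihood at each
// candidate per-bp rho.
// [[Rcpp::export(name = ".composite_scan")]]
NumericVector composite_scan(IntegerVector key_idx, NumericVector dist,
                             NumericMatrix lik_mat, NumericVector grid_rho,
                             NumericVector cand_rho_bp, double floor_log) {
  int P = key_idx.size(), G = grid_rho.size(), C = cand_rho_bp.size();
  std::vector<double> gt(G);
  for (int g = 0; g < G; ++g) gt[g] = std::log1p(grid_rho[g]);
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double r = cand_rho_bp[c], ll = 0.0;
    for (int p = 0; p < P; ++p) {
      int k = key_idx[p];
      if (k <= 0) { ll += floor_log; continue; }
      double t = std::log1p(r * dist[p]);
      int j = (int)(std::upper_bound(gt.begin(), gt.end(), t) - gt.begin());
      double v;
      if (j <= 0) v = lik_mat(k - 1, 0);
      else if (j >= G) v = lik_mat(k - 1, G - 1);
      else {
        double w = (t - gt[j - 1]) / (gt[j] - gt[j - 1]);
        v = (1.0 - w) * lik_mat(k - 1, j - 1) + w * lik_mat(k - 1, j);
      }
      ll += v;
    }
    out[c] = ll;
  }
  return out;
}

// One copying-chain update for diploid phasing: builds the phase-
// marginalised emissions (given the genotype and the partner chain's
// current template alleles), runs a scaled forward pass and samples a
// copying path backward.  u supplies the S uniforms used for sampling so
// that the caller's RNG governs reproducibility.  tpl entries < 0 mean
// "allele unknown" (uniform emission); other_al < 0 likewise.
// [[Rcpp::export(name = ".ls_chain_path")]]
IntegerVector ls_chain_path(IntegerMatrix tpl, IntegerVector g,
                            IntegerVector other_al, NumericVector s,
                            double eps, NumericVector u) {
  const int K = tpl.nrow(), S = tpl.ncol();
  if (g.size() != S || other_al.size() != S || u.size() != S ||
      (S > 1 && s.size() != S - 1))
    stop("inconsistent dimensions in ls_chain_path");
  NumericMatrix alpha(K, S);
  std::vector<double> work(K);
  const double e_hom_match = 1.0 - eps, e_hom_mis = eps;
  const double e_het_comp = (1.0 - eps) * (1.0 - eps) + eps * eps;
  const double e_het_same = 2.0 * eps * (1.0 - eps);

  for (int j = 0; j < S; ++j) {
    bool gna = IntegerVector::is_na(g[j]);
    int gj = gna ? -1 : g[j];
    int oj = other_al[j];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      int c = tpl(k, j);
      double e;
      if (gna) e = 1.0;
      else if (gj != 1) {                       // homozygous anchor
        if (c < 0) e = 0.5;
        else e = (c == gj / 2) ? e_hom_match : e_hom_mis;
      } else {                                  // heterozygous site
        if (c < 0 || oj < 0) e = 0.5;
        else e = (c == 1 - oj) ? e_het_comp : e_het_same;
      }
      double prev;
      if (j == 0) prev = 1.0 / K;
      else prev = (1.0 - s[j - 1]) * alpha(k, j - 1) + s[j - 1] / K;
      double a = e * prev;
      alpha(k, j) = a;
      tot += a;
    }
    if (tot <= 0.0) stop("zero forward probability at site ", j + 1);
    for (int k = 0; k < K; ++k) alpha(k, j) /= tot;
  }

  IntegerVector path(S);
  // sample final state
  {
    double target = u[S - 1], acc = 0.0;
    int k = 0;
    for (; k < K; ++k) { acc += alpha(k, S - 1); if (target < acc) break; }
    path[S - 1] = std::min(k, K - 1);
  }
  for (int j = S - 2; j >= 0; --j) {
    int nxt = path[j + 1];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double w = alpha(k, j) * s[j] / K;
      if (k == nxt) w += alpha(k, j) * (1.0 - s[j]);
      work[k] = w;
      tot += w;
    }
    double target = u[j] * tot, acc = 0.0;
    int k = 0;
    for (; k < K; ++k) { acc += work[k]; if (target < acc) break; }
    path[j] = std::min(k, K - 1);
  }
  for (int j = 0; j < S; ++j) path[j] += 1;   // 1-based template rows
  return path;
}
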