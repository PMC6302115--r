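#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Forward Wright-Fisher engine. Haplotypes are stored sites x haplotypes
// (column-major), so copying one gamete is a contiguous block. All
// randomness uses R's RNG, so results are reproducible from set.seed().

namespace {

// Form one gamete from parent `par` (0-based diploid index) of `hap`
// into column `out_col` of `out`: pick a starting haplotype, then switch
// at Poisson-count uniformly placed crossovers.
void make_gamete(const IntegerMatrix& hap, const NumericVector& pos,
                 double map_len, int par, IntegerMatrix& out,
                 int out_col) {
  const int L = hap.nrow();
  int start = (unif_rand() < 0.5) ? 0 : 1;
  int nx = static_cast<int>(R::rpois(map_len));
  const int* c0 = &hap(0, 2 * par + start);
  int* dst = &out(0, out_col);
  if (nx == 0) {
    std::copy(c0, c0 + L, dst);
    return;
  }
  const int* c1 = &hap(0, 2 * par + (1 - start));
  std::vector<double> breaks(nx);
  for (int i = 0; i < nx; ++i) breaks[i] = unif_rand() * map_len;
  std::sort(breaks.begin(), breaks.end());
  int seg = 0;          // 0 -> copy from c0, 1 -> from c1
  int bi = 0;
  int lo = 0;
  while (lo < L) {
    // find end of current segment: first site past the next breakpoint
    int hi = L;
    if (bi < nx) {
      hi = static_cast<int>(
        std::lower_bound(&pos[0] + lo, &pos[0] + L, breaks[bi]) - &pos[0]);
    }
    const int* src = (seg == 0) ? c0 : c1;
    std::copy(src + lo, src + hi, dst + lo);
    lo = hi;
    seg ^= 1;
    ++bi;
    if (bi > nx) break;
  }
  // tail after the last breakpoint
  if (lo < L) {
    const int* src = (seg == 0) ? c0 : c1;
    std::copy(src + lo, src + L, dst + lo);
  }
}

}  // namespace

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(List haps, List pos_morgan, NumericVector map_len,
                   IntegerVector schedule, int monogamy, double mu) {
  const int n_chr = haps.size();
  std::vector<IntegerMatrix> cur(n_chr);
  for (int c = 0; c < n_chr; ++c) cur[c] = as<IntegerMatrix>(haps[c]);

  IntegerVector fathers, mothers, fathers_prev, mothers_prev;

  for (int g = 0; g < schedule.size(); ++g) {
    const int n_cur = cur[0].ncol() / 2;
    const int n_next = schedule[g];
    IntegerVector fa(n_next), mo(n_next);
    if (monogamy) {
      const int n_couples = n_cur / 2;
      IntegerVector perm = sample(n_cur, n_cur, false);  // 1-based
      for (int i = 0; i < n_next; ++i) {
        int cpl = static_cast<int>(unif_rand() * n_couples);
        if (cpl == n_couples) cpl = n_couples - 1;
        fa[i] = perm[2 * cpl] - 1;
        mo[i] = perm[2 * cpl + 1] - 1;
      }
    } else {
      for (int i = 0; i < n_next; ++i) {
        fa[i] = static_cast<int>(unif_rand() * n_cur);
        if (fa[i] == n_cur) fa[i] = n_cur - 1;
        mo[i] = static_cast<int>(unif_rand() * n_cur);
        if (mo[i] == n_cur) mo[i] = n_cur - 1;
      }
    }
    for (int c = 0; c < n_chr; ++c) {
      const int L = cur[c].nrow();
      IntegerMatrix nxt(L, 2 * n_next);
      const NumericVector& pos = pos_morgan[c];
      for (int i = 0; i < n_next; ++i) {
        make_gamete(cur[c], pos, map_len[c], fa[i], nxt, 2 * i);
        make_gamete(cur[c], pos, map_len[c], mo[i], nxt, 2 * i + 1);
      }
      if (mu > 0) {
        const double total = static_cast<double>(L) * 2.0 * n_next;
        int n_mut = static_cast<int>(R::rbinom(total, mu));
        int* dat = nxt.begin();
        for (int k = 0; k < n_mut; ++k) {
          int idx = static_cast<int>(unif_rand() * total);
          if (idx >= total) idx = static_cast<int>(total) - 1;
          dat[idx] = 1 - dat[idx];
        }
      }
      cur[c] = nxt;
    }
    fathers_prev = fathers;
    mothers_prev = mothers;
    fathers = fa;
    mothers = mo;
  }

  List out_haps(n_chr);
  for (int c = 0; c < n_chr; ++c) out_haps[c] = cur[c];
  return List::create(
    _["haps"] = out_haps,
    _["fathers"] = fathers, _["mothers"] = mothers,
    _["fathers_prev"] = fathers_prev, _["mothers_prev"] = mothers_prev);
}
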