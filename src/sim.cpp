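// Gamete formation and the constant-size historical population loop.
//
// Haplotypes are integer matrices (loci x haplotype columns, alleles 0/1);
// individual i owns columns 2i-1 and 2i (1-based).  Crossovers follow the
// Haldane model: Poisson(count = map length in Morgans) breakpoints placed
// uniformly on the Morgan scale, no interference.  Mutation flips each
// allele independently with a fixed per-locus per-meiosis probability.
// All randomness comes from R's RNG (reproducible via set.seed()).

#include <Rcpp.h>
using namespace Rcpp;

// write one gamete from parental haplotype columns c1, c2 (0-based) into out
static void make_gamete(const IntegerMatrix& hap, int c1, int c2,
                        const NumericVector& pos,
                        const IntegerVector& chr_first, const IntegerVector& chr_last,
                        const NumericVector& chr_len, double mu,
                        IntegerMatrix& out, int out_col) {
  const int n_chr = chr_len.size();
  const int L = pos.size();
  const int *h1 = &hap(0, c1), *h2 = &hap(0, c2);
  int *o = &out(0, out_col);
  const double *pp = &pos[0];
  std::vector<double> bp;
  for (int c = 0; c < n_chr; ++c) {
    int f = chr_first[c] - 1, l = chr_last[c] - 1;
    int ncx = (int)R::rpois(chr_len[c]);
    bp.clear();
    for (int k = 0; k < ncx; ++k) bp.push_back(unif_rand() * chr_len[c]);
    std::sort(bp.begin(), bp.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int i = f;
    for (size_t bi = 0; bi <= bp.size(); ++bi) {
      // segment end: first locus index past the breakpoint (or chromosome end)
      int e = (bi < bp.size())
        ? (int)(std::upper_bound(pp + i, pp + l + 1, bp[bi]) - pp)
        : l + 1;
      const int *src = (cur == 0) ? h1 : h2;
      std::copy(src + i, src + e, o + i);
      i = e;
      cur ^= 1;
    }
  }
  if (mu > 0.0) {
    int nmut = (int)R::rbinom((double)L, mu);
    for (int k = 0; k < nmut; ++k) {
      int i = (int)(unif_rand() * L);
      if (i >= L) i = L - 1;
      o[i] ^= 1;
    }
  }
}

// gametes for arbitrary parent haplotype column pairs (par_cols is n_gam x 2,
// 1-based column indices into hap); returns loci x n_gam matrix
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hap, const IntegerMatrix& par_cols,
                          const NumericVector& pos,
                          const IntegerVector& chr_first, const IntegerVector& chr_last,
                          const NumericVector& chr_len, double mu) {
  const int L = hap.nrow(), G = par_cols.nrow();
  IntegerMatrix out(L, G);
  for (int g = 0; g < G; ++g)
    make_gamete(hap, par_cols(g, 0) - 1, par_cols(g, 1) - 1,
                pos, chr_first, chr_last, chr_len, mu, out, g);
  return out;
}

// Fisher-Yates shuffle of 0..n-1 using R's RNG
static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// Constant-size history: N/2 males (individuals 0 .. N/2-1) and N/2 females
// mate in random monogamous pairs, each pair leaving one male and one female
// offspring, for n_gen non-overlapping generations.  Sex layout is preserved
// (first half of the individuals male).  Returns the final generation.
// [[Rcpp::export]]
IntegerMatrix cpp_evolve_history(const IntegerMatrix& hap0, int n_gen,
                                 const NumericVector& pos,
                                 const IntegerVector& chr_first, const IntegerVector& chr_last,
                                 const NumericVector& chr_len, double mu) {
  const int L = hap0.nrow(), H = hap0.ncol(), N = H / 2, half = N / 2;
  if (H % 2 || N % 2) stop("haplotype count must give an even number of individuals");
  IntegerMatrix cur = clone(hap0), nxt(L, H);
  std::vector<int> males(half), females(half);
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < half; ++i) { males[i] = i; females[i] = half + i; }
    shuffle_idx(males); shuffle_idx(females);
    for (int p = 0; p < half; ++p) {
      int sc = 2 * males[p], dc = 2 * females[p];
      // offspring p (male) and half + p (female): sire gamete then dam gamete
      for (int off = 0; off < 2; ++off) {
        int oc = 2 * (off == 0 ? p : half + p);
        make_gamete(cur, sc, sc + 1, pos, chr_first, chr_last, chr_len, mu, nxt, oc);
        make_gamete(cur, dc, dc + 1, pos, chr_first, chr_last, chr_len, mu, nxt, oc + 1);
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
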