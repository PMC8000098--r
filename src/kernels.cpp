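#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Site positions are in centimorgans, sorted within chromosome. Crossover
// counts are Poisson(length_cM / 100) with positions uniform on the map
// (no interference, Haldane model).

static inline int draw_parent(int n) {
  // uniform diploid index in [0, n)
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Copy one recombinant gamete from two parental haplotype arrays into `out`.
// h1/h2 are arrays over `n` sites with map positions pos_cM (ascending),
// chromosome total length len_cM.
static void meiosis_into(const unsigned char *h1, const unsigned char *h2,
                         const double *pos_cM, int n, double len_cM,
                         unsigned char *out) {
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (len_cM <= 0.0 || n == 0) {
    const unsigned char *src = cur ? h2 : h1;
    std::copy(src, src + n, out);
    return;
  }
  int nxo = (int)R::rpois(len_cM / 100.0);
  if (nxo == 0) {
    const unsigned char *src = cur ? h2 : h1;
    std::copy(src, src + n, out);
    return;
  }
  std::vector<double> xo(nxo);
  for (int i = 0; i < nxo; ++i) xo[i] = unif_rand() * len_cM;
  std::sort(xo.begin(), xo.end());
  int lo = 0;
  for (int i = 0; i < nxo; ++i) {
    // sites with pos < xo[i] keep current haplotype
    int hi = (int)(std::lower_bound(pos_cM + lo, pos_cM + n, xo[i]) - pos_cM);
    const unsigned char *src = cur ? h2 : h1;
    std::copy(src + lo, src + hi, out + lo);
    lo = hi;
    cur = 1 - cur;
  }
  const unsigned char *src = cur ? h2 : h1;
  std::copy(src + lo, src + n, out + lo);
}

// [[Rcpp::export(name = ".wf_burnin_chr")]]
RawMatrix wf_burnin_chr(int n_sites, NumericVector site_cM, double len_cM,
                        double mu_site, IntegerVector epoch_gens,
                        IntegerVector epoch_ne, int n_out) {
  if (n_out % 2 != 0) stop("n_out must be even");
  if (epoch_gens.size() != epoch_ne.size()) stop("epoch length mismatch");
  // population buffers: haplotypes x sites, row-contiguous per haplotype
  int ne0 = epoch_ne[0];
  std::vector<unsigned char> pop((size_t)2 * ne0 * n_sites, 0), nxt;
  int cur_n = 2 * ne0; // haplotype count in `pop`
  const double *pos = REAL(site_cM);
  // epoch generations, then one terminal expansion generation to n_out
  int n_epochs = epoch_gens.size();
  for (int e = 0; e <= n_epochs; ++e) {
    int gens = (e < n_epochs) ? epoch_gens[e] : 1;
    int n_child = (e < n_epochs) ? 2 * epoch_ne[e] : n_out;
    for (int g = 0; g < gens; ++g) {
      nxt.assign((size_t)n_child * n_sites, 0);
      int n_par_dip = cur_n / 2;
      for (int c = 0; c < n_child; ++c) {
        int p = draw_parent(n_par_dip);
        unsigned char *out = nxt.data() + (size_t)c * n_sites;
        meiosis_into(pop.data() + (size_t)(2 * p) * n_sites,
                     pop.data() + (size_t)(2 * p + 1) * n_sites,
                     pos, n_sites, len_cM, out);
        if (mu_site > 0) {
          int nm = (int)R::rbinom((double)n_sites, mu_site);
          for (int m = 0; m < nm; ++m) {
            int s = draw_parent(n_sites);
            out[s] = 1 - out[s];
          }
        }
      }
      pop.swap(nxt);
      cur_n = n_child;
    }
  }
  RawMatrix res(n_out, n_sites);
  for (int i = 0; i < n_out; ++i)
    for (int j = 0; j < n_sites; ++j)
      res(i, j) = pop[(size_t)i * n_sites + j];
  return res;
}

// Single-gamete meiosis for one genome (all chromosomes concatenated).
// chr_start: 0-based offsets of chromosome starts (length C), chr_len_cM per
// chromosome; h1/h2 raw vectors over all sites.
// [[Rcpp::export(name = ".meiosis_genome")]]
RawVector meiosis_genome(RawVector h1, RawVector h2, NumericVector site_cM,
                         IntegerVector chr_start, NumericVector chr_len_cM) {
  int S = h1.size();
  RawVector out(S);
  int C = chr_start.size();
  for (int c = 0; c < C; ++c) {
    int lo = chr_start[c];
    int hi = (c + 1 < C) ? chr_start[c + 1] : S;
    meiosis_into(&h1[0] + lo, &h2[0] + lo, REAL(site_cM) + lo, hi - lo,
                 chr_len_cM[c], &out[0] + lo);
  }
  return out;
}

// Batch gene drop: for each offspring, one meiosis per parent.
// hapA/hapB: parental gametes (n_parent x S raw matrices, rows = parents).
// sire_row/dam_row: 0-based rows per offspring.
// Returns list(pat, mat): offspring gamete matrices (n_off x S).
// [[Rcpp::export(name = ".gene_drop")]]
List gene_drop(RawMatrix hapA, RawMatrix hapB, IntegerVector sire_row,
               IntegerVector dam_row, NumericVector site_cM,
               IntegerVector chr_start, NumericVector chr_len_cM) {
  int S = hapA.ncol();
  int n_off = sire_row.size();
  int C = chr_start.size();
  RawMatrix pat(n_off, S), mat(n_off, S);
  // row-major scratch: RawMatrix is column-major, so stage rows in vectors
  std::vector<unsigned char> p1(S), p2(S), g(S);
  for (int i = 0; i < n_off; ++i) {
    for (int side = 0; side < 2; ++side) {
      int r = side == 0 ? sire_row[i] : dam_row[i];
      for (int j = 0; j < S; ++j) { p1[j] = hapA(r, j); p2[j] = hapB(r, j); }
      for (int c = 0; c < C; ++c) {
        int lo = chr_start[c];
        int hi = (c + 1 < C) ? chr_start[c + 1] : S;
        meiosis_into(p1.data() + lo, p2.data() + lo, REAL(site_cM) + lo,
                     hi - lo, chr_len_cM[c], g.data() + lo);
      }
      if (side == 0) for (int j = 0; j < S; ++j) pat(i, j) = g[j];
      else           for (int j = 0; j < S; ++j) mat(i, j) = g[j];
    }
  }
  return List::create(Named("pat") = pat, Named("mat") = mat);
}

// [[Rcpp::export(name = ".dosage_from_gametes")]]
IntegerMatrix dosage_from_gametes(RawMatrix pat, RawMatrix mat) {
  int n = pat.nrow(), S = pat.ncol();
  IntegerMatrix d(n, S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < n; ++i)
      d(i, j) = (int)pat(i, j) + (int)mat(i, j);
  return d;
}

// Tabular relationship recursion: A[j,i] = (A[j,s]+A[j,d])/2 for j < i,
// A[i,i] = 1 + A[s,d]/2; sire/dam are 0-based row indices or -1 if unknown,
// and must precede their offspring.
// [[Rcpp::export(name = ".tabular_a_cpp")]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s >= i || d >= i) stop("pedigree is not topologically ordered");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Gamete-origin Viterbi for one animal: joint 4-state path (sire haplotype x
// dam haplotype) over the animal's typed sites, scored by
// |dosage - a_sire - a_dam| with parental soft alleles, switch penalty per
// parental haplotype change. Untyped sites take the state of the nearest typed
// site (cM midpoint split); chromosomes without typed sites fall back to the
// parental genotype mean. Returns the two inferred gametes (soft alleles).
// sh1, sh2, dh1, dh2: parental soft haplotypes over all S sites (values in
// [0,1]; callers substitute the population frequency where phase is unknown).
// [[Rcpp::export(name = ".impute_duo")]]
List impute_duo(IntegerVector typed_idx, NumericVector typed_dos,
                NumericVector sh1, NumericVector sh2, NumericVector dh1,
                NumericVector dh2, NumericVector site_cM,
                IntegerVector chr_start, double switch_penalty) {
  int S = sh1.size();
  int C = chr_start.size();
  NumericVector gp(S), gm(S);       // paternal, maternal inferred gametes
  IntegerVector state(S);           // 0..3: (sire hap, dam hap)
  int T = typed_idx.size();
  const double *cm = REAL(site_cM);

  int t0 = 0; // cursor into typed_idx (ascending)
  for (int c = 0; c < C; ++c) {
    int lo = chr_start[c];
    int hi = (c + 1 < C) ? chr_start[c + 1] : S;
    // typed sites on this chromosome
    int ta = t0;
    while (t0 < T && typed_idx[t0] < hi) ++t0;
    int tb = t0; // typed sites are typed_idx[ta..tb)
    int nt = tb - ta;
    if (nt == 0) {
      for (int j = lo; j < hi; ++j) {
        gp[j] = 0.5 * (sh1[j] + sh2[j]);
        gm[j] = 0.5 * (dh1[j] + dh2[j]);
        state[j] = -1;
      }
      continue;
    }
    // Viterbi over typed sites, 4 states
    std::vector<double> cost(4, 0.0), ncost(4);
    std::vector<int> bp((size_t)nt * 4);
    for (int t = 0; t < nt; ++t) {
      int j = typed_idx[ta + t];
      double d = typed_dos[ta + t];
      double em[4];
      em[0] = std::fabs(d - sh1[j] - dh1[j]);
      em[1] = std::fabs(d - sh1[j] - dh2[j]);
      em[2] = std::fabs(d - sh2[j] - dh1[j]);
      em[3] = std::fabs(d - sh2[j] - dh2[j]);
      for (int s = 0; s < 4; ++s) {
        if (t == 0) { ncost[s] = em[s]; bp[t * 4 + s] = s; continue; }
        double best = R_PosInf; int barg = 0;
        for (int q = 0; q < 4; ++q) {
          int nsw = ((q & 2) != (s & 2)) + ((q & 1) != (s & 1));
          double v = cost[q] + switch_penalty * nsw;
          if (v < best) { best = v; barg = q; }
        }
        ncost[s] = best + em[s];
        bp[t * 4 + s] = barg;
      }
      cost = ncost;
    }
    std::vector<int> path(nt);
    int s = 0;
    for (int q = 1; q < 4; ++q) if (cost[q] < cost[s]) s = q;
    for (int t = nt - 1; t >= 0; --t) { path[t] = s; s = bp[t * 4 + s]; }
    // assign states to all sites: nearest typed site by cM midpoint
    int t = 0;
    for (int j = lo; j < hi; ++j) {
      while (t + 1 < nt) {
        double mid = 0.5 * (cm[typed_idx[ta + t]] + cm[typed_idx[ta + t + 1]]);
        if (cm[j] > mid) ++t; else break;
      }
      int st = path[t];
      state[j] = st;
      gp[j] = (st & 2) ? sh2[j] : sh1[j];
      gm[j] = (st & 1) ? dh2[j] : dh1[j];
    }
  }
  // typed sites: exact dosage; re-normalise the phase split
  for (int t = 0; t < T; ++t) {
    int j = typed_idx[t];
    double d = typed_dos[t];
    if (d <= 0.0) { gp[j] = 0.0; gm[j] = 0.0; }
    else if (d >= 2.0) { gp[j] = 1.0; gm[j] = 1.0; }
    else {
      double tot = gp[j] + gm[j];
      if (tot <= 0.0 || tot >= 2.0) { gp[j] = 0.5; gm[j] = 0.5; }
      else {
        double a = gp[j] * d / tot;
        double b = d - a;
        if (a > 1.0) { b += a - 1.0; a = 1.0; }
        if (b > 1.0) { a += b - 1.0; b = 1.0; }
        gp[j] = a; gm[j] = b;
      }
    }
  }
  return List::create(Named("pat") = gp, Named("mat") = gm,
                      Named("state") = state);
}
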