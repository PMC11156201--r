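#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One generation of a diploid Wright-Fisher population under viability
// selection, partial selfing and free recombination ("independent sites").
//
// The parental state is the row-concatenation of G (existing sites x
// individuals dosage matrix, values 0/1/2) and `extra` (sites newly
// activated this generation, same column layout).  `addRow`/`addCol`
// (0-based) are recurrent-mutation events: one more copy of the derived
// allele for individual addCol at site addRow (ignored at dosage 2).
// Fitness is multiplicative across sites: 1, 1-h*s, 1-s for dosage 0/1/2
// (clamped at 0).  Each of nOffspring offspring draws parent 1
// proportionally to fitness; with probability `selfing` parent 2 is the
// same individual, otherwise an independent fitness-weighted draw.  Each
// parent transmits one allele per site independently (Mendelian, no
// linkage).  Returns a (sites x nOffspring) matrix; 0x0 signals total
// fitness zero (extinction), which the caller turns into an error.
//
// [[Rcpp::export]]
IntegerMatrix wf_next_generation(const IntegerMatrix& G,
                                 const IntegerMatrix& extra,
                                 const IntegerVector& addRow,
                                 const IntegerVector& addCol,
                                 const NumericVector& s,
                                 const NumericVector& h,
                                 const double selfing,
                                 const int nOffspring) {
  const int S0 = G.nrow(), K = extra.nrow(), N = G.ncol();
  const int S = S0 + K;
  if (K > 0 && extra.ncol() != N) stop("extra must have the same columns as G");
  if (s.size() != S || h.size() != S)
    stop("selection coefficient vectors must match the number of sites");
  if (N < 1) stop("empty parental population");

  std::vector<int> W((size_t)S * N);
  for (int i = 0; i < N; ++i) {
    int* wc = W.data() + (size_t)i * S;
    const int* gc = G.begin() + (R_xlen_t)i * S0;
    std::copy(gc, gc + S0, wc);
    const int* ec = extra.begin() + (R_xlen_t)i * K;
    std::copy(ec, ec + K, wc + S0);
  }
  for (int m = 0; m < addRow.size(); ++m) {
    int& g = W[(size_t)addCol[m] * S + addRow[m]];
    if (g < 2) ++g;
  }

  // most sites are rare variants, so per-individual nonzero-site lists make
  // both the fitness pass and gamete formation sparse
  std::vector<std::vector<int>> nz(N);
  std::vector<double> cumw(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    const int* col = W.data() + (size_t)i * S;
    std::vector<int>& nzi = nz[i];
    for (int j = 0; j < S; ++j) {
      const int g = col[j];
      if (g == 0) continue;
      nzi.push_back(j);
      if (g == 1) w *= 1.0 - h[j] * s[j];
      else w *= 1.0 - s[j];
    }
    if (w < 0.0) w = 0.0;
    tot += w;
    cumw[i] = tot;
  }
  if (tot <= 0.0) return IntegerMatrix(0, 0);

  IntegerMatrix out(S, nOffspring);  // zero-initialized
  for (int i = 0; i < nOffspring; ++i) {
    const double u1 = unif_rand() * tot;
    const int p1 = (int)(std::lower_bound(cumw.begin(), cumw.end(), u1) -
                         cumw.begin());
    int p2 = p1;
    if (unif_rand() >= selfing) {
      const double u2 = unif_rand() * tot;
      p2 = (int)(std::lower_bound(cumw.begin(), cumw.end(), u2) -
                 cumw.begin());
    }
    int* oc = out.begin() + (R_xlen_t)i * S;
    const int* c1 = W.data() + (size_t)p1 * S;
    for (int j : nz[p1]) {
      const int g = c1[j];
      oc[j] += (g == 2) ? 1 : (unif_rand() < 0.5);
    }
    const int* c2 = W.data() + (size_t)p2 * S;
    for (int j : nz[p2]) {
      const int g = c2[j];
      oc[j] += (g == 2) ? 1 : (unif_rand() < 0.5);
    }
  }
  return out;
}

// Same update for a single non-recombining block.  H and extra are
// (sites x 2N) 0/1 haplotype matrices with individual i owning columns 2i
// and 2i+1 (0-based); addCol indexes haplotype columns.  A gamete is an
// intact copy of one randomly chosen parental haplotype.  Returns
// (sites x 2*nOffspring); 0x0 signals extinction.
//
// [[Rcpp::export]]
IntegerMatrix wf_next_generation_block(const IntegerMatrix& H,
                                       const IntegerMatrix& extra,
                                       const IntegerVector& addRow,
                                       const IntegerVector& addCol,
                                       const NumericVector& s,
                                       const NumericVector& h,
                                       const double selfing,
                                       const int nOffspring) {
  const int S0 = H.nrow(), K = extra.nrow();
  const int S = S0 + K;
  const int M = H.ncol();
  const int N = M / 2;
  if (M != 2 * N || N < 1) stop("haplotype matrix must have 2N columns");
  if (K > 0 && extra.ncol() != M) stop("extra must have the same columns as H");
  if (s.size() != S || h.size() != S)
    stop("selection coefficient vectors must match the number of sites");

  std::vector<int> W((size_t)S * M);
  for (int i = 0; i < M; ++i) {
    int* wc = W.data() + (size_t)i * S;
    const int* gc = H.begin() + (R_xlen_t)i * S0;
    std::copy(gc, gc + S0, wc);
    const int* ec = extra.begin() + (R_xlen_t)i * K;
    std::copy(ec, ec + K, wc + S0);
  }
  for (int m = 0; m < addRow.size(); ++m) {
    W[(size_t)addCol[m] * S + addRow[m]] = 1;
  }

  std::vector<double> cumw(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    const int* h1 = W.data() + (size_t)(2 * i) * S;
    const int* h2 = W.data() + (size_t)(2 * i + 1) * S;
    for (int j = 0; j < S; ++j) {
      const int g = h1[j] + h2[j];
      if (g == 1) w *= 1.0 - h[j] * s[j];
      else if (g == 2) w *= 1.0 - s[j];
    }
    if (w < 0.0) w = 0.0;
    tot += w;
    cumw[i] = tot;
  }
  if (tot <= 0.0) return IntegerMatrix(0, 0);

  IntegerMatrix out(S, 2 * nOffspring);
  for (int i = 0; i < nOffspring; ++i) {
    const double u1 = unif_rand() * tot;
    const int p1 = (int)(std::lower_bound(cumw.begin(), cumw.end(), u1) -
                         cumw.begin());
    int p2 = p1;
    if (unif_rand() >= selfing) {
      const double u2 = unif_rand() * tot;
      p2 = (int)(std::lower_bound(cumw.begin(), cumw.end(), u2) -
                 cumw.begin());
    }
    const int g1 = 2 * p1 + (unif_rand() < 0.5);
    const int g2 = 2 * p2 + (unif_rand() < 0.5);
    std::copy(W.data() + (size_t)g1 * S, W.data() + (size_t)(g1 + 1) * S,
              out.begin() + (R_xlen_t)(2 * i) * S);
    std::copy(W.data() + (size_t)g2 * S, W.data() + (size_t)(g2 + 1) * S,
              out.begin() + (R_xlen_t)(2 * i + 1) * S);
  }
  return out;
}
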