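#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard-swap Markov chain over 0/1 matrices with fixed margins.
// Uses R's RNG (unif_rand) so results are governed by set.seed().
static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void attempt_swaps(IntegerMatrix cur, int n_attempts, int nr, int nc) {
  for (int a = 0; a < n_attempts; ++a) {
    int r1 = rand_int(nr);
    int r2 = rand_int(nr - 1);
    if (r2 >= r1) ++r2;
    int c1 = rand_int(nc);
    int c2 = rand_int(nc - 1);
    if (c2 >= c1) ++c2;
    int a11 = cur(r1, c1), a12 = cur(r1, c2);
    int a21 = cur(r2, c1), a22 = cur(r2, c2);
    if (a11 == 1 && a22 == 1 && a12 == 0 && a21 == 0) {
      cur(r1, c1) = 0; cur(r2, c2) = 0; cur(r1, c2) = 1; cur(r2, c1) = 1;
    } else if (a11 == 0 && a22 == 0 && a12 == 1 && a21 == 1) {
      cur(r1, c1) = 1; cur(r2, c2) = 1; cur(r1, c2) = 0; cur(r2, c1) = 0;
    }
  }
}

// [[Rcpp::export]]
List swap_chain_cpp(IntegerMatrix m, int n_draws, int burn_in, int thin) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix cur = clone(m);
  List out(n_draws);
  attempt_swaps(cur, burn_in, nr, nc);
  for (int d = 0; d < n_draws; ++d) {
    if (d > 0) attempt_swaps(cur, thin, nr, nc);
    out[d] = clone(cur);
  }
  return out;
}

// Per-row mean pairwise distance; NA when richness < 2.
// [[Rcpp::export]]
NumericVector mpd_rows_cpp(IntegerMatrix comm, NumericMatrix d) {
  int nr = comm.nrow(), nc = comm.ncol();
  NumericVector out(nr);
  std::vector<int> idx;
  for (int i = 0; i < nr; ++i) {
    idx.clear();
    for (int j = 0; j < nc; ++j) if (comm(i, j) > 0) idx.push_back(j);
    int k = idx.size();
    if (k < 2) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        s += d(idx[a], idx[b]);
    out[i] = s / (k * (k - 1) / 2.0);
  }
  return out;
}

// Per-row mean nearest-neighbour distance; NA when richness < 2.
// [[Rcpp::export]]
NumericVector mntd_rows_cpp(IntegerMatrix comm, NumericMatrix d) {
  int nr = comm.nrow(), nc = comm.ncol();
  NumericVector out(nr);
  std::vector<int> idx;
  for (int i = 0; i < nr; ++i) {
    idx.clear();
    for (int j = 0; j < nc; ++j) if (comm(i, j) > 0) idx.push_back(j);
    int k = idx.size();
    if (k < 2) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int a = 0; a < k; ++a) {
      double mn = R_PosInf;
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double v = d(idx[a], idx[b]);
        if (v < mn) mn = v;
      }
      s += mn;
    }
    out[i] = s / k;
  }
  return out;
}
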