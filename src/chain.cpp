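#include <Rcpp.h>
using namespace Rcpp;

// Draw an integer uniformly from {0, ..., n-1} using R's RNG so that results
// are governed by set.seed() on the R side.
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k == n) k = n - 1;  // guard against unif_rand() == 1.0
  return k;
}

// One checkerboard proposal on a binary matrix: pick a random row pair and
// column pair; if the 2x2 submatrix is a checkerboard (and, when strata are
// given, both rows share a stratum) flip it, otherwise leave the matrix
// unchanged. Row and column sums are preserved in either case.
static inline void checkerboard_propose(IntegerMatrix m,
                                        const IntegerVector &strata,
                                        bool use_strata) {
  const int nr = m.nrow(), nc = m.ncol();
  int i1 = runif_int(nr);
  int i2 = runif_int(nr - 1);
  if (i2 >= i1) i2++;
  int j1 = runif_int(nc);
  int j2 = runif_int(nc - 1);
  if (j2 >= j1) j2++;
  if (use_strata && strata[i1] != strata[i2]) return;
  const int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
  if ((a == 1 && d == 1 && b == 0 && c == 0) ||
      (a == 0 && d == 0 && b == 1 && c == 1)) {
    m(i1, j1) = 1 - a;
    m(i1, j2) = 1 - b;
    m(i2, j1) = 1 - c;
    m(i2, j2) = 1 - d;
  }
}

// [[Rcpp::export(name = ".chain_run")]]
IntegerMatrix chain_run(IntegerMatrix mat, int nsteps, IntegerVector strata) {
  IntegerMatrix m = clone(mat);
  const bool use_strata = strata.size() > 0;
  if (use_strata && strata.size() != m.nrow())
    stop("strata length must equal the number of rows");
  for (int s = 0; s < nsteps; s++) {
    checkerboard_propose(m, strata, use_strata);
  }
  return m;
}

// Run the chain recording, after every step, the matrix state packed into the
// bits of an integer (column-major). Only valid for matrices with at most 30
// cells; used by small-matrix uniformity diagnostics.
// [[Rcpp::export(name = ".chain_run_packed")]]
IntegerVector chain_run_packed(IntegerMatrix mat, int nsteps,
                               IntegerVector strata) {
  IntegerMatrix m = clone(mat);
  const int ncell = m.nrow() * m.ncol();
  if (ncell > 30) stop("packed recording supports at most 30 cells");
  const bool use_strata = strata.size() > 0;
  IntegerVector out(nsteps);
  for (int s = 0; s < nsteps; s++) {
    checkerboard_propose(m, strata, use_strata);
    int code = 0;
    for (int k = 0; k < ncell; k++) {
      if (m[k]) code |= (1 << k);
    }
    out[s] = code;
  }
  return out;
}

// Preference swaps (simulator step 3). `mat` is a clusters x species binary
// matrix; `target_rel` the observed relative association strengths (upper
// triangle used, normalized to sum 1, or all zero). Performs k proposals:
// pick two distinct clusters and one species occurrence in each and swap
// them; reject if the swap would duplicate a species within a cluster or
// strictly increase the sum of squared differences between simulated and
// target relative association strengths. Cluster sizes and per-species
// occurrence totals are invariant; the difference score never increases.
// [[Rcpp::export(name = ".preference_swaps")]]
List preference_swaps(IntegerMatrix mat, NumericMatrix target_rel, int k) {
  IntegerMatrix m = clone(mat);
  const int nr = m.nrow(), nc = m.ncol();
  if (target_rel.nrow() != nc || target_rel.ncol() != nc)
    stop("target_rel must be a square matrix over the species set");
  if (nr < 2) stop("need at least two clusters to swap");

  // co-occurrence counts and total (total is invariant: cluster sizes fixed)
  NumericMatrix w(nc, nc);
  std::vector<int> rowsize(nr);
  for (int i = 0; i < nr; i++) {
    int sz = 0;
    for (int j = 0; j < nc; j++) sz += m(i, j);
    rowsize[i] = sz;
    for (int j1 = 0; j1 < nc; j1++) {
      if (!m(i, j1)) continue;
      for (int j2 = j1 + 1; j2 < nc; j2++) {
        if (m(i, j2)) { w(j1, j2) += 1.0; w(j2, j1) += 1.0; }
      }
    }
  }
  double total = 0.0;
  for (int j1 = 0; j1 < nc; j1++)
    for (int j2 = j1 + 1; j2 < nc; j2++) total += w(j1, j2);
  const double denom = total > 0 ? total : 1.0;

  double D = 0.0;
  for (int j1 = 0; j1 < nc; j1++) {
    for (int j2 = j1 + 1; j2 < nc; j2++) {
      double diff = w(j1, j2) / denom - target_rel(j1, j2);
      D += diff * diff;
    }
  }

  NumericVector d_trace(k);
  int accepted = 0;

  // scratch for the pairs touched by one proposal
  std::vector<int> touched_i, touched_j;
  NumericMatrix delta(nc, nc);

  for (int s = 0; s < k; s++) {
    int a = runif_int(nr);
    int b = runif_int(nr - 1);
    if (b >= a) b++;
    // random occurrence (species) in each cluster
    int xi = runif_int(rowsize[a]);
    int x = -1;
    for (int j = 0; j < nc; j++) {
      if (m(a, j)) { if (xi == 0) { x = j; break; } xi--; }
    }
    int yi = runif_int(rowsize[b]);
    int y = -1;
    for (int j = 0; j < nc; j++) {
      if (m(b, j)) { if (yi == 0) { y = j; break; } yi--; }
    }
    if (x == y) { d_trace[s] = D; continue; }           // no-op swap
    if (m(a, y) || m(b, x)) { d_trace[s] = D; continue; } // would duplicate

    // accumulate count deltas on the pairs involving x or y in a or b
    touched_i.clear(); touched_j.clear();
    auto touch = [&](int p, int q, double dv) {
      int i = p < q ? p : q, j = p < q ? q : p;
      if (delta(i, j) == 0.0) { touched_i.push_back(i); touched_j.push_back(j); }
      delta(i, j) += dv;
    };
    for (int j = 0; j < nc; j++) {
      if (j != x && m(a, j)) { touch(x, j, -1.0); touch(y, j, +1.0); }
      if (j != y && m(b, j)) { touch(y, j, -1.0); touch(x, j, +1.0); }
    }
    double dD = 0.0;
    for (size_t t = 0; t < touched_i.size(); t++) {
      int i = touched_i[t], j = touched_j[t];
      double dv = delta(i, j);
      if (dv != 0.0) {
        double olddiff = w(i, j) / denom - target_rel(i, j);
        double newdiff = (w(i, j) + dv) / denom - target_rel(i, j);
        dD += newdiff * newdiff - olddiff * olddiff;
      }
    }
    if (dD <= 1e-12) {  // accept (ties accepted; strict increase reversed)
      for (size_t t = 0; t < touched_i.size(); t++) {
        int i = touched_i[t], j = touched_j[t];
        w(i, j) += delta(i, j);
        w(j, i) = w(i, j);
      }
      m(a, x) = 0; m(a, y) = 1;
      m(b, y) = 0; m(b, x) = 1;
      D += dD;
      if (D < 0) D = 0;  // guard against rounding drift
      accepted++;
    }
    for (size_t t = 0; t < touched_i.size(); t++)
      delta(touched_i[t], touched_j[t]) = 0.0;
    d_trace[s] = D;
  }

  return List::create(_["matrix"] = m, _["d_trace"] = d_trace,
                      _["accepted"] = accepted);
}
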