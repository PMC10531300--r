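#include <Rcpp.h>
using namespace Rcpp;

// Genealogy samplers for expected branch-length spectra. Time is measured in
// units of 2N generations (N = reference population size, see R wrappers).
// Each sampler accumulates, per allele-count class i, the total branch
// length subtending exactly i sampled leaves, and returns its Monte-Carlo
// mean and the standard error of that mean over replicates. Uses R's RNG so
// results are reproducible under set.seed().

// Two-deme structured coalescent with symmetric scaled migration rate M
// (per-lineage migration rate M/2, within-deme pair coalescence rate 1 per
// unit time, equal deme sizes). All n lineages are sampled from deme 0.
// [[Rcpp::export]]
NumericMatrix sim_subdivision_branch(int n, double M, int reps) {
  if (n < 2 || reps < 1 || M <= 0.0) stop("invalid sampler parameters");
  NumericVector sum(n - 1), sumsq(n - 1), cur(n - 1);
  std::vector<int> deme(n), leaves(n);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) { deme[i] = 0; leaves[i] = 1; }
    std::fill(cur.begin(), cur.end(), 0.0);
    while (k > 1) {
      int k0 = 0;
      for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k0;
      int k1 = k - k0;
      double rc0 = k0 * (k0 - 1) / 2.0;
      double rc1 = k1 * (k1 - 1) / 2.0;
      double rm  = k * M / 2.0;
      double tot = rc0 + rc1 + rm;
      double t = R::rexp(1.0 / tot);
      for (int i = 0; i < k; ++i) cur[leaves[i] - 1] += t;
      double u = unif_rand() * tot;
      if (u < rc0 + rc1) {
        int d = (u < rc0) ? 0 : 1;
        int kd = (d == 0) ? k0 : k1;
        int a = (int)(unif_rand() * kd);
        int b = (int)(unif_rand() * (kd - 1));
        if (b >= a) ++b;
        // map within-deme ranks to lineage indices
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == d) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        }
        int lo = (ia < ib) ? ia : ib, hi = (ia < ib) ? ib : ia;
        leaves[lo] += leaves[hi];
        deme[lo] = d;
        leaves[hi] = leaves[k - 1];
        deme[hi] = deme[k - 1];
        --k;
      } else {
        int j = (int)(unif_rand() * k);
        deme[j] = 1 - deme[j];
      }
    }
    for (int i = 0; i < n - 1; ++i) {
      sum[i] += cur[i];
      sumsq[i] += cur[i] * cur[i];
    }
  }
  NumericMatrix out(2, n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double m = sum[i] / reps;
    double v = (sumsq[i] - reps * m * m) / (reps - 1.0);
    out(0, i) = m;
    out(1, i) = sqrt(v / reps);
  }
  return out;
}

// Single population with a stepwise size change: pair coalescence rate 1
// for t < T2 (recent epoch, reference size) and `growth` for t >= T2 (the
// ancestral population is `growth` times smaller). T2 in units of 2N.
// [[Rcpp::export]]
NumericMatrix sim_expansion_branch(int n, double T2, double growth, int reps) {
  if (n < 2 || reps < 1 || T2 < 0.0 || growth <= 0.0)
    stop("invalid sampler parameters");
  NumericVector sum(n - 1), sumsq(n - 1), cur(n - 1);
  std::vector<int> leaves(n);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) leaves[i] = 1;
    std::fill(cur.begin(), cur.end(), 0.0);
    double time = 0.0;
    while (k > 1) {
      double base = k * (k - 1) / 2.0;
      double mult = (time < T2) ? 1.0 : growth;
      double t = R::rexp(1.0 / (base * mult));
      if (time < T2 && time + t > T2) {
        // crossed the epoch boundary: accrue up to T2, then redraw
        double dt = T2 - time;
        for (int i = 0; i < k; ++i) cur[leaves[i] - 1] += dt;
        time = T2;
        continue;
      }
      for (int i = 0; i < k; ++i) cur[leaves[i] - 1] += t;
      time += t;
      int a = (int)(unif_rand() * k);
      int b = (int)(unif_rand() * (k - 1));
      if (b >= a) ++b;
      int lo = (a < b) ? a : b, hi = (a < b) ? b : a;
      leaves[lo] += leaves[hi];
      leaves[hi] = leaves[k - 1];
      --k;
    }
    for (int i = 0; i < n - 1; ++i) {
      sum[i] += cur[i];
      sumsq[i] += cur[i] * cur[i];
    }
  }
  NumericMatrix out(2, n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double m = sum[i] / reps;
    double v = (sumsq[i] - reps * m * m) / (reps - 1.0);
    out(0, i) = m;
    out(1, i) = sqrt(v / reps);
  }
  return out;
}
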