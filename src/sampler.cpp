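#include <Rcpp.h>
using namespace Rcpp;

// Abundances above this signal a near-critical x = b/d; the draw is aborted.
static const double ABUND_CAP = 1e9;
// Cap on consecutive zero rejections (only reachable when zeros are common,
// in which case CDF inversion is used instead, so this is a belt-and-braces
// guard).
static const int ZERO_REJECT_CAP = 1000000;
static const int MAX_BINS = 34;

// floor(log2(n)) for integral n >= 1, exact
static inline int ilog2(double v) {
  unsigned long long n = (unsigned long long)v;
  int b = 0;
  while (n >>= 1) ++b;
  return b;
}

// One zero-truncated NB draw with x = b/d, r = s/b.
// R's NB parametrization: size = r, prob = 1 - x.
// When P(X = 0) <= 0.5 rejection of zeros is cheap (expected <= 2 tries);
// otherwise zeros dominate and the truncated CDF is inverted directly by
// walking the pmf recurrence P(n+1)/P(n) = x (n + r) / (n + 1), whose
// expected cost is the (small) truncated mean, with a qnbinom fallback for
// the rare long excursions.
// Returns -1 when the rejection cap is exceeded.
static double draw_ztnb(double x, double r) {
  double p = 1.0 - x;
  double v;
  double log_p0 = r * log1p(-x);
  double p0 = exp(log_p0);
  if (p0 <= 0.5) {
    int tries = 0;
    do {
      v = R::rnbinom(r, p);
      if (++tries > ZERO_REJECT_CAP) return -1.0;
    } while (v < 1.0);
  } else {
    double u = unif_rand();
    double one_m_p0 = -expm1(log_p0);             // 1 - (1-x)^r, stable
    double pmf = r * x * p0 / one_m_p0;           // ZTNB pmf at n = 1
    double cum = pmf;
    double n = 1.0;
    while (cum < u && n < 2048.0) {
      pmf *= x * (n + r) / (n + 1.0);
      cum += pmf;
      n += 1.0;
    }
    if (cum < u) {                                 // deep tail: exact inversion
      v = R::qnbinom(p0 + u * one_m_p0, r, p, 1, 0);
      if (v < 1.0) v = 1.0;
    } else {
      v = n;
    }
  }
  return v;
}

static inline int pick_niche(const double *cw, int K) {
  if (K == 1) return 0;
  double u = unif_rand();
  int k = 0;
  while (k < K - 1 && u > cw[k]) ++k;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_sample_community(int n_obs, NumericVector x,
                                   NumericVector r, NumericVector w) {
  int K = x.size();
  double cw[3];
  double acc = 0.0;
  for (int k = 0; k < K; ++k) { acc += w[k]; cw[k] = acc; }
  NumericVector out(n_obs);
  RNGScope scope;
  for (int j = 0; j < n_obs; ++j) {
    int k = pick_niche(cw, K);
    double v = draw_ztnb(x[k], r[k]);
    if (v < 0.0)
      stop("zero-truncation rejection cap exceeded (x = %g, r = %g)", x[k], r[k]);
    if (v > ABUND_CAP)
      stop("sampled abundance %g exceeds cap 1e9 (x = %g, r = %g)", v, x[k], r[k]);
    out[j] = v;
  }
  return out;
}

// ABC rejection inner loop. For each proposal i: reseed the RNG with
// seeds[i] (so results are independent of proposal order and of early
// bailing), simulate a community of n_obs species, bin it into Preston
// octaves, and apply the two acceptance conditions:
//   1. per data-positive bin, |sim - data| <= bin_tol * data
//   2. chi2 = sum (d - s)^2 / (d + s) over bins with d + s > 0,
//      df = number of such bins (df_union) or of data-positive bins,
//      accept iff pchisq(chi2, df) < cutoff.
// Simulation bails out as soon as some data-positive bin exceeds its upper
// tolerance: counts only grow, so the proposal is already lost and, because
// the community is fully determined by its seed, bailing cannot change
// which proposals are accepted.
// status: 0 = bailed on condition 1, 1 = fully evaluated and rejected,
//         2 = accepted, 3 = aborted (sampling caps).
// [[Rcpp::export]]
DataFrame cpp_abc_loop(IntegerVector data_bins, int n_obs,
                       NumericMatrix x, NumericMatrix r, NumericMatrix w,
                       IntegerVector seeds, double bin_tol, double cutoff,
                       bool df_union, bool tol_total) {
  int n = x.nrow(), K = x.ncol(), nd = data_bins.size();
  Function set_seed("set.seed");

  // integer tolerance bounds per bin: the allowance is bin_tol times the
  // bin's own data count (per-bin reading) or times the total data count
  // (total reading, where only gross deviations violate condition 1)
  double total = 0.0;
  for (int i = 0; i < nd; ++i) total += data_bins[i];
  std::vector<int> up(nd), lo(nd);
  int up_beyond = n_obs + 1;  // bound for sim bins beyond the data bins
  for (int i = 0; i < nd; ++i) {
    double d = data_bins[i];
    double allow = bin_tol * (tol_total ? total : d);
    up[i] = (int)std::floor(d + allow + 1e-9);
    lo[i] = (int)std::ceil(d - allow - 1e-9);
    if (lo[i] < 0) lo[i] = 0;
  }
  if (tol_total) up_beyond = (int)std::floor(bin_tol * total + 1e-9);

  LogicalVector accept(n);
  NumericVector chi2_out(n, NA_REAL);
  IntegerVector df_out(n, NA_INTEGER);
  IntegerVector status(n);

  for (int i = 0; i < n; ++i) {
    double cw[3];
    double accw = 0.0;
    for (int k = 0; k < K; ++k) { accw += w(i, k); cw[k] = accw; }

    set_seed(seeds[i]);
    GetRNGstate();
    int bins[MAX_BINS] = {0};
    bool bail = false, abort = false;
    for (int j = 0; j < n_obs; ++j) {
      int k = pick_niche(cw, K);
      double v = draw_ztnb(x(i, k), r(i, k));
      if (v < 0.0 || v > ABUND_CAP) { abort = true; break; }
      int b = ilog2(v);
      if (b >= MAX_BINS) { abort = true; break; }
      ++bins[b];
      if (b < nd) {
        if ((tol_total || data_bins[b] > 0) && bins[b] > up[b]) { bail = true; break; }
      } else if (tol_total && bins[b] > up_beyond) { bail = true; break; }
    }
    PutRNGstate();

    if (abort) { status[i] = 3; accept[i] = false; continue; }
    if (bail)  { status[i] = 0; accept[i] = false; continue; }

    bool cond1 = true;
    for (int b = 0; b < nd; ++b) {
      if ((tol_total || data_bins[b] > 0) &&
          (bins[b] < lo[b] || bins[b] > up[b])) {
        cond1 = false; break;
      }
    }
    if (cond1 && tol_total) {
      for (int b = nd; b < MAX_BINS; ++b) {
        if (bins[b] > up_beyond) { cond1 = false; break; }
      }
    }
    int top = nd;
    for (int b = MAX_BINS - 1; b >= nd; --b) {
      if (bins[b] > 0) { top = b + 1; break; }
    }
    double chi2 = 0.0;
    int df = 0;
    for (int b = 0; b < top; ++b) {
      double d = (b < nd) ? data_bins[b] : 0.0;
      double s = bins[b];
      if (d + s > 0.0) {
        double diff = d - s;
        chi2 += diff * diff / (d + s);
        if (df_union) ++df; else df += (d > 0.0);
      }
    }
    double cdf = (df > 0) ? R::pchisq(chi2, (double)df, 1, 0) : 0.0;
    bool ok = cond1 && (cdf < cutoff);
    accept[i] = ok;
    chi2_out[i] = chi2;
    df_out[i] = df;
    status[i] = ok ? 2 : 1;
  }

  return DataFrame::create(_["accept"] = accept, _["chi2"] = chi2_out,
                           _["df"] = df_out, _["status"] = status);
}
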