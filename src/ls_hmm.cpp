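#include <Rcpp.h>
using namespace Rcpp;

// Li-Stephens forward-backward over K reference haplotypes for one phased
// study haplotype observed at T typed sites.
//
// obs:  length-T 0/1 study alleles
// refs: K x T 0/1 reference alleles
// rho:  length T-1 per-gap recombination intensity 4*Ne*Morgans
// eps:  per-site copying-error probability
//
// Transition over a gap with intensity r: stay = exp(-r/K); probability of
// landing on a *specific* state j is stay*I(j==cur) + (1-stay)/K.
// Emission: P(obs | copied allele a) = 1-eps if a==obs else eps.
// Messages are normalised per site; the posterior is invariant to the
// scaling.
// [[Rcpp::export]]
NumericMatrix ls_forward_backward(IntegerVector obs, IntegerMatrix refs,
                                  NumericVector rho, double eps) {
  const int K = refs.nrow(), T = refs.ncol();
  if (obs.size() != T) stop("obs length does not match refs columns");
  if (rho.size() != T - 1) stop("rho length must be T-1");
  const int* R = refs.begin();  // column-major: site t contiguous over k
  std::vector<double> F((size_t)T * K);  // forward, t-major

  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    double e = (R[k] == obs[0]) ? 1.0 - eps : eps;
    F[k] = e / K;
    tot += F[k];
  }
  for (int k = 0; k < K; ++k) F[k] /= tot;
  for (int t = 1; t < T; ++t) {
    double stay = std::exp(-rho[t - 1] / K);
    double sw = (1.0 - stay) / K;  // previous row sums to 1
    const int* col = R + (size_t)t * K;
    double* prev = &F[(size_t)(t - 1) * K];
    double* cur = &F[(size_t)t * K];
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = (col[k] == obs[t]) ? 1.0 - eps : eps;
      double v = (stay * prev[k] + sw) * e;
      cur[k] = v;
      tot += v;
    }
    for (int k = 0; k < K; ++k) cur[k] /= tot;
  }

  // backward pass folded into the posterior, t-major buffer reused
  std::vector<double> bwd(K, 1.0 / K), nxt(K);
  NumericMatrix gamma(T, K);
  double* G = gamma.begin();  // column-major T x K
  {
    double* cur = &F[(size_t)(T - 1) * K];
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) s2 += cur[k] * bwd[k];
    for (int k = 0; k < K; ++k) G[(size_t)k * T + (T - 1)] = cur[k] * bwd[k] / s2;
  }
  for (int t = T - 2; t >= 0; --t) {
    double stay = std::exp(-rho[t] / K);
    double sw = (1.0 - stay) / K;
    const int* col = R + (size_t)(t + 1) * K;
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = (col[k] == obs[t + 1]) ? 1.0 - eps : eps;
      nxt[k] = bwd[k] * e;
      s += nxt[k];
    }
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = stay * nxt[k] + sw * s;
      bwd[k] = v;
      tot += v;
    }
    double* cur = &F[(size_t)t * K];
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) {
      bwd[k] /= tot;
      s2 += cur[k] * bwd[k];
    }
    for (int k = 0; k < K; ++k) G[(size_t)k * T + t] = cur[k] * bwd[k] / s2;
  }
  return gamma;
}

// P(ALT) at every site of the (selected) reference matrix given the typed-
// site posteriors.  State probabilities at an untyped site are linearly
// interpolated on cumulative cM between the flanking typed sites; before
// the first / after the last typed site the nearest posterior row is used.
//
// gamma:     T x K typed-site posteriors
// refs:      K x S selected reference alleles over all sites
// typed_idx: length-T 1-based site indices of the typed sites (increasing)
// cm:        length-S cumulative cM per site
// [[Rcpp::export]]
NumericVector ls_impute_alleles(NumericMatrix gamma, IntegerMatrix refs,
                                IntegerVector typed_idx, NumericVector cm,
                                double eps) {
  const int K = refs.nrow(), S = refs.ncol(), T = typed_idx.size();
  if (gamma.nrow() != T || gamma.ncol() != K)
    stop("gamma dimensions do not match typed sites / references");
  // transpose gamma so each typed site's state vector is contiguous
  std::vector<double> gT((size_t)T * K);
  for (int k = 0; k < K; ++k)
    for (int t = 0; t < T; ++t)
      gT[(size_t)t * K + k] = gamma(t, k);
  const int* R = refs.begin();  // column-major: site s contiguous over k
  NumericVector p(S);
  std::vector<double> mix(K);
  int left = -1;  // index (0-based) of last typed site at or before s
  for (int s = 0; s < S; ++s) {
    while (left + 1 < T && typed_idx[left + 1] - 1 <= s) ++left;
    const int* col = R + (size_t)s * K;
    double psum = 0.0;
    if (left >= 0 && typed_idx[left] - 1 == s) {
      const double* g = &gT[(size_t)left * K];
      for (int k = 0; k < K; ++k)
        psum += g[k] * (col[k] ? 1.0 - eps : eps);
    } else {
      int lo = left < 0 ? 0 : left;
      int hi = left < 0 ? 0 : (left >= T - 1 ? T - 1 : left + 1);
      double w = 0.0;
      if (hi > lo) {
        double c0 = cm[typed_idx[lo] - 1], c1 = cm[typed_idx[hi] - 1];
        w = (c1 > c0) ? (cm[s] - c0) / (c1 - c0) : 0.5;
        if (w < 0.0) w = 0.0;
        if (w > 1.0) w = 1.0;
      }
      const double* glo = &gT[(size_t)lo * K];
      const double* ghi = &gT[(size_t)hi * K];
      for (int k = 0; k < K; ++k) {
        double g = (1.0 - w) * glo[k] + w * ghi[k];
        psum += g * (col[k] ? 1.0 - eps : eps);
      }
    }
    p[s] = psum;
  }
  return p;
}

// Length (in typed sites) of the maximal run of consecutive matches
// between the study haplotype and each reference, for each anchor site;
// 0 where study and reference mismatch at the anchor itself.
//
// study: length-T 0/1; refs: K x T; anchors: 1-based typed-site indices.
// Returns K x A matrix of tract lengths.
// [[Rcpp::export]]
IntegerMatrix ls_tract_lengths(IntegerVector study, IntegerMatrix refs,
                               IntegerVector anchors) {
  const int K = refs.nrow(), T = refs.ncol(), A = anchors.size();
  IntegerMatrix out(K, A);
  std::vector<int> runlen(T), tot(T);
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < T; ++t) {
      bool m = refs(k, t) == study[t];
      runlen[t] = m ? (t > 0 ? runlen[t - 1] + 1 : 1) : 0;
    }
    for (int t = T - 1; t >= 0; --t) {
      if (runlen[t] == 0) tot[t] = 0;
      else if (t < T - 1 && runlen[t + 1] > 0) tot[t] = tot[t + 1];
      else tot[t] = runlen[t];
    }
    for (int a = 0; a < A; ++a) out(k, a) = tot[anchors[a] - 1];
  }
  return out;
}
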