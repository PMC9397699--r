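#include <Rcpp.h>
using namespace Rcpp;

// Nearest Euclidean neighbor of every row, excluding a Theiler band of
// |i - j| <= theiler and (optionally) exact-zero separations. Ties are
// broken toward the smallest index. Returns 1-based indices and distances
// (index 0 / dist Inf when no admissible neighbor exists).
// [[Rcpp::export]]
List cppNearestNeighbor(NumericMatrix pts, int theiler, bool excludeZero) {
  const int m = pts.nrow(), d = pts.ncol();
  const double* p = REAL(pts);          // column-major, stride m
  IntegerVector nn(m);
  NumericVector nd(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    int bi = -1;
    const int jlo1 = i - theiler, jhi1 = i + theiler;
    for (int j = 0; j < m; ++j) {
      if (j >= jlo1 && j <= jhi1) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = p[(size_t)k * m + i] - p[(size_t)k * m + j];
        s += diff * diff;
        if (s >= best) break;           // partial sum already too large
      }
      if (s >= best) continue;
      if (excludeZero && s <= 0.0) continue;
      best = s; bi = j;
    }
    nn[i] = bi + 1;
    nd[i] = (bi < 0) ? R_PosInf : std::sqrt(best);
  }
  return List::create(_["index"] = nn, _["dist"] = nd);
}

// Same search restricted to the given 1-based query rows.
// [[Rcpp::export]]
List cppNearestNeighborQ(NumericMatrix pts, IntegerVector queries,
                         int theiler, bool excludeZero) {
  const int m = pts.nrow(), d = pts.ncol(), nq = queries.size();
  const double* p = REAL(pts);
  IntegerVector nn(nq);
  NumericVector nd(nq);
  for (int qi = 0; qi < nq; ++qi) {
    const int i = queries[qi] - 1;
    double best = R_PosInf;
    int bi = -1;
    const int jlo1 = i - theiler, jhi1 = i + theiler;
    for (int j = 0; j < m; ++j) {
      if (j >= jlo1 && j <= jhi1) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = p[(size_t)k * m + i] - p[(size_t)k * m + j];
        s += diff * diff;
        if (s >= best) break;
      }
      if (s >= best) continue;
      if (excludeZero && s <= 0.0) continue;
      best = s; bi = j;
    }
    nn[qi] = bi + 1;
    nd[qi] = (bi < 0) ? R_PosInf : std::sqrt(best);
  }
  return List::create(_["index"] = nn, _["dist"] = nd);
}

// Euclidean separation of point pairs (a[p]+i, b[p]+i) for i = 0..steps.
// a and b are 1-based row indices; caller guarantees a+steps, b+steps stay
// within the trajectory.
// [[Rcpp::export]]
NumericMatrix cppPairTrack(NumericMatrix pts, IntegerVector a,
                           IntegerVector b, int steps) {
  const int np = a.size(), d = pts.ncol(), m = pts.nrow();
  const double* p = REAL(pts);
  NumericMatrix out(np, steps + 1);
  double* o = REAL(out);
  for (int q = 0; q < np; ++q) {
    const int ra0 = a[q] - 1, rb0 = b[q] - 1;
    for (int i = 0; i <= steps; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = p[(size_t)k * m + ra0 + i] -
                            p[(size_t)k * m + rb0 + i];
        s += diff * diff;
      }
      o[(size_t)i * np + q] = std::sqrt(s);
    }
  }
  return out;
}

// Mutual information (bits) between x_t and x_{t+lag} for lag = 1..maxLag,
// over an equal-width nBins x nBins histogram of the range-normalized
// series. Mirrors the R reference implementation.
// [[Rcpp::export]]
NumericVector cppMICurve(NumericVector x, int maxLag, int nBins) {
  const int n = x.size();
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  std::vector<int> bin(n);
  const double width = hi - lo;
  for (int i = 0; i < n; ++i) {
    int b = (int)std::floor((x[i] - lo) / width * nBins);
    if (b >= nBins) b = nBins - 1;
    bin[i] = b;
  }
  NumericVector out(maxLag);
  std::vector<double> joint(nBins * nBins), p1(nBins), p2(nBins);
  const double log2e = 1.0 / std::log(2.0);
  for (int lag = 1; lag <= maxLag; ++lag) {
    std::fill(joint.begin(), joint.end(), 0.0);
    std::fill(p1.begin(), p1.end(), 0.0);
    std::fill(p2.begin(), p2.end(), 0.0);
    const int np = n - lag;
    for (int t = 0; t < np; ++t) {
      joint[bin[t] + nBins * bin[t + lag]] += 1.0;
      p1[bin[t]] += 1.0;
      p2[bin[t + lag]] += 1.0;
    }
    double mi = 0.0;
    for (int a = 0; a < nBins; ++a) {
      for (int b = 0; b < nBins; ++b) {
        const double j = joint[a + nBins * b];
        if (j > 0.0)
          mi += (j / np) * std::log(j * np / (p1[a] * p2[b])) * log2e;
      }
    }
    out[lag - 1] = mi;
  }
  return out;
}

// False-nearest-neighbor fraction at dimension `dim` (Kennel criteria),
// embedding built implicitly from the scalar series. Queries are the
// evenly spaced 1-based indices passed in; the neighbor search scans every
// admissible point.
// [[Rcpp::export]]
double cppFnnFraction(NumericVector x, int lag, int dim, double rtol,
                      double atol, int theiler, IntegerVector queries,
                      double attractorSize) {
  const int n = x.size();
  const int mNext = n - dim * lag;       // points still defined at dim+1
  const double* xp = REAL(x);
  int nFalse = 0, nTested = 0;
  for (int qi = 0; qi < queries.size(); ++qi) {
    const int i = queries[qi] - 1;
    double best = R_PosInf;
    int bi = -1;
    for (int j = 0; j < mNext; ++j) {
      int gap = i - j; if (gap < 0) gap = -gap;
      if (gap <= theiler) continue;
      double s = 0.0;
      for (int k = 0; k < dim; ++k) {
        const double diff = xp[i + k * lag] - xp[j + k * lag];
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bi = j; }
    }
    if (bi < 0) continue;
    const double dist0 = std::sqrt(best);
    if (!(dist0 > 0.0)) continue;
    const double extra = std::fabs(xp[i + dim * lag] - xp[bi + dim * lag]);
    ++nTested;
    if (extra / dist0 > rtol ||
        std::sqrt(dist0 * dist0 + extra * extra) / attractorSize > atol)
      ++nFalse;
  }
  if (nTested == 0) return 1.0;
  return (double)nFalse / nTested;
}
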