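#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// reflect an index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing with reflective boundaries.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& x, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t j = 0; j < k.size(); ++j) k[j] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * x(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

static double vec_median(std::vector<double>& v) {
  size_t n = v.size();
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Iterated threshold-gated, distance-weighted channelwise median filter.
// A neighbour at Euclidean distance r < radius gets weight w = (1 - r/radius)^falloff;
// it contributes iff |dL| <= thr_lum * w and sqrt(da^2 + db^2) <= thr_chrom * w.
// [[Rcpp::export]]
List ranked_filter_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                       int radius, double falloff,
                       double thr_lum, double thr_chrom, int iterations) {
  int nr = L.nrow(), nc = L.ncol();
  std::vector<int> dr, dc;
  std::vector<double> wt;
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j) {
      double r = std::sqrt((double)(i * i + j * j));
      if (r < radius) {
        dr.push_back(i); dc.push_back(j);
        wt.push_back(std::pow(1.0 - r / radius, falloff));
      }
    }
  int noff = (int)dr.size();
  NumericMatrix curL = clone(L), curA = clone(A), curB = clone(B);
  std::vector<double> bufL, bufA, bufB;
  bufL.reserve(noff); bufA.reserve(noff); bufB.reserve(noff);
  for (int it = 0; it < iterations; ++it) {
    NumericMatrix nxL(nr, nc), nxA(nr, nc), nxB(nr, nc);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double l0 = curL(r, c), a0 = curA(r, c), b0 = curB(r, c);
        bufL.clear(); bufA.clear(); bufB.clear();
        for (int o = 0; o < noff; ++o) {
          int rr = r + dr[o], cc = c + dc[o];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double dl = curL(rr, cc) - l0;
          double da = curA(rr, cc) - a0;
          double db = curB(rr, cc) - b0;
          double w = wt[o];
          if (std::fabs(dl) <= thr_lum * w &&
              std::sqrt(da * da + db * db) <= thr_chrom * w) {
            bufL.push_back(curL(rr, cc));
            bufA.push_back(curA(rr, cc));
            bufB.push_back(curB(rr, cc));
          }
        }
        nxL(r, c) = vec_median(bufL);
        nxA(r, c) = vec_median(bufA);
        nxB(r, c) = vec_median(bufB);
      }
    curL = nxL; curA = nxA; curB = nxB;
  }
  return List::create(Named("L") = curL, Named("a") = curA, Named("b") = curB);
}

// Connected components within equal-label regions. NA labels are background
// (component id 0). connectivity is 4 or 8. Component ids are 1..P in raster
// discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& lab, int connectivity) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix comp(nr, nc);
  std::fill(comp.begin(), comp.end(), 0);
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next_id = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) == NA_INTEGER || comp(r0, c0) != 0) continue;
      int val = lab(r0, c0);
      ++next_id;
      comp(r0, c0) = next_id;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int o = 0; o < nnb; ++o) {
          int rr = r + dr8[o], cc = c + dc8[o];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (comp(rr, cc) != 0) continue;
          if (lab(rr, cc) == NA_INTEGER || lab(rr, cc) != val) continue;
          comp(rr, cc) = next_id;
          stack.push_back(rr + cc * nr);
        }
      }
    }
  return comp;
}

// Efron partial log-likelihood, score and information for a Cox model.
// Rows must be sorted by (stratum, time ascending); strata are contiguous
// integer blocks. Returns ll, grad (p) and info (p x p, negative Hessian).
// [[Rcpp::export]]
List cox_efron_cpp(const NumericMatrix& X, const NumericVector& time,
                   const IntegerVector& status, const IntegerVector& strata,
                   const NumericVector& beta) {
  int n = X.nrow(), p = X.ncol();
  // row-major copy: covariates of one subject are contiguous
  std::vector<double> Xt((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xt[(size_t)i * p + j] = X(i, j);
  std::vector<double> eta(n, 0.0);
  double emax = -1e300;
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt[(size_t)i * p];
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += xi[j] * beta[j];
    eta[i] = s;
    if (s > emax) emax = s;
  }
  // constant shift cancels exactly in the Efron terms
  for (int i = 0; i < n; ++i) eta[i] -= emax;

  double ll = 0.0;
  NumericVector grad(p);
  NumericMatrix info(p, p);
  std::vector<double> S1(p), S1D(p), S2(p * p), S2D(p * p), z(p);

  int i = n - 1;
  while (i >= 0) {
    int str = strata[i];
    // start of a stratum block: reset risk-set sums
    double S0 = 0.0;
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    while (i >= 0 && strata[i] == str) {
      double t = time[i];
      int d = 0;
      double S0D = 0.0;
      std::fill(S1D.begin(), S1D.end(), 0.0);
      std::fill(S2D.begin(), S2D.end(), 0.0);
      while (i >= 0 && strata[i] == str && time[i] == t) {
        const double* xi = &Xt[(size_t)i * p];
        double w = std::exp(eta[i]);
        S0 += w;
        for (int j = 0; j < p; ++j) {
          double wx = w * xi[j];
          S1[j] += wx;
          double* s2row = &S2[(size_t)j * p];
          for (int k = j; k < p; ++k) s2row[k] += wx * xi[k];
        }
        if (status[i] == 1) {
          ++d;
          S0D += w;
          ll += eta[i];
          for (int j = 0; j < p; ++j) {
            grad[j] += xi[j];
            double wx = w * xi[j];
            S1D[j] += wx;
            double* s2row = &S2D[(size_t)j * p];
            for (int k = j; k < p; ++k) s2row[k] += wx * xi[k];
          }
        }
        --i;
      }
      for (int l = 0; l < d; ++l) {
        double f = (double)l / d;
        double s0 = S0 - f * S0D;
        ll -= std::log(s0);
        for (int j = 0; j < p; ++j) z[j] = (S1[j] - f * S1D[j]) / s0;
        for (int j = 0; j < p; ++j) {
          grad[j] -= z[j];
          const double* s2row = &S2[(size_t)j * p];
          const double* s2drow = &S2D[(size_t)j * p];
          for (int k = j; k < p; ++k)
            info(j, k) += (s2row[k] - f * s2drow[k]) / s0 - z[j] * z[k];
        }
      }
    }
  }
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < j; ++k) info(j, k) = info(k, j);
  return List::create(Named("ll") = ll, Named("grad") = grad,
                      Named("info") = info);
}
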