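#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Joint spatial-range mean-shift filtering with a flat (truncated) kernel.
// Each pixel starts at its own (row, col, L, a, b) position and is moved to
// the mean of the data points falling inside the spatial ball of radius hs
// and the range (Lab) ball of radius hr around the current estimate, until
// the shift is below tol or max_iter is reached.  Returns the converged
// range mode per pixel (the spatial mode is not needed downstream).
// [[Rcpp::export]]
List ms_filter(NumericMatrix L, NumericMatrix A, NumericMatrix B,
               double hs, double hr, int max_iter, double tol) {
  const int nr = L.nrow(), nc = L.ncol();
  NumericMatrix mL(nr, nc), mA(nr, nc), mB(nr, nc);
  const double hs2 = hs * hs, hr2 = hr * hr, tol2 = tol * tol;
  const int w = (int)std::ceil(hs);

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      double yr = r0, yc = c0;
      double yL = L(r0, c0), yA = A(r0, c0), yB = B(r0, c0);
      for (int it = 0; it < max_iter; ++it) {
        const int rc = (int)std::lround(yr), cc = (int)std::lround(yc);
        const int rlo = std::max(0, rc - w), rhi = std::min(nr - 1, rc + w);
        const int clo = std::max(0, cc - w), chi = std::min(nc - 1, cc + w);
        double sr = 0, sc = 0, sL = 0, sA = 0, sB = 0;
        int n = 0;
        for (int c = clo; c <= chi; ++c) {
          const double dc = c - yc;
          for (int r = rlo; r <= rhi; ++r) {
            const double dr = r - yr;
            if (dr * dr + dc * dc > hs2) continue;
            const double dL = L(r, c) - yL, dA = A(r, c) - yA, dB = B(r, c) - yB;
            if (dL * dL + dA * dA + dB * dB > hr2) continue;
            sr += r; sc += c; sL += L(r, c); sA += A(r, c); sB += B(r, c);
            ++n;
          }
        }
        if (n == 0) break;  // isolated point: stays where it is
        const double nr_ = sr / n, nc_ = sc / n;
        const double nL = sL / n, nA = sA / n, nB = sB / n;
        const double shift = (nr_ - yr) * (nr_ - yr) + (nc_ - yc) * (nc_ - yc) +
                             (nL - yL) * (nL - yL) + (nA - yA) * (nA - yA) +
                             (nB - yB) * (nB - yB);
        yr = nr_; yc = nc_; yL = nL; yA = nA; yB = nB;
        if (shift < tol2) break;
      }
      mL(r0, c0) = yL; mA(r0, c0) = yA; mB(r0, c0) = yB;
    }
  }
  return List::create(_["L"] = mL, _["a"] = mA, _["b"] = mB);
}

// Group pixels into superpixels: 4-connected flood fill where two
// neighbouring pixels join the same cluster when their converged range
// modes are closer than thresh in Lab.  Labels are 1-based.
// [[Rcpp::export]]
IntegerMatrix ms_label(NumericMatrix mL, NumericMatrix mA, NumericMatrix mB,
                       double thresh) {
  const int nr = mL.nrow(), nc = mL.ncol();
  const double t2 = thresh * thresh;
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int k = 0; k < 4; ++k) {
          const int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) != 0) continue;
          const double dL = mL(r2, c2) - mL(r, c);
          const double dA = mA(r2, c2) - mA(r, c);
          const double dB = mB(r2, c2) - mB(r, c);
          if (dL * dL + dA * dA + dB * dB > t2) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}

// 4-connected component labelling of a logical mask (FALSE pixels get 0).
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int k = 0; k < 4; ++k) {
          const int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}
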