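#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample) reflection of a 0-based index into [0, n).
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Windowed NL-Means with optional gradient augmentation and optional
// cluster restriction of the candidate set.
//
// img, grad, labels: nr x nc matrices (grad ignored unless use_gradient;
//   labels restrict candidates to label(j) == label(i)).
// kernel: (2*pr+1)^2 Gaussian patch weights, normalized to sum 1.
// search_radius < 0 means whole-image search.
// ah2 = a^2 * h^2, the exponent denominator.
//
// Patch comparisons use symmetric (mirror) padding at the image border.
// The candidate j == i always contributes exp(0) = 1, so the normalizer
// is never degenerate and the output is a convex combination of
// candidate intensities.
// [[Rcpp::export]]
NumericMatrix nlm_core(const NumericMatrix& img,
                       const NumericMatrix& grad,
                       const IntegerMatrix& labels,
                       const NumericMatrix& kernel,
                       int patch_radius,
                       int search_radius,
                       double ah2,
                       bool use_gradient) {
  const int nr = img.nrow(), nc = img.ncol(), pr = patch_radius;
  const bool whole = search_radius < 0;
  NumericMatrix out(nr, nc);

  // precomputed mirror-reflected index tables: refR[i + pr] = reflect(i)
  std::vector<int> refR(nr + 2 * pr), refC(nc + 2 * pr);
  for (int i = -pr; i < nr + pr; ++i) refR[i + pr] = reflect(i, nr);
  for (int i = -pr; i < nc + pr; ++i) refC[i + pr] = reflect(i, nc);

  const double* pimg = &img(0, 0);
  const double* pgrad = &grad(0, 0);
  const double* pker = &kernel(0, 0);
  const int kside = 2 * pr + 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int lab = labels(r, c);
      const int r0 = whole ? 0 : std::max(0, r - search_radius);
      const int r1 = whole ? nr - 1 : std::min(nr - 1, r + search_radius);
      const int c0 = whole ? 0 : std::max(0, c - search_radius);
      const int c1 = whole ? nc - 1 : std::min(nc - 1, c + search_radius);
      double wsum = 0.0, vsum = 0.0;
      for (int jc = c0; jc <= c1; ++jc) {
        for (int jr = r0; jr <= r1; ++jr) {
          if (labels(jr, jc) != lab) continue;
          double d = 0.0;
          for (int dc = 0; dc < kside; ++dc) {
            const double* colA = pimg + (size_t)refC[c + dc] * nr;
            const double* colB = pimg + (size_t)refC[jc + dc] * nr;
            const double* gcolA = pgrad + (size_t)refC[c + dc] * nr;
            const double* gcolB = pgrad + (size_t)refC[jc + dc] * nr;
            const double* kcol = pker + (size_t)dc * kside;
            for (int dr = 0; dr < kside; ++dr) {
              const int ar = refR[r + dr], br = refR[jr + dr];
              double diff = colA[ar] - colB[br];
              if (use_gradient) diff *= gcolA[ar] - gcolB[br];
              d += kcol[dr] * diff * diff;
            }
          }
          const double wgt = std::exp(-d / ah2);
          wsum += wgt;
          vsum += wgt * img(jr, jc);
        }
      }
      out(r, c) = vsum / wsum;
    }
  }
  return out;
}

// Per-pixel patch mean and standard deviation over a mirror-padded
// square patch, the K-means feature map.  Returns an nr x nc x 2 array
// flattened to an (nr*nc) x 2 matrix in column-major pixel order.
// [[Rcpp::export]]
NumericMatrix patch_moments(const NumericMatrix& img, int patch_radius) {
  const int nr = img.nrow(), nc = img.ncol(), pr = patch_radius;
  const double npix = (2 * pr + 1) * (2 * pr + 1);
  NumericMatrix out(nr * nc, 2);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      // two-pass moments: exact zero variance on constant patches
      double s = 0.0;
      for (int dc = -pr; dc <= pr; ++dc) {
        const int ac = reflect(c + dc, nc);
        for (int dr = -pr; dr <= pr; ++dr)
          s += img(reflect(r + dr, nr), ac);
      }
      const double m = s / npix;
      double ss = 0.0;
      for (int dc = -pr; dc <= pr; ++dc) {
        const int ac = reflect(c + dc, nc);
        for (int dr = -pr; dr <= pr; ++dr) {
          const double d = img(reflect(r + dr, nr), ac) - m;
          ss += d * d;
        }
      }
      out(c * nr + r, 0) = m;
      out(c * nr + r, 1) = std::sqrt(ss / npix);
    }
  }
  return out;
}
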