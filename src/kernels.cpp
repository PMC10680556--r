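// Hot numerical kernels for image simulation and spot quantification.
// Everything here has a direct R-level definition in the test suite's
// brute-force oracles; these are performance ports, not new semantics.

#include <Rcpp.h>
using namespace Rcpp;

// Expected photoelectrons per pixel for point emitters with an integrated
// 2-D Gaussian PSF.  pos: n x 2 of 0-based (row, col); amp: expected total
// photoelectrons per emitter.
// [[Rcpp::export]]
NumericMatrix render_psf_cpp(NumericMatrix pos, NumericVector amp,
                             double sigma, int nr, int nc) {
  NumericMatrix img(nr, nc);
  int half = (int)std::ceil(4.0 * sigma);
  for (int i = 0; i < pos.nrow(); ++i) {
    double a = amp[i];
    if (a <= 0) continue;
    double y = pos(i, 0), x = pos(i, 1);
    int r0 = std::max(0, (int)std::floor(y) - half);
    int r1 = std::min(nr - 1, (int)std::floor(y) + half + 1);
    int c0 = std::max(0, (int)std::floor(x) - half);
    int c1 = std::min(nc - 1, (int)std::floor(x) + half + 1);
    if (r0 > r1 || c0 > c1) continue;
    std::vector<double> fy(r1 - r0 + 1), fx(c1 - c0 + 1);
    for (int r = r0; r <= r1; ++r)
      fy[r - r0] = R::pnorm((r + 0.5 - y) / sigma, 0.0, 1.0, 1, 0) -
                   R::pnorm((r - 0.5 - y) / sigma, 0.0, 1.0, 1, 0);
    for (int c = c0; c <= c1; ++c)
      fx[c - c0] = R::pnorm((c + 0.5 - x) / sigma, 0.0, 1.0, 1, 0) -
                   R::pnorm((c - 0.5 - x) / sigma, 0.0, 1.0, 1, 0);
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        img(r, c) += a * fy[r - r0] * fx[c - c0];
  }
  return img;
}

// Strict 8-neighbour local maxima; returns 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      bool is_max = true;
      for (int dc = -1; dc <= 1 && is_max; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (img(rr, cc) >= v) { is_max = false; break; }
        }
      }
      if (is_max) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// Disc / annulus photometry around a sub-pixel centroid (0-based row, col).
// Returns (summed_intensity, background_mean, background_sd, n_disc,
// n_annulus, valid, truncated).  exclude: m x 2 other-centroid matrix whose
// inner discs are dropped from the annulus (ignored if that empties it).
// [[Rcpp::export]]
NumericVector measure_spot_cpp(NumericMatrix img, double cy, double cx,
                               double inner, double ann_in, double ann_out,
                               NumericMatrix exclude) {
  int nr = img.nrow(), nc = img.ncol();
  int r0 = std::max(0, (int)std::floor(cy - ann_out));
  int r1 = std::min(nr - 1, (int)std::ceil(cy + ann_out));
  int c0 = std::max(0, (int)std::floor(cx - ann_out));
  int c1 = std::min(nc - 1, (int)std::ceil(cx + ann_out));
  double disc_sum = 0.0;
  int n_disc = 0;
  double ann_s = 0.0, ann_ss = 0.0;
  double ann_all_s = 0.0, ann_all_ss = 0.0;
  int n_ann = 0, n_ann_all = 0;
  double inner2 = inner * inner, in2 = ann_in * ann_in,
         out2 = ann_out * ann_out;
  int nex = exclude.nrow();
  for (int c = c0; c <= c1; ++c) {
    for (int r = r0; r <= r1; ++r) {
      double dy = r - cy, dx = c - cx;
      double d2 = dy * dy + dx * dx;
      if (d2 <= inner2) {
        disc_sum += img(r, c);
        ++n_disc;
      } else if (d2 > in2 && d2 <= out2) {
        double v = img(r, c);
        ann_all_s += v; ann_all_ss += v * v; ++n_ann_all;
        bool near = false;
        for (int j = 0; j < nex; ++j) {
          double ey = exclude(j, 0), ex = exclude(j, 1);
          double dcy = ey - cy, dcx = ex - cx;
          if (dcy * dcy + dcx * dcx < 1.0) continue;  // the spot itself
          double ddy = r - ey, ddx = c - ex;
          if (ddy * ddy + ddx * ddx <= inner2) { near = true; break; }
        }
        if (!near) { ann_s += v; ann_ss += v * v; ++n_ann; }
      }
    }
  }
  if (n_ann == 0) { ann_s = ann_all_s; ann_ss = ann_all_ss; n_ann = n_ann_all; }
  bool truncated = (cy - ann_out < -0.5) || (cx - ann_out < -0.5) ||
                   (cy + ann_out > nr - 0.5) || (cx + ann_out > nc - 0.5);
  NumericVector out(7);
  if (n_ann == 0) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL;
    out[3] = n_disc; out[4] = 0; out[5] = 0; out[6] = truncated ? 1 : 0;
    return out;
  }
  double bg_mean = ann_s / n_ann;
  double bg_var = n_ann > 1 ?
    (ann_ss - ann_s * ann_s / n_ann) / (n_ann - 1) : 0.0;
  if (bg_var < 0) bg_var = 0;
  out[0] = disc_sum - n_disc * bg_mean;
  out[1] = bg_mean;
  out[2] = std::sqrt(bg_var);
  out[3] = n_disc;
  out[4] = n_ann;
  out[5] = 1;
  out[6] = truncated ? 1 : 0;
  return out;
}

// Chung-Kennedy edge-preserving filter: variance-weighted blend of the
// means of a trailing and a leading window, both including the sample.
// [[Rcpp::export]]
NumericVector ck_filter_cpp(NumericVector x, int window, double p,
                            double eps) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int f0 = std::max(0, i - window + 1), f1 = i;
    int b0 = i, b1 = std::min(n - 1, i + window - 1);
    double fs = 0, fss = 0, bs = 0, bss = 0;
    int fn = f1 - f0 + 1, bn = b1 - b0 + 1;
    for (int j = f0; j <= f1; ++j) { fs += x[j]; fss += x[j] * x[j]; }
    for (int j = b0; j <= b1; ++j) { bs += x[j]; bss += x[j] * x[j]; }
    double fm = fs / fn, bm = bs / bn;
    double fv = fn > 1 ? std::max(0.0, (fss - fs * fs / fn) / (fn - 1)) : 0.0;
    double bv = bn > 1 ? std::max(0.0, (bss - bs * bs / bn) / (bn - 1)) : 0.0;
    double wf = std::pow(1.0 / (fv + eps), p);
    double wb = std::pow(1.0 / (bv + eps), p);
    out[i] = (wf * fm + wb * bm) / (wf + wb);
  }
  return out;
}
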