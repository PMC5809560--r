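#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Offset convention (row, col), 0-based, top-left origin:
//   theta =   0 deg : (r, c) <-> (r,     c + d)
//   theta =  45 deg : (r, c) <-> (r - d, c + d)
//   theta =  90 deg : (r, c) <-> (r - d, c)
//   theta = 135 deg : (r, c) <-> (r - d, c - d)
static void theta_offset(int theta, int d, int &dr, int &dc) {
  switch (theta) {
  case 0:   dr = 0;  dc = d;  break;
  case 45:  dr = -d; dc = d;  break;
  case 90:  dr = -d; dc = 0;  break;
  case 135: dr = -d; dc = -d; break;
  default: stop("theta must be one of 0, 45, 90, 135");
  }
}

// Accumulate co-occurrence counts for one offset into `counts` (levels x levels).
// Returns the number of ordered pairs counted.
static double glcm_counts(const IntegerMatrix &roi, int dr, int dc,
                          int levels, bool symmetric, NumericMatrix &counts) {
  int nr = roi.nrow(), nc = roi.ncol();
  double total = 0.0;
  for (int r = 0; r < nr; ++r) {
    int r2 = r + dr;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      int i = roi(r, c), j = roi(r2, c2);
      if (i < 0 || i >= levels || j < 0 || j >= levels)
        stop("gray levels must lie in [0, levels-1]");
      counts(i, j) += 1.0;
      total += 1.0;
      if (symmetric) {
        counts(j, i) += 1.0;
        total += 1.0;
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerMatrix roi, int d, int theta, int levels,
                       bool symmetric) {
  int dr, dc;
  theta_offset(theta, d, dr, dc);
  NumericMatrix counts(levels, levels);
  double total = glcm_counts(roi, dr, dc, levels, symmetric, counts);
  if (total == 0.0)
    stop("ROI contains no pixel pairs at the requested (d, theta)");
  for (int i = 0; i < levels; ++i)
    for (int j = 0; j < levels; ++j)
      counts(i, j) /= total;
  return counts;
}

// Eight Haralick parameters from a normalized GLCM.
// Entropies use -sum(p log p), natural log, 0 log 0 = 0.
// Correlation is 0 when a marginal standard deviation vanishes.
// Order: correlation, asm, contrast, idm, entropy, sum_entropy,
//        sum_average, sum_variance
static void params_from_glcm(const NumericMatrix &p, double *out) {
  int n = p.nrow();
  std::vector<double> pi(n, 0.0), pj(n, 0.0), pxy(2 * n - 1, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = p(i, j);
      pi[i] += v;
      pj[j] += v;
      pxy[i + j] += v;
    }
  double mui = 0, muj = 0;
  for (int i = 0; i < n; ++i) { mui += i * pi[i]; muj += i * pj[i]; }
  double vi = 0, vj = 0;
  for (int i = 0; i < n; ++i) {
    vi += (i - mui) * (i - mui) * pi[i];
    vj += (i - muj) * (i - muj) * pj[i];
  }
  double si = std::sqrt(vi), sj = std::sqrt(vj);

  double cor = 0, asm_ = 0, con = 0, idm = 0, ent = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = p(i, j);
      asm_ += v * v;
      con += (double)(i - j) * (i - j) * v;
      idm += v / (1.0 + std::abs(i - j));
      if (v > 0) ent -= v * std::log(v);
      if (si > 0 && sj > 0) cor += (i - mui) * (j - muj) * v;
    }
  if (si > 0 && sj > 0) cor /= si * sj; else cor = 0.0;

  double sent = 0, savg = 0;
  for (int i = 0; i < 2 * n - 1; ++i) {
    double v = pxy[i];
    if (v > 0) sent -= v * std::log(v);
    savg += i * v;
  }
  double svar = 0;
  for (int i = 0; i < 2 * n - 1; ++i)
    svar += (i - savg) * (i - savg) * pxy[i];

  out[0] = cor; out[1] = asm_; out[2] = con; out[3] = idm;
  out[4] = ent; out[5] = sent; out[6] = savg; out[7] = svar;
}

// [[Rcpp::export]]
NumericVector cpp_texture_params(NumericMatrix p) {
  double out[8];
  params_from_glcm(p, out);
  NumericVector res(8);
  for (int i = 0; i < 8; ++i) res[i] = out[i];
  res.attr("names") = CharacterVector::create(
      "correlation", "asm", "contrast", "idm", "entropy", "sum_entropy",
      "sum_average", "sum_variance");
  return res;
}

// All eight parameters for every ROI of the fixed 8x8 block partition of a
// square patch, at the four standard orientations. Returns an
// (n_roi x 8 params x 4 thetas) array flattened column-major as a matrix of
// n_roi rows and 32 columns (param-major within theta blocks handled in R).
// Column layout: theta index slow, parameter fast:
//   col = t * 8 + p  for theta t in {0,45,90,135}, parameter p as above.
// [[Rcpp::export]]
NumericMatrix cpp_roi_params(IntegerMatrix patch, int roi_size, int d,
                             int levels, bool symmetric) {
  int nr = patch.nrow(), nc = patch.ncol();
  if (nr % roi_size != 0 || nc % roi_size != 0)
    stop("patch dimensions must be multiples of roi_size");
  int br = nr / roi_size, bc = nc / roi_size;
  int nroi = br * bc;
  static const int thetas[4] = {0, 45, 90, 135};
  NumericMatrix out(nroi, 32);
  IntegerMatrix roi(roi_size, roi_size);
  NumericMatrix counts(levels, levels);
  double pars[8];
  for (int a = 0; a < br; ++a) {
    for (int b = 0; b < bc; ++b) {
      int idx = a * bc + b; // row-major ROI order
      for (int r = 0; r < roi_size; ++r)
        for (int c = 0; c < roi_size; ++c)
          roi(r, c) = patch(a * roi_size + r, b * roi_size + c);
      for (int t = 0; t < 4; ++t) {
        int dr, dc;
        theta_offset(thetas[t], d, dr, dc);
        std::fill(counts.begin(), counts.end(), 0.0);
        double total = glcm_counts(roi, dr, dc, levels, symmetric, counts);
        if (total == 0.0)
          stop("ROI contains no pixel pairs at the requested (d, theta)");
        for (int k = 0; k < levels * levels; ++k) counts[k] /= total;
        params_from_glcm(counts, pars);
        for (int p = 0; p < 8; ++p) out(idx, t * 8 + p) = pars[p];
      }
    }
  }
  return out;
}
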