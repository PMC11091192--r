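// Contact-map and triplet-contact kernels over conformation ensembles.
// Frames are (nBeads x 3 x nFrames) arrays of unwrapped coordinates.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_contact_counts")]]
NumericMatrix cpp_contact_counts(NumericVector frames, double threshold) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  double t2 = threshold * threshold;
  NumericMatrix counts(n, n);
  for (int f = 0; f < nf; ++f) {
    const double *fx = &frames[static_cast<R_xlen_t>(f) * n * 3];
    const double *fy = fx + n, *fz = fy + n;
    for (int i = 0; i < n; ++i) {
      counts(i, i) += 1.0;
      for (int j = i + 1; j < n; ++j) {
        double dx = fx[i] - fx[j], dy = fy[i] - fy[j], dz = fz[i] - fz[j];
        if (dx * dx + dy * dy + dz * dz < t2) {
          counts(i, j) += 1.0;
          counts(j, i) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Triple contacts (viewpoint i fixed): cell (j,k) counted when all three
// mutual distances d_ij, d_jk, d_ki are below the threshold.
// [[Rcpp::export(name = ".cpp_triplet_counts")]]
NumericMatrix cpp_triplet_counts(NumericVector frames, int viewpoint,
                                 double threshold) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  double t2 = threshold * threshold;
  NumericMatrix counts(n, n);
  std::vector<int> near;
  for (int f = 0; f < nf; ++f) {
    const double *fx = &frames[static_cast<R_xlen_t>(f) * n * 3];
    const double *fy = fx + n, *fz = fy + n;
    near.clear();
    for (int j = 0; j < n; ++j) {
      double dx = fx[j] - fx[viewpoint], dy = fy[j] - fy[viewpoint],
             dz = fz[j] - fz[viewpoint];
      if (dx * dx + dy * dy + dz * dz < t2) near.push_back(j);
    }
    for (size_t a = 0; a < near.size(); ++a)
      for (size_t b = a; b < near.size(); ++b) {
        int j = near[a], k = near[b];
        double dx = fx[j] - fx[k], dy = fy[j] - fy[k], dz = fz[j] - fz[k];
        if (dx * dx + dy * dy + dz * dz < t2) {
          counts(j, k) += 1.0;
          if (j != k) counts(k, j) += 1.0;
        }
      }
  }
  return counts;
}

// Per-frame indicator that every pairwise distance within a bead set is
// below the threshold (co-occurrence / planted-triple statistics).
// [[Rcpp::export(name = ".cpp_all_close_indicator")]]
LogicalVector cpp_all_close_indicator(NumericVector frames,
                                      IntegerVector beads, double threshold) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2], m = beads.size();
  double t2 = threshold * threshold;
  LogicalVector out(nf);
  for (int f = 0; f < nf; ++f) {
    const double *fx = &frames[static_cast<R_xlen_t>(f) * n * 3];
    const double *fy = fx + n, *fz = fy + n;
    bool all = true;
    for (int a = 0; a < m && all; ++a)
      for (int b = a + 1; b < m && all; ++b) {
        int i = beads[a], j = beads[b];
        double dx = fx[i] - fx[j], dy = fy[i] - fy[j], dz = fz[i] - fz[j];
        if (dx * dx + dy * dy + dz * dz >= t2) all = false;
      }
    out[f] = all;
  }
  return out;
}
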