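#include <Rcpp.h>
using namespace Rcpp;

// Composite one video frame: copy the static background, add iid Gaussian
// pixel noise (R's RNG, so set.seed() controls it), clamp to [0,1], then
// overwrite the dot patch (already colour-blended in R) and noise/clamp it.
// Fusing copy+noise+clamp into one pass keeps frame synthesis at memcpy-like
// cost instead of several full-array temporaries.
// [[Rcpp::export]]
NumericVector render_frame_cpp(NumericVector background,
                               IntegerVector patch_idx,
                               NumericVector patch_val,
                               double noise_sd) {
  R_xlen_t n = background.size();
  NumericVector out(no_init(n));
  if (noise_sd > 0.0) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = background[i] + norm_rand() * noise_sd;
      out[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  } else {
    std::copy(background.begin(), background.end(), out.begin());
  }
  R_xlen_t m = patch_idx.size();
  for (R_xlen_t j = 0; j < m; ++j) {
    double v = patch_val[j];
    if (noise_sd > 0.0) v += norm_rand() * noise_sd;
    out[patch_idx[j] - 1] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
  }
  out.attr("dim") = background.attr("dim");
  return out;
}

// Red-dominance candidate pixels for laser-dot segmentation. `frame` is an
// H x W x 3 array in [0,1]; returns 1-based linear indices into the first
// (red) channel plane. A pixel is a candidate when it is strongly red
// (R >= t_abs and R - max(G,B) >= t_margin) or near-saturated (R >= white_core,
// the blown-out laser core).
// [[Rcpp::export]]
IntegerVector red_candidates_cpp(NumericVector frame, int npix,
                                 double t_abs, double t_margin,
                                 double white_core) {
  const double* r = REAL(frame);
  const double* g = r + npix;
  const double* b = r + 2 * npix;
  std::vector<int> idx;
  for (int i = 0; i < npix; ++i) {
    double m = g[i] > b[i] ? g[i] : b[i];
    if ((r[i] >= t_abs && r[i] - m >= t_margin) || r[i] >= white_core)
      idx.push_back(i + 1);
  }
  return wrap(idx);
}
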