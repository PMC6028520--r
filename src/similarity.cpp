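#include <Rcpp.h>
using namespace Rcpp;

// Cosine-similarity kernel shared by the batch and streaming paths: both
// call the same accumulation loop, so a streamed clip reproduces the batch
// similarity vector bit for bit. A zero-norm frame yields NA; the R side
// raises the classed error (with the frame index) on NA.

static inline double cos_to_ref(const double* v, const double* ref,
                                R_xlen_t n, double ref_norm) {
  double s2 = 0.0, sp = 0.0;
  for (R_xlen_t j = 0; j < n; ++j) {
    s2 += v[j] * v[j];
    sp += v[j] * ref[j];
  }
  if (s2 == 0.0) return NA_REAL;
  double s = sp / (std::sqrt(s2) * ref_norm);
  // absorb sub-ulp overshoot so cosines stay inside [-1, 1]
  if (s > 1.0) s = 1.0;
  if (s < -1.0) s = -1.0;
  return s;
}

// [[Rcpp::export(name = ".cpp_cos_sim_one")]]
double cpp_cos_sim_one(NumericVector v, NumericVector ref, double ref_norm) {
  if (v.size() != ref.size())
    stop("vector lengths differ");
  return cos_to_ref(REAL(v), REAL(ref), v.size(), ref_norm);
}

// frames: m*n*k array flattened column-major; one similarity per frame
// [[Rcpp::export(name = ".cpp_cos_sim_stack")]]
NumericVector cpp_cos_sim_stack(NumericVector frames, R_xlen_t pixels,
                                NumericVector ref, double ref_norm) {
  if (ref.size() != pixels)
    stop("reference length does not match pixel count");
  R_xlen_t k = frames.size() / pixels;
  NumericVector out(k);
  const double* f = REAL(frames);
  const double* r = REAL(ref);
  for (R_xlen_t i = 0; i < k; ++i) {
    out[i] = cos_to_ref(f + i * pixels, r, pixels, ref_norm);
  }
  return out;
}
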