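#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coherent complex scattering amplitude of a set of atoms on a pixel grid:
// A(pix) = sum_j f[pix, elem(j)] * exp(i q(pix) . x_j).
// fPix has one column per element class; elemIdx is 1-based into those
// columns. Returns a 2-column matrix (Re, Im), one row per pixel.
// [[Rcpp::export]]
NumericMatrix cpp_atomic_amplitude(NumericVector qx, NumericVector qy,
                                   NumericVector qz, NumericMatrix xyz,
                                   IntegerVector elemIdx, NumericMatrix fPix) {
  const R_xlen_t npix = qx.size();
  const int natom = xyz.nrow();
  if (qy.size() != npix || qz.size() != npix || fPix.nrow() != npix)
    stop("pixel array length mismatch");
  if (elemIdx.size() != natom) stop("elemIdx length must match atom count");

  NumericMatrix out(npix, 2);
  for (R_xlen_t p = 0; p < npix; ++p) {
    const double ax = qx[p], ay = qy[p], az = qz[p];
    double re = 0.0, im = 0.0;
    for (int j = 0; j < natom; ++j) {
      const double ph = ax * xyz(j, 0) + ay * xyz(j, 1) + az * xyz(j, 2);
      const double f = fPix(p, elemIdx[j] - 1);
      re += f * std::cos(ph);
      im += f * std::sin(ph);
    }
    out(p, 0) = re;
    out(p, 1) = im;
  }
  return out;
}
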