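#include <Rcpp.h>
using namespace Rcpp;

// Z-buffered flat-shaded triangle rasterizer.
//
// uv:      V x 2 image coordinates (0-based pixel centers at integers)
// z:       V camera-frame depths (positive)
// faces:   F x 3 one-based vertex indices
// fcol:    F x 3 per-face RGB in [0,1]
// image:   H*W*3 background, column-major array(H, W, 3) layout
//
// Returns the painted image and the final depth buffer (Inf where empty).
// [[Rcpp::export(name = ".rasterize_cpp")]]
List rasterize_cpp(NumericMatrix uv, NumericVector z, IntegerMatrix faces,
                   NumericMatrix fcol, NumericVector image,
                   int width, int height) {
  NumericVector img = clone(image);
  NumericVector zbuf(width * height, R_PosInf);
  const int F = faces.nrow();
  for (int f = 0; f < F; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ua = uv(a, 0), va = uv(a, 1);
    double ub = uv(b, 0), vb = uv(b, 1);
    double uc = uv(c, 0), vc = uv(c, 1);
    // inverse depths interpolate linearly in screen space
    double ia = 1.0 / z[a], ib = 1.0 / z[b], ic = 1.0 / z[c];
    int x0 = std::max(0, (int)std::ceil(std::min({ua, ub, uc})));
    int x1 = std::min(width - 1, (int)std::floor(std::max({ua, ub, uc})));
    int y0 = std::max(0, (int)std::ceil(std::min({va, vb, vc})));
    int y1 = std::min(height - 1, (int)std::floor(std::max({va, vb, vc})));
    if (x0 > x1 || y0 > y1) continue;
    double det = (ub - ua) * (vc - va) - (uc - ua) * (vb - va);
    if (std::fabs(det) < 1e-12) continue;
    double r = fcol(f, 0), g = fcol(f, 1), bl = fcol(f, 2);
    for (int y = y0; y <= y1; ++y) {
      for (int x = x0; x <= x1; ++x) {
        double w1 = ((double)x - ua) * (vc - va) - (uc - ua) * ((double)y - va);
        w1 /= det;
        double w2 = (ub - ua) * ((double)y - va) - ((double)x - ua) * (vb - va);
        w2 /= det;
        double w0 = 1.0 - w1 - w2;
        if (w0 < -1e-9 || w1 < -1e-9 || w2 < -1e-9) continue;
        double iz = w0 * ia + w1 * ib + w2 * ic;
        double depth = 1.0 / iz;
        int pix = y + x * height;          // array(H, W, .) layout
        if (depth < zbuf[pix]) {
          zbuf[pix] = depth;
          img[pix] = r;
          img[pix + width * height] = g;
          img[pix + 2 * width * height] = bl;
        }
      }
    }
  }
  return List::create(_["image"] = img, _["zbuffer"] = zbuf);
}
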