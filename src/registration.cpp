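#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid in-plane transform: q = R(theta) (p - c) + c + t, with c the image
// center ((w-1)/2, (h-1)/2) in 0-based (x, y) pixel coordinates. Resampling
// evaluates the inverse mapping p = R^T (q - c - t) + c at every output pixel.

static inline double sampleBilinear(const NumericMatrix &img, double x,
                                    double y) {
  int h = img.nrow(), w = img.ncol();
  if (x < 0 || y < 0 || x > w - 1 || y > h - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < w ? x0 + 1 : x0;
  int y1 = y0 + 1 < h ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0), v01 = img(y0, x1);
  double v10 = img(y1, x0), v11 = img(y1, x1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// Catmull-Rom cubic interpolation: sharper than bilinear near the texture
// Nyquist scale, which matters for sub-pixel/rotation metric accuracy.
static inline double cubicKernel(double t) {
  t = std::fabs(t);
  if (t < 1) return 1 - 2.5 * t * t + 1.5 * t * t * t;
  if (t < 2) return 2 - 4 * t + 2.5 * t * t - 0.5 * t * t * t;
  return 0;
}

static inline double sampleCubic(const NumericMatrix &img, double x,
                                 double y) {
  int h = img.nrow(), w = img.ncol();
  if (x < 0 || y < 0 || x > w - 1 || y > h - 1) return 0.0;
  if (x < 1 || y < 1 || x > w - 2 || y > h - 2)
    return sampleBilinear(img, x, y);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double v = 0;
  for (int j = -1; j <= 2; ++j) {
    double wy = cubicKernel(y - (y0 + j));
    if (wy == 0) continue;
    for (int i = -1; i <= 2; ++i) {
      double wx = cubicKernel(x - (x0 + i));
      if (wx == 0) continue;
      v += wx * wy * img(y0 + j, x0 + i);
    }
  }
  return v;
}

static inline double sampleNearest(const NumericMatrix &img, double x,
                                   double y) {
  int h = img.nrow(), w = img.ncol();
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  if (xi < 0 || yi < 0 || xi >= w || yi >= h) return 0.0;
  return img(yi, xi);
}

// [[Rcpp::export(name = ".cpp_resample_rigid")]]
NumericMatrix cpp_resample_rigid(NumericMatrix img, double thetaDeg,
                                 double tx, double ty, int bilinear) {
  int h = img.nrow(), w = img.ncol();
  double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  double th = thetaDeg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  NumericMatrix out(h, w);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      double qx = c - cx - tx, qy = r - cy - ty;
      // inverse rotation R^T
      double px = ct * qx + st * qy + cx;
      double py = -st * qx + ct * qy + cy;
      out(r, c) = bilinear ? sampleBilinear(img, px, py)
                           : sampleNearest(img, px, py);
    }
  }
  return out;
}

// Normalized cross-correlation between `fixedImg` and the rigidly
// transformed `movingImg`, evaluated over the overlap of the fixed
// foreground and the transformed moving foreground, without materializing
// the resampled image. Restricting to the overlap keeps the metric free of
// the boundary bias that fixed-only pixels (moving side = 0) would
// introduce when consecutive sections have different tissue footprints.
// Returns NA when the metric is undefined (constant image over the
// overlap) or the overlap shrinks below half of the smaller footprint.
// [[Rcpp::export(name = ".cpp_ncc_rigid")]]
double cpp_ncc_rigid(NumericMatrix fixedImg, NumericMatrix movingImg,
                     LogicalMatrix fmask, LogicalMatrix mmask,
                     double thetaDeg, double tx, double ty) {
  int h = fixedImg.nrow(), w = fixedImg.ncol();
  double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  double th = thetaDeg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  long n = 0, nFixed = 0, nMoving = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      if (fmask(r, c)) ++nFixed;
      if (mmask(r, c)) ++nMoving;
    }
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!fmask(r, c)) continue;
      double qx = c - cx - tx, qy = r - cy - ty;
      double px = ct * qx + st * qy + cx;
      double py = -st * qx + ct * qy + cy;
      int xi = (int)std::lround(px), yi = (int)std::lround(py);
      if (xi < 0 || yi < 0 || xi >= w || yi >= h || !mmask(yi, xi))
        continue;
      double mv = sampleCubic(movingImg, px, py);
      double fv = fixedImg(r, c);
      sf += fv; sm += mv; sff += fv * fv; smm += mv * mv; sfm += fv * mv;
      ++n;
    }
  }
  long minFoot = nFixed < nMoving ? nFixed : nMoving;
  if (n < 10 || n < minFoot / 2) return NA_REAL;
  double varf = sff - sf * sf / n, varm = smm - sm * sm / n;
  if (varf <= 0 || varm <= 0) return NA_REAL;
  double ncc = (sfm - sf * sm / n) / std::sqrt(varf * varm);
  // gentle overlap penalty: anchors the footprints without reintroducing
  // the boundary bias of scoring fixed-only pixels against zeros
  return ncc * std::pow((double)n / minFoot, 0.25);
}

// Sample `img` at the inverse-rigid-transformed positions of the s x s
// subpixel centers of every output pixel; returns an (h*w) x (s*s) matrix
// of bilinear samples (column-major pixel order). Used by the phantom
// generator to rasterize a continuous section model under a known rigid
// displacement with physical pixel integration.
// [[Rcpp::export(name = ".cpp_sample_rigid_sub")]]
NumericMatrix cpp_sample_rigid_sub(NumericMatrix img, double thetaDeg,
                                   double tx, double ty, int s) {
  int h = img.nrow(), w = img.ncol();
  double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  double th = thetaDeg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  NumericMatrix out(h * w, s * s);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      long pix = r + (long)h * c;
      int sub = 0;
      for (int sx = 0; sx < s; ++sx) {
        for (int sy = 0; sy < s; ++sy, ++sub) {
          double ox = (sx - (s - 1) / 2.0) / s;
          double oy = (sy - (s - 1) / 2.0) / s;
          double qx = c + ox - cx - tx, qy = r + oy - cy - ty;
          double px = ct * qx + st * qy + cx;
          double py = -st * qx + ct * qy + cy;
          out(pix, sub) = sampleBilinear(img, px, py);
        }
      }
    }
  }
  return out;
}
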