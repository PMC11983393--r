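#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Demons-type nonrigid registration core: iterative intensity-driven update
// with symmetric gradients and per-iteration Gaussian regularization of the
// accumulated field (diffusion-like behavior). The field (uy, ux) maps the
// moving image onto the fixed one: warped(p) = moving(p + u(p)).

static inline double bilinear(const NumericMatrix &img, double y, double x) {
  int ny = img.nrow(), nx = img.ncol();
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// separable Gaussian smoothing with replicate borders, in place
static void gauss_smooth(NumericMatrix &m, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &w : k) w /= s;
  int ny = m.nrow(), nx = m.ncol();
  std::vector<double> buf(std::max(ny, nx));
  for (int x = 0; x < nx; ++x) {       // along y
    for (int y = 0; y < ny; ++y) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i) {
        int yy = y + i;
        if (yy < 0) yy = 0; if (yy > ny - 1) yy = ny - 1;
        acc += k[i + radius] * m(yy, x);
      }
      buf[y] = acc;
    }
    for (int y = 0; y < ny; ++y) m(y, x) = buf[y];
  }
  for (int y = 0; y < ny; ++y) {       // along x
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0; if (xx > nx - 1) xx = nx - 1;
        acc += k[i + radius] * m(y, xx);
      }
      buf[x] = acc;
    }
    for (int x = 0; x < nx; ++x) m(y, x) = buf[x];
  }
}

// [[Rcpp::export]]
List demons_level(NumericMatrix fixed, NumericMatrix moving,
                  NumericMatrix uy, NumericMatrix ux,
                  int n_iter, double smooth_sigma, double step_cap) {
  int ny = fixed.nrow(), nx = fixed.ncol();
  NumericMatrix warped(ny, nx), sy(ny, nx), sx(ny, nx);
  NumericVector mad_history(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    double mad = 0;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        warped(y, x) = bilinear(moving, y + uy(y, x), x + ux(y, x));
        mad += std::fabs(fixed(y, x) - warped(y, x));
      }
    mad_history[it] = mad / (ny * nx);
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        int ym = y > 0 ? y - 1 : 0, yp = y < ny - 1 ? y + 1 : ny - 1;
        int xm = x > 0 ? x - 1 : 0, xp = x < nx - 1 ? x + 1 : nx - 1;
        double gfy = 0.5 * (fixed(yp, x) - fixed(ym, x));
        double gfx = 0.5 * (fixed(y, xp) - fixed(y, xm));
        double gwy = 0.5 * (warped(yp, x) - warped(ym, x));
        double gwx = 0.5 * (warped(y, xp) - warped(y, xm));
        double gy = 0.5 * (gfy + gwy), gx = 0.5 * (gfx + gwx);
        double diff = fixed(y, x) - warped(y, x);
        double denom = gy * gy + gx * gx + diff * diff;
        double stepy = 0, stepx = 0;
        if (denom > 1e-12) {
          stepy = diff * gy / denom;
          stepx = diff * gx / denom;
          double mag = std::sqrt(stepy * stepy + stepx * stepx);
          if (mag > step_cap) { stepy *= step_cap / mag; stepx *= step_cap / mag; }
        }
        sy(y, x) = uy(y, x) + stepy;
        sx(y, x) = ux(y, x) + stepx;
      }
    }
    gauss_smooth(sy, smooth_sigma);
    gauss_smooth(sx, smooth_sigma);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) { uy(y, x) = sy(y, x); ux(y, x) = sx(y, x); }
  }
  return List::create(_["uy"] = uy, _["ux"] = ux,
                      _["mad_history"] = mad_history);
}
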