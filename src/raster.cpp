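#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Flat-shaded triangle fill for the software renderer. Triangles arrive
// pre-sorted back to front (painter's algorithm); `v` holds projected
// pixel coordinates (x right, y down) per vertex, `col` one RGB per
// triangle. Returns an array laid out as R's array(dim = c(h, w, 3)).

// [[Rcpp::export(name = ".rasterize_triangles")]]
NumericVector rasterize_triangles(NumericMatrix v, IntegerMatrix tri,
                                  NumericMatrix col, int width, int height,
                                  NumericVector background) {
  NumericVector img((R_xlen_t)width * height * 3);
  R_xlen_t plane = (R_xlen_t)width * height;
  for (int ch = 0; ch < 3; ++ch) {
    double bg = background[ch];
    for (R_xlen_t p = 0; p < plane; ++p) img[ch * plane + p] = bg;
  }

  int ntri = tri.nrow();
  for (int t = 0; t < ntri; ++t) {
    int i0 = tri(t, 0) - 1, i1 = tri(t, 1) - 1, i2 = tri(t, 2) - 1;
    double x0 = v(i0, 0), y0 = v(i0, 1);
    double x1 = v(i1, 0), y1 = v(i1, 1);
    double x2 = v(i2, 0), y2 = v(i2, 1);
    double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;

    int xmin = std::max(0, (int)std::floor(std::min(x0, std::min(x1, x2))));
    int xmax = std::min(width - 1, (int)std::ceil(std::max(x0, std::max(x1, x2))));
    int ymin = std::max(0, (int)std::floor(std::min(y0, std::min(y1, y2))));
    int ymax = std::min(height - 1, (int)std::ceil(std::max(y0, std::max(y1, y2))));
    if (xmin > xmax || ymin > ymax) continue;

    double r = col(t, 0), g = col(t, 1), b = col(t, 2);
    for (int py = ymin; py <= ymax; ++py) {
      double cy = py + 0.5;
      for (int px = xmin; px <= xmax; ++px) {
        double cx = px + 0.5;
        double w0 = (x1 - x0) * (cy - y0) - (cx - x0) * (y1 - y0);
        double w1 = (x2 - x1) * (cy - y1) - (cx - x1) * (y2 - y1);
        double w2 = (x0 - x2) * (cy - y2) - (cx - x2) * (y0 - y2);
        bool inside = (area > 0)
          ? (w0 >= 0 && w1 >= 0 && w2 >= 0)
          : (w0 <= 0 && w1 <= 0 && w2 <= 0);
        if (!inside) continue;
        R_xlen_t p = (R_xlen_t)py + (R_xlen_t)height * px;
        img[p] = r;
        img[plane + p] = g;
        img[2 * plane + p] = b;
      }
    }
  }
  return img;
}
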