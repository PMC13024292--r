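// Low-level raster kernels: CRC32 + scanline unfiltering for the PNG codec,
// connected components, exact Euclidean distance transform, boundary
// extraction, and the rotated-template overlap objectives used by the
// rotation tracker.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------- crc32 ----

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1u) ? (0xedb88320u ^ (c >> 1)) : (c >> 1);
      table[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xffffffffu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ (uint32_t)data[i]) & 0xffu] ^ (crc >> 8);
  return (double)(crc ^ 0xffffffffu);
}

// ----------------------------------------------------- PNG scanline path ----

// data holds height scanlines, each 1 filter byte + rowbytes bytes.
// bpp = bytes per pixel (filter distance). Returns height*rowbytes bytes.
// [[Rcpp::export]]
RawVector cpp_png_unfilter(RawVector data, int height, int rowbytes, int bpp) {
  if ((R_xlen_t)height * (rowbytes + 1) != data.size())
    stop("corrupt PNG image data: expected %d bytes, got %d",
         height * (rowbytes + 1), (int)data.size());
  RawVector out((R_xlen_t)height * rowbytes);
  std::vector<unsigned char> prev(rowbytes, 0), cur(rowbytes);
  R_xlen_t pos = 0;
  for (int y = 0; y < height; ++y) {
    int ft = data[pos++];
    for (int i = 0; i < rowbytes; ++i) cur[i] = data[pos++];
    switch (ft) {
    case 0: break;
    case 1:
      for (int i = bpp; i < rowbytes; ++i)
        cur[i] = (unsigned char)(cur[i] + cur[i - bpp]);
      break;
    case 2:
      for (int i = 0; i < rowbytes; ++i)
        cur[i] = (unsigned char)(cur[i] + prev[i]);
      break;
    case 3:
      for (int i = 0; i < rowbytes; ++i) {
        int a = i >= bpp ? cur[i - bpp] : 0;
        cur[i] = (unsigned char)(cur[i] + ((a + prev[i]) >> 1));
      }
      break;
    case 4:
      for (int i = 0; i < rowbytes; ++i) {
        int a = i >= bpp ? cur[i - bpp] : 0;
        int b = prev[i];
        int c = i >= bpp ? prev[i - bpp] : 0;
        int p = a + b - c;
        int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
        int pr = (pa <= pb && pa <= pc) ? a : ((pb <= pc) ? b : c);
        cur[i] = (unsigned char)(cur[i] + pr);
      }
      break;
    default:
      stop("unsupported PNG filter type %d", ft);
    }
    for (int i = 0; i < rowbytes; ++i) out[(R_xlen_t)y * rowbytes + i] = cur[i];
    prev = cur;
  }
  return out;
}

// --------------------------------------------------- connected components ----

// Label the connected components of a 0/1 mask; labels 1..k in first-seen
// order, 0 stays background. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity = 8) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nn = connectivity == 4 ? 4 : 8;
  int *dx = connectivity == 4 ? dx4 : dx8;
  int *dy = connectivity == 4 ? dy4 : dy8;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(i + j * H);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % H, cj = idx / H;
        for (int d = 0; d < nn; ++d) {
          int ni = ci + dy[d], nj = cj + dx[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(ni + nj * H);
          }
        }
      }
    }
  return lab;
}

// ------------------------------------------------------ distance transform ----

static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in px) from every pixel to the nearest nonzero
// pixel of `sites`. All-zero input gives Inf everywhere. A large finite
// sentinel stands in for "no site" during the two 1D passes (true infinity
// breaks the parabola-envelope intersections).
// [[Rcpp::export]]
NumericMatrix cpp_edt(IntegerMatrix sites) {
  int H = sites.nrow(), W = sites.ncol();
  double INF = std::numeric_limits<double>::infinity();
  const double big = 1e18;
  bool any = false;
  for (int j = 0; j < W && !any; ++j)
    for (int i = 0; i < H; ++i)
      if (sites(i, j) != 0) { any = true; break; }
  NumericMatrix out(H, W);
  if (!any) {
    std::fill(out.begin(), out.end(), INF);
    return out;
  }
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = sites(i, j) != 0 ? 0.0 : big;
    edt_1d(f, d, H);
    for (int i = 0; i < H; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = g(i, j);
    edt_1d(f, d, W);
    for (int j = 0; j < W; ++j)
      out(i, j) = d[j] >= big ? INF : std::sqrt(d[j]);
  }
  return out;
}

// Boundary pixels: mask pixels with at least one 4-neighbour outside the mask
// (image border counts as outside).
// [[Rcpp::export]]
IntegerMatrix cpp_boundary(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix b(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      bool edge = (i == 0 || i == H - 1 || j == 0 || j == W - 1);
      if (edge || mask(i - 1, j) == 0 || mask(i + 1, j) == 0 ||
          mask(i, j - 1) == 0 || mask(i, j + 1) == 0)
        b(i, j) = 1;
    }
  return b;
}

// ------------------------------------------------------- overlap objectives ----

// Fast surrogate objective for the coarse angle scan: forward-map the
// template's foreground pixel centres (offsets from its centroid, columns
// x,y) into the frame at the candidate angle, count nearest-pixel hits in
// `mask`. criterion 0 = Dice, 1 = intersection fraction of the template.
// [[Rcpp::export]]
double cpp_overlap_nn(NumericMatrix pts, IntegerMatrix mask,
                      double mcx, double mcy, double angle_deg,
                      int mask_count, int criterion = 0) {
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  int H = mask.nrow(), W = mask.ncol(), n = pts.nrow(), hits = 0;
  for (int i = 0; i < n; ++i) {
    double lx = pts(i, 0), ly = pts(i, 1);
    double x = mcx + ca * lx - sa * ly;
    double y = mcy + sa * lx + ca * ly;
    int cx = (int)std::lround(x), cy = (int)std::lround(y);
    if (cx >= 1 && cx <= W && cy >= 1 && cy <= H && mask(cy - 1, cx - 1) != 0)
      ++hits;
  }
  if (criterion == 1) return n > 0 ? (double)hits / n : 0.0;
  return (n + mask_count) > 0 ? 2.0 * hits / (n + mask_count) : 0.0;
}

// Exact objective: rasterize the template rotated by angle_deg with its
// centroid at (mcx, mcy) (bilinear sampling, 0.5 threshold) and compare with
// `mask`. Template pixels falling outside the image still count in the Dice
// denominator. tmpl holds 0/1; (tcx, tcy) is the template centroid in its
// own 1-based (col, row) coordinates.
// [[Rcpp::export]]
double cpp_overlap_bilinear(NumericMatrix tmpl, double tcx, double tcy,
                            IntegerMatrix mask, double mcx, double mcy,
                            double angle_deg, int mask_count,
                            int criterion = 0) {
  int th = tmpl.nrow(), tw = tmpl.ncol();
  int H = mask.nrow(), W = mask.ncol();
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  // extent of the rotated template bbox around the mask centroid
  double exx = 0, exy = 0;
  double cxs[2] = {1.0 - tcx, tw - tcx}, cys[2] = {1.0 - tcy, th - tcy};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      double rx = ca * cxs[i] - sa * cys[j];
      double ry = sa * cxs[i] + ca * cys[j];
      exx = std::max(exx, std::fabs(rx));
      exy = std::max(exy, std::fabs(ry));
    }
  int x0 = (int)std::floor(mcx - exx) - 1, x1 = (int)std::ceil(mcx + exx) + 1;
  int y0 = (int)std::floor(mcy - exy) - 1, y1 = (int)std::ceil(mcy + exy) + 1;
  long T = 0, I = 0;
  for (int x = x0; x <= x1; ++x) {
    double dx = x - mcx;
    for (int y = y0; y <= y1; ++y) {
      double dy = y - mcy;
      // inverse rotation into template coordinates
      double tx = tcx + ca * dx + sa * dy;
      double ty = tcy - sa * dx + ca * dy;
      if (tx < 1.0 || tx >= tw || ty < 1.0 || ty >= th) continue;
      int ix = (int)tx, iy = (int)ty;
      double fx = tx - ix, fy = ty - iy;
      double v = tmpl(iy - 1, ix - 1) * (1 - fx) * (1 - fy) +
                 tmpl(iy - 1, ix) * fx * (1 - fy) +
                 tmpl(iy, ix - 1) * (1 - fx) * fy +
                 tmpl(iy, ix) * fx * fy;
      if (v >= 0.5) {
        ++T;
        if (x >= 1 && x <= W && y >= 1 && y <= H && mask(y - 1, x - 1) != 0)
          ++I;
      }
    }
  }
  if (criterion == 1) return T > 0 ? (double)I / T : 0.0;
  return (T + mask_count) > 0 ? 2.0 * (double)I / (T + mask_count) : 0.0;
}

// Smooth overlap objective for refinement: partial-volume (soft) Dice of
// the bilinearly sampled rotated template against the bilinearly
// interpolated mask, evaluated on a 2x supersampled (half-pixel) grid.
// Unlike the 0.5-thresholded rasterization this varies continuously with
// the angle and is nearly free of pixel-phase bias, so the golden-section
// argmax is not limited by rasterization effects.
// criterion 0 = soft Dice, 1 = soft intersection fraction.
// [[Rcpp::export]]
double cpp_overlap_soft(NumericMatrix tmpl, double tcx, double tcy,
                        IntegerMatrix mask, double mcx, double mcy,
                        double angle_deg, int mask_count,
                        int criterion = 0) {
  int th = tmpl.nrow(), tw = tmpl.ncol();
  int H = mask.nrow(), W = mask.ncol();
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  double exx = 0, exy = 0;
  double cxs[2] = {1.0 - tcx, tw - tcx}, cys[2] = {1.0 - tcy, th - tcy};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      double rx = ca * cxs[i] - sa * cys[j];
      double ry = sa * cxs[i] + ca * cys[j];
      exx = std::max(exx, std::fabs(rx));
      exy = std::max(exy, std::fabs(ry));
    }
  double x0 = std::floor(mcx - exx) - 1, x1 = std::ceil(mcx + exx) + 1;
  double y0 = std::floor(mcy - exy) - 1, y1 = std::ceil(mcy + exy) + 1;
  const double step = 0.5, cell = step * step;
  double T = 0, I = 0;
  for (double x = x0; x <= x1; x += step) {
    double dx = x - mcx;
    for (double y = y0; y <= y1; y += step) {
      double dy = y - mcy;
      double tx = tcx + ca * dx + sa * dy;
      double ty = tcy - sa * dx + ca * dy;
      if (tx < 1.0 || tx >= tw || ty < 1.0 || ty >= th) continue;
      int ix = (int)tx, iy = (int)ty;
      double fx = tx - ix, fy = ty - iy;
      double v = tmpl(iy - 1, ix - 1) * (1 - fx) * (1 - fy) +
                 tmpl(iy - 1, ix) * fx * (1 - fy) +
                 tmpl(iy, ix - 1) * (1 - fx) * fy +
                 tmpl(iy, ix) * fx * fy;
      if (v <= 0) continue;
      T += v * cell;
      if (x >= 1 && x < W && y >= 1 && y < H) {
        int mx = (int)x, my = (int)y;
        double gx = x - mx, gy = y - my;
        double mval = (mask(my - 1, mx - 1) != 0) * (1 - gx) * (1 - gy) +
                      (mask(my - 1, mx) != 0) * gx * (1 - gy) +
                      (mask(my, mx - 1) != 0) * (1 - gx) * gy +
                      (mask(my, mx) != 0) * gx * gy;
        I += v * mval * cell;
      }
    }
  }
  if (criterion == 1) return T > 0 ? I / T : 0.0;
  return (T + mask_count) > 0 ? 2.0 * I / (T + mask_count) : 0.0;
}

// Rasterize the template rotated by angle_deg with centroid at (mcx, mcy)
// into an H x W frame (bilinear, 0.5 threshold).
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_rotated(NumericMatrix tmpl, double tcx, double tcy,
                                    int H, int W, double mcx, double mcy,
                                    double angle_deg) {
  int th = tmpl.nrow(), tw = tmpl.ncol();
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  IntegerMatrix out(H, W);
  for (int x = 1; x <= W; ++x) {
    double dx = x - mcx;
    for (int y = 1; y <= H; ++y) {
      double dy = y - mcy;
      double tx = tcx + ca * dx + sa * dy;
      double ty = tcy - sa * dx + ca * dy;
      if (tx < 1.0 || tx >= tw || ty < 1.0 || ty >= th) continue;
      int ix = (int)tx, iy = (int)ty;
      double fx = tx - ix, fy = ty - iy;
      double v = tmpl(iy - 1, ix - 1) * (1 - fx) * (1 - fy) +
                 tmpl(iy - 1, ix) * fx * (1 - fy) +
                 tmpl(iy, ix - 1) * (1 - fx) * fy +
                 tmpl(iy, ix) * fx * fy;
      if (v >= 0.5) out(y - 1, x - 1) = 1;
    }
  }
  return out;
}

// Sample a frame mask into an aligned local window: out(v, u) is the
// bilinear value of `mask` at (cx, cy) + R(angle) * ((u, v) - (ocx, ocy)).
// Used by the mean-shape builder to de-rotate per-frame masks into the
// template frame before averaging.
// [[Rcpp::export]]
NumericMatrix cpp_sample_aligned(IntegerMatrix mask, double cx, double cy,
                                 double angle_deg, int oh, int ow,
                                 double ocx, double ocy) {
  int H = mask.nrow(), W = mask.ncol();
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  NumericMatrix out(oh, ow);
  for (int u = 1; u <= ow; ++u) {
    double lx = u - ocx;
    for (int v = 1; v <= oh; ++v) {
      double ly = v - ocy;
      double x = cx + ca * lx - sa * ly;
      double y = cy + sa * lx + ca * ly;
      if (x < 1.0 || x >= W || y < 1.0 || y >= H) continue;
      int ix = (int)x, iy = (int)y;
      double fx = x - ix, fy = y - iy;
      out(v - 1, u - 1) =
        (mask(iy - 1, ix - 1) != 0) * (1 - fx) * (1 - fy) +
        (mask(iy - 1, ix) != 0) * fx * (1 - fy) +
        (mask(iy, ix - 1) != 0) * (1 - fx) * fy +
        (mask(iy, ix) != 0) * fx * fy;
    }
  }
  return out;
}
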