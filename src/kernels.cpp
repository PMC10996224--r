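// Numerical kernels for the multi-task U-Net and the phantom generator.
//
// Tensor convention (shared with the R layer): a feature map is a numeric
// 3D array with dim c(H, W, C), column-major, which maps directly onto an
// arma::cube(H, W, C).  Convolution weights are arrays with
// dim c(k, k, C_in, C_out); flattened column-major they form the K x C_out
// matrix used in the im2col GEMM below (K = k * k * C_in).

#include <RcppArmadillo.h>
#include <zlib.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array (H, W, C)");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// im2col for stride-1 'same' convolution with zero padding pad = (k-1)/2.
// Transposed layout for contiguous writes: colsT is (H*W) x K; row
// n = h + H*w corresponds to output pixel (h, w); column kh + k*kw + k*k*cin.
static void im2col(const arma::cube& x, int k, int pad, arma::mat& colsT) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  colsT.zeros(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* sl = x.slice_memptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* dst = colsT.colptr(kh + k * kw + k * k * c);
        const int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          memcpy(dst + h0 + H * w, sl + h0 + dh + H * sw,
                 (h1 - h0) * sizeof(double));
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& colsT, int H, int W, int C, int k,
                       int pad, arma::cube& out) {
  out.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    double* sl = out.slice_memptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* src = colsT.colptr(kh + k * kw + k * k * c);
        const int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          double* d = sl + h0 + dh + H * sw;
          const double* s = src + h0 + H * w;
          for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  arma::cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (k, k, C_in, C_out)");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if (wd[1] != k) stop("kernels must be square");
  if ((int)xc.n_slices != cin) stop("input channel mismatch");
  const int pad = (k - 1) / 2;
  const int H = xc.n_rows, W = xc.n_cols;

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
  arma::mat colsT;
  im2col(xc, k, pad, colsT);
  arma::mat Y = colsT * Wm;                // (H*W) x cout; slices contiguous
  arma::cube out(Y.memptr(), H, W, cout);  // copy into cube layout
  for (int co = 0; co < cout; ++co) out.slice(co) += b[co];
  return cube_to_r(out);
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector grad_out) {
  arma::cube xc = as_cube(x);
  arma::cube gc = as_cube(grad_out);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int pad = (k - 1) / 2;
  const int H = xc.n_rows, W = xc.n_cols, N = H * W;

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
  // gradient slices are already contiguous: view as (H*W) x cout
  arma::mat Gt(gc.memptr(), N, cout, false, true);

  arma::mat colsT;
  im2col(xc, k, pad, colsT);
  arma::mat dW = colsT.t() * Gt;           // K x cout
  arma::vec db = arma::sum(Gt, 0).t();
  arma::mat dcolsT = Gt * Wm.t();          // N x K
  arma::cube dx;
  col2im_add(dcolsT, H, W, cin, k, pad, dx);

  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(k, k, cin, cout);
  return List::create(_["dx"] = cube_to_r(dx), _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2.  Returns pooled map and the linear (1-based)
// index into the input array of each selected element, for the backward pass.
// Ties resolved to the first element in column-major scan order.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  if (H % 2 || W % 2) stop("maxpool input must have even height and width");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const int hh = 2 * h + dh, ww = 2 * w + dw;
            const double v = xc(hh, ww, c);
            if (v > best) { best = v; bi = hh + H * ww + H * W * c; }
          }
        }
        y(h, w, c) = best;
        idx[h + Ho * w + Ho * Wo * c] = bi + 1;
        ++p;
      }
    }
  }
  (void)p;
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector grad_y,
                                    int H, int W, int C) {
  NumericVector dx(H * W * C);
  const int n = idx.size();
  for (int i = 0; i < n; ++i) dx[idx[i] - 1] += grad_y[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Bilinear 2x upsampling (align_corners = FALSE convention): output pixel i
// samples the input at (i + 0.5) / 2 - 0.5, clamped to the valid range.
static void bilinear2_weights(int Ho, int Hi, std::vector<int>& i0,
                              std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > Hi - 1) s = Hi - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, Hi - 1);
    i0[i] = lo; i1[i] = hi; w1[i] = s - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  bilinear2_weights(Ho, H, r0, r1, rw);
  bilinear2_weights(Wo, W, c0, c1, cw);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = xc.slice(c);
    arma::mat& out = y.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double a = sl(r0[h], c0[w]) * (1 - rw[h]) * (1 - cw[w])
                       + sl(r1[h], c0[w]) * rw[h] * (1 - cw[w])
                       + sl(r0[h], c1[w]) * (1 - rw[h]) * cw[w]
                       + sl(r1[h], c1[w]) * rw[h] * cw[w];
        out(h, w) = a;
      }
    }
  }
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector grad_y) {
  arma::cube gc = as_cube(grad_y);
  const int Ho = gc.n_rows, Wo = gc.n_cols, C = gc.n_slices;
  const int H = Ho / 2, W = Wo / 2;
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  bilinear2_weights(Ho, H, r0, r1, rw);
  bilinear2_weights(Wo, W, c0, c1, cw);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& g = gc.slice(c);
    arma::mat& out = dx.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double v = g(h, w);
        out(r0[h], c0[w]) += v * (1 - rw[h]) * (1 - cw[w]);
        out(r1[h], c0[w]) += v * rw[h] * (1 - cw[w]);
        out(r0[h], c1[w]) += v * (1 - rw[h]) * cw[w];
        out(r1[h], c1[w]) += v * rw[h] * cw[w];
      }
    }
  }
  return cube_to_r(dx);
}

// 8-connected component labelling of a binary matrix (iterative flood fill).
// Labels are 1..n in first-encounter (column-major) order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({h, w});
      lab(h, w) = next;
      while (!stack.empty()) {
        auto [ch, cw] = stack.back();
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            if (!dh && !dw) continue;
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back({nh, nw});
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Minimal grayscale PNG codec (bit depth 8 or 16, colour type 0, no
// interlace).  No PNG reader/writer package is guaranteed in the target
// environment, and the format itself is small enough to handle directly.

static void u32be(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void png_chunk(std::vector<unsigned char>& out, const char* type,
                      const std::vector<unsigned char>& data) {
  u32be(out, (uint32_t)data.size());
  size_t start = out.size();
  for (int i = 0; i < 4; ++i) out.push_back((unsigned char)type[i]);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  u32be(out, (uint32_t)crc);
}

// img: integer matrix (H x W) of samples in [0, 2^depth - 1].
// [[Rcpp::export]]
void cpp_png_write(std::string path, IntegerMatrix img, int bit_depth) {
  if (bit_depth != 8 && bit_depth != 16) stop("bit depth must be 8 or 16");
  const int H = img.nrow(), W = img.ncol();
  const int bpp = bit_depth / 8;
  const int maxv = (1 << bit_depth) - 1;
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * bpp));
  size_t p = 0;
  for (int h = 0; h < H; ++h) {
    raw[p++] = 0;  // filter type: none
    for (int w = 0; w < W; ++w) {
      int v = img(h, w);
      if (v < 0 || v > maxv) stop("pixel value out of range for bit depth");
      if (bpp == 2) { raw[p++] = (v >> 8) & 0xff; raw[p++] = v & 0xff; }
      else raw[p++] = v & 0xff;
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(clen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  u32be(ihdr, (uint32_t)W); u32be(ihdr, (uint32_t)H);
  ihdr.push_back((unsigned char)bit_depth);
  ihdr.push_back(0);  // colour type: grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  png_chunk(out, "IHDR", ihdr);
  png_chunk(out, "IDAT", comp);
  png_chunk(out, "IEND", {});

  FILE* f = fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  fwrite(out.data(), 1, out.size(), f);
  fclose(f);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
List cpp_png_read(std::string path) {
  FILE* f = fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::vector<unsigned char> buf;
  unsigned char tmp[65536];
  size_t n;
  while ((n = fread(tmp, 1, sizeof(tmp), f)) > 0) buf.insert(buf.end(), tmp, tmp + n);
  fclose(f);
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (buf.size() < 8 || memcmp(buf.data(), sig, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  size_t pos = 8;
  int W = 0, H = 0, depth = 0, ctype = -1;
  std::vector<unsigned char> idat;
  auto rd32 = [&](size_t at) {
    return ((uint32_t)buf[at] << 24) | ((uint32_t)buf[at+1] << 16) |
           ((uint32_t)buf[at+2] << 8) | (uint32_t)buf[at+3];
  };
  while (pos + 8 <= buf.size()) {
    uint32_t len = rd32(pos);
    std::string type((char*)&buf[pos + 4], 4);
    size_t data = pos + 8;
    if (data + len > buf.size()) stop("truncated PNG");
    if (type == "IHDR") {
      W = rd32(data); H = rd32(data + 4);
      depth = buf[data + 8]; ctype = buf[data + 9];
      if (buf[data + 12] != 0) stop("interlaced PNG not supported");
    } else if (type == "IDAT") {
      idat.insert(idat.end(), buf.begin() + data, buf.begin() + data + len);
    } else if (type == "IEND") break;
    pos = data + len + 4;
  }
  if (ctype != 0) stop("only grayscale (colour type 0) PNG supported");
  if (depth != 8 && depth != 16) stop("only 8/16-bit PNG supported");

  const int bpp = depth / 8;
  const size_t stride = 1 + (size_t)W * bpp;
  uLongf rlen = (uLongf)(stride * H);
  std::vector<unsigned char> raw(rlen);
  if (uncompress(raw.data(), &rlen, idat.data(), (uLong)idat.size()) != Z_OK ||
      rlen != stride * (size_t)H)
    stop("PNG inflate failed");

  // undo scanline filters in place (per-byte, bpp-offset neighbours)
  for (int h = 0; h < H; ++h) {
    unsigned char* row = raw.data() + h * stride;
    unsigned char* prev = h ? raw.data() + (h - 1) * stride : nullptr;
    const int ft = row[0];
    for (size_t i = 1; i < stride; ++i) {
      const int a = (i > (size_t)bpp) ? row[i - bpp] : 0;
      const int b = prev ? prev[i] : 0;
      const int c = (prev && i > (size_t)bpp) ? prev[i - bpp] : 0;
      int v = row[i];
      switch (ft) {
        case 0: break;
        case 1: v = (v + a) & 0xff; break;
        case 2: v = (v + b) & 0xff; break;
        case 3: v = (v + (a + b) / 2) & 0xff; break;
        case 4: v = (v + paeth(a, b, c)) & 0xff; break;
        default: stop("unsupported PNG filter %d", ft);
      }
      row[i] = (unsigned char)v;
    }
  }

  IntegerMatrix img(H, W);
  for (int h = 0; h < H; ++h) {
    const unsigned char* row = raw.data() + h * stride + 1;
    for (int w = 0; w < W; ++w) {
      img(h, w) = (bpp == 2) ? ((row[2 * w] << 8) | row[2 * w + 1]) : row[w];
    }
  }
  return List::create(_["image"] = img, _["bit_depth"] = depth);
}
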