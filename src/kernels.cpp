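#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Activations are stored channel-first: dim = (C, H, W, N), column-major.
// im2col lowers a convolution input to a position-major
// (HO*WO*N) x (C*KH*KW) matrix so the convolution becomes one BLAS gemm;
// with positions as the fastest index the inner copy loops are contiguous
// in the output. Column index = c + C*(kh + KH*kw).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int KH, int KW, int stride, int padH, int padW) {
  int HO = (H + 2 * padH - KH) / stride + 1;
  int WO = (W + 2 * padW - KW) / stride + 1;
  const size_t npos = (size_t)HO * WO * N;
  NumericMatrix out(npos, C * KH * KW);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int kw = 0; kw < KW; kw++) {
    for (int kh = 0; kh < KH; kh++) {
      for (int c = 0; c < C; c++) {
        double* ocol = op + npos * ((size_t)kw * KH * C + (size_t)kh * C + c);
        for (int n = 0; n < N; n++) {
          const double* xn = xp + (size_t)n * W * H * C;
          for (int wo = 0; wo < WO; wo++) {
            int w = wo * stride - padW + kw;
            double* dst = ocol + (size_t)n * HO * WO + (size_t)wo * HO;
            if (w < 0 || w >= W) {
              std::memset(dst, 0, HO * sizeof(double));
              continue;
            }
            const double* xw = xn + (size_t)w * H * C + c;
            int h = -padH + kh;
            for (int ho = 0; ho < HO; ho++, h += stride) {
              dst[ho] = (h >= 0 && h < H) ? xw[(size_t)h * C] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add position-major columns back into the
// (C,H,W,N) input gradient.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int KH, int KW, int stride, int padH, int padW) {
  int HO = (H + 2 * padH - KH) / stride + 1;
  int WO = (W + 2 * padW - KW) / stride + 1;
  const size_t npos = (size_t)HO * WO * N;
  NumericVector out((size_t)C * H * W * N);
  const double* cp = REAL(cols);
  double* op = REAL(out);
  for (int kw = 0; kw < KW; kw++) {
    for (int kh = 0; kh < KH; kh++) {
      for (int c = 0; c < C; c++) {
        const double* ccol = cp + npos * ((size_t)kw * KH * C + (size_t)kh * C + c);
        for (int n = 0; n < N; n++) {
          double* on = op + (size_t)n * W * H * C;
          for (int wo = 0; wo < WO; wo++) {
            int w = wo * stride - padW + kw;
            if (w < 0 || w >= W) continue;
            const double* src = ccol + (size_t)n * HO * WO + (size_t)wo * HO;
            double* ow = on + (size_t)w * H * C + c;
            int h = -padH + kh;
            for (int ho = 0; ho < HO; ho++, h += stride) {
              if (h >= 0 && h < H) ow[(size_t)h * C] += src[ho];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}

// 2x2 stride-2 max pooling; returns pooled values and flat argmax indices
// (1-based into the input vector) for the backward scatter.
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int C, int H, int W, int N) {
  int HO = H / 2, WO = W / 2;
  NumericVector out((size_t)C * HO * WO * N);
  IntegerVector arg((size_t)C * HO * WO * N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ap = INTEGER(arg);
  for (int n = 0; n < N; n++) {
    for (int wo = 0; wo < WO; wo++) {
      for (int ho = 0; ho < HO; ho++) {
        for (int c = 0; c < C; c++) {
          double best = -1e300; size_t bidx = 0;
          for (int dw = 0; dw < 2; dw++) {
            for (int dh = 0; dh < 2; dh++) {
              size_t idx = (size_t)n * W * H * C + (size_t)(2 * wo + dw) * H * C +
                           (size_t)(2 * ho + dh) * C + c;
              if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
            }
          }
          size_t oidx = (size_t)n * WO * HO * C + (size_t)wo * HO * C +
                        (size_t)ho * C + c;
          op[oidx] = best;
          ap[oidx] = (int)(bidx + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, HO, WO, N);
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// 8-connected component labelling of a binary matrix (H x W, column-major).
// Components are numbered 1..n in raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix cc_label8_cpp(LogicalMatrix m) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w = 0; w < W; w++) {
    for (int h = 0; h < H; h++) {
      if (!m(h, w) || lab(h, w)) continue;
      next++;
      stack.push_back(w * H + h);
      lab(h, w) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ch = idx % H, cw = idx / H;
        for (int dw = -1; dw <= 1; dw++) {
          for (int dh = -1; dh <= 1; dh++) {
            int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (m(nh, nw) && !lab(nh, nw)) {
              lab(nh, nw) = next;
              stack.push_back(nw * H + nh);
            }
          }
        }
      }
    }
  }
  return lab;
}

struct FloodItem {
  double e; long long seq; int idx; int label;
};
struct FloodCmp {
  bool operator()(const FloodItem& a, const FloodItem& b) const {
    if (a.e != b.e) return a.e > b.e;       // lower energy first
    return a.seq > b.seq;                   // FIFO within plateaus
  }
};

// Marker-controlled watershed: priority flood of `energy` from labelled
// `markers`, confined to `mask`. Equal-energy plateaus are flooded in FIFO
// order, so a binary energy reduces to geodesic growth from the markers.
// [[Rcpp::export]]
IntegerMatrix watershed_flood_cpp(NumericMatrix energy, IntegerMatrix markers,
                                  LogicalMatrix mask) {
  int H = energy.nrow(), W = energy.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<FloodItem, std::vector<FloodItem>, FloodCmp> pq;
  long long seq = 0;
  for (int w = 0; w < W; w++)
    for (int h = 0; h < H; h++)
      if (markers(h, w) > 0 && mask(h, w)) {
        lab(h, w) = markers(h, w);
        pq.push({energy(h, w), seq++, w * H + h, markers(h, w)});
      }
  while (!pq.empty()) {
    FloodItem it = pq.top(); pq.pop();
    int ch = it.idx % H, cw = it.idx / H;
    for (int dw = -1; dw <= 1; dw++) {
      for (int dh = -1; dh <= 1; dh++) {
        if (dh == 0 && dw == 0) continue;
        int nh = ch + dh, nw = cw + dw;
        if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        if (!mask(nh, nw) || lab(nh, nw)) continue;
        lab(nh, nw) = it.label;
        pq.push({energy(nh, nw), seq++, nw * H + nh, it.label});
      }
    }
  }
  return lab;
}

// CRC-32 over raw vectors (PNG chunk checksums).
// [[Rcpp::export]]
double crc32_cpp(RawVector data, double init) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have = true;
  }
  uint32_t crc = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); i++)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
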