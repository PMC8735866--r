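#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding cross-correlation kernels for the toy feature extractor.
// Arrays are column-major R arrays: x is H x W x Cin, w is 3 x 3 x Cin x Cout.

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2];
  const int Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin)
    stop("weight array must be 3 x 3 x Cin x Cout");
  NumericVector out(H * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  double *po = out.begin();
  for (int o = 0; o < Cout; ++o) {
    const size_t ooff = (size_t)o * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        po[ooff + (size_t)j * H + i] = pb[o];
    for (int ci = 0; ci < Cin; ++ci) {
      const size_t xoff = (size_t)ci * H * W;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double wv = pw[(di + 1) + 3 * (dj + 1) + 9 * ci + 9 * Cin * o];
          if (wv == 0.0) continue;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *xc = px + xoff + (size_t)(j + dj) * H + di;
            double *oc = po + ooff + (size_t)j * H;
            for (int i = i0; i < i1; ++i)
              oc[i] += wv * xc[i];
          }
        }
      }
    }
  }
  return out;
}

// gradient of conv output w.r.t. input: correlate upstream gradient with the
// spatially flipped kernels, summing over output channels
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd(NumericVector gout, NumericVector w) {
  IntegerVector dg = gout.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dg[0], W = dg[1], Cout = dg[2];
  const int Cin = dw[2];
  NumericVector gin(H * W * Cin);
  gin.attr("dim") = IntegerVector::create(H, W, Cin);
  const double *pg = gout.begin(), *pw = w.begin();
  double *pi = gin.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    const size_t ioff = (size_t)ci * H * W;
    for (int o = 0; o < Cout; ++o) {
      const size_t goff = (size_t)o * H * W;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          // out[i,j] received w[di,dj] * x[i+di, j+dj]  =>
          // gin[p,q] += w[di,dj] * gout[p-di, q-dj]
          const double wv = pw[(di + 1) + 3 * (dj + 1) + 9 * ci + 9 * Cin * o];
          if (wv == 0.0) continue;
          const int q0 = std::max(0, dj), q1 = std::min(W, W + dj);
          const int p0 = std::max(0, di), p1 = std::min(H, H + di);
          for (int q = q0; q < q1; ++q) {
            const double *gc = pg + goff + (size_t)(q - dj) * H - di;
            double *ic = pi + ioff + (size_t)q * H;
            for (int p = p0; p < p1; ++p)
              ic[p] += wv * gc[p];
          }
        }
      }
    }
  }
  return gin;
}

// 2x2 average pooling, stride 2; trailing row/column dropped when odd
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2];
  const int Hp = H / 2, Wp = W / 2;
  NumericVector out((size_t)Hp * Wp * C);
  out.attr("dim") = IntegerVector::create(Hp, Wp, C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wp; ++j)
      for (int i = 0; i < Hp; ++i) {
        const size_t b = (size_t)c * H * W + (size_t)(2 * j) * H + 2 * i;
        po[(size_t)c * Hp * Wp + (size_t)j * Hp + i] =
          0.25 * (px[b] + px[b + 1] + px[b + H] + px[b + H + 1]);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector g, int H, int W) {
  IntegerVector dg = g.attr("dim");
  const int Hp = dg[0], Wp = dg[1], C = dg[2];
  NumericVector gin((size_t)H * W * C);
  gin.attr("dim") = IntegerVector::create(H, W, C);
  const double *pg = g.begin();
  double *pi = gin.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wp; ++j)
      for (int i = 0; i < Hp; ++i) {
        const double v = 0.25 * pg[(size_t)c * Hp * Wp + (size_t)j * Hp + i];
        const size_t b = (size_t)c * H * W + (size_t)(2 * j) * H + 2 * i;
        pi[b] += v; pi[b + 1] += v; pi[b + H] += v; pi[b + H + 1] += v;
      }
  return gin;
}

// bilinear resize of an H x W x C array to H2 x W2 (align-corners style when
// target > 1, degenerate axes map to the centre)
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H2, int W2) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2];
  NumericVector out((size_t)H2 * W2 * C);
  out.attr("dim") = IntegerVector::create(H2, W2, C);
  const double *px = x.begin();
  double *po = out.begin();
  std::vector<int> i0(H2), i1(H2), j0(W2), j1(W2);
  std::vector<double> fi(H2), fj(W2);
  const double sy = (H2 > 1) ? (double)(H - 1) / (H2 - 1) : 0.0;
  const double sx = (W2 > 1) ? (double)(W - 1) / (W2 - 1) : 0.0;
  for (int i = 0; i < H2; ++i) {
    double p = (H2 > 1) ? i * sy : 0.5 * (H - 1);
    i0[i] = (int)std::floor(p);
    i1[i] = std::min(i0[i] + 1, H - 1);
    fi[i] = p - i0[i];
  }
  for (int j = 0; j < W2; ++j) {
    double p = (W2 > 1) ? j * sx : 0.5 * (W - 1);
    j0[j] = (int)std::floor(p);
    j1[j] = std::min(j0[j] + 1, W - 1);
    fj[j] = p - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const size_t xoff = (size_t)c * H * W;
    const size_t ooff = (size_t)c * H2 * W2;
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const double a = px[xoff + (size_t)j0[j] * H + i0[i]];
        const double b = px[xoff + (size_t)j0[j] * H + i1[i]];
        const double cxy = px[xoff + (size_t)j1[j] * H + i0[i]];
        const double d = px[xoff + (size_t)j1[j] * H + i1[i]];
        const double top = a + fi[i] * (b - a);
        const double bot = cxy + fi[i] * (d - cxy);
        po[ooff + (size_t)j * H2 + i] = top + fj[j] * (bot - top);
      }
  }
  return out;
}
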