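// Low-level numeric kernels: 3D convolution (im2col + GEMM), 3D max
// pooling, and 6-connected component labeling. Arrays follow R's
// column-major layout with dims (D1, D2, D3, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

static void im2col(const double* x, const int* D, int Cin,
                   int k, int s, int p, arma::mat& col) {
  const int O1 = out_dim(D[0], k, s, p);
  const int O2 = out_dim(D[1], k, s, p);
  const int O3 = out_dim(D[2], k, s, p);
  const long S = (long)D[0] * D[1] * D[2];
  long l = 0;
  for (int o3 = 0; o3 < O3; ++o3)
    for (int o2 = 0; o2 < O2; ++o2)
      for (int o1 = 0; o1 < O1; ++o1, ++l) {
        double* dst = col.colptr(l);
        int r = 0;
        for (int c = 0; c < Cin; ++c) {
          const double* xc = x + c * S;
          for (int kz = 0; kz < k; ++kz) {
            int i3 = o3 * s - p + kz;
            for (int ky = 0; ky < k; ++ky) {
              int i2 = o2 * s - p + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                int i1 = o1 * s - p + kx;
                if (i1 < 0 || i1 >= D[0] || i2 < 0 || i2 >= D[1] ||
                    i3 < 0 || i3 >= D[2])
                  dst[r] = 0.0;
                else
                  dst[r] = xc[i1 + (long)D[0] * (i2 + (long)D[1] * i3)];
              }
            }
          }
        }
      }
}

static void col2im_add(const arma::mat& col, const int* D, int Cin,
                       int k, int s, int p, double* dx) {
  const int O1 = out_dim(D[0], k, s, p);
  const int O2 = out_dim(D[1], k, s, p);
  const int O3 = out_dim(D[2], k, s, p);
  const long S = (long)D[0] * D[1] * D[2];
  long l = 0;
  for (int o3 = 0; o3 < O3; ++o3)
    for (int o2 = 0; o2 < O2; ++o2)
      for (int o1 = 0; o1 < O1; ++o1, ++l) {
        const double* src = col.colptr(l);
        int r = 0;
        for (int c = 0; c < Cin; ++c) {
          double* xc = dx + c * S;
          for (int kz = 0; kz < k; ++kz) {
            int i3 = o3 * s - p + kz;
            for (int ky = 0; ky < k; ++ky) {
              int i2 = o2 * s - p + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                int i1 = o1 * s - p + kx;
                if (i1 >= 0 && i1 < D[0] && i2 >= 0 && i2 < D[1] &&
                    i3 >= 0 && i3 < D[2])
                  xc[i1 + (long)D[0] * (i2 + (long)D[1] * i3)] += src[r];
              }
            }
          }
        }
      }
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");   // D1 D2 D3 Cin N
  IntegerVector wd = w.attr("dim");   // k k k Cin Cout
  int D[3] = {xd[0], xd[1], xd[2]};
  int Cin = xd[3], N = xd[4];
  int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("conv3d: channel mismatch");
  int O1 = out_dim(D[0], k, stride, pad);
  int O2 = out_dim(D[1], k, stride, pad);
  int O3 = out_dim(D[2], k, stride, pad);
  if (O1 < 1 || O2 < 1 || O3 < 1) stop("conv3d: input too small for kernel");
  const long L = (long)O1 * O2 * O3;
  const int K = Cin * k * k * k;
  NumericVector out(L * Cout * N);
  out.attr("dim") = IntegerVector::create(O1, O2, O3, Cout, N);
  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, L);
  arma::rowvec bias(const_cast<double*>(b.begin()), Cout, false, true);
  const long Sx = (long)D[0] * D[1] * D[2] * Cin;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * Sx, D, Cin, k, stride, pad, col);
    arma::mat o(out.begin() + n * L * Cout, L, Cout, false, true);
    o = col.t() * W;
    o.each_row() += bias;
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector dout,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int D[3] = {xd[0], xd[1], xd[2]};
  int Cin = xd[3], N = xd[4];
  int k = wd[0], Cout = wd[4];
  int O1 = out_dim(D[0], k, stride, pad);
  int O2 = out_dim(D[1], k, stride, pad);
  int O3 = out_dim(D[2], k, stride, pad);
  const long L = (long)O1 * O2 * O3;
  const int K = Cin * k * k * k;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dW(dw.begin(), K, Cout, false, true);
  arma::rowvec dB(db.begin(), Cout, false, true);
  arma::mat col(K, L);
  const long Sx = (long)D[0] * D[1] * D[2] * Cin;
  const long So = L * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * Sx, D, Cin, k, stride, pad, col);
    arma::mat dO(const_cast<double*>(dout.begin()) + n * So, L, Cout,
                 false, true);
    dW += col * dO;
    dB += arma::sum(dO, 0);
    arma::mat dcol = W * dO.t();           // K x L
    col2im_add(dcol, D, Cin, k, stride, pad, dx.begin() + n * Sx);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3d_fw")]]
List maxpool3d_fw(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");   // D1 D2 D3 C N
  int D[3] = {xd[0], xd[1], xd[2]};
  int C = xd[3], N = xd[4];
  int O1 = out_dim(D[0], k, stride, 0);
  int O2 = out_dim(D[1], k, stride, 0);
  int O3 = out_dim(D[2], k, stride, 0);
  if (O1 < 1 || O2 < 1 || O3 < 1) stop("maxpool3d: input too small");
  const long S = (long)D[0] * D[1] * D[2];
  const long Lo = (long)O1 * O2 * O3;
  NumericVector out(Lo * C * N);
  out.attr("dim") = IntegerVector::create(O1, O2, O3, C, N);
  IntegerVector arg(out.size());
  arg.attr("dim") = out.attr("dim");
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((long)n * C + c) * S;
      for (int o3 = 0; o3 < O3; ++o3)
        for (int o2 = 0; o2 < O2; ++o2)
          for (int o1 = 0; o1 < O1; ++o1, ++q) {
            double best = -INFINITY; long besti = -1;
            for (int kz = 0; kz < k; ++kz) {
              int i3 = o3 * stride + kz; if (i3 >= D[2]) break;
              for (int ky = 0; ky < k; ++ky) {
                int i2 = o2 * stride + ky; if (i2 >= D[1]) break;
                for (int kx = 0; kx < k; ++kx) {
                  int i1 = o1 * stride + kx; if (i1 >= D[0]) break;
                  long idx = i1 + (long)D[0] * (i2 + (long)D[1] * i3);
                  if (xc[idx] > best) { best = xc[idx]; besti = idx; }
                }
              }
            }
            out[q] = best; arg[q] = (int)besti;
          }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bw")]]
NumericVector maxpool3d_bw(NumericVector dout, IntegerVector argmax,
                           IntegerVector xdim) {
  int C = xdim[3], N = xdim[4];
  const long S = (long)xdim[0] * xdim[1] * xdim[2];
  NumericVector dx((long)S * C * N);
  dx.attr("dim") = xdim;
  const long Lo = dout.size() / ((long)C * N);
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* d = dx.begin() + ((long)n * C + c) * S;
      for (long l = 0; l < Lo; ++l, ++q) d[argmax[q]] += dout[q];
    }
  return dx;
}

// 6-connected component labeling of a logical mask.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask) {
  IntegerVector md = mask.attr("dim");
  int D1 = md[0], D2 = md[1], D3 = md[2];
  long S = (long)D1 * D2 * D3;
  IntegerVector lab(S);
  lab.attr("dim") = md;
  std::vector<long> stack;
  int next = 0;
  const int off1[6] = {-1, 1, 0, 0, 0, 0};
  const int off2[6] = {0, 0, -1, 1, 0, 0};
  const int off3[6] = {0, 0, 0, 0, -1, 1};
  for (long i = 0; i < S; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int i1 = p % D1, i2 = (p / D1) % D2, i3 = p / ((long)D1 * D2);
      for (int d = 0; d < 6; ++d) {
        int j1 = i1 + off1[d], j2 = i2 + off2[d], j3 = i3 + off3[d];
        if (j1 < 0 || j1 >= D1 || j2 < 0 || j2 >= D2 || j3 < 0 || j3 >= D3)
          continue;
        long pj = j1 + (long)D1 * (j2 + (long)D2 * j3);
        if (mask[pj] && !lab[pj]) { lab[pj] = next; stack.push_back(pj); }
      }
    }
  }
  return lab;
}
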