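// Numerical kernels shared by the warping, loss and network layers.
// Tensors are channel-first R arrays: dim = c(C, S1, ..., SD), D in {2, 3}.
// Spatial index order is column-major (first spatial axis fastest), matching R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims(const NumericVector& x, int& C, int s[3], int& D) {
  IntegerVector d = x.attr("dim");
  C = d[0];
  D = d.size() - 1;
  s[0] = s[1] = s[2] = 1;
  for (int a = 0; a < D; a++) s[a] = d[a + 1];
}

static IntegerVector make_dim(int C, const int q[3], int D) {
  IntegerVector d(D + 1);
  d[0] = C;
  for (int a = 0; a < D; a++) d[a + 1] = q[a];
  return d;
}

// ---------------------------------------------------------------------------
// Convolution, kernel 3 per active axis, zero padding 1, stride 1 or 2.
// Weight array dim = c(Cout, Cin, 3, 3[, 3]); column-major flattening gives a
// Cout x (Cin*K) matrix whose column order is (cin fastest, then offsets).
// ---------------------------------------------------------------------------

static arma::mat im2col(const double* x, int Cin, const int s[3], int D,
                        const int q[3], int stride) {
  int K = 1;
  for (int a = 0; a < D; a++) K *= 3;
  int tmax[3] = {D >= 1 ? 3 : 1, D >= 2 ? 3 : 1, D >= 3 ? 3 : 1};
  const R_xlen_t Nout = (R_xlen_t)q[0] * q[1] * q[2];
  arma::mat col(Cin * K, Nout, arma::fill::zeros);
  for (int o2 = 0; o2 < q[2]; o2++)
    for (int o1 = 0; o1 < q[1]; o1++)
      for (int o0 = 0; o0 < q[0]; o0++) {
        R_xlen_t oc = o0 + (R_xlen_t)q[0] * (o1 + (R_xlen_t)q[1] * o2);
        double* dst = col.colptr(oc);
        int k = 0;
        for (int t2 = 0; t2 < tmax[2]; t2++)
          for (int t1 = 0; t1 < tmax[1]; t1++)
            for (int t0 = 0; t0 < tmax[0]; t0++, k++) {
              int i0 = stride * o0 + (tmax[0] == 3 ? t0 - 1 : 0);
              int i1 = stride * o1 + (tmax[1] == 3 ? t1 - 1 : 0);
              int i2 = stride * o2 + (tmax[2] == 3 ? t2 - 1 : 0);
              if (i0 < 0 || i0 >= s[0] || i1 < 0 || i1 >= s[1] ||
                  i2 < 0 || i2 >= s[2])
                continue;  // zero padding
              R_xlen_t iv = i0 + (R_xlen_t)s[0] * (i1 + (R_xlen_t)s[1] * i2);
              const double* src = x + (R_xlen_t)Cin * iv;
              double* d = dst + (R_xlen_t)Cin * k;
              for (int c = 0; c < Cin; c++) d[c] = src[c];
            }
      }
  return col;
}

static void out_dims(const int s[3], int D, int stride, int q[3]) {
  q[0] = q[1] = q[2] = 1;
  for (int a = 0; a < D; a++) q[a] = (s[a] - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride) {
  int Cin, s[3], D;
  get_dims(x, Cin, s, D);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0];
  int K = 1;
  for (int a = 0; a < D; a++) K *= 3;
  int q[3];
  out_dims(s, D, stride, q);
  arma::mat col = im2col(x.begin(), Cin, s, D, q, stride);
  arma::mat W(const_cast<double*>(w.begin()), Cout, Cin * K, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat Y = W * col;
  Y.each_col() += bv;
  NumericVector y(Y.begin(), Y.end());
  y.attr("dim") = make_dim(Cout, q, D);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride) {
  int Cin, s[3], D;
  get_dims(x, Cin, s, D);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[0];
  int K = 1;
  for (int a = 0; a < D; a++) K *= 3;
  int q[3];
  out_dims(s, D, stride, q);
  const R_xlen_t Nout = (R_xlen_t)q[0] * q[1] * q[2];
  arma::mat col = im2col(x.begin(), Cin, s, D, q, stride);
  arma::mat W(const_cast<double*>(w.begin()), Cout, Cin * K, false, true);
  arma::mat GY(const_cast<double*>(gy.begin()), Cout, Nout, false, true);

  arma::mat GW = GY * col.t();
  arma::vec GB = arma::sum(GY, 1);
  arma::mat Gcol = W.t() * GY;

  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  double* gxp = gx.begin();
  int tmax[3] = {D >= 1 ? 3 : 1, D >= 2 ? 3 : 1, D >= 3 ? 3 : 1};
  for (int o2 = 0; o2 < q[2]; o2++)
    for (int o1 = 0; o1 < q[1]; o1++)
      for (int o0 = 0; o0 < q[0]; o0++) {
        R_xlen_t oc = o0 + (R_xlen_t)q[0] * (o1 + (R_xlen_t)q[1] * o2);
        const double* src = Gcol.colptr(oc);
        int k = 0;
        for (int t2 = 0; t2 < tmax[2]; t2++)
          for (int t1 = 0; t1 < tmax[1]; t1++)
            for (int t0 = 0; t0 < tmax[0]; t0++, k++) {
              int i0 = stride * o0 + (tmax[0] == 3 ? t0 - 1 : 0);
              int i1 = stride * o1 + (tmax[1] == 3 ? t1 - 1 : 0);
              int i2 = stride * o2 + (tmax[2] == 3 ? t2 - 1 : 0);
              if (i0 < 0 || i0 >= s[0] || i1 < 0 || i1 >= s[1] ||
                  i2 < 0 || i2 >= s[2])
                continue;
              R_xlen_t iv = i0 + (R_xlen_t)s[0] * (i1 + (R_xlen_t)s[1] * i2);
              double* d = gxp + (R_xlen_t)Cin * iv;
              const double* sc = src + (R_xlen_t)Cin * k;
              for (int c = 0; c < Cin; c++) d[c] += sc[c];
            }
      }
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = w.attr("dim");
  NumericVector gbv(GB.begin(), GB.end());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// ---------------------------------------------------------------------------
// Nearest-neighbour upsampling by 2 to an explicit target size (handles odd
// targets by clamping the source index).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector target) {
  int C, s[3], D;
  get_dims(x, C, s, D);
  int q[3] = {1, 1, 1};
  for (int a = 0; a < D; a++) q[a] = target[a];
  NumericVector y((R_xlen_t)C * q[0] * q[1] * q[2]);
  y.attr("dim") = make_dim(C, q, D);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int i2 = 0; i2 < q[2]; i2++) {
    int j2 = std::min(i2 / 2, s[2] - 1);
    for (int i1 = 0; i1 < q[1]; i1++) {
      int j1 = std::min(i1 / 2, s[1] - 1);
      for (int i0 = 0; i0 < q[0]; i0++) {
        int j0 = std::min(i0 / 2, s[0] - 1);
        R_xlen_t iv = i0 + (R_xlen_t)q[0] * (i1 + (R_xlen_t)q[1] * i2);
        R_xlen_t jv = j0 + (R_xlen_t)s[0] * (j1 + (R_xlen_t)s[1] * j2);
        for (int c = 0; c < C; c++) yp[c + C * iv] = xp[c + C * jv];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector gy, IntegerVector src) {
  int C, q[3], D;
  get_dims(gy, C, q, D);
  int s[3] = {1, 1, 1};
  for (int a = 0; a < D; a++) s[a] = src[a];
  NumericVector gx((R_xlen_t)C * s[0] * s[1] * s[2]);
  gx.attr("dim") = make_dim(C, s, D);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int i2 = 0; i2 < q[2]; i2++) {
    int j2 = std::min(i2 / 2, s[2] - 1);
    for (int i1 = 0; i1 < q[1]; i1++) {
      int j1 = std::min(i1 / 2, s[1] - 1);
      for (int i0 = 0; i0 < q[0]; i0++) {
        int j0 = std::min(i0 / 2, s[0] - 1);
        R_xlen_t iv = i0 + (R_xlen_t)q[0] * (i1 + (R_xlen_t)q[1] * i2);
        R_xlen_t jv = j0 + (R_xlen_t)s[0] * (j1 + (R_xlen_t)s[1] * j2);
        for (int c = 0; c < C; c++) xp[c + C * jv] += gp[c + C * iv];
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Dense-field warping (pull/backward): out(p) = img(p + field(p)).
// Displacements are in voxel units; samples outside the grid clamp to the
// border. img is (C, S...), field is (D, S...).
// ---------------------------------------------------------------------------

struct SampleInfo {
  int base[3];
  double frac[3];
  bool clamped[3];  // true where the raw position fell outside [0, S-1]
};

static inline void locate(const double pos[3], const int s[3], int D,
                          SampleInfo& si) {
  for (int a = 0; a < 3; a++) {
    if (a >= D || s[a] == 1) {
      si.base[a] = 0;
      si.frac[a] = 0.0;
      si.clamped[a] = true;
      continue;
    }
    double p = pos[a];
    if (!std::isfinite(p)) p = 0.0;  // non-finite field: sample the origin
    si.clamped[a] = (p <= 0.0 || p >= s[a] - 1.0);
    if (p < 0.0) p = 0.0;
    if (p > s[a] - 1.0) p = s[a] - 1.0;
    int b = (int)std::floor(p);
    if (b > s[a] - 2) b = s[a] - 2;
    si.base[a] = b;
    si.frac[a] = p - b;
  }
}

// [[Rcpp::export]]
NumericVector cpp_warp_fwd(NumericVector img, NumericVector field,
                           bool nearest) {
  int C, s[3], D;
  get_dims(img, C, s, D);
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double* ip = img.begin();
  const double* fp = field.begin();
  double* op = out.begin();
  int ncorner = 1 << D;
  for (int i2 = 0; i2 < s[2]; i2++)
    for (int i1 = 0; i1 < s[1]; i1++)
      for (int i0 = 0; i0 < s[0]; i0++) {
        R_xlen_t v = i0 + (R_xlen_t)s[0] * (i1 + (R_xlen_t)s[1] * i2);
        double pos[3] = {(double)i0, (double)i1, (double)i2};
        for (int a = 0; a < D; a++) pos[a] += fp[a + (R_xlen_t)D * v];
        if (nearest) {
          int j[3];
          for (int a = 0; a < 3; a++) {
            if (a >= D) { j[a] = 0; continue; }
            long r = std::isfinite(pos[a]) ? std::lround(pos[a]) : 0;
            if (r < 0) r = 0;
            if (r > s[a] - 1) r = s[a] - 1;
            j[a] = (int)r;
          }
          R_xlen_t jv = j[0] + (R_xlen_t)s[0] * (j[1] + (R_xlen_t)s[1] * j[2]);
          for (int c = 0; c < C; c++) op[c + C * v] = ip[c + C * jv];
        } else {
          SampleInfo si;
          locate(pos, s, D, si);
          for (int c = 0; c < C; c++) op[c + C * v] = 0.0;
          for (int m = 0; m < ncorner; m++) {
            double wgt = 1.0;
            int j[3] = {0, 0, 0};
            for (int a = 0; a < D; a++) {
              int bit = (m >> a) & 1;
              wgt *= bit ? si.frac[a] : 1.0 - si.frac[a];
              j[a] = std::min(si.base[a] + bit, s[a] - 1);
            }
            if (wgt == 0.0) continue;
            R_xlen_t jv = j[0] + (R_xlen_t)s[0] * (j[1] + (R_xlen_t)s[1] * j[2]);
            for (int c = 0; c < C; c++) op[c + C * v] += wgt * ip[c + C * jv];
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
List cpp_warp_bwd(NumericVector img, NumericVector field, NumericVector gy,
                  bool need_gimg, bool need_gfield) {
  int C, s[3], D;
  get_dims(img, C, s, D);
  NumericVector gimg(need_gimg ? img.size() : 0);
  NumericVector gfield(need_gfield ? field.size() : 0);
  if (need_gimg) gimg.attr("dim") = img.attr("dim");
  if (need_gfield) gfield.attr("dim") = field.attr("dim");
  const double* ip = img.begin();
  const double* fp = field.begin();
  const double* gp = gy.begin();
  int ncorner = 1 << D;
  for (int i2 = 0; i2 < s[2]; i2++)
    for (int i1 = 0; i1 < s[1]; i1++)
      for (int i0 = 0; i0 < s[0]; i0++) {
        R_xlen_t v = i0 + (R_xlen_t)s[0] * (i1 + (R_xlen_t)s[1] * i2);
        double pos[3] = {(double)i0, (double)i1, (double)i2};
        for (int a = 0; a < D; a++) pos[a] += fp[a + (R_xlen_t)D * v];
        SampleInfo si;
        locate(pos, s, D, si);
        for (int m = 0; m < ncorner; m++) {
          double wgt = 1.0;
          int j[3] = {0, 0, 0};
          for (int a = 0; a < D; a++) {
            int bit = (m >> a) & 1;
            wgt *= bit ? si.frac[a] : 1.0 - si.frac[a];
            j[a] = std::min(si.base[a] + bit, s[a] - 1);
          }
          R_xlen_t jv = j[0] + (R_xlen_t)s[0] * (j[1] + (R_xlen_t)s[1] * j[2]);
          if (need_gimg && wgt != 0.0)
            for (int c = 0; c < C; c++)
              gimg[c + C * jv] += wgt * gp[c + C * v];
          if (need_gfield) {
            for (int a = 0; a < D; a++) {
              if (si.clamped[a]) continue;  // border clamp: no position grad
              double dw = 1.0;
              for (int a2 = 0; a2 < D; a2++) {
                int bit = (m >> a2) & 1;
                if (a2 == a)
                  dw *= bit ? 1.0 : -1.0;
                else
                  dw *= bit ? si.frac[a2] : 1.0 - si.frac[a2];
              }
              if (dw == 0.0) continue;
              double acc = 0.0;
              for (int c = 0; c < C; c++)
                acc += gp[c + C * v] * ip[c + C * jv];
              gfield[a + (R_xlen_t)D * v] += dw * acc;
            }
          }
        }
      }
  return List::create(_["gimg"] = gimg, _["gfield"] = gfield);
}

// ---------------------------------------------------------------------------
// Box sums over the n^D window centered at each voxel, truncated at the grid
// border (windows near the edge sum over the in-grid voxels only).
// x here is a plain spatial array (no channel axis).
// ---------------------------------------------------------------------------

static void boxsum_axis(std::vector<double>& buf, const int s[3], int axis,
                        int n) {
  int h = n / 2;
  int len = s[axis];
  std::vector<double> line(len), cum(len + 1);
  int outer1, outer2, stride;
  // iterate all 1-D lines along `axis`
  int dims[3] = {s[0], s[1], s[2]};
  int other[2], oi = 0;
  for (int a = 0; a < 3; a++)
    if (a != axis) other[oi++] = a;
  R_xlen_t strides[3] = {1, (R_xlen_t)s[0], (R_xlen_t)s[0] * s[1]};
  for (int u = 0; u < dims[other[1]]; u++)
    for (int t = 0; t < dims[other[0]]; t++) {
      R_xlen_t base = (R_xlen_t)t * strides[other[0]] +
                      (R_xlen_t)u * strides[other[1]];
      R_xlen_t st = strides[axis];
      cum[0] = 0.0;
      for (int i = 0; i < len; i++) cum[i + 1] = cum[i] + buf[base + i * st];
      for (int i = 0; i < len; i++) {
        int lo = std::max(0, i - h);
        int hi = std::min(len - 1, i + h);
        line[i] = cum[hi + 1] - cum[lo];
      }
      for (int i = 0; i < len; i++) buf[base + i * st] = line[i];
    }
  (void)outer1; (void)outer2; (void)stride;
}

static std::vector<double> boxsum(const double* x, const int s[3], int D,
                                  int n) {
  R_xlen_t N = (R_xlen_t)s[0] * s[1] * s[2];
  std::vector<double> buf(x, x + N);
  for (int a = 0; a < D; a++) boxsum_axis(buf, s, a, n);
  return buf;
}

// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, int n) {
  IntegerVector d = x.attr("dim");
  int D = d.size();
  int s[3] = {1, 1, 1};
  for (int a = 0; a < D; a++) s[a] = d[a];
  std::vector<double> buf = boxsum(x.begin(), s, D, n);
  NumericVector y(buf.begin(), buf.end());
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_ncc(NumericVector F, NumericVector W, int n, double eps,
             bool want_grad) {
  IntegerVector d = F.attr("dim");
  int D = d.size();
  int s[3] = {1, 1, 1};
  for (int a = 0; a < D; a++) s[a] = d[a];
  R_xlen_t N = (R_xlen_t)s[0] * s[1] * s[2];
  const double* Fp = F.begin();
  const double* Wp = W.begin();

  std::vector<double> ones(N, 1.0), FW(N), FF(N), WW(N);
  for (R_xlen_t i = 0; i < N; i++) {
    FW[i] = Fp[i] * Wp[i];
    FF[i] = Fp[i] * Fp[i];
    WW[i] = Wp[i] * Wp[i];
  }
  std::vector<double> cnt = boxsum(ones.data(), s, D, n);
  std::vector<double> sF = boxsum(Fp, s, D, n);
  std::vector<double> sW = boxsum(Wp, s, D, n);
  std::vector<double> sFW = boxsum(FW.data(), s, D, n);
  std::vector<double> sFF = boxsum(FF.data(), s, D, n);
  std::vector<double> sWW = boxsum(WW.data(), s, D, n);

  double value = 0.0;
  std::vector<double> c1, c2, c1Fb, c2Wb;
  if (want_grad) {
    c1.assign(N, 0.0);
    c2.assign(N, 0.0);
    c1Fb.assign(N, 0.0);
    c2Wb.assign(N, 0.0);
  }
  for (R_xlen_t i = 0; i < N; i++) {
    double k = cnt[i];
    double Fb = sF[i] / k, Wb = sW[i] / k;
    double A = sFW[i] - sF[i] * sW[i] / k;
    double B = sFF[i] - sF[i] * sF[i] / k;
    double Cc = sWW[i] - sW[i] * sW[i] / k;
    double denom = B * Cc + eps;
    double cc = A * A / denom;
    value += cc;
    if (want_grad) {
      double t1 = 2.0 * A / denom / (double)N;
      double t2 = 2.0 * A * A * B / (denom * denom) / (double)N;
      c1[i] = t1;
      c2[i] = t2;
      c1Fb[i] = t1 * Fb;
      c2Wb[i] = t2 * Wb;
    }
  }
  value /= (double)N;

  if (!want_grad)
    return List::create(_["value"] = value);

  std::vector<double> b1 = boxsum(c1.data(), s, D, n);
  std::vector<double> b2 = boxsum(c2.data(), s, D, n);
  std::vector<double> b1F = boxsum(c1Fb.data(), s, D, n);
  std::vector<double> b2W = boxsum(c2Wb.data(), s, D, n);
  NumericVector gW(N);
  gW.attr("dim") = F.attr("dim");
  for (R_xlen_t i = 0; i < N; i++)
    gW[i] = b1[i] * Fp[i] - b1F[i] - b2[i] * Wp[i] + b2W[i];
  return List::create(_["value"] = value, _["gW"] = gW);
}

// ---------------------------------------------------------------------------
// Field smoothness: mean over voxels of the squared norm of the forward
// finite-difference gradient (differences at the far boundary are zero).
// field is (D, S...).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_smooth_fwd(NumericVector field) {
  int Dc, s[3], D;
  get_dims(field, Dc, s, D);
  R_xlen_t N = (R_xlen_t)s[0] * s[1] * s[2];
  const double* fp = field.begin();
  R_xlen_t strides[3] = {1, (R_xlen_t)s[0], (R_xlen_t)s[0] * s[1]};
  double acc = 0.0;
  for (int i2 = 0; i2 < s[2]; i2++)
    for (int i1 = 0; i1 < s[1]; i1++)
      for (int i0 = 0; i0 < s[0]; i0++) {
        int idx[3] = {i0, i1, i2};
        R_xlen_t v = i0 + strides[1] * i1 + strides[2] * i2;
        for (int a = 0; a < D; a++) {
          if (idx[a] + 1 >= s[a]) continue;
          R_xlen_t v2 = v + strides[a];
          for (int c = 0; c < Dc; c++) {
            double dd = fp[c + Dc * v2] - fp[c + Dc * v];
            acc += dd * dd;
          }
        }
      }
  return acc / (double)N;
}

// [[Rcpp::export]]
NumericVector cpp_smooth_bwd(NumericVector field) {
  int Dc, s[3], D;
  get_dims(field, Dc, s, D);
  R_xlen_t N = (R_xlen_t)s[0] * s[1] * s[2];
  NumericVector g(field.size());
  g.attr("dim") = field.attr("dim");
  const double* fp = field.begin();
  double* gp = g.begin();
  R_xlen_t strides[3] = {1, (R_xlen_t)s[0], (R_xlen_t)s[0] * s[1]};
  double scale = 2.0 / (double)N;
  for (int i2 = 0; i2 < s[2]; i2++)
    for (int i1 = 0; i1 < s[1]; i1++)
      for (int i0 = 0; i0 < s[0]; i0++) {
        int idx[3] = {i0, i1, i2};
        R_xlen_t v = i0 + strides[1] * i1 + strides[2] * i2;
        for (int a = 0; a < D; a++) {
          if (idx[a] + 1 >= s[a]) continue;
          R_xlen_t v2 = v + strides[a];
          for (int c = 0; c < Dc; c++) {
            double dd = fp[c + Dc * v2] - fp[c + Dc * v];
            gp[c + Dc * v2] += scale * dd;
            gp[c + Dc * v] -= scale * dd;
          }
        }
      }
  return g;
}

// ---------------------------------------------------------------------------
// Fraction of voxels with non-positive Jacobian determinant of the map
// p -> p + u(p), forward differences, interior voxels only.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_neg_jacobian_frac(NumericVector field) {
  int Dc, s[3], D;
  get_dims(field, Dc, s, D);
  const double* fp = field.begin();
  R_xlen_t strides[3] = {1, (R_xlen_t)s[0], (R_xlen_t)s[0] * s[1]};
  R_xlen_t nbad = 0, ntot = 0;
  for (int i2 = 0; i2 < (D >= 3 ? s[2] - 1 : 1); i2++)
    for (int i1 = 0; i1 < s[1] - 1; i1++)
      for (int i0 = 0; i0 < s[0] - 1; i0++) {
        R_xlen_t v = i0 + strides[1] * i1 + strides[2] * i2;
        double J[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int a = 0; a < D; a++) {
          R_xlen_t v2 = v + strides[a];
          for (int c = 0; c < D; c++)
            J[c][a] = (c == a ? 1.0 : 0.0) +
                      fp[c + Dc * v2] - fp[c + Dc * v];
        }
        double det;
        if (D == 2)
          det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
        else
          det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        ntot++;
        if (det <= 0.0) nbad++;
      }
  return ntot == 0 ? 0.0 : (double)nbad / (double)ntot;
}
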