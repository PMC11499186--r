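// 3D CNN engine for volumetric age regression.
//
// Layout conventions (match R's column-major arrays):
//   * a feature map batch is one arma::mat of size (N*V x C): sample s
//     occupies the contiguous row block [s*V, (s+1)*V), voxel index
//     v = i1 + d1*(i2 + d2*i3), 0-based;
//   * conv weights are (27*C_in x C_out) for 3x3x3 same-padded kernels,
//     column block k*C_in..(k+1)*C_in-1 holds kernel offset k, with
//     k = (o1+1) + 3*((o2+1) + 3*(o3+1)), o* in {-1,0,1}.
//
// Stacking the batch turns every convolution into a single dgemm, and
// batch-norm statistics pooled over voxels and samples become plain
// column means.
//
// Architecture (fixed family, sizes from R):
//   [conv3 -> batchnorm -> maxpool2 -> relu] x B
//   -> conv1x1 -> batchnorm -> relu
//   -> global average pool -> dropout -> linear head (scalar age).
//
// Batch norm uses biased batch variance in training and running statistics
// at inference; eps = 1e-5. All randomness (dropout masks, init, noise)
// lives on the R side so runs are reproducible from R seeds alone.

#include <RcppArmadillo.h>
#include <cstring>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;

static const double BN_EPS = 1e-5;

struct Dim3 {
  int d1, d2, d3;
  int V() const { return d1 * d2 * d3; }
};

// g .* 1[y > 0]
static inline mat relu_grad(const mat& g, const mat& y) {
  return g % arma::conv_to<mat>::from(y > 0);
}

// Gather the (N*V x 27*C) patch matrix for a same-padded 3x3x3 conv.
static mat im2col3(const mat& X, const Dim3& d, int N) {
  const int C = X.n_cols, V = d.V();
  mat col(X.n_rows, 27 * C, arma::fill::zeros);
  int k = 0;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1, ++k) {
        const int i1lo = std::max(0, -o1), i1hi = std::min(d.d1, d.d1 - o1);
        const int run = i1hi - i1lo;
        if (run <= 0) continue;
        const int i2lo = std::max(0, -o2), i2hi = std::min(d.d2, d.d2 - o2);
        const int i3lo = std::max(0, -o3), i3hi = std::min(d.d3, d.d3 - o3);
        for (int c = 0; c < C; ++c) {
          const double* src = X.colptr(c);
          double* dst = col.colptr(k * C + c);
          for (int s = 0; s < N; ++s) {
            const int base = s * V;
            for (int i3 = i3lo; i3 < i3hi; ++i3)
              for (int i2 = i2lo; i2 < i2hi; ++i2) {
                const int vdst = base + i1lo + d.d1 * (i2 + d.d2 * i3);
                const int vsrc = base + (i1lo + o1) +
                  d.d1 * ((i2 + o2) + d.d2 * (i3 + o3));
                std::memcpy(dst + vdst, src + vsrc, run * sizeof(double));
              }
          }
        }
      }
  return col;
}

// Scatter-add adjoint of im2col3: dX(src) += dcol(dst, k).
static mat col2im3(const mat& dcol, const Dim3& d, int N, int C) {
  const int V = d.V();
  mat dX(dcol.n_rows, C, arma::fill::zeros);
  int k = 0;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1, ++k) {
        const int i1lo = std::max(0, -o1), i1hi = std::min(d.d1, d.d1 - o1);
        const int run = i1hi - i1lo;
        if (run <= 0) continue;
        const int i2lo = std::max(0, -o2), i2hi = std::min(d.d2, d.d2 - o2);
        const int i3lo = std::max(0, -o3), i3hi = std::min(d.d3, d.d3 - o3);
        for (int c = 0; c < C; ++c) {
          const double* src = dcol.colptr(k * C + c);
          double* dst = dX.colptr(c);
          for (int s = 0; s < N; ++s) {
            const int base = s * V;
            for (int i3 = i3lo; i3 < i3hi; ++i3)
              for (int i2 = i2lo; i2 < i2hi; ++i2) {
                const int vdst = base + i1lo + d.d1 * (i2 + d.d2 * i3);
                const int vsrc = base + (i1lo + o1) +
                  d.d1 * ((i2 + o2) + d.d2 * (i3 + o3));
                const double* sp = src + vdst;
                double* tp = dst + vsrc;
                for (int r = 0; r < run; ++r) tp[r] += sp[r];
              }
          }
        }
      }
  return dX;
}

// 2x2x2 max pooling with floor semantics (trailing odd slice dropped);
// argmax stores the absolute stacked row index of the winner.
static mat maxpool2(const mat& X, const Dim3& d, int N, Dim3& dp, umat& arg) {
  dp.d1 = d.d1 / 2; dp.d2 = d.d2 / 2; dp.d3 = d.d3 / 2;
  const int C = X.n_cols, V = d.V(), Vp = dp.V();
  mat Y(N * Vp, C);
  arg.set_size(N * Vp, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    arma::uword* a = arg.colptr(c);
    for (int s = 0; s < N; ++s) {
      const int bin = s * V, bout = s * Vp;
      for (int j3 = 0; j3 < dp.d3; ++j3)
        for (int j2 = 0; j2 < dp.d2; ++j2)
          for (int j1 = 0; j1 < dp.d1; ++j1) {
            double best = -arma::datum::inf;
            int bidx = -1;
            for (int o3 = 0; o3 < 2; ++o3)
              for (int o2 = 0; o2 < 2; ++o2)
                for (int o1 = 0; o1 < 2; ++o1) {
                  const int v = bin + (2 * j1 + o1) +
                    d.d1 * ((2 * j2 + o2) + d.d2 * (2 * j3 + o3));
                  if (x[v] > best) { best = x[v]; bidx = v; }
                }
            const int vp = bout + j1 + dp.d1 * (j2 + dp.d2 * j3);
            y[vp] = best;
            a[vp] = (arma::uword)bidx;
          }
    }
  }
  return Y;
}

// Adjoint of maxpool2.
static mat unpool(const mat& dP, const umat& arg, int nrow_in) {
  const int C = dP.n_cols;
  mat dU(nrow_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = dP.colptr(c);
    const arma::uword* a = arg.colptr(c);
    double* u = dU.colptr(c);
    for (arma::uword r = 0; r < dP.n_rows; ++r) u[a[r]] += g[r];
  }
  return dU;
}

// Batch norm, training mode; Z is normalized in place, xhat kept.
static void bn_train(mat& Z, vec& mu, vec& invstd, mat& xhat,
                     const vec& gamma, const vec& beta) {
  mu = arma::mean(Z, 0).t();
  vec var = arma::mean(arma::square(Z), 0).t() - arma::square(mu);
  var.transform([](double v) { return v < 0 ? 0.0 : v; });
  invstd = 1.0 / arma::sqrt(var + BN_EPS);
  Z.each_row() -= mu.t();
  Z.each_row() %= invstd.t();
  xhat = Z;
  Z.each_row() %= gamma.t();
  Z.each_row() += beta.t();
}

// Batch norm backward; returns dZ, accumulates dgamma/dbeta.
static mat bn_backward(const mat& dY, const mat& xhat, const vec& invstd,
                       const vec& gamma, vec& dgamma, vec& dbeta) {
  const double m = (double)dY.n_rows;
  dbeta = arma::sum(dY, 0).t();
  dgamma = arma::sum(dY % xhat, 0).t();
  vec s1 = dbeta % gamma, s2 = dgamma % gamma;
  mat dxhat = dY;
  dxhat.each_row() %= gamma.t();
  mat corr = xhat;
  corr.each_row() %= (s2 / m).t();
  dxhat.each_row() -= (s1 / m).t();
  dxhat -= corr;
  dxhat.each_row() %= invstd.t();
  return dxhat;
}

// Forward + backward over one mini-batch; returns predictions, loss,
// parameter gradients and updated running statistics.
// [[Rcpp::export]]
List cnn_train_batch(const arma::mat& xbatch, IntegerVector dims, List params,
                     NumericVector target, std::string loss,
                     const arma::mat& dropmask, double bn_momentum) {
  const int N = xbatch.n_cols;
  List convW = params["conv_W"], convB = params["conv_b"];
  List gamL = params["bn_gamma"], betL = params["bn_beta"];
  List rmL = params["bn_mean"], rvL = params["bn_var"];
  mat projW = as<mat>(params["proj_W"]);
  vec projB = as<vec>(params["proj_b"]);
  vec headW = as<vec>(params["head_w"]);
  double headB = as<double>(params["head_b"]);
  const int B = convW.size();

  std::vector<Dim3> din(B + 1);
  din[0] = { dims[0], dims[1], dims[2] };

  std::vector<mat> cols(B), xhat(B + 1), post(B + 1);
  std::vector<umat> argm(B);
  std::vector<vec> invstd(B + 1), muv(B + 1);
  List new_rm(B + 1), new_rv(B + 1);

  mat X(arma::vectorise(xbatch));

  // ---- forward ----
  for (int b = 0; b < B; ++b) {
    vec gamma = as<vec>(gamL[b]), beta = as<vec>(betL[b]);
    cols[b] = im2col3(X, din[b], N);
    mat Z = cols[b] * as<mat>(convW[b]);
    Z.each_row() += as<vec>(convB[b]).t();
    bn_train(Z, muv[b], invstd[b], xhat[b], gamma, beta);
    vec var = 1.0 / arma::square(invstd[b]) - BN_EPS;
    new_rm[b] = (1.0 - bn_momentum) * as<vec>(rmL[b]) + bn_momentum * muv[b];
    new_rv[b] = (1.0 - bn_momentum) * as<vec>(rvL[b]) + bn_momentum * var;
    Dim3 dp;
    mat P = maxpool2(Z, din[b], N, dp, argm[b]);
    post[b] = arma::clamp(P, 0.0, arma::datum::inf);
    X = post[b];
    din[b + 1] = dp;
  }

  mat Xproj = X; // input to the 1x1x1 block, needed for its weight grad
  {
    vec gamma = as<vec>(gamL[B]), beta = as<vec>(betL[B]);
    mat Z = X * projW;
    Z.each_row() += projB.t();
    bn_train(Z, muv[B], invstd[B], xhat[B], gamma, beta);
    vec var = 1.0 / arma::square(invstd[B]) - BN_EPS;
    new_rm[B] = (1.0 - bn_momentum) * as<vec>(rmL[B]) + bn_momentum * muv[B];
    new_rv[B] = (1.0 - bn_momentum) * as<vec>(rvL[B]) + bn_momentum * var;
    post[B] = arma::clamp(Z, 0.0, arma::datum::inf);
  }

  const int Ch = projW.n_cols;
  const int Vp = din[B].V();
  mat G(Ch, N), H(Ch, N);
  vec pred(N);
  for (int s = 0; s < N; ++s) {
    G.col(s) = arma::mean(post[B].rows(s * Vp, (s + 1) * Vp - 1), 0).t();
    H.col(s) = G.col(s) % dropmask.col(s);
    pred(s) = arma::dot(headW, H.col(s)) + headB;
  }

  // ---- loss ----
  vec tgt = as<vec>(target);
  vec diff = pred - tgt;
  double lval;
  vec dpred(N);
  if (loss == "mse") {
    lval = arma::mean(arma::square(diff));
    dpred = 2.0 * diff / N;
  } else { // mae
    lval = arma::mean(arma::abs(diff));
    dpred = arma::sign(diff) / N;
  }

  // ---- backward ----
  vec d_headW = H * dpred;
  double d_headB = arma::sum(dpred);
  mat dG = (headW * dpred.t()) % dropmask; // Ch x N

  mat dY(N * Vp, Ch);
  for (int s = 0; s < N; ++s)
    dY.rows(s * Vp, (s + 1) * Vp - 1) =
      arma::ones<mat>(Vp, 1) * (dG.col(s).t() / Vp);

  List d_convW(B), d_convB(B), d_gam(B + 1), d_bet(B + 1);

  // projection block backward
  dY = relu_grad(dY, post[B]);
  vec dg, db;
  dY = bn_backward(dY, xhat[B], invstd[B], as<vec>(gamL[B]), dg, db);
  d_gam[B] = dg; d_bet[B] = db;
  mat d_projW = Xproj.t() * dY;
  vec d_projB = arma::sum(dY, 0).t();
  dY = dY * projW.t();

  for (int b = B - 1; b >= 0; --b) {
    mat W = as<mat>(convW[b]);
    dY = relu_grad(dY, post[b]);
    mat dZ = unpool(dY, argm[b], cols[b].n_rows);
    dZ = bn_backward(dZ, xhat[b], invstd[b], as<vec>(gamL[b]), dg, db);
    d_gam[b] = dg; d_bet[b] = db;
    d_convW[b] = cols[b].t() * dZ;
    d_convB[b] = arma::sum(dZ, 0).t();
    if (b > 0) { // the gradient w.r.t. the network input is not needed
      mat dcol = dZ * W.t();
      dY = col2im3(dcol, din[b], N, as<mat>(convW[b - 1]).n_cols);
    }
  }

  List grads = List::create(
    Named("conv_W") = d_convW, Named("conv_b") = d_convB,
    Named("bn_gamma") = d_gam, Named("bn_beta") = d_bet,
    Named("proj_W") = d_projW, Named("proj_b") = d_projB,
    Named("head_w") = d_headW, Named("head_b") = d_headB);

  return List::create(Named("pred") = pred, Named("loss") = lval,
                      Named("grads") = grads,
                      Named("bn_mean") = new_rm, Named("bn_var") = new_rv);
}

// Inference forward pass (running BN statistics, no dropout); optionally
// returns d(pred)/d(input) for each sample (the saliency gradient).
// [[Rcpp::export]]
List cnn_infer(const arma::mat& xbatch, IntegerVector dims, List params,
               bool input_grad) {
  const int N = xbatch.n_cols;
  List convW = params["conv_W"], convB = params["conv_b"];
  List gamL = params["bn_gamma"], betL = params["bn_beta"];
  List rmL = params["bn_mean"], rvL = params["bn_var"];
  mat projW = as<mat>(params["proj_W"]);
  vec projB = as<vec>(params["proj_b"]);
  vec headW = as<vec>(params["head_w"]);
  double headB = as<double>(params["head_b"]);
  const int B = convW.size();

  std::vector<Dim3> din(B + 1);
  din[0] = { dims[0], dims[1], dims[2] };

  std::vector<mat> post(B + 1);
  std::vector<umat> argm(B);
  std::vector<vec> scale(B + 1); // per-channel gamma / sqrt(rv + eps)

  mat X(arma::vectorise(xbatch));

  for (int b = 0; b < B; ++b) {
    vec gamma = as<vec>(gamL[b]), beta = as<vec>(betL[b]);
    vec rm = as<vec>(rmL[b]), rv = as<vec>(rvL[b]);
    scale[b] = gamma / arma::sqrt(rv + BN_EPS);
    vec shift = beta - rm % scale[b];
    mat Z = im2col3(X, din[b], N) * as<mat>(convW[b]);
    Z.each_row() += as<vec>(convB[b]).t();
    Z.each_row() %= scale[b].t();
    Z.each_row() += shift.t();
    Dim3 dp;
    mat P = maxpool2(Z, din[b], N, dp, argm[b]);
    post[b] = arma::clamp(P, 0.0, arma::datum::inf);
    X = post[b];
    din[b + 1] = dp;
  }

  {
    vec gamma = as<vec>(gamL[B]), beta = as<vec>(betL[B]);
    vec rm = as<vec>(rmL[B]), rv = as<vec>(rvL[B]);
    scale[B] = gamma / arma::sqrt(rv + BN_EPS);
    vec shift = beta - rm % scale[B];
    mat Z = X * projW;
    Z.each_row() += projB.t();
    Z.each_row() %= scale[B].t();
    Z.each_row() += shift.t();
    post[B] = arma::clamp(Z, 0.0, arma::datum::inf);
  }

  const int Vp = din[B].V();
  vec pred(N);
  for (int s = 0; s < N; ++s)
    pred(s) = arma::dot(headW,
                        arma::mean(post[B].rows(s * Vp, (s + 1) * Vp - 1), 0)
                          .t()) + headB;

  if (!input_grad)
    return List::create(Named("pred") = pred);

  // d pred / d GAP-input rows = headW / Vp, back through the (affine at
  // inference) BN layers, relu masks, pool argmaxes and convolutions.
  mat dY(N * Vp, projW.n_cols);
  for (int s = 0; s < N; ++s)
    dY.rows(s * Vp, (s + 1) * Vp - 1) =
      arma::ones<mat>(Vp, 1) * (headW.t() / Vp);
  dY = relu_grad(dY, post[B]);
  dY.each_row() %= scale[B].t();
  dY = dY * projW.t();
  for (int b = B - 1; b >= 0; --b) {
    mat W = as<mat>(convW[b]);
    dY = relu_grad(dY, post[b]);
    mat dU = unpool(dY, argm[b], (arma::uword)N * din[b].V());
    dU.each_row() %= scale[b].t();
    const int Cin = (b == 0) ? 1 : as<mat>(convW[b - 1]).n_cols;
    mat dcol = dU * W.t();
    dY = col2im3(dcol, din[b], N, Cin);
  }
  mat gout(din[0].V(), N);
  for (int s = 0; s < N; ++s)
    gout.col(s) = dY.col(0).rows((arma::uword)s * din[0].V(),
                                 (arma::uword)(s + 1) * din[0].V() - 1);
  return List::create(Named("pred") = pred, Named("input_grad") = gout);
}
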