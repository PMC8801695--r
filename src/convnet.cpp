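// Residual encoder-bottleneck-decoder network for 2-D slice-to-slice
// kernel conversion, with hand-written backpropagation and Adam.
//
// Feature maps are stored as (Npix x C) matrices with column-major pixel
// index p = r + c*H, matching R's array layout. Convolutions are 3x3 with
// zero padding 1, implemented via im2col + GEMM. All randomness (weight
// init, shuffling) is supplied by the caller, so given identical inputs the
// training loop is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static const double IN_EPS = 1e-5;

static void im2col(const mat& X, int H, int W, int C, int stride, int k,
                   mat& K, int& Ho, int& Wo) {
  int pad = k / 2;
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
  K.zeros(Ho * Wo, C * k * k);
  for (int c = 0; c < C; c++) {
    const double* xc = X.colptr(c);
    for (int dc = 0; dc < k; dc++) {
      for (int dr = 0; dr < k; dr++) {
        double* kcol = K.colptr(c * k * k + dr * k + dc);
        for (int oc = 0; oc < Wo; oc++) {
          int ic = oc * stride - pad + dc;
          if (ic < 0 || ic >= W) continue;
          for (int orr = 0; orr < Ho; orr++) {
            int ir = orr * stride - pad + dr;
            if (ir < 0 || ir >= H) continue;
            kcol[orr + oc * Ho] = xc[ir + ic * H];
          }
        }
      }
    }
  }
}

static void col2im(const mat& dK, int H, int W, int C, int stride, int k,
                   int Ho, int Wo, mat& dX) {
  int pad = k / 2;
  dX.zeros(H * W, C);
  for (int c = 0; c < C; c++) {
    double* xc = dX.colptr(c);
    for (int dc = 0; dc < k; dc++) {
      for (int dr = 0; dr < k; dr++) {
        const double* kcol = dK.colptr(c * k * k + dr * k + dc);
        for (int oc = 0; oc < Wo; oc++) {
          int ic = oc * stride - pad + dc;
          if (ic < 0 || ic >= W) continue;
          for (int orr = 0; orr < Ho; orr++) {
            int ir = orr * stride - pad + dr;
            if (ir < 0 || ir >= H) continue;
            xc[ir + ic * H] += kcol[orr + oc * Ho];
          }
        }
      }
    }
  }
}

// nearest-neighbour 2x upsampling, (h*w, C) -> (4*h*w, C)
static mat up2(const mat& A, int h, int w) {
  int C = A.n_cols, H2 = 2 * h;
  mat U(4 * h * w, C);
  for (int c = 0; c < C; c++) {
    const double* a = A.colptr(c);
    double* u = U.colptr(c);
    for (int oc = 0; oc < 2 * w; oc++) {
      int ic = oc >> 1;
      for (int orr = 0; orr < H2; orr++) {
        u[orr + oc * H2] = a[(orr >> 1) + ic * h];
      }
    }
  }
  return U;
}

// backward of up2: sum gradients of each 2x2 block. h, w are low-res dims.
static mat up2_bwd(const mat& dU, int h, int w) {
  int C = dU.n_cols, H2 = 2 * h;
  mat dA(h * w, C, fill::zeros);
  for (int c = 0; c < C; c++) {
    const double* u = dU.colptr(c);
    double* a = dA.colptr(c);
    for (int oc = 0; oc < 2 * w; oc++) {
      int ic = oc >> 1;
      for (int orr = 0; orr < H2; orr++) {
        a[(orr >> 1) + ic * h] += u[orr + oc * H2];
      }
    }
  }
  return dA;
}

struct Model {
  int n_down, n_res, C, L;
  bool use_in, use_skip, global_res;
  std::vector<mat> Wt;
  std::vector<vec> bv, gv, bev;
  std::vector<int> cin, cout, stridev, ksz;
  std::vector<bool> hasin;

  void layout(const List& cfg) {
    n_down = Rcpp::as<int>(cfg["n_down"]);
    n_res = Rcpp::as<int>(cfg["n_res"]);
    C = Rcpp::as<int>(cfg["base_channels"]);
    use_in = Rcpp::as<bool>(cfg["use_instance_norm"]);
    use_skip = Rcpp::as<bool>(cfg["skip_connections"]);
    global_res = cfg.containsElementNamed("global_residual") ?
      Rcpp::as<bool>(cfg["global_residual"]) : false;
    L = 1 + n_down + 2 * n_res + n_down + 1;
    cin.resize(L); cout.resize(L); stridev.resize(L); hasin.resize(L);
    ksz.assign(L, 3);
    int li = 0;
    cin[li] = 1; cout[li] = C; stridev[li] = 1; hasin[li] = use_in; li++;
    int ch = C;
    for (int d = 0; d < n_down; d++) {
      cin[li] = ch; cout[li] = 2 * ch; stridev[li] = 2; hasin[li] = use_in;
      ch *= 2; li++;
    }
    for (int r = 0; r < 2 * n_res; r++) {
      cin[li] = ch; cout[li] = ch; stridev[li] = 1; hasin[li] = use_in; li++;
    }
    for (int u = 0; u < n_down; u++) {
      cin[li] = ch; cout[li] = ch / 2; stridev[li] = 1; hasin[li] = use_in;
      ch /= 2; li++;
    }
    cin[li] = ch; cout[li] = 1; stridev[li] = 1; hasin[li] = false;
  }

  void from_list(const List& cfg, const List& params) {
    layout(cfg);
    Wt.resize(L); bv.resize(L); gv.resize(L); bev.resize(L);
    int pi = 0;
    for (int li = 0; li < L; li++) {
      Wt[li] = Rcpp::as<mat>(params[pi++]);
      bv[li] = Rcpp::as<vec>(params[pi++]);
      if ((int)Wt[li].n_rows != cin[li] * ksz[li] * ksz[li] ||
          (int)Wt[li].n_cols != cout[li]) {
        Rcpp::stop("weight shape mismatch at conv layer %d", li);
      }
      if (hasin[li]) {
        gv[li] = Rcpp::as<vec>(params[pi++]);
        bev[li] = Rcpp::as<vec>(params[pi++]);
      }
    }
  }

  List to_list() const {
    List out;
    for (int li = 0; li < L; li++) {
      out.push_back(Wt[li]);
      out.push_back(bv[li]);
      if (hasin[li]) {
        out.push_back(gv[li]);
        out.push_back(bev[li]);
      }
    }
    return out;
  }
};

struct Caches {
  std::vector<mat> K, xhat, out;
  std::vector<rowvec> sdv;
  std::vector<int> Hin, Win, Hout, Wout;
  std::vector<mat> skips;
  mat Zfinal;
  void init(int L, int n_down) {
    K.resize(L); xhat.resize(L); out.resize(L); sdv.resize(L);
    Hin.assign(L, 0); Win.assign(L, 0); Hout.assign(L, 0); Wout.assign(L, 0);
    skips.resize(n_down);
  }
};

struct Grads {
  std::vector<mat> dW;
  std::vector<vec> db, dg, dbe;
  void init(const Model& M) {
    dW.resize(M.L); db.resize(M.L); dg.resize(M.L); dbe.resize(M.L);
    for (int li = 0; li < M.L; li++) {
      dW[li].zeros(M.cin[li] * M.ksz[li] * M.ksz[li], M.cout[li]);
      db[li].zeros(M.cout[li]);
      if (M.hasin[li]) {
        dg[li].zeros(M.cout[li]);
        dbe[li].zeros(M.cout[li]);
      }
    }
  }
  void zero() {
    for (size_t li = 0; li < dW.size(); li++) {
      dW[li].zeros(); db[li].zeros();
      if (dg[li].n_elem) { dg[li].zeros(); dbe[li].zeros(); }
    }
  }
};

// conv -> (instance norm) -> (ReLU), caching what backward needs
static mat block_fwd(const Model& M, Caches& ca, int li, const mat& X,
                     int Hin, int Win, bool relu) {
  int Ho, Wo;
  im2col(X, Hin, Win, M.cin[li], M.stridev[li], M.ksz[li], ca.K[li], Ho, Wo);
  ca.Hin[li] = Hin; ca.Win[li] = Win; ca.Hout[li] = Ho; ca.Wout[li] = Wo;
  mat Z = ca.K[li] * M.Wt[li];
  Z.each_row() += M.bv[li].t();
  if (M.hasin[li]) {
    int N = Z.n_rows;
    ca.xhat[li].set_size(N, Z.n_cols);
    ca.sdv[li].set_size(Z.n_cols);
    for (unsigned j = 0; j < Z.n_cols; j++) {
      double mu = mean(Z.col(j));
      vec d = Z.col(j) - mu;
      double s = std::sqrt(dot(d, d) / N + IN_EPS);
      ca.sdv[li](j) = s;
      ca.xhat[li].col(j) = d / s;
      Z.col(j) = M.gv[li](j) * ca.xhat[li].col(j) + M.bev[li](j);
    }
  }
  if (relu) Z.transform([](double v) { return v > 0 ? v : 0.0; });
  ca.out[li] = Z;
  return Z;
}

// backward through (ReLU) -> (instance norm) -> conv; returns grad wrt input
static mat block_bwd(const Model& M, const Caches& ca, Grads& G, int li,
                     mat dOut, bool relu) {
  if (relu) dOut %= conv_to<mat>::from(ca.out[li] > 0);
  mat dZ(dOut.n_rows, dOut.n_cols);
  if (M.hasin[li]) {
    int N = dOut.n_rows;
    for (unsigned j = 0; j < dOut.n_cols; j++) {
      const vec xh = ca.xhat[li].col(j);
      G.dg[li](j) += dot(dOut.col(j), xh);
      G.dbe[li](j) += accu(dOut.col(j));
      vec dxh = dOut.col(j) * M.gv[li](j);
      double m1 = accu(dxh) / N;
      double m2 = dot(dxh, xh) / N;
      dZ.col(j) = (dxh - m1 - xh * m2) / ca.sdv[li](j);
    }
  } else {
    dZ = dOut;
  }
  G.dW[li] += ca.K[li].t() * dZ;
  G.db[li] += sum(dZ, 0).t();
  mat dK = dZ * M.Wt[li].t();
  mat dX;
  col2im(dK, ca.Hin[li], ca.Win[li], M.cin[li], M.stridev[li], M.ksz[li],
         ca.Hout[li], ca.Wout[li], dX);
  return dX;
}

// full forward for one slice; x is (H*W x 1) in normalised units
static vec net_forward(const Model& M, Caches& ca, const vec& x, int H, int W) {
  ca.init(M.L, M.n_down);
  mat A(x);
  int li = 0, h = H, w = W;
  A = block_fwd(M, ca, li++, A, h, w, true); // stem
  if (M.use_skip) ca.skips[0] = A;
  for (int d = 0; d < M.n_down; d++) {
    A = block_fwd(M, ca, li++, A, h, w, true);
    h /= 2; w /= 2;
    if (M.use_skip && d < M.n_down - 1) ca.skips[d + 1] = A;
  }
  for (int r = 0; r < M.n_res; r++) {
    mat B = block_fwd(M, ca, li++, A, h, w, true);
    B = block_fwd(M, ca, li++, B, h, w, false);
    A += B;
  }
  for (int u = 0; u < M.n_down; u++) {
    A = up2(A, h, w);
    h *= 2; w *= 2;
    A = block_fwd(M, ca, li++, A, h, w, true);
    if (M.use_skip) A += ca.skips[M.n_down - 1 - u];
  }
  ca.Zfinal = block_fwd(M, ca, li++, A, h, w, false);
  if (M.global_res) {
    // parameter-free identity path: the bounded output stays anchored to
    // the input level, so the network learns the kernel-difference residual
    ca.Zfinal.col(0) += tan(0.5 * datum::pi * clamp(x, -0.999, 0.999));
  }
  return (2.0 / datum::pi) * atan(ca.Zfinal.col(0));
}

// full backward; dy is grad wrt the network output vector
static void net_backward(const Model& M, const Caches& ca, Grads& G,
                         const vec& dy) {
  vec z = ca.Zfinal.col(0);
  mat dA((2.0 / datum::pi) * (dy / (1.0 + z % z)));
  int li = M.L - 1;
  dA = block_bwd(M, ca, G, li--, dA, false); // final conv
  std::vector<mat> dskips(M.n_down);
  for (int u = M.n_down - 1; u >= 0; u--) {
    int sidx = M.n_down - 1 - u;
    if (M.use_skip) {
      if (dskips[sidx].n_elem == 0) dskips[sidx] = dA;
      else dskips[sidx] += dA;
    }
    dA = block_bwd(M, ca, G, li, dA, true);
    dA = up2_bwd(dA, ca.Hin[li] / 2, ca.Win[li] / 2);
    li--;
  }
  for (int r = M.n_res - 1; r >= 0; r--) {
    mat dB = block_bwd(M, ca, G, li--, dA, false);
    dB = block_bwd(M, ca, G, li--, dB, true);
    dA += dB;
  }
  for (int d = M.n_down - 1; d >= 0; d--) {
    dA = block_bwd(M, ca, G, li--, dA, true);
    if (M.use_skip && d >= 1 && dskips[d].n_elem) dA += dskips[d];
  }
  if (M.use_skip && dskips[0].n_elem) dA += dskips[0];
  block_bwd(M, ca, G, li--, dA, true); // stem; input grad discarded
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb, mg, vg, mbe, vbe;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Model& M) {
    mW.resize(M.L); vW.resize(M.L); mb.resize(M.L); vb.resize(M.L);
    mg.resize(M.L); vg.resize(M.L); mbe.resize(M.L); vbe.resize(M.L);
    for (int li = 0; li < M.L; li++) {
      mW[li].zeros(M.cin[li] * M.ksz[li] * M.ksz[li], M.cout[li]);
      vW[li] = mW[li];
      mb[li].zeros(M.cout[li]); vb[li] = mb[li];
      if (M.hasin[li]) {
        mg[li].zeros(M.cout[li]); vg[li] = mg[li];
        mbe[li].zeros(M.cout[li]); vbe[li] = mbe[li];
      }
    }
  }
  template <class T>
  void upd(T& p, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    p -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Model& M, const Grads& G, double lr) {
    t++;
    for (int li = 0; li < M.L; li++) {
      upd(M.Wt[li], mW[li], vW[li], G.dW[li], lr);
      upd(M.bv[li], mb[li], vb[li], G.db[li], lr);
      if (M.hasin[li]) {
        upd(M.gv[li], mg[li], vg[li], G.dg[li], lr);
        upd(M.bev[li], mbe[li], vbe[li], G.dbe[li], lr);
      }
    }
  }
};

// [[Rcpp::export]]
arma::cube cnn_forward_cpp(List params, List cfg, const arma::cube& X) {
  Model M;
  M.from_list(cfg, params);
  int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  cube Y(H, W, N);
  Caches ca;
  for (int i = 0; i < N; i++) {
    vec x = vectorise(X.slice(i));
    vec y = net_forward(M, ca, x, H, W);
    Y.slice(i) = reshape(y, H, W);
    if (i % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return Y;
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, List cfg, const arma::cube& X,
                   const arma::cube& Y, const arma::cube& Msk,
                   double l1w, double l2w, int batch,
                   const arma::vec& lr_epoch, const arma::imat& order,
                   double adam_beta1 = 0.9, double adam_beta2 = 0.999,
                   int swa_from = 0,
                   Rcpp::Nullable<Rcpp::IntegerMatrix> flips = R_NilValue) {
  // flips: optional n x epochs matrix of codes 0..3 (bit 1 = flip rows,
  // bit 2 = flip cols) applied to input/target/mask as augmentation
  // swa_from > 0: also return parameters averaged over epochs swa_from..E
  // (tail averaging; valid under instance norm, which keeps no running stats)
  Model M;
  M.from_list(cfg, params);
  int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  int epochs = lr_epoch.n_elem;
  if ((int)order.n_rows != N || (int)order.n_cols != epochs) {
    Rcpp::stop("shuffle order must be n_slices x epochs");
  }
  imat flipm;
  bool use_flips = flips.isNotNull();
  if (use_flips) {
    flipm = Rcpp::as<imat>(flips.get());
    if ((int)flipm.n_rows != N || (int)flipm.n_cols != epochs) {
      Rcpp::stop("flip matrix must be n_slices x epochs");
    }
  }
  Adam opt;
  opt.b1 = adam_beta1;
  opt.b2 = adam_beta2;
  opt.init(M);
  Grads G;
  G.init(M);
  Caches ca;
  vec loss_hist(epochs, fill::zeros);
  Model Mswa;
  int n_swa = 0;
  for (int e = 0; e < epochs; e++) {
    double lr = lr_epoch(e);
    double eloss = 0;
    int nbatch = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int b1 = std::min(b0 + batch, N);
      G.zero();
      double nvalid = 0;
      for (int k = b0; k < b1; k++) {
        nvalid += accu(Msk.slice(order(k, e) - 1));
      }
      if (nvalid <= 0) continue;
      double bloss = 0;
      for (int k = b0; k < b1; k++) {
        int i = order(k, e) - 1;
        mat xs = X.slice(i), ys = Y.slice(i), ms = Msk.slice(i);
        if (use_flips) {
          int f = flipm(k, e);
          if (f & 1) { xs = flipud(xs); ys = flipud(ys); ms = flipud(ms); }
          if (f & 2) { xs = fliplr(xs); ys = fliplr(ys); ms = fliplr(ms); }
        }
        vec x = vectorise(xs);
        vec y = vectorise(ys);
        vec m = vectorise(ms);
        vec out = net_forward(M, ca, x, H, W);
        vec err = out - y;
        bloss += accu((l1w * abs(err) + l2w * err % err) % m) / nvalid;
        vec dy = (l1w * sign(err) + 2.0 * l2w * err) % m / nvalid;
        net_backward(M, ca, G, dy);
      }
      if (!std::isfinite(bloss)) {
        Rcpp::stop("training loss became non-finite at epoch %d, batch %d",
                   e + 1, nbatch + 1);
      }
      opt.step(M, G, lr);
      eloss += bloss;
      nbatch++;
      Rcpp::checkUserInterrupt();
    }
    loss_hist(e) = nbatch > 0 ? eloss / nbatch : datum::nan;
    if (swa_from > 0 && e + 1 >= swa_from) {
      if (n_swa == 0) {
        Mswa = M;
      } else {
        for (int li = 0; li < M.L; li++) {
          Mswa.Wt[li] += M.Wt[li];
          Mswa.bv[li] += M.bv[li];
          if (M.hasin[li]) { Mswa.gv[li] += M.gv[li]; Mswa.bev[li] += M.bev[li]; }
        }
      }
      n_swa++;
    }
  }
  if (swa_from > 0 && n_swa > 0) {
    for (int li = 0; li < M.L; li++) {
      Mswa.Wt[li] /= n_swa;
      Mswa.bv[li] /= n_swa;
      if (M.hasin[li]) { Mswa.gv[li] /= n_swa; Mswa.bev[li] /= n_swa; }
    }
    return List::create(Rcpp::Named("params") = Mswa.to_list(),
                        Rcpp::Named("loss_history") = loss_hist,
                        Rcpp::Named("last_params") = M.to_list());
  }
  return List::create(Rcpp::Named("params") = M.to_list(),
                      Rcpp::Named("loss_history") = loss_hist);
}

// loss and gradients on a fixed batch; the hook for finite-difference checks
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List params, List cfg, const arma::cube& X,
                       const arma::cube& Y, const arma::cube& Msk,
                       double l1w, double l2w) {
  Model M;
  M.from_list(cfg, params);
  int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  Grads G;
  G.init(M);
  Caches ca;
  double nvalid = accu(Msk);
  double loss = 0;
  for (int i = 0; i < N; i++) {
    vec x = vectorise(X.slice(i));
    vec y = vectorise(Y.slice(i));
    vec m = vectorise(Msk.slice(i));
    vec out = net_forward(M, ca, x, H, W);
    vec err = out - y;
    loss += accu((l1w * abs(err) + l2w * err % err) % m) / nvalid;
    vec dy = (l1w * sign(err) + 2.0 * l2w * err) % m / nvalid;
    net_backward(M, ca, G, dy);
  }
  List gl;
  for (int li = 0; li < M.L; li++) {
    gl.push_back(G.dW[li]);
    gl.push_back(G.db[li]);
    if (M.hasin[li]) {
      gl.push_back(G.dg[li]);
      gl.push_back(G.dbe[li]);
    }
  }
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grads") = gl);
}
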