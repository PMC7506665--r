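// Minimal CNN / CRNN engine for log-mel spectrogram classification.
//
// Feature maps are stored per sample as (H*W) x C matrices, column-major
// over channels; spatial position (i, j) maps to row i + j*H with i the
// time axis and j the frequency axis. Convolution is im2col + GEMM; the
// im2col matrix is rebuilt in the backward pass rather than cached so the
// memory high-water mark stays proportional to the activations.
//
// The trunk is pairs of 3x3 convolutions (stride 1, zero padding 1), each
// followed by batch normalisation and ReLU, with a 2x2 max pool (floor)
// closing every stage. Heads: global average pooling -> dense softmax
// (cnn), or a bidirectional GRU/LSTM over the pooled time axis whose
// ReLU'd outputs are time-averaged before the dense softmax (crnn).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;
using arma::uvec;
using arma::uword;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.9;

struct Shape { int H; int W; };

// neighbour row indices for a 3x3 window; out-of-bounds -> H*W (zero row)
static umat make_nbr(int H, int W) {
  umat nbr(H * W, 9);
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          int ii = i + di, jj = j + dj;
          uword r = (uword)(i + j * H);
          nbr(r, k) = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                          ? (uword)(ii + jj * H)
                          : (uword)(H * W);
        }
      }
      ++k;
    }
  }
  return nbr;
}

static void im2col(const mat& X, const umat& nbr, mat& M) {
  const uword Cin = X.n_cols, HW = X.n_rows;
  M.set_size(HW, 9 * Cin);
  for (int k = 0; k < 9; ++k) {
    const uword* idx = nbr.colptr(k);
    for (uword c = 0; c < Cin; ++c) {
      const double* xp = X.colptr(c);
      double* mp = M.colptr(k * Cin + c);
      for (uword r = 0; r < HW; ++r) {
        const uword j = idx[r];
        mp[r] = (j < HW) ? xp[j] : 0.0;
      }
    }
  }
}

// scatter dM back onto dX; within one k the targets are distinct
static void col2im_add(mat& dX, const mat& dM, const umat& nbr) {
  const uword Cin = dX.n_cols, HW = dX.n_rows;
  for (int k = 0; k < 9; ++k) {
    const uword* idx = nbr.colptr(k);
    for (uword c = 0; c < Cin; ++c) {
      double* xp = dX.colptr(c);
      const double* mp = dM.colptr(k * Cin + c);
      for (uword r = 0; r < HW; ++r) {
        const uword j = idx[r];
        if (j < HW) xp[j] += mp[r];
      }
    }
  }
}

struct ConvCache {
  const std::vector<mat>* in; // layer input; owned by the previous cache
  std::vector<mat> z;         // conv output, pre-BN
  rowvec mean, var;           // batch statistics (training) or running (eval)
  std::vector<mat> out;       // post-ReLU
};

struct PoolCache {
  std::vector<umat> argmax; // source row per pooled element
};

struct RnnCache {
  // batch-major per timestep
  std::vector<mat> h_prev, z, r, n;          // GRU
  std::vector<mat> i_, f_, g_, o_, c_, cprev; // LSTM
  std::vector<mat> out; // per-direction hidden per step
};

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

class Net {
public:
  arma::ivec channels;
  std::string kind; // "cnn", "gru", "lstm"
  int R, K, H0, W0, B;
  bool training;
  List params;

  std::vector<Shape> shapes;       // per stage input shape
  Shape final_shape;               // after last pool
  std::vector<umat> nbrs;          // per stage

  // caches
  std::vector<ConvCache> cc;       // 2 per stage: index 2*s + l
  std::vector<PoolCache> pc;
  std::vector<std::vector<mat>> pool_out; // per stage, per sample (HW x C)
  // rnn
  RnnCache rcf, rcb;
  mat seq_mean; // B x F features entering head
  mat relu_mask_rnn_f, relu_mask_rnn_b; // unused; masks kept per step
  std::vector<mat> O; // per step B x 2R post-ReLU
  std::vector<mat> Opre; // pre-ReLU
  mat logits, probs;

  // grad-cam capture: post-ReLU activation of the last conv layer and its
  // gradient, sample 0
  mat gc_act, gc_grad;

  Net(List cfg, List params_, List state, bool training_)
      : params(params_), training(training_) {
    state_ = clone(state);
    channels = as<arma::ivec>(cfg["channels"]);
    kind = as<std::string>(cfg["kind"]);
    R = as<int>(cfg["rnn_width"]);
    K = as<int>(cfg["n_classes"]);
    H0 = as<int>(cfg["input_frames"]);
    W0 = as<int>(cfg["n_mels"]);
    int H = H0, W = W0;
    for (uword s = 0; s < channels.n_elem; ++s) {
      shapes.push_back({H, W});
      nbrs.push_back(make_nbr(H, W));
      H /= 2; W /= 2;
      if (H < 1 || W < 1)
        stop("architecture: input too small for the pooling plan");
    }
    final_shape = {H, W};
  }

  mat P(const std::string& nm) { return as<mat>(params[nm]); }
  vec Pv(const std::string& nm) { return as<vec>(params[nm]); }
  rowvec Sv(const std::string& nm) {
    return as<rowvec>(state_[nm]);
  }

  // ---------- forward ----------
  mat forward(const std::vector<mat>& xs) {
    B = (int)xs.size();
    int S = (int)channels.n_elem;
    cc.resize(2 * S);
    pc.resize(S);
    pool_out.resize(S);
    const std::vector<mat>* cur = &xs;
    for (int s = 0; s < S; ++s) {
      for (int l = 0; l < 2; ++l) {
        conv_bn_relu(cur, s, l);
        cur = &cc[2 * s + l].out;
      }
      if (s == S - 1) { gc_act = (*cur)[0]; }
      maxpool(*cur, s);
      cur = &pool_out[s];
    }

    const std::vector<mat>& trunk = pool_out[S - 1];
    mat feat;
    if (kind == "cnn") {
      int C = (int)channels(S - 1);
      feat.set_size(B, C);
      for (int b = 0; b < B; ++b) feat.row(b) = arma::mean(trunk[b], 0);
    } else {
      feat = rnn_forward(trunk);
    }
    seq_mean = feat;
    mat Wy = P("head_W");
    rowvec by = P("head_b").row(0);
    logits = feat * Wy;
    logits.each_row() += by;
    mat m = arma::max(logits, 1) * arma::ones<rowvec>(K);
    mat e = arma::exp(logits - m);
    probs = e / (arma::sum(e, 1) * arma::ones<rowvec>(K));
    return probs;
  }

  void conv_bn_relu(const std::vector<mat>* in_ptr, int s, int l) {
    const std::vector<mat>& in = *in_ptr;
    char nm[64];
    snprintf(nm, sizeof nm, "conv%d_%d", s + 1, l + 1);
    std::string base(nm);
    mat Wm = P(base + "_W");
    rowvec bv = P(base + "_b").row(0);
    rowvec gamma = P(base + "_g").row(0);
    rowvec beta = P(base + "_be").row(0);
    ConvCache& C = cc[2 * s + l];
    C.in = in_ptr;
    C.z.resize(B);
    C.out.resize(B);
    const umat& nbr = nbrs[s];
    uword Cout = Wm.n_cols;
    // conv (im2col buffer reused across the batch)
    mat M;
    for (int b = 0; b < B; ++b) {
      im2col(in[b], nbr, M);
      C.z[b] = M * Wm;
      C.z[b].each_row() += bv;
    }
    // batch norm
    rowvec mean(Cout), var(Cout);
    if (training) {
      mean.zeros(); var.zeros();
      double N = (double)B * C.z[0].n_rows;
      for (int b = 0; b < B; ++b) mean += arma::sum(C.z[b], 0);
      mean /= N;
      for (int b = 0; b < B; ++b) {
        for (uword c = 0; c < Cout; ++c) {
          const double* zp = C.z[b].colptr(c);
          const double mu = mean(c);
          double acc = 0.0;
          for (uword r = 0; r < C.z[b].n_rows; ++r) {
            const double d = zp[r] - mu;
            acc += d * d;
          }
          var(c) += acc;
        }
      }
      var /= N;
      // update running stats
      rowvec rm = Sv(base + "_rm"), rv = Sv(base + "_rv");
      rm = BN_MOM * rm + (1 - BN_MOM) * mean;
      rv = BN_MOM * rv + (1 - BN_MOM) * var;
      state_[base + "_rm"] = rm;
      state_[base + "_rv"] = rv;
    } else {
      mean = Sv(base + "_rm");
      var = Sv(base + "_rv");
    }
    C.mean = mean; C.var = var;
    // fused affine + ReLU, single pass
    rowvec scale = gamma / arma::sqrt(var + BN_EPS);
    rowvec shift = beta - mean % scale;
    for (int b = 0; b < B; ++b) {
      const uword n = C.z[b].n_rows;
      C.out[b].set_size(n, Cout);
      for (uword c = 0; c < Cout; ++c) {
        const double sc = scale(c), sh = shift(c);
        const double* zp = C.z[b].colptr(c);
        double* op = C.out[b].colptr(c);
        for (uword r = 0; r < n; ++r) {
          const double v = zp[r] * sc + sh;
          op[r] = v > 0.0 ? v : 0.0;
        }
      }
    }
  }

  void maxpool(const std::vector<mat>& in, int s) {
    Shape sh = shapes[s];
    int H = sh.H, W = sh.W, H2 = H / 2, W2 = W / 2;
    uword C = in[0].n_cols;
    PoolCache& PC = pc[s];
    PC.argmax.resize(B);
    // source rows of the 4 children of each pooled cell
    uvec src[4];
    for (int q = 0; q < 4; ++q) src[q].set_size((uword)H2 * W2);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        uword r = (uword)(i + j * H2);
        src[0](r) = (uword)(2 * i + 2 * j * H);
        src[1](r) = (uword)(2 * i + 1 + 2 * j * H);
        src[2](r) = (uword)(2 * i + (2 * j + 1) * H);
        src[3](r) = (uword)(2 * i + 1 + (2 * j + 1) * H);
      }
    }
    std::vector<mat>& out = pool_out[s];
    out.resize(B);
    for (int b = 0; b < B; ++b) {
      mat best = in[b].rows(src[0]);
      umat arg((uword)H2 * W2, C);
      for (uword c = 0; c < C; ++c) arg.col(c).fill(0);
      for (int q = 1; q < 4; ++q) {
        mat cand = in[b].rows(src[q]);
        for (uword c = 0; c < C; ++c) {
          for (uword r = 0; r < best.n_rows; ++r) {
            if (cand(r, c) > best(r, c)) {
              best(r, c) = cand(r, c);
              arg(r, c) = (uword)q;
            }
          }
        }
      }
      // translate quadrant to source row
      for (uword c = 0; c < C; ++c) {
        for (uword r = 0; r < arg.n_rows; ++r) {
          arg(r, c) = src[arg(r, c)](r);
        }
      }
      PC.argmax[b] = arg;
      out[b] = best;
    }
  }

  // build batch-major sequences from trunk output: step t feature is the
  // concatenation over frequency positions of the channel vector
  mat seq_step(const std::vector<mat>& cur, int t) {
    int W = final_shape.W, H = final_shape.H;
    int C = (int)channels(channels.n_elem - 1);
    mat Xt(B, W * C);
    for (int b = 0; b < B; ++b) {
      for (int w = 0; w < W; ++w) {
        Xt.submat(b, w * C, b, (w + 1) * C - 1) =
            cur[b].row(t + w * H);
      }
    }
    return Xt;
  }

  mat rnn_dir(const std::vector<mat>& cur, bool backward_dir, RnnCache& rc) {
    int T = final_shape.H;
    int G = (kind == "gru") ? 3 : 4;
    std::string d = backward_dir ? "rnn_b" : "rnn_f";
    mat Wx = P(d + "_Wx"), Wh = P(d + "_Wh");
    rowvec bb = P(d + "_b").row(0);
    mat h(B, R, arma::fill::zeros), c(B, R, arma::fill::zeros);
    rc.h_prev.assign(T, mat()); rc.z.assign(T, mat()); rc.r.assign(T, mat());
    rc.n.assign(T, mat()); rc.i_.assign(T, mat()); rc.f_.assign(T, mat());
    rc.g_.assign(T, mat()); rc.o_.assign(T, mat()); rc.c_.assign(T, mat());
    rc.cprev.assign(T, mat()); rc.out.assign(T, mat());
    mat dummy(B, T * R);
    for (int step = 0; step < T; ++step) {
      int t = backward_dir ? (T - 1 - step) : step;
      mat Xt = seq_step(cur, t);
      mat ax = Xt * Wx;
      ax.each_row() += bb;
      rc.h_prev[t] = h;
      if (G == 3) {
        mat ah = h * Wh;
        mat z = sigmoid(ax.cols(0, R - 1) + ah.cols(0, R - 1));
        mat r = sigmoid(ax.cols(R, 2 * R - 1) + ah.cols(R, 2 * R - 1));
        mat rh = r % h;
        // candidate uses the reset-gated hidden state, not ah
        mat n = arma::tanh(ax.cols(2 * R, 3 * R - 1) +
                           rh * Wh.cols(2 * R, 3 * R - 1));
        h = (1.0 - z) % n + z % h;
        rc.z[t] = z; rc.r[t] = r; rc.n[t] = n;
      } else {
        mat ah = h * Wh;
        mat a = ax + ah;
        mat i = sigmoid(a.cols(0, R - 1));
        mat f = sigmoid(a.cols(R, 2 * R - 1));
        mat g = arma::tanh(a.cols(2 * R, 3 * R - 1));
        mat o = sigmoid(a.cols(3 * R, 4 * R - 1));
        rc.cprev[t] = c;
        c = f % c + i % g;
        h = o % arma::tanh(c);
        rc.i_[t] = i; rc.f_[t] = f; rc.g_[t] = g; rc.o_[t] = o;
        rc.c_[t] = c;
      }
      rc.out[t] = h;
    }
    return dummy;
  }

  mat rnn_forward(const std::vector<mat>& cur) {
    int T = final_shape.H;
    rnn_dir(cur, false, rcf);
    rnn_dir(cur, true, rcb);
    O.assign(T, mat());
    Opre.assign(T, mat());
    mat feat(B, 2 * R, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      Opre[t] = arma::join_rows(rcf.out[t], rcb.out[t]);
      O[t] = arma::clamp(Opre[t], 0.0, arma::datum::inf);
      feat += O[t];
    }
    feat /= (double)T;
    return feat;
  }

  // ---------- backward ----------
  List backward(const mat& dlogits) {
    List g;
    int S = (int)channels.n_elem;
    mat Wy = P("head_W");
    g["head_W"] = mat(seq_mean.t() * dlogits);
    g["head_b"] = mat(arma::sum(dlogits, 0));
    mat dfeat = dlogits * Wy.t();

    std::vector<mat> dcur(B);
    int Hf = final_shape.H, Wf = final_shape.W;
    int Cf = (int)channels(S - 1);
    for (int b = 0; b < B; ++b) {
      dcur[b] = mat((uword)Hf * Wf, (uword)Cf, arma::fill::zeros);
    }
    if (kind == "cnn") {
      double HW = (double)Hf * Wf;
      for (int b = 0; b < B; ++b) {
        dcur[b].each_row() += dfeat.row(b) / HW;
      }
    } else {
      rnn_backward(dfeat, dcur, g);
    }
    // trunk
    for (int s = S - 1; s >= 0; --s) {
      dcur = unpool(dcur, s);
      if (s == S - 1) { gc_grad = dcur[0]; }
      for (int l = 1; l >= 0; --l) {
        dcur = conv_bn_relu_backward(dcur, s, l, g);
      }
    }
    return g;
  }

  std::vector<mat> unpool(const std::vector<mat>& dout, int s) {
    Shape sh = shapes[s];
    uword HW = (uword)sh.H * sh.W;
    uword C = dout[0].n_cols;
    std::vector<mat> din(B);
    for (int b = 0; b < B; ++b) {
      din[b] = mat(HW, C, arma::fill::zeros);
      const umat& arg = pc[s].argmax[b];
      for (uword c = 0; c < C; ++c) {
        for (uword r = 0; r < arg.n_rows; ++r) {
          din[b](arg(r, c), c) += dout[b](r, c);
        }
      }
    }
    return din;
  }

  std::vector<mat> conv_bn_relu_backward(const std::vector<mat>& dout,
                                         int s, int l, List& g) {
    char nm[64];
    snprintf(nm, sizeof nm, "conv%d_%d", s + 1, l + 1);
    std::string base(nm);
    ConvCache& C = cc[2 * s + l];
    const std::vector<mat>& in = *C.in;
    mat Wm = P(base + "_W");
    rowvec gamma = P(base + "_g").row(0);
    uword Cout = Wm.n_cols;
    rowvec inv_sd = 1.0 / arma::sqrt(C.var + BN_EPS);
    const uword n_rows = C.z[0].n_rows;
    double N = (double)B * n_rows;

    // ReLU mask + BN stat reductions, one pass per sample
    rowvec dgamma(Cout, arma::fill::zeros), dbeta(Cout, arma::fill::zeros);
    std::vector<mat> dy(B);
    for (int b = 0; b < B; ++b) {
      dy[b].set_size(n_rows, Cout);
      for (uword c = 0; c < Cout; ++c) {
        const double mu = C.mean(c), is = inv_sd(c);
        const double* op = C.out[b].colptr(c);
        const double* zp = C.z[b].colptr(c);
        const double* dp = dout[b].colptr(c);
        double* yp = dy[b].colptr(c);
        double sg = 0.0, sb = 0.0;
        for (uword r = 0; r < n_rows; ++r) {
          const double d = op[r] > 0.0 ? dp[r] : 0.0;
          yp[r] = d;
          sg += d * (zp[r] - mu) * is;
          sb += d;
        }
        dgamma(c) += sg;
        dbeta(c) += sb;
      }
    }
    g[base + "_g"] = mat(dgamma);
    g[base + "_be"] = mat(dbeta);

    // BN backward (training: full batch-statistics path; eval: affine)
    std::vector<mat> dz(B);
    if (training) {
      // sum_dxhat = gamma * dbeta; sum_dxhat_xhat = gamma * dgamma
      for (int b = 0; b < B; ++b) {
        dz[b].set_size(n_rows, Cout);
        for (uword c = 0; c < Cout; ++c) {
          const double ga = gamma(c), mu = C.mean(c), is = inv_sd(c);
          const double s1 = ga * dbeta(c);        // sum of dxhat
          const double s2 = ga * dgamma(c);       // sum of dxhat*xhat
          const double* yp = dy[b].colptr(c);
          const double* zp = C.z[b].colptr(c);
          double* zo = dz[b].colptr(c);
          for (uword r = 0; r < n_rows; ++r) {
            const double xh = (zp[r] - mu) * is;
            zo[r] = (yp[r] * ga * N - s1 - xh * s2) * (is / N);
          }
        }
      }
    } else {
      for (int b = 0; b < B; ++b) {
        mat d = dy[b];
        d.each_row() %= (gamma % inv_sd);
        dz[b] = d;
      }
    }

    // conv backward
    const umat& nbr = nbrs[s];
    uword Cin = in[0].n_cols;
    mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
    rowvec db(Cout, arma::fill::zeros);
    std::vector<mat> din(B);
    mat M, dM;
    for (int b = 0; b < B; ++b) {
      im2col(in[b], nbr, M);
      dW += M.t() * dz[b];
      db += arma::sum(dz[b], 0);
      dM = dz[b] * Wm.t();
      din[b] = mat(in[b].n_rows, Cin, arma::fill::zeros);
      col2im_add(din[b], dM, nbr);
    }
    g[base + "_W"] = dW;
    g[base + "_b"] = mat(db);
    return din;
  }

  void rnn_backward(const mat& dfeat, std::vector<mat>& dcur, List& g) {
    int T = final_shape.H;
    int G = (kind == "gru") ? 3 : 4;
    int Wf = final_shape.W;
    int C = (int)channels(channels.n_elem - 1);
    for (int dir = 0; dir < 2; ++dir) {
      bool bwd = (dir == 1);
      RnnCache& rc = bwd ? rcb : rcf;
      std::string d = bwd ? "rnn_b" : "rnn_f";
      mat Wx = P(d + "_Wx"), Wh = P(d + "_Wh");
      mat dWx(Wx.n_rows, Wx.n_cols, arma::fill::zeros);
      mat dWh(Wh.n_rows, Wh.n_cols, arma::fill::zeros);
      rowvec db(G * R, arma::fill::zeros);
      mat dh_next(B, R, arma::fill::zeros), dc_next(B, R, arma::fill::zeros);
      for (int step = T - 1; step >= 0; --step) {
        // reverse of the forward iteration order
        int t = bwd ? (T - 1 - step) : step;
        // gradient flowing into h_t from the head (time-mean of ReLU'd
        // concat outputs)
        mat relu_mask = arma::conv_to<mat>::from(Opre[t] > 0);
        mat dO = dfeat / (double)T;
        dO %= relu_mask;
        mat dh = (bwd ? dO.cols(R, 2 * R - 1) : dO.cols(0, R - 1)) + dh_next;
        mat Xt = seq_step(pool_out.back(), t); // trunk output sequence
        mat dXt(B, Wf * C, arma::fill::zeros);
        mat dh_prev(B, R, arma::fill::zeros);
        if (G == 3) {
          const mat& h = rc.h_prev[t];
          const mat& z = rc.z[t];
          const mat& r = rc.r[t];
          const mat& n = rc.n[t];
          mat dz_ = dh % (h - n);
          mat dn = dh % (1.0 - z);
          dh_prev = dh % z;
          mat dn_pre = dn % (1.0 - n % n);
          mat rh = r % h;
          // candidate
          dWx.cols(2 * R, 3 * R - 1) += Xt.t() * dn_pre;
          dWh.cols(2 * R, 3 * R - 1) += rh.t() * dn_pre;
          db.cols(2 * R, 3 * R - 1) += arma::sum(dn_pre, 0);
          dXt += dn_pre * Wx.cols(2 * R, 3 * R - 1).t();
          mat drh = dn_pre * Wh.cols(2 * R, 3 * R - 1).t();
          mat dr = drh % h;
          dh_prev += drh % r;
          // gates
          mat dz_pre = dz_ % z % (1.0 - z);
          mat dr_pre = dr % r % (1.0 - r);
          dWx.cols(0, R - 1) += Xt.t() * dz_pre;
          dWh.cols(0, R - 1) += h.t() * dz_pre;
          db.cols(0, R - 1) += arma::sum(dz_pre, 0);
          dXt += dz_pre * Wx.cols(0, R - 1).t();
          dh_prev += dz_pre * Wh.cols(0, R - 1).t();
          dWx.cols(R, 2 * R - 1) += Xt.t() * dr_pre;
          dWh.cols(R, 2 * R - 1) += h.t() * dr_pre;
          db.cols(R, 2 * R - 1) += arma::sum(dr_pre, 0);
          dXt += dr_pre * Wx.cols(R, 2 * R - 1).t();
          dh_prev += dr_pre * Wh.cols(R, 2 * R - 1).t();
        } else {
          const mat& h = rc.h_prev[t];
          const mat& i = rc.i_[t];
          const mat& f = rc.f_[t];
          const mat& gg = rc.g_[t];
          const mat& o = rc.o_[t];
          const mat& c = rc.c_[t];
          const mat& cprev = rc.cprev[t];
          mat tc = arma::tanh(c);
          mat do_ = dh % tc;
          mat dc = dh % o % (1.0 - tc % tc) + dc_next;
          mat di = dc % gg;
          mat df = dc % cprev;
          mat dg = dc % i;
          dc_next = dc % f;
          mat da = arma::join_rows(
              arma::join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
              arma::join_rows(dg % (1.0 - gg % gg), do_ % o % (1.0 - o)));
          dWx += Xt.t() * da;
          dWh += h.t() * da;
          db += arma::sum(da, 0);
          dXt += da * Wx.t();
          dh_prev = da * Wh.t();
        }
        dh_next = dh_prev;
        // scatter dXt back onto the trunk gradient
        int Hf = final_shape.H;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < Wf; ++w) {
            dcur[b].row(t + w * Hf) +=
                dXt.submat(b, w * C, b, (w + 1) * C - 1);
          }
        }
      }
      g[d + "_Wx"] = dWx;
      g[d + "_Wh"] = dWh;
      g[d + "_b"] = mat(db);
    }
  }

  List state() { return state_; }

private:
  List state_;
};

static std::vector<mat> as_batch(List xs) {
  std::vector<mat> out(xs.size());
  for (int i = 0; i < xs.size(); ++i) out[i] = as<mat>(xs[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_nn_forward(List cfg, List params, List state, List xs) {
  Net net(cfg, params, state, false);
  std::vector<mat> batch = as_batch(xs);
  mat probs = net.forward(batch);
  return List::create(_["probs"] = probs, _["logits"] = net.logits,
                      _["trunk_frames"] = net.final_shape.H,
                      _["trunk_bands"] = net.final_shape.W);
}

// [[Rcpp::export]]
List cpp_nn_train_step(List cfg, List params, List state, List xs,
                       IntegerVector y, NumericVector wts) {
  Net net(cfg, params, state, true);
  std::vector<mat> batch = as_batch(xs);
  mat probs = net.forward(batch);
  int B = (int)batch.size();
  int K = probs.n_cols;
  double loss = 0.0;
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) {
    int cls = y[b];
    if (cls < 0 || cls >= K) stop("train step: class index out of range");
    loss += -wts[b] * std::log(std::max(probs(b, cls), 1e-12));
    dlogits.row(b) *= wts[b];
    dlogits(b, cls) -= wts[b];
  }
  loss /= B;
  dlogits /= (double)B;
  List g = net.backward(dlogits);
  return List::create(_["loss"] = loss, _["probs"] = probs,
                      _["grads"] = g, _["state"] = net.state());
}

// [[Rcpp::export]]
List cpp_nn_gradcam(List cfg, List params, List state, List xs,
                    int class_idx) {
  Net net(cfg, params, state, false);
  std::vector<mat> batch = as_batch(xs);
  mat probs = net.forward(batch);
  int K = probs.n_cols;
  if (class_idx < 0 || class_idx >= K) {
    stop("grad_cam: class index out of range");
  }
  mat dlogits(batch.size(), K, arma::fill::zeros);
  dlogits(0, class_idx) = 1.0;
  net.backward(dlogits);
  // shape of the last conv activation (pre final pool)
  int S = (int)net.channels.n_elem;
  Shape sh = net.shapes[S - 1];
  return List::create(
      _["act"] = net.gc_act, _["grad"] = net.gc_grad,
      _["H"] = sh.H, _["W"] = sh.W, _["probs"] = probs);
}
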