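// Hybrid CNN-BiLSTM for raw single-lead ECG segments.
//
// Architecture (full model): 1-D convolution (F filters, kernel K, stride S)
// -> ReLU -> dropout -> max-pool (P) -> BiLSTM(H) x 2 -> FC(ReLU) -> dropout
// -> softmax(C). Ablation variants: cnn_only (conv block -> flatten -> FC head)
// and bilstm_only (block-averaged input sequence -> BiLSTM x 2 -> FC head).
// Trained with Adam on cross-entropy. All randomness (init, dropout, batch
// shuffling) is drawn from R's RNG so runs are reproducible via set.seed().

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// single-precision internals: standard for neural-network training and about
// twice the GEMM throughput of double on this architecture
using mat = arma::fmat;
using cube = arma::fcube;
using rowvec = arma::frowvec;
using arma::uvec;
static arma::mat to_double(const mat& m) { return arma::conv_to<arma::mat>::from(m); }
static mat to_single(const arma::mat& m) { return arma::conv_to<mat>::from(m); }

enum NetType { FULL = 0, CNN_ONLY = 1, BILSTM_ONLY = 2 };

struct Config {
  int type, L, K, S, F, P, H, n_lstm, fc, C, ds, lstm_sub;
  double dropout;
  int conv_len() const { return (L - K) / S + 1; }
  int pool_len() const { return conv_len() / P; }
  // sequence length and feature width entering the first LSTM (or flatten)
  int seq_len() const {
    int t = (type == BILSTM_ONLY) ? L / ds : pool_len();
    return (lstm_sub > 1) ? t / lstm_sub : t;
  }
  int seq_dim() const { return (type == BILSTM_ONLY) ? 1 : F; }
  int head_in() const {
    if (type == CNN_ONLY) return pool_len() * F;
    return 2 * H;
  }
};

static Config read_config(const List& cfg) {
  Config c;
  std::string ty = as<std::string>(cfg["type"]);
  c.type = (ty == "cnn_only") ? CNN_ONLY : (ty == "bilstm_only") ? BILSTM_ONLY : FULL;
  c.L = as<int>(cfg["input_len"]);
  c.K = as<int>(cfg["conv_kernel"]);
  c.S = as<int>(cfg["conv_stride"]);
  c.F = as<int>(cfg["conv_filters"]);
  c.P = as<int>(cfg["pool_size"]);
  c.H = as<int>(cfg["lstm_units"]);
  c.n_lstm = as<int>(cfg["lstm_layers"]);
  c.fc = as<int>(cfg["fc_units"]);
  c.C = as<int>(cfg["n_classes"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.ds = cfg.containsElementNamed("bilstm_downsample") ?
           as<int>(cfg["bilstm_downsample"]) : c.S * c.P;
  c.lstm_sub = cfg.containsElementNamed("lstm_subsample") ?
                 as<int>(cfg["lstm_subsample"]) : 1;
  return c;
}

struct LstmLayer { mat W, U; rowvec b; };

struct Params {
  mat Wc; rowvec bc;
  std::vector<std::vector<LstmLayer>> lstm;  // [layer][dir 0=fwd,1=bwd]
  mat W1; rowvec b1;
  mat W2; rowvec b2;
  bool has_conv = false, has_lstm = false;
};

static double runifR() { return unif_rand(); }

static mat glorot(int nr, int nc) {
  double lim = std::sqrt(6.0 / (nr + nc));
  mat m(nr, nc);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (float)((2.0 * runifR() - 1.0) * lim);
  return m;
}

static Params init_params(const Config& c) {
  Params p;
  p.has_conv = (c.type != BILSTM_ONLY);
  p.has_lstm = (c.type != CNN_ONLY);
  if (p.has_conv) {
    p.Wc = glorot(c.K, c.F);
    p.bc = rowvec(c.F, arma::fill::zeros);
  }
  if (p.has_lstm) {
    int din = c.seq_dim();
    for (int l = 0; l < c.n_lstm; ++l) {
      std::vector<LstmLayer> dirs(2);
      for (int d = 0; d < 2; ++d) {
        dirs[d].W = glorot(din, 4 * c.H);
        dirs[d].U = glorot(c.H, 4 * c.H);
        dirs[d].b = rowvec(4 * c.H, arma::fill::zeros);
        dirs[d].b.subvec(c.H, 2 * c.H - 1).fill(1.0);  // forget-gate bias
      }
      p.lstm.push_back(dirs);
      din = 2 * c.H;
    }
  }
  p.W1 = glorot(c.head_in(), c.fc);
  p.b1 = rowvec(c.fc, arma::fill::zeros);
  p.W2 = glorot(c.fc, c.C);
  p.b2 = rowvec(c.C, arma::fill::zeros);
  return p;
}

// ---- serialization to/from R ----

static List params_to_list(const Params& p, const Config& c) {
  List out;
  out["has_conv"] = p.has_conv;
  out["has_lstm"] = p.has_lstm;
  if (p.has_conv) { out["Wc"] = to_double(p.Wc); out["bc"] = to_double(mat(p.bc)); }
  if (p.has_lstm) {
    for (int l = 0; l < (int)p.lstm.size(); ++l) {
      for (int d = 0; d < 2; ++d) {
        std::string tag = "l" + std::to_string(l + 1) + (d == 0 ? "f" : "b");
        out["W_" + tag] = to_double(p.lstm[l][d].W);
        out["U_" + tag] = to_double(p.lstm[l][d].U);
        out["b_" + tag] = to_double(mat(p.lstm[l][d].b));
      }
    }
  }
  out["W1"] = to_double(p.W1); out["b1"] = to_double(mat(p.b1));
  out["W2"] = to_double(p.W2); out["b2"] = to_double(mat(p.b2));
  return out;
}

static Params params_from_list(const List& w, const Config& c) {
  Params p;
  p.has_conv = as<bool>(w["has_conv"]);
  p.has_lstm = as<bool>(w["has_lstm"]);
  if (p.has_conv) { p.Wc = to_single(as<arma::mat>(w["Wc"])); p.bc = to_single(as<arma::mat>(w["bc"])).row(0); }
  if (p.has_lstm) {
    for (int l = 0; l < c.n_lstm; ++l) {
      std::vector<LstmLayer> dirs(2);
      for (int d = 0; d < 2; ++d) {
        std::string tag = "l" + std::to_string(l + 1) + (d == 0 ? "f" : "b");
        dirs[d].W = to_single(as<arma::mat>(w["W_" + tag]));
        dirs[d].U = to_single(as<arma::mat>(w["U_" + tag]));
        dirs[d].b = to_single(as<arma::mat>(w["b_" + tag])).row(0);
      }
      p.lstm.push_back(dirs);
    }
  }
  p.W1 = to_single(as<arma::mat>(w["W1"])); p.b1 = to_single(as<arma::mat>(w["b1"])).row(0);
  p.W2 = to_single(as<arma::mat>(w["W2"])); p.b2 = to_single(as<arma::mat>(w["b2"])).row(0);
  return p;
}

// ---- forward/backward caches ----

struct LstmCache {
  cube gates;   // B x 4H x T (post-nonlinearity)
  cube cstate;  // B x H x T
  cube hstate;  // B x H x T
  const cube* input;  // B x D x T
};

struct Cache {
  mat patches;      // (B*T1) x K
  mat conv_pre;     // (B*T1) x F (pre-ReLU)
  arma::umat pool_arg;  // (B*T) x F  row index into conv rows
  cube seq0;        // LSTM input sequence
  std::vector<std::vector<LstmCache>> lstm;  // [layer][dir]
  std::vector<cube> layer_out;  // BiLSTM concatenated outputs per layer
  mat feat;         // B x head_in
  mat fc1_pre, fc1_drop;
  mat probs;
  mat drop_mask_conv, drop_mask_fc;
};

static void sigmoid_inplace(mat& m) { m = 1.0 / (1.0 + arma::exp(-m)); }

// stack a (B x D x T) cube into a ((B*T) x D) matrix, time-major blocks
static mat cube_to_mat(const cube& in) {
  int B = in.n_rows, D = in.n_cols, T = in.n_slices;
  mat out(B * T, D);
  for (int t = 0; t < T; ++t) out.rows(t * B, (t + 1) * B - 1) = in.slice(t);
  return out;
}

// one direction of one LSTM layer; input B x D x T
static void lstm_forward(const cube& in, const LstmLayer& pl, bool reverse,
                         int H, LstmCache& cc) {
  int B = in.n_rows, T = in.n_slices;
  cc.gates.set_size(B, 4 * H, T);
  cc.cstate.set_size(B, H, T);
  cc.hstate.set_size(B, H, T);
  cc.input = &in;
  // input projection for every step in one GEMM
  mat XW = cube_to_mat(in) * pl.W;
  XW.each_row() += pl.b;
  mat h(B, H, arma::fill::zeros);
  mat A(B, 4 * H);
  const int n = B * H;
  for (int step = 0; step < T; ++step) {
    int t = reverse ? (T - 1 - step) : step;
    A = XW.rows(t * B, (t + 1) * B - 1);
    A += h * pl.U;
    // fused gate nonlinearities and state update, written straight into the
    // caches (gate order i, f, g, o)
    float* G = cc.gates.slice(t).memptr();
    float* C = cc.cstate.slice(t).memptr();
    float* Hs = cc.hstate.slice(t).memptr();
    const float* Ap = A.memptr();
    const float* Cprev = (step > 0)
      ? cc.cstate.slice(reverse ? (T - step) : (step - 1)).memptr() : nullptr;
    for (int j = 0; j < n; ++j) {
      float gi = 1.0f / (1.0f + std::exp(-Ap[j]));
      float gf = 1.0f / (1.0f + std::exp(-Ap[n + j]));
      float gg = std::tanh(Ap[2 * n + j]);
      float go = 1.0f / (1.0f + std::exp(-Ap[3 * n + j]));
      float cs = gf * (Cprev ? Cprev[j] : 0.0f) + gi * gg;
      G[j] = gi; G[n + j] = gf; G[2 * n + j] = gg; G[3 * n + j] = go;
      C[j] = cs;
      Hs[j] = go * std::tanh(cs);
    }
    h = cc.hstate.slice(t);
  }
}

struct LstmGrad { mat W, U; rowvec b; };

// BPTT for one direction; dh_seq: per-step gradient into h (B x H x T, may be
// zero except at the final step). Returns gradient w.r.t. the input sequence.
static cube lstm_backward(const LstmCache& cc, const LstmLayer& pl, bool reverse,
                          int H, const cube& dh_seq, LstmGrad& g) {
  const cube& in = *cc.input;
  int B = in.n_rows, T = in.n_slices;
  g.U.zeros(H, 4 * H);
  mat dA_all(B * T, 4 * H);
  mat dh(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  mat dA(B, 4 * H);
  const int n = B * H;
  for (int step = T - 1; step >= 0; --step) {
    int t = reverse ? (T - 1 - step) : step;
    dh += dh_seq.slice(t);
    const float* G = cc.gates.slice(t).memptr();
    const float* C = cc.cstate.slice(t).memptr();
    const float* Cprev = (step > 0)
      ? cc.cstate.slice(reverse ? (T - step) : (step - 1)).memptr() : nullptr;
    float* dAp = dA.memptr();
    const float* dhp = dh.memptr();
    float* dcp = dc.memptr();
    // fused gate-gradient pass (reads each cached value once)
    for (int j = 0; j < n; ++j) {
      float gi = G[j], gf = G[n + j], gg = G[2 * n + j], go = G[3 * n + j];
      float tc = std::tanh(C[j]);
      float dct = dhp[j] * go * (1.0f - tc * tc) + dcp[j];
      float cprev = Cprev ? Cprev[j] : 0.0f;
      dAp[j]         = (dct * gg) * gi * (1.0f - gi);
      dAp[n + j]     = (dct * cprev) * gf * (1.0f - gf);
      dAp[2 * n + j] = (dct * gi) * (1.0f - gg * gg);
      dAp[3 * n + j] = (dhp[j] * tc) * go * (1.0f - go);
      dcp[j] = dct * gf;
    }
    dA_all.rows(t * B, (t + 1) * B - 1) = dA;
    if (step > 0) {
      int tp = reverse ? (T - step) : (step - 1);
      g.U += cc.hstate.slice(tp).t() * dA;
    }
    dh = dA * pl.U.t();
  }
  g.b = arma::sum(dA_all, 0);
  // input-side products batched over all steps
  g.W = cube_to_mat(in).t() * dA_all;
  mat din_mat = dA_all * pl.W.t();
  cube din(B, in.n_cols, T);
  for (int t = 0; t < T; ++t) din.slice(t) = din_mat.rows(t * B, (t + 1) * B - 1);
  return din;
}

// block-average temporal downsampling of a sequence cube
static cube downsample_seq(const cube& in, int k) {
  if (k <= 1) return in;
  int T2 = in.n_slices / k;
  cube out(in.n_rows, in.n_cols, T2);
  for (int t = 0; t < T2; ++t) {
    mat acc = in.slice(t * k);
    for (int j = 1; j < k; ++j) acc += in.slice(t * k + j);
    out.slice(t) = acc / k;
  }
  return out;
}

static cube upsample_seq_grad(const cube& dout, int k, int T_orig) {
  if (k <= 1) return dout;
  cube din(dout.n_rows, dout.n_cols, T_orig, arma::fill::zeros);
  for (int t = 0; t < (int)dout.n_slices; ++t) {
    for (int j = 0; j < k; ++j) din.slice(t * k + j) = dout.slice(t) / k;
  }
  return din;
}

static mat softmax_rows(mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

// forward pass over a batch; X rows are segments
static void forward(const mat& X, const Params& p, const Config& c,
                    bool training, Cache& cc) {
  int B = X.n_rows;
  int T1 = c.conv_len(), T = c.pool_len();
  double keep = 1.0 - c.dropout;
  if (p.has_conv) {
    // patches in time-major row order (row = t*B + b): each (k, t) pair is a
    // contiguous column-to-column copy
    cc.patches.set_size(B * T1, c.K);
    for (int k = 0; k < c.K; ++k) {
      float* dst = cc.patches.colptr(k);
      for (int t = 0; t < T1; ++t) {
        std::memcpy(dst + (size_t)t * B, X.colptr(t * c.S + k), B * sizeof(float));
      }
    }
    cc.conv_pre = cc.patches * p.Wc;
    cc.conv_pre.each_row() += p.bc;
    mat act = cc.conv_pre;
    act.transform([](float v) { return v > 0 ? v : 0.0f; });
    // max-pool over P consecutive conv steps, per channel; the block's
    // dropout is applied to the pooled features (multiplicatively rescaled
    // dropout before a max() changes the activation scale between training
    // and inference, which a normalization-free network cannot absorb)
    mat pooled(B * T, c.F);
    cc.pool_arg.set_size(B * T, c.F);
    for (int f = 0; f < c.F; ++f) {
      const float* col = act.colptr(f);
      float* pc = pooled.colptr(f);
      arma::uword* ac = cc.pool_arg.colptr(f);
      for (int t = 0; t < T; ++t) {
        for (int b = 0; b < B; ++b) {
          size_t r0 = (size_t)(t * c.P) * B + b;
          float best = col[r0]; size_t arg = r0;
          for (int j = 1; j < c.P; ++j) {
            size_t r = r0 + (size_t)j * B;
            if (col[r] > best) { best = col[r]; arg = r; }
          }
          pc[(size_t)t * B + b] = best;
          ac[(size_t)t * B + b] = arg;
        }
      }
    }
    if (training && c.dropout > 0) {
      cc.drop_mask_conv.set_size(arma::size(pooled));
      for (arma::uword i = 0; i < pooled.n_elem; ++i) {
        cc.drop_mask_conv(i) = (runifR() < keep) ? (float)(1.0 / keep) : 0.0f;
      }
      pooled %= cc.drop_mask_conv;
    }
    if (c.type == CNN_ONLY) {
      cc.feat.set_size(B, T * c.F);
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T; ++t) {
          for (int f = 0; f < c.F; ++f) cc.feat(b, t * c.F + f) = pooled((size_t)t * B + b, f);
        }
      }
    } else {
      cube seq(B, c.F, T);
      for (int t = 0; t < T; ++t) {
        seq.slice(t) = pooled.rows((size_t)t * B, (size_t)(t + 1) * B - 1);
      }
      cc.seq0 = downsample_seq(seq, c.lstm_sub);
    }
  } else {
    // bilstm_only: block-average the raw input to a 1-feature sequence
    int T2 = c.L / c.ds;
    cube seq(B, 1, T2);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < T2; ++t) {
        float acc = 0;
        for (int j = 0; j < c.ds; ++j) acc += X(b, t * c.ds + j);
        seq(b, 0, t) = acc / c.ds;
      }
    }
    cc.seq0 = downsample_seq(seq, c.lstm_sub);
  }

  if (p.has_lstm) {
    cc.lstm.assign(c.n_lstm, std::vector<LstmCache>(2));
    cc.layer_out.clear();
    cc.layer_out.reserve(c.n_lstm);  // caches hold pointers into this vector
    const cube* cur = &cc.seq0;
    for (int l = 0; l < c.n_lstm; ++l) {
      lstm_forward(*cur, p.lstm[l][0], false, c.H, cc.lstm[l][0]);
      lstm_forward(*cur, p.lstm[l][1], true, c.H, cc.lstm[l][1]);
      int T_l = cur->n_slices;
      cube out(B, 2 * c.H, T_l);
      for (int t = 0; t < T_l; ++t) {
        out.slice(t) = arma::join_rows(cc.lstm[l][0].hstate.slice(t),
                                       cc.lstm[l][1].hstate.slice(t));
      }
      cc.layer_out.push_back(out);
      cur = &cc.layer_out.back();
    }
    int T_l = cur->n_slices;
    // final representation: forward state at the last step, backward state at
    // step 0 (i.e. after the backward pass has consumed the whole sequence)
    cc.feat = arma::join_rows(cc.lstm[c.n_lstm - 1][0].hstate.slice(T_l - 1),
                              cc.lstm[c.n_lstm - 1][1].hstate.slice(0));
  }

  cc.fc1_pre = cc.feat * p.W1;
  cc.fc1_pre.each_row() += p.b1;
  mat a1 = cc.fc1_pre;
  a1.transform([](float v) { return v > 0 ? v : 0.0f; });
  if (training && c.dropout > 0) {
    cc.drop_mask_fc.set_size(arma::size(a1));
    for (arma::uword i = 0; i < a1.n_elem; ++i) {
      cc.drop_mask_fc(i) = (runifR() < keep) ? (float)(1.0 / keep) : 0.0f;
    }
    a1 %= cc.drop_mask_fc;
  }
  cc.fc1_drop = a1;
  mat logits = a1 * p.W2;
  logits.each_row() += p.b2;
  cc.probs = softmax_rows(logits);
}

// backward pass; dlogits is the gradient at the logits. Fills grads in `g`
// (same structure as Params). If cam_grad != nullptr, also stores the
// gradient w.r.t. the post-ReLU conv activations ((B*T1) x F).
static void backward(const mat& X, const Params& p, const Config& c,
                     const Cache& cc, const mat& dlogits, Params& g,
                     bool training, mat* cam_grad = nullptr) {
  int B = X.n_rows;
  int T1 = c.conv_len(), T = c.pool_len();
  g.has_conv = p.has_conv; g.has_lstm = p.has_lstm;
  g.W2 = cc.fc1_drop.t() * dlogits;
  g.b2 = arma::sum(dlogits, 0);
  mat da1 = dlogits * p.W2.t();
  if (training && c.dropout > 0) da1 %= cc.drop_mask_fc;
  { const float* pre = cc.fc1_pre.memptr(); float* dd = da1.memptr();
    for (arma::uword i = 0; i < da1.n_elem; ++i) if (pre[i] <= 0) dd[i] = 0; }
  g.W1 = cc.feat.t() * da1;
  g.b1 = arma::sum(da1, 0);
  mat dfeat = da1 * p.W1.t();

  mat dpooled;  // (B*T) x F gradient at the pool output (conv path)
  if (p.has_lstm) {
    g.lstm.assign(c.n_lstm, std::vector<LstmLayer>(2));
    // seed gradient at the final representation
    int T_top = cc.layer_out.empty() ? cc.seq0.n_slices
                                     : cc.layer_out.back().n_slices;
    cube dh_f(B, c.H, T_top, arma::fill::zeros);
    cube dh_b(B, c.H, T_top, arma::fill::zeros);
    dh_f.slice(T_top - 1) = dfeat.cols(0, c.H - 1);
    dh_b.slice(0) = dfeat.cols(c.H, 2 * c.H - 1);
    cube dseq;  // gradient flowing into the layer's input
    for (int l = c.n_lstm - 1; l >= 0; --l) {
      LstmGrad gf_, gb_;
      cube din_f = lstm_backward(cc.lstm[l][0], p.lstm[l][0], false, c.H, dh_f, gf_);
      cube din_b = lstm_backward(cc.lstm[l][1], p.lstm[l][1], true, c.H, dh_b, gb_);
      g.lstm[l][0].W = gf_.W; g.lstm[l][0].U = gf_.U; g.lstm[l][0].b = gf_.b;
      g.lstm[l][1].W = gb_.W; g.lstm[l][1].U = gb_.U; g.lstm[l][1].b = gb_.b;
      dseq = din_f + din_b;
      if (l > 0) {
        int T_prev = dseq.n_slices;
        dh_f.zeros(B, c.H, T_prev);
        dh_b.zeros(B, c.H, T_prev);
        for (int t = 0; t < T_prev; ++t) {
          dh_f.slice(t) = dseq.slice(t).cols(0, c.H - 1);
          dh_b.slice(t) = dseq.slice(t).cols(c.H, 2 * c.H - 1);
        }
      }
    }
    if (p.has_conv) {
      cube dseq_full = upsample_seq_grad(dseq, c.lstm_sub, T);
      dpooled.set_size(B * T, c.F);
      for (int t = 0; t < T; ++t) {
        dpooled.rows((size_t)t * B, (size_t)(t + 1) * B - 1) = dseq_full.slice(t);
      }
    }
  } else {
    dpooled.set_size(B * T, c.F);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < T; ++t) {
        for (int f = 0; f < c.F; ++f) dpooled((size_t)t * B + b, f) = dfeat(b, t * c.F + f);
      }
    }
  }

  if (p.has_conv) {
    if (training && c.dropout > 0) dpooled %= cc.drop_mask_conv;
    mat dact(B * T1, c.F, arma::fill::zeros);
    for (int f = 0; f < c.F; ++f) {
      float* dc_ = dact.colptr(f);
      const arma::uword* ac = cc.pool_arg.colptr(f);
      const float* dp = dpooled.colptr(f);
      for (arma::uword r = 0; r < dpooled.n_rows; ++r) dc_[ac[r]] += dp[r];
    }
    if (cam_grad) *cam_grad = dact;
    {
      const float* pre = cc.conv_pre.memptr();
      float* d = dact.memptr();
      for (arma::uword i = 0; i < dact.n_elem; ++i) if (pre[i] <= 0) d[i] = 0;
    }
    g.Wc = cc.patches.t() * dact;
    g.bc = arma::sum(dact, 0);
  }
}

// ---- Adam ----

struct AdamState {
  std::vector<mat> m, v;
  long t = 0;
};

static void collect(Params& p, std::vector<mat*>& out) {
  if (p.has_conv) { out.push_back(&p.Wc); }
  if (p.has_lstm) {
    for (auto& layer : p.lstm) {
      for (auto& d : layer) { out.push_back(&d.W); out.push_back(&d.U); }
    }
  }
  out.push_back(&p.W1); out.push_back(&p.W2);
}

static void collect_bias(Params& p, std::vector<rowvec*>& out) {
  if (p.has_conv) out.push_back(&p.bc);
  if (p.has_lstm) {
    for (auto& layer : p.lstm) for (auto& d : layer) out.push_back(&d.b);
  }
  out.push_back(&p.b1); out.push_back(&p.b2);
}

static void adam_step(Params& p, Params& g, AdamState& st, double lr,
                      double clip_norm, double b1 = 0.9, double b2 = 0.999,
                      double eps = 1e-8) {
  std::vector<mat*> ps, gs;
  collect(p, ps); collect(g, gs);
  std::vector<rowvec*> pb, gb;
  collect_bias(p, pb); collect_bias(g, gb);
  if (clip_norm > 0) {
    double sq = 0;
    for (auto* gm : gs) sq += arma::accu(arma::square(*gm));
    for (auto* gv : gb) sq += arma::accu(arma::square(*gv));
    double nrm = std::sqrt(sq);
    if (nrm > clip_norm) {
      double sc = clip_norm / nrm;
      for (auto* gm : gs) (*gm) *= sc;
      for (auto* gv : gb) (*gv) *= sc;
    }
  }
  size_t n = ps.size() + pb.size();
  if (st.m.empty()) {
    st.m.resize(n); st.v.resize(n);
    for (size_t i = 0; i < ps.size(); ++i) {
      st.m[i].zeros(arma::size(*ps[i])); st.v[i].zeros(arma::size(*ps[i]));
    }
    for (size_t i = 0; i < pb.size(); ++i) {
      st.m[ps.size() + i].zeros(1, pb[i]->n_elem);
      st.v[ps.size() + i].zeros(1, pb[i]->n_elem);
    }
  }
  st.t += 1;
  double c1 = 1.0 - std::pow(b1, (double)st.t);
  double c2 = 1.0 - std::pow(b2, (double)st.t);
  for (size_t i = 0; i < ps.size(); ++i) {
    st.m[i] = b1 * st.m[i] + (1 - b1) * (*gs[i]);
    st.v[i] = b2 * st.v[i] + (1 - b2) * arma::square(*gs[i]);
    *ps[i] -= lr * (st.m[i] / c1) / (arma::sqrt(st.v[i] / c2) + eps);
  }
  for (size_t i = 0; i < pb.size(); ++i) {
    size_t j = ps.size() + i;
    mat gbi = mat(*gb[i]);
    st.m[j] = b1 * st.m[j] + (1 - b1) * gbi;
    st.v[j] = b2 * st.v[j] + (1 - b2) * arma::square(gbi);
    *pb[i] -= lr * rowvec((st.m[j] / c1) / (arma::sqrt(st.v[j] / c2) + eps));
  }
}

// ---- exported entry points ----

// [[Rcpp::export]]
List cbl_init_weights_cpp(List cfg) {
  RNGScope scope;
  Config c = read_config(cfg);
  Params p = init_params(c);
  return params_to_list(p, c);
}

// [[Rcpp::export]]
List cbl_train_cpp(arma::mat X_, arma::ivec y, List weights, List cfg,
                   double lr, int batch, int epochs,
                   double early_stop_acc, int early_stop_patience,
                   double clip_norm = 1.0, double ema_decay = 0.0) {
  RNGScope scope;
  mat X = to_single(X_);
  X_.reset();
  Config c = read_config(cfg);
  Params p = params_from_list(weights, c);
  // EMA of the weights for evaluation: averages out the noise of the last
  // optimizer steps (dropout + small batches) without touching the dynamics
  Params ema = p;
  bool use_ema = ema_decay > 0;
  long ema_steps = 0;
  AdamState st;
  int n = X.n_rows;
  std::vector<double> hist_loss, hist_acc;
  Cache cc;
  int streak = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0; int ep_correct = 0;
    for (int start = 0; start < n; start += batch) {
      int stop = std::min(n, start + batch);
      int B = stop - start;
      mat Xb(B, X.n_cols);
      arma::ivec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = X.row(idx[start + i]);
        yb(i) = y(idx[start + i]);
      }
      forward(Xb, p, c, true, cc);
      mat dlog = cc.probs;
      for (int i = 0; i < B; ++i) {
        ep_loss -= std::log(std::max((double)cc.probs(i, yb(i)), 1e-12));
        dlog(i, yb(i)) -= 1.0;
        arma::uword am = cc.probs.row(i).index_max();
        if ((int)am == yb(i)) ++ep_correct;
      }
      dlog /= B;
      Params g;
      backward(Xb, p, c, cc, dlog, g, true);
      if (lr > 0) {
        adam_step(p, g, st, lr, clip_norm);
        if (use_ema) {
          ++ema_steps;
          float d = (float)std::min(ema_decay, (double)ema_steps / (ema_steps + 1.0));
          std::vector<mat*> pa, ea;
          collect(p, pa); collect(ema, ea);
          for (size_t q = 0; q < pa.size(); ++q) {
            float* e = ea[q]->memptr(); const float* w_ = pa[q]->memptr();
            for (arma::uword z = 0; z < ea[q]->n_elem; ++z) {
              e[z] = d * e[z] + (1 - d) * w_[z];
            }
          }
          std::vector<rowvec*> pv, ev;
          collect_bias(p, pv); collect_bias(ema, ev);
          for (size_t q = 0; q < pv.size(); ++q) {
            float* e = ev[q]->memptr(); const float* w_ = pv[q]->memptr();
            for (arma::uword z = 0; z < ev[q]->n_elem; ++z) {
              e[z] = d * e[z] + (1 - d) * w_[z];
            }
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
    hist_loss.push_back(ep_loss / n);
    hist_acc.push_back((double)ep_correct / n);
    if (early_stop_acc < 1.0 + 1e-9 && hist_acc.back() >= early_stop_acc) {
      if (++streak >= early_stop_patience) break;
    } else streak = 0;
  }
  return List::create(_["weights"] = params_to_list(use_ema ? ema : p, c),
                      _["raw_weights"] = params_to_list(p, c),
                      _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}

// mean cross-entropy and analytic gradients on a batch (no dropout);
// used by gradient-sanity tests
// [[Rcpp::export]]
List cbl_loss_grad_cpp(arma::mat X_, arma::ivec y, List weights, List cfg) {
  mat X = to_single(X_);
  Config c = read_config(cfg);
  Params p = params_from_list(weights, c);
  Cache cc;
  forward(X, p, c, false, cc);
  int B = X.n_rows;
  double loss = 0;
  mat dlog = cc.probs;
  for (int i = 0; i < B; ++i) {
    loss -= std::log(std::max((double)cc.probs(i, y(i)), 1e-12));
    dlog(i, y(i)) -= 1.0;
  }
  loss /= B;
  dlog /= B;
  Params g;
  backward(X, p, c, cc, dlog, g, false);
  return List::create(_["loss"] = loss, _["grad"] = params_to_list(g, c));
}

// [[Rcpp::export]]
arma::mat cbl_predict_cpp(arma::mat X_, List weights, List cfg, int batch = 120) {
  mat X = to_single(X_);
  X_.reset();
  Config c = read_config(cfg);
  Params p = params_from_list(weights, c);
  int n = X.n_rows;
  mat out(n, c.C);
  Cache cc;
  for (int start = 0; start < n; start += batch) {
    int stop = std::min(n, start + batch);
    mat Xb = X.rows(start, stop - 1);
    forward(Xb, p, c, false, cc);
    out.rows(start, stop - 1) = cc.probs;
  }
  return to_double(out);
}

// [[Rcpp::export]]
List cbl_gradcam_cpp(arma::mat X_, List weights, List cfg, int target_class) {
  mat X = to_single(X_);
  Config c = read_config(cfg);
  if (c.type == BILSTM_ONLY) stop("Grad-CAM requires a convolutional block");
  Params p = params_from_list(weights, c);
  Cache cc;
  forward(X, p, c, false, cc);
  mat dlog(X.n_rows, c.C, arma::fill::zeros);
  dlog.col(target_class).ones();  // gradient of the target-class logit
  Params g;
  mat cam_grad;
  backward(X, p, c, cc, dlog, g, false, &cam_grad);
  int T1 = c.conv_len();
  // per-segment CAM: weights = temporal mean of gradients per channel,
  // CAM = ReLU(weighted sum of post-ReLU feature maps)
  mat relu_act = cc.conv_pre;
  relu_act.transform([](float v) { return v > 0 ? v : 0.0f; });
  int B = X.n_rows;
  mat cams(B, T1);
  // conv rows are time-major (row = t*B + b)
  for (int b = 0; b < B; ++b) {
    mat Gb(T1, c.F), Ab(T1, c.F);
    for (int t = 0; t < T1; ++t) {
      Gb.row(t) = cam_grad.row((size_t)t * B + b);
      Ab.row(t) = relu_act.row((size_t)t * B + b);
    }
    rowvec w = arma::mean(Gb, 0);
    arma::fvec cam = Ab * w.t();
    cam.transform([](float v) { return v > 0 ? v : 0.0f; });
    cams.row(b) = cam.t();
  }
  return List::create(_["cam"] = to_double(cams), _["conv_len"] = T1,
                      _["probs"] = to_double(cc.probs));
}
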