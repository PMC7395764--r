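// Multi-output convolutional regressor: five 5x5 conv layers (ReLU), 2x2
// stride-2 average pooling after the first four, dropout before a single
// fully connected layer with one output per trait. Implemented as
// im2col + single-precision GEMM; plain SGD with momentum and a stepped
// learning-rate schedule. All randomness (init, shuffling, dropout) comes
// from one mt19937 stream so training is bit-reproducible per seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const int KS = 5;  // conv kernel side

struct Shapes {
  int n_conv;
  std::vector<int> cin, cout, s_in, s_out, pad;
  std::vector<bool> pooled;  // pooling after this conv layer?
  int fc_in, outputs;
};

static Shapes plan_shapes(int input_side, const arma::ivec &channels,
                          const arma::ivec &pads, int outputs) {
  Shapes sh;
  sh.n_conv = channels.n_elem;
  int side = input_side, cin = 3;
  for (int l = 0; l < sh.n_conv; ++l) {
    int p = pads[l];
    if (side + 2 * p < KS)
      stop("Conv layer %d input side %d is smaller than the 5x5 kernel.", l + 1, side);
    sh.cin.push_back(cin);
    sh.cout.push_back(channels[l]);
    sh.s_in.push_back(side);
    sh.pad.push_back(p);
    side = side + 2 * p - (KS - 1);
    sh.s_out.push_back(side);
    bool pool = l < sh.n_conv - 1;  // four pooling layers after convs 1..4
    sh.pooled.push_back(pool);
    if (pool) {
      if (side % 2 != 0)
        stop("Pooling after conv layer %d would hit an odd side (%d).", l + 1, side);
      side /= 2;
    }
    cin = channels[l];
  }
  sh.fc_in = cin * side * side;
  sh.outputs = outputs;
  return sh;
}

// feature maps are C x P (channels x pixels), pixel index r + c*S
static void im2col(const fmat &in, fmat &col, int s_in, int s_out, int pad,
                   int cin) {
  col.zeros();
  for (int c = 0; c < s_out; ++c) {
    for (int r = 0; r < s_out; ++r) {
      int p = r + c * s_out;
      float *dst = col.colptr(p);
      for (int kc = 0; kc < KS; ++kc) {
        int ic = c + kc - pad;
        if (ic < 0 || ic >= s_in) continue;
        for (int kr = 0; kr < KS; ++kr) {
          int ir = r + kr - pad;
          if (ir < 0 || ir >= s_in) continue;
          int q = ir + ic * s_in;
          std::memcpy(dst + (size_t)(kc * KS + kr) * cin, in.colptr(q),
                      sizeof(float) * cin);
        }
      }
    }
  }
}

static void col2im(const fmat &dcol, fmat &din, int s_in, int s_out, int pad,
                   int cin) {
  din.zeros();
  for (int c = 0; c < s_out; ++c) {
    for (int r = 0; r < s_out; ++r) {
      int p = r + c * s_out;
      const float *src = dcol.colptr(p);
      for (int kc = 0; kc < KS; ++kc) {
        int ic = c + kc - pad;
        if (ic < 0 || ic >= s_in) continue;
        for (int kr = 0; kr < KS; ++kr) {
          int ir = r + kr - pad;
          if (ir < 0 || ir >= s_in) continue;
          float *dst = din.colptr(ir + ic * s_in);
          const float *s = src + (size_t)(kc * KS + kr) * cin;
          for (int ch = 0; ch < cin; ++ch) dst[ch] += s[ch];
        }
      }
    }
  }
}

static void avgpool(const fmat &in, fmat &out, int side) {
  int half = side / 2;
  for (int c = 0; c < half; ++c) {
    for (int r = 0; r < half; ++r) {
      out.col(r + c * half) =
          0.25f * (in.col(2 * r + 2 * c * side) + in.col(2 * r + 1 + 2 * c * side) +
                   in.col(2 * r + (2 * c + 1) * side) +
                   in.col(2 * r + 1 + (2 * c + 1) * side));
    }
  }
}

static void avgpool_back(const fmat &dout, fmat &din, int side) {
  int half = side / 2;
  for (int c = 0; c < half; ++c) {
    for (int r = 0; r < half; ++r) {
      fvec g = 0.25f * dout.col(r + c * half);
      din.col(2 * r + 2 * c * side) = g;
      din.col(2 * r + 1 + 2 * c * side) = g;
      din.col(2 * r + (2 * c + 1) * side) = g;
      din.col(2 * r + 1 + (2 * c + 1) * side) = g;
    }
  }
}

struct Workspace {
  std::vector<fmat> col, act, pooled, dact, dpooled;
  fvec h, hdrop, dh;
  Workspace(const Shapes &sh) {
    for (int l = 0; l < sh.n_conv; ++l) {
      col.emplace_back(KS * KS * sh.cin[l], sh.s_out[l] * sh.s_out[l]);
      act.emplace_back(sh.cout[l], sh.s_out[l] * sh.s_out[l]);
      dact.emplace_back(sh.cout[l], sh.s_out[l] * sh.s_out[l]);
      int ps = sh.pooled[l] ? sh.s_out[l] / 2 : sh.s_out[l];
      pooled.emplace_back(sh.cout[l], ps * ps);
      dpooled.emplace_back(sh.cout[l], ps * ps);
    }
    h.set_size(0);
  }
};

struct Params {
  std::vector<fmat> W;
  std::vector<fvec> b;
  fmat Wfc;
  fvec bfc;
};

// forward through the conv stack; returns the network output (length
// `outputs`). When `dropmask` is non-null it is applied (inverted dropout).
static fvec forward(const fmat &x, const Params &P, const Shapes &sh,
                    Workspace &ws, const fvec *dropmask) {
  const fmat *in = &x;
  for (int l = 0; l < sh.n_conv; ++l) {
    im2col(*in, ws.col[l], sh.s_in[l], sh.s_out[l], sh.pad[l], sh.cin[l]);
    ws.act[l] = P.W[l] * ws.col[l];
    ws.act[l].each_col() += P.b[l];
    ws.act[l].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (sh.pooled[l]) {
      avgpool(ws.act[l], ws.pooled[l], sh.s_out[l]);
    } else {
      ws.pooled[l] = ws.act[l];
    }
    in = &ws.pooled[l];
  }
  ws.h = arma::vectorise(ws.pooled[sh.n_conv - 1]);
  ws.hdrop = dropmask ? fvec(ws.h % (*dropmask)) : ws.h;
  return P.Wfc * ws.hdrop + P.bfc;
}

static void backward(const fmat &x, const fvec &dy, const Params &P,
                     const Shapes &sh, Workspace &ws, const fvec *dropmask,
                     Params &G) {
  G.Wfc += dy * ws.hdrop.t();
  G.bfc += dy;
  ws.dh = P.Wfc.t() * dy;
  if (dropmask) ws.dh %= *dropmask;

  int last = sh.n_conv - 1;
  ws.dact[last] = fmat(ws.dh.memptr(), sh.cout[last],
                       sh.s_out[last] * sh.s_out[last]);
  for (int l = last; l >= 0; --l) {
    if (l != last) {
      if (sh.pooled[l]) {
        avgpool_back(ws.dpooled[l], ws.dact[l], sh.s_out[l]);
      } else {
        ws.dact[l] = ws.dpooled[l];
      }
    }
    // ReLU gate
    ws.dact[l] %= arma::conv_to<fmat>::from(ws.act[l] > 0.0f);
    G.W[l] += ws.dact[l] * ws.col[l].t();
    G.b[l] += arma::sum(ws.dact[l], 1);
    if (l > 0) {
      fmat dcol = P.W[l].t() * ws.dact[l];
      col2im(dcol, ws.dpooled[l - 1], sh.s_in[l], sh.s_out[l], sh.pad[l],
             sh.cin[l]);
    }
  }
}

static std::vector<fmat> images_to_fmats(const NumericVector &arr) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 4) stop("Image array must be S x S x C x N.");
  int S = dim[0], C = dim[2], N = dim[3];
  if (dim[1] != S) stop("Images must be square.");
  std::vector<fmat> out;
  out.reserve(N);
  const double *p = arr.begin();
  size_t per = (size_t)S * S * C;
  for (int i = 0; i < N; ++i) {
    fmat f(C, S * S);
    for (int ch = 0; ch < C; ++ch)
      for (int q = 0; q < S * S; ++q)
        f(ch, q) = (float)p[i * per + (size_t)ch * S * S + q];
    out.push_back(std::move(f));
  }
  return out;
}

static Params params_from_list(const List &w, const Shapes &sh) {
  Params P;
  for (int l = 0; l < sh.n_conv; ++l) {
    P.W.push_back(arma::conv_to<fmat>::from(
        as<arma::mat>(w[std::string("W") + std::to_string(l + 1)])));
    P.b.push_back(arma::conv_to<fvec>::from(
        as<arma::vec>(w[std::string("b") + std::to_string(l + 1)])));
  }
  P.Wfc = arma::conv_to<fmat>::from(as<arma::mat>(w["Wfc"]));
  P.bfc = arma::conv_to<fvec>::from(as<arma::vec>(w["bfc"]));
  return P;
}

static List params_to_list(const Params &P) {
  List w;
  for (size_t l = 0; l < P.W.size(); ++l) {
    w[std::string("W") + std::to_string(l + 1)] =
        wrap(arma::conv_to<arma::mat>::from(P.W[l]));
    w[std::string("b") + std::to_string(l + 1)] =
        wrap(arma::conv_to<arma::vec>::from(P.b[l]));
  }
  w["Wfc"] = wrap(arma::conv_to<arma::mat>::from(P.Wfc));
  w["bfc"] = wrap(arma::conv_to<arma::vec>::from(P.bfc));
  return w;
}

// [[Rcpp::export]]
List cpp_cnn_train(NumericVector X, NumericMatrix Y, NumericVector Xval,
                   NumericMatrix Yval, IntegerVector channels,
                   IntegerVector pads, double lr0, int drop_every,
                   double drop_factor, double momentum, int batch, int epochs,
                   double dropout_rate, double init_gain, int seed,
                   bool verbose) {
  IntegerVector dims = X.attr("dim");
  Shapes sh = plan_shapes(dims[0], as<arma::ivec>(channels),
                          as<arma::ivec>(pads), Y.ncol());
  std::vector<fmat> xtr = images_to_fmats(X);
  int N = xtr.size();
  bool has_val = Xval.size() > 0;
  std::vector<fmat> xval;
  if (has_val) xval = images_to_fmats(Xval);
  fmat ytr = arma::conv_to<fmat>::from(as<arma::mat>(Y));
  fmat yval = has_val ? arma::conv_to<fmat>::from(as<arma::mat>(Yval)) : fmat();

  if (batch > N) {
    Rcpp::warning("Batch size %d exceeds training set size %d; clipped.", batch, N);
    batch = N;
  }

  std::mt19937 gen(seed);
  std::normal_distribution<float> nd(0.0f, 1.0f);
  std::uniform_real_distribution<float> ud(0.0f, 1.0f);

  Params P, V, G;
  for (int l = 0; l < sh.n_conv; ++l) {
    int K = KS * KS * sh.cin[l];
    fmat W(sh.cout[l], K);
    float s = std::sqrt(2.0f / K);  // He fan-in
    for (auto &v : W) v = nd(gen) * s;
    P.W.push_back(W);
    P.b.push_back(fvec(sh.cout[l], arma::fill::zeros));
    V.W.push_back(fmat(arma::size(W), arma::fill::zeros));
    V.b.push_back(fvec(sh.cout[l], arma::fill::zeros));
    G.W.push_back(fmat(arma::size(W), arma::fill::zeros));
    G.b.push_back(fvec(sh.cout[l], arma::fill::zeros));
  }
  {
    fmat W(sh.outputs, sh.fc_in);
    float s = std::sqrt(1.0f / sh.fc_in);
    for (auto &v : W) v = nd(gen) * s;
    P.Wfc = W;
    P.bfc = fvec(sh.outputs, arma::fill::zeros);
    V.Wfc = fmat(arma::size(W), arma::fill::zeros);
    V.bfc = fvec(sh.outputs, arma::fill::zeros);
    G.Wfc = fmat(arma::size(W), arma::fill::zeros);
    G.bfc = fvec(sh.outputs, arma::fill::zeros);
  }

  Workspace ws(sh);

  // variance calibration of the seeded He init: average pooling shrinks
  // activation variance layer by layer, which starves the head of gradient
  // at the fixed learning rate. Rescale each layer's weights so its
  // pre-activations have unit standard deviation on a calibration batch.
  {
    int ncal = std::min(N, 16);
    std::vector<fmat> cur;
    for (int i = 0; i < ncal; ++i) cur.push_back(xtr[i]);
    for (int l = 0; l < sh.n_conv; ++l) {
      double ss = 0.0;
      size_t cnt = 0;
      std::vector<fmat> z(ncal);
      for (int i = 0; i < ncal; ++i) {
        im2col(cur[i], ws.col[l], sh.s_in[l], sh.s_out[l], sh.pad[l], sh.cin[l]);
        z[i] = P.W[l] * ws.col[l];
        ss += arma::accu(arma::square(z[i]));
        cnt += z[i].n_elem;
      }
      double sd = std::sqrt(ss / std::max<size_t>(cnt, 1)) / init_gain;
      if (sd > 1e-8) P.W[l] /= (float)sd;
      for (int i = 0; i < ncal; ++i) {
        fmat a = z[i] / (float)(sd > 1e-8 ? sd : 1.0);
        a.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        if (sh.pooled[l]) {
          fmat p(sh.cout[l], (sh.s_out[l] / 2) * (sh.s_out[l] / 2));
          avgpool(a, p, sh.s_out[l]);
          cur[i] = p;
        } else {
          cur[i] = a;
        }
      }
    }
    double ss = 0.0;
    size_t cnt = 0;
    for (int i = 0; i < ncal; ++i) {
      fvec y = P.Wfc * arma::vectorise(cur[i]);
      ss += arma::dot(y, y);
      cnt += y.n_elem;
    }
    double sd = std::sqrt(ss / std::max<size_t>(cnt, 1)) / init_gain;
    if (sd > 1e-8) P.Wfc /= (float)sd;
  }

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  NumericVector log_epoch(epochs), log_lr(epochs), log_train(epochs),
      log_val(epochs);
  double best_val = R_PosInf;
  int best_epoch = epochs;
  Params best = P;
  float keep = 1.0f - (float)dropout_rate;

  for (int e = 0; e < epochs; ++e) {
    double lr = lr0 * std::pow(drop_factor, e / drop_every);
    std::shuffle(order.begin(), order.end(), gen);
    double epoch_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < N; start += batch) {
      int bs = std::min(batch, N - start);
      for (auto &g : G.W) g.zeros();
      for (auto &g : G.b) g.zeros();
      G.Wfc.zeros();
      G.bfc.zeros();
      double bloss = 0.0;
      for (int bi = 0; bi < bs; ++bi) {
        int i = order[start + bi];
        fvec dropmask(sh.fc_in);
        if (dropout_rate > 0) {
          for (int j = 0; j < sh.fc_in; ++j)
            dropmask[j] = ud(gen) < keep ? 1.0f / keep : 0.0f;
        } else {
          dropmask.ones();
        }
        fvec y = forward(xtr[i], P, sh, ws, &dropmask);
        fvec err = y - ytr.row(i).t();
        bloss += arma::dot(err, err);
        fvec dy = (2.0f / bs) * err;
        backward(xtr[i], dy, P, sh, ws, &dropmask, G);
      }
      bloss /= bs;
      if (!std::isfinite(bloss))
        stop("NaN/Inf training loss at epoch %d (lr %.2g); aborting.", e + 1, lr);
      epoch_loss += bloss;
      nb++;
      // SGD with momentum
      for (int l = 0; l < sh.n_conv; ++l) {
        V.W[l] = (float)momentum * V.W[l] - (float)lr * G.W[l];
        P.W[l] += V.W[l];
        V.b[l] = (float)momentum * V.b[l] - (float)lr * G.b[l];
        P.b[l] += V.b[l];
      }
      V.Wfc = (float)momentum * V.Wfc - (float)lr * G.Wfc;
      P.Wfc += V.Wfc;
      V.bfc = (float)momentum * V.bfc - (float)lr * G.bfc;
      P.bfc += V.bfc;
    }
    epoch_loss /= std::max(nb, 1);

    double vloss = NA_REAL;
    if (has_val) {
      double s = 0.0;
      for (size_t i = 0; i < xval.size(); ++i) {
        fvec y = forward(xval[i], P, sh, ws, nullptr);
        fvec err = y - yval.row(i).t();
        s += arma::dot(err, err);
      }
      vloss = s / xval.size();
      if (vloss < best_val) {
        best_val = vloss;
        best_epoch = e + 1;
        best = P;
      }
    }
    log_epoch[e] = e + 1;
    log_lr[e] = lr;
    log_train[e] = epoch_loss;
    log_val[e] = vloss;
    if (verbose && ((e + 1) % 5 == 0 || e == 0))
      Rcout << "epoch " << (e + 1) << " lr " << lr << " train " << epoch_loss
            << " val " << vloss << "\n";
    Rcpp::checkUserInterrupt();
  }
  if (!has_val) {
    best = P;
    best_epoch = epochs;
  }

  return List::create(
      _["weights"] = params_to_list(best),
      _["final_weights"] = params_to_list(P),
      _["log"] = DataFrame::create(_["epoch"] = log_epoch, _["lr"] = log_lr,
                                   _["train_loss"] = log_train,
                                   _["val_loss"] = log_val),
      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List weights, NumericVector X,
                              IntegerVector channels, IntegerVector pads,
                              int outputs) {
  IntegerVector dims = X.attr("dim");
  Shapes sh = plan_shapes(dims[0], as<arma::ivec>(channels),
                          as<arma::ivec>(pads), outputs);
  Params P = params_from_list(weights, sh);
  std::vector<fmat> xs = images_to_fmats(X);
  Workspace ws(sh);
  NumericMatrix out(xs.size(), outputs);
  for (size_t i = 0; i < xs.size(); ++i) {
    fvec y = forward(xs[i], P, sh, ws, nullptr);
    for (int k = 0; k < outputs; ++k) out(i, k) = y[k];
  }
  return out;
}
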