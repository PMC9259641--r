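// U-net forward/backward and SGDM training loop.
//
// Feature maps are (H*W) x C matrices, pixels in column-major image order
// (index = col*H + row, 0-based), matching how R flattens an H x W x C array.
// 3x3 convolutions use im2col + BLAS dgemm; zero padding keeps "same" size.
// The architecture is the symmetric encoder-decoder with skip concatenation:
// `depth` encoder blocks (two 3x3 conv+ReLU, then 2x2 max-pool), a bottleneck
// block, `depth` decoder blocks (2x nearest-neighbour upsample, concat skip,
// two 3x3 conv+ReLU) and a final 1x1 conv scored with softmax. The loss is
// the generalized dice loss with squared-inverse class-volume weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

static const double GDL_EPS = 1e-7;

// ---- geometry helpers -------------------------------------------------

// 3x3 neighbour table at resolution H x W: nbr(n, k) is the 0-based pixel
// index of the k-th kernel tap for output pixel n, or -1 outside the image.
static arma::Mat<long long> make_nbr(int H, int W) {
  arma::Mat<long long> nbr(H * W, 9);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          int rr = r + dr, cc = c + dc;
          nbr(c * H + r, k) =
              (rr < 0 || rr >= H || cc < 0 || cc >= W) ? -1LL
                                                       : (long long)(cc * H + rr);
        }
      ++k;
    }
  }
  return nbr;
}

static mat im2col(const mat& X, const arma::Mat<long long>& nbr) {
  const int N = X.n_rows, C = X.n_cols;
  mat P(N, (arma::uword)C * 9);
  for (int c = 0; c < C; ++c) {
    const double* in = X.colptr(c);
    for (int k = 0; k < 9; ++k) {
      double* out = P.colptr((arma::uword)c * 9 + k);
      const long long* idx = nbr.colptr(k);
      for (int n = 0; n < N; ++n) out[n] = (idx[n] < 0) ? 0.0 : in[idx[n]];
    }
  }
  return P;
}

static void col2im_add(mat& dX, const mat& dP, const arma::Mat<long long>& nbr) {
  const int N = dX.n_rows, C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    double* out = dX.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const double* in = dP.colptr((arma::uword)c * 9 + k);
      const long long* idx = nbr.colptr(k);
      for (int n = 0; n < N; ++n)
        if (idx[n] >= 0) out[idx[n]] += in[n];
    }
  }
}

static mat maxpool(const mat& X, int H, int W, arma::umat& argmax) {
  const int Ho = H / 2, Wo = W / 2, C = X.n_cols;
  mat Y(Ho * Wo, C);
  argmax.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* in = X.colptr(c);
    double* out = Y.colptr(c);
    arma::uword* am = argmax.colptr(c);
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro) {
        const int base = (2 * co) * H + 2 * ro;
        const int cand[4] = {base, base + 1, base + H, base + H + 1};
        int best = cand[0];
        double bv = in[best];
        for (int t = 1; t < 4; ++t)
          if (in[cand[t]] > bv) { bv = in[cand[t]]; best = cand[t]; }
        out[co * Ho + ro] = bv;
        am[co * Ho + ro] = (arma::uword)best;
      }
  }
  return Y;
}

static mat unpool(const mat& dY, const arma::umat& argmax, int H, int W) {
  const int C = dY.n_cols;
  mat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* in = dY.colptr(c);
    const arma::uword* am = argmax.colptr(c);
    double* out = dX.colptr(c);
    for (arma::uword n = 0; n < dY.n_rows; ++n) out[am[n]] += in[n];
  }
  return dX;
}

static mat upsample(const mat& X, int Ho, int Wo) {
  const int Hp = Ho / 2, C = X.n_cols;
  mat Y(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* in = X.colptr(c);
    double* out = Y.colptr(c);
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro)
        out[co * Ho + ro] = in[(co / 2) * Hp + (ro / 2)];
  }
  return Y;
}

static mat downsum(const mat& dY, int Ho, int Wo) {
  const int Hp = Ho / 2, Wp = Wo / 2, C = dY.n_cols;
  mat dX(Hp * Wp, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* in = dY.colptr(c);
    double* out = dX.colptr(c);
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro)
        out[(co / 2) * Hp + (ro / 2)] += in[co * Ho + ro];
  }
  return dX;
}

// ---- network definition ----------------------------------------------

struct UNet {
  int depth, K, Cin, H, W;
  std::vector<mat> Wt;          // conv weights, execution order; last is 1x1
  std::vector<rowvec> b;
  std::vector<arma::Mat<long long>> nbr;  // per level 0..depth
  std::vector<int> Hs, Ws;                // dims per level

  void init_geometry(int H_, int W_) {
    H = H_; W = W_;
    Hs.clear(); Ws.clear(); nbr.clear();
    int h = H, w = W;
    for (int l = 0; l <= depth; ++l) {
      Hs.push_back(h); Ws.push_back(w);
      nbr.push_back(make_nbr(h, w));
      h /= 2; w /= 2;
    }
  }
};

static UNet parse_net(List weights, int depth, int K, int Cin) {
  UNet net;
  net.depth = depth; net.K = K; net.Cin = Cin;
  const int nlayer = 4 * depth + 3;
  if (weights.size() != nlayer) stop("weight list has wrong length");
  for (int i = 0; i < nlayer; ++i) {
    List lay = weights[i];
    net.Wt.push_back(as<mat>(lay["W"]));
    net.b.push_back(as<rowvec>(lay["b"]));
  }
  return net;
}

struct Cache {
  std::vector<mat> P;       // im2col input per conv layer
  std::vector<mat> A;       // post-ReLU activation per conv layer
  std::vector<mat> skip;    // encoder block outputs (pre-pool), 1..depth
  std::vector<arma::umat> argmax;
  mat concat_in;            // not stored per-layer; see backward
  mat prob;                 // softmax output
};

// forward pass; if cache != nullptr store everything needed for backward
static mat forward(const UNet& net, const mat& X0, Cache* cache) {
  const int D = net.depth;
  mat X = X0;
  int li = 0;  // conv layer cursor
  std::vector<mat> skips(D + 1);
  std::vector<arma::umat> argmaxes(D + 1);

  auto conv_relu = [&](const mat& in, int level, bool relu) {
    mat P = im2col(in, net.nbr[level]);
    mat Y = P * net.Wt[li];
    Y.each_row() += net.b[li];
    if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (cache) { cache->P.push_back(std::move(P)); cache->A.push_back(Y); }
    ++li;
    return Y;
  };

  for (int i = 1; i <= D; ++i) {
    X = conv_relu(X, i - 1, true);
    X = conv_relu(X, i - 1, true);
    skips[i] = X;
    arma::umat am;
    X = maxpool(X, net.Hs[i - 1], net.Ws[i - 1], am);
    argmaxes[i] = std::move(am);
  }
  X = conv_relu(X, D, true);
  X = conv_relu(X, D, true);
  for (int i = D; i >= 1; --i) {
    mat up = upsample(X, net.Hs[i - 1], net.Ws[i - 1]);
    X = arma::join_rows(skips[i], up);
    X = conv_relu(X, i - 1, true);
    X = conv_relu(X, i - 1, true);
  }
  // final 1x1 conv + softmax
  mat logits = X * net.Wt[li];
  logits.each_row() += net.b[li];
  if (cache) { cache->P.push_back(X); cache->A.push_back(logits); }
  arma::vec mx = arma::max(logits, 1);
  logits.each_col() -= mx;
  mat prob = arma::exp(logits);
  arma::vec s = arma::sum(prob, 1);
  prob.each_col() /= s;
  if (cache) {
    cache->skip = std::move(skips);
    cache->argmax = std::move(argmaxes);
    cache->prob = prob;
  }
  return prob;
}

// training criterion: generalized dice loss, optionally compounded with a
// cross-entropy term (ce_w * mean pixel CE). The CE gradient (p - r)/N does
// not vanish when a class's probability saturates near zero, so it keeps
// rare classes recoverable; the dice term does the class balancing.
static double gdl(const mat& p, const arma::ivec& y, int K, mat* dLdp,
                  double ce_w = 0.0) {
  const int N = p.n_rows;
  arma::vec rsum(K, arma::fill::zeros), inter(K, arma::fill::zeros),
      psum = arma::sum(p, 0).t();
  for (int n = 0; n < N; ++n) {
    const int k = y[n];
    rsum[k] += 1.0;
    inter[k] += p(n, k);
  }
  // classes absent from the reference carry no weight: with the tiny eps the
  // inverse-square-volume weight of an empty class would otherwise dwarf
  // every present class and stall the optimisation
  arma::vec w(K);
  for (int k = 0; k < K; ++k)
    w[k] = rsum[k] > 0.0 ? 1.0 / std::pow(rsum[k] + GDL_EPS, 2.0) : 0.0;
  double num = arma::dot(w, inter);
  double den = arma::dot(w, rsum + psum) + GDL_EPS;
  double loss = 1.0 - 2.0 * num / den;
  if (dLdp) {
    dLdp->set_size(N, K);
    // dL/dp_nk = -2 (w_k r_nk den - num w_k) / den^2
    for (int k = 0; k < K; ++k) {
      double base = 2.0 * num * w[k] / (den * den);
      dLdp->col(k).fill(base);
    }
    for (int n = 0; n < N; ++n) {
      const int k = y[n];
      (*dLdp)(n, k) -= 2.0 * w[k] / den;
    }
  }
  if (ce_w > 0.0) {
    double ce = 0.0;
    for (int n = 0; n < N; ++n) {
      double pt = std::max(p(n, y[n]), 1e-12);
      ce -= std::log(pt);
      if (dLdp) (*dLdp)(n, y[n]) -= ce_w / (N * pt);
    }
    loss += ce_w * ce / N;
  }
  return loss;
}

struct Grads {
  std::vector<mat> dW;
  std::vector<rowvec> db;
  void init_like(const UNet& net) {
    dW.clear(); db.clear();
    for (size_t i = 0; i < net.Wt.size(); ++i) {
      dW.push_back(mat(net.Wt[i].n_rows, net.Wt[i].n_cols, arma::fill::zeros));
      db.push_back(rowvec(net.b[i].n_elem, arma::fill::zeros));
    }
  }
};

// backward pass accumulating into g; returns the loss
static double backward(const UNet& net, const mat& X0, const arma::ivec& y,
                       Grads& g, double ce_w) {
  Cache cache;
  forward(net, X0, &cache);
  const int D = net.depth, K = net.K;
  mat dLdp;
  double loss = gdl(cache.prob, y, K, &dLdp, ce_w);

  // softmax jacobian: dz = p .* (dLdp - rowsum(p .* dLdp))
  mat dz = cache.prob % dLdp;
  arma::vec rs = arma::sum(dz, 1);
  dz = cache.prob % (dLdp - arma::repmat(rs, 1, K));

  const int nlayer = 4 * D + 3;
  int li = nlayer - 1;

  // final 1x1 conv
  g.dW[li] += cache.P[li].t() * dz;
  g.db[li] += arma::sum(dz, 0);
  mat dX = dz * net.Wt[li].t();
  --li;

  // decoder blocks, i = 1..D in forward order; reverse: i = 1 is last
  for (int i = 1; i <= D; ++i) {
    const int level = i - 1;
    for (int rep = 0; rep < 2; ++rep) {
      // ReLU mask from stored activation
      dX %= arma::conv_to<mat>::from(cache.A[li] > 0.0);
      g.dW[li] += cache.P[li].t() * dX;
      g.db[li] += arma::sum(dX, 0);
      mat dP = dX * net.Wt[li].t();
      dX.zeros(net.Hs[level] * net.Ws[level],
               net.Wt[li].n_rows / 9);
      col2im_add(dX, dP, net.nbr[level]);
      --li;
    }
    // split concat: [skip_i, up]
    const int cskip = cache.skip[i].n_cols;
    mat dSkip = dX.cols(0, cskip - 1);
    mat dUp = dX.cols(cskip, dX.n_cols - 1);
    mat dPrev = downsum(dUp, net.Hs[level], net.Ws[level]);
    // stash dSkip for the encoder pass
    cache.skip[i] = std::move(dSkip);  // reuse slot as gradient store
    dX = std::move(dPrev);
  }

  // bottleneck (level D), two convs
  for (int rep = 0; rep < 2; ++rep) {
    dX %= arma::conv_to<mat>::from(cache.A[li] > 0.0);
    g.dW[li] += cache.P[li].t() * dX;
    g.db[li] += arma::sum(dX, 0);
    mat dP = dX * net.Wt[li].t();
    dX.zeros(net.Hs[D] * net.Ws[D], net.Wt[li].n_rows / 9);
    col2im_add(dX, dP, net.nbr[D]);
    --li;
  }

  // encoder blocks, reverse order i = D..1
  for (int i = D; i >= 1; --i) {
    const int level = i - 1;
    // back through pool, then add skip gradient
    dX = unpool(dX, cache.argmax[i], net.Hs[level], net.Ws[level]);
    dX += cache.skip[i];
    for (int rep = 0; rep < 2; ++rep) {
      dX %= arma::conv_to<mat>::from(cache.A[li] > 0.0);
      g.dW[li] += cache.P[li].t() * dX;
      g.db[li] += arma::sum(dX, 0);
      if (li > 0) {  // no need to propagate into the input image
        mat dP = dX * net.Wt[li].t();
        dX.zeros(net.Hs[level] * net.Ws[level], net.Wt[li].n_rows / 9);
        col2im_add(dX, dP, net.nbr[level]);
      }
      --li;
    }
  }
  return loss;
}

// apply an augmentation permutation (0-based) to a feature matrix / labels
static mat permute_rows(const mat& X, const arma::Col<long long>& perm) {
  mat Y(X.n_rows, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* in = X.colptr(c);
    double* out = Y.colptr(c);
    for (arma::uword n = 0; n < X.n_rows; ++n) out[n] = in[perm[n]];
  }
  return Y;
}

// ---- exported entry points --------------------------------------------

// [[Rcpp::export(name = ".unet_forward_cpp")]]
NumericMatrix unet_forward_cpp(List weights, NumericMatrix image, int H, int W,
                               int depth, int K, int Cin) {
  UNet net = parse_net(weights, depth, K, Cin);
  net.init_geometry(H, W);
  mat X(image.begin(), image.nrow(), image.ncol());
  mat prob = forward(net, X, nullptr);
  return wrap(prob);
}

// [[Rcpp::export(name = ".unet_gdl_cpp")]]
double unet_gdl_cpp(NumericMatrix prob, IntegerVector y, int K) {
  mat p(prob.begin(), prob.nrow(), prob.ncol());
  arma::ivec yy = as<arma::ivec>(y);
  return gdl(p, yy, K, nullptr);
}

// [[Rcpp::export(name = ".unet_train_cpp")]]
List unet_train_cpp(List images, List labels, List val_images, List val_labels,
                    List weights, int H, int W, int depth, int K, int Cin,
                    IntegerMatrix order, IntegerMatrix aug, List perms,
                    int batch_size, double lr0, double momentum, double l2,
                    double drop_factor, int drop_every, double grad_clip,
                    double ce_weight) {
  UNet net = parse_net(weights, depth, K, Cin);
  net.init_geometry(H, W);
  const int n = images.size(), epochs = order.nrow();
  const int nval = val_images.size();

  std::vector<mat> X(n);
  std::vector<arma::ivec> Y(n);
  for (int i = 0; i < n; ++i) {
    X[i] = as<mat>(images[i]);
    Y[i] = as<arma::ivec>(labels[i]);
  }
  std::vector<mat> Xv(nval);
  std::vector<arma::ivec> Yv(nval);
  for (int i = 0; i < nval; ++i) {
    Xv[i] = as<mat>(val_images[i]);
    Yv[i] = as<arma::ivec>(val_labels[i]);
  }
  std::vector<arma::Col<long long>> pm(perms.size());
  for (int i = 0; i < perms.size(); ++i)
    pm[i] = arma::conv_to<arma::Col<long long>>::from(as<arma::ivec>(perms[i]));

  // momentum buffers
  std::vector<mat> vW;
  std::vector<rowvec> vb;
  for (size_t i = 0; i < net.Wt.size(); ++i) {
    vW.push_back(mat(net.Wt[i].n_rows, net.Wt[i].n_cols, arma::fill::zeros));
    vb.push_back(rowvec(net.b[i].n_elem, arma::fill::zeros));
  }

  NumericVector train_loss(epochs), val_loss(epochs), lr_log(epochs);
  Grads g;

  for (int e = 0; e < epochs; ++e) {
    const double lr = lr0 * std::pow(drop_factor, e / drop_every);
    lr_log[e] = lr;
    double esum = 0.0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch_size, n - done);
      g.init_like(net);
      for (int t = 0; t < bs; ++t) {
        const int idx = order(e, done + t) - 1;
        const int code = aug(e, done + t);
        mat Xi = (code == 0) ? X[idx] : permute_rows(X[idx], pm[code]);
        arma::ivec Yi = Y[idx];
        if (code != 0) {
          arma::ivec Yp(Yi.n_elem);
          for (arma::uword q = 0; q < Yi.n_elem; ++q) Yp[q] = Yi[pm[code][q]];
          Yi = Yp;
        }
        esum += backward(net, Xi, Yi, g, ce_weight);
      }
      // global L2-norm gradient clipping tames the overshoot that can kill
      // a rare class under the inverse-volume-weighted loss
      double scale = 1.0;
      if (std::isfinite(grad_clip) && grad_clip > 0) {
        double sq = 0.0;
        for (size_t i = 0; i < net.Wt.size(); ++i) {
          sq += arma::accu(arma::square(g.dW[i] / bs));
          sq += arma::accu(arma::square(g.db[i] / bs));
        }
        double nrm = std::sqrt(sq);
        if (nrm > grad_clip) scale = grad_clip / nrm;
      }
      for (size_t i = 0; i < net.Wt.size(); ++i) {
        vW[i] = momentum * vW[i] - lr * (scale * g.dW[i] / bs + l2 * net.Wt[i]);
        net.Wt[i] += vW[i];
        vb[i] = momentum * vb[i] - lr * (scale * g.db[i] / bs);
        net.b[i] += vb[i];
      }
      done += bs;
      Rcpp::checkUserInterrupt();
    }
    train_loss[e] = esum / n;
    double vsum = 0.0;
    for (int i = 0; i < nval; ++i) {
      mat p = forward(net, Xv[i], nullptr);
      vsum += gdl(p, Yv[i], K, nullptr, ce_weight);
    }
    val_loss[e] = nval > 0 ? vsum / nval : NA_REAL;
  }

  List wout(net.Wt.size());
  for (size_t i = 0; i < net.Wt.size(); ++i)
    wout[i] = List::create(_["W"] = net.Wt[i], _["b"] = net.b[i]);
  return List::create(_["weights"] = wout, _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss, _["lr"] = lr_log);
}
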