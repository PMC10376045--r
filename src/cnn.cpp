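// 1-D convolutional network for FBP regression: conv -> max-pool ->
// batch-norm -> ReLU blocks, dense ReLU layers, scalar ReLU output,
// trained with a mean-absolute-percentage-error loss and ADAM.
//
// Layout conventions (must match the R wrappers in R/model.R):
//  * activations: arma::cube (batch x length x channels)
//  * conv weights: mat (K * C_in) x F, row index j = c * K + k
//  * im2col matrix rows indexed r = t * B + n (B = batch size)
//  * dense weights: mat (n_in x n_out); flattened feature j = c * L + u

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

struct BlockCfg {
  int F, K, P;
};

struct NetCfg {
  std::vector<BlockCfg> blocks;
  std::vector<int> dense; // hidden sizes + final 1
  int input_len;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  IntegerVector nf = cfg["n_filters"], ks = cfg["kernel_size"],
                ps = cfg["pool_size"], ds = cfg["dense_sizes"];
  for (int i = 0; i < nf.size(); ++i)
    c.blocks.push_back({nf[i], ks[i], ps[i]});
  for (int i = 0; i < ds.size(); ++i) c.dense.push_back(ds[i]);
  c.dense.push_back(1); // scalar output layer
  c.input_len = as<int>(cfg["input_len"]);
  return c;
}

// ---- single-block helpers -------------------------------------------------

static arma::mat im2col(const arma::cube& A, int K, int Lo) {
  const int B = A.n_rows, C = A.n_slices;
  arma::mat M(B * Lo, K * C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < Lo; ++t)
        M.col(c * K + k).subvec(t * B, t * B + B - 1) =
            A.slice(c).col(t + k);
  return M;
}

static arma::cube mat_to_cube(const arma::mat& M, int B, int L, int F) {
  arma::cube out(B, L, F);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < L; ++t)
      out.slice(f).col(t) = M.col(f).subvec(t * B, t * B + B - 1);
  return out;
}

static arma::mat cube_to_mat(const arma::cube& A) {
  const int B = A.n_rows, L = A.n_cols, F = A.n_slices;
  arma::mat M(B * L, F);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < L; ++t)
      M.col(f).subvec(t * B, t * B + B - 1) = A.slice(f).col(t);
  return M;
}

struct BlockCache {
  arma::mat M;            // im2col of the block input
  arma::ucube argmax;     // pooling winners (flat index into conv output)
  arma::cube xpool;       // pooled pre-BN values
  arma::vec mu, var;      // batch statistics used
  arma::cube out;         // post-ReLU block output
  int Lo;                 // conv output length
  int B, Cin;
};

// forward through one block; training=true uses batch stats and fills cache
static arma::cube block_forward(const arma::cube& A, const BlockCfg& bc,
                                const arma::mat& W, const arma::vec& b,
                                const arma::vec& gamma,
                                const arma::vec& beta, arma::vec& rmean,
                                arma::vec& rvar, bool training,
                                double bn_momentum, BlockCache* cache) {
  const int B = A.n_rows, L = A.n_cols;
  const int Lo = L - bc.K + 1;
  const int Lp = Lo / bc.P;
  arma::mat M = im2col(A, bc.K, Lo);
  arma::mat convM = M * W;
  convM.each_row() += b.t();
  arma::cube conv = mat_to_cube(convM, B, Lo, bc.F);

  arma::cube pooled(B, Lp, bc.F);
  arma::ucube amax(B, Lp, bc.F);
  for (int f = 0; f < bc.F; ++f)
    for (int u = 0; u < Lp; ++u) {
      arma::vec best = conv.slice(f).col(u * bc.P);
      arma::uvec bidx(B, arma::fill::zeros);
      for (int p = 1; p < bc.P; ++p) {
        arma::vec cand = conv.slice(f).col(u * bc.P + p);
        for (int n = 0; n < B; ++n)
          if (cand(n) > best(n)) { best(n) = cand(n); bidx(n) = p; }
      }
      pooled.slice(f).col(u) = best;
      amax.slice(f).col(u) = bidx;
    }

  arma::vec mu(bc.F), var(bc.F);
  arma::cube bn(B, Lp, bc.F);
  for (int f = 0; f < bc.F; ++f) {
    arma::vec x = arma::vectorise(pooled.slice(f));
    double m_, v_;
    if (training) {
      m_ = arma::mean(x);
      v_ = arma::mean(arma::square(x - m_));
      rmean(f) = bn_momentum * rmean(f) + (1 - bn_momentum) * m_;
      rvar(f) = bn_momentum * rvar(f) + (1 - bn_momentum) * v_;
    } else {
      m_ = rmean(f);
      v_ = rvar(f);
    }
    mu(f) = m_;
    var(f) = v_;
    arma::mat xhat = (pooled.slice(f) - m_) / std::sqrt(v_ + BN_EPS);
    bn.slice(f) = gamma(f) * xhat + beta(f);
  }
  arma::cube out = arma::max(bn, arma::cube(B, Lp, bc.F, arma::fill::zeros));
  if (cache) {
    cache->M = std::move(M);
    cache->argmax = std::move(amax);
    cache->xpool = std::move(pooled);
    cache->mu = mu;
    cache->var = var;
    cache->out = out;
    cache->Lo = Lo;
    cache->B = B;
    cache->Cin = A.n_slices;
  }
  return out;
}

// ---- full-network forward / backward --------------------------------------

struct Params {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc, gamma, beta;
  std::vector<arma::mat> Wd;
  std::vector<arma::vec> bd;
};

static Params parse_params(const List& params, const NetCfg& cfg) {
  Params P;
  List pc = params["conv"], pd = params["dense"];
  for (int i = 0; i < (int)cfg.blocks.size(); ++i) {
    List blk = pc[i];
    P.Wc.push_back(as<arma::mat>(blk["W"]));
    P.bc.push_back(as<arma::vec>(blk["b"]));
    P.gamma.push_back(as<arma::vec>(blk["gamma"]));
    P.beta.push_back(as<arma::vec>(blk["beta"]));
  }
  for (int i = 0; i < (int)cfg.dense.size(); ++i) {
    List lay = pd[i];
    P.Wd.push_back(as<arma::mat>(lay["W"]));
    P.bd.push_back(as<arma::vec>(lay["b"]));
  }
  return P;
}

struct Buffers {
  std::vector<arma::vec> rmean, rvar;
};

static Buffers parse_buffers(const List& buffers) {
  Buffers B;
  List rm = buffers["running_mean"], rv = buffers["running_var"];
  for (int i = 0; i < rm.size(); ++i) {
    B.rmean.push_back(as<arma::vec>(rm[i]));
    B.rvar.push_back(as<arma::vec>(rv[i]));
  }
  return B;
}

static List buffers_to_list(const Buffers& B) {
  List rm(B.rmean.size()), rv(B.rvar.size());
  for (size_t i = 0; i < B.rmean.size(); ++i) {
    rm[i] = B.rmean[i];
    rv[i] = B.rvar[i];
  }
  return List::create(Named("running_mean") = rm,
                      Named("running_var") = rv);
}

struct ForwardCache {
  std::vector<BlockCache> blocks;
  arma::mat Z0;                    // flattened conv features
  std::vector<arma::mat> H;        // post-ReLU dense activations
  std::vector<arma::mat> preact;   // dense pre-activations
  arma::vec yhat;
};

static arma::vec net_forward(const arma::mat& X, const NetCfg& cfg,
                             Params& P, Buffers& B, bool training,
                             double bn_momentum, ForwardCache* fc) {
  const int n = X.n_rows;
  arma::cube A(n, X.n_cols, 1);
  A.slice(0) = X;
  if (fc) fc->blocks.resize(cfg.blocks.size());
  for (size_t i = 0; i < cfg.blocks.size(); ++i) {
    BlockCache* cache = fc ? &fc->blocks[i] : nullptr;
    A = block_forward(A, cfg.blocks[i], P.Wc[i], P.bc[i], P.gamma[i],
                      P.beta[i], B.rmean[i], B.rvar[i], training,
                      bn_momentum, cache);
  }
  // flatten: feature j = c * L + u
  const int L = A.n_cols, C = A.n_slices;
  arma::mat Z(n, L * C);
  for (int c = 0; c < C; ++c)
    Z.cols(c * L, c * L + L - 1) = A.slice(c);
  if (fc) fc->Z0 = Z;
  arma::mat H = Z;
  for (size_t j = 0; j < P.Wd.size(); ++j) {
    arma::mat pre = H * P.Wd[j];
    pre.each_row() += P.bd[j].t();
    H = arma::max(pre, arma::mat(pre.n_rows, pre.n_cols,
                                 arma::fill::zeros));
    if (fc) {
      fc->preact.push_back(pre);
      fc->H.push_back(H);
    }
  }
  arma::vec yhat = H.col(0);
  if (fc) fc->yhat = yhat;
  return yhat;
}

// mean absolute percentage error (percent) and its gradient wrt yhat
static double mape(const arma::vec& yhat, const arma::vec& y,
                   arma::vec* grad) {
  arma::vec denom = arma::clamp(arma::abs(y), 1e-6, arma::datum::inf);
  arma::vec e = yhat - y;
  double loss = arma::mean(100.0 * arma::abs(e) / denom);
  if (grad) *grad = (100.0 / y.n_elem) * arma::sign(e) / denom;
  return loss;
}

struct Grads {
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc, gamma, beta;
  std::vector<arma::mat> Wd;
  std::vector<arma::vec> bd;
};

static double net_backward(const arma::mat& X, const arma::vec& y,
                           const NetCfg& cfg, Params& P, Buffers& B,
                           double bn_momentum, Grads& G) {
  ForwardCache fc;
  net_forward(X, cfg, P, B, true, bn_momentum, &fc);
  arma::vec dyhat;
  double loss = mape(fc.yhat, y, &dyhat);

  const int nd = P.Wd.size();
  G.Wd.resize(nd);
  G.bd.resize(nd);
  // output layer gradient enters as column vector
  arma::mat dH(X.n_rows, 1);
  dH.col(0) = dyhat;
  for (int j = nd - 1; j >= 0; --j) {
    arma::mat mask = arma::conv_to<arma::mat>::from(fc.preact[j] > 0);
    arma::mat dpre = dH % mask;
    const arma::mat& Hin = (j == 0) ? fc.Z0 : fc.H[j - 1];
    G.Wd[j] = Hin.t() * dpre;
    G.bd[j] = arma::sum(dpre, 0).t();
    dH = dpre * P.Wd[j].t();
  }

  const int nb = cfg.blocks.size();
  G.Wc.resize(nb);
  G.bc.resize(nb);
  G.gamma.resize(nb);
  G.beta.resize(nb);
  // unflatten dH into cube matching last block output
  const BlockCache& last = fc.blocks[nb - 1];
  int L = last.out.n_cols, C = last.out.n_slices;
  arma::cube dA(X.n_rows, L, C);
  for (int c = 0; c < C; ++c)
    dA.slice(c) = dH.cols(c * L, c * L + L - 1);

  for (int i = nb - 1; i >= 0; --i) {
    const BlockCfg& bc = cfg.blocks[i];
    const BlockCache& cache = fc.blocks[i];
    const int Bn = cache.B, Lp = cache.out.n_cols;
    const double m = (double)Bn * Lp;
    // ReLU
    for (int f = 0; f < bc.F; ++f)
      dA.slice(f) %= arma::conv_to<arma::mat>::from(cache.out.slice(f) > 0);
    // batch-norm backward (per channel)
    G.gamma[i].set_size(bc.F);
    G.beta[i].set_size(bc.F);
    arma::cube dpool(Bn, Lp, bc.F);
    for (int f = 0; f < bc.F; ++f) {
      double iv = 1.0 / std::sqrt(cache.var(f) + BN_EPS);
      arma::mat xc = cache.xpool.slice(f) - cache.mu(f);
      arma::mat xhat = xc * iv;
      const arma::mat& dy = dA.slice(f);
      G.gamma[i](f) = arma::accu(dy % xhat);
      G.beta[i](f) = arma::accu(dy);
      arma::mat dxhat = dy * P.gamma[i](f);
      double sum_dxhat = arma::accu(dxhat);
      double sum_dxhat_xhat = arma::accu(dxhat % xhat);
      dpool.slice(f) =
          iv * (dxhat - sum_dxhat / m - xhat * (sum_dxhat_xhat / m));
    }
    // max-pool backward -> conv-output gradient
    arma::cube dconv(Bn, cache.Lo, bc.F, arma::fill::zeros);
    for (int f = 0; f < bc.F; ++f)
      for (int u = 0; u < Lp; ++u)
        for (int n = 0; n < Bn; ++n)
          dconv(n, u * bc.P + cache.argmax(n, u, f), f) +=
              dpool(n, u, f);
    // conv backward
    arma::mat dOut = cube_to_mat(dconv);
    G.Wc[i] = cache.M.t() * dOut;
    G.bc[i] = arma::sum(dOut, 0).t();
    if (i > 0) {
      arma::mat dM = dOut * P.Wc[i].t();
      const BlockCache& below = fc.blocks[i - 1];
      int Lin = below.out.n_cols, Cin = below.out.n_slices;
      arma::cube dAin(Bn, Lin, Cin, arma::fill::zeros);
      for (int c = 0; c < Cin; ++c)
        for (int k = 0; k < bc.K; ++k)
          for (int t = 0; t < cache.Lo; ++t)
            dAin.slice(c).col(t + k) +=
                dM.col(c * bc.K + k).subvec(t * Bn, t * Bn + Bn - 1);
      dA = dAin;
    }
  }
  return loss;
}

// ---- R entry points -------------------------------------------------------

static List grads_to_list(const Grads& G) {
  List conv(G.Wc.size()), dense(G.Wd.size());
  for (size_t i = 0; i < G.Wc.size(); ++i)
    conv[i] = List::create(Named("W") = G.Wc[i], Named("b") = G.bc[i],
                           Named("gamma") = G.gamma[i],
                           Named("beta") = G.beta[i]);
  for (size_t i = 0; i < G.Wd.size(); ++i)
    dense[i] = List::create(Named("W") = G.Wd[i], Named("b") = G.bd[i]);
  return List::create(Named("conv") = conv, Named("dense") = dense);
}

// [[Rcpp::export(name = ".cpp_predict")]]
arma::vec cpp_predict(List params, List buffers, arma::mat X, List cfg) {
  NetCfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  Buffers B = parse_buffers(buffers);
  // chunked to bound im2col memory
  const int chunk = 1024;
  arma::vec out(X.n_rows);
  for (int s = 0; s < (int)X.n_rows; s += chunk) {
    int e = std::min<int>(s + chunk, X.n_rows) - 1;
    out.subvec(s, e) =
        net_forward(X.rows(s, e), c, P, B, false, 0.9, nullptr);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_loss_grad")]]
List cpp_loss_grad(List params, List buffers, arma::mat X, arma::vec y,
                   List cfg) {
  NetCfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  Buffers B = parse_buffers(buffers);
  Grads G;
  double loss = net_backward(X, y, c, P, B, 0.9, G);
  return List::create(Named("loss") = loss,
                      Named("grads") = grads_to_list(G));
}

// One ADAM epoch over pre-shuffled mini-batches. `order` is a 1-based
// permutation from R. Returns updated params/adam state/buffers and the
// mean training loss.
// [[Rcpp::export(name = ".cpp_train_epoch")]]
List cpp_train_epoch(List params, List adam_m, List adam_v, int step,
                     List buffers, arma::mat X, arma::vec y,
                     arma::uvec order, List cfg, double lr,
                     int batch_size, double bn_momentum) {
  NetCfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  Params M = parse_params(adam_m, c);
  Params V = parse_params(adam_v, c);
  Buffers B = parse_buffers(buffers);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const int n = X.n_rows;
  double total_loss = 0;
  int n_batches = 0;

  auto adam_update = [&](arma::mat& w, arma::mat& m, arma::mat& v,
                         const arma::mat& g, double bc1, double bc2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * arma::square(g);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  };
  auto adam_update_v = [&](arma::vec& w, arma::vec& m, arma::vec& v,
                           const arma::vec& g, double bc1, double bc2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * arma::square(g);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  };

  for (int s = 0; s < n; s += batch_size) {
    int e = std::min(s + batch_size, n) - 1;
    arma::uvec idx = order.subvec(s, e) - 1;
    arma::mat Xb = X.rows(idx);
    arma::vec yb = y(idx);
    Grads G;
    total_loss += net_backward(Xb, yb, c, P, B, bn_momentum, G);
    ++n_batches;
    ++step;
    double bc1 = 1 - std::pow(b1, step), bc2 = 1 - std::pow(b2, step);
    for (size_t i = 0; i < P.Wc.size(); ++i) {
      adam_update(P.Wc[i], M.Wc[i], V.Wc[i], G.Wc[i], bc1, bc2);
      adam_update_v(P.bc[i], M.bc[i], V.bc[i], G.bc[i], bc1, bc2);
      adam_update_v(P.gamma[i], M.gamma[i], V.gamma[i], G.gamma[i], bc1,
                    bc2);
      adam_update_v(P.beta[i], M.beta[i], V.beta[i], G.beta[i], bc1, bc2);
    }
    for (size_t i = 0; i < P.Wd.size(); ++i) {
      adam_update(P.Wd[i], M.Wd[i], V.Wd[i], G.Wd[i], bc1, bc2);
      adam_update_v(P.bd[i], M.bd[i], V.bd[i], G.bd[i], bc1, bc2);
    }
  }

  auto pack = [&](const Params& Q) {
    List conv(Q.Wc.size()), dense(Q.Wd.size());
    for (size_t i = 0; i < Q.Wc.size(); ++i)
      conv[i] = List::create(Named("W") = Q.Wc[i], Named("b") = Q.bc[i],
                             Named("gamma") = Q.gamma[i],
                             Named("beta") = Q.beta[i]);
    for (size_t i = 0; i < Q.Wd.size(); ++i)
      dense[i] = List::create(Named("W") = Q.Wd[i], Named("b") = Q.bd[i]);
    return List::create(Named("conv") = conv, Named("dense") = dense);
  };

  return List::create(
      Named("params") = pack(P), Named("adam_m") = pack(M),
      Named("adam_v") = pack(V), Named("step") = step,
      Named("buffers") = buffers_to_list(B),
      Named("train_loss") = total_loss / std::max(n_batches, 1));
}
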