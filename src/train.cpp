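// Compiled training core: minibatch Adam for the dense/batch-norm networks
// and for the VAE (encoder trunk + mu/log-var heads + decoder with the
// reparameterization trick). Forward/backward math mirrors the R reference
// implementation in R/nn.R, which is gradient-checked in the test suite.
// All randomness (shuffles, reparameterization draws) comes from R's RNG so
// set.seed()/withr::with_seed() give bit-reproducible training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum ActKind { ACT_LINEAR = 0, ACT_RELU = 1, ACT_SIGMOID = 2, ACT_GAUSSIAN = 3 };

static int act_code(const std::string &a) {
  if (a == "linear") return ACT_LINEAR;
  if (a == "relu") return ACT_RELU;
  if (a == "sigmoid") return ACT_SIGMOID;
  if (a == "gaussian") return ACT_GAUSSIAN;
  stop("unknown activation: " + a);
}

static arma::mat act_fwd(const arma::mat &z, int act) {
  switch (act) {
  case ACT_LINEAR: return z;
  case ACT_RELU: return arma::clamp(z, 0.0, arma::datum::inf);
  case ACT_SIGMOID: return 1.0 / (1.0 + arma::exp(-z));
  default: return arma::exp(-arma::square(z));
  }
}

static arma::mat act_bwd(const arma::mat &z, const arma::mat &a, int act) {
  switch (act) {
  case ACT_LINEAR: return arma::ones<arma::mat>(z.n_rows, z.n_cols);
  case ACT_RELU: return arma::conv_to<arma::mat>::from(z > 0.0);
  case ACT_SIGMOID: return a % (1.0 - a);
  default: return -2.0 * z % a;
  }
}

struct Layer {
  int type; // 0 dense, 1 bn
  int act;
  arma::mat W; arma::rowvec b;
  arma::rowvec gamma, beta, run_mean, run_var;
  double momentum, eps;
  // Adam state (W/b double as gamma/beta state for bn layers)
  arma::mat mW, vW; arma::rowvec mb, vb, mg, vg, mbe, vbe;
};

struct Cache { arma::mat X, Z, A, xhat; arma::rowvec invstd; };

typedef std::vector<Layer> Net;

static Net net_from_list(List layers) {
  Net net;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    Layer L;
    std::string type = as<std::string>(l["type"]);
    if (type == "dense") {
      L.type = 0;
      L.act = act_code(as<std::string>(l["act"]));
      L.W = as<arma::mat>(l["W"]);
      L.b = arma::rowvec(as<arma::vec>(l["b"]).t());
      L.mW.zeros(L.W.n_rows, L.W.n_cols); L.vW.zeros(L.W.n_rows, L.W.n_cols);
      L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
    } else {
      L.type = 1;
      L.gamma = arma::rowvec(as<arma::vec>(l["gamma"]).t());
      L.beta = arma::rowvec(as<arma::vec>(l["beta"]).t());
      L.run_mean = arma::rowvec(as<arma::vec>(l["run_mean"]).t());
      L.run_var = arma::rowvec(as<arma::vec>(l["run_var"]).t());
      L.momentum = as<double>(l["momentum"]);
      L.eps = as<double>(l["eps"]);
      L.mg.zeros(L.gamma.n_elem); L.vg.zeros(L.gamma.n_elem);
      L.mbe.zeros(L.beta.n_elem); L.vbe.zeros(L.beta.n_elem);
    }
    net.push_back(L);
  }
  return net;
}

static List net_to_list(const Net &net) {
  List out(net.size());
  for (size_t i = 0; i < net.size(); ++i) {
    const Layer &L = net[i];
    if (L.type == 0) {
      out[i] = List::create(
        _["type"] = "dense",
        _["act"] = (L.act == ACT_LINEAR ? "linear" : L.act == ACT_RELU ? "relu"
                    : L.act == ACT_SIGMOID ? "sigmoid" : "gaussian"),
        _["W"] = L.W, _["b"] = arma::vec(L.b.t()));
    } else {
      out[i] = List::create(
        _["type"] = "bn",
        _["gamma"] = arma::vec(L.gamma.t()), _["beta"] = arma::vec(L.beta.t()),
        _["run_mean"] = arma::vec(L.run_mean.t()), _["run_var"] = arma::vec(L.run_var.t()),
        _["momentum"] = L.momentum, _["eps"] = L.eps);
    }
  }
  return out;
}

static arma::mat net_forward(Net &net, const arma::mat &X, bool training,
                             std::vector<Cache> *caches) {
  arma::mat A = X;
  for (size_t i = 0; i < net.size(); ++i) {
    Layer &L = net[i];
    if (L.type == 0) {
      arma::mat Z = A * L.W;
      Z.each_row() += L.b;
      arma::mat A_out = act_fwd(Z, L.act);
      if (caches) { (*caches)[i].X = A; (*caches)[i].Z = Z; (*caches)[i].A = A_out; }
      A = A_out;
    } else {
      arma::rowvec invstd;
      arma::mat xhat;
      if (training) {
        arma::rowvec mu = arma::mean(A, 0);
        arma::mat xc = A.each_row() - mu;
        arma::rowvec v = arma::mean(arma::square(xc), 0);
        invstd = 1.0 / arma::sqrt(v + L.eps);
        xhat = xc.each_row() % invstd;
        L.run_mean = (1.0 - L.momentum) * L.run_mean + L.momentum * mu;
        L.run_var = (1.0 - L.momentum) * L.run_var + L.momentum * v;
      } else {
        invstd = 1.0 / arma::sqrt(L.run_var + L.eps);
        xhat = (A.each_row() - L.run_mean).each_row() % invstd;
      }
      arma::mat A_out = xhat.each_row() % L.gamma;
      A_out.each_row() += L.beta;
      if (caches) { (*caches)[i].xhat = xhat; (*caches)[i].invstd = invstd; }
      A = A_out;
    }
  }
  return A;
}

struct Grads { arma::mat dW; arma::rowvec db, dgamma, dbeta; };

// returns dX; fills grads
static arma::mat net_backward(const Net &net, const std::vector<Cache> &caches,
                              const arma::mat &dOut, std::vector<Grads> &grads) {
  arma::mat dA = dOut;
  for (int i = (int)net.size() - 1; i >= 0; --i) {
    const Layer &L = net[i];
    const Cache &C = caches[i];
    if (L.type == 0) {
      arma::mat dZ = dA % act_bwd(C.Z, C.A, L.act);
      grads[i].dW = C.X.t() * dZ;
      grads[i].db = arma::sum(dZ, 0);
      dA = dZ * L.W.t();
    } else {
      double n = (double)C.xhat.n_rows;
      grads[i].dgamma = arma::sum(dA % C.xhat, 0);
      grads[i].dbeta = arma::sum(dA, 0);
      arma::mat dxhat = dA.each_row() % L.gamma;
      arma::rowvec s1 = arma::sum(dxhat, 0) / n;
      arma::rowvec s2 = arma::sum(dxhat % C.xhat, 0) / n;
      arma::mat tmp = dxhat;
      tmp.each_row() -= s1;
      tmp -= C.xhat.each_row() % s2;
      dA = tmp.each_row() % C.invstd;
    }
  }
  return dA;
}

static void adam_update(arma::mat &p, arma::mat &m, arma::mat &v, const arma::mat &g,
                        double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  p -= lr * (m / (1.0 - std::pow(b1, t))) /
       (arma::sqrt(v / (1.0 - std::pow(b2, t))) + eps);
}

static void adam_update_row(arma::rowvec &p, arma::rowvec &m, arma::rowvec &v,
                            const arma::rowvec &g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  p -= lr * (m / (1.0 - std::pow(b1, t))) /
       (arma::sqrt(v / (1.0 - std::pow(b2, t))) + eps);
}

static void net_adam_step(Net &net, std::vector<Grads> &grads, double lr, double t) {
  for (size_t i = 0; i < net.size(); ++i) {
    Layer &L = net[i];
    if (L.type == 0) {
      adam_update(L.W, L.mW, L.vW, grads[i].dW, lr, t);
      adam_update_row(L.b, L.mb, L.vb, grads[i].db, lr, t);
    } else {
      adam_update_row(L.gamma, L.mg, L.vg, grads[i].dgamma, lr, t);
      adam_update_row(L.beta, L.mbe, L.vbe, grads[i].dbeta, lr, t);
    }
  }
}

// Fisher-Yates shuffle driven by R's RNG
static std::vector<arma::uword> r_permutation(int n) {
  std::vector<arma::uword> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  return perm;
}

// weighted pooled R^2 (weights = squared original-scale sds of the target
// columns; zero-weight/zero-variance columns drop out of both sums)
static double pooled_r2(const arma::mat &Y, const arma::mat &Yhat, const arma::vec &w) {
  double sse = 0.0, sst = 0.0;
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    arma::vec yj = Y.col(j);
    double mu = arma::mean(yj);
    double tot = arma::accu(arma::square(yj - mu));
    if (tot * w(j) <= 1e-12) continue;
    sse += w(j) * arma::accu(arma::square(yj - Yhat.col(j)));
    sst += w(j) * tot;
  }
  if (sst <= 0.0) return NA_REAL;
  return 1.0 - sse / sst;
}

// [[Rcpp::export]]
List cpp_train_mlp(List layers, const arma::mat &X, const arma::mat &Y,
                   int epochs, int batch, double lr,
                   int monitor_every, double early_stop_mse,
                   const arma::vec &col_weights) {
  Net net = net_from_list(layers);
  int n = X.n_rows;
  if (batch > n) batch = n;
  if (monitor_every < 1) monitor_every = 1;
  if (monitor_every > epochs) monitor_every = epochs;
  std::vector<Cache> caches(net.size());
  std::vector<Grads> grads(net.size());
  double t = 0.0;
  Net best = net;
  double best_r2 = -arma::datum::inf;
  std::vector<double> log_epoch, log_mse, log_r2;
  bool diverged = false;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::vector<arma::uword> perm = r_permutation(n);
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n) - 1;
      arma::uvec rows(end - start + 1);
      for (int r = start; r <= end; ++r) rows(r - start) = perm[r];
      arma::mat Xb = X.rows(rows);
      arma::mat Yb = Y.rows(rows);
      arma::mat out = net_forward(net, Xb, true, &caches);
      arma::mat dOut = 2.0 * (out - Yb) / (double)(Yb.n_rows * Yb.n_cols);
      net_backward(net, caches, dOut, grads);
      t += 1.0;
      net_adam_step(net, grads, lr, t);
    }
    if (ep % monitor_every == 0 || ep == epochs) {
      arma::mat pred = net_forward(net, X, false, nullptr);
      double mse = arma::accu(arma::square(pred - Y)) / (double)(Y.n_rows * Y.n_cols);
      if (!std::isfinite(mse)) { diverged = true; break; }
      double r2 = pooled_r2(Y, pred, col_weights);
      log_epoch.push_back(ep); log_mse.push_back(mse); log_r2.push_back(r2);
      if (std::isfinite(r2) && r2 > best_r2) { best_r2 = r2; best = net; }
      if (early_stop_mse > 0.0 && mse < early_stop_mse) break;
    }
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (!std::isfinite(best_r2)) { best = net; }
  return List::create(
    _["layers"] = net_to_list(best),
    _["final_layers"] = net_to_list(net),
    _["epoch"] = wrap(log_epoch), _["mse"] = wrap(log_mse), _["r2"] = wrap(log_r2),
    _["best_r2"] = best_r2, _["diverged"] = diverged);
}

// [[Rcpp::export]]
List cpp_train_vae(List trunk_l, List mu_l, List lv_l, List dec_l,
                   const arma::mat &X, int epochs, int batch, double lr,
                   double beta, int monitor_every, const arma::vec &col_weights) {
  Net trunk = net_from_list(trunk_l);
  Net mu_head = net_from_list(mu_l);
  Net lv_head = net_from_list(lv_l);
  Net dec = net_from_list(dec_l);
  int n = X.n_rows;
  int latent = mu_head.back().W.n_cols;
  if (batch > n) batch = n;
  if (monitor_every < 1) monitor_every = 1;
  if (monitor_every > epochs) monitor_every = epochs;

  std::vector<Cache> c_t(trunk.size()), c_mu(mu_head.size()), c_lv(lv_head.size()), c_d(dec.size());
  std::vector<Grads> g_t(trunk.size()), g_mu(mu_head.size()), g_lv(lv_head.size()), g_d(dec.size());
  double t = 0.0;
  Net b_t = trunk, b_mu = mu_head, b_lv = lv_head, b_d = dec;
  double best_r2 = -arma::datum::inf;
  std::vector<double> log_epoch, log_loss, log_r2;
  bool diverged = false;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::vector<arma::uword> perm = r_permutation(n);
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n) - 1;
      int nb = end - start + 1;
      arma::uvec rows(nb);
      for (int r = start; r <= end; ++r) rows(r - start) = perm[r];
      arma::mat xb = X.rows(rows);

      arma::mat H = net_forward(trunk, xb, true, &c_t);
      arma::mat mu = net_forward(mu_head, H, true, &c_mu);
      arma::mat lv_raw = net_forward(lv_head, H, true, &c_lv);
      arma::mat logvar = arma::clamp(lv_raw, -10.0, 10.0);
      arma::mat sigma = arma::exp(0.5 * logvar);
      arma::mat eps(nb, latent);
      for (int i = 0; i < nb; ++i)
        for (int j = 0; j < latent; ++j) eps(i, j) = norm_rand();
      arma::mat z = mu + sigma % eps;

      // loss = mean_batch[ sum_dims (x - xhat)^2 + beta * KL ]
      arma::mat xhat = net_forward(dec, z, true, &c_d);
      arma::mat d_xhat = 2.0 * (xhat - xb) / (double)nb;
      arma::mat dz = net_backward(dec, c_d, d_xhat, g_d);
      arma::mat inside = arma::conv_to<arma::mat>::from(lv_raw > -10.0) %
                         arma::conv_to<arma::mat>::from(lv_raw < 10.0);
      arma::mat d_mu = dz + beta * mu / (double)nb;
      arma::mat d_lv = (dz % sigma % eps * 0.5 +
                        beta * 0.5 * (arma::exp(logvar) - 1.0) / (double)nb) % inside;
      arma::mat dH = net_backward(mu_head, c_mu, d_mu, g_mu) +
                     net_backward(lv_head, c_lv, d_lv, g_lv);
      net_backward(trunk, c_t, dH, g_t);
      t += 1.0;
      net_adam_step(dec, g_d, lr, t);
      net_adam_step(mu_head, g_mu, lr, t);
      net_adam_step(lv_head, g_lv, lr, t);
      net_adam_step(trunk, g_t, lr, t);
    }
    if (ep % monitor_every == 0 || ep == epochs) {
      // deterministic reconstruction at z = mu for monitoring/checkpointing
      arma::mat H = net_forward(trunk, X, false, nullptr);
      arma::mat mu_all = net_forward(mu_head, H, false, nullptr);
      arma::mat xhat_all = net_forward(dec, mu_all, false, nullptr);
      if (!xhat_all.is_finite()) { diverged = true; break; }
      double r2 = pooled_r2(X, xhat_all, col_weights);
      arma::mat lv_all = arma::clamp(net_forward(lv_head, H, false, nullptr), -10.0, 10.0);
      arma::vec kl_rows = 0.5 * arma::sum(arma::square(mu_all) + arma::exp(lv_all)
                                          - 1.0 - lv_all, 1);
      arma::vec sse_rows = arma::sum(arma::square(xhat_all - X), 1);
      double loss = arma::mean(sse_rows) + beta * arma::mean(kl_rows);
      log_epoch.push_back(ep); log_loss.push_back(loss); log_r2.push_back(r2);
      if (std::isfinite(r2) && r2 > best_r2) {
        best_r2 = r2; b_t = trunk; b_mu = mu_head; b_lv = lv_head; b_d = dec;
      }
    }
    if (ep % 20 == 0) Rcpp::checkUserInterrupt();
  }
  if (!std::isfinite(best_r2)) { b_t = trunk; b_mu = mu_head; b_lv = lv_head; b_d = dec; }
  return List::create(
    _["trunk"] = net_to_list(b_t), _["mu_head"] = net_to_list(b_mu),
    _["lv_head"] = net_to_list(b_lv), _["decoder"] = net_to_list(b_d),
    _["epoch"] = wrap(log_epoch), _["loss"] = wrap(log_loss), _["r2"] = wrap(log_r2),
    _["best_r2"] = best_r2, _["diverged"] = diverged);
}
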