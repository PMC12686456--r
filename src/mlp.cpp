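// Feed-forward binary MLP: ReLU hidden layers, sigmoid output, mean BCE +
// L2 penalty on weights, inverted dropout, mini-batch Adam. Kept in C++
// because the genetic wrapper fitness retrains this network thousands of
// times per run.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

struct Net {
  std::vector<mat> W;  // W[l]: n_out x n_in
  std::vector<vec> b;  // b[l]: n_out
};

static Net net_from_list(List W_, List b_) {
  Net net;
  for (int l = 0; l < W_.size(); ++l) {
    net.W.push_back(as<mat>(W_[l]));
    net.b.push_back(as<vec>(b_[l]));
  }
  return net;
}

static List net_to_list(const Net& net) {
  List W(net.W.size()), b(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    W[l] = wrap(net.W[l]);
    b[l] = wrap(net.b[l]);
  }
  return List::create(Named("W") = W, Named("b") = b);
}

// Forward pass. If masks is non-null its matrices (n x width, entries 0 or
// 1/keep) multiply the hidden activations (inverted dropout).
static vec forward_net(const Net& net, const mat& X,
                       const std::vector<mat>* masks,
                       std::vector<mat>* Zs = nullptr,
                       std::vector<mat>* As = nullptr) {
  mat A = X;
  size_t L = net.W.size();
  if (As) As->push_back(A);
  for (size_t l = 0; l + 1 < L; ++l) {
    mat Z = A * net.W[l].t();
    Z.each_row() += net.b[l].t();
    if (Zs) Zs->push_back(Z);
    A = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
    if (masks) A %= (*masks)[l];
    if (As) As->push_back(A);
  }
  vec z = A * net.W[L - 1].t() + net.b[L - 1](0);
  return 1.0 / (1.0 + arma::exp(-z));
}

static double bce_loss(const vec& y, vec p) {
  p = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return arma::mean(-(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p)));
}

static double l2_penalty(const Net& net, double lambda) {
  double s = 0.0;
  for (const mat& W : net.W) s += arma::accu(arma::square(W));
  return lambda * s;
}

// Backprop of mean-BCE + lambda * sum(W^2) on a batch. Fills gW/gb.
static double loss_grad(const Net& net, const mat& X, const vec& y,
                        double lambda, const std::vector<mat>* masks,
                        std::vector<mat>& gW, std::vector<vec>& gb) {
  std::vector<mat> Zs, As;
  vec p = forward_net(net, X, masks, &Zs, &As);
  double loss = bce_loss(y, p) + l2_penalty(net, lambda);
  size_t L = net.W.size();
  double n = static_cast<double>(X.n_rows);
  gW.assign(L, mat());
  gb.assign(L, vec());
  // output layer: delta = (p - y)/n  (exact for sigmoid + mean BCE)
  vec delta = (p - y) / n;
  gW[L - 1] = delta.t() * As[L - 1] + 2.0 * lambda * net.W[L - 1];
  gb[L - 1] = vec(1);
  gb[L - 1](0) = arma::accu(delta);
  mat D = delta * net.W[L - 1];  // n x width(L-1)
  for (int l = static_cast<int>(L) - 2; l >= 0; --l) {
    if (masks) D %= (*masks)[l];
    D %= arma::conv_to<mat>::from(Zs[l] > 0.0);
    gW[l] = D.t() * As[l] + 2.0 * lambda * net.W[l];
    gb[l] = arma::sum(D, 0).t();
    if (l > 0) D = D * net.W[l];
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_mlp_init(IntegerVector sizes, int seed) {
  // sizes = c(n_in, hidden..., 1); He-normal weights, zero biases.
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  Net net;
  for (int l = 0; l + 1 < sizes.size(); ++l) {
    int n_in = sizes[l], n_out = sizes[l + 1];
    mat W(n_out, n_in);
    double sd = std::sqrt(2.0 / n_in);
    for (int i = 0; i < n_out; ++i)
      for (int j = 0; j < n_in; ++j) W(i, j) = sd * norm(rng);
    net.W.push_back(W);
    net.b.push_back(vec(n_out, arma::fill::zeros));
  }
  return net_to_list(net);
}

// [[Rcpp::export]]
NumericVector cpp_mlp_forward(List W, List b, arma::mat X) {
  Net net = net_from_list(W, b);
  if (X.n_cols != net.W[0].n_cols)
    stop("shape error: X has %d columns, network expects %d",
         (int)X.n_cols, (int)net.W[0].n_cols);
  vec p = forward_net(net, X, nullptr);
  return wrap(p);
}

// [[Rcpp::export]]
List cpp_mlp_loss_grad(List W, List b, arma::mat X, arma::vec y,
                       double lambda, Nullable<List> masks_) {
  Net net = net_from_list(W, b);
  std::vector<mat> masks;
  std::vector<mat>* mp = nullptr;
  if (masks_.isNotNull()) {
    List ml(masks_);
    for (int l = 0; l < ml.size(); ++l) masks.push_back(as<mat>(ml[l]));
    mp = &masks;
  }
  std::vector<mat> gW;
  std::vector<vec> gb;
  double loss = loss_grad(net, X, y, lambda, mp, gW, gb);
  List gWl(gW.size()), gbl(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) { gWl[l] = wrap(gW[l]); gbl[l] = wrap(gb[l]); }
  return List::create(Named("loss") = loss, Named("gW") = gWl, Named("gb") = gbl);
}

// [[Rcpp::export]]
double cpp_mlp_loss(List W, List b, arma::mat X, arma::vec y,
                    double lambda, Nullable<List> masks_) {
  Net net = net_from_list(W, b);
  std::vector<mat> masks;
  std::vector<mat>* mp = nullptr;
  if (masks_.isNotNull()) {
    List ml(masks_);
    for (int l = 0; l < ml.size(); ++l) masks.push_back(as<mat>(ml[l]));
    mp = &masks;
  }
  vec p = forward_net(net, X, mp);
  return bce_loss(y, p) + l2_penalty(net, lambda);
}

// [[Rcpp::export]]
List cpp_mlp_train(arma::mat Xtr, arma::vec ytr, arma::mat Xval, arma::vec yval,
                   IntegerVector hidden, double lambda, double dropout,
                   double lr, double beta1, double beta2, double adam_eps,
                   int batch, int epochs, int patience, int seed) {
  IntegerVector sizes(hidden.size() + 2);
  sizes[0] = Xtr.n_cols;
  for (int l = 0; l < hidden.size(); ++l) sizes[l + 1] = hidden[l];
  sizes[hidden.size() + 1] = 1;
  List init = cpp_mlp_init(sizes, seed);
  Net net = net_from_list(init["W"], init["b"]);
  size_t L = net.W.size();

  std::mt19937 rng(static_cast<unsigned>(seed) ^ 0x9e3779b9u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = mat(arma::size(net.W[l]), arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = vec(net.b[l].n_elem, arma::fill::zeros);
    vb[l] = mb[l];
  }

  int n = Xtr.n_rows;
  bool use_val = Xval.n_rows > 0;
  std::vector<double> train_log, val_log;
  Net best = net;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0;
  long t = 0;
  double keep = 1.0 - dropout;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  // Persistent workspace: assignment into same-sized matrices does not
  // reallocate, which matters at these batch/layer sizes.
  std::vector<mat> Zs(L - 1), As(L), Msk(L - 1), gW(L);
  std::vector<vec> gb(L);
  mat Xb, D;
  vec yb, p, z, delta;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n);
      int nb = end - start;
      arma::uvec idx(nb);
      for (int i = start; i < end; ++i) idx[i - start] = order[i];
      Xb = Xtr.rows(idx);
      yb = ytr.elem(idx);
      // forward
      As[0] = Xb;
      for (size_t l = 0; l + 1 < L; ++l) {
        Zs[l] = As[l] * net.W[l].t();
        Zs[l].each_row() += net.b[l].t();
        mat& A = As[l + 1];
        A = Zs[l];
        double* a = A.memptr();
        for (arma::uword i = 0; i < A.n_elem; ++i) if (a[i] < 0.0) a[i] = 0.0;
        if (dropout > 0.0) {
          Msk[l].set_size(A.n_rows, A.n_cols);
          double* m = Msk[l].memptr();
          for (arma::uword i = 0; i < A.n_elem; ++i)
            m[i] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
          A %= Msk[l];
        }
      }
      z = As[L - 1] * net.W[L - 1].t() + net.b[L - 1](0);
      p = 1.0 / (1.0 + arma::exp(-z));
      epoch_loss += bce_loss(yb, p) + l2_penalty(net, lambda);
      // backward
      delta = (p - yb) / static_cast<double>(nb);
      gW[L - 1] = delta.t() * As[L - 1] + 2.0 * lambda * net.W[L - 1];
      gb[L - 1].set_size(1);
      gb[L - 1](0) = arma::accu(delta);
      D = delta * net.W[L - 1];
      for (int l = static_cast<int>(L) - 2; l >= 0; --l) {
        if (dropout > 0.0) D %= Msk[l];
        {
          double* d = D.memptr();
          const double* zp = Zs[l].memptr();
          for (arma::uword i = 0; i < D.n_elem; ++i) if (zp[i] <= 0.0) d[i] = 0.0;
        }
        gW[l] = D.t() * As[l] + 2.0 * lambda * net.W[l];
        gb[l] = arma::sum(D, 0).t();
        if (l > 0) D = D * net.W[l];
      }
      ++n_batches;
      ++t;
      double c1 = 1.0 - std::pow(beta1, (double)t);
      double c2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t l = 0; l < L; ++l) {
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW[l];
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW[l]);
        net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + adam_eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb[l];
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb[l]);
        net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + adam_eps);
      }
    }
    train_log.push_back(epoch_loss / n_batches);
    if (use_val) {
      vec pv = forward_net(net, Xval, nullptr);
      double vl = bce_loss(yval, pv);
      val_log.push_back(vl);
      if (vl < best_val - 1e-12) {
        best_val = vl;
        best = net;
        best_epoch = epoch;
        wait = 0;
      } else {
        ++wait;
        if (wait >= std::max(patience, 1)) break;
      }
    } else {
      best = net;
      best_epoch = epoch;
    }
  }
  List out = net_to_list(best);
  out["train_loss"] = train_log;
  out["val_loss"] = val_log;
  out["best_epoch"] = best_epoch;
  return out;
}
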