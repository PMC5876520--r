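// Compiled core of the per-timestep sequence classifier: a time-distributed
// dense layer (batch norm + ELU), two stacked bidirectional GRU layers
// (batch norm on their outputs), dropout on every hidden layer, and a
// per-timestep softmax head, trained with class-weighted categorical
// cross-entropy. Forward and backward passes are written out explicitly;
// the R side owns parameter initialization, batching and the Adam update.
//
// Shape conventions: a batch of windows is a cube (B, F, T) whose slice t is
// the (B x F) matrix of all windows at timestep t. Flattened matrices stack
// slices, so flat row index = t * B + b.

#include <RcppArmadillo.h>
#include <cmath>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double BN_EPS = 1e-5;
static const double LOG_FLOOR = 1e-12;

static mat flatten_time(const cube &X) {
  mat M(X.n_rows * X.n_slices, X.n_cols);
  for (uword t = 0; t < X.n_slices; ++t)
    M.rows(t * X.n_rows, (t + 1) * X.n_rows - 1) = X.slice(t);
  return M;
}

static cube unflatten_time(const mat &M, uword B, uword T) {
  cube X(B, M.n_cols, T);
  for (uword t = 0; t < T; ++t)
    X.slice(t) = M.rows(t * B, (t + 1) * B - 1);
  return X;
}

// ---- GRU -------------------------------------------------------------------

struct GruCache {
  cube Z, R, C, H;
};

// X: (B, D, T); Wx: D x 3U (gate order z, r, candidate); Uh: U x 3U; b: 3U.
// h_t = (1 - z_t) .* h_{t-1} + z_t .* c_t
static void gru_forward(const cube &X, const mat &Wx, const mat &Uh,
                        const rowvec &b, bool reverse, GruCache &cc) {
  uword B = X.n_rows, T = X.n_slices, U = Uh.n_rows;
  cc.Z.set_size(B, U, T);
  cc.R.set_size(B, U, T);
  cc.C.set_size(B, U, T);
  cc.H.set_size(B, U, T);
  mat h(B, U, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? T - 1 - step : step;
    mat pre = X.slice(t) * Wx;
    pre.each_row() += b;
    mat z = 1.0 / (1.0 + exp(-(pre.cols(0, U - 1) + h * Uh.cols(0, U - 1))));
    mat r = 1.0 / (1.0 + exp(-(pre.cols(U, 2 * U - 1) + h * Uh.cols(U, 2 * U - 1))));
    mat c = tanh(pre.cols(2 * U, 3 * U - 1) + (r % h) * Uh.cols(2 * U, 3 * U - 1));
    h = (1.0 - z) % h + z % c;
    cc.Z.slice(t) = z;
    cc.R.slice(t) = r;
    cc.C.slice(t) = c;
    cc.H.slice(t) = h;
  }
}

static cube gru_backward(const cube &X, const mat &Wx, const mat &Uh,
                         const GruCache &cc, const cube &dH, bool reverse,
                         mat &dWx, mat &dUh, rowvec &db) {
  uword B = X.n_rows, D = X.n_cols, T = X.n_slices, U = Uh.n_rows;
  dWx.zeros(D, 3 * U);
  dUh.zeros(U, 3 * U);
  db.zeros(3 * U);
  cube dX(B, D, T, fill::zeros);
  mat dh_next(B, U, fill::zeros);
  for (uword step = T; step-- > 0;) {
    uword t = reverse ? T - 1 - step : step;
    mat hprev(B, U, fill::zeros);
    if (step > 0) {
      uword tprev = reverse ? T - step : step - 1;
      hprev = cc.H.slice(tprev);
    }
    mat z = cc.Z.slice(t), r = cc.R.slice(t), c = cc.C.slice(t);
    mat dh = dH.slice(t) + dh_next;
    mat dsc = dh % z % (1.0 - c % c);
    mat dsz = dh % (c - hprev) % z % (1.0 - z);
    mat drh = dsc * Uh.cols(2 * U, 3 * U - 1).t(); // grad wrt r .* hprev
    mat dsr = drh % hprev % r % (1.0 - r);
    dh_next = dh % (1.0 - z) + dsz * Uh.cols(0, U - 1).t() +
              dsr * Uh.cols(U, 2 * U - 1).t() + drh % r;
    mat gates = join_rows(dsz, join_rows(dsr, dsc));
    dWx += X.slice(t).t() * gates;
    dUh.cols(0, U - 1) += hprev.t() * dsz;
    dUh.cols(U, 2 * U - 1) += hprev.t() * dsr;
    dUh.cols(2 * U, 3 * U - 1) += (r % hprev).t() * dsc;
    db += sum(gates, 0);
    dX.slice(t) = gates * Wx.t();
  }
  return dX;
}

// ---- batch normalization ---------------------------------------------------

struct BnCache {
  mat xhat;
  rowvec invstd;
};

static mat bn_forward_train(const mat &X, const rowvec &gamma, const rowvec &beta,
                            rowvec &run_mean, rowvec &run_var, double momentum,
                            BnCache &cc) {
  rowvec mu = mean(X, 0);
  rowvec v = mean(square(X.each_row() - mu), 0);
  cc.invstd = 1.0 / sqrt(v + BN_EPS);
  cc.xhat = (X.each_row() - mu).each_row() % cc.invstd;
  run_mean = momentum * run_mean + (1.0 - momentum) * mu;
  run_var = momentum * run_var + (1.0 - momentum) * v;
  mat out = cc.xhat.each_row() % gamma;
  out.each_row() += beta;
  return out;
}

static mat bn_forward_infer(const mat &X, const rowvec &gamma, const rowvec &beta,
                            const rowvec &run_mean, const rowvec &run_var) {
  rowvec scale = gamma / sqrt(run_var + BN_EPS);
  mat out = (X.each_row() - run_mean).each_row() % scale;
  out.each_row() += beta;
  return out;
}

static mat bn_backward(const mat &dY, const rowvec &gamma, const BnCache &cc,
                       rowvec &dgamma, rowvec &dbeta) {
  double N = (double)dY.n_rows;
  dgamma = sum(dY % cc.xhat, 0);
  dbeta = sum(dY, 0);
  mat dxhat = dY.each_row() % gamma;
  mat dx = dxhat * N;
  dx.each_row() -= sum(dxhat, 0);
  dx -= cc.xhat.each_row() % sum(dxhat % cc.xhat, 0);
  dx /= N;
  dx.each_row() %= cc.invstd;
  return dx;
}

// ---- misc ------------------------------------------------------------------

static mat elu(const mat &X) {
  mat out = X;
  out.transform([](double x) { return x > 0 ? x : std::expm1(x); });
  return out;
}

static mat dropout_mask(uword n, uword m, double rate, std::mt19937_64 &rng) {
  mat mask(n, m);
  if (rate <= 0) {
    mask.ones();
    return mask;
  }
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double keep = 1.0 - rate;
  for (uword j = 0; j < m; ++j)
    for (uword i = 0; i < n; ++i)
      mask(i, j) = unif(rng) < keep ? 1.0 / keep : 0.0;
  return mask;
}

static mat softmax_rows(const mat &L) {
  mat m = L.each_col() - max(L, 1);
  m = exp(m);
  m.each_col() /= sum(m, 1);
  return m;
}

#define P(name) as<mat>(params[name])
#define PV(name) as<rowvec>(params[name])
using Rcpp::as;

// Inference-mode forward pass: probabilities for a batch of windows.
// X: (B, feature_dim, T) cube; returns (B, K, T) cube of row-stochastic slices.
// [[Rcpp::export]]
arma::cube cpp_net_forward(List params, List running, arma::cube X) {
  uword B = X.n_rows, T = X.n_slices;
  mat Xf = flatten_time(X);
  mat A1 = elu(bn_forward_infer(Xf * P("W1"), PV("bn1_gamma"), PV("bn1_beta"),
                                as<rowvec>(running["bn1_mean"]),
                                as<rowvec>(running["bn1_var"])));
  // dense output has bias folded into batch norm's beta; no separate b1 needed
  cube X1 = unflatten_time(A1, B, T);
  GruCache f1, b1;
  gru_forward(X1, P("gru1f_Wx"), P("gru1f_Uh"), PV("gru1f_b"), false, f1);
  gru_forward(X1, P("gru1b_Wx"), P("gru1b_Uh"), PV("gru1b_b"), true, b1);
  cube H1(B, f1.H.n_cols + b1.H.n_cols, T);
  for (uword t = 0; t < T; ++t)
    H1.slice(t) = join_rows(f1.H.slice(t), b1.H.slice(t));
  mat F1 = bn_forward_infer(flatten_time(H1), PV("bn2_gamma"), PV("bn2_beta"),
                            as<rowvec>(running["bn2_mean"]),
                            as<rowvec>(running["bn2_var"]));
  cube X2 = unflatten_time(F1, B, T);
  GruCache f2, b2;
  gru_forward(X2, P("gru2f_Wx"), P("gru2f_Uh"), PV("gru2f_b"), false, f2);
  gru_forward(X2, P("gru2b_Wx"), P("gru2b_Uh"), PV("gru2b_b"), true, b2);
  cube H2(B, f2.H.n_cols + b2.H.n_cols, T);
  for (uword t = 0; t < T; ++t)
    H2.slice(t) = join_rows(f2.H.slice(t), b2.H.slice(t));
  mat F2 = bn_forward_infer(flatten_time(H2), PV("bn3_gamma"), PV("bn3_beta"),
                            as<rowvec>(running["bn3_mean"]),
                            as<rowvec>(running["bn3_var"]));
  mat logits = F2 * P("Wo");
  logits.each_row() += PV("bo");
  return unflatten_time(softmax_rows(logits), B, T);
}

// One training step on one mini-batch: forward with batch statistics and
// dropout, class-weighted cross-entropy, full backward pass. Returns the
// loss, gradients named like the parameters, and updated running stats.
// Y: (B, T) integer matrix of 0-based class indices; alpha: length-K weights.
// [[Rcpp::export]]
List cpp_net_train_batch(List params, List running, arma::cube X,
                         arma::imat Y, arma::vec alpha, double dropout_rate,
                         double bn_momentum, int seed, bool update_running) {
  uword B = X.n_rows, T = X.n_slices;
  std::mt19937_64 rng((uint64_t)seed);

  rowvec bn1_mean = as<rowvec>(running["bn1_mean"]);
  rowvec bn1_var = as<rowvec>(running["bn1_var"]);
  rowvec bn2_mean = as<rowvec>(running["bn2_mean"]);
  rowvec bn2_var = as<rowvec>(running["bn2_var"]);
  rowvec bn3_mean = as<rowvec>(running["bn3_mean"]);
  rowvec bn3_var = as<rowvec>(running["bn3_var"]);
  double mom = update_running ? bn_momentum : 1.0;

  // forward
  mat Xf = flatten_time(X);
  mat Z1 = Xf * P("W1");
  BnCache bnc1;
  mat S1 = bn_forward_train(Z1, PV("bn1_gamma"), PV("bn1_beta"), bn1_mean,
                            bn1_var, mom, bnc1);
  mat A1 = elu(S1);
  mat M1 = dropout_mask(A1.n_rows, A1.n_cols, dropout_rate, rng);
  mat A1d = A1 % M1;
  cube X1 = unflatten_time(A1d, B, T);

  GruCache g1f, g1b;
  gru_forward(X1, P("gru1f_Wx"), P("gru1f_Uh"), PV("gru1f_b"), false, g1f);
  gru_forward(X1, P("gru1b_Wx"), P("gru1b_Uh"), PV("gru1b_b"), true, g1b);
  uword U1 = g1f.H.n_cols;
  cube H1(B, 2 * U1, T);
  for (uword t = 0; t < T; ++t)
    H1.slice(t) = join_rows(g1f.H.slice(t), g1b.H.slice(t));
  BnCache bnc2;
  mat S2 = bn_forward_train(flatten_time(H1), PV("bn2_gamma"), PV("bn2_beta"),
                            bn2_mean, bn2_var, mom, bnc2);
  mat M2 = dropout_mask(S2.n_rows, S2.n_cols, dropout_rate, rng);
  mat A2 = S2 % M2;
  cube X2 = unflatten_time(A2, B, T);

  GruCache g2f, g2b;
  gru_forward(X2, P("gru2f_Wx"), P("gru2f_Uh"), PV("gru2f_b"), false, g2f);
  gru_forward(X2, P("gru2b_Wx"), P("gru2b_Uh"), PV("gru2b_b"), true, g2b);
  uword U2 = g2f.H.n_cols;
  cube H2(B, 2 * U2, T);
  for (uword t = 0; t < T; ++t)
    H2.slice(t) = join_rows(g2f.H.slice(t), g2b.H.slice(t));
  BnCache bnc3;
  mat S3 = bn_forward_train(flatten_time(H2), PV("bn3_gamma"), PV("bn3_beta"),
                            bn3_mean, bn3_var, mom, bnc3);
  mat M3 = dropout_mask(S3.n_rows, S3.n_cols, dropout_rate, rng);
  mat A3 = S3 % M3;

  mat logits = A3 * P("Wo");
  logits.each_row() += PV("bo");
  mat Pr = softmax_rows(logits);

  // weighted cross-entropy; flat row index = t * B + b matches flatten_time
  uword Nrows = Pr.n_rows;
  double loss = 0.0;
  mat dlogits = Pr;
  for (uword t = 0; t < T; ++t) {
    for (uword b = 0; b < B; ++b) {
      uword row = t * B + b;
      uword cls = (uword)Y(b, t);
      double a = alpha((uword)cls);
      loss += -a * std::log(std::max(Pr(row, cls), LOG_FLOOR));
      dlogits.row(row) *= a;
      dlogits(row, cls) -= a;
    }
  }
  loss /= (double)Nrows;
  dlogits /= (double)Nrows;

  // backward
  mat dWo = A3.t() * dlogits;
  rowvec dbo = sum(dlogits, 0);
  mat dA3 = dlogits * P("Wo").t();
  mat dS3 = dA3 % M3;
  rowvec dbn3_gamma, dbn3_beta;
  mat dF2 = bn_backward(dS3, PV("bn3_gamma"), bnc3, dbn3_gamma, dbn3_beta);
  cube dH2 = unflatten_time(dF2, B, T);
  cube dH2f = dH2.cols(0, U2 - 1);
  cube dH2b = dH2.cols(U2, 2 * U2 - 1);
  mat dg2f_Wx, dg2f_Uh, dg2b_Wx, dg2b_Uh;
  rowvec dg2f_b, dg2b_b;
  cube dX2 = gru_backward(X2, P("gru2f_Wx"), P("gru2f_Uh"), g2f, dH2f, false,
                          dg2f_Wx, dg2f_Uh, dg2f_b) +
             gru_backward(X2, P("gru2b_Wx"), P("gru2b_Uh"), g2b, dH2b, true,
                          dg2b_Wx, dg2b_Uh, dg2b_b);
  mat dA2 = flatten_time(dX2);
  mat dS2 = dA2 % M2;
  rowvec dbn2_gamma, dbn2_beta;
  mat dF1 = bn_backward(dS2, PV("bn2_gamma"), bnc2, dbn2_gamma, dbn2_beta);
  cube dH1 = unflatten_time(dF1, B, T);
  cube dH1f = dH1.cols(0, U1 - 1);
  cube dH1b = dH1.cols(U1, 2 * U1 - 1);
  mat dg1f_Wx, dg1f_Uh, dg1b_Wx, dg1b_Uh;
  rowvec dg1f_b, dg1b_b;
  cube dX1 = gru_backward(X1, P("gru1f_Wx"), P("gru1f_Uh"), g1f, dH1f, false,
                          dg1f_Wx, dg1f_Uh, dg1f_b) +
             gru_backward(X1, P("gru1b_Wx"), P("gru1b_Uh"), g1b, dH1b, true,
                          dg1b_Wx, dg1b_Uh, dg1b_b);
  mat dA1d = flatten_time(dX1);
  mat dA1 = dA1d % M1;
  // ELU'(s) = 1 for s > 0 else elu(s) + 1
  mat dS1 = dA1 % (conv_to<mat>::from(S1 > 0) +
                   (conv_to<mat>::from(S1 <= 0) % (A1 + 1.0)));
  rowvec dbn1_gamma, dbn1_beta;
  mat dZ1 = bn_backward(dS1, PV("bn1_gamma"), bnc1, dbn1_gamma, dbn1_beta);
  mat dW1 = Xf.t() * dZ1;

  List grads = List::create(
      Named("W1") = dW1, Named("bn1_gamma") = dbn1_gamma,
      Named("bn1_beta") = dbn1_beta, Named("gru1f_Wx") = dg1f_Wx,
      Named("gru1f_Uh") = dg1f_Uh, Named("gru1f_b") = dg1f_b,
      Named("gru1b_Wx") = dg1b_Wx, Named("gru1b_Uh") = dg1b_Uh,
      Named("gru1b_b") = dg1b_b, Named("bn2_gamma") = dbn2_gamma,
      Named("bn2_beta") = dbn2_beta, Named("gru2f_Wx") = dg2f_Wx,
      Named("gru2f_Uh") = dg2f_Uh, Named("gru2f_b") = dg2f_b,
      Named("gru2b_Wx") = dg2b_Wx, Named("gru2b_Uh") = dg2b_Uh,
      Named("gru2b_b") = dg2b_b, Named("bn3_gamma") = dbn3_gamma,
      Named("bn3_beta") = dbn3_beta, Named("Wo") = dWo, Named("bo") = dbo);
  List new_running = List::create(
      Named("bn1_mean") = bn1_mean, Named("bn1_var") = bn1_var,
      Named("bn2_mean") = bn2_mean, Named("bn2_var") = bn2_var,
      Named("bn3_mean") = bn3_mean, Named("bn3_var") = bn3_var);
  return List::create(Named("loss") = loss, Named("grads") = grads,
                      Named("running") = new_running);
}
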