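#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 4-3-1 multilayer perceptron, logistic activations on both layers.
//
// Parameter packing (19 components, shared with the R side):
//   par[0..11]  W1, the 3x4 hidden weight matrix in column-major order
//               (W1[j,i] = par[j + 3*i], hidden unit j, input i)
//   par[12..14] b1, hidden biases
//   par[15..17] w2, hidden-to-output weights
//   par[18]     b2, output bias
//
// Loss: E = sum_i (y_i - t_i)^2 / 2 (sum of squared errors).

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static inline double forward_one(const double* par, const double* x, int n,
                                 double* h) {
  // x points into a column-major n x 4 matrix: x[i-th input] = x[input * n]
  double z = par[18];
  for (int j = 0; j < 3; ++j) {
    double a = par[12 + j];
    for (int i = 0; i < 4; ++i) a += par[j + 3 * i] * x[(size_t)i * n];
    h[j] = sigmoid(a);
    z += par[15 + j] * h[j];
  }
  return sigmoid(z);
}

// [[Rcpp::export]]
NumericVector cpp_mlp_forward(NumericVector par, NumericMatrix X) {
  if (par.size() != 19) stop("parameter vector must have 19 components");
  if (X.ncol() != 4) stop("input matrix must have 4 columns");
  int n = X.nrow();
  NumericVector out(n);
  double h[3];
  const double* xp = X.begin();
  for (int r = 0; r < n; ++r) out[r] = forward_one(&par[0], xp + r, n, h);
  return out;
}

// Accumulate the gradient of E over all rows; returns E.
static double grad_sse(const double* par, const double* X, const double* t,
                       int n, double* g) {
  for (int k = 0; k < 19; ++k) g[k] = 0.0;
  double h[3], err = 0.0;
  for (int r = 0; r < n; ++r) {
    const double* x = X + r;
    double y = forward_one(par, x, n, h);
    double resid = y - t[r];
    err += 0.5 * resid * resid;
    double dz = resid * y * (1.0 - y);  // dE/dz_out
    g[18] += dz;
    for (int j = 0; j < 3; ++j) {
      g[15 + j] += dz * h[j];
      double dh = dz * par[15 + j] * h[j] * (1.0 - h[j]);  // dE/dz_hidden_j
      g[12 + j] += dh;
      for (int i = 0; i < 4; ++i) g[j + 3 * i] += dh * x[(size_t)i * n];
    }
  }
  return err;
}

// [[Rcpp::export]]
List cpp_mlp_gradient(NumericVector par, NumericMatrix X, NumericVector t) {
  if (par.size() != 19) stop("parameter vector must have 19 components");
  if (X.ncol() != 4) stop("input matrix must have 4 columns");
  if (t.size() != X.nrow()) stop("target length must match rows of X");
  NumericVector g(19);
  double err = grad_sse(&par[0], X.begin(), t.begin(), X.nrow(), &g[0]);
  return List::create(_["gradient"] = g, _["error"] = err);
}

// Full-batch gradient descent with backtracking: a step that would increase
// the error is rejected and the step size halved; accepted steps grow the
// step size slightly (capped).  Stops when the largest absolute gradient
// component falls below `stop_threshold`.
// [[Rcpp::export]]
List cpp_mlp_train(NumericVector par0, NumericMatrix X, NumericVector t,
                   double learning_rate, int max_epochs,
                   double stop_threshold) {
  if (par0.size() != 19) stop("parameter vector must have 19 components");
  if (X.ncol() != 4) stop("input matrix must have 4 columns");
  if (t.size() != X.nrow()) stop("target length must match rows of X");
  int n = X.nrow();
  const double* Xp = X.begin();
  const double* tp = t.begin();
  double par[19], trial[19], g[19];
  for (int k = 0; k < 19; ++k) par[k] = par0[k];
  double lr = learning_rate;
  const double lr_cap = learning_rate * 64.0;
  double err = grad_sse(par, Xp, tp, n, g);
  bool converged = false;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    double gmax = 0.0;
    for (int k = 0; k < 19; ++k) gmax = std::max(gmax, std::fabs(g[k]));
    if (gmax < stop_threshold) { converged = true; break; }
    // backtrack until the trial step does not increase the error
    double trial_err = 0.0, gt[19];
    int halvings = 0;
    for (; halvings < 60; ++halvings) {
      for (int k = 0; k < 19; ++k) trial[k] = par[k] - lr * g[k];
      trial_err = grad_sse(trial, Xp, tp, n, gt);
      if (R_finite(trial_err) && trial_err <= err * (1.0 + 1e-12)) break;
      lr *= 0.5;
    }
    if (halvings == 60) break;  // step size underflowed; treat as stalled
    for (int k = 0; k < 19; ++k) { par[k] = trial[k]; g[k] = gt[k]; }
    err = trial_err;
    lr = std::min(lr * 1.1, lr_cap);
    if (!R_finite(err)) break;
  }
  NumericVector out(19);
  for (int k = 0; k < 19; ++k) out[k] = par[k];
  return List::create(_["par"] = out, _["error"] = err,
                      _["epochs"] = epoch, _["converged"] = converged);
}

// Mean forward output over an ensemble: pars is a 19 x M matrix of member
// parameter vectors; returns the length-n consolidated prediction.
// [[Rcpp::export]]
NumericVector cpp_ensemble_consolidate(NumericMatrix pars, NumericMatrix X) {
  if (pars.nrow() != 19) stop("parameter matrix must have 19 rows");
  if (X.ncol() != 4) stop("input matrix must have 4 columns");
  int n = X.nrow(), M = pars.ncol();
  if (M == 0) stop("ensemble is empty");
  NumericVector out(n);
  double h[3];
  const double* xp = X.begin();
  for (int m = 0; m < M; ++m) {
    const double* p = &pars(0, m);
    for (int r = 0; r < n; ++r) out[r] += forward_one(p, xp + r, n, h);
  }
  for (int r = 0; r < n; ++r) out[r] /= M;
  return out;
}
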