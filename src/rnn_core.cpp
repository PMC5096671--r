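// Continuous-rate RNN: Euler-integrated forward pass and backpropagation
// through time for the reach-velocity task.
//
// Dynamics (per condition column):
//   x_t = (1 - alpha) x_{t-1} + alpha (J r_{t-1} + B u_t),  alpha = dt / tau
//   r_t = rtanh(x_t) = 0 for x < 0, tanh(x) for x >= 0
//   z_t = W r_t
// Loss = sum ||z - v||^2 / sst
//      + reg_rate * mean(r^2)
//      + reg_weights * (sum B^2 + sum W^2)
//      + reg_complexity * mean(||x_t - x_{t-1}||^2)   (state-velocity surrogate)
// Sums/means run over all delays, conditions and time steps; x_0 = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat rtanh(const arma::mat& x) {
  return arma::tanh(arma::clamp(x, 0.0, arma::datum::inf));
}
static inline arma::mat rtanh_deriv(const arma::mat& x) {
  arma::mat d = 1.0 - arma::square(arma::tanh(x));
  d.elem(arma::find(x < 0)).zeros();
  return d;
}

// Forward simulation of one trial set (all conditions of one delay).
// u: inputs cube (I x C x T); returns states x (N x C x T), rates r, outputs z.
// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& J, const arma::mat& B, const arma::mat& W,
                     double alpha, const arma::cube& u) {
  const int N = J.n_rows, C = u.n_cols, T = u.n_slices;
  arma::cube x(N, C, T), r(N, C, T), z(W.n_rows, C, T);
  arma::mat xt(N, C, arma::fill::zeros), rt(N, C, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    xt = (1.0 - alpha) * xt + alpha * (J * rt + B * u.slice(t));
    if (!xt.is_finite()) stop("RNN state diverged at step %d", t + 1);
    rt = rtanh(xt);
    x.slice(t) = xt;
    r.slice(t) = rt;
    z.slice(t) = W * rt;
  }
  return List::create(_["x"] = x, _["r"] = r, _["z"] = z);
}

// Loss and analytic gradients over a list of trial sets.
// us / vs: lists of cubes (I x C x T) and (O x C x T); sst = total target
// variance; nr / mc: element counts for the rate and complexity means.
// [[Rcpp::export]]
List rnn_loss_grad_cpp(const arma::mat& J, const arma::mat& B, const arma::mat& W,
                       double alpha, List us, List vs, double sst,
                       double reg_rate, double reg_weights, double reg_complexity,
                       double nr, double mc) {
  const int N = J.n_rows;
  arma::mat dJ(arma::size(J), arma::fill::zeros);
  arma::mat dB(arma::size(B), arma::fill::zeros);
  arma::mat dW(arma::size(W), arma::fill::zeros);
  double err_ss = 0, rate_ss = 0, comp_ss = 0;

  for (int s = 0; s < us.size(); ++s) {
    arma::cube u = us[s];
    arma::cube v = vs[s];
    const int C = u.n_cols, T = u.n_slices;
    arma::cube x(N, C, T), r(N, C, T), e(W.n_rows, C, T);
    { // forward
      arma::mat xt(N, C, arma::fill::zeros), rt(N, C, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        xt = (1.0 - alpha) * xt + alpha * (J * rt + B * u.slice(t));
        if (!xt.is_finite()) stop("RNN state diverged during training forward pass");
        rt = rtanh(xt);
        x.slice(t) = xt; r.slice(t) = rt;
        arma::mat et = W * rt - v.slice(t);
        e.slice(t) = et;
        err_ss += arma::accu(arma::square(et));
        rate_ss += arma::accu(arma::square(rt));
        comp_ss += (t == 0) ? arma::accu(arma::square(xt))
                            : arma::accu(arma::square(xt - x.slice(t - 1)));
      }
    }
    { // backward
      arma::mat delta_next(N, C, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        const arma::mat& xt = x.slice(t);
        const arma::mat& rt = r.slice(t);
        arma::mat g_r = W.t() * (2.0 / sst * e.slice(t)) + (2.0 * reg_rate / nr) * rt;
        if (t < T - 1) g_r += alpha * (J.t() * delta_next);
        arma::mat delta = rtanh_deriv(xt) % g_r;
        if (t < T - 1) delta += (1.0 - alpha) * delta_next;
        // complexity: d/dx_t of ||x_t - x_{t-1}||^2 + ||x_{t+1} - x_t||^2
        arma::mat comp = xt;
        if (t > 0) comp -= x.slice(t - 1);
        if (t < T - 1) comp += xt - x.slice(t + 1);
        delta += (2.0 * reg_complexity / mc) * comp;
        dW += (2.0 / sst) * e.slice(t) * rt.t();
        if (t > 0) dJ += alpha * delta * r.slice(t - 1).t();
        dB += alpha * delta * u.slice(t).t();
        delta_next = delta;
      }
    }
  }
  dW += 2.0 * reg_weights * W;
  dB += 2.0 * reg_weights * B;
  double loss = err_ss / sst + reg_rate * rate_ss / nr +
                reg_weights * (arma::accu(arma::square(B)) + arma::accu(arma::square(W))) +
                reg_complexity * comp_ss / mc;
  return List::create(_["loss"] = loss, _["err_ss"] = err_ss,
                      _["dJ"] = dJ, _["dB"] = dB, _["dW"] = dW);
}
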