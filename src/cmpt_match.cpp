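// Greedy covariance matching for the covariance-matched permutation test.
//
// State: an n x (c*t) matrix of permuted traces (condition blocks of t
// columns). Proposals swap two whole condition blocks within one neuron's
// row; a proposal is accepted iff it strictly increases the similarity
// between the permuted and observed neuron-by-neuron covariance matrices.
// Only row/column i of the covariance changes under such a swap (row means
// and own-variances are permutation invariant), so the change in the summed
// squared difference is computed incrementally from the two affected blocks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List cmpt_match_cpp(const arma::mat& X_obs, int n_cond, int n_time,
                    IntegerMatrix assign0, double threshold,
                    double max_swaps, bool record_trace = false) {
  const int n = X_obs.n_rows;
  const int ct = X_obs.n_cols;
  if (ct != n_cond * n_time) stop("column count must equal n_cond * n_time");

  // center rows (means are invariant under within-row block permutations)
  arma::mat Xc = X_obs;
  Xc.each_col() -= arma::mean(Xc, 1);

  // apply initial assignment: row i, slot c <- original condition assign0(c,i)
  IntegerMatrix assign = clone(assign0);
  arma::mat Xp(n, ct);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_cond; ++c) {
      int src = assign(c, i) - 1;
      Xp.submat(i, c * n_time, i, (c + 1) * n_time - 1) =
        Xc.submat(i, src * n_time, i, (src + 1) * n_time - 1);
    }

  const double denom = ct - 1;
  arma::mat C_obs = (Xc * Xc.t()) / denom;
  arma::mat C_perm = (Xp * Xp.t()) / denom;
  const double tss = arma::accu(arma::square(C_obs - arma::mean(arma::vectorise(C_obs))));
  if (tss <= 0) stop("zero-variance observed covariance: similarity undefined");
  double ssd = arma::accu(arma::square(C_obs - C_perm));

  std::vector<double> trace;
  double proposals = 0, accepted = 0;
  arma::vec delta(n), diff_blk(n_time);
  while (1.0 - ssd / tss < threshold && proposals < max_swaps) {
    ++proposals;
    int i = runif_int(n);
    int a = runif_int(n_cond);
    int b = runif_int(n_cond - 1);
    if (b >= a) ++b;
    const arma::uword a0 = (arma::uword)a * n_time, a1 = a0 + n_time - 1;
    const arma::uword b0 = (arma::uword)b * n_time, b1 = b0 + n_time - 1;
    // delta = row i's block b minus block a (current permuted values)
    diff_blk = (Xp.submat(i, b0, i, b1) - Xp.submat(i, a0, i, a1)).t();
    // change in C[i,j] for all j: delta . (x_j[a] - x_j[b]) / (ct-1)
    delta = (Xp.cols(a0, a1) * diff_blk - Xp.cols(b0, b1) * diff_blk) / denom;
    delta(i) = 0; // own variance is unchanged by the swap
    // d(SSD) over row i and column i (symmetric)
    double dssd = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double e = C_perm(i, j) - C_obs(i, j);
      dssd += 2.0 * delta(j) * (2.0 * e + delta(j));
    }
    if (dssd < 0) {
      ++accepted;
      arma::rowvec tmp = Xp.submat(i, a0, i, a1);
      Xp.submat(i, a0, i, a1) = Xp.submat(i, b0, i, b1);
      Xp.submat(i, b0, i, b1) = tmp;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        C_perm(i, j) += delta(j);
        C_perm(j, i) += delta(j);
      }
      ssd += dssd;
      std::swap(assign(a, i), assign(b, i));
      if (record_trace) trace.push_back(1.0 - ssd / tss);
    }
  }

  // exact recomputation guards against accumulated round-off
  arma::mat C_final = (Xp * Xp.t()) / denom;
  double ssd_exact = arma::accu(arma::square(C_obs - C_final));
  double sim = 1.0 - ssd_exact / tss;

  return List::create(
    _["assignment"] = assign,
    _["similarity"] = sim,
    _["similarity_incremental"] = 1.0 - ssd / tss,
    _["proposals"] = proposals,
    _["accepted"] = accepted,
    _["converged"] = sim >= threshold - 1e-9,
    _["trace"] = trace
  );
}
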