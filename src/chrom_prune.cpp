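// Pruning kernel for the chromosome-number chain: propagates conditional
// likelihood vectors along a postordered edge list using per-regime
// eigendecompositions of the rate matrix (real spectrum assumed; the R
// caller verifies this and falls back to an R implementation otherwise).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List chrom_prune_cpp(const IntegerMatrix edge, const NumericVector edge_length,
                     const IntegerVector edge_regime, const List V_list,
                     const List Vi_list, const List lam_list,
                     const List Q_list, const LogicalVector use_expm,
                     const IntegerVector tip_idx, const int n_node) {
  const int n_regime = V_list.size();
  const int n_tip = tip_idx.size();
  const int n_edge = edge.nrow();

  std::vector<arma::cx_mat> V(n_regime), Vi(n_regime);
  std::vector<arma::cx_vec> lam(n_regime);
  std::vector<arma::mat> Q(n_regime);
  int n_states = 0;
  for (int r = 0; r < n_regime; r++) {
    if (use_expm[r]) {
      Q[r] = as<arma::mat>(Q_list[r]);
      n_states = Q[r].n_rows;
    } else {
      V[r] = as<arma::cx_mat>(V_list[r]);
      Vi[r] = as<arma::cx_mat>(Vi_list[r]);
      lam[r] = as<arma::cx_vec>(lam_list[r]);
      n_states = V[r].n_rows;
    }
  }

  arma::mat D(n_states, n_node, arma::fill::zeros);
  arma::mat M(n_states, n_node, arma::fill::zeros);
  arma::vec logsc(n_node, arma::fill::zeros);
  arma::vec logscM(n_node, arma::fill::zeros);
  std::vector<char> done(n_node, 0);
  for (int i = 0; i < n_tip; i++) D(tip_idx[i] - 1, i) = 1.0;

  for (int k = 0; k < n_edge; k++) {
    const int parent = edge(k, 0) - 1, child = edge(k, 1) - 1;
    const int r = edge_regime[k] - 1;
    arma::vec w;
    if (use_expm[r]) {
      // scaling-and-squaring matrix exponential for near-defective Q
      w = arma::expmat(Q[r] * edge_length[k]) * D.col(child);
    } else {
      w = arma::real(
        V[r] * (arma::exp(lam[r] * edge_length[k]) %
                (Vi[r] * arma::cx_vec(D.col(child),
                                      arma::vec(n_states, arma::fill::zeros)))));
    }
    w.transform([](double x) { return x > 0.0 ? x : 0.0; });
    const double mx = w.max();
    if (mx <= 0.0) {
      M.col(child).zeros();
      logscM(child) = -arma::datum::inf;
    } else {
      M.col(child) = w / mx;
      logscM(child) = logsc(child) + std::log(mx);
    }
    if (!done[parent]) {
      D.col(parent) = M.col(child);
      logsc(parent) = logscM(child);
      done[parent] = 1;
    } else {
      D.col(parent) %= M.col(child);
      logsc(parent) += logscM(child);
      const double mx2 = D.col(parent).max();
      if (mx2 > 0.0) {
        D.col(parent) /= mx2;
        logsc(parent) += std::log(mx2);
      } else {
        logsc(parent) = -arma::datum::inf;
      }
    }
  }
  return List::create(_["D"] = D, _["logsc"] = logsc, _["M"] = M,
                      _["logscM"] = logscM);
}
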