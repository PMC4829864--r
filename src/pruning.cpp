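#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for Brownian traits on a rooted binary tree.
//
// `edge` must be in postorder (each child edge before its parent's edge),
// with ape node numbering: tips 1..n_tip, root n_tip+1. X holds the tip
// values, one column per dataset, rows in tip-id order.
//
// The Gaussian likelihood factorises into n-1 independent contrasts plus
// the GLS root estimate, so we return that decomposition: per internal
// node the raw contrast between its two daughters and the pooled
// (branch-augmented) variance, plus the root value and its variance
// factor v_root = 1/(1' C^-1 1).
// [[Rcpp::export]]
List bm_pruning_cpp(const IntegerMatrix& edge,
                    const NumericVector& edge_length,
                    const int n_tip,
                    const NumericMatrix& X) {
  const int n_edge = edge.nrow();
  const int m = X.ncol();
  const int n_node = 2 * n_tip - 1;
  if (X.nrow() != n_tip) stop("X must have one row per tip");
  if (n_edge != n_node - 1) stop("tree is not a rooted binary tree");

  std::vector<double> xhat((n_node + 1) * m, 0.0);
  std::vector<double> v(n_node + 1, 0.0);
  std::vector<double> dv1(n_node + 1, 0.0);
  std::vector<int> first_child(n_node + 1, 0);
  std::vector<int> arrived(n_node + 1, 0);

  for (int i = 0; i < n_tip; ++i)
    for (int j = 0; j < m; ++j) xhat[(i + 1) * m + j] = X(i, j);

  NumericMatrix contrasts(n_tip - 1, m);
  NumericVector contrast_var(n_tip - 1);
  IntegerVector contrast_node(n_tip - 1);
  int k = 0;

  for (int e = 0; e < n_edge; ++e) {
    const int p = edge(e, 0), c = edge(e, 1);
    const double len = edge_length[e];
    if (len < 0) stop("negative branch length on edge %d", e + 1);
    const double dv = len + v[c];
    if (arrived[p] == 0) {
      first_child[p] = c;
      dv1[p] = dv;
      arrived[p] = 1;
    } else if (arrived[p] == 1) {
      const int c1 = first_child[p];
      const double V = dv1[p] + dv;
      if (V <= 0)
        stop("zero pooled variance at node %d: contrasts undefined", p);
      for (int j = 0; j < m; ++j) {
        const double x1 = xhat[c1 * m + j], x2 = xhat[c * m + j];
        contrasts(k, j) = x1 - x2;
        xhat[p * m + j] = (dv * x1 + dv1[p] * x2) / V;
      }
      contrast_var[k] = V;
      contrast_node[k] = p;
      v[p] = dv1[p] * dv / V;
      arrived[p] = 2;
      ++k;
    } else {
      stop("node %d has more than two children; tree must be binary", p);
    }
  }
  if (k != n_tip - 1) stop("tree traversal incomplete; is `edge` postorder?");

  const int root = n_tip + 1;
  NumericVector root_value(m);
  for (int j = 0; j < m; ++j) root_value[j] = xhat[root * m + j];

  return List::create(_["contrasts"] = contrasts,
                      _["contrast_var"] = contrast_var,
                      _["contrast_node"] = contrast_node,
                      _["root_value"] = root_value,
                      _["root_var"] = v[root]);
}
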