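#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-vertex normal and surface-variation curvature from the covariance of
// the k nearest vertices (the query vertex counts as one of the k).
// Normals are unit length and oriented away from the mesh centroid where
// possible; exact ties keep the eigenvector sign.
// [[Rcpp::export(name = ".cpp_vertex_attributes")]]
List cpp_vertex_attributes(const arma::mat& V, int k) {
  const int n = V.n_rows;
  if (k < 3) stop("k must be >= 3");
  if (n < k) stop("mesh has fewer vertices than the neighbourhood size");

  arma::mat Vt = V.t();                 // 3 x n, column access is contiguous
  arma::rowvec centroid = arma::mean(V, 0);

  arma::mat normals(n, 3);
  arma::vec curvature(n);

  std::vector<double> d2(n);
  std::vector<int> idx(n);

  for (int i = 0; i < n; ++i) {
    const arma::vec pi = Vt.col(i);
    for (int j = 0; j < n; ++j) {
      const double dx = Vt(0, j) - pi(0);
      const double dy = Vt(1, j) - pi(1);
      const double dz = Vt(2, j) - pi(2);
      d2[j] = dx * dx + dy * dy + dz * dz;
      idx[j] = j;
    }
    std::nth_element(idx.begin(), idx.begin() + k - 1, idx.end(),
                     [&](int a, int b) {
                       if (d2[a] != d2[b]) return d2[a] < d2[b];
                       return a < b;
                     });
    // covariance of the k nearest (including self)
    arma::vec mu(3, arma::fill::zeros);
    for (int t = 0; t < k; ++t) mu += Vt.col(idx[t]);
    mu /= k;
    arma::mat C(3, 3, arma::fill::zeros);
    for (int t = 0; t < k; ++t) {
      arma::vec d = Vt.col(idx[t]) - mu;
      C += d * d.t();
    }
    C /= k;

    arma::vec eigval;
    arma::mat eigvec;
    arma::eig_sym(eigval, eigvec, C);   // ascending
    arma::vec nrm = eigvec.col(0);
    const double tot = eigval(0) + eigval(1) + eigval(2);
    curvature(i) = tot > 0 ? std::max(0.0, eigval(0)) / tot : 0.0;

    // orient away from centroid
    const double dot = nrm(0) * (pi(0) - centroid(0)) +
                       nrm(1) * (pi(1) - centroid(1)) +
                       nrm(2) * (pi(2) - centroid(2));
    if (dot < 0) nrm = -nrm;
    const double len = arma::norm(nrm);
    if (len > 0) nrm /= len;
    normals(i, 0) = nrm(0);
    normals(i, 1) = nrm(1);
    normals(i, 2) = nrm(2);
  }

  return List::create(_["normals"] = normals, _["curvature"] = curvature);
}

// Greedy region growing over the vertex adjacency graph.
// Seeds are taken in order of increasing curvature (ties by vertex index).
// A neighbour v of a front vertex u joins the region when the unsigned angle
// between their normals is <= eps_a degrees; v becomes a growth front only
// if curvature(v) <= eps_b. Returns 1-based cluster labels (0 = unassigned,
// which cannot happen: every vertex seeds its own cluster eventually).
// [[Rcpp::export(name = ".cpp_region_growing")]]
IntegerVector cpp_region_growing(const arma::mat& N, const arma::vec& curv,
                                 const IntegerVector& adj_ptr,
                                 const IntegerVector& adj_idx,
                                 double eps_a_deg, double eps_b) {
  const int n = N.n_rows;
  IntegerVector labels(n, 0);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (curv(a) != curv(b)) return curv(a) < curv(b);
    return a < b;
  });

  const double cos_eps = std::cos(eps_a_deg * M_PI / 180.0);
  int next_label = 0;

  for (int s = 0; s < n; ++s) {
    const int seed = order[s];
    if (labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    std::queue<int> fronts;
    fronts.push(seed);
    while (!fronts.empty()) {
      const int u = fronts.front();
      fronts.pop();
      for (int p = adj_ptr[u]; p < adj_ptr[u + 1]; ++p) {
        const int v = adj_idx[p];
        if (labels[v] != 0) continue;
        const double dot = N(u, 0) * N(v, 0) + N(u, 1) * N(v, 1) +
                           N(u, 2) * N(v, 2);
        if (std::fabs(dot) + 1e-12 >= cos_eps) {
          labels[v] = next_label;
          if (curv(v) <= eps_b) fronts.push(v);
        }
      }
    }
  }
  return labels;
}
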