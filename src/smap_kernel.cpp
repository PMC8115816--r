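// S-Map inner loop: per query, exponentially distance-weighted linear fit
// over admissible library points, solved by SVD with a relative singular
// value cutoff (rcond), shared weights across the K output coefficients.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List smap_kernel(const arma::mat& lib_pts, const arma::mat& lib_tgts,
                       const arma::ivec& lib_time, const arma::mat& q_pts,
                       const arma::ivec& q_time, double theta, double rcond,
                       int exclusion_steps, bool same_source,
                       bool intercept, bool save_coef) {
  const uword n_lib = lib_pts.n_rows;
  const uword n_q = q_pts.n_rows;
  const uword D = lib_pts.n_cols;
  const uword K = lib_tgts.n_cols;
  const uword n_coef = D + (intercept ? 1 : 0);

  mat pred(n_q, K, fill::zeros);
  cube coefs;
  if (save_coef) coefs.set_size(n_coef, K, n_q);

  for (uword i = 0; i < n_q; ++i) {
    // admissible library points (temporal exclusion within the same source)
    uvec adm;
    if (same_source) {
      std::vector<uword> keep;
      keep.reserve(n_lib);
      for (uword j = 0; j < n_lib; ++j) {
        if (std::abs(lib_time[j] - q_time[i]) > exclusion_steps)
          keep.push_back(j);
      }
      adm = uvec(keep);
    } else {
      adm = regspace<uvec>(0, n_lib - 1);
    }
    if (adm.n_elem < n_coef + 1) {
      Rcpp::stop("query at sample %d: only %d admissible library points for %d fit coefficients",
                 (int)q_time[i], (int)adm.n_elem, (int)n_coef);
    }

    const rowvec x = q_pts.row(i);
    vec dist(adm.n_elem);
    for (uword j = 0; j < adm.n_elem; ++j) {
      dist[j] = norm(lib_pts.row(adm[j]) - x, 2);
    }
    double dbar = mean(dist);
    vec w(adm.n_elem, fill::ones);
    if (theta > 0.0 && dbar > 0.0) w = exp(-theta * dist / dbar);
    vec sw = sqrt(w);

    mat A(adm.n_elem, n_coef);
    uword off = 0;
    if (intercept) { A.col(0) = sw; off = 1; }
    for (uword c = 0; c < D; ++c) {
      vec col(adm.n_elem);
      for (uword j = 0; j < adm.n_elem; ++j) col[j] = lib_pts(adm[j], c);
      A.col(off + c) = sw % col;
    }
    mat B(adm.n_elem, K);
    for (uword k = 0; k < K; ++k) {
      vec col(adm.n_elem);
      for (uword j = 0; j < adm.n_elem; ++j) col[j] = lib_tgts(adm[j], k);
      B.col(k) = sw % col;
    }

    mat U, V;
    vec s;
    if (!svd_econ(U, s, V, A))
      Rcpp::stop("SVD failed for query at sample %d", (int)q_time[i]);
    vec sinv(s.n_elem, fill::zeros);
    const double tol = rcond * s.max();
    for (uword j = 0; j < s.n_elem; ++j)
      if (s[j] > tol) sinv[j] = 1.0 / s[j];
    mat coef = V * diagmat(sinv) * U.t() * B;  // n_coef x K

    rowvec xfull(n_coef);
    if (intercept) { xfull[0] = 1.0; xfull.subvec(1, n_coef - 1) = x; }
    else xfull = x;
    pred.row(i) = xfull * coef;
    if (save_coef) coefs.slice(i) = coef;
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("pred") = pred);
  if (save_coef) out["coefficients"] = coefs;
  return out;
}
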