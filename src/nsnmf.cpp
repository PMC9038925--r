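// Multiplicative-update core for non-smooth NMF under the KL divergence.
// V (p x n) is approximated by W * S * H with the smoothing matrix
// S = (1 - theta) I + (theta/k) 11'.  The W step treats SH as the fixed
// coefficient matrix and the H step treats WS as the fixed basis, so each
// half-step is a standard KL-NMF update and the objective D(V || WSH) is
// non-increasing.  All randomness (initialisation) happens on the R side.
//
// The loop preallocates every work matrix (consensus clustering calls this
// thousands of times, so allocation would otherwise dominate) and is
// templated over the element type: consensus runs, which only consume the
// per-sample argmax pattern of H, can use single precision for speed,
// while the default double path supports tight objective tolerances.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

template <typename eT>
static inline void floor_inplace(Mat<eT>& X, eT eps) {
  eT* ptr = X.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i)
    if (ptr[i] < eps) ptr[i] = eps;
}

template <typename eT>
static Rcpp::List nsnmf_impl(const Mat<eT>& V, Mat<eT> W, Mat<eT> H,
                             double theta_, int max_iter, double tol,
                             int check_every, int label_every, double eps_,
                             int stable_stop) {
  const eT theta = eT(theta_);
  const eT eps = eT(eps_);
  const uword p = V.n_rows, n = V.n_cols, k = W.n_cols;
  const eT kinv = theta / eT(k);
  const double v_sum = accu(conv_to<mat>::from(V));
  double vlogv_sum = 0.0;
  for (uword i = 0; i < V.n_elem; ++i)
    if (V[i] > 0) vlogv_sum += double(V[i]) * std::log(double(V[i]));

  Mat<eT> SH(k, n), WS(p, k), Q(p, n), numW(p, k), numH(k, n);

  std::vector<double> obj_trace;
  std::vector<int> obj_iter;
  double prev_obj = datum::inf;
  bool converged = false;
  int iter_done = max_iter;
  // early stop once the per-sample argmax factor (what consensus
  // clustering consumes) has been unchanged for stable_stop checks
  urowvec prev_lab;
  int stable_count = 0;

  for (int it = 1; it <= max_iter; ++it) {
    // SH = S * H  (row-mixing of H)
    SH = H;
    SH *= (eT(1) - theta);
    SH.each_row() += kinv * sum(H, 0);

    // W <- W .* (Q * SH') / rowSums(SH)'
    Q = W * SH;              // Q holds WH
    floor_inplace(Q, eps);
    Q = V / Q;
    Row<eT> denW = sum(SH, 1).t();
    floor_inplace(denW, eps);
    numW = Q * SH.t();
    W %= numW;
    W.each_row() /= denW;
    floor_inplace(W, eps);

    // WS = W * S  (column-mixing of W)
    WS = W;
    WS *= (eT(1) - theta);
    WS.each_col() += kinv * sum(W, 1);

    // H <- H .* (WS' * Q2) / colSums(WS)
    Q = WS * H;
    floor_inplace(Q, eps);
    Q = V / Q;
    Col<eT> denH = sum(WS, 0).t();
    floor_inplace(denH, eps);
    numH = WS.t() * Q;
    H %= numH;
    H.each_col() /= denH;
    floor_inplace(H, eps);

    bool last = (it == max_iter);
    if (it % check_every == 0 || last) {
      WS = W;
      WS *= (eT(1) - theta);
      WS.each_col() += kinv * sum(W, 1);
      Q = WS * H;            // Q holds WSH
      floor_inplace(Q, eps);
      // D(V||X) = sum_{v>0} v log(v/x) - v + x
      double obj = vlogv_sum - accu(conv_to<mat>::from(V % log(Q))) -
                   v_sum + accu(conv_to<mat>::from(Q));
      obj_trace.push_back(obj);
      obj_iter.push_back(it);
      double denom = std::max(std::abs(prev_obj), eps_);
      if (std::isfinite(prev_obj) &&
          std::abs(prev_obj - obj) / denom < tol) {
        converged = true;
        iter_done = it;
        break;
      }
      prev_obj = obj;
      iter_done = it;
    }
    if (stable_stop > 0 && (it % label_every == 0 || last)) {
      urowvec lab = index_max(H, 0);
      if (prev_lab.n_elem == lab.n_elem && all(vectorise(lab == prev_lab))) {
        if (++stable_count >= stable_stop) {
          converged = true;
          iter_done = it;
          break;
        }
      } else {
        stable_count = 0;
      }
      prev_lab = lab;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(W),
      Rcpp::Named("H") = conv_to<mat>::from(H),
      Rcpp::Named("objective") = obj_trace,
      Rcpp::Named("objective_iter") = obj_iter,
      Rcpp::Named("iterations") = iter_done,
      Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List nsnmf_core(const arma::mat& V, const arma::mat& W,
                      const arma::mat& H, double theta, int max_iter,
                      double tol, int check_every, int label_every,
                      double eps, int stable_stop, bool single_precision) {
  if (single_precision) {
    fmat Vf = conv_to<fmat>::from(V);
    fmat Wf = conv_to<fmat>::from(W);
    fmat Hf = conv_to<fmat>::from(H);
    // epsilon floors below float resolution are clamped to float-safe
    double epsf = std::max(eps, 1e-30);
    return nsnmf_impl<float>(Vf, Wf, Hf, theta, max_iter, tol, check_every,
                             label_every, epsf, stable_stop);
  }
  return nsnmf_impl<double>(V, W, H, theta, max_iter, tol, check_every,
                            label_every, eps, stable_stop);
}
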