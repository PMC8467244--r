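// Restarted Lloyd-type k-means over gene profiles.
//
// Correlation mode works in the space of row-standardized profiles
// (centered, unit L2 norm), where 1 - Pearson(x, c) is half the squared
// Euclidean distance between standardized vectors; the centroid update
// (normalized mean of standardized member rows) is the spherical-k-means
// update, so the objective is non-increasing within a run. Euclidean mode
// is classic Lloyd on the raw rows with a squared-distance objective.
//
// Initial assignments are supplied by the caller (one column per restart)
// so all randomness stays under R's RNG. Empty clusters are reseeded with
// the gene farthest from its current centroid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat standardize_rows(const arma::mat& X) {
  arma::mat S = X.each_col() - arma::mean(X, 1);
  arma::vec nrm = arma::sqrt(arma::sum(arma::square(S), 1));
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    if (nrm(i) > 1e-12) S.row(i) /= nrm(i);
  }
  return S;
}

// [[Rcpp::export(name = ".kmeans_profiles_cpp")]]
List kmeans_profiles_cpp(const arma::mat& X, const arma::imat& inits,
                         int k, int max_iter, bool correlation) {
  const arma::uword m = X.n_rows;
  const int runs = inits.n_cols;

  arma::mat W = correlation ? standardize_rows(X) : X;
  arma::vec row_ss = arma::sum(arma::square(W), 1);

  double best_obj = arma::datum::inf;
  arma::ivec best_assign;
  arma::vec best_trace;
  int best_run = -1, best_iters = 0, best_reseeds = 0;
  arma::vec run_obj(runs);

  for (int r = 0; r < runs; ++r) {
    arma::ivec assign = inits.col(r);  // 1-based
    std::vector<double> trace;
    int reseeds = 0;
    double obj = arma::datum::inf;
    int iter = 0;

    for (iter = 1; iter <= max_iter; ++iter) {
      // centroid update in working space
      arma::mat C(k, W.n_cols, arma::fill::zeros);
      arma::vec cnt(k, arma::fill::zeros);
      for (arma::uword g = 0; g < m; ++g) {
        C.row(assign(g) - 1) += W.row(g);
        cnt(assign(g) - 1) += 1.0;
      }
      arma::uvec dead(k, arma::fill::zeros);
      for (int j = 0; j < k; ++j) {
        if (cnt(j) > 0) {
          C.row(j) /= cnt(j);
          if (correlation) {
            double n2 = arma::norm(C.row(j), 2);
            if (n2 > 1e-12) C.row(j) /= n2; else dead(j) = 1;
          }
        } else {
          dead(j) = 1;
        }
      }

      // distances: D(g, j) = 1 - <w_g, c_j>  (correlation mode, unit rows)
      //            D(g, j) = ||w_g - c_j||^2 (euclidean mode)
      arma::mat D;
      if (correlation) {
        D = 1.0 - W * C.t();
      } else {
        arma::vec c_ss = arma::sum(arma::square(C), 1);
        D = -2.0 * (W * C.t());
        D.each_col() += row_ss;
        D.each_row() += c_ss.t();
        D.transform([](double v) { return v < 0 ? 0.0 : v; });
      }
      const double big = correlation ? 4.0 : arma::datum::inf;
      for (int j = 0; j < k; ++j) if (dead(j)) D.col(j).fill(big);

      // reseed empty/degenerate clusters with the farthest-from-centroid gene
      int reseeds_now = 0;
      for (int j = 0; j < k; ++j) {
        if (!dead(j)) continue;
        double worst = -1.0; arma::uword gw = 0;
        for (arma::uword g = 0; g < m; ++g) {
          double d = D(g, assign(g) - 1);
          if (!std::isfinite(d)) d = big;
          if (d > worst && cnt(assign(g) - 1) > 1) { worst = d; gw = g; }
        }
        ++reseeds;
        ++reseeds_now;
        cnt(assign(gw) - 1) -= 1.0;
        cnt(j) = 1.0;
        assign(gw) = j + 1;
        arma::rowvec cj = W.row(gw);
        if (correlation) D.col(j) = 1.0 - W * cj.t();
        else {
          D.col(j) = row_ss - 2.0 * (W * cj.t()) +
                     arma::as_scalar(arma::dot(cj, cj));
        }
      }

      // assignment step; ties go to the lowest cluster id
      arma::ivec new_assign(m);
      double new_obj = 0.0;
      for (arma::uword g = 0; g < m; ++g) {
        int bestj = 0;
        double bestd = D(g, 0);
        for (int j = 1; j < k; ++j) {
          if (D(g, j) < bestd) { bestd = D(g, j); bestj = j; }
        }
        new_assign(g) = bestj + 1;
        new_obj += bestd;
      }
      trace.push_back(new_obj);
      // a reseed leaves donor centroids stale: never declare convergence
      // in the same iteration
      bool stable = (reseeds_now == 0) && arma::all(new_assign == assign);
      assign = new_assign;
      obj = new_obj;
      if (stable) break;
    }

    run_obj(r) = obj;
    if (obj < best_obj) {
      best_obj = obj;
      best_assign = assign;
      best_trace = arma::vec(trace);
      best_run = r + 1;
      best_iters = (int)trace.size();
      best_reseeds = reseeds;
    }
  }

  return List::create(
    _["assignment"] = IntegerVector(best_assign.begin(), best_assign.end()),
    _["objective"] = best_obj,
    _["trace"] = NumericVector(best_trace.begin(), best_trace.end()),
    _["run_objectives"] = NumericVector(run_obj.begin(), run_obj.end()),
    _["best_run"] = best_run,
    _["iterations"] = best_iters,
    _["reseeds"] = best_reseeds);
}
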