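// Forward pass of the MARS fitting algorithm.
//
// Greedy two-at-a-time addition of reflected hinge pairs
//   h+ = parent * max(0, x_v - t),  h- = parent * max(0, t - x_v)
// choosing, at every step, the (parent, variable, knot) triple whose pair
// maximises the residual sum-of-squares reduction.  Because the running
// residual r is orthogonal to the span of the current basis B, the reduction
// for a candidate pair reduces to a 2x2 solve against the components of the
// pair orthogonal to B, which keeps the scan at one matrix product per
// (parent, variable) block.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec safe_solve(const arma::mat& G, const arma::vec& b) {
  arma::vec out;
  if (!arma::solve(out, G, b, arma::solve_opts::no_approx)) {
    out = arma::pinv(G) * b;
  }
  return out;
}

static arma::mat safe_solve_mat(const arma::mat& G, const arma::mat& Bm) {
  arma::mat out;
  if (!arma::solve(out, G, Bm, arma::solve_opts::no_approx)) {
    out = arma::pinv(G) * Bm;
  }
  return out;
}

static arma::mat ridged(const arma::mat& G, double ridge_rel) {
  if (ridge_rel <= 0) return G;
  arma::mat Gd = G;                 // scale-invariant shrinkage: each
  Gd.diag() += ridge_rel * G.diag();  // coefficient relative to its column
  return Gd;
}

// [[Rcpp::export]]
List mars_forward_cpp(const arma::mat& X,
                      const arma::vec& y,
                      const List& knots,      // per-variable candidate knots
                      int max_terms,          // max non-intercept basis columns
                      int degree,             // max hinge factors per term
                      double thresh,          // stop when dRSS/SST < thresh
                      double ridge_rel,       // relative ridge on the Gram
                      double ortho_tol) {     // min orthogonal fraction of
                                              // a candidate column
  const int n = X.n_rows;
  const int p = X.n_cols;

  arma::mat B(n, 1, arma::fill::ones);        // basis matrix, col 0 = intercept
  std::vector<int> term_parent(1, -1);        // per column: parent column index
  std::vector<int> term_var(1, -1);
  std::vector<double> term_knot(1, NA_REAL);
  std::vector<int> term_dir(1, 0);            // +1 / -1 hinge direction
  std::vector<int> term_nfac(1, 0);           // factor count of each column

  std::vector<arma::vec> cand(p);
  for (int v = 0; v < p; ++v) cand[v] = as<arma::vec>(knots[v]);

  arma::mat G = B.t() * B;
  arma::mat Gr = ridged(G, ridge_rel);
  arma::vec g = B.t() * y;
  arma::vec coef = safe_solve(Gr, g);
  arma::vec r = y - B * coef;
  double rss = arma::dot(r, r);
  const double ybar = arma::mean(y);
  double sst = arma::dot(y - ybar, y - ybar);
  if (sst <= 0) sst = 1.0;

  std::vector<double> rss_path;
  rss_path.push_back(rss);

  while ((int)B.n_cols - 1 < max_terms - 1 && rss > 1e-13 * sst) {
    double best_red = 0.0;
    int best_parent = -1, best_var = -1, best_dir_mask = 0;
    double best_knot = 0.0;
    arma::vec best_h1, best_h2;

    const arma::mat Bt = B.t();
    for (int m = 0; m < (int)B.n_cols; ++m) {
      if (term_nfac[m] >= degree) continue;
      const arma::vec bcol = B.col(m);
      // variables already present in this basis function (walk up parents)
      std::vector<bool> used(p, false);
      for (int q = m; q > 0; q = term_parent[q]) used[term_var[q]] = true;

      for (int v = 0; v < p; ++v) {
        if (used[v]) continue;
        const arma::vec& tv = cand[v];
        const int K = tv.n_elem;
        if (K == 0) continue;
        const arma::vec xv = X.col(v);

        arma::mat H1(n, K), H2(n, K);
        for (int k = 0; k < K; ++k) {
          arma::vec d = xv - tv[k];
          H1.col(k) = bcol % arma::clamp(d, 0.0, arma::datum::inf);
          H2.col(k) = bcol % arma::clamp(-d, 0.0, arma::datum::inf);
        }
        const arma::mat A1 = Bt * H1;
        const arma::mat A2 = Bt * H2;
        const arma::mat W1 = safe_solve_mat(Gr, A1);
        const arma::mat W2 = safe_solve_mat(Gr, A2);

        for (int k = 0; k < K; ++k) {
          const double n1 = arma::dot(H1.col(k), H1.col(k));
          const double n2 = arma::dot(H2.col(k), H2.col(k));
          double m11 = n1 - arma::dot(A1.col(k), W1.col(k));
          double m22 = n2 - arma::dot(A2.col(k), W2.col(k));
          double m12 = arma::dot(H1.col(k), H2.col(k)) -
                       arma::dot(A1.col(k), W2.col(k));
          const double z1 = arma::dot(H1.col(k), r);
          const double z2 = arma::dot(H2.col(k), r);
          // a candidate almost entirely inside the current span carries
          // no real information (its tiny orthogonal part is dominated by
          // measurement noise and yields unstable coefficients)
          const bool ok1 = (n1 > 0) && (m11 > ortho_tol * n1);
          const bool ok2 = (n2 > 0) && (m22 > ortho_tol * n2);

          double red = 0.0;
          int dir_mask = 0;  // bit 1: keep h+, bit 2: keep h-
          if (ok1 && ok2) {
            const double det = m11 * m22 - m12 * m12;
            if (det > 1e-12 * m11 * m22) {
              red = (m22 * z1 * z1 - 2.0 * m12 * z1 * z2 + m11 * z2 * z2) / det;
              dir_mask = 3;
            }
          }
          if (dir_mask == 0) {  // pair collinear/degenerate: best single hinge
            const double r1 = ok1 ? z1 * z1 / m11 : 0.0;
            const double r2 = ok2 ? z2 * z2 / m22 : 0.0;
            if (r1 >= r2 && ok1) { red = r1; dir_mask = 1; }
            else if (ok2)        { red = r2; dir_mask = 2; }
          }
          if (dir_mask == 0) continue;

          // strict improvement, ties broken by lower variable then lower knot
          const double tol = 1e-10 * (best_red > 0 ? best_red : 1.0);
          bool better = red > best_red + tol;
          bool tie = std::abs(red - best_red) <= tol && best_parent >= 0;
          if (tie) {
            if (v < best_var || (v == best_var && tv[k] < best_knot)) {
              better = true;
            }
          }
          if (better) {
            best_red = red;
            best_parent = m; best_var = v; best_knot = tv[k];
            best_dir_mask = dir_mask;
            best_h1 = H1.col(k); best_h2 = H2.col(k);
          }
        }
      }
    }

    if (best_parent < 0 || best_red < thresh * sst) break;

    // append the selected column(s)
    std::vector<arma::vec> newcols;
    std::vector<int> newdirs;
    if (best_dir_mask & 1) { newcols.push_back(best_h1); newdirs.push_back(1); }
    if (best_dir_mask & 2) { newcols.push_back(best_h2); newdirs.push_back(-1); }
    // respect max_terms: drop the reflected partner if it would overflow
    while ((int)B.n_cols - 1 + (int)newcols.size() > max_terms - 1 &&
           newcols.size() > 1) {
      newcols.pop_back();
      newdirs.pop_back();
    }
    for (size_t j = 0; j < newcols.size(); ++j) {
      B.insert_cols(B.n_cols, newcols[j]);
      term_parent.push_back(best_parent);
      term_var.push_back(best_var);
      term_knot.push_back(best_knot);
      term_dir.push_back(newdirs[j]);
      term_nfac.push_back(term_nfac[best_parent] + 1);
    }

    G = B.t() * B;
    Gr = ridged(G, ridge_rel);
    g = B.t() * y;
    coef = safe_solve(Gr, g);
    r = y - B * coef;
    rss = arma::dot(r, r);
    rss_path.push_back(rss);
  }

  return List::create(
    _["B"] = B,
    _["parent"] = IntegerVector(term_parent.begin(), term_parent.end()),
    _["var"] = IntegerVector(term_var.begin(), term_var.end()),
    _["knot"] = NumericVector(term_knot.begin(), term_knot.end()),
    _["dir"] = IntegerVector(term_dir.begin(), term_dir.end()),
    _["coef"] = NumericVector(coef.begin(), coef.end()),
    _["rss"] = rss,
    _["rss_path"] = NumericVector(rss_path.begin(), rss_path.end()));
}
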