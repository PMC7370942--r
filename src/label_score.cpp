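// Exhaustive / sampled RANSAC scoring for fiducial labeling.
//
// A hypothesis assigns an ordered triple of model labels to a triple of
// observed cluster centroids, fits the closed-form three-point similarity
// transform (rotation + uniform scale + translation, Umeyama), maps the
// remaining model fiducials through it, and scores the hypothesis by the
// total distance under the optimal one-to-one assignment of remaining
// model points to remaining centroids (exact branch-and-bound, <= 6
// remaining). The minimum-score hypothesis wins; ties go to the first
// hypothesis in lexicographic label-triple order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Similarity {
  arma::mat33 R;
  double s;
  arma::vec3 t;
  bool ok;
};

Similarity fit_similarity3(const arma::mat &X, const arma::mat &Y) {
  Similarity out;
  out.ok = false;
  arma::rowvec mx = arma::mean(X, 0), my = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - mx, Yc = Y.each_row() - my;
  double varx = arma::accu(Xc % Xc) / X.n_rows;
  if (varx < 1e-9) return out;
  arma::mat C = (Yc.t() * Xc) / X.n_rows;
  arma::mat U, V;
  arma::vec d;
  if (!arma::svd(U, d, V, C)) return out;
  double sgn = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::vec3 dd = {1.0, 1.0, sgn};
  out.R = U * arma::diagmat(dd) * V.t();
  out.s = arma::dot(d, dd) / varx;
  if (!std::isfinite(out.s) || out.s < 1e-9) return out;
  out.t = my.t() - out.s * (out.R * mx.t());
  out.ok = true;
  return out;
}

bool collinear(const arma::mat &P) {
  arma::vec3 u = P.row(1).t() - P.row(0).t();
  arma::vec3 v = P.row(2).t() - P.row(0).t();
  double denom = arma::norm(u) * arma::norm(v);
  if (denom < 1e-12) return true;
  return arma::norm(arma::cross(u, v)) / denom < 1e-9;
}

// exact min-cost injective assignment over the smaller side of D
// (rows = remaining centroids, cols = remaining model points); every
// element of the smaller side must be matched. assignment[r] = matched
// column of row r (or -1).
double assign_cost(const arma::mat &D, double bound,
                   std::vector<int> &best_assign) {
  const int q = D.n_rows, m = D.n_cols;
  best_assign.assign(q, -1);
  std::vector<int> cur(q, -1);
  double best = bound;
  if (q <= m) {
    std::vector<bool> used(m, false);
    std::function<void(int, double)> rec = [&](int r, double acc) {
      if (acc >= best) return;
      if (r == q) {
        best = acc;
        best_assign = cur;
        return;
      }
      for (int c = 0; c < m; ++c) {
        if (used[c]) continue;
        used[c] = true;
        cur[r] = c;
        rec(r + 1, acc + D(r, c));
        used[c] = false;
      }
      cur[r] = -1;
    };
    rec(0, 0.0);
  } else {
    // more centroids than model points: every model point must be matched
    std::vector<bool> used(q, false);
    std::vector<int> colpick(m, -1);
    std::function<void(int, double)> rec = [&](int c, double acc) {
      if (acc >= best) return;
      if (c == m) {
        best = acc;
        best_assign.assign(q, -1);
        for (int k = 0; k < m; ++k) best_assign[colpick[k]] = k;
        return;
      }
      for (int r = 0; r < q; ++r) {
        if (used[r]) continue;
        used[r] = true;
        colpick[c] = r;
        rec(c + 1, acc + D(r, c));
        used[r] = false;
      }
    };
    rec(0, 0.0);
  }
  return best;
}

} // namespace

// model: 9 x 3 model fiducials; centroids: n x 3 observed cluster
// centroids; triples: m x 3 one-based centroid index triples to try.
// [[Rcpp::export(name = ".ransac_label_score")]]
List ransac_label_score(const arma::mat &model, const arma::mat &centroids,
                        const arma::imat &triples) {
  const int n = centroids.n_rows;
  const int nl = model.n_rows; // 9
  double best_cost = std::numeric_limits<double>::infinity();
  bool found = false;
  arma::ivec3 best_lab, best_cen;
  Similarity best_fit;
  std::vector<int> best_rest_assign; // per remaining centroid: model index
  std::vector<int> best_rc, best_rm;

  arma::mat M3(3, 3), C3(3, 3);
  std::vector<int> rm, rc;
  std::vector<int> assign;

  // ordered label triples in lexicographic order (tie-break rule)
  for (int a = 0; a < nl; ++a)
    for (int b = 0; b < nl; ++b) {
      if (b == a) continue;
      for (int c = 0; c < nl; ++c) {
        if (c == a || c == b) continue;
        M3.row(0) = model.row(a);
        M3.row(1) = model.row(b);
        M3.row(2) = model.row(c);
        if (collinear(M3)) continue;
        rm.clear();
        for (int k = 0; k < nl; ++k)
          if (k != a && k != b && k != c) rm.push_back(k);

        for (arma::uword ti = 0; ti < triples.n_rows; ++ti) {
          int i = triples(ti, 0) - 1, j = triples(ti, 1) - 1,
              k = triples(ti, 2) - 1;
          C3.row(0) = centroids.row(i);
          C3.row(1) = centroids.row(j);
          C3.row(2) = centroids.row(k);
          if (collinear(C3)) continue;
          Similarity f = fit_similarity3(M3, C3);
          if (!f.ok) continue;

          rc.clear();
          for (int r = 0; r < n; ++r)
            if (r != i && r != j && r != k) rc.push_back(r);

          arma::mat P(rm.size(), 3);
          for (size_t u = 0; u < rm.size(); ++u)
            P.row(u) = (f.s * (f.R * model.row(rm[u]).t()) + f.t).t();
          arma::mat D(rc.size(), rm.size());
          for (size_t r = 0; r < rc.size(); ++r)
            for (size_t m2 = 0; m2 < rm.size(); ++m2)
              D(r, m2) = arma::norm(centroids.row(rc[r]).t() - P.row(m2).t());

          double cost = assign_cost(D, best_cost, assign);
          if (cost < best_cost) {
            best_cost = cost;
            found = true;
            best_lab = {a + 1, b + 1, c + 1};
            best_cen = {i + 1, j + 1, k + 1};
            best_fit = f;
            best_rest_assign = assign;
            best_rc = rc;
            best_rm = rm;
          }
        }
      }
    }

  if (!found)
    return List::create(Named("ok") = false);

  // full labeling: per centroid, one-based model label index (0 = none)
  IntegerVector labels(n, 0);
  for (int u = 0; u < 3; ++u) labels[best_cen[u] - 1] = best_lab[u];
  for (size_t r = 0; r < best_rc.size(); ++r)
    if (best_rest_assign[r] >= 0)
      labels[best_rc[r]] = best_rm[best_rest_assign[r]] + 1;

  return List::create(
      Named("ok") = true, Named("cost") = best_cost,
      Named("labels") = labels,
      Named("rotation") = wrap(arma::mat(best_fit.R)),
      Named("scale") = best_fit.s,
      Named("translation") = wrap(arma::vec(best_fit.t)));
}
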