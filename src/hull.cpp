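#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Hyperplane through the d points in rows(V): unit normal + offset.
// Normal taken as the right-singular vector of (V - v0) with the smallest
// singular value, so near-degenerate (sliver) facets still get a plane.
static void facet_plane(const arma::mat& pts, const arma::uvec& verts,
                        arma::vec& normal, double& offset) {
  const arma::uword d = pts.n_cols;
  arma::mat B(verts.n_elem - 1, d);
  for (arma::uword i = 1; i < verts.n_elem; ++i)
    B.row(i - 1) = pts.row(verts(i)) - pts.row(verts(0));
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, B);
  normal = V.col(d - 1);
  offset = arma::dot(normal, pts.row(verts(0)).t());
}

struct Facet {
  std::vector<arma::uword> verts;  // d vertex indices, sorted
  arma::vec normal;
  double offset;
  bool alive;
};

// Incremental (beneath-beyond) convex hull of n points in d dimensions.
// Returns hull volume, vertex indices (1-based) and a degeneracy flag.
// Caller must pass de-duplicated points. Facets are kept simplicial;
// points within eps of a facet plane are treated as non-visible.
// [[Rcpp::export]]
List convhull_cpp(const arma::mat& pts, double tol = 1e-10) {
  const arma::uword n = pts.n_rows, d = pts.n_cols;
  double scale = 1.0;
  if (n > 0) scale += arma::abs(pts).max();
  const double eps = tol * scale;

  if (d == 1) {
    // interval length
    if (n < 2 || pts.max() - pts.min() <= eps)
      return List::create(_["volume"] = NA_REAL, _["vertices"] = IntegerVector(0),
                          _["degenerate"] = true);
    IntegerVector v = IntegerVector::create(
        (int)pts.col(0).index_min() + 1, (int)pts.col(0).index_max() + 1);
    return List::create(_["volume"] = pts.max() - pts.min(), _["vertices"] = v,
                        _["degenerate"] = false);
  }

  if (n < d + 1)
    return List::create(_["volume"] = NA_REAL, _["vertices"] = IntegerVector(0),
                        _["degenerate"] = true);

  // --- initial simplex: greedy affinely independent set -------------------
  std::vector<arma::uword> simp;
  simp.push_back(pts.col(0).index_min());
  {
    // farthest point from the first
    arma::vec dist2(n);
    for (arma::uword i = 0; i < n; ++i)
      dist2(i) = arma::accu(arma::square(pts.row(i) - pts.row(simp[0])));
    arma::uword far = dist2.index_max();
    if (std::sqrt(dist2(far)) <= eps)
      return List::create(_["volume"] = NA_REAL, _["vertices"] = IntegerVector(0),
                          _["degenerate"] = true);
    simp.push_back(far);
  }
  arma::mat Q(d, 0);  // orthonormal basis of the affine span
  {
    arma::vec e = (pts.row(simp[1]) - pts.row(simp[0])).t();
    Q = arma::normalise(e);
  }
  while (simp.size() < d + 1) {
    double best = -1.0;
    arma::uword bi = 0;
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec v = (pts.row(i) - pts.row(simp[0])).t();
      arma::vec r = v - Q * (Q.t() * v);
      double rn = arma::norm(r);
      if (rn > best) { best = rn; bi = i; }
    }
    if (best <= eps)  // points span < d dimensions
      return List::create(_["volume"] = NA_REAL, _["vertices"] = IntegerVector(0),
                          _["degenerate"] = true);
    simp.push_back(bi);
    arma::vec v = (pts.row(bi) - pts.row(simp[0])).t();
    arma::vec r = v - Q * (Q.t() * v);
    Q = arma::join_rows(Q, arma::normalise(r));
  }

  // interior reference point: centroid of the initial simplex
  arma::vec c0 = arma::zeros(d);
  for (arma::uword k = 0; k <= d; ++k) c0 += pts.row(simp[k]).t();
  c0 /= (double)(d + 1);

  std::vector<Facet> facets;
  auto add_facet = [&](std::vector<arma::uword> verts) {
    std::sort(verts.begin(), verts.end());
    Facet f;
    f.verts = verts;
    arma::uvec uv(verts.size());
    for (size_t i = 0; i < verts.size(); ++i) uv(i) = verts[i];
    facet_plane(pts, uv, f.normal, f.offset);
    if (arma::dot(f.normal, c0) > f.offset) {  // orient outward
      f.normal = -f.normal;
      f.offset = -f.offset;
    }
    f.alive = true;
    facets.push_back(std::move(f));
  };

  // d+1 facets of the initial simplex (drop one vertex each)
  for (arma::uword k = 0; k <= d; ++k) {
    std::vector<arma::uword> verts;
    for (arma::uword j = 0; j <= d; ++j)
      if (j != k) verts.push_back(simp[j]);
    add_facet(verts);
  }

  std::vector<bool> used(n, false);
  for (arma::uword k = 0; k <= d; ++k) used[simp[k]] = true;

  // --- insert remaining points -------------------------------------------
  for (arma::uword p = 0; p < n; ++p) {
    if (used[p]) continue;
    arma::vec xp = pts.row(p).t();
    std::vector<size_t> visible;
    for (size_t f = 0; f < facets.size(); ++f)
      if (facets[f].alive &&
          arma::dot(facets[f].normal, xp) - facets[f].offset > eps)
        visible.push_back(f);
    if (visible.empty()) continue;  // inside (or on) current hull

    // horizon ridges: (d-1)-subsets appearing in exactly one visible facet
    std::map<std::vector<arma::uword>, int> ridge_count;
    for (size_t vi : visible) {
      const std::vector<arma::uword>& fv = facets[vi].verts;
      for (arma::uword drop = 0; drop < fv.size(); ++drop) {
        std::vector<arma::uword> ridge;
        for (arma::uword j = 0; j < fv.size(); ++j)
          if (j != drop) ridge.push_back(fv[j]);
        ridge_count[ridge]++;
      }
    }
    for (size_t vi : visible) facets[vi].alive = false;
    for (auto& rc : ridge_count) {
      if (rc.second != 1) continue;
      std::vector<arma::uword> verts = rc.first;
      verts.push_back(p);
      add_facet(verts);
    }
  }

  // --- volume: fan of simplices from c0 over alive facets ----------------
  double dfact = 1.0;
  for (arma::uword k = 2; k <= d; ++k) dfact *= (double)k;
  double vol = 0.0;
  std::vector<bool> isvert(n, false);
  arma::mat M(d, d);
  for (const Facet& f : facets) {
    if (!f.alive) continue;
    for (arma::uword i = 0; i < d; ++i)
      M.row(i) = pts.row(f.verts[i]) - c0.t();
    vol += std::abs(arma::det(M)) / dfact;
    for (arma::uword i = 0; i < d; ++i) isvert[f.verts[i]] = true;
  }
  IntegerVector vertices;
  for (arma::uword i = 0; i < n; ++i)
    if (isvert[i]) vertices.push_back((int)i + 1);
  return List::create(_["volume"] = vol, _["vertices"] = vertices,
                      _["degenerate"] = false);
}

// Prim's minimum spanning tree on a dense symmetric distance matrix.
// Deterministic: scans candidate nodes in index order with strict
// improvement, so ties resolve to the smallest (parent, child) index pair.
// Returns (S-1) x 2 matrix of 1-based vertex indices.
// [[Rcpp::export]]
arma::umat prim_mst_cpp(const arma::mat& D) {
  const arma::uword n = D.n_rows;
  arma::umat edges(n > 0 ? n - 1 : 0, 2);
  if (n < 2) return edges;
  std::vector<bool> inTree(n, false);
  arma::vec key(n);
  key.fill(arma::datum::inf);
  arma::uvec parent(n, arma::fill::zeros);
  inTree[0] = true;
  for (arma::uword j = 1; j < n; ++j) { key(j) = D(0, j); parent(j) = 0; }
  for (arma::uword e = 0; e < n - 1; ++e) {
    double best = arma::datum::inf;
    arma::uword bj = 0;
    bool found = false;
    for (arma::uword j = 0; j < n; ++j)
      if (!inTree[j] && key(j) < best) { best = key(j); bj = j; found = true; }
    if (!found) break;
    inTree[bj] = true;
    edges(e, 0) = parent(bj) + 1;
    edges(e, 1) = bj + 1;
    for (arma::uword j = 0; j < n; ++j)
      if (!inTree[j] && D(bj, j) < key(j)) { key(j) = D(bj, j); parent(j) = bj; }
  }
  return edges;
}

// Functional evenness (MST-based) for one assemblage.
// D: pairwise distances in the retained ordination space; w: weights
// (any positive scaling; only relative values matter). NA if S < 3 or an
// MST branch joins two zero-weight species.
// [[Rcpp::export]]
double feve_cpp(const arma::mat& D, const arma::vec& w) {
  const arma::uword S = D.n_rows;
  if (S < 3) return NA_REAL;
  arma::umat edges = prim_mst_cpp(D);
  const arma::uword L = edges.n_rows;
  arma::vec EW(L);
  for (arma::uword l = 0; l < L; ++l) {
    arma::uword i = edges(l, 0) - 1, j = edges(l, 1) - 1;
    double denom = w(i) + w(j);
    if (denom <= 0.0) return NA_REAL;
    EW(l) = D(i, j) / denom;
  }
  double tot = arma::accu(EW);
  if (!(tot > 0.0)) return NA_REAL;  // all species at one point
  const double thr = 1.0 / (double)(S - 1);
  double acc = 0.0;
  for (arma::uword l = 0; l < L; ++l) acc += std::min(EW(l) / tot, thr);
  return (acc - thr) / (1.0 - thr);
}
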