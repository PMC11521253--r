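# Independent brute-force oracles. These never call the package's own
# implementation path for the quantity they check.

# FEve: direct Villeger formula with the MST taken from vegan::spantree
oracle_feve <- function(coords, w) {
  S <- nrow(coords)
  if (S < 3) return(NA_real_)
  D <- as.matrix(dist(coords))
  sp <- vegan::spantree(stats::as.dist(D))
  edges <- cbind(2:S, sp$kid)
  EW <- apply(edges, 1, function(e) D[e[1], e[2]] / (w[e[1]] + w[e[2]]))
  PEW <- EW / sum(EW)
  thr <- 1 / (S - 1)
  (sum(pmin(PEW, thr)) - thr) / (1 - thr)
}

# FDiv: direct three-sum formula; hull vertices from 2-D chull or, in
# higher dimension, scipy's qhull via the system python
oracle_fdiv <- function(coords, w) {
  verts <- if (ncol(coords) == 2) grDevices::chull(coords) else
    scipy_hull(coords)$vertices
  G <- colMeans(coords[verts, , drop = FALSE])
  dG <- sqrt(colSums((t(coords) - G)^2))
  dbar <- mean(dG)
  wr <- w / sum(w)
  dd <- sum(wr * (dG - dbar))
  dabs <- sum(wr * abs(dG - dbar))
  (dd + dbar) / (dabs + dbar)
}

# FDis: direct Laliberte & Legendre formula
oracle_fdis <- function(coords, w) {
  wr <- w / sum(w)
  ctr <- colSums(coords * wr)
  sum(wr * sqrt(colSums((t(coords) - ctr)^2)))
}

# 2-D polygon area by the shoelace formula over chull vertices
oracle_area2d <- function(coords) {
  v <- grDevices::chull(coords)
  x <- coords[v, 1]; y <- coords[v, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# d-dimensional hull volume and vertices from scipy.spatial.ConvexHull
scipy_hull <- function(coords) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  utils::write.table(coords, f, row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from scipy.spatial import ConvexHull; ",
    "X = np.loadtxt('", f, "'); h = ConvexHull(X); ",
    "print(repr(h.volume)); print(' '.join(str(v + 1) for v in h.vertices))"
  ))), stdout = TRUE)
  list(volume = as.numeric(out[1]),
       vertices = sort(as.integer(strsplit(out[2], " ")[[1]])))
}

# O(n^3) brute-force 2-D hull membership: a point is a vertex iff some
# line through it and another point keeps all remaining points strictly
# on one side
oracle_hull_vertices_2d <- function(coords) {
  n <- nrow(coords)
  is_vertex <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- coords[j, ] - coords[i, ]
      s <- vapply(seq_len(n)[-c(i, j)], function(k) {
        v <- coords[k, ] - coords[i, ]
        d[1] * v[2] - d[2] * v[1]
      }, numeric(1))
      if (all(s > 1e-12) || all(s < -1e-12)) {
        is_vertex[i] <- TRUE
        break
      }
    }
  }
  which(is_vertex)
}

# classical CA eigenvalues by explicit eigen-decomposition of the
# residual cross-product (independent of the package's SVD route)
oracle_ca_eigenvalues <- function(X) {
  P <- X / sum(X)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - r %o% cm) / sqrt(r %o% cm)
  ev <- eigen(t(S) %*% S, symmetric = TRUE, only.values = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# brute-force functional entity count: O(n^2) pairwise row comparison
oracle_entities <- function(mat) {
  n <- nrow(mat)
  grp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (all(mat[i, ] == mat[j, ])) { grp[i] <- grp[j]; break }
  }
  length(unique(grp))
}
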