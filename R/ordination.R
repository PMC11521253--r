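#' Principal coordinates analysis of a trait distance matrix
#'
#' Classical (Gower) PCoA: eigen-decomposition of the double-centred
#' squared-distance matrix. All eigenvalues are reported (negatives may
#' occur for non-Euclidean distances but their axes are never retained);
#' axes with eigenvalues at or below the tolerance carry no coordinates.
#' Each retained axis is oriented so that its largest-magnitude species
#' coordinate is positive, making outputs reproducible across platforms.
#'
#' @param d A [stats::dist] object or symmetric zero-diagonal matrix.
#' @param tol Relative eigenvalue tolerance: `|lambda| < tol * max|lambda|`
#'   is treated as zero (default `1e-10`).
#' @return A `trait_pcoa` object: list with `species`, `eigenvalues`
#'   (full spectrum, descending), `coordinates` (species x positive-axis
#'   matrix), `trace` and `tol`.
#' @examples
#' pool <- simulate_pool(scenario_config(n_species = 10, seed = 1))
#' ord <- trait_pcoa(trait_distance(code_traits(pool)))
#' head(ord$eigenvalues)
#' @export
trait_pcoa <- function(d, tol = 1e-10) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(D) < 2) stop("need at least two species", call. = FALSE)
  species <- rownames(D)
  if (is.null(species)) species <- paste0("sp", seq_len(nrow(D)))
  B <- .gower_center(D)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  thr <- tol * max(abs(ev), .Machine$double.eps)
  pos <- which(ev > thr)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                    length(pos))
  # sign convention: largest-|coordinate| species positive on each axis
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(species, sprintf("A%d", seq_along(pos)))
  structure(list(species = species, eigenvalues = ev, coordinates = coords,
                 trace = sum(diag(B)), tol = tol),
            class = "trait_pcoa")
}

#' @export
print.trait_pcoa <- function(x, ...) {
  cat("<trait_pcoa> ", length(x$species), " species, ",
      ncol(x$coordinates), " positive axes (trace ",
      signif(x$trace, 4), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trait_pcoa <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "axis",
                        values_to = "coordinate")
}

#' @exportS3Method generics::glance
glance.trait_pcoa <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble::tibble(n_species = length(x$species),
                 n_positive_axes = ncol(x$coordinates),
                 trace = x$trace,
                 min_eigenvalue = min(x$eigenvalues),
                 prop_axis12 = sum(pos[seq_len(min(2, length(pos)))]) /
                   sum(abs(x$eigenvalues)))
}

#' Number of ordination axes to retain
#'
#' The "min" rule: the largest integer \eqn{t} such that \eqn{s \ge 2^t}
#' for \eqn{s} species, i.e. `floor(log2(s))`. When applied, the result
#' is additionally capped at the number of positive eigenvalues.
#'
#' @param n_species Number of species in the pool (>= 2).
#' @return Integer number of axes.
#' @examples
#' retain_axes(103)  # 6
#' @export
retain_axes <- function(n_species) {
  stopifnot(length(n_species) == 1, !is.na(n_species))
  if (n_species < 2) stop("need at least two species", call. = FALSE)
  # guard against floating-point log2 at exact powers of two
  t <- floor(log2(n_species) + 1e-12)
  as.integer(t)
}

#' Quality of the reduced-space representation
#'
#' The fraction of total distance variation captured by the `m` retained
#' axes: sum of the `m` largest positive eigenvalues over the sum of
#' absolute values of all eigenvalues. Equals 1 for Euclidean distances
#' when all positive axes are kept. Reported as `quali.FRic` alongside
#' the FD metrics.
#'
#' @param eigenvalues Full PCoA spectrum.
#' @param m Number of retained axes (>= 1).
#' @return A fraction in \[0, 1\].
#' @export
representation_quality <- function(eigenvalues, m) {
  stopifnot(m >= 1)
  pos <- sort(eigenvalues[eigenvalues > 0], decreasing = TRUE)
  denom <- sum(abs(eigenvalues))
  if (denom == 0) return(1)
  sum(pos[seq_len(min(m, length(pos)))]) / denom
}

#' Convex-hull vertex species in a 2-D trait space
#'
#' Species lying on the convex hull of a two-dimensional ordination
#' scatter, in hull order. These "vertex species" carry the most unusual
#' trait combinations. In the collinear degenerate case the two extreme
#' species are returned.
#'
#' @param coords Species x 2 coordinate matrix with row names, or a data
#'   frame with `species` plus two coordinate columns.
#' @return Character vector of species names in hull order.
#' @export
hull_vertices <- function(coords) {
  if (is.data.frame(coords)) {
    species <- coords$species
    coords <- as.matrix(coords[setdiff(names(coords), "species")])
    rownames(coords) <- species
  }
  stopifnot(ncol(coords) == 2)
  if (nrow(coords) < 3) stop("need at least three species", call. = FALSE)
  species <- rownames(coords)
  if (is.null(species)) species <- paste0("sp", seq_len(nrow(coords)))
  ctr <- sweep(coords, 2, colMeans(coords))
  if (min(svd(ctr)$d) < 1e-12 * max(1, max(abs(ctr)))) {
    # collinear: project on principal direction, return the two extremes
    u <- svd(ctr)$v[, 1]
    proj <- ctr %*% u
    return(species[c(which.min(proj), which.max(proj))])
  }
  species[grDevices::chull(coords)]
}
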