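#' Per-block trait dissimilarity
#'
#' Dissimilarity between species on a single trait block. For a crisp
#' (one-hot) block this is the matching dissimilarity: 0 for the same
#' modality, 1 otherwise. For a fuzzy block it is half the Manhattan
#' distance between affinity profiles, which lies in \[0, 1\] because each
#' profile sums to one. (For one-hot rows the two definitions coincide.)
#'
#' @param block Numeric species x modality matrix for one trait; rows must
#'   sum to 1.
#' @param coding `"crisp"` or `"fuzzy"` (affects only the construction
#'   used; the value is identical for one-hot rows).
#' @return A symmetric species x species matrix of dissimilarities in
#'   \[0, 1\] with zero diagonal.
#' @export
block_dissimilarity <- function(block, coding = c("crisp", "fuzzy")) {
  coding <- match.arg(coding)
  block <- as.matrix(block)
  if (any(abs(rowSums(block) - 1) > 1e-8))
    stop("block rows must sum to 1", call. = FALSE)
  if (coding == "crisp") {
    mod <- max.col(block, ties.method = "first")
    d <- 1 - outer(mod, mod, "==")
    storage.mode(d) <- "double"
  } else {
    d <- as.matrix(dist(block, method = "manhattan")) / 2
  }
  dimnames(d) <- list(rownames(block), rownames(block))
  d
}

#' Mixed Gower-type trait distance
#'
#' Builds the species x species functional distance matrix from a coded
#' trait matrix: the weighted mean over trait blocks of the per-block
#' dissimilarities ([block_dissimilarity()]), optionally followed by a
#' square-root transform (default on) that makes the distance Euclidean-
#' embeddable in most practical cases, which suits the downstream
#' principal coordinates analysis. Default weights give each trait equal
#' influence (1/14 in the reference schema) regardless of how many
#' modalities it has.
#'
#' @param coded A `coded_traits` matrix from [code_traits()].
#' @param block_weights Optional non-negative per-trait weights, either
#'   unnamed in block order or named by trait; normalised internally.
#' @param sqrt_transform Take the square root of the mixed dissimilarity
#'   (default `TRUE`).
#' @return A [stats::dist] object with species labels; entries in \[0, 1\].
#' @examples
#' pool <- simulate_pool(scenario_config(n_species = 8, seed = 1))
#' d <- trait_distance(code_traits(pool))
#' range(as.vector(d))
#' @export
trait_distance <- function(coded, block_weights = NULL,
                           sqrt_transform = TRUE) {
  stopifnot(inherits(coded, "coded_traits"))
  if (nrow(coded) < 2) stop("need at least two species", call. = FALSE)
  b <- attr(coded, "blocks")
  if (is.null(block_weights)) {
    w <- rep(1, nrow(b))
  } else {
    w <- block_weights
    if (!is.null(names(w))) w <- w[b$trait]
    if (length(w) != nrow(b) || anyNA(w))
      stop("block_weights must supply one weight per trait", call. = FALSE)
    if (any(w < 0)) stop("block_weights must be non-negative", call. = FALSE)
  }
  w <- w / sum(w)
  acc <- matrix(0, nrow(coded), nrow(coded))
  for (k in seq_len(nrow(b))) {
    blk <- unclass(coded)[, b$start[k]:b$end[k], drop = FALSE]
    acc <- acc + w[k] * block_dissimilarity(blk, b$coding[k])
  }
  if (sqrt_transform) acc <- sqrt(acc)
  d <- stats::as.dist(acc)
  attr(d, "Labels") <- rownames(coded)
  attr(d, "method") <- if (sqrt_transform) "gower_mixed_sqrt" else
    "gower_mixed"
  d
}

#' Is a distance matrix Euclidean-embeddable?
#'
#' Tests whether the Gower-centred matrix \eqn{-\frac{1}{2} J D^2 J} (J
#' the centring operator) has no eigenvalue below `-tol` times the largest
#' eigenvalue magnitude, i.e. whether the distances can be realised
#' exactly by points in Euclidean space.
#'
#' @param d A [stats::dist] object or symmetric matrix.
#' @param tol Relative negative-eigenvalue tolerance (default `1e-8`).
#' @return A list with `euclidean` (logical) and `min_eigenvalue`.
#' @export
is_euclidean <- function(d, tol = 1e-8) {
  B <- .gower_center(as.matrix(d))
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 0)
  list(euclidean = min(ev) >= -tol * max(scale, .Machine$double.eps),
       min_eigenvalue = min(ev))
}

# -0.5 * J D^2 J with J = I - 11'/n
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

#' Export a distance matrix as square CSV
#'
#' Full-precision square CSV with a species header row and column.
#'
#' @param d A [stats::dist] object or square matrix with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(species = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}
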