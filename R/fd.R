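# --- low-level hull wrapper -------------------------------------------------

#' Convex hull volume and vertices in the retained trait space
#'
#' Volume of the convex hull of a set of species points in m dimensions
#' (quickhull-style incremental construction). Exact duplicate coordinate
#' rows are collapsed first; assemblages with fewer than m + 1 distinct
#' points (or spanning fewer than m dimensions) are degenerate and return
#' `NA` volume with a flag rather than an error.
#'
#' @param coords Numeric species x m coordinate matrix with row names.
#' @return A list: `volume` (`NA` if degenerate), `vertices` (species
#'   names on the hull), `degenerate` (logical).
#' @export
hull_volume <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) < 1) stop("need m >= 1 axes", call. = FALSE)
  species <- rownames(coords)
  if (is.null(species)) species <- paste0("sp", seq_len(nrow(coords)))
  dup <- duplicated(coords)
  u <- coords[!dup, , drop = FALSE]
  res <- convhull_cpp(u, 1e-10)
  verts <- if (length(res$vertices)) species[!dup][res$vertices] else
    character(0)
  list(volume = res$volume, vertices = verts,
       degenerate = isTRUE(res$degenerate))
}

# --- the four metrics -------------------------------------------------------

#' Functional richness (FRic)
#'
#' The amount of trait space occupied by an assemblage: the convex-hull
#' volume of the present species in the m retained ordination axes.
#' Presence-only (weights are not used). Degenerate assemblages (too few
#' functionally distinct species for the dimensionality) return `NA` with
#' a flag.
#'
#' @param coords Species x m coordinate matrix for the *present* species.
#' @return List as in [hull_volume()].
#' @export
functional_richness <- function(coords) hull_volume(coords)

#' Standardise FRic by the global pool
#'
#' Divides an assemblage's raw hull volume by the global pool's volume,
#' constraining FRic to \[0, 1\] with the full pool mapping to exactly 1.
#'
#' @param raw Assemblage hull volume (may be `NA` when degenerate; a
#'   degenerate sub-assemblage occupies zero volume, reported as 0 by
#'   [compute_fd()] with a flag).
#' @param global_raw Hull volume of the full species pool (> 0).
#' @return Standardised FRic in \[0, 1\].
#' @export
standardize_fric <- function(raw, global_raw) {
  if (!is.finite(global_raw) || global_raw <= 0)
    stop("global FRic must be positive", call. = FALSE)
  raw / global_raw
}

#' Functional evenness (FEve)
#'
#' Regularity of species spacing and weighting along the minimum spanning
#' tree of the assemblage in the retained trait space. For each MST
#' branch l joining species i and j, \eqn{EW_l = d(i,j)/(w_i + w_j)};
#' with \eqn{PEW_l = EW_l / \sum EW} and S species,
#' \deqn{FEve = \frac{\sum_l \min(PEW_l, 1/(S-1)) - 1/(S-1)}{1 - 1/(S-1)}.}
#' FEve is 1 when branches are equal in weighted length and decreases as
#' spacing or weighting becomes uneven. MST edge-weight ties are broken
#' deterministically by species index order.
#'
#' @param coords Species x m coordinate matrix for the present species,
#'   or a precomputed distance matrix (square, symmetric).
#' @param weights Non-negative weights (standardised landings), in species
#'   order; only relative values matter.
#' @return FEve in \[0, 1\], or `NA` for fewer than 3 species or when an
#'   MST branch joins two zero-weight species.
#' @export
functional_evenness <- function(coords, weights) {
  coords <- as.matrix(coords)
  D <- if (nrow(coords) == ncol(coords) &&
           isTRUE(all.equal(coords, t(coords), tolerance = 1e-8,
                            check.attributes = FALSE)) &&
           all(diag(coords) == 0)) coords else as.matrix(dist(coords))
  stopifnot(length(weights) == nrow(D), all(weights >= 0))
  feve_cpp(D, as.numeric(weights))
}

#' Functional divergence (FDiv)
#'
#' Weighted deviation of species from the mean distance to the centre of
#' gravity G of the convex-hull vertex species (unweighted centroid of
#' the vertices). With distances \eqn{dG_i} to G, mean \eqn{\bar{dG}},
#' relative weights \eqn{w_i}, \eqn{\Delta d = \sum w_i (dG_i - \bar{dG})}
#' and \eqn{\Delta|d| = \sum w_i |dG_i - \bar{dG}|}:
#' \deqn{FDiv = \frac{\Delta d + \bar{dG}}{\Delta|d| + \bar{dG}}.}
#' High values mean the heavily landed species sit at extreme positions
#' in trait space.
#'
#' @inheritParams functional_evenness
#' @return FDiv in \[0, 1\], or `NA` when the hull is degenerate.
#' @export
functional_divergence <- function(coords, weights) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("sp", seq_len(nrow(coords)))
  stopifnot(length(weights) == nrow(coords), all(weights >= 0))
  h <- hull_volume(coords)
  if (h$degenerate) return(NA_real_)
  G <- colMeans(coords[h$vertices, , drop = FALSE])
  dG <- sqrt(colSums((t(coords) - G)^2))
  dbar <- mean(dG)
  w <- weights / sum(weights)
  dd <- sum(w * (dG - dbar))
  dabs <- sum(w * abs(dG - dbar))
  if (dabs + dbar == 0) return(NA_real_)
  (dd + dbar) / (dabs + dbar)
}

#' Functional dispersion (FDis)
#'
#' Weighted mean distance of species to the weighted centroid of the
#' assemblage in the retained trait space:
#' \eqn{c = \sum a_j x_j / \sum a_j}, \eqn{FDis = \sum a_j \lVert x_j - c
#' \rVert / \sum a_j}.
#'
#' @inheritParams functional_evenness
#' @return Non-negative FDis (0 for a single species or identical
#'   points).
#' @export
functional_dispersion <- function(coords, weights) {
  coords <- as.matrix(coords)
  stopifnot(length(weights) == nrow(coords), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  ctr <- colSums(coords * w)
  sum(w * sqrt(colSums((t(coords) - ctr)^2)))
}

# --- full per-assemblage pipeline ------------------------------------------

#' Compute all FD metrics for a weighted assemblage
#'
#' Runs the full per-function pipeline: restrict the pool's coded trait
#' matrix to each requested ecosystem function, build the mixed trait
#' distance, ordinate by PCoA, retain `m = floor(log2(nbsp_pool))` axes
#' (capped at the positive spectrum), and compute FRic (presence-only,
#' standardised by the global pool hull), FEve, FDiv and FDis (weighted
#' by standardised landings), together with `nbsp`, `sing.sp` and
#' `quali.FRic`. The ordination and the retained dimensionality come from
#' the *pool*, so assemblages of one comparison share a common trait
#' space; zero-weight species (the min-max minimum) stay present for
#' FRic but contribute zero weight elsewhere.
#'
#' @param pool A `coded_traits` matrix for the full species pool.
#' @param weights The assemblage: a data frame with columns `species` and
#'   `weight` (standardised landings in \[0, 1\]), or a named numeric
#'   vector. Species must be a subset of the pool.
#' @param functions Character vector of function tags (subset of
#'   [fd_functions] and/or `"all"`); default all five sets.
#' @param m Retained axes; default `retain_axes(nrow(pool))`.
#' @param sqrt_transform,block_weights Passed to [trait_distance()].
#' @return A tibble with one row per function set: `fun`, `nbsp`,
#'   `sing_sp`, `quali_fric`, `n_axes`, `fric_raw`, `fric_std`, `feve`,
#'   `fdiv`, `fdis`, `flags` (semicolon-joined degenerate-case notes,
#'   `NA` if clean).
#' @examples
#' cfg <- scenario_config(n_species = 25, seed = 7)
#' pool <- code_traits(simulate_pool(cfg))
#' w <- tibble::tibble(species = rownames(pool)[1:20],
#'                     weight = seq(0, 1, length.out = 20))
#' compute_fd(pool, w, functions = "all")
#' @export
compute_fd <- function(pool, weights, functions = c(fd_functions, "all"),
                       m = NULL, sqrt_transform = TRUE,
                       block_weights = NULL) {
  stopifnot(inherits(pool, "coded_traits"))
  w <- .as_weights(weights)
  missing_sp <- setdiff(w$species, rownames(pool))
  if (length(missing_sp))
    stop("assemblage species not in pool: ",
         paste(head(missing_sp, 5), collapse = ", "), call. = FALSE)
  if (is.null(m)) m <- retain_axes(nrow(pool))
  purrr::map_dfr(functions, function(fun) {
    sub <- subset_by_function(pool, fun)
    ord <- trait_pcoa(trait_distance(sub, block_weights = block_weights,
                                     sqrt_transform = sqrt_transform))
    .fd_one(sub, ord, w, fun, m)
  })
}

# weights normaliser: data frame or named vector -> tibble(species, weight)
.as_weights <- function(weights) {
  if (is.data.frame(weights)) {
    stopifnot(all(c("species", "weight") %in% names(weights)))
    w <- tibble::as_tibble(weights[c("species", "weight")])
  } else {
    stopifnot(!is.null(names(weights)))
    w <- tibble::tibble(species = names(weights),
                        weight = as.numeric(weights))
  }
  if (anyDuplicated(w$species)) stop("duplicate species in weights",
                                     call. = FALSE)
  if (any(w$weight < 0) || anyNA(w$weight))
    stop("weights must be non-negative", call. = FALSE)
  if (sum(w$weight) <= 0) stop("need at least one positive weight",
                               call. = FALSE)
  w
}

# metrics for one function subset given the pool ordination
.fd_one <- function(sub, ord, w, fun, m) {
  flags <- character(0)
  m_eff <- min(m, ncol(ord$coordinates))
  if (m_eff < m) flags <- c(flags, "axes_capped_at_positive_spectrum")
  coords <- ord$coordinates[, seq_len(m_eff), drop = FALSE]
  if (m_eff == 0) {
    # no positive axis at all (e.g. every species functionally identical):
    # a single zero coordinate keeps the metrics well-defined downstream
    coords <- matrix(0, length(ord$species), 1,
                     dimnames = list(ord$species, "A1"))
    m_eff <- 1L
    flags <- c(flags, "no_positive_axes")
  }
  idx <- match(w$species, rownames(coords))
  pres <- coords[idx, , drop = FALSE]
  wt <- w$weight

  glob <- hull_volume(coords)
  ass <- hull_volume(pres)
  if (glob$degenerate) flags <- c(flags, "global_hull_degenerate")
  fric_raw <- ass$volume
  if (ass$degenerate) {
    flags <- c(flags, "assemblage_hull_degenerate")
    fric_raw <- NA_real_
  }
  fric_std <- if (!glob$degenerate && is.finite(glob$volume) &&
                  glob$volume > 0) {
    standardize_fric(ifelse(is.na(fric_raw), 0, fric_raw), glob$volume)
  } else NA_real_

  feve <- functional_evenness(pres, wt)
  if (is.na(feve)) flags <- c(flags, "feve_undefined")
  fdiv <- if (!ass$degenerate) functional_divergence(pres, wt) else
    NA_real_
  if (is.na(fdiv)) flags <- c(flags, "fdiv_undefined")
  fdis <- functional_dispersion(pres, wt)

  tibble::tibble(
    fun = fun, nbsp = nrow(pres), sing_sp = n_entities(
      new_coded_traits(unclass(sub)[w$species, , drop = FALSE],
                       attr(sub, "blocks"), attr(sub, "schema"))),
    quali_fric = representation_quality(ord$eigenvalues, m_eff),
    n_axes = m_eff, fric_raw = fric_raw, fric_std = fric_std,
    feve = feve, fdiv = fdiv, fdis = fdis,
    flags = if (length(flags)) paste(unique(flags), collapse = ";") else
      NA_character_)
}
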