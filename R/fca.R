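#' Fuzzy correspondence analysis of a coded trait table
#'
#' Correspondence analysis of the row-normalised fuzzy/binary trait table:
#' with \eqn{n} species and \eqn{K} trait blocks the correspondence matrix
#' is \eqn{P = X/(nK)} (every row of X sums to K, so row masses are
#' exactly 1/n and column masses are the column sums of P). Standardised
#' residuals are decomposed by SVD; eigenvalues are the squared singular
#' values, and species (rows) and modalities (columns) get principal
#' coordinates. Modalities never assigned to any species carry zero mass
#' and are excluded from the decomposition (reported in `dropped`).
#' Axis signs follow the largest-magnitude species coordinate.
#'
#' @param coded A `coded_traits` matrix from [code_traits()] (optionally
#'   restricted with [subset_by_function()]).
#' @param n_axes Minimum number of axes to retain when available
#'   (default 4); all axes up to the rank are kept if fewer.
#' @return A `trait_fca` object: list with `species_coords`,
#'   `modality_coords`, `eigenvalues` (per-axis inertia), `total_inertia`,
#'   `inertia_contributions` (modality x axis fractions, each axis summing
#'   to 1), `modality_correlations` (tibble: `trait`, `modality`, `axis`,
#'   `r`, `r_squared`, `flag`), `vertex_species` (list per retained axis
#'   pair) and `dropped` (zero-mass modalities).
#' @examples
#' pool <- simulate_pool(scenario_config(n_species = 20, seed = 1))
#' fca <- trait_fca(code_traits(pool))
#' glance(fca)
#' @export
trait_fca <- function(coded, n_axes = 4) {
  stopifnot(inherits(coded, "coded_traits"))
  X <- unclass(coded)
  n <- nrow(X)
  if (n < 3) stop("need at least three species", call. = FALSE)
  b <- attr(coded, "blocks")
  K <- nrow(b)
  trait_of <- rep(b$trait, b$end - b$start + 1L)
  modality <- sub("^[^.]*\\.", "", colnames(X))

  dropped <- colnames(X)[colSums(X) == 0]
  keep <- colSums(X) > 0
  Xk <- X[, keep, drop = FALSE]
  P <- Xk / (n * K)
  r <- rowSums(P)                 # = 1/n
  cm <- colSums(P)
  S <- (P - r %o% cm) / sqrt(r %o% cm)
  sv <- svd(S)
  tol <- 1e-10 * max(sv$d, .Machine$double.eps)
  rank <- sum(sv$d > tol)
  eig <- sv$d^2
  total_inertia <- sum(eig)
  m <- min(max(n_axes, 0), rank)

  if (m == 0) {
    # constant table: zero inertia
    return(structure(list(
      species = rownames(X),
      species_coords = matrix(0, n, 0, dimnames = list(rownames(X), NULL)),
      modality_coords = matrix(0, sum(keep), 0),
      eigenvalues = numeric(0), total_inertia = 0,
      inertia_contributions = matrix(0, sum(keep), 0),
      modality_correlations = tibble::tibble(
        trait = character(), modality = character(), axis = integer(),
        r = double(), r_squared = double(), flag = character()),
      vertex_species = list(), dropped = dropped), class = "trait_fca"))
  }

  U <- sv$u[, seq_len(m), drop = FALSE]
  V <- sv$v[, seq_len(m), drop = FALSE]
  dvals <- sv$d[seq_len(m)]
  F_ <- sweep(U, 1, sqrt(r), "/") %*% diag(dvals, m)        # species
  G_ <- sweep(V, 1, sqrt(cm), "/") %*% diag(dvals, m)       # modalities
  for (k in seq_len(m)) {   # sign convention via species coordinates
    i <- which.max(abs(F_[, k]))
    if (F_[i, k] < 0) { F_[, k] <- -F_[, k]; G_[, k] <- -G_[, k] }
  }
  axnm <- paste0("A", seq_len(m))
  dimnames(F_) <- list(rownames(X), axnm)
  dimnames(G_) <- list(colnames(Xk), axnm)

  # contribution of modality j to axis k: c_j * G_jk^2 / lambda_k
  ctr <- sweep(G_^2 * cm, 2, eig[seq_len(m)], "/")
  dimnames(ctr) <- dimnames(G_)

  corr <- purrr::map_dfr(seq_len(m), function(k) {
    sds <- apply(Xk, 2, sd)
    r_ <- rep(NA_real_, ncol(Xk))
    ok <- sds > 0 & sd(F_[, k]) > 0
    r_[ok] <- apply(Xk[, ok, drop = FALSE], 2, cor, y = F_[, k])
    tibble::tibble(
      trait = trait_of[keep], modality = modality[keep], axis = k,
      r = r_, r_squared = r_^2,
      flag = ifelse(ok, NA_character_, "zero_variance"))
  })

  pairs <- list()
  for (a in seq_len(m %/% 2)) {
    ax <- c(2 * a - 1, 2 * a)
    nm <- paste0("A", ax[1], "-A", ax[2])
    pairs[[nm]] <- tryCatch(hull_vertices(F_[, ax, drop = FALSE]),
                            error = function(e) character(0))
  }

  structure(list(species = rownames(X), species_coords = F_,
                 modality_coords = G_, eigenvalues = eig[seq_len(m)],
                 all_eigenvalues = eig[seq_len(rank)],
                 total_inertia = total_inertia,
                 inertia_contributions = ctr,
                 modality_correlations = corr,
                 vertex_species = pairs, dropped = dropped),
            class = "trait_fca")
}

#' @export
print.trait_fca <- function(x, ...) {
  cat("<trait_fca> ", length(x$species), " species, ",
      nrow(x$modality_coords), " modalities; total inertia ",
      signif(x$total_inertia, 4), "; ", ncol(x$species_coords),
      " axes retained\n", sep = "")
  invisible(x)
}

#' Tidy fuzzy correspondence analysis results
#'
#' @param x A `trait_fca` object.
#' @param matrix Which component to tidy: species or modality principal
#'   coordinates, per-axis modality inertia contributions, modality-axis
#'   Pearson correlations, or per-axis eigenvalues.
#' @param ... Unused.
#' @return A tibble in long format.
#' @exportS3Method generics::tidy
tidy.trait_fca <- function(x, matrix = c("species", "modalities",
                                         "contributions", "correlations",
                                         "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  long <- function(M, id) tibble::as_tibble(M, rownames = id) |>
    tidyr::pivot_longer(-dplyr::all_of(id), names_to = "axis",
                        values_to = "value")
  switch(matrix,
    species = long(x$species_coords, "species"),
    modalities = long(x$modality_coords, "modality"),
    contributions = long(x$inertia_contributions, "modality"),
    correlations = x$modality_correlations,
    eigenvalues = tibble::tibble(
      axis = paste0("A", seq_along(x$eigenvalues)),
      eigenvalue = x$eigenvalues,
      proportion = if (x$total_inertia > 0)
        x$eigenvalues / x$total_inertia else rep(0, length(x$eigenvalues))))
}

#' @exportS3Method generics::glance
glance.trait_fca <- function(x, ...) {
  p12 <- if (x$total_inertia > 0 && length(x$eigenvalues) >= 2)
    sum(x$eigenvalues[1:2]) / x$total_inertia else NA_real_
  tibble::tibble(n_species = length(x$species),
                 n_modalities = nrow(x$modality_coords),
                 n_axes = ncol(x$species_coords),
                 total_inertia = x$total_inertia,
                 prop_axis12 = p12)
}

#' Pearson correlation between modalities and an FCA axis
#'
#' For each modality column of the coded table, the Pearson correlation
#' between the species' affinities and their coordinates on the given
#' axis; both the signed `r` and `r_squared` are reported. Zero-variance
#' modalities are flagged undefined.
#'
#' @param fca A `trait_fca` object.
#' @param axis Integer index of a retained axis.
#' @return A tibble: `trait`, `modality`, `axis`, `r`, `r_squared`,
#'   `flag`.
#' @export
modality_axis_correlation <- function(fca, axis) {
  stopifnot(inherits(fca, "trait_fca"))
  if (!axis %in% unique(fca$modality_correlations$axis))
    stop("axis ", axis, " not retained", call. = FALSE)
  dplyr::filter(fca$modality_correlations, .data$axis == !!axis)
}

#' Plot an FCA trait space
#'
#' Modalities are drawn as labelled points coloured by trait; optionally
#' the species scatter and its convex hull (vertex species) are overlaid.
#'
#' @param object A `trait_fca` object.
#' @param axes Length-2 integer vector of axes to plot (default 1:2).
#' @param species Overlay species points and hull (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trait_fca <- function(object, axes = c(1, 2), species = TRUE,
                               ...) {
  stopifnot(length(axes) == 2, all(axes <= ncol(object$species_coords)))
  ax <- paste0("A", axes)
  mods <- tibble::as_tibble(object$modality_coords[, ax, drop = FALSE],
                            rownames = "modality")
  mods$trait <- sub("\\..*$", "", mods$modality)
  p <- ggplot2::ggplot(mods, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]]))
  if (species) {
    sp <- tibble::as_tibble(object$species_coords[, ax, drop = FALSE],
                            rownames = "species")
    hull <- tryCatch(hull_vertices(object$species_coords[, axes,
                                                         drop = FALSE]),
                     error = function(e) character(0))
    p <- p +
      ggplot2::geom_point(data = sp, colour = "grey70", size = 1) +
      ggplot2::geom_polygon(data = sp[match(hull, sp$species), ],
                            fill = NA, colour = "grey60",
                            linetype = "dashed")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$trait), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = sub("^[^.]*\\.", "",
                                                .data$modality),
                                    colour = .data$trait),
                       vjust = -0.7, size = 2.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = ax[1], y = ax[2], colour = "trait") +
    ggplot2::theme_minimal()
}
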