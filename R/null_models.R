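#' Permute trait profiles across species labels
#'
#' The randomisation scheme behind the null models: complete coded trait
#' rows (whole trait profiles) are reassigned to species labels by one
#' uniform random permutation. Each profile stays intact, so trait
#' combinations that co-occur in real species are never broken apart and
#' the multiset of rows is unchanged; only the species-to-profile (and
#' hence landings-to-profile) pairing is randomised.
#'
#' @param coded A `coded_traits` matrix.
#' @return A `coded_traits` matrix with the same row multiset, rows
#'   permuted under the original species names.
#' @export
permute_trait_assignment <- function(coded) {
  stopifnot(inherits(coded, "coded_traits"), nrow(coded) >= 2)
  perm <- sample.int(nrow(coded))
  x <- unclass(coded)[perm, , drop = FALSE]
  rownames(x) <- rownames(coded)
  new_coded_traits(x, attr(coded, "blocks"), attr(coded, "schema"))
}

# metric evaluator on fixed retained-space geometry.
# coords: pool coordinates (n x m); Dc: pairwise distances in that space;
# idx: row indices of the assemblage; wt: weights; global_vol: pool hull
# volume (invariant under row permutation).
.metric_eval <- function(metric, coords, Dc, idx, wt, global_vol) {
  switch(metric,
    FRic = {
      h <- hull_volume(coords[idx, , drop = FALSE])
      if (h$degenerate || !is.finite(global_vol) || global_vol <= 0)
        NA_real_ else h$volume / global_vol
    },
    FEve = feve_cpp(Dc[idx, idx, drop = FALSE], wt),
    FDiv = functional_divergence(coords[idx, , drop = FALSE], wt),
    FDis = functional_dispersion(coords[idx, , drop = FALSE], wt))
}

#' Permutation null test for an FD metric difference
#'
#' Tests whether two weighted assemblages (e.g. two fleets, or two
#' decades within a fleet) differ in one FD metric more than expected
#' when species trait profiles are arranged at random. The observed
#' statistic is \eqn{|M_A - M_B|}. Each of `n_iter` iterations reassigns
#' whole trait profiles to species by a uniform permutation
#' ([permute_trait_assignment()]), recomputes the metric for both groups
#' and stores the simulated \eqn{|M_A - M_B|}; the p-value is the
#' fraction of simulated differences at or above the observed one.
#'
#' Because a whole-row permutation is a relabelling, the permuted trait
#' matrix has distance matrix \eqn{P D P'} whose PCoA is the same point
#' configuration with permuted labels; the metrics depend only on that
#' geometry, so iterations permute labels over the observed ordination
#' rather than re-running the eigen-decomposition (an exact shortcut,
#' verified in the test suite against the literal recomputation).
#'
#' @param pool A `coded_traits` matrix for the species pool.
#' @param weights_a,weights_b The two assemblages (see [compute_fd()] for
#'   accepted forms); species must be subsets of the pool.
#' @param metric One of `"FRic"`, `"FEve"`, `"FDiv"`, `"FDis"`.
#' @param fun Ecosystem function tag, or `"all"` for the combined
#'   76-modality matrix.
#' @param n_iter Number of permutations (default 999).
#' @param seed Optional integer seed for this test.
#' @param include_observed If `TRUE`, count the observed arrangement as
#'   one more exceedance and use denominator `n_iter + 1`; the default
#'   (`FALSE`) divides exceedances by `n_iter`.
#' @param m Retained axes; default `retain_axes(nrow(pool))`.
#' @return An `fd_null_test` object; see [tidy.fd_null_test()]. Contains
#'   observed per-group values, the simulated difference distribution,
#'   the exceedance p-value, and the effective denominator after
#'   excluding degenerate iterations. If the metric is undefined for a
#'   group on the observed data the test is skipped (`p_value = NA`) with
#'   the reason in `skipped`.
#' @examples
#' sc <- simulate_scenario(scenario_config(n_species = 30, seed = 2))
#' agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
#' wa <- dplyr::filter(agg, fleet == "local")
#' wb <- dplyr::filter(agg, fleet == "coastal")
#' nt <- null_test(sc$coded, wa, wb, metric = "FEve", n_iter = 99, seed = 1)
#' tidy(nt)
#' @export
null_test <- function(pool, weights_a, weights_b,
                      metric = c("FRic", "FEve", "FDiv", "FDis"),
                      fun = "all", n_iter = 999, seed = NULL,
                      include_observed = FALSE, m = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(pool, "coded_traits"), n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  wa <- .as_weights(weights_a)
  wb <- .as_weights(weights_b)
  n <- nrow(pool)
  if (is.null(m)) m <- retain_axes(n)

  sub <- subset_by_function(pool, fun)
  ord <- trait_pcoa(trait_distance(sub))
  m_eff <- min(m, ncol(ord$coordinates))
  coords <- ord$coordinates[, seq_len(m_eff), drop = FALSE]
  Dc <- as.matrix(dist(coords))
  idx_a <- match(wa$species, rownames(coords))
  idx_b <- match(wb$species, rownames(coords))
  if (anyNA(idx_a) || anyNA(idx_b))
    stop("assemblage species not in pool", call. = FALSE)
  global_vol <- if (metric == "FRic") hull_volume(coords)$volume else
    NA_real_

  obs_a <- .metric_eval(metric, coords, Dc, idx_a, wa$weight, global_vol)
  obs_b <- .metric_eval(metric, coords, Dc, idx_b, wb$weight, global_vol)
  res <- list(metric = metric, fun = fun,
              group_a = attr(weights_a, "label") %||% "A",
              group_b = attr(weights_b, "label") %||% "B",
              observed_a = obs_a, observed_b = obs_b,
              n_iter = n_iter, seed = seed, m = m_eff)
  if (is.na(obs_a) || is.na(obs_b)) {
    res <- c(res, list(observed_diff = NA_real_,
                       simulated_diffs = numeric(0), p_value = NA_real_,
                       n_effective = 0L,
                       skipped = "metric undefined for a group on \
observed data"))
    class(res) <- "fd_null_test"
    return(res)
  }
  obs <- abs(obs_a - obs_b)
  sims <- vapply(seq_len(n_iter), function(it) {
    perm <- sample.int(n)
    # species s now carries the profile (hence coordinates) of perm[s]
    a <- .metric_eval(metric, coords, Dc, perm[idx_a], wa$weight,
                      global_vol)
    b <- .metric_eval(metric, coords, Dc, perm[idx_b], wb$weight,
                      global_vol)
    abs(a - b)
  }, numeric(1))
  ok <- is.finite(sims)
  n_eff <- sum(ok)
  exceed <- sum(sims[ok] >= obs)
  p <- if (include_observed) (exceed + 1) / (n_eff + 1) else
    if (n_eff > 0) exceed / n_eff else NA_real_
  res <- c(res, list(observed_diff = obs, simulated_diffs = sims,
                     p_value = p, n_effective = n_eff,
                     skipped = NA_character_))
  class(res) <- "fd_null_test"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fd_null_test <- function(x, ...) {
  cat("<fd_null_test> ", x$metric, " / ", x$fun, ": |",
      signif(x$observed_a, 4), " - ", signif(x$observed_b, 4), "| = ",
      signif(x$observed_diff, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_effective, " of ", x$n_iter, " iterations)\n", sep = "")
  invisible(x)
}

#' Tidy a null-test result
#'
#' @param x An `fd_null_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `fun`, `group_a`, `group_b`,
#'   `observed_a`, `observed_b`, `difference`, `sim_mean`, `p_value`,
#'   `n_iter`, `n_effective`, `seed`, `skipped`.
#' @exportS3Method generics::tidy
tidy.fd_null_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, fun = x$fun, group_a = x$group_a,
    group_b = x$group_b, observed_a = x$observed_a,
    observed_b = x$observed_b, difference = x$observed_diff,
    sim_mean = if (length(x$simulated_diffs))
      mean(x$simulated_diffs[is.finite(x$simulated_diffs)]) else NA_real_,
    p_value = x$p_value, n_iter = x$n_iter,
    n_effective = x$n_effective,
    seed = x$seed %||% NA_integer_, skipped = x$skipped)
}

#' @exportS3Method generics::glance
glance.fd_null_test <- function(x, ...) tidy(x)

#' Histogram of the simulated null distribution
#'
#' @param object An `fd_null_test` object.
#' @param ... Unused.
#' @return A ggplot: simulated |A - B| distribution with the observed
#'   difference marked.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_null_test <- function(object, ...) {
  df <- tibble::tibble(sim = object$simulated_diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sim)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "red") +
    ggplot2::labs(
      x = sprintf("simulated |%s(A) - %s(B)|", object$metric,
                  object$metric),
      y = "count",
      title = sprintf("%s / %s: p = %.4g", object$metric, object$fun,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Run the full battery of fleet and decade comparisons
#'
#' One [null_test()] per combination of metric, function set (the four
#' ecosystem functions plus the combined matrix) and comparison: local
#' vs coastal (aggregated over the whole period) and, within each fleet,
#' every decade pair. Reproducible: a master seed spawns one sub-seed
#' per cell of the full canonical grid, so each test's stream is
#' independent of execution order and of which cells are skipped.
#'
#' @param pool A `coded_traits` matrix for the pool.
#' @param records Validated landings records (see [read_landings()]).
#' @param metrics Metrics to test (default all four).
#' @param functions Function sets (default the four tags plus `"all"`).
#' @param n_iter Permutations per test (default 999).
#' @param seed Master seed.
#' @param decades A [decade_table()].
#' @param scope Standardisation scope for weights
#'   (see [standardize_weights()]).
#' @param include_observed Passed to [null_test()].
#' @return A tibble with one row per attempted test (the
#'   [tidy.fd_null_test()] columns plus `fleet`); comparisons whose
#'   assemblage is missing or degenerate carry the reason in `skipped`.
#' @export
run_comparisons <- function(pool, records,
                            metrics = c("FRic", "FEve", "FDiv", "FDis"),
                            functions = c(fd_functions, "all"),
                            n_iter = 999, seed = 1L,
                            decades = decade_table(),
                            scope = "assemblage",
                            include_observed = FALSE) {
  stopifnot(inherits(pool, "coded_traits"))
  by_fleet <- standardize_weights(
    aggregate_landings(records, by = "fleet"), scope = scope)
  by_fd <- standardize_weights(
    aggregate_landings(records, by = "fleet_decade", decades = decades),
    scope = scope)
  fleets <- sort(unique(records$fleet))
  dp <- decade_pairs(decades)

  cmp <- dplyr::bind_rows(
    tibble::tibble(fleet = NA_character_, group_a = fleets[1],
                   group_b = fleets[2]),
    purrr::map_dfr(fleets, function(fl)
      tibble::tibble(fleet = fl, group_a = dp$decade_a,
                     group_b = dp$decade_b)))
  grid <- tidyr::expand_grid(metric = metrics, fun = functions,
                             cmp_id = seq_len(nrow(cmp)))
  set.seed(seed)
  grid$sub_seed <- sample.int(.Machine$integer.max, nrow(grid))

  pick <- function(fleet, group) {
    if (is.na(fleet)) {
      w <- dplyr::filter(by_fleet, .data$fleet == group)
    } else {
      w <- dplyr::filter(by_fd, .data$fleet == !!fleet,
                         .data$decade == group)
    }
    if (nrow(w) == 0) return(NULL)
    out <- tibble::tibble(species = w$species, weight = w$weight)
    attr(out, "label") <- if (is.na(fleet)) group else
      paste0(fleet, ":", group)
    out
  }

  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cm <- cmp[grid$cmp_id[g], ]
    wa <- pick(cm$fleet, cm$group_a)
    wb <- pick(cm$fleet, cm$group_b)
    base <- tibble::tibble(
      fleet = cm$fleet, metric = grid$metric[g], fun = grid$fun[g],
      group_a = cm$group_a, group_b = cm$group_b)
    if (is.null(wa) || is.null(wb) || is.na(cm$group_b))
      return(dplyr::mutate(base, observed_a = NA_real_,
                           observed_b = NA_real_, difference = NA_real_,
                           sim_mean = NA_real_, p_value = NA_real_,
                           n_iter = n_iter, n_effective = 0L,
                           seed = grid$sub_seed[g],
                           skipped = "missing assemblage"))
    nt <- null_test(pool, wa, wb, metric = grid$metric[g],
                    fun = grid$fun[g], n_iter = n_iter,
                    seed = grid$sub_seed[g],
                    include_observed = include_observed)
    dplyr::bind_cols(base["fleet"], tidy(nt))
  })
}
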