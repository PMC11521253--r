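test_that("trait-profile permutation preserves the row multiset", {
  m <- code_traits(make_traits(12, seed = 61))
  set.seed(1)
  for (rep in 1:20) {
    p <- permute_trait_assignment(m)
    expect_equal(rownames(p), rownames(m))
    key <- function(x) sort(unname(apply(unclass(x), 1, paste,
                                         collapse = ",")))
    expect_equal(key(p), key(m))
  }
  # 2 species: identity or swap with roughly equal frequency
  m2 <- code_traits(make_traits(2, seed = 62))
  set.seed(2)
  swaps <- mean(replicate(400, {
    !identical(unclass(permute_trait_assignment(m2))[1, ],
               unclass(m2)[1, ])
  }))
  expect_gt(swaps, 0.4)
  expect_lt(swaps, 0.6)
})

test_that("identical assemblages give observed_diff 0 and p = 1", {
  sc <- simulate_scenario(scenario_config(n_species = 20, seed = 63))
  agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
  w <- dplyr::filter(agg, fleet == "local")[, c("species", "weight")]
  for (metric in c("FRic", "FEve", "FDiv", "FDis")) {
    nt <- null_test(sc$coded, w, w, metric = metric, n_iter = 49, seed = 3)
    expect_equal(nt$observed_diff, 0)
    expect_equal(nt$p_value, 1)
  }
})

test_that("p-values live on the exceedance grid and respect the seed", {
  sc <- simulate_scenario(scenario_config(n_species = 20, seed = 64))
  agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
  wa <- dplyr::filter(agg, fleet == "local")[, c("species", "weight")]
  wb <- dplyr::filter(agg, fleet == "coastal")[, c("species", "weight")]
  n1 <- null_test(sc$coded, wa, wb, metric = "FEve", n_iter = 99, seed = 7)
  expect_true(n1$p_value %in% ((0:n1$n_effective) / n1$n_effective))
  expect_equal(length(n1$simulated_diffs), 99)
  # determinism under the seed
  n2 <- null_test(sc$coded, wa, wb, metric = "FEve", n_iter = 99, seed = 7)
  expect_identical(n1$simulated_diffs, n2$simulated_diffs)
  expect_identical(n1$p_value, n2$p_value)
  # label symmetry
  n3 <- null_test(sc$coded, wb, wa, metric = "FEve", n_iter = 99, seed = 7)
  expect_equal(n3$p_value, n1$p_value)
  # observed-included denominator variant
  n4 <- null_test(sc$coded, wa, wb, metric = "FEve", n_iter = 99, seed = 7,
                  include_observed = TRUE)
  expect_equal(n4$p_value,
               (sum(n1$simulated_diffs >= n1$observed_diff) + 1) / 100)
})

test_that("label permutation equals the literal recompute-from-matrix route", {
  # the fast path permutes labels over the fixed ordination; the direct
  # route re-runs distance -> PCoA -> metric on the permuted matrix
  sc <- simulate_scenario(scenario_config(n_species = 15, seed = 65))
  agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
  wa <- dplyr::filter(agg, fleet == "local")[, c("species", "weight")]
  m <- retain_axes(15)
  for (metric in c("FEve", "FDis", "FRic", "FDiv")) {
    set.seed(42)
    perm <- sample.int(15)

    ord <- trait_pcoa(trait_distance(sc$coded))
    coords <- ord$coordinates[, 1:m]
    Dc <- as.matrix(dist(coords))
    idx <- match(wa$species, rownames(coords))
    gl <- if (metric == "FRic") hull_volume(coords)$volume else NA
    fast <- fdlandings:::.metric_eval(metric, coords, Dc, perm[idx],
                                      wa$weight, gl)

    pm <- unclass(sc$coded)[perm, , drop = FALSE]
    rownames(pm) <- rownames(sc$coded)
    pmat <- fdlandings:::new_coded_traits(pm, attr(sc$coded, "blocks"),
                                          attr(sc$coded, "schema"))
    ord2 <- trait_pcoa(trait_distance(pmat))
    coords2 <- ord2$coordinates[, 1:m]
    Dc2 <- as.matrix(dist(coords2))
    idx2 <- match(wa$species, rownames(coords2))
    gl2 <- if (metric == "FRic") hull_volume(coords2)$volume else NA
    slow <- fdlandings:::.metric_eval(metric, coords2, Dc2, idx2,
                                      wa$weight, gl2)
    expect_equal(fast, slow, tolerance = 1e-8)
  }
})

test_that("identical trait rows force zero differences and p = 1", {
  tt <- make_traits(4, seed = 66)
  tt12 <- tt[rep(1, 12), ]
  tt12$species <- sprintf("e%02d", 1:12)
  m <- code_traits(tt12)
  wa <- setNames(runif(6) + 0.5, tt12$species[1:6])
  wb <- setNames(runif(6) + 0.5, tt12$species[7:12])
  nt <- null_test(m, wa, wb, metric = "FDis", n_iter = 29, seed = 1)
  expect_equal(nt$observed_diff, 0)
  expect_equal(nt$p_value, 1)
})

test_that("run_comparisons assembles the full grid deterministically", {
  sc <- simulate_scenario(scenario_config(n_species = 15, seed = 67))
  res <- run_comparisons(sc$coded, sc$landings, metrics = "FDis",
                         functions = c("feeding", "all"), n_iter = 19,
                         seed = 11)
  # 1 fleet pair + 2 fleets x 6 decade pairs = 13 comparisons per cell
  expect_equal(nrow(res), 2 * 13)
  expect_true(all(res$n_iter == 19))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  res2 <- run_comparisons(sc$coded, sc$landings, metrics = "FDis",
                          functions = c("feeding", "all"), n_iter = 19,
                          seed = 11)
  expect_identical(res$p_value, res2$p_value)
  # per-test sub-seeds differ across cells
  expect_equal(anyDuplicated(res$seed), 0)
})

test_that("a strong decade composition shift is detected by the dispersion metric", {
  # the same scenario whose FEve response is weak (see the methods
  # vignette) moves FDis decisively: weight lands on functionally
  # distinct species far from the centroid
  ps <- vapply(1:12, function(r) {
    sc <- simulate_scenario(scenario_config(
      n_species = 100, seed = 7000 + r, effect = "decade_shift",
      effect_size = 6))
    agg <- standardize_weights(aggregate_landings(sc$landings,
                                                  by = "fleet_decade"))
    pick <- function(dec) {
      w <- dplyr::filter(agg, fleet == "local", decade == dec)
      tibble::tibble(species = w$species, weight = w$weight)
    }
    null_test(sc$coded, pick("80s"), pick("10s"), metric = "FDis",
              fun = "all", n_iter = 99, seed = r)$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
})
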