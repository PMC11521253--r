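test_that("scenario configs validate their fields", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_species = 5))
  expect_error(scenario_config(effect_size = -1))
  expect_error(scenario_config(effect = "null", effect_size = 2),
               "one generating")
})

test_that("generated pools always pass validation and are reproducible", {
  cfg <- scenario_config(n_species = 40, seed = 77)
  p1 <- simulate_pool(cfg)
  p2 <- simulate_pool(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(validate_traits(p1)), 0)
  expect_equal(nrow(p1), 40)
  expect_false(anyNA(as.matrix(p1)))
  # a different seed gives a different pool
  expect_false(identical(as.data.frame(p1),
                         as.data.frame(simulate_pool(
                           scenario_config(n_species = 40, seed = 78)))))
})

test_that("forced duplicate profiles propagate to sing.sp downstream", {
  cfg <- scenario_config(n_species = 30, n_profiles = 4, seed = 5)
  pool <- simulate_pool(cfg)
  expect_lte(n_entities(code_traits(pool)), 4)
})

test_that("landings emulate the assumed structure", {
  cfg <- scenario_config(n_species = 25, seed = 9)
  pool <- simulate_pool(cfg)
  rec <- simulate_landings(pool, cfg)
  # full coverage: every species, year in range, both fleets, months 1-12
  expect_setequal(unique(rec$species), pool$species)
  expect_true(all(rec$year >= 1980 & rec$year <= 2020))
  expect_setequal(unique(rec$fleet), c("local", "coastal"))
  expect_true(all(rec$weight_kg > 0))
  # records pass the landings validator with zero rejections
  ok <- validate_landings(rec)
  expect_equal(nrow(attr(ok, "rejected")), 0)
  # skewed totals: the top species dominates the median species
  tot <- sort(tapply(rec$weight_kg, rec$species, sum), decreasing = TRUE)
  expect_gt(tot[1] / stats::median(tot), 5)
  # reproducibility
  expect_identical(rec, simulate_landings(pool, cfg))
})

test_that("seasonality modulates monthly landings per species", {
  cfg <- scenario_config(n_species = 15, seed = 10, seasonality = 0.9)
  rec <- simulate_landings(simulate_pool(cfg), cfg)
  by_m <- rec |>
    dplyr::filter(species == "sp001", fleet == "local") |>
    dplyr::group_by(month) |>
    dplyr::summarise(w = sum(weight_kg))
  expect_gt(max(by_m$w) / min(by_m$w), 1.05)
})

test_that("dominance controls skew and its limit trips the constant flag", {
  flat <- scenario_config(n_species = 15, seed = 11, dominance = 0)
  rec <- simulate_landings(simulate_pool(flat), flat)
  tot <- tapply(rec$weight_kg, rec$species, sum)
  expect_lt(max(tot) / min(tot), 5)
  skew <- scenario_config(n_species = 15, seed = 11, dominance = 2)
  rec2 <- simulate_landings(simulate_pool(skew), skew)
  tot2 <- tapply(rec2$weight_kg, rec2$species, sum)
  expect_gt(max(tot2) / min(tot2), max(tot) / min(tot))
})

test_that("fleet-divergent and decade-shift scenarios move the target group", {
  cfg <- scenario_config(n_species = 40, seed = 12,
                         effect = "fleet_divergent", effect_size = 2)
  pool <- simulate_pool(cfg)
  rec <- simulate_landings(pool, cfg)
  z <- attr(pool, "depth_score")
  agg <- aggregate_landings(rec, by = "fleet")
  share <- agg |>
    dplyr::group_by(fleet) |>
    dplyr::mutate(p = total_kg / sum(total_kg)) |>
    dplyr::summarise(deep = sum(p[z[species] > 1]))
  expect_gt(share$deep[share$fleet == "coastal"],
            share$deep[share$fleet == "local"])

  cfg2 <- scenario_config(n_species = 40, seed = 12,
                          effect = "decade_shift", effect_size = 6)
  rec2 <- simulate_landings(pool, cfg2)
  iso <- fdlandings:::.trait_isolation(pool)
  agg2 <- standardize_weights(aggregate_landings(rec2))
  co <- function(dec) {
    g <- dplyr::filter(agg2, fleet == "local", decade == dec)
    cor(g$total_kg, iso[g$species], method = "spearman")
  }
  # landings track functional distinctness only in the shifted decade
  expect_gt(co("10s"), 0.8)
  expect_lt(abs(co("80s")), 0.5)
})
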