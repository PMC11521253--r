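#' Scenario configuration for the synthetic landings generator
#'
#' Defines one simulated study: a species pool with correlated trait
#' draws and a multi-decadal, two-fleet landings series with strongly
#' skewed (log-normal) per-species totals and seasonal availability.
#' Effect scenarios perturb the generating process:
#' \describe{
#'   \item{`null`}{both fleets and all decades come from one process
#'     (traits independent of landings) - the calibration scenario.}
#'   \item{`fleet_divergent`}{the coastal fleet up-weights deep-water
#'     species by `exp(effect_size * depth score)`, mimicking the deeper
#'     operating range of coastal vessels.}
#'   \item{`decade_shift`}{in the final decade, landings concentrate on
#'     the trait-distinct deep-water subset of the pool (multiplier
#'     `exp(effect_size)`).}
#'   \item{`dominance_shift`}{in the final decade the landings
#'     distribution becomes more skewed (totals raised to the power
#'     `1 + effect_size`).}
#' }
#'
#' @param n_species Pool size (>= 10; default 100, the order of the
#'   species count in multi-decadal landings series).
#' @param years Year span (default `1980:2020`).
#' @param fleets Fleet labels (default `local`/`coastal`).
#' @param dominance Log-normal sigma of per-species base totals
#'   (default 1.5: a few taxa dominate the landings).
#' @param seasonality Maximum seasonal amplitude in \[0, 1\]
#'   (default 0.5).
#' @param effect One of `"null"`, `"fleet_divergent"`, `"decade_shift"`,
#'   `"dominance_shift"`.
#' @param effect_size Non-negative effect magnitude (log-scale
#'   multiplier; default 0).
#' @param n_profiles Optionally draw only this many distinct trait
#'   profiles and reuse them across species (forces functional entities
#'   with `sing.sp < nbsp`).
#' @param seed Integer seed; every generator call is reproducible given
#'   the config.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 100, years = 1980:2020,
                            fleets = c("local", "coastal"),
                            dominance = 1.5, seasonality = 0.5,
                            effect = c("null", "fleet_divergent",
                                       "decade_shift", "dominance_shift"),
                            effect_size = 0, n_profiles = NULL,
                            seed = 1L) {
  effect <- match.arg(effect)
  stopifnot(n_species >= 10, length(years) >= 1, length(fleets) >= 1,
            dominance >= 0, seasonality >= 0, seasonality <= 1,
            effect_size >= 0)
  if (effect == "null" && effect_size != 0)
    stop("effect = 'null' requires effect_size = 0 (one generating ",
         "process)", call. = FALSE)
  structure(list(n_species = as.integer(n_species), years = years,
                 fleets = fleets, dominance = dominance,
                 seasonality = seasonality, effect = effect,
                 effect_size = effect_size, n_profiles = n_profiles,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# marginal modality frequencies used by the pool generator; skewed toward
# the common shallow-water, fusiform, small-bodied profile so that rare
# modalities exist without dominating
.pool_marginals <- function(schema) {
  tl <- schema_traits(schema)
  purrr::set_names(purrr::map(seq_len(nrow(tl)), function(k) {
    n <- tl$n_modalities[k]
    p <- 0.75^(seq_len(n) - 1)  # geometric decay over modality order
    p / sum(p)
  }), tl$trait)
}

#' Generate a synthetic species pool
#'
#' Draws one modality per crisp trait and a 1-3 item diet per species.
#' A latent depth/size axis per species correlates the habitat traits
#' (deep `max_depth` goes with bathydemersal/bathypelagic water-column
#' position, colder temperature preference and larger body size), so
#' fleet-selectivity scenarios are ecologically coherent. Species names
#' are synthetic identifiers (`sp001`, ...). Duplicate trait profiles may
#' occur by chance (or by construction via `n_profiles`), exercising
#' `sing.sp < nbsp` downstream. No missing values are ever emitted.
#'
#' @param config A [scenario_config()].
#' @param schema A [trait_schema()].
#' @return A tibble of species trait records (passes [validate_traits()]
#'   with zero violations), with the latent depth score in attribute
#'   `"depth_score"`.
#' @export
simulate_pool <- function(config, schema = trait_schema()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- if (is.null(config$n_profiles)) config$n_species else
    as.integer(config$n_profiles)
  # latent depth axis: two-component mixture emulating the shelf vs
  # deep-sea assemblage discontinuity of oceanic island fisheries
  deep_mode <- runif(n) < 0.3
  z <- ifelse(deep_mode, rnorm(n, 1.6, 0.5), rnorm(n, -0.8, 0.7))
  marg <- .pool_marginals(schema)
  tl <- schema_traits(schema)

  draw_ordinal <- function(trait, score, noise = 0.8) {
    # map a noisy latent score to ordered bins at fixed Gaussian
    # cutpoints, so clusters in the latent axis stay clustered in the
    # assigned modalities (quantile binning would flatten them)
    mods <- schema$modality[schema$trait == trait]
    k <- length(mods)
    s <- score + rnorm(n, sd = noise)
    br <- c(-Inf, qnorm(seq_len(k - 1) / k, mean = mean(s), sd = sd(s)),
            Inf)
    mods[cut(s, breaks = br, labels = FALSE)]
  }
  out <- tibble::tibble(species = sprintf("sp%03d", seq_len(n)))
  for (k in seq_len(nrow(tl))) {
    tr <- tl$trait[k]
    mods <- schema$modality[schema$trait == tr]
    if (tl$coding[k] == "fuzzy") {
      # diet follows the depth gradient: deep-water species take fish,
      # cephalopods and decapods; shallow species plankton, algae and
      # benthic invertebrates
      pred <- mods %in% c("Ceph", "Chon", "Crde", "Tele")
      out[[tr]] <- purrr::map_chr(seq_len(n), function(i) {
        p <- marg[[tr]] * exp(ifelse(pred, 0.9, -0.9) * z[i])
        sz <- sample(1:3, 1)
        paste(sample(mods, sz, prob = p), collapse = ";")
      })
    } else if (tr == "max_depth") {
      out[[tr]] <- draw_ordinal(tr, z, noise = 0.35)
    } else if (tr == "water_column_position") {
      # deep species demersal-leaning: Batd/Batp for high z
      p <- marg[[tr]]
      out[[tr]] <- purrr::map_chr(seq_len(n), function(i) {
        w <- p * exp(ifelse(mods %in% c("Batd", "Batp"), 1.5 * z[i], 0))
        sample(mods, 1, prob = w / sum(w))
      })
    } else if (tr == "temperature_preference") {
      out[[tr]] <- draw_ordinal(tr, z, noise = 0.8)  # deep = cold bins
    } else if (tr == "max_body_size") {
      out[[tr]] <- draw_ordinal(tr, 0.4 * z, noise = 1)
    } else if (tr == "generation_time") {
      # deep-water species: long-lived, slow-growing, late-maturing,
      # lower fecundity (the deep-sea life-history syndrome)
      out[[tr]] <- draw_ordinal(tr, z, noise = 0.6)
    } else if (tr == "growth_coefficient") {
      out[[tr]] <- draw_ordinal(tr, -z, noise = 0.6)
    } else if (tr == "maturity_size") {
      out[[tr]] <- draw_ordinal(tr, 0.7 * z, noise = 0.8)
    } else if (tr == "fecundity") {
      out[[tr]] <- draw_ordinal(tr, -0.7 * z, noise = 0.8)
    } else if (tr == "trophic_position") {
      out[[tr]] <- draw_ordinal(tr, 0.5 * z, noise = 1.2)
    } else if (tr == "food_consumption") {
      # deep-sea species have low metabolic rates, hence low Q/B
      out[[tr]] <- draw_ordinal(tr, -z, noise = 0.8)
    } else if (tr == "body_shape") {
      # elongate and eel-like bodies prevail at depth, fusiform and
      # short/deep bodies in shallow water
      elong <- mods %in% c("Eeli", "Elon")
      p0 <- marg[[tr]]
      out[[tr]] <- purrr::map_chr(seq_len(n), function(i) {
        p <- p0 * exp(ifelse(elong, 1.2, -1.2) * z[i])
        sample(mods, 1, prob = p / sum(p))
      })
    } else if (tr == "reproductive_guild") {
      # live-bearing elasmobranchs dominate the deep assemblage,
      # broadcast-spawning nonguarders the shallow one
      bear <- mods == "Bear"
      ngua <- mods == "Ngua"
      p0 <- marg[[tr]]
      out[[tr]] <- purrr::map_chr(seq_len(n), function(i) {
        p <- p0 * exp(1.0 * z[i] * bear - 1.0 * z[i] * ngua)
        sample(mods, 1, prob = p / sum(p))
      })
    } else {
      out[[tr]] <- sample(mods, n, replace = TRUE, prob = marg[[tr]])
    }
  }
  if (!is.null(config$n_profiles)) {
    pick <- sample(seq_len(n), config$n_species, replace = TRUE)
    z <- z[pick]
    out <- out[pick, ]
    out$species <- sprintf("sp%03d", seq_len(config$n_species))
  }
  attr(out, "depth_score") <- setNames(z, out$species)
  out
}

#' Generate synthetic landings records
#'
#' Per-species base totals are heavy-tailed log-normal (sigma =
#' `dominance`), modulated by fleet-specific catchability, per-year
#' log-normal noise, sinusoidal monthly seasonality (per-species
#' amplitude and phase) and the configured effect scenario (see
#' [scenario_config()]). Under `effect = "null"` the two fleets are
#' exchangeable and landings are independent of traits, so downstream
#' permutation tests are calibrated by construction. All weights are
#' strictly positive.
#'
#' @param pool A species pool from [simulate_pool()] (its latent depth
#'   score attribute drives depth-linked scenarios).
#' @param config The same [scenario_config()].
#' @return A tibble of landings records: `species`, `year`, `month`,
#'   `fleet`, `weight_kg`; one row per (species, year, month, fleet).
#' @export
simulate_landings <- function(pool, config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  sp <- pool$species
  n <- length(sp)
  z <- attr(pool, "depth_score")
  if (is.null(z)) z <- setNames(rep(0, n), sp)
  last_decade_start <- max(config$years) - 10L

  base <- rlnorm(n, meanlog = log(1000), sdlog = config$dominance)
  amp <- runif(n, 0, config$seasonality)
  phase <- sample(1:12, n, replace = TRUE)

  grid <- tidyr::expand_grid(
    species = sp, year = config$years, month = 1:12,
    fleet = config$fleets)
  i <- match(grid$species, sp)
  w <- base[i]
  # fleet catchability: equal under the null, depth-linked when divergent
  if (config$effect == "fleet_divergent") {
    coastal <- grid$fleet == "coastal"
    w <- w * exp(config$effect_size * z[i] * ifelse(coastal, 0.5, -0.5))
  }
  # per (species, year, fleet) availability noise
  set.seed(config$seed + 2L)
  key <- paste(grid$species, grid$year, grid$fleet)
  uk <- unique(key)
  noise <- setNames(rlnorm(length(uk), 0, 0.4), uk)
  w <- w * noise[key]
  # seasonality
  w <- w * (1 + amp[i] * cos(2 * pi * (grid$month - phase[i]) / 12))
  # decade effects target the final decade
  target <- grid$year >= last_decade_start
  if (config$effect == "decade_shift") {
    # catch composition shifts: in the target decade the heaviest
    # landings move onto the functionally most distinct species (largest
    # nearest-neighbour distance in trait space - the bearers of unusual
    # trait combinations), while the multiset of totals stays comparable.
    # effect_size scales how deterministically rank follows distinctness.
    iso <- .trait_isolation(pool)
    score <- config$effect_size * scale(iso)[, 1] + rnorm(length(iso))
    shifted <- sort(base, decreasing = TRUE)[rank(-score,
                                                  ties.method = "first")]
    w <- ifelse(target, w / base[i] * shifted[i], w)
  } else if (config$effect == "dominance_shift") {
    w <- ifelse(target, w^(1 + config$effect_size), w)
  }
  grid$weight_kg <- w
  grid[grid$weight_kg > 0, ]
}

# functional distinctness of each pool species: nearest-neighbour
# distance in the combined trait space
.trait_isolation <- function(pool) {
  D <- as.matrix(trait_distance(code_traits(pool)))
  diag(D) <- NA
  apply(D, 1, min, na.rm = TRUE)
}

#' Run one synthetic scenario end to end
#'
#' Convenience wrapper: generates pool and landings and returns both with
#' the coded matrix.
#'
#' @param config A [scenario_config()].
#' @param schema A [trait_schema()].
#' @return A list: `pool` (trait records), `coded` (`coded_traits`),
#'   `landings` (records tibble), `config`.
#' @export
simulate_scenario <- function(config, schema = trait_schema()) {
  pool <- simulate_pool(config, schema)
  list(pool = pool, coded = code_traits(pool, schema),
       landings = simulate_landings(pool, config), config = config)
}
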