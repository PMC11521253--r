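test_that("FRic equals independent hull-area oracles on small fixtures", {
  # unit square corners in 2 axes
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(functional_richness(sq)$volume, 1)
  # degenerate: 3 collinear species in 2 axes
  lin <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_true(functional_richness(lin)$degenerate)
  # random 2-D clouds vs the shoelace oracle
  set.seed(51)
  for (rep in 1:5) {
    pts <- matrix(runif(20), 10, 2)
    expect_equal(functional_richness(pts)$volume, oracle_area2d(pts),
                 tolerance = 1e-9)
  }
})

test_that("FRic standardisation maps the pool to 1 and halves to halves", {
  expect_equal(standardize_fric(1, 1), 1)
  expect_equal(standardize_fric(0.25, 0.5), 0.5)
  expect_error(standardize_fric(1, 0), "positive")
})

test_that("FEve analytic limits and hand-computed branch cases", {
  # equally spaced collinear species, equal weights -> exactly 1
  line <- cbind(0:4, rep(0, 5))
  expect_equal(functional_evenness(line, rep(1, 5)), 1, tolerance = 1e-12)
  # 3 species with branch PEW (0.9, 0.1):
  # FEve = (min(.9,.5) + min(.1,.5) - .5) / (1 - .5) = 0.2
  # realised by collinear points 0, 1, 10 with weights making
  # EW proportional to (9, 1): d = (1, 9), weights equal -> EW = (0.5, 4.5)
  coords <- cbind(c(0, 1, 10), c(0, 0, 0))
  expect_equal(functional_evenness(coords, c(1, 1, 1)), 0.2,
               tolerance = 1e-12)
  # weight concentrated on one species of an equilateral triad -> < 1
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_lt(functional_evenness(tri, c(10, 1, 1)), 1)
  # undefined below 3 species
  expect_true(is.na(functional_evenness(line[1:2, ], c(1, 1))))
})

test_that("FDiv analytic limits and direct-formula agreement", {
  # regular polygon, any weights -> exactly 1
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  poly <- cbind(cos(th), sin(th))
  for (w in list(rep(1, 6), c(5, 1, 1, 1, 1, 3)))
    expect_equal(functional_divergence(poly, w), 1, tolerance = 1e-12)
  # weight concentrated near the centre pulls FDiv below 0.5
  conf <- rbind(c(0, 0.01), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_lt(functional_divergence(conf, c(100, 1, 1, 1, 1)), 0.5)
  # random configurations match the independent three-sum oracle
  set.seed(52)
  for (rep in 1:5) {
    pts <- matrix(rnorm(24), 12, 2)
    w <- runif(12)
    expect_equal(functional_divergence(pts, w), oracle_fdiv(pts, w),
                 tolerance = 1e-9)
  }
})

test_that("FDis limits, scaling laws and rigid-motion invariance", {
  expect_equal(functional_dispersion(matrix(c(1, 2), 1, 2), 1), 0)
  # two species, equal weights, distance d -> d/2
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(functional_dispersion(two, c(1, 1)), 2.5)
  # weights (3, 1) at distance 1 -> 0.375
  pair <- rbind(c(0, 0), c(1, 0))
  expect_equal(functional_dispersion(pair, c(3, 1)), 0.375)
  set.seed(53)
  pts <- matrix(rnorm(20), 10, 2)
  w <- runif(10)
  f0 <- functional_dispersion(pts, w)
  expect_equal(f0, oracle_fdis(pts, w), tolerance = 1e-12)
  # rotation + translation invariance; linear scaling
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(functional_dispersion(pts %*% R + 5, w), f0,
               tolerance = 1e-9)
  expect_equal(functional_dispersion(pts * 3.5, w), 3.5 * f0,
               tolerance = 1e-9)
})

test_that("all four metrics match brute-force oracles on a 20-species pool", {
  sc <- simulate_scenario(scenario_config(n_species = 20, seed = 54))
  agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
  w <- dplyr::filter(agg, fleet == "local")
  ord <- trait_pcoa(trait_distance(sc$coded))
  m <- retain_axes(20)
  coords <- ord$coordinates[w$species, seq_len(m)]
  fd <- compute_fd(sc$coded, tibble::tibble(species = w$species,
                                            weight = w$weight),
                   functions = "all")
  expect_equal(fd$feve, oracle_feve(coords, w$weight), tolerance = 1e-9)
  expect_equal(fd$fdiv, oracle_fdiv(coords, w$weight), tolerance = 1e-9)
  expect_equal(fd$fdis, oracle_fdis(coords, w$weight), tolerance = 1e-9)
  expect_equal(fd$fric_raw, scipy_hull(unique(coords))$volume,
               tolerance = 1e-9)
})

test_that("compute_fd fills the descriptive fields and flags", {
  sc <- simulate_scenario(scenario_config(n_species = 18, seed = 55))
  agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
  w <- dplyr::filter(agg, fleet == "coastal")
  fd <- compute_fd(sc$coded, tibble::tibble(species = w$species,
                                            weight = w$weight))
  expect_equal(nrow(fd), 5)          # four functions + combined
  expect_equal(unique(fd$nbsp), 18)
  expect_true(all(fd$sing_sp <= fd$nbsp & fd$sing_sp >= 1))
  expect_true(all(fd$quali_fric > 0 & fd$quali_fric <= 1))
  # full pool present -> standardised FRic exactly 1
  expect_equal(fd$fric_std, rep(1, 5))
  expect_true(all(fd$feve >= 0 & fd$feve <= 1, na.rm = TRUE))
  expect_true(all(fd$fdiv >= 0 & fd$fdiv <= 1, na.rm = TRUE))
  # unknown species rejected
  expect_error(compute_fd(sc$coded, c(ghost = 1)), "not in pool")
})

test_that("identical-trait assemblages collapse to one entity with zero FDis", {
  tt <- make_traits(4, seed = 56)
  tt10 <- tt[rep(1, 10), ]
  tt10$species <- sprintf("d%02d", 1:10)
  m <- code_traits(tt10)
  fd <- compute_fd(m, setNames(runif(10) + 0.1, tt10$species),
                   functions = "all", m = 2)
  expect_equal(fd$sing_sp, 1)
  expect_equal(fd$fdis, 0)
  expect_match(fd$flags, "degenerate")
})

test_that("FEve and FDiv stay in [0, 1] over many random configurations", {
  set.seed(57)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    d <- sample(2:4, 1)
    pts <- matrix(rnorm(n * d), n, d)
    w <- runif(n)
    fe <- functional_evenness(pts, w)
    fv <- functional_divergence(pts, w)
    expect_true(is.na(fe) || (fe >= 0 && fe <= 1))
    expect_true(is.na(fv) || (fv >= 0 && fv <= 1))
  }
})

test_that("FRic is monotone under species addition and duplicate-proof", {
  set.seed(58)
  pts <- matrix(rnorm(30), 15, 2)
  v0 <- functional_richness(pts[1:10, ])$volume
  v1 <- functional_richness(pts)$volume
  expect_gte(v1, v0)
  expect_equal(functional_richness(rbind(pts, pts[3, ]))$volume, v1)
})
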