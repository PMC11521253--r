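test_that("FCA eigenvalues match the brute-force CA oracle and ade4", {
  m <- code_traits(make_traits(15, seed = 31))
  f <- trait_fca(m, n_axes = 4)

  X <- unclass(m)
  X <- X[, colSums(X) > 0]
  expect_equal(f$all_eigenvalues,
               oracle_ca_eigenvalues(X)[seq_along(f$all_eigenvalues)],
               tolerance = 1e-9)

  # ade4's fuzzy CA of the same table (the field-standard implementation)
  b <- attr(m, "blocks")
  blo <- rep(seq_len(nrow(b)), b$end - b$start + 1L)
  keep <- colSums(unclass(m)) > 0
  fz <- ade4::prep.fuzzy.var(as.data.frame(unclass(m)[, keep]),
                             as.vector(table(blo[keep])))
  dd <- ade4::dudi.fca(fz, scannf = FALSE, nf = 4)
  expect_equal(f$eigenvalues, dd$eig[1:4], tolerance = 1e-9)
  expect_equal(f$total_inertia, sum(dd$eig), tolerance = 1e-9)
})

test_that("FCA invariants: inertia decomposition and weighted centring", {
  for (seed in c(7, 8)) {
    m <- code_traits(make_traits(12, seed = seed))
    f <- trait_fca(m)
    # per-axis modality contributions sum to 1
    expect_equal(unname(colSums(f$inertia_contributions)),
                 rep(1, ncol(f$inertia_contributions)), tolerance = 1e-9)
    # total inertia equals the full eigenvalue sum
    expect_equal(f$total_inertia, sum(f$all_eigenvalues),
                 tolerance = 1e-9)
    # species coordinates have (equal-mass) mean zero
    expect_true(all(abs(colMeans(f$species_coords)) < 1e-9))
    # eigenvalues non-negative, descending
    expect_true(all(diff(f$eigenvalues) <= 1e-12))
    expect_true(all(f$eigenvalues >= 0))
  }
})

test_that("a constant table yields zero inertia and empty correlations", {
  tt <- tiny_traits()[c(1, 2, 1), ]  # identical rows
  tt$species <- c("a", "b", "c")
  tt$body_shape <- "Fusi"
  tt$diet <- "Tele"
  f <- trait_fca(code_traits(tt))
  expect_equal(f$total_inertia, 0)
  expect_equal(length(f$eigenvalues), 0)
  expect_equal(nrow(f$modality_correlations), 0)
})

test_that("modality-axis correlations behave as Pearson r on affinities", {
  m <- code_traits(make_traits(14, seed = 33))
  f <- trait_fca(m)
  co <- modality_axis_correlation(f, 1)
  X <- unclass(m)[, colSums(unclass(m)) > 0]
  # spot-check several modalities against stats::cor directly
  for (j in c(1, 5, 11)) {
    nm <- colnames(X)[j]
    expected <- if (sd(X[, j]) == 0) NA_real_ else
      cor(X[, j], f$species_coords[, 1])
    row <- co[paste(co$trait, co$modality, sep = ".") == nm, ]
    expect_equal(row$r, expected, tolerance = 1e-12)
    expect_equal(row$r_squared, expected^2, tolerance = 1e-12)
  }
  # a constant modality is flagged undefined
  expect_true(all(is.na(co$r[co$flag == "zero_variance"])))
  expect_error(modality_axis_correlation(f, 99), "not retained")
})

test_that("anti-aligned one-hot modality gives r = -1 on a 2-group table", {
  # a single binary trait splitting 4 species into two groups: the two
  # modality columns correlate +1 and -1 with the single axis
  x <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  blocks <- tibble::tibble(trait = "tA", coding = "crisp",
                           start = 1L, end = 2L,
                           functions = list("feeding"))
  m <- make_coded(x, blocks)
  f <- trait_fca(m)
  co <- modality_axis_correlation(f, 1)
  expect_equal(sort(co$r), c(-1, 1), tolerance = 1e-9)
  expect_equal(co$r_squared, c(1, 1), tolerance = 1e-9)
})

test_that("tidiers and autoplot expose the FCA tables", {
  f <- trait_fca(code_traits(make_traits(12, seed = 35)))
  expect_equal(nrow(tidy(f, "eigenvalues")), length(f$eigenvalues))
  expect_equal(sum(tidy(f, "eigenvalues")$proportion) *
                 f$total_inertia,
               sum(f$eigenvalues), tolerance = 1e-9)
  sp <- tidy(f, "species")
  expect_equal(nrow(sp), length(f$species) * ncol(f$species_coords))
  g <- glance(f)
  expect_equal(g$n_axes, ncol(f$species_coords))
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
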