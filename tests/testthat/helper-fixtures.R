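# Small builders shared across the suite. Everything is generated in code.

# a coded_traits object built directly from a numeric matrix + block spec;
# bypasses trait records for geometric tests
make_coded <- function(x, blocks) {
  rownames(x) <- rownames(x) %||% sprintf("sp%02d", seq_len(nrow(x)))
  fdlandings:::new_coded_traits(x, blocks, trait_schema())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a valid trait record table for n species drawn from the reference schema
# (deterministic given seed)
make_traits <- function(n, seed = 1) {
  out <- simulate_pool(scenario_config(n_species = max(n, 10),
                                       seed = seed))[seq_len(n), ]
  attr(out, "depth_score") <- NULL
  out
}

# tiny hand-built trait table: 3 species over the reference schema with
# known values (species a and b identical)
tiny_traits <- function() {
  sch <- trait_schema()
  tl <- schema_traits(sch)
  first_mod <- vapply(tl$trait, function(tr)
    sch$modality[sch$trait == tr][1], character(1))
  df <- tibble::tibble(species = c("a", "b", "c"))
  for (tr in tl$trait) df[[tr]] <- rep(first_mod[[tr]], 3)
  df$diet <- c("Tele;Ceph", "Tele;Ceph", "Zoop")
  df$body_shape <- c("Fusi", "Fusi", "Eeli")
  df
}

# landings records tibble with explicit fields
make_records <- function(species, year, month = 6, fleet = "local",
                         weight_kg = 100) {
  tibble::tibble(species = species, year = year, month = month,
                 fleet = fleet, weight_kg = weight_kg)
}
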