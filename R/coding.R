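#' Code species trait records into the merged binary/fuzzy matrix
#'
#' Turns a validated species-by-trait table into the block-structured
#' species x modality affinity matrix ("bin-fuzzy" matrix) used by all
#' downstream stages. Crisp traits are one-hot coded; fuzzy traits are
#' coded as frequencies over the assigned modality set (an unweighted set
#' of k items becomes 1/k each; user-supplied weights, `"Tele:2;Ceph:1"`,
#' are renormalised to sum to one). Every trait block row therefore sums
#' to exactly one, and blocks are concatenated in schema order.
#'
#' @param traits A data frame of species trait records (see
#'   [validate_traits()] for the contract). Records failing validation are
#'   rejected with the violation list in the error message.
#' @param schema A [trait_schema()].
#' @return A `coded_traits` object: a numeric species x modality matrix
#'   with row names (species) and `"trait.modality"` column names, plus a
#'   `blocks` attribute (tibble: `trait`, `coding`, `start`, `end`,
#'   `functions`) and the `schema` used.
#' @examples
#' pool <- simulate_pool(scenario_config(n_species = 12, seed = 1))
#' m <- code_traits(pool)
#' dim(m)  # 12 x 76
#' @export
code_traits <- function(traits, schema = trait_schema()) {
  viol <- validate_traits(traits, schema)
  if (nrow(viol) > 0) {
    msg <- utils::capture.output(print(viol, n = 10))
    stop("invalid trait records (", nrow(viol), " violation(s)):\n",
         paste(msg, collapse = "\n"), call. = FALSE)
  }
  if (nrow(traits) < 1) stop("need at least one species", call. = FALSE)
  species <- traits$species
  tl <- schema_traits(schema)
  blocks <- list()
  start <- 1L
  cols <- list()
  for (k in seq_len(nrow(tl))) {
    tr <- tl$trait[k]
    mods <- schema$modality[schema$trait == tr]
    B <- matrix(0, nrow(traits), length(mods),
                dimnames = list(species, paste(tr, mods, sep = ".")))
    if (tl$coding[k] == "crisp") {
      B[cbind(seq_len(nrow(traits)), match(traits[[tr]], mods))] <- 1
    } else {
      for (i in seq_len(nrow(traits))) {
        it <- .parse_fuzzy(traits[[tr]][i])
        B[i, match(it$modality, mods)] <- it$weight / sum(it$weight)
      }
    }
    cols[[k]] <- B
    blocks[[k]] <- tibble::tibble(
      trait = tr, coding = tl$coding[k], start = start,
      end = start + length(mods) - 1L, functions = tl$functions[k])
    start <- start + length(mods)
  }
  new_coded_traits(do.call(cbind, cols), dplyr::bind_rows(blocks), schema)
}

new_coded_traits <- function(x, blocks, schema) {
  structure(x, blocks = blocks, schema = schema,
            class = c("coded_traits", "matrix", "array"))
}

#' @export
print.coded_traits <- function(x, ...) {
  b <- attr(x, "blocks")
  cat("<coded_traits> ", nrow(x), " species x ", ncol(x),
      " modalities in ", nrow(b), " trait blocks (",
      sum(b$coding == "fuzzy"), " fuzzy)\n", sep = "")
  invisible(x)
}

#' Tidy a coded trait matrix into long format
#'
#' @param x A `coded_traits` matrix.
#' @param ... Unused.
#' @return A tibble with columns `species`, `trait`, `modality`,
#'   `affinity` (zero affinities included).
#' @exportS3Method tibble::as_tibble
as_tibble.coded_traits <- function(x, ...) {
  b <- attr(x, "blocks")
  trait <- rep(b$trait, b$end - b$start + 1L)
  modality <- sub("^[^.]*\\.", "", colnames(x))
  tibble::tibble(
    species = rep(rownames(x), times = ncol(x)),
    trait = rep(trait, each = nrow(x)),
    modality = rep(modality, each = nrow(x)),
    affinity = as.vector(unclass(x)))
}

#' Restrict a coded matrix to one ecosystem function
#'
#' Keeps the trait blocks whose definition lists the requested function
#' (a trait serving several functions appears in each of its functions'
#' subsets). Block row sums are preserved.
#'
#' @param coded A `coded_traits` matrix from [code_traits()].
#' @param fun One of [fd_functions], or `"all"` (returns `coded` itself).
#' @return A `coded_traits` matrix with the selected blocks, in schema
#'   order.
#' @export
subset_by_function <- function(coded, fun) {
  stopifnot(inherits(coded, "coded_traits"))
  fun <- match.arg(fun, c(fd_functions, "all"))
  if (fun == "all") return(coded)
  b <- attr(coded, "blocks")
  keep <- purrr::map_lgl(b$functions, ~ fun %in% .x)
  if (!any(keep)) stop("no trait block carries function '", fun, "'",
                       call. = FALSE)
  bk <- b[keep, ]
  idx <- unlist(purrr::map2(bk$start, bk$end, seq))
  x <- unclass(coded)[, idx, drop = FALSE]
  width <- bk$end - bk$start + 1L
  bk$end <- cumsum(width)
  bk$start <- bk$end - width + 1L
  sch <- attr(coded, "schema")
  new_coded_traits(x, bk, sch[sch$trait %in% bk$trait, ])
}

#' Functional entities: groups of species with identical trait profiles
#'
#' Species whose coded rows are exactly equal form one functional entity
#' (FE). The number of entities in an assemblage is the `sing.sp`
#' statistic (species functionally different in the landings).
#'
#' @param coded A `coded_traits` matrix (often a function subset).
#' @return A tibble with columns `species` and `entity` (integer id,
#'   numbered by first occurrence).
#' @examples
#' pool <- simulate_pool(scenario_config(n_species = 10, seed = 1))
#' fe <- functional_entities(code_traits(pool))
#' dplyr::n_distinct(fe$entity)  # sing.sp
#' @export
functional_entities <- function(coded) {
  stopifnot(inherits(coded, "coded_traits"), nrow(coded) >= 1)
  key <- apply(unclass(coded), 1, paste, collapse = "\r")
  tibble::tibble(species = rownames(coded),
                 entity = match(key, unique(key)))
}

#' @rdname functional_entities
#' @return `n_entities()` returns the entity count (`sing.sp`) directly.
#' @export
n_entities <- function(coded) max(functional_entities(coded)$entity)
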