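# Reference trait registry: 14 traits, 76 modalities, 4 functions.
# Interval traits use canonical ASCII strings with unit suffixes; the
# growth-coefficient and fecundity bins are encoded so each trait's bins
# partition the positive line.
.reference_traits <- list(
  water_column_position = list(
    coding = "crisp", functions = "habitat_use",
    modalities = c("Batd", "Batp", "Benp", "Deme", "Pene", "Peoc", "Reas")),
  temperature_preference = list(
    coding = "crisp", functions = "habitat_use",
    modalities = c("<10C", "10-15C", "15-20C", "20-25C", ">25C")),
  max_depth = list(
    coding = "crisp", functions = "habitat_use",
    modalities = c("<500m", "500-1000m", "1000-1500m", "1500-2000m", ">2000m")),
  swimming_mode = list(
    coding = "crisp", functions = "locomotion",
    modalities = c("Amii", "Angu", "Bali", "Cara", "Labr", "Raji", "Subc",
                   "Tetr", "Thun")),
  body_shape = list(
    coding = "crisp", functions = c("habitat_use", "locomotion"),
    modalities = c("Eeli", "Elon", "Flat", "Fusi", "Shde")),
  max_body_size = list(
    coding = "crisp", functions = c("feeding", "life_history", "locomotion"),
    modalities = c("<100cm", "100-200cm", "200-300cm", "300-400cm", ">400cm")),
  trophic_position = list(
    coding = "crisp", functions = c("habitat_use", "feeding"),
    modalities = c("<2.5", "2.5-3.5", "3.5-4.5", ">4.5")),
  diet = list(
    coding = "fuzzy", functions = c("habitat_use", "feeding"),
    modalities = c("Binv", "Ceph", "Chon", "Crde", "Detr", "Herb", "Tele",
                   "Zoop")),
  generation_time = list(
    coding = "crisp", functions = "life_history",
    modalities = c("<5y", "5-10y", "10-15y", ">15y")),
  growth_coefficient = list(
    coding = "crisp", functions = "life_history",
    modalities = c("<0.3", "0.3-0.6", "0.6-0.9", ">0.9")),
  food_consumption = list(
    coding = "crisp", functions = c("habitat_use", "feeding"),
    modalities = c("<5QB", "5-10QB", "10-15QB", ">15QB")),
  maturity_size = list(
    coding = "crisp", functions = "life_history",
    modalities = c("<50cm", "50-100cm", "100-150cm", "150-200cm", ">200cm")),
  reproductive_guild = list(
    coding = "crisp", functions = "life_history",
    modalities = c("Bear", "Guar", "Mixe", "Ngua")),
  fecundity = list(
    coding = "crisp", functions = "life_history",
    modalities = c("<10", "10-1e2", "1e2-1e3", "1e3-1e4", "1e4-1e5",
                   "1e5-1e6", ">1e6"))
)

#' Build a trait schema
#'
#' A trait schema is a tibble with one row per (trait, modality) pair and
#' columns `trait`, `coding` (`"crisp"` or `"fuzzy"`), `modality` and
#' `functions` (a list-column of ecosystem function tags). The default,
#' `trait_schema()`, returns the reference fish-trait registry: 14 traits
#' and 76 modalities spanning habitat use, locomotion, feeding and life
#' history, with each function represented by at least four modalities.
#' Crisp traits take exactly one modality per species; the single fuzzy
#' trait (diet) takes a set of modalities coded as affinities.
#'
#' @param traits A named list defining a custom schema: each element is a
#'   list with components `coding`, `functions` and `modalities`. Defaults
#'   to the reference registry.
#' @return A tibble of class `trait_schema`.
#' @examples
#' sch <- trait_schema()
#' dplyr::n_distinct(sch$trait)  # 14
#' nrow(sch)                     # 76
#' @export
trait_schema <- function(traits = .reference_traits) {
  stopifnot(is.list(traits), length(traits) >= 1, !is.null(names(traits)))
  if (anyDuplicated(names(traits)))
    stop("trait names must be unique", call. = FALSE)
  rows <- purrr::imap(traits, function(tr, nm) {
    stopifnot(tr$coding %in% c("crisp", "fuzzy"))
    if (length(tr$modalities) == 0 || anyDuplicated(tr$modalities))
      stop("trait '", nm, "': modalities must be non-empty and unique",
           call. = FALSE)
    if (length(tr$functions) == 0)
      stop("trait '", nm, "': functions must be non-empty", call. = FALSE)
    bad <- setdiff(tr$functions, fd_functions)
    if (length(bad))
      stop("trait '", nm, "': unknown function tag(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    tibble::tibble(
      trait = nm, coding = tr$coding, modality = tr$modalities,
      functions = rep(list(tr$functions), length(tr$modalities)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trait_schema", class(out))
  out
}

#' Summarise a schema at the trait level
#'
#' @param schema A [trait_schema()].
#' @return A tibble with one row per trait: `trait`, `coding`,
#'   `n_modalities` and `functions` (list-column).
#' @export
schema_traits <- function(schema) {
  schema |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(coding = .data$coding[1],
                     n_modalities = dplyr::n(),
                     functions = .data$functions[1],
                     .groups = "drop") |>
    # preserve schema (registry) order rather than alphabetical
    dplyr::arrange(match(.data$trait, unique(schema$trait)))
}

#' Traits belonging to an ecosystem function
#'
#' @param schema A [trait_schema()].
#' @param fun One of [fd_functions], or `"all"`.
#' @return Character vector of trait names, in schema order.
#' @export
schema_function_traits <- function(schema, fun) {
  fun <- match.arg(fun, c(fd_functions, "all"))
  tl <- schema_traits(schema)
  if (fun == "all") return(tl$trait)
  tl$trait[purrr::map_lgl(tl$functions, ~ fun %in% .x)]
}

#' Validate species trait records against a schema
#'
#' Checks a species-by-trait table: every schema trait must be present as
#' a column, every crisp value must be a single known modality, every
#' fuzzy value a non-empty semicolon-separated set of known modalities
#' (optionally weighted, `"Tele:2;Ceph:1"`), species names unique, and no
#' missing values. Violations are returned as data, not raised.
#'
#' @param traits A data frame with a `species` column and one column per
#'   schema trait (see [read_trait_table()] for the file dialect).
#' @param schema A [trait_schema()].
#' @return A tibble of violations with columns `species`, `trait`,
#'   `problem`; zero rows when the table is valid.
#' @export
validate_traits <- function(traits, schema = trait_schema()) {
  stopifnot(is.data.frame(traits))
  v <- list()
  note <- function(species, trait, problem)
    tibble::tibble(species = species, trait = trait, problem = problem)
  if (!"species" %in% names(traits)) {
    return(note(NA_character_, NA_character_, "missing 'species' column"))
  }
  dup <- unique(traits$species[duplicated(traits$species)])
  if (length(dup))
    v <- c(v, list(note(dup, NA_character_, "duplicate species name")))
  tl <- schema_traits(schema)
  for (k in seq_len(nrow(tl))) {
    tr <- tl$trait[k]
    if (!tr %in% names(traits)) {
      v <- c(v, list(note(NA_character_, tr, "missing trait column")))
      next
    }
    vals <- traits[[tr]]
    mods <- schema$modality[schema$trait == tr]
    na <- is.na(vals) | !nzchar(trimws(as.character(vals)))
    if (any(na))
      v <- c(v, list(note(traits$species[na], tr, "missing value")))
    if (tl$coding[k] == "crisp") {
      bad <- !na & !(as.character(vals) %in% mods)
      if (any(bad))
        v <- c(v, list(note(traits$species[bad], tr, paste0(
          "modality not in trait ('", as.character(vals)[bad], "')"))))
    } else {
      for (i in which(!na)) {
        items <- .parse_fuzzy(vals[i])
        if (length(items$modality) == 0) {
          v <- c(v, list(note(traits$species[i], tr, "empty modality set")))
        } else {
          bad <- setdiff(items$modality, mods)
          if (length(bad))
            v <- c(v, list(note(traits$species[i], tr, paste0(
              "modality not in trait ('", paste(bad, collapse = ","), "')"))))
          if (any(items$weight <= 0) || anyDuplicated(items$modality))
            v <- c(v, list(note(traits$species[i], tr,
                                "invalid fuzzy weights or duplicates")))
        }
      }
    }
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(species = character(), trait = character(),
                   problem = character())
}

# Parse "Tele;Ceph" or "Tele:2;Ceph:1" into modality/weight vectors.
.parse_fuzzy <- function(x) {
  parts <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  has_w <- grepl(":", parts, fixed = TRUE)
  modality <- ifelse(has_w, sub(":.*$", "", parts), parts)
  weight <- rep(1, length(parts))
  weight[has_w] <- suppressWarnings(as.numeric(sub("^.*:", "", parts[has_w])))
  weight[is.na(weight)] <- -1  # flagged invalid downstream
  list(modality = trimws(modality), weight = weight)
}

#' Read a species trait table
#'
#' Reads a CSV/TSV trait table (UTF-8, header row mandatory): one row per
#' species, a `species` column, one column per crisp trait holding a
#' modality code, and a fuzzy-trait column (e.g. `diet`) holding
#' semicolon-separated modality codes.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A tibble of species trait records.
#' @export
read_trait_table <- function(path) {
  reader <- if (grepl("\\.tsv$|\\.txt$", path)) readr::read_tsv else
    readr::read_csv
  reader(path, col_types = readr::cols(.default = readr::col_character()),
         progress = FALSE)
}

#' Export / import a trait schema
#'
#' The schema is serialised as a structured YAML document listing, for each
#' trait, its coding kind, ecosystem functions and ordered modalities. The
#' round trip `read_trait_schema(write_trait_schema(s, f))` reproduces the
#' schema exactly.
#'
#' @param schema A [trait_schema()].
#' @param path Output (input) file path.
#' @return `write_trait_schema()` returns `path` invisibly;
#'   `read_trait_schema()` returns a [trait_schema()].
#' @export
write_trait_schema <- function(schema, path) {
  tl <- schema_traits(schema)
  doc <- purrr::map(seq_len(nrow(tl)), function(k) list(
    coding = tl$coding[k],
    functions = as.list(tl$functions[[k]]),
    modalities = as.list(schema$modality[schema$trait == tl$trait[k]])))
  names(doc) <- tl$trait
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_trait_schema
#' @export
read_trait_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  trait_schema(purrr::map(doc, function(tr) list(
    coding = tr$coding,
    functions = unlist(tr$functions),
    modalities = unlist(tr$modalities))))
}
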