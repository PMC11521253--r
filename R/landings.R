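#' Decade definitions for landings aggregation
#'
#' Default decades partition 1980-2020: `80s` = 1980-1989, `90s` =
#' 1990-1999, `00s` = 2000-2009 and `10s` = 2010-2020 (2020 is folded
#' into the last decade so the 41st year is not orphaned).
#'
#' @param breaks Optional custom table with columns `decade`, `start`,
#'   `end`; ranges must be non-overlapping and contiguous.
#' @return A tibble: `decade`, `start`, `end`.
#' @export
decade_table <- function(breaks = NULL) {
  if (is.null(breaks))
    breaks <- tibble::tibble(
      decade = c("80s", "90s", "00s", "10s"),
      start = c(1980L, 1990L, 2000L, 2010L),
      end = c(1989L, 1999L, 2009L, 2020L))
  breaks <- tibble::as_tibble(breaks)
  stopifnot(all(c("decade", "start", "end") %in% names(breaks)),
            all(breaks$start <= breaks$end))
  o <- order(breaks$start)
  breaks <- breaks[o, ]
  if (nrow(breaks) > 1 &&
      any(breaks$start[-1] != breaks$end[-nrow(breaks)] + 1L))
    stop("decade ranges must partition the year span without gaps or ",
         "overlaps", call. = FALSE)
  breaks
}

#' All within-fleet decade pair labels
#'
#' @param decades A [decade_table()].
#' @return Tibble with columns `decade_a`, `decade_b`, one row per
#'   ordered pair (earlier first): 6 pairs for four decades.
#' @export
decade_pairs <- function(decades = decade_table()) {
  d <- decades$decade
  idx <- utils::combn(seq_along(d), 2)
  tibble::tibble(decade_a = d[idx[1, ]], decade_b = d[idx[2, ]])
}

#' Read and validate a landings table
#'
#' Reads a CSV/TSV of per-record landings with mandatory header columns
#' `species`, `year`, `month`, `fleet`, `weight_kg`. Malformed rows
#' (unknown fleet, year outside the configured span, month outside 1-12,
#' negative or unparseable weight, missing species) are excluded and
#' collected into a rejection report attached as the `"rejected"`
#' attribute (with line numbers and reasons); a warning summarises the
#' count.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param fleets Allowed fleet levels (default `local`/`coastal`).
#' @param years Allowed year range (default 1980-2020).
#' @return A tibble of validated [landings records][simulate_landings]:
#'   `species`, `year`, `month`, `fleet`, `weight_kg`.
#' @export
read_landings <- function(path, fleets = c("local", "coastal"),
                          years = c(1980L, 2020L)) {
  reader <- if (grepl("\\.tsv$|\\.txt$", path)) readr::read_tsv else
    readr::read_csv
  raw <- reader(path,
                col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  need <- c("species", "year", "month", "fleet", "weight_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("landings table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- raw[need]
  # strtod-based conversion is correctly rounding, so full-precision
  # weights survive the text round trip bit-for-bit
  raw$year <- suppressWarnings(as.numeric(raw$year))
  raw$month <- suppressWarnings(as.numeric(raw$month))
  raw$weight_kg <- suppressWarnings(as.numeric(raw$weight_kg))
  validate_landings(raw, fleets = fleets, years = years)
}

#' @rdname read_landings
#' @param records An in-memory landings tibble to validate.
#' @export
validate_landings <- function(records, fleets = c("local", "coastal"),
                              years = c(1980L, 2020L)) {
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(!nzchar(records$species) | is.na(records$species),
                "missing species")
  reason <- bad(records$year != as.integer(records$year) |
                  records$year < years[1] | records$year > years[2],
                "year out of range")
  reason <- bad(records$month != as.integer(records$month) |
                  records$month < 1 | records$month > 12,
                "month out of range")
  reason <- bad(!records$fleet %in% fleets, "unknown fleet")
  reason <- bad(records$weight_kg < 0, "negative weight")
  rejected <- records[!is.na(reason), ]
  rejected$line <- which(!is.na(reason)) + 1L  # header is line 1
  rejected$reason <- reason[!is.na(reason)]
  ok <- records[is.na(reason), ]
  ok$year <- as.integer(ok$year)
  ok$month <- as.integer(ok$month)
  if (nrow(rejected))
    warning(nrow(rejected), " landings record(s) rejected; see attr(x, ",
            "'rejected')", call. = FALSE)
  attr(ok, "rejected") <- rejected
  ok
}

#' Aggregate landings into assemblage totals
#'
#' Sums landed weight per species within each (fleet, decade) group, or
#' per fleet across the whole period. Species absent from a group get no
#' row (absence is distinct from zero weight).
#'
#' @param records Validated landings records.
#' @param by `"fleet_decade"` (default) or `"fleet"`.
#' @param decades A [decade_table()].
#' @return A tibble: `fleet`, (`decade`,) `species`, `total_kg`.
#' @export
aggregate_landings <- function(records, by = c("fleet_decade", "fleet"),
                               decades = decade_table()) {
  by <- match.arg(by)
  if (by == "fleet") {
    out <- records |>
      dplyr::group_by(.data$fleet, .data$species) |>
      dplyr::summarise(total_kg = sum(.data$weight_kg), .groups = "drop")
    return(dplyr::arrange(out, .data$fleet, .data$species))
  }
  idx <- purrr::map_int(records$year, function(y) {
    k <- which(decades$start <= y & y <= decades$end)
    if (length(k) != 1) NA_integer_ else k
  })
  if (anyNA(idx))
    stop("record year(s) outside the decade table", call. = FALSE)
  records$decade <- decades$decade[idx]
  records |>
    dplyr::group_by(.data$fleet, .data$decade, .data$species) |>
    dplyr::summarise(total_kg = sum(.data$weight_kg), .groups = "drop") |>
    dplyr::arrange(.data$fleet, match(.data$decade, decades$decade),
                   .data$species)
}

#' Min-max standardise landings weights to the 0-1 scale
#'
#' Applies \eqn{x' = (x - \min x) / (\max x - \min x)} to per-species
#' totals, either within each assemblage (fleet or fleet-decade group;
#' default) or over all totals globally. The least-landed species of a
#' group maps to exactly 0 (it stays *present*: downstream FD code keeps
#' zero-weight species for presence-based FRic). Groups where all totals
#' are equal (including single-species groups) get weight 1 for every
#' species and are flagged.
#'
#' @param agg Aggregated landings from [aggregate_landings()].
#' @param scope `"assemblage"` (per group; default) or `"global"`.
#' @return `agg` with extra columns `weight` (standardised, in \[0, 1\])
#'   and `constant_group` (logical flag).
#' @export
standardize_weights <- function(agg, scope = c("assemblage", "global")) {
  scope <- match.arg(scope)
  minmax <- function(x) {
    if (max(x) == min(x)) return(rep(1, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  gvars <- intersect(c("fleet", "decade"), names(agg))
  if (scope == "global") {
    agg$weight <- minmax(agg$total_kg)
    agg$constant_group <- max(agg$total_kg) == min(agg$total_kg)
    return(agg)
  }
  agg |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gvars))) |>
    dplyr::mutate(weight = minmax(.data$total_kg),
                  constant_group = max(.data$total_kg) ==
                    min(.data$total_kg)) |>
    dplyr::ungroup()
}
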