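#' Default column-name mapping for PBDB-style downloads
#'
#' Maps the standard field names used throughout formdiv to the candidate
#' header names found in Paleobiology Database occurrence downloads. For each
#' field the first candidate present in the file is used. `midage` may instead
#' be derived as the midpoint of `max_ma` and `min_ma` when no midage column
#' exists.
#'
#' @return A named list of character vectors (field -> candidate headers).
#' @export
#' @examples
#' pbdb_columns()$species
pbdb_columns <- function() {
  list(
    collection_id   = c("collection_id", "collection_no"),
    species         = c("species", "identified_name", "accepted_name"),
    formation       = c("formation"),
    midage          = c("midage", "mid_ma"),
    max_ma          = c("max_ma", "ma_max"),
    min_ma          = c("min_ma", "ma_min"),
    reference_id    = c("reference_id", "reference_no"),
    environment_raw = c("environment_raw", "environment"),
    paleolat        = c("paleolat", "paleolatdec"),
    paleolng        = c("paleolng", "paleolngdec")
  )
}

#' Normalize a binomial species name
#'
#' Species identity is the genus + epithet string after whitespace squashing
#' and case folding; no synonymization is attempted.
#'
#' @param x Character vector of identified names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_species("  Mucrospirifer   mucronatus ")
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Detect unclear genus identification
#'
#' The default predicate flags occurrences whose genus portion carries an
#' identification qualifier: `aff.`, `cf.`, `ex gr.`, a question mark, or
#' quotation marks. Qualifiers attached to the species epithet only (after the
#' first whitespace) are not treated as genus uncertainty.
#'
#' @param x Character vector of identified names (un-normalized).
#' @return Logical vector.
#' @export
#' @examples
#' genus_uncertain(c("cf. Lingula sp.", "Lingula cf. anatina", "Lingula anatina"))
genus_uncertain <- function(x) {
  x <- trimws(x)
  first <- sub("\\s.*$", "", x)
  qualified <- tolower(first) %in% c("aff.", "aff", "cf.", "cf", "ex", "?")
  marked <- grepl("[?\"']", first)
  qualified | marked
}

#' Read a PBDB-style occurrence table
#'
#' Reads a delimited (comma or tab) occurrence file and returns one row per
#' occurrence with standardized fields. Malformed values are never silently
#' dropped: rows with an unparseable or missing `midage` get
#' `flag = "missing_midage"`, rows with out-of-range or missing coordinates get
#' `flag = "missing_coords"` (coordinates are set to `NA` but the record is
#' kept; spread metrics simply ignore it). Vetting later removes
#' `missing_midage` records.
#'
#' @param path Path to a delimited text file.
#' @param col_map Header mapping, see [pbdb_columns()].
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.csv` -> comma, otherwise tab).
#' @param uncertain_fun Predicate used to flag unclear genus identification;
#'   defaults to [genus_uncertain()].
#' @return A tibble with columns `collection_id`, `species`, `genus_uncertain`,
#'   `formation`, `midage`, `reference_id`, `environment_raw`, `paleolat`,
#'   `paleolng`, `flag`.
#' @export
read_occurrences <- function(path, col_map = pbdb_columns(), delim = NULL,
                             uncertain_fun = genus_uncertain) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)

  pick <- function(field, required = TRUE) {
    hit <- intersect(col_map[[field]], names(raw))
    if (length(hit) == 0L) {
      if (required) abort(sprintf("required column for `%s` not found (looked for: %s)",
                                  field, paste(col_map[[field]], collapse = ", ")))
      return(rep(NA_character_, nrow(raw)))
    }
    raw[[hit[[1L]]]]
  }

  species_raw <- pick("species")
  midage <- suppressWarnings(as.numeric(pick("midage", required = FALSE)))
  if (all(is.na(midage))) {
    max_ma <- suppressWarnings(as.numeric(pick("max_ma", required = FALSE)))
    min_ma <- suppressWarnings(as.numeric(pick("min_ma", required = FALSE)))
    if (all(is.na(max_ma)) && all(is.na(min_ma)) && nrow(raw) > 0L) {
      abort("no usable age column: need `midage` or `max_ma` + `min_ma`")
    }
    midage <- (max_ma + min_ma) / 2
  }
  lat <- suppressWarnings(as.numeric(pick("paleolat", required = FALSE)))
  lng <- suppressWarnings(as.numeric(pick("paleolng", required = FALSE)))
  bad_coord <- is.na(lat) | is.na(lng) | abs(lat) > 90 | lng <= -180 | lng > 180
  lat[bad_coord] <- NA_real_
  lng[bad_coord] <- NA_real_

  occ <- tibble::tibble(
    collection_id = as.character(pick("collection_id")),
    species = normalize_species(species_raw),
    genus_uncertain = uncertain_fun(species_raw),
    formation = dplyr::na_if(trimws(as.character(pick("formation", required = FALSE))), ""),
    midage = midage,
    reference_id = as.character(pick("reference_id", required = FALSE)),
    environment_raw = as.character(pick("environment_raw", required = FALSE)),
    paleolat = lat,
    paleolng = lng
  )
  bad_age <- is.na(occ$midage) | occ$midage <= 0 | occ$midage > 541
  occ$flag <- dplyr::case_when(
    bad_age ~ "missing_midage",
    bad_coord ~ "missing_coords",
    TRUE ~ NA_character_
  )
  occ
}

#' The closed vocabulary of depositional-environment categories
#'
#' @return Character vector of the seven categories.
#' @export
environment_categories <- function() {
  c("reefal", "deep_subtidal", "shallow_subtidal", "marginal_marine",
    "slope", "basin", "unknown")
}

#' Default environment term-to-category mapping
#'
#' A best-effort mapping from PBDB depositional-environment vocabulary to the
#' seven analysis categories. Editable: the table ships as
#' `inst/extdata/environment_map.tsv`; pass your own tibble with columns
#' `term` and `category` to override.
#'
#' @return A tibble with columns `term`, `category`.
#' @export
default_environment_map <- function() {
  path <- system.file("extdata", "environment_map.tsv", package = "formdiv", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Standardize depositional-environment terms
#'
#' Total function: every raw term maps to exactly one category; terms absent
#' from the mapping (and `NA`) map to `"unknown"`.
#'
#' @param raw_term Character vector of free-text environment terms.
#' @param mapping Tibble with columns `term`, `category`.
#' @return Character vector of categories (see [environment_categories()]).
#' @export
#' @examples
#' standardize_environment(c("reef, buildup or bioherm", "lagoonal??"))
standardize_environment <- function(raw_term, mapping = default_environment_map()) {
  bad <- setdiff(unique(mapping$category), environment_categories())
  if (length(bad) > 0L) {
    abort(sprintf("mapping contains categories outside the vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  idx <- match(tolower(trimws(raw_term)), tolower(mapping$term))
  out <- mapping$category[idx]
  out[is.na(out)] <- "unknown"
  out
}

#' Default geological timescale
#'
#' Eleven Phanerozoic periods, Cambrian base at 541 Ma, Neogene extended to
#' the present. Ships as `inst/extdata/timescale.tsv`; supply your own tibble
#' (columns `period`, `older_ma`, `younger_ma`) for a different calibration.
#'
#' @return A tibble with columns `period`, `older_ma`, `younger_ma`.
#' @export
default_timescale <- function() {
  path <- system.file("extdata", "timescale.tsv", package = "formdiv", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cdd", progress = FALSE)
}

#' Assign geological periods from midages
#'
#' Uses the half-open convention `[older, younger)`: an age lying exactly on a
#' period boundary is assigned to the younger period.
#'
#' @param midage Numeric vector of ages in Ma; must lie in (0, 541].
#' @param timescale Boundary table, see [default_timescale()].
#' @return Character vector of period names.
#' @export
#' @examples
#' assign_period(c(300, 443.8))
assign_period <- function(midage, timescale = default_timescale()) {
  if (any(is.na(midage)) || any(midage <= 0) || any(midage > max(timescale$older_ma))) {
    abort(sprintf("midage must lie in (0, %s] Ma", max(timescale$older_ma)))
  }
  ts <- dplyr::arrange(timescale, dplyr::desc(.data$older_ma))
  out <- rep(NA_character_, length(midage))
  for (i in seq_len(nrow(ts))) {
    hit <- midage <= ts$older_ma[i] & midage > ts$younger_ma[i]
    out[hit] <- ts$period[i]
  }
  # boundary hits (midage == younger bound of some period) go to the younger
  # period; the strict > above already arranges this because the younger
  # period's older_ma equals that bound and the test is <=.
  out
}

#' Vet an occurrence table
#'
#' Applies, in order: (1) drop occurrences with unclear genus identification;
#' (2) drop occurrences lacking a formation assignment; (3) drop occurrences
#' whose collection is on a user-supplied exclusion list (the programmatic
#' stand-in for manual age revision); (4) drop collections left with fewer
#' than two distinct species; (5) drop formations left with fewer than
#' `min_collections` collections. Records flagged `missing_midage` at read
#' time are removed first (step 0). The per-step ledger is attached as the
#' `"report"` attribute and retrievable with [vetting_report()].
#'
#' @param occ Occurrence tibble from [read_occurrences()] (a `flag` column is
#'   optional; absent means no flagged records).
#' @param min_collections Minimum number of collections a formation must
#'   retain; default 26, i.e. strictly more than 25.
#' @param exclude Character vector of collection_ids to drop at step 3.
#' @return The vetted occurrence tibble with a `"report"` attribute.
#' @export
vet <- function(occ, min_collections = 26, exclude = NULL) {
  if (nrow(occ) == 0L) abort("no occurrence records supplied")
  check_number(min_collections, "min_collections", lower = 1)

  steps <- list()
  note <- function(x, step, what) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = step, rule = what, records_removed = nrow(occ) - nrow(x),
      records_remaining = nrow(x))
    x
  }

  if (!"flag" %in% names(occ)) occ$flag <- NA_character_
  kept <- note(dplyr::filter(occ, is.na(.data$flag) | .data$flag != "missing_midage"),
               0L, "missing or invalid midage")
  n0 <- nrow(occ); occ <- kept
  kept <- note(dplyr::filter(occ, !.data$genus_uncertain), 1L, "unclear genus identification")
  occ <- kept
  kept <- note(dplyr::filter(occ, !is.na(.data$formation)), 2L, "no formation assignment")
  occ <- kept
  kept <- note(dplyr::filter(occ, !(.data$collection_id %in% exclude)), 3L, "user exclusion list")
  occ <- kept
  multi <- occ |>
    dplyr::distinct(.data$collection_id, .data$species) |>
    dplyr::count(.data$collection_id) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::pull(.data$collection_id)
  kept <- note(dplyr::filter(occ, .data$collection_id %in% multi), 4L, "single-taxon collections")
  occ <- kept
  big <- occ |>
    dplyr::distinct(.data$formation, .data$collection_id) |>
    dplyr::count(.data$formation) |>
    dplyr::filter(.data$n >= min_collections) |>
    dplyr::pull(.data$formation)
  kept <- note(dplyr::filter(occ, .data$formation %in% big), 5L,
               sprintf("formations with fewer than %d collections", min_collections))
  occ <- kept

  if (nrow(occ) == 0L) abort("no analyzable formations remain after vetting")
  report <- dplyr::bind_rows(steps)
  stopifnot(n0 == nrow(occ) + sum(report$records_removed))
  occ <- dplyr::arrange(occ, .data$formation, .data$collection_id, .data$species)
  attr(occ, "report") <- report
  occ
}

#' Retrieve the vetting ledger
#'
#' @param occ A vetted occurrence tibble from [vet()].
#' @return Tibble with one row per vetting step: records removed and remaining.
#' @export
vetting_report <- function(occ) {
  rep <- attr(occ, "report")
  if (is.null(rep)) abort("no vetting report attached; was this table produced by vet()?")
  rep
}

#' Build the collections-by-species incidence matrix of one formation
#'
#' Incidence, not abundance: duplicate occurrences of a species in a
#' collection collapse to a single 1. Rows (collections) and columns (species)
#' are sorted so construction is order-stable.
#'
#' @param occ Occurrence tibble (normally vetted).
#' @param formation Formation name.
#' @return Binary integer matrix with collection ids as rownames and species
#'   as colnames.
#' @export
build_incidence <- function(occ, formation) {
  sub <- dplyr::filter(occ, .data$formation == .env$formation)
  if (nrow(sub) == 0L) abort(sprintf("unknown formation: %s", formation))
  colls <- sort(unique(sub$collection_id))
  spp <- sort(unique(sub$species))
  m <- matrix(0L, nrow = length(colls), ncol = length(spp),
              dimnames = list(colls, spp))
  m[cbind(match(sub$collection_id, colls), match(sub$species, spp))] <- 1L
  m
}

#' Per-formation metadata table
#'
#' Computes, for every formation present, the metadata the downstream screens
#' use: period (from the mean midage), mean midage, duration (max midage -
#' min midage over collections), `CollpF` (collections), `Environments`
#' (distinct standardized environment categories, `unknown` included),
#' `RefForm` (distinct references), geographic spread (`maxGCD`, `medianGCD`,
#' `coord_mad`, in km; `NA` when fewer than 2 collections carry coordinates),
#' and optionally `n_higher_taxa` via a genus-to-higher-taxon lookup.
#'
#' @param occ Occurrence tibble (normally vetted).
#' @param environment_map Term mapping, see [default_environment_map()].
#' @param timescale See [default_timescale()].
#' @param higher_taxa Optional tibble with columns `genus`, `taxon`; when
#'   given, `n_higher_taxa` counts distinct higher taxa among the formation's
#'   genera.
#' @return Tibble, one row per formation.
#' @export
formation_metadata <- function(occ, environment_map = default_environment_map(),
                               timescale = default_timescale(), higher_taxa = NULL) {
  occ$environment <- standardize_environment(occ$environment_raw, environment_map)
  per_coll <- occ |>
    dplyr::group_by(.data$formation, .data$collection_id) |>
    dplyr::summarise(
      midage = .data$midage[1L], paleolat = .data$paleolat[1L],
      paleolng = .data$paleolng[1L], .groups = "drop")
  meta <- per_coll |>
    dplyr::group_by(.data$formation) |>
    dplyr::summarise(
      mean_midage = mean(.data$midage),
      duration = max(.data$midage) - min(.data$midage),
      CollpF = dplyr::n(),
      spread = list(formation_spread(.data$paleolat, .data$paleolng)),
      .groups = "drop") |>
    tidyr::unnest("spread")
  env_ref <- occ |>
    dplyr::group_by(.data$formation) |>
    dplyr::summarise(
      Environments = dplyr::n_distinct(.data$environment),
      RefForm = dplyr::n_distinct(.data$reference_id),
      .groups = "drop")
  meta <- dplyr::left_join(meta, env_ref, by = "formation")
  meta$Period <- assign_period(meta$mean_midage, timescale)
  if (!is.null(higher_taxa)) {
    gen <- occ |>
      dplyr::mutate(genus = sub(" .*$", "", .data$species)) |>
      dplyr::left_join(dplyr::mutate(higher_taxa, genus = tolower(.data$genus)),
                       by = "genus") |>
      dplyr::group_by(.data$formation) |>
      dplyr::summarise(n_higher_taxa = dplyr::n_distinct(.data$taxon[!is.na(.data$taxon)]),
                       .groups = "drop")
    meta <- dplyr::left_join(meta, gen, by = "formation")
  }
  dplyr::select(meta, "formation", "Period", "mean_midage", "duration",
                "CollpF", "Environments", "RefForm", "maxGCD", "medianGCD",
                "coord_mad", dplyr::any_of("n_higher_taxa"))
}
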