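#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks for ties; p from the large-sample t approximation (adequate
#' at the sample sizes of formation tables).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) abort("need at least 4 complete pairs")
  if (var(x) == 0 || var(y) == 0) abort("Spearman's rho is undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Confounder screen: metadata vs diversity estimates
#'
#' Full grid of Spearman tests of every potentially confounding metadata
#' factor against every subsampled diversity estimate.
#'
#' @param table Estimate + metadata tibble from [run_all_formations()].
#' @param factors Metadata columns to screen; `n_higher_taxa` is used only
#'   when present.
#' @param metrics Diversity estimate columns.
#' @return Tibble with one row per factor x metric: `factor`, `metric`,
#'   `rho`, `p_value`, `n`.
#' @export
confounder_screen <- function(table,
                              factors = c("RefForm", "CollpF", "Environments",
                                          "duration", "n_higher_taxa"),
                              metrics = c("AlphaForm", "BetaWForm",
                                          "BetaSimForm", "GammaForm")) {
  factors <- if ("n_higher_taxa" %in% factors && !"n_higher_taxa" %in% names(table)) {
    setdiff(factors, "n_higher_taxa")
  } else factors
  missing <- setdiff(c(factors, metrics), names(table))
  if (length(missing) > 0L) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(factor = factors, metric = metrics)
  res <- purrr::pmap(grid, function(factor, metric) {
    tryCatch(spearman_rho(table[[factor]], table[[metric]]),
             error = function(e) {
               # constant factor (or too few pairs): undefined, not fatal
               tibble::tibble(rho = NA_real_, p_value = NA_real_,
                              n = sum(is.finite(table[[factor]]) &
                                        is.finite(table[[metric]])))
             })
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Drop formations dominated by monographic contributions
#'
#' Taxon-specific monographs can split one fauna across many database
#' collections, inflating apparent beta diversity. This filter keeps only
#' formations with at most `max_refs` contributing references so the analysis
#' can be re-run as a sensitivity check.
#'
#' @param dataset Estimate (or metadata) tibble with a `RefForm` column.
#' @param max_refs Maximum references (default 10; formations with strictly
#'   more are discarded). `Inf` is the identity.
#' @return The filtered tibble.
#' @export
monographic_filter <- function(dataset, max_refs = 10) {
  if (!"RefForm" %in% names(dataset)) abort("dataset has no RefForm column")
  check_number(max_refs, "max_refs", lower = 0)
  out <- dplyr::filter(dataset, .data$RefForm <= max_refs)
  if (nrow(out) == 0L) abort(sprintf("no formations with RefForm <= %s", max_refs))
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lng1,lat2,lng2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 180)  # half the circumference
haversine_km <- function(lat1, lng1, lat2, lng2) {
  ok <- function(lat, lng) all(is.finite(lat)) && all(is.finite(lng)) &&
    all(abs(lat) <= 90) && all(lng > -180) && all(lng <= 180)
  if (!ok(lat1, lng1) || !ok(lat2, lng2)) abort("coordinates out of range")
  geosphere::distHaversine(cbind(lng1, lat1), cbind(lng2, lat2), r = 6371) # km
}

#' Geographic spread of a formation's collections
#'
#' `maxGCD` and `medianGCD` are the maximum and median over all pairwise
#' great-circle distances between collections; `coord_mad` is the median of
#' the great-circle distances from each collection to the coordinate-wise
#' median point (a distance-based median absolute deviation, in km).
#'
#' @param paleolat,paleolng Coordinate vectors in degrees; `NA` entries are
#'   dropped.
#' @return One-row tibble: `maxGCD`, `medianGCD`, `coord_mad` (all `NA` when
#'   fewer than 2 usable points).
#' @export
formation_spread <- function(paleolat, paleolng) {
  keep <- is.finite(paleolat) & is.finite(paleolng)
  lat <- paleolat[keep]; lng <- paleolng[keep]
  if (length(lat) < 2L) {
    return(tibble::tibble(maxGCD = NA_real_, medianGCD = NA_real_,
                          coord_mad = NA_real_))
  }
  idx <- which(upper.tri(diag(length(lat))), arr.ind = TRUE)
  pair <- haversine_km(lat[idx[, 1L]], lng[idx[, 1L]], lat[idx[, 2L]], lng[idx[, 2L]])
  centre <- c(median(lng), median(lat))
  to_centre <- haversine_km(lat, lng, centre[2L], centre[1L])
  tibble::tibble(maxGCD = max(pair), medianGCD = median(pair),
                 coord_mad = median(to_centre))
}
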