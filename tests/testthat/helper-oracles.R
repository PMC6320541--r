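# Independent oracles and fixture builders shared across tests.

# Brute-force multiple-site Simpson via explicit set differences over all
# ordered pairs; deliberately structured nothing like the package's
# matrix-algebra implementation.
oracle_multisite_simpson <- function(m) {
  sets <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] > 0))
  n <- length(sets)
  sum_min <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      bij <- length(setdiff(sets[[i]], sets[[j]]))
      bji <- length(setdiff(sets[[j]], sets[[i]]))
      sum_min <- sum_min + min(bij, bji)
    }
  }
  pooled <- length(unique(unlist(sets)))
  nest <- sum(lengths(sets)) - pooled
  if (sum_min == 0) return(0)
  sum_min / (nest + sum_min)
}

# haversine from first principles (radius 6371 km)
oracle_haversine_km <- function(lat1, lng1, lat2, lng2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlng <- (lng2 - lng1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlng / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# random incidence matrix with non-empty rows and no empty species columns
random_incidence <- function(n_coll, n_spp, p = 0.3) {
  m <- matrix(rbinom(n_coll * n_spp, 1L, p), nrow = n_coll)
  for (i in seq_len(n_coll)) {
    if (sum(m[i, ]) < 2L) m[i, sample.int(n_spp, 2L)] <- 1L
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

# quick occurrence-table builder in the standard layout
make_occ <- function(collection_id, species, formation = "Fm A", midage = 100,
                     reference_id = "r1", environment_raw = "marine indet.",
                     paleolat = 0, paleolng = 0, genus_uncertain = FALSE,
                     flag = NA_character_) {
  tibble::tibble(collection_id = as.character(collection_id),
                 species = species, genus_uncertain = genus_uncertain,
                 formation = formation, midage = midage,
                 reference_id = as.character(reference_id),
                 environment_raw = environment_raw,
                 paleolat = paleolat, paleolng = paleolng, flag = flag)
}

# a formation of n_coll collections where each species set is drawn iid,
# guaranteed to pass vetting; returns the occurrence tibble
make_formation_occ <- function(formation = "Fm A", n_coll = 30, n_spp = 25,
                               p = 0.25, midage = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- random_incidence(n_coll, n_spp, p)
  idx <- which(m > 0, arr.ind = TRUE)
  make_occ(collection_id = paste0(formation, "-", rownames(m)[idx[, 1]]),
           species = paste0("genus sp", idx[, 2]),
           formation = formation, midage = midage)
}
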