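#' Parameters of one simulated formation
#'
#' A formation is simulated as a metacommunity: a regional pool of
#' `pool_size` species spread over `n_habitats` habitat types. Each species
#' has a home habitat; each collection samples one habitat. A species enters
#' a matching collection with probability `occupancy` (patchiness: even a
#' matching species is usually absent) and a non-matching one with
#' `occupancy * (1 - habitat_fidelity * (1 - time_averaging))`: time
#' averaging taphonomically mixes noncontemporaneous communities into each
#' assemblage, eroding the effective habitat fidelity -- monotonically
#' raising alpha and lowering beta, with `time_averaging = 1` fully
#' homogenized (indistinguishable from `habitat_fidelity = 0`).
#' References emulate the monographic effect: with probability
#' `reference_clustering` a collection's reference is tied to its habitat,
#' so high clustering splits habitats across references.
#'
#' @param pool_size Regional species richness (>= 2).
#' @param n_collections Number of collections (> 25 for a formation meant to
#'   pass vetting).
#' @param n_habitats Number of habitat types (>= 1).
#' @param habitat_fidelity In \[0, 1\]: 0 = species ignore habitats, 1 =
#'   species occur only in their home habitat.
#' @param occupancy Per-species detection probability in a matching
#'   collection, in (0, 1\].
#' @param occupancy_sd Lognormal heterogeneity of occupancy across species
#'   (sd on the log scale; 0 = homogeneous).
#' @param time_averaging In \[0, 1\]: degree of taphonomic mixing across
#'   habitats (1 = full homogenization).
#' @param midage_range Length-2 numeric, (older, younger) in Ma.
#' @param n_references Number of contributing references (>= 1).
#' @param reference_clustering In \[0, 1\].
#' @param centroid Length-2 numeric, (lat, lng) of the formation centre.
#' @param coord_sd Scatter (degrees) of collections around the centroid.
#' @return A `formation_params` list.
#' @export
formation_params <- function(pool_size = 80, n_collections = 40, n_habitats = 3,
                             habitat_fidelity = 0.6, occupancy = 0.15,
                             occupancy_sd = 0, time_averaging = 0.3,
                             midage_range = c(450, 445), n_references = 6,
                             reference_clustering = 0.5, centroid = c(0, 0),
                             coord_sd = 1.5) {
  check_number(pool_size, "pool_size", lower = 2)
  check_number(n_collections, "n_collections", lower = 2)
  check_number(n_habitats, "n_habitats", lower = 1)
  check_number(habitat_fidelity, "habitat_fidelity", lower = 0, upper = 1)
  check_number(occupancy, "occupancy", lower = 1e-9, upper = 1)
  check_number(occupancy_sd, "occupancy_sd", lower = 0)
  check_number(time_averaging, "time_averaging", lower = 0, upper = 1)
  check_number(n_references, "n_references", lower = 1)
  check_number(reference_clustering, "reference_clustering", lower = 0, upper = 1)
  stopifnot(length(midage_range) == 2L, all(midage_range > 0), all(midage_range <= 541))
  structure(
    list(pool_size = as.integer(pool_size), n_collections = as.integer(n_collections),
         n_habitats = as.integer(n_habitats), habitat_fidelity = habitat_fidelity,
         occupancy = occupancy, occupancy_sd = occupancy_sd,
         time_averaging = time_averaging,
         midage_range = sort(as.numeric(midage_range), decreasing = TRUE),
         n_references = as.integer(n_references),
         reference_clustering = reference_clustering,
         centroid = as.numeric(centroid), coord_sd = coord_sd),
    class = "formation_params")
}

habitat_category <- function(h) {
  cats <- c("shallow_subtidal", "deep_subtidal", "reefal", "marginal_marine",
            "slope", "basin")
  cats[(h - 1L) %% length(cats) + 1L]
}

# one representative raw PBDB-style term per category, for occurrence output
category_term <- function(category) {
  terms <- c(shallow_subtidal = "shallow subtidal indet.",
             deep_subtidal = "deep subtidal indet.",
             reefal = "reef, buildup or bioherm",
             marginal_marine = "marginal marine indet.",
             slope = "slope",
             basin = "basin indet.",
             unknown = "marine indet.")
  unname(terms[category])
}

#' Simulate one formation
#'
#' Draws the incidence matrix and a PBDB-dialect occurrence table under the
#' generative model described in [formation_params()]. Collections that come
#' out with fewer than two species are redrawn (so fixtures pass vetting by
#' construction); disable with `ensure_multitaxon = FALSE`.
#'
#' @param params A [formation_params()] object.
#' @param seed Optional integer seed.
#' @param formation Formation name.
#' @param ensure_multitaxon Redraw single-taxon collections? Default `TRUE`.
#' @return List with `incidence` (binary matrix), `occurrences` (tibble in
#'   the standard occurrence layout), and `truth` (one-row tibble: the
#'   parameters plus the realized full-formation alpha, gamma, Whittaker and
#'   Simpson beta).
#' @export
simulate_formation <- function(params, seed = NULL, formation = "SimFm",
                               ensure_multitaxon = TRUE) {
  stopifnot(inherits(params, "formation_params"))
  p <- params
  with_seed(seed, {
    genus_of <- ceiling(seq_len(p$pool_size) / 3)
    species <- sprintf("g%s%02d sp%03d", tolower(gsub("[^a-z0-9]", "", tolower(formation))),
                       genus_of, seq_len(p$pool_size))
    home <- sample.int(p$n_habitats, p$pool_size, replace = TRUE)
    occ_sp <- if (p$occupancy_sd > 0) {
      pmin(1, p$occupancy * exp(stats::rnorm(p$pool_size, -p$occupancy_sd^2 / 2,
                                             p$occupancy_sd)))
    } else rep(p$occupancy, p$pool_size)

    hab <- sample.int(p$n_habitats, p$n_collections, replace = TRUE)
    midage <- runif(p$n_collections, min(p$midage_range), max(p$midage_range))
    lat <- pmin(90, pmax(-90, p$centroid[1L] + stats::rnorm(p$n_collections, 0, p$coord_sd)))
    lng <- p$centroid[2L] + stats::rnorm(p$n_collections, 0, p$coord_sd)
    lng <- ((lng + 180) %% 360) - 180
    lng[lng == -180] <- 180

    # reference assignment; clustering ties references to habitats
    refs <- sprintf("r%s%02d", tolower(gsub("[^a-z0-9]", "", tolower(formation))),
                    seq_len(p$n_references))
    ref_habitat <- (seq_len(p$n_references) - 1L) %% p$n_habitats + 1L
    ref_of <- vapply(seq_len(p$n_collections), function(i) {
      if (runif(1) < p$reference_clustering && any(ref_habitat == hab[i])) {
        sample(refs[ref_habitat == hab[i]], 1L)
      } else sample(refs, 1L)
    }, character(1))

    # time averaging mixes noncontemporaneous communities into every
    # assemblage: it erodes effective habitat fidelity, admitting
    # out-of-habitat species with probability occupancy * (1 - f_eff)
    f_eff <- p$habitat_fidelity * (1 - p$time_averaging)
    draw_collection <- function(i) {
      match <- home == hab[i]
      prob <- occ_sp * ifelse(match, 1, 1 - f_eff)
      present <- runif(p$pool_size) < prob
      if (ensure_multitaxon) {
        tries <- 0L
        while (sum(present) < 2L && tries < 50L) {
          present <- runif(p$pool_size) < prob
          tries <- tries + 1L
        }
        if (sum(present) < 2L) {
          # force occupancy-weighted picks so generation always terminates
          absent <- which(!present)
          extra <- absent[sample.int(length(absent), 2L - sum(present),
                                     prob = pmax(prob[absent], 1e-12))]
          present[extra] <- TRUE
        }
      }
      present
    }
    pres <- vapply(seq_len(p$n_collections), draw_collection, logical(p$pool_size))
    m <- t(pres) * 1L  # collections x species
    coll_ids <- sprintf("c%s%03d", tolower(gsub("[^a-z0-9]", "", tolower(formation))),
                        seq_len(p$n_collections))
    dimnames(m) <- list(coll_ids, species)
    m_seen <- m[, colSums(m) > 0, drop = FALSE]

    idx <- which(m > 0, arr.ind = TRUE)
    occs <- tibble::tibble(
      collection_id = coll_ids[idx[, 1L]],
      species = species[idx[, 2L]],
      genus_uncertain = FALSE,
      formation = formation,
      midage = midage[idx[, 1L]],
      reference_id = ref_of[idx[, 1L]],
      environment_raw = category_term(habitat_category(hab[idx[, 1L]])),
      paleolat = lat[idx[, 1L]],
      paleolng = lng[idx[, 1L]],
      flag = NA_character_
    )
    occs <- dplyr::arrange(occs, .data$collection_id, .data$species)

    truth <- tibble::tibble(
      formation = formation, pool_size = p$pool_size,
      n_collections = p$n_collections, n_habitats = p$n_habitats,
      habitat_fidelity = p$habitat_fidelity, occupancy = p$occupancy,
      time_averaging = p$time_averaging,
      n_references = p$n_references,
      reference_clustering = p$reference_clustering,
      true_alpha = alpha_mean(m_seen),
      true_gamma = gamma_total(m_seen),
      true_beta_w = whittaker_beta(m_seen),
      true_beta_sim = if (nrow(m_seen) >= 2L) multisite_simpson(m_seen) else NA_real_
    )
    list(incidence = m_seen, occurrences = occs, truth = truth)
  })
}

#' Default per-formation parameter sampler
#'
#' Draws `formation_params` for one formation of a given period: collection
#' counts 26-60, pools of 30-150 species, mostly 2-4 habitats, moderate
#' fidelity, patchy occupancy and light-to-moderate time averaging -- the
#' regime the vetting and subsampling defaults are designed for. With
#' `coupling = "low_beta_first"`, habitat fidelity rises with pool size up to
#' ~100 species and flattens above, so beta increases with gamma at low gamma
#' and levels off -- the textbook low-beta-first trajectory.
#'
#' @param coupling `"none"` or `"low_beta_first"`.
#' @return A function `(period, older_ma, younger_ma, centroid)` returning a
#'   [formation_params()] object; call it inside an RNG context.
#' @export
formation_sampler <- function(coupling = c("none", "low_beta_first")) {
  coupling <- match.arg(coupling)
  function(period, older_ma, younger_ma, centroid = c(runif(1, -60, 60),
                                                      runif(1, -150, 150))) {
    pool <- sample(30:150, 1L)
    fidelity <- if (coupling == "low_beta_first") {
      min(0.95, 0.1 + 0.85 * min(pool, 100) / 100)
    } else runif(1, 0.3, 0.9)
    ta <- if (coupling == "low_beta_first") runif(1, 0, 0.2) else runif(1, 0, 0.5)
    mid <- runif(1, younger_ma + 0.5, older_ma - 0.5)
    half <- runif(1, 0.5, 5)
    formation_params(
      pool_size = pool,
      n_collections = sample(26:60, 1L),
      n_habitats = sample(1:4, 1L, prob = c(0.15, 0.35, 0.30, 0.20)),
      habitat_fidelity = fidelity,
      occupancy = runif(1, 0.08, 0.25),
      time_averaging = ta,
      midage_range = c(min(older_ma, mid + half), max(younger_ma, mid - half)),
      n_references = sample(2:15, 1L),
      reference_clustering = runif(1, 0.2, 0.8),
      centroid = centroid
    )
  }
}

#' Simulate a multi-period occurrence dataset
#'
#' Builds a PBDB-like dataset spanning several geological periods, each with
#' a set of simulated formations, plus the generating truth table and a
#' genus-to-higher-taxon lookup. All randomness flows from `seed` through
#' per-formation child streams keyed by formation name, so the dataset is
#' reproducible and independent of processing order.
#'
#' @param spec Tibble with columns `period` and `n_formations`; defaults to
#'   three Paleozoic periods of 10 formations each.
#' @param seed Master seed.
#' @param sampler Parameter sampler from [formation_sampler()].
#' @param timescale See [default_timescale()].
#' @return List with `occurrences` (standard layout, all formations),
#'   `truth` (one row per formation), `higher_taxa` (tibble `genus`,
#'   `taxon`).
#' @export
simulate_dataset <- function(spec = tibble::tibble(
                               period = c("Ordovician", "Devonian", "Permian"),
                               n_formations = 10L),
                             seed = NULL,
                             sampler = formation_sampler(),
                             timescale = default_timescale()) {
  stopifnot(all(c("period", "n_formations") %in% names(spec)), nrow(spec) >= 1L)
  bad <- setdiff(spec$period, timescale$period)
  if (length(bad) > 0L) abort(sprintf("unknown period(s): %s", paste(bad, collapse = ", ")))

  taxa <- c("Trilobita", "Brachiopoda", "Echinodermata", "Gastropoda", "Bivalvia")
  out <- purrr::pmap(spec, function(period, n_formations) {
    ts <- timescale[timescale$period == period, ]
    purrr::map(seq_len(n_formations), function(i) {
      fname <- sprintf("%s Fm %02d", period, i)
      fseed <- if (is.null(seed)) NULL else child_seed(seed, paste0("form:", fname))
      with_seed(fseed, {
        params <- sampler(period, ts$older_ma, ts$younger_ma)
        sim <- simulate_formation(params, seed = NULL, formation = fname)
        sim$truth$Period <- period
        sim
      })
    })
  })
  sims <- purrr::list_flatten(out)
  occurrences <- dplyr::bind_rows(purrr::map(sims, "occurrences"))
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  # genera are formation-specific; draw each formation's class pool first so
  # the number of higher taxa genuinely varies between formations
  hseed <- if (is.null(seed)) NULL else child_seed(seed, "higher_taxa")
  higher_taxa <- with_seed(hseed, {
    per_form <- purrr::map(sims, function(sim) {
      genera <- sort(unique(sub(" .*$", "", sim$occurrences$species)))
      classes <- sample(taxa, sample(2:5, 1L))
      tibble::tibble(genus = genera,
                     taxon = sample(classes, length(genera), replace = TRUE))
    })
    dplyr::distinct(dplyr::bind_rows(per_form))
  })
  list(occurrences = occurrences, truth = truth, higher_taxa = higher_taxa)
}

#' Write occurrences in the PBDB download dialect
#'
#' Writes the standard occurrence tibble with PBDB download headers
#' (`collection_no`, `identified_name`, `formation`, `midage`,
#' `reference_no`, `environment`, `paleolat`, `paleolng`) so that
#' [read_occurrences()] round-trips it.
#'
#' @param occ Occurrence tibble.
#' @param path Output file (`.csv` -> comma-delimited, otherwise tab).
#' @return `occ`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  out <- tibble::tibble(
    collection_no = occ$collection_id,
    identified_name = occ$species,
    formation = occ$formation,
    midage = occ$midage,
    reference_no = occ$reference_id,
    environment = occ$environment_raw,
    paleolat = occ$paleolat,
    paleolng = occ$paleolng
  )
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(out, path)
  } else {
    readr::write_tsv(out, path)
  }
  invisible(occ)
}
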