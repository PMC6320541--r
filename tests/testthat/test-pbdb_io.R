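test_that("read_occurrences preserves rows, flags bad ages, round-trips quoting", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "collection_no,identified_name,formation,midage,reference_no,environment,paleolat,paleolng",
    "1,Lingula anatina,Fm A,100,r1,slope,10,20",
    "2,\"Composita, the ambigua\",Fm A,100,r1,slope,10,20",
    "3,Mucrospirifer mucronatus,Fm A,NA,r1,slope,10,20"
  ), path)
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3L)
  expect_equal(occ$species[2], "composita, the ambigua")  # quoted comma intact
  expect_equal(occ$flag, c(NA, NA, "missing_midage"))

  # vetting removes the flagged record
  occ_big <- dplyr::bind_rows(occ, make_formation_occ("Fm A", n_coll = 30))
  vetted <- vet(occ_big)
  expect_false("3" %in% vetted$collection_id)
})

test_that("read_occurrences fails on a missing required column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("collection_no,formation,midage", "1,Fm A,100"), path)
  expect_error(read_occurrences(path), "species")
})

test_that("genus-level identification qualifiers are detected, epithet ones are not", {
  expect_equal(
    genus_uncertain(c("cf. Lingula anatina", "aff. Composita sp.",
                      "? Lingula", "\"Lingula\" anatina",
                      "Lingula cf. anatina", "Lingula anatina")),
    c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("environment standardization is total and deterministic", {
  expect_equal(standardize_environment("deep-water",
                                       tibble::tibble(term = "deep-water",
                                                      category = "basin")),
               "basin")
  expect_equal(standardize_environment("lagoonal??"), "unknown")
  expect_equal(standardize_environment("reef, buildup or bioherm"), "reefal")
  expect_equal(standardize_environment(NA_character_), "unknown")
  expect_error(standardize_environment("x", tibble::tibble(term = "x",
                                                           category = "abyssopelagic")),
               "vocabulary")
})

test_that("vetting applies the collection and formation thresholds strictly", {
  # formation with exactly 25 multi-taxon collections is excluded
  occ25 <- make_formation_occ("Fm 25", n_coll = 25, seed = 1)
  occ26 <- make_formation_occ("Fm 26", n_coll = 26, seed = 2)
  expect_error(vet(occ25), "no analyzable formations")
  both <- vet(dplyr::bind_rows(occ25, occ26))
  expect_equal(unique(both$formation), "Fm 26")

  # a collection whose only two occurrences are genus-uncertain disappears
  occ <- dplyr::bind_rows(
    occ26,
    make_occ("bad-coll", c("cf. genus sp1", "cf. genus sp2"), formation = "Fm 26",
             genus_uncertain = TRUE))
  expect_false("bad-coll" %in% vet(occ)$collection_id)

  # 30 collections, 4 single-taxon: formation retained with 26 collections
  base <- make_formation_occ("Fm 30", n_coll = 26, seed = 3)
  singles <- make_occ(paste0("single-", 1:4), "genus sp1", formation = "Fm 30")
  vetted <- vet(dplyr::bind_rows(base, singles))
  expect_equal(dplyr::n_distinct(vetted$collection_id), 26L)
})

test_that("vetting is idempotent, order-stable, and its ledger sums", {
  occ <- dplyr::bind_rows(
    make_formation_occ("Fm A", n_coll = 30, seed = 4),
    make_formation_occ("Fm B", n_coll = 10, seed = 5),   # too small, dropped
    make_occ("c-unc", c("cf. genus sp1", "genus sp2", "genus sp3"),
             genus_uncertain = c(TRUE, FALSE, FALSE), formation = "Fm A"),
    make_occ("c-nofm", c("genus sp1", "genus sp2"), formation = NA_character_))

  strip <- function(x) { attr(x, "report") <- NULL; as.data.frame(x) }
  v1 <- vet(occ)
  v2 <- vet(v1)
  expect_equal(strip(v1), strip(v2))  # same record set; only the ledger differs

  shuffled <- occ[sample.int(nrow(occ)), ]
  expect_equal(strip(vet(shuffled)), strip(v1))

  rep <- vetting_report(v1)
  expect_equal(nrow(occ), nrow(v1) + sum(rep$records_removed))
  expect_equal(rep$records_removed[rep$rule == "no formation assignment"], 2L)
})

test_that("vetting honours the user exclusion list", {
  occ <- make_formation_occ("Fm A", n_coll = 30, seed = 6)
  drop_id <- occ$collection_id[[1L]]
  v <- vet(occ, exclude = drop_id)
  expect_false(drop_id %in% v$collection_id)
  expect_gt(vetting_report(v)$records_removed[4L], 0L)
})

test_that("period assignment uses the half-open younger-period convention", {
  expect_equal(assign_period(300), "Carboniferous")
  expect_equal(assign_period(443.8), "Silurian")   # boundary -> younger period
  expect_equal(assign_period(541), "Cambrian")
  expect_error(assign_period(600), "midage")
  expect_error(assign_period(0), "midage")
})

test_that("incidence construction is binary, idempotent under duplicates", {
  occ <- make_occ(c("A", "A", "B", "B"),
                  c("g s1", "g s2", "g s2", "g s3"))
  m <- build_incidence(occ, "Fm A")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(rowSums(m)), c(2, 2))
  expect_equal(unname(colSums(m)), c(1, 2, 1))

  dup <- dplyr::bind_rows(occ, occ[2, ])
  expect_identical(build_incidence(dup, "Fm A"), m)
  expect_error(build_incidence(occ, "No Such Fm"), "unknown formation")
})

test_that("formation metadata computes duration, counts and period", {
  occ <- dplyr::bind_rows(
    make_occ("A", c("g s1", "g s2"), midage = 250, reference_id = "r1",
             environment_raw = "slope"),
    make_occ("B", c("g s2", "g s3"), midage = 240, reference_id = "r2",
             environment_raw = "reef, buildup or bioherm"))
  meta <- formation_metadata(occ)
  expect_equal(meta$duration, 10)
  expect_equal(meta$CollpF, 2L)
  expect_equal(meta$RefForm, 2L)
  expect_equal(meta$Environments, 2L)
  expect_equal(meta$Period, "Triassic")  # mean midage 245

  ht <- tibble::tibble(genus = "g", taxon = "Brachiopoda")
  meta2 <- formation_metadata(occ, higher_taxa = ht)
  expect_equal(meta2$n_higher_taxa, 1L)
})
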