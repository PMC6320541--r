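test_that("parameter validation rejects out-of-range values", {
  expect_error(formation_params(habitat_fidelity = 1.2), "habitat_fidelity")
  expect_error(formation_params(occupancy = 0), "occupancy")
  expect_error(formation_params(time_averaging = -0.1), "time_averaging")
  expect_error(formation_params(pool_size = 1), "pool_size")
})

test_that("the saturated limit produces alpha = gamma, beta = 0", {
  p <- formation_params(pool_size = 30, n_collections = 28, n_habitats = 3,
                        habitat_fidelity = 0, occupancy = 1, time_averaging = 1)
  sim <- simulate_formation(p, seed = 1)
  expect_equal(sim$truth$true_alpha, sim$truth$true_gamma)
  expect_equal(sim$truth$true_beta_w, 1)
  expect_equal(sim$truth$true_beta_sim, 0)
  expect_equal(sim$truth$true_gamma, 30)
})

test_that("simulation is seed-reproducible and collections pass vetting", {
  p <- formation_params(n_collections = 30)
  a <- simulate_formation(p, seed = 5)
  b <- simulate_formation(p, seed = 5)
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$occurrences, b$occurrences)
  expect_true(all(rowSums(a$incidence) >= 2))
  expect_true(all(a$occurrences$midage >= min(p$midage_range) &
                    a$occurrences$midage <= max(p$midage_range)))
})

test_that("habitat fidelity raises beta; full time-averaging erases its effect", {
  reps <- 30
  beta_of <- function(fidelity, ta, seed) {
    p <- formation_params(pool_size = 60, n_collections = 12, n_habitats = 4,
                          habitat_fidelity = fidelity, occupancy = 0.6,
                          time_averaging = ta)
    simulate_formation(p, seed = seed)$truth$true_beta_sim
  }
  b_none <- vapply(1:reps, function(s) beta_of(0, 0, s), numeric(1))
  b_high <- vapply(1:reps, function(s) beta_of(1, 0, 1000 + s), numeric(1))
  b_mixed <- vapply(1:reps, function(s) beta_of(1, 1, 2000 + s), numeric(1))
  expect_gt(mean(b_high), mean(b_none) + 0.1)
  # fully time-averaged high-fidelity formations look like fidelity-0 ones
  expect_lt(abs(mean(b_mixed) - mean(b_none)), 0.05)
})

test_that("time averaging never lowers alpha nor raises beta (paired seeds)", {
  levels <- c(0, 0.5, 1)
  reps <- 25
  res <- purrr::map(levels, function(ta) {
    vals <- purrr::map(1:reps, function(s) {
      p <- formation_params(pool_size = 50, n_collections = 12, n_habitats = 4,
                            habitat_fidelity = 0.9, occupancy = 0.5,
                            time_averaging = ta)
      simulate_formation(p, seed = s)$truth  # same seeds across ta levels
    })
    vals <- dplyr::bind_rows(vals)
    c(alpha = mean(vals$true_alpha), beta = mean(vals$true_beta_sim))
  })
  alpha <- vapply(res, `[[`, numeric(1), "alpha")
  beta <- vapply(res, `[[`, numeric(1), "beta")
  expect_true(all(diff(alpha) > 0))
  expect_true(all(diff(beta) < 0))
})

test_that("simulated datasets have the right shape and survive vetting", {
  spec <- tibble::tibble(period = c("Ordovician", "Devonian", "Permian"),
                         n_formations = c(4L, 3L, 3L))
  ds <- simulate_dataset(spec, seed = 11)
  expect_equal(nrow(ds$truth), 10L)
  expect_equal(sort(unique(ds$truth$Period)), sort(spec$period))
  v <- vet(ds$occurrences)
  expect_equal(dplyr::n_distinct(v$formation), 10L)  # all built to pass
  expect_true(all(ds$higher_taxa$taxon %in%
                    c("Trilobita", "Brachiopoda", "Echinodermata",
                      "Gastropoda", "Bivalvia")))
  # midages respect the period bins
  meta <- formation_metadata(v)
  expect_equal(unname(assign_period(meta$mean_midage)), meta$Period)
  # reproducible
  ds2 <- simulate_dataset(spec, seed = 11)
  expect_identical(ds$occurrences, ds2$occurrences)
  expect_error(simulate_dataset(tibble::tibble(period = "Hadean",
                                               n_formations = 1L)),
               "unknown period")
})

test_that("datasets round-trip through the PBDB dialect bit-perfectly", {
  ds <- simulate_dataset(tibble::tibble(period = "Devonian", n_formations = 2L),
                         seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(ds$occurrences, path)
  back <- read_occurrences(path)
  for (f in unique(ds$occurrences$formation)) {
    expect_identical(build_incidence(back, f), build_incidence(ds$occurrences, f))
  }
})

test_that("the low-beta-first sampler induces a positive beta-gamma slope", {
  spec <- tibble::tibble(period = "Ordovician", n_formations = 25L)
  ds <- simulate_dataset(spec, seed = 17,
                         sampler = formation_sampler("low_beta_first"))
  v <- vet(ds$occurrences)
  est <- run_all_formations(v, n_trials = 40, seed = 19)
  est_r <- restrict_gamma(est, 100)
  f <- fit_logarithmic(est_r$GammaForm, est_r$BetaSimForm)
  expect_gt(f$coefficients[["slope"]], 0)
})
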