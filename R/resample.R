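#' Subsampled diversity estimate for one formation
#'
#' Draws `subsample_size` collections without replacement `n_trials` times;
#' in each trial, species columns left empty by the draw are dropped and
#' alpha, gamma, Whittaker's beta and the multiple-site Simpson dissimilarity
#' are computed on the subsampled matrix. Trial means and standard deviations
#' are reported. Defaults (20 collections, 500 trials) are the standard
#' protocol this package targets.
#'
#' @param m Binary incidence matrix of the full formation.
#' @param subsample_size Collections drawn per trial (default 20).
#' @param n_trials Number of trials (default 500).
#' @param seed Optional integer seed; when given, results are exactly
#'   reproducible and the caller's RNG state is left untouched.
#' @param formation Formation name carried into the output.
#' @return One-row tibble: `formation`, `AlphaForm`, `BetaWForm`,
#'   `BetaSimForm`, `GammaForm` (trial means), `AlphaSD`, `BetaWSD`,
#'   `BetaSimSD`, `GammaSD`, `n_trials`, `subsample_size`, `seed`.
#' @export
subsample_formation <- function(m, subsample_size = 20, n_trials = 500,
                                seed = NULL, formation = NA_character_) {
  check_incidence(m, min_rows = 2L)
  check_number(subsample_size, "subsample_size", lower = 2)
  check_number(n_trials, "n_trials", lower = 1)
  if (nrow(m) < subsample_size) {
    abort(sprintf("formation %s has %d collections, fewer than subsample_size = %d",
                  formation, nrow(m), subsample_size))
  }
  trials <- with_seed(seed, {
    purrr::map(seq_len(n_trials), function(i) {
      rows <- sample.int(nrow(m), subsample_size, replace = FALSE)
      sub <- m[rows, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      diversity_values(sub)
    })
  })
  trials <- dplyr::bind_rows(trials)
  tibble::tibble(
    formation = formation,
    AlphaForm = mean(trials$alpha),
    BetaWForm = mean(trials$beta_w),
    BetaSimForm = mean(trials$beta_sim),
    GammaForm = mean(trials$gamma),
    AlphaSD = stats::sd(trials$alpha),
    BetaWSD = stats::sd(trials$beta_w),
    BetaSimSD = stats::sd(trials$beta_sim),
    GammaSD = stats::sd(trials$gamma),
    n_trials = as.integer(n_trials),
    subsample_size = as.integer(subsample_size),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Subsampled diversity estimates for every vetted formation
#'
#' Runs [subsample_formation()] on each formation of a vetted occurrence
#' table and joins the per-formation metadata. Each formation gets its own
#' RNG stream derived from `seed` and the formation name, so results do not
#' depend on processing order and the table is bit-identical across reruns
#' with the same master seed.
#'
#' @param occ Vetted occurrence tibble (see [vet()]).
#' @param subsample_size,n_trials Passed to [subsample_formation()].
#' @param seed Master seed (integer).
#' @param metadata Join [formation_metadata()] columns? Default `TRUE`.
#' @param environment_map,timescale,higher_taxa Passed to
#'   [formation_metadata()].
#' @return Tibble with one row per formation: the estimate columns
#'   (`AlphaForm`, `BetaWForm`, `BetaSimForm`, `GammaForm` + SDs) and, when
#'   `metadata` is `TRUE`, `Period`, `mean_midage`, `duration`, `CollpF`,
#'   `Environments`, `RefForm`, `maxGCD`, `medianGCD`, `coord_mad`.
#' @export
run_all_formations <- function(occ, subsample_size = 20, n_trials = 500,
                               seed = NULL, metadata = TRUE,
                               environment_map = default_environment_map(),
                               timescale = default_timescale(),
                               higher_taxa = NULL) {
  forms <- sort(unique(occ$formation))
  if (length(forms) == 0L) abort("no formations in input")
  est <- purrr::map(forms, function(f) {
    m <- build_incidence(occ, f)
    fseed <- if (is.null(seed)) NULL else child_seed(seed, f)
    subsample_formation(m, subsample_size, n_trials, seed = fseed, formation = f)
  })
  est <- dplyr::bind_rows(est)
  if (metadata) {
    meta <- formation_metadata(occ, environment_map, timescale, higher_taxa)
    est <- dplyr::left_join(est, meta, by = "formation")
  }
  est
}

#' Write / read the per-formation estimate table
#'
#' Plain CSV round-trip for the final analysis table.
#'
#' @param estimates Tibble from [run_all_formations()].
#' @param path File path.
#' @return `write_estimates` returns `estimates` invisibly; `read_estimates`
#'   the tibble.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(estimates, path)
  invisible(estimates)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
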