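#' Restrict the estimate table to the beta-dependent gamma range
#'
#' Beta-gamma coupling only operates while beta can still rise with gamma;
#' above roughly 100 subsampled species beta has levelled off, so fits and
#' null draws are restricted to formations with `GammaForm <= gamma_max`.
#'
#' @param estimates Estimate table with a `GammaForm` column.
#' @param gamma_max Upper gamma threshold (default 100); `Inf` is the
#'   identity.
#' @return The filtered tibble.
#' @export
restrict_gamma <- function(estimates, gamma_max = 100) {
  check_number(gamma_max, "gamma_max", lower = 0)
  out <- dplyr::filter(estimates, .data$GammaForm <= gamma_max)
  if (nrow(out) == 0L) {
    abort(sprintf("no formations with GammaForm <= %s", gamma_max))
  }
  out
}

#' Randomization null distribution of beta-gamma slopes
#'
#' Per trial, draws `draw_size` formations without replacement from the
#' pooled estimate table (with replacement across trials), fits the
#' logarithmic beta-gamma regression and records its slope. The mean and SD
#' of the slopes form the time-independent reference against which each
#' period's observed slope is scored.
#'
#' @param pool Estimate table (normally already gamma-restricted, see
#'   [restrict_gamma()]).
#' @param draw_size Formations per trial (default 20).
#' @param n_trials Number of trials (default 200).
#' @param seed Optional integer seed.
#' @return A `null_distribution` object: `slopes`, `mean_slope`, `sd_slope`
#'   (`NA` when `n_trials` is 1), `n_trials`, `draw_size`, `gamma_max` (the
#'   max `GammaForm` in the pool), `seed`.
#' @export
null_slopes <- function(pool, draw_size = 20, n_trials = 200, seed = NULL) {
  check_number(draw_size, "draw_size", lower = 3)
  check_number(n_trials, "n_trials", lower = 1)
  if (nrow(pool) < draw_size) {
    abort(sprintf("pool has %d formations, fewer than draw_size = %d",
                  nrow(pool), draw_size))
  }
  gamma <- pool$GammaForm
  beta <- pool$BetaSimForm
  slopes <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      idx <- sample.int(nrow(pool), draw_size, replace = FALSE)
      log_slope(gamma[idx], beta[idx])
    }, numeric(1))
  })
  structure(
    list(slopes = slopes,
         mean_slope = mean(slopes),
         sd_slope = if (n_trials >= 2L) sd(slopes) else NA_real_,
         n_trials = as.integer(n_trials),
         draw_size = as.integer(draw_size),
         gamma_max = max(gamma),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %d trials of %d formations>\n",
              x$n_trials, x$draw_size))
  cat(sprintf("  slope mean %.4g, sd %.4g\n", x$mean_slope, x$sd_slope))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.null_distribution <- function(x, ...) {
  tibble::tibble(mean_slope = x$mean_slope, sd_slope = x$sd_slope,
                 n_trials = x$n_trials, draw_size = x$draw_size)
}

#' @exportS3Method generics::tidy
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(trial = seq_along(x$slopes), slope = x$slopes)
}

#' Score one period's beta-gamma slope against the null
#'
#' @param period_estimates Estimate table restricted to one period (and
#'   normally to the gamma range of the null pool).
#' @param null A `null_distribution`.
#' @param z_threshold Verdict threshold (default 1.96).
#' @return One-row tibble: `n_formations`, `slope`, `z`, `verdict`
#'   (`"coupled"` / `"uncoupled"`).
#' @export
period_zscore <- function(period_estimates, null, z_threshold = 1.96) {
  if (!inherits(null, "null_distribution")) abort("`null` must come from null_slopes()")
  if (is.na(null$sd_slope) || null$sd_slope <= 0) {
    abort("null sd_slope undefined or zero; cannot z-score")
  }
  if (nrow(period_estimates) < 3L) {
    abort("need at least 3 formations for a logarithmic fit")
  }
  slope <- log_slope(period_estimates$GammaForm, period_estimates$BetaSimForm)
  z <- (slope - null$mean_slope) / null$sd_slope
  tibble::tibble(n_formations = nrow(period_estimates), slope = slope, z = z,
                 verdict = ifelse(z > z_threshold, "coupled", "uncoupled"))
}

#' Per-period beta-gamma coupling table
#'
#' Convenience wrapper: restricts to the gamma range, builds the pooled null
#' once, and scores every period with enough formations; periods below the
#' minimum are skipped with a warning.
#'
#' @param estimates Estimate table with `Period` column.
#' @param gamma_max Gamma restriction applied to both pool and periods.
#' @param draw_size,n_trials,seed Passed to [null_slopes()].
#' @param z_threshold Passed to [period_zscore()].
#' @param min_formations Minimum formations per period (default 5).
#' @param restrict_null Apply the gamma restriction to the null pool too
#'   (default `TRUE`)?
#' @return List with elements `null` (the `null_distribution`) and `periods`
#'   (tibble: `Period`, `n_formations`, `slope`, `z`, `verdict`).
#' @export
coupling_test <- function(estimates, gamma_max = 100, draw_size = 20,
                          n_trials = 200, seed = NULL, z_threshold = 1.96,
                          min_formations = 5, restrict_null = TRUE) {
  if (!"Period" %in% names(estimates)) abort("estimates table has no Period column")
  restricted <- restrict_gamma(estimates, gamma_max)
  pool <- if (restrict_null) restricted else estimates
  null <- null_slopes(pool, draw_size, n_trials, seed)
  periods <- split(restricted, restricted$Period)
  rows <- purrr::imap(periods, function(p, name) {
    if (nrow(p) < max(3, min_formations)) {
      warn(sprintf("period %s skipped: only %d formations", name, nrow(p)))
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(Period = name), period_zscore(p, null, z_threshold))
  })
  list(null = null, periods = dplyr::bind_rows(purrr::compact(rows)))
}
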