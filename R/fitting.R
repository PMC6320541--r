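new_div_fit <- function(kind, model, coefficients, band, n, r_squared = NA_real_,
                        aic = NA_real_, span = NA_real_) {
  structure(
    list(kind = kind, model = model, coefficients = coefficients, band = band,
         n = n, r_squared = r_squared, aic = aic, span = span),
    class = "div_fit")
}

band_grid <- function(x, n = 80L) {
  seq(min(x), max(x), length.out = n)
}

#' Linear trajectory fit (alpha vs gamma)
#'
#' Ordinary least squares `y = a + b x` with a pointwise 95% confidence band
#' over the observed x range.
#'
#' @param x,y Numeric vectors, at least 3 points; `x` must vary.
#' @return A `div_fit` object; see [tidy.div_fit()] and [glance.div_fit()].
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) abort("need at least 3 points")
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) abort("x values are all equal")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  grid <- band_grid(x)
  ci <- predict(fit, newdata = data.frame(x = grid), interval = "confidence")
  band <- tibble::tibble(x = grid, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"])
  new_div_fit("linear", fit,
              c(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L])),
              band, length(x),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              aic = AIC(fit))
}

#' Logarithmic trajectory fit (beta vs gamma)
#'
#' Least squares on a log-transformed predictor, `y = a + b ln(x)`. The slope
#' `b` is the beta-gamma coupling statistic scored against the randomization
#' null (see [null_slopes()]). Identical, coefficient for coefficient, to
#' `fit_linear(log(x), y)`.
#'
#' @param x Positive numeric vector (gamma values).
#' @param y Numeric vector (beta values).
#' @return A `div_fit` object.
#' @export
fit_logarithmic <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) abort("need at least 3 points")
  if (any(x <= 0)) abort("logarithmic fit requires all x > 0")
  lx <- log(x)
  if (var(lx) == 0) abort("x values are all equal")
  fit <- lm(y ~ lx, data = data.frame(lx = lx, y = y))
  grid <- band_grid(x)
  ci <- predict(fit, newdata = data.frame(lx = log(grid)), interval = "confidence")
  band <- tibble::tibble(x = grid, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"])
  new_div_fit("logarithmic", fit,
              c(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L])),
              band, length(x),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              aic = AIC(fit))
}

# fast path used by the null model: slope of y ~ log(x), identical to the
# lm coefficient but without the model object overhead
log_slope <- function(x, y) {
  lx <- log(x)
  sum((lx - mean(lx)) * (y - mean(y))) / sum((lx - mean(lx))^2)
}

#' Loess trajectory fit
#'
#' Locally weighted regression (default span 0.75, degree 2) with a pointwise
#' band of +/- 1.96 local standard errors, evaluated on a grid spanning the
#' observed x.
#'
#' @param x,y Numeric vectors, at least 10 points.
#' @param span Smoothing fraction in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @return A `div_fit` object.
#' @export
fit_loess <- function(x, y, span = 0.75, degree = 2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) abort("need at least 10 points for a loess fit")
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    abort("span must lie in (0, 1]")
  }
  fit <- loess(y ~ x, data = data.frame(x = x, y = y), span = span,
               degree = degree, surface = "direct")
  grid <- band_grid(x)
  pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  z <- qnorm(0.975)
  band <- tibble::tibble(x = grid, fit = pr$fit,
                         lower = pr$fit - z * pr$se.fit,
                         upper = pr$fit + z * pr$se.fit)
  new_div_fit("loess", fit, c(span = span), band, length(x), span = span)
}

#' @export
print.div_fit <- function(x, ...) {
  cat(sprintf("<div_fit: %s, n = %d>\n", x$kind, x$n))
  if (x$kind != "loess") {
    cat(sprintf("  intercept %.4g, slope %.4g, R^2 %.3f\n",
                x$coefficients[["intercept"]], x$coefficients[["slope"]],
                x$r_squared))
  } else {
    cat(sprintf("  span %.2f\n", x$span))
  }
  invisible(x)
}

#' Tidy a trajectory fit
#'
#' @param x A `div_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error` (parametric
#'   kinds only).
#' @exportS3Method generics::tidy
tidy.div_fit <- function(x, ...) {
  if (x$kind == "loess") {
    return(tibble::tibble(term = "span", estimate = x$span, std.error = NA_real_))
  }
  se <- sqrt(diag(stats::vcov(x$model)))
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(x$coefficients),
                 std.error = unname(se))
}

#' One-line summary of a trajectory fit
#'
#' @param x A `div_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `kind`, `n`, `r.squared`, `AIC`.
#' @exportS3Method generics::glance
glance.div_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, r.squared = x$r_squared, AIC = x$aic)
}

#' @export
predict.div_fit <- function(object, newdata = NULL, ...) {
  xg <- if (is.null(newdata)) object$band$x else newdata
  if (object$kind == "linear") {
    unname(object$coefficients[["intercept"]] + object$coefficients[["slope"]] * xg)
  } else if (object$kind == "logarithmic") {
    unname(object$coefficients[["intercept"]] + object$coefficients[["slope"]] * log(xg))
  } else {
    as.numeric(predict(object$model, newdata = data.frame(x = xg)))
  }
}

#' Compare parametric trajectory shapes by information criterion
#'
#' Fits both the linear and the logarithmic shape to the same points and
#' reports their AICs, making "which shape represents the data better"
#' reproducible on any dataset.
#'
#' @param x,y Numeric vectors (`x` positive).
#' @return Tibble with columns `kind`, `AIC`, `r.squared`, `best` (logical).
#' @export
compare_fits <- function(x, y) {
  fits <- list(linear = fit_linear(x, y), logarithmic = fit_logarithmic(x, y))
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$best <- out$AIC == min(out$AIC)
  dplyr::select(out, "kind", "AIC", "r.squared", "best")
}

#' Alpha-beta-gamma plot bundles
#'
#' For the whole dataset or per geological period, fits the alpha-vs-gamma
#' and beta-vs-gamma trajectories and packages them with the scatter points,
#' ready for plotting (see [autoplot.abg_bundle()]) or serialization.
#'
#' @param estimates Estimate table from [run_all_formations()].
#' @param grouping `"all"` (one bundle) or `"period"` (one per `Period`).
#' @param alpha_kind,beta_kind Fit kind per diversity component:
#'   `"linear"`, `"logarithmic"` or `"loess"`.
#' @param min_points Groups with fewer formations are skipped with a warning.
#' @param span Loess span, when used.
#' @return An `abg_bundle`: tibble with columns `group`, `n`, `points`
#'   (list of tibbles), `alpha_fit`, `beta_fit` (lists of `div_fit`).
#' @export
abg_plot_data <- function(estimates, grouping = c("all", "period"),
                          alpha_kind = "linear", beta_kind = "logarithmic",
                          min_points = 3, span = 0.75) {
  grouping <- match.arg(grouping)
  if (grouping == "period" && !"Period" %in% names(estimates)) {
    abort("estimates table has no Period column")
  }
  groups <- if (grouping == "all") {
    list(Phanerozoic = estimates)
  } else {
    split(estimates, estimates$Period)
  }
  fit_one <- function(kind, x, y) {
    switch(kind,
           linear = fit_linear(x, y),
           logarithmic = fit_logarithmic(x, y),
           loess = fit_loess(x, y, span = span),
           abort(sprintf("unknown fit kind: %s", kind)))
  }
  need <- if (alpha_kind == "loess" || beta_kind == "loess") max(min_points, 10) else min_points
  rows <- purrr::imap(groups, function(g, name) {
    if (nrow(g) < need) {
      warn(sprintf("group %s skipped: %d formations < %d required", name, nrow(g), need))
      return(NULL)
    }
    tibble::tibble(
      group = name, n = nrow(g),
      points = list(dplyr::select(g, gamma = "GammaForm", alpha = "AlphaForm",
                                  beta_sim = "BetaSimForm")),
      alpha_fit = list(fit_one(alpha_kind, g$GammaForm, g$AlphaForm)),
      beta_fit = list(fit_one(beta_kind, g$GammaForm, g$BetaSimForm)))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) abort("no group had enough formations to fit")
  class(out) <- c("abg_bundle", class(out))
  out
}

#' Serialize a plot bundle as plain tables
#'
#' @param bundle An `abg_bundle`.
#' @return List of two tibbles: `points` (group, gamma, alpha, beta_sim) and
#'   `bands` (group, component, x, fit, lower, upper).
#' @export
bundle_tables <- function(bundle) {
  points <- bundle |>
    dplyr::select("group", "points") |>
    tidyr::unnest("points")
  bands <- bundle |>
    dplyr::mutate(
      alpha_band = purrr::map(.data$alpha_fit, "band"),
      beta_band = purrr::map(.data$beta_fit, "band")) |>
    dplyr::select("group", "alpha_band", "beta_band") |>
    tidyr::pivot_longer(c("alpha_band", "beta_band"), names_to = "component",
                        values_to = "band") |>
    dplyr::mutate(component = sub("_band$", "", .data$component)) |>
    tidyr::unnest("band")
  list(points = points, bands = bands)
}

#' Label a period's diversity-accumulation trajectory
#'
#' Scores the logarithmic beta-gamma slope against a randomization null and
#' labels the trajectory: `low_beta_first` when the slope is positive and its
#' z-score against the null exceeds `z_threshold` (beta diversity rises with
#' gamma before levelling off), `high_beta_first` when the slope is
#' statistically indistinguishable from zero (its 95% CI covers 0),
#' `indeterminate` otherwise.
#'
#' @param beta_fit A logarithmic `div_fit` of beta on gamma (normally on the
#'   gamma-restricted range, see [restrict_gamma()]).
#' @param null A `null_distribution` from [null_slopes()].
#' @param z_threshold Coupling threshold on the z-score (default 1.96).
#' @return One-row tibble: `label`, `slope`, `z`, `ci_lower`, `ci_upper`.
#' @export
classify_trajectory <- function(beta_fit, null, z_threshold = 1.96) {
  if (!inherits(null, "null_distribution")) abort("`null` must come from null_slopes()")
  if (!inherits(beta_fit, "div_fit") || beta_fit$kind != "logarithmic") {
    abort("`beta_fit` must be a logarithmic div_fit")
  }
  if (!is.finite(null$sd_slope) || null$sd_slope <= 0) {
    abort("null distribution has no usable spread (sd_slope <= 0 or undefined)")
  }
  slope <- beta_fit$coefficients[["slope"]]
  se <- tidy(beta_fit)$std.error[2L]
  z <- (slope - null$mean_slope) / null$sd_slope
  ci <- slope + c(-1, 1) * qnorm(0.975) * se
  label <- if (slope > 0 && z > z_threshold) {
    "low_beta_first"
  } else if (ci[1L] <= 0 && ci[2L] >= 0) {
    "high_beta_first"
  } else {
    "indeterminate"
  }
  tibble::tibble(label = label, slope = slope, z = z,
                 ci_lower = ci[1L], ci_upper = ci[2L])
}
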