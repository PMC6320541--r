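test_that("linear fit recovers exact lines and matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  f <- fit_linear(x, 2 * x)
  expect_equal(unname(f$coefficients[["slope"]]), 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  f0 <- fit_linear(x, rep(3, 5))
  expect_equal(unname(f0$coefficients[["slope"]]), 0, tolerance = 1e-12)

  set.seed(41)
  x <- runif(10, 1, 50); y <- 3 + 0.4 * x + rnorm(10)
  f <- fit_linear(x, y)
  X <- cbind(1, x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)  # normal-equations oracle
  expect_equal(unname(f$coefficients), as.numeric(beta_hat), tolerance = 1e-10)
  expect_error(fit_linear(rep(2, 5), 1:5), "equal")
  expect_error(fit_linear(1:2, 1:2), "3 points")
})

test_that("logarithmic fit is fit_linear on log(x) and recovers noiseless truth", {
  x <- c(2, 5, 12, 30, 80, 200)
  y <- 0.1 + 0.2 * log(x)
  f <- fit_logarithmic(x, y)
  expect_equal(unname(f$coefficients), c(0.1, 0.2), tolerance = 1e-12)

  set.seed(43)
  xr <- runif(20, 1, 100); yr <- runif(20)
  expect_equal(fit_logarithmic(xr, yr)$coefficients,
               fit_linear(log(xr), yr)$coefficients, tolerance = 1e-12)
  expect_equal(unname(fit_logarithmic(x, rep(1, 6))$coefficients[["slope"]]), 0,
               tolerance = 1e-12)
  expect_error(fit_logarithmic(c(0, 1, 2), 1:3), "x > 0")
  expect_equal(log_slope(xr, yr),
               unname(fit_logarithmic(xr, yr)$coefficients[["slope"]]),
               tolerance = 1e-12)
})

test_that("logarithmic slope CI achieves near-nominal coverage", {
  set.seed(47)
  hits <- vapply(1:100, function(i) {
    x <- runif(30, 5, 150)
    y <- 0.2 + 0.1 * log(x) + rnorm(30, 0, 0.05)
    td <- tidy(fit_logarithmic(x, y))
    ci <- td$estimate[2] + c(-1, 1) * qt(0.975, 28) * td$std.error[2]
    ci[1] <= 0.1 && 0.1 <= ci[2]
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("fit bands bracket the fitted curve pointwise", {
  set.seed(53)
  x <- runif(30, 1, 100); y <- 1 + 0.3 * log(x) + rnorm(30, 0, 0.1)
  for (f in list(fit_linear(x, y), fit_logarithmic(x, y), fit_loess(x, y))) {
    expect_true(all(f$band$lower <= f$band$fit + 1e-10))
    expect_true(all(f$band$upper >= f$band$fit - 1e-10))
  }
})

test_that("loess tracks lines and beats the global line on curved data", {
  set.seed(59)
  x <- sort(runif(40, 0, 10)); y <- 1 + 2 * x
  f <- fit_loess(x, y, span = 1)
  expect_equal(predict(f, x), y, tolerance = 1e-6)

  yc <- sin(x) + rnorm(40, 0, 0.05)  # non-monotone
  fl <- fit_loess(x, yc, span = 0.5)
  lin <- fit_linear(x, yc)
  mse <- function(pred) mean((yc - pred)^2)
  expect_lt(mse(predict(fl, x)), mse(predict(lin, x)))
  expect_error(fit_loess(x, yc, span = 1.5), "span")
  expect_error(fit_loess(1:5, 1:5), "10 points")
})

test_that("fits are invariant to point order and model comparison prefers the truth", {
  set.seed(61)
  x <- runif(40, 2, 120); y <- 0.1 + 0.25 * log(x) + rnorm(40, 0, 0.03)
  o <- sample.int(40)
  expect_equal(fit_logarithmic(x[o], y[o])$coefficients,
               fit_logarithmic(x, y)$coefficients, tolerance = 1e-12)
  cmp <- compare_fits(x, y)
  expect_equal(cmp$kind[cmp$best], "logarithmic")
})

test_that("abg_plot_data groups, skips small groups, and serializes", {
  est <- tibble::tibble(
    formation = paste0("f", 1:24),
    Period = rep(c("Ordovician", "Devonian", "Permian"), each = 8),
    GammaForm = runif(24, 10, 120),
    AlphaForm = runif(24, 3, 20),
    BetaWForm = runif(24, 1, 4),
    BetaSimForm = runif(24, 0.2, 0.9))
  b <- abg_plot_data(est, grouping = "period")
  expect_s3_class(b, "abg_bundle")
  expect_equal(nrow(b), 3L)
  expect_equal(sort(b$group), sort(unique(est$Period)))

  small <- dplyr::bind_rows(est, tibble::tibble(
    formation = "x", Period = "Cambrian", GammaForm = 50, AlphaForm = 5,
    BetaWForm = 2, BetaSimForm = 0.5))
  expect_warning(b2 <- abg_plot_data(small, grouping = "period"), "Cambrian")
  expect_equal(nrow(b2), 3L)

  one <- abg_plot_data(est, grouping = "all")
  expect_equal(one$group, "Phanerozoic")
  tabs <- bundle_tables(b)
  expect_equal(nrow(tabs$points), 24L)
  expect_true(all(c("group", "component", "x", "fit", "lower", "upper")
                  %in% names(tabs$bands)))
  p <- ggplot2::autoplot(b)
  expect_s3_class(p, "ggplot")
})

test_that("trajectory classification follows the z and CI rules", {
  fake_null <- structure(
    list(slopes = rnorm(200), mean_slope = 0, sd_slope = 0.05,
         n_trials = 200L, draw_size = 20L, gamma_max = 100, seed = 1L),
    class = "null_distribution")

  # strong positive slope, tiny noise: z >> 1.96 -> low_beta_first
  x <- c(5, 10, 20, 40, 80, 100)
  strong <- fit_logarithmic(x, 0.05 + 0.2 * log(x) + c(1, -1, 1, -1, 1, -1) * 1e-4)
  expect_equal(classify_trajectory(strong, fake_null)$label, "low_beta_first")

  # slope near zero with CI covering 0 -> high_beta_first
  set.seed(67)
  flat <- fit_logarithmic(runif(30, 5, 100), rnorm(30, 0.5, 0.1))
  expect_equal(classify_trajectory(flat, fake_null)$label, "high_beta_first")

  # negative, precisely estimated slope: neither rule -> indeterminate
  neg <- fit_logarithmic(x, 1 - 0.2 * log(x) + c(1, -1, 1, -1, 1, -1) * 1e-4)
  expect_equal(classify_trajectory(neg, fake_null)$label, "indeterminate")

  expect_error(classify_trajectory(strong, list()), "null")
  lin <- fit_linear(x, 2 * x)
  expect_error(classify_trajectory(lin, fake_null), "logarithmic")
})
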