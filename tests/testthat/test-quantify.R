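test_that("the Gaussian histogram fit recovers location on clean samples", {
  v <- withr::with_seed(41, rnorm(5000, 30, 10))
  fit <- fit_velocity_gaussian(v)
  expect_lt(abs(fit$mean_nt_s - 30), 0.5)
  # oracle equivalence with raw moments for untruncated samples
  expect_lt(abs(fit$mean_nt_s / mean(v) - 1), 0.02)
  expect_lt(abs(fit$sd_nt_s / sd(v) - 1), 0.1)

  # symmetric two-bin sample -> fitted mean at the centre of symmetry
  sym <- c(rep(42, 30), rep(58, 30))
  expect_equal(fit_velocity_gaussian(sym)$mean_nt_s, 50, tolerance = 0.02)

  expect_error(fit_velocity_gaussian(rnorm(5)), "at least 10")
})

test_that("the detection-floor-aware fit is unbiased under truncation", {
  # heavy truncation: N(29, 29) observed only above 5 nt/s
  v <- withr::with_seed(42, {
    x <- rnorm(3e4, 29, 29)
    while (any(x < 5)) x[x < 5] <- rnorm(sum(x < 5), 29, 29)
    x
  })
  fit <- fit_velocity_gaussian(v, detection_floor = 5)
  expect_lt(abs(fit$mean_nt_s - 29), 1)
  expect_lt(abs(fit$sd_nt_s - 29), 1.5)
})

test_that("survival curves follow the survive-at-least convention", {
  sc <- survival_curve(c(1, 2, 3))
  expect_equal(sc$surviving, c(1, 2 / 3, 1 / 3))
  # all equal -> a single step from 1
  expect_equal(unique(survival_curve(rep(7, 5))$surviving), 1)
  # large-sample quantile oracle: S(median) ~ 0.5
  d <- withr::with_seed(5, rexp(1e4, log(2) / 4100))
  sc2 <- survival_curve(d)
  at_med <- sc2$surviving[which.min(abs(sc2$distance_nt - median(d)))]
  expect_lt(abs(at_med - 0.5), 4 * sqrt(0.25 / 1e4))
})

test_that("exponential half-life fitting matches the closed form and samples", {
  # exact curve S(d) = exp(-d / 5000): half-life = 5000 ln 2
  d <- seq(50, 30000, by = 50)
  curve <- tibble::tibble(distance_nt = d, surviving = exp(-d / 5000))
  fit <- fit_survival_halflife(curve, ci = FALSE)
  expect_equal(fit$halflife_knt, 5 * log(2), tolerance = 1e-6)
  expect_equal(fit$decay_rate_per_knt * fit$halflife_knt, log(2),
               tolerance = 1e-9)

  # 1e4 draws at half-life 4100 nt -> within 2 %
  draws <- withr::with_seed(6, rexp(1e4, log(2) / 4100))
  fit2 <- fit_survival_halflife(draws, ci = FALSE)
  expect_lt(abs(fit2$halflife_knt / 4.1 - 1), 0.02)

  expect_error(fit_survival_halflife(rep(1000, 20), ci = FALSE),
               "degenerate")
})

test_that("bootstrap intervals are deterministic, consistent and shrink as 1/sqrt(n)", {
  x <- withr::with_seed(7, rnorm(200))
  ci1 <- bootstrap_ci(x, mean, n_boot = 300, seed = 9)
  ci2 <- bootstrap_ci(x, mean, n_boot = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_equal(bootstrap_ci(rep(3, 50), mean, n_boot = 100, seed = 1)$low, 3)
  expect_equal(bootstrap_ci(rep(3, 50), mean, n_boot = 100, seed = 1)$high, 3)

  widths <- purrr::map_dbl(c(50, 200, 800), function(n) {
    y <- withr::with_seed(n, rnorm(n))
    ci <- bootstrap_ci(y, mean, n_boot = 300, seed = 2)
    ci$high - ci$low
  })
  expect_true(all(diff(widths) < 0))

  # coverage of the mean at ~95 % over replicated experiments
  hits <- withr::with_seed(12, {
    vapply(1:150, function(i) {
      y <- rnorm(100)
      ci <- bootstrap_ci(y, mean, n_boot = 200)
      ci$low <= 0 && 0 <= ci$high
    }, logical(1))
  })
  expect_gt(mean(hits), 0.89)
  expect_lt(mean(hits), 0.99)
})

test_that("colocalization fractions reproduce worked examples", {
  res <- coloc_fraction(c(rep(TRUE, 270), rep(FALSE, 72)), n_boot = 100,
                        seed = 1)
  expect_equal(res$n_coloc, 270)
  expect_equal(res$n_total, 342)
  expect_equal(res$fraction, 270 / 342)
  expect_equal(res$percent, 79)
  inv <- coloc_fraction(c(rep(FALSE, 270), rep(TRUE, 72)), n_boot = 100,
                        seed = 1)
  expect_equal(inv$percent, 21)
  expect_equal(coloc_fraction(rep(FALSE, 10), n_boot = 50)$fraction, 0)
  expect_error(coloc_fraction(logical(0)), "no events")
})

test_that("binding distributions are normalised with calibrated bootstrap bands", {
  u <- withr::with_seed(8, runif(1e4) * 150000)
  # 99 % bands: with 10 bins checked jointly, 95 % per-bin bands would be
  # expected to miss somewhere in roughly 2 of 5 datasets
  bd <- binding_distribution(u, 150000, n_bins = 10, n_boot = 300,
                             level = 0.99, seed = 3)
  expect_equal(sum(bd$density), 1)
  expect_true(all(bd$ci_low <= 1 / 10 & 1 / 10 <= bd$ci_high))
  # all events in one place -> all mass in the first bin
  point <- binding_distribution(rep(0, 50), 150000, n_bins = 10,
                                n_boot = 50, seed = 3)
  expect_equal(point$density[1], 1)
  expect_error(binding_distribution(c(-5, 10), 100), "within the molecule")
})

test_that("group comparisons behave like a two-sample t test", {
  x <- withr::with_seed(9, rnorm(50))
  same <- compare_groups(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  big <- compare_groups(x, withr::with_seed(10, rnorm(50, 5)))
  expect_lt(big$p_value, 1e-10)
  # degenerate variance with equal means -> p = 1
  deg <- compare_groups(rep(2, 5), rep(2, 7))
  expect_equal(deg$p_value, 1)
  # groups simulated from printed summaries are not significantly different
  a <- withr::with_seed(11, rnorm(58, 46, 35))
  b <- withr::with_seed(12, rnorm(45, 50, 33))
  expect_gt(compare_groups(a, b)$p_value, 0.05)
  # Welch and pooled forms agree on balanced equal-variance designs
  expect_equal(compare_groups(a, b)$statistic,
               compare_groups(a, b, pooled = TRUE)$statistic, tolerance = 0.05)
})

test_that("events-per-molecule statistics include empty molecules", {
  expect_equal(events_per_molecule(integer(0), 10)$mean_per_molecule, 0)
  expect_equal(events_per_molecule(integer(0), 10)$sd_per_molecule, 0)
  one_each <- events_per_molecule(1:5, 5)
  expect_equal(one_each$mean_per_molecule, 1)
  expect_equal(one_each$sd_per_molecule, 0)
  mixed <- events_per_molecule(c(1, 1, 2), 4)
  expect_equal(mixed$mean_per_molecule, 3 / 4)
})

test_that("initial-rate fits invert the ATPase simulator", {
  tc <- simulate_atpase(256, 1e-9, 2e-3, times_s = seq(10, 2000, by = 10))
  fit <- fit_initial_rate(tc)
  expect_lt(abs(fit$kcat_s / 256 - 1), 0.01)
  # flat time course -> kcat 0
  flat <- simulate_atpase(0, 1e-9, 2e-3, times_s = seq(10, 100, by = 10))
  expect_equal(fit_initial_rate(flat)$kcat_s, 0)
  # doubling the slope doubles kcat
  tc2 <- simulate_atpase(512, 1e-9, 2e-3, times_s = seq(10, 2000, by = 10))
  expect_equal(fit_initial_rate(tc2)$kcat_s, 2 * fit$kcat_s, tolerance = 1e-6)
  expect_error(fit_initial_rate(simulate_atpase(256, 1e-6, 2e-3,
                                                times_s = c(10, 20, 30))),
               ">= 3 points")
})

test_that("rate ratios divide and round to one significant figure", {
  r <- rate_ratio(256, 0.012)
  expect_equal(r$ratio, 256 / 0.012, tolerance = 1e-12)
  expect_equal(r$ratio_1sf, 2e4)
  expect_equal(r$label, "2 x 10^4")
  expect_equal(rate_ratio(5, 5)$ratio, 1)
  expect_equal(rate_ratio(10, 2)$ratio, 5)
  expect_error(rate_ratio(10, 0), "kcat_b")
})

test_that("tidiers and autoplot produce well-formed output", {
  v <- withr::with_seed(13, rnorm(500, 40, 12))
  gf <- fit_velocity_gaussian(v)
  expect_named(broom::tidy(gf), c("term", "estimate"))
  expect_equal(nrow(broom::glance(gf)), 1)
  sf <- fit_survival_halflife(withr::with_seed(14, rexp(200, 1 / 5000)),
                              n_boot = 50, seed = 1)
  expect_true(broom::glance(sf)$ci_low <= sf$halflife_knt)
  expect_true(sf$halflife_knt <= broom::glance(sf)$ci_high)
  expect_s3_class(ggplot2::autoplot(gf), "ggplot")
  expect_s3_class(ggplot2::autoplot(sf), "ggplot")
})
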