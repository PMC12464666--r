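test_that("particle/molar conversion matches Avogadro bookkeeping", {
  # 6.02214076e20 particles/mL is exactly 1 mol/L = 1e15 fM
  expect_equal(particles_per_ml_to_femtomolar(6.02214076e20), 1e15)
  expect_equal(round(particles_per_ml_to_femtomolar(5.6e5), 2), 0.93)
  expect_equal(round(particles_per_ml_to_femtomolar(5.7e5), 2), 0.95)
  expect_error(particles_per_ml_to_femtomolar(-1), "non-negative")
})

test_that("unit conversions round-trip to 1e-12 relative", {
  x <- c(1e3, 5.6e5, 3.23e7, 7.5e8)
  back <- femtomolar_to_particles_per_ml(particles_per_ml_to_femtomolar(x))
  expect_lt(max(abs(back - x) / x), 1e-12)
  fm <- c(0.93, 600, 1e6)
  back_fm <- particles_per_ml_to_femtomolar(femtomolar_to_particles_per_ml(fm))
  expect_lt(max(abs(back_fm - fm) / fm), 1e-12)
})

test_that("calibration fitting recovers an exact line", {
  conc <- c(1e6, 3e6, 1e7, 3e7)
  q <- 2e-9 * conc + 0.001
  # lm warns on an exactly perfect fit; that is the point of this case
  curve <- suppressWarnings(fit_calibration(conc, q))
  expect_equal(curve$slope, 2e-9, tolerance = 1e-10)
  expect_equal(curve$intercept, 0.001, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$valid_range, c(1e6, 3e7))
  expect_error(fit_calibration(c(1e6, 1e6, 1e6), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(c(1, 2, 3), c(1, 2)), "paired")
})

test_that("a flat calibration is flagged unusable", {
  curve <- fit_calibration(c(1e6, 2e6, 3e6), rep(0.5, 3))
  expect_equal(curve$r_squared, 0)
  expect_lte(curve$slope, 0)
  expect_error(q_to_concentration(0.5, curve), "unusable")
})

test_that("q_to_concentration inverts the curve with range guarding", {
  conc <- c(1e6, 3e6, 1e7)
  curve <- suppressWarnings(fit_calibration(conc, 2e-9 * conc + 0.001))
  expect_equal(as.numeric(suppressWarnings(
    q_to_concentration(2e-9 * conc + 0.001, curve))),
    conc, tolerance = 1e-6)
  expect_equal(as.numeric(suppressWarnings(
    q_to_concentration(curve$intercept, curve))), 0)
  expect_warning(out <- q_to_concentration(1, curve), "outside")
  expect_true(attr(out, "out_of_range"))
})

test_that("calibration on simulated series recovers the truth-implied slope", {
  # Q responds linearly to concentration in the antibody-dominated regime;
  # the oracle slope comes from ground-truth species counts, the estimate
  # from the full detection pipeline.
  base <- quick_config(seed = 83L)
  rates <- c(5, 10, 20)
  conc_per_rate <- 1e6  # nominal particles/mL per transit/s
  runs <- simulate_concentration_series(base, rates, replicates = 3L)
  # a fixed threshold well above background keeps false events out, so the
  # detected populations line up with the ground-truth species labels
  params <- detection_params("fixed", fixed_threshold = 10)
  q_est <- vapply(runs, function(r) analyze_trace(r$trace, params)$q,
                  numeric(1))
  q_true <- vapply(runs, function(r) {
    with(r$truth, {
      n_a <- sum(n_green >= 1); n_b <- sum(n_red >= 1)
      cc <- sum(n_green >= 1 & n_red >= 1)
      cc / (n_a + n_b - cc)
    })
  }, numeric(1))
  conc <- rep(rates, each = 3L) * conc_per_rate
  est <- fit_calibration(conc, q_est)
  oracle <- fit_calibration(conc, q_true)
  expect_lt(abs(est$slope - oracle$slope) / oracle$slope, 0.1)
  expect_gt(est$r_squared, 0.9)
})

test_that("limit of blank and detection follow the 1.645-sigma arithmetic", {
  expect_equal(limit_of_blank(c(0, 0, 0)), 0)
  expect_equal(limit_of_blank(c(1, 1, 1)), 1)
  expect_equal(limit_of_blank(c(0, 1, 2)), 1 + 1.645)
  expect_equal(limit_of_detection(2.645, c(4, 5, 6)), 2.645 + 1.645)
  expect_equal(limit_of_detection(3, c(2, 2, 2)), 3)     # sd = 0 -> LoD = LoB
  expect_error(limit_of_blank(1), ">= 2")
  expect_error(limit_of_detection(1, numeric(0)), ">= 2")
  # the multiplier is a parameter
  expect_equal(limit_of_blank(c(0, 1, 2), alpha_factor = 2), 3)
})

test_that("sensitivity summary carries consistent molar conversions", {
  s <- sensitivity_summary(c(0, 1e5, 2e5), c(5e5, 6e5, 7e5))
  expect_gte(s$lod, s$lob)
  expect_gte(s$lob, 0)
  expect_equal(s$lob_molar, particles_per_ml_to_femtomolar(s$lob))
  expect_equal(s$lod_molar, particles_per_ml_to_femtomolar(s$lod))
  expect_equal(s$n_blank, 3L)
})

test_that("single-antibody brightness is a median over single-colored events", {
  expect_equal(single_antibody_intensity(rep(42, 20)), 42)
  expect_error(single_antibody_intensity(numeric(0)), "calibrant")
  expect_error(single_antibody_intensity(rep(1, 5)), "only 5")

  cfg <- quick_config(ev_rate = 0, free_ab_rate_b = 0, duration = 10,
                      seed = 89L)
  sim <- simulate_trace(cfg)
  es <- detect_events(sim$trace, "a")
  est <- single_antibody_intensity(es)
  expect_lt(abs(est - cfg$brightness) / cfg$brightness, 0.15)
})

test_that("raw stoichiometry ratio follows its definition", {
  one <- antibodies_per_ev(77.7, 77.7, method = "ratio")
  expect_equal(one$mean_antibodies_per_ev, 1.0)
  zero <- antibodies_per_ev(c(0, 0, 0), 50, method = "ratio")
  expect_equal(zero$mean_antibodies_per_ev, 0)
  three <- antibodies_per_ev(132.13, 44.04333, method = "ratio")
  expect_equal(three$mean_antibodies_per_ev, 3, tolerance = 1e-4)
  expect_equal(three$per_event, 132.13 / 44.04333)
  expect_error(antibodies_per_ev(numeric(0), 10), "no coincident")
  expect_error(antibodies_per_ev(100, 0), "positive")
})

test_that("dual-color selection correction matches an enumeration oracle", {
  # oracle: E[n | >=1 of each color] by direct enumeration of the
  # zero-truncated Poisson with Bernoulli(p) color assignment
  dual_mean <- function(lambda, p) {
    n <- 1:200
    w <- dpois(n, lambda) * (1 - (1 - p)^n - p^n)
    sum(n * w) / sum(w)
  }
  beta <- 44
  for (case in list(c(3, 0.5), c(1.5, 0.5), c(3, 0.3), c(8, 0.5))) {
    lam <- case[1]; p <- case[2]
    totals <- rep(beta * dual_mean(lam, p), 20)
    est <- antibodies_per_ev(totals, beta, p_green = p)
    expect_equal(est$mean_antibodies_per_ev, lam, tolerance = 1e-6,
                 label = sprintf("lambda recovered at (%g, %g)", lam, p))
  }
  # below the two-antibody floor the estimate collapses to zero, with warning
  expect_warning(low <- antibodies_per_ev(rep(44, 5), 44), "floor")
  expect_equal(low$mean_antibodies_per_ev, 0)
})

test_that("series fitting equals the closed-form OLS solution", {
  ols_oracle <- function(x, y, at, level = 0.95) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    yhat <- intercept + slope * x
    s <- sqrt(sum((y - yhat)^2) / (n - 2))
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    fit_at <- intercept + slope * at
    half <- qt(1 - (1 - level) / 2, n - 2) * s *
      sqrt(1 / n + (at - mean(x))^2 / sxx)
    list(slope = slope, intercept = intercept, r2 = r2, s = s,
         lwr = fit_at - half, upr = fit_at + half)
  }
  withr::local_seed(97)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- runif(n, 0, 10)
    y <- 2.5 * x - 1 + rnorm(n)
    at <- seq(min(x), max(x), length.out = 7)
    fit <- fit_series(x, y, at = at)
    o <- ols_oracle(x, y, at)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, o$r2, tolerance = 1e-10)
    expect_equal(fit$residual_sd, o$s, tolerance = 1e-10)
    expect_equal(fit$ci_band$lwr, o$lwr, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit$ci_band$upr, o$upr, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("confidence band brackets the line and is narrowest at mean(x)", {
  withr::local_seed(101)
  x <- 1:10
  y <- x + rnorm(10, sd = 0.5)
  at <- seq(1, 10, by = 0.5)
  fit <- fit_series(x, y, at = at)
  expect_true(all(fit$ci_band$lwr <= fit$ci_band$fit))
  expect_true(all(fit$ci_band$upr >= fit$ci_band$fit))
  widths <- fit$ci_band$upr - fit$ci_band$lwr
  expect_equal(at[which.min(widths)], at[which.min(abs(at - mean(x)))])
})

test_that("degenerate series fits are handled as contracts state", {
  # exact line: r^2 = 1 and a zero-width band (lm warns on perfect fits)
  fit <- suppressWarnings(fit_series(1:5, 2 * (1:5) + 1))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residual_sd, 0)
  expect_equal(max(fit$ci_band$upr - fit$ci_band$lwr), 0)
  # constant response: r^2 = 0 by definition
  expect_equal(suppressWarnings(fit_series(1:5, rep(3, 5)))$r_squared, 0)
  expect_error(fit_series(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_series(1:2, 1:2), ">= 3")
})

test_that("intensity histograms bin and conserve counts", {
  h1 <- intensity_histogram(55, bin_width = 10, range = c(0, 100))
  expect_equal(sum(h1$count), 1L)
  expect_equal(h1$count[h1$lower == 50], 1L)

  withr::local_seed(103)
  v <- rpois(500, 130)
  h <- intensity_histogram(v, bin_width = 10, range = c(0, max(v)))
  expect_equal(sum(h$count), length(v))
  expect_equal(attr(h, "n_dropped"), 0L)
  # histogram mean tracks the sample mean to within a bin width
  expect_lt(abs(sum(h$midpoint * h$count) / sum(h$count) - mean(v)), 10)

  # default range drops the top tail and reports it
  h99 <- intensity_histogram(c(rep(10, 99), 1e6))
  expect_gte(attr(h99, "n_dropped"), 1L)
  expect_error(intensity_histogram(numeric(0)), "non-empty")
})

test_that("simulated coincident intensities match brightness x stoichiometry", {
  cfg <- quick_config(ev_rate = 30, duration = 20, seed = 107L)
  sim <- simulate_trace(cfg)
  ea <- detect_events(sim$trace, "a")
  eb <- detect_events(sim$trace, "b")
  tab <- coincident_intensity_table(ea, eb)
  # expected mean total intensity of dual-colored EVs: brightness times the
  # dual-color conditional mean copy number (enumeration, as above)
  n <- 1:200
  w <- dpois(n, 3) * (1 - 2 * 0.5^n)
  expected <- cfg$brightness * sum(n * w) / sum(w)
  expect_lt(abs(mean(tab$total) - expected) / expected, 0.1)
})
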