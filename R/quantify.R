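AVOGADRO <- 6.02214076e23  # mol^-1 (exact, SI definition)

#' Convert between particles/mL and femtomolar concentration
#'
#' `particles_per_ml_to_femtomolar(c)` returns `c * 1e3 / N_A` expressed in
#' fM (1 fM = 1e-15 mol/L); `femtomolar_to_particles_per_ml` is its exact
#' inverse. For example, 5.6e5 particles/mL is 0.93 fM.
#'
#' @param particles_per_ml Particle concentration in particles per mL
#'   (non-negative).
#' @param femtomolar Molar concentration in fM (non-negative).
#' @return The converted concentration (vectorized).
#' @examples
#' particles_per_ml_to_femtomolar(5.6e5)  # 0.93 fM
#' @export
particles_per_ml_to_femtomolar <- function(particles_per_ml) {
  if (any(particles_per_ml < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  particles_per_ml * 1e18 / AVOGADRO
}

#' @rdname particles_per_ml_to_femtomolar
#' @export
femtomolar_to_particles_per_ml <- function(femtomolar) {
  if (any(femtomolar < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  femtomolar * AVOGADRO / 1e18
}

#' Fit a Q-versus-concentration calibration curve
#'
#' Ordinary least-squares line `Q = slope * concentration + intercept` over
#' the supplied calibrant range (e.g. dye-filled synthetic vesicles at known
#' particle concentrations). No saturation model is fitted: at high analyte
#' levels Q is expected to roll off as free antibody depletes, so use of the
#' curve outside its fitted range is flagged, never silently trusted.
#'
#' @param concentrations Particle concentrations (particles/mL); at least 3
#'   distinct values.
#' @param q_values Paired association quotients.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `n_points` and `valid_range`.
#' @export
fit_calibration <- function(concentrations, q_values) {
  if (length(concentrations) != length(q_values)) {
    stop("concentrations and q_values must be paired", call. = FALSE)
  }
  if (length(unique(concentrations)) < 3L) {
    stop("calibration needs >= 3 distinct concentrations", call. = FALSE)
  }
  if (stats::sd(concentrations) == 0) {
    stop("concentrations have zero variance", call. = FALSE)
  }
  fit <- stats::lm(q_values ~ concentrations)
  r2 <- if (stats::var(q_values) == 0) 0 else summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(concentrations),
                 valid_range = range(concentrations)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> Q = %.4g * c + %.4g  (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  valid range: %.4g to %.4g particles/mL\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Convert an association quotient to a particle concentration
#'
#' Inverts the calibration line: `(q - intercept) / slope`, floored at zero.
#' Values mapping outside the calibrated range are returned but flagged with
#' a warning and an `out_of_range` attribute.
#'
#' @param q Association quotient(s).
#' @param curve A [fit_calibration()] curve with positive slope.
#' @return Concentration(s) in particles/mL, with a logical `out_of_range`
#'   attribute per element.
#' @export
q_to_concentration <- function(q, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) {
    stop("calibration curve is unusable: slope must be positive",
         call. = FALSE)
  }
  conc <- pmax((q - curve$intercept) / curve$slope, 0)
  oor <- conc < curve$valid_range[1] | conc > curve$valid_range[2]
  if (any(oor)) {
    warning(sprintf("%d value(s) map outside the calibrated range [%g, %g]",
                    sum(oor), curve$valid_range[1], curve$valid_range[2]),
            call. = FALSE)
  }
  attr(conc, "out_of_range") <- oor
  conc
}

#' Limit of blank and limit of detection
#'
#' CLSI-style one-sided 95% limits on the calibrated concentration readout:
#' `LoB = mean(blanks) + alpha_factor * sd(blanks)` over replicate
#' measurements of a sample containing no analyte, and
#' `LoD = LoB + alpha_factor * sd(low_sample_values)` over replicates of a
#' low-concentration sample. Standard deviations use the n-1 denominator;
#' `alpha_factor` defaults to 1.645 (the one-sided 95% normal quantile) and
#' is a parameter.
#'
#' @param blank_values Concentration estimates from >= 2 blank replicates.
#' @param lob A limit of blank, from [limit_of_blank()].
#' @param low_sample_values Concentration estimates from >= 2 replicates of
#'   a low-concentration sample.
#' @param alpha_factor One-sided quantile multiplier (default 1.645).
#' @return The limit, in the units of the supplied estimates.
#' @examples
#' limit_of_blank(c(0, 1, 2))            # 1 + 1.645 * 1
#' limit_of_detection(2.645, c(4, 5, 6)) # 2.645 + 1.645 * 1
#' @export
limit_of_blank <- function(blank_values, alpha_factor = 1.645) {
  if (length(blank_values) < 2L) {
    stop("limit of blank needs >= 2 blank replicates", call. = FALSE)
  }
  mean(blank_values) + alpha_factor * stats::sd(blank_values)
}

#' @rdname limit_of_blank
#' @export
limit_of_detection <- function(lob, low_sample_values,
                               alpha_factor = 1.645) {
  if (length(low_sample_values) < 2L) {
    stop("limit of detection needs >= 2 low-sample replicates",
         call. = FALSE)
  }
  lob + alpha_factor * stats::sd(low_sample_values)
}

#' Assay sensitivity summary
#'
#' Convenience wrapper combining [limit_of_blank()] and
#' [limit_of_detection()] on concentration estimates in particles/mL, with
#' the femtomolar equivalents attached.
#'
#' @param blank_values Blank-replicate concentration estimates
#'   (particles/mL).
#' @param low_sample_values Low-sample replicate estimates (particles/mL).
#' @param alpha_factor One-sided quantile multiplier (default 1.645).
#' @return An object of class `sensitivity_result` with `lob`, `lod`
#'   (particles/mL), `lob_molar`, `lod_molar` (fM), `n_blank`, `n_low` and
#'   `alpha_factor`.
#' @export
sensitivity_summary <- function(blank_values, low_sample_values,
                                alpha_factor = 1.645) {
  lob <- limit_of_blank(blank_values, alpha_factor)
  lod <- limit_of_detection(lob, low_sample_values, alpha_factor)
  structure(list(lob = lob, lod = lod,
                 lob_molar = particles_per_ml_to_femtomolar(max(lob, 0)),
                 lod_molar = particles_per_ml_to_femtomolar(max(lod, 0)),
                 n_blank = length(blank_values),
                 n_low = length(low_sample_values),
                 alpha_factor = alpha_factor),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> (alpha factor %.3f)\n", x$alpha_factor))
  cat(sprintf("  LoB = %.4g particles/mL (%.3g fM), n_blank = %d\n",
              x$lob, x$lob_molar, x$n_blank))
  cat(sprintf("  LoD = %.4g particles/mL (%.3g fM), n_low = %d\n",
              x$lod, x$lod_molar, x$n_low))
  invisible(x)
}

#' Single-antibody burst brightness from single-colored events
#'
#' The median background-corrected intensity of single-colored
#' (non-coincident) events in one channel — the brightness calibrant for
#' antibodies-per-vesicle stoichiometry. The median is used rather than the
#' mean because rare aggregates contaminating the single-colored population
#' would drag a mean upwards.
#'
#' When an `event_set` is supplied, events whose peak count does not clear
#' the detection threshold by more than `peak_margin` are excluded first.
#' At sub-count-per-bin backgrounds the threshold sits only a few counts
#' above zero, and background fluctuations that barely cross it form a
#' false-event population clustered at the detection limit; genuine
#' single-fluorophore bursts peak at the full fluorophore brightness, far
#' above it. The margin removes the former and not the latter (the
#' estimator assumes the single-fluorophore brightness is well above
#' threshold, which detection itself already requires).
#'
#' @param events An `event_set` (e.g. one channel of
#'   [noncoincident_events()]) or a numeric vector of event intensities
#'   (used as given, no filtering).
#' @param min_events Minimum events required after filtering (default 10).
#' @param peak_margin Counts by which an event's peak must exceed the
#'   detection threshold to enter the median (default 1; only applies to
#'   `event_set` input).
#' @return Median intensity in photon counts.
#' @export
single_antibody_intensity <- function(events, min_events = 10L,
                                      peak_margin = 1L) {
  if (inherits(events, "event_set")) {
    keep <- events$events$peak_count > events$threshold + peak_margin
    x <- events$events$intensity[keep]
  } else {
    x <- events
  }
  if (length(x) < min_events) {
    stop(sprintf(paste("only %d single-colored events (need >= %d);",
                       "supply an external calibrant intensity instead"),
                 length(x), min_events), call. = FALSE)
  }
  stats::median(x)
}

# Mean total antibody copies on a vesicle *given* that both colors are
# present, under n ~ Poisson(lambda) copies thinned Bernoulli(p) into
# colors: the color counts are independent Poissons, each conditioned >= 1.
mean_abs_given_dual_color <- function(lambda, p_green) {
  term <- function(l) if (l == 0) 1 else l / (1 - exp(-l))
  term(lambda * p_green) + term(lambda * (1 - p_green))
}

#' Mean antibodies per vesicle from coincident burst intensities
#'
#' Estimates the mean antibody copy number per EV from the total (A + B)
#' background-corrected intensity of coincident bursts, scaled by the
#' single-antibody brightness. The raw ratio
#' `mean(coincident_totals) / single_ab_intensity` estimates the mean copy
#' number *of the dual-colored subpopulation*: requiring a burst in both
#' channels censors vesicles whose antibodies all carried one color, which
#' biases the raw ratio upward (e.g. for a population mean of 3 with an
#' equimolar color mix, the dual-colored subpopulation averages 3.86). The
#' default method inverts that selection under a zero-truncated-Poisson copy
#'-number model with Bernoulli color assignment, returning the population
#' mean; `method = "ratio"` returns the uncorrected ratio.
#'
#' @param coincident_totals Total intensities of coincident bursts, e.g.
#'   the `total` column of [coincident_intensity_table()].
#' @param single_ab_intensity Single-antibody brightness in photon counts
#'   (> 0), e.g. from [single_antibody_intensity()].
#' @param method `"ztp_corrected"` (default) or `"ratio"`; see Details.
#' @param p_green Probability an antibody carries the channel-A fluorophore
#'   (used by the correction; default 0.5).
#' @return An object of class `stoichiometry_estimate`: a list with
#'   `mean_antibodies_per_ev`, the uncorrected `raw_ratio`, the `method`,
#'   and `per_event` (raw per-event intensity ratios, for histograms).
#' @export
antibodies_per_ev <- function(coincident_totals, single_ab_intensity,
                              method = c("ztp_corrected", "ratio"),
                              p_green = 0.5) {
  method <- match.arg(method)
  if (length(coincident_totals) < 1L) {
    stop("no coincident bursts supplied", call. = FALSE)
  }
  if (!is.numeric(single_ab_intensity) || single_ab_intensity <= 0) {
    stop("single_ab_intensity must be positive", call. = FALSE)
  }
  if (p_green <= 0 || p_green >= 1) {
    stop("p_green must lie strictly in (0, 1) for dual-color detection",
         call. = FALSE)
  }
  per_event <- coincident_totals / single_ab_intensity
  raw <- mean(per_event)
  est <- raw
  if (method == "ztp_corrected") {
    floor_val <- mean_abs_given_dual_color(0, p_green)  # limit as lambda -> 0
    if (raw <= floor_val) {
      warning(paste("mean dual-color intensity is at or below the",
                    "two-antibody detection floor; returning 0"),
              call. = FALSE)
      est <- 0
    } else {
      est <- stats::uniroot(
        function(l) mean_abs_given_dual_color(l, p_green) - raw,
        lower = 1e-8, upper = 1e4, tol = 1e-10)$root
    }
  }
  structure(list(mean_antibodies_per_ev = est, raw_ratio = raw,
                 method = method, p_green = p_green,
                 n_events = length(coincident_totals),
                 per_event = per_event),
            class = "stoichiometry_estimate")
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  cat(sprintf(
    "<stoichiometry_estimate> %.3g antibodies/EV (%s; raw ratio %.3g, n = %d)\n",
    x$mean_antibodies_per_ev, x$method, x$raw_ratio, x$n_events))
  invisible(x)
}

#' Ordinary least-squares fit with pointwise confidence band
#'
#' Fits `y = slope * x + intercept` and returns the fit diagnostics and the
#' pointwise confidence band on the fitted values,
#' `yhat(x) +/- t(1 - (1-confidence)/2, n-2) * s * sqrt(1/n + (x - xbar)^2 / Sxx)`,
#' as drawn as the shaded band around concentration-series fits.
#'
#' @param x Predictor (e.g. particle concentration); >= 3 points with
#'   nonzero variance.
#' @param y Response (e.g. coincident event rate or Q).
#' @param confidence Band coverage (default 0.95).
#' @param at Points at which to evaluate the band (default `x`).
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n`, `confidence`, and `ci_band`, a data
#'   frame with columns `x`, `fit`, `lwr`, `upr`.
#' @export
fit_series <- function(x, y, confidence = 0.95, at = x) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  band <- stats::predict(fit, newdata = data.frame(x = at),
                         interval = "confidence", level = confidence)
  r2 <- if (stats::var(y) == 0) 0 else summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 residual_sd = summary(fit)$sigma,
                 n = length(x), confidence = confidence,
                 ci_band = data.frame(x = at, fit = band[, "fit"],
                                      lwr = band[, "lwr"],
                                      upr = band[, "upr"])),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4g x + %.4g\n", x$slope, x$intercept))
  cat(sprintf("  r^2 = %.4f, residual sd = %.4g, n = %d (%.0f%% band)\n",
              x$r_squared, x$residual_sd, x$n, 100 * x$confidence))
  invisible(x)
}

#' Histogram of burst intensities
#'
#' Equal-width binning of event intensities (e.g. coincident totals per EV
#' concentration). The default range runs from 0 to the 99th percentile so a
#' handful of very bright aggregates do not stretch the axis; values outside
#' the range are dropped and reported. Bins are left-closed, right-open,
#' except the last which is closed.
#'
#' @param values Non-empty numeric vector of intensities.
#' @param bin_width Bin width in photon counts (default 10).
#' @param range Length-2 numeric range; default
#'   `c(0, quantile(values, 0.99))`.
#' @return A data frame with columns `lower`, `upper`, `midpoint`, `count`,
#'   plus an attribute `n_dropped` (values outside the range).
#' @export
intensity_histogram <- function(values, bin_width = 10, range = NULL) {
  if (length(values) < 1L) stop("values must be non-empty", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (is.null(range)) {
    range <- c(0, unname(stats::quantile(values, 0.99)))
  }
  if (length(range) != 2L || range[2] < range[1]) {
    stop("range must be c(lo, hi) with hi >= lo", call. = FALSE)
  }
  edges <- seq(range[1], range[2] + bin_width, by = bin_width)
  keep <- values >= range[1] & values <= range[2]
  idx <- pmin(floor((values[keep] - range[1]) / bin_width) + 1L,
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1L],
                    midpoint = (edges[-length(edges)] + edges[-1L]) / 2,
                    count = counts)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
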