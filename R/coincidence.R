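check_same_source <- function(events_a, events_b) {
  stopifnot(inherits(events_a, "event_set"), inherits(events_b, "event_set"))
  if (events_a$source_n_bins != events_b$source_n_bins ||
      !isTRUE(all.equal(events_a$source_bin_width,
                        events_b$source_bin_width))) {
    stop("event sets derive from different traces (n_bins or bin_width differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Greedy one-to-one matching of overlapping spans, walking both channels in
# bin order; each event is matched at most once. Returns index pairs.
match_events <- function(ev_a, ev_b) {
  na <- nrow(ev_a); nb <- nrow(ev_b)
  cap <- min(na, nb)
  ia <- integer(cap); ib <- integer(cap); k <- 0L
  sa <- ev_a$start_bin; ea <- ev_a$end_bin
  sb <- ev_b$start_bin; eb <- ev_b$end_bin
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    if (ea[i] < sb[j]) {
      i <- i + 1L
    } else if (eb[j] < sa[i]) {
      j <- j + 1L
    } else {
      k <- k + 1L
      ia[k] <- i; ib[k] <- j
      i <- i + 1L; j <- j + 1L
    }
  }
  list(a = ia[seq_len(k)], b = ib[seq_len(k)])
}

# Total number of bins covered by both channels' events (bin-level
# coincidence), via reconstructed supra-threshold bin masks.
span_mask <- function(ev, n_bins) {
  mask <- logical(n_bins)
  if (nrow(ev)) {
    len <- ev$end_bin - ev$start_bin + 1L
    mask[sequence(len, from = ev$start_bin + 1L)] <- TRUE
  }
  mask
}

overlap_bins <- function(ev_a, ev_b, n_bins) {
  sum(span_mask(ev_a, n_bins) & span_mask(ev_b, n_bins))
}

#' Count coincident events between the two channels
#'
#' @param events_a,events_b `event_set`s from [detect_events()] on the same
#'   trace (same bin count and width; anything else is an error).
#' @param mode `"event_level"` (default): number of channel-A events whose
#'   bin span overlaps at least one channel-B event's span, each event
#'   matched at most once by a greedy sweep in bin order. `"bin_level"`:
#'   number of bins supra-threshold in both channels.
#' @return Integer count of observed coincidences `c_obs`.
#' @export
count_coincidences <- function(events_a, events_b,
                               mode = c("event_level", "bin_level")) {
  mode <- match.arg(mode)
  check_same_source(events_a, events_b)
  if (mode == "bin_level") {
    return(as.integer(overlap_bins(events_a$events, events_b$events,
                                   events_a$source_n_bins)))
  }
  length(match_events(events_a$events, events_b$events)$a)
}

#' Expected chance coincidences of two independent event streams
#'
#' For two independent rare processes occupying `n_a` and `n_b` of `n_bins`
#' bins uniformly at random, the expected number of co-occupied bins is
#' `n_a * n_b / n_bins`. This is the null against which observed
#' coincidences are corrected. It is exact for bin-level statistics; for
#' merged (event-level) counts it is an approximation valid when events are
#' rare and short.
#'
#' @param n_a,n_b Event counts in channels A and B.
#' @param n_bins Number of bins in the source trace.
#' @return Expected chance coincidences (a real number).
#' @export
chance_coincidences <- function(n_a, n_b, n_bins) {
  stopifnot(n_bins >= 1, n_a >= 0, n_b >= 0)
  n_a * n_b / n_bins
}

#' Association quotient Q
#'
#' The chance-corrected fraction of events that are coincident: with
#' `C = max(c_obs - e_chance, 0)`,
#' `Q = C / (n_a + n_b - C)` (variant `"corrected"`, the default) or
#' `Q = C / (n_a + n_b - c_obs)` (variant `"observed"`, which removes the
#' observed rather than the corrected coincidences from the denominator).
#' Both variants are 0 when the denominator is 0, and lie in `[0, 1]`.
#'
#' @param n_a,n_b Event counts in channels A and B.
#' @param c_obs Observed coincidences (`<= min(n_a, n_b)`).
#' @param e_chance Expected chance coincidences, e.g. from
#'   [chance_coincidences()].
#' @param variant Denominator convention; see Details. Outputs downstream
#'   record which variant was used.
#' @return Q in `[0, 1]`.
#' @examples
#' association_quotient(110, 105, 11, 1)  # 10/205
#' @export
association_quotient <- function(n_a, n_b, c_obs, e_chance,
                                 variant = c("corrected", "observed")) {
  variant <- match.arg(variant)
  stopifnot(e_chance >= 0, c_obs >= 0)
  if (c_obs > min(n_a, n_b)) {
    stop("c_obs cannot exceed min(n_a, n_b)", call. = FALSE)
  }
  c_corr <- max(c_obs - e_chance, 0)
  den <- if (variant == "corrected") n_a + n_b - c_corr else
    n_a + n_b - c_obs
  if (den <= 0) return(0)
  min(c_corr / den, 1)
}

#' Full TCCD analysis of one trace
#'
#' Runs the burst search on both channels, counts coincidences, applies the
#' chance-coincidence correction, and computes the association quotient and
#' the chance-corrected coincident event rate (`C / duration`, i.e. specific
#' analyte transits per second).
#'
#' @param trace A [time_trace()].
#' @param params A [detection_params()] applied to both channels.
#' @param mode Coincidence mode, as in [count_coincidences()]. In
#'   `"bin_level"` mode `n_a`/`n_b` are supra-threshold bin counts rather
#'   than merged event counts, so that the chance null is exact.
#' @param q_variant Q denominator convention, as in [association_quotient()].
#' @return An object of class `coincidence_summary` with fields `n_a`,
#'   `n_b`, `c_obs`, `e_chance`, `c_corr`, `q`, `event_rate` (per second),
#'   `duration` (seconds), `mode`, `q_variant`, and per-channel `threshold_a`,
#'   `threshold_b`, `background_a`, `background_b`.
#' @examples
#' sim <- simulate_trace(sim_config(duration = 2, seed = 3))
#' analyze_trace(sim$trace)
#' @export
analyze_trace <- function(trace, params = detection_params(),
                          mode = c("event_level", "bin_level"),
                          q_variant = c("corrected", "observed")) {
  mode <- match.arg(mode)
  q_variant <- match.arg(q_variant)
  ea <- detect_events(trace, "a", params)
  eb <- detect_events(trace, "b", params)
  nb <- n_bins(trace)
  if (mode == "bin_level") {
    n_a <- sum(ea$events$end_bin - ea$events$start_bin + 1L)
    n_b <- sum(eb$events$end_bin - eb$events$start_bin + 1L)
    c_obs <- count_coincidences(ea, eb, "bin_level")
  } else {
    n_a <- nrow(ea$events)
    n_b <- nrow(eb$events)
    c_obs <- count_coincidences(ea, eb, "event_level")
  }
  e <- chance_coincidences(n_a, n_b, nb)
  c_corr <- max(c_obs - e, 0)
  q <- association_quotient(n_a, n_b, c_obs, e, q_variant)
  dur <- trace_duration(trace)
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 c_obs = as.integer(c_obs), e_chance = e, c_corr = c_corr,
                 q = q, event_rate = c_corr / dur, duration = dur,
                 mode = mode, q_variant = q_variant,
                 threshold_a = ea$threshold, threshold_b = eb$threshold,
                 background_a = ea$background, background_b = eb$background),
            class = "coincidence_summary")
}

#' @export
print.coincidence_summary <- function(x, ...) {
  cat(sprintf("<coincidence_summary> (%s, Q variant '%s')\n", x$mode,
              x$q_variant))
  cat(sprintf("  n_a = %d, n_b = %d, c_obs = %d\n", x$n_a, x$n_b, x$c_obs))
  cat(sprintf("  chance E = %.4g  ->  corrected C = %.4g\n", x$e_chance,
              x$c_corr))
  cat(sprintf("  Q = %.4g; event rate = %.4g /s over %.4g s\n", x$q,
              x$event_rate, x$duration))
  invisible(x)
}

#' @export
as.data.frame.coincidence_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Serialize an analysis summary to JSON
#'
#' Writes every `coincidence_summary` field (including the detection
#' thresholds, backgrounds, mode and Q-variant tag) for auditability.
#'
#' @param summary A `coincidence_summary` from [analyze_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "coincidence_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Intensity table of coincident event pairs
#'
#' One row per matched (coincident) A/B event pair, with the background-
#' corrected intensity in each channel and their total — the input for
#' intensity histograms and antibodies-per-vesicle stoichiometry. Pairing
#' uses the same greedy span-overlap matching as event-level
#' [count_coincidences()], so with `mode = "event_level"` the table has
#' exactly `c_obs` rows.
#'
#' @param events_a,events_b `event_set`s from the same trace.
#' @param mode Kept for symmetry with [count_coincidences()]; pairing is
#'   span-overlap based in both modes.
#' @return Data frame with columns `intensity_a`, `intensity_b`, `total`.
#' @export
coincident_intensity_table <- function(events_a, events_b,
                                       mode = c("event_level", "bin_level")) {
  mode <- match.arg(mode)
  check_same_source(events_a, events_b)
  m <- match_events(events_a$events, events_b$events)
  ia <- events_a$events$intensity[m$a]
  ib <- events_b$events$intensity[m$b]
  data.frame(intensity_a = ia, intensity_b = ib, total = ia + ib)
}

#' Split event sets into coincident and single-colored populations
#'
#' Convenience for stoichiometry work: the unmatched ("single-colored")
#' events of each channel calibrate the single-antibody brightness, while
#' the matched pairs feed [coincident_intensity_table()].
#'
#' @param events_a,events_b `event_set`s from the same trace.
#' @return A list with `a` and `b`, each an `event_set` containing only the
#'   events with no span-overlapping partner in the other channel.
#' @export
noncoincident_events <- function(events_a, events_b) {
  check_same_source(events_a, events_b)
  m <- match_events(events_a$events, events_b$events)
  drop_rows <- function(es, idx) {
    out <- es
    if (length(idx)) out$events <- es$events[-idx, , drop = FALSE]
    rownames(out$events) <- NULL
    out
  }
  list(a = drop_rows(events_a, m$a), b = drop_rows(events_b, m$b))
}
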