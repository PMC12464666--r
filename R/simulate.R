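#' Simulation configuration for dual-labeled vesicle transits
#'
#' Parameterizes the generative model of a TCCD acquisition under fast flow:
#' Poisson background photons in each channel, rare single-bin bursts from
#' free (single-labeled) antibodies, dual-antibody-tagged EVs, and unlabeled
#' contaminant particles (LUVs, lipoproteins, protein oligomers) that transit
#' the confocal volume but emit nothing.
#'
#' @param bin_width Bin width in seconds (default `1e-4`).
#' @param duration Acquisition length in seconds (default 100).
#' @param background_a,background_b Mean background counts per bin per
#'   channel (Poisson; default 0.3, a typical few-kHz detector/buffer
#'   background at 0.1 ms binning).
#' @param ev_rate Expected EV transits per second; proportional to EV
#'   concentration at fixed flow (default 20).
#' @param free_ab_rate_a,free_ab_rate_b Expected free-antibody transits per
#'   second carrying the channel-A or channel-B fluorophore (default 50
#'   each; the free-antibody level is a free parameter of the assay mix).
#' @param contaminant_rate Expected transits per second of unlabeled
#'   particles (default 0). Contaminants are recorded in the ground-truth
#'   log but deposit no photons unless `nonspecific_abs_per_contaminant > 0`.
#' @param mean_abs_per_ev Mean antibody copies bound per EV (lambda of a
#'   zero-truncated Poisson; default 3, matching tetraspanin copy numbers of
#'   a few per vesicle). Zero-truncation reflects that an EV binding no
#'   antibody is invisible and does not contribute to the labeled-EV rate.
#' @param p_green Probability that any bound antibody carries the channel-A
#'   fluorophore (default 0.5, an equimolar two-color antibody mix).
#' @param brightness Mean photons emitted per fluorophore per transit, into
#'   its own channel (default 44).
#' @param crosstalk Fraction of channel-A photons duplicated into channel B
#'   (default 0). Applied after all signal and background generation.
#' @param nonspecific_abs_per_contaminant Mean antibodies nonspecifically
#'   bound per contaminant transit (plain Poisson, default 0); provided for
#'   sensitivity analyses of imperfect specificity.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   full configuration.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_trace()]
#' @export
sim_config <- function(bin_width = 1e-4, duration = 100,
                       background_a = 0.3, background_b = 0.3,
                       ev_rate = 20, free_ab_rate_a = 50, free_ab_rate_b = 50,
                       contaminant_rate = 0, mean_abs_per_ev = 3,
                       p_green = 0.5, brightness = 44, crosstalk = 0,
                       nonspecific_abs_per_contaminant = 0, seed = 1L) {
  cfg <- list(bin_width = bin_width, duration = duration,
              background_a = background_a, background_b = background_b,
              ev_rate = ev_rate, free_ab_rate_a = free_ab_rate_a,
              free_ab_rate_b = free_ab_rate_b,
              contaminant_rate = contaminant_rate,
              mean_abs_per_ev = mean_abs_per_ev, p_green = p_green,
              brightness = brightness, crosstalk = crosstalk,
              nonspecific_abs_per_contaminant = nonspecific_abs_per_contaminant,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  nonneg <- c("background_a", "background_b", "ev_rate", "free_ab_rate_a",
              "free_ab_rate_b", "contaminant_rate", "mean_abs_per_ev",
              "brightness", "nonspecific_abs_per_contaminant")
  for (f in nonneg) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("%s must be a single non-negative number", f),
           call. = FALSE)
    }
  }
  if (!num1(cfg$bin_width) || cfg$bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  if (!num1(cfg$duration) || cfg$duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  if (!num1(cfg$p_green) || cfg$p_green < 0 || cfg$p_green > 1) {
    stop("p_green must lie in [0, 1]", call. = FALSE)
  }
  if (!num1(cfg$crosstalk) || cfg$crosstalk < 0 || cfg$crosstalk > 1) {
    stop("crosstalk must lie in [0, 1]", call. = FALSE)
  }
  if (floor(cfg$duration / cfg$bin_width) < 1) {
    stop("duration/bin_width yields < 1 bin", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %s: %g\n", f, x[[f]]))
  invisible(x)
}

# Zero-truncated Poisson deviates via the inverse-CDF trick: a uniform on
# (P(X=0), 1] pushed through qpois never lands on zero.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  if (lambda == 0) return(rep(1L, n))  # degenerate limit: exactly one copy
  as.integer(stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda))
}

#' Simulate a two-channel photon trace with ground truth
#'
#' Draws one acquisition from the generative model. Transit counts per
#' species are Poisson(rate x duration); each transit lands in one uniformly
#' random bin (single-bin deposition: the transit time under fast flow is at
#' most one bin). An EV binds `n ~` zero-truncated Poisson(`mean_abs_per_ev`)
#' antibodies, each independently "green" with probability `p_green`; the
#' transit deposits Poisson(`brightness` x n_green) photons into channel A
#' and Poisson(`brightness` x n_red) into channel B. Free antibodies deposit
#' one fluorophore's worth into their own channel; contaminants deposit
#' nothing (unless nonspecific binding is enabled). Poisson background is
#' added per bin per channel, and crosstalk (if any) duplicates a binomial
#' fraction of each bin's channel-A counts into channel B afterwards.
#' Transits falling in the same bin simply sum their photons.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{trace}{a [time_trace()];}
#'     \item{truth}{the ground-truth log, a data frame with one row per
#'       transit: `bin` (0-based), `species` (one of `"EV"`, `"FREE_AB_A"`,
#'       `"FREE_AB_B"`, `"CONTAMINANT"`), `n_green`, `n_red` (fluorophore
#'       copies carried).}
#'   }
#' @examples
#' sim <- simulate_trace(sim_config(duration = 1, seed = 7))
#' table(sim$truth$species)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  nb <- as.integer(floor(config$duration / config$bin_width))
  withr::with_seed(config$seed, {
    draw_species <- function(rate, species, n_green_fun) {
      n <- stats::rpois(1L, rate * config$duration)
      if (n == 0L) {
        return(data.frame(bin = integer(0), species = character(0),
                          n_green = integer(0), n_red = integer(0),
                          stringsAsFactors = FALSE))
      }
      bins <- sample.int(nb, n, replace = TRUE) - 1L
      gr <- n_green_fun(n)
      data.frame(bin = bins, species = rep(species, n),
                 n_green = gr$green, n_red = gr$red,
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(
      draw_species(config$ev_rate, "EV", function(n) {
        nab <- rztpois(n, config$mean_abs_per_ev)
        g <- stats::rbinom(n, nab, config$p_green)
        list(green = g, red = nab - g)
      }),
      draw_species(config$free_ab_rate_a, "FREE_AB_A", function(n) {
        list(green = rep(1L, n), red = rep(0L, n))
      }),
      draw_species(config$free_ab_rate_b, "FREE_AB_B", function(n) {
        list(green = rep(0L, n), red = rep(1L, n))
      }),
      draw_species(config$contaminant_rate, "CONTAMINANT", function(n) {
        nab <- stats::rpois(n, config$nonspecific_abs_per_contaminant)
        g <- stats::rbinom(n, nab, config$p_green)
        list(green = g, red = nab - g)
      })
    )
    truth <- truth[order(truth$bin), , drop = FALSE]
    rownames(truth) <- NULL

    deposit <- function(base, n_fluor) {
      sel <- n_fluor > 0L
      if (any(sel)) {
        ph <- stats::rpois(sum(sel), config$brightness * n_fluor[sel])
        agg <- rowsum(ph, truth$bin[sel])
        at <- as.integer(rownames(agg)) + 1L
        base[at] <- base[at] + as.integer(agg[, 1L])
      }
      base
    }
    counts_a <- deposit(stats::rpois(nb, config$background_a), truth$n_green)
    counts_b <- deposit(stats::rpois(nb, config$background_b), truth$n_red)
    if (config$crosstalk > 0) {
      counts_b <- counts_b + stats::rbinom(nb, counts_a, config$crosstalk)
    }
    trace <- time_trace(counts_a, counts_b, bin_width = config$bin_width,
                        metadata = list(simulated = "true",
                                        seed = config$seed))
    list(trace = trace, truth = truth)
  })
}

# seed + run index keeps series members reproducible yet independent
derive_seed <- function(base_seed, run_index) {
  as.integer((as.numeric(base_seed) + run_index) %% 2147483647)
}

#' Simulate a concentration series
#'
#' One acquisition per (EV rate, replicate), all other parameters held fixed
#' (a fixed antibody concentration), with seeds derived as base seed + run
#' index so replicates carry independent noise.
#'
#' @param base A [sim_config()] providing all parameters except `ev_rate`.
#' @param ev_rates Non-empty vector of EV transit rates (per second), the
#'   stand-in for a dilution series spanning the concentration range.
#' @param replicates Replicate acquisitions per rate (default 1).
#' @return A list with one element per run:
#'   `list(trace, truth, ev_rate, replicate)`, ordered rate-major.
#' @export
simulate_concentration_series <- function(base, ev_rates, replicates = 1L) {
  stopifnot(inherits(base, "sim_config"))
  if (length(ev_rates) < 1L) stop("ev_rates must be non-empty", call. = FALSE)
  if (any(ev_rates < 0)) stop("ev_rates must be non-negative", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  run <- 0L
  out <- list()
  for (r in ev_rates) {
    for (j in seq_len(replicates)) {
      cfg <- base
      cfg$ev_rate <- r
      cfg$seed <- derive_seed(base$seed, run)
      sim <- simulate_trace(cfg)
      out[[length(out) + 1L]] <- list(trace = sim$trace, truth = sim$truth,
                                      ev_rate = r, replicate = j)
      run <- run + 1L
    }
  }
  out
}

#' Simulate a constant-total-particle mixture series
#'
#' Emulates the specificity experiment in which EVs are mixed with unlabeled
#' EV-sized vesicles (LUVs) such that the total particle load is constant
#' while the EV fraction varies: for each fraction `f`, `ev_rate = f *
#' total_rate` and `contaminant_rate = (1 - f) * total_rate`.
#'
#' @param base A [sim_config()] providing all parameters except the two
#'   rates.
#' @param total_rate Total particle transit rate per second (constant across
#'   the series).
#' @param ev_fractions Vector of EV fractions in `[0, 1]`.
#' @param replicates Replicate acquisitions per fraction (default 1).
#' @return A list with one element per run:
#'   `list(trace, truth, ev_fraction, replicate)`, ordered fraction-major.
#' @export
simulate_mixture_series <- function(base, total_rate, ev_fractions,
                                    replicates = 1L) {
  stopifnot(inherits(base, "sim_config"))
  if (total_rate < 0) stop("total_rate must be non-negative", call. = FALSE)
  if (length(ev_fractions) < 1L ||
      any(ev_fractions < 0 | ev_fractions > 1)) {
    stop("ev_fractions must lie in [0, 1]", call. = FALSE)
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  run <- 0L
  out <- list()
  for (f in ev_fractions) {
    for (j in seq_len(replicates)) {
      cfg <- base
      cfg$ev_rate <- f * total_rate
      cfg$contaminant_rate <- (1 - f) * total_rate
      cfg$seed <- derive_seed(base$seed, run)
      sim <- simulate_trace(cfg)
      out[[length(out) + 1L]] <- list(trace = sim$trace, truth = sim$truth,
                                      ev_fraction = f, replicate = j)
      run <- run + 1L
    }
  }
  out
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown sim_config fields in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Read / write a ground-truth transit log as CSV
#'
#' Columns `bin,species,n_green,n_red`, one row per transit.
#'
#' @param truth Ground-truth data frame from [simulate_trace()].
#' @param path File path.
#' @return `read_ground_truth` returns the data frame; `write_ground_truth`
#'   returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[, c("bin", "species", "n_green", "n_red")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("integer", "character", "integer",
                                 "integer"))
}
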