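# Hand-built event sets for exercising coincidence logic directly,
# bypassing the burst search.
make_event_set <- function(start_bin, end_bin, intensity = NULL,
                           channel = "A", n_bins = 100L,
                           bin_width = 1e-4, threshold = 10L,
                           background = 0) {
  if (is.null(intensity)) intensity <- rep(1, length(start_bin))
  ev <- data.frame(start_bin = as.integer(start_bin),
                   end_bin = as.integer(end_bin),
                   intensity = intensity,
                   peak_count = as.integer(pmax(intensity, threshold)),
                   channel = rep(channel, length(start_bin)),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$start_bin), , drop = FALSE]
  structure(list(events = ev, channel = channel, threshold = threshold,
                 background = background, source_n_bins = as.integer(n_bins),
                 source_bin_width = bin_width),
            class = "event_set")
}

# A short acquisition for cheap simulator-driven tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(duration = 10, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
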