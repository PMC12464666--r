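#' Construct a two-channel photon-count time trace
#'
#' A `time_trace` holds the raw observable of a TCCD measurement: photon
#' counts per fixed-width time bin in two detection channels acquired
#' simultaneously (channel A, conventionally the "green" fluorophore, and
#' channel B, the "red" one). Bins are indexed from 0 to `n_bins - 1`
#' throughout the package, matching the on-disk CSV format.
#'
#' @param counts_a Integer-valued vector of photon counts per bin, channel A.
#' @param counts_b Integer-valued vector of photon counts per bin, channel B.
#'   Must have the same length as `counts_a`.
#' @param bin_width Width of one time bin in seconds. Default `1e-4` (0.1 ms),
#'   appropriate for sub-millisecond transits under fast flow.
#' @param metadata Named list of free-form metadata (sample id, dilution
#'   factor, acquisition notes).
#'
#' @return An object of class `time_trace` with elements `counts_a`,
#'   `counts_b` (integer vectors), `bin_width` and `metadata`.
#'
#' @details Counts must be non-negative integers; non-integer or negative
#' values are an error, never rounded or clipped — photon counts are
#' integral, and silently repairing them would hide upstream faults.
#'
#' @examples
#' tr <- time_trace(c(0L, 5L, 0L), c(0L, 2L, 1L))
#' n_bins(tr)
#' @export
time_trace <- function(counts_a, counts_b, bin_width = 1e-4,
                       metadata = list()) {
  if (!is.numeric(counts_a) || !is.numeric(counts_b)) {
    stop("counts must be numeric vectors of non-negative integers",
         call. = FALSE)
  }
  if (length(counts_a) != length(counts_b)) {
    stop(sprintf("channel lengths differ: counts_a has %d bins, counts_b %d",
                 length(counts_a), length(counts_b)), call. = FALSE)
  }
  if (length(counts_a) < 1L) stop("no bins: a trace needs n_bins >= 1",
                                  call. = FALSE)
  check_counts <- function(x, name) {
    if (anyNA(x)) {
      stop(sprintf("%s contains NA values", name), call. = FALSE)
    }
    if (!is.integer(x)) {  # integer vectors need no finiteness/round check
      if (any(!is.finite(x))) {
        stop(sprintf("%s contains non-finite values", name), call. = FALSE)
      }
      if (any(x != round(x))) {
        stop(sprintf(
          "%s contains non-integer counts; photon counts are integral",
          name), call. = FALSE)
      }
    }
    if (min(x) < 0) stop(sprintf("%s contains negative counts", name),
                         call. = FALSE)
  }
  check_counts(counts_a, "counts_a")
  check_counts(counts_b, "counts_b")
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be a single positive number of seconds",
         call. = FALSE)
  }
  if (!is.list(metadata)) stop("metadata must be a list", call. = FALSE)
  structure(
    list(counts_a = as.integer(counts_a),
         counts_b = as.integer(counts_b),
         bin_width = as.numeric(bin_width),
         metadata = metadata),
    class = "time_trace"
  )
}

#' Number of bins in a trace
#' @param trace A [time_trace()].
#' @return Integer bin count.
#' @export
n_bins <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  length(trace$counts_a)
}

#' Duration of a trace in seconds
#' @param trace A [time_trace()].
#' @return `n_bins * bin_width`, in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  length(trace$counts_a) * trace$bin_width
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d bins x %g s = %g s\n",
              n_bins(x), x$bin_width, trace_duration(x)))
  cat(sprintf("  channel A: total %d photons, max %d counts/bin\n",
              sum(x$counts_a), max(x$counts_a)))
  cat(sprintf("  channel B: total %d photons, max %d counts/bin\n",
              sum(x$counts_b), max(x$counts_b)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`==.time_trace` <- function(e1, e2) {
  identical(e1$counts_a, e2$counts_a) &&
    identical(e1$counts_b, e2$counts_b) &&
    isTRUE(all.equal(e1$bin_width, e2$bin_width))
}

#' Read a two-channel trace from disk
#'
#' Reads the package's plain-text trace format: UTF-8 CSV with leading
#' comment lines `# key=value` (which must include `bin_width_s`), then a
#' header row `bin,counts_a,counts_b`, then one row per bin with 0-based bin
#' indices. All `# key=value` lines other than `bin_width_s` populate the
#' trace metadata.
#'
#' @param path Path to the file.
#' @param format File format; only `"csv"` is supported.
#' @return A validated [time_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("hdf5 traces are not supported by this build; use the csv format",
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_comment <- startsWith(lines, "#")
  header_kv <- sub("^#\\s*", "", lines[is_comment])
  kv_ok <- grepl("=", header_kv, fixed = TRUE)
  if (any(!kv_ok)) {
    stop(sprintf("malformed header line (expected '# key=value'): '%s'",
                 header_kv[!kv_ok][1]), call. = FALSE)
  }
  keys <- sub("=.*$", "", header_kv)
  vals <- sub("^[^=]*=", "", header_kv)
  if (!"bin_width_s" %in% keys) {
    stop("header is missing required field 'bin_width_s'", call. = FALSE)
  }
  bin_width <- suppressWarnings(as.numeric(vals[match("bin_width_s", keys)]))
  if (is.na(bin_width)) {
    stop("field 'bin_width_s' is not a number", call. = FALSE)
  }
  meta_keys <- keys[keys != "bin_width_s"]
  metadata <- as.list(vals[keys != "bin_width_s"])
  names(metadata) <- meta_keys

  body <- lines[!is_comment]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L || trimws(body[1]) != "bin,counts_a,counts_b") {
    stop("malformed file: expected header row 'bin,counts_a,counts_b'",
         call. = FALSE)
  }
  if (length(body) < 2L) stop("no bins: the data section is empty",
                              call. = FALSE)
  df <- utils::read.csv(text = body, header = TRUE,
                        stringsAsFactors = FALSE)
  for (col in c("bin", "counts_a", "counts_b")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop(sprintf("malformed data row %d, field '%s': not a number",
                   which(is.na(v))[1], col), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!all(df$bin == seq_len(nrow(df)) - 1L)) {
    stop("bin column must run 0,1,...,n_bins-1 without gaps", call. = FALSE)
  }
  time_trace(df$counts_a, df$counts_b, bin_width = bin_width,
             metadata = metadata)
}

#' Write a two-channel trace to disk
#'
#' Inverse of [read_trace()]: counts and `bin_width` round-trip exactly.
#'
#' @param trace A [time_trace()].
#' @param path Output path.
#' @param format File format; only `"csv"` is supported.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("hdf5 traces are not supported by this build; use the csv format",
         call. = FALSE)
  }
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s=%.17g", trace$bin_width), con)
  if (length(trace$metadata)) {
    writeLines(sprintf("# %s=%s", names(trace$metadata),
                       vapply(trace$metadata, as.character, character(1))),
               con)
  }
  writeLines("bin,counts_a,counts_b", con)
  writeLines(sprintf("%d,%d,%d", seq_along(trace$counts_a) - 1L,
                     trace$counts_a, trace$counts_b), con)
  invisible(path)
}

#' Extract a contiguous sub-trace
#'
#' @param trace A [time_trace()].
#' @param start_bin First bin of the slice (0-based, inclusive).
#' @param end_bin Last bin of the slice (0-based, inclusive).
#' @return A [time_trace()] over bins `start_bin..end_bin`; metadata and
#'   `bin_width` are carried over.
#' @export
slice_trace <- function(trace, start_bin, end_bin) {
  stopifnot(inherits(trace, "time_trace"))
  nb <- n_bins(trace)
  if (!(start_bin == round(start_bin) && end_bin == round(end_bin))) {
    stop("bin indices must be integers", call. = FALSE)
  }
  if (start_bin < 0 || end_bin >= nb || start_bin > end_bin) {
    stop(sprintf(
      "slice [%s, %s] out of range for a trace with bins 0..%d",
      format(start_bin), format(end_bin), nb - 1L), call. = FALSE)
  }
  idx <- (start_bin + 1L):(end_bin + 1L)
  time_trace(trace$counts_a[idx], trace$counts_b[idx],
             bin_width = trace$bin_width, metadata = trace$metadata)
}
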