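#' Time-tagged two-channel photon stream
#'
#' The universal input of the package: one record per detected photon, with a
#' coarse absolute arrival time (macrotime, integer clock ticks), a fine delay
#' since the last laser sync pulse (nanotime, integer TCSPC bins) and a
#' detector index. Metadata carry the tick duration, the TCSPC bin width, the
#' laser synchronization rate and the acquisition duration.
#'
#' @param macrotimes numeric vector of non-negative integer-valued clock ticks,
#'   non-decreasing. Stored as doubles so that multi-hour acquisitions at
#'   nanosecond tick resolution stay exact (integer-valued doubles are exact
#'   up to 2^53).
#' @param nanotimes numeric vector of non-negative integer-valued TCSPC bins,
#'   same length as `macrotimes`.
#' @param detectors integer vector of detector indices (same length);
#'   conventionally `1` = green detector, `2` = red detector.
#' @param tick_s duration of one macrotime clock tick in seconds (default
#'   1 ns, 64-bit safe over hours of acquisition).
#' @param tcspc_bin_s width of one TCSPC nanotime bin in seconds (default
#'   5 ps, the resolution of typical time-resolved counting electronics).
#' @param sync_rate_hz laser synchronization frequency in Hz (default 40 MHz).
#' @param duration_s acquisition length in seconds. Defaults to the time of
#'   the last photon (or 0 for an empty stream).
#'
#' @return An object of class `photon_stream`.
#' @examples
#' ps <- photon_stream(macrotimes = c(0, 100, 250), nanotimes = c(10, 900, 2600),
#'                     detectors = c(1L, 1L, 2L), duration_s = 1e-6)
#' n_photons(ps)
#' @export
photon_stream <- function(macrotimes = numeric(0), nanotimes = numeric(0),
                          detectors = integer(0),
                          tick_s = 1e-9, tcspc_bin_s = 5e-12,
                          sync_rate_hz = 40e6, duration_s = NULL) {
  macrotimes <- as.numeric(macrotimes)
  nanotimes <- as.numeric(nanotimes)
  detectors <- as.integer(detectors)
  if (is.null(duration_s)) {
    duration_s <- if (length(macrotimes)) max(macrotimes) * tick_s else 0
  }
  x <- structure(list(
    macrotimes = macrotimes,
    nanotimes = nanotimes,
    detectors = detectors,
    tick_s = as.numeric(tick_s),
    tcspc_bin_s = as.numeric(tcspc_bin_s),
    sync_rate_hz = as.numeric(sync_rate_hz),
    duration_s = as.numeric(duration_s)
  ), class = "photon_stream")
  validate_photon_stream(x)
  x
}

#' Validate a photon stream's invariants
#'
#' Checks equal array lengths, non-decreasing macrotimes, non-negative
#' integer-valued times, positive resolutions, and that every nanotime falls
#' within one sync period.
#'
#' @param x a `photon_stream`.
#' @return `x`, invisibly. Errors describe the first offending record.
#' @export
validate_photon_stream <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  n <- length(x$macrotimes)
  if (length(x$nanotimes) != n || length(x$detectors) != n) {
    stop("photon_stream: macrotimes, nanotimes and detectors must have equal length")
  }
  if (!is.finite(x$tick_s) || x$tick_s <= 0) stop("photon_stream: tick_s must be > 0")
  if (!is.finite(x$tcspc_bin_s) || x$tcspc_bin_s <= 0) stop("photon_stream: tcspc_bin_s must be > 0")
  if (!is.finite(x$sync_rate_hz) || x$sync_rate_hz <= 0) stop("photon_stream: sync_rate_hz must be > 0")
  if (x$duration_s < 0) stop("photon_stream: duration_s must be >= 0")
  if (n > 0) {
    d <- diff(x$macrotimes)
    if (any(d < 0)) {
      i <- which(d < 0)[1]
      stop(sprintf("photon_stream: macrotimes not non-decreasing at index %d", i + 1L))
    }
    if (any(x$macrotimes < 0)) stop("photon_stream: negative macrotime")
    if (any(x$nanotimes < 0)) stop("photon_stream: negative nanotime")
    period_bins <- 1 / (x$sync_rate_hz * x$tcspc_bin_s)
    if (any(x$nanotimes * x$tcspc_bin_s >= 1 / x$sync_rate_hz + 1e-15)) {
      stop(sprintf(
        "photon_stream: nanotime exceeds one sync period (max allowed %.0f bins)",
        period_bins))
    }
  }
  invisible(x)
}

#' Number of photons in a stream
#' @param x a `photon_stream`.
#' @return integer photon count.
#' @export
n_photons <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  length(x$macrotimes)
}

#' Photon arrival times in seconds
#' @param x a `photon_stream`.
#' @return numeric vector `macrotimes * tick_s`.
#' @export
arrival_times <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  x$macrotimes * x$tick_s
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> %d photons over %.3f s\n", n_photons(x), x$duration_s))
  cat(sprintf("  tick %.3g s, TCSPC bin %.3g s, sync %.4g MHz\n",
              x$tick_s, x$tcspc_bin_s, x$sync_rate_hz / 1e6))
  if (n_photons(x) > 0) {
    tab <- table(x$detectors)
    cat("  detectors:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract a time window from a photon stream
#'
#' Returns exactly the photons with arrival time in `[t0, t1)` seconds.
#' Macrotimes are re-referenced to `t0` so the slice is a self-contained
#' acquisition of duration `t1 - t0`; metadata are preserved.
#'
#' @param stream a `photon_stream`.
#' @param t0,t1 window boundaries in seconds, `0 <= t0 < t1 <= duration`.
#' @return a `photon_stream` of duration `t1 - t0`.
#' @export
slice_stream <- function(stream, t0, t1) {
  validate_photon_stream(stream)
  if (!is.finite(t0) || !is.finite(t1) || t0 < 0 || t1 <= t0) {
    stop("slice_stream: need 0 <= t0 < t1")
  }
  if (t1 > stream$duration_s + stream$tick_s) {
    stop("slice_stream: t1 exceeds acquisition duration")
  }
  tt <- arrival_times(stream)
  keep <- tt >= t0 & tt < t1
  offset_ticks <- round(t0 / stream$tick_s)
  photon_stream(
    macrotimes = stream$macrotimes[keep] - offset_ticks,
    nanotimes = stream$nanotimes[keep],
    detectors = stream$detectors[keep],
    tick_s = stream$tick_s, tcspc_bin_s = stream$tcspc_bin_s,
    sync_rate_hz = stream$sync_rate_hz, duration_s = t1 - t0
  )
}

#' Time-binned intensity trace
#'
#' Bins photon arrivals into consecutive windows of `bin_width` seconds.
#' The number of bins is `ceiling(duration / bin_width)`; the sum of the
#' counts equals the photon count.
#'
#' @param stream a `photon_stream`.
#' @param bin_width bin width in seconds, `0 < bin_width <= duration`.
#' @return a data.frame with columns `time_s` (bin centers) and `counts`.
#' @export
count_rate_trace <- function(stream, bin_width) {
  validate_photon_stream(stream)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("count_rate_trace: bin_width must be > 0")
  }
  if (bin_width > stream$duration_s) {
    stop("count_rate_trace: bin_width exceeds acquisition duration")
  }
  nbins <- as.integer(ceiling(stream$duration_s / bin_width))
  idx <- pmin(floor(arrival_times(stream) / bin_width) + 1, nbins)
  counts <- tabulate(idx, nbins = nbins)
  data.frame(time_s = (seq_len(nbins) - 0.5) * bin_width, counts = counts)
}
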