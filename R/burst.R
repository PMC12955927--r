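#' Sliding-window burst search parameters
#'
#' A photon is "hot" when the `m`-photon window centred on it spans at most
#' `m / (K * B)` seconds, i.e. when the local photon rate is at least `K`
#' times the background rate `B`. Maximal runs of hot photons form bursts;
#' runs shorter than `min_photons` are discarded. `K` is conventionally
#' rescaled per acquisition so that the product `K * B` (the threshold rate)
#' stays fixed when the background varies.
#'
#' @param m number of consecutive photons in the local-rate window (>= 3).
#' @param k threshold factor above background (> 1).
#' @param background_rate background rate B (counts/s, >= 0; `K * B` must be
#'   positive).
#' @param min_photons minimum photons for a valid burst.
#' @return an object of class `burst_search_params`.
#' @export
burst_search_params <- function(m = 10, k = 6, background_rate, min_photons = 20) {
  if (m < 3) stop("burst_search_params: m must be >= 3")
  if (k <= 1) stop("burst_search_params: K must be > 1")
  if (background_rate < 0) stop("burst_search_params: background rate must be >= 0")
  if (k * background_rate <= 0) stop("burst_search_params: threshold rate K*B must be > 0")
  structure(list(m = as.integer(m), k = k, background_rate = background_rate,
                 min_photons = as.integer(min_photons)),
            class = "burst_search_params")
}

#' Iterative background-rate estimate of a photon stream
#'
#' Starts from the global rate `count/duration`, detects bursts at that
#' estimate, re-estimates the rate from the photons and time outside bursts,
#' and performs one refinement pass of the same cycle. Robust to sparse
#' bright transits riding on a Poisson background.
#'
#' @param stream a non-empty [photon_stream()].
#' @param m,k,min_photons burst-search settings used during the estimate.
#' @return background rate (counts/s).
#' @export
estimate_background <- function(stream, m = 10, k = 6, min_photons = 20) {
  validate_photon_stream(stream)
  if (n_photons(stream) == 0) stop("estimate_background: empty stream")
  rate <- n_photons(stream) / stream$duration_s
  for (pass in 1:2) {
    bs <- detect_bursts(stream, burst_search_params(m, k, rate, min_photons))
    if (nrow(bs$bursts) == 0) return(rate)
    in_burst_photons <- sum(bs$bursts$n_photons)
    in_burst_time <- sum(bs$bursts$duration_s)
    free_photons <- n_photons(stream) - in_burst_photons
    free_time <- stream$duration_s - in_burst_time
    if (free_photons <= 0 || free_time <= 0) {
      stop("estimate_background: all photons inside bursts; background degenerate")
    }
    rate <- free_photons / free_time
  }
  rate
}

#' Detect photon bursts with the sliding-window rate criterion
#'
#' Applies the rule of [burst_search_params()]: the `m`-photon window centred
#' on photon `i` (indices `i - floor((m-1)/2) .. i + ceiling((m-1)/2)`) must
#' span at most `m/(K*B)` seconds for `i` to be hot; photons too close to
#' either end of the record to own a full window are never hot. Bursts are
#' the maximal runs of hot photons, are disjoint by construction, and carry
#' first-to-last photon times, photon counts, mean rates and the midpoint
#' centre time.
#'
#' A diffusing particle frequently re-crosses the detection-volume edge,
#' splitting one transit into several nearby fragments; `fuse_gap_s > 0`
#' merges bursts whose gap is below that value (the standard burst-fusion
#' post-processing step) before the `min_photons` filter is applied.
#'
#' @param stream a non-empty [photon_stream()].
#' @param params a [burst_search_params()].
#' @param center one of `"midpoint"` (default, `(start+stop)/2`) or
#'   `"photon_mean"` (mean photon arrival time).
#' @param fuse_gap_s merge bursts separated by less than this gap (s);
#'   0 (default) disables fusion.
#' @return an object of class `burst_set`: data.frame `bursts` with columns
#'   `start_s, stop_s, duration_s, n_photons, mean_rate, center_s,
#'   first_photon, last_photon`, plus the parameters, channel guess,
#'   acquisition duration and total burst rate.
#' @export
detect_bursts <- function(stream, params, center = c("midpoint", "photon_mean"),
                          fuse_gap_s = 0) {
  validate_photon_stream(stream)
  stopifnot(inherits(params, "burst_search_params"))
  center <- match.arg(center)
  n <- n_photons(stream)
  if (n == 0) stop("detect_bursts: empty stream")
  t <- arrival_times(stream)
  m <- params$m
  max_span <- m / (params$k * params$background_rate)
  h_l <- (m - 1L) %/% 2L
  h_r <- m - 1L - h_l
  hot <- rep(FALSE, n)
  if (n >= m) {
    i <- seq.int(h_l + 1L, n - h_r)
    hot[i] <- (t[i + h_r] - t[i - h_l]) <= max_span
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- r$values
  first <- starts[runs]
  last <- ends[runs]
  if (fuse_gap_s > 0 && length(first) > 1) {
    gap <- t[first[-1]] - t[last[-length(last)]]
    grp <- cumsum(c(1L, as.integer(gap >= fuse_gap_s)))
    first <- as.integer(tapply(first, grp, min))
    last <- as.integer(tapply(last, grp, max))
  }
  keep <- (last - first + 1L) >= params$min_photons
  bursts <- data.frame(
    start_s = t[first[keep]], stop_s = t[last[keep]],
    first_photon = first[keep], last_photon = last[keep])
  if (nrow(bursts)) {
    bursts$duration_s <- bursts$stop_s - bursts$start_s
    bursts$n_photons <- bursts$last_photon - bursts$first_photon + 1L
    bursts$mean_rate <- ifelse(bursts$duration_s > 0,
                               bursts$n_photons / bursts$duration_s, Inf)
    bursts$center_s <- if (center == "midpoint") {
      (bursts$start_s + bursts$stop_s) / 2
    } else {
      vapply(seq_len(nrow(bursts)),
             function(i) mean(t[bursts$first_photon[i]:bursts$last_photon[i]]),
             numeric(1))
    }
  } else {
    bursts$duration_s <- numeric(0); bursts$n_photons <- integer(0)
    bursts$mean_rate <- numeric(0); bursts$center_s <- numeric(0)
  }
  bursts <- bursts[, c("start_s", "stop_s", "duration_s", "n_photons",
                       "mean_rate", "center_s", "first_photon", "last_photon")]
  structure(list(
    bursts = bursts, params = params,
    duration_s = stream$duration_s,
    background_rate = params$background_rate,
    burst_rate = nrow(bursts) / stream$duration_s
  ), class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts in %.1f s (%.3g bursts/s), K = %.3g, m = %d, B = %.4g/s\n",
              nrow(x$bursts), x$duration_s, x$burst_rate, x$params$k,
              x$params$m, x$background_rate))
  invisible(x)
}

#' Distribution summaries of a burst set
#'
#' Duration quantiles (linear interpolation between order statistics,
#' including the 10% quantile and the median), mean-rate summary and
#' inter-burst gap statistics. An empty set returns a record flagged
#' `empty = TRUE` instead of raising.
#'
#' @param bs a [detect_bursts()] result.
#' @param probs quantile probabilities for the duration distribution.
#' @return a list of summaries carrying sample sizes.
#' @export
burst_statistics <- function(bs, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(bs, "burst_set"))
  b <- bs$bursts
  if (nrow(b) == 0) {
    return(list(empty = TRUE, n = 0L))
  }
  gaps <- if (nrow(b) > 1) b$start_s[-1] - b$stop_s[-nrow(b)] else numeric(0)
  list(
    empty = FALSE, n = nrow(b),
    duration_quantiles_s = stats::quantile(b$duration_s, probs, names = TRUE),
    duration_q10_s = unname(stats::quantile(b$duration_s, 0.1)),
    duration_median_s = stats::median(b$duration_s),
    mean_rate_summary = summary(b$mean_rate),
    interburst_gap_mean_s = if (length(gaps)) mean(gaps) else NA_real_,
    burst_rate = bs$burst_rate
  )
}

#' Calibrate burst-search parameters against an FCCS diffusion time
#'
#' Grid search over candidate `(K, m)` pairs minimizing the absolute
#' difference between the median burst duration and a target diffusion time
#' from a converged FCS fit. Ties break toward larger `K` (the stricter
#' threshold). Candidates yielding fewer than `min_bursts` bursts are
#' skipped; if none qualifies an insufficient-data error is raised.
#'
#' @param stream the gated [photon_stream()] of one channel.
#' @param target_tau_d_s FCCS-determined diffusion time (s).
#' @param k_grid,m_grid candidate threshold factors and window sizes.
#' @param background_rate background B (counts/s); estimated from the stream
#'   when omitted.
#' @param min_photons minimum photons per burst.
#' @param min_bursts minimum burst count for a candidate to qualify.
#' @return the chosen [burst_search_params()], with the achieved median
#'   duration and the grid diagnostics attached as attributes
#'   `achieved_median_s` and `grid`.
#' @export
calibrate_burst_params <- function(stream, target_tau_d_s,
                                   k_grid = c(2, 3, 4, 6, 8, 12, 16, 24, 32),
                                   m_grid = c(5, 10, 15, 20),
                                   background_rate = NULL,
                                   min_photons = 10, min_bursts = 20,
                                   fuse_gap_s = 0) {
  validate_photon_stream(stream)
  if (target_tau_d_s <= 0) stop("calibrate_burst_params: target tau_D must be > 0")
  if (is.null(background_rate)) background_rate <- estimate_background(stream)
  grid <- expand.grid(k = sort(k_grid), m = sort(m_grid))
  grid$n_bursts <- NA_integer_
  grid$median_duration_s <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- burst_search_params(grid$m[i], grid$k[i], background_rate, min_photons)
    bs <- detect_bursts(stream, p, fuse_gap_s = fuse_gap_s)
    grid$n_bursts[i] <- nrow(bs$bursts)
    if (nrow(bs$bursts) >= min_bursts) {
      grid$median_duration_s[i] <- stats::median(bs$bursts$duration_s)
    }
  }
  ok <- which(!is.na(grid$median_duration_s))
  if (!length(ok)) {
    stop("calibrate_burst_params: no candidate produced at least ", min_bursts,
         " bursts; insufficient data")
  }
  dev <- abs(grid$median_duration_s[ok] - target_tau_d_s)
  best_dev <- min(dev)
  cand <- ok[dev <= best_dev * (1 + 1e-12)]
  best <- cand[which.max(grid$k[cand])]  # tie-break toward stricter threshold
  out <- burst_search_params(grid$m[best], grid$k[best], background_rate,
                             min_photons)
  attr(out, "achieved_median_s") <- grid$median_duration_s[best]
  attr(out, "grid") <- grid
  out
}

#' Export a burst table as tab-separated text
#' @param bs a [detect_bursts()] result.
#' @param path output file.
#' @param channel channel label written in the first column.
#' @return `path`, invisibly.
#' @export
write_burst_table <- function(bs, path, channel = "unknown") {
  stopifnot(inherits(bs, "burst_set"))
  b <- bs$bursts
  df <- data.frame(channel = channel, start_s = b$start_s, stop_s = b$stop_s,
                   duration_ms = b$duration_s * 1e3, n_photons = b$n_photons,
                   rate_cps = b$mean_rate, center_s = b$center_s)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
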