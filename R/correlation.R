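#' Correlation curve container
#'
#' @param pair one of `"gg"`, `"rr"`, `"rg"` (or any label).
#' @param lags_s strictly increasing positive lag times (s).
#' @param values G(tau) values (dimensionless).
#' @param mean_rates named numeric, mean count rates of the input stream(s)
#'   (counts/s).
#' @param duration_used_s acquisition length used (s).
#' @param stderr optional per-lag standard errors.
#' @param detail optional data.frame of estimator internals (level, k, bin
#'   width per lag).
#' @return an object of class `correlation_curve`.
#' @export
correlation_curve <- function(pair, lags_s, values, mean_rates,
                              duration_used_s, stderr = NULL, detail = NULL) {
  if (length(lags_s) != length(values)) stop("correlation_curve: lags/values length mismatch")
  if (length(lags_s) && (any(lags_s <= 0) || any(diff(lags_s) <= 0))) {
    stop("correlation_curve: lags must be strictly increasing and > 0")
  }
  structure(list(pair = pair, lags_s = as.numeric(lags_s),
                 values = as.numeric(values), mean_rates = mean_rates,
                 duration_used_s = duration_used_s,
                 stderr = stderr, detail = detail),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> pair %s, %d lags", x$pair, length(x$lags_s)))
  if (length(x$lags_s)) {
    cat(sprintf(" [%.3g .. %.3g s], G(first) = %.4g", min(x$lags_s),
                max(x$lags_s), x$values[1]))
  }
  cat("\n")
  invisible(x)
}

multitau_lag_table <- function(base_bin, points_per_level, n_levels) {
  if (points_per_level %% 2 != 0 || points_per_level < 4) {
    stop("multitau_correlate: points_per_level must be even and >= 4")
  }
  lev <- integer(0); kk <- integer(0)
  for (l in seq_len(n_levels) - 1L) {
    k <- if (l == 0) seq_len(points_per_level) else
      seq.int(points_per_level / 2 + 1L, points_per_level)
    lev <- c(lev, rep(l, length(k)))
    kk <- c(kk, k)
  }
  data.frame(level = lev, k = kk, width_s = base_bin * 2^lev,
             lag_s = kk * base_bin * 2^lev)
}

# shared estimator core: symmetric normalization with range-local means,
#   G(k) = M * sum_{i<M} a_i b_{i+k} / (sum_{i<M} a_i * sum_{i>=k} b_i) - 1
# on integer count traces; all sums are exact in doubles, so the sparse
# (multi-tau) and dense (brute-force) evaluations agree bit-for-bit.
correlate_level_sparse <- function(bins_a, ca, bins_b, cb, n_bins, ks) {
  vapply(ks, function(k) {
    m <- n_bins - k
    if (m <= 0) return(NA_real_)
    sel <- bins_a <= m - 1
    idx <- match(bins_a[sel] + k, bins_b)
    ok <- !is.na(idx)
    sab <- sum(ca[sel][ok] * cb[idx[ok]])
    sa <- sum(ca[sel])
    sb <- sum(cb[bins_b >= k])
    if (sa == 0 || sb == 0) return(NA_real_)
    m * sab / (sa * sb) - 1
  }, numeric(1))
}

sparse_bins <- function(times_s, width_s, n_bins) {
  idx <- floor(times_s / width_s)
  idx <- idx[idx < n_bins]
  r <- rle(idx)
  list(bins = r$values, counts = as.numeric(r$lengths))
}

#' Multi-tau auto-/cross-correlation of photon streams
#'
#' Computes the normalized intensity correlation
#' `G(tau) = <dFa(t) dFb(t+tau)> / (<Fa><Fb>)` on a logarithmic multi-tau
#' lag cascade: level 0 covers lags of 1..`points_per_level` base bins, and
#' every further level doubles the bin width and covers lags of
#' `points_per_level/2+1 .. points_per_level` coarse bins. Normalization is
#' symmetric with range-local means (the direct and delayed monitors are
#' summed over exactly the bins entering each lag's product sum), so each
#' lag equals a direct evaluation on the rebinned trace - the property
#' [brute_force_correlate()] verifies. With `stream_a = stream_b` this is
#' the autocorrelation; with two gated channels, the cross-correlation.
#'
#' Levels whose lags exceed one tenth of the acquisition are dropped with a
#' warning (with fewer than ~10 traversals the estimator is dominated by a
#' single low-frequency fluctuation).
#'
#' @param stream_a,stream_b [photon_stream()]s sharing a time origin and
#'   duration (pass the same object twice for an autocorrelation).
#' @param base_bin_s finest bin width (s), default 1 microsecond.
#' @param points_per_level even number of lags per cascade level, default 8.
#' @param n_levels number of cascade levels, default 20.
#' @param pair label stored on the curve (`"gg"`, `"rr"`, `"rg"`, ...).
#' @param n_segments if > 0, additionally estimates per-lag standard errors
#'   by recomputing the curve on this many equal sub-segments of the
#'   acquisition and taking sd/sqrt(n) across them.
#' @return a [correlation_curve()].
#' @export
multitau_correlate <- function(stream_a, stream_b = stream_a,
                               base_bin_s = 1e-6, points_per_level = 8,
                               n_levels = 20, pair = NULL, n_segments = 0) {
  validate_photon_stream(stream_a)
  validate_photon_stream(stream_b)
  if (abs(stream_a$duration_s - stream_b$duration_s) > stream_a$tick_s) {
    stop("multitau_correlate: streams must share duration")
  }
  if (base_bin_s < stream_a$tick_s) {
    stop("multitau_correlate: base_bin_s below the macrotime tick resolution")
  }
  if (n_photons(stream_a) == 0 || n_photons(stream_b) == 0) {
    stop("multitau_correlate: zero counts in a stream; normalization undefined")
  }
  duration <- stream_a$duration_s
  tab <- multitau_lag_table(base_bin_s, points_per_level, n_levels)
  keep <- tab$lag_s <= duration / 10
  if (!any(keep)) stop("multitau_correlate: acquisition shorter than 10x the smallest lag")
  if (!all(keep)) {
    warning(sprintf("multitau_correlate: dropped %d lags beyond duration/10",
                    sum(!keep)))
    tab <- tab[keep, ]
  }
  ta <- arrival_times(stream_a)
  tb <- arrival_times(stream_b)
  same <- identical(stream_a, stream_b)
  g <- numeric(nrow(tab))
  for (l in unique(tab$level)) {
    width <- base_bin_s * 2^l
    n_bins <- floor(duration / width)
    sa <- sparse_bins(ta, width, n_bins)
    sb <- if (same) sa else sparse_bins(tb, width, n_bins)
    rows <- tab$level == l
    g[rows] <- correlate_level_sparse(sa$bins, sa$counts, sb$bins, sb$counts,
                                      n_bins, tab$k[rows])
  }
  ok <- !is.na(g)
  se <- NULL
  if (n_segments > 1) {
    seg_len <- duration / n_segments
    seg_vals <- matrix(NA_real_, n_segments, nrow(tab))
    for (s in seq_len(n_segments)) {
      t0 <- (s - 1) * seg_len
      sel_a <- ta >= t0 & ta < t0 + seg_len
      sel_b <- tb >= t0 & tb < t0 + seg_len
      if (!any(sel_a) || !any(sel_b)) next
      tsa <- ta[sel_a] - t0
      tsb <- tb[sel_b] - t0
      for (l in unique(tab$level)) {
        width <- base_bin_s * 2^l
        n_bins <- floor(seg_len / width)
        rows <- which(tab$level == l & tab$lag_s <= seg_len / 5)
        if (!length(rows) || n_bins < 2) next
        ba <- sparse_bins(tsa, width, n_bins)
        bb <- if (same) ba else sparse_bins(tsb, width, n_bins)
        seg_vals[s, rows] <- correlate_level_sparse(ba$bins, ba$counts,
                                                    bb$bins, bb$counts,
                                                    n_bins, tab$k[rows])
      }
    }
    nseg_ok <- colSums(!is.na(seg_vals))
    se <- ifelse(nseg_ok >= 2,
                 apply(seg_vals, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nseg_ok, 1)),
                 NA_real_)
  }
  if (is.null(pair)) pair <- if (same) "auto" else "cross"
  correlation_curve(
    pair = pair, lags_s = tab$lag_s[ok], values = g[ok],
    mean_rates = c(a = n_photons(stream_a) / duration,
                   b = n_photons(stream_b) / duration),
    duration_used_s = duration,
    stderr = if (!is.null(se)) se[ok] else NULL,
    detail = tab[ok, ])
}

#' Brute-force binned correlation (estimator oracle)
#'
#' Direct dense evaluation of the identical estimator used by
#' [multitau_correlate()]: both streams are binned at `bin_width_s`, and for
#' each requested lag (which must be an integer multiple of the bin width)
#' the normalized covariance with range-local means is computed by explicit
#' summation, O(bins x lags). Intended as ground truth on small inputs; a
#' memory guard rejects traces longer than `max_bins`.
#'
#' @param stream_a,stream_b [photon_stream()]s sharing a duration.
#' @param lags_s explicit lag times (s), each an integer multiple of
#'   `bin_width_s`. An empty list yields an empty curve.
#' @param bin_width_s bin width (s).
#' @param pair curve label.
#' @param max_bins memory guard (default 2e6 bins).
#' @return a [correlation_curve()].
#' @export
brute_force_correlate <- function(stream_a, stream_b = stream_a, lags_s,
                                  bin_width_s, pair = NULL, max_bins = 2e6) {
  validate_photon_stream(stream_a)
  validate_photon_stream(stream_b)
  duration <- stream_a$duration_s
  n_bins <- floor(duration / bin_width_s)
  if (n_bins > max_bins) {
    stop(sprintf("brute_force_correlate: %d bins exceeds the %d-bin memory guard",
                 n_bins, as.integer(max_bins)))
  }
  if (is.null(pair)) pair <- if (identical(stream_a, stream_b)) "auto" else "cross"
  if (!length(lags_s)) {
    return(correlation_curve(pair, numeric(0), numeric(0),
                             mean_rates = c(a = NA_real_, b = NA_real_),
                             duration_used_s = duration))
  }
  ks <- round(lags_s / bin_width_s)
  if (any(abs(ks * bin_width_s - lags_s) > 1e-9 * bin_width_s) || any(ks < 1)) {
    stop("brute_force_correlate: lags must be positive integer multiples of bin_width_s")
  }
  bin_of <- function(s) {
    idx <- floor(arrival_times(s) / bin_width_s) + 1
    as.numeric(tabulate(idx[idx <= n_bins], nbins = n_bins))
  }
  a <- bin_of(stream_a)
  b <- if (identical(stream_a, stream_b)) a else bin_of(stream_b)
  g <- vapply(ks, function(k) {
    m <- n_bins - k
    if (m <= 0) return(NA_real_)
    sab <- sum(a[seq_len(m)] * b[seq.int(k + 1, n_bins)])
    sa <- sum(a[seq_len(m)])
    sb <- sum(b[seq.int(k + 1, n_bins)])
    if (sa == 0 || sb == 0) return(NA_real_)
    m * sab / (sa * sb) - 1
  }, numeric(1))
  correlation_curve(pair, lags_s, g,
                    mean_rates = c(a = n_photons(stream_a) / duration,
                                   b = n_photons(stream_b) / duration),
                    duration_used_s = duration)
}

#' Export a correlation curve as tab-separated text
#'
#' Writes `#key=value` header metadata followed by columns
#' `lag_s`, `G`, `stderr`.
#'
#' @param curve a [correlation_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  hdr <- c(sprintf("#pair=%s", curve$pair),
           sprintf("#duration_used_s=%.17g", curve$duration_used_s),
           sprintf("#mean_rate_%s=%.17g", names(curve$mean_rates), curve$mean_rates),
           "lag_s\tG\tstderr")
  se <- if (is.null(curve$stderr)) rep(NA_real_, length(curve$lags_s)) else curve$stderr
  writeLines(c(hdr, sprintf("%.12g\t%.12g\t%.6g", curve$lags_s, curve$values, se)),
             path)
  invisible(path)
}
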