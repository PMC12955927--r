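#' Size-estimation configuration
#'
#' Physical constants and beam geometry for Stokes-Einstein sizing of
#' burst durations: `size = 4 kB T tau_burst / (3 pi eta omega0^2)`.
#'
#' @param temperature_k absolute temperature (K).
#' @param viscosity_pa_s medium viscosity (Pa s).
#' @param waist_green_m,waist_red_m lateral beam waists of the two excitation
#'   colors (m); defaults 287 and 372 nm.
#' @param boltzmann Boltzmann constant (J/K).
#' @return an object of class `size_estimation_config`.
#' @export
size_estimation_config <- function(temperature_k = 298.15,
                                   viscosity_pa_s = 8.9e-4,
                                   waist_green_m = 287e-9,
                                   waist_red_m = 372e-9,
                                   boltzmann = kB) {
  vals <- c(temperature_k, viscosity_pa_s, waist_green_m, waist_red_m, boltzmann)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("size_estimation_config: all parameters must be > 0")
  }
  structure(list(temperature_k = temperature_k, viscosity_pa_s = viscosity_pa_s,
                 waist_green_m = waist_green_m, waist_red_m = waist_red_m,
                 boltzmann = boltzmann),
            class = "size_estimation_config")
}

#' Hydrodynamic vesicle size from a burst duration
#'
#' Inverts the lateral transit relation through the Stokes-Einstein law:
#' a burst of duration `tau_burst` through a waist `omega0` corresponds to a
#' hydrodynamic diameter `4 kB T tau_burst / (3 pi eta omega0^2)`, reported
#' in nanometres. Vectorised over durations.
#'
#' @param duration_s burst duration(s) in seconds (> 0).
#' @param cfg a [size_estimation_config()].
#' @param channel `"green"` or `"red"`; selects the waist.
#' @return size(s) in nm.
#' @export
ev_size_from_burst <- function(duration_s, cfg, channel = c("green", "red")) {
  stopifnot(inherits(cfg, "size_estimation_config"))
  channel <- match.arg(channel)
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop("ev_size_from_burst: burst duration must be > 0")
  }
  w <- if (channel == "green") cfg$waist_green_m else cfg$waist_red_m
  size_m <- 4 * cfg$boltzmann * cfg$temperature_k * duration_s /
    (3 * pi * cfg$viscosity_pa_s * w^2)
  size_m * 1e9
}

#' Coincidence tolerance window from burst-duration quantiles
#'
#' The default rule takes half the absolute difference between the 10%
#' duration quantiles of the green and red burst sets,
#' `|q10_g - q10_r| / 2`, reflecting the polydispersity of the two channels'
#' transit times. Two alternative readings of the same prescription are
#' selectable: `"half_q10_pairdiff"` (half the 10% quantile of per-burst
#' duration differences between nearest-centre pairs) and `"half_min_q10"`
#' (half the smaller of the two 10% quantiles).
#'
#' @param green,red [detect_bursts()] results with at least `min_bursts`
#'   bursts each.
#' @param rule tolerance rule, see above.
#' @param min_bursts minimum bursts per channel.
#' @return an object of class `tolerance_window`: `value_s`, `q10_green_s`,
#'   `q10_red_s`, `rule`.
#' @export
compute_tolerance_window <- function(green, red,
                                     rule = c("half_q10_diff",
                                              "half_q10_pairdiff",
                                              "half_min_q10"),
                                     min_bursts = 10) {
  stopifnot(inherits(green, "burst_set"), inherits(red, "burst_set"))
  rule <- match.arg(rule)
  if (nrow(green$bursts) < min_bursts || nrow(red$bursts) < min_bursts) {
    stop("compute_tolerance_window: need at least ", min_bursts,
         " bursts per channel")
  }
  q10g <- unname(stats::quantile(green$bursts$duration_s, 0.1))
  q10r <- unname(stats::quantile(red$bursts$duration_s, 0.1))
  value <- switch(rule,
    half_q10_diff = abs(q10g - q10r) / 2,
    half_q10_pairdiff = {
      near <- vapply(green$bursts$center_s, function(cg) {
        j <- which.min(abs(red$bursts$center_s - cg))
        abs(green$bursts$duration_s[which(green$bursts$center_s == cg)[1]] -
              red$bursts$duration_s[j])
      }, numeric(1))
      unname(stats::quantile(near, 0.1)) / 2
    },
    half_min_q10 = min(q10g, q10r) / 2
  )
  structure(list(value_s = value, q10_green_s = q10g, q10_red_s = q10r,
                 rule = rule),
            class = "tolerance_window")
}

#' Match green and red bursts into coincident events
#'
#' One-to-one matching of burst centre times: candidate pairs are ranked by
#' ascending centre offset (ties by burst order) and accepted greedily, each
#' burst used at most once. Matching is symmetric in the two channels.
#'
#' With `duration_slack = TRUE` (default) a pair is a candidate when
#' `|center_green - center_red| <= |dur_green - dur_red|/2 + window`: the
#' two burst time ranges must (nearly) overlap, with the tolerance window
#' absorbing edge jitter. A short burst contained anywhere inside a long
#' partner burst of the same transit then matches even though their centres
#' differ by several milliseconds. With `duration_slack = FALSE` the
#' criterion is the bare `|center_green - center_red| <= window`.
#'
#' @param green,red [detect_bursts()] results from the same acquisition.
#' @param window a [compute_tolerance_window()] result, or a number
#'   (seconds).
#' @param duration_slack widen the per-pair acceptance by half the
#'   burst-duration difference (see above).
#' @return an object of class `coincident_events`: data.frame `events`
#'   (time-ordered; green/red burst ids, centres, offset, durations, photon
#'   counts, mean rates), `n_unmatched_green`, `n_unmatched_red`, `window_s`,
#'   `duration_s`.
#' @export
match_coincident_bursts <- function(green, red, window, duration_slack = TRUE) {
  stopifnot(inherits(green, "burst_set"), inherits(red, "burst_set"))
  w <- if (inherits(window, "tolerance_window")) window$value_s else as.numeric(window)
  if (w < 0) stop("match_coincident_bursts: window must be >= 0")
  gb <- green$bursts; rb <- red$bursts
  pairs <- NULL
  if (nrow(gb) && nrow(rb)) {
    wmax <- if (duration_slack) {
      w + (max(gb$duration_s) + max(rb$duration_s)) / 2
    } else w
    ord_r <- order(rb$center_s)
    rc <- rb$center_s[ord_r]
    lo <- findInterval(gb$center_s - wmax, rc) + 1L
    hi <- findInterval(gb$center_s + wmax, rc)
    gi <- rep.int(seq_len(nrow(gb)), pmax(hi - lo + 1L, 0L))
    ri <- unlist(lapply(seq_len(nrow(gb)), function(i)
      if (hi[i] >= lo[i]) ord_r[lo[i]:hi[i]] else integer(0)))
    if (length(gi)) {
      off <- rb$center_s[ri] - gb$center_s[gi]
      thr <- if (duration_slack) {
        abs(gb$duration_s[gi] - rb$duration_s[ri]) / 2 + w
      } else w
      keep <- abs(off) <= thr
      pairs <- data.frame(g = gi[keep], r = ri[keep], offset = off[keep])
    }
  }
  ev <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(abs(pairs$offset), pairs$g, pairs$r), ]
    used_g <- logical(nrow(gb)); used_r <- logical(nrow(rb))
    take <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (!used_g[pairs$g[i]] && !used_r[pairs$r[i]]) {
        take[i] <- TRUE
        used_g[pairs$g[i]] <- TRUE
        used_r[pairs$r[i]] <- TRUE
      }
    }
    sel <- pairs[take, ]
    ev <- data.frame(
      green_id = sel$g, red_id = sel$r,
      center_green_s = gb$center_s[sel$g], center_red_s = rb$center_s[sel$r],
      center_offset_s = sel$offset,
      duration_green_s = gb$duration_s[sel$g],
      duration_red_s = rb$duration_s[sel$r],
      n_photons_green = gb$n_photons[sel$g],
      n_photons_red = rb$n_photons[sel$r],
      rate_green = gb$mean_rate[sel$g], rate_red = rb$mean_rate[sel$r])
    ev <- ev[order(ev$center_green_s), ]
    rownames(ev) <- NULL
  } else {
    ev <- data.frame(green_id = integer(0), red_id = integer(0),
                     center_green_s = numeric(0), center_red_s = numeric(0),
                     center_offset_s = numeric(0), duration_green_s = numeric(0),
                     duration_red_s = numeric(0), n_photons_green = integer(0),
                     n_photons_red = integer(0), rate_green = numeric(0),
                     rate_red = numeric(0))
  }
  structure(list(events = ev,
                 n_unmatched_green = nrow(gb) - nrow(ev),
                 n_unmatched_red = nrow(rb) - nrow(ev),
                 window_s = w,
                 duration_s = max(green$duration_s, red$duration_s)),
            class = "coincident_events")
}

#' @export
print.coincident_events <- function(x, ...) {
  cat(sprintf("<coincident_events> %d events (window %.3g ms); unmatched green %d, red %d\n",
              nrow(x$events), x$window_s * 1e3, x$n_unmatched_green,
              x$n_unmatched_red))
  invisible(x)
}

#' Cargo molecule count from a coincident burst
#'
#' Divides the background-subtracted green burst mean rate by the
#' independently calibrated single-molecule brightness:
#' `raw = max(0, rate - B_g) / epsilon`; the integer count rounds to
#' nearest (half away from zero) with a floor at zero. A raw value of zero
#' flags a likely chance coincidence.
#'
#' @param rate_green green burst mean rate(s), counts/s.
#' @param brightness single-molecule brightness epsilon (counts/s per
#'   molecule, > 0), from [molecular_brightness()].
#' @param background_green green background rate (counts/s).
#' @return data.frame with `cargo_raw` and integer `cargo_count`.
#' @export
cargo_count <- function(rate_green, brightness, background_green = 0) {
  if (!is.finite(brightness) || brightness <= 0) {
    stop("cargo_count: brightness calibration must be > 0")
  }
  raw <- pmax(0, rate_green - background_green) / brightness
  data.frame(cargo_raw = raw, cargo_count = as.integer(floor(raw + 0.5)))
}

#' Annotate coincident events with sizes and cargo counts
#'
#' Adds per-event hydrodynamic sizes from both channels' burst durations
#' ([ev_size_from_burst()]) and, when a brightness calibration is given,
#' cargo molecule counts.
#'
#' Two cargo scales are available. `"direct"` divides the
#' background-subtracted green burst rate by the free-molecule brightness
#' ([cargo_count()]); it is simple but inherits a burst-selection bias:
#' detected bursts oversample bright central transits for dim particles and
#' dim peripheral ones for bright particles, so the scale drifts with the
#' search threshold. `"fcs_anchored"` (used when `cargo_anchor` is given)
#' keeps the relative per-event intensities but rescales them so their mean
#' equals `cargo_anchor`, the mean cargo per vesicle measured independently
#' from correlation amplitudes as (per-vesicle FCS brightness)/(per-molecule
#' FCS brightness) - both volume-averaged, hence free of burst-selection
#' bias.
#'
#' @param events a [match_coincident_bursts()] result.
#' @param size_cfg a [size_estimation_config()].
#' @param brightness optional single-molecule brightness (counts/s).
#' @param background_green green background rate (counts/s).
#' @param cargo_anchor optional mean cargo molecules per vesicle from the
#'   correlation analysis; when given, event intensities are rescaled to
#'   this mean instead of divided by `brightness`.
#' @return `events` with columns `size_green_nm`, `size_red_nm` and (if
#'   calibrated) `cargo_raw`, `cargo_count` added.
#' @export
annotate_coincident_events <- function(events, size_cfg, brightness = NULL,
                                       background_green = 0,
                                       cargo_anchor = NULL) {
  stopifnot(inherits(events, "coincident_events"))
  ev <- events$events
  if (nrow(ev)) {
    ev$size_green_nm <- ev_size_from_burst(ev$duration_green_s, size_cfg, "green")
    ev$size_red_nm <- ev_size_from_burst(ev$duration_red_s, size_cfg, "red")
    if (!is.null(cargo_anchor)) {
      u <- pmax(0, ev$rate_green - background_green)
      ev$cargo_raw <- if (mean(u) > 0) u * cargo_anchor / mean(u) else u
      ev$cargo_count <- as.integer(floor(ev$cargo_raw + 0.5))
    } else if (!is.null(brightness)) {
      cc <- cargo_count(ev$rate_green, brightness, background_green)
      ev$cargo_raw <- cc$cargo_raw
      ev$cargo_count <- cc$cargo_count
    }
  } else {
    ev$size_green_nm <- numeric(0); ev$size_red_nm <- numeric(0)
    if (!is.null(brightness) || !is.null(cargo_anchor)) {
      ev$cargo_raw <- numeric(0); ev$cargo_count <- integer(0)
    }
  }
  events$events <- ev
  events
}

#' Rescaled-gamma fit of a size distribution
#'
#' Fits the rescaled gamma function
#' `f(x) = C lambda^alpha / Gamma(alpha) x^(alpha-1) exp(-lambda x)` to the
#' size histogram; the distribution mean is `alpha / lambda`.
#'
#' With `method = "histogram"` (default) `alpha`, `lambda` and the scale `C`
#' are fitted by least squares to the histogram counts. This tracks the
#' bulk of the distribution the way the rescaled-histogram fit is used on
#' experimental size data; the sparse long-transit tail is downweighted.
#' With `method = "mle"` the gamma parameters come from maximum likelihood
#' on the raw sizes (for which the fitted mean equals the sample mean) and
#' `C = n * bin width` from histogram normalization.
#'
#' @param sizes_nm vector of at least `min_n` positive sizes (nm).
#' @param method `"histogram"` (least squares on histogram counts) or
#'   `"mle"`.
#' @param min_n minimum sample size (default 30).
#' @param bin_width_nm histogram bin width (default the Freedman-Diaconis
#'   choice).
#' @return an object of class `size_distribution_fit`: `alpha`, `lambda`,
#'   `c_scale`, `mean_nm`, `method`, standard errors where available.
#' @export
fit_gamma_size_distribution <- function(sizes_nm,
                                        method = c("histogram", "mle"),
                                        min_n = 30, bin_width_nm = NULL) {
  method <- match.arg(method)
  sizes_nm <- as.numeric(sizes_nm)
  if (length(sizes_nm) < min_n) {
    stop("fit_gamma_size_distribution: need at least ", min_n, " sizes")
  }
  if (any(!is.finite(sizes_nm)) || any(sizes_nm <= 0)) {
    stop("fit_gamma_size_distribution: sizes must be positive")
  }
  if (stats::sd(sizes_nm) < 1e-9 * mean(sizes_nm)) {
    stop("fit_gamma_size_distribution: degenerate (constant) sizes; shape diverges")
  }
  if (is.null(bin_width_nm)) {
    bin_width_nm <- 2 * stats::IQR(sizes_nm) / length(sizes_nm)^(1 / 3)
    if (bin_width_nm <= 0) bin_width_nm <- diff(range(sizes_nm)) / 30
  }
  n <- length(sizes_nm)
  # moment starting values
  a0 <- max((mean(sizes_nm) / stats::sd(sizes_nm))^2, 0.2)
  l0 <- a0 / mean(sizes_nm)
  if (method == "mle") {
    ft <- tryCatch(
      fitdistrplus::fitdist(sizes_nm, "gamma", method = "mle",
                            start = list(shape = a0, rate = l0)),
      error = function(e) stop("fit_gamma_size_distribution: gamma fit failed (",
                               conditionMessage(e), ")"))
    alpha <- unname(ft$estimate["shape"])
    lambda <- unname(ft$estimate["rate"])
    alpha_se <- unname(ft$sd["shape"]); lambda_se <- unname(ft$sd["rate"])
    c_scale <- n * bin_width_nm
  } else {
    brk <- seq(0, max(sizes_nm) + bin_width_nm, by = bin_width_nm)
    h <- graphics::hist(sizes_nm, breaks = brk, plot = FALSE)
    dat <- data.frame(x = h$mids, y = h$counts)
    ft <- tryCatch(
      minpack.lm::nlsLM(y ~ cc * stats::dgamma(x, a, l), data = dat,
                        start = list(cc = n * bin_width_nm, a = a0, l = l0),
                        lower = c(cc = 0, a = 1e-3, l = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) stop("fit_gamma_size_distribution: gamma fit failed (",
                               conditionMessage(e), ")"))
    cf <- stats::coef(ft)
    vc <- tryCatch(stats::vcov(ft), error = function(e) NULL)
    alpha <- unname(cf["a"]); lambda <- unname(cf["l"])
    alpha_se <- if (!is.null(vc)) sqrt(vc["a", "a"]) else NA_real_
    lambda_se <- if (!is.null(vc)) sqrt(vc["l", "l"]) else NA_real_
    c_scale <- unname(cf["cc"])
  }
  structure(list(alpha = alpha, lambda = lambda,
                 alpha_se = alpha_se, lambda_se = lambda_se,
                 c_scale = c_scale, bin_width_nm = bin_width_nm,
                 mean_nm = alpha / lambda, n = n, method = method),
            class = "size_distribution_fit")
}

#' @export
print.size_distribution_fit <- function(x, ...) {
  cat(sprintf("<size_distribution_fit> alpha = %.3g, lambda = %.3g /nm, mean = %.4g nm (n = %d)\n",
              x$alpha, x$lambda, x$mean_nm, x$n))
  invisible(x)
}

#' Coincident-burst rate and burst-based loading yield
#'
#' `coincident_rate = 60 * n_events / duration` (events per minute) and
#' `loading_yield_burst = n_events / n_red_bursts` - the burst-analysis
#' analogue of the FCCS loading yield.
#'
#' @param events a [match_coincident_bursts()] result.
#' @param red the red-channel [detect_bursts()] result.
#' @param duration_s acquisition duration (s).
#' @return list with `coincident_rate_per_min`, `loading_yield_burst`,
#'   `n_events`, `n_red_bursts`.
#' @export
coincidence_metrics <- function(events, red, duration_s) {
  stopifnot(inherits(events, "coincident_events"), inherits(red, "burst_set"))
  if (duration_s <= 0) stop("coincidence_metrics: duration must be > 0")
  if (nrow(red$bursts) == 0) {
    stop("coincidence_metrics: empty red burst set; yield undefined")
  }
  n <- nrow(events$events)
  list(coincident_rate_per_min = 60 * n / duration_s,
       loading_yield_burst = n / nrow(red$bursts),
       n_events = n, n_red_bursts = nrow(red$bursts))
}

#' Expected chance-coincidence count of independent channels
#'
#' For independent green and red bursts arriving at rates `r_g` and `r_r`,
#' the expected number of centre-time matches within a window `w` over a
#' duration `T` is `2 r_g r_r w T`. Reported for comparison; not subtracted
#' from the measured coincidence metrics.
#'
#' @param green,red [detect_bursts()] results.
#' @param window a [compute_tolerance_window()] or a number (s).
#' @param duration_slack account for the duration-aware acceptance of
#'   [match_coincident_bursts()] by adding the mean half duration
#'   difference of random burst pairs to the window.
#' @return expected chance-coincidence event count.
#' @export
chance_coincidence_count <- function(green, red, window, duration_slack = TRUE) {
  stopifnot(inherits(green, "burst_set"), inherits(red, "burst_set"))
  w <- if (inherits(window, "tolerance_window")) window$value_s else as.numeric(window)
  if (duration_slack && nrow(green$bursts) && nrow(red$bursts)) {
    dg <- green$bursts$duration_s
    dr <- red$bursts$duration_s
    if (length(dg) > 300) dg <- stats::quantile(dg, seq(0.005, 0.995, length.out = 300))
    if (length(dr) > 300) dr <- stats::quantile(dr, seq(0.005, 0.995, length.out = 300))
    w <- w + mean(abs(outer(dg, dr, "-"))) / 2
  }
  2 * green$burst_rate * red$burst_rate * w * green$duration_s
}

#' 2D histogram of vesicle size versus cargo count
#'
#' @param events an annotated [coincident_events] object (see
#'   [annotate_coincident_events()]) carrying sizes and cargo counts.
#' @param size_bins_nm monotone size bin edges (nm); must cover the data.
#' @param cargo_bins monotone cargo bin edges; must cover the data.
#' @param channel which channel's size estimate to histogram.
#' @return integer matrix (size bins x cargo bins) whose sum equals the
#'   event count, with bin-edge dimnames.
#' @export
size_cargo_histogram2d <- function(events, size_bins_nm, cargo_bins,
                                   channel = c("green", "red")) {
  stopifnot(inherits(events, "coincident_events"))
  channel <- match.arg(channel)
  if (length(size_bins_nm) < 2 || length(cargo_bins) < 2 ||
      any(diff(size_bins_nm) <= 0) || any(diff(cargo_bins) <= 0)) {
    stop("size_cargo_histogram2d: bin edges must be monotone increasing with >= 2 edges")
  }
  ev <- events$events
  if (!"cargo_count" %in% names(ev)) {
    stop("size_cargo_histogram2d: events lack cargo counts; annotate first")
  }
  sizes <- if (channel == "green") ev$size_green_nm else ev$size_red_nm
  m <- matrix(0L, length(size_bins_nm) - 1, length(cargo_bins) - 1,
              dimnames = list(size = sprintf("[%g,%g)", utils::head(size_bins_nm, -1),
                                             utils::tail(size_bins_nm, -1)),
                              cargo = sprintf("[%g,%g)", utils::head(cargo_bins, -1),
                                              utils::tail(cargo_bins, -1))))
  if (nrow(ev)) {
    si <- findInterval(sizes, size_bins_nm, rightmost.closed = TRUE)
    ci <- findInterval(ev$cargo_count, cargo_bins, rightmost.closed = TRUE)
    if (any(si < 1 | si >= length(size_bins_nm)) ||
        any(ci < 1 | ci >= length(cargo_bins))) {
      stop("size_cargo_histogram2d: bins do not cover all events")
    }
    for (i in seq_along(si)) m[si[i], ci[i]] <- m[si[i], ci[i]] + 1L
  }
  m
}

#' Read an externally produced size histogram (e.g. particle-tracking data)
#'
#' Two-column plain text: size in nm and density (relative units); `#`
#' comment lines allowed. Used only for overlay comparison with burst-based
#' size distributions.
#'
#' @param path file to read.
#' @return data.frame with columns `size_nm`, `density`.
#' @export
read_external_size_histogram <- function(path) {
  if (!file.exists(path)) stop("read_external_size_histogram: file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("size_nm", "density"),
                           colClasses = "numeric")
  if (any(tab$size_nm <= 0)) stop("read_external_size_histogram: sizes must be > 0")
  tab
}
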