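#' Split coincident events into fixed-count subsets
#'
#' Consecutive blocks of `per_subset` coincident events (default 20) define
#' time spans from the first event's earliest burst start to the last
#' event's latest burst stop. Each subset reports its own coincident rate
#' (`60 * per_subset / span`) and burst-based loading yield
#' (`per_subset / red bursts with centre inside the span`). A trailing
#' partial block is dropped (its size is recorded).
#'
#' @param events an (optionally annotated) [match_coincident_bursts()]
#'   result with at least `per_subset` events.
#' @param red the red-channel [detect_bursts()] result.
#' @param per_subset events per subset.
#' @return data.frame of class `subset_metrics` with columns `subset`,
#'   `t_start_s`, `t_stop_s`, `span_s`, `rate_per_min`, `yield`,
#'   `n_red_bursts`; attribute `n_dropped` counts the discarded remainder.
#' @export
split_into_subsets <- function(events, red, per_subset = 20) {
  stopifnot(inherits(events, "coincident_events"), inherits(red, "burst_set"))
  ev <- events$events
  if (nrow(ev) < per_subset) {
    stop("split_into_subsets: fewer than ", per_subset, " coincident events")
  }
  ev <- ev[order(ev$center_green_s), ]
  n_full <- nrow(ev) %/% per_subset
  start_ev <- pmin(ev$center_green_s - ev$duration_green_s / 2,
                   ev$center_red_s - ev$duration_red_s / 2)
  stop_ev <- pmax(ev$center_green_s + ev$duration_green_s / 2,
                  ev$center_red_s + ev$duration_red_s / 2)
  out <- lapply(seq_len(n_full), function(b) {
    idx <- seq.int((b - 1) * per_subset + 1, b * per_subset)
    t0 <- min(start_ev[idx]); t1 <- max(stop_ev[idx])
    span <- t1 - t0
    nred <- sum(red$bursts$center_s >= t0 & red$bursts$center_s <= t1)
    data.frame(subset = b, t_start_s = t0, t_stop_s = t1, span_s = span,
               rate_per_min = 60 * per_subset / span,
               yield = per_subset / nred, n_red_bursts = nred)
  })
  res <- do.call(rbind, out)
  attr(res, "n_dropped") <- nrow(ev) - n_full * per_subset
  attr(res, "per_subset") <- per_subset
  class(res) <- c("subset_metrics", class(res))
  res
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with the Welch-Satterthwaite degrees of freedom,
#' as used to compare per-subset coincident rates and loading yields between
#' experimental conditions.
#'
#' @param a,b numeric vectors, each of length >= 2 with nonzero variance.
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("welch_t_test: each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1, mean_a = mean(a), mean_b = mean(b)))
    stop("welch_t_test: degenerate zero variance in both groups")
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("welch_t_test: zero variance in one group; Welch statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Event-level coincidence generator for statistical power studies
#'
#' Generates an acquisition at the burst level rather than the photon
#' level: coincident events arrive as a homogeneous Poisson process at
#' `coincident_rate_per_min`, red bursts as an independent Poisson process
#' at `red_rate_per_s` superimposed on the coincident times (every
#' coincident event has a red burst by construction), with fixed nominal
#' burst durations. This is orders of magnitude faster than photon-level
#' simulation and is the appropriate scale for studying the power of
#' condition comparisons, whose statistics are driven entirely by event
#' counts and spans.
#'
#' @param coincident_rate_per_min true coincident-event rate (per minute).
#' @param red_rate_per_s rate of additional (non-coincident) red bursts
#'   (per second).
#' @param duration_s acquisition length (s).
#' @param per_subset events per subset (default 20).
#' @param seed RNG seed.
#' @param burst_duration_s nominal burst duration assigned to every event.
#' @return the [split_into_subsets()] metrics of the generated acquisition.
#' @export
simulate_subset_metrics <- function(coincident_rate_per_min, red_rate_per_s,
                                    duration_s, per_subset = 20, seed,
                                    burst_duration_s = 4e-3) {
  set.seed(seed)
  n_ev <- stats::rpois(1, coincident_rate_per_min / 60 * duration_s)
  if (n_ev < per_subset) {
    stop("simulate_subset_metrics: fewer than one subset of events generated")
  }
  t_ev <- sort(stats::runif(n_ev, 0, duration_s))
  n_extra <- stats::rpois(1, red_rate_per_s * duration_s)
  t_red <- sort(c(t_ev, stats::runif(n_extra, 0, duration_s)))
  mk_bursts <- function(tt) {
    data.frame(start_s = tt - burst_duration_s / 2,
               stop_s = tt + burst_duration_s / 2,
               duration_s = burst_duration_s,
               n_photons = 30L, mean_rate = 30 / burst_duration_s,
               center_s = tt, first_photon = NA_integer_,
               last_photon = NA_integer_)
  }
  red <- structure(list(bursts = mk_bursts(t_red), params = NULL,
                        duration_s = duration_s, background_rate = NA_real_,
                        burst_rate = length(t_red) / duration_s),
                   class = "burst_set")
  ev <- data.frame(green_id = seq_along(t_ev), red_id = match(t_ev, t_red),
                   center_green_s = t_ev, center_red_s = t_ev,
                   center_offset_s = 0,
                   duration_green_s = burst_duration_s,
                   duration_red_s = burst_duration_s,
                   n_photons_green = 30L, n_photons_red = 30L,
                   rate_green = 30 / burst_duration_s,
                   rate_red = 30 / burst_duration_s)
  events <- structure(list(events = ev, n_unmatched_green = 0L,
                           n_unmatched_red = length(t_red) - length(t_ev),
                           window_s = burst_duration_s / 2,
                           duration_s = duration_s),
                      class = "coincident_events")
  split_into_subsets(events, red, per_subset)
}

#' Pipeline analysis configuration
#'
#' Bundles every tunable of [run_pipeline()]: the PIE gates, correlator
#' settings, diffusion-fit settings, burst-search calibration grids, the
#' coincidence tolerance rule, the sizing constants and the brightness
#' calibration.
#'
#' @param gates a [pie_gate_config()].
#' @param base_bin_s,points_per_level,n_levels correlator settings.
#' @param n_segments segments for correlation error bars.
#' @param kappa axial ratio for diffusion fits.
#' @param two_component_green fit the green autocorrelation with a fast free
#'   species plus a slow vesicle component (default TRUE).
#' @param k_grid,m_grid burst-calibration candidate grids.
#' @param min_photons_green,min_photons_red minimum photons per burst,
#'   per channel. The defaults are asymmetric on purpose: the red
#'   (membrane-label) burst set is the denominator of the burst-based
#'   loading yield, so it should only count solidly established vesicle
#'   transits, while the green (cargo) set is the numerator's evidence and
#'   is kept permissive so faint cargo signal can still claim a match.
#' @param tolerance_rule see [compute_tolerance_window()].
#' @param window_floor_tau_frac the coincidence window actually used is
#'   `max(rule value, window_floor_tau_frac * (tau_D_green + tau_D_red))`.
#'   The centre-time jitter between the two channels' bursts of one transit
#'   scales with the transit time itself, so when the two duration
#'   distributions are similar the quantile-difference rule degenerates to
#'   a near-zero window and rejects genuine coincidences; the floor keeps
#'   the window on the physical jitter scale. Set to 0 to disable.
#' @param size_cfg a [size_estimation_config()].
#' @param brightness_cal single-molecule green brightness (counts/s) for
#'   cargo counting, or `NULL` to skip cargo estimates.
#' @param cargo_method `"fcs_anchored"` (default) rescales per-event burst
#'   intensities to the mean cargo per vesicle derived from correlation
#'   amplitudes; `"direct"` divides each burst rate by `brightness_cal`.
#'   See [annotate_coincident_events()]. The anchored scale requires a
#'   single-component green fit; with a two-component fit the pipeline
#'   falls back to the direct scale.
#' @param background_green,background_red known post-gating background rates
#'   (counts/s), e.g. from an independent buffer measurement; `NULL` (the
#'   default) estimates them from the gated streams with
#'   [estimate_background()]. Note the estimate on a busy stream includes
#'   out-of-burst signal from particles at the edges of the detection
#'   volume, which is appropriate for burst thresholds but overstates the
#'   uncorrelated background entering the amplitude correction.
#' @param volume_correction list of waists for the occupancy volume-mismatch
#'   correction (see [occupancy_from_amplitudes()]); defaults to the waists
#'   in `size_cfg` with axial ratio 5 and 300 nm offset.
#' @param per_subset coincident events per statistics subset.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(gates = pie_gate_config(),
                            base_bin_s = 2e-6, points_per_level = 8,
                            n_levels = 20, n_segments = 5,
                            kappa = 5, two_component_green = TRUE,
                            k_grid = c(2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64),
                            m_grid = c(5, 10, 15, 20),
                            min_photons_green = 10, min_photons_red = 30,
                            tolerance_rule = "half_q10_diff",
                            window_floor_tau_frac = 0.25,
                            size_cfg = size_estimation_config(),
                            brightness_cal = NULL,
                            cargo_method = "fcs_anchored",
                            background_green = NULL, background_red = NULL,
                            volume_correction = NULL,
                            per_subset = 20) {
  if (is.null(volume_correction)) {
    volume_correction <- list(
      waist_xy_green = size_cfg$waist_green_m,
      waist_z_green = 5 * size_cfg$waist_green_m,
      waist_xy_red = size_cfg$waist_red_m,
      waist_z_red = 5 * size_cfg$waist_red_m,
      axial_offset_red = 300e-9)
  }
  structure(list(gates = gates, base_bin_s = base_bin_s,
                 points_per_level = points_per_level, n_levels = n_levels,
                 n_segments = n_segments, kappa = kappa,
                 two_component_green = two_component_green,
                 k_grid = k_grid, m_grid = m_grid,
                 min_photons_green = min_photons_green,
                 min_photons_red = min_photons_red,
                 tolerance_rule = tolerance_rule,
                 window_floor_tau_frac = window_floor_tau_frac,
                 size_cfg = size_cfg,
                 brightness_cal = brightness_cal,
                 cargo_method = match.arg(cargo_method, c("fcs_anchored", "direct")),
                 background_green = background_green,
                 background_red = background_red,
                 volume_correction = volume_correction,
                 per_subset = per_subset),
            class = "pipeline_config")
}

#' Run the full PIE-FCCS + coincident-burst pipeline on one acquisition
#'
#' Executes, in order: PIE gating, background estimation per channel,
#' multi-tau auto- and cross-correlation, 3D-diffusion fits, occupancy and
#' FCCS loading-yield extraction, burst-search calibration against the
#' fitted diffusion times, coincident-burst matching, Stokes-Einstein sizing
#' and cargo counting, gamma size-distribution fits, subset splitting, and
#' report assembly. Fully deterministic for a given input stream.
#'
#' @param stream the raw two-detector [photon_stream()].
#' @param config a [pipeline_config()].
#' @param condition label stored in the report.
#' @return a `condition_report`: see [summarize_condition()].
#' @export
run_pipeline <- function(stream, config = pipeline_config(),
                         condition = "unnamed") {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_pipeline: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  gated <- stage("gate", apply_pie_gating(stream, config$gates))
  bg_est_g <- stage("background_green", estimate_background(gated$green))
  bg_est_r <- stage("background_red", estimate_background(gated$red))
  bg_g <- if (is.null(config$background_green)) bg_est_g else config$background_green
  bg_r <- if (is.null(config$background_red)) bg_est_r else config$background_red
  corr <- stage("correlate", list(
    gg = multitau_correlate(gated$green, base_bin_s = config$base_bin_s,
                            points_per_level = config$points_per_level,
                            n_levels = config$n_levels, pair = "gg",
                            n_segments = config$n_segments),
    rr = multitau_correlate(gated$red, base_bin_s = config$base_bin_s,
                            points_per_level = config$points_per_level,
                            n_levels = config$n_levels, pair = "rr",
                            n_segments = config$n_segments),
    rg = multitau_correlate(gated$red, gated$green,
                            base_bin_s = config$base_bin_s,
                            points_per_level = config$points_per_level,
                            n_levels = config$n_levels, pair = "rg",
                            n_segments = config$n_segments)))
  f_g <- n_photons(gated$green) / gated$green$duration_s
  f_r <- n_photons(gated$red) / gated$red$duration_s
  fits <- stage("fit", list(
    gg = fit_diffusion_model(corr$gg,
                             n_components = if (config$two_component_green) 2 else 1,
                             kappa = config$kappa, background_rate = bg_g,
                             mean_rate = f_g),
    rr = fit_diffusion_model(corr$rr, n_components = 1, kappa = config$kappa,
                             background_rate = bg_r, mean_rate = f_r),
    rg = fit_diffusion_model(corr$rg, n_components = 1, kappa = config$kappa)))
  occ <- stage("occupancy", occupancy_from_amplitudes(
    fits$gg, fits$rr, fits$rg, volume_correction = config$volume_correction))
  tau_g <- fits$gg$components$tau_d_s[fits$gg$n_components]  # slow = vesicle
  tau_r <- fits$rr$components$tau_d_s[1]
  params_g <- stage("burst_calibration_green", calibrate_burst_params(
    gated$green, tau_g, k_grid = config$k_grid, m_grid = config$m_grid,
    background_rate = bg_est_g, min_photons = config$min_photons_green))
  params_r <- stage("burst_calibration_red", calibrate_burst_params(
    gated$red, tau_r, k_grid = config$k_grid, m_grid = config$m_grid,
    background_rate = bg_est_r, min_photons = config$min_photons_red))
  bursts_g <- stage("bursts_green", detect_bursts(gated$green, params_g))
  bursts_r <- stage("bursts_red", detect_bursts(gated$red, params_r))
  tol <- stage("tolerance", compute_tolerance_window(
    bursts_g, bursts_r, rule = config$tolerance_rule))
  tol$value_s <- max(tol$value_s,
                     config$window_floor_tau_frac * (tau_g + tau_r))
  events <- stage("coincidence", match_coincident_bursts(bursts_g, bursts_r, tol))
  anchor <- NULL
  if (!is.null(config$brightness_cal) && config$cargo_method == "fcs_anchored" &&
      fits$gg$n_components == 1) {
    eps_vesicle <- (fits$gg$mean_rate - fits$gg$background_rate) /
      fits$gg$occupancy_total
    anchor <- eps_vesicle / config$brightness_cal
  }
  events <- stage("annotate", annotate_coincident_events(
    events, config$size_cfg, brightness = config$brightness_cal,
    background_green = bg_est_g, cargo_anchor = anchor))
  metrics <- stage("metrics", coincidence_metrics(events, bursts_r,
                                                  stream$duration_s))
  gamma_fits <- list(green = NULL, red = NULL)
  if (nrow(events$events) >= 30) {
    gamma_fits$green <- stage("gamma_green",
      fit_gamma_size_distribution(events$events$size_green_nm))
    gamma_fits$red <- stage("gamma_red",
      fit_gamma_size_distribution(events$events$size_red_nm))
  }
  subsets <- if (nrow(events$events) >= config$per_subset) {
    stage("subsets", split_into_subsets(events, bursts_r, config$per_subset))
  } else NULL
  summarize_condition(condition = condition, config = config,
                      gated = gated,
                      backgrounds = c(green = bg_g, red = bg_r,
                                      green_est = bg_est_g, red_est = bg_est_r),
                      curves = corr, fits = fits, occupancy = occ,
                      burst_params = list(green = params_g, red = params_r),
                      bursts = list(green = bursts_g, red = bursts_r),
                      tolerance = tol, events = events, metrics = metrics,
                      gamma_fits = gamma_fits, subsets = subsets)
}

#' Assemble a structured condition report
#'
#' Validates that every pipeline stage is present and collects the
#' condition-level results - occupancies, both loading yields, the
#' coincident rate, size-fit means, cargo quantiles, the parameters used -
#' into one record. Raises an incomplete-report error naming any missing
#' stage.
#'
#' @param condition condition label.
#' @param config the [pipeline_config()] used.
#' @param gated,backgrounds,curves,fits,occupancy,burst_params,bursts
#'   intermediate stage outputs.
#' @param tolerance,events,metrics,gamma_fits,subsets later stage outputs
#'   (`gamma_fits`/`subsets` may be `NULL` for sparse data).
#' @return an object of class `condition_report`.
#' @export
summarize_condition <- function(condition, config, gated, backgrounds, curves,
                                fits, occupancy, burst_params, bursts,
                                tolerance, events, metrics,
                                gamma_fits = list(green = NULL, red = NULL),
                                subsets = NULL) {
  required <- list(gated = gated, backgrounds = backgrounds, curves = curves,
                   fits = fits, occupancy = occupancy,
                   burst_params = burst_params, bursts = bursts,
                   tolerance = tolerance, events = events, metrics = metrics)
  missing <- names(required)[vapply(required, is.null, TRUE)]
  if (length(missing)) {
    stop("summarize_condition: incomplete report; missing stage(s): ",
         paste(missing, collapse = ", "))
  }
  ev <- events$events
  cargo_q <- if ("cargo_count" %in% names(ev) && nrow(ev)) {
    stats::quantile(ev$cargo_count, c(0.1, 0.25, 0.5, 0.75, 0.9))
  } else NULL
  structure(list(
    condition = condition,
    software_version = as.character(utils::packageVersion("pieburst")),
    n_photons = c(green = n_photons(gated$green), red = n_photons(gated$red)),
    duration_s = gated$green$duration_s,
    backgrounds = backgrounds,
    occupancy = list(n_g = occupancy$n_g, n_g_total = occupancy$n_g_total,
                     n_r = occupancy$n_r, n_rg = occupancy$n_rg),
    loading_yield_fccs = occupancy$loading_yield_fccs,
    bound_fraction_green = occupancy$bound_fraction_green,
    tau_d_s = c(green_slow = fits$gg$components$tau_d_s[fits$gg$n_components],
                red = fits$rr$components$tau_d_s[1]),
    burst_params = list(
      green = unclass(burst_params$green)[c("m", "k", "background_rate", "min_photons")],
      red = unclass(burst_params$red)[c("m", "k", "background_rate", "min_photons")]),
    n_bursts = c(green = nrow(bursts$green$bursts), red = nrow(bursts$red$bursts)),
    burst_rates = c(green = bursts$green$burst_rate, red = bursts$red$burst_rate),
    tolerance_window_s = tolerance$value_s,
    n_coincident = metrics$n_events,
    coincident_rate_per_min = metrics$coincident_rate_per_min,
    loading_yield_burst = metrics$loading_yield_burst,
    size_mean_nm = c(green = if (!is.null(gamma_fits$green)) gamma_fits$green$mean_nm else NA_real_,
                     red = if (!is.null(gamma_fits$red)) gamma_fits$red$mean_nm else NA_real_),
    gamma_fits = gamma_fits,
    cargo_quantiles = cargo_q,
    subsets = subsets,
    fits = fits, curves = curves, events = events, bursts = bursts
  ), class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> '%s' (%.1f s, %d+%d photons)\n", x$condition,
              x$duration_s, x$n_photons["green"], x$n_photons["red"]))
  cat(sprintf("  N_g = %.4g, N_r = %.4g, N_rg = %.4g; FCCS yield = %.3g\n",
              x$occupancy$n_g, x$occupancy$n_r, x$occupancy$n_rg,
              x$loading_yield_fccs))
  cat(sprintf("  bursts: %d green, %d red; %d coincident (%.3g /min); burst yield = %.3g\n",
              x$n_bursts["green"], x$n_bursts["red"], x$n_coincident,
              x$coincident_rate_per_min, x$loading_yield_burst))
  if (any(is.finite(x$size_mean_nm))) {
    cat(sprintf("  gamma size means: green %.4g nm, red %.4g nm\n",
                x$size_mean_nm["green"], x$size_mean_nm["red"]))
  }
  invisible(x)
}

#' Serialize a condition report to JSON
#'
#' Writes the scalar summary fields (not the bulky per-photon/per-burst
#' intermediates) as a JSON record.
#'
#' @param report a `condition_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_condition_report <- function(report, path) {
  stopifnot(inherits(report, "condition_report"))
  keep <- report[c("condition", "software_version", "n_photons", "duration_s",
                   "backgrounds", "occupancy", "loading_yield_fccs",
                   "bound_fraction_green", "tau_d_s", "burst_params",
                   "n_bursts", "burst_rates", "tolerance_window_s",
                   "n_coincident", "coincident_rate_per_min",
                   "loading_yield_burst", "size_mean_nm", "cargo_quantiles")]
  if (!is.null(report$subsets)) {
    keep$subsets <- as.data.frame(report$subsets)
  }
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Compare two conditions by Welch t-tests on subset metrics
#'
#' Welch's two-sided unequal-variance t-test on the per-subset coincident
#' rates and loading yields of two condition reports (no multiple-testing
#' correction; raw p-values are reported).
#'
#' @param report_a,report_b `condition_report`s with subset metrics.
#' @return an object of class `condition_comparison`: per-condition means
#'   and standard deviations, t statistics, Welch-Satterthwaite degrees of
#'   freedom and two-sided p-values for rate and yield.
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "condition_report"),
            inherits(report_b, "condition_report"))
  if (is.null(report_a$subsets) || is.null(report_b$subsets)) {
    stop("compare_conditions: both reports need subset metrics")
  }
  cmp1 <- function(field) {
    a <- report_a$subsets[[field]]
    b <- report_b$subsets[[field]]
    tt <- welch_t_test(a, b)
    list(mean = c(a = mean(a), b = mean(b)),
         sd = c(a = stats::sd(a), b = stats::sd(b)),
         t = tt$t, df = tt$df, p = tt$p)
  }
  structure(list(conditions = c(report_a$condition, report_b$condition),
                 rate = cmp1("rate_per_min"), yield = cmp1("yield")),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s\n", x$conditions[1], x$conditions[2]))
  cat(sprintf("  rate:  %.3g vs %.3g /min, t = %.3g, df = %.3g, p = %.3g\n",
              x$rate$mean["a"], x$rate$mean["b"], x$rate$t, x$rate$df, x$rate$p))
  cat(sprintf("  yield: %.3g vs %.3g,      t = %.3g, df = %.3g, p = %.3g\n",
              x$yield$mean["a"], x$yield$mean["b"], x$yield$t, x$yield$df,
              x$yield$p))
  invisible(x)
}
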