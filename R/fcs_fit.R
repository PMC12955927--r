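#' Forward 3D-diffusion correlation model
#'
#' Evaluates the standard single-focus FCS model
#' `G(tau) = (1 - B/F)^2 / N * sum_i f_i / ((1 + tau/tauD_i) *
#' sqrt(1 + tau / (kappa^2 tauD_i)))`, where `kappa = omega_z / omega_xy`
#' is the axial ratio of the detection volume, `B` the background rate, `F`
#' the mean signal rate and `N` the occupancy. Multiple components are an
#' amplitude-weighted sum.
#'
#' @param tau_s lag times (s).
#' @param n occupancy (mean particles in the effective volume).
#' @param tau_d_s diffusion time(s), one per component.
#' @param kappa axial ratio (>= 1).
#' @param fractions amplitude fractions per component (sum to 1).
#' @param background_rate,mean_rate B and F (counts/s) for the amplitude
#'   correction; `(1 - B/F)^2 = 1` by default.
#' @return numeric G values.
#' @export
fcs_diffusion_model <- function(tau_s, n, tau_d_s, kappa = 5,
                                fractions = rep(1 / length(tau_d_s), length(tau_d_s)),
                                background_rate = 0, mean_rate = 1) {
  if (background_rate >= mean_rate) stop("fcs_diffusion_model: need B < F")
  stopifnot(length(fractions) == length(tau_d_s))
  amp <- (1 - background_rate / mean_rate)^2 / n
  shape <- rep(0, length(tau_s))
  for (i in seq_along(tau_d_s)) {
    x <- tau_s / tau_d_s[i]
    shape <- shape + fractions[i] / ((1 + x) * sqrt(1 + x / kappa^2))
  }
  amp * shape
}

multicomp_shape <- function(tau, tau_d, fractions, kappa) {
  s <- 0
  for (i in seq_along(tau_d)) {
    x <- tau / tau_d[i]
    s <- s + fractions[i] / ((1 + x) * sqrt(1 + x / kappa^2))
  }
  s
}

#' Fit the 3D-diffusion model to a correlation curve
#'
#' Weighted least squares of the model in [fcs_diffusion_model()] using
#' Levenberg-Marquardt. The zero-lag amplitude `G0` is always the fitted
#' model amplitude (never the raw first lag point, which carries shot-noise
#' and afterpulsing contamination). Occupancies are derived from `G0` via
#' `N = (1 - B/F)^2 / G0`; for multi-component fits each component's
#' occupancy uses its amplitude share `G0 * f_i`. Weights default to
#' inverse-variance from the curve's segment-split standard errors when
#' present, otherwise unweighted.
#'
#' @param curve a [correlation_curve()] with at least 15 lag points.
#' @param n_components 1 or 2 diffusing components.
#' @param kappa axial ratio `omega_z/omega_xy`; a number fixes it (default 5,
#'   typical of a confocal calibration), `"free"` lets it float.
#' @param background_rate background B (counts/s).
#' @param mean_rate mean signal rate F (counts/s); defaults to the curve's
#'   stored rate (geometric mean for cross-curves).
#' @param init optional named list of starting values
#'   (`g0`, `tau_d` vector, `f1`).
#' @param weights optional explicit per-lag weights.
#' @return an object of class `diffusion_fit`: components table (occupancy,
#'   tau_d, fraction, standard errors), `amplitude_g0`, `kappa`,
#'   `background_rate`, `mean_rate`, `occupancy_total`, residual norm and the
#'   underlying `nls` fit.
#' @export
fit_diffusion_model <- function(curve, n_components = 1, kappa = 5,
                                background_rate = 0, mean_rate = NULL,
                                init = NULL, weights = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(curve$lags_s) < 15) {
    stop("fit_diffusion_model: need at least 15 lag points")
  }
  if (!n_components %in% c(1, 2)) stop("fit_diffusion_model: n_components must be 1 or 2")
  if (is.null(mean_rate)) mean_rate <- exp(mean(log(curve$mean_rates)))
  if (background_rate >= mean_rate) {
    stop("fit_diffusion_model: background rate must be below the mean rate")
  }
  tau <- curve$lags_s
  g <- curve$values
  kappa_free <- identical(kappa, "free")
  kappa_fix <- if (kappa_free) 5 else as.numeric(kappa)
  if (!kappa_free && kappa_fix < 1) stop("fit_diffusion_model: kappa must be >= 1")

  if (is.null(weights)) {
    if (!is.null(curve$stderr) && any(is.finite(curve$stderr) & curve$stderr > 0)) {
      se <- curve$stderr
      worst <- max(se[is.finite(se) & se > 0])
      se[!is.finite(se) | se <= 0] <- worst
      weights <- 1 / se^2
    } else {
      weights <- rep(1, length(tau))
    }
  }

  g0_start <- max(mean(g[seq_len(min(3, length(g)))]), 1e-4)
  below <- tau[g < g0_start / 2]
  tau_start <- if (length(below)) min(below) else stats::median(tau)
  if (!is.null(init$g0)) g0_start <- init$g0
  if (!is.null(init$tau_d)) tau_start <- init$tau_d[1]

  dat <- data.frame(tau = tau, g = g)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  # multi-start ladder: a near-zero curve (e.g. the cross-correlation of
  # independent species) makes the Jacobian singular at a tiny amplitude
  # start, so later candidates begin from a finite amplitude
  try_fit <- function(g0s, taus) tryCatch({
    if (n_components == 1) {
      start <- list(g0 = g0s, ltd = log(taus))
      lower <- c(g0 = 0, ltd = log(min(tau) / 10))
      upper <- c(g0 = Inf, ltd = log(max(tau) * 10))
      if (kappa_free) {
        start$lk <- log(kappa_fix)
        lower <- c(lower, lk = 0)
        upper <- c(upper, lk = log(50))
        minpack.lm::nlsLM(
          g ~ g0 / ((1 + tau / exp(ltd)) * sqrt(1 + tau / (exp(2 * lk) * exp(ltd)))),
          data = dat, start = start, lower = lower, upper = upper,
          weights = weights, control = ctrl)
      } else {
        minpack.lm::nlsLM(
          g ~ g0 / ((1 + tau / exp(ltd)) * sqrt(1 + tau / (kappa_fix^2 * exp(ltd)))),
          data = dat, start = start, lower = lower, upper = upper,
          weights = weights, control = ctrl)
      }
    } else {
      td1 <- if (!is.null(init$tau_d) && length(init$tau_d) >= 2)
        init$tau_d[1] else taus / 10
      td2 <- if (!is.null(init$tau_d) && length(init$tau_d) >= 2)
        init$tau_d[2] else taus * 3
      f1 <- if (!is.null(init$f1)) init$f1 else 0.5
      start <- list(g0 = g0s, ltd1 = log(td1), ltd2 = log(td2), f1 = f1)
      lower <- c(g0 = 0, ltd1 = log(min(tau) / 10), ltd2 = log(min(tau) / 10), f1 = 0)
      upper <- c(g0 = Inf, ltd1 = log(max(tau) * 10), ltd2 = log(max(tau) * 10), f1 = 1)
      minpack.lm::nlsLM(
        g ~ g0 * (f1 / ((1 + tau / exp(ltd1)) * sqrt(1 + tau / (kappa_fix^2 * exp(ltd1)))) +
                  (1 - f1) / ((1 + tau / exp(ltd2)) * sqrt(1 + tau / (kappa_fix^2 * exp(ltd2))))),
        data = dat, start = start, lower = lower, upper = upper,
        weights = weights, control = ctrl)
    }
  }, error = function(e) e)
  starts <- list(c(g0_start, tau_start),
                 c(max(g0_start, 0.01), tau_start),
                 c(max(g0_start, 0.01), stats::median(tau)),
                 c(1, stats::median(tau)))
  fit <- NULL
  last_err <- NULL
  for (s in starts) {
    res <- try_fit(s[1], s[2])
    if (!inherits(res, "error")) { fit <- res; break }
    last_err <- res
  }
  if (is.null(fit) && n_components == 1 && !kappa_free) {
    # a curve whose best amplitude is <= 0 (e.g. the cross-correlation of
    # independent species, where the finite-acquisition ratio bias makes
    # G slightly negative) drives the bounded amplitude to the zero
    # boundary, where the Jacobian is singular; diagnose with an
    # unconstrained fit and report a zero-amplitude result
    g0_free <- if (abs(mean(g)) > 1e-3) mean(g) else 0.1
    free <- tryCatch(minpack.lm::nlsLM(
      g ~ g0 / ((1 + tau / exp(ltd)) * sqrt(1 + tau / (kappa_fix^2 * exp(ltd)))),
      data = dat, start = list(g0 = g0_free, ltd = log(stats::median(tau))),
      weights = weights, control = ctrl), error = function(e) e)
    if (!inherits(free, "error") && unname(stats::coef(free)["g0"]) <= 0) {
      tdz <- exp(unname(stats::coef(free)["ltd"]))
      return(structure(list(
        n_components = 1L,
        components = data.frame(component = 1L, tau_d_s = tdz,
                                tau_d_se_s = NA_real_, fraction = 1,
                                occupancy = Inf),
        amplitude_g0 = 0, amplitude_g0_se = NA_real_,
        kappa = kappa_fix, kappa_free = FALSE,
        background_rate = background_rate, mean_rate = mean_rate,
        occupancy_total = Inf,
        residual_norm = sqrt(sum(stats::resid(free)^2)),
        pair = curve$pair, fit = free, zero_amplitude = TRUE
      ), class = "diffusion_fit"))
    }
  }
  if (is.null(fit)) {
    stop("fit_diffusion_model: fit failed to converge (",
         conditionMessage(last_err), "); inspect the curve or supply init guesses")
  }

  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se_of <- function(nm) if (!is.null(vc) && nm %in% rownames(vc)) sqrt(vc[nm, nm]) else NA_real_
  g0 <- unname(cf["g0"])
  amp_corr <- (1 - background_rate / mean_rate)^2
  if (n_components == 1) {
    tds <- exp(unname(cf["ltd"]))
    fr <- 1
    td_se <- tds * se_of("ltd")
  } else {
    tds <- exp(unname(c(cf["ltd1"], cf["ltd2"])))
    fr <- unname(c(cf["f1"], 1 - cf["f1"]))
    td_se <- tds * c(se_of("ltd1"), se_of("ltd2"))
    o <- order(tds)
    tds <- tds[o]; fr <- fr[o]; td_se <- td_se[o]
  }
  kap <- if (kappa_free) exp(unname(cf["lk"])) else kappa_fix
  occ <- ifelse(g0 * fr > 0, amp_corr / (g0 * fr), Inf)
  comps <- data.frame(component = seq_along(tds), tau_d_s = tds,
                      tau_d_se_s = td_se, fraction = fr, occupancy = occ)
  res <- stats::resid(fit)
  structure(list(
    n_components = n_components, components = comps,
    amplitude_g0 = g0, amplitude_g0_se = se_of("g0"),
    kappa = kap, kappa_free = kappa_free,
    background_rate = background_rate, mean_rate = mean_rate,
    occupancy_total = if (g0 > 0) amp_corr / g0 else Inf,
    residual_norm = sqrt(sum(res^2)),
    pair = curve$pair, fit = fit
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> pair %s, %d component(s), G0 = %.4g, N = %.4g\n",
              x$pair, x$n_components, x$amplitude_g0, x$occupancy_total))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Occupancies, bound fractions and FCCS loading yield from fit amplitudes
#'
#' Standard dual-color amplitude algebra with background correction:
#' `N_x = (1 - B_x/F_x)^2 / G_x(0)` for each channel, and
#' `N_rg = G_rg(0) N_g N_r / ((1 - B_g/F_g)(1 - B_r/F_r))`. The loading
#' yield is `N_rg / N_r`; the green bound fraction `N_rg / N_g`. When the
#' green fit has two components, the slow (vesicle-bound) one supplies the
#' green occupancy for the bound fraction by default, while the total green
#' occupancy enters the `N_rg` algebra (all green emitters contribute to the
#' mean green intensity).
#'
#' The raw `N_rg` refers to the two-color overlap volume. When
#' `volume_correction` supplies the beam geometry, `N_rg` is rescaled by
#' `V_r / V_rg` (overlap volume incl. axial offset) so that
#' `N_rg / N_r` estimates the true fraction of red-labelled particles that
#' are dual-labelled.
#'
#' @param fit_g,fit_r,fit_rg [fit_diffusion_model()] results for the green
#'   and red autocorrelations and the cross-correlation of one acquisition.
#' @param use_slow_green use the slow green component for the bound fraction
#'   (default TRUE for two-component green fits).
#' @param volume_correction `NULL`, or a list with `waist_xy_green`,
#'   `waist_z_green`, `waist_xy_red`, `waist_z_red` and optionally
#'   `axial_offset_red` (m).
#' @param tolerance slack for the `N_rg <= min(N_g, N_r)` consistency warning.
#' @return an object of class `occupancy_result` with fields `n_g`, `n_g_total`,
#'   `n_r`, `n_rg`, `loading_yield_fccs`, `bound_fraction_green` and the
#'   amplitudes used.
#' @export
occupancy_from_amplitudes <- function(fit_g, fit_r, fit_rg,
                                      use_slow_green = TRUE,
                                      volume_correction = NULL,
                                      tolerance = 0.2) {
  stopifnot(inherits(fit_g, "diffusion_fit"), inherits(fit_r, "diffusion_fit"),
            inherits(fit_rg, "diffusion_fit"))
  for (f in list(fit_g, fit_r)) {
    if (f$amplitude_g0 <= 0) stop("occupancy_from_amplitudes: non-positive autocorrelation amplitude; no signal")
  }
  cg <- 1 - fit_g$background_rate / fit_g$mean_rate
  cr <- 1 - fit_r$background_rate / fit_r$mean_rate
  n_g_total <- cg^2 / fit_g$amplitude_g0
  n_r <- cr^2 / fit_r$amplitude_g0
  g0_rg <- max(fit_rg$amplitude_g0, 0)
  n_rg <- g0_rg * n_g_total * n_r / (cg * cr)
  if (n_rg > min(n_r, n_g_total) * (1 + tolerance)) {
    warning("occupancy_from_amplitudes: N_rg exceeds min(N_g, N_r) beyond tolerance")
  }
  vol_factor <- 1
  if (!is.null(volume_correction)) {
    vc <- volume_correction
    off <- if (is.null(vc$axial_offset_red)) 0 else vc$axial_offset_red
    vr <- effective_volume(vc$waist_xy_red, vc$waist_z_red)
    ovl <- overlap_volume(vc$waist_xy_green, vc$waist_z_green,
                          vc$waist_xy_red, vc$waist_z_red, off)
    vol_factor <- vr / (ovl$volume * ovl$offset_factor)
    n_rg <- n_rg * vol_factor
  }
  n_g <- n_g_total
  if (use_slow_green && fit_g$n_components == 2) {
    n_g <- fit_g$components$occupancy[fit_g$n_components]  # slow component
  }
  yield <- if (n_r > 0) n_rg / n_r else NA_real_
  bound_g <- if (n_g > 0 && is.finite(n_g)) n_rg / n_g else NA_real_
  if (is.finite(yield) && yield > 1 + tolerance) {
    warning(sprintf("occupancy_from_amplitudes: loading yield %.3g exceeds 1; inconsistent amplitudes", yield))
  }
  structure(list(
    n_g = n_g, n_g_total = n_g_total, n_r = n_r, n_rg = n_rg,
    loading_yield_fccs = yield, bound_fraction_green = bound_g,
    amplitudes = c(g = fit_g$amplitude_g0, r = fit_r$amplitude_g0,
                   rg = fit_rg$amplitude_g0),
    volume_factor = vol_factor
  ), class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> N_g = %.4g (total %.4g), N_r = %.4g, N_rg = %.4g\n",
              x$n_g, x$n_g_total, x$n_r, x$n_rg))
  cat(sprintf("  loading yield (FCCS) = %.4g, green bound fraction = %.4g\n",
              x$loading_yield_fccs, x$bound_fraction_green))
  invisible(x)
}

#' Molecular brightness from a calibration measurement
#'
#' `epsilon = (F - B) / N`: detected counts per second per molecule, from
#' the mean rate, background rate and fitted occupancy of a single-species
#' calibration stream. This volume-averaged brightness is the divisor used
#' to convert burst intensities into cargo molecule numbers.
#'
#' @param stream the calibration [photon_stream()] (gated single channel).
#' @param fit the [fit_diffusion_model()] result of its autocorrelation.
#' @return brightness (counts/s per molecule).
#' @export
molecular_brightness <- function(stream, fit) {
  validate_photon_stream(stream)
  stopifnot(inherits(fit, "diffusion_fit"))
  n <- fit$occupancy_total
  if (!is.finite(n) || n <= 0) stop("molecular_brightness: fitted occupancy must be > 0")
  f <- n_photons(stream) / stream$duration_s
  (f - fit$background_rate) / n
}
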