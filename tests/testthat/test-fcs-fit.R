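log_lags <- function() exp(seq(log(2e-6), log(1), length.out = 60))

test_that("forward model amplitude reflects the background correction", {
  # (1 - B/F)^2 / N with B = F/2, N = 1 gives G(0) = 0.25
  g0 <- fcs_diffusion_model(0, n = 1, tau_d_s = 1e-3, kappa = 5,
                            background_rate = 1000, mean_rate = 2000)
  expect_equal(g0, 0.25)
  expect_error(fcs_diffusion_model(0, 1, 1e-3, background_rate = 3,
                                   mean_rate = 2), "B < F")
})

test_that("fitting a noiseless model curve recovers its parameters exactly", {
  tau <- log_lags()
  g <- fcs_diffusion_model(tau, n = 1, tau_d_s = 1e-3, kappa = 5)
  curve <- correlation_curve("gg", tau, g, c(a = 1e4, b = 1e4), 10)
  fit <- fit_diffusion_model(curve, 1, kappa = 5)
  expect_equal(fit$occupancy_total, 1, tolerance = 1e-6)
  expect_equal(fit$components$tau_d_s, 1e-3, tolerance = 1e-6)

  # two components, recovered and ordered slow-last
  g2 <- fcs_diffusion_model(tau, n = 0.5, tau_d_s = c(2e-4, 5e-3), kappa = 5,
                            fractions = c(0.4, 0.6))
  curve2 <- correlation_curve("gg", tau, g2, c(a = 1e4, b = 1e4), 10)
  fit2 <- fit_diffusion_model(curve2, 2, kappa = 5)
  expect_equal(fit2$components$tau_d_s, c(2e-4, 5e-3), tolerance = 1e-4)
  expect_equal(fit2$components$fraction, c(0.4, 0.6), tolerance = 1e-4)
  expect_true(all(diff(fit2$components$tau_d_s) > 0))
})

test_that("kappa can float and is recovered from a clean curve", {
  tau <- log_lags()
  g <- fcs_diffusion_model(tau, n = 2, tau_d_s = 2e-3, kappa = 4)
  curve <- correlation_curve("gg", tau, g, c(a = 1e4, b = 1e4), 10)
  fit <- fit_diffusion_model(curve, 1, kappa = "free")
  expect_equal(fit$kappa, 4, tolerance = 1e-3)
})

test_that("occupancy algebra inverts forward-simulated amplitudes", {
  # construct three fits from known occupancies via the forward relations
  tau <- log_lags()
  n_g <- 0.5; n_r <- 0.2; n_rg <- 0.06
  bf_g <- 0.8; bf_r <- 0.9   # (1 - B/F) factors
  mk_fit <- function(g0, bq, fq, pair) {
    g <- g0 * fcs_diffusion_model(tau, 1, 3e-3, 5)
    fit_diffusion_model(correlation_curve(pair, tau, g,
                                          c(a = 1e4, b = 1e4), 10),
                        1, kappa = 5, background_rate = (1 - bq) * fq,
                        mean_rate = fq)
  }
  fit_g <- mk_fit(bf_g^2 / n_g, bf_g, 1e4, "gg")
  fit_r <- mk_fit(bf_r^2 / n_r, bf_r, 2e4, "rr")
  fit_rg <- mk_fit(n_rg * bf_g * bf_r / (n_g * n_r), 1, 1e4, "rg")
  occ <- occupancy_from_amplitudes(fit_g, fit_r, fit_rg)
  expect_equal(occ$n_g, n_g, tolerance = 1e-5)
  expect_equal(occ$n_r, n_r, tolerance = 1e-5)
  expect_equal(occ$n_rg, n_rg, tolerance = 1e-5)
  expect_equal(occ$loading_yield_fccs, n_rg / n_r, tolerance = 1e-5)
  expect_equal(occ$bound_fraction_green, n_rg / n_g, tolerance = 1e-5)
})

test_that("zero cross-amplitude means zero co-diffusion; equal amplitudes mean full loading", {
  tau <- log_lags()
  mk <- function(g0, pair = "gg") {
    g <- g0 * fcs_diffusion_model(tau, 1, 3e-3, 5)
    fit_diffusion_model(correlation_curve(pair, tau, g, c(a = 1e4, b = 1e4), 10),
                        1, kappa = 5)
  }
  fit_auto <- mk(2)
  occ0 <- occupancy_from_amplitudes(fit_auto, fit_auto, mk(1e-12, "rg"))
  expect_equal(occ0$n_rg, 0, tolerance = 1e-9)
  expect_equal(occ0$loading_yield_fccs, 0, tolerance = 1e-9)

  # perfectly co-labelled single species: all three amplitudes equal
  occ1 <- occupancy_from_amplitudes(fit_auto, fit_auto, mk(2, "rg"))
  expect_equal(occ1$loading_yield_fccs, 1, tolerance = 1e-6)
  expect_equal(occ1$bound_fraction_green, 1, tolerance = 1e-6)
})

test_that("molecular brightness follows its definition and calibrates within 25%", {
  tau <- log_lags()
  g <- fcs_diffusion_model(tau, n = 2, tau_d_s = 2e-4, kappa = 5)
  fit <- fit_diffusion_model(correlation_curve("gg", tau, g,
                                               c(a = 2000, b = 2000), 10),
                             1, kappa = 5, background_rate = 0,
                             mean_rate = 2000)
  stream <- photon_stream(macrotimes = round(seq(0, 1e9, length.out = 2000)),
                          nanotimes = rep(0, 2000),
                          detectors = rep(1L, 2000), duration_s = 1)
  # F = 2000, B = 0, N = 2 -> 1000 counts/s per molecule
  expect_equal(molecular_brightness(stream, fit), 1000, tolerance = 1e-4)

  # simulated free dye: recovered within 25% of the volume-averaged truth
  cal <- fx_calibration()
  expect_lt(abs(cal$brightness / (8000 * 2^-1.5) - 1), 0.25)
})

test_that("brightness is invariant under doubling the concentration", {
  eps <- sapply(c(0.4, 0.8), function(occ) {
    cfg <- sim_config(
      species_spec("dye", diffusion_coefficient = 8e-11, n_green_labels = 1,
                   brightness_green = 8000, concentration = occ / VEFF_G),
      duration_s = 12, seed = 61)
    sim <- simulate_photon_stream(cfg)
    gated <- apply_pie_gating(sim$stream, pie_gate_config())
    curve <- suppressWarnings(multitau_correlate(gated$green, pair = "gg",
                                                 n_segments = 5))
    fit <- fit_diffusion_model(curve, 1, kappa = 5, background_rate = 100,
                               mean_rate = n_photons(gated$green) / 12)
    molecular_brightness(gated$green, fit)
  })
  expect_lt(abs(eps[2] / eps[1] - 1), 0.2)
})

test_that("degenerate fits are refused", {
  tau <- log_lags()
  curve <- correlation_curve("gg", tau[1:10], rep(1, 10), c(a = 1, b = 1), 10)
  expect_error(fit_diffusion_model(curve, 1), "15 lag")
  g <- fcs_diffusion_model(tau, 1, 1e-3, 5)
  cv <- correlation_curve("gg", tau, g, c(a = 10, b = 10), 10)
  expect_error(fit_diffusion_model(cv, 1, background_rate = 20, mean_rate = 10),
               "below the mean rate")
})
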