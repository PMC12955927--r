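# Shared simulation fixtures, built lazily and cached for the whole test run.
# Every fixture is fully seeded, so the suite is deterministic.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, force(expr), envir = .fx)
  }
  get(name, envir = .fx)
}

# beam geometry shared by all fixtures (287 / 372 nm lateral waists, axial
# ratio 5, 300 nm red axial offset)
W_G <- 287e-9
W_R <- 372e-9
VEFF_G <- effective_volume(W_G, 5 * W_G)
VEFF_R <- effective_volume(W_R, 5 * W_R)

tau_d_theory <- function(diameter_m, waist_m) {
  diffusion_time(diffusion_coefficient_from_diameter(diameter_m), waist_m)
}

volume_correction_default <- list(
  waist_xy_green = W_G, waist_z_green = 5 * W_G,
  waist_xy_red = W_R, waist_z_red = 5 * W_R,
  axial_offset_red = 300e-9)

# single dual-labelled vesicle species in the sparse single-vesicle regime
single_species_config <- function(diameter_m, seed, duration_s = 300,
                                  occupancy_red = 0.04,
                                  n_green = 10, bright_green = 8000,
                                  n_red = 20, bright_red = 2400) {
  sim_config(
    species_spec("ev", diameter_m = diameter_m,
                 n_green_labels = n_green, n_red_labels = n_red,
                 brightness_green = bright_green, brightness_red = bright_red,
                 concentration = occupancy_red / VEFF_R),
    box_m = c(1.6e-5, 1.6e-5, 2.5e-5),
    duration_s = duration_s, seed = seed)
}

# two-species mixture with a dual-labelled fraction among red vesicles
mixture_config <- function(seed, dual_fraction = 0.30, duration_s = 300,
                           occupancy_red_total = 0.03, n_green_dual = 10) {
  c_total <- occupancy_red_total / VEFF_R
  sim_config(list(
    species_spec("ev_dual", diameter_m = 90e-9,
                 n_green_labels = n_green_dual, n_red_labels = 20,
                 brightness_green = 8000, brightness_red = 2400,
                 concentration = dual_fraction * c_total),
    species_spec("ev_red_only", diameter_m = 90e-9, n_red_labels = 20,
                 brightness_red = 2400,
                 concentration = (1 - dual_fraction) * c_total)),
    box_m = c(1.6e-5, 1.6e-5, 2.5e-5),
    duration_s = duration_s, seed = seed)
}

# brightness calibration: free green-labelled protein, one label
fx_calibration <- function() fixture("calibration", {
  sim <- simulate_photon_stream(
    make_scenario("calibration_free_dye", duration_s = 20, seed = 101))
  gated <- apply_pie_gating(sim$stream, pie_gate_config())
  curve <- suppressWarnings(
    multitau_correlate(gated$green, pair = "gg", n_segments = 5))
  fit <- fit_diffusion_model(curve, 1, kappa = 5, background_rate = 100,
                             mean_rate = n_photons(gated$green) / 20)
  list(sim = sim, gated = gated, fit = fit,
       brightness = molecular_brightness(gated$green, fit))
})

fx_ev90 <- function() fixture("ev90", {
  sim <- simulate_photon_stream(single_species_config(90e-9, seed = 90))
  gated <- apply_pie_gating(sim$stream, pie_gate_config())
  list(sim = sim, gated = gated)
})

fx_ev120 <- function() fixture("ev120", {
  sim <- simulate_photon_stream(single_species_config(120e-9, seed = 120,
                                                      duration_s = 240))
  gated <- apply_pie_gating(sim$stream, pie_gate_config())
  list(sim = sim, gated = gated)
})

# calibrated per-channel burst sets for a gated single-species acquisition
calibrated_bursts <- function(gated, diameter_m) {
  bg_g <- estimate_background(gated$green)
  bg_r <- estimate_background(gated$red)
  pg <- calibrate_burst_params(gated$green, tau_d_theory(diameter_m, W_G),
                               background_rate = bg_g, min_photons = 10)
  pr <- calibrate_burst_params(gated$red, tau_d_theory(diameter_m, W_R),
                               background_rate = bg_r, min_photons = 30)
  list(green = detect_bursts(gated$green, pg),
       red = detect_bursts(gated$red, pr),
       bg_green = bg_g, bg_red = bg_r)
}

fx_mixture_reports <- function() fixture("mixture_reports", {
  pc <- pipeline_config(two_component_green = FALSE,
                        background_green = 100, background_red = 100)
  lapply(1:5, function(seed) {
    sim <- simulate_photon_stream(mixture_config(seed))
    truth <- ground_truth_summary(sim$ground_truth)
    rep <- suppressWarnings(run_pipeline(sim$stream, pc,
                                         condition = paste0("mixture_", seed)))
    list(report = rep, truth = truth)
  })
})

fx_cargo_reports <- function() fixture("cargo_reports", {
  pc <- pipeline_config(two_component_green = FALSE,
                        background_green = 100, background_red = 100,
                        brightness_cal = fx_calibration()$brightness)
  lapply(c(202, 77, 303), function(seed) {
    sim <- simulate_photon_stream(
      mixture_config(seed, dual_fraction = 0.5, n_green_dual = 2))
    suppressWarnings(run_pipeline(sim$stream, pc, condition = "cargo"))
  })
})

fx_independent_report <- function() fixture("independent_report", {
  sim <- simulate_photon_stream(
    make_scenario("independent_species", duration_s = 150, seed = 303))
  pc <- pipeline_config(two_component_green = FALSE,
                        background_green = 100, background_red = 110)
  suppressWarnings(run_pipeline(sim$stream, pc, condition = "independent"))
})

# constructed deterministic photon stream: uniform 1 kHz background with one
# inserted 50 kHz cluster of 100 photons (macrotime tick 1 us for exactness)
cluster_stream <- function() {
  bg <- seq(0, 1000 - 1e-3, by = 1e-3)
  cluster <- 500.0002 + (0:99) * 2e-5
  tt <- sort(c(bg, cluster))
  photon_stream(macrotimes = round(tt / 1e-6), nanotimes = rep(0, length(tt)),
                detectors = rep(1L, length(tt)), tick_s = 1e-6,
                tcspc_bin_s = 5e-12, sync_rate_hz = 40e6, duration_s = 1000)
}

# independent evaluation of the sliding-window rule (reference oracle)
hot_photons_oracle <- function(times, m, threshold_rate) {
  n <- length(times)
  h_l <- (m - 1) %/% 2
  h_r <- m - 1 - h_l
  hot <- logical(n)
  for (i in seq_len(n)) {
    if (i - h_l < 1 || i + h_r > n) next
    hot[i] <- (times[i + h_r] - times[i - h_l]) <= m / threshold_rate
  }
  hot
}

# burst set built directly from duration/centre vectors (unit-test scaffold)
synthetic_burst_set <- function(centers_s, durations_s, acq_duration_s = NULL) {
  o <- order(centers_s)
  centers_s <- centers_s[o]; durations_s <- durations_s[o]
  if (is.null(acq_duration_s)) acq_duration_s <- max(centers_s) + 1
  structure(list(
    bursts = data.frame(
      start_s = centers_s - durations_s / 2,
      stop_s = centers_s + durations_s / 2,
      duration_s = durations_s,
      n_photons = rep(50L, length(centers_s)),
      mean_rate = 50 / durations_s, center_s = centers_s,
      first_photon = rep(NA_integer_, length(centers_s)),
      last_photon = rep(NA_integer_, length(centers_s))),
    params = NULL, duration_s = acq_duration_s,
    background_rate = NA_real_,
    burst_rate = length(centers_s) / acq_duration_s),
    class = "burst_set")
}

# exhaustive optimal one-to-one assignment (oracle for the greedy matcher):
# maximises the number of pairs within the window, then minimises total
# offset; enumeration, so only for tiny sets
optimal_matching_oracle <- function(green, red, window) {
  ng <- nrow(green$bursts); nr <- nrow(red$bursts)
  ok <- abs(outer(green$bursts$center_s, red$bursts$center_s, "-")) <= window
  best_n <- 0; best_cost <- Inf
  assign_rec <- function(gi, used_r, n_pairs, cost) {
    if (gi > ng) {
      if (n_pairs > best_n || (n_pairs == best_n && cost < best_cost)) {
        best_n <<- n_pairs; best_cost <<- cost
      }
      return(invisible())
    }
    assign_rec(gi + 1, used_r, n_pairs, cost)  # leave gi unmatched
    for (ri in seq_len(nr)) {
      if (!used_r[ri] && ok[gi, ri]) {
        used_r[ri] <- TRUE
        assign_rec(gi + 1, used_r,
                   n_pairs + 1,
                   cost + abs(green$bursts$center_s[gi] - red$bursts$center_s[ri]))
        used_r[ri] <- FALSE
      }
    }
  }
  assign_rec(1, logical(nr), 0, 0)
  list(n_pairs = best_n, cost = best_cost)
}
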