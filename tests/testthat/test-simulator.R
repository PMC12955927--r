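test_that("Stokes-Einstein conversions match independent arithmetic", {
  # kB*T/(3*pi*eta*d) evaluated by hand for d = 90 nm, water at 25 C:
  # 1.380649e-23 * 298.15 / (3*pi*8.9e-4*90e-9) = 5.455e-12 m^2/s
  d90 <- diffusion_coefficient_from_diameter(90e-9, 298.15, 8.9e-4)
  expect_equal(d90, 5.455e-12, tolerance = 1e-3)
  # doubling the diameter halves D exactly
  expect_equal(diffusion_coefficient_from_diameter(180e-9), d90 / 2)
  # algebraic round trip diameter -> D -> diameter
  expect_equal(diameter_from_diffusion_coefficient(d90), 90e-9)
  # transit time omega^2/(4D) for 90 nm at the 287 nm green waist
  expect_equal(diffusion_time(d90, 287e-9), 3.776e-3, tolerance = 1e-3)
  expect_error(diffusion_coefficient_from_diameter(-1), "> 0")
})

test_that("size round trip through the burst relation is an identity", {
  # a burst lasting exactly tau_D = w^2/(4D) maps back to the true diameter
  for (d in c(50e-9, 90e-9, 250e-9)) {
    tau <- tau_d_theory(d, W_G)
    size <- ev_size_from_burst(tau, size_estimation_config(), "green")
    expect_equal(size, d * 1e9, tolerance = 1e-12)
  }
})

test_that("simulation is empty without emitters and deterministic with a seed", {
  dark <- sim_config(
    species_spec("dark", diameter_m = 90e-9, concentration = 1e16),
    duration_s = 1, seed = 1,
    background_rate_green = 0, background_rate_red = 0)
  expect_equal(n_photons(simulate_photon_stream(dark)$stream), 0L)

  cfg <- single_species_config(90e-9, seed = 33, duration_s = 5)
  s1 <- simulate_photon_stream(cfg)
  s2 <- simulate_photon_stream(cfg)
  expect_identical(s1$stream, s2$stream)
  expect_identical(s1$ground_truth$photons, s2$ground_truth$photons)
  expect_error(sim_config(species_spec("x", diameter_m = 90e-9,
                                       concentration = 1e16),
                          duration_s = 1), "seed")
})

test_that("photon times are sorted and nanotimes sit in the exciting gate", {
  sim <- simulate_photon_stream(mixture_config(seed = 9, duration_s = 10))
  st <- sim$stream
  expect_true(all(diff(st$macrotimes) >= 0))
  gt <- sim$ground_truth$photons
  nt <- st$nanotimes * st$tcspc_bin_s
  expect_true(all(nt[gt$origin == "signal_green"] < 12.5e-9))
  red_sig <- gt$origin == "signal_red"
  expect_true(all(nt[red_sig] >= 12.5e-9 & nt[red_sig] < 25e-9))
  # ground truth covers every photon
  expect_equal(nrow(gt), n_photons(st))
})

test_that("mean detected rate converges to the analytic expectation", {
  cfg <- sim_config(
    species_spec("ev", diameter_m = 90e-9, n_green_labels = 5,
                 brightness_green = 8000, concentration = 0.2 / VEFF_G),
    duration_s = 40, seed = 77,
    background_rate_green = 0, background_rate_red = 0)
  sim <- simulate_photon_stream(cfg)
  np <- nrow(sim$ground_truth$particles)
  # per-particle detected rate = eps_center * (pi/2)^(3/2) wxy^2 wz / V_box
  per <- 5 * 8000 * (pi / 2)^1.5 * cfg$waist_xy_green^2 * cfg$waist_z_green /
    prod(cfg$box_m)
  expected <- np * per * cfg$duration_s
  observed <- n_photons(sim$stream)
  # 3 Monte-Carlo standard errors; occupancy-fluctuation noise dominates:
  # relative sd ~ sqrt(2 tau_c / (T * N))
  n_occ <- np * VEFF_G / prod(cfg$box_m)
  rel_sd <- sqrt(2 * 3.78e-3 / (cfg$duration_s * n_occ))
  expect_lt(abs(observed - expected), 3 * (rel_sd * expected + sqrt(expected)))
})

test_that("background inter-photon delays are exponential", {
  cfg <- sim_config(
    species_spec("none", diameter_m = 90e-9, concentration = 0),
    duration_s = 30, seed = 4,
    background_rate_green = 200, background_rate_red = 0)
  sim <- simulate_photon_stream(cfg)
  gaps <- diff(arrival_times(sim$stream))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 200))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground truth summary reports the defining expectations", {
  sim <- simulate_photon_stream(mixture_config(seed = 6, duration_s = 2))
  gts <- ground_truth_summary(sim$ground_truth)
  p <- sim$ground_truth$particles
  vol <- prod(sim$ground_truth$config$box_m)
  # loading fraction is the realised dual / red particle ratio
  expect_equal(gts$loading_fraction,
               sum(p$n_green_labels > 0) / nrow(p))
  expect_equal(gts$n_r, nrow(p) / vol * VEFF_R)
  # transit times from the closed form
  expect_equal(unique(gts$species$tau_d_green_s), tau_d_theory(90e-9, W_G))

  # red-only species alone: no dual-labelled occupancy
  red_only <- simulate_photon_stream(sim_config(
    species_spec("r", diameter_m = 90e-9, n_red_labels = 5,
                 brightness_red = 2000, concentration = 0.05 / VEFF_R),
    duration_s = 1, seed = 2))
  expect_equal(ground_truth_summary(red_only$ground_truth)$n_rg, 0)
})

test_that("scenario constructors honour their contracts", {
  cal <- make_scenario("calibration_free_dye", duration_s = 1, seed = 1)
  expect_length(cal$species, 1)
  expect_equal(cal$species[[1]]$diffusion_coefficient, 8e-11)
  expect_equal(cal$species[[1]]$n_green_labels, 1)
  expect_equal(cal$species[[1]]$n_red_labels, 0)

  ind <- simulate_photon_stream(
    make_scenario("independent_species", duration_s = 2, seed = 3))
  expect_equal(ground_truth_summary(ind$ground_truth)$n_rg, 0)

  # undifferentiated-like: configured dual occupancy and loading fraction
  und <- make_scenario("undifferentiated_like", duration_s = 1, seed = 1)
  ov <- overlap_volume(W_G, 5 * W_G, W_R, 5 * W_R, 300e-9)
  n_rg_cfg <- und$species[[1]]$concentration * ov$volume * ov$offset_factor
  expect_equal(n_rg_cfg, 1.8e-2, tolerance = 1e-10)
  frac_cfg <- und$species[[1]]$concentration /
    (und$species[[1]]$concentration + und$species[[2]]$concentration)
  expect_equal(frac_cfg, 0.031, tolerance = 1e-10)
  expect_error(make_scenario("nope"), "arg")
})

test_that("a too-coarse explicit time step is rejected", {
  expect_error(simulate_photon_stream(sim_config(
    species_spec("fast", diffusion_coefficient = 8e-11, n_green_labels = 1,
                 brightness_green = 1000, concentration = 1e16),
    time_step_s = 1e-3, duration_s = 1, seed = 1)),
    "too coarse")
})
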