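#' Specify one diffusing fluorescent species
#'
#' A species is a population of identical particles (vesicles, free dyes,
#' ...) characterised by its hydrodynamic diameter (or, exclusively, its
#' diffusion coefficient - the other is derived by Stokes-Einstein at
#' simulation time), its label stoichiometry per particle, per-label detected
#' brightness at beam centre, fluorescence lifetimes and number
#' concentration.
#'
#' @param name species label.
#' @param diameter_m hydrodynamic diameter (m); give exactly one of
#'   `diameter_m` / `diffusion_coefficient`.
#' @param diffusion_coefficient diffusion coefficient (m^2/s).
#' @param n_green_labels,n_red_labels label counts per particle (>= 0).
#' @param brightness_green,brightness_red detected counts/s per label at
#'   beam centre.
#' @param lifetime_green,lifetime_red fluorescence lifetimes (s).
#' @param concentration number concentration (particles/m^3).
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, diameter_m = NULL, diffusion_coefficient = NULL,
                         n_green_labels = 0, n_red_labels = 0,
                         brightness_green = 0, brightness_red = 0,
                         lifetime_green = 2.5e-9, lifetime_red = 1.2e-9,
                         concentration = 0) {
  if (is.null(diameter_m) == is.null(diffusion_coefficient)) {
    stop("species_spec: give exactly one of diameter_m / diffusion_coefficient")
  }
  if (n_green_labels < 0 || n_red_labels < 0) stop("species_spec: label counts must be >= 0")
  if (brightness_green < 0 || brightness_red < 0) stop("species_spec: brightness must be >= 0")
  if (concentration < 0) stop("species_spec: concentration must be >= 0")
  structure(list(
    name = as.character(name),
    diameter_m = diameter_m,
    diffusion_coefficient = diffusion_coefficient,
    n_green_labels = n_green_labels, n_red_labels = n_red_labels,
    brightness_green = brightness_green, brightness_red = brightness_red,
    lifetime_green = lifetime_green, lifetime_red = lifetime_red,
    concentration = concentration
  ), class = "species_spec")
}

#' Simulation configuration
#'
#' Full specification of a synthetic PIE two-colour acquisition: the species
#' mixture, the periodic simulation box, the two Gaussian detection volumes,
#' the medium, detector background rates, spectral crosstalk, the pulsed
#' excitation scheme and the run length and seed.
#'
#' Each box dimension must be at least 10x the largest lateral beam waist
#' (defaults additionally keep the z dimension at >= 10x the largest axial
#' extent, so periodic images never graze the detection volume). `time_step`
#' may be left `NULL`: each species then diffuses with its own step of
#' transit-time/20, which keeps the intensity-profile discretisation error
#' below ~1% without forcing slow vesicles onto the step a free dye needs.
#'
#' @param species list of [species_spec()] objects.
#' @param box_m numeric length-3 cuboid dimensions (m).
#' @param waist_xy_green,waist_z_green,waist_xy_red,waist_z_red 1/e^2
#'   Gaussian detection radii (m); defaults are 287/372 nm lateral with an
#'   axial ratio of 5.
#' @param axial_offset_red focal z-shift of the red volume (m), default 300 nm.
#' @param temperature_k,viscosity_pa_s medium; default water at 25 C.
#' @param background_rate_green,background_rate_red detector background
#'   (counts/s), default 200 each.
#' @param crosstalk_green_into_red probability that a green-label photon
#'   registers on the red detector (with green-excitation nanotime, so PIE
#'   gating removes it).
#' @param sync_rate_hz pulsed-laser sync rate (Hz), default 40 MHz.
#' @param interleave_delay_s red-pulse start delay within the sync period,
#'   default half a period (12.5 ns at 40 MHz).
#' @param time_step_s global Brownian step (s), or `NULL` for per-species
#'   automatic steps.
#' @param duration_s acquisition length (s).
#' @param seed integer RNG seed (required: runs must be reproducible).
#' @param tick_s,tcspc_bin_s macrotime tick and TCSPC bin width (s).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(species, box_m = c(4e-6, 4e-6, 2e-5),
                       waist_xy_green = 287e-9, waist_z_green = 5 * 287e-9,
                       waist_xy_red = 372e-9, waist_z_red = 5 * 372e-9,
                       axial_offset_red = 300e-9,
                       temperature_k = 298.15, viscosity_pa_s = 8.9e-4,
                       background_rate_green = 200, background_rate_red = 200,
                       crosstalk_green_into_red = 0,
                       sync_rate_hz = 40e6, interleave_delay_s = NULL,
                       time_step_s = NULL, duration_s = 10, seed = NULL,
                       tick_s = 1e-9, tcspc_bin_s = 5e-12) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1, all(vapply(species, inherits, TRUE, "species_spec")))
  if (is.null(seed)) stop("sim_config: a seed is required for reproducible runs")
  if (is.null(interleave_delay_s)) interleave_delay_s <- 0.5 / sync_rate_hz
  if (any(box_m <= 0) || length(box_m) != 3) stop("sim_config: box_m must be 3 positive lengths")
  wmax <- max(waist_xy_green, waist_xy_red)
  if (any(box_m < 10 * wmax)) {
    stop("sim_config: each box dimension must be >= 10x the largest lateral waist")
  }
  if (any(c(waist_xy_green, waist_z_green, waist_xy_red, waist_z_red) <= 0)) {
    stop("sim_config: waists must be > 0")
  }
  if (background_rate_green < 0 || background_rate_red < 0) {
    stop("sim_config: background rates must be >= 0")
  }
  if (crosstalk_green_into_red < 0 || crosstalk_green_into_red > 1) {
    stop("sim_config: crosstalk must be a probability")
  }
  structure(list(
    species = species, box_m = box_m,
    waist_xy_green = waist_xy_green, waist_z_green = waist_z_green,
    waist_xy_red = waist_xy_red, waist_z_red = waist_z_red,
    axial_offset_red = axial_offset_red,
    temperature_k = temperature_k, viscosity_pa_s = viscosity_pa_s,
    background_rate_green = background_rate_green,
    background_rate_red = background_rate_red,
    crosstalk_green_into_red = crosstalk_green_into_red,
    sync_rate_hz = sync_rate_hz, interleave_delay_s = interleave_delay_s,
    time_step_s = time_step_s, duration_s = duration_s,
    seed = as.integer(seed), tick_s = tick_s, tcspc_bin_s = tcspc_bin_s
  ), class = "sim_config")
}

species_diffusion_coefficient <- function(sp, config) {
  if (!is.null(sp$diffusion_coefficient)) return(sp$diffusion_coefficient)
  diffusion_coefficient_from_diameter(sp$diameter_m, config$temperature_k,
                                      config$viscosity_pa_s)
}

species_time_step <- function(sp, config) {
  d <- species_diffusion_coefficient(sp, config)
  transit <- diffusion_time(d, min(config$waist_xy_green, config$waist_xy_red))
  auto <- transit / 20
  if (!is.null(config$time_step_s)) {
    if (config$time_step_s > transit / 20 + 1e-15) {
      stop(sprintf(
        "sim_config: time_step %.3g s too coarse for species '%s' (transit %.3g s needs <= %.3g s)",
        config$time_step_s, sp$name, transit, transit / 20))
    }
    return(config$time_step_s)
  }
  auto
}

#' Simulate a two-colour PIE photon stream with ground truth
#'
#' Runs Brownian dynamics for every species in the configuration: particle
#' numbers are drawn as Poisson(concentration x box volume), positions start
#' uniform in the periodic box, and each particle's labels emit detected
#' photons as Poisson thinning of the 3D Gaussian detection profile of its
#' colour. Detector background is homogeneous Poisson. Macrotimes are snapped
#' to the start of their sync period (the sub-period information lives in the
#' nanotime, mirroring photon-counting hardware); nanotimes are exponential
#' lifetime delays truncated to the exciting laser's gate. A fixed seed gives
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return a list with elements `stream` (a [photon_stream()] sorted by
#'   macrotime) and `ground_truth` (class `ground_truth`: per-photon particle
#'   id / species / origin, the per-particle table, and the config).
#' @export
simulate_photon_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vol <- prod(config$box_m)
  gate_w <- config$interleave_delay_s
  period <- 1 / config$sync_rate_hz

  parts <- list()
  tick <- numeric(0); nano <- integer(0); det <- integer(0)
  pid <- integer(0); orig <- integer(0); spn <- character(0)
  ptab <- list()
  next_id <- 1L
  for (si in seq_along(config$species)) {
    sp <- config$species[[si]]
    np <- stats::rpois(1, sp$concentration * vol)
    if (np == 0) next
    dcoef <- species_diffusion_coefficient(sp, config)
    dt <- species_time_step(sp, config)
    pos0 <- cbind(stats::runif(np, -0.5, 0.5) * config$box_m[1],
                  stats::runif(np, -0.5, 0.5) * config$box_m[2],
                  stats::runif(np, -0.5, 0.5) * config$box_m[3])
    res <- simulate_species_cpp(
      pos0, sigma_step = sqrt(2 * dcoef * dt), dt = dt,
      duration = config$duration_s, box = config$box_m,
      rate_g_center_per_step = sp$n_green_labels * sp$brightness_green * dt,
      rate_r_center_per_step = sp$n_red_labels * sp$brightness_red * dt,
      wxy_g = config$waist_xy_green, wz_g = config$waist_z_green,
      wxy_r = config$waist_xy_red, wz_r = config$waist_z_red,
      z_offset_r = config$axial_offset_red,
      crosstalk_g_to_r = config$crosstalk_green_into_red,
      sync_period = period, tick_s = config$tick_s,
      gate_start_g = 0, gate_start_r = config$interleave_delay_s,
      gate_width = gate_w,
      lifetime_g = sp$lifetime_green, lifetime_r = sp$lifetime_red,
      tcspc_bin_s = config$tcspc_bin_s,
      first_particle_id = next_id,
      seed = config$seed, rng_stream = si)
    tick <- c(tick, res$tick); nano <- c(nano, res$nano)
    det <- c(det, res$det); pid <- c(pid, res$pid); orig <- c(orig, res$origin)
    spn <- c(spn, rep(sp$name, length(res$tick)))
    dia <- if (!is.null(sp$diameter_m)) sp$diameter_m else
      diameter_from_diffusion_coefficient(dcoef, config$temperature_k,
                                          config$viscosity_pa_s)
    ptab[[si]] <- data.frame(
      particle = seq.int(next_id, next_id + np - 1L), species = sp$name,
      diameter_m = dia, diffusion_coefficient = dcoef,
      n_green_labels = sp$n_green_labels, n_red_labels = sp$n_red_labels)
    next_id <- next_id + np
  }

  # homogeneous Poisson detector background, uniform nanotime over the period
  for (ch in 1:2) {
    rate <- if (ch == 1) config$background_rate_green else config$background_rate_red
    nb <- stats::rpois(1, rate * config$duration_s)
    if (nb == 0) next
    tb <- stats::runif(nb, 0, config$duration_s)
    tick_b <- floor(tb / period) * round(period / config$tick_s)
    nano_b <- as.integer(floor(stats::runif(nb, 0, period / config$tcspc_bin_s)))
    tick <- c(tick, tick_b); nano <- c(nano, nano_b)
    det <- c(det, rep(ch, nb)); pid <- c(pid, rep(0L, nb))
    orig <- c(orig, rep(3L, nb)); spn <- c(spn, rep("background", nb))
  }

  ord <- order(tick)
  stream <- photon_stream(
    macrotimes = tick[ord], nanotimes = nano[ord], detectors = det[ord],
    tick_s = config$tick_s, tcspc_bin_s = config$tcspc_bin_s,
    sync_rate_hz = config$sync_rate_hz, duration_s = config$duration_s)
  origin_lab <- c("signal_green", "signal_red", "background", "crosstalk")
  gt <- structure(list(
    photons = data.frame(particle = pid[ord], species = spn[ord],
                         origin = origin_lab[orig[ord]]),
    particles = if (length(ptab)) do.call(rbind, ptab) else
      data.frame(particle = integer(0), species = character(0),
                 diameter_m = numeric(0), diffusion_coefficient = numeric(0),
                 n_green_labels = numeric(0), n_red_labels = numeric(0)),
    config = config
  ), class = "ground_truth")
  if (nrow(gt$photons) != n_photons(stream)) {
    stop("simulate_photon_stream: internal bookkeeping mismatch")
  }
  list(stream = stream, ground_truth = gt)
}

#' Closed-form expected observables of a simulated scenario
#'
#' Converts the realised particle table of a simulation into the
#' expectations every analysis stage is scored against: true single-colour
#' occupancies (particles bearing that colour's labels per effective
#' detection volume), the true dual-labelled occupancy referred to the
#' two-colour overlap volume, the true loading fraction (dual-labelled
#' particles among red-labelled particles), per-species transit times
#' omega_xy^2/(4 D), and per-particle brightness (beam-centre and
#' volume-averaged).
#'
#' @param gt the `ground_truth` from [simulate_photon_stream()].
#' @param config the matching [sim_config()] (defaults to the one stored in
#'   `gt`).
#' @return a list of expected observables.
#' @export
ground_truth_summary <- function(gt, config = gt$config) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  if (!identical(config$seed, gt$config$seed) ||
      !identical(config$duration_s, gt$config$duration_s)) {
    stop("ground_truth_summary: config does not match ground truth")
  }
  vol <- prod(config$box_m)
  p <- gt$particles
  vg <- effective_volume(config$waist_xy_green, config$waist_z_green)
  vr <- effective_volume(config$waist_xy_red, config$waist_z_red)
  ov <- overlap_volume(config$waist_xy_green, config$waist_z_green,
                       config$waist_xy_red, config$waist_z_red,
                       config$axial_offset_red)
  n_green_particles <- sum(p$n_green_labels > 0)
  n_red_particles <- sum(p$n_red_labels > 0)
  n_dual_particles <- sum(p$n_green_labels > 0 & p$n_red_labels > 0)
  species_tab <- unique(p[, c("species", "diameter_m", "diffusion_coefficient",
                              "n_green_labels", "n_red_labels")])
  species_tab$tau_d_green_s <- diffusion_time(species_tab$diffusion_coefficient,
                                              config$waist_xy_green)
  species_tab$tau_d_red_s <- diffusion_time(species_tab$diffusion_coefficient,
                                            config$waist_xy_red)
  bri <- lapply(config$species, function(sp) {
    data.frame(species = sp$name,
               brightness_green_center = sp$n_green_labels * sp$brightness_green,
               brightness_red_center = sp$n_red_labels * sp$brightness_red,
               brightness_green_fcs = sp$n_green_labels * sp$brightness_green * 2^-1.5,
               brightness_red_fcs = sp$n_red_labels * sp$brightness_red * 2^-1.5)
  })
  list(
    n_g = n_green_particles / vol * vg,
    n_r = n_red_particles / vol * vr,
    n_rg = n_dual_particles / vol * ov$volume * ov$offset_factor,
    loading_fraction = if (n_red_particles > 0) n_dual_particles / n_red_particles else 0,
    species = species_tab,
    brightness = do.call(rbind, bri),
    effective_volume_green = vg, effective_volume_red = vr,
    overlap_volume = ov$volume * ov$offset_factor
  )
}

#' Ready-made simulation scenarios
#'
#' Construct fully specified [sim_config()]s emulating the experimental
#' conditions the analysis is designed for. All scenarios use the default
#' beam geometry (287/372 nm lateral waists, axial ratio 5, 300 nm red axial
#' offset), 40 MHz PIE with a 12.5 ns interleave, 200 counts/s background per
#' channel and water at 25 C.
#'
#' * `undifferentiated_like`: dual-labelled 90 nm vesicles (2 green cargo
#'   labels, 20 red membrane labels) at a dual occupancy of 1.8e-2 - the
#'   working occupancy of 1.8e-4 scaled up 100x so desk-scale runs
#'   accumulate usable statistics - red-only vesicles setting a loading
#'   fraction of 3.1%, and a fast free green species at occupancy 0.23 (the
#'   working 2.3e-2 scaled 10x; the free species is scaled less than the
#'   vesicles so that vesicle bursts remain resolvable above the free-dye
#'   glow at desk scale), with 5% spectral crosstalk.
#' * `partially_differentiated_like`: same structure with dual occupancy
#'   2.8e-2, loading fraction 4.4% and free green occupancy 0.42.
#' * `calibration_free_dye`: a single free green-labelled protein species
#'   (D = 8e-11 m^2/s, one label) at occupancy 0.5, for brightness
#'   calibration.
#' * `independent_species`: non-interacting green-only and red-only vesicle
#'   species (no dual labelling), for null cross-correlation and
#'   chance-coincidence tests.
#'
#' @param name scenario name.
#' @param duration_s acquisition length (s).
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
make_scenario <- function(name = c("undifferentiated_like",
                                   "partially_differentiated_like",
                                   "calibration_free_dye",
                                   "independent_species"),
                          duration_s = 30, seed = 1L) {
  name <- match.arg(name)
  wxy_g <- 287e-9; wz_g <- 5 * wxy_g
  wxy_r <- 372e-9; wz_r <- 5 * wxy_r
  vg <- effective_volume(wxy_g, wz_g)
  vr <- effective_volume(wxy_r, wz_r)
  ov <- overlap_volume(wxy_g, wz_g, wxy_r, wz_r, 300e-9)
  vov <- ov$volume * ov$offset_factor

  ev_mixture <- function(n_rg_target, yield_target, n_g_free) {
    c_dual <- n_rg_target / vov
    c_red_only <- c_dual * (1 - yield_target) / yield_target
    c_free <- n_g_free / vg
    list(
      species_spec("ev_dual", diameter_m = 90e-9,
                   n_green_labels = 2, n_red_labels = 20,
                   brightness_green = 8000, brightness_red = 2400,
                   concentration = c_dual),
      species_spec("ev_red_only", diameter_m = 110e-9,
                   n_red_labels = 20, brightness_red = 2400,
                   concentration = c_red_only),
      species_spec("free_green", diffusion_coefficient = 8e-11,
                   n_green_labels = 1, brightness_green = 8000,
                   concentration = c_free)
    )
  }

  species <- switch(name,
    undifferentiated_like = ev_mixture(1.8e-2, 0.031, 0.23),
    partially_differentiated_like = ev_mixture(2.8e-2, 0.044, 0.42),
    calibration_free_dye = list(
      species_spec("free_dye", diffusion_coefficient = 8e-11,
                   n_green_labels = 1, brightness_green = 8000,
                   concentration = 0.5 / vg)),
    independent_species = list(
      species_spec("ev_green_only", diameter_m = 90e-9,
                   n_green_labels = 4, brightness_green = 8000,
                   concentration = 0.1 / vg),
      species_spec("ev_red_only", diameter_m = 110e-9,
                   n_red_labels = 20, brightness_red = 2400,
                   concentration = 0.1 / vr))
  )
  sim_config(species, duration_s = duration_s, seed = seed,
             crosstalk_green_into_red = if (name == "calibration_free_dye") 0 else 0.05)
}
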