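# pieburst

Dual-color PIE-FCCS and coincident fluorescence-burst analysis of single
diffusing vesicles, in R.

Extracellular vesicles (EVs) and similar nanoparticles carry only a handful
of labelled cargo molecules each. The established single-molecule answer is
a two-color confocal measurement: the particle membrane carries a red
label, the cargo protein a green one, and two picosecond-pulsed lasers
alternate at 40 MHz (pulsed interleaved excitation, PIE) so that every
detected photon can be assigned to its exciting laser from its nanotime.
From one two-channel photon time-tag record, `pieburst` computes both
standard readouts:

* **Fluorescence cross-correlation spectroscopy (FCCS).** Auto- and
  cross-correlations of the gated traces are fitted with the 3D diffusion
  model
  `G(τ) = (1−B/F)²/N · 1/(1+τ/τ_D) · 1/sqrt(1+τ/(κ²τ_D))`,
  giving occupancies `N_g`, `N_r`, the dual-labelled occupancy `N_rg`, and
  the loading yield `N_rg/N_r` — the fraction of vesicles carrying cargo.
* **Coincident burst analysis.** Sliding-window burst search (`m` photons
  at local rate ≥ `K·B`) in each channel, calibrated so the median burst
  duration matches the FCCS diffusion time; temporally matched green+red
  bursts are single loaded vesicles. Each event yields a hydrodynamic size
  via Stokes–Einstein, `d = 4 k_B T τ_burst/(3π η ω₀²)`, and a
  cargo-molecule count from its brightness; event rates and the
  coincident/red burst ratio give a second, independent loading yield.
  Size distributions are summarised by rescaled-gamma histogram fits, and
  conditions are compared by Welch t-tests on 20-event subsets.

A Brownian-dynamics photon-emission simulator with per-photon ground truth
(`simulate_photon_stream()`, `make_scenario()`) makes the whole chain
verifiable: every analysis stage is tested against closed forms, brute-force
oracles, or the simulator's truth.

## Worked example

Simulate 30 s of the baseline EV scenario, gate it, and fit the red-channel
autocorrelation:

```r
library(pieburst)

cfg   <- make_scenario("undifferentiated_like", duration_s = 30, seed = 42)
sim   <- simulate_photon_stream(cfg)
sim$stream
#> <photon_stream> 469863 photons over 30.000 s
#>   tick 1e-09 s, TCSPC bin 5e-12 s, sync 40 MHz
#>   detectors: 1=29750, 2=440113

gated <- apply_pie_gating(sim$stream, pie_gate_config())
gated
#> <gated_streams> green 26779, red 435808, discarded 7276 photons

curve <- multitau_correlate(gated$red, pair = "rr", n_segments = 5)
fit   <- fit_diffusion_model(curve, 1, kappa = 5, background_rate = 100,
                             mean_rate = n_photons(gated$red) / 30)
fit
#> <diffusion_fit> pair rr, 1 component(s), G0 = 1.161, N = 0.8496
#>  component     tau_d_s   tau_d_se_s fraction occupancy
#>          1 0.007765468 0.0001680229        1 0.8495835
```

The fitted red diffusion time of 7.8 ms sits close to the Stokes–Einstein
expectation for this scenario's 90–110 nm vesicles at the 372 nm red waist
(6.3–7.8 ms), and the occupancy `N ≈ 0.85` reflects the scenario's red
vesicle concentration. `run_pipeline()` chains the full analysis — gating,
background estimation, correlation, fitting, occupancy extraction,
calibrated burst search, coincidence matching, sizing, cargo counting,
subset statistics — into a single `condition_report`;
`compare_conditions()` runs Welch t-tests between two such reports.

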