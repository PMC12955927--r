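---
title: "Methods: dual-color PIE-FCCS and coincident burst analysis of diffusing vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-color PIE-FCCS and coincident burst analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Extracellular vesicles (EVs) are 30-200 nm membrane vesicles whose protein
cargo is of direct biological interest, but a single vesicle carries only a
handful of labelled cargo molecules and diffuses freely in solution.
`pieburst` implements a complete analysis chain for the standard two-color
confocal answer to this problem: the vesicle membrane carries many copies of
a red label, the cargo protein a green fluorescent fusion, both excited by
alternating picosecond laser pulses (pulsed interleaved excitation, PIE) at
40 MHz, and every detected photon is recorded with a coarse absolute
macrotime and a fine nanotime relative to the last sync pulse.

Two complementary readouts are computed from one photon record:

* **FCCS** - auto- and cross-correlation of the two gated intensity traces
  give mean occupancies $N_g$, $N_r$ of green- and red-labelled particles in
  the confocal volume and the dual-labelled occupancy $N_{rg}$; the loading
  yield is $N_{rg}/N_r$, the fraction of vesicles that carry cargo.
* **Coincident bursts** - individual vesicle transits appear as photon
  bursts; temporally matched green+red bursts are single loaded vesicles,
  giving a per-vesicle size (from the transit duration), a cargo-molecule
  count (from the burst intensity), a coincident-event rate, and a second,
  independent estimate of the loading yield.

A Brownian-dynamics photon simulator with per-photon ground truth makes
every stage verifiable at desk scale.

# PIE gating

With both lasers at sync rate $f$ and the red pulse delayed by half a
period ($12.5\,$ns at 40 MHz), emission can be assigned to its exciting
laser from the photon nanotime alone. Gates are half-open intervals
$[t_0, t_1)$; photons on the right edge are discarded, which makes the
assignment deterministic. Spectral crosstalk (a green-excited photon
registered by the red detector) keeps the green-excitation nanotime and is
therefore removed by the red gate - the purpose of PIE. The instrument
response function and lifetime tails leaking past a gate edge are not
modelled; with 12.5 ns windows against 1-4 ns lifetimes the loss is
$e^{-W/\tau} \lesssim 1\%$ and is simply discarded.

# Correlation analysis

`multitau_correlate()` estimates
$G(\tau) = \langle\delta F_a(t)\,\delta F_b(t+\tau)\rangle /
(\langle F_a\rangle\langle F_b\rangle)$ on a multi-tau cascade: level 0
covers lags of 1-8 base bins (default base bin 2 µs in the pipeline), and
each further level doubles the bin width. Normalization is symmetric with
*range-local* monitor sums, so every lag equals a direct evaluation on the
rebinned trace; `brute_force_correlate()` performs exactly that dense
evaluation and serves as the estimator's oracle in the test suite (the two
agree to floating-point exactness because all sums involved are integer
sums). Lags beyond one tenth of the acquisition are dropped: with fewer
than ~10 traversals of a lag the estimator is dominated by a single
low-frequency fluctuation.

Curves are fitted with the 3D diffusion model

$$G(\tau) = \frac{(1-B/F)^2}{N}\sum_i
  \frac{f_i}{(1+\tau/\tau_{D,i})\sqrt{1+\tau/(\kappa^2\tau_{D,i})}},$$

where $B$ is the uncorrelated background rate, $F$ the mean detected rate,
$\kappa = \omega_z/\omega_{xy}$ the axial ratio (fixed at the calibration
value, default 5 - floating it invites a well-known degeneracy with
$\tau_D$), and $\tau_{D,i} = \omega_{xy}^2/4D_i$. The zero-lag amplitude is
always the fitted model amplitude, never the raw first lag point
(shot-noise and afterpulse contamination). Weights come from splitting the
acquisition into 5 segments and using the inverse variance of the
segment-wise curves. Two components are fitted for green EV samples by
default because residual free cargo protein contributes a fast component;
the slow component is taken as vesicle-bound.

## Occupancies, background, and the detection-volume correction

The standard dual-color amplitude algebra is used:
$N_x = (1-B_x/F_x)^2 / G_x(0)$ and
$N_{rg} = G_{rg}(0)\,N_g N_r/((1-B_g/F_g)(1-B_r/F_r))$. Two refinements
matter in practice and are documented choices of this package:

* **Background.** `estimate_background()` iterates burst detection and
  re-estimates the rate outside bursts. On a busy stream this operational
  "quiet rate" includes faint glow from particles at the detection-volume
  edges; it is the right scale for burst thresholds (and is used there) but
  overstates the uncorrelated background of the amplitude correction. When
  the instrument background is known independently (dark counts/buffer
  measurement - the usual situation), supply it via
  `pipeline_config(background_green=, background_red=)`.
* **Volume mismatch.** The raw $N_{rg}$ refers to the two-color overlap
  volume $V_{rg} = \pi^{3/2}\,\tfrac{\omega_g^2+\omega_r^2}{2}\,
  \sqrt{\tfrac{\omega_{z,g}^2+\omega_{z,r}^2}{2}}$, attenuated by
  $e^{-2\Delta z^2/(\omega_{z,g}^2+\omega_{z,r}^2)}$ for an axial focus
  offset $\Delta z$ (300 nm by default, matching a typical two-color
  alignment). With different beam waists per color (287 and 372 nm laterally
  by default) $V_{rg} \ne V_r$, and the uncorrected yield $N_{rg}/N_r$
  would be biased by $V_{rg}/V_r \approx 0.69$ for the default geometry.
  `occupancy_from_amplitudes()` therefore rescales $N_{rg}$ by
  $V_r/V_{rg}$ when the beam geometry is supplied, so that $N_{rg}/N_r$
  estimates the true dual-labelled fraction of red particles.

# Burst search and calibration

A photon is *hot* when its $m$-photon window spans at most $m/(KB)$
seconds (local rate at least $K$ times background); maximal runs of hot
photons are bursts, with first-to-last-photon durations and midpoint
centres. $K$ and $m$ are calibrated per channel by grid search so that the
median burst duration matches the FCCS diffusion time of that channel - the
field's standard self-consistency calibration. The threshold product $KB$
is the invariant quantity; $K$ is rescaled when the background changes.

The pipeline deliberately uses asymmetric `min_photons` (10 green, 30 red).
The red burst set is the *denominator* of the burst-based loading yield and
should count only solidly established vesicle transits; transits grazing
the detection-volume edge are caught stochastically by each channel
half the time, and counting them in the denominator while the matching
numerator misses them depresses the yield systematically. The lenient green
setting keeps faint cargo evidence available for matching.

# Coincidence analysis

The quantile tolerance window $|q_{10}(d_g) - q_{10}(d_r)|/2$ (half the
difference of the channels' 10% duration quantiles) is implemented
literally in `compute_tolerance_window()`, along with two alternative
readings of the same prescription, because the underlying rule is stated
ambiguously in the literature this package follows. Two further choices
were forced by the physics:

* **Duration slack.** A short burst contained anywhere inside a long
  partner burst of the same transit has a centre offset of up to half the
  duration difference. Matching therefore accepts
  $|c_g - c_r| \le |d_g - d_r|/2 + w$ by default, which preserves overlap
  of the burst time ranges; bare centre matching is selectable.
* **Window floor.** The centre jitter between the two channels' bursts of
  one transit is set by photon statistics of threshold crossings, i.e. by
  the transit time itself. When the two duration distributions are similar
  the quantile difference collapses to zero and would reject genuine
  coincidences wholesale. `run_pipeline()` floors the window at
  $0.25\,(\tau_{D,g}+\tau_{D,r})$ (configurable), a scale at which the
  chance-coincidence contamination $2 r_g r_r w T$ stays at the percent
  level for single-vesicle burst rates.

Matching is greedy one-to-one by ascending centre offset; an exhaustive
optimal assignment is used as an oracle in the tests. The expected chance
coincidence count is reported (`chance_coincidence_count()`) but never
subtracted.

# Vesicle sizing

Each burst converts to a hydrodynamic diameter through the Stokes-Einstein
relation applied to the transit, $d = 4k_BT\,\tau_\mathrm{burst} /
(3\pi\eta\,\omega_0^2)$, with the waist of the burst's channel. Size
distributions are summarised by the rescaled gamma function
$C\lambda^\alpha x^{\alpha-1}e^{-\lambda x}/\Gamma(\alpha)$ fitted by least
squares to the histogram (mean $\alpha/\lambda$). Histogram fitting rather
than maximum likelihood is the default on purpose: transit durations of
diffusing particles are strongly right-skewed (mean/median around 1.3-1.5),
gamma MLE pins the fitted mean to the sample mean, and the resulting size
means would sit far above the calibrated median; the histogram fit follows
the bulk of the distribution, which is what the calibration controls. MLE
is available as `method = "mle"`.

# Cargo counting

The direct estimator divides the background-subtracted green burst rate by
the free-molecule brightness $\varepsilon = (F-B)/N$ from a calibration
measurement of the free cargo protein (`molecular_brightness()`). It is
kept (`cargo_method = "direct"`, and `cargo_count()`), but it inherits a
*burst-selection bias*: for dim particles, detected bursts oversample
bright central transits (counts biased high); for bright particles the
threshold reaches far into the dim periphery (counts biased low), and the
bias moves with the calibrated threshold.

The pipeline default (`cargo_method = "fcs_anchored"`) therefore keeps the
relative per-event intensities but anchors their mean to the mean cargo per
vesicle measured from correlation amplitudes,
$\bar n = \varepsilon_\mathrm{vesicle}/\varepsilon_\mathrm{molecule}$ with
$\varepsilon_\mathrm{vesicle} = (F_g-B_g)/N_g$. Both brightnesses are
volume-averaged, so their ratio is free of burst-selection effects. The
anchored scale requires a single-component green fit; with a two-component
fit (free cargo present) the per-species brightness decomposition is not
identified and the pipeline falls back to the direct estimator.

# The synthetic-data generator

`simulate_photon_stream()` performs Brownian dynamics of non-interacting
particles in a periodic cuboid, with per-axis Gaussian steps of standard
deviation $\sqrt{2D\Delta t}$ and a per-species step of one twentieth of
the transit time. Each label emits detected photons as Poisson thinning of
the 3D Gaussian detection profile of its color; the red focus can be
axially offset. Background is homogeneous Poisson per detector; crosstalk
re-routes a green photon to the red detector while keeping green-excitation
nanotime statistics. Macrotimes are snapped to the start of their sync
period - the sub-period information lives entirely in the nanotime, exactly
as photon-counting hardware records it. Nanotimes are exponential lifetime
delays truncated to the exciting gate.

Two implementation points are worth knowing. The core uses its own
PCG32/ziggurat random generator (seeded from the configuration seed), so a
fixed seed yields bit-identical photon records across platforms. Particles
far from the detection region take a single Gaussian step covering many
fine steps; because emission is already treated as zero beyond intensity
$e^{-16}$ of the peak and the step is capped so the particle cannot reach
that region within it, the photon record is statistically unchanged while
runs become an order of magnitude faster. The simulated mean rate is tested
against the closed form
$C\,\varepsilon\,(\pi/2)^{3/2}\omega_{xy}^2\omega_z$.

What the generator does *not* emulate - and hence what passing tests do not
establish about real data: triplet/blinking photophysics and bleaching
(the fitted model carries no triplet term either), detector afterpulsing
and dead time, optical aberrations and saturation, vesicle polydispersity
within a species (each species is monodisperse; mixtures of species model
polydispersity), label-number heterogeneity within a species, and sample
drift.

## Scenario defaults

The ready-made scenarios use the default beam geometry (287/372 nm waists,
axial ratio 5, 300 nm red offset), 200 counts/s background per detector,
water at 25 °C, and 40 MHz PIE. The baseline EV scenario places the
dual-labelled occupancy at $1.8\times10^{-2}$ - the working value of
$1.8\times10^{-4}$ scaled up 100x so that desk-scale minutes of simulated
acquisition contain usable statistics - with a loading fraction of 3.1%,
and the stressed-condition scenario at $2.8\times10^{-2}$ and 4.4%. The
free cargo-protein species is scaled only 10x (occupancy 0.23 / 0.42):
scaling it 100x like the vesicles would bury vesicle bursts under free-dye
glow, a regime in which the burst branch of the analysis is undefined -
correlation-based quantities remain valid there and are what these
scenarios are used to test. Per-label brightnesses (8000 counts/s green,
2400 counts/s red at beam centre) are in the range of bright fluorescent
proteins and dim far-red membrane dyes in a confocal at moderate power, and
give the two channels comparable per-transit photon budgets, which any
coincidence scheme implicitly assumes.

## Problem sizes used by the tests and the acceptance analysis

Single-species and mixture runs use a 16 × 16 × 25 µm box with total
vesicle occupancy 0.03-0.06, 240-300 s of simulated acquisition for
burst-statistics questions, 20-40 s for correlation-only questions, and
5 seeds where seed robustness is the point. These lengths put a few
hundred to a few thousand bursts in each channel - enough for stable
medians and gamma fits. Statistical power of condition comparisons is
studied at the event level (`simulate_subset_metrics()`): the Welch test on
20-event subsets depends only on event counts and spans, so photon-level
simulation would add hours of compute and no information.

# Known limitations

* The burst-based loading yield carries a residual downward bias of a few
  percentage points: transits grazing the detection volume are detected
  stochastically per channel, and no window or threshold choice fully
  removes the asymmetry between one-channel and two-channel detection.
  The FCCS yield does not share this bias; the two are reported together.
* The tolerance-window prescription is ambiguous in its source; all three
  implemented readings collapse for symmetric channels, which is why the
  transit-time floor exists.
* Cargo counts for multi-component green samples fall back to the direct,
  selection-biased estimator.
* The amplitude algebra assumes ideal Gaussian detection volumes; real
  confocal point-spread functions deviate at the 10-20% level in absolute
  occupancies, which cancels only partially in the yield ratios.
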