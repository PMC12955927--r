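test_that("tolerance window rules follow their definitions", {
  green <- synthetic_burst_set(1:20, rep(c(1e-3, 2e-3), 10))
  red <- synthetic_burst_set(1:20 + 0.1, rep(c(3e-3, 6e-3), 10))
  tw <- compute_tolerance_window(green, red)
  # q10 of green durations = 1 ms, of red = 3 ms -> window 1 ms
  expect_equal(tw$value_s, 1e-3)
  expect_equal(tw$rule, "half_q10_diff")

  # symmetry under channel exchange
  tw_swap <- compute_tolerance_window(red, green)
  expect_equal(tw_swap$value_s, tw$value_s)

  # identical duration distributions give a zero window
  tw0 <- compute_tolerance_window(green, green)
  expect_equal(tw0$value_s, 0)

  # alternative rule: half the smaller 10% quantile
  twm <- compute_tolerance_window(green, red, rule = "half_min_q10")
  expect_equal(twm$value_s, 0.5e-3)

  expect_error(compute_tolerance_window(synthetic_burst_set(1:3, rep(1e-3, 3)),
                                        red), "at least")
})

test_that("matching is one-to-one, symmetric, and optimal on small cases", {
  g <- synthetic_burst_set(c(1, 2, 3, 4, 5), rep(2e-3, 5))
  r <- synthetic_burst_set(c(1.0004, 2.2, 3.0006, 4.0009, 10), rep(2e-3, 5))
  ev <- match_coincident_bursts(g, r, 1e-3, duration_slack = FALSE)
  # exactly the three pairs within 1 ms
  expect_equal(nrow(ev$events), 3L)
  expect_equal(sort(ev$events$green_id), c(1L, 3L, 4L))
  oracle <- optimal_matching_oracle(g, r, 1e-3)
  expect_equal(nrow(ev$events), oracle$n_pairs)
  expect_equal(sum(abs(ev$events$center_offset_s)), oracle$cost,
               tolerance = 1e-12)

  # identical burst lists match completely; disjoint lists do not match
  full <- match_coincident_bursts(g, g, 1e-3)
  expect_equal(nrow(full$events), 5L)
  expect_equal(full$n_unmatched_green, 0L)
  none <- match_coincident_bursts(g, synthetic_burst_set(100 + 1:5, rep(2e-3, 5)),
                                  1e-3)
  expect_equal(nrow(none$events), 0L)

  # symmetry: swapping channels pairs the same bursts
  swap <- match_coincident_bursts(r, g, 1e-3, duration_slack = FALSE)
  expect_equal(sort(swap$events$red_id), sort(ev$events$green_id))

  # cardinality bound
  expect_lte(nrow(ev$events), min(nrow(g$bursts), nrow(r$bursts)))
})

test_that("duration slack admits a short burst contained in a long partner", {
  g <- synthetic_burst_set(10, 2e-3)
  r <- synthetic_burst_set(10.004, 12e-3)  # centre 4 ms away, interval overlaps
  expect_equal(nrow(match_coincident_bursts(g, r, 1e-3,
                                            duration_slack = FALSE)$events), 0L)
  expect_equal(nrow(match_coincident_bursts(g, r, 1e-3)$events), 1L)
})

test_that("burst sizing follows the Stokes-Einstein relation", {
  cfg <- size_estimation_config()
  # tau_burst = 3.776 ms at the 287 nm waist corresponds to ~90 nm
  expect_equal(ev_size_from_burst(3.776e-3, cfg, "green"), 90, tolerance = 1e-3)
  # linear in duration
  expect_equal(ev_size_from_burst(2 * 3.776e-3, cfg, "green"),
               2 * ev_size_from_burst(3.776e-3, cfg, "green"))
  # red-channel waist 372 nm
  expect_equal(ev_size_from_burst(6.345e-3, cfg, "red"), 90, tolerance = 1e-3)
  expect_error(ev_size_from_burst(0, cfg), "> 0")
})

test_that("direct cargo counts follow their definition", {
  # burst rate = eps + B -> one molecule; rate = B -> zero (flagged raw 0)
  cc <- cargo_count(c(1000 + 200, 200, 3500 + 200), brightness = 1000,
                    background_green = 200)
  expect_equal(cc$cargo_raw, c(1, 0, 3.5))
  expect_equal(cc$cargo_count, c(1L, 0L, 4L))  # half rounds away from zero
  expect_error(cargo_count(1000, brightness = 0), "> 0")
})

test_that("gamma fits recover known distributions", {
  set.seed(40)
  x <- rgamma(500, shape = 4, rate = 0.04)
  ft <- fit_gamma_size_distribution(x)
  expect_lt(abs(ft$mean_nm / 100 - 1), 0.10)
  ft_mle <- fit_gamma_size_distribution(x, method = "mle")
  expect_lt(abs(ft_mle$mean_nm / 100 - 1), 0.10)

  # exponential special case alpha = 1
  set.seed(41)
  y <- rgamma(1000, shape = 1, rate = 0.02)
  fe <- fit_gamma_size_distribution(y, method = "mle")
  expect_gt(fe$alpha, 0.8)
  expect_lt(fe$alpha, 1.2)

  expect_error(fit_gamma_size_distribution(rep(100, 50)), "degenerate")
  expect_error(fit_gamma_size_distribution(c(-1, x[1:40])), "positive")
  expect_error(fit_gamma_size_distribution(x[1:10]), "at least")
})

test_that("coincidence metrics and the 2D histogram satisfy their identities", {
  g <- synthetic_burst_set(seq(10, 600, length.out = 27), rep(4e-3, 27),
                           acq_duration_s = 600)
  r <- synthetic_burst_set(c(seq(10, 600, length.out = 27),
                             seq(15, 300, length.out = 13)),
                           rep(4e-3, 40), acq_duration_s = 600)
  ev <- match_coincident_bursts(g, r, 1e-3)
  m <- coincidence_metrics(ev, r, 600)
  # 27 events in 600 s is 2.7 per minute
  expect_equal(m$coincident_rate_per_min, 2.7)
  expect_equal(m$loading_yield_burst, 27 / 40)

  none <- match_coincident_bursts(g, synthetic_burst_set(1000 + 1:12,
                                                         rep(4e-3, 12),
                                                         acq_duration_s = 1200),
                                  1e-4)
  m0 <- coincidence_metrics(none, r, 600)
  expect_equal(m0$coincident_rate_per_min, 0)
  expect_equal(m0$loading_yield_burst, 0)
  expect_error(coincidence_metrics(ev, synthetic_burst_set(numeric(0), numeric(0), 1),
                                   600), "empty red")

  ev <- annotate_coincident_events(ev, size_estimation_config(),
                                   brightness = 1000, background_green = 0)
  h <- size_cargo_histogram2d(ev, size_bins_nm = seq(0, 400, by = 50),
                              cargo_bins = 0:30)
  expect_equal(sum(h), nrow(ev$events))
  # marginal over cargo equals the 1D size histogram
  sz <- ev$events$size_green_nm
  h1 <- table(cut(sz, seq(0, 400, by = 50), right = FALSE))
  expect_equal(unname(rowSums(h)), as.vector(h1))

  one <- ev
  one$events <- one$events[1, ]
  h_one <- size_cargo_histogram2d(one, c(0, 400), c(0, 50))
  expect_equal(sum(h_one > 0), 1L)
  expect_error(size_cargo_histogram2d(ev, c(1), 0:30), "bin edges")
})

test_that("external size histograms are read for overlay", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# NTA-style synthetic overlay", "50\t0.1", "100\t0.8", "150\t0.3"),
             path)
  tab <- read_external_size_histogram(path)
  expect_equal(tab$size_nm, c(50, 100, 150))
  expect_equal(tab$density, c(0.1, 0.8, 0.3))
})
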