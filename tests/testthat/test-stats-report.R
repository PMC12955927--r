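test_that("subset splitting blocks exactly per_subset events and drops the remainder", {
  red <- synthetic_burst_set(seq(0.5, 599.5, by = 0.5), rep(4e-3, 1199),
                             acq_duration_s = 600)
  ev20 <- match_coincident_bursts(
    synthetic_burst_set(seq(10, 200, length.out = 20), rep(4e-3, 20),
                        acq_duration_s = 600), red, 1e-3)
  s1 <- split_into_subsets(ev20, red, 20)
  expect_equal(nrow(s1), 1L)
  expect_equal(attr(s1, "n_dropped"), 0L)
  expect_equal(s1$rate_per_min, 60 * 20 / s1$span_s)
  expect_equal(s1$yield, 20 / s1$n_red_bursts)

  ev45 <- match_coincident_bursts(
    synthetic_burst_set(seq(10, 230, by = 5), rep(4e-3, 45),
                        acq_duration_s = 600), red, 1e-3)
  s2 <- split_into_subsets(ev45, red, 20)
  expect_equal(nrow(s2), 2L)
  expect_equal(attr(s2, "n_dropped"), 5L)
  # spans disjoint and ordered
  expect_true(s2$t_start_s[2] > s2$t_stop_s[1])
  expect_error(split_into_subsets(ev20, red, 21), "fewer than")
})

test_that("subset rates of a stationary process agree with the global rate", {
  sm <- simulate_subset_metrics(coincident_rate_per_min = 3,
                                red_rate_per_s = 2, duration_s = 4000,
                                seed = 5)
  expect_gte(nrow(sm), 8)
  global <- 3
  se <- sd(sm$rate_per_min) / sqrt(nrow(sm))
  expect_lt(abs(mean(sm$rate_per_min) - global), 3 * se + 0.3)
  # pooled consistency: subsets cover per_subset events each
  expect_true(all(attr(sm, "per_subset") == 20))
})

test_that("Welch test matches the textbook formulas", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  res <- welch_t_test(a, b)
  # hand evaluation: var = 5/3 each, se = sqrt(5/6), t = -2/se,
  # Welch-Satterthwaite df = 6, p = 2*pt(t, 6)
  expect_equal(res$t, -2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(res$df, 6, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2 / sqrt(5 / 6), 6), tolerance = 1e-12)

  # identical samples: no difference
  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_test(1, b), ">= 2")
  expect_error(welch_t_test(c(1, 1, 1), b), "zero variance")

  # property: agreement with an independent textbook implementation
  set.seed(13)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(x, y)
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t_ref <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df_ref <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    p_ref <- 2 * pt(-abs(t_ref), df_ref)
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    expect_equal(got$df, df_ref, tolerance = 1e-10)
    expect_equal(got$p, p_ref, tolerance = 1e-10)
  }
})

test_that("condition reports validate completeness and serialize", {
  reports <- fx_mixture_reports()
  rep1 <- reports[[1]]$report
  expect_s3_class(rep1, "condition_report")
  expect_equal(rep1$loading_yield_burst,
               coincidence_metrics(rep1$events, rep1$bursts$red,
                                   rep1$duration_s)$loading_yield_burst)
  path <- withr::local_tempfile(fileext = ".json")
  write_condition_report(rep1, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$condition, "mixture_1")
  expect_equal(as.numeric(js$loading_yield_burst), rep1$loading_yield_burst,
               tolerance = 1e-9)

  expect_error(summarize_condition("x", NULL, gated = NULL, backgrounds = 1,
                                   curves = 1, fits = 1, occupancy = 1,
                                   burst_params = 1, bursts = 1,
                                   tolerance = 1, events = 1, metrics = 1),
               "missing stage")
})

test_that("condition comparison detects a rate contrast with correct ordering", {
  a <- simulate_subset_metrics(2.7, 3, 4200, seed = 71)
  b <- simulate_subset_metrics(8.1, 3, 1500, seed = 72)
  fake_report <- function(name, subsets) {
    structure(list(condition = name, subsets = subsets),
              class = "condition_report")
  }
  cmp <- compare_conditions(fake_report("undiff", a), fake_report("partial", b))
  expect_lt(cmp$rate$mean["a"], cmp$rate$mean["b"])
  expect_lt(cmp$rate$p, 0.05)
  expect_gt(cmp$rate$df, 0)
  expect_true(cmp$yield$p >= 0 && cmp$yield$p <= 1)
})

test_that("the pipeline is deterministic for a fixed input", {
  cfg <- mixture_config(seed = 3, duration_s = 60)
  sim <- simulate_photon_stream(cfg)
  pc <- pipeline_config(two_component_green = FALSE,
                        background_green = 100, background_red = 100)
  r1 <- suppressWarnings(run_pipeline(sim$stream, pc, condition = "a"))
  r2 <- suppressWarnings(run_pipeline(sim$stream, pc, condition = "a"))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_condition_report(r1, p1)
  write_condition_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
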