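test_that("dF extraction subtracts manual and rolling baselines correctly", {
  f <- rep(100, 50)
  expect_equal(compute_dff(f, baseline_manual(100)), rep(0, 50))
  expect_equal(compute_dff(f + 3, baseline_manual(100)), rep(3, 50))
  expect_error(compute_dff(numeric(0), baseline_manual(1)),
               class = "scoliquant_param_error")
  expect_error(compute_dff(rnorm(10), baseline_rolling_percentile(window_s = 20),
                           fps = 10),
               class = "scoliquant_param_error")

  # a simulated transient of peak 10 over a drifting baseline of 100:
  # the rolling-percentile baseline recovers the peak within 5%
  sim <- simulate_bilateral_traces(
    cpg_sim_params(event_rate = 0.05, switch_prob = 1, duration = 60,
                   noise_sd = 0.05, amplitude_mean = 10, amplitude_cv = 0,
                   baseline_level = 100, baseline_drift_slope = 0.05,
                   seed = 9))
  expect_equal(sum(sim$events$side == "left"), 1L)
  tr <- sim$traces$data$value[sim$traces$data$roi_id == "left_01"]
  dff <- compute_dff(tr, baseline_rolling_percentile(), fps = 10)
  expect_equal(max(dff), 10, tolerance = 0.05)
})

test_that("relative intensity normalizes to mean 100", {
  expect_equal(relative_intensity(c(1, 3)), c(50, 150))
  expect_equal(relative_intensity(rep(2.5, 7)), rep(100, 7))
  set.seed(1)
  x <- rexp(200) + 0.1
  expect_equal(mean(relative_intensity(x)), 100)
  expect_error(relative_intensity(c(-1, 1)), class = "scoliquant_param_error")
})

test_that("event detector: flat traces, refractory merging, shift invariance", {
  expect_equal(nrow(detect_events(rep(0, 100), fps = 10)), 0L)

  # two peaks 0.05 s apart at 100 fps with a 0.5 s refractory: one event
  x <- rep(0, 400)
  x[100:102] <- c(4, 6, 4)
  x[105:107] <- c(3, 5, 3)
  ev <- detect_events(x, fps = 100, min_interval_s = 0.5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 6, tolerance = 1e-9)
  # with a permissive refractory both survive
  expect_equal(nrow(detect_events(x, fps = 100, min_interval_s = 0.02)), 2L)

  # detection through a rolling-percentile baseline ignores constant offsets
  sim <- simulate_bilateral_traces(
    cpg_sim_params(event_rate = 0.2, switch_prob = 0.9, duration = 120,
                   noise_sd = 0.3, seed = 6))
  summ <- function(shift) {
    tr <- sim$traces
    tr$data$value <- tr$data$value + shift
    s <- activity_summary(tr)
    s$events$onset_time
  }
  expect_identical(summ(0), summ(57.3))
})

test_that("simulated events at 10x noise are all recovered with frame-accurate onsets", {
  sim <- simulate_bilateral_traces(
    cpg_sim_params(event_rate = 0.2, switch_prob = 1, duration = 120,
                   noise_sd = 0.3, amplitude_mean = 3, amplitude_cv = 0,
                   seed = 2))
  s <- activity_summary(sim$traces)
  err <- vapply(sim$events$onset_time, function(t0)
    min(abs(s$events$onset_time - t0)), numeric(1))
  # every rendered event is recovered; noise can delay the threshold
  # crossing by one extra sample, so onsets are accurate to two
  # frames at 10 fps
  expect_lte(max(err), 0.2 + 1e-9)
  # a 3-robust-SD threshold admits occasional noise excursions, so a
  # small false-positive margin is expected but no more
  expect_gte(s$n_events, nrow(sim$events))
  expect_lte(s$n_events, nrow(sim$events) + 3L)
})

test_that("detector recall is at least 95% for well-separated events at 5x noise", {
  recalls <- vapply(1:6, function(seed) {
    sim <- simulate_bilateral_traces(
      cpg_sim_params(event_rate = 0.2, min_gap = 2, switch_prob = 0.8,
                     duration = 240, noise_sd = 0.5, amplitude_mean = 2.5,
                     amplitude_cv = 0, seed = seed))
    s <- activity_summary(sim$traces)
    event_recall(sim$events, s$events)
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("alternation index matches hand-enumerated cases and its bounds", {
  lr <- function(s) event_train(seq_along(s), s, rep(1, length(s)))
  expect_equal(alternation_index(lr(c("left", "right", "left", "right", "left"))), 1)
  expect_equal(alternation_index(lr(rep("left", 4))), 0)
  expect_equal(alternation_index(lr(c("left", "left", "right", "left", "right"))), 0.75)
  # bilateral events break alternation
  expect_equal(alternation_index(lr(c("left", "bilateral", "right"))), 0)
  expect_error(alternation_index(lr("left")), class = "scoliquant_param_error")

  set.seed(3)
  for (i in 1:25) {
    sides <- sample(c("left", "right", "bilateral"), sample(2:40, 1),
                    replace = TRUE)
    ai <- alternation_index(lr(sides))
    expect_gte(ai, 0); expect_lte(ai, 1)
    strict <- length(unique(sides[sides != "bilateral"])) == 2 &&
      !"bilateral" %in% sides && all(sides[-1] != sides[-length(sides)])
    expect_identical(ai == 1, strict)
  }
})

test_that("mean alternation index of i.i.d. equiprobable sides approaches 0.5", {
  set.seed(17)
  sides <- sample(c("left", "right"), 10000, replace = TRUE)
  ai <- alternation_index(event_train(seq_along(sides), sides,
                                      rep(1, length(sides))))
  expect_equal(ai, 0.5, tolerance = 0.02 / 0.5)
})

test_that("event frequency counts one side over the duration", {
  ev <- event_train(seq(5, 55, by = 10), rep(c("left", "right"), 3),
                    rep(1, 6))
  expect_equal(event_frequency(ev, "left", 60), 3 / 60)
  expect_equal(event_frequency(event_train(), "left", 60), 0)

  # rate recovery: whole-fish renewal at 0.4 events/s splits evenly,
  # so the left side runs at 0.2 Hz
  sim <- simulate_bilateral_traces(
    cpg_sim_params(event_rate = 0.4, switch_prob = 0.5, duration = 600,
                   noise_sd = 0.3, seed = 3))
  s <- activity_summary(sim$traces)
  expect_equal(s$left_frequency_hz, 0.2, tolerance = 0.05 / 0.2)
})

test_that("total signal integrates dF, matching the closed-form kernel area", {
  expect_equal(total_signal(rep(0, 600), 10), 0)
  expect_equal(total_signal(rep(1, 601), 10), 60)
  tg <- seq(0, 30, by = 1 / 10)
  dff <- 7 * calcium_kernel(tg - 5, 0.1, 0.8)
  expect_equal(total_signal(dff, 10), 7 * calcium_kernel_area(0.1, 0.8),
               tolerance = 0.02)
})
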