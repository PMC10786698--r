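make_rec <- function(chans, fs = 2000) semg_recording(chans, fs = fs)

test_that("preprocessing zero-means every channel and respects the band", {
  fs <- 2000
  t_grid <- seq(0, 5, by = 1 / fs)
  sim <- simulate_semg(duration_s = 5, seed = 2)
  pre <- semg_preprocess(sim$recording)
  for (ch in pre$channels) expect_lt(abs(mean(ch)), 1e-9)

  att_db <- function(f) {
    x <- sin(2 * pi * f * t_grid)
    y <- bandpass <- semg_preprocess(make_rec(list(a = x)))$channels$a
    core <- 2000:8000  # avoid filter edge transients
    20 * log10(sd(y[core]) / sd(x[core]))
  }
  expect_lte(att_db(5), -20)          # below-band tone suppressed
  expect_gte(att_db(50), -1)          # in-band tone passed
  expect_lte(att_db(50), 1)

  expect_error(semg_preprocess(sim$recording, band = c(100, 50)),
               class = "scoliquant_param_error")
})

test_that("preprocessing is idempotent on muscle-band signals", {
  # myoelectric power lives well inside the 15-1000 Hz acquisition
  # band; on such signals a second pass is a near no-op (broadband
  # noise at the band edges would lose transition-band energy)
  sim <- simulate_semg(duration_s = 5, ecg_amplitude = 1, seed = 5)
  muscle <- semg_recording(
    lapply(sim$recording$channels, function(x)
      scoliquant:::bandpass_zero_phase(x, 2000, c(30, 400))),
    fs = 2000)
  once <- semg_preprocess(muscle)
  twice <- semg_preprocess(once)
  for (nm in names(once$channels)) {
    r1 <- sqrt(mean(once$channels[[nm]]^2))
    r2 <- sqrt(mean(twice$channels[[nm]]^2))
    expect_lt(abs(r2 - r1) / r1, 0.01)
  }
})

test_that("ECG removal subtracts over 90% of injected template energy", {
  sim <- simulate_semg(duration_s = 30, ecg_amplitude = 2, seed = 3)
  rec <- sim$recording
  cleaned <- remove_ecg(rec$channels$rec_left, rec$channels$ref_left,
                        fs = rec$fs)
  expect_true(attr(cleaned, "ecg_removed"))
  inj <- sim$ecg_component$rec_left
  uncontaminated <- rec$channels$rec_left - inj
  residual <- as.numeric(cleaned) - uncontaminated
  expect_gt(1 - sum(residual^2) / sum(inj^2), 0.9)
})

test_that("ECG removal is conservative without a usable reference", {
  set.seed(4)
  x <- rnorm(2000)
  expect_warning(out <- remove_ecg(x, rep(0, 2000), fs = 2000))
  expect_identical(as.numeric(out), x)
  expect_false(attr(out, "ecg_removed"))

  # template absent from the signal: no spurious subtraction beyond
  # the template-estimation noise floor
  clean <- simulate_semg(duration_s = 30, ecg_amplitude = 0, seed = 6)
  with_ecg_ref <- simulate_semg(duration_s = 30, ecg_amplitude = 2, seed = 7)
  sig <- clean$recording$channels$rec_left
  out2 <- remove_ecg(sig, with_ecg_ref$recording$channels$ref_left, fs = 2000)
  expect_lt(sum((as.numeric(out2) - sig)^2) / sum(sig^2), 0.05)
  expect_error(remove_ecg(rnorm(10), rnorm(11), fs = 2000),
               class = "scoliquant_param_error")
})

test_that("bending normalization divides by same-side reference RMS", {
  set.seed(11)
  stand <- make_rec(list(rec_left = rnorm(4000), rec_right = rnorm(4000),
                         ref_left = rnorm(4000), ref_right = rnorm(4000)))
  # standing identical to bending: normalized RMS is 1
  norm1 <- bending_normalize(stand, stand, stand)
  for (ch in norm1$channels)
    expect_equal(sqrt(mean(ch^2)), 1, tolerance = 1e-10)

  # standing at half the bending RMS: normalized RMS is 0.5
  half <- make_rec(lapply(stand$channels, function(x) x / 2))
  norm2 <- bending_normalize(half, stand, stand)
  for (ch in norm2$channels)
    expect_equal(sqrt(mean(ch^2)), 0.5, tolerance = 1e-10)

  # zero standing signal maps to zero
  zero <- make_rec(lapply(stand$channels, function(x) x * 0))
  norm3 <- bending_normalize(zero, stand, stand)
  for (ch in norm3$channels) expect_equal(ch, rep(0, 4000))

  # invariant to a common gain on all recordings
  g <- 7.3
  scaled <- function(r) make_rec(lapply(r$channels, function(x) g * x))
  norm4 <- bending_normalize(scaled(half), scaled(stand), scaled(stand))
  expect_equal(norm4$channels, norm2$channels, tolerance = 1e-10)

  expect_error(bending_normalize(stand, zero, stand),
               class = "scoliquant_param_error")
})

test_that("burst metrics separate stationary noise from injected bursts", {
  set.seed(12)
  stationary <- rnorm(2000 * 20)
  bm <- burst_metrics(stationary, fs = 2000)
  expect_lt(bm$burst_fraction, 0.01)

  sb <- simulate_semg(duration_s = 20, burst_spec = list(
    side = "left", fraction = 0.10, gain = 5), seed = 6)
  bml <- burst_metrics(sb$recording$channels$rec_left, fs = 2000)
  expect_equal(bml$burst_fraction, 0.10, tolerance = 0.3)
  # contralateral side stays quiet
  bmr <- burst_metrics(sb$recording$channels$rec_right, fs = 2000)
  expect_lt(bmr$burst_fraction, 0.01)

  expect_equal(burst_metrics(rep(0, 4000), fs = 2000)$burst_count, 0L)
  expect_error(burst_metrics(rnorm(100), fs = 2000),
               class = "scoliquant_param_error")

  m <- semg_metrics(sb$recording)
  expect_gt(m$lr_rms_ratio, 1)  # bursting side carries more power
})
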