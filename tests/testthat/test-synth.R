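test_that("pulse simulation honors the zero and constant-rate cases", {
  # all amplitudes zero: silent trace, beat schedule still reported
  cfg <- pulse_sim_config(pulse_amp = 0, baseline_amp = 0, powerline_amp = 0,
                          noise_sd = 0, twave_frac = 0, duration = 10)
  sim <- simulate_pulse_wave(cfg)
  expect_equal(sim$trace$samples, numeric(10 * 500))
  expect_gt(length(sim$truth$beat_times), 5)
  expect_true(all(diff(sim$truth$beat_times) > 0))
  # zero jitter at 80 beats/min: all scheduled intervals exactly 750 ms
  sim <- clean_sim(duration = 30)
  expect_equal(unique(diff(sim$truth$beat_times)), 750)
})

test_that("trace length, determinism and beat-count conservation hold", {
  cfg <- pulse_sim_config(duration = 12.3, seed = 7)
  s1 <- simulate_pulse_wave(cfg)
  s2 <- simulate_pulse_wave(cfg)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth$beat_times, s2$truth$beat_times)
  expect_equal(length(s1$trace$samples), round(500 * 12.3))
  expect_error(pulse_sim_config(fs = 0), "positive")
  expect_error(pulse_sim_config(duration = -1), "positive")
  expect_error(pulse_sim_config(twave_frac = 1), "twave_frac")
})

test_that("power-line interference lands at the configured frequency", {
  cfg <- pulse_sim_config(fs = 200, duration = 20, pulse_amp = 0,
                          baseline_amp = 0, powerline_amp = 1,
                          powerline_freq = 50, noise_sd = 0, twave_frac = 0)
  x <- simulate_pulse_wave(cfg)$trace$samples
  spec <- Mod(stats::fft(x))[1:(length(x) / 2)]
  f <- (seq_along(spec) - 1) * 200 / length(x)
  expect_equal(f[which.max(spec)], 50, tolerance = 0.1)
})

test_that("temperature simulation respects level, SD and seed", {
  expect_equal(length(simulate_temperature(1, 0)$samples), 0L)
  const <- simulate_temperature(2, 50, sd = 0)
  expect_equal(unique(const$samples), 39.8)
  expect_error(simulate_temperature(4, 10), "unknown stress level")
  a <- simulate_temperature(3, 100, seed = 5)
  b <- simulate_temperature(3, 100, seed = 5)
  expect_identical(a$samples, b$samples)
  # configured ordering of level means shows up in large samples
  m1 <- mean(simulate_temperature(1, 1e4, seed = 1)$samples)
  m2 <- mean(simulate_temperature(2, 1e4, seed = 1)$samples)
  expect_lt(m1, m2)
})

test_that("cohort simulation produces the 195-record 136/59 design", {
  co <- simulate_cohort(seed = 1)
  expect_s3_class(co, "labeled_cohort")
  expect_equal(nrow(co$features), 195L)
  expect_equal(length(co$train_idx), 136L)
  expect_equal(length(co$test_idx), 59L)
  expect_equal(tabulate(co$labels[co$test_idx], 3L), c(18L, 11L, 30L))
  expect_equal(colnames(co$features),
               c("HR", "MR", "SDNN", "RMSSD", "pNN50", "CV", "TO"))
  expect_identical(co$features, simulate_cohort(seed = 1)$features)
  # derived-feature identities hold for every record
  expect_equal(co$features[, "HR"] * co$features[, "MR"],
               rep(60000, 195), tolerance = 1e-9)
  expect_equal(co$features[, "CV"],
               co$features[, "SDNN"] / co$features[, "MR"], tolerance = 1e-12)
})

test_that("degenerate splits are rejected", {
  expect_error(
    labeled_cohort(matrix(rnorm(40 * 7), 40), rep(c(1, 2), 20), 1:39, 40),
    "absent|degenerate|levels")
  expect_error(stress_class_model(class_counts = c(5, 5, 5),
                                  test_counts = c(5, 1, 1)),
               "training record")
})

test_that("widely separated classes are trivially separable", {
  co <- simulate_cohort(separated_model(), seed = 3)
  nco <- normalize_cohort(co)
  fit <- pulsegrade:::nc_fit(nco$features[nco$train_idx, ],
                             nco$labels[nco$train_idx])
  pred <- predict(fit, nco$features[nco$test_idx, ])
  expect_equal(mean(pred == nco$labels[nco$test_idx]), 1)
})

test_that("more noise never helps downstream beat detection", {
  noise <- c(0.02, 0.3, 1.0)
  f1 <- matrix(NA_real_, length(noise), 6)
  for (i in seq_along(noise)) for (sd in 1:6) {
    sim <- simulate_pulse_wave(pulse_sim_config(duration = 30,
                                                noise_sd = noise[i],
                                                seed = sd))
    f1[i, sd] <- score_beats(extract_beats(sim$trace),
                             sim$truth$beat_times)$f1
  }
  m <- rowMeans(f1)
  expect_true(all(diff(m) <= 0.005))
})
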