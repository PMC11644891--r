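test_that("mean and biased variance estimators follow their formulas", {
  expect_equal(estimate_mean(c(1, 2, 3)), 2)
  expect_equal(estimate_mean(rep(4.2, 9)), 4.2)
  expect_error(estimate_mean(numeric(0)), "non-empty")
  expect_equal(estimate_variance(c(1, 2, 3)), 2 / 3)
  expect_equal(estimate_variance(rep(7, 5)), 0)
  expect_equal(estimate_variance(c(0, 2)), 1)
  set.seed(31)
  x <- rnorm(1e4, 5, 1)
  expect_lt(abs(estimate_mean(x) - 5), 0.05)
  # the 1/N estimator relates to the sample variance by (n-1)/n exactly
  for (n in c(2, 5, 40)) {
    y <- rnorm(n)
    expect_equal(estimate_variance(y), (n - 1) / n * stats::var(y),
                 tolerance = 1e-12)
  }
})

test_that("HRV features match the hand-computed oracle", {
  f <- hrv_features(c(800, 800, 800))
  expect_equal(unname(f), c(75, 800, 0, 0, 0, 0))
  f <- hrv_features(c(800, 900, 800, 900))
  expect_equal(f[["MR"]], 850)
  expect_equal(f[["HR"]], 60000 / 850, tolerance = 1e-9)
  expect_equal(f[["SDNN"]], sqrt(sum((c(800, 900, 800, 900) - 850)^2) / 3),
               tolerance = 1e-9)
  expect_equal(f[["RMSSD"]], 100, tolerance = 1e-9)
  expect_equal(f[["pNN50"]], 100)
  expect_equal(f[["CV"]], f[["SDNN"]] / 850, tolerance = 1e-12)
  expect_error(hrv_features(c(800)), "at least 2")
})

test_that("HRV features transform correctly under scaling and shifts", {
  set.seed(13)
  ibi <- 800 + 60 * rnorm(30)
  f <- hrv_features(ibi)
  f2 <- hrv_features(2 * ibi)
  expect_equal(f2[["MR"]], 2 * f[["MR"]])
  expect_equal(f2[["SDNN"]], 2 * f[["SDNN"]])
  expect_equal(f2[["RMSSD"]], 2 * f[["RMSSD"]])
  expect_equal(f2[["CV"]], f[["CV"]], tolerance = 1e-12)
  # constant shift leaves dispersion features unchanged
  fs <- hrv_features(ibi + 500)
  expect_equal(fs[["SDNN"]], f[["SDNN"]], tolerance = 1e-9)
  expect_equal(fs[["RMSSD"]], f[["RMSSD"]], tolerance = 1e-9)
  expect_equal(fs[["pNN50"]], f[["pNN50"]])
  # the HR * MR identity holds for every computed record
  expect_equal(f[["HR"]] * f[["MR"]], 60000, tolerance = 1e-9)
})

test_that("infrared temperature inversion round-trips the forward law", {
  expect_equal(object_temperature(0, sensor_temp = 298.15), 298.15)
  sb <- 5.670374419e-8
  P <- sb * 300^4
  expect_equal(object_temperature(P, emissivity = 1, k = 1, sensor_temp = 0),
               300, tolerance = 1e-9)
  set.seed(8)
  for (Tt in runif(5, 270, 320)) {
    P <- 0.97 * 1.3 * sb * (Tt^4 - 295^4)
    expect_equal(object_temperature(P, emissivity = 0.97, k = 1.3,
                                    sensor_temp = 295), Tt, tolerance = 1e-9)
  }
  expect_error(object_temperature(-1e4, emissivity = 1, sensor_temp = 100),
               "non-physical")
})

test_that("min-max normalization fits on training rows and clips the rest", {
  m <- matrix(c(2, 4, 6), ncol = 1)
  expect_equal(as.numeric(minmax_normalize(m)$features), c(0, 0.5, 1))
  expect_warning(r <- minmax_normalize(matrix(rep(5, 4), ncol = 1)),
                 "constant")
  expect_equal(as.numeric(r$features), rep(0, 4))
  # fit on rows 1-2 (range 0-10); row 3 value 12 clips to 1
  m <- matrix(c(0, 10, 12), ncol = 1)
  expect_equal(as.numeric(minmax_normalize(m, fit_rows = 1:2)$features),
               c(0, 1, 1))
  co <- simulate_cohort(seed = 2)
  nco <- normalize_cohort(co)
  expect_true(all(nco$features >= 0 & nco$features <= 1))
  tr <- nco$features[nco$train_idx, ]
  expect_equal(unname(apply(tr, 2, min)), rep(0, 7))
  expect_equal(unname(apply(tr, 2, max)), rep(1, 7))
})

test_that("feature records combine HRV and temperature", {
  rec <- feature_record(c(800, 900, 800, 900),
                        simulate_temperature(1, 30, sd = 0))
  expect_equal(length(rec), 7L)
  expect_equal(rec[["TO"]], 38.5)
  expect_error(feature_record(c(800, 900), signal_trace(numeric(0), 1)),
               "empty temperature")
})
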