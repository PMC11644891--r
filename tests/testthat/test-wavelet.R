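test_that("one analysis step reproduces an independently computed reference", {
  # bior6.8 analysis of sin(1:40), half-point symmetric extension, computed
  # with an independent wavelet implementation and frozen here
  cA_ref <- c(
    1.40410873479566, -0.411739626032063, -1.03003448571865, 1.15172618485505,
    1.2734765490831, 0.246023851147024, -1.38224978979851, 0.933067511010975,
    0.584214273475287, -1.41757424848272, 0.595623804678269, 0.921840324304654,
    -1.36286567420022, 0.212464153609563, 1.18603310339164, -1.19959200164281,
    -0.187620270129826, 1.3557471654161, -0.940759517961508, -0.572758970713512,
    1.41918826512669, -0.623787749278687, -0.86630529289974, 1.21882355322907,
    1.14284613473616, 0.469504224734466, -1.43051781050977, 0.751880536134028)
  cD_ref <- c(
    -0.103810532406517, 0.163659039469767, -0.0987163013093814,
    0.190786819092639, -0.271612635626545, 0.132665548487226,
    0.0441504768700438, -0.156328616935324, 0.0859608419288068,
    0.0847839520641206, -0.156525988811704, 0.045491638098687,
    0.118663586243471, -0.144254590155806, 0.00139859645801525,
    0.143090547172588, -0.12049195354936, -0.0428058565746857,
    0.156118997147852, -0.0871309970012962, -0.083600419613276,
    0.16974864569716, -0.128901708290206, 0.229968122079798,
    -0.289690403862388, 0.115736719515577, 0.0676571957088961,
    -0.15799619468609)
  st <- pulsegrade:::dwt_step(sin(1:40), pulsegrade:::bior68_filters())
  expect_equal(st$a, cA_ref, tolerance = 1e-12)
  expect_equal(st$d, cD_ref, tolerance = 1e-12)
})

test_that("decomposition reconstructs perfectly before thresholding", {
  set.seed(5)
  for (n in c(300, 301, 2048)) {
    x <- rnorm(n)
    pyr <- wt_decompose(x, wavelet_plan(levels = 9))
    expect_lt(max(abs(wt_reconstruct(pyr) - x)) / max(abs(x)), 1e-8)
  }
  z <- wt_decompose(numeric(256), wavelet_plan(levels = 5,
                                               kill_detail_levels = 1:3))
  expect_true(all(vapply(z$d, function(d) all(d == 0), logical(1))))
  expect_true(all(z$a == 0))
})

test_that("too-deep decompositions error naming the feasible depth", {
  err <- expect_error(wt_decompose(rnorm(40), wavelet_plan(levels = 9)),
                      "maximum feasible depth")
  expect_match(conditionMessage(err), "[0-9]+")
  expect_error(wt_decompose(rnorm(10), wavelet_plan(levels = 1)),
               "filter length")
})

test_that("a 50 Hz tone concentrates its energy in the finest detail band", {
  t <- (0:2047) / 200
  x <- sin(2 * pi * 50 * t)
  pyr <- wt_decompose(x, wavelet_plan(levels = 4, kill_detail_levels = 1))
  # energy of d1 (the 50-100 Hz band at fs = 200) dominates
  e <- vapply(pyr$d, function(d) sum(d^2), numeric(1))
  expect_gt(e[1] / (sum(e) + sum(pyr$a^2)), 0.90)
})

test_that("minimax threshold follows the printed rule", {
  expect_equal(minimax_threshold(rnorm(1024), 0), 0)
  expect_equal(minimax_threshold(rnorm(32), 3), 0)
  expect_equal(minimax_threshold(rnorm(1024), 1), 0.3936 + 0.1829 * 10,
               tolerance = 1e-12)
  expect_error(minimax_threshold(rnorm(10), -1), "non-negative")
  expect_error(minimax_threshold(numeric(0), 1), "empty")
})

test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(c(3, -3), 1), c(2, -2))
  expect_equal(soft_threshold(c(0.5), 1), 0)
  x <- rnorm(50)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -0.1), "non-negative")
})

test_that("denoising removes interference and drift bands", {
  expect_equal(wt_denoise(numeric(2048)), numeric(2048))
  t <- (0:2047) / 200
  tone <- sin(2 * pi * 50 * t)
  drift <- sin(2 * pi * 0.1 * t)
  expect_lt(sum(wt_denoise(tone)^2) / sum(tone^2), 0.05)
  expect_lt(sum(wt_denoise(drift)^2) / sum(drift^2), 0.05)
})

test_that("denoising is near-idempotent on a smooth pulse signal", {
  sim <- clean_sim(duration = 20)
  x <- resample_trace(sim$trace, 200)$samples
  d1 <- wt_denoise(x)
  d2 <- wt_denoise(d1)
  expect_lt(abs(sum(d2^2) - sum(d1^2)) / sum(d1^2), 0.01)
})

test_that("energy left in the killed fine-detail bands is negligible", {
  sim <- simulate_pulse_wave(pulse_sim_config(duration = 20, seed = 3))
  x <- resample_trace(sim$trace, 200)$samples
  y <- wt_denoise(x)
  pyr <- wt_decompose(y, wavelet_plan())
  band_energy <- function(p)
    c(vapply(p$d, function(d) sum(d^2), numeric(1)), sum(p$a^2))
  e <- band_energy(pyr)
  # the zeroed fine scales d1-d3 stay empty on re-analysis
  expect_lt(sum(e[1:3]) / sum(e), 1e-6)
  # dropping the approximation removes the DC pedestal of the pulse train
  # (the a9 band itself cannot vanish exactly on re-analysis: a biorthogonal
  # analysis/synthesis pair is not an orthogonal projection)
  expect_lt(abs(mean(y)), 0.02 * abs(mean(x)))
})

test_that("denoising improves SNR against the clean template", {
  wins <- 0L
  n_seeds <- 10L
  for (sd in seq_len(n_seeds)) {
    cfg_noisy <- pulse_sim_config(duration = 20, seed = sd)
    cfg_clean <- pulse_sim_config(duration = 20, seed = sd, baseline_amp = 0,
                                  powerline_amp = 0, noise_sd = 0)
    noisy <- resample_trace(simulate_pulse_wave(cfg_noisy)$trace, 200)$samples
    clean <- resample_trace(simulate_pulse_wave(cfg_clean)$trace, 200)$samples
    # compare against the band-passed clean reference (the denoiser removes
    # the sub-0.1 Hz and 50+ Hz bands by design, including the DC pedestal)
    ref <- wt_denoise(clean)
    before <- sum((noisy - mean(noisy) - ref)^2)
    after <- sum((wt_denoise(noisy) - ref)^2)
    if (after < before) wins <- wins + 1L
  }
  expect_gte(wins, n_seeds - 1L)
})
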