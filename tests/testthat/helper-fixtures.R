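# shared fixtures built in code

# a clean pulse train: no noise, no jitter, no secondary bump
clean_sim <- function(seed = 1L, duration = 60, bpm = 80)
  simulate_pulse_wave(pulse_sim_config(
    duration = duration, beat_rate_bpm = bpm, hrv_sd = 0,
    baseline_amp = 0, powerline_amp = 0, noise_sd = 0, twave_frac = 0,
    seed = seed))

# direct polynomial-convolution oracle for the two recursive stages
fir_oracle <- function(x, stage) {
  h <- pulsegrade:::chain_fir_kernel(stage)
  y <- stats::convolve(x, rev(h), type = "open")
  y[seq_along(x)]
}

# a small widely separated class model (>= 10 SDs between level means)
separated_model <- function(counts = c(20L, 20L, 20L),
                            test_counts = c(6L, 6L, 6L))
  stress_class_model(
    means = list("1" = c(MR = 400,  SDNN = 10,  TO = 36),
                 "2" = c(MR = 800,  SDNN = 60,  TO = 39),
                 "3" = c(MR = 1200, SDNN = 110, TO = 42)),
    sds = lapply(1:3, function(i) c(MR = 2, SDNN = 0.5, TO = 0.02)) |>
      stats::setNames(c("1", "2", "3")),
    class_counts = counts, test_counts = test_counts)

# identical class means: labels carry no information
chance_model <- function(counts = c(65L, 65L, 65L),
                         test_counts = c(18L, 11L, 30L)) {
  one <- c(MR = 700, SDNN = 40, TO = 39)
  s <- c(MR = 50, SDNN = 10, TO = 0.4)
  stress_class_model(
    means = list("1" = one, "2" = one, "3" = one),
    sds = list("1" = s, "2" = s, "3" = s),
    class_counts = counts, test_counts = test_counts)
}
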