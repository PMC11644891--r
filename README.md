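# pulsegrade

Wearable-biosignal processing and transport-stress grading for livestock.

Animals transported to market experience stress that harms welfare and
meat quality. `pulsegrade` implements an end-to-end pipeline that turns
two wearable-sensor signals — a photoplethysmography (PPG) pulse wave and
an infrared body-temperature trace — into a three-level stress grade
(1 comfort, 2 stress, 3 intermediate). It is aimed at researchers in
precision-livestock monitoring and at anyone who needs a fully testable,
self-contained reference implementation of this processing chain.

## What it computes

* **Beat extraction** at a 200 Hz design rate via the integer-coefficient
  band-pass chain
  `H_lp(z) = (1/32)(1-z^-6)^2/(1-z^-1)^2` (−3 dB ≈ 11 Hz, delay 5
  samples) and `H_hp(z) = z^-16 − (1/32)(1−z^-32)/(1−z^-1)` (−3 dB ≈
  5 Hz, delay 80 ms), a five-point derivative, squaring and a 30-sample
  moving-window integral, followed by an adaptive two-threshold peak
  classifier with a 200 ms refractory, 360 ms T-wave rejection and
  `1.5·RR` searchback.
* **Wavelet denoising**: 9-level bior6.8 decomposition, soft minimax
  thresholding (`t = σ(0.3936 + 0.1829·log2 n)`), fine scales 1–3 zeroed,
  the scale-9 approximation (baseline drift) dropped.
* **Features**: HR, MR, SDNN, RMSSD, pNN50, CV from the inter-beat
  intervals plus the temperature feature TO, min-max normalized on the
  training split only.
* **Grading**: a bench of eight classifiers — GaussianNB, a
  passive-aggressive classifier, nearest centroid, KNN, random forest,
  one-vs-all SVM with 4-kernel grid search, a from-scratch reference
  gradient-boosted-tree learner (300 rounds, step 0.1), and xgboost with
  the tuned hyperparameters (softmax, 3 classes, depth 12,
  min_child_weight 3, gamma 0.1) — reported as per-level correct/total
  counts, rank accuracy and total accuracy.
* **Synthesis**: pulse-wave traces with known beat times and labeled
  195-record cohorts (136/59 split, 18/11/30 test composition), so every
  stage is testable without any external data.

## Worked example

```r
library(pulsegrade)

# synthesize a 30 s pulse-wave record (500 Hz) with drift, 50 Hz
# interference and sensor noise, then recover the beats
sim <- simulate_pulse_wave(pulse_sim_config(duration = 30, seed = 42))
ann <- extract_beats(sim$trace)   # resample -> denoise -> chain -> detect
ann
#> <beat_annotation> 39 beats, mean IBI 750.7 ms (79.9 bpm)

round(hrv_features(ann$ibi), 3)
#>      HR      MR    SDNN   RMSSD   pNN50      CV
#>  79.930 750.658  49.989  75.936  62.162   0.067

# a labeled synthetic cohort: 195 animals, 136 train / 59 test
co    <- normalize_cohort(simulate_cohort(seed = 42))
bench <- stress_bench(co, seed = 42)
evaluate_bench(bench, co)$XGB
#> Stress Level  Prediction Accuracy/Test Set  Rank Accuracy (%)
#>            1                         18/18             100.00
#>            2                          7/11              63.64
#>            3                         25/30              83.33
#> Total Accuracy (%): 84.75
```

The detector recovers the simulated ~80 beats/min physiology (mean IBI
750.7 ms); the report shows, per stress level, how many of the held-out
animals were graded correctly (comfort is easiest, the intermediate
level hardest) and the pooled accuracy over all 59 test animals.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pulsegrade.R simulate --duration 30 --seed 42 --out trace.csv
Rscript inst/cli/pulsegrade.R process  --in trace.csv --out beats.csv
Rscript inst/cli/pulsegrade.R run      --seed 1 --out-dir runs/demo
```

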