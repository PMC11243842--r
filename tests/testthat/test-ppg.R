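test_that("PPG synthesis is reproducible and rejects non-physical inputs", {
  a <- synthesize_ppg(hr = 72, duration = 5, seed = 3, noise_sd = 0.01)
  b <- synthesize_ppg(hr = 72, duration = 5, seed = 3, noise_sd = 0.01)
  expect_identical(a$ir, b$ir)
  expect_identical(a$red, b$red)
  expect_error(synthesize_ppg(hr = 300, duration = 5), "non-physical")
  expect_error(synthesize_ppg(hr = 60, duration = -1), "duration")
})

test_that("peak detection finds the generated beats", {
  sig <- synthesize_ppg(hr = 60, rr = 15, duration = 10, noise_sd = 0, seed = 1)
  beats <- detect_peaks(sig)
  expect_true(abs(length(beats$peak_times) - 10) <= 1)
  expect_true(all(diff(beats$peak_times) > 0))
  # clean 60 bpm: inter-peak spacing 1.0 +/- 0.02 s
  expect_true(all(abs(diff(beats$peak_times) - 1) <= 0.02))

  sig2 <- synthesize_ppg(hr = 120, rr = 15, duration = 10, noise_sd = 0, seed = 1)
  beats2 <- detect_peaks(sig2)
  expect_true(abs(length(beats2$peak_times) - 2 * length(beats$peak_times)) <= 2)

  flat <- sig
  flat$ir <- rep(0, length(flat$ir))
  expect_error(detect_peaks(flat), "no beats")
  expect_error(detect_peaks(window_short <- synthesize_ppg(hr = 60, duration = 1)),
               "insufficient")
})

test_that("heart rate is the reciprocal mean inter-beat interval", {
  expect_equal(estimate_hr(rep(1000, 5)), 60)
  expect_equal(estimate_hr(rep(500, 5)), 120)
  expect_equal(estimate_hr(c(800, 810, 790)), 75)
  expect_error(estimate_hr(numeric(0)), "insufficient")
})

test_that("RMSSD matches its definition and invariances", {
  expect_identical(estimate_prv_rmssd(rep(850, 10)), 0)
  expect_equal(estimate_prv_rmssd(c(800, 810, 790)), sqrt(250))
  ibis <- c(800, 830, 795, 810, 805)
  # shift invariance
  expect_equal(estimate_prv_rmssd(ibis + 120), estimate_prv_rmssd(ibis))
  # homogeneity: scaling all successive differences by k scales RMSSD by k
  scaled <- ibis[1] + 3 * cumsum(c(0, diff(ibis)))
  expect_equal(estimate_prv_rmssd(scaled), 3 * estimate_prv_rmssd(ibis))
  expect_error(estimate_prv_rmssd(c(800)), "insufficient")
})

test_that("respiratory rate is recovered from amplitude modulation", {
  sig <- synthesize_ppg(hr = 75, rr = 15, duration = 60, noise_sd = 0, seed = 2)
  rr <- estimate_rr(sig)
  expect_true(abs(as.numeric(rr) - 15) <= 1)
  expect_false(attr(rr, "low_confidence"))

  # ordering preserved between slow and fast breathing
  rr12 <- as.numeric(estimate_rr(synthesize_ppg(hr = 75, rr = 12, duration = 60,
                                                noise_sd = 0, seed = 2)))
  rr18 <- as.numeric(estimate_rr(synthesize_ppg(hr = 75, rr = 18, duration = 60,
                                                noise_sd = 0, seed = 2)))
  expect_lt(rr12, rr18)

  expect_error(estimate_rr(synthesize_ppg(hr = 75, duration = 10)),
               "insufficient")
})

test_that("unmodulated pulse trains are flagged low-confidence", {
  sig <- synthesize_ppg(hr = 75, rr = 15, duration = 60, noise_sd = 0.001,
                        seed = 4)
  # strip the respiratory modulation: regenerate pulses without AM by mixing
  # the two channels back to a constant-amplitude train
  beats <- detect_peaks(sig)
  # build a synthetic constant-amplitude signal directly
  t <- sig$t
  pulse <- rowSums(sapply(beats$peak_times, function(bt)
    exp(-((t - bt)^2) / (2 * 0.075^2))))
  flatmod <- structure(list(fs = sig$fs, t = t, ir = 1 + 0.1 * pulse,
                            red = 1 + 0.05 * pulse), class = "ppg_signal")
  rr <- estimate_rr(flatmod)
  expect_true(attr(rr, "low_confidence"))
})

test_that("SpO2 follows the calibration line and round-trips", {
  expect_equal(spo2_from_ratio(1.0), 85)
  expect_equal(spo2_from_ratio(0.4), 100)  # clipped at the ceiling
  for (true_spo2 in c(92, 97, 98)) {
    sig <- synthesize_ppg(hr = 72, rr = 15, spo2 = true_spo2, duration = 30,
                          noise_sd = 0, seed = 5)
    expect_true(abs(estimate_spo2(sig) - true_spo2) <= 0.5)
  }
  zero <- structure(list(fs = 300, t = 1:300 / 300, ir = rep(0, 300),
                         red = rep(0, 300)), class = "ppg_signal")
  expect_error(estimate_spo2(zero), "DC")
})

test_that("round-trip recovery meets the stated tolerances", {
  sig <- synthesize_ppg(hr = 72, rr = 15, spo2 = 97, duration = 60,
                        noise_sd = 0.002, seed = 6, ibi_jitter_sd = 0.01)
  beats <- detect_peaks(sig)
  expect_true(abs(estimate_hr(beats) - 72) <= 2)
  expect_true(abs(as.numeric(estimate_rr(sig, beats)) - 15) <= 1)
  expect_true(abs(estimate_spo2(sig) - 97) <= 0.5)
})

test_that("windowed extraction emits two estimates per second", {
  sig <- synthesize_ppg(hr = 70, rr = 14, spo2 = 98, duration = 40,
                        noise_sd = 0.002, seed = 8)
  vit <- extract_vitals(sig)
  expect_equal(unique(round(diff(vit$t), 6)), 0.5)  # 2 Hz cadence
  # roughly 2 estimates per second of signal past the first window
  expect_equal(nrow(vit), length(seq(8, 40, by = 0.5)))
  ok <- !is.na(vit$hr)
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(vit$hr[ok] - 70) <= 3))
})
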