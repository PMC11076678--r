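test_that("band-pass keeps in-band tones and rejects out-of-band content", {
  cfg <- spectral_config()
  t <- seq(0, 4, by = 1e-3)[-1]
  tone10 <- sin(2 * pi * 10 * t)
  out <- bandpass(tone10, cfg)
  expect_length(out, length(tone10))
  mid <- seq(500, length(t) - 500)                 # avoid filter edges
  amp <- sqrt(2 * mean(out[mid]^2))
  expect_lt(abs(amp - 1), 0.01)                    # amplitude within 1%
  tone100 <- sin(2 * pi * 100 * t)
  amp100 <- sqrt(2 * mean(bandpass(tone100, cfg)[mid]^2))
  expect_lt(amp100, 0.05)                          # > 95% attenuation
  # DC outside the passband: zero steady state (middle of a longer record,
  # past the 1-Hz high-pass edge transient)
  dc <- bandpass(rep(3, 16000), cfg)
  expect_lt(max(abs(dc[7000:9000])), 1e-6)
})

test_that("spectral configuration invariants are enforced", {
  expect_error(spectral_config(band_high = 600, fs = 1000), "passband")
  expect_error(spectral_config(band_low = 0), "passband")
  expect_error(spectral_config(alpha_high = 60), "alpha band")
  expect_error(spectral_config(welch_overlap = 1), "welch_overlap")
  expect_error(bandpass(rnorm(10), spectral_config()), "too short")
})

test_that("Welch PSD reproduces independently computed two-tone densities", {
  # expected values frozen from an independent reference implementation of
  # the averaged periodogram (and analytic for exact-bin Hann tones:
  # A^2/2 divided by the 1.5-bin equivalent noise bandwidth)
  cfg <- spectral_config(fs = 200, band_low = 1, band_high = 80,
                         welch_segment = 2, welch_overlap = 0.5)
  t <- (0:(200 * 8 - 1)) / 200
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 23 * t)
  w <- welch_psd(x, cfg)
  expect_equal(w$freq[2] - w$freq[1], 0.5)
  expect_equal(w$psd[w$freq == 7], 2 / 3, tolerance = 1e-9)
  expect_equal(w$psd[w$freq == 23], 1 / 6, tolerance = 1e-9)
  expect_lt(w$psd[w$freq == 50], 1e-20)
  expect_true(all(w$psd >= 0))
})

test_that("Welch PSD localizes a tone and integrates to the variance", {
  cfg <- spectral_config()
  t <- (0:(28 * 1000 - 1)) / 1000
  w <- welch_psd(sin(2 * pi * 10 * t), cfg)
  expect_lt(abs(w$freq[which.max(w$psd)] - 10), 0.25 + 1e-9)
  # variance identity on white noise
  set.seed(41)
  x <- rnorm(20 * 500, sd = 2)
  cfgw <- spectral_config(fs = 500, band_high = 200)
  ww <- welch_psd(x, cfgw)
  total <- sum(diff(ww$freq) * (ww$psd[-1] + ww$psd[-length(ww$psd)]) / 2)
  expect_lt(abs(total - 4) / 4, 0.10)
  # degenerate inputs
  expect_identical(welch_psd(rep(0, 5000), cfg)$psd, rep(0, 2001))
  expect_error(welch_psd(rnorm(100), cfg), "shorter than one Welch segment")
})

test_that("alpha summary extracts peak, dominant frequency and sub-bands", {
  cfg <- spectral_config()
  freq <- seq(0, 40, by = 0.25)
  # flat spectrum: every 1-Hz sub-band integrates to the level, ties at the
  # band's low edge
  flat <- alpha_summary(freq, rep(2.5, length(freq)), cfg)
  expect_identical(flat$peak_power, 2.5)
  expect_identical(flat$dominant_freq, 8)
  expect_equal(unname(flat$subband_powers), rep(2.5, 5))
  expect_named(flat$subband_powers,
               c("8-9Hz", "9-10Hz", "10-11Hz", "11-12Hz", "12-13Hz"))
  # two equal maxima: the smaller frequency wins
  psd2 <- rep(1, length(freq)); psd2[freq == 9] <- 5; psd2[freq == 12] <- 5
  expect_identical(alpha_summary(freq, psd2, cfg)$dominant_freq, 9)
  # a single interior maximum is located exactly
  psd3 <- exp(-(freq - 10)^2)
  expect_identical(alpha_summary(freq, psd3, cfg)$dominant_freq, 10)
  expect_error(alpha_summary(seq(0, 6, 0.25), rep(1, 25), cfg),
               "does not cover")
})

test_that("sub-band powers tile the alpha band and scale linearly", {
  cfg <- spectral_config()
  freq <- seq(0, 40, by = 0.25)
  set.seed(51)
  psd <- abs(stats::filter(rexp(length(freq)), rep(1 / 5, 5),
                           circular = TRUE))
  sm <- alpha_summary(freq, psd, cfg)
  idx <- freq >= 8 & freq <= 13
  total <- sum(diff(freq[idx]) * (psd[idx][-1] + psd[idx][-sum(idx)]) / 2)
  expect_equal(sum(sm$subband_powers), total, tolerance = 1e-9)
  sm3 <- alpha_summary(freq, 3 * psd, cfg)
  expect_equal(sm3$peak_power, 3 * sm$peak_power)
  expect_equal(unname(sm3$subband_powers), 3 * unname(sm$subband_powers))
  expect_identical(sm3$dominant_freq, sm$dominant_freq)
})

test_that("repeat-averaged analysis equals the mean of per-repeat spectra", {
  sim <- run_repeats(model_parameters(), quick_sim(duration = 7,
                                                   n_repeats = 3))
  sm <- analyze_simulation(sim, keep_repeats = TRUE)
  expect_identical(sm$psd, rowMeans(sm$psd_repeats))
  expect_identical(ncol(sm$psd_repeats), 3L)
  expect_gte(sm$dominant_freq, 8)
  expect_lte(sm$dominant_freq, 13)
  expect_error(analyze_simulation(sim, spectral_config(fs = 250)),
               "sampling rate")
})
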