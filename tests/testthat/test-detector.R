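test_that("clean synthetic beats are detected exactly, with no extras", {
  s <- synth_single_ecg(120, 10, 500, role = "maternal", seed = 1)
  det <- detect_r_peaks(s$signal, 500, detector_config("gaus1"))
  m <- match_peaks(det, s$track, tolerance_ms = 10)
  expect_equal(m$tp, length(s$track$indices))
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
})

test_that("degenerate inputs give empty tracks or errors", {
  expect_length(detect_r_peaks(numeric(1000), 500, detector_config()), 0)
  expect_error(detect_r_peaks(numeric(100), 500, detector_config()), "1 s")
})

test_that("detection is invariant to positive amplitude scaling", {
  s <- synth_single_ecg(90, 10, 500, seed = 2)
  cfg <- detector_config("gaus1")
  d1 <- detect_r_peaks(s$signal, 500, cfg)
  d2 <- detect_r_peaks(0.05 * s$signal, 500, cfg)
  d3 <- detect_r_peaks(40 * s$signal, 500, cfg)
  expect_identical(d1$indices, d2$indices)
  expect_identical(d1$indices, d3$indices)
})

test_that("output is strictly increasing with refractory spacing", {
  sim <- get_sim(30, 2)
  filt <- get_filtered(30, 2)
  cfg <- detector_config("gaus1", refractory_s = 0.33)
  det <- detect_r_peaks(filt$channels[, 1], 500, cfg)
  expect_true(all(diff(det$indices) > 0))
  expect_true(all(diff(det$indices) >= round(0.33 * 500)))
})

test_that("modulus pairs wider than the pairing limit emit no peak", {
  # a 3 Hz tone: CWT extrema alternate every ~167 ms, beyond the 120 ms limit
  t <- (0:4999) / 500
  slow <- sin(2 * pi * 3 * t)
  det <- detect_r_peaks(slow, 500, detector_config("gaus1"))
  expect_length(det, 0)
  # a 10 Hz tone pairs at ~50 ms and is detected
  fast <- sin(2 * pi * 10 * t)
  det2 <- detect_r_peaks(fast, 500, detector_config("gaus1"))
  expect_gt(length(det2), 0)
  # shrinking the pairing limit below the modulus separation silences it
  det3 <- detect_r_peaks(fast, 500, detector_config("gaus1", pairing_limit_ms = 10))
  expect_length(det3, 0)
})

test_that("gaussian wavelets at levels 4-5 keep jitter within the refinement window", {
  s <- synth_single_ecg(110, 10, 500, role = "maternal", seed = 4)
  for (w in paste0("gaus", 1:8)) {
    for (lev in c(4, 5)) {
      det <- detect_r_peaks(s$signal, 500, detector_config(w, level = lev))
      m <- match_peaks(det, s$track, tolerance_ms = 25)
      expect_equal(m$fn, 0, label = sprintf("%s level %d", w, lev))
      if (nrow(m$pairs))
        expect_lte(max(abs(m$pairs[, 1] - m$pairs[, 2])), round(0.025 * 500))
    }
  }
})

test_that("detector config validates its arguments", {
  expect_error(detector_config(threshold_fraction = 1.2), "threshold_fraction")
  expect_error(detector_config(pairing_limit_ms = 0), "pairing_limit_ms")
  expect_error(detector_config(refractory_s = -1), "refractory_s")
  expect_error(detector_config("nope99"), "unknown wavelet")
})
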