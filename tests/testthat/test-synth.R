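test_that("generation is deterministic under a seed and leaves the RNG alone", {
  a <- mix_aecg(synth_config(duration_s = 10, seed = 5))
  set.seed(99); before <- .Random.seed
  b <- mix_aecg(synth_config(duration_s = 10, seed = 5))
  expect_identical(before, .Random.seed)   # generator restored global RNG state
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$truth$maternal$indices, b$truth$maternal$indices)
  c <- mix_aecg(synth_config(duration_s = 10, seed = 6))
  expect_false(identical(a$recording$channels, c$recording$channels))
})

test_that("beat counts follow duration * HR / 60", {
  s <- synth_single_ecg(80, 60, 500, seed = 2)
  expect_gte(length(s$track$indices), 79)
  expect_lte(length(s$track$indices), 81)
  expect_error(synth_single_ecg(-10, 10, 500), "config error")
  # zero jitter: beat count identical across seeds
  n1 <- length(synth_single_ecg(100, 30, 500, hr_jitter = 0, seed = 1)$track$indices)
  n2 <- length(synth_single_ecg(100, 30, 500, hr_jitter = 0, seed = 77)$track$indices)
  expect_identical(n1, n2)
})

test_that("annotated R apices sit on the waveform peaks", {
  s <- synth_single_ecg(120, 10, 500, seed = 3)
  for (a in s$track$indices) {
    win <- (max(1, a - 10)):(min(length(s$signal), a + 10))
    expect_lte(abs(win[which.max(s$signal[win])] - a), 1)
  }
})

test_that("components reconstruct the mixture exactly", {
  sim <- get_sim(10, 5)
  expect_equal(sim$recording$channels,
               sim$truth$maternal_components + sim$truth$fetal_components +
                 sim$truth$noise_components,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a noise-free, fetal-free mixture is purely maternal", {
  cfg <- synth_config(duration_s = 8, noise_sd = 0, baseline_uv = 0,
                      fetal_amplitude_ratio = 0, fetal_gains = c(0, 0, 0, 0),
                      seed = 4)
  sim <- mix_aecg(cfg)
  expect_equal(sim$recording$channels, sim$truth$maternal_components,
               ignore_attr = TRUE)
})

test_that("the configured fetal-to-maternal amplitude ratio is realized", {
  cfg <- synth_config(duration_s = 30, seed = 8, noise_sd = 0.5)
  sim <- mix_aecg(cfg)
  for (ch in 1:4) {
    m_amp <- stats::median(abs(sim$truth$maternal_components[sim$truth$maternal$indices, ch]))
    f_amp <- stats::median(abs(sim$truth$fetal_components[sim$truth$fetal$indices, ch]))
    target <- cfg$fetal_amplitude_ratio * cfg$fetal_gains[ch] / cfg$maternal_gains[ch]
    expect_lt(abs(f_amp / m_amp - target) / target, 0.1)
  }
})

test_that("config validation catches impossible settings", {
  expect_error(synth_config(duration_s = 1), "exceed 2 s")
  expect_error(synth_config(maternal_hr_bpm = 0), "config error")
  expect_warning(synth_config(fetal_gains = c(0, 0, 0, 0)), "config warning")
  expect_error(synth_config(maternal_gains = c(1, 1)), "equal length")
})

test_that("amplitude modulation makes scaling methods beat the plain template", {
  for (seed in 1:5) {
    sim <- get_sim(30, seed)
    filt <- get_filtered(30, seed)
    other <- apply_bandpass(recording(
      sim$truth$fetal_components + sim$truth$noise_components, 500))
    leftover <- sapply(c("ts", "ts_sf", "sa"), function(m) {
      fit <- fecg_ts(filt$channels[, 1], sim$truth$maternal, 500, m)
      win <- fecgx:::in_window_mask(fit)
      sum((residuals(fit)[win] - other$channels[win, 1])^2)
    })
    expect_lt(leftover[["ts_sf"]], leftover[["ts"]])
    expect_lt(leftover[["sa"]], leftover[["ts"]])
  }
})
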