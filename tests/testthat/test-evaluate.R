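tr <- function(idx, fs = 500) annotation_track(idx, fs, kind = "fetal")

test_that("the +-50 ms rule classifies pairs as TP / FP / FN", {
  m1 <- match_peaks(tr(1020), tr(1000), 50)       # 40 ms
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1, 0, 0))
  m2 <- match_peaks(tr(1030), tr(1000), 50)       # 60 ms
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  m3 <- match_peaks(tr(1025), tr(1000), 50)       # exactly 50 ms: inclusive
  expect_equal(m3$tp, 1)
  # tie at 20 ms from two references: earlier reference wins
  m4 <- match_peaks(tr(1010), tr(c(1000, 1020)), 50)
  expect_equal(c(m4$tp, m4$fn, m4$fp), c(1, 1, 0))
  expect_equal(unname(m4$pairs[1, "reference"]), 1000)
  expect_error(match_peaks(tr(100, 500), tr(100, 250)), "sampling rates")
})

test_that("greedy matching equals the exhaustive optimum on random tracks", {
  set.seed(123)
  for (i in 1:500) {
    p <- random_track_pair(tol = 25)
    if (!length(p$ref) || !length(p$det)) {
      expect_equal(match_peaks(tr(pmax(p$det, 1)), tr(pmax(p$ref, 1)), 50)$tp, 0)
      next
    }
    got <- match_peaks(tr(p$det), tr(p$ref), 50)$tp
    expect_equal(got, brute_force_tp(p$ref, p$det, 25))
  }
})

test_that("SE, PPV and F1 follow their defining ratios", {
  m <- compute_metrics(list(tp = 9, fp = 1, fn = 1))
  expect_equal(c(m$se, m$ppv, m$f1), c(90, 90, 90))
  m2 <- compute_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(c(m2$se, m2$ppv, m2$f1), c(0, 0, 0))
  expect_true(m2$degenerate)
  m3 <- compute_metrics(list(tp = 7, fp = 0, fn = 0))
  expect_equal(c(m3$se, m3$ppv, m3$f1), c(100, 100, 100))
  m4 <- compute_metrics(list(tp = 8, fp = 2, fn = 4))
  expect_equal(m4$f1, 2 * m4$se * m4$ppv / (m4$se + m4$ppv))
})

test_that("pipeline matches keep the count identities", {
  sim <- get_sim(30, 2)
  rep <- run_pipeline(sim$recording, sim$truth$fetal, method = "ts")
  for (ch in 1:4) {
    m <- match_peaks(rep$fetal_tracks[[ch]], sim$truth$fetal, 50)
    expect_equal(m$tp + m$fn, length(sim$truth$fetal$indices))
    expect_equal(m$tp + m$fp, length(rep$fetal_tracks[[ch]]$indices))
    expect_equal(m$tp, NROW(m$pairs))
  }
})

test_that("best channel maximizes F1 with ties to the earlier channel", {
  b <- benchmark_f1()
  sa_r1 <- subset(b, dataset == "labour" & method == "sa" & recording == "r1")
  got <- best_channel(stats::setNames(sa_r1$f1, sa_r1$channel))
  expect_equal(got$channel, "4")
  expect_equal(got$f1, 99.45)
  expect_equal(best_channel(c(a = 77))$channel, "a")
  expect_equal(best_channel(c(x = 90, y = 90, z = 80))$channel, "x")
  expect_error(best_channel(numeric(0)), "no channels")
})

test_that("aggregation is the plain arithmetic mean", {
  expect_equal(aggregate_mean(rep(42.5, 7)), 42.5)
  expect_equal(aggregate_mean(c(90, 100)), 95)
  expect_error(aggregate_mean(numeric(0)), "empty")
})

test_that("quality classes split at 80 and 90", {
  expect_equal(as.character(classify_quality(60.91)), "low")
  expect_equal(as.character(classify_quality(84.30)), "medium")
  expect_equal(as.character(classify_quality(95.08)), "high")
  expect_equal(as.character(classify_quality(c(80, 90, 100, 0))),
               c("medium", "high", "high", "low"))
  expect_error(classify_quality(101), "within")
})

test_that("amplitude change reads beat apices around the annotations", {
  fs <- 500
  x <- numeric(3000)
  peaks <- c(500, 1200, 1900, 2600)
  x[peaks] <- 20
  y <- numeric(3000)
  y[peaks + 3] <- -15    # shifted within 10 ms, negative polarity
  res <- amplitude_change(x, y, tr(peaks), fs)
  expect_equal(res$mean_aecg, 20)
  expect_equal(res$mean_fecg, 15)
  expect_equal(res$difference, 5)
  same <- amplitude_change(x, x, tr(peaks), fs)
  expect_equal(same$difference, 0)
  expect_warning(amplitude_change(x, y, tr(c(peaks, 4000)), fs), "skipped")
})

test_that("heart-rate estimation, smoothing and error behave as documented", {
  fs <- 500
  beats <- tr(seq(250, 5250, by = 250))   # constant RR of 0.5 s
  s <- estimate_fhr(beats, fs)
  expect_true(all(s$bpm == 120))
  expect_equal(s$times, beats$indices[-1] / fs)
  expect_equal(smooth_fhr(s)$bpm, s$bpm)         # constant: identity
  expect_equal(fhr_error(s, s)$error_bpm, rep(0, length(s$bpm)))
  expect_length(estimate_fhr(tr(100), fs)$bpm, 0)
  # smoothing shrinks the window at the edges
  s2 <- structure(list(times = 1:6, bpm = c(100, 130, 100, 130, 100, 130)),
                  class = "fhr_series")
  sm <- smooth_fhr(s2, 5)
  expect_equal(sm$bpm[1], 100)
  expect_equal(sm$bpm[3], mean(c(100, 130, 100, 130, 100)))
})

test_that("the wavelet benchmark sweeps wavelets over the corpus", {
  sim1 <- get_sim(15, 11)
  sim2 <- get_sim(15, 12)
  entry <- function(sim, g) list(recording = apply_bandpass(sim$recording),
                                 maternal = sim$truth$maternal,
                                 fetal_ref = sim$truth$fetal, group = g)
  corpus <- list(entry(sim1, "a"), entry(sim2, "b"))
  tab <- wavelet_benchmark(corpus, c("gaus1", "gaus3"), method = "ts")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$wavelet, c("gaus1", "gaus3"))
  expect_true(all(c("mean_f1_a", "mean_f1_b", "mean_f1") %in% names(tab)))
  expect_true(all(tab$ok))
  expect_true(all(tab$mean_f1 >= 0 & tab$mean_f1 <= 100))
  # corpus order must not matter
  tab2 <- wavelet_benchmark(rev(corpus), c("gaus1", "gaus3"), method = "ts")
  expect_equal(tab2$mean_f1, tab$mean_f1)
  # unresolvable wavelets are flagged, not fatal
  expect_warning(tab3 <- wavelet_benchmark(corpus[1], c("gaus1", "qqq9")),
                 "skipped")
  expect_equal(tab3$ok, c(TRUE, FALSE))
  expect_true(is.na(tab3$mean_f1[2]))
})
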