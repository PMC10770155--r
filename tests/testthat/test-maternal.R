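test_that("PCA on rank-1 input concentrates variance in the first component", {
  base <- sin((1:2000) / 8)
  rec <- recording(cbind(base, base, base, base) +
                     matrix(rnorm(8000, sd = 1e-6), ncol = 4), 500)
  p <- pca_decompose(rec)
  expect_gt(p$explained_variance[1] / sum(p$explained_variance), 0.999)
})

test_that("components are uncorrelated and complete", {
  filt <- get_filtered(30, 2)
  p <- pca_decompose(filt)
  cc <- stats::cor(p$components)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-9))
  centred <- scale(filt$channels, center = TRUE, scale = FALSE)
  expect_equal(p$components %*% t(p$loadings), unclass(centred),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(pca_decompose(recording(matrix(5, 100, 3), 500)), "degenerate")
  expect_error(pca_decompose(recording(matrix(rnorm(100), 100, 1), 500)),
               "at least 2")
})

test_that("maternal detection picks the maternal component on mixed channels", {
  sim <- get_sim(60, 1)
  filt <- get_filtered(60, 1)
  tr <- detect_maternal(filt)
  expect_equal(length(tr$indices), length(sim$truth$maternal$indices))
  m <- compute_metrics(match_peaks(tr, sim$truth$maternal, 50))
  expect_equal(m$f1, 100)
})

test_that("selection is invariant to channel order", {
  filt <- get_filtered(30, 2)
  perm <- recording(filt$channels[, c(3, 1, 4, 2)], filt$fs)
  expect_identical(detect_maternal(filt)$indices, detect_maternal(perm)$indices)
})

test_that("a maternal-only recording yields ~HR * duration / 60 beats", {
  m <- synth_single_ecg(80, 30, 500, role = "maternal", seed = 9)
  rec <- recording(cbind(1.0 * m$signal + rnorm(15000, sd = 1),
                         0.7 * m$signal + rnorm(15000, sd = 1)), 500)
  tr <- detect_maternal(apply_bandpass(rec))
  expect_lt(abs(length(tr$indices) - 80 * 30 / 60), 3)
})

test_that("the selection rule prefers fewer peaks, non-empty, then PC1", {
  sel <- fecgx:::select_maternal_track
  t_a <- annotation_track(c(500, 1000, 1500), 500, kind = "maternal")
  t_b <- annotation_track(c(500, 1000), 500, kind = "maternal")
  t_empty <- annotation_track(integer(0), 500, kind = "maternal")
  expect_identical(sel(t_a, t_b), t_b)       # fewer peaks wins
  expect_identical(sel(t_b, t_a), t_b)
  expect_identical(sel(t_a, t_a), t_a)       # tie -> first component
  expect_identical(sel(t_a, t_empty), t_a)   # empty never wins
  expect_identical(sel(t_empty, t_a), t_a)
  expect_error(sel(t_empty, t_empty), "detection failure")
})
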