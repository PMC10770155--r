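test_that("beat windows follow the 0.25/0.45 s rule", {
  x <- as.numeric(1:5000)
  tr <- annotation_track(c(100, 2001, 3000), 500, kind = "maternal")
  bm <- segment_beats(x, tr, 500)
  expect_equal(bm$pre, 125)
  expect_equal(bm$post, 225)
  expect_equal(ncol(bm$beats), 350)
  # anchor 2001 (1-based) covers samples 1876..2225, R at offset 126
  expect_equal(bm$beats[1, ], x[1876:2225])
  expect_equal(bm$beats[1, 126], 2001)
  # anchor 100 would start before the signal: invalid, no row
  expect_equal(bm$valid, c(FALSE, TRUE, TRUE))
  expect_equal(nrow(bm$beats), 2)
  expect_error(segment_beats(x, annotation_track(10, 500), 500),
               "segmentation error")
})

test_that("the template is the element-wise median of the beats", {
  v <- sin((1:350) / 20)
  w <- cos((1:350) / 15)
  mk <- function(rows) {
    bm <- list(beats = do.call(rbind, rows), anchors = integer(0),
               valid = logical(0), pre = 125, post = 225, fs = 500)
    class(bm) <- "beat_matrix"
    bm
  }
  expect_equal(build_template(mk(list(v, v, v)))$tecg, v)
  # median of {v, v, w} is v in every column (the duplicated value)
  expect_equal(build_template(mk(list(v, v, w)))$tecg, v)
  # odd-count median of {0, 2v, v} is v whatever the sign of v
  expect_equal(build_template(mk(list(0 * v, 2 * v, v)))$tecg, v)
  expect_error(build_template(mk(list())), "empty")
})

test_that("template segments partition the window as P | QRS | T", {
  segs <- fecgx:::template_segments(350, 500)
  expect_equal(segs$P, 1:100)        # 0 - 0.2 s
  expect_equal(segs$QRS, 101:150)    # 0.2 - 0.3 s
  expect_equal(segs$T, 151:350)      # 0.3 - 0.7 s
  expect_equal(sort(c(segs$P, segs$QRS, segs$T)), 1:350)
})

test_that("adaptation identities hold exactly", {
  set.seed(21)
  L <- 350
  v <- sin((1:L) / 12); w <- cos((1:L) / 9)
  tmpl <- structure(list(tecg = v, segments = fecgx:::template_segments(L, 500),
                         fs = 500), class = "tecg_template")

  # none
  expect_equal(adapt_none(tmpl, w)$tecg_adapted, v)

  # svd: full rank reproduces a stored beat; rank-1 handles scaling;
  # orthogonal beats project to zero
  bm <- list(beats = rbind(v, w, v + w, rnorm(L)), pre = 125, post = 225, fs = 500)
  class(bm) <- "beat_matrix"
  full <- adapt_svd(bm, w, k = 4)
  expect_lt(sqrt(sum((full$tecg_adapted - w)^2) / sum(w^2)), 1e-9)
  bm1 <- list(beats = rbind(v, v, v), pre = 125, post = 225, fs = 500)
  class(bm1) <- "beat_matrix"
  expect_equal(adapt_svd(bm1, 3 * v, k = 1)$tecg_adapted, 3 * v, tolerance = 1e-9)
  orth <- w - v * sum(v * w) / sum(v * v)
  expect_lt(max(abs(adapt_svd(bm1, orth, k = 1)$tecg_adapted)), 1e-9)
  expect_error(adapt_svd(bm1, v, k = 9), "config error")

  # lp: 1-D least squares, exact fit in the span, orthogonal -> zero
  lp1 <- adapt_lp(rbind(v), 2 * v, ridge = 1e-14)
  expect_equal(lp1$params$lambda, 2, tolerance = 1e-6)
  expect_equal(lp1$tecg_adapted, 2 * v, tolerance = 1e-6)
  lp2 <- adapt_lp(rbind(v, w), 0.5 * v + 0.5 * w, ridge = 1e-14)
  expect_equal(lp2$params$lambda, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(lp2$tecg_adapted, 0.5 * v + 0.5 * w, tolerance = 1e-6)
  expect_lt(max(abs(adapt_lp(rbind(v), orth, ridge = 1e-14)$tecg_adapted)), 1e-6)
  expect_warning(res <- adapt_lp(NULL, v, template = tmpl), "history")
  expect_equal(res$tecg_adapted, v)

  # sf: exact ratio, zero for orthogonal input, unit factor + orthogonal residual
  expect_equal(adapt_sf(tmpl, 3 * v)$params$alpha, 3)
  expect_equal(adapt_sf(tmpl, 3 * v)$tecg_adapted, 3 * v)
  expect_equal(adapt_sf(tmpl, orth)$params$alpha, 0)
  sf <- adapt_sf(tmpl, v + orth)
  expect_equal(sf$params$alpha, 1, tolerance = 1e-12)
  expect_lt(abs(sum((v + orth - sf$tecg_adapted) * v)), 1e-8)
  zt <- tmpl; zt$tecg <- numeric(L)
  expect_error(adapt_sf(zt, v), "degenerate")

  # sa: per-segment recovery and degenerate segment handling
  segs <- tmpl$segments
  beat <- v
  beat[segs$P] <- 2 * v[segs$P]
  beat[segs$QRS] <- 0.5 * v[segs$QRS]
  beat[segs$T] <- 1.5 * v[segs$T]
  sa <- adapt_sa(tmpl, beat)
  expect_equal(unlist(sa$params), c(P = 2, QRS = 0.5, T = 1.5), tolerance = 1e-12)
  expect_equal(sa$tecg_adapted, beat, tolerance = 1e-12)
  expect_equal(unlist(adapt_sa(tmpl, v)$params), c(P = 1, QRS = 1, T = 1),
               tolerance = 1e-12)
  tz <- tmpl; tz$tecg[segs$T] <- 0
  expect_warning(saz <- adapt_sa(tz, beat), "zero-norm")
  expect_equal(saz$params$T, 1)
  expect_equal(saz$params$P, 2, tolerance = 1e-12)
})

test_that("identical-beat trains are cancelled almost completely", {
  pb <- planted_beat_signal(rep(1, 12))
  for (method in c("ts", "ts_sf", "sa")) {
    fit <- fecg_ts(pb$signal, pb$track, pb$fs, method)
    win <- fecgx:::in_window_mask(fit)
    expect_lt(sqrt(mean(residuals(fit)[win]^2)) /
                sqrt(mean(pb$signal[win]^2)), 0.01, label = method)
  }
  # svd with k = n_beats removes everything in the beat subspace
  fit <- fecg_ts(pb$signal, pb$track, pb$fs, "ts_svd", svd_k = 12)
  win <- fecgx:::in_window_mask(fit)
  expect_lt(max(abs(residuals(fit)[win])), 1e-9)
})

test_that("samples outside the beat windows are never touched", {
  sim <- get_sim(30, 3)
  filt <- get_filtered(30, 3)
  x <- filt$channels[, 2]
  for (method in c("ts", "ts_svd", "ts_lp", "ts_sf", "sa")) {
    fit <- fecg_ts(x, sim$truth$maternal, 500, method)
    win <- fecgx:::in_window_mask(fit)
    expect_identical(residuals(fit)[!win], x[!win], label = method)
  }
})

test_that("sf leaves a residual orthogonal to the template in every window", {
  pb <- planted_beat_signal(c(1.2, 0.8, 1.1, 0.9, 1.05, 0.97, 1.3))
  noise <- sin((seq_along(pb$signal)) / 3) * 0.2   # deterministic interference
  fit <- fecg_ts(pb$signal + noise, pb$track, pb$fs, "ts_sf")
  t <- fit$template$tecg
  for (a in fit$anchors) {
    ix <- (a - 125):(a + 224)
    r <- residuals(fit)[ix]
    expect_lt(abs(sum(r * t)) / sqrt(sum(t^2)), 1e-8)
  }
})

test_that("sf recovers planted per-beat scale factors exactly (noise-free)", {
  scales <- c(1.15, 0.85, 1.05, 0.95, 1.2, 0.9, 1.0, 1.1)
  pb <- planted_beat_signal(scales)
  fit <- fecg_ts(pb$signal, pb$track, pb$fs, "ts_sf")
  alpha <- coef(fit)
  med <- stats::median(scales)
  expect_equal(alpha * med, scales, tolerance = 1e-6)
})

test_that("sa equals sf when the beat scales all segments equally", {
  scales <- c(1.2, 0.9, 1.07, 0.95, 1.02)
  pb <- planted_beat_signal(scales)
  sf <- fecg_ts(pb$signal, pb$track, pb$fs, "ts_sf")
  sa <- fecg_ts(pb$signal, pb$track, pb$fs, "sa")
  expect_equal(residuals(sa), residuals(sf), tolerance = 1e-9)
  expect_equal(unname(coef(sa)[, "QRS"]), coef(sf), tolerance = 1e-9)
})

test_that("lp reproduces a beat lying in the span of its history", {
  # beats alternate between two shapes; from the third beat on, the current
  # beat is an exact combination of the previous ones
  pb <- planted_beat_signal(rep(c(1, 1.3), 5))
  fit <- fecg_ts(pb$signal, pb$track, pb$fs, "ts_lp", lp_ridge = 1e-12)
  win_res <- vapply(seq_along(fit$anchors), function(i) {
    a <- fit$anchors[i]
    max(abs(residuals(fit)[(a - 125):(a + 224)]))
  }, numeric(1))
  expect_lt(max(win_res[-1]), 1e-6)   # every beat after the first
})

test_that("the fit object carries coherent metadata and methods", {
  sim <- get_sim(30, 3)
  filt <- get_filtered(30, 3)
  fit <- fecg_ts(filt$channels[, 1], sim$truth$maternal, 500, "sa")
  expect_s3_class(fit, "fecg_ts")
  expect_equal(residuals(fit) + fitted(fit), fit$input, tolerance = 1e-12)
  expect_equal(dim(coef(fit)), c(length(fit$anchors), 3))
  s <- summary(fit)
  expect_gt(s$energy_reduction, 0.9)
  expect_output(print(fit), "energy reduction")
  expect_error(fecg_ts(filt$channels[, 1], sim$truth$maternal, 500, "bogus"))
})
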