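#' Pipeline configuration
#'
#' Bundles every tunable setting of the extraction experiment with the
#' reference defaults: 5-70 Hz order-500 FIR band-pass, `gaus1` maternal
#' and `gaus3` fetal detector wavelets at level 5, 120 ms modulus pairing,
#' +-50 ms evaluation tolerance, 0.25/0.45 s beat windows, quality
#' thresholds 80/90%, and 5-beat heart-rate smoothing.
#'
#' @param bandpass_low,bandpass_high,bandpass_order FIR band-pass design.
#' @param maternal_detector,fetal_detector [detector_config()]s per role.
#' @param svd_k,lp_m,lp_ridge template adaptation settings (see
#'   [fecg_ts()]).
#' @param pre_s,post_s beat window, seconds.
#' @param tolerance_ms beat-matching tolerance.
#' @param quality_thresholds `c(low_upper, medium_upper)` F1 boundaries.
#' @param fhr_smooth_window heart-rate moving-average window, beats.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(bandpass_low = 5, bandpass_high = 70,
                            bandpass_order = 500,
                            maternal_detector = detector_config("gaus1",
                                                                refractory_s = 0.33),
                            fetal_detector = detector_config("gaus3",
                                                             refractory_s = 0.25),
                            svd_k = 3L, lp_m = 10L, lp_ridge = 1e-8,
                            pre_s = 0.25, post_s = 0.45,
                            tolerance_ms = 50,
                            quality_thresholds = c(80, 90),
                            fhr_smooth_window = 5L) {
  if (pre_s <= 0 || post_s <= 0) stop("beat window durations must be > 0")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full extraction experiment on one recording
#'
#' The experiment flow: band-pass preprocessing of all channels, maternal
#' R-peak detection on the principal components, per-channel fECG
#' extraction with the requested template-subtraction method, fetal R-peak
#' detection on each extracted channel, evaluation against the fetal
#' reference (when given), and best-channel selection by F1.
#'
#' @param rec a [recording()] (raw; preprocessing is applied here).
#' @param fetal_ref optional [annotation_track()] of reference fetal
#'   R-peaks; metrics are omitted without it.
#' @param method extraction method (see [fecg_ts()]).
#' @param cfg a [pipeline_config()].
#' @param maternal optional externally supplied maternal track; detected
#'   from the recording when `NULL`.
#' @return An object of class `"run_report"`: list with `method`,
#'   `maternal` (track used), `extracted` (matrix, one column per
#'   channel), `fetal_tracks` (list per channel), `metrics` (list of
#'   [compute_metrics()] per channel, or `NULL`), `f1` (named vector),
#'   `best` (list channel/f1), `quality` (factor), `fhr` (per-channel
#'   smoothed [estimate_fhr()] series), `config`, `log` (character).
#' @export
run_pipeline <- function(rec, fetal_ref = NULL,
                         method = c("sa", "ts", "ts_svd", "ts_lp", "ts_sf"),
                         cfg = pipeline_config(), maternal = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "recording"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  spec <- design_bandpass(rec$fs, cfg$bandpass_low, cfg$bandpass_high,
                          cfg$bandpass_order)
  filt <- apply_bandpass(rec, spec)
  note("band-pass %g-%g Hz applied to %d channel(s)",
       cfg$bandpass_low, cfg$bandpass_high, n_channels(rec))

  if (is.null(maternal)) {
    maternal <- detect_maternal(filt, cfg$maternal_detector)
    note("maternal detection: %d beats", length(maternal$indices))
  } else {
    check_track_in_recording(maternal, rec)
    note("maternal track supplied externally: %d beats",
         length(maternal$indices))
  }

  n_ch <- n_channels(rec)
  extracted <- matrix(0, n_samples(rec), n_ch,
                      dimnames = list(NULL, rec$channel_ids))
  fetal_tracks <- vector("list", n_ch)
  names(fetal_tracks) <- rec$channel_ids
  for (ch in seq_len(n_ch)) {
    fit <- fecg_ts(filt$channels[, ch], maternal, rec$fs, method,
                   svd_k = cfg$svd_k, lp_m = cfg$lp_m, lp_ridge = cfg$lp_ridge,
                   pre_s = cfg$pre_s, post_s = cfg$post_s)
    extracted[, ch] <- residuals(fit)
    fetal_tracks[[ch]] <- detect_r_peaks(extracted[, ch], rec$fs,
                                         cfg$fetal_detector, kind = "fetal")
    note("channel %s: %d fetal beats detected (%d maternal beats fitted)",
         rec$channel_ids[ch], length(fetal_tracks[[ch]]$indices),
         length(fit$anchors))
  }

  metrics <- f1 <- best <- quality <- NULL
  if (!is.null(fetal_ref)) {
    metrics <- lapply(fetal_tracks, function(tr)
      compute_metrics(match_peaks(tr, fetal_ref, cfg$tolerance_ms)))
    f1 <- vapply(metrics, function(m) m$f1, numeric(1))
    best <- best_channel(f1)
    quality <- classify_quality(f1)
    names(quality) <- names(f1)
    note("best channel %s (F1 = %.2f%%)", best$channel, best$f1)
  }

  fhr <- lapply(fetal_tracks, function(tr)
    smooth_fhr(estimate_fhr(tr, rec$fs), cfg$fhr_smooth_window))

  structure(
    list(method = method, maternal = maternal, extracted = extracted,
         fetal_tracks = fetal_tracks, metrics = metrics, f1 = f1,
         best = best, quality = quality, fhr = fhr, config = cfg, log = log),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("fECG extraction report (method '%s')\n", x$method))
  cat(sprintf("  maternal beats: %d (%s)\n", length(x$maternal$indices),
              x$maternal$provenance))
  for (ch in colnames(x$extracted)) {
    line <- sprintf("  %s: %d fetal beats", ch,
                    length(x$fetal_tracks[[ch]]$indices))
    if (!is.null(x$f1))
      line <- sprintf("%s, F1 = %.2f%% (%s quality)", line, x$f1[[ch]],
                      as.character(x$quality[[ch]]))
    cat(line, "\n")
  }
  if (!is.null(x$best))
    cat(sprintf("  best channel: %s (F1 = %.2f%%)\n", x$best$channel,
                x$best$f1))
  invisible(x)
}
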