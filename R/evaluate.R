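#' Match detected against reference R-peaks
#'
#' One-to-one greedy matching: all candidate pairs within the tolerance
#' (inclusive; 25 samples at 500 Hz for the standard +-50 ms rule) are
#' sorted by ascending time difference, ties broken by the earlier
#' reference peak, and consumed so that each peak is used at most once.
#' Matched pairs are true positives; leftover detected peaks are false
#' positives and leftover reference peaks false negatives.
#'
#' For tracks whose within-track spacing exceeds twice the tolerance (always
#' true for refractory-limited detectors at the 50 ms tolerance), this
#' greedy matching attains the maximum possible number of true positives.
#'
#' @param detected,reference [annotation_track()]s sharing one sampling
#'   rate.
#' @param tolerance_ms matching tolerance, milliseconds.
#' @return An object of class `"match_result"`: list with counts `tp`,
#'   `fp`, `fn`, a `pairs` matrix (columns `reference`, `detected`) and
#'   `tolerance_ms`.
#' @export
match_peaks <- function(detected, reference, tolerance_ms = 50) {
  stopifnot(inherits(detected, "annotation_track"),
            inherits(reference, "annotation_track"))
  if (detected$fs != reference$fs)
    stop("tracks have different sampling rates")
  tol <- tolerance_ms / 1000 * reference$fs
  det <- detected$indices
  ref <- reference$indices

  cand <- NULL
  if (length(det) && length(ref)) {
    grid <- expand.grid(r = seq_along(ref), d = seq_along(det))
    dt <- abs(ref[grid$r] - det[grid$d])
    ok <- dt <= tol
    cand <- cbind(r = grid$r[ok], d = grid$d[ok], dt = dt[ok])
    cand <- cand[order(cand[, "dt"], cand[, "r"]), , drop = FALSE]
  }
  used_r <- logical(length(ref))
  used_d <- logical(length(det))
  pairs <- NULL
  for (i in seq_len(NROW(cand))) {
    r <- cand[i, "r"]; d <- cand[i, "d"]
    if (!used_r[r] && !used_d[d]) {
      used_r[r] <- TRUE
      used_d[d] <- TRUE
      pairs <- rbind(pairs, c(reference = ref[r], detected = det[d]))
    }
  }
  tp <- sum(used_r)
  structure(
    list(tp = tp, fp = length(det) - tp, fn = length(ref) - tp,
         pairs = pairs, tolerance_ms = tolerance_ms),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FP %d, FN %d (+-%g ms)>\n",
              x$tp, x$fp, x$fn, x$tolerance_ms))
  invisible(x)
}

#' Detection metrics from a match result
#'
#' Sensitivity `SE = 100 TP / (TP + FN)`, positive predictive value
#' `PPV = 100 TP / (TP + FP)` and their harmonic mean
#' `F1 = 2 SE PPV / (SE + PPV)`, all in percent.  A degenerate 0/0 ratio
#' yields 0 and sets the `degenerate` flag so that batch summaries can
#' still be assembled.
#'
#' @param m a [match_peaks()] result, or a list with `tp`, `fp`, `fn`.
#' @return List of class `"detection_metrics"` with `se`, `ppv`, `f1`
#'   (percent) and `degenerate`.
#' @export
compute_metrics <- function(m) {
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      return(0)
    }
    100 * num / den
  }
  se <- ratio(m$tp, m$tp + m$fn)
  ppv <- ratio(m$tp, m$tp + m$fp)
  f1 <- if (se + ppv == 0) {
    degenerate <- TRUE
    0
  } else 2 * se * ppv / (se + ppv)
  structure(list(se = se, ppv = ppv, f1 = f1, degenerate = degenerate),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("SE %.2f%%  PPV %.2f%%  F1 %.2f%%%s\n", x$se, x$ppv, x$f1,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' Best channel by F1
#'
#' Picks the channel with the highest F1 value; ties go to the earlier
#' channel in the list.
#'
#' @param per_channel a named numeric vector of F1 values, or a list of
#'   `detection_metrics` (names = channel ids).
#' @return List with `channel` (name or index) and `f1`.
#' @export
best_channel <- function(per_channel) {
  if (!length(per_channel)) stop("no channels to choose from")
  f1 <- if (is.numeric(per_channel)) per_channel
        else vapply(per_channel, function(m) m$f1, numeric(1))
  k <- which.max(f1)   # which.max returns the first maximum: earlier channel
  list(channel = if (!is.null(names(f1))) names(f1)[k] else k,
       f1 = unname(f1[k]))
}

#' Mean of percentage scores
#'
#' Plain arithmetic mean of F1 (or other percentage) values; reporting
#' convention is two decimals, but the full-precision value is returned.
#'
#' @param values numeric vector of percentages.
#' @return The mean.
#' @export
aggregate_mean <- function(values) {
  if (!length(values)) stop("cannot aggregate an empty vector")
  mean(values)
}

#' Classify signal quality from F1
#'
#' Channels are binned by fetal detection F1: `low` below 80%, `medium`
#' from 80 to below 90%, `high` at 90% and above.
#'
#' @param f1 F1 value(s) in percent, within \[0, 100\].
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_quality <- function(f1) {
  if (any(f1 < 0 | f1 > 100)) stop("F1 must be within [0, 100]")
  cut(f1, breaks = c(-Inf, 80, 90, Inf), labels = c("low", "medium", "high"),
      right = FALSE)
}

#' Fetal R-peak amplitude change through extraction
#'
#' Template subtraction can shave amplitude off fetal R-peaks that overlap
#' maternal beats.  For each reference fetal annotation the beat amplitude
#' is read as the largest-magnitude sample within +-10 ms of the
#' annotation, in both the input aECG channel and the extracted fECG;
#' the mean amplitudes and their difference quantify the attenuation.
#'
#' @param aecg,fecg numeric signals (input channel and extracted channel).
#' @param fetal_ref an [annotation_track()] of reference fetal R-peaks.
#' @param fs sampling rate in Hz.
#' @param window_ms half-width of the amplitude read-out window.
#' @return List with `mean_aecg`, `mean_fecg`, `difference` (microvolts)
#'   and `n_beats`.
#' @export
amplitude_change <- function(aecg, fecg, fetal_ref, fs, window_ms = 10) {
  stopifnot(inherits(fetal_ref, "annotation_track"))
  if (!length(fetal_ref$indices)) stop("empty fetal reference track")
  half <- round(window_ms / 1000 * fs)
  read_amp <- function(x, idx) {
    lo <- max(1L, idx - half)
    hi <- min(length(x), idx + half)
    seg <- x[lo:hi]
    abs(seg[which.max(abs(seg))])
  }
  ok <- fetal_ref$indices >= 1L & fetal_ref$indices <= length(aecg)
  if (!all(ok)) warning("annotations outside the signal were skipped")
  idx <- fetal_ref$indices[ok]
  amp_a <- vapply(idx, function(i) read_amp(aecg, i), numeric(1))
  amp_f <- vapply(idx, function(i) read_amp(fecg, i), numeric(1))
  list(mean_aecg = mean(amp_a), mean_fecg = mean(amp_f),
       difference = mean(amp_a) - mean(amp_f), n_beats = length(idx))
}

#' Fetal heart rate series from an annotation track
#'
#' Beat-to-beat heart rate `bpm_i = 60 fs / RR_i`, time-stamped at the
#' later peak of each interval.
#'
#' @param fetal an [annotation_track()] with at least two peaks.
#' @param fs sampling rate in Hz.
#' @return An object of class `"fhr_series"`: list with `times` (s) and
#'   `bpm`; empty when fewer than two peaks are available.
#' @export
estimate_fhr <- function(fetal, fs = fetal$fs) {
  stopifnot(inherits(fetal, "annotation_track"))
  idx <- fetal$indices
  if (length(idx) < 2L)
    return(structure(list(times = numeric(0), bpm = numeric(0)),
                     class = "fhr_series"))
  rr <- diff(idx)
  structure(
    list(times = idx[-1L] / fs, bpm = 60 * fs / rr),
    class = "fhr_series"
  )
}

#' Smooth a heart-rate series
#'
#' Centred moving average over `window` beats (default 5); the window
#' shrinks symmetrically at the series edges.
#'
#' @param s an [estimate_fhr()] series.
#' @param window window length in beats (odd).
#' @return A smoothed `"fhr_series"`.
#' @export
smooth_fhr <- function(s, window = 5L) {
  stopifnot(inherits(s, "fhr_series"))
  n <- length(s$bpm)
  if (n == 0L) return(s)
  half <- window %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(s$bpm[(i - h):(i + h)])
  }, numeric(1))
  structure(list(times = s$times, bpm = sm), class = "fhr_series")
}

#' Heart-rate error against a reference series
#'
#' Aligns each estimated point with the nearest-in-time reference point and
#' returns the signed difference (estimate minus reference).
#'
#' @param est,ref `"fhr_series"` objects.
#' @return List with `times` and `error_bpm`.
#' @export
fhr_error <- function(est, ref) {
  stopifnot(inherits(est, "fhr_series"), inherits(ref, "fhr_series"))
  if (!length(est$bpm) || !length(ref$bpm))
    return(list(times = numeric(0), error_bpm = numeric(0)))
  nearest <- vapply(est$times, function(t) which.min(abs(ref$times - t)),
                    integer(1))
  list(times = est$times, error_bpm = est$bpm - ref$bpm[nearest])
}

#' @export
print.fhr_series <- function(x, ...) {
  if (!length(x$bpm)) cat("<fhr_series: empty>\n")
  else cat(sprintf("<fhr_series: %d beats, %.0f-%.0f bpm>\n",
                   length(x$bpm), min(x$bpm), max(x$bpm)))
  invisible(x)
}

#' Benchmark mother wavelets for fetal R-peak detection
#'
#' Runs the full extraction + detection pipeline once per requested mother
#' wavelet (swapping the fetal detector's wavelet) over a corpus of
#' recordings with maternal annotations and fetal references, and reports
#' the mean F1 per corpus group and overall.  Rows follow registry order;
#' a wavelet that fails to resolve is kept as a flagged `NA` row with a
#' warning.
#'
#' @param corpus list of entries, each a list with elements `recording`
#'   (preprocessed [recording()]), `maternal` ([annotation_track()]),
#'   `fetal_ref` ([annotation_track()]) and optionally `group` (character)
#'   and `id`.
#' @param wavelets character vector of wavelet names (default: the full
#'   registry).
#' @param method extraction method passed to [extract_fecg()].
#' @param cfg [pipeline_config()] supplying the remaining settings.
#' @return A data frame with one row per wavelet: `wavelet`, one mean-F1
#'   column per group, `mean_f1` (all corpus entries), `ok`.
#' @export
wavelet_benchmark <- function(corpus, wavelets = wavelet_registry(),
                              method = "ts", cfg = pipeline_config()) {
  if (!length(corpus)) stop("empty corpus")
  groups <- vapply(corpus, function(e) e$group %||% "all", character(1))
  res <- matrix(NA_real_, length(wavelets), length(corpus))
  ok <- logical(length(wavelets))
  for (wi in seq_along(wavelets)) {
    w <- wavelets[wi]
    f1s <- tryCatch({
      vapply(corpus, function(e) {
        per_channel_f1(e, method, cfg, fetal_wavelet = w)
      }, numeric(1))
    }, error = function(err) {
      warning("wavelet '", w, "' skipped: ", conditionMessage(err))
      NULL
    })
    if (!is.null(f1s)) {
      res[wi, ] <- f1s
      ok[wi] <- TRUE
    }
  }
  out <- data.frame(wavelet = wavelets, stringsAsFactors = FALSE)
  for (g in unique(groups))
    out[[paste0("mean_f1_", g)]] <- rowMeans(res[, groups == g, drop = FALSE])
  out$mean_f1 <- rowMeans(res)
  out$ok <- ok
  out
}

# mean F1 over the channels of one corpus entry for one fetal wavelet
per_channel_f1 <- function(entry, method, cfg, fetal_wavelet) {
  rec <- entry$recording
  fcfg <- cfg$fetal_detector
  fcfg$wavelet_name <- fetal_wavelet
  f1s <- vapply(seq_len(n_channels(rec)), function(ch) {
    y <- extract_fecg(rec$channels[, ch], entry$maternal, rec$fs, method,
                      svd_k = cfg$svd_k, lp_m = cfg$lp_m,
                      lp_ridge = cfg$lp_ridge)
    det <- detect_r_peaks(y, rec$fs, fcfg, kind = "fetal")
    compute_metrics(match_peaks(det, entry$fetal_ref, cfg$tolerance_ms))$f1
  }, numeric(1))
  mean(f1s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
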