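#' Detector configuration
#'
#' Settings of the CWT modulus-maxima R-peak detector.  The defaults encode
#' the reference configuration: CWT decomposition at scale level 5, modulus
#' pairs at most 120 ms apart, adaptive threshold at 30% of the largest
#' coefficient magnitude within each 2 s block, R-peak refinement within
#' +-25 ms of the zero crossing, and a physiological refractory period
#' (0.33 s for the maternal rhythm, i.e. a 182 bpm cap; 0.25 s = 240 bpm
#' for the fetal rhythm).
#'
#' @param wavelet_name mother wavelet (default `"gaus1"`, the maternal
#'   detector choice; the fetal detector uses `"gaus3"`).
#' @param level CWT scale (see [cwt_at_level()]).
#' @param pairing_limit_ms maximum separation of a modulus min/max pair.
#' @param refractory_s minimum spacing between emitted peaks, seconds.
#' @param threshold_fraction adaptive threshold as a fraction of the block
#'   maximum coefficient magnitude, in (0, 1).
#' @param threshold_window_s block length for the adaptive threshold.
#' @param refine_window_ms half-width of the refinement window around each
#'   zero crossing.
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(wavelet_name = "gaus1", level = 5L,
                            pairing_limit_ms = 120, refractory_s = 0.33,
                            threshold_fraction = 0.3, threshold_window_s = 2,
                            refine_window_ms = 25) {
  if (pairing_limit_ms <= 0) stop("pairing_limit_ms must be > 0")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  if (refractory_s <= 0) stop("refractory_s must be > 0")
  wavelet_family(wavelet_name)  # validates the name
  structure(
    list(wavelet_name = wavelet_name, level = level,
         pairing_limit_ms = pairing_limit_ms, refractory_s = refractory_s,
         threshold_fraction = threshold_fraction,
         threshold_window_s = threshold_window_s,
         refine_window_ms = refine_window_ms),
    class = "detector_config"
  )
}

#' Detect R-peaks with the CWT modulus-maxima detector
#'
#' The detection pipeline: (1) CWT coefficients at one scale
#' ([cwt_at_level()]); (2) local minima and maxima of the coefficients;
#' (3) adaptive thresholding -- an extremum survives if its coefficient
#' magnitude reaches `threshold_fraction` of the largest magnitude within
#' its `threshold_window_s` block; (4) a surviving positive maximum and
#' negative minimum separated by at most `pairing_limit_ms` form a modulus
#' pair; (5) the zero crossing of the coefficients between the pair
#' localizes the QRS; (6) the emitted index is the largest `abs(signal)`
#' sample within `refine_window_ms` of the crossing; (7) a refractory
#' period prunes candidates closer than `refractory_s`, keeping the
#' larger-amplitude one (the earlier on ties).
#'
#' @param x numeric signal (one channel, preprocessed).
#' @param fs sampling rate in Hz.
#' @param cfg a [detector_config()].
#' @param kind annotated rhythm kind for the returned track.
#' @return An [annotation_track()] with `provenance = "detected"`.
#' @examples
#' s <- synth_single_ecg(hr_bpm = 120, duration_s = 10, fs = 500, seed = 1)
#' det <- detect_r_peaks(s$signal, 500, detector_config("gaus1"))
#' @export
detect_r_peaks <- function(x, fs, cfg = detector_config(),
                           kind = c("maternal", "fetal")) {
  kind <- match.arg(kind)
  if (length(x) < fs) stop("signal must be at least 1 s long")
  cf <- cwt_at_level(x, fs, cfg$wavelet_name, cfg$level)

  ext <- local_extrema(cf)
  if (!length(ext$idx))
    return(annotation_track(integer(0), fs, kind = kind, provenance = "detected"))

  keep <- adaptive_threshold_keep(cf, ext$idx, cfg$threshold_fraction,
                                  round(cfg$threshold_window_s * fs))
  idx <- ext$idx[keep]
  typ <- ext$type[keep]
  if (!length(idx))
    return(annotation_track(integer(0), fs, kind = kind, provenance = "detected"))

  pair_limit <- round(cfg$pairing_limit_ms / 1000 * fs)
  refine_half <- round(cfg$refine_window_ms / 1000 * fs)
  n <- length(x)
  cand <- integer(0)
  i <- 1L
  while (i < length(idx)) {
    a <- idx[i]; b <- idx[i + 1L]
    opposite <- (typ[i] == 1L && cf[a] > 0 && typ[i + 1L] == -1L && cf[b] < 0) ||
      (typ[i] == -1L && cf[a] < 0 && typ[i + 1L] == 1L && cf[b] > 0)
    if (opposite && (b - a) <= pair_limit) {
      zc <- zero_crossing_between(cf, a, b)
      lo <- max(1L, zc - refine_half)
      hi <- min(n, zc + refine_half)
      cand <- c(cand, lo - 1L + which.max(abs(x[lo:hi])))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  cand <- unique(sort(cand))
  cand <- enforce_refractory(cand, abs(x[cand]), round(cfg$refractory_s * fs))
  annotation_track(cand, fs, kind = kind, provenance = "detected")
}

local_extrema <- function(cf) {
  n <- length(cf)
  if (n < 3L) return(list(idx = integer(0), type = integer(0)))
  mid <- 2:(n - 1L)
  is_max <- cf[mid] > cf[mid - 1L] & cf[mid] >= cf[mid + 1L]
  is_min <- cf[mid] < cf[mid - 1L] & cf[mid] <= cf[mid + 1L]
  idx <- mid[is_max | is_min]
  type <- ifelse(is_max[is_max | is_min], 1L, -1L)
  list(idx = idx, type = as.integer(type))
}

adaptive_threshold_keep <- function(cf, idx, fraction, window) {
  block <- pmin((idx - 1L) %/% window + 1L, max(1L, ceiling(length(cf) / window)))
  n_blocks <- ceiling(length(cf) / window)
  keep <- logical(length(idx))
  for (b in unique(block)) {
    lo <- (b - 1L) * window + 1L
    hi <- min(length(cf), b * window)
    thr <- fraction * max(abs(cf[lo:hi]))
    sel <- block == b
    keep[sel] <- abs(cf[idx[sel]]) >= thr
  }
  keep
}

zero_crossing_between <- function(cf, a, b) {
  seg <- cf[a:b]
  sgn <- sign(seg)
  flips <- which(sgn[-length(sgn)] * sgn[-1L] <= 0)
  if (!length(flips)) return(as.integer(round((a + b) / 2)))
  # crossing nearest the pair midpoint; pick the sample with smaller |cf|
  k <- flips[which.min(abs(flips - length(seg) / 2))]
  cross <- if (abs(seg[k]) <= abs(seg[k + 1L])) k else k + 1L
  a + cross - 1L
}

enforce_refractory <- function(idx, amp, min_gap) {
  if (length(idx) < 2L) return(idx)
  keep_idx <- idx[1L]
  keep_amp <- amp[1L]
  out <- list()
  for (j in 2:length(idx)) {
    if (idx[j] - keep_idx >= min_gap) {
      out[[length(out) + 1L]] <- keep_idx
      keep_idx <- idx[j]
      keep_amp <- amp[j]
    } else if (amp[j] > keep_amp) {   # tie keeps the earlier candidate
      keep_idx <- idx[j]
      keep_amp <- amp[j]
    }
  }
  out[[length(out) + 1L]] <- keep_idx
  unlist(out)
}
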