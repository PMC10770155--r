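#' Synthetic abdominal-ECG configuration
#'
#' Settings for the synthetic aECG generator, chosen to emulate the signal
#' regime of clinical abdominal recordings: a dominant maternal ECG around
#' 80 bpm, a fetal ECG an order of magnitude weaker (amplitude ratio 0.15)
#' around 140 bpm with overlapping spectrum, slow sinusoidal beat-to-beat
#' maternal amplitude modulation (depth 0.1 at 0.25 Hz, the respiratory
#' band), baseline wander below the 5 Hz filter edge, broadband white
#' noise, and an optional 50 Hz mains component (off by default, matching
#' recordings already notch-filtered upstream).
#'
#' @param fs sampling rate, Hz.
#' @param duration_s record length, seconds (> 2).
#' @param maternal_hr_bpm,fetal_hr_bpm mean heart rates.
#' @param hr_jitter relative standard deviation of each RR interval.
#' @param fetal_amplitude_ratio fetal-to-maternal R amplitude ratio before
#'   per-channel gains.
#' @param modulation_depth maternal beat amplitude modulation depth.
#' @param modulation_hz modulation frequency.
#' @param noise_sd white noise standard deviation, microvolts.
#' @param baseline_uv,baseline_hz baseline wander amplitude and frequency.
#' @param powerline_uv 50 Hz mains amplitude.
#' @param maternal_gains,fetal_gains per-channel gains (length = number of
#'   channels).
#' @param maternal_r_uv maternal R amplitude, microvolts.
#' @param seed integer RNG seed.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(fs = 500, duration_s = 60,
                         maternal_hr_bpm = 80, fetal_hr_bpm = 140,
                         hr_jitter = 0.02,
                         fetal_amplitude_ratio = 0.15,
                         modulation_depth = 0.1, modulation_hz = 0.25,
                         noise_sd = 2, baseline_uv = 20, baseline_hz = 0.3,
                         powerline_uv = 0,
                         maternal_gains = c(1.0, 0.8, 0.9, 0.7),
                         fetal_gains = c(0.9, 1.1, 0.7, 1.0),
                         maternal_r_uv = 100, seed = 1L) {
  if (duration_s <= 2) stop("duration must exceed 2 s")
  if (maternal_hr_bpm <= 0 || fetal_hr_bpm <= 0)
    stop("config error: heart rates must be positive")
  if (length(maternal_gains) != length(fetal_gains))
    stop("gain vectors must have equal length")
  if (fetal_amplitude_ratio > 0 && all(fetal_gains == 0))
    warning("config warning: fetal ratio > 0 but all fetal gains are 0")
  structure(as.list(environment()), class = "synth_config")
}

# P, Q, R, S, T gaussians: centre (s, relative to R), amplitude (relative
# to R), width (s).  The fetal morphology is compressed in time, as the
# fetal heart's depolarization intervals are shorter.
beat_morphology <- function(role = c("maternal", "fetal")) {
  role <- match.arg(role)
  if (role == "maternal") {
    list(centers = c(-0.17, -0.025, 0, 0.025, 0.22),
         amps = c(0.12, -0.14, 1, -0.22, 0.30),
         widths = c(0.025, 0.010, 0.011, 0.010, 0.055))
  } else {
    list(centers = c(-0.10, -0.016, 0, 0.016, 0.13),
         amps = c(0.10, -0.12, 1, -0.20, 0.25),
         widths = c(0.015, 0.007, 0.008, 0.007, 0.035))
  }
}

#' Synthesize a single-source ECG with ground-truth R-peaks
#'
#' Each beat is a sum of five Gaussians (P, Q, R, S, T) placed relative to
#' the R time; RR intervals are `60 / hr` seconds with multiplicative
#' jitter.  R apices fall exactly on the annotated samples.
#'
#' @param hr_bpm mean heart rate.
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz.
#' @param role `"maternal"` or `"fetal"` beat morphology.
#' @param r_amplitude R-peak amplitude (microvolts).
#' @param hr_jitter relative RR jitter standard deviation.
#' @param amplitude_modulation per-beat amplitude factors (recycled), e.g.
#'   from respiratory modulation; default none.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return List with `signal`, `track` (an [annotation_track()]),
#'   `beat_scale` (per-beat amplitude factors) and `fs`.
#' @export
synth_single_ecg <- function(hr_bpm, duration_s, fs = 500,
                             role = c("maternal", "fetal"),
                             r_amplitude = 100, hr_jitter = 0.02,
                             amplitude_modulation = NULL, seed = NULL) {
  role <- match.arg(role)
  if (hr_bpm <= 0) stop("config error: hr must be positive")
  if (!is.null(seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed))
    set.seed(seed)
  }
  n <- round(duration_s * fs)
  morph <- beat_morphology(role)
  mean_rr <- 60 / hr_bpm

  # R times: start after the window head, jittered RR steps
  t_r <- 0.4 * mean_rr
  r_times <- numeric(0)
  while (t_r < duration_s - 0.3 * mean_rr) {
    r_times <- c(r_times, t_r)
    t_r <- t_r + mean_rr * max(0.5, 1 + hr_jitter * stats::rnorm(1))
  }
  r_idx <- round(r_times * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  r_idx <- unique(r_idx)

  scale <- if (is.null(amplitude_modulation)) rep(1, length(r_idx))
           else rep_len(amplitude_modulation, length(r_idx))
  sig <- numeric(n)
  t_axis <- (seq_len(n) - 1) / fs
  for (b in seq_along(r_idx)) {
    t0 <- (r_idx[b] - 1) / fs
    lo <- max(1L, r_idx[b] - round(0.35 * fs))
    hi <- min(n, r_idx[b] + round(0.45 * fs))
    tt <- t_axis[lo:hi] - t0
    beat <- numeric(length(tt))
    for (g in seq_along(morph$centers)) {
      beat <- beat + morph$amps[g] *
        exp(-((tt - morph$centers[g]) / morph$widths[g])^2)
    }
    sig[lo:hi] <- sig[lo:hi] + r_amplitude * scale[b] * beat
  }
  list(signal = sig,
       track = annotation_track(r_idx, fs,
                                kind = if (role == "maternal") "maternal" else "fetal",
                                provenance = "reference"),
       beat_scale = scale, fs = fs)
}

#' Synthesize a multi-channel abdominal ECG with ground truth
#'
#' Mixes independent maternal and fetal ECG sources into the configured
#' number of channels: channel `c` equals
#' `maternal_gain[c] * mECG + fetal_gain[c] * fECG + noise`, where the
#' noise term is baseline wander + white noise + optional mains.  The
#' maternal source carries sinusoidal beat-to-beat amplitude modulation.
#' Clean per-channel components and both ground-truth tracks are returned,
#' so `recording - fetal - noise = maternal` holds exactly.
#'
#' @param cfg a [synth_config()].
#' @return List with `recording` (a [recording()]) and `truth` (list:
#'   `maternal`, `fetal` tracks; `maternal_components`, `fetal_components`,
#'   `noise_components` matrices; `maternal_scale` per-beat factors).
#' @examples
#' sim <- mix_aecg(synth_config(duration_s = 10, seed = 7))
#' sim$recording
#' @export
mix_aecg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)

  n <- round(cfg$duration_s * cfg$fs)
  n_ch <- length(cfg$maternal_gains)

  # maternal source with respiratory amplitude modulation per beat
  mean_rr_m <- 60 / cfg$maternal_hr_bpm
  approx_beats <- ceiling(cfg$duration_s / mean_rr_m) + 2L
  beat_times <- (seq_len(approx_beats) - 1) * mean_rr_m
  modulation <- 1 + cfg$modulation_depth *
    sin(2 * pi * cfg$modulation_hz * beat_times)
  m <- synth_single_ecg(cfg$maternal_hr_bpm, cfg$duration_s, cfg$fs,
                        role = "maternal", r_amplitude = cfg$maternal_r_uv,
                        hr_jitter = cfg$hr_jitter,
                        amplitude_modulation = modulation)
  f <- synth_single_ecg(cfg$fetal_hr_bpm, cfg$duration_s, cfg$fs,
                        role = "fetal",
                        r_amplitude = cfg$maternal_r_uv * cfg$fetal_amplitude_ratio,
                        hr_jitter = cfg$hr_jitter)

  t_axis <- (seq_len(n) - 1) / cfg$fs
  chans <- matrix(0, n, n_ch)
  m_comp <- matrix(0, n, n_ch)
  f_comp <- matrix(0, n, n_ch)
  noise_comp <- matrix(0, n, n_ch)
  for (c in seq_len(n_ch)) {
    m_comp[, c] <- cfg$maternal_gains[c] * m$signal
    f_comp[, c] <- cfg$fetal_gains[c] * f$signal
    wander <- cfg$baseline_uv *
      sin(2 * pi * cfg$baseline_hz * t_axis + stats::runif(1, 0, 2 * pi))
    mains <- if (cfg$powerline_uv > 0)
      cfg$powerline_uv * sin(2 * pi * 50 * t_axis + stats::runif(1, 0, 2 * pi))
    else 0
    white <- stats::rnorm(n, sd = cfg$noise_sd)
    noise_comp[, c] <- wander + mains + white
    chans[, c] <- m_comp[, c] + f_comp[, c] + noise_comp[, c]
  }

  list(
    recording = recording(chans, cfg$fs,
                          recording_id = sprintf("synth-seed%d", cfg$seed)),
    truth = list(maternal = m$track, fetal = f$track,
                 maternal_components = m_comp, fetal_components = f_comp,
                 noise_components = noise_comp,
                 maternal_scale = m$beat_scale)
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
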