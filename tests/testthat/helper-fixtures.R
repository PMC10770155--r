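# session-level cache of synthetic fixtures so several files can share them
.fixtures <- new.env(parent = emptyenv())

get_sim <- function(duration_s = 60, seed = 1) {
  key <- sprintf("sim_%g_%d", duration_s, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- mix_aecg(synth_config(duration_s = duration_s, seed = seed))
  .fixtures[[key]]
}

get_filtered <- function(duration_s = 60, seed = 1) {
  key <- sprintf("filt_%g_%d", duration_s, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- apply_bandpass(get_sim(duration_s, seed)$recording)
  .fixtures[[key]]
}

# beat train with planted per-beat scale factors: waveform w (zero outside
# the template window) placed at regular anchors
planted_beat_signal <- function(scales, fs = 500, rr_s = 0.75) {
  pre <- round(0.25 * fs); post <- round(0.45 * fs)
  L <- pre + post
  tt <- ((seq_len(L) - pre) - 1) / fs
  w <- exp(-(tt / 0.012)^2) - 0.3 * exp(-((tt - 0.12) / 0.04)^2) +
    0.15 * exp(-((tt + 0.15) / 0.03)^2)
  anchors <- pre + 1 + round((seq_along(scales) - 1) * rr_s * fs)
  n <- max(anchors) + post + 50
  x <- numeric(n)
  for (b in seq_along(scales)) {
    ix <- (anchors[b] - pre):(anchors[b] + post - 1)
    x[ix] <- x[ix] + scales[b] * w
  }
  list(signal = x, anchors = anchors, waveform = w, fs = fs,
       track = annotation_track(anchors, fs, kind = "maternal"))
}

# exhaustive maximum-cardinality matching (oracle for match_peaks)
brute_force_tp <- function(ref, det, tol) {
  rec <- function(ri, avail) {
    if (ri > length(ref)) return(0L)
    best <- rec(ri + 1L, avail)
    for (di in which(avail)) {
      if (abs(ref[ri] - det[di]) <= tol) {
        avail2 <- avail
        avail2[di] <- FALSE
        best <- max(best, 1L + rec(ri + 1L, avail2))
      }
    }
    best
  }
  if (!length(ref) || !length(det)) return(0L)
  rec(1L, rep(TRUE, length(det)))
}

# random annotation-track pair with physiological spacing (> 2 * tol even
# after per-peak jitter, as refractory-limited detectors guarantee)
random_track_pair <- function(tol = 25, n_max = 8) {
  one_track <- function() {
    n <- sample(0:n_max, 1)
    if (n == 0) return(integer(0))
    spacing <- 2 * tol + sample(25:150, 1)
    cumsum(c(sample(200:400, 1), rep(spacing, n - 1))) +
      sample(0:10, n, replace = TRUE)
  }
  list(ref = one_track(), det = one_track())
}
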