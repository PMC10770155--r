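#' Multi-channel sampled recording
#'
#' Container for a multi-channel abdominal ECG (aECG) signal.  Channels are
#' stored as columns of a numeric matrix in microvolts; all channels share
#' one sampling rate.  Sample positions are addressed with R's native
#' 1-based indexing throughout the package; on-disk annotation files use the
#' 0-based interchange convention (see [read_annotations()]).
#'
#' @param channels numeric matrix (samples x channels) or a vector for a
#'   single channel, amplitudes in microvolts.
#' @param fs sampling rate in Hz, a single positive number.
#' @param channel_ids optional character vector of channel labels; defaults
#'   to `"aECG1"`, `"aECG2"`, ...
#' @param recording_id optional label for the recording.
#' @return An object of class `"recording"`: a list with elements
#'   `channels`, `fs`, `channel_ids`, `recording_id`.
#' @examples
#' rec <- recording(cbind(sin(1:1000 / 10), cos(1:1000 / 10)), fs = 500)
#' n_samples(rec)
#' @export
recording <- function(channels, fs, channel_ids = NULL, recording_id = "rec") {
  if (is.vector(channels)) channels <- matrix(channels, ncol = 1L)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (ncol(channels) < 1L) stop("recording needs at least one channel")
  if (is.null(channel_ids)) channel_ids <- paste0("aECG", seq_len(ncol(channels)))
  if (length(channel_ids) != ncol(channels))
    stop("`channel_ids` length must match the number of channels")
  colnames(channels) <- channel_ids
  structure(
    list(channels = channels, fs = as.numeric(fs),
         channel_ids = as.character(channel_ids),
         recording_id = as.character(recording_id)),
    class = "recording"
  )
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_samples <- function(x) nrow(x$channels)

#' @rdname recording
#' @export
n_channels <- function(x) ncol(x$channels)

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)>\n",
              x$recording_id, n_channels(x), n_samples(x), x$fs,
              n_samples(x) / x$fs))
  invisible(x)
}

#' R-peak annotation track
#'
#' An ordered set of R-peak sample positions together with the sampling rate
#' they refer to, the kind of rhythm annotated (maternal or fetal) and its
#' provenance (expert reference or detector output).  Indices are 1-based
#' sample positions.
#'
#' Unsorted input is sorted with a warning; duplicate indices are collapsed
#' with a warning.
#'
#' @param indices integer-valued sample positions (1-based).
#' @param fs sampling rate in Hz the indices refer to.
#' @param kind `"maternal"` or `"fetal"`.
#' @param provenance `"reference"` or `"detected"`.
#' @return An object of class `"annotation_track"`.
#' @examples
#' annotation_track(c(100, 350, 600), fs = 500, kind = "fetal")
#' @export
annotation_track <- function(indices, fs,
                             kind = c("maternal", "fetal"),
                             provenance = c("detected", "reference")) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  indices <- as.numeric(indices)
  if (anyNA(indices) || any(indices != round(indices)))
    stop("annotation indices must be integer-valued")
  if (any(indices < 1)) stop("annotation indices must be >= 1")
  if (is.unsorted(indices)) {
    warning("annotation indices were not sorted; sorting ascending")
    indices <- sort(indices)
  }
  if (anyDuplicated(indices)) {
    warning("duplicate annotation indices collapsed")
    indices <- unique(indices)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(indices = as.integer(indices), fs = as.numeric(fs),
         kind = kind, provenance = provenance),
    class = "annotation_track"
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track: %d %s %s peak(s) @ %g Hz>\n",
              length(x$indices), x$provenance, x$kind, x$fs))
  invisible(x)
}

#' @export
length.annotation_track <- function(x) length(x$indices)

check_track_in_recording <- function(track, rec) {
  if (length(track$indices) && max(track$indices) > n_samples(rec))
    stop("annotation indices exceed the recording length")
  if (track$fs != rec$fs)
    stop("annotation track and recording sampling rates differ")
  invisible(TRUE)
}
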