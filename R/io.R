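#' Read a multi-channel recording from disk
#'
#' Two dialects are supported.  `"csv"` is the package's plain-text signal
#' format: a header row of channel ids, one column per channel, one sample
#' per row (microvolts), plus a sidecar file `<path>.meta` holding a line
#' `fs=<Hz>`.  `"wfdb"` reads a minimal subset of the WFDB format: a `.hea`
#' header naming one binary `.dat` file in format 16 (little-endian 16-bit
#' integers, channel-interleaved), with per-channel gain and baseline;
#' samples are converted to physical units.
#'
#' @param path file path (for `"wfdb"`, the record path without extension,
#'   or the `.hea` file).
#' @param dialect `"csv"` or `"wfdb"`.
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  switch(dialect, csv = read_recording_csv(path), wfdb = read_recording_wfdb(path))
}

read_recording_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path))
    stop("metadata error: sidecar '", meta_path, "' with 'fs=<Hz>' is required")
  meta <- readLines(meta_path, warn = FALSE)
  fs_line <- grep("^fs=", meta, value = TRUE)
  if (!length(fs_line)) stop("metadata error: no 'fs=' line in ", meta_path)
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", fs_line[1L])))
  if (is.na(fs)) stop("metadata error: unparsable fs in ", meta_path)
  id_line <- grep("^id=", meta, value = TRUE)
  rid <- if (length(id_line)) sub("^id=", "", id_line[1L]) else
    sub("\\.[^.]*$", "", basename(path))

  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first)) stop("format error: empty signal file ", path)
  header <- strsplit(first, ",", fixed = TRUE)[[1L]]
  dat <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (!nrow(dat)) stop("format error: no samples in ", path)
  mat <- matrix(NA_real_, nrow(dat), ncol(dat))
  for (j in seq_len(ncol(dat))) {
    col <- dat[[j]]
    if (any(col == "" | is.na(col)))
      stop("format error: ragged or missing values in column ", header[j])
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("parse error: non-numeric value in column ", header[j])
    mat[, j] <- v
  }
  recording(mat, fs = fs, channel_ids = header, recording_id = rid)
}

read_recording_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(rec_line) < 4L) stop("format error: malformed WFDB header")
  nsig <- as.integer(rec_line[2L])
  fs <- as.numeric(rec_line[3L])
  nsamp <- as.integer(rec_line[4L])
  sig <- lines[1L + seq_len(nsig)]
  fields <- lapply(sig, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  dat_file <- vapply(fields, `[`, "", 1L)
  if (length(unique(dat_file)) != 1L)
    stop("format error: multi-file WFDB records are not supported")
  fmt <- vapply(fields, `[`, "", 2L)
  if (!all(sub("x.*", "", fmt) == "16"))
    stop("format error: only WFDB format 16 is supported")
  # field 3: gain(baseline)/units, e.g. 200(0)/uV ; defaults per WFDB spec
  gain <- rep(200, nsig); base <- rep(0, nsig)
  g3 <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else "", "")
  for (i in seq_len(nsig)) {
    if (nzchar(g3[i])) {
      g <- sub("/.*", "", g3[i])
      b <- regmatches(g, regexec("\\(([-0-9]+)\\)", g))[[1L]]
      if (length(b) == 2L) base[i] <- as.numeric(b[2L])
      gain[i] <- as.numeric(sub("\\(.*", "", g))
    }
  }
  names <- vapply(seq_len(nsig), function(i) {
    f <- fields[[i]]
    if (length(f) >= 9L) f[length(f)] else paste0("aECG", i)
  }, "")
  dat_path <- file.path(dirname(hea), dat_file[1L])
  if (!file.exists(dat_path)) stop("file not found: ", dat_path)
  raw <- readBin(dat_path, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp)
    stop("format error: WFDB .dat shorter than header promises")
  mat <- matrix(as.numeric(raw), ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig)) mat[, i] <- (mat[, i] - base[i]) / gain[i]
  recording(mat, fs = fs, channel_ids = names,
            recording_id = sub("\\.hea$", "", basename(hea)))
}

#' Write a recording to disk
#'
#' Writes the `"csv"` dialect understood by [read_recording()]: a header of
#' channel ids, one sample per row, and a `<path>.meta` sidecar with the
#' sampling rate.  Values are written with 17 significant digits, so a
#' write/read round trip reproduces the doubles bit-exactly.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param dialect only `"csv"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = "csv") {
  stopifnot(inherits(rec, "recording"))
  if (dialect != "csv") stop("only the csv dialect is writable")
  cols <- apply(rec$channels, 2L, function(x) sprintf("%.17g", x))
  lines <- c(paste(rec$channel_ids, collapse = ","),
             do.call(paste, c(split(cols, col(cols)), sep = ",")))
  writeLines(lines, path)
  writeLines(c(paste0("fs=", format(rec$fs, digits = 12)),
               paste0("id=", rec$recording_id)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read an R-peak annotation track
#'
#' Annotation files are plain text, one sample index per line (or a CSV
#' whose first column holds the indices), using the 0-based sample
#' convention of the public abdominal-ECG datasets.  Indices are converted
#' to 1-based positions in memory.  An empty file yields an empty track.
#'
#' @param path file path.
#' @param fs sampling rate the indices refer to (Hz).
#' @param kind,provenance passed to [annotation_track()].
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, fs,
                             kind = c("maternal", "fetal"),
                             provenance = c("reference", "detected")) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(vapply(strsplit(lines, ","), `[`, "", 1L))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(annotation_track(integer(0), fs, kind = kind, provenance = provenance))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stop("parse error: non-numeric annotation index in ", path)
  if (any(vals != round(vals))) stop("parse error: non-integer annotation index")
  if (any(vals < 0)) stop("range error: negative annotation index")
  annotation_track(vals + 1, fs, kind = kind, provenance = provenance)
}

#' Write an R-peak annotation track
#'
#' Inverse of [read_annotations()]: one 0-based sample index per line.
#'
#' @param track an [annotation_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  writeLines(as.character(track$indices - 1L), path)
  invisible(path)
}
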