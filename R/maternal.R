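#' Principal component analysis of a multi-channel recording
#'
#' Pools all abdominal channels into uncorrelated component signals ordered
#' by explained variance.  Channels are mean-centred but not variance
#' scaled (they share microvolt units); the decomposition is the
#' eigen-decomposition of the channel covariance matrix.  Each component's
#' sign is fixed so that its largest-magnitude loading is positive, making
#' the output deterministic.
#'
#' @param rec a [recording()] with at least two channels.
#' @return An object of class `"pca_decomposition"`: list with `components`
#'   (samples x components matrix of component signals),uncorrelated
#'   columns ordered by decreasing variance, `explained_variance`, and
#'   `loadings` (channels x components weight matrix).
#' @export
pca_decompose <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (n_channels(rec) < 2L) stop("PCA needs at least 2 channels")
  x <- scale(rec$channels, center = TRUE, scale = FALSE)
  cv <- stats::cov(x)
  if (all(abs(cv) < .Machine$double.eps * 100))
    stop("degenerate input: all channels are constant")
  eig <- eigen(cv, symmetric = TRUE)
  load <- eig$vectors
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  comp <- x %*% load
  structure(
    list(components = comp, explained_variance = pmax(eig$values, 0),
         loadings = load, center = attr(x, "scaled:center")),
    class = "pca_decomposition"
  )
}

#' @export
print.pca_decomposition <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<pca_decomposition: %d components; variance %% = %s>\n",
              ncol(x$components), paste(sprintf("%.1f", pct), collapse = ", ")))
  invisible(x)
}

#' Detect maternal R-peaks from all abdominal channels
#'
#' The maternal rhythm dominates the abdominal mixture, so the first
#' principal components concentrate its energy.  The CWT detector runs on
#' the first and the second component; whichever yields *fewer* peaks is
#' returned (spurious fetal or noise peaks inflate the count of a
#' component that carries more than the maternal rhythm).  On an equal
#' count the first component wins, it being the higher-energy one.
#'
#' Note the rule's documented blind spot: if the first component carried
#' only the fetal signal *and* fewer peaks than the maternal component, it
#' would be mis-selected.  This does not arise while the maternal signal
#' dominates every channel.
#'
#' @param rec a preprocessed [recording()], at least 2 channels.
#' @param cfg maternal [detector_config()] (default `gaus1`, refractory
#'   0.33 s).
#' @return An [annotation_track()] with `kind = "maternal"`.
#' @export
detect_maternal <- function(rec, cfg = detector_config("gaus1")) {
  stopifnot(inherits(rec, "recording"))
  pca <- pca_decompose(rec)
  t1 <- detect_r_peaks(pca$components[, 1L], rec$fs, cfg, kind = "maternal")
  t2 <- detect_r_peaks(pca$components[, 2L], rec$fs, cfg, kind = "maternal")
  select_maternal_track(t1, t2)
}

# fewer peaks wins (extra peaks are spurious); an empty track never wins
# over a populated one (a maternal-only recording leaves the second
# component with nothing to detect); ties go to the first component
select_maternal_track <- function(t1, t2) {
  n1 <- length(t1$indices)
  n2 <- length(t2$indices)
  if (!n1 && !n2)
    stop("detection failure: no maternal R-peaks found on either component")
  if (!n2) return(t1)
  if (!n1) return(t2)
  if (n2 < n1) t2 else t1
}
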