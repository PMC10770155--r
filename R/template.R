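#' Cut maternal beat windows out of one channel
#'
#' Each maternal R-peak anchors a window from 0.25 s before to 0.45 s after
#' the peak (350 samples at 500 Hz, R-peak at in-window offset 126, 1-based).
#' Windows that would leave the signal are flagged invalid and carry no row
#' in the beat matrix, but their anchors are retained so the extraction can
#' report them.
#'
#' @param x numeric signal (one channel).
#' @param maternal an [annotation_track()] of maternal R-peaks.
#' @param fs sampling rate in Hz.
#' @param pre_s,post_s window extent before/after the R-peak, seconds.
#' @return An object of class `"beat_matrix"`: list with `beats` (one row
#'   per valid beat), `anchors`, `valid` (logical per anchor), `pre`,
#'   `post` (in samples), and `fs`.
#' @export
segment_beats <- function(x, maternal, fs, pre_s = 0.25, post_s = 0.45) {
  stopifnot(inherits(maternal, "annotation_track"))
  if (!length(maternal$indices)) stop("segmentation error: empty maternal track")
  pre <- round(pre_s * fs)
  post <- round(post_s * fs)
  anchors <- maternal$indices
  valid <- anchors - pre >= 1L & anchors + post - 1L <= length(x)
  if (!any(valid)) stop("segmentation error: no beat window fits the signal")
  rows <- t(vapply(anchors[valid],
                   function(a) x[(a - pre):(a + post - 1L)],
                   numeric(pre + post)))
  structure(
    list(beats = rows, anchors = anchors, valid = valid,
         pre = pre, post = post, fs = fs),
    class = "beat_matrix"
  )
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix: %d valid / %d beats, window %d samples>\n",
              nrow(x$beats), length(x$anchors), x$pre + x$post))
  invisible(x)
}

#' Median beat template
#'
#' The maternal ECG template (TECG) is the element-wise median over all
#' valid beat windows.  The template is split into P wave (first 0.2 s),
#' QRS complex (0.2-0.3 s) and T wave (0.3 s to the end), the segments the
#' sequential-analysis adaptation scales independently.
#'
#' @param bm a [segment_beats()] beat matrix.
#' @return An object of class `"tecg_template"`: list with `tecg` (numeric
#'   vector), `segments` (named list of index ranges), `fs`.
#' @export
build_template <- function(bm) {
  stopifnot(inherits(bm, "beat_matrix"))
  if (is.null(bm$beats) || !nrow(bm$beats))
    stop("cannot build a template from an empty beat matrix")
  tecg <- apply(bm$beats, 2L, stats::median)
  structure(
    list(tecg = tecg, segments = template_segments(length(tecg), bm$fs),
         fs = bm$fs),
    class = "tecg_template"
  )
}

template_segments <- function(L, fs) {
  p_end <- round(0.2 * fs)
  qrs_end <- round(0.3 * fs)
  list(P = seq_len(min(p_end, L)),
       QRS = seq(min(p_end, L) + 1L, min(qrs_end, L)),
       T = if (qrs_end < L) seq(qrs_end + 1L, L) else integer(0))
}

#' @export
print.tecg_template <- function(x, ...) {
  cat(sprintf("<tecg_template: %d samples (P %d | QRS %d | T %d)>\n",
              length(x$tecg), length(x$segments$P), length(x$segments$QRS),
              length(x$segments$T)))
  invisible(x)
}

#' Template adaptation rules
#'
#' Each rule maps the stored template (or beat history) and the current
#' maternal beat window to the waveform that will be subtracted:
#'
#' * `adapt_none()`: the template unchanged (plain template subtraction).
#' * `adapt_svd()`: orthogonal projection of the current beat onto the
#'   span of the top-`k` left singular vectors `U` of the beat matrix
#'   (beats as columns), i.e. `U U' b`.
#' * `adapt_lp()`: linear prediction -- the least-squares combination of
#'   the `m` previous beats, `lambda = (B B' + eps I)^{-1} B b` with `B`
#'   the m x L history matrix; the subtracted waveform is `lambda' B`.
#' * `adapt_sf()`: global scaling factor `alpha = <t, b> / <t, t>` applied
#'   to the whole template (the 1-D least-squares fit of the template to
#'   the beat).
#' * `adapt_sa()`: sequential analysis -- the scaling factor computed
#'   independently on the P, QRS and T segments; a zero-norm segment keeps
#'   factor 1 with a warning.
#'
#' @param template a [build_template()] object.
#' @param beat numeric vector, the current beat window.
#' @param bm a [segment_beats()] beat matrix (for `adapt_svd`).
#' @param k number of singular vectors retained.
#' @param history matrix with one row per previous beat (for `adapt_lp`).
#' @param ridge ridge term stabilising collinear histories, expressed as a
#'   fraction of the mean diagonal of `B B'`.
#' @return List with `tecg_adapted` (vector to subtract) and `params`
#'   (adaptation parameters: `NULL`, the basis `U`, weights `lambda`,
#'   scalar `alpha`, or the `(alpha_P, alpha_QRS, alpha_T)` triple).
#' @name template-adaptation
NULL

#' @rdname template-adaptation
#' @export
adapt_none <- function(template, beat) {
  list(tecg_adapted = template$tecg, params = NULL)
}

#' @rdname template-adaptation
#' @export
adapt_svd <- function(bm, beat, k = 3L) {
  stopifnot(inherits(bm, "beat_matrix"))
  n <- nrow(bm$beats)
  if (k < 1L || k > min(n, ncol(bm$beats)))
    stop("config error: k must be in 1..min(n_beats, window length)")
  U <- svd_basis(bm, k)
  list(tecg_adapted = drop(U %*% crossprod(U, beat)), params = list(U = U))
}

svd_basis <- function(bm, k) {
  sv <- svd(t(bm$beats), nu = k, nv = 0)
  sv$u
}

#' @rdname template-adaptation
#' @export
adapt_lp <- function(history, beat, ridge = 1e-8, template = NULL) {
  if (is.null(history) || !nrow(history)) {
    warning("empty linear-prediction history; falling back to the unadapted template")
    if (!is.null(template)) return(adapt_none(template, beat))
    return(list(tecg_adapted = rep(0, length(beat)), params = list(lambda = numeric(0))))
  }
  B <- history
  G <- tcrossprod(B)
  eps <- ridge * mean(diag(G))
  lambda <- solve(G + diag(eps, nrow(G)), B %*% beat)
  list(tecg_adapted = drop(crossprod(B, lambda)),
       params = list(lambda = unname(drop(lambda))))
}

#' @rdname template-adaptation
#' @export
adapt_sf <- function(template, beat) {
  t <- template$tecg
  denom <- sum(t * t)
  if (denom == 0) stop("degenerate error: zero-norm template")
  alpha <- sum(t * beat) / denom
  list(tecg_adapted = alpha * t, params = list(alpha = alpha))
}

#' @rdname template-adaptation
#' @export
adapt_sa <- function(template, beat) {
  t <- template$tecg
  segs <- template$segments
  out <- numeric(length(t))
  alphas <- c(P = 1, QRS = 1, T = 1)
  for (nm in names(segs)) {
    ix <- segs[[nm]]
    if (!length(ix)) next
    denom <- sum(t[ix]^2)
    if (denom == 0) {
      warning("zero-norm ", nm, " segment; scaling factor kept at 1")
      alphas[nm] <- 1
    } else {
      alphas[nm] <- sum(t[ix] * beat[ix]) / denom
    }
    out[ix] <- alphas[nm] * t[ix]
  }
  list(tecg_adapted = out, params = as.list(alphas))
}

#' Fit the maternal beat model and extract the fetal ECG
#'
#' The central estimator: at every maternal R-peak a maternal beat waveform
#' is fitted (per the chosen adaptation rule) and subtracted in place, in
#' chronological order; what remains is the fetal ECG estimate plus noise.
#' Overlapping windows (maternal RR below 0.7 s) subtract sequentially on
#' the already-updated signal.  Edge beats whose window does not fit are
#' left unsubtracted and counted in the fit object.
#'
#' Methods: `residuals()` returns the extracted fetal signal (the model
#' residual), `fitted()` the subtracted maternal estimate, `coef()` the
#' per-beat adaptation parameters, `plot()` an overview of input, fitted
#' maternal component and residual.
#'
#' @param x numeric signal (one preprocessed channel, microvolts).
#' @param maternal an [annotation_track()] of maternal R-peaks.
#' @param fs sampling rate in Hz.
#' @param method one of `"ts"` (median template), `"ts_svd"` (subspace
#'   projection), `"ts_lp"` (linear prediction), `"ts_sf"` (scaling
#'   factor), `"sa"` (segment-wise scaling).
#' @param svd_k singular vectors kept by `"ts_svd"`.
#' @param lp_m maximum number of previous beats in the `"ts_lp"` history.
#' @param lp_ridge relative ridge term for the `"ts_lp"` normal equations.
#' @param pre_s,post_s beat window, seconds before/after the R-peak.
#' @return An object of class `"fecg_ts"`.
#' @examples
#' sim <- mix_aecg(synth_config(duration_s = 20, seed = 1))
#' filt <- apply_bandpass(sim$recording)
#' fit <- fecg_ts(filt$channels[, 1], sim$truth$maternal, filt$fs, "sa")
#' fit
#' @export
fecg_ts <- function(x, maternal, fs,
                    method = c("ts", "ts_svd", "ts_lp", "ts_sf", "sa"),
                    svd_k = 3L, lp_m = 10L, lp_ridge = 1e-8,
                    pre_s = 0.25, post_s = 0.45) {
  method <- match.arg(method)
  stopifnot(inherits(maternal, "annotation_track"))
  bm <- segment_beats(x, maternal, fs, pre_s, post_s)
  template <- build_template(bm)
  U <- if (method == "ts_svd") svd_basis(bm, svd_k) else NULL

  y <- x
  n <- length(x)
  valid_anchors <- bm$anchors[bm$valid]
  params <- vector("list", length(valid_anchors))
  lp_history <- list()

  for (i in seq_along(valid_anchors)) {
    a <- valid_anchors[i]
    ix <- (a - bm$pre):(a + bm$post - 1L)
    beat <- y[ix]
    ad <- switch(
      method,
      ts = adapt_none(template, beat),
      ts_sf = adapt_sf(template, beat),
      sa = adapt_sa(template, beat),
      ts_svd = list(tecg_adapted = drop(U %*% crossprod(U, beat)),
                    params = NULL),
      ts_lp = {
        if (length(lp_history)) {
          adapt_lp(do.call(rbind, lp_history), beat, lp_ridge)
        } else {
          # no previous cycle yet: fall back to the median template
          adapt_none(template, beat)
        }
      }
    )
    y[ix] <- y[ix] - ad$tecg_adapted
    params[[i]] <- ad$params
    if (method == "ts_lp") {
      lp_history[[length(lp_history) + 1L]] <- beat
      if (length(lp_history) > lp_m) lp_history[[1L]] <- NULL
    }
  }

  structure(
    list(call = match.call(), method = method, fs = fs,
         residuals = y, fitted = x - y, input = x,
         template = template, beat_matrix = bm,
         anchors = valid_anchors, n_edge_beats = sum(!bm$valid),
         params = params, svd_k = if (method == "ts_svd") svd_k else NULL),
    class = "fecg_ts"
  )
}

#' Extract the fetal ECG from one channel
#'
#' Thin functional wrapper around [fecg_ts()] returning just the extracted
#' signal.
#'
#' @inheritParams fecg_ts
#' @param ... passed on to [fecg_ts()].
#' @return Numeric vector, same length as `x`.
#' @export
extract_fecg <- function(x, maternal, fs,
                         method = c("ts", "ts_svd", "ts_lp", "ts_sf", "sa"),
                         ...) {
  stats::residuals(fecg_ts(x, maternal, fs, match.arg(method), ...))
}

#' @export
residuals.fecg_ts <- function(object, ...) object$residuals

#' @export
fitted.fecg_ts <- function(object, ...) object$fitted

#' @export
coef.fecg_ts <- function(object, ...) {
  switch(
    object$method,
    ts_sf = vapply(object$params, function(p) p$alpha, numeric(1)),
    sa = t(vapply(object$params,
                  function(p) c(P = p$P, QRS = p$QRS, T = p$T), numeric(3))),
    ts_lp = lapply(object$params, function(p) if (is.null(p)) NULL else p$lambda),
    NULL
  )
}

#' @export
print.fecg_ts <- function(x, ...) {
  cat(sprintf("fecg_ts maternal beat model (method '%s')\n", x$method))
  cat(sprintf("  %d beats fitted (%d edge beats skipped), window %d samples @ %g Hz\n",
              length(x$anchors), x$n_edge_beats,
              x$beat_matrix$pre + x$beat_matrix$post, x$fs))
  win <- in_window_mask(x)
  reduction <- 1 - sum(x$residuals[win]^2) / sum(x$input[win]^2)
  cat(sprintf("  maternal-window energy reduction: %.1f%%\n", 100 * reduction))
  invisible(x)
}

#' @export
summary.fecg_ts <- function(object, ...) {
  win <- in_window_mask(object)
  res <- list(
    method = object$method,
    n_beats = length(object$anchors),
    n_edge_beats = object$n_edge_beats,
    energy_reduction = 1 - sum(object$residuals[win]^2) / sum(object$input[win]^2),
    residual_rms = sqrt(mean(object$residuals[win]^2)),
    coef = coef(object)
  )
  class(res) <- "summary.fecg_ts"
  res
}

#' @export
print.summary.fecg_ts <- function(x, ...) {
  cat(sprintf("Maternal template subtraction, method '%s'\n", x$method))
  cat(sprintf("  beats fitted: %d (+%d edge beats skipped)\n",
              x$n_beats, x$n_edge_beats))
  cat(sprintf("  maternal-window energy reduction: %.2f%%\n",
              100 * x$energy_reduction))
  cat(sprintf("  residual RMS inside windows: %.3f uV\n", x$residual_rms))
  if (is.numeric(x$coef) && is.null(dim(x$coef)))
    cat(sprintf("  scaling factors: %s\n",
                paste(sprintf("%.3f", utils::head(x$coef, 6)), collapse = ", ")))
  invisible(x)
}

#' @export
plot.fecg_ts <- function(x, window_s = 5, ...) {
  n <- min(length(x$input), round(window_s * x$fs))
  t <- seq_len(n) / x$fs
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(t, x$input[seq_len(n)], type = "l", xlab = "",
                 ylab = "aECG (uV)", main = paste("method", x$method), ...)
  graphics::plot(t, x$fitted[seq_len(n)], type = "l", xlab = "",
                 ylab = "fitted mECG (uV)", ...)
  graphics::plot(t, x$residuals[seq_len(n)], type = "l", xlab = "time (s)",
                 ylab = "extracted fECG (uV)", ...)
  invisible(x)
}

# logical mask of samples covered by any valid maternal beat window
in_window_mask <- function(fit) {
  bm <- fit$beat_matrix
  mask <- logical(length(fit$input))
  for (a in fit$anchors) mask[(a - bm$pre):(a + bm$post - 1L)] <- TRUE
  mask
}
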