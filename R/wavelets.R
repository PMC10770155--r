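#' The 124-wavelet registry of the CWT detector benchmark
#'
#' Names of the mother wavelets the detector benchmark sweeps, grouped by
#' family: biorthogonal (15), coiflet (5), Daubechies (45), Fejer-Korovkin
#' style (6), Gaussian derivative (8), reverse biorthogonal (15) and symlet
#' (30) -- 124 distinct names in all.
#'
#' @param families optional character vector restricting the registry to
#'   some families (`"bior"`, `"coif"`, `"db"`, `"fk"`, `"gaus"`, `"rbio"`,
#'   `"sym"`).
#' @return Character vector of wavelet names, in fixed registry order.
#' @examples
#' length(wavelet_registry())        # 124
#' wavelet_registry("gaus")          # gaus1 ... gaus8
#' @export
wavelet_registry <- function(families = NULL) {
  reg <- list(
    bior = paste0("bior", c("1.1", "1.3", "1.5", "2.2", "2.4", "2.6", "2.8",
                            "3.1", "3.3", "3.5", "3.7", "3.9", "4.4", "5.5",
                            "6.8")),
    coif = paste0("coif", 1:5),
    db = paste0("db", 1:45),
    fk = paste0("fk", c(4, 6, 8, 14, 18, 22)),
    gaus = paste0("gaus", 1:8),
    rbio = paste0("rbio", c("1.1", "1.3", "1.5", "2.2", "2.4", "2.6", "2.8",
                            "3.1", "3.3", "3.5", "3.7", "3.9", "4.4", "5.5",
                            "6.8")),
    sym = paste0("sym", 1:30)
  )
  if (!is.null(families)) {
    unknown <- setdiff(families, names(reg))
    if (length(unknown)) stop("unknown wavelet family: ",
                              paste(unknown, collapse = ", "))
    reg <- reg[families]
  }
  unname(unlist(reg))
}

wavelet_family <- function(name) {
  fam <- sub("[0-9].*$", "", name)
  if (!fam %in% c("bior", "coif", "db", "fk", "gaus", "rbio", "sym"))
    stop("config error: unknown wavelet '", name, "'")
  fam
}

# cache for filter tables and sampled wavelet functions
.wavelet_cache <- new.env(parent = emptyenv())

read_filter_table <- function(family) {
  key <- paste0("table_", family)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  path <- system.file("extdata", "wavelets", paste0(family, ".txt"),
                      package = "fecgx", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- list()
  for (p in parts) {
    vals <- as.numeric(strsplit(p[[3L]], " ", fixed = TRUE)[[1L]])
    if (is.null(tab[[p[[1L]]]])) tab[[p[[1L]]]] <- list()
    tab[[p[[1L]]]][[p[[2L]]]] <- vals
  }
  .wavelet_cache[[key]] <- tab
  tab
}

#' Filter bank of a discrete wavelet in the registry
#'
#' Returns the synthesis filter pair used to build the wavelet function by
#' the cascade algorithm.  For orthogonal families the high-pass filter is
#' derived from the low-pass by the quadrature-mirror relation
#' `g[k] = (-1)^k h[L-1-k]`.
#'
#' @param name a discrete wavelet name from [wavelet_registry()] (all
#'   families except `gaus`).
#' @return List with numeric vectors `lo` and `hi`.
#' @export
wavelet_filters <- function(name) {
  fam <- wavelet_family(name)
  if (fam == "gaus")
    stop("gaussian wavelets are analytic; they have no filter bank")
  tab <- read_filter_table(fam)
  entry <- tab[[name]]
  if (is.null(entry)) stop("config error: unknown wavelet '", name, "'")
  lo <- entry$lo
  hi <- entry$hi
  if (is.null(hi)) {
    L <- length(lo)
    hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  }
  list(lo = lo, hi = hi)
}

# cascade approximation of the wavelet function psi on a dyadic grid:
# psi(k / 2^iter) up to normalization, from the two-scale relations
#   phi(t) = sqrt(2) sum h_k phi(2t - k),  psi(t) = sqrt(2) sum g_k phi(2t - k)
cascade_psi <- function(lo, hi, iter = 7L) {
  v <- 1  # phi sampled at integers, delta start
  for (j in seq_len(iter - 1L)) {
    up <- rep(0, (length(lo) - 1L) * 2^(j - 1L) + 1L)
    up[seq(1L, length(up), by = 2^(j - 1L))] <- lo
    v <- sqrt(2) * conv_full(up, v)
  }
  up <- rep(0, (length(hi) - 1L) * 2^(iter - 1L) + 1L)
  up[seq(1L, length(up), by = 2^(iter - 1L))] <- hi
  w <- sqrt(2) * conv_full(up, v)
  step <- 2^-iter
  x <- (seq_along(w) - 1) * step
  # L2-normalize on the grid
  nrm <- sqrt(sum(w^2) * step)
  list(x = x, psi = w / nrm)
}

conv_full <- function(a, b) {
  if (length(a) < 2L) return(a * b)
  stats::convolve(a, rev(b), type = "open")
}

# analytic Gaussian-derivative wavelet: N-th derivative of exp(-t^2),
# L2-normalized, sampled on [-5, 5]
gaus_psi <- function(order, step = 2^-7) {
  x <- seq(-5, 5, by = step)
  # d^N/dt^N exp(-t^2) = (-1)^N H_N(t) exp(-t^2), physicists' Hermite H_N
  h_prev <- rep(1, length(x))
  h <- 2 * x
  if (order == 0) h <- h_prev
  if (order > 1) {
    for (n in seq_len(order - 1L)) {
      h_new <- 2 * x * h - 2 * n * h_prev
      h_prev <- h
      h <- h_new
    }
  }
  psi <- (-1)^order * h * exp(-x^2)
  nrm <- sqrt(sum(psi^2) * step)
  list(x = x, psi = psi / nrm)
}

#' Sampled wavelet function
#'
#' The mother wavelet \eqn{\psi} on a fine regular grid: analytic for the
#' Gaussian-derivative family, cascade-algorithm approximation (7 dyadic
#' refinement levels) for the discrete families.  Used by [cwt_at_level()]
#' to sample \eqn{\psi(t/a)} at integer lags.
#'
#' @param name wavelet name from [wavelet_registry()].
#' @return List with `x` (grid, unit spacing of the wavelet's natural time
#'   axis) and `psi` (values, L2-normalized on the grid).
#' @export
wavelet_function <- function(name) {
  key <- paste0("psi_", name)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  fam <- wavelet_family(name)
  res <- if (fam == "gaus") {
    gaus_psi(as.integer(sub("gaus", "", name)))
  } else {
    f <- wavelet_filters(name)
    cascade_psi(f$lo, f$hi)
  }
  .wavelet_cache[[key]] <- res
  res
}
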