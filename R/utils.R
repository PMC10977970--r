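# Shared numerical helpers: Gaussian smoothing, peak detection, sub-seeding.

#' Discrete Gaussian kernel
#'
#' @param sd Kernel standard deviation in bins.
#' @param radius Half-width in bins; defaults to `ceiling(4 * sd)`.
#' @return Numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel <- function(sd, radius = ceiling(4 * sd)) {
  stopifnot(sd > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

#' Gaussian smoothing with reflective padding
#'
#' Convolves a vector with a Gaussian kernel, reflecting the signal at both
#' ends so that the smoothed signal conserves mass away from degenerate cases.
#' `NA` values are treated as missing: the kernel is renormalised over the
#' observed samples (so isolated gaps do not drag estimates towards zero) and
#' positions that were `NA` stay `NA`.
#'
#' @param x Numeric vector.
#' @param sd Kernel SD in bins. `sd = 0` returns `x` unchanged.
#' @return Smoothed vector, same length as `x`.
#' @export
smooth_gaussian <- function(x, sd) {
  if (sd == 0) return(x)
  n <- length(x)
  k <- gaussian_kernel(sd)
  r <- (length(k) - 1L) / 2L
  na <- is.na(x)
  x0 <- ifelse(na, 0, x)
  w <- as.numeric(!na)
  pad <- function(v) {
    # reflect; if the pad radius exceeds the signal, recycle reflections
    idx <- c(rev(seq_len(n)), seq_len(n), rev(seq_len(n)))
    m <- n + 1L
    v2 <- v[idx]
    v2[(m - r):(m + n - 1L + r)]
  }
  if (r >= n) {
    # very short signals relative to kernel: fall back to full renormalised sum
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      kk <- gaussian_kernel(sd, radius = max(n, r))
      j <- seq_len(n)
      ww <- kk[j - i + max(n, r) + 1L] * w
      out[i] <- if (sum(ww) > 0) sum(x0[j] * ww) / sum(ww) else NA_real_
    }
    out[na] <- NA_real_
    return(out)
  }
  num <- stats::filter(pad(x0), k, method = "convolution", sides = 2)
  den <- stats::filter(pad(w), k, method = "convolution", sides = 2)
  out <- as.numeric(num)[(r + 1L):(r + n)] / as.numeric(den)[(r + 1L):(r + n)]
  out[na] <- NA_real_
  out
}

#' Smooth the rows of a trials-by-bins matrix
#' @keywords internal
smooth_rows <- function(m, sd) {
  t(apply(m, 1L, smooth_gaussian, sd = sd))
}

#' Local maxima with a minimum-distance constraint
#'
#' Finds local maxima (plateaus contribute their midpoint) and then greedily
#' removes smaller peaks until all surviving peaks are at least
#' `min_distance` bins apart, mirroring the usual distance-constrained
#' peak-finding convention.
#'
#' @param x Numeric vector.
#' @param min_distance Minimum separation between surviving peaks, in bins.
#' @return Integer vector of peak indices, sorted ascending.
#' @export
find_peaks <- function(x, min_distance = 1) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # plateau-aware local maxima: run-length encode, then a run is a peak if
  # strictly above both neighbouring runs
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  peaks <- integer(0)
  for (i in seq_len(nr)) {
    left_ok <- i > 1L && r$values[i] > r$values[i - 1L]
    right_ok <- i < nr && r$values[i] > r$values[i + 1L]
    if (left_ok && right_ok) {
      peaks <- c(peaks, as.integer(floor((starts[i] + ends[i]) / 2)))
    }
  }
  if (length(peaks) < 2L || min_distance <= 1) return(sort(peaks))
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  keep <- integer(0)
  for (p in ord) {
    if (all(abs(keep - p) >= min_distance)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Derive a reproducible sub-seed from a global seed and a component key
#'
#' A single session seed fans out to independent per-component streams, so
#' adding one simulated cell never perturbs the draws of another.
#'
#' @param seed Integer global seed.
#' @param key Character key naming the component (e.g. `"cell3"`).
#' @return Integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (cc in utf8ToInt(as.character(key))) {
    h <- (h * 131 + cc) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate with a local RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' 99th percentile helper used for shuffle thresholds
#' @keywords internal
p99 <- function(x) unname(stats::quantile(x, 0.99, type = 7, names = FALSE))
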