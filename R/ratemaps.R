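# Firing rate maps: trial-wise 1 cm linear maps with occupancy, spatial
# information, and open-arena analysis (2.5 cm maps, spatial autocorrelogram,
# grid score, half-session stability, time-shift shuffle classification).

#' Trial-wise linear firing rate map
#'
#' Divides the track into 1 cm bins, counts spikes per (trial, bin), divides
#' by dwell time and smooths each trial with a Gaussian filter (SD 2 cm,
#' reflective edges). Both smoothed and unsmoothed maps are kept: the field
#' shuffle operates on the unsmoothed map. Bins never occupied within a trial
#' are flagged (`visited` matrix) rather than silently zeroed.
#'
#' @param spike_times Numeric spike times (s), within the trace's time span.
#' @param trace Position trace (`time_s`, `pos_cm`, `trial_number`).
#' @param track_length_cm Track length (cm).
#' @param smoothing_sd_cm Gaussian SD for the smoothed map.
#' @return An object of class `"linear_rate_map"`: list with `rates`
#'   (smoothed, trials x bins, Hz), `rates_unsmoothed`, `occupancy_s`,
#'   `visited` (logical), `n_spikes`.
#' @export
linear_rate_map <- function(spike_times, trace, track_length_cm = 200,
                            smoothing_sd_cm = 2) {
  if (nrow(trace) == 0) stop("empty position trace")
  len <- as.integer(track_length_cm)
  nt <- max(trace$trial_number)
  dt <- stats::median(diff(trace$time_s))
  bin <- pmin(as.integer(trace$pos_cm) + 1L, len)
  idx <- (trace$trial_number - 1L) * len + bin
  occ <- matrix(tabulate(idx, nbins = nt * len) * dt, nt, len, byrow = TRUE)
  if (length(spike_times) > 0) {
    si <- findInterval(spike_times, trace$time_s)
    si <- si[si >= 1 & si <= nrow(trace)]
    sidx <- (trace$trial_number[si] - 1L) * len + bin[si]
    cnt <- matrix(tabulate(sidx, nbins = nt * len), nt, len, byrow = TRUE)
  } else {
    cnt <- matrix(0, nt, len)
  }
  visited <- occ > 0
  raw <- matrix(0, nt, len)
  raw[visited] <- cnt[visited] / occ[visited]
  raw[!visited] <- NA_real_
  sm <- smooth_rows(raw, smoothing_sd_cm)
  structure(list(rates = sm, rates_unsmoothed = raw, occupancy_s = occ,
                 visited = visited, n_spikes = sum(cnt),
                 smoothing_sd_cm = smoothing_sd_cm,
                 track_length_cm = track_length_cm),
            class = "linear_rate_map")
}

#' Spatial information in bits per second
#'
#' Computes `sum_i P_i * lambda_i * log2(lambda_i / lambda)` where `P_i` is
#' the occupancy probability of bin `i`, `lambda_i` its firing rate and
#' `lambda` the occupancy-weighted mean rate. Zero-rate bins contribute 0;
#' unvisited bins are excluded.
#'
#' @param map A `"linear_rate_map"`, or a numeric rate vector.
#' @param occupancy_s Dwell times matching `map` when a vector is given.
#' @param trials Optional subset of trials to pool (defaults to all).
#' @param smoothed Use the smoothed (default) or unsmoothed rates.
#' @return Numeric scalar, bits per second (>= 0 up to float error).
#' @export
spatial_information <- function(map, occupancy_s = NULL, trials = NULL,
                                smoothed = TRUE) {
  if (inherits(map, "linear_rate_map")) {
    tr <- if (is.null(trials)) seq_len(nrow(map$rates)) else trials
    occ <- colSums(map$occupancy_s[tr, , drop = FALSE])
    r <- if (smoothed) map$rates else map$rates_unsmoothed
    # occupancy-weighted pooled rate per bin across the selected trials
    w <- map$occupancy_s[tr, , drop = FALSE]
    r0 <- r[tr, , drop = FALSE]
    r0[is.na(r0)] <- 0
    rates <- ifelse(occ > 0, colSums(r0 * w) / pmax(occ, .Machine$double.eps), 0)
  } else {
    rates <- map
    occ <- occupancy_s
    if (is.null(occ)) stop("occupancy_s required when map is a vector")
  }
  keep <- occ > 0
  if (!any(keep)) stop("all-zero occupancy")
  P <- occ[keep] / sum(occ[keep])
  lam_i <- rates[keep]
  lam <- sum(P * lam_i)
  if (lam <= 0) return(0)
  nz <- lam_i > 0
  sum(P[nz] * lam_i[nz] * log2(lam_i[nz] / lam))
}

#' Equalise trial counts between two epochs
#'
#' For spatial-information comparisons between label epochs, randomly subsets
#' the larger group to the size of the smaller.
#'
#' @param labels Per-trial labels (any two-or-more level vector).
#' @param groups Length-2 character giving the two labels to compare.
#' @param seed Integer seed.
#' @return Named list of two integer trial-index vectors of equal length.
#' @export
equalise_epoch_trials <- function(labels, groups = c("TA", "TI"), seed = 1L) {
  a <- which(labels == groups[1])
  b <- which(labels == groups[2])
  if (length(a) == 0 || length(b) == 0) stop("both epochs must be non-empty")
  n <- min(length(a), length(b))
  with_seed(seed, {
    if (length(a) > n) a <- sort(sample(a, n))
    if (length(b) > n) b <- sort(sample(b, n))
    stats::setNames(list(a, b), groups)
  })
}

# ---------------------------------------------------------------------------
# Open arena ----------------------------------------------------------------

#' Open-arena firing rate map
#'
#' Bins spikes into square spatial bins (default 2.5 cm), divides by
#' occupancy time and smooths with a 2D Gaussian (applied over visited bins
#' with kernel renormalisation; unvisited bins stay `NA`).
#'
#' @param spike_times Spike times (s).
#' @param positions `data.frame(time_s, x_cm, y_cm)`.
#' @param bin_cm Bin side (cm).
#' @param smoothing_sd_bins 2D Gaussian SD in bins.
#' @return Object of class `"openfield_rate_map"`: `rates`, `occupancy_s`,
#'   `bin_cm`.
#' @export
open_field_rate_map <- function(spike_times, positions, bin_cm = 2.5,
                                smoothing_sd_bins = 1.5) {
  if (nrow(positions) == 0) stop("empty position data")
  dt <- stats::median(diff(positions$time_s))
  nx <- as.integer(ceiling((max(positions$x_cm) + 1e-9) / bin_cm))
  ny <- as.integer(ceiling((max(positions$y_cm) + 1e-9) / bin_cm))
  bx <- pmin(as.integer(positions$x_cm / bin_cm) + 1L, nx)
  by <- pmin(as.integer(positions$y_cm / bin_cm) + 1L, ny)
  idx <- (by - 1L) * nx + bx
  occ <- matrix(tabulate(idx, nbins = nx * ny) * dt, nx, ny)
  if (length(spike_times) > 0) {
    si <- findInterval(spike_times, positions$time_s)
    si <- si[si >= 1 & si <= nrow(positions)]
    cnt <- matrix(tabulate(idx[si], nbins = nx * ny), nx, ny)
  } else {
    cnt <- matrix(0, nx, ny)
  }
  raw <- matrix(NA_real_, nx, ny)
  v <- occ > 0
  raw[v] <- cnt[v] / occ[v]
  sm <- smooth_matrix_2d(raw, smoothing_sd_bins)
  structure(list(rates = sm, rates_unsmoothed = raw, occupancy_s = occ,
                 bin_cm = bin_cm), class = "openfield_rate_map")
}

# Separable NA-aware 2D Gaussian smoothing.
#' @keywords internal
smooth_matrix_2d <- function(m, sd) {
  if (sd == 0) return(m)
  tmp <- t(apply(m, 1L, smooth_gaussian, sd = sd))
  apply(tmp, 2L, smooth_gaussian, sd = sd)
}

#' Spatial autocorrelogram of a rate map
#'
#' Slides the rate map over all integer bin lags in x and y, computing the
#' Pearson correlation over the overlapping visited bins at each lag. Lags
#' with fewer than `min_overlap` overlapping bins are `NA`.
#'
#' @param map `"openfield_rate_map"` or a numeric matrix (NA = unvisited).
#' @param min_overlap Minimum number of overlapping bins.
#' @return Matrix of size `(2*nx-1) x (2*ny-1)`, class `"autocorrelogram"`.
#' @export
rate_map_autocorr <- function(map, min_overlap = 20) {
  m <- if (inherits(map, "openfield_rate_map")) map$rates else map
  nx <- nrow(m); ny <- ncol(m)
  v <- !is.na(m)
  a <- ifelse(v, m, 0)
  # FFT cross-correlations of a with itself and with the mask give all the
  # sums needed for Pearson r at every lag
  px <- 2L * nx; py <- 2L * ny
  F <- function(x) stats::fft(pad0(x, px, py))
  cc <- function(A, B) {
    # sum over overlap of A(i) * B(i + lag), all lags
    Re(stats::fft(Conj(F(A)) * F(B), inverse = TRUE)) / (px * py)
  }
  M <- v * 1
  n_ov <- cc(M, M); s_ab <- cc(a, a)
  s_a <- cc(a, M); s_b <- cc(M, a)
  s_a2 <- cc(a^2, M); s_b2 <- cc(M, a^2)
  take <- function(x) {
    # reorder FFT lags (0..nx-1, then negative) into -(nx-1)..(nx-1)
    xi <- c((px - nx + 2L):px, 1L:nx)
    yi <- c((py - ny + 2L):py, 1L:ny)
    x[xi, yi]
  }
  n_ov <- round(take(n_ov)); s_ab <- take(s_ab); s_a <- take(s_a)
  s_b <- take(s_b); s_a2 <- take(s_a2); s_b2 <- take(s_b2)
  num <- n_ov * s_ab - s_a * s_b
  den <- sqrt(pmax(n_ov * s_a2 - s_a^2, 0)) * sqrt(pmax(n_ov * s_b2 - s_b^2, 0))
  r <- ifelse(n_ov >= min_overlap & den > 0, num / den, NA_real_)
  structure(r, class = c("autocorrelogram", "matrix"))
}

#' @keywords internal
pad0 <- function(m, px, py) {
  out <- matrix(0, px, py)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Local maxima of a binary matrix as 8-connected components (one maximum per
# component).
#' @keywords internal
binary_local_maxima <- function(b) {
  nx <- nrow(b); ny <- ncol(b)
  lab <- matrix(0L, nx, ny)
  comp <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (b[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j)); lab[i, j] <- comp
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi >= 1 && qi <= nx && qj >= 1 && qj <= ny &&
              b[qi, qj] && lab[qi, qj] == 0L) {
            lab[qi, qj] <- comp
            queue[[length(queue) + 1L]] <- c(qi, qj)
          }
        }
      }
    }
  }
  if (comp == 0L) return(matrix(numeric(0), 0, 2))
  cent <- t(vapply(seq_len(comp), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  cent
}

#' Grid score of a spatial autocorrelogram
#'
#' Binarises the autocorrelogram at 20% of its maximum, requires more than
#' seven local maxima (8-connected components), locates the six fields
#' closest to the centre, and correlates the autocorrelogram with rotated
#' copies of itself inside an annulus around those fields (outer border
#' 1.25x, inner border 0.25x the mean field distance). The score is the
#' minimum correlation at 60 and 120 degrees minus the maximum at 30, 90 and
#' 150 degrees.
#'
#' @param autocorr An `"autocorrelogram"` (or numeric matrix).
#' @return Numeric grid score, or `NA` (with attribute `reason`) when fewer
#'   than eight local maxima are present or the geometry is degenerate.
#' @export
grid_score <- function(autocorr) {
  r <- unclass(autocorr)
  mx <- max(r, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    return(structure(NA_real_, reason = "degenerate autocorrelogram"))
  }
  b <- !is.na(r) & r >= 0.2 * mx
  cent <- binary_local_maxima(b)
  if (nrow(cent) <= 7L) {
    return(structure(NA_real_, reason = "fewer than 8 local maxima"))
  }
  c0 <- (dim(r) + 1) / 2
  d <- sqrt((cent[, 1] - c0[1])^2 + (cent[, 2] - c0[2])^2)
  ord <- order(d)
  ring_fields <- cent[setdiff(ord, which.min(d))[1:6], , drop = FALSE]
  avg_d <- mean(sqrt((ring_fields[, 1] - c0[1])^2 + (ring_fields[, 2] - c0[2])^2))
  outer_r <- 1.25 * avg_d
  inner_r <- 0.25 * avg_d
  xi <- row(r) - c0[1]; yi <- col(r) - c0[2]
  rad <- sqrt(xi^2 + yi^2)
  ring <- rad >= inner_r & rad <= outer_r
  rots <- c(30, 60, 90, 120, 150)
  cors <- vapply(rots, function(theta) {
    rr <- rotate_matrix(r, theta)
    ok <- ring & !is.na(r) & !is.na(rr)
    if (sum(ok) < 20) return(NA_real_)
    stats::cor(r[ok], rr[ok])
  }, numeric(1))
  if (anyNA(cors)) return(structure(NA_real_, reason = "degenerate ring"))
  min(cors[rots %in% c(60, 120)]) - max(cors[rots %in% c(30, 90, 150)])
}

# Rotate a matrix about its centre by theta degrees (bilinear interpolation,
# NA outside or where source values are missing).
#' @keywords internal
rotate_matrix <- function(m, theta) {
  nx <- nrow(m); ny <- ncol(m)
  c0 <- (c(nx, ny) + 1) / 2
  th <- theta * pi / 180
  xi <- row(m) - c0[1]; yi <- col(m) - c0[2]
  # source coordinates: rotate backwards
  sx <- cos(th) * xi + sin(th) * yi + c0[1]
  sy <- -sin(th) * xi + cos(th) * yi + c0[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get <- function(i, j) {
    ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
    out <- rep(NA_real_, length(i))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  v00 <- get(x0, y0); v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, nx, ny)
}

#' Half-session spatial stability
#'
#' Pearson correlation between rate maps built from the first and second half
#' of the session, excluding bins unvisited in either half.
#'
#' @inheritParams open_field_rate_map
#' @return Numeric r in `[-1, 1]` (`NA` if fewer than 20 shared bins).
#' @export
half_session_stability <- function(spike_times, positions, bin_cm = 2.5,
                                   smoothing_sd_bins = 1.5) {
  tmid <- (min(positions$time_s) + max(positions$time_s)) / 2
  p1 <- positions[positions$time_s <= tmid, ]
  p2 <- positions[positions$time_s > tmid, ]
  m1 <- open_field_rate_map(spike_times[spike_times <= tmid], p1, bin_cm,
                            smoothing_sd_bins)
  m2 <- open_field_rate_map(spike_times[spike_times > tmid], p2, bin_cm,
                            smoothing_sd_bins)
  nx <- min(nrow(m1$rates), nrow(m2$rates))
  ny <- min(ncol(m1$rates), ncol(m2$rates))
  a <- m1$rates[1:nx, 1:ny]; b <- m2$rates[1:nx, 1:ny]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 20) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

#' Grid-cell identification against time-shift shuffles
#'
#' Shuffled spike trains are built by adding a single uniform time shift
#' (20 to `duration - 20` s, the classic 20-580 s range for 600 s sessions)
#' to every spike, wrapping past the session end. A cell is called a grid
#' cell when both its grid score and its half-session stability exceed the
#' 99th percentile of the corresponding shuffled distributions.
#'
#' @inheritParams open_field_rate_map
#' @param n_shuffles Number of shuffles (warning below 100, error below 2).
#' @param seed Integer seed.
#' @return Object of class `"grid_cell_call"`: `grid_score`, `stability_r`,
#'   `is_grid`, `shuffle_p99_grid`, `shuffle_p99_stability`, `n_shuffles`.
#' @export
open_field_shuffle_call <- function(spike_times, positions, n_shuffles = 1000,
                                    seed = 1L, bin_cm = 2.5,
                                    smoothing_sd_bins = 1.5) {
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  if (n_shuffles < 100) warning("fewer than 100 shuffles; thresholds will be noisy")
  dur <- max(positions$time_s) - min(positions$time_s)
  t0 <- min(positions$time_s)
  lo <- 20; hi <- max(dur - 20, lo + 1e-6)
  map <- open_field_rate_map(spike_times, positions, bin_cm, smoothing_sd_bins)
  gs <- grid_score(rate_map_autocorr(map))
  st <- half_session_stability(spike_times, positions, bin_cm, smoothing_sd_bins)
  sh <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      shift <- stats::runif(1, lo, hi)
      ts <- ((spike_times - t0 + shift) %% dur) + t0
      m <- open_field_rate_map(ts, positions, bin_cm, smoothing_sd_bins)
      c(grid_score(rate_map_autocorr(m)),
        half_session_stability(ts, positions, bin_cm, smoothing_sd_bins))
    }, numeric(2))
  })
  fin1 <- sh[1, ][is.finite(sh[1, ])]
  fin2 <- sh[2, ][is.finite(sh[2, ])]
  # a shuffle without a defined score contributes nothing; if none is defined
  # the cell cannot beat the null and is not called a grid cell
  g_thr <- if (length(fin1) > 0) p99(fin1) else Inf
  s_thr <- if (length(fin2) > 0) p99(fin2) else Inf
  is_grid <- is.finite(gs) && is.finite(st) && gs > g_thr && st > s_thr
  structure(list(grid_score = as.numeric(gs), stability_r = st,
                 is_grid = is_grid, shuffle_p99_grid = g_thr,
                 shuffle_p99_stability = s_thr, n_shuffles = n_shuffles),
            class = "grid_cell_call")
}
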