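# Spatial periodicity: Lomb-Scargle periodograms computed in the distance
# domain over a flattened (trial-concatenated) firing rate signal, field
# shuffle surrogates, 99th-percentile false alarm thresholds, and
# classification into task-anchored (TA), task-independent (TI) or aperiodic
# at session, rolling-window and single-trial level.
#
# The periodogram uses the generalized (floating-mean) least-squares
# formulation with the standard normalisation, so power is bounded in [0, 1]
# and invariant to rescaling of the signal. Because the rate signal is
# sampled on a uniform 1 cm grid, the sinusoid design matrix is identical for
# every 600 cm window; all windows are therefore evaluated with two matrix
# products against a shared precomputed basis.

#' Flatten a trial-wise rate map into a distance-domain signal
#'
#' Concatenates the per-trial 1 cm bins in trial order, yielding firing rate
#' as a function of cumulative distance. Bin (trial t, position p) maps to
#' index `(t - 1) * n_bins + p`.
#'
#' @param map A `"linear_rate_map"` or a trials x bins matrix.
#' @param smoothed Use the smoothed rates (default) or unsmoothed.
#' @return Numeric vector of length `n_trials * n_bins` (NA-free: unvisited
#'   bins are linearly bridged from neighbours before spectral analysis).
#' @export
flatten_rate_signal <- function(map, smoothed = TRUE) {
  m <- if (inherits(map, "linear_rate_map")) {
    if (smoothed) map$rates else map$rates_unsmoothed
  } else map
  if (nrow(m) < 1) stop("rate map must contain at least one trial")
  x <- as.vector(t(m))
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    if (length(ok) == 0) {
      x[] <- 0
    } else {
      x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
    }
  }
  x
}

#' Restore a flattened signal into a trials x bins matrix
#' @param signal Flattened signal.
#' @param n_bins Bins per trial.
#' @return Matrix with `length(signal) / n_bins` rows.
#' @export
unflatten_rate_signal <- function(signal, n_bins = 200) {
  matrix(signal, ncol = n_bins, byrow = TRUE)
}

#' Default spatial frequency grid (oscillations per trial)
#' @param max_freq Upper cap; frequencies above it are discarded.
#' @param step Grid step.
#' @return Numeric vector from 0.05 to `max_freq`.
#' @export
frequency_grid <- function(max_freq = 5, step = 0.01) {
  seq(0.05, max_freq, by = step)
}

# Precompute the Lomb-Scargle basis for a window of n_bins uniform samples.
#' @keywords internal
ls_basis <- function(freqs, n_bins, track_length_cm = 200) {
  x <- (seq_len(n_bins) - 0.5) / track_length_cm  # trial units
  omega <- 2 * pi * freqs
  ang <- outer(x, omega)            # n_bins x n_freqs
  cosM <- cos(ang); sinM <- sin(ang)
  C <- colMeans(cosM); S <- colMeans(sinM)
  CC <- colMeans(cosM^2) - C^2
  SS <- colMeans(sinM^2) - S^2
  CS <- colMeans(cosM * sinM) - C * S
  D <- CC * SS - CS^2
  list(freqs = freqs, n = n_bins, cosM = cosM, sinM = sinM,
       CC = CC, SS = SS, CS = CS, D = D)
}

# Power for windows stacked as columns of Y (n_bins x n_windows).
#' @keywords internal
ls_power <- function(Y, basis) {
  n <- basis$n
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  YY <- colMeans(Yc^2)
  YC <- crossprod(basis$cosM, Yc) / n   # n_freqs x n_windows
  YS <- crossprod(basis$sinM, Yc) / n
  num <- basis$SS * YC^2 - 2 * basis$CS * YC * YS + basis$CC * YS^2
  P <- sweep(num / basis$D, 2L, YY, "/")
  P[, YY <= 0] <- 0
  pmin(pmax(P, 0), 1)
}

#' Windowed Lomb-Scargle spatial periodograms
#'
#' Computes one periodogram per `step_cm` of cumulative distance, each over a
#' `window_cm` (default 600 cm = three track lengths) stretch of the
#' flattened rate signal. Track locations are expressed in trial units so
#' frequencies are oscillations per trial; frequencies above `max_freq` are
#' discarded. Windows that would run past the end of the signal are dropped.
#'
#' @param signal Flattened rate signal (1 cm bins).
#' @param window_cm Window length (cm).
#' @param step_cm Step between window starts (cm).
#' @param max_freq Frequency cap (oscillations/trial).
#' @param track_length_cm Track length (cm).
#' @param freq_step Frequency grid step.
#' @return Object of class `"periodograms"`: `freqs`, `power` (windows x
#'   freqs), `centre_cm` (window centres, cumulative cm), `midpoint_trial`.
#' @export
lomb_scargle_windows <- function(signal, window_cm = 600, step_cm = 10,
                                 max_freq = 5, track_length_cm = 200,
                                 freq_step = 0.01) {
  n <- length(signal)
  if (n < window_cm) stop("signal shorter than one window")
  freqs <- frequency_grid(max_freq, freq_step)
  basis <- ls_basis(freqs, window_cm, track_length_cm)
  starts <- seq(1L, n - window_cm + 1L, by = step_cm)
  idx <- outer(0:(window_cm - 1L), starts - 1L, "+") + 1L
  Y <- matrix(signal[idx], nrow = window_cm)
  P <- t(ls_power(Y, basis))
  centre <- (starts - 1) + window_cm / 2
  structure(list(freqs = freqs, power = P, centre_cm = centre,
                 midpoint_trial = centre / track_length_cm,
                 window_cm = window_cm, step_cm = step_cm,
                 track_length_cm = track_length_cm),
            class = "periodograms")
}

#' Average a set of periodograms
#'
#' Element-wise mean power across periodograms sharing one frequency grid.
#'
#' @param pgrams A `"periodograms"` object, or a list of vectors on one grid.
#' @param freqs Frequency grid when `pgrams` is a plain list.
#' @return List with `freqs` and `power` (vector), class `"periodogram_avg"`.
#' @export
average_periodogram <- function(pgrams, freqs = NULL) {
  if (inherits(pgrams, "periodograms")) {
    structure(list(freqs = pgrams$freqs, power = colMeans(pgrams$power)),
              class = "periodogram_avg")
  } else {
    lens <- vapply(pgrams, length, integer(1))
    if (length(unique(lens)) != 1) stop("mismatched frequency grids")
    if (is.null(freqs)) stop("freqs required for a plain list")
    if (length(freqs) != lens[1]) stop("mismatched frequency grids")
    structure(list(freqs = freqs, power = Reduce(`+`, pgrams) / length(pgrams)),
              class = "periodogram_avg")
  }
}

# ---------------------------------------------------------------------------
# Field shuffle -------------------------------------------------------------

#' Detect firing fields in a flattened rate signal
#'
#' Smooths the unsmoothed signal with a Gaussian (SD 4 cm), detects peaks and
#' troughs with a minimum peak distance of 20 cm, and segments the signal
#' into fields (inter-trough regions containing a peak) and non-field gaps.
#' The segmentation is disjoint and exhaustive.
#'
#' @param signal Unsmoothed flattened rate signal.
#' @param smooth_sd Gaussian SD (cm) for the detection signal.
#' @param min_peak_distance Minimum distance between peaks/troughs (cm).
#' @return Object of class `"field_segments"`: list with `fields` (list of
#'   integer index ranges), `peaks`, `troughs`.
#' @export
detect_fields <- function(signal, smooth_sd = 4, min_peak_distance = 20) {
  sm <- smooth_gaussian(signal, smooth_sd)
  peaks <- find_peaks(sm, min_peak_distance)
  if (length(peaks) == 0 || all(signal == 0)) {
    return(structure(list(fields = list(), peaks = integer(0),
                          troughs = integer(0), n = length(signal)),
                     class = "field_segments"))
  }
  troughs <- find_peaks(-sm, min_peak_distance)
  bounds <- sort(unique(c(1L, troughs, length(signal) + 1L)))
  fields <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- bounds[k]:(bounds[k + 1L] - 1L)
    if (any(peaks %in% seg)) fields[[length(fields) + 1L]] <- range(seg)
  }
  structure(list(fields = fields, peaks = peaks, troughs = troughs,
                 n = length(signal)), class = "field_segments")
}

#' Field-shuffle surrogate of a rate signal
#'
#' Reallocates the detected fields of an unsmoothed rate map to random
#' positions, preserving each field's internal spatial organisation, while
#' the non-field bins fill the remaining gaps in their original relative
#' order. The output is a permutation of the input bins. The caller smooths
#' the result (SD 2 cm) before computing periodograms.
#'
#' @param signal Unsmoothed flattened rate signal.
#' @param fields A `"field_segments"` from [detect_fields()].
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @return Shuffled unsmoothed signal (same length and value multiset).
#' @export
field_shuffle <- function(signal, fields, seed = NULL) {
  stopifnot(inherits(fields, "field_segments"))
  n <- length(signal)
  segs <- fields$fields
  do_shuffle <- function() {
    k <- length(segs)
    if (k == 0L) return(signal[sample.int(n)])
    lens <- vapply(segs, function(r) r[2] - r[1] + 1L, integer(1))
    ord <- sample.int(k)
    lens_o <- lens[ord]
    free <- n - sum(lens)
    gaps <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
    starts <- gaps + c(0L, cumsum(lens_o))[seq_len(k)] + 1L
    out <- rep(NA_real_, n)
    for (i in seq_len(k)) {
      r <- segs[[ord[i]]]
      out[starts[i]:(starts[i] + lens_o[i] - 1L)] <- signal[r[1]:r[2]]
    }
    in_field <- unlist(lapply(segs, function(r) r[1]:r[2]))
    out[is.na(out)] <- signal[-in_field]
    out
  }
  if (is.null(seed)) do_shuffle() else with_seed(seed, do_shuffle())
}

#' False alarm threshold from field-shuffled surrogates
#'
#' Repeats the field shuffle `n_shuffles` times; for each surrogate the
#' shuffled unsmoothed map is smoothed (SD 2 cm) and its windowed
#' periodograms computed. With `scope = "session"` the peak power of the
#' surrogate's session-average periodogram is recorded; with
#' `scope = "rolling_adjusted"` the average of the surrogate's first
#' `n_average` (default 200) periodograms is used, matching the adjusted
#' threshold for rolling-window classification; with `scope = "single"` the
#' first single periodogram's peak is used. The threshold is the 99th
#' percentile of the recorded peak powers. Field segmentation is performed
#' once on the observed map and reused across shuffles.
#'
#' @param map A `"linear_rate_map"`.
#' @param n_shuffles Number of surrogates (warning below 100).
#' @param scope `"session"`, `"rolling_adjusted"` or `"single"`.
#' @param seed Integer seed.
#' @param n_average Periodograms averaged in the rolling_adjusted scope.
#' @param smoothing_sd_cm Smoothing applied to surrogates before analysis.
#' @param ... Passed to [lomb_scargle_windows()].
#' @return Object of class `"fa_threshold"`: `threshold_power`,
#'   `shuffled_peaks`, `n_shuffles`, `percentile`, `scope`.
#' @export
false_alarm_threshold <- function(map, n_shuffles = 1000,
                                  scope = c("session", "rolling_adjusted",
                                            "single"),
                                  seed = 1L, n_average = 200,
                                  smoothing_sd_cm = 2, ...) {
  scope <- match.arg(scope)
  if (n_shuffles < 100) warning("fewer than 100 shuffles; threshold will be noisy")
  raw <- flatten_rate_signal(map, smoothed = FALSE)
  fields <- detect_fields(raw)
  dots <- list(...)
  window_cm <- if (!is.null(dots$window_cm)) dots$window_cm else 600
  step_cm <- if (!is.null(dots$step_cm)) dots$step_cm else 10
  # the rolling/single scopes only consume the leading periodograms, so the
  # surrogate signal can be truncated after shuffling (the shuffle itself is
  # always global)
  keep_cm <- switch(scope,
    session = Inf,
    rolling_adjusted = (n_average - 1L) * step_cm + window_cm,
    single = window_cm)
  peaks <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      surr <- smooth_gaussian(field_shuffle(raw, fields), smoothing_sd_cm)
      if (is.finite(keep_cm) && length(surr) > keep_cm) {
        surr <- surr[seq_len(keep_cm)]
      }
      pg <- do.call(lomb_scargle_windows, c(list(surr), dots))
      pw <- switch(scope,
        session = colMeans(pg$power),
        rolling_adjusted = colMeans(pg$power[seq_len(min(n_average, nrow(pg$power))), ,
                                             drop = FALSE]),
        single = pg$power[1L, ])
      max(pw)
    }, numeric(1))
  })
  structure(list(threshold_power = p99(peaks), shuffled_peaks = peaks,
                 n_shuffles = n_shuffles, percentile = 99, scope = scope),
            class = "fa_threshold")
}

# ---------------------------------------------------------------------------
# Classification ------------------------------------------------------------

#' @keywords internal
peak_of <- function(freqs, power) {
  i <- which.max(power)  # plateau ties resolve to the lower frequency
  list(freq = freqs[i], power = power[i])
}

#' @keywords internal
integer_distance <- function(freq) {
  ni <- max(1, round(freq))  # nearest positive integer
  abs(freq - ni)
}

#' Classify an average periodogram
#'
#' The peak of the average periodogram is compared against the false alarm
#' threshold; below it the cell is aperiodic. Above it, the distance between
#' the peak frequency and the nearest positive integer decides the label:
#' task-anchored (`"TA"`) when the distance is at most `tol` (default 0.05),
#' task-independent (`"TI"`) otherwise. With `threshold = NULL` (as used for
#' simulated data, where no field shuffle is computed) the decision is forced
#' two-way between TA and TI.
#'
#' @param avg A `"periodogram_avg"` (or list with `freqs`, `power`).
#' @param threshold A `"fa_threshold"`, a numeric scalar, or `NULL`.
#' @param tol Frequency tolerance (oscillations/trial).
#' @return Object of class `"session_classification"`: `label`, `peak_freq`,
#'   `peak_power`, `threshold`, `tol`.
#' @export
classify_session <- function(avg, threshold = NULL, tol = 0.05) {
  if (length(avg$power) == 0) stop("empty periodogram")
  pk <- peak_of(avg$freqs, avg$power)
  thr <- if (inherits(threshold, "fa_threshold")) threshold$threshold_power else threshold
  label <- if (!is.null(thr) && pk$power <= thr) {
    "aperiodic"
  } else if (integer_distance(pk$freq) <= tol) "TA" else "TI"
  structure(list(label = label, peak_freq = pk$freq, peak_power = pk$power,
                 threshold = thr, tol = tol),
            class = "session_classification")
}

#' Rolling-window classification
#'
#' Averages periodograms across a rolling window (default 200 periodograms,
#' i.e. 10 trials at 20 periodograms per trial) and classifies each window
#' against the adjusted false alarm threshold as in [classify_session()].
#'
#' @param pgrams A `"periodograms"` object.
#' @param threshold Adjusted threshold (`"fa_threshold"`, numeric or NULL for
#'   the forced two-way decision used with simulated data).
#' @param window Number of periodograms per rolling window.
#' @param tol Frequency tolerance.
#' @return `data.frame` with one row per window: `midpoint_trial`, `label`,
#'   `peak_freq`, `peak_power`.
#' @export
rolling_classify <- function(pgrams, threshold = NULL, window = 200,
                             tol = 0.05) {
  stopifnot(inherits(pgrams, "periodograms"))
  nw <- nrow(pgrams$power)
  if (nw < window) stop("fewer periodograms than the rolling window size")
  # rolling mean over rows via cumulative sums
  cs <- rbind(0, apply(pgrams$power, 2L, cumsum))
  avg <- (cs[(window + 1L):(nw + 1L), , drop = FALSE] -
            cs[1L:(nw - window + 1L), , drop = FALSE]) / window
  thr <- if (inherits(threshold, "fa_threshold")) threshold$threshold_power else threshold
  i_pk <- max.col(avg, ties.method = "first")
  pk_f <- pgrams$freqs[i_pk]
  pk_p <- avg[cbind(seq_len(nrow(avg)), i_pk)]
  lab <- ifelse(vapply(pk_f, integer_distance, numeric(1)) <= tol, "TA", "TI")
  if (!is.null(thr)) lab[pk_p <= thr] <- "aperiodic"
  mids <- (pgrams$midpoint_trial[1L:(nw - window + 1L)] +
             pgrams$midpoint_trial[window:nw]) / 2
  data.frame(midpoint_trial = mids, label = lab, peak_freq = pk_f,
             peak_power = pk_p, stringsAsFactors = FALSE)
}

#' Assign rolling-window labels to trials
#'
#' Each window is assigned to the trial number nearest its midpoint (border
#' cases half-way between two trials go to the upper trial: midpoint 10.4 is
#' trial 10, midpoints 10.5 and 10.6 are trial 11). All windows pooled on a
#' trial vote; the label with the most counts wins (ties broken in the fixed
#' order TA, TI, aperiodic). Trials with no window (the first and last few
#' trials of a session) inherit the label of the nearest labelled trial and
#' are flagged `imputed`.
#'
#' @param window_labels Character labels per window.
#' @param midpoints Window midpoints in trial units.
#' @param n_trials Number of trials in the session.
#' @return Object of class `"trial_raster"`: `data.frame` with
#'   `trial_number`, `label`, `n_windows`, `imputed`.
#' @export
assign_trials <- function(window_labels, midpoints, n_trials) {
  if (length(window_labels) != length(midpoints)) stop("length mismatch")
  trial <- pmin(pmax(as.integer(floor(midpoints + 0.5)), 1L), n_trials)
  levels_ <- c("TA", "TI", "aperiodic")
  lab <- rep(NA_character_, n_trials)
  nw <- integer(n_trials)
  for (t in unique(trial)) {
    counts <- table(factor(window_labels[trial == t], levels = levels_))
    lab[t] <- levels_[which.max(counts)]
    nw[t] <- sum(trial == t)
  }
  imputed <- is.na(lab)
  if (any(imputed) && !all(imputed)) {
    known <- which(!imputed)
    for (t in which(imputed)) {
      lab[t] <- lab[known[which.min(abs(known - t))]]
    }
  }
  out <- data.frame(trial_number = seq_len(n_trials), label = lab,
                    n_windows = nw, imputed = imputed,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_raster", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Fitted-classifier front end ------------------------------------------------

#' Classify a cell's spatial code
#'
#' The main fitting function: builds the trial-wise rate map from spikes and
#' positions, computes windowed Lomb-Scargle periodograms of the flattened
#' rate signal, derives the field-shuffle false alarm threshold (unless
#' disabled, as for simulated data) and classifies the cell at session level
#' and, optionally, per rolling window and per trial.
#'
#' @param spike_times Spike times (s).
#' @param trace Position trace (`time_s`, `pos_cm`, `trial_number`).
#' @param mode `"session"` for a whole-session label only, `"rolling"` to
#'   add rolling-window and per-trial labels.
#' @param use_field_shuffle Compute the shuffle threshold? With `FALSE` the
#'   classification is a forced TA/TI choice (aperiodic only for silent
#'   cells), the convention used for simulated data.
#' @param n_shuffles Shuffles for the threshold(s).
#' @param window Rolling window size (periodograms).
#' @param tol Frequency tolerance.
#' @param track_length_cm Track length (cm).
#' @param seed Integer seed (shuffles).
#' @return Object of class `"gridcode"` with the rate map, periodograms,
#'   average periodogram, thresholds, session classification and (rolling
#'   mode) the window labels and per-trial raster.
#' @export
classify_grid_code <- function(spike_times, trace,
                               mode = c("session", "rolling"),
                               use_field_shuffle = TRUE, n_shuffles = 1000,
                               window = 200, tol = 0.05,
                               track_length_cm = 200, seed = 1L) {
  mode <- match.arg(mode)
  map <- linear_rate_map(spike_times, trace, track_length_cm)
  n_trials <- nrow(map$rates)
  out <- list(map = map, mode = mode, tol = tol, window = window,
              n_shuffles = if (use_field_shuffle) n_shuffles else 0L,
              seed = seed)
  signal <- flatten_rate_signal(map)
  if (length(spike_times) == 0 || stats::var(signal) == 0) {
    # silent or constant cell: aperiodic by convention
    out$session <- structure(list(label = "aperiodic", peak_freq = NA_real_,
                                  peak_power = 0, threshold = NA_real_,
                                  tol = tol), class = "session_classification")
    if (mode == "rolling") {
      out$raster <- assign_trials(rep("aperiodic", n_trials),
                                  seq_len(n_trials), n_trials)
      out$raster$imputed <- FALSE
    }
    class(out) <- "gridcode"
    return(out)
  }
  pg <- lomb_scargle_windows(signal, track_length_cm = track_length_cm)
  out$periodograms <- pg
  out$avg <- average_periodogram(pg)
  thr_session <- if (use_field_shuffle) {
    false_alarm_threshold(map, n_shuffles, "session",
                          seed = derive_seed(seed, "thr_session"),
                          track_length_cm = track_length_cm)
  } else NULL
  out$threshold_session <- thr_session
  out$session <- classify_session(out$avg, thr_session, tol)
  if (mode == "rolling") {
    thr_roll <- if (use_field_shuffle) {
      false_alarm_threshold(map, n_shuffles, "rolling_adjusted",
                            seed = derive_seed(seed, "thr_rolling"),
                            n_average = window,
                            track_length_cm = track_length_cm)
    } else NULL
    out$threshold_rolling <- thr_roll
    out$windows <- rolling_classify(pg, thr_roll, window, tol)
    out$raster <- assign_trials(out$windows$label, out$windows$midpoint_trial,
                                n_trials)
  }
  class(out) <- "gridcode"
  out
}

#' @export
print.gridcode <- function(x, ...) {
  cat("Spatial code classification (", x$mode, " mode)\n", sep = "")
  cat("  trials: ", nrow(x$map$rates), ", spikes: ", x$map$n_spikes, "\n",
      sep = "")
  s <- x$session
  cat("  session label: ", s$label, sep = "")
  if (is.finite(s$peak_freq)) {
    cat(sprintf("  (peak %.3f osc/trial, power %.3f", s$peak_freq, s$peak_power))
    if (!is.null(s$threshold) && is.finite(s$threshold)) {
      cat(sprintf(", threshold %.3f", s$threshold))
    }
    cat(")")
  }
  cat("\n")
  if (!is.null(x$raster)) {
    tab <- table(x$raster$label)
    cat("  trial labels: ",
        paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.gridcode <- function(object, ...) {
  out <- list(session = object$session,
              n_trials = nrow(object$map$rates),
              n_spikes = object$map$n_spikes,
              mean_rate_hz = sum(object$map$rates_unsmoothed *
                                   object$map$occupancy_s, na.rm = TRUE) /
                sum(object$map$occupancy_s),
              spatial_info_bits_s = tryCatch(spatial_information(object$map),
                                             error = function(e) NA_real_),
              trial_label_table = if (!is.null(object$raster))
                table(object$raster$label) else NULL)
  class(out) <- "summary.gridcode"
  out
}

#' @export
print.summary.gridcode <- function(x, ...) {
  cat("Session label:", x$session$label, "\n")
  cat(sprintf("Trials: %d  Spikes: %d  Mean rate: %.2f Hz  Spatial info: %.3f bits/s\n",
              x$n_trials, x$n_spikes, x$mean_rate_hz, x$spatial_info_bits_s))
  if (!is.null(x$trial_label_table)) {
    cat("Per-trial labels:\n")
    print(x$trial_label_table)
  }
  invisible(x)
}

#' Plot a classified cell
#'
#' Left: trial-wise rate map (trials against track position). Right: average
#' periodogram with the false alarm threshold and the integer frequencies
#' marked. Rolling mode adds the per-trial label raster.
#'
#' @param x A `"gridcode"` object.
#' @param ... Unused.
#' @export
plot.gridcode <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  has_raster <- !is.null(x$raster)
  graphics::par(mfrow = c(1, if (has_raster) 3 else 2), mar = c(4, 4, 2, 1))
  m <- x$map$rates
  graphics::image(x = seq_len(ncol(m)) - 0.5, y = seq_len(nrow(m)),
                  z = t(m), xlab = "position (cm)", ylab = "trial",
                  main = "firing rate", col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE)
  if (!is.null(x$avg)) {
    graphics::plot(x$avg$freqs, x$avg$power, type = "l",
                   xlab = "frequency (oscillations/trial)", ylab = "power",
                   main = paste("session:", x$session$label))
    graphics::abline(v = 1:5, lty = 3, col = "grey")
    thr <- x$session$threshold
    if (!is.null(thr) && is.finite(thr)) {
      graphics::abline(h = thr, col = "red", lty = 2)
    }
  } else {
    graphics::plot.new()
  }
  if (has_raster) {
    cols <- c(TA = "#1b9e77", TI = "#d95f02", aperiodic = "grey70")
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, nrow(x$raster)),
                   xlab = "", ylab = "trial", xaxt = "n",
                   main = "trial labels")
    graphics::rect(0, seq_len(nrow(x$raster)) - 1, 1, seq_len(nrow(x$raster)),
                   col = cols[x$raster$label], border = NA)
  }
  invisible(x)
}
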