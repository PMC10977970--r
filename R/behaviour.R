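# Behavioural scoring on the virtual track: running-speed profiles, stop
# detection, hit / try / run trial outcomes, stop-density profiles with
# uniform-shuffle baselines, and code/session-weighted aggregation.

#' Trial-wise running-speed profile
#'
#' Bins speed into 1 cm location bins for each trial and smooths each trial
#' with a Gaussian filter (SD 2 cm). Speed is taken from `speed_cm_s` if the
#' trace carries it, otherwise differentiated from cumulative distance.
#' Trials with no samples in a bin leave that bin `NA`.
#'
#' @param trace Position trace; optionally with a `speed_cm_s` column (or a
#'   separate `speed` vector).
#' @param speed Optional per-sample speed overriding the trace column.
#' @param track_length_cm Track length (cm).
#' @param smoothing_sd_cm Gaussian SD (cm).
#' @return Matrix trials x bins (cm/s), class `"speed_profile"`.
#' @export
speed_profile <- function(trace, speed = NULL, track_length_cm = 200,
                          smoothing_sd_cm = 2) {
  if (is.null(speed)) {
    speed <- if (!is.null(trace$speed_cm_s)) trace$speed_cm_s else {
      d <- diff(trace$cum_dist_cm) / diff(trace$time_s)
      c(d[1], d)
    }
  }
  len <- as.integer(track_length_cm)
  nt <- max(trace$trial_number)
  bin <- pmin(as.integer(trace$pos_cm) + 1L, len)
  idx <- (trace$trial_number - 1L) * len + bin
  sums <- tapply_sum(speed, idx, nt * len)
  counts <- tabulate(idx, nbins = nt * len)
  m <- matrix(ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
              nt, len, byrow = TRUE)
  out <- smooth_rows(m, smoothing_sd_cm)
  class(out) <- c("speed_profile", "matrix")
  out
}

#' @keywords internal
tapply_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Detect stops in a sampled speed trace
#'
#' A stop is a sample with speed below the threshold (4.7 cm/s); a contiguous
#' sub-threshold interval counts as one stop, positioned at its first sample.
#'
#' @param trace Position trace.
#' @param speed Per-sample speed (cm/s); defaults to `trace$speed_cm_s`.
#' @param threshold_cm_s Stop threshold.
#' @return `data.frame(trial_number, pos_cm)`.
#' @export
detect_stops <- function(trace, speed = NULL, threshold_cm_s = 4.7) {
  if (is.null(speed)) speed <- trace$speed_cm_s
  below <- speed < threshold_cm_s
  starts <- which(below & !c(FALSE, below[-length(below)]))
  data.frame(trial_number = trace$trial_number[starts],
             pos_cm = trace$pos_cm[starts])
}

#' Classify trial outcomes (hit / try / run / unclassified)
#'
#' A trial is a hit when the animal stopped (speed below 4.7 cm/s) within the
#' reward zone. Trials whose mean speed outside the reward zone is below
#' 10 cm/s are left unclassified (this rule is applied first). Remaining
#' non-hit trials are split by comparing their mean reward-zone speed to the
#' 95th percentile of the hit trials' mean reward-zone speeds: below it they
#' are try trials, above it run trials. With no hit trials in the session the
#' try/run split is undefined and non-hit trials are flagged indeterminate
#' (`NA` label).
#'
#' @param speeds A `"speed_profile"` (trials x 1 cm bins).
#' @param stops `data.frame(trial_number, pos_cm)`.
#' @param reward_zone Numeric length-2, default `c(60, 80)` cm.
#' @param unclassified_cut_cm_s Mean out-of-zone speed below which a trial is
#'   unclassified.
#' @param exclude_black_box Exclude the 140-200 cm black box from the
#'   out-of-zone speed (default FALSE: the whole track outside the reward
#'   zone counts).
#' @return `data.frame(trial_number, label, mean_rz_speed, mean_out_speed)`,
#'   class `"trial_outcomes"`; attribute `p95_rz_speed` records the try/run
#'   cut.
#' @export
classify_outcomes <- function(speeds, stops, reward_zone = c(60, 80),
                              unclassified_cut_cm_s = 10,
                              exclude_black_box = FALSE) {
  nt <- nrow(speeds)
  bins <- seq_len(ncol(speeds)) - 0.5
  rz <- bins >= reward_zone[1] & bins < reward_zone[2]
  out_zone <- !rz
  if (exclude_black_box) out_zone <- out_zone & bins < 140
  mean_rz <- rowMeans(speeds[, rz, drop = FALSE], na.rm = TRUE)
  mean_out <- rowMeans(speeds[, out_zone, drop = FALSE], na.rm = TRUE)
  stopped_in_rz <- tabulate(stops$trial_number[
    stops$pos_cm >= reward_zone[1] & stops$pos_cm < reward_zone[2]],
    nbins = nt) > 0
  label <- rep(NA_character_, nt)
  uncl <- !is.nan(mean_out) & mean_out < unclassified_cut_cm_s
  label[uncl] <- "unclassified"
  hit <- !uncl & stopped_in_rz
  label[hit] <- "hit"
  p95 <- if (any(hit)) stats::quantile(mean_rz[hit], 0.95, names = FALSE) else NA_real_
  rest <- !uncl & !hit
  if (any(hit)) {
    label[rest] <- ifelse(mean_rz[rest] < p95, "try", "run")
  }  # else: indeterminate, left NA
  out <- data.frame(trial_number = seq_len(nt), label = label,
                    mean_rz_speed = mean_rz, mean_out_speed = mean_out,
                    stringsAsFactors = FALSE)
  attr(out, "p95_rz_speed") <- p95
  class(out) <- c("trial_outcomes", "data.frame")
  out
}

#' Stop-density profile
#'
#' Counts stops within 1 cm location bins, divides by the number of trials
#' (stops/cm/trial) and smooths with a Gaussian filter (SD 1 cm).
#'
#' @param stops `data.frame(trial_number, pos_cm)` or a vector of positions.
#' @param n_trials Number of trials the stops came from.
#' @param track_length_cm Track length (cm).
#' @param smoothing_sd_cm Gaussian SD (cm).
#' @return Numeric vector of length `track_length_cm` (stops/cm/trial).
#' @export
stop_density <- function(stops, n_trials, track_length_cm = 200,
                         smoothing_sd_cm = 1) {
  if (n_trials <= 0) stop("n_trials must be positive")
  pos <- if (is.data.frame(stops)) stops$pos_cm else stops
  len <- as.integer(track_length_cm)
  counts <- tabulate(pmin(as.integer(pos) + 1L, len), nbins = len)
  smooth_gaussian(counts / n_trials, smoothing_sd_cm)
}

#' Baseline-subtracted stop density
#'
#' Subtracts from the observed stop-density profile the average of profiles
#' computed from shuffled stops in which each trial keeps its stop count but
#' stop locations are drawn uniformly over the track. Values below zero can
#' be read as below chance.
#'
#' @inheritParams stop_density
#' @param n_shuffles Number of shuffles averaged into the baseline.
#' @param seed Integer seed.
#' @return List with `density` (subtracted profile), `observed`, `baseline`.
#' @export
baseline_subtracted_density <- function(stops, n_trials, n_shuffles = 100,
                                        seed = 1L, track_length_cm = 200,
                                        smoothing_sd_cm = 1) {
  obs <- stop_density(stops, n_trials, track_length_cm, smoothing_sd_cm)
  n_stops <- if (is.data.frame(stops)) nrow(stops) else length(stops)
  base <- with_seed(seed, {
    acc <- numeric(track_length_cm)
    for (i in seq_len(n_shuffles)) {
      # per-trial stop counts are preserved: each stop is re-drawn uniformly
      pos <- stats::runif(n_stops, 0, track_length_cm)
      acc <- acc + stop_density(pos, n_trials, track_length_cm, smoothing_sd_cm)
    }
    acc / max(n_shuffles, 1L)
  })
  list(density = obs - base, observed = obs, baseline = base)
}

#' Weighted aggregation of profiles
#'
#' Weighted mean across profiles where each profile's weight is the product
#' of a code weight (proportion of trials in the coding scheme of interest)
#' and a session weight (1 / number of simultaneously recorded grid cells),
#' so that each session contributes as one unit.
#'
#' @param profiles Matrix, one profile per row (or list of vectors).
#' @param code_weights Numeric, one per profile.
#' @param session_weights Numeric, one per profile.
#' @return Numeric weighted-mean profile.
#' @export
weighted_aggregate <- function(profiles, code_weights, session_weights) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  w <- code_weights * session_weights
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w) == 0) stop("at least one weight must be positive")
  colSums(profiles * w) / sum(w)
}
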