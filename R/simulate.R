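# Synthetic sessions: constant-speed kinematics on a 200 cm virtual track,
# firing probability-density functions (PDFs) for grid / place / ramp /
# shuffled-field / noise cells, Bernoulli spike draws, and a configurable
# stopping-behaviour generator. Ground-truth per-trial labels are retained so
# every downstream stage can be validated.

TRIAL_TYPES <- c(B = "beaconed", N = "non_beaconed", P = "probe")

#' Simulation configuration
#'
#' Bundles the parameters of a synthetic session. Defaults reproduce the
#' standard simulated conditions: an agent moving at a constant 10 cm/s across
#' 100 trials of a 200 cm track, sampled at 1000 Hz, with spike probability
#' scaled by `p_max_spike = 0.1`.
#'
#' @param track_length_cm Track length per trial (cm).
#' @param speed_cm_s Constant running speed (cm/s).
#' @param n_trials Number of trials.
#' @param sample_rate_hz Position sampling rate (Hz).
#' @param p_max_spike Peak per-sample spike probability, in (0, 1].
#' @param grid_spacing_cm Grid field spacing lambda (cm); kernel SD is
#'   `0.1 * grid_spacing_cm`.
#' @param jitter_sd_cm SD of the Gaussian per-field jitter (cm); 0 disables.
#' @param mode Firing mode: `"anchored"`, `"independent"`,
#'   `"alternating_blocks"` or `"alternating_trials"`.
#' @param switch_prob Per-trial probability of switching PDF in block
#'   alternation.
#' @param trial_block_pattern Repeating trial-type block, a string over
#'   `B` (beaconed), `N` (non-beaconed), `P` (probe), e.g. `"BBN"`.
#' @param seed Integer seed; fans out to per-component sub-seeds.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(track_length_cm = 200, speed_cm_s = 10, n_trials = 100,
                       sample_rate_hz = 1000, p_max_spike = 0.1,
                       grid_spacing_cm = 70, jitter_sd_cm = 0,
                       mode = c("anchored", "independent",
                                "alternating_blocks", "alternating_trials"),
                       switch_prob = 0.1, trial_block_pattern = "BBN",
                       seed = 1L) {
  mode <- match.arg(mode)
  if (track_length_cm <= 0) stop("track_length_cm must be positive")
  if (speed_cm_s <= 0) stop("speed_cm_s must be positive")
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (p_max_spike <= 0 || p_max_spike > 1) stop("p_max_spike must be in (0, 1]")
  if (grid_spacing_cm <= 0) stop("grid_spacing_cm must be positive")
  if (jitter_sd_cm < 0) stop("jitter_sd_cm must be non-negative")
  if (switch_prob < 0 || switch_prob > 1) stop("switch_prob must be in [0, 1]")
  pat <- strsplit(trial_block_pattern, "")[[1]]
  if (length(pat) == 0 || !all(pat %in% names(TRIAL_TYPES))) {
    stop("trial_block_pattern must be a non-empty string over B, N, P")
  }
  structure(list(track_length_cm = track_length_cm, speed_cm_s = speed_cm_s,
                 n_trials = as.integer(n_trials),
                 sample_rate_hz = sample_rate_hz, p_max_spike = p_max_spike,
                 grid_spacing_cm = grid_spacing_cm, jitter_sd_cm = jitter_sd_cm,
                 mode = mode, switch_prob = switch_prob,
                 trial_block_pattern = trial_block_pattern,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trial types from a repeating block pattern
#' @keywords internal
trial_types_from_pattern <- function(pattern, n_trials) {
  pat <- strsplit(pattern, "")[[1]]
  unname(TRIAL_TYPES[rep_len(pat, n_trials)])
}

#' Constant-speed position trace
#'
#' Generates the kinematic reference frame: time stamps, within-trial
#' position, trial number, trial type (cycling the block pattern) and
#' cumulative distance, for an agent traversing the track at constant speed.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `time_s`, `pos_cm`, `trial_number`,
#'   `trial_type`, `cum_dist_cm`.
#' @export
make_position_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dt <- 1 / config$sample_rate_hz
  total_dist <- config$n_trials * config$track_length_cm
  duration <- total_dist / config$speed_cm_s
  n <- as.integer(round(duration * config$sample_rate_hz))
  time_s <- (seq_len(n) - 1L) * dt
  cum <- time_s * config$speed_cm_s
  trial <- pmin(as.integer(cum %/% config$track_length_cm) + 1L, config$n_trials)
  pos <- cum - (trial - 1L) * config$track_length_cm
  types <- trial_types_from_pattern(config$trial_block_pattern, config$n_trials)
  data.frame(time_s = time_s, pos_cm = pos, trial_number = trial,
             trial_type = types[trial], cum_dist_cm = cum,
             stringsAsFactors = FALSE)
}

#' @keywords internal
pdf_bin_centres <- function(track_length_cm) seq(0.5, track_length_cm - 0.5, by = 1)

#' @keywords internal
new_cell_pdf <- function(density, cell_kind, true_label = NULL) {
  stopifnot(all(density >= 0), all(density <= 1 + 1e-12))
  structure(list(density = density, cell_kind = cell_kind,
                 true_label_per_trial = true_label),
            class = "cell_pdf")
}

# Sum of truncated Gaussian kernels (+/- 4 SD) at the given centres, evaluated
# on 1 cm bin centres over [0, len).
#' @keywords internal
kernel_sum <- function(centres, sd, len) {
  x <- seq(0.5, len - 0.5, by = 1)
  out <- numeric(length(x))
  for (c0 in centres) {
    lo <- max(1L, as.integer(floor(c0 - 4 * sd)) + 1L)
    hi <- min(length(x), as.integer(ceiling(c0 + 4 * sd)))
    if (hi >= lo) {
      i <- lo:hi
      out[i] <- out[i] + exp(-(x[i] - c0)^2 / (2 * sd^2))
    }
  }
  out
}

#' Grid-cell firing PDF
#'
#' Places Gaussian kernels (SD = 0.1 * spacing) at equidistant locations.
#' Task-anchored cells keep the kernels at identical track positions on every
#' trial; task-independent cells continue the lattice across trial boundaries
#' in cumulative distance, so fields drift through the track reference frame
#' by `track mod spacing` per trial. Optional zero-mean Gaussian jitter (one
#' draw per field instance) displaces individual fields. The PDF is
#' renormalised to a maximum of 1.
#'
#' @param config A [sim_config()]; `mode` selects anchored vs independent.
#' @param mode Override of `config$mode` (only `"anchored"` or
#'   `"independent"` are meaningful here).
#' @param seed Override of the jitter seed.
#' @return A `"cell_pdf"` whose `density` is an `n_trials x track_length`
#'   matrix with values in `[0, 1]`.
#' @export
grid_pdf <- function(config, mode = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lambda <- config$grid_spacing_cm
  if (lambda <= 0) stop("grid spacing must be positive")
  mode <- if (is.null(mode)) config$mode else mode
  if (!mode %in% c("anchored", "independent")) {
    stop("grid_pdf generates 'anchored' or 'independent' PDFs")
  }
  sd <- 0.1 * lambda
  len <- config$track_length_cm
  nt <- config$n_trials
  seed <- if (is.null(seed)) derive_seed(config$seed, paste0("grid_", mode)) else seed
  dens <- with_seed(seed, {
    if (mode == "anchored") {
      base_centres <- seq(lambda / 2, len - 1e-9, by = lambda)
      m <- matrix(0, nt, len)
      for (t in seq_len(nt)) {
        jit <- if (config$jitter_sd_cm > 0) {
          stats::rnorm(length(base_centres), 0, config$jitter_sd_cm)
        } else 0
        m[t, ] <- kernel_sum(base_centres + jit, sd, len)
      }
      m
    } else {
      total <- nt * len
      centres <- seq(lambda / 2, total - 1e-9, by = lambda)
      jit <- if (config$jitter_sd_cm > 0) {
        stats::rnorm(length(centres), 0, config$jitter_sd_cm)
      } else 0
      flat <- kernel_sum(centres + jit, sd, total)
      matrix(flat, nt, len, byrow = TRUE)
    }
  })
  mx <- max(dens)
  if (mx > 0) dens <- dens / mx
  label <- rep(if (mode == "anchored") "TA" else "TI", nt)
  new_cell_pdf(dens, paste0("grid_", mode), label)
}

#' Non-grid firing PDFs
#'
#' `place`: one Gaussian kernel (mean 100 cm, SD 10 cm) repeated on every
#' trial. `ramp`: a linear ramp from 0 at the track start to 1 at the end.
#' `shuffled_field`: the place PDF passed through the field shuffle
#' ([field_shuffle()]). `noise`: a uniform PDF.
#'
#' @param kind One of `"place"`, `"ramp"`, `"shuffled_field"`, `"noise"`.
#' @param config A [sim_config()].
#' @param seed Seed for the shuffled-field variant.
#' @return A `"cell_pdf"`.
#' @export
nongrid_pdf <- function(kind = c("place", "ramp", "shuffled_field", "noise"),
                        config, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "sim_config"))
  len <- config$track_length_cm
  nt <- config$n_trials
  x <- pdf_bin_centres(len)
  row <- switch(kind,
    place = ,
    shuffled_field = exp(-(x - 100)^2 / (2 * 10^2)),
    ramp = x / len,
    noise = rep(1, len))
  dens <- matrix(row, nt, len, byrow = TRUE)
  if (kind == "shuffled_field") {
    seed <- if (is.null(seed)) derive_seed(config$seed, "shuffled_field") else seed
    flat <- as.vector(t(dens))
    fields <- detect_fields(flat)
    dens <- matrix(with_seed(seed, field_shuffle(flat, fields)), nt, len,
                   byrow = TRUE)
  }
  mx <- max(dens)
  if (mx > 0) dens <- dens / mx
  new_cell_pdf(dens, kind)
}

#' Merge anchored and independent PDFs with mode alternation
#'
#' In the `blocks` scheme the first trial is assigned to one PDF by a fair
#' coin and every subsequent trial switches to the other PDF with probability
#' `switch_prob`. In the `trials` scheme every trial is assigned by an
#' independent fair coin.
#'
#' @param anchored,independent `"cell_pdf"` objects with equal trial counts.
#' @param scheme `"blocks"` or `"trials"`.
#' @param switch_prob Per-trial switch probability (blocks scheme).
#' @param seed Integer seed.
#' @return A `"cell_pdf"` with `true_label_per_trial` in `{"TA", "TI"}`.
#' @export
alternate_modes <- function(anchored, independent, scheme = c("blocks", "trials"),
                            switch_prob = 0.1, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(anchored, "cell_pdf"), inherits(independent, "cell_pdf"))
  nt <- nrow(anchored$density)
  if (nrow(independent$density) != nt) stop("trial counts differ between PDFs")
  if (switch_prob < 0 || switch_prob > 1) stop("switch_prob must be in [0, 1]")
  labels <- with_seed(seed, {
    if (scheme == "blocks") {
      lab <- character(nt)
      lab[1] <- if (stats::runif(1) < 0.5) "TA" else "TI"
      if (nt > 1) {
        sw <- stats::runif(nt - 1) < switch_prob
        for (t in 2:nt) {
          lab[t] <- if (sw[t - 1]) setdiff(c("TA", "TI"), lab[t - 1]) else lab[t - 1]
        }
      }
      lab
    } else {
      ifelse(stats::runif(nt) < 0.5, "TA", "TI")
    }
  })
  dens <- anchored$density
  ti <- labels == "TI"
  dens[ti, ] <- independent$density[ti, , drop = FALSE]
  new_cell_pdf(dens, "grid_alternating", labels)
}

#' Draw a Bernoulli spike train from a firing PDF
#'
#' At every position sample a spike occurs independently with probability
#' `p_max_spike * density(position, trial)`.
#'
#' @param pdf A `"cell_pdf"`.
#' @param trace A position trace from [make_position_trace()].
#' @param p_max_spike Scalar in (0, 1].
#' @param seed Integer seed.
#' @return Numeric vector of spike times (s).
#' @export
draw_spikes <- function(pdf, trace, p_max_spike = 0.1, seed = 1L) {
  stopifnot(inherits(pdf, "cell_pdf"))
  if (p_max_spike <= 0 || p_max_spike > 1) stop("p_max_spike must be in (0, 1]")
  len <- ncol(pdf$density)
  bin <- pmin(as.integer(trace$pos_cm) + 1L, len)
  idx <- (trace$trial_number - 1L) * len + bin
  flat <- as.vector(t(pdf$density))
  p <- p_max_spike * flat[idx]
  with_seed(seed, trace$time_s[stats::runif(length(p)) < p])
}

#' Stopping-behaviour policy
#'
#' Describes per-trial stopping as a per-position stop probability, optionally
#' elevated inside the reward zone, optionally only on a subset of trials
#' (e.g. only while the simulated grid code is task-anchored).
#'
#' @param p_stop_base Per-visited-cm probability of initiating a stop outside
#'   the reward zone.
#' @param p_stop_rz Per-visited-cm stop probability inside the reward zone.
#' @param reward_zone Numeric length-2, default `c(60, 80)` cm.
#' @param active_trials Optional integer vector of trials on which
#'   `p_stop_rz` applies; other trials fall back to `p_stop_base` everywhere.
#' @param baseline_speed_cm_s Mean running speed between stops.
#' @param speed_noise_sd Gaussian SD of sampled speed (cm/s).
#' @param stop_duration_s Dwell time of each stop (s).
#' @return An object of class `"stop_policy"`.
#' @export
stop_policy <- function(p_stop_base = 0.002, p_stop_rz = 0.05,
                        reward_zone = c(60, 80), active_trials = NULL,
                        baseline_speed_cm_s = 40, speed_noise_sd = 5,
                        stop_duration_s = 0.5) {
  if (any(c(p_stop_base, p_stop_rz) < 0) || any(c(p_stop_base, p_stop_rz) > 1)) {
    stop("stop probabilities must be in [0, 1]")
  }
  structure(list(p_stop_base = p_stop_base, p_stop_rz = p_stop_rz,
                 reward_zone = reward_zone, active_trials = active_trials,
                 baseline_speed_cm_s = baseline_speed_cm_s,
                 speed_noise_sd = speed_noise_sd,
                 stop_duration_s = stop_duration_s),
            class = "stop_policy")
}

#' Simulate stopping behaviour over a position trace
#'
#' Overlays a synthetic running-speed channel on the kinematic reference
#' trace: baseline speed with Gaussian noise, interrupted by stops (speed
#' drawn below the 4.7 cm/s stop threshold) initiated per visited cm with the
#' policy's probabilities. The kinematic positions are left untouched; the
#' speed channel and registered stops are what the behaviour module consumes.
#'
#' @param trace Position trace.
#' @param policy A [stop_policy()].
#' @param seed Integer seed.
#' @param stop_threshold_cm_s Speed below which a sample counts as stopped.
#' @return List with `speed_cm_s` (per sample) and `stops`
#'   (`data.frame(trial_number, pos_cm)`).
#' @export
simulate_behaviour <- function(trace, policy = stop_policy(), seed = 1L,
                               stop_threshold_cm_s = 4.7) {
  stopifnot(inherits(policy, "stop_policy"))
  n <- nrow(trace)
  with_seed(seed, {
    speed <- stats::rnorm(n, policy$baseline_speed_cm_s, policy$speed_noise_sd)
    speed <- pmax(speed, stop_threshold_cm_s + 0.1)
    # candidate stop initiations: one Bernoulli per visited whole cm
    cm_mark <- c(TRUE, diff(floor(trace$cum_dist_cm)) >= 1)
    cand <- which(cm_mark)
    pos <- trace$pos_cm[cand]
    trial <- trace$trial_number[cand]
    in_rz <- pos >= policy$reward_zone[1] & pos < policy$reward_zone[2]
    rz_active <- if (is.null(policy$active_trials)) rep(TRUE, length(cand)) else
      trial %in% policy$active_trials
    p <- ifelse(in_rz & rz_active, policy$p_stop_rz, policy$p_stop_base)
    hit <- cand[stats::runif(length(cand)) < p]
    dt <- if (n > 1) stats::median(diff(trace$time_s)) else 1
    dur <- max(1L, as.integer(round(policy$stop_duration_s / dt)))
    stops <- data.frame(trial_number = integer(0), pos_cm = numeric(0))
    for (i in hit) {
      j <- i:min(n, i + dur - 1L)
      speed[j] <- pmax(stats::rnorm(length(j), 1, 0.5), 0)
      stops <- rbind(stops, data.frame(trial_number = trace$trial_number[i],
                                       pos_cm = trace$pos_cm[i]))
    }
    list(speed_cm_s = speed, stops = stops)
  })
}

#' Simulate a full session
#'
#' Convenience wrapper tying the generator together: kinematics, one or more
#' cells (each a firing mode with ground-truth labels), spike draws and
#' stopping behaviour.
#'
#' @param config A [sim_config()].
#' @param cells Named list of `"cell_pdf"` objects; defaults to a single cell
#'   built from `config$mode`.
#' @param policy A [stop_policy()] or `NULL` to skip behaviour.
#' @return An object of class `"synthetic_session"`: list with `positions`,
#'   `spikes` (named list of spike-time vectors), `truth` (named list of
#'   per-trial label vectors), `behaviour`, `config`.
#' @export
simulate_session <- function(config = sim_config(), cells = NULL,
                             policy = stop_policy()) {
  trace <- make_position_trace(config)
  if (is.null(cells)) {
    cells <- list(cell1 = switch(config$mode,
      anchored = grid_pdf(config, "anchored"),
      independent = grid_pdf(config, "independent"),
      alternating_blocks = alternate_modes(
        grid_pdf(config, "anchored"), grid_pdf(config, "independent"),
        "blocks", config$switch_prob, derive_seed(config$seed, "alt")),
      alternating_trials = alternate_modes(
        grid_pdf(config, "anchored"), grid_pdf(config, "independent"),
        "trials", seed = derive_seed(config$seed, "alt"))))
  }
  spikes <- lapply(seq_along(cells), function(i) {
    draw_spikes(cells[[i]], trace, config$p_max_spike,
                seed = derive_seed(config$seed, paste0("spikes_", names(cells)[i])))
  })
  names(spikes) <- names(cells)
  truth <- lapply(cells, function(p) p$true_label_per_trial)
  behaviour <- if (is.null(policy)) NULL else
    simulate_behaviour(trace, policy, seed = derive_seed(config$seed, "behaviour"))
  structure(list(positions = trace, spikes = spikes, truth = truth,
                 behaviour = behaviour, config = config),
            class = "synthetic_session")
}
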