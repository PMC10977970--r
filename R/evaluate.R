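# Validation harness: classifier accuracy and bias on simulated grid cells,
# swept over frequency tolerance, rolling window size, spike probability and
# field jitter. Following the simulated-data convention, no field shuffle is
# computed, which forces a two-way TA/TI decision.

#' Cell-level classifier evaluation
#'
#' Simulates `n_ta` task-anchored and `n_ti` task-independent grid cells with
#' spacings drawn uniformly from `spacing_range`, classifies each from its
#' session-average periodogram (forced two-way decision), and reports
#' prediction accuracy (% of cells correctly labelled) and prediction bias
#' (% of actual task-anchored cells minus % of predicted task-anchored
#' cells) for every combination of `tolerances`, `p_max_grid` and
#' `jitter_grid`.
#'
#' @param n_ta,n_ti Numbers of task-anchored / task-independent cells.
#' @param spacing_range Grid-spacing range (cm).
#' @param tolerances Frequency tolerances to sweep.
#' @param p_max_grid Values of the peak spike probability to sweep.
#' @param jitter_grid Field-jitter SDs (cm) to sweep.
#' @param n_trials Trials per simulated session.
#' @param seed Integer seed; sub-seeds are derived per sweep point and cell.
#' @return `data.frame` with columns `tolerance`, `p_max`, `jitter_sd`,
#'   `accuracy_pct`, `bias_pct`, `n_cells`.
#' @export
cell_level_eval <- function(n_ta = 50, n_ti = 50, spacing_range = c(40, 400),
                            tolerances = 0.05, p_max_grid = 0.1,
                            jitter_grid = 0, n_trials = 100, seed = 1L) {
  if (n_ta < 1 || n_ti < 1) stop("need at least one cell per class")
  if (length(tolerances) == 0) stop("empty tolerance sweep")
  res <- list()
  for (p_max in p_max_grid) for (jit in jitter_grid) {
    key <- sprintf("p%g_j%g", p_max, jit)
    cfg0 <- sim_config(p_max_spike = p_max, jitter_sd_cm = jit,
                       n_trials = n_trials, seed = derive_seed(seed, key))
    trace <- make_position_trace(cfg0)
    truth <- c(rep("TA", n_ta), rep("TI", n_ti))
    spacings <- with_seed(derive_seed(seed, paste0(key, "_spacing")),
                          stats::runif(n_ta + n_ti, spacing_range[1],
                                       spacing_range[2]))
    peak_freqs <- vapply(seq_along(truth), function(i) {
      cfg <- sim_config(p_max_spike = p_max, jitter_sd_cm = jit,
                        n_trials = n_trials, grid_spacing_cm = spacings[i],
                        mode = if (truth[i] == "TA") "anchored" else "independent",
                        seed = derive_seed(seed, paste0(key, "_cell", i)))
      pdf <- grid_pdf(cfg)
      spikes <- draw_spikes(pdf, trace, p_max,
                            seed = derive_seed(cfg$seed, "spk"))
      map <- linear_rate_map(spikes, trace)
      avg <- average_periodogram(lomb_scargle_windows(flatten_rate_signal(map)))
      peak_of(avg$freqs, avg$power)$freq
    }, numeric(1))
    dist <- vapply(peak_freqs, integer_distance, numeric(1))
    for (tol in tolerances) {
      pred <- ifelse(dist <= tol, "TA", "TI")
      res[[length(res) + 1L]] <- data.frame(
        tolerance = tol, p_max = p_max, jitter_sd = jit,
        accuracy_pct = 100 * mean(pred == truth),
        bias_pct = 100 * (mean(truth == "TA") - mean(pred == "TA")),
        n_cells = length(truth))
    }
  }
  do.call(rbind, res)
}

#' Trial-level classifier evaluation
#'
#' Simulates grid cells that alternate between task-anchored and
#' task-independent firing (in blocks of trials or every trial), classifies
#' every trial through the rolling-window pipeline (forced two-way decision)
#' for each window size, and reports the across-cell average per-trial
#' accuracy and bias.
#'
#' @param n_cells Number of simulated alternating cells.
#' @param alternation `"blocks"` or `"trials"`.
#' @param window_sizes Rolling window sizes (periodogram counts) to sweep.
#' @param switch_prob Block-alternation switch probability.
#' @param spacing_range Grid-spacing range (cm).
#' @param p_max Peak spike probability.
#' @param jitter_sd Field jitter SD (cm).
#' @param n_trials Trials per session.
#' @param tol Frequency tolerance.
#' @param seed Integer seed.
#' @return `data.frame` with `window_size`, `alternation`, `accuracy_pct`,
#'   `bias_pct`, `n_cells`.
#' @export
trial_level_eval <- function(n_cells = 100, alternation = c("blocks", "trials"),
                             window_sizes = 200, switch_prob = 0.1,
                             spacing_range = c(40, 400), p_max = 0.1,
                             jitter_sd = 0, n_trials = 100, tol = 0.05,
                             seed = 1L) {
  alternation <- match.arg(alternation)
  if (any(window_sizes < 1)) stop("window sizes must be at least 1")
  cfg0 <- sim_config(p_max_spike = p_max, jitter_sd_cm = jitter_sd,
                     n_trials = n_trials, seed = derive_seed(seed, "trace"))
  trace <- make_position_trace(cfg0)
  spacings <- with_seed(derive_seed(seed, "spacing"),
                        stats::runif(n_cells, spacing_range[1], spacing_range[2]))
  acc <- matrix(NA_real_, n_cells, length(window_sizes))
  bias <- matrix(NA_real_, n_cells, length(window_sizes))
  for (i in seq_len(n_cells)) {
    cfg <- sim_config(p_max_spike = p_max, jitter_sd_cm = jitter_sd,
                      n_trials = n_trials, grid_spacing_cm = spacings[i],
                      switch_prob = switch_prob,
                      seed = derive_seed(seed, paste0("cell", i)))
    merged <- alternate_modes(grid_pdf(cfg, "anchored"),
                              grid_pdf(cfg, "independent"),
                              scheme = alternation, switch_prob = switch_prob,
                              seed = derive_seed(cfg$seed, "alt"))
    spikes <- draw_spikes(merged, trace, p_max,
                          seed = derive_seed(cfg$seed, "spk"))
    map <- linear_rate_map(spikes, trace)
    pg <- lomb_scargle_windows(flatten_rate_signal(map))
    truth <- merged$true_label_per_trial
    for (w in seq_along(window_sizes)) {
      rc <- rolling_classify(pg, NULL, window_sizes[w], tol)
      raster <- assign_trials(rc$label, rc$midpoint_trial, n_trials)
      acc[i, w] <- 100 * mean(raster$label == truth)
      bias[i, w] <- 100 * (mean(truth == "TA") - mean(raster$label == "TA"))
    }
  }
  data.frame(window_size = window_sizes, alternation = alternation,
             accuracy_pct = colMeans(acc), bias_pct = colMeans(bias),
             n_cells = n_cells)
}
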