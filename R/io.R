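# Session interchange (CSV + JSON) and the pipeline driver. A session on disk
# is a directory with positions.csv (time_s, pos_cm, trial_number,
# trial_type, cum_dist_cm), spikes.csv (cell_id, time_s), optional
# speed.csv (time_s, speed_cm_s), optional truth.csv (cell_id, trial_number,
# label) for synthetic sessions, and config.json.

#' Write a synthetic session to a directory
#'
#' @param session A `"synthetic_session"` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) signif(col, 9) else col
    })
    df
  }
  utils::write.csv(fmt(session$positions), file.path(dir, "positions.csv"),
                   row.names = FALSE)
  spikes <- do.call(rbind, lapply(names(session$spikes), function(id) {
    if (length(session$spikes[[id]]) == 0) return(NULL)
    data.frame(cell_id = id, time_s = session$spikes[[id]])
  }))
  if (is.null(spikes)) spikes <- data.frame(cell_id = character(0),
                                            time_s = numeric(0))
  utils::write.csv(fmt(spikes), file.path(dir, "spikes.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(names(session$truth), function(id) {
    lab <- session$truth[[id]]
    if (is.null(lab)) return(NULL)
    data.frame(cell_id = id, trial_number = seq_along(lab), label = lab)
  }))
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  if (!is.null(session$behaviour)) {
    utils::write.csv(fmt(data.frame(time_s = session$positions$time_s,
                                    speed_cm_s = session$behaviour$speed_cm_s)),
                     file.path(dir, "speed.csv"), row.names = FALSE)
  }
  jsonlite::write_json(unclass(session$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session directory
#'
#' Validates the schema: required columns present, monotone non-decreasing
#' time and trial numbers, positions within `[0, track_length)`.
#'
#' @param dir Session directory.
#' @return Object of class `"session_bundle"`: `positions`, `spikes` (named
#'   list), `speed` (or NULL), `truth` (or NULL), `config` (or NULL).
#' @export
read_session <- function(dir) {
  need <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("missing session file: ", file)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  pos <- need("positions.csv")
  req <- c("time_s", "pos_cm", "trial_number", "trial_type", "cum_dist_cm")
  missing_cols <- setdiff(req, names(pos))
  if (length(missing_cols) > 0) {
    stop("positions.csv missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.unsorted(pos$time_s)) stop("positions.csv: time_s is not monotone")
  if (is.unsorted(pos$trial_number)) {
    stop("positions.csv: trial_number is not non-decreasing")
  }
  config <- if (file.exists(file.path(dir, "config.json"))) {
    jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  } else NULL
  track <- if (!is.null(config$track_length_cm)) config$track_length_cm else 200
  if (any(pos$pos_cm < 0 | pos$pos_cm >= track)) {
    stop("positions.csv: pos_cm outside [0, ", track, ")")
  }
  sp <- need("spikes.csv")
  if (!all(c("cell_id", "time_s") %in% names(sp))) {
    stop("spikes.csv missing column(s): cell_id and/or time_s")
  }
  spikes <- split(sp$time_s, sp$cell_id)
  speed <- if (file.exists(file.path(dir, "speed.csv"))) {
    utils::read.csv(file.path(dir, "speed.csv"))$speed_cm_s
  } else NULL
  truth <- if (file.exists(file.path(dir, "truth.csv"))) {
    tr <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
    lapply(split(tr, tr$cell_id), function(d) d$label[order(d$trial_number)])
  } else NULL
  structure(list(positions = pos, spikes = spikes, speed = speed,
                 truth = truth, config = config, dir = dir),
            class = "session_bundle")
}

#' Run the full analysis pipeline on a session
#'
#' Rate maps, periodograms, session / rolling / trial classification for
#' every cell, the common population label, behavioural outcomes (when a
#' speed channel is present) and a joined per-trial table. When `out_dir` is
#' given, results are written as CSV along with a JSON manifest recording
#' parameters and file checksums.
#'
#' @param bundle A `"session_bundle"` (or `"synthetic_session"`).
#' @param use_field_shuffle Compute field-shuffle thresholds (disable for
#'   simulated data, forcing the two-way TA/TI decision).
#' @param n_shuffles Shuffles per threshold.
#' @param window Rolling window size.
#' @param tol Frequency tolerance.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return Object of class `"pipeline_result"`: `cells` (list of
#'   `"gridcode"`), `common`, `outcomes`, `trial_table`, `manifest`.
#' @export
run_pipeline <- function(bundle, use_field_shuffle = TRUE, n_shuffles = 1000,
                         window = 200, tol = 0.05, seed = 1L, out_dir = NULL) {
  if (inherits(bundle, "synthetic_session")) {
    speed <- if (!is.null(bundle$behaviour)) bundle$behaviour$speed_cm_s else NULL
    bundle <- structure(list(positions = bundle$positions,
                             spikes = bundle$spikes, speed = speed,
                             truth = bundle$truth,
                             config = unclass(bundle$config)),
                        class = "session_bundle")
  }
  stopifnot(inherits(bundle, "session_bundle"))
  pos <- bundle$positions
  track <- if (!is.null(bundle$config$track_length_cm)) {
    bundle$config$track_length_cm
  } else 200
  n_trials <- max(pos$trial_number)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cells <- stage("classification", {
    lapply(seq_along(bundle$spikes), function(i) {
      classify_grid_code(bundle$spikes[[i]], pos, mode = "rolling",
                         use_field_shuffle = use_field_shuffle,
                         n_shuffles = n_shuffles, window = window, tol = tol,
                         track_length_cm = track,
                         seed = derive_seed(seed, names(bundle$spikes)[i]))
    })
  })
  names(cells) <- names(bundle$spikes)
  common <- stage("concordance", {
    common_label(lapply(cells, function(g) g$raster),
                 seed = derive_seed(seed, "common"))
  })
  outcomes <- NULL
  if (!is.null(bundle$speed)) {
    outcomes <- stage("behaviour", {
      sp <- speed_profile(pos, speed = bundle$speed, track_length_cm = track)
      stops <- detect_stops(pos, bundle$speed)
      classify_outcomes(sp, stops)
    })
  }
  trial_table <- data.frame(trial_number = seq_len(n_trials),
                            trial_type = pos$trial_type[
                              match(seq_len(n_trials), pos$trial_number)],
                            common_label = common,
                            stringsAsFactors = FALSE)
  for (id in names(cells)) {
    trial_table[[paste0("label_", id)]] <- cells[[id]]$raster$label
  }
  if (!is.null(outcomes)) trial_table$outcome <- outcomes$label
  manifest <- list(
    package_version = as.character(utils::packageVersion("gridtask")),
    seed = seed, window = window, tol = tol, n_shuffles = n_shuffles,
    use_field_shuffle = use_field_shuffle,
    parameters = list(stop_threshold_cm_s = 4.7, unclassified_cut_cm_s = 10,
                      percentile = 99, rate_map_smoothing_sd_cm = 2,
                      field_detection_sd_cm = 4, stop_density_sd_cm = 1,
                      arena_bin_cm = 2.5, shift_range_s = c(20, 580),
                      stable_session_cut_pct = 85))
  result <- structure(list(cells = cells, common = common, outcomes = outcomes,
                           trial_table = trial_table, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trial_table, file.path(out_dir, "trial_table.csv"),
                     row.names = FALSE)
    raster_wide <- do.call(cbind, lapply(cells, function(g) g$raster$label))
    utils::write.csv(data.frame(trial_number = seq_len(n_trials), raster_wide),
                     file.path(out_dir, "rasters.csv"), row.names = FALSE)
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$cells), "cell(s),",
      nrow(x$trial_table), "trials\n")
  for (id in names(x$cells)) {
    cat("  ", id, ": session ", x$cells[[id]]$session$label, "\n", sep = "")
  }
  if (!is.null(x$outcomes)) {
    tab <- table(x$outcomes$label, useNA = "ifany")
    cat("  outcomes: ",
        paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
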