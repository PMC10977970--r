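# Template-matching trial classifier: correlate each trial's firing rate
# profile against the mean profile of the task-anchored trials.

#' Build the task-anchored template of a unit
#'
#' Bin-wise mean of the smoothed rate map over trials labelled task-anchored
#' by the periodogram classifier. Units with fewer than 15% task-anchored
#' trials are discarded (no template of sufficient quality can be built).
#'
#' @param map A `"linear_rate_map"`.
#' @param raster Per-trial labels (`"trial_raster"` or character).
#' @param min_ta_fraction Eligibility cut (default 0.15).
#' @return Object of class `"ta_template"`: `template` (numeric, one value
#'   per bin), `eligible`, `ta_fraction`. When ineligible, `template` is
#'   `NULL`.
#' @export
build_template <- function(map, raster, min_ta_fraction = 0.15) {
  lab <- raster_labels(raster)
  if (length(lab) != nrow(map$rates)) stop("raster/map trial counts differ")
  frac <- mean(lab == "TA")
  if (frac < min_ta_fraction) {
    return(structure(list(template = NULL, eligible = FALSE,
                          ta_fraction = frac), class = "ta_template"))
  }
  tpl <- colMeans(map$rates[lab == "TA", , drop = FALSE], na.rm = TRUE)
  structure(list(template = tpl, eligible = TRUE, ta_fraction = frac),
            class = "ta_template")
}

#' Classify trials by correlation with the task-anchored template
#'
#' Pearson correlation between each trial's smoothed rate profile and the
#' template; trials with r of at least 0.5 are task-anchored positive
#' (`"TA_plus"`), others task-anchored negative (`"TA_minus"`). Bins flagged
#' unvisited are excluded pairwise; zero-variance trial profiles get an `NA`
#' correlation and label (flagged).
#'
#' @param map A `"linear_rate_map"`.
#' @param template A `"ta_template"` (eligible) or numeric profile.
#' @param r_threshold Correlation threshold (default 0.5).
#' @return `data.frame(trial_number, r, label)`.
#' @export
classify_by_template <- function(map, template, r_threshold = 0.5) {
  tpl <- if (inherits(template, "ta_template")) {
    if (!template$eligible) stop("unit ineligible: fewer than 15% TA trials")
    template$template
  } else template
  nt <- nrow(map$rates)
  r <- vapply(seq_len(nt), function(t) {
    y <- map$rates[t, ]
    ok <- map$visited[t, ] & !is.na(y) & !is.na(tpl)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(tpl[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(y[ok], tpl[ok])
  }, numeric(1))
  label <- ifelse(is.na(r), NA_character_,
                  ifelse(r >= r_threshold, "TA_plus", "TA_minus"))
  data.frame(trial_number = seq_len(nt), r = r, label = label,
             stringsAsFactors = FALSE)
}
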