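# Coding agreement between simultaneously recorded cells, splice shuffles of
# trial-label rasters, the common population label, epoch block-length
# statistics, and the task-anchored vs task-independent spatial-information
# contrast.

#' @keywords internal
raster_labels <- function(raster) {
  if (inherits(raster, "trial_raster") || is.data.frame(raster)) raster$label
  else as.character(raster)
}

#' Agreement score between two trial-label rasters
#'
#' The percentage of trials whose classifications agree. Trials where both
#' cells are aperiodic count as agreeing (same label).
#'
#' @param a,b Rasters (`"trial_raster"` or character vectors) of equal length.
#' @return Numeric percentage in `[0, 100]`.
#' @export
agreement <- function(a, b) {
  a <- raster_labels(a); b <- raster_labels(b)
  if (length(a) != length(b)) stop("rasters have different trial counts")
  100 * mean(a == b)
}

#' Splice shuffle of a trial-label raster
#'
#' Splices the raster where consecutive trials switch coding scheme and
#' reorders the resulting blocks at random, preserving each block's labels
#' (hence both the label multiset and the block-length multiset).
#'
#' @param raster Raster (labels).
#' @param n Number of shuffles.
#' @param seed Integer seed.
#' @return List of `n` shuffled label vectors.
#' @export
splice_shuffle <- function(raster, n = 10, seed = 1L) {
  lab <- raster_labels(raster)
  if (length(lab) == 0) stop("empty raster")
  r <- rle(lab)
  k <- length(r$values)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ord <- sample.int(k)
      out <- rep(r$values[ord], r$lengths[ord])
      # the reordered block structure (same-label blocks that land next to
      # each other would merge under a fresh run-length encoding)
      attr(out, "blocks") <- data.frame(label = r$values[ord],
                                        length = r$lengths[ord])
      out
    })
  })
}

#' Mean agreement against splice-shuffled rasters
#'
#' Shuffles the second raster `n` times (the choice of which member of the
#' pair is shuffled is immaterial, agreement being symmetric) and reports the
#' mean of the shuffled agreement scores.
#'
#' @inheritParams agreement
#' @param n Number of shuffles.
#' @param seed Integer seed.
#' @return List with `percent_agree`, `shuffle_mean`, `delta`.
#' @export
agreement_vs_shuffle <- function(a, b, n = 10, seed = 1L) {
  obs <- agreement(a, b)
  sh <- vapply(splice_shuffle(b, n, seed), agreement, numeric(1), a = a)
  list(percent_agree = obs, shuffle_mean = mean(sh), delta = obs - mean(sh))
}

#' Common population label across simultaneously recorded cells
#'
#' Per-trial modal label across the cells. For exactly two cells that do not
#' agree on 100% of trials, one cell is selected at random to represent the
#' population for the whole session. Modal ties with three or more cells are
#' broken in the fixed order TA, TI, aperiodic.
#'
#' @param rasters List of rasters (equal trial counts).
#' @param seed Integer seed (two-cell tie-break).
#' @return Character vector of per-trial labels.
#' @export
common_label <- function(rasters, seed = 1L) {
  if (length(rasters) == 0) stop("no rasters supplied")
  labs <- lapply(rasters, raster_labels)
  nt <- unique(vapply(labs, length, integer(1)))
  if (length(nt) != 1) stop("rasters have different trial counts")
  if (length(labs) == 1) return(labs[[1]])
  if (length(labs) == 2 && any(labs[[1]] != labs[[2]])) {
    pick <- with_seed(seed, sample.int(2, 1))
    return(labs[[pick]])
  }
  levels_ <- c("TA", "TI", "aperiodic")
  m <- do.call(rbind, labs)
  apply(m, 2L, function(v) {
    counts <- table(factor(v, levels = levels_))
    levels_[which.max(counts)]
  })
}

#' Run lengths of same-label epochs
#'
#' @param raster Raster (labels).
#' @return `data.frame(label, length)`; lengths sum to the trial count.
#' @export
epoch_blocks <- function(raster) {
  lab <- raster_labels(raster)
  r <- rle(lab)
  data.frame(label = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' Epoch block lengths against a trial-permutation null
#'
#' Compares the observed distribution of same-label block lengths with block
#' lengths from rasters whose trial labels are randomly permuted, using the
#' two-sample Kolmogorov-Smirnov statistic (computed directly from the
#' empirical CDFs; block lengths are heavily tied).
#'
#' @param raster Raster (labels).
#' @param n_shuffles Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed` (run lengths), `shuffled` (pooled run
#'   lengths), `ks_stat`, `degenerate` (TRUE when the raster has < 2 blocks).
#' @export
epoch_blocks_vs_shuffle <- function(raster, n_shuffles = 100, seed = 1L) {
  lab <- raster_labels(raster)
  obs <- rle(lab)$lengths
  degenerate <- length(obs) < 2L
  shuffled <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      rle(lab[sample.int(length(lab))])$lengths
    }))
  })
  grid <- sort(unique(c(obs, shuffled)))
  F1 <- stats::ecdf(obs)(grid)
  F2 <- stats::ecdf(shuffled)(grid)
  list(observed = obs, shuffled = shuffled, ks_stat = max(abs(F1 - F2)),
       degenerate = degenerate)
}

#' Spatial-information contrast between TA and TI epochs
#'
#' Percentage change in spatial information between task-anchored and
#' task-independent epochs, `100 * (SI_TA - SI_TI) / SI_TA`, after
#' equalising the number of trials contributed by each epoch.
#'
#' @param map A `"linear_rate_map"`.
#' @param labels Per-trial labels (the population label `G` or one cell's
#'   raster).
#' @param seed Integer seed for the trial-count equalisation.
#' @return List with `percent_change`, `si_ta`, `si_ti`, `n_trials_used`;
#'   `percent_change` is `NA` (flagged) if `SI_TA` is 0.
#' @export
spatial_info_contrast <- function(map, labels, seed = 1L) {
  labels <- raster_labels(labels)
  sub <- equalise_epoch_trials(labels, c("TA", "TI"), seed)
  si_ta <- spatial_information(map, trials = sub$TA)
  si_ti <- spatial_information(map, trials = sub$TI)
  pc <- if (si_ta == 0) NA_real_ else 100 * (si_ta - si_ti) / si_ta
  list(percent_change = pc, si_ta = si_ta, si_ti = si_ti,
       n_trials_used = length(sub$TA))
}
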