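# Flagellation accounting: per-cell count summaries with t-based
# confidence intervals, absolute population flagella from CFU, pole
# occupancy classes, hook-end statistics and swim-track velocimetry.

#' Mean per-cell flagella count with a t-based confidence interval
#'
#' Student-t interval on the mean of per-cell counts. Counts from
#' biological replicates may be pooled (default, matching the study's
#' 150-cell pooled counts) or averaged per replicate first.
#'
#' @param counts non-negative integer vector of flagella per cell, or,
#'   with `pooling = "perReplicate"`, a list of such vectors.
#' @param confidence confidence level (default 0.95).
#' @param pooling `"pooled"` (all cells as one sample) or
#'   `"perReplicate"` (replicate means as the sample).
#' @return named numeric: `mean`, `lo`, `hi`, `n`. With `n = 1` the
#'   interval is `NA` (flagged by a warning).
#' @examples
#' meanFlagellaCI(c(4, 6))  # mean 5, half-width qt(.975, 1) * 1
#' @export
meanFlagellaCI <- function(counts, confidence = 0.95,
                           pooling = c("pooled", "perReplicate")) {
  pooling <- match.arg(pooling)
  if (pooling == "perReplicate") {
    stopifnot(is.list(counts))
    counts <- vapply(counts, mean, 0)
  } else if (is.list(counts)) {
    counts <- unlist(counts)
  }
  stopifnot(length(counts) >= 1, all(counts >= 0))
  n <- length(counts)
  m <- mean(counts)
  if (n == 1L) {
    warning("single observation: confidence interval undefined")
    return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  }
  se <- stats::sd(counts) / sqrt(n)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * se
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

#' Absolute number of flagella in a population
#'
#' The mean per-cell flagella count scaled by the total viable cells
#' (CFU/ml times volume). Uncertainty from the mean's confidence interval
#' is propagated by the same scaling; CFU is treated as exact (the study
#' reports no CFU uncertainty).
#'
#' @param meanPerCell mean flagella per cell (or the `meanFlagellaCI`
#'   vector, in which case the interval is propagated).
#' @param cfuPerMl colony-forming units per ml.
#' @param volumeMl culture volume in ml (default 1).
#' @return named numeric: `estimate`, and `lo`/`hi` when an interval was
#'   supplied.
#' @examples
#' absoluteFlagella(2, 1e8)  # 2e8
#' @export
absoluteFlagella <- function(meanPerCell, cfuPerMl, volumeMl = 1) {
  stopifnot(all(cfuPerMl >= 0), volumeMl >= 0)
  cells <- cfuPerMl * volumeMl
  if (length(meanPerCell) > 1 && all(c("mean", "lo", "hi") %in%
                                     names(meanPerCell))) {
    stopifnot(meanPerCell[["mean"]] >= 0)
    return(c(estimate = unname(meanPerCell[["mean"]]) * cells,
             lo = unname(meanPerCell[["lo"]]) * cells,
             hi = unname(meanPerCell[["hi"]]) * cells))
  }
  stopifnot(length(meanPerCell) == 1, meanPerCell >= 0)
  c(estimate = unname(meanPerCell) * cells)
}

#' Fraction of sampled flagellar ends bearing a hook
#'
#' Every flagellum has two ends; under base-of-hook ejection exactly one
#' of them carries the hook, so exhaustive enumeration yields exactly 1/2;
#' mid-filament shearing yields 0. Sampling is uniform without replacement
#' over the 2n ends.
#'
#' @param flagella data.frame from [simulateDetachedFlagella()] (needs
#'   `end1_hook`, `end2_hook`).
#' @param endsSampled how many ends to sample; `NULL` (default) or any
#'   value >= 2n enumerates all ends exhaustively.
#' @param seed RNG seed for the sampling step.
#' @return named numeric: `fraction`, `hooked`, `sampled`.
#' @examples
#' fl <- simulateDetachedFlagella(10, "base_of_hook", seed = 1)
#' hookEndFraction(fl)["fraction"]  # exactly 0.5
#' @export
hookEndFraction <- function(flagella, endsSampled = NULL, seed = NULL) {
  stopifnot(all(c("end1_hook", "end2_hook") %in% names(flagella)))
  ends <- c(flagella$end1_hook, flagella$end2_hook)
  if (!is.null(endsSampled) && endsSampled < length(ends)) {
    stopifnot(endsSampled >= 1)
    ends <- .withSeed(seed, sample(ends, endsSampled))
  }
  c(fraction = mean(ends), hooked = sum(ends), sampled = length(ends))
}

#' Pole occupancy-class percentages
#'
#' Classifies poles by what they carry (both filaments and relics, only
#' filaments, only relics, or neither) and recomputes the class
#' percentages and per-pole averages, as tabulated from pole counts at
#' each growth stage.
#'
#' Input is either a per-pole table (`n_filaments`, `n_relics` per row)
#' or an aggregated class-count table (`n_poles`, `n_both`,
#' `n_filaments_only`, `n_relics_only`, `n_neither`).
#'
#' @param poles data.frame, per-pole or aggregated (see Details).
#' @return data.frame with one row per input group (`group` column taken
#'   from `od600` if present): `n_poles`, `pct_both`, `pct_filaments_only`,
#'   `pct_relics_only`, `pct_neither`, and, for per-pole input, the
#'   per-pole filament/relic averages.
#' @examples
#' tab <- data.frame(od600 = c(0.25, 1.0), n_poles = c(44, 25),
#'                   n_both = c(21, 9), n_filaments_only = c(19, 0),
#'                   n_relics_only = c(0, 3), n_neither = c(4, 13))
#' occupancyPercentages(tab)
#' @export
occupancyPercentages <- function(poles) {
  aggCols <- c("n_poles", "n_both", "n_filaments_only", "n_relics_only",
               "n_neither")
  if (all(aggCols %in% names(poles))) {
    stopifnot(all(poles$n_both + poles$n_filaments_only +
                  poles$n_relics_only + poles$n_neither == poles$n_poles))
    out <- data.frame(
      group = if ("od600" %in% names(poles)) poles$od600
              else seq_len(nrow(poles)),
      n_poles = poles$n_poles,
      pct_both = 100 * poles$n_both / poles$n_poles,
      pct_filaments_only = 100 * poles$n_filaments_only / poles$n_poles,
      pct_relics_only = 100 * poles$n_relics_only / poles$n_poles,
      pct_neither = 100 * poles$n_neither / poles$n_poles)
    return(out)
  }
  stopifnot(all(c("n_filaments", "n_relics") %in% names(poles)))
  grp <- if ("od600" %in% names(poles)) poles$od600 else rep(1, nrow(poles))
  do.call(rbind, lapply(unique(grp), function(g) {
    sub <- poles[grp == g, ]
    f <- sub$n_filaments > 0; r <- sub$n_relics > 0
    data.frame(group = g, n_poles = nrow(sub),
               pct_both = 100 * mean(f & r),
               pct_filaments_only = 100 * mean(f & !r),
               pct_relics_only = 100 * mean(!f & r),
               pct_neither = 100 * mean(!f & !r),
               avg_filaments_all = mean(sub$n_filaments),
               avg_relics_all = mean(sub$n_relics),
               avg_filaments_if_present = if (any(f))
                 mean(sub$n_filaments[f]) else NA_real_,
               avg_relics_if_present = if (any(r))
                 mean(sub$n_relics[r]) else NA_real_)
  }))
}

#' Speed of one swim track
#'
#' Path-length speed: frame-to-frame displacements summed and divided by
#' elapsed time. The net-displacement speed (start-to-end distance over
#' elapsed time) is reported alongside; for the short 10 s tracks of
#' interest the path-length definition is the primary one.
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um` (times strictly
#'   increasing).
#' @return named numeric: `speed` (um/s, path length based),
#'   `net_speed`, `path_um`, `duration_s`.
#' @examples
#' tr <- data.frame(t_s = 0:1, x_um = c(0, 10), y_um = 0)
#' trackSpeed(tr)["speed"]  # 10
#' @export
trackSpeed <- function(track) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)),
            nrow(track) >= 2, all(diff(track$t_s) > 0))
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  dur <- track$t_s[nrow(track)] - track$t_s[1]
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  c(speed = sum(steps) / dur, net_speed = net / dur,
    path_um = sum(steps), duration_s = dur)
}

#' Cohort swim-speed summary
#'
#' Mean speed with standard error, speed relative to a baseline (e.g. the
#' early-growth speed), and the fraction of motile tracks. The motility
#' threshold is a package default (5 um/s, configurable and reported);
#' the source data state none.
#'
#' @param tracks data.frame of track samples (`track_id`, `t_s`, `x_um`,
#'   `y_um`).
#' @param baselineSpeed reference speed in um/s for the relative measure
#'   (NA to skip).
#' @param motilityThreshold um/s above which a track counts as motile
#'   (default 5).
#' @return named numeric: `mean_speed`, `se`, `relative_to_baseline`,
#'   `fraction_motile`, `n_tracks`, `motility_threshold`.
#' @export
cohortSpeedSummary <- function(tracks, baselineSpeed = NA,
                               motilityThreshold = 5) {
  ids <- unique(tracks$track_id)
  speeds <- vapply(ids, function(id) {
    trackSpeed(tracks[tracks$track_id == id, ])[["speed"]]
  }, 0)
  c(mean_speed = mean(speeds),
    se = stats::sd(speeds) / sqrt(length(speeds)),
    relative_to_baseline = if (is.na(baselineSpeed)) NA_real_
                           else mean(speeds) / baselineSpeed,
    fraction_motile = mean(speeds > motilityThreshold),
    n_tracks = length(speeds),
    motility_threshold = motilityThreshold)
}
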