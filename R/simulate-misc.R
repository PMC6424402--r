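#' Simulate detached (shed) flagella
#'
#' A flagellum has exactly two ends and carries a hook at exactly one of
#' them iff it was released at the base of the hook (determinate
#' ejection); filaments sheared mid-filament carry no hook at either
#' broken end. This construction drives the end-sampling statistic: 50%
#' of ends are hooked under base-of-hook ejection, 0% under shearing.
#'
#' @param n number of flagella (>= 1).
#' @param breakMode `"base_of_hook"` or `"midfilament"`; may be a vector
#'   of length `n` for mixed populations.
#' @param seed RNG seed (which end carries the hook is random).
#' @return data.frame: `id`, `break_mode`, `hook_end` (1 or 2, NA when no
#'   hook), `end1_hook`, `end2_hook` (logical).
#' @examples
#' fl <- simulateDetachedFlagella(100, "base_of_hook", seed = 1)
#' sum(fl$end1_hook) + sum(fl$end2_hook)  # 100 hooks over 200 ends
#' @export
simulateDetachedFlagella <- function(n, breakMode = c("base_of_hook",
                                                      "midfilament"),
                                     seed = NULL) {
  stopifnot(n >= 1)
  if (length(breakMode) != n)
    breakMode <- rep(match.arg(breakMode), n)
  stopifnot(all(breakMode %in% c("base_of_hook", "midfilament")))
  .withSeed(seed, {
    hookEnd <- ifelse(breakMode == "base_of_hook",
                      sample(c(1L, 2L), n, replace = TRUE), NA_integer_)
    data.frame(id = sprintf("fl%d", seq_len(n)), break_mode = breakMode,
               hook_end = hookEnd,
               end1_hook = !is.na(hookEnd) & hookEnd == 1L,
               end2_hook = !is.na(hookEnd) & hookEnd == 2L,
               stringsAsFactors = FALSE)
  })
}

#' Simulate swim tracks
#'
#' Straight runs with optional heading noise: each track has a constant
#' ground-truth speed drawn from N(`speedMean`, `speedSD`) (truncated at
#' 0), and a heading that random-walks with SD `headingSD` radians per
#' frame. Because speed is constant along the track, the path-length
#' estimator recovers the ground truth exactly when `headingSD` leaves
#' frame displacements unchanged (it does; heading noise bends the path
#' without shortening frame steps).
#'
#' @param nTracks number of tracks.
#' @param speedMean,speedSD mean and SD of track speeds (um/s).
#' @param duration track duration in s (default 10, the study's tracking
#'   window).
#' @param frameDt frame interval in s (default 0.1).
#' @param headingSD per-frame heading noise SD in radians (default 0.2).
#' @param seed RNG seed.
#' @return data.frame `track_id`, `t_s`, `x_um`, `y_um` with the per-track
#'   ground-truth speeds in `attr(, "trueSpeeds")`.
#' @export
simulateTracks <- function(nTracks, speedMean = 40, speedSD = 5,
                           duration = 10, frameDt = 0.1, headingSD = 0.2,
                           seed = NULL) {
  stopifnot(nTracks >= 1, duration / frameDt >= 2, speedMean >= 0,
            speedSD >= 0)
  .withSeed(seed, {
    nFrames <- floor(duration / frameDt) + 1L
    t_s <- (seq_len(nFrames) - 1L) * frameDt
    speeds <- pmax(0, stats::rnorm(nTracks, speedMean, speedSD))
    tracks <- lapply(seq_len(nTracks), function(i) {
      heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                          stats::rnorm(nFrames - 2L, 0, headingSD)))
      step <- speeds[i] * frameDt
      x <- cumsum(c(0, step * cos(heading)))
      y <- cumsum(c(0, step * sin(heading)))
      data.frame(track_id = sprintf("tr%d", i), t_s = t_s,
                 x_um = x, y_um = y, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tracks)
    attr(out, "trueSpeeds") <- speeds
    out
  })
}

#' Write / read swim-track tables
#'
#' TSV with columns `track_id`, `t_s`, `x_um`, `y_um`.
#' @param tracks data.frame as returned by [simulateTracks()].
#' @param path file path.
#' @export
writeTrackTable <- function(tracks, path) {
  utils::write.table(tracks[, c("track_id", "t_s", "x_um", "y_um")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Simulate periplasmic distance measurements
#'
#' Draws inner-membrane-to-outer-disk distances for motor and relic
#' classes from uniform distributions parametrised by (mean, full range),
#' so the configured range is the large-sample limit of the observed
#' sample range. Relics, lacking an inner-membrane connection, are
#' expected to show the larger spread.
#'
#' @param classParams data.frame with columns `klass`, `mean_nm`,
#'   `range_nm` (one row per class). Defaults encode the study's observed
#'   spreads: relic range 13.9 nm, motor range 7.9 nm, around a 20 nm
#'   periplasmic distance.
#' @param nPerClass measurements per class.
#' @param seed RNG seed.
#' @return data.frame `structure_id`, `klass`, `distance_nm`.
#' @export
simulatePeriplasmMeasurements <- function(
    classParams = data.frame(klass = c("motor", "relic"),
                             mean_nm = c(20, 20),
                             range_nm = c(7.9, 13.9)),
    nPerClass = 50L, seed = NULL) {
  stopifnot(all(c("klass", "mean_nm", "range_nm") %in% names(classParams)),
            all(classParams$range_nm >= 0),
            all(classParams$mean_nm > classParams$range_nm / 2),
            nPerClass >= 1)
  .withSeed(seed, {
    do.call(rbind, lapply(seq_len(nrow(classParams)), function(i) {
      m <- classParams$mean_nm[i]; r <- classParams$range_nm[i]
      data.frame(
        structure_id = sprintf("%s%d", classParams$klass[i],
                               seq_len(nPerClass)),
        klass = classParams$klass[i],
        distance_nm = stats::runif(nPerClass, m - r / 2, m + r / 2),
        stringsAsFactors = FALSE)
    }))
  })
}
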