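# Periplasmic distance morphometrics: compare the spread of
# inner-membrane-to-outer-disk distances at intact motors vs. relics.
# A wider spread at relics indicates no physical tether to the inner
# membrane. Quartiles use the linear-interpolation convention
# (`stats::quantile` type 7) so summaries are bit-reproducible.

#' Summary statistics of periplasmic distances for one class
#'
#' @param measurements data.frame with `klass` and `distance_nm`
#'   (positive).
#' @param klass which class to summarize (`"motor"` or `"relic"`); NULL
#'   summarizes all rows.
#' @return one-row data.frame: `klass`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `range` (max - min), all nm.
#' @examples
#' df <- data.frame(klass = "motor", distance_nm = c(10, 12, 14))
#' summarizeDistances(df, "motor")  # median 12, range 4
#' @export
summarizeDistances <- function(measurements, klass = NULL) {
  stopifnot(all(c("klass", "distance_nm") %in% names(measurements)))
  if (!is.null(klass))
    measurements <- measurements[measurements$klass == klass, ]
  d <- measurements$distance_nm
  if (length(d) < 1)
    stop("no measurements", if (!is.null(klass))
      paste0(" for class '", klass, "'") else "")
  stopifnot(all(d > 0))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(klass = if (is.null(klass)) "all" else klass,
             n = length(d), mean = mean(d), median = q[2],
             q1 = q[1], q3 = q[3], range = max(d) - min(d),
             stringsAsFactors = FALSE)
}

#' Compare the distance ranges of two classes
#'
#' Reports the difference in range (max - min) and which class varies
#' more; deliberately descriptive, with no inferential claim.
#'
#' @param summaryA,summaryB rows from [summarizeDistances()].
#' @return list: `difference` (|range A - range B|, nm), `larger` (the
#'   `klass` with the larger range, `"equal"` on a tie).
#' @export
compareRanges <- function(summaryA, summaryB) {
  d <- summaryA$range - summaryB$range
  list(difference = abs(d),
       larger = if (d > 0) summaryA$klass
                else if (d < 0) summaryB$klass
                else "equal")
}
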