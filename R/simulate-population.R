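# Stochastic population simulator: per-cell flagellar birth-death dynamics
# on top of logistic culture growth. Two modes contrast the two lifestyles
# in the study: polar ejection (flagella are actively shed once the
# culture passes a nutrient-depletion trigger OD) and peritrichous
# dilution (no ejection; a cell's flagella are split binomially between
# daughters at division, as for Salmonella).

#' Specify a population flagellation model
#'
#' Rates are illustrative defaults chosen once for qualitative realism:
#' the growth rate corresponds to a 19-minute doubling time in fresh
#' medium, the trigger OD of 0.8 is where swimming collapses, and the
#' initial per-cell flagella distribution is Poisson with mean 5 (polar
#' poles carry ~5 filaments early in growth).
#'
#' @param mode `"polar_ejection"` or `"peritrichous_dilution"`.
#' @param growthRate culture growth rate, per hour (default
#'   `log(2) / (19/60)`).
#' @param assemblyRate flagella assembled per cell per hour (default 0.5).
#' @param ejectionRate per-flagellum ejection rate after the trigger, per
#'   hour (default 2; polar mode only).
#' @param triggerOD OD600 at which nutrient depletion triggers ejection
#'   (default 0.8).
#' @param carryingCapacity logistic OD600 plateau (default 1.2).
#' @param initialOD OD600 at time 0 (default 0.2).
#' @param initialMeanFlagella mean of the Poisson initial per-cell count
#'   (default 5).
#' @param cfuPerOD CFU per ml per OD600 unit (default 5e8).
#' @return list of class `PopulationModel`.
#' @export
populationModel <- function(mode = c("polar_ejection",
                                     "peritrichous_dilution"),
                            growthRate = log(2) / (19 / 60),
                            assemblyRate = 0.5, ejectionRate = 2,
                            triggerOD = 0.8, carryingCapacity = 1.2,
                            initialOD = 0.2, initialMeanFlagella = 5,
                            cfuPerOD = 5e8) {
  mode <- match.arg(mode)
  stopifnot(growthRate >= 0, assemblyRate >= 0, ejectionRate >= 0,
            triggerOD > 0, carryingCapacity > initialOD, initialOD > 0,
            initialMeanFlagella >= 0, cfuPerOD > 0)
  structure(list(mode = mode, growthRate = growthRate,
                 assemblyRate = assemblyRate, ejectionRate = ejectionRate,
                 triggerOD = triggerOD, carryingCapacity = carryingCapacity,
                 initialOD = initialOD,
                 initialMeanFlagella = initialMeanFlagella,
                 cfuPerOD = cfuPerOD),
            class = "PopulationModel")
}

# Logistic OD(t) and the time at which it reaches a given OD.
.odAt <- function(model, t) {
  K <- model$carryingCapacity; od0 <- model$initialOD; r <- model$growthRate
  K / (1 + (K - od0) / od0 * exp(-r * t))
}

.timeAtOD <- function(model, od) {
  K <- model$carryingCapacity; od0 <- model$initialOD; r <- model$growthRate
  if (od >= K) return(Inf)
  if (od <= od0) return(0)
  log(((K - od0) / od0) / ((K - od) / od)) / r
}

#' Simulate a flagellation time course
#'
#' Per-cell flagellar counts evolve by an exact event-driven (Gillespie)
#' birth-death process: assembly events at the constant `assemblyRate`,
#' and, in polar-ejection mode once the culture OD has passed `triggerOD`,
#' ejection events at `ejectionRate` per attached flagellum. In
#' peritrichous-dilution mode there is no ejection; instead each simulated
#' lineage divides at the growth rate and keeps a Binomial(k, 1/2) share
#' of its flagella. CFU follows the logistic growth curve.
#'
#' @param model a [populationModel()].
#' @param timepoints increasing vector of times in hours.
#' @param nCells number of sample cells tracked per time course
#'   (default 150, as counted in the study's micrographs).
#' @param seed RNG seed.
#' @return list with `timepoints` (data.frame: `t_h`, `od600`,
#'   `cfu_per_ml`, `mean_flagella`, `ci95_lo`, `ci95_hi`,
#'   `absolute_flagella`) and `counts` (nCells x length(timepoints) matrix
#'   of per-cell counts).
#' @examples
#' m <- populationModel("polar_ejection")
#' sim <- simulatePopulation(m, timepoints = c(0, 1, 2, 3), seed = 1)
#' sim$timepoints
#' @export
simulatePopulation <- function(model, timepoints, nCells = 150L,
                               seed = NULL) {
  stopifnot(inherits(model, "PopulationModel"),
            length(timepoints) >= 1L, all(diff(timepoints) > 0),
            all(timepoints >= 0), nCells >= 1L)
  .withSeed(seed, {
    tEnd <- max(timepoints)
    tTrig <- if (model$mode == "polar_ejection")
      .timeAtOD(model, model$triggerOD) else Inf
    counts <- vapply(seq_len(nCells), function(cell) {
      .simulateCell(model, timepoints, tTrig)
    }, numeric(length(timepoints)))
    counts <- t(matrix(counts, nrow = length(timepoints)))
    od <- .odAt(model, timepoints)
    cfu <- od * model$cfuPerOD
    tp <- do.call(rbind, lapply(seq_along(timepoints), function(i) {
      ci <- meanFlagellaCI(counts[, i])
      abs <- absoluteFlagella(ci["mean"], cfu[i])
      data.frame(t_h = timepoints[i], od600 = od[i], cfu_per_ml = cfu[i],
                 mean_flagella = unname(ci["mean"]),
                 ci95_lo = unname(ci["lo"]), ci95_hi = unname(ci["hi"]),
                 absolute_flagella = unname(abs["estimate"]))
    }))
    list(timepoints = tp, counts = counts, triggerTime = tTrig)
  })
}

# Exact birth-death trajectory of one cell, sampled at `timepoints`.
# Division events (peritrichous mode) occur at the growth rate.
.simulateCell <- function(model, timepoints, tTrig) {
  k <- stats::rpois(1, model$initialMeanFlagella)
  t <- 0
  tEnd <- max(timepoints)
  out <- numeric(length(timepoints))
  nextIdx <- 1L
  record <- function(upto) {
    while (nextIdx <= length(timepoints) && timepoints[nextIdx] <= upto) {
      out[nextIdx] <<- k
      nextIdx <<- nextIdx + 1L
    }
  }
  repeat {
    a <- model$assemblyRate
    ej <- if (model$mode == "polar_ejection" && t >= tTrig)
      model$ejectionRate * k else 0
    dv <- if (model$mode == "peritrichous_dilution") model$growthRate else 0
    total <- a + ej + dv
    # next ejection may switch on mid-interval: cap the jump at tTrig
    tNext <- if (total == 0) Inf else t + stats::rexp(1, total)
    if (model$mode == "polar_ejection" && t < tTrig && tNext > tTrig &&
        tTrig <= tEnd) {
      record(tTrig)
      t <- tTrig
      next
    }
    if (tNext > tEnd) {
      record(tEnd)
      break
    }
    record(tNext)
    t <- tNext
    u <- stats::runif(1, 0, total)
    if (u < a) {
      k <- k + 1L
    } else if (u < a + ej) {
      k <- max(0L, k - 1L)
    } else {
      k <- stats::rbinom(1, k, 0.5)
    }
  }
  out
}

#' Write / read a population time-course table
#'
#' TSV with one row per timepoint: `t_h`, `od600`, `cfu_per_ml`, and the
#' per-cell counts joined as a comma-separated list in `counts`.
#'
#' @param sim result of [simulatePopulation()].
#' @param path file path.
#' @return `writePopulationTable`: path invisibly; `readPopulationTable`:
#'   list with `timepoints` data.frame and `counts` matrix.
#' @export
writePopulationTable <- function(sim, path) {
  tp <- sim$timepoints
  df <- data.frame(t_h = tp$t_h, od600 = tp$od600,
                   cfu_per_ml = tp$cfu_per_ml,
                   counts = apply(sim$counts, 2, paste, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePopulationTable
#' @export
readPopulationTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- sapply(strsplit(df$counts, ","), as.integer)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  list(timepoints = df[, c("t_h", "od600", "cfu_per_ml")],
       counts = counts)
}
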