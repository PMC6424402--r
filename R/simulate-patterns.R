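# Point-pattern generators for cell poles. These encode the placement
# hypotheses the spatial analysis discriminates: complete spatial
# randomness (uniform), steric-clash-only placement (hardcore, random
# sequential adsorption), a jittered hexagonal grid (the dispersion the
# data resemble), and a Thomas cluster process (the R < 1 alternative).

#' Specify a pole point-pattern model
#'
#' @param kind `"uniform"`, `"hardcore"`, `"grid"`, or `"cluster"`.
#' @param nPoints number of structures to place (>= 1).
#' @param semiAxes ellipse semi-axes (a, b) in nm; default 200 x 150,
#'   a realistic pole-projection size.
#' @param exclusionDiameter hard-core exclusion in nm (default 45, one
#'   C-ring diameter); used by `kind = "hardcore"`.
#' @param latticeSpacing hexagonal lattice constant in nm (grid).
#' @param jitterSD isotropic Gaussian jitter SD in nm applied to lattice
#'   points (grid; 0 = perfect lattice).
#' @param nParents Thomas-process parent count (cluster).
#' @param offspringSD Gaussian offspring SD in nm around parents (cluster).
#' @param motorFraction probability a point is labelled `motor` rather
#'   than `relic` (default 0.5).
#' @return list of class `PatternModel`.
#' @examples
#' m <- patternModel("hardcore", nPoints = 6, exclusionDiameter = 45)
#' p <- simulatePole(m, seed = 1)
#' min(nearestNeighborDistances(p))  # >= 45
#' @export
patternModel <- function(kind = c("uniform", "hardcore", "grid", "cluster"),
                         nPoints, semiAxes = c(200, 150),
                         exclusionDiameter = 45, latticeSpacing = 64,
                         jitterSD = 0, nParents = 2, offspringSD = 10,
                         motorFraction = 0.5) {
  kind <- match.arg(kind)
  stopifnot(nPoints >= 1, length(semiAxes) == 2L, all(semiAxes > 0),
            exclusionDiameter > 0, latticeSpacing > 0, jitterSD >= 0,
            nParents >= 1, offspringSD > 0,
            motorFraction >= 0, motorFraction <= 1)
  if (kind == "hardcore") {
    # feasibility guard: disks must not claim more than ~half the ellipse
    packing <- nPoints * pi * (exclusionDiameter / 2)^2
    if (packing > 0.5 * pi * semiAxes[1] * semiAxes[2])
      stop("infeasible hard-core packing: ", nPoints, " exclusion disks ",
           "exceed half the ellipse area")
  }
  structure(list(kind = kind, nPoints = as.integer(nPoints),
                 semiAxes = as.numeric(semiAxes),
                 exclusionDiameter = exclusionDiameter,
                 latticeSpacing = latticeSpacing, jitterSD = jitterSD,
                 nParents = as.integer(nParents), offspringSD = offspringSD,
                 motorFraction = motorFraction),
            class = "PatternModel")
}

#' Simulate one cell-pole point pattern
#'
#' Deterministic given `(model, seed)`. All points lie inside the model
#' ellipse; the hard-core generator guarantees all pairwise distances are
#' at least the exclusion diameter (random sequential adsorption with a
#' retry cap of 1e4 per point); the grid generator places the `nPoints`
#' hexagonal lattice sites closest to the pole centre and adds isotropic
#' Gaussian jitter (resampled while outside the ellipse); the cluster
#' generator is a Thomas process with uniformly placed parents.
#'
#' @param model a [patternModel()].
#' @param poleId identifier for the resulting pattern.
#' @param cringDiameter C-ring diameter attached to the pattern (nm).
#' @param seed RNG seed (NULL = use current stream).
#' @return a [PolePattern-class] with exactly `model$nPoints` points.
#' @export
simulatePole <- function(model, seed = NULL, poleId = "sim",
                         cringDiameter = 45) {
  stopifnot(inherits(model, "PatternModel"))
  .withSeed(seed, {
    a <- model$semiAxes[1]; b <- model$semiAxes[2]
    n <- model$nPoints
    xy <- switch(model$kind,
      uniform = .runifEllipse(n, a, b),
      hardcore = .rsaPack(n, a, b, model$exclusionDiameter),
      grid = .hexPattern(n, a, b, model$latticeSpacing, model$jitterSD),
      cluster = .thomasPattern(n, a, b, model$nParents, model$offspringSD))
    labels <- ifelse(stats::runif(n) < model$motorFraction, "motor", "relic")
    PolePattern(poleId, xy[, 1], xy[, 2], labels, cringDiameter)
  })
}

# Random sequential adsorption of n hard disks in an ellipse.
.rsaPack <- function(n, a, b, exclusion, retryCap = 1e4) {
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retryCap)) {
      cand <- .runifEllipse(1, a, b)
      if (i == 1L || all(sqrt((pts[seq_len(i - 1), 1] - cand[1])^2 +
                              (pts[seq_len(i - 1), 2] - cand[2])^2)
                         >= exclusion)) {
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "hard-core packing saturated: placed %d of %d points (exclusion %.1f nm)",
        i - 1L, n, exclusion))
  }
  colnames(pts) <- c("x_nm", "y_nm")
  pts
}

# The nPoints hexagonal lattice sites nearest the centre, jittered.
.hexPattern <- function(n, a, b, spacing, jitterSD) {
  dy <- spacing * sqrt(3) / 2
  jmax <- ceiling(b / dy) + 2L
  imax <- ceiling(a / spacing) + 2L
  rows <- lapply(seq(-jmax, jmax), function(j) {
    xoff <- if (j %% 2 == 0) 0 else spacing / 2
    cbind(seq(-imax, imax) * spacing + xoff, j * dy)
  })
  lattice <- do.call(rbind, rows)
  keep <- .inEllipse(lattice, a, b)
  lattice <- lattice[keep, , drop = FALSE]
  if (nrow(lattice) < n)
    stop(sprintf("lattice spacing %.1f nm fits only %d sites in the ellipse (%d requested)",
                 spacing, nrow(lattice), n))
  ord <- order(lattice[, 1]^2 / a^2 + lattice[, 2]^2 / b^2)
  pts <- lattice[ord[seq_len(n)], , drop = FALSE]
  if (jitterSD > 0) {
    for (i in seq_len(n)) {
      repeat {
        cand <- pts[i, ] + stats::rnorm(2, 0, jitterSD)
        if (.inEllipse(matrix(cand, 1), a, b)) { pts[i, ] <- cand; break }
      }
    }
  }
  colnames(pts) <- c("x_nm", "y_nm")
  pts
}

# Thomas process conditioned on n offspring: parents uniform in the
# ellipse, each offspring assigned a uniformly chosen parent plus
# isotropic Gaussian displacement, resampled while outside the ellipse.
.thomasPattern <- function(n, a, b, nParents, offspringSD) {
  parents <- .runifEllipse(nParents, a, b)
  assign <- sample.int(nParents, n, replace = TRUE)
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      cand <- parents[assign[i], ] + stats::rnorm(2, 0, offspringSD)
      if (.inEllipse(matrix(cand, 1), a, b)) { pts[i, ] <- cand; break }
    }
  }
  colnames(pts) <- c("x_nm", "y_nm")
  pts
}
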