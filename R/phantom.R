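# Sub-bin offset of a peak by fitting a parabola through the maximum and
# its two neighbours; 0 at the array ends or for degenerate curvature.
.parabolicOffset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  den <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (v[i - 1] - v[i + 1]) / den
  max(-0.5, min(0.5, off))
}

# Synthetic motor/relic density phantoms. The geometry encodes the
# measured architecture of the polar flagellar motor's outer-membrane
# region: a T-ring (MotX/MotY) of 44 nm diameter sitting 19 nm below the
# outer membrane, a 15 nm rod exit aperture held open by the L-ring, and
# an optional plug density occluding the aperture (the relic state). The
# T-ring carries nSubunits azimuthal density bumps (13 in vivo, the
# stator-complex symmetry); nSubunits = 1 means an unmodulated,
# rotationally smooth ring.

#' Specify a motor/relic phantom
#'
#' @param tRingDiameter T-ring diameter in nm (default 44).
#' @param tRingToOM axial distance from T-ring plane to the outer
#'   membrane in nm (default 19).
#' @param apertureDiameter rod exit hole diameter in nm (default 15).
#' @param nSubunits azimuthal subunit count on the T-ring (default 13;
#'   1 = smooth ring).
#' @param plug logical: fill the aperture with a plug density (the relic
#'   state; default FALSE, the motor state with an open aperture).
#' @param voxelSize voxel edge in nm (default 1).
#' @param boxSize cubic box edge in voxels (default 56).
#' @param membraneThickness outer-membrane slab thickness in nm
#'   (default 4).
#' @param ringSigma Gaussian tube radius of the T-ring torus in nm
#'   (default 1.5).
#' @param modulationAmp relative amplitude of the azimuthal modulation
#'   for nSubunits >= 2 (default 0.6).
#' @return list of class `PhantomSpec`.
#' @export
phantomSpec <- function(tRingDiameter = 44, tRingToOM = 19,
                        apertureDiameter = 15, nSubunits = 13L,
                        plug = FALSE, voxelSize = 1, boxSize = 56L,
                        membraneThickness = 4, ringSigma = 1.5,
                        modulationAmp = 0.6) {
  stopifnot(tRingDiameter > 0, tRingToOM > 0, apertureDiameter > 0,
            nSubunits >= 1, voxelSize > 0, boxSize >= 8,
            membraneThickness > 0, ringSigma > 0,
            modulationAmp >= 0, modulationAmp <= 1)
  structure(list(tRingDiameter = tRingDiameter, tRingToOM = tRingToOM,
                 apertureDiameter = apertureDiameter,
                 nSubunits = as.integer(nSubunits), plug = plug,
                 voxelSize = voxelSize, boxSize = as.integer(boxSize),
                 membraneThickness = membraneThickness,
                 ringSigma = ringSigma, modulationAmp = modulationAmp),
            class = "PhantomSpec")
}

#' Build a motor/relic density phantom
#'
#' Constructs a [DensityMap-class] containing an outer-membrane slab
#' (density 1) pierced by the aperture, a T-ring torus of the specified
#' diameter at the specified axial offset below the membrane with
#' nSubunits azimuthal density bumps, and, for the relic state, a plug
#' density (1.5, above membrane level) filling the aperture. The symmetry
#' axis is z through the grid centre. Optional Gaussian noise is added at
#' a target signal-to-noise ratio, defined as the RMS of the non-zero
#' noise-free voxels divided by the noise SD.
#'
#' @param spec a [phantomSpec()].
#' @param snr signal-to-noise ratio; `Inf` (default) adds no noise.
#' @param seed RNG seed for the noise.
#' @return a [DensityMap-class]; attributes `zMembrane` and `zRing` give
#'   the construction z positions (voxels) for reference.
#' @examples
#' motor <- buildPhantom(phantomSpec(plug = FALSE))
#' relic <- buildPhantom(phantomSpec(plug = TRUE))
#' measureRing(motor)
#' @export
buildPhantom <- function(spec, snr = Inf, seed = NULL) {
  stopifnot(inherits(spec, "PhantomSpec"), snr > 0)
  vs <- spec$voxelSize
  N <- spec$boxSize
  half <- (N - 1) / 2 * vs
  rRing <- spec$tRingDiameter / 2
  if (rRing + 3 * spec$ringSigma > half ||
      spec$tRingToOM + spec$membraneThickness > (N - 2) * vs)
    stop("phantom geometry exceeds the box; enlarge boxSize")
  ctr <- (N + 1) / 2  # voxels
  # membrane slab near the top, ring below it, both inside the box
  zMem <- ctr + (spec$tRingToOM / 2) / vs
  zRing <- zMem - spec$tRingToOM / vs
  if ((zMem + spec$membraneThickness / vs) > N || zRing < 1)
    stop("phantom geometry exceeds the box; enlarge boxSize")
  x <- (seq_len(N) - ctr) * vs
  X <- array(rep(x, times = N * N), c(N, N, N))
  Y <- array(rep(rep(x, each = N), times = N), c(N, N, N))
  Zv <- array(rep(seq_len(N), each = N * N), c(N, N, N))  # voxel index
  R <- sqrt(X^2 + Y^2)
  vox <- array(0, c(N, N, N))
  # Edges are erf-smoothed (SD one voxel) so the phantom is band-limited
  # enough for interpolation-based operations; half-maximum crossings sit
  # exactly at the specified geometry. The membrane is a disk confined to
  # the inscribed cylinder so rotations about z never move density out of
  # the grid.
  es <- vs
  rMem <- (N / 2 - 2) * vs
  slabZ <- stats::pnorm((Zv - zMem) * vs, -spec$membraneThickness / 2, es) -
           stats::pnorm((Zv - zMem) * vs, spec$membraneThickness / 2, es)
  diskEdge <- stats::pnorm(rMem - R, 0, es)
  hole <- stats::pnorm(R - spec$apertureDiameter / 2, 0, es)
  vox <- vox + slabZ * diskEdge * hole
  if (spec$plug)
    vox <- vox + 1.5 * slabZ * diskEdge * (1 - hole)
  # T-ring: Gaussian torus with azimuthal modulation
  theta <- atan2(Y, X)
  mod <- if (spec$nSubunits >= 2L)
    1 + spec$modulationAmp * cos(spec$nSubunits * theta) else 1
  dz <- (Zv - zRing) * vs
  torus <- exp(-((R - rRing)^2 + dz^2) / (2 * spec$ringSigma^2))
  torus[torus < 1e-6] <- 0
  vox <- vox + mod * torus
  if (is.finite(snr)) {
    sig <- sqrt(mean(vox[vox != 0]^2))
    vox <- .withSeed(seed,
      vox + array(stats::rnorm(length(vox), 0, sig / snr), dim(vox)))
  }
  out <- DensityMap(vox, voxelSize = vs)
  attr(out, "zMembrane") <- zMem
  attr(out, "zRing") <- zRing
  out
}

#' Measure ring geometry of a motor/relic map
#'
#' Morphometry of the outer-membrane region: the axial density profile
#' locates the membrane slab and the T-ring plane (their separation is
#' the axial offset); the radial profile in the ring plane peaks at the
#' ring radius; the radial profile in the membrane slab rises from the
#' aperture to the membrane plateau, crossed at half height. If the
#' density on the axis within the membrane slab reaches half the
#' membrane plateau the aperture is reported occluded (the plugged relic
#' state) and its diameter is `NA`.
#'
#' @param map a [DensityMap-class] with cubic voxels.
#' @param axialWindow optional (lo, hi) in nm restricting the axial
#'   search; default: whole map.
#' @return list: `ringDiameter`, `axialOffset`, `apertureDiameter` (nm),
#'   `occluded` (logical).
#' @export
measureRing <- function(map, axialWindow = NULL) {
  vs <- .assertIsotropic(map, "ring measurement")
  vox <- voxels(map)
  d <- dim(vox)
  zIdx <- seq_len(d[3])
  if (!is.null(axialWindow))
    zIdx <- zIdx[zIdx * vs >= axialWindow[1] & zIdx * vs <= axialWindow[2]]
  axial <- vapply(zIdx, function(k) mean(vox[, , k]), 0)
  # membrane slab: flat-topped, so take the density-weighted centroid of
  # the contiguous above-half-maximum region around the global maximum
  iPeak <- which.max(axial)
  half <- axial >= 0.5 * max(axial)
  lo <- iPeak; while (lo > 1 && half[lo - 1]) lo <- lo - 1
  hi <- iPeak; while (hi < length(axial) && half[hi + 1]) hi <- hi + 1
  zMem <- sum(zIdx[lo:hi] * axial[lo:hi]) / sum(axial[lo:hi])
  excl <- abs(zIdx - zMem) * vs <= 6
  if (all(excl)) stop("axial window too narrow to separate membrane and ring")
  iR <- which(!excl)[which.max(axial[!excl])]
  zRing <- zIdx[iR] + .parabolicOffset(axial, iR)
  offset <- abs(zMem - zRing) * vs
  ctr <- (d[1] + 1) / 2
  x <- (seq_len(d[1]) - ctr) * vs
  Rsl <- sqrt(outer(x^2, x^2, "+"))
  radialProfile <- function(zs) {
    sl <- vox[, , zs, drop = FALSE]
    slm <- apply(sl, c(1, 2), mean)
    bins <- floor(Rsl / vs) + 1L
    prof <- vapply(split(as.numeric(slm), as.numeric(bins)), mean, 0)
    r <- (as.integer(names(prof)) - 0.5) * vs
    ord <- order(r)
    list(r = r[ord], v = prof[ord])
  }
  # ring diameter from the ring-plane radial peak (parabolic refinement)
  ringZ <- intersect(seq(round(zRing) - 1, round(zRing) + 1), seq_len(d[3]))
  rp <- radialProfile(ringZ)
  iPk <- which.max(rp$v)
  ringDiameter <- 2 * (rp$r[iPk] + .parabolicOffset(rp$v, iPk) * vs)
  # aperture from the membrane-slab radial profile
  memZ <- intersect(seq(round(zMem) - 1, round(zMem) + 1), seq_len(d[3]))
  mp <- radialProfile(memZ)
  plateau <- stats::quantile(mp$v, 0.9, names = FALSE)
  axisLevel <- mp$v[1]
  if (axisLevel >= 0.5 * plateau) {
    return(list(ringDiameter = ringDiameter, axialOffset = offset,
                apertureDiameter = NA_real_, occluded = TRUE))
  }
  above <- which(mp$v >= 0.5 * plateau)
  i <- above[1]
  rAp <- if (i == 1) mp$r[1] else {
    mp$r[i - 1] + (0.5 * plateau - mp$v[i - 1]) /
      (mp$v[i] - mp$v[i - 1]) * (mp$r[i] - mp$r[i - 1])
  }
  list(ringDiameter = unname(ringDiameter), axialOffset = offset,
       apertureDiameter = unname(2 * rAp), occluded = FALSE)
}
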