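# Post-processing operations for subtomogram-average density maps:
# n-fold rotational symmetrization about z, azimuthal symmetry-order
# detection, Fourier shell correlation with threshold resolution, and
# masked composite merging. All operate on DensityMap objects; rotations
# interpolate trilinearly (bilinearly within z slices) about the z axis
# through the grid centre.

# Rotate a volume about the z axis through the grid centre (radians,
# counter-clockwise in the xy plane). Voxels sampled from outside the
# grid become `fill`.
.rotateZ <- function(vox, angle, fill = 0) {
  d <- dim(vox)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  X <- rep(seq_len(d[1]), times = d[2]) - cx
  Y <- rep(seq_len(d[2]), each = d[1]) - cy
  ca <- cos(angle); sa <- sin(angle)
  # inverse mapping: source coordinates of each target voxel
  xs <- ca * X + sa * Y + cx
  ys <- -sa * X + ca * Y + cy
  i0 <- floor(xs); j0 <- floor(ys)
  fx <- xs - i0; fy <- ys - j0
  ok <- i0 >= 1 & i0 + 1 <= d[1] & j0 >= 1 & j0 + 1 <= d[2]
  nx <- d[1]
  idx00 <- i0 + (j0 - 1) * nx
  out <- array(fill, d)
  sliceSize <- d[1] * d[2]
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  for (k in seq_len(d[3])) {
    base <- (k - 1) * sliceSize
    v <- rep(fill, sliceSize)
    ib <- idx00[ok] + base
    v[ok] <- w00[ok] * vox[ib] + w10[ok] * vox[ib + 1] +
             w01[ok] * vox[ib + nx] + w11[ok] * vox[ib + nx + 1]
    out[, , k] <- v
  }
  out
}

#' n-fold rotational symmetrization about the z axis
#'
#' Averages the map over the cyclic group Cn: the mean of the map rotated
#' by 2*pi*k/n for k = 0..n-1 about the z axis through the grid centre.
#' `n = 1` is the identity. Interpolation is bilinear within each z slice;
#' the identity rotation is taken verbatim, so symmetrization conserves
#' the total density up to interpolation error.
#'
#' @param map a [DensityMap-class] with cubic voxels.
#' @param n symmetry order (>= 1); 13 for the polar motor's stator ring.
#' @return symmetrized [DensityMap-class].
#' @examples
#' ph <- buildPhantom(phantomSpec(nSubunits = 13))
#' sym <- rotationalSymmetrize(ph, 13)
#' @export
rotationalSymmetrize <- function(map, n) {
  stopifnot(is(map, "DensityMap"))
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("symmetry order n must be a positive integer")
  .assertIsotropic(map, "rotational symmetrization")
  vox <- voxels(map)
  if (n == 1) return(map)
  acc <- vox  # k = 0 term, no interpolation
  for (k in seq_len(n - 1))
    acc <- acc + .rotateZ(vox, 2 * pi * k / n)
  DensityMap(acc / n, voxelSize = voxelSize(map))
}

# Azimuthal density profile averaged over an annulus band and z window.
.azimuthalProfile <- function(map, radiusRange, zRange = NULL,
                              nTheta = 360L) {
  vs <- .assertIsotropic(map, "azimuthal profiling")
  vox <- voxels(map)
  d <- dim(vox)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  radii <- seq(radiusRange[1], radiusRange[2], by = vs / 2) / vs  # voxels
  if (!length(radii)) stop("empty radius band")
  zs <- if (is.null(zRange)) seq_len(d[3])
        else seq(max(1, floor(zRange[1] / vs)),
                 min(d[3], ceiling(zRange[2] / vs)))
  if (!length(zs)) stop("empty z window")
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  prof <- vapply(theta, function(th) {
    g <- expand.grid(r = radii, z = zs)
    mean(.interpTrilinear(vox, cx + g$r * cos(th), cy + g$r * sin(th), g$z))
  }, 0)
  prof
}

#' Detect the azimuthal symmetry order of a map
#'
#' Extracts the azimuthal density profile on an annulus band (averaged
#' over the band radii and a z window), Fourier-transforms it, and
#' returns the candidate order with maximal rotational power. A flat
#' profile (relative azimuthal modulation below `flatTol`) returns `NA`
#' with a no-symmetry flag rather than an arbitrary order.
#'
#' @param map a [DensityMap-class] with cubic voxels.
#' @param radiusRange annulus (inner, outer) radius in nm; should bracket
#'   the ring of interest (e.g. the T-ring at radius 22 nm).
#' @param zRange optional (lo, hi) z window in nm from the grid bottom;
#'   default: all slices.
#' @param orders candidate symmetry orders (default 2:20; order 0 is
#'   always excluded).
#' @param nTheta azimuthal samples (default 360).
#' @param flatTol relative modulation (sd/|mean|) below which the profile
#'   counts as rotationally smooth (default 0.02).
#' @return integer order, or `NA` with attribute `noSymmetry = TRUE`.
#' @examples
#' ph <- buildPhantom(phantomSpec(nSubunits = 13))
#' detectSymmetryOrder(ph, radiusRange = c(16, 28))  # 13
#' @export
detectSymmetryOrder <- function(map, radiusRange, zRange = NULL,
                                orders = 2:20, nTheta = 360L,
                                flatTol = 0.02) {
  stopifnot(length(radiusRange) == 2L, radiusRange[1] < radiusRange[2],
            all(orders >= 1), max(orders) < nTheta / 2)
  prof <- .azimuthalProfile(map, radiusRange, zRange, nTheta)
  if (all(prof == 0))
    stop("annulus band does not intersect any density")
  rel <- stats::sd(prof) / max(abs(mean(prof)), .Machine$double.eps)
  if (rel < flatTol) {
    out <- NA_integer_
    attr(out, "noSymmetry") <- TRUE
    return(out)
  }
  power <- Mod(stats::fft(prof))^2
  # coefficient k+1 carries order k
  best <- orders[which.max(power[orders + 1L])]
  attr(best, "power") <- stats::setNames(power[orders + 1L],
                                         as.character(orders))
  best
}

#' Fourier shell correlation between two maps
#'
#' Normalized cross-correlation of the Fourier coefficients of two maps,
#' computed in concentric shells one Fourier voxel thick. Used on two
#' independent half-set averages to estimate resolution.
#'
#' @param mapA,mapB [DensityMap-class] objects on the same grid with the
#'   same voxel size.
#' @return data.frame `shell`, `freq_inv_nm` (shell centre spatial
#'   frequency, 1/nm), `correlation` (in `[-1, 1]`), up to Nyquist.
#' @seealso [resolutionAt()]
#' @export
fsc <- function(mapA, mapB) {
  stopifnot(is(mapA, "DensityMap"), is(mapB, "DensityMap"))
  if (!identical(dim(voxels(mapA)), dim(voxels(mapB))))
    stop("maps have different grid dimensions")
  if (max(abs(voxelSize(mapA) - voxelSize(mapB))) > 1e-9)
    stop("maps have different voxel sizes")
  vs <- .assertIsotropic(mapA, "Fourier shell correlation")
  d <- dim(voxels(mapA))
  FA <- stats::fft(voxels(mapA))
  FB <- stats::fft(voxels(mapB))
  fax <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fx <- fax(d[1]); fy <- fax(d[2]); fz <- fax(d[3])
  r2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  shell <- round(sqrt(r2) * d[1])  # shells one Fourier voxel thick
  nShells <- floor(min(d) / 2)
  keep <- shell <= nShells
  sh <- shell[keep] + 1L
  num <- Re(FA[keep] * Conj(FB[keep]))
  pa <- Mod(FA[keep])^2
  pb <- Mod(FB[keep])^2
  sNum <- vapply(split(num, sh), sum, 0)
  sPa <- vapply(split(pa, sh), sum, 0)
  sPb <- vapply(split(pb, sh), sum, 0)
  idx <- as.integer(names(sNum)) - 1L
  corr <- sNum / sqrt(sPa * sPb)
  corr[!is.finite(corr)] <- 0
  data.frame(shell = idx,
             freq_inv_nm = idx / (d[1] * vs),
             correlation = pmin(1, pmax(-1, corr)))[order(idx), ]
}

#' Resolution at an FSC threshold
#'
#' The resolution is 1/frequency at the first crossing of the FSC curve
#' below the threshold, with linear interpolation between shells. The
#' conventional threshold for subtomogram averages here is 0.5.
#'
#' @param curve data.frame from [fsc()].
#' @param threshold correlation threshold (default 0.5).
#' @return resolution in nm, or `NA` with a warning if the curve never
#'   drops below the threshold (resolution beyond Nyquist).
#' @export
resolutionAt <- function(curve, threshold = 0.5) {
  stopifnot(all(c("freq_inv_nm", "correlation") %in% names(curve)))
  co <- curve$correlation
  fr <- curve$freq_inv_nm
  below <- which(co < threshold & seq_along(co) > 1L)
  if (!length(below)) {
    warning("FSC never drops below ", threshold,
            "; resolution is beyond Nyquist")
    return(NA_real_)
  }
  i <- below[1]
  f <- fr[i - 1] + (co[i - 1] - threshold) / (co[i - 1] - co[i]) *
    (fr[i] - fr[i - 1])
  1 / f
}

#' Soft-edged z mask
#'
#' Builds a mask selecting the region below or above a z plane with a
#' cosine soft edge, used to merge independently refined top
#' (outer-membrane ring) and bottom (cytoplasmic) averages.
#'
#' @param dim grid dimensions (3 integers) or a [DensityMap-class].
#' @param zCenter edge position in voxels (may be fractional).
#' @param softWidth total width of the cosine ramp in voxels (0 = hard
#'   edge).
#' @param side `"below"` (weight 1 for z < zCenter) or `"above"`.
#' @return 3D array of weights in `[0, 1]`.
#' @export
softZMask <- function(dim, zCenter, softWidth = 4, side = c("below",
                                                            "above")) {
  side <- match.arg(side)
  if (is(dim, "DensityMap")) dim <- base::dim(voxels(dim))
  stopifnot(length(dim) == 3L, softWidth >= 0)
  z <- seq_len(dim[3])
  w <- if (softWidth == 0) as.numeric(z < zCenter) else {
    t <- pmin(1, pmax(0, (zCenter - z) / softWidth + 0.5))
    0.5 - 0.5 * cos(pi * t)  # cosine ramp, 1 well below, 0 well above
  }
  if (side == "above") w <- 1 - w
  array(rep(w, each = dim[1] * dim[2]), dim)
}

#' Merge two maps through soft masks
#'
#' Voxel-wise weighted average `(wTop * top + wBottom * bottom) /
#' (wTop + wBottom)`. Voxels where both weights vanish are set to the
#' solvent value and counted in the `flaggedVoxels` attribute. This is
#' the composite step that stitches independently aligned top-ring and
#' cytoplasmic averages into one structure.
#'
#' @param mapTop,mapBottom [DensityMap-class] objects on a shared grid.
#' @param maskTop,maskBottom weight arrays in `[0, 1]` (e.g. from
#'   [softZMask()]) matching the grid.
#' @param solvent density assigned to zero-weight voxels (default 0).
#' @return merged [DensityMap-class]; `attr(, "flaggedVoxels")` counts
#'   zero-weight voxels.
#' @export
compositeMerge <- function(mapTop, mapBottom, maskTop, maskBottom,
                           solvent = 0) {
  stopifnot(is(mapTop, "DensityMap"), is(mapBottom, "DensityMap"))
  d <- dim(voxels(mapTop))
  if (!identical(d, dim(voxels(mapBottom))))
    stop("maps have different grid dimensions")
  if (!identical(d, dim(maskTop)) || !identical(d, dim(maskBottom)))
    stop("masks must match the map grid")
  if (min(maskTop) < 0 || max(maskTop) > 1 ||
      min(maskBottom) < 0 || max(maskBottom) > 1)
    stop("mask weights must lie in [0, 1]")
  wsum <- maskTop + maskBottom
  zero <- wsum <= .Machine$double.eps
  out <- (maskTop * voxels(mapTop) + maskBottom * voxels(mapBottom))
  out[!zero] <- out[!zero] / wsum[!zero]
  out[zero] <- solvent
  res <- DensityMap(out, voxelSize = voxelSize(mapTop))
  attr(res, "flaggedVoxels") <- sum(zero)
  res
}

#' Write an FSC curve as TSV
#'
#' @param curve data.frame from [fsc()].
#' @param path file path.
#' @export
writeFSCTable <- function(curve, path) {
  utils::write.table(curve[, c("freq_inv_nm", "correlation")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
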