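#' @import methods
NULL

.LABELS <- c("motor", "relic")

#' Labelled structure positions on one cell pole
#'
#' A `PolePattern` holds the 2D positions (nm, pole-plane projection) of
#' flagellar motors and relic structures annotated on a single cell pole,
#' together with the C-ring diameter used by the pole-area convention.
#' Coordinates are continuous, 0-based, in nm; no pixel indexing.
#'
#' @slot poleId single character identifier of the pole.
#' @slot coords numeric matrix with columns `x_nm`, `y_nm`, one row per
#'   structure.
#' @slot labels character vector, one of `"motor"` or `"relic"` per row.
#' @slot cringDiameter C-ring diameter in nm (default 45), the steric
#'   footprint of one motor and the margin added to the pole ellipse.
#'
#' @seealso [PolePattern()], [clarkEvansRatio()], [poleGeometry()]
#' @exportClass PolePattern
setClass("PolePattern",
  representation(
    poleId = "character",
    coords = "matrix",
    labels = "character",
    cringDiameter = "numeric"
  )
)

setValidity("PolePattern", function(object) {
  msg <- character()
  if (length(object@poleId) != 1L || is.na(object@poleId))
    msg <- c(msg, "poleId must be a single non-NA string")
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be a numeric matrix with 2 columns")
  if (nrow(object@coords) < 1L)
    msg <- c(msg, "a PolePattern needs at least one point")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@labels) != nrow(object@coords))
    msg <- c(msg, "one label per coordinate row required")
  if (!all(object@labels %in% .LABELS))
    msg <- c(msg, sprintf("labels must be one of: %s",
                          paste(.LABELS, collapse = ", ")))
  if (length(object@cringDiameter) != 1L || !is.finite(object@cringDiameter) ||
      object@cringDiameter <= 0)
    msg <- c(msg, "cringDiameter must be a single positive length in nm")
  if (length(msg)) msg else TRUE
})

#' Construct a PolePattern
#'
#' @param poleId pole identifier.
#' @param x,y numeric coordinates in nm.
#' @param labels `"motor"`/`"relic"` per point; recycled if length 1.
#' @param cringDiameter C-ring diameter in nm used by the pole-area
#'   convention (default 45).
#' @return a [PolePattern-class] object.
#' @examples
#' p <- PolePattern("pole1", x = c(0, 3), y = c(0, 4), labels = "motor")
#' nearestNeighborDistances(p)
#' @export
PolePattern <- function(poleId, x, y, labels = "motor", cringDiameter = 45) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  labels <- rep_len(as.character(labels), length(x))
  coords <- cbind(x_nm = as.numeric(x), y_nm = as.numeric(y))
  new("PolePattern", poleId = as.character(poleId), coords = coords,
      labels = labels, cringDiameter = cringDiameter)
}

#' 3D density map with a z symmetry axis
#'
#' A `DensityMap` is a 3D voxel grid of density values (e.g. a subtomogram
#' average or a synthetic phantom) with its voxel size in nm. The rotational
#' symmetry axis is the z axis through the grid centre. Voxel sizes are
#' stored per axis; symmetry operations require cubic (isotropic) voxels.
#'
#' @slot voxels numeric 3D array of densities.
#' @slot voxelSize numeric length-3 vector, voxel edge length in nm along
#'   x, y, z.
#'
#' @seealso [DensityMap()], [readDensityMap()], [rotationalSymmetrize()]
#' @exportClass DensityMap
setClass("DensityMap",
  representation(voxels = "array", voxelSize = "numeric")
)

setValidity("DensityMap", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "voxel values must be finite")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths in nm")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityMap
#'
#' @param voxels numeric 3D array.
#' @param voxelSize voxel edge length in nm; a scalar is recycled to the
#'   three axes.
#' @return a [DensityMap-class] object.
#' @examples
#' m <- DensityMap(array(0, c(8, 8, 8)), voxelSize = 1)
#' dim(voxels(m))
#' @export
DensityMap <- function(voxels, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("DensityMap", voxels = voxels, voxelSize = as.numeric(voxelSize))
}
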