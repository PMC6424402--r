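#' @rdname PolePattern-class
#' @param object,x a `PolePattern` or `DensityMap`.
#' @export
setGeneric("poleId", function(object) standardGeneric("poleId"))

#' @rdname PolePattern-class
#' @export
setGeneric("poleCoords", function(object) standardGeneric("poleCoords"))

#' @rdname PolePattern-class
#' @export
setGeneric("structureLabels", function(object) standardGeneric("structureLabels"))

#' @rdname PolePattern-class
#' @export
setGeneric("cringDiameter", function(object) standardGeneric("cringDiameter"))

#' @rdname DensityMap-class
#' @param object a `DensityMap`.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname DensityMap-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname nearestNeighborDistances
#' @export
setGeneric("nearestNeighborDistances",
           function(object) standardGeneric("nearestNeighborDistances"))

setMethod("poleId", "PolePattern", function(object) object@poleId)
setMethod("poleCoords", "PolePattern", function(object) object@coords)
setMethod("structureLabels", "PolePattern", function(object) object@labels)
setMethod("cringDiameter", "PolePattern", function(object) object@cringDiameter)

setMethod("voxels", "DensityMap", function(object) object@voxels)
setMethod("voxelSize", "DensityMap", function(object) object@voxelSize)

#' @rdname PolePattern-class
#' @export
setMethod("length", "PolePattern", function(x) nrow(x@coords))

setMethod("show", "PolePattern", function(object) {
  tab <- table(factor(object@labels, levels = .LABELS))
  cat(sprintf("PolePattern '%s': %d structures (%d motor, %d relic), C-ring %.0f nm\n",
              object@poleId, nrow(object@coords), tab[["motor"]],
              tab[["relic"]], object@cringDiameter))
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@voxels)
  vs <- object@voxelSize
  iso <- if (isTRUE(all.equal(max(vs), min(vs)))) "isotropic" else "anisotropic"
  cat(sprintf("DensityMap %d x %d x %d voxels, voxel %.4g x %.4g x %.4g nm (%s)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], iso))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(object@voxels), max(object@voxels), mean(object@voxels)))
})
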