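#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics: `records()` returns the underlying data.frame of a
#' [LocalizationTable-class]; `locCoords()` its n x 3 coordinate matrix in nm;
#' `nLocs()` its record count; `photonRatio()` the per-record photon ratio;
#' `fluorLabel()` the fluorophore assignment; `movieData()` the intensity
#' array of a [FluorescenceMovie-class]; `nFrames()` its frame count.
#'
#' @param object a pipeline object.
#' @return see the individual descriptions above.
#' @name accessors
#' @aliases records locCoords nLocs photonRatio fluorLabel movieData nFrames
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("locCoords", function(object) standardGeneric("locCoords"))

#' @rdname accessors
#' @export
setGeneric("nLocs", function(object) standardGeneric("nLocs"))

#' @rdname accessors
#' @export
setGeneric("photonRatio", function(object) standardGeneric("photonRatio"))

#' @rdname accessors
#' @export
setGeneric("fluorLabel", function(object) standardGeneric("fluorLabel"))

#' @rdname accessors
#' @export
setGeneric("movieData", function(object) standardGeneric("movieData"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("records", "LocalizationTable", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("locCoords", "LocalizationTable", function(object) {
  as.matrix(object@records[, c("x", "y", "z"), drop = FALSE])
})

#' @rdname accessors
#' @export
setMethod("nLocs", "LocalizationTable", function(object) nrow(object@records))

#' @rdname accessors
#' @export
setMethod("photonRatio", "LocalizationTable", function(object) object@records$ratio)

#' @rdname accessors
#' @export
setMethod("fluorLabel", "LocalizationTable", function(object) object@records$fluor)

#' @rdname accessors
#' @export
setMethod("movieData", "FluorescenceMovie", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("nFrames", "FluorescenceMovie", function(object) dim(object@data)[3L])

setMethod("show", "FluorescenceMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "FluorescenceMovie [%s]: %d x %d px, %d frames, %.0f nm/px, %.2f Hz, stim @ %d\n",
    object@channel, d[1], d[2], d[3], object@pixelSize, object@frameRate,
    object@stimFrame))
})

setMethod("show", "LocalizationTable", function(object) {
  rec <- object@records
  cat(sprintf("LocalizationTable: %d localisations\n", nrow(rec)))
  if (nrow(rec)) {
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm  z: [%.1f, %.1f] nm\n",
                min(rec$x), max(rec$x), min(rec$y), max(rec$y),
                min(rec$z), max(rec$z)))
    cat("  fluor: ", paste(sprintf("%s=%d", levels(rec$fluor),
                                   tabulate(rec$fluor, 4L)), collapse = " "), "\n")
  }
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  live: %.0f nm/px @ %.2f Hz, stim frame %d\n",
              object@livePixelSize, object@liveFrameRate, object@stimFrame))
  cat(sprintf("  traces: ROI %dx%d, bg %dx%d, smooth %d, baseline %d, peak %d, %g SD\n",
              object@roiSize, object@roiSize, object@bgSize, object@bgSize,
              object@smoothWindow, object@baselineFrames, object@peakWindow,
              object@responseSdFactor))
  cat(sprintf("  smlm: camera %.0f nm, render %.0f nm, drift bins %d @ %.0f nm\n",
              object@stormCameraPixel, object@renderPixel, object@driftBinFrames,
              object@driftGrid))
  cat(sprintf("  segmentation: factor %g (%s), link %g/%g nm, min %d/%d molecules\n",
              object@densityFactor, object@densityReference,
              object@maxNeighbourDist[1], object@maxNeighbourDist[2],
              object@minMolecules[1], object@minMolecules[2]))
})

setMethod("show", "DriftTrajectory", function(object) {
  n <- length(object@binStart)
  cat(sprintf("DriftTrajectory: %d bins, endpoint (%.1f, %.1f) nm\n",
              n, object@dx[n], object@dy[n]))
})

setMethod("show", "DemixModel", function(object) {
  cat(sprintf(
    "DemixModel: muA = %.3f (sd %.3f, w %.2f), muB = %.3f (sd %.3f, w %.2f), threshold %.2f\n",
    object@muA, object@sdA, object@weightA, object@muB, object@sdB,
    object@weightB, object@threshold))
})

setMethod("show", "VoronoiDensityMap", function(object) {
  cat(sprintf(
    "VoronoiDensityMap: %d points (%d finite cells), mean %.3g nm^-3, global %.3g nm^-3\n",
    length(object@density), sum(object@finite), object@meanDensity,
    object@globalDensity))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet (colour %d): %d clusters\n", object@colour,
              nrow(object@stats)))
  if (nrow(object@stats)) {
    cat(sprintf("  n: %d-%d detections, volume median %.3g nm^3\n",
                min(object@stats$n), max(object@stats$n),
                median(object@stats$volume, na.rm = TRUE)))
  }
})

setMethod("show", "SynapseStructureSet", function(object) {
  cat(sprintf("SynapseStructureSet: %d synapses, %d SSD associations (%d orphan-assigned), %d unassigned SSDs\n",
              nrow(object@synapses), nrow(object@associations),
              sum(object@associations$provenance == "orphan-assigned"),
              length(object@unassigned)))
})

setMethod("show", "AffineTransform2D", function(object) {
  cat(sprintf("AffineTransform2D: det %.4g, RMSE %.3g nm over %d landmarks\n",
              det(object@A), object@rmse, object@nLandmarks))
  print(cbind(object@A, t = object@t))
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g, n = %s\n", object@method,
              object@statistic, object@p,
              paste(object@n, collapse = "/")))
})
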