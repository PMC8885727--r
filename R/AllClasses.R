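#' @import methods
#' @importFrom stats rnorm runif rpois rlnorm sd fft pt cor median quantile setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib SynapseCorr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.FLUOR_LEVELS <- c("unassigned", "fluorA", "fluorB", "rejected")

# ---------------------------------------------------------------------------
# PipelineConfig
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Holds every fixed parameter of the correlative pipeline: live-imaging
#' geometry and trace-analysis settings, localisation processing settings, and
#' Voronoi segmentation thresholds. Defaults mirror the acquisition and
#' analysis settings of the correlative SypHy-RGECO / SD-dSTORM protocol:
#' 433 nm live pixels (4x4 binning), 12.5 Hz per channel, 5x5-pixel signal and
#' 15x15-pixel background ROIs, 4-frame trace smoothing, 15-frame baseline and
#' peak windows, a 3 SD response threshold, 97 nm camera pixels, 10 nm
#' rendered pixels, a density threshold of 1 x the dataset average, 200/100 nm
#' maximum neighbour distances and 200/20 minimum molecules for colour 1 and
#' colour 2.
#'
#' @slot livePixelSize live-imaging pixel size in nm.
#' @slot liveFrameRate acquisition rate per channel in Hz.
#' @slot stimFrame 1-based frame index of the stimulus.
#' @slot roiSize signal ROI edge length in pixels (odd).
#' @slot bgSize background ROI edge length in pixels (odd).
#' @slot smoothWindow trailing moving-average window in frames.
#' @slot baselineFrames number of pre-stimulus frames defining the baseline.
#' @slot peakWindow number of frames from the stimulus searched for the peak.
#' @slot responseSdFactor response threshold in baseline SD units.
#' @slot baselineSdOn whether baseline SD is taken on the "raw" (default)
#'   or "smoothed" trace. The raw-trace SD is the noise scale the 3 SD
#'   threshold was designed against; thresholding the peak of the smoothed
#'   trace at 3 x the smoothed-baseline SD misclassifies ~10-15% of
#'   non-responding boutons (the smoothed SD is smaller and its 15-frame
#'   estimate is noisy, while the peak search maximises over the window).
#' @slot stormCameraPixel localisation camera pixel size in nm.
#' @slot renderPixel super-resolved rendering pixel size in nm.
#' @slot densityFactor multiple of the dataset average density used as the
#'   Voronoi segmentation threshold.
#' @slot densityReference reference density definition: "global" (detections
#'   per dataset bounding-box volume) or "mean" (mean of finite per-point
#'   Voronoi densities).
#' @slot maxNeighbourDist length-2 numeric, maximum neighbour distance in nm
#'   for colour 1 and colour 2 cluster linking.
#' @slot minMolecules length-2 integer, minimum molecules per cluster for
#'   colour 1 and colour 2.
#' @slot matchDist maximum live-to-dSTORM synapse matching distance in nm.
#' @slot orphanDist maximum centroid distance in nm for orphan SSD assignment.
#' @slot pairTol two-camera detection pairing tolerance in nm.
#' @slot demixThreshold posterior probability required to assign a fluorophore.
#' @slot driftBinFrames frames per drift-estimation time bin.
#' @slot driftGrid drift-estimation histogram pixel size in nm.
#' @slot seed integer seed for simulation helpers.
#'
#' @seealso [pipelineConfig()], [readPipelineConfig()]
#' @export
setClass("PipelineConfig",
  representation(
    livePixelSize = "numeric", liveFrameRate = "numeric", stimFrame = "integer",
    roiSize = "integer", bgSize = "integer", smoothWindow = "integer",
    baselineFrames = "integer", peakWindow = "integer",
    responseSdFactor = "numeric", baselineSdOn = "character",
    stormCameraPixel = "numeric", renderPixel = "numeric",
    densityFactor = "numeric", densityReference = "character",
    maxNeighbourDist = "numeric", minMolecules = "integer",
    matchDist = "numeric", orphanDist = "numeric", pairTol = "numeric",
    demixThreshold = "numeric", driftBinFrames = "integer",
    driftGrid = "numeric", seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c(
    livePixelSize = object@livePixelSize, liveFrameRate = object@liveFrameRate,
    roiSize = object@roiSize, bgSize = object@bgSize,
    smoothWindow = object@smoothWindow, baselineFrames = object@baselineFrames,
    peakWindow = object@peakWindow, responseSdFactor = object@responseSdFactor,
    stormCameraPixel = object@stormCameraPixel, renderPixel = object@renderPixel,
    densityFactor = object@densityFactor, matchDist = object@matchDist,
    orphanDist = object@orphanDist, pairTol = object@pairTol,
    driftBinFrames = object@driftBinFrames, driftGrid = object@driftGrid
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    msg <- c(msg, paste0("parameters must be strictly positive: ",
                         paste(bad, collapse = ", ")))
  }
  if (object@stimFrame < 1L) msg <- c(msg, "stimFrame must be >= 1")
  if (object@roiSize >= object@bgSize) {
    msg <- c(msg, "roiSize must be smaller than bgSize")
  }
  if (length(object@maxNeighbourDist) != 2L ||
      any(object@maxNeighbourDist <= 0)) {
    msg <- c(msg, "maxNeighbourDist must be two positive values (colour 1, colour 2)")
  }
  if (length(object@minMolecules) != 2L || any(object@minMolecules <= 0L)) {
    msg <- c(msg, "minMolecules must be two positive counts (colour 1, colour 2)")
  }
  if (!object@baselineSdOn %in% c("smoothed", "raw")) {
    msg <- c(msg, "baselineSdOn must be 'smoothed' or 'raw'")
  }
  if (!object@densityReference %in% c("global", "mean")) {
    msg <- c(msg, "densityReference must be 'global' or 'mean'")
  }
  if (object@demixThreshold <= 0.5 || object@demixThreshold > 1) {
    msg <- c(msg, "demixThreshold must be in (0.5, 1]")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# FluorescenceMovie
# ---------------------------------------------------------------------------

#' Single-channel fluorescence time-lapse movie
#'
#' A de-interleaved channel of a dual-reporter acquisition: a row x col x
#' frame intensity array with its pixel size, frame rate and stimulus frame.
#'
#' @slot data numeric array, dim = c(rows, cols, frames), arbitrary intensity
#'   units.
#' @slot channel "G" (SypHy / release reporter) or "R" (RGECO / calcium
#'   reporter).
#' @slot pixelSize pixel size in nm.
#' @slot frameRate acquisition rate in Hz.
#' @slot stimFrame 1-based index of the first stimulated frame.
#' @export
setClass("FluorescenceMovie",
  representation(data = "array", channel = "character", pixelSize = "numeric",
                 frameRate = "numeric", stimFrame = "integer"))

setValidity("FluorescenceMovie", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) {
    msg <- c(msg, "data must be a rows x cols x frames array")
  }
  if (!object@channel %in% c("G", "R")) msg <- c(msg, "channel must be 'G' or 'R'")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# LocalizationTable
# ---------------------------------------------------------------------------

#' 3D single-molecule localisation table
#'
#' Localised molecule coordinates in nm with frame indices, per-camera photon
#' counts from the spectral-demixing beam splitter, the photon ratio
#' rho = I_cam1 / (I_cam1 + I_cam2), and the assigned fluorophore label.
#'
#' @slot records data.frame with columns x, y, z (nm), frame (0-based index),
#'   I_cam1, I_cam2 (photons, NA when unavailable), ratio (rho in \[0, 1\], NA
#'   when undefined) and fluor (factor: unassigned/fluorA/fluorB/rejected).
#' @export
setClass("LocalizationTable", representation(records = "data.frame"))

setValidity("LocalizationTable", function(object) {
  rec <- object@records
  need <- c("x", "y", "z", "frame", "I_cam1", "I_cam2", "ratio", "fluor")
  if (!all(need %in% names(rec))) {
    return(paste0("records must have columns: ", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (nrow(rec)) {
    if (any(rec$frame < 0, na.rm = TRUE)) msg <- c(msg, "frame indices must be >= 0")
    if (any(rec$I_cam1 < 0, na.rm = TRUE) || any(rec$I_cam2 < 0, na.rm = TRUE)) {
      msg <- c(msg, "camera intensities must be non-negative")
    }
    if (any(rec$ratio < 0 | rec$ratio > 1, na.rm = TRUE)) {
      msg <- c(msg, "photon ratio must lie in [0, 1]")
    }
    assigned <- rec$fluor %in% c("fluorA", "fluorB")
    if (any(assigned)) {
      tot <- rec$I_cam1[assigned] + rec$I_cam2[assigned]
      if (any(!is.finite(tot) | tot <= 0)) {
        msg <- c(msg, "assigned records must have I_cam1 + I_cam2 > 0")
      }
    }
  }
  if (!is.factor(rec$fluor) || !all(levels(rec$fluor) == .FLUOR_LEVELS)) {
    msg <- c(msg, "fluor must be a factor with levels unassigned/fluorA/fluorB/rejected")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TraceSet
# ---------------------------------------------------------------------------

#' Per-bouton fluorescence traces
#'
#' Background-subtracted mean-intensity traces for both channels, one column
#' per bouton, plus the shared background traces and ROI geometry.
#'
#' @slot g frames x boutons matrix of background-subtracted G traces.
#' @slot r frames x boutons matrix of background-subtracted R traces.
#' @slot bgG background-ROI mean trace, G channel.
#' @slot bgR background-ROI mean trace, R channel.
#' @slot centres boutons x 2 matrix of ROI centre pixel coordinates (row, col).
#' @slot bgCentre background ROI centre pixel coordinates (row, col).
#' @slot stimFrame stimulus frame carried over from the movies.
#' @slot frameRate frame rate in Hz.
#' @export
setClass("TraceSet",
  representation(g = "matrix", r = "matrix", bgG = "numeric", bgR = "numeric",
                 centres = "matrix", bgCentre = "numeric",
                 stimFrame = "integer", frameRate = "numeric"))

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!identical(dim(object@g), dim(object@r))) {
    msg <- c(msg, "G and R trace matrices must have identical dimensions")
  }
  if (length(object@bgG) != nrow(object@g) ||
      length(object@bgR) != nrow(object@r)) {
    msg <- c(msg, "background traces must have one value per frame")
  }
  if (nrow(object@centres) != ncol(object@g)) {
    msg <- c(msg, "one ROI centre per bouton required")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SMLM processing classes
# ---------------------------------------------------------------------------

#' Lateral drift trajectory
#'
#' Per-time-bin lateral drift relative to the first bin, interpolated linearly
#' between bin centres; the end segments are extrapolated linearly beyond the
#' first and last bin centre when the correction is applied.
#'
#' @slot binStart first frame (0-based) of each bin.
#' @slot binCentre centre frame of each bin, where the drift value applies.
#' @slot dx,dy drift in nm per bin; the first bin is (0, 0) by convention.
#' @export
setClass("DriftTrajectory",
  representation(binStart = "numeric", binCentre = "numeric",
                 dx = "numeric", dy = "numeric"))

setValidity("DriftTrajectory", function(object) {
  msg <- character()
  n <- length(object@binStart)
  if (length(object@dx) != n || length(object@dy) != n ||
      length(object@binCentre) != n) {
    msg <- c(msg, "binStart, binCentre, dx, dy must have equal length")
  }
  if (n && is.unsorted(object@binStart, strictly = TRUE)) {
    msg <- c(msg, "bins must be ordered and non-overlapping")
  }
  if (n && (abs(object@dx[1]) > 1e-9 || abs(object@dy[1]) > 1e-9)) {
    msg <- c(msg, "drift of the first bin must be (0, 0)")
  }
  if (length(msg)) msg else TRUE
})

#' Two-component photon-ratio mixture model
#'
#' Gaussian mixture fitted to the photon-ratio histogram; detections are
#' assigned to a fluorophore only when the posterior probability reaches the
#' threshold, otherwise rejected (crosstalk guard).
#'
#' @slot muA,muB component means on the photon-ratio axis (muB < muA).
#' @slot sdA,sdB component standard deviations.
#' @slot weightA,weightB mixing weights (sum to 1).
#' @slot threshold posterior assignment threshold (default 0.99).
#' @export
setClass("DemixModel",
  representation(muA = "numeric", muB = "numeric", sdA = "numeric",
                 sdB = "numeric", weightA = "numeric", weightB = "numeric",
                 threshold = "numeric"))

setValidity("DemixModel", function(object) {
  msg <- character()
  if (object@muB >= object@muA) msg <- c(msg, "muB must be smaller than muA")
  if (abs(object@weightA + object@weightB - 1) > 1e-8) {
    msg <- c(msg, "mixing weights must sum to 1")
  }
  if (object@sdA <= 0 || object@sdB <= 0) msg <- c(msg, "component SDs must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Cluster analysis classes
# ---------------------------------------------------------------------------

#' Per-point Voronoi density map
#'
#' Per-localisation densities from the 3D Voronoi tessellation: `density`
#' is the first-rank density (median inverse cell volume over the cell and
#' its Voronoi neighbours, the quantity thresholded in segmentation) and
#' `cellDensity` is the raw inverse cell volume delta_i = 1 / V_i (0 for
#' unbounded cells, whose points lie on the dataset hull boundary). Two
#' reference densities are stored: the global dataset density (detections
#' per dataset extent) and the mean of delta_i over finite interior cells
#' (bounded cells lying fully inside the dataset bounding box; cells
#' bulging outside it would bias the mean upward).
#'
#' @slot density first-rank (neighbourhood-median) density per point, nm^-3.
#' @slot cellDensity inverse Voronoi cell volume per point, nm^-3 (0 for
#'   unbounded cells).
#' @slot finite logical, TRUE for bounded cells fully inside the bounding box.
#' @slot meanDensity mean of cellDensity over finite cells (nm^-3).
#' @slot globalDensity n points / dataset extent volume (nm^-3).
#' @slot bbox 2 x 3 matrix (min/max rows) of the dataset bounding box in nm.
#' @export
setClass("VoronoiDensityMap",
  representation(density = "numeric", cellDensity = "numeric",
                 finite = "logical", meanDensity = "numeric",
                 globalDensity = "numeric", bbox = "matrix"))

setValidity("VoronoiDensityMap", function(object) {
  msg <- character()
  if (length(object@density) != length(object@finite)) {
    msg <- c(msg, "density and finite must have equal length")
  }
  if (any(object@density < 0) || any(object@cellDensity < 0)) {
    msg <- c(msg, "densities must be non-negative")
  }
  if (any(object@cellDensity[object@finite] <= 0)) {
    msg <- c(msg, "finite interior cells must carry positive density")
  }
  if (length(msg)) msg else TRUE
})

#' Set of segmented point-cloud clusters for one colour
#'
#' Connected components of above-threshold-density localisations, with their
#' convex-hull volume, density (detections / hull volume) and centroid.
#'
#' @slot colour 1 (synaptic-vesicle reporter) or 2 (active-zone protein).
#' @slot members list of integer vectors, point indices per cluster (indices
#'   into the point matrix segmentation was run on).
#' @slot stats data.frame with one row per cluster: n, volume (nm^3), density
#'   (nm^-3), cx, cy, cz (nm), degenerate.
#' @export
setClass("ClusterSet",
  representation(colour = "integer", members = "list", stats = "data.frame"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (!object@colour %in% c(1L, 2L)) msg <- c(msg, "colour must be 1 or 2")
  if (length(object@members) != nrow(object@stats)) {
    msg <- c(msg, "one stats row per cluster required")
  }
  if (length(object@members) > 1) {
    all_members <- unlist(object@members)
    if (anyDuplicated(all_members)) {
      msg <- c(msg, "clusters of one colour must be disjoint point sets")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synapse-level two-colour structure
#'
#' Associates each colour-1 cluster (presynaptic bouton) with its colour-2
#' subsynaptic domains (SSDs), recording whether each association came from
#' hull overlap or from orphan assignment (the automated stand-in for manual
#' colocalisation correction).
#'
#' @slot synapses data.frame, one row per colour-1 cluster: synapse,
#'   n_ssd, c1_n, c1_volume, c1_density, cx, cy, cz, ssd_total_detections,
#'   ssd_mean_density.
#' @slot associations data.frame: synapse, ssd (colour-2 cluster index),
#'   provenance ("overlap" or "orphan-assigned").
#' @slot unassigned integer vector of colour-2 cluster indices beyond the
#'   orphan distance of every synapse.
#' @slot clusters1,clusters2 the underlying [ClusterSet-class] objects.
#' @export
setClass("SynapseStructureSet",
  representation(synapses = "data.frame", associations = "data.frame",
                 unassigned = "integer", clusters1 = "ClusterSet",
                 clusters2 = "ClusterSet"))

setValidity("SynapseStructureSet", function(object) {
  msg <- character()
  if (nrow(object@associations) &&
      anyDuplicated(object@associations$ssd)) {
    msg <- c(msg, "each SSD may be associated with at most one synapse")
  }
  if (nrow(object@synapses)) {
    tab <- table(factor(object@associations$synapse,
                        levels = object@synapses$synapse))
    if (!all(object@synapses$n_ssd == as.integer(tab))) {
      msg <- c(msg, "n_ssd must equal the number of associated SSDs")
    }
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Registration / statistics classes
# ---------------------------------------------------------------------------

#' 2D affine transform between imaging modalities
#'
#' The live-to-dSTORM coordinate map x -> A x + t estimated from landmark
#' pairs by least squares.
#'
#' @slot A 2 x 2 matrix (unitless).
#' @slot t length-2 translation (nm).
#' @slot rmse root-mean-square landmark residual (nm).
#' @slot nLandmarks number of landmark pairs used.
#' @export
setClass("AffineTransform2D",
  representation(A = "matrix", t = "numeric", rmse = "numeric",
                 nLandmarks = "integer"))

setValidity("AffineTransform2D", function(object) {
  msg <- character()
  if (!identical(dim(object@A), c(2L, 2L))) msg <- c(msg, "A must be 2 x 2")
  else if (abs(det(object@A)) < .Machine$double.eps) {
    msg <- c(msg, "transform must be invertible (det A != 0)")
  }
  if (length(object@t) != 2L) msg <- c(msg, "t must have length 2")
  if (object@rmse < 0) msg <- c(msg, "RMSE must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Statistical test result
#'
#' @slot statistic Spearman r or Kolmogorov-Smirnov D.
#' @slot p two-sided p-value.
#' @slot n sample size(s).
#' @slot method human-readable method label.
#' @export
setClass("StatResult",
  representation(statistic = "numeric", p = "numeric", n = "integer",
                 method = "character"))

setValidity("StatResult", function(object) {
  msg <- character()
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1)) {
    msg <- c(msg, "p must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})
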