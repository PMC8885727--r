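#' @include AllClasses.R
NULL

# canonical snake_case keys used in YAML configs <-> slot names
.CONFIG_KEYS <- c(
  live_pixel_size = "livePixelSize", live_frame_rate = "liveFrameRate",
  stim_frame = "stimFrame", roi_size = "roiSize", bg_size = "bgSize",
  smooth_window = "smoothWindow", baseline_frames = "baselineFrames",
  peak_window = "peakWindow", response_sd_factor = "responseSdFactor",
  baseline_sd_on = "baselineSdOn", storm_camera_pixel = "stormCameraPixel",
  render_pixel = "renderPixel", density_factor = "densityFactor",
  density_reference = "densityReference",
  max_neighbour_dist = "maxNeighbourDist", min_molecules = "minMolecules",
  match_dist = "matchDist", orphan_dist = "orphanDist", pair_tol = "pairTol",
  demix_threshold = "demixThreshold", drift_bin_frames = "driftBinFrames",
  drift_grid = "driftGrid", seed = "seed")

.INT_SLOTS <- c("stimFrame", "roiSize", "bgSize", "smoothWindow",
                "baselineFrames", "peakWindow", "minMolecules",
                "driftBinFrames", "seed")

#' Create a pipeline configuration
#'
#' All arguments default to the standard protocol settings; see
#' [PipelineConfig-class] for their meaning and units.
#'
#' @param livePixelSize live pixel size, nm.
#' @param liveFrameRate frames per second per channel.
#' @param stimFrame 1-based stimulus frame.
#' @param roiSize,bgSize signal / background ROI edge length, pixels.
#' @param smoothWindow trailing smoothing window, frames.
#' @param baselineFrames baseline window, frames.
#' @param peakWindow peak-search window, frames.
#' @param responseSdFactor responder threshold in baseline-SD units.
#' @param baselineSdOn "smoothed" or "raw".
#' @param stormCameraPixel camera pixel size, nm.
#' @param renderPixel rendered super-resolution pixel size, nm.
#' @param densityFactor Voronoi threshold multiple of the reference density.
#' @param densityReference "global" or "mean".
#' @param maxNeighbourDist length-2 linking distances, nm (colour 1, colour 2).
#' @param minMolecules length-2 minimum molecules per cluster.
#' @param matchDist synapse matching cutoff, nm.
#' @param orphanDist orphan SSD assignment cutoff, nm.
#' @param pairTol two-camera pairing tolerance, nm.
#' @param demixThreshold posterior assignment threshold.
#' @param driftBinFrames frames per drift bin.
#' @param driftGrid drift histogram pixel, nm.
#' @param seed integer seed used by simulation helpers.
#' @return a validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig(stimFrame = 40L)
#' cfg
#' @export
pipelineConfig <- function(livePixelSize = 433, liveFrameRate = 12.5,
                           stimFrame = 40L, roiSize = 5L, bgSize = 15L,
                           smoothWindow = 4L, baselineFrames = 15L,
                           peakWindow = 15L, responseSdFactor = 3,
                           baselineSdOn = "raw",
                           stormCameraPixel = 97, renderPixel = 10,
                           densityFactor = 1.0, densityReference = "global",
                           maxNeighbourDist = c(200, 100),
                           minMolecules = c(200L, 20L),
                           matchDist = 500, orphanDist = 500, pairTol = 97,
                           demixThreshold = 0.99, driftBinFrames = 2000L,
                           driftGrid = 20, seed = 1L) {
  new("PipelineConfig",
      livePixelSize = as.numeric(livePixelSize),
      liveFrameRate = as.numeric(liveFrameRate),
      stimFrame = as.integer(stimFrame), roiSize = as.integer(roiSize),
      bgSize = as.integer(bgSize), smoothWindow = as.integer(smoothWindow),
      baselineFrames = as.integer(baselineFrames),
      peakWindow = as.integer(peakWindow),
      responseSdFactor = as.numeric(responseSdFactor),
      baselineSdOn = baselineSdOn,
      stormCameraPixel = as.numeric(stormCameraPixel),
      renderPixel = as.numeric(renderPixel),
      densityFactor = as.numeric(densityFactor),
      densityReference = densityReference,
      maxNeighbourDist = as.numeric(maxNeighbourDist),
      minMolecules = as.integer(minMolecules),
      matchDist = as.numeric(matchDist), orphanDist = as.numeric(orphanDist),
      pairTol = as.numeric(pairTol),
      demixThreshold = as.numeric(demixThreshold),
      driftBinFrames = as.integer(driftBinFrames),
      driftGrid = as.numeric(driftGrid), seed = as.integer(seed))
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file uses snake_case keys mirroring the configuration fields
#' (e.g. `live_pixel_size`, `max_neighbour_dist`). Unknown keys raise an
#' error; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @param config a [PipelineConfig-class] object.
#' @return `readPipelineConfig` returns a [PipelineConfig-class];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.CONFIG_KEYS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (key in names(raw)) {
    slot_name <- .CONFIG_KEYS[[key]]
    val <- raw[[key]]
    if (slot_name %in% .INT_SLOTS) val <- as.integer(val)
    args[[slot_name]] <- val
  }
  do.call(pipelineConfig, args)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  out <- lapply(.CONFIG_KEYS, function(s) {
    v <- slot(config, s)
    if (is.integer(v)) as.integer(v) else v
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
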