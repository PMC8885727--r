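#' @include AllClasses.R
NULL

.roi_bounds <- function(centre, half, dims) {
  rows <- (centre[1] - half):(centre[1] + half)
  cols <- (centre[2] - half):(centre[2] + half)
  list(rows = rows, cols = cols,
       inside = all(rows >= 1) && all(cols >= 1) &&
         all(rows <= dims[1]) && all(cols <= dims[2]))
}

# mean-intensity trace over a square ROI, one value per frame
.roi_trace <- function(data, rows, cols) {
  apply(data[rows, cols, , drop = FALSE], 3, mean)
}

# default background ROI: the bg-size window with minimum mean intensity in
# the time-averaged G frame, searched on a half-window stride
.auto_background <- function(data, bgSize) {
  meanframe <- rowMeans(data, dims = 2)
  half <- (bgSize - 1L) %/% 2L
  d <- dim(meanframe)
  stride <- max(1L, half)
  rs <- unique(pmin(pmax(seq(1L + half, d[1] - half, by = stride), 1L + half),
                    d[1] - half))
  cs <- unique(pmin(pmax(seq(1L + half, d[2] - half, by = stride), 1L + half),
                    d[2] - half))
  best <- NULL
  best_val <- Inf
  for (r in rs) {
    for (cc in cs) {
      v <- mean(meanframe[(r - half):(r + half), (cc - half):(cc + half)])
      if (v < best_val) {
        best_val <- v
        best <- c(r, cc)
      }
    }
  }
  best
}

#' Extract background-subtracted bouton traces
#'
#' For each bouton a square signal ROI (default 5 x 5 pixels) is centred on
#' the supplied pixel position and the per-frame ROI mean is computed in both
#' channels; a single larger background ROI (default 15 x 15 pixels) provides
#' the per-frame background mean that is subtracted from every bouton trace
#' of its channel.
#'
#' @param gMovie,rMovie [FluorescenceMovie-class] objects of equal geometry.
#' @param centres boutons x 2 matrix of ROI centre pixel indices (row, col),
#'   1-based.
#' @param bgCentre optional background ROI centre (row, col); by default the
#'   minimum-mean background-sized window of the time-averaged G channel.
#' @param config a [PipelineConfig-class].
#' @return a [TraceSet-class].
#' @export
extractTraces <- function(gMovie, rMovie, centres, bgCentre = NULL,
                          config = pipelineConfig()) {
  stopifnot(is(gMovie, "FluorescenceMovie"), is(rMovie, "FluorescenceMovie"))
  if (!identical(dim(gMovie@data), dim(rMovie@data))) {
    stop("G and R movies must have identical dimensions")
  }
  centres <- matrix(as.numeric(centres), ncol = 2)
  d <- dim(gMovie@data)
  halfR <- (config@roiSize - 1L) %/% 2L
  halfB <- (config@bgSize - 1L) %/% 2L
  if (is.null(bgCentre)) bgCentre <- .auto_background(gMovie@data, config@bgSize)
  bg <- .roi_bounds(round(bgCentre), halfB, d)
  if (!bg$inside) stop("placement error: background ROI clipped by the frame edge")
  bgG <- .roi_trace(gMovie@data, bg$rows, bg$cols)
  bgR <- .roi_trace(rMovie@data, bg$rows, bg$cols)
  n <- nrow(centres)
  g <- matrix(0, d[3], n)
  r <- matrix(0, d[3], n)
  for (i in seq_len(n)) {
    roi <- .roi_bounds(round(centres[i, ]), halfR, d)
    if (!roi$inside) {
      stop(sprintf("placement error: ROI of bouton %d clipped by the frame edge", i))
    }
    g[, i] <- .roi_trace(gMovie@data, roi$rows, roi$cols) - bgG
    r[, i] <- .roi_trace(rMovie@data, roi$rows, roi$cols) - bgR
  }
  new("TraceSet", g = g, r = r, bgG = bgG, bgR = bgR, centres = centres,
      bgCentre = as.numeric(bgCentre), stimFrame = gMovie@stimFrame,
      frameRate = gMovie@frameRate)
}

#' Trailing moving-average trace smoothing
#'
#' Causal smoothing: `output[t] = mean(input[max(1, t - window + 1) .. t])`.
#' A trailing window cannot leak post-stimulus signal into the baseline,
#' which a centred window would.
#'
#' @param trace numeric intensity-vs-frame vector.
#' @param window window length in frames (>= 1, <= trace length).
#' @return smoothed trace of the same length.
#' @examples
#' smoothTrace(c(0, 0, 0, 0, 4, 4, 4, 4), 4)  # 0 0 0 0 1 2 3 4
#' @export
smoothTrace <- function(trace, window) {
  n <- length(trace)
  window <- as.integer(window)
  if (window < 1L || window > n) {
    stop("contract error: window must be in [1, length(trace)]")
  }
  cs <- cumsum(trace)
  out <- numeric(n)
  head_part <- seq_len(min(window, n))
  out[head_part] <- cs[head_part] / head_part
  if (n > window) {
    idx <- (window + 1L):n
    out[idx] <- (cs[idx] - cs[idx - window]) / window
  }
  out
}

#' Analyse per-bouton stimulus responses
#'
#' On the smoothed traces: the baselines G0 and R0 are the means of the
#' `baselineFrames` frames ending one frame before the stimulus; the baseline
#' SDs are taken over the same frames (on the smoothed trace by default, on
#' the raw trace when `config@baselineSdOn == "raw"`); the peak responses
#' dG and dR are the maxima of (signal - baseline) within `peakWindow` frames
#' starting at the stimulus frame inclusive. A bouton is a calcium responder
#' when dR exceeds `responseSdFactor` x its baseline R SD (strictly, so a
#' flat zero-SD trace never classifies as responding), and release is
#' detected when dG exceeds the same multiple of the baseline G SD. dG and dR
#' are both normalised to R0 (the baseline reporter level); dG/dR is reported
#' only for calcium responders with dR > 0.
#'
#' @param traces a [TraceSet-class].
#' @param config a [PipelineConfig-class].
#' @return data.frame with one row per bouton: bouton, G0, R0, baseline_sd_G,
#'   baseline_sd_R, dG, dR, dG_over_R, dR_over_R, dG_over_dR,
#'   calcium_responder, release_detected, valid, reason. Boutons with
#'   R0 <= 0 are flagged invalid with the reason logged and their derived
#'   ratios set NA (they are excluded downstream).
#' @export
analyseResponse <- function(traces, config = pipelineConfig()) {
  stopifnot(is(traces, "TraceSet"))
  n_frames <- nrow(traces@g)
  stim <- config@stimFrame
  if (stim - config@baselineFrames < 1L ||
      stim + config@peakWindow - 1L > n_frames) {
    stop(sprintf(
      "stimulus frame %d leaves no room for a %d-frame baseline and %d-frame peak window in %d frames",
      stim, config@baselineFrames, config@peakWindow, n_frames))
  }
  base_idx <- (stim - config@baselineFrames):(stim - 1L)
  peak_idx <- stim:(stim + config@peakWindow - 1L)
  n <- ncol(traces@g)
  out <- data.frame(
    bouton = seq_len(n), G0 = NA_real_, R0 = NA_real_,
    baseline_sd_G = NA_real_, baseline_sd_R = NA_real_,
    dG = NA_real_, dR = NA_real_, dG_over_R = NA_real_, dR_over_R = NA_real_,
    dG_over_dR = NA_real_, calcium_responder = FALSE, release_detected = FALSE,
    valid = TRUE, reason = "")
  for (i in seq_len(n)) {
    sg <- smoothTrace(traces@g[, i], config@smoothWindow)
    sr <- smoothTrace(traces@r[, i], config@smoothWindow)
    G0 <- mean(sg[base_idx])
    R0 <- mean(sr[base_idx])
    sdG <- if (config@baselineSdOn == "smoothed") sd(sg[base_idx]) else
      sd(traces@g[base_idx, i])
    sdR <- if (config@baselineSdOn == "smoothed") sd(sr[base_idx]) else
      sd(traces@r[base_idx, i])
    dG <- max(sg[peak_idx]) - G0
    dR <- max(sr[peak_idx]) - R0
    out$G0[i] <- G0
    out$R0[i] <- R0
    out$baseline_sd_G[i] <- sdG
    out$baseline_sd_R[i] <- sdR
    out$dG[i] <- dG
    out$dR[i] <- dR
    out$calcium_responder[i] <- dR > config@responseSdFactor * sdR
    out$release_detected[i] <- dG > config@responseSdFactor * sdG
    if (R0 <= 0) {
      out$valid[i] <- FALSE
      out$reason[i] <- sprintf("baseline R0 = %.4g <= 0", R0)
      next
    }
    out$dG_over_R[i] <- dG / R0
    out$dR_over_R[i] <- dR / R0
    if (out$calcium_responder[i] && dR > 0) out$dG_over_dR[i] <- dG / dR
  }
  excluded <- which(!out$valid)
  if (length(excluded)) {
    message(sprintf("analyseResponse: excluded %d bouton(s) with invalid baseline: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  out
}
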