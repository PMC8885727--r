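#' @include AllClasses.R io.R
NULL

# stimulus response kernel: step to a plateau lasting `plateau` frames, then
# exponential decay. The plateau is at least as long as the smoothing window
# so that trailing-window smoothing of a noiseless response recovers the
# programmed amplitude exactly.
.response_kernel <- function(nFrames, stim, plateau, tau) {
  t <- seq_len(nFrames)
  h <- numeric(nFrames)
  on <- t >= stim & t <= stim + plateau - 1L
  h[on] <- 1
  late <- t > stim + plateau - 1L
  h[late] <- exp(-(t[late] - (stim + plateau - 1L)) / tau)
  h
}

.grid_centres <- function(n, sep, margin) {
  side <- ceiling(sqrt(n))
  rows <- margin + sep * (seq_len(side) - 1L)
  centres <- as.matrix(expand.grid(row = rows, col = rows))[seq_len(n), , drop = FALSE]
  dims <- rep(margin * 2L + sep * (side - 1L), 2L)
  list(centres = centres, dims = dims)
}

#' Simulate a stimulus-locked two-channel functional movie
#'
#' Each bouton is a Gaussian spot (sigma = 1.5 px) whose ROI-mean amplitude is
#' normalised to 1, sitting on channel baselines G0 (low) and R0 (high). At
#' the stimulus frame both channels step up by the programmed amplitude, hold
#' a plateau at least as long as the smoothing window, then decay
#' exponentially (tau = 40 frames for G, emulating slow pHluorin re-quenching;
#' 8 frames for R, emulating calcium extrusion). i.i.d. Gaussian noise of SD
#' `noiseSd` is added per pixel. Identical seeds give bit-identical movies.
#'
#' @param config a [PipelineConfig-class]; supplies stimulus frame, pixel
#'   size, frame rate and ROI geometry.
#' @param nSynapses number of boutons.
#' @param amplitudes nSynapses x 2 matrix of programmed (dG, dR) peak
#'   amplitudes in intensity units.
#' @param noiseSd per-pixel Gaussian noise SD (0 = noiseless).
#' @param seed integer seed.
#' @param nFrames frames per channel.
#' @param baseline length-2 baseline intensities c(G0, R0).
#' @param tauG,tauR decay time constants in frames.
#' @param spotSigma Gaussian spot SD in pixels.
#' @param centres optional nSynapses x 2 integer matrix of bouton centres
#'   (row, col); auto-placed on a grid separated by more than the background
#'   ROI size when NULL.
#' @return list with elements `g`, `r` ([FluorescenceMovie-class]) and
#'   `truth` (bouton centres, programmed amplitudes, baselines, kernels).
#' @export
simulateFunctionalMovie <- function(config = pipelineConfig(), nSynapses = 10,
                                    amplitudes, noiseSd = 0,
                                    seed = config@seed, nFrames = 80L,
                                    baseline = c(G = 10, R = 100),
                                    tauG = 40, tauR = 8, spotSigma = 1.5,
                                    centres = NULL) {
  set.seed(seed)
  amplitudes <- matrix(as.numeric(amplitudes), ncol = 2)
  if (nrow(amplitudes) != nSynapses) {
    stop("one (dG, dR) amplitude pair per synapse required")
  }
  sep <- config@bgSize + 2L
  if (is.null(centres)) {
    g <- .grid_centres(nSynapses, sep, margin = 2L * config@bgSize)
    centres <- g$centres
    dims <- g$dims
  } else {
    centres <- matrix(as.integer(round(centres)), ncol = 2)
    dims <- c(max(centres[, 1]) + config@bgSize, max(centres[, 2]) + config@bgSize)
  }
  if (nSynapses > 1) {
    dmin <- min(dist(centres))
    if (dmin <= config@bgSize) {
      stop(sprintf("placement error: boutons overlap (min separation %.1f px <= bg ROI %d px)",
                   dmin, config@bgSize))
    }
  }
  stim <- config@stimFrame
  if (stim - config@baselineFrames < 1L || stim + config@peakWindow - 1L > nFrames) {
    stop("stimulus frame incompatible with baseline/peak windows for this movie length")
  }
  hG <- .response_kernel(nFrames, stim, config@smoothWindow, tauG)
  hR <- .response_kernel(nFrames, stim, config@smoothWindow, tauR)

  half <- (config@roiSize - 1L) %/% 2L
  rowidx <- matrix(seq_len(dims[1]), dims[1], dims[2])
  colidx <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  spotG <- matrix(0, dims[1], dims[2])   # sum_i K_i * dG_i, time-invariant parts
  spotR <- matrix(0, dims[1], dims[2])
  baseG <- matrix(0, dims[1], dims[2])
  baseR <- matrix(0, dims[1], dims[2])
  spots <- vector("list", nSynapses)
  for (i in seq_len(nSynapses)) {
    K <- exp(-((rowidx - centres[i, 1])^2 + (colidx - centres[i, 2])^2) /
               (2 * spotSigma^2))
    roi <- K[(centres[i, 1] - half):(centres[i, 1] + half),
             (centres[i, 2] - half):(centres[i, 2] + half)]
    K <- K / mean(roi)                  # ROI-mean amplitude of 1
    spots[[i]] <- K
    baseG <- baseG + baseline[1] * K
    baseR <- baseR + baseline[2] * K
    spotG <- spotG + amplitudes[i, 1] * K
    spotR <- spotR + amplitudes[i, 2] * K
  }
  gArr <- array(0, dim = c(dims, nFrames))
  rArr <- array(0, dim = c(dims, nFrames))
  for (f in seq_len(nFrames)) {
    gArr[, , f] <- baseG + hG[f] * spotG
    rArr[, , f] <- baseR + hR[f] * spotR
  }
  if (noiseSd > 0) {
    gArr <- gArr + array(rnorm(length(gArr), 0, noiseSd), dim = dim(gArr))
    rArr <- rArr + array(rnorm(length(rArr), 0, noiseSd), dim = dim(rArr))
  }
  mk <- function(a, ch) new("FluorescenceMovie", data = a, channel = ch,
                            pixelSize = config@livePixelSize,
                            frameRate = config@liveFrameRate, stimFrame = stim)
  list(g = mk(gArr, "G"), r = mk(rArr, "R"),
       truth = list(centresPx = centres, amplitudes = amplitudes,
                    baseline = baseline, kernelG = hG, kernelR = hR,
                    noiseSd = noiseSd, seed = seed))
}

#' Simulate two-camera single-emitter intensities for spectral demixing
#'
#' Total photon counts are lognormal with the requested mean; the photon
#' ratio of each emitter is Normal around its fluorophore's mean, truncated
#' to \[0, 1\]. Camera intensities are I_cam1 = rho x total and
#' I_cam2 = (1 - rho) x total. Defaults mimic the bimodal photon-ratio
#' histogram of an AF647 / CF680 pair split by a long-pass dichroic.
#'
#' @param nPerFluor length-2 counts c(nA, nB).
#' @param ratioMeans length-2 ratio means c(muA, muB) with 0 < muB < muA < 1.
#' @param ratioSd ratio SD (> 0).
#' @param photonBudget mean total photons per emitter.
#' @param seed integer seed.
#' @return list with `table` (a [LocalizationTable-class], fluorophore
#'   unassigned) and `labels` (factor of true fluorophores, fluorA first).
#' @export
simulateTwoCameraEmitters <- function(nPerFluor = c(1000, 1000),
                                      ratioMeans = c(0.75, 0.30),
                                      ratioSd = 0.05, photonBudget = 3000,
                                      seed = 1L) {
  if (ratioSd <= 0) stop("contract error: ratioSd must be > 0")
  if (!(ratioMeans[2] > 0 && ratioMeans[2] < ratioMeans[1] && ratioMeans[1] < 1)) {
    stop("contract error: require 0 < muB < muA < 1")
  }
  set.seed(seed)
  n <- sum(nPerFluor)
  labels <- factor(rep(c("fluorA", "fluorB"), nPerFluor),
                   levels = c("fluorA", "fluorB"))
  if (n == 0) {
    return(list(table = localizationTable(), labels = labels))
  }
  mu <- ratioMeans[as.integer(labels)]
  rho <- rnorm(n, mu, ratioSd)
  while (any(bad <- rho < 0 | rho > 1)) {          # truncate by resampling
    rho[bad] <- rnorm(sum(bad), mu[bad], ratioSd)
  }
  sdlog <- 0.5
  total <- rlnorm(n, log(photonBudget) - sdlog^2 / 2, sdlog)
  tbl <- localizationTable(
    x = runif(n, 0, 20000), y = runif(n, 0, 20000), z = runif(n, 0, 600),
    frame = sample(0:59999, n, replace = TRUE),
    I_cam1 = rho * total, I_cam2 = (1 - rho) * total)
  list(table = tbl, labels = labels)
}

#' Simulate a two-colour 3D synapse point-cloud scene
#'
#' Each synapse is a large diffuse colour-1 cluster (Gaussian, default
#' sigma = 150 nm, emulating the synaptic-vesicle reporter cloud) with 1-6
#' compact colour-2 subclusters (SSDs; Gaussian, default sigma = 40 nm)
#' placed on its periphery at a fixed offset from the colour-1 centroid,
#' emulating active-zone geometry. Uniform Poisson background is added in
#' both colours. The z span of the scene is limited to 1000 nm, the usable
#' axial range of astigmatic 3D localisation.
#'
#' @param nSynapses number of synapses.
#' @param ssdCountRange length-2 integer range of SSDs per synapse.
#' @param colour1N length-2 range of colour-1 detections per synapse
#'   (drawn uniformly), or a single fixed count.
#' @param colour1Sigma colour-1 cluster SD, nm.
#' @param ssdN length-2 range (or fixed count) of detections per SSD.
#' @param ssdSigma SSD cluster SD, nm.
#' @param ssdOffset minimum SSD centre offset from the colour-1 centroid, nm
#'   (radii are drawn up to 3x this value).
#' @param minSsdSep minimum mutual separation of SSD centres within one
#'   synapse, nm. Ground-truth SSD counts are counts of link-separable
#'   domains, so centres must stay far enough apart that distinct domains do
#'   not merge under the colour-2 linking distance; 400 nm keeps the chance
#'   of a Gaussian-tail bridge between 40 nm-SD domains negligible.
#' @param backgroundDensity uniform background density, points per um^3,
#'   applied to both colours.
#' @param box 2 x 3 matrix (rows = min, max) of the scene volume in nm;
#'   by default the field of a 512 x 512 pixel acquisition at 97 nm with a
#'   1 um axial range (never cropping tighter than the synapse grid). The
#'   field volume matters: the segmentation reference density is the
#'   dataset average over the field.
#' @param centres optional nSynapses x 3 matrix of synapse centres in nm
#'   (>= 2 um apart); auto-placed on a grid when NULL.
#' @param seed integer seed.
#' @return list with `points1`, `points2` (n x 3 matrices, nm) and `truth`
#'   (centres, per-point labels — synapse index for colour 1, synapse and SSD
#'   index for colour 2, 0 = background — SSD counts and detection counts,
#'   box, seed).
#' @export
simulateSynapseScene <- function(nSynapses = 5, ssdCountRange = c(1L, 6L),
                                 colour1N = c(200, 2000), colour1Sigma = 150,
                                 ssdN = c(20, 200), ssdSigma = 40,
                                 ssdOffset = 150, minSsdSep = 400,
                                 backgroundDensity = 5,
                                 box = NULL, centres = NULL, seed = 1L) {
  set.seed(seed)
  min_sep <- 2000
  if (is.null(centres)) {
    side <- ceiling(sqrt(nSynapses))
    sep <- 2500
    margin <- 1000
    xy <- as.matrix(expand.grid(
      x = margin + sep * (seq_len(side) - 1L),
      y = margin + sep * (seq_len(side) - 1L)))[seq_len(nSynapses), , drop = FALSE]
    centres <- cbind(xy, z = 500)
  } else {
    centres <- matrix(as.numeric(centres), ncol = 3)
  }
  if (is.null(box)) {
    # default field emulates a 512 x 512 px (97 nm) acquisition with a 1 um
    # axial range; the box never crops tighter than the synapse grid
    field <- 512 * 97
    box <- rbind(min = c(min(centres[, 1]) - 1000, min(centres[, 2]) - 1000, 0),
                 max = c(max(max(centres[, 1]) + 1000, min(centres[, 1]) - 1000 + field),
                         max(max(centres[, 2]) + 1000, min(centres[, 2]) - 1000 + field),
                         1000))
  } else {
    box <- matrix(as.numeric(box), 2, 3)
  }
  if (nrow(centres) > 1 && min(dist(centres)) < min_sep) {
    stop("placement error: synapse centres closer than 2 um")
  }
  inside <- all(centres >= matrix(box[1, ], nrow(centres), 3, byrow = TRUE) &
                centres <= matrix(box[2, ], nrow(centres), 3, byrow = TRUE))
  if (!inside) stop("placement error: box too small for the requested synapses")

  draw_count <- function(spec) {
    if (length(spec) == 1L) as.integer(spec) else
      as.integer(round(runif(1, spec[1], spec[2])))
  }
  rand_dir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  p1 <- list(); lab1 <- list()
  p2 <- list(); lab2_syn <- list(); lab2_ssd <- list()
  ssd_counts <- integer(nrow(centres))
  ssd_points <- list()
  for (i in seq_len(nrow(centres))) {
    n1 <- draw_count(colour1N)
    pts <- sweep(matrix(rnorm(n1 * 3, 0, colour1Sigma), n1, 3), 2,
                 centres[i, ], "+")
    p1[[i]] <- pts
    lab1[[i]] <- rep(i, n1)
    rng <- seq(ssdCountRange[1], ssdCountRange[2])
    k <- rng[sample.int(length(rng), 1)]
    ssd_counts[i] <- k
    counts_i <- integer(k)
    # SSD centres keep a minimum mutual separation: the ground-truth SSD
    # count is the number of link-separable domains (as in the real
    # analysis, where SSD counts are segmentation outputs), so domains must
    # not merge under the colour-2 linking distance
    placed <- matrix(numeric(), 0, 3)
    for (s in seq_len(k)) {
      for (try in seq_len(500)) {
        ctr <- centres[i, ] + runif(1, ssdOffset, 3 * ssdOffset) * rand_dir()
        if (!nrow(placed) ||
            min(sqrt(rowSums(sweep(placed, 2, ctr)^2))) >= minSsdSep) break
      }
      placed <- rbind(placed, ctr)
      ns <- draw_count(ssdN)
      counts_i[s] <- ns
      pts2 <- sweep(matrix(rnorm(ns * 3, 0, ssdSigma), ns, 3), 2, ctr, "+")
      p2[[length(p2) + 1L]] <- pts2
      lab2_syn[[length(lab2_syn) + 1L]] <- rep(i, ns)
      lab2_ssd[[length(lab2_ssd) + 1L]] <- rep(s, ns)
    }
    ssd_points[[i]] <- counts_i
  }
  vol_um3 <- prod(box[2, ] - box[1, ]) / 1e9
  add_bg <- function() {
    nb <- rpois(1, backgroundDensity * vol_um3)
    cbind(runif(nb, box[1, 1], box[2, 1]), runif(nb, box[1, 2], box[2, 2]),
          runif(nb, box[1, 3], box[2, 3]))
  }
  bg1 <- add_bg()
  bg2 <- add_bg()
  points1 <- rbind(do.call(rbind, p1), bg1)
  points2 <- rbind(do.call(rbind, p2), bg2)
  colnames(points1) <- colnames(points2) <- c("x", "y", "z")
  truth <- list(
    centres = centres,
    labels1 = c(unlist(lab1), rep(0L, nrow(bg1))),
    labels2_synapse = c(unlist(lab2_syn), rep(0L, nrow(bg2))),
    labels2_ssd = c(unlist(lab2_ssd), rep(0L, nrow(bg2))),
    ssdCounts = ssd_counts, ssdPointCounts = ssd_points,
    box = box, backgroundDensity = backgroundDensity, seed = seed)
  list(points1 = points1, points2 = points2, truth = truth)
}

#' Simulate a full correlative dataset with programmed coupling
#'
#' Generates everything the pipeline consumes end to end: bouton centres in
#' live pixel space are mapped through a randomly drawn invertible affine
#' (scale close to the live pixel size, small rotation and shear) into the nm
#' space where the two-colour point clouds are placed; exact landmark pairs
#' are emitted for registration; per-point two-camera intensities follow the
#' spectral-demixing ratio model; and the functional movies are generated
#' with amplitudes coupled (or not) to structure. Under positive coupling
#' dG = couplingCoeff x (total SSD detections) x exp(eps), with eps Normal of
#' SD `sigmaLog` centred so the factor has mean 1; under null coupling dG is
#' drawn independently of structure.
#'
#' @param config a [PipelineConfig-class].
#' @param nSynapses number of synapses (>= 3 advised for correlation).
#' @param coupling "positive" or "null".
#' @param couplingCoeff intensity units per SSD detection.
#' @param sigmaLog lognormal coupling noise SD (0 = deterministic coupling).
#' @param noiseSd per-pixel movie noise SD.
#' @param seed integer seed.
#' @param nFrames frames per channel.
#' @param sceneArgs named list of overrides passed to
#'   [simulateSynapseScene()].
#' @return list with `g`, `r` (movies), `locs` (combined
#'   [LocalizationTable-class] with camera intensities, unassigned),
#'   `landmarks` (list of `src` live-px and `dst` nm coordinates), and
#'   `truth` (true affine `A`, `t`; live-px and nm synapse centres; scene
#'   ground truth; programmed amplitudes; SSD totals; coupling settings).
#' @export
simulateCorrelativeDataset <- function(config = pipelineConfig(),
                                       nSynapses = 20,
                                       coupling = c("positive", "null"),
                                       couplingCoeff = 0.1, sigmaLog = 0.3,
                                       noiseSd = 1, seed = config@seed,
                                       nFrames = 80L, sceneArgs = list()) {
  coupling <- match.arg(coupling)
  if (nSynapses < 3 && coupling == "positive") {
    warning("correlation underpowered: fewer than 3 synapses")
  }
  set.seed(seed)
  sep <- config@bgSize + 2L
  g <- .grid_centres(nSynapses, sep, margin = 2L * config@bgSize)
  centresPx <- g$centres                       # (row, col)
  liveXY <- cbind(x = centresPx[, 2], y = centresPx[, 1])

  theta <- runif(1, -0.0873, 0.0873)           # +/- 5 degrees
  shear <- runif(1, -0.03, 0.03)
  scale <- config@livePixelSize * (1 + runif(1, -0.02, 0.02))
  A <- scale * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2) %*%
    matrix(c(1, 0, shear, 1), 2)
  tvec <- runif(2, 0, 2000)
  toNm <- function(xy) sweep(xy %*% t(A), 2, tvec, "+")
  centresNm <- cbind(toNm(liveXY), z = 500)

  zspan <- c(0, 1000)
  box <- rbind(min = c(apply(centresNm[, 1:2, drop = FALSE], 2, min) - 1000, zspan[1]),
               max = c(apply(centresNm[, 1:2, drop = FALSE], 2, max) + 1000, zspan[2]))
  scene <- do.call(simulateSynapseScene, utils::modifyList(
    list(nSynapses = nSynapses, centres = centresNm, box = box,
         colour1N = c(300, 1200), seed = seed + 1L), sceneArgs))

  ssdTotal <- vapply(scene$truth$ssdPointCounts, sum, 0L)
  eps <- rnorm(nSynapses, -sigmaLog^2 / 2, sigmaLog)
  dG <- if (coupling == "positive") {
    couplingCoeff * ssdTotal * exp(eps)
  } else {
    couplingCoeff * mean(ssdTotal) * exp(rnorm(nSynapses, -sigmaLog^2 / 2,
                                               max(sigmaLog, 0.3)))
  }
  dR <- runif(nSynapses, 20, 60)
  movies <- simulateFunctionalMovie(config, nSynapses,
                                    amplitudes = cbind(dG, dR),
                                    noiseSd = noiseSd, seed = seed + 2L,
                                    nFrames = nFrames, centres = centresPx)

  pts <- rbind(scene$points1, scene$points2)
  n1 <- nrow(scene$points1)
  n2 <- nrow(scene$points2)
  mu <- c(rep(0.75, n1), rep(0.30, n2))
  rho <- rnorm(n1 + n2, mu, 0.05)
  while (any(bad <- rho < 0 | rho > 1)) {
    rho[bad] <- rnorm(sum(bad), mu[bad], 0.05)
  }
  total <- rlnorm(n1 + n2, log(3000) - 0.125, 0.5)
  locs <- localizationTable(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            frame = sample(0:59999, n1 + n2, replace = TRUE),
                            I_cam1 = rho * total, I_cam2 = (1 - rho) * total)
  trueColour <- rep(c(1L, 2L), c(n1, n2))

  lmSrc <- cbind(x = runif(6, 1, max(liveXY[, 1])),
                 y = runif(6, 1, max(liveXY[, 2])))
  lmDst <- toNm(lmSrc)

  list(g = movies$g, r = movies$r, locs = locs,
       landmarks = list(src = lmSrc, dst = lmDst),
       truth = list(A = A, t = tvec, centresPx = centresPx, liveXY = liveXY,
                    centresNm = centresNm, scene = scene$truth,
                    trueColour = trueColour, amplitudes = cbind(dG = dG, dR = dR),
                    ssdTotal = ssdTotal, coupling = coupling,
                    couplingCoeff = couplingCoeff, sigmaLog = sigmaLog,
                    movieTruth = movies$truth, seed = seed))
}
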