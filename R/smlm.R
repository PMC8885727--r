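#' @include AllClasses.R io.R
NULL

#' Pair detections of the same emitter from two cameras
#'
#' Detections on the two cameras of a spectral-demixing splitter that fall on
#' the same acquisition frame and are mutual nearest neighbours within the
#' tolerance are merged into single records carrying both camera intensities
#' (camera 1 supplies the coordinates). Unpaired detections are dropped and
#' their counts logged.
#'
#' @param cam1,cam2 [LocalizationTable-class] objects in a common coordinate
#'   frame; `I_cam1` of `cam1` and `I_cam1` of `cam2` hold each camera's
#'   measured intensity.
#' @param tol pairing tolerance in nm (default one camera pixel, 97 nm).
#' @param frameMatch require identical frame indices (default TRUE).
#' @return a paired [LocalizationTable-class] with both intensities filled.
#' @export
pairDetections <- function(cam1, cam2, tol = 97, frameMatch = TRUE) {
  if (tol <= 0) stop("contract error: tol must be > 0")
  r1 <- records(cam1)
  r2 <- records(cam2)
  pairs <- matrix(integer(), 0, 2)
  if (nrow(r1) && nrow(r2)) {
    groups <- if (frameMatch) {
      shared <- intersect(unique(r1$frame), unique(r2$frame))
      lapply(shared, function(f) list(i1 = which(r1$frame == f),
                                      i2 = which(r2$frame == f)))
    } else {
      list(list(i1 = seq_len(nrow(r1)), i2 = seq_len(nrow(r2))))
    }
    for (g in groups) {
      d <- outer(r1$x[g$i1], r2$x[g$i2], "-")^2 +
        outer(r1$y[g$i1], r2$y[g$i2], "-")^2
      nn12 <- apply(d, 1, which.min)
      nn21 <- apply(d, 2, which.min)
      mutual <- which(nn21[nn12] == seq_along(g$i1) &
                        d[cbind(seq_along(g$i1), nn12)] <= tol^2)
      if (length(mutual)) {
        pairs <- rbind(pairs, cbind(g$i1[mutual], g$i2[nn12[mutual]]))
      }
    }
  }
  message(sprintf("pairDetections: %d pairs; dropped %d of %d (camera 1) and %d of %d (camera 2)",
                  nrow(pairs), nrow(r1) - nrow(pairs), nrow(r1),
                  nrow(r2) - nrow(pairs), nrow(r2)))
  localizationTable(
    x = r1$x[pairs[, 1]], y = r1$y[pairs[, 1]], z = r1$z[pairs[, 1]],
    frame = r1$frame[pairs[, 1]],
    I_cam1 = r1$I_cam1[pairs[, 1]], I_cam2 = r2$I_cam1[pairs[, 2]])
}

#' Compute the spectral-demixing photon ratio
#'
#' Fills `ratio` with rho = I_cam1 / (I_cam1 + I_cam2) for every record with
#' both camera intensities. Records with zero total intensity are flagged
#' rejected; records lacking camera intensities raise an error (demixing is
#' impossible, not silently defaulted).
#'
#' @param table a [LocalizationTable-class].
#' @return the table with `ratio` filled.
#' @export
computePhotonRatio <- function(table) {
  rec <- records(table)
  if (!nrow(rec)) return(table)
  if (anyNA(rec$I_cam1) || anyNA(rec$I_cam2)) {
    stop("camera intensities missing: cannot compute photon ratio ",
         "(supply I_cam1/I_cam2 columns or pair the two camera tables first)")
  }
  tot <- rec$I_cam1 + rec$I_cam2
  zero <- tot <= 0
  rec$ratio[!zero] <- rec$I_cam1[!zero] / tot[!zero]
  rec$ratio[zero] <- NA_real_
  rec$fluor[zero] <- "rejected"
  new("LocalizationTable", records = rec)
}

#' Fit a two-component photon-ratio mixture for spectral demixing
#'
#' A two-component Gaussian mixture (unequal variances) is fitted to the
#' photon-ratio histogram; the component with the larger mean is fluorophore
#' A (stronger on camera 1). Mixtures whose component means are closer than
#' one pooled SD cannot separate the fluorophores and raise a
#' demixing-failure error.
#'
#' @param ratios numeric photon ratios (>= 100 values).
#' @param threshold posterior assignment threshold (default 0.99): detections
#'   with a smaller posterior for both components are rejected, bounding the
#'   crosstalk explicitly.
#' @return a [DemixModel-class].
#' @export
fitDemixModel <- function(ratios, threshold = 0.99) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 100) {
    stop("contract error: at least 100 photon ratios required")
  }
  # EM via mclust's engine, initialised from a quantile-centred 2-means split
  init <- stats::kmeans(ratios, centers = unname(stats::quantile(ratios, c(0.25, 0.75))))
  z0 <- mclust::unmap(init$cluster, groups = 1:2)
  fit <- tryCatch(mclust::meV(data = ratios, z = z0), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$parameters$mean)) {
    fit <- tryCatch(mclust::meE(data = ratios, z = z0), error = function(e) NULL)
  }
  if (is.null(fit) || anyNA(fit$parameters$mean)) {
    stop("demixing failure: mixture fit did not converge")
  }
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  w <- fit$parameters$pro
  hi <- which.max(mu)
  lo <- which.min(mu)
  pooled <- sqrt(mean(sigma^2))
  if (abs(mu[hi] - mu[lo]) < pooled) {
    stop(sprintf(
      "demixing failure: components degenerate (|muA - muB| = %.3f < pooled SD %.3f)",
      abs(mu[hi] - mu[lo]), pooled))
  }
  # antimode guard: a genuine two-fluorophore histogram dips between the
  # component means; unimodal data fitted as a split pair does not
  fmix <- function(x) {
    w[hi] * stats::dnorm(x, mu[hi], sigma[hi]) +
      w[lo] * stats::dnorm(x, mu[lo], sigma[lo])
  }
  dip <- fmix((mu[hi] + mu[lo]) / 2) / min(fmix(mu[hi]), fmix(mu[lo]))
  if (!is.finite(dip) || dip > 0.5) {
    stop(sprintf(
      "demixing failure: no density dip between components (ratio %.2f); photon-ratio histogram is unimodal",
      dip))
  }
  new("DemixModel", muA = mu[hi], muB = mu[lo], sdA = sigma[hi],
      sdB = sigma[lo], weightA = w[hi], weightB = w[lo],
      threshold = threshold)
}

#' Assign fluorophores from the photon ratio
#'
#' Each record with a defined photon ratio is assigned fluorA when the
#' posterior probability of component A reaches the model threshold, fluorB
#' when the posterior of B does, and rejected otherwise (the crosstalk
#' guard). Records without a ratio stay as they are.
#'
#' @param table a [LocalizationTable-class] with `ratio` filled (see
#'   [computePhotonRatio()]).
#' @param model a [DemixModel-class].
#' @return the table with `fluor` labels filled.
#' @export
classifyFluorophores <- function(table, model) {
  stopifnot(is(model, "DemixModel"))
  rec <- records(table)
  ok <- !is.na(rec$ratio)
  if (any(ok)) {
    dA <- model@weightA * stats::dnorm(rec$ratio[ok], model@muA, model@sdA)
    dB <- model@weightB * stats::dnorm(rec$ratio[ok], model@muB, model@sdB)
    postA <- dA / (dA + dB)
    lab <- rep("rejected", sum(ok))
    lab[postA >= model@threshold] <- "fluorA"
    lab[1 - postA >= model@threshold] <- "fluorB"
    rec$fluor[ok] <- lab
  }
  new("LocalizationTable", records = rec)
}

# ---------------------------------------------------------------------------
# Drift correction
# ---------------------------------------------------------------------------

# integer-pixel cross-correlation shift (b relative to a) via FFT, then
# sub-pixel refinement by upsampled DFT of the cross-power spectrum. The
# spectrum is Gaussian low-pass filtered (sigma in histogram pixels) so that
# the correlation peak of sparse localisation histograms is smooth enough
# for sub-pixel interpolation.
.cross_corr_shift <- function(a, b, upsample = 10, sigma = 1.5) {
  d <- dim(a)
  kr <- 2 * pi * (seq_len(d[1]) - 1) / d[1]
  kc <- 2 * pi * (seq_len(d[2]) - 1) / d[2]
  kr <- ifelse(kr > pi, kr - 2 * pi, kr)
  kc <- ifelse(kc > pi, kc - 2 * pi, kc)
  CP <- fft(b) * Conj(fft(a))
  CP <- CP * exp(-outer(kr^2, kc^2, "+") * sigma^2)
  cc <- Re(fft(CP, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  shift <- peak - 1L
  shift <- ifelse(shift > d / 2, shift - d, shift)
  if (upsample > 1) {
    # refine on a 1.5-pixel neighbourhood at 1/upsample steps (matrix DFT)
    win <- 1.5
    r_off <- shift[1] + seq(-win, win, by = 1 / upsample)
    c_off <- shift[2] + seq(-win, win, by = 1 / upsample)
    ER <- exp(1i * outer(r_off, kr))          # |r_off| x d1
    EC <- exp(1i * outer(kc, c_off))          # d2 x |c_off|
    cc_up <- Re(ER %*% CP %*% EC)
    pk <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    shift <- c(r_off[pk[1]], c_off[pk[2]])
  }
  shift
}

.bin_histogram <- function(x, y, origin, dims, grid) {
  r <- floor((y - origin[2]) / grid) + 1L
  cc <- floor((x - origin[1]) / grid) + 1L
  keep <- r >= 1L & r <= dims[1] & cc >= 1L & cc <= dims[2]
  m <- matrix(0, dims[1], dims[2])
  tab <- table(factor(r[keep], levels = seq_len(dims[1])),
               factor(cc[keep], levels = seq_len(dims[2])))
  m[] <- as.numeric(tab)
  m
}

#' Estimate lateral drift by redundant cross-correlation
#'
#' Localisations are split into time bins; each bin is rendered as a 2D
#' histogram on a coarse grid and cross-correlated (with 10x-upsampled
#' sub-pixel refinement) against the first usable bin. The recovered (dx,
#' dy) per bin, relative to the first, forms the trajectory; bins with too
#' few localisations are skipped and interpolated over with a warning.
#'
#' @param table a [LocalizationTable-class] spanning at least 2 bins.
#' @param binFrames frames per bin (default 2000).
#' @param grid histogram pixel size in nm (default 20).
#' @param minPerBin minimum localisations per usable bin (default 50).
#' @param upsample sub-pixel refinement factor (default 10).
#' @return a [DriftTrajectory-class].
#' @export
estimateDrift <- function(table, binFrames = 2000L, grid = 20, minPerBin = 50L,
                          upsample = 10L) {
  rec <- records(table)
  if (!nrow(rec)) stop("contract error: empty localisation table")
  bin <- floor(rec$frame / binFrames)
  bins <- seq(min(bin), max(bin))
  if (length(bins) < 2L) {
    stop("contract error: table spans a single time bin; cannot estimate drift")
  }
  origin <- c(min(rec$x), min(rec$y))
  dims <- c(floor((max(rec$y) - origin[2]) / grid) + 1L,
            floor((max(rec$x) - origin[1]) / grid) + 1L)
  hists <- vector("list", length(bins))
  counts <- integer(length(bins))
  for (k in seq_along(bins)) {
    idx <- bin == bins[k]
    counts[k] <- sum(idx)
    if (counts[k] >= minPerBin) {
      hists[[k]] <- .bin_histogram(rec$x[idx], rec$y[idx], origin, dims, grid)
    }
  }
  usable <- which(counts >= minPerBin)
  if (length(usable) < 2L) {
    stop("contract error: fewer than 2 bins with enough localisations")
  }
  skipped <- setdiff(seq_along(bins), usable)
  if (length(skipped)) {
    warning(sprintf("estimateDrift: %d bin(s) with < %d localisations skipped and interpolated",
                    length(skipped), minPerBin))
  }
  ref <- hists[[usable[1]]]
  dx <- rep(NA_real_, length(bins))
  dy <- rep(NA_real_, length(bins))
  for (k in usable) {
    s <- .cross_corr_shift(ref, hists[[k]], upsample)
    dy[k] <- s[1] * grid
    dx[k] <- s[2] * grid
  }
  centres <- (bins + 0.5) * binFrames
  if (length(skipped)) {
    dx[skipped] <- stats::approx(centres[usable], dx[usable],
                                 xout = centres[skipped], rule = 2)$y
    dy[skipped] <- stats::approx(centres[usable], dy[usable],
                                 xout = centres[skipped], rule = 2)$y
  }
  dx <- dx - dx[1]                     # first bin is (0, 0) by convention
  dy <- dy - dy[1]
  new("DriftTrajectory", binStart = bins * binFrames, binCentre = centres,
      dx = dx, dy = dy)
}

#' Apply a drift correction to a localisation table
#'
#' Each record's drift is linearly interpolated at its frame between bin
#' centres and subtracted from x and y; beyond the first and last bin centre
#' the end segments are extrapolated linearly, so that a steady drift is
#' corrected without an endpoint residual. z is untouched (only lateral
#' drift is corrected).
#'
#' @param table a [LocalizationTable-class].
#' @param drift a [DriftTrajectory-class].
#' @return the corrected table.
#' @export
applyDrift <- function(table, drift) {
  stopifnot(is(drift, "DriftTrajectory"))
  rec <- records(table)
  if (!nrow(rec)) return(table)
  interp <- function(v) {
    cen <- drift@binCentre
    m <- length(cen)
    if (m == 1L) return(rep(v, nrow(rec)))
    out <- stats::approx(cen, v, xout = rec$frame, rule = 2)$y
    lo <- rec$frame < cen[1]
    hi <- rec$frame > cen[m]
    if (any(lo)) {
      s <- (v[2] - v[1]) / (cen[2] - cen[1])
      out[lo] <- v[1] + s * (rec$frame[lo] - cen[1])
    }
    if (any(hi)) {
      s <- (v[m] - v[m - 1]) / (cen[m] - cen[m - 1])
      out[hi] <- v[m] + s * (rec$frame[hi] - cen[m])
    }
    out
  }
  rec$x <- rec$x - interp(drift@dx)
  rec$y <- rec$y - interp(drift@dy)
  new("LocalizationTable", records = rec)
}

#' Render a super-resolved 2D histogram image
#'
#' Counts localisations into pixels of the requested size (default 10 nm).
#' Row index follows y, column index follows x; the image origin (the
#' physical position of the min corner) and pixel size are recorded as
#' attributes. Rendering conserves counts: `sum(image)` equals the number of
#' rendered localisations.
#'
#' @param table a non-empty [LocalizationTable-class].
#' @param pixel rendering pixel size in nm.
#' @param fluor optional fluorophore filter ("fluorA" or "fluorB").
#' @param origin optional c(x, y) origin in nm; defaults to the min corner
#'   snapped down to the pixel grid.
#' @return numeric count matrix with attributes `origin` and `pixelSize`.
#' @export
renderImage <- function(table, pixel = 10, fluor = NULL, origin = NULL) {
  rec <- records(table)
  if (!is.null(fluor)) rec <- rec[rec$fluor %in% fluor, , drop = FALSE]
  if (!nrow(rec)) stop("empty-image error: no localisations to render")
  if (is.null(origin)) origin <- floor(c(min(rec$x), min(rec$y)) / pixel) * pixel
  dims <- c(floor((max(rec$y) - origin[2]) / pixel) + 1L,
            floor((max(rec$x) - origin[1]) / pixel) + 1L)
  img <- .bin_histogram(rec$x, rec$y, origin, dims, pixel)
  attr(img, "origin") <- origin
  attr(img, "pixelSize") <- pixel
  img
}
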