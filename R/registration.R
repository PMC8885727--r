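#' @include AllClasses.R
NULL

#' Maximum z-projection of a movie
#'
#' Per-pixel maximum over frames; the standard live-side image used for
#' landmark selection against the rendered dSTORM image.
#'
#' @param movie a [FluorescenceMovie-class] with >= 1 frame.
#' @return 2D numeric matrix.
#' @export
maxProjection <- function(movie) {
  stopifnot(is(movie, "FluorescenceMovie"))
  apply(movie@data, c(1, 2), max)
}

#' Fit a 2D affine transform from landmark pairs
#'
#' Least-squares estimate of the map x -> A x + t from >= 3 non-collinear
#' landmark pairs, with the per-coordinate root-mean-square landmark
#' residual reported so users can judge the alignment.
#'
#' @param src n x 2 matrix of source coordinates (live side, pixel units).
#' @param dst n x 2 matrix of matched destination coordinates (nm).
#' @return an [AffineTransform2D-class].
#' @export
fitAffine <- function(src, dst) {
  src <- matrix(as.numeric(as.matrix(src)), ncol = 2)
  dst <- matrix(as.numeric(as.matrix(dst)), ncol = 2)
  if (nrow(src) != nrow(dst)) {
    stop("contract error: src and dst must have the same number of landmarks")
  }
  if (nrow(src) < 3) stop("contract error: at least 3 landmark pairs required")
  X <- cbind(src, 1)
  qx <- qr(X)
  if (qx$rank < 3) {
    stop("rank-deficiency error: landmarks are collinear or degenerate")
  }
  B <- qr.coef(qx, dst)                 # 3 x 2: rows = (a1, a2, t)
  A <- t(B[1:2, , drop = FALSE])
  tvec <- as.numeric(B[3, ])
  fitted <- X %*% B
  rmse <- sqrt(mean((dst - fitted)^2))   # per-coordinate RMS residual
  new("AffineTransform2D", A = A, t = tvec, rmse = rmse,
      nLandmarks = nrow(src))
}

#' Apply an affine transform to 2D coordinates
#'
#' @param transform an [AffineTransform2D-class].
#' @param xy n x 2 coordinate matrix.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transformPoints <- function(transform, xy) {
  stopifnot(is(transform, "AffineTransform2D"))
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  sweep(xy %*% t(transform@A), 2, transform@t, "+")
}

#' Match functional boutons to structural synapses across modalities
#'
#' Calcium-responder ROI centres are mapped into dSTORM space through the
#' fitted transform and matched one-to-one to colour-1 cluster centroids,
#' greedily by ascending distance, within `maxDist`. A responder whose
#' second-nearest remaining candidate lies within `ambiguity` x its best
#' distance is excluded and logged — the deterministic replacement for the
#' manual curation of well-aligned synapses.
#'
#' @param responses the data.frame from [analyseResponse()].
#' @param liveXY boutons x 2 matrix of ROI centres in live (x, y) pixel
#'   coordinates (x = column, y = row).
#' @param structures a [SynapseStructureSet-class], or any data.frame with
#'   columns cx, cy (+ structural metrics) — one row per synapse.
#' @param transform an [AffineTransform2D-class] mapping live px to nm.
#' @param maxDist matching cutoff in nm (default 500).
#' @param ambiguity relative second-candidate distance that voids a match
#'   (default 1.1, i.e. within 10%).
#' @return data.frame of correlated synapses: the functional response
#'   columns, the structural columns, `match_dist` (nm) and the matched
#'   `synapse` id. Only valid calcium responders are matched (the inclusion
#'   rule for all downstream statistics).
#' @export
matchSynapses <- function(responses, liveXY, structures, transform,
                          maxDist = 500, ambiguity = 1.1) {
  stopifnot(is(transform, "AffineTransform2D"))
  syn <- if (is(structures, "SynapseStructureSet")) structures@synapses else
    as.data.frame(structures)
  liveXY <- matrix(as.numeric(as.matrix(liveXY)), ncol = 2)
  include <- which(responses$valid & responses$calcium_responder)
  if (!length(include) || !nrow(syn)) {
    return(cbind(responses[0, ], syn[0, ], match_dist = numeric()))
  }
  mapped <- transformPoints(transform, liveXY[include, , drop = FALSE])
  cen <- as.matrix(syn[, c("cx", "cy"), drop = FALSE])
  D <- outer(mapped[, 1], cen[, 1], "-")^2 + outer(mapped[, 2], cen[, 2], "-")^2
  D <- sqrt(D)
  matched_r <- integer()
  matched_s <- integer()
  matched_d <- numeric()
  ambiguous <- integer()
  open_r <- seq_along(include)
  open_s <- seq_len(nrow(syn))
  while (length(open_r) && length(open_s)) {
    sub <- D[open_r, open_s, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    d1 <- sub[k[1], k[2]]
    if (d1 > maxDist) break
    ri <- open_r[k[1]]
    if (length(open_s) > 1) {
      d2 <- min(sub[k[1], -k[2]])
      if (d2 <= ambiguity * d1) {
        ambiguous <- c(ambiguous, include[ri])
        open_r <- setdiff(open_r, ri)
        next
      }
    }
    matched_r <- c(matched_r, ri)
    matched_s <- c(matched_s, open_s[k[2]])
    matched_d <- c(matched_d, d1)
    open_r <- setdiff(open_r, ri)
    open_s <- setdiff(open_s, open_s[k[2]])
  }
  if (length(ambiguous)) {
    message(sprintf("matchSynapses: %d responder(s) excluded as ambiguous: %s",
                    length(ambiguous), paste(ambiguous, collapse = ", ")))
  }
  out <- cbind(responses[include[matched_r], , drop = FALSE],
               syn[matched_s, , drop = FALSE],
               match_dist = matched_d)
  rownames(out) <- NULL
  out
}
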