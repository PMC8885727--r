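#' @include AllClasses.R
NULL

.as_points3 <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("contract error: points must be an n x 3 matrix (nm)")
  storage.mode(points) <- "double"
  points
}

#' Per-point 3D Voronoi density estimation
#'
#' Computes the 3D Voronoi tessellation of the point cloud. Each point gets
#' two densities: the raw inverse cell volume delta_i = 1 / V_i (nm^-3;
#' zero for unbounded cells, whose points lie on the dataset hull boundary)
#' and the first-rank density used for segmentation — the median inverse
#' cell volume over the cell and its Voronoi neighbours. The first-rank
#' median is the robust local estimate where single cells bulge into empty
#' space (a cluster's outward shell inherits its dense neighbourhood),
#' while a genuinely sparse neighbourhood stays sparse. Two reference
#' densities are reported: the global dataset density (points per extent)
#' and the mean of delta_i over finite interior cells (see
#' [VoronoiDensityMap-class]).
#'
#' @param points n x 3 matrix of coordinates in nm (n >= 5, not all
#'   coplanar).
#' @param pad bounding-box padding in nm used to cap the growth of
#'   unbounded boundary cells; defaults to 8 x the mean inter-point spacing.
#' @param extent the analysed volume that defines the global reference
#'   density: NULL (default) uses the dataset convex-hull volume, a scalar
#'   gives the volume in nm^3 directly, and a 2 x 3 matrix (min/max rows)
#'   gives the acquisition box. Supply the acquisition volume when the data
#'   occupy only part of the imaged field — the reference density of a
#'   dataset is defined over the field, not over the points' own footprint.
#' @return a [VoronoiDensityMap-class].
#' @export
voronoiDensity <- function(points, pad = NULL, extent = NULL) {
  points <- .as_points3(points)
  n <- nrow(points)
  if (n < 5L) stop("contract error: at least 5 points required")
  sv <- svd(sweep(points, 2, colMeans(points)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate-tessellation error: points are (nearly) coplanar")
  }
  bbox <- rbind(min = apply(points, 2, min), max = apply(points, 2, max))
  vol_box <- prod(pmax(bbox[2, ] - bbox[1, ], .Machine$double.eps))
  if (is.null(pad)) pad <- 8 * (vol_box / n)^(1 / 3)
  hull <- .convex_hull_3d_cpp(points)
  # a Voronoi cell is unbounded exactly when its point lies on the boundary
  # of the dataset convex hull — a rigid-motion-invariant classification
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  on_hull <- rep(FALSE, n)
  for (f in seq_len(nrow(hull$facets))) {
    d <- points %*% hull$facets[f, 1:3] - hull$facets[f, 4]
    on_hull <- on_hull | abs(d) <= 1e-9 * diag_len
  }
  res <- .voronoi_cell_volumes_cpp(points, pad, on_hull)
  bounded <- as.logical(res$bounded)
  interior <- as.logical(res$interior)
  cell_density <- ifelse(bounded, 1 / res$volume, 0)
  extent_vol <- if (is.null(extent)) {
    hull$volume                      # dataset extent: rigid-motion invariant
  } else if (length(extent) == 1L) {
    as.numeric(extent)
  } else {
    extent <- matrix(as.numeric(extent), 2, 3)
    prod(extent[2, ] - extent[1, ])
  }
  new("VoronoiDensityMap", density = res$rank_density,
      cellDensity = cell_density, finite = interior,
      meanDensity = mean(cell_density[interior]),
      globalDensity = n / extent_vol, bbox = bbox)
}

#' Segment density-thresholded clusters from a point cloud
#'
#' The segmentation used for both colours: points whose Voronoi density
#' reaches `densityFactor` x the dataset reference density are kept; kept
#' points within the colour's maximum neighbour distance (200 nm for colour
#' 1, 100 nm for colour 2) are linked, and connected components with at least
#' the colour's minimum number of molecules (200 for colour 1, 20 for colour
#' 2) become clusters. Cluster volume is the 3D convex hull of the member
#' points and density is detections / hull volume.
#'
#' @param points n x 3 coordinate matrix in nm.
#' @param densityMap the [VoronoiDensityMap-class] computed on the same
#'   points.
#' @param colour 1 or 2; selects linking distance and minimum molecules.
#' @param config a [PipelineConfig-class]; `densityReference` selects the
#'   reference density ("global" dataset density by default, or "mean" of
#'   finite per-point densities).
#' @return a [ClusterSet-class]; empty output is valid.
#' @export
segmentClusters <- function(points, densityMap, colour,
                            config = pipelineConfig()) {
  points <- .as_points3(points)
  stopifnot(is(densityMap, "VoronoiDensityMap"))
  colour <- as.integer(colour)
  if (length(densityMap@density) != nrow(points)) {
    stop("contract error: density map does not match the point set")
  }
  ref <- switch(config@densityReference,
                global = densityMap@globalDensity,
                mean = densityMap@meanDensity)
  keep <- which(densityMap@density >= config@densityFactor * ref)
  empty <- new("ClusterSet", colour = colour, members = list(),
               stats = data.frame(n = integer(), volume = numeric(),
                                  density = numeric(), cx = numeric(),
                                  cy = numeric(), cz = numeric(),
                                  degenerate = logical()))
  if (!length(keep)) return(empty)
  comp <- .link_components_cpp(points[keep, , drop = FALSE],
                               config@maxNeighbourDist[colour])
  sizes <- tabulate(comp)
  ids <- which(sizes >= config@minMolecules[colour])
  if (!length(ids)) return(empty)
  ids <- ids[order(sizes[ids], decreasing = TRUE)]
  members <- lapply(ids, function(id) keep[comp == id])
  stats <- do.call(rbind, lapply(members, function(m) {
    clusterMetrics(m, points)
  }))
  new("ClusterSet", colour = colour, members = members, stats = stats)
}

#' Compute cluster volume, density and centroid
#'
#' Volume is the 3D convex hull of the member points; density is
#' n_detections / volume. Clusters with fewer than 4 points or with all
#' points (nearly) coplanar are flagged degenerate with undefined volume and
#' density.
#'
#' @param members integer vector of point indices forming the cluster.
#' @param points the n x 3 coordinate matrix the indices refer to.
#' @return one-row data.frame: n, volume (nm^3), density (nm^-3), cx, cy, cz
#'   (nm), degenerate.
#' @export
clusterMetrics <- function(members, points) {
  points <- .as_points3(points)
  members <- as.integer(members)
  if (any(members < 1L | members > nrow(points))) {
    stop("contract error: membership index out of range")
  }
  pts <- points[members, , drop = FALSE]
  cen <- colMeans(pts)
  hull <- .convex_hull_3d_cpp(pts)
  if (isTRUE(hull$degenerate)) {
    return(data.frame(n = length(members), volume = NA_real_,
                      density = NA_real_, cx = cen[1], cy = cen[2],
                      cz = cen[3], degenerate = TRUE))
  }
  data.frame(n = length(members), volume = hull$volume,
             density = length(members) / hull$volume,
             cx = cen[1], cy = cen[2], cz = cen[3], degenerate = FALSE)
}

# points-in-hull test against the facet planes of a colour-1 cluster
.any_point_in_hull <- function(facets, pts, tol = 1e-7) {
  if (!nrow(facets)) return(rep(FALSE, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  for (f in seq_len(nrow(facets))) {
    d <- pts %*% facets[f, 1:3] - facets[f, 4]
    inside <- inside & (d <= tol * max(abs(facets[f, 4]), 1))
    if (!any(inside)) break
  }
  inside
}

#' Associate colour-2 subsynaptic domains with colour-1 synapses
#'
#' An SSD overlaps a synapse when any of its member points lies inside the
#' colour-1 convex hull (provenance "overlap"). SSDs overlapping no synapse
#' are assigned to the nearest colour-1 centroid within `orphanDist`
#' (provenance "orphan-assigned") — the automated, deterministic stand-in
#' for the manual correction of missed colocalisations, needed because
#' active-zone SSDs often sit at the edge of (or just outside) the
#' vesicle-cloud cluster. SSDs beyond `orphanDist` of every synapse stay
#' unassigned and are reported. Synapses with zero SSDs are retained with
#' `n_ssd = 0`; downstream analyses may exclude them.
#'
#' @param clusters1 colour-1 [ClusterSet-class] (one cluster per synapse).
#' @param clusters2 colour-2 [ClusterSet-class] (candidate SSDs).
#' @param points1,points2 the coordinate matrices the cluster member indices
#'   refer to.
#' @param orphanDist orphan assignment cutoff in nm (default 500).
#' @return a [SynapseStructureSet-class].
#' @export
colocalise <- function(clusters1, clusters2, points1, points2,
                       orphanDist = 500) {
  stopifnot(is(clusters1, "ClusterSet"), is(clusters2, "ClusterSet"))
  points1 <- .as_points3(points1)
  points2 <- .as_points3(points2)
  n1 <- length(clusters1@members)
  n2 <- length(clusters2@members)
  hulls <- lapply(seq_len(n1), function(i) {
    if (clusters1@stats$degenerate[i]) return(NULL)
    .convex_hull_3d_cpp(points1[clusters1@members[[i]], , drop = FALSE])$facets
  })
  cen1 <- as.matrix(clusters1@stats[, c("cx", "cy", "cz"), drop = FALSE])
  assoc_syn <- integer()
  assoc_ssd <- integer()
  assoc_prov <- character()
  unassigned <- integer()
  for (j in seq_len(n2)) {
    pts <- points2[clusters2@members[[j]], , drop = FALSE]
    hits <- integer()
    hit_counts <- integer()
    for (i in seq_len(n1)) {
      if (is.null(hulls[[i]])) next
      k <- sum(.any_point_in_hull(hulls[[i]], pts))
      if (k > 0) {
        hits <- c(hits, i)
        hit_counts <- c(hit_counts, k)
      }
    }
    cen_j <- colMeans(pts)
    if (length(hits)) {
      # rare multi-overlap: keep the synapse containing the most SSD points,
      # nearest centroid as tie-break
      best <- hits[order(-hit_counts,
                         sqrt(colSums((t(cen1[hits, , drop = FALSE]) - cen_j)^2)))][1]
      assoc_syn <- c(assoc_syn, best)
      assoc_ssd <- c(assoc_ssd, j)
      assoc_prov <- c(assoc_prov, "overlap")
    } else if (n1 > 0) {
      d <- sqrt(colSums((t(cen1) - cen_j)^2))
      if (min(d) <= orphanDist) {
        assoc_syn <- c(assoc_syn, which.min(d))
        assoc_ssd <- c(assoc_ssd, j)
        assoc_prov <- c(assoc_prov, "orphan-assigned")
      } else {
        unassigned <- c(unassigned, j)
      }
    } else {
      unassigned <- c(unassigned, j)
    }
  }
  associations <- data.frame(synapse = assoc_syn, ssd = assoc_ssd,
                             provenance = assoc_prov)
  syn <- data.frame(
    synapse = seq_len(n1),
    n_ssd = as.integer(tabulate(assoc_syn, n1)),
    c1_n = clusters1@stats$n,
    c1_volume = clusters1@stats$volume,
    c1_density = clusters1@stats$density,
    cx = clusters1@stats$cx, cy = clusters1@stats$cy, cz = clusters1@stats$cz,
    ssd_total_detections = vapply(seq_len(n1), function(i) {
      as.numeric(sum(clusters2@stats$n[assoc_ssd[assoc_syn == i]]))
    }, 0),
    ssd_mean_density = vapply(seq_len(n1), function(i) {
      v <- clusters2@stats$density[assoc_ssd[assoc_syn == i]]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, 0))
  new("SynapseStructureSet", synapses = syn, associations = associations,
      unassigned = unassigned, clusters1 = clusters1, clusters2 = clusters2)
}
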