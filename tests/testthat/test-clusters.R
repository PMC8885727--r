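test_that("Voronoi density is exact on a forced interior grid cell", {
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 100
  vd <- voronoiDensity(g)
  centre <- which(rowSums(g == 200) == 3)
  expect_equal(vd@density[centre], 1e-6, tolerance = 1e-12)
  expect_equal(sum(vd@finite), 27L)          # the 3 x 3 x 3 interior
  # hull-boundary cells are salvaged from their interior neighbours: on the
  # grid the face-centre neighbours are exact 100 nm cubes
  face_centre <- which(g[, 1] == 0 & g[, 2] == 200 & g[, 3] == 200)
  expect_equal(vd@density[face_centre], 1e-6, tolerance = 1e-12)
  expect_equal(vd@meanDensity, mean(vd@cellDensity[vd@finite]))
  # raw inverse cell volume agrees on the forced interior cell
  expect_equal(vd@cellDensity[centre], 1e-6, tolerance = 1e-12)
})

test_that("Voronoi densities scale as s^-3 under uniform scaling", {
  set.seed(12)
  pts <- matrix(runif(900, 0, 1000), 300, 3)
  a <- voronoiDensity(pts)
  b <- voronoiDensity(pts * 2.5)
  expect_identical(a@finite, b@finite)
  expect_equal(b@density, a@density / 2.5^3, tolerance = 1e-9)
  expect_equal(b@cellDensity, a@cellDensity / 2.5^3, tolerance = 1e-9)
})

test_that("mean finite-cell volume matches the expected density", {
  set.seed(7)
  pts <- matrix(runif(6000, 0, 2000), 2000, 3)
  vd <- voronoiDensity(pts)
  expect_lt(abs(mean(1 / vd@cellDensity[vd@finite]) / (2000^3 / 2000) - 1), 0.1)
})

test_that("degenerate point sets are rejected", {
  flat <- cbind(runif(50), runif(50), 0)
  expect_error(voronoiDensity(flat), "coplanar")
  expect_error(voronoiDensity(matrix(runif(12), 4, 3)), "at least 5")
})

test_that("two well-separated clusters are segmented completely", {
  set.seed(22)
  p <- rbind(gauss_cluster(300, c(0, 0, 0), 30),
             gauss_cluster(300, c(2000, 0, 0), 30))
  # the clusters sit in a standard acquisition field (512 x 512 px of
  # 97 nm, 1 um axial range), which defines the dataset average density
  field <- (512 * 97)^2 * 1000
  cl <- segmentClusters(p, voronoiDensity(p, extent = field), colour = 2,
                        test_cfg())
  expect_equal(length(cl@members), 2L)
  truth <- rep(1:2, each = 300)
  for (k in 1:2) {
    gen <- which(truth == k)
    captured <- max(vapply(cl@members, function(m) mean(gen %in% m), 0))
    expect_gte(captured, 0.95)
  }
})

test_that("clusters below the minimum molecule count are discarded", {
  set.seed(23)
  p <- gauss_cluster(150, c(0, 0, 0), 30)
  cl <- segmentClusters(p, voronoiDensity(p), colour = 1, test_cfg())
  expect_equal(length(cl@members), 0L)        # colour-1 minimum is 200
  cl2 <- segmentClusters(p, voronoiDensity(p), colour = 2, test_cfg())
  expect_equal(length(cl2@members), 1L)       # colour-2 minimum is 20

  empty <- segmentClusters(matrix(numeric(), 0, 3),
                           new("VoronoiDensityMap", density = numeric(),
                               finite = logical(), meanDensity = NA_real_,
                               globalDensity = NA_real_,
                               bbox = matrix(0, 2, 3)),
                           colour = 1, test_cfg())
  expect_equal(length(empty@members), 0L)
})

test_that("raising thresholds never increases the cluster count", {
  set.seed(24)
  p <- rbind(gauss_cluster(120, c(0, 0, 0), 40),
             gauss_cluster(60, c(1500, 0, 0), 40),
             gauss_cluster(25, c(0, 1500, 0), 40),
             matrix(runif(300, -500, 2000), 100, 3))
  vd <- voronoiDensity(p)
  counts_f <- vapply(c(0.5, 1, 2, 4, 8), function(f) {
    length(segmentClusters(p, vd, 2, test_cfg(densityFactor = f))@members)
  }, 0L)
  expect_true(all(diff(counts_f) <= 0))
  counts_m <- vapply(c(10L, 20L, 40L, 80L), function(m) {
    length(segmentClusters(p, vd, 2,
                           test_cfg(minMolecules = c(200L, m)))@members)
  }, 0L)
  expect_true(all(diff(counts_m) <= 0))
})

test_that("cluster metrics are exact on known geometry", {
  cube <- as.matrix(expand.grid(c(0, 100), c(0, 100), c(0, 100)))
  inner <- matrix(runif(30, 10, 90), 10, 3)
  pts <- rbind(cube, inner)
  m <- clusterMetrics(seq_len(nrow(pts)), pts)
  expect_equal(m$volume, 1e6, tolerance = 1e-9)
  expect_equal(m$density, nrow(pts) / 1e6, tolerance = 1e-9)
  expect_false(m$degenerate)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_true(clusterMetrics(1:10, line)$degenerate)

  m2 <- clusterMetrics(seq_len(nrow(pts)), pts * 2)
  expect_equal(m2$volume, 8e6, tolerance = 1e-9)
  expect_equal(m2$density, m$density / 8, tolerance = 1e-9)

  expect_error(clusterMetrics(c(1, 99), cube), "out of range")
})

test_that("segmentation metrics are invariant under rigid motions", {
  set.seed(25)
  p <- rbind(gauss_cluster(200, c(0, 0, 500), 35),
             gauss_cluster(80, c(1800, 200, 500), 35))
  theta <- 0.7
  Rz <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  q <- p %*% t(Rz) + matrix(c(300, -150, 40), nrow(p), 3, byrow = TRUE)
  cfg <- test_cfg()
  va <- voronoiDensity(p)
  vb <- voronoiDensity(q)
  # the continuous quantities are rigid-motion invariant to fp precision
  # (interior cells only: cells reaching the axis-aligned padded cube are
  # truncated orientation-dependently, and those cells are never interior)
  # (the interior mask itself follows the axis-aligned bounding box and so
  # legitimately depends on orientation)
  fin <- va@finite & vb@finite
  expect_equal(vb@cellDensity[fin], va@cellDensity[fin], tolerance = 1e-9)
  expect_equal(vb@globalDensity, va@globalDensity, tolerance = 1e-9)
  a <- segmentClusters(p, va, 2, cfg)
  b <- segmentClusters(q, vb, 2, cfg)
  # thresholded memberships may flip for points at the decision boundary
  # (near-degenerate Voronoi adjacencies), so cluster counts must agree
  # exactly but sizes and hull metrics only up to a marginal-point allowance
  expect_equal(length(a@members), length(b@members))
  oa <- order(-a@stats$n)
  ob <- order(-b@stats$n)
  expect_lte(max(abs(a@stats$n[oa] - b@stats$n[ob])), 2)
  expect_equal(a@stats$volume[oa], b@stats$volume[ob], tolerance = 0.05)
  expect_equal(a@stats$density[oa], b@stats$density[ob], tolerance = 0.05)
})

test_that("cluster membership partitions the kept points", {
  set.seed(26)
  sc <- simulateSynapseScene(nSynapses = 2, seed = 26)
  cl <- segmentClusters(sc$points2, voronoiDensity(sc$points2), 2, test_cfg())
  all_members <- unlist(cl@members)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_lte(length(all_members), nrow(sc$points2))
})

test_that("colocalisation records overlap, orphan and unassigned provenance", {
  set.seed(27)
  p1 <- gauss_cluster(400, c(0, 0, 0), 80)
  # SSD inside the colour-1 hull; one well beyond it but within the orphan
  # distance; one far away
  p2 <- rbind(gauss_cluster(40, c(0, 0, 0), 20),
              gauss_cluster(40, c(420, 0, 0), 15),
              gauss_cluster(40, c(2000, 0, 0), 20))
  cfg <- test_cfg()
  cl1 <- new("ClusterSet", colour = 1L, members = list(seq_len(400)),
             stats = clusterMetrics(seq_len(400), p1))
  cl2 <- new("ClusterSet", colour = 2L,
             members = list(1:40, 41:80, 81:120),
             stats = do.call(rbind, lapply(list(1:40, 41:80, 81:120),
                                           clusterMetrics, points = p2)))
  st <- colocalise(cl1, cl2, p1, p2, orphanDist = 500)
  prov <- st@associations$provenance[order(st@associations$ssd)]
  expect_equal(st@associations$ssd[order(st@associations$ssd)], c(1L, 2L))
  expect_equal(prov[1], "overlap")
  expect_equal(prov[2], "orphan-assigned")
  expect_equal(st@unassigned, 3L)
  expect_equal(st@synapses$n_ssd, 2L)
  expect_equal(st@synapses$ssd_total_detections, 80)
})

test_that("synapses without SSDs are retained with n_ssd = 0", {
  set.seed(28)
  p1 <- gauss_cluster(300, c(0, 0, 0), 100)
  p2 <- gauss_cluster(30, c(5000, 0, 0), 20)
  cl1 <- new("ClusterSet", colour = 1L, members = list(seq_len(300)),
             stats = clusterMetrics(seq_len(300), p1))
  cl2 <- new("ClusterSet", colour = 2L, members = list(1:30),
             stats = clusterMetrics(1:30, p2))
  st <- colocalise(cl1, cl2, p1, p2, orphanDist = 500)
  expect_equal(st@synapses$n_ssd, 0L)
  expect_true(is.na(st@synapses$ssd_mean_density))
  expect_equal(st@unassigned, 1L)
})
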