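test_that("photon ratio follows its definition with rejection at zero total", {
  tbl <- localizationTable(x = 1:3, y = 1:3, I_cam1 = c(300, 0, 0),
                           I_cam2 = c(100, 50, 0))
  out <- records(computePhotonRatio(tbl))
  expect_equal(out$ratio[1:2], c(0.75, 0))
  expect_true(is.na(out$ratio[3]))
  expect_equal(as.character(out$fluor[3]), "rejected")

  missing <- localizationTable(x = 1, y = 1)
  expect_error(computePhotonRatio(missing), "intensities missing")
})

test_that("two-camera pairing keeps mutual nearest neighbours on a frame", {
  t1 <- localizationTable(x = c(0, 1000), y = c(0, 0), frame = c(0, 0),
                          I_cam1 = c(10, 20))
  t2 <- localizationTable(x = c(5, 1010), y = c(0, 0), frame = c(0, 0),
                          I_cam1 = c(3, 7))
  suppressMessages(p <- pairDetections(t1, t2, tol = 100))
  expect_equal(nLocs(p), 2L)
  expect_equal(records(p)$I_cam2, c(3, 7))

  suppressMessages(none <- pairDetections(t1, localizationTable(), tol = 100))
  expect_equal(nLocs(none), 0L)

  # two cam1 records near one cam2 record: mutual NN keeps exactly one pair
  t1b <- localizationTable(x = c(0, 30), y = c(0, 0), frame = c(0, 0),
                           I_cam1 = c(1, 2))
  t2b <- localizationTable(x = 10, y = 0, frame = 0, I_cam1 = 9)
  suppressMessages(pb <- pairDetections(t1b, t2b, tol = 100))
  expect_equal(nLocs(pb), 1L)
  expect_equal(records(pb)$x, 0)        # the closer one

  # frame matching separates detections on different frames
  t2c <- localizationTable(x = 0, y = 0, frame = 1, I_cam1 = 9)
  suppressMessages(pc <- pairDetections(t1b, t2c, tol = 100))
  expect_equal(nLocs(pc), 0L)

  expect_error(pairDetections(t1, t2, tol = 0), "tol")
})

test_that("demixing recovers symmetric mixture means and flags degeneracy", {
  sim <- simulateTwoCameraEmitters(c(4000, 4000), ratioMeans = c(0.7, 0.3),
                                   seed = 5)
  model <- fitDemixModel(photonRatio(computePhotonRatio(sim$table)))
  expect_lt(abs(model@muA - 0.7), 0.01)
  expect_lt(abs(model@muB - 0.3), 0.01)

  set.seed(9)
  expect_error(fitDemixModel(rnorm(500, 0.5, 0.05)), "demixing failure")
  expect_error(fitDemixModel(runif(50)), "100")
})

test_that("classification depends only on the photon ratio (scale invariant)", {
  sim <- simulateTwoCameraEmitters(c(800, 800), seed = 8)
  tbl <- computePhotonRatio(sim$table)
  model <- fitDemixModel(photonRatio(tbl))
  lab1 <- fluorLabel(classifyFluorophores(tbl, model))
  rec <- records(sim$table)
  scaled <- computePhotonRatio(localizationTable(
    x = rec$x, y = rec$y, z = rec$z, frame = rec$frame,
    I_cam1 = rec$I_cam1 * 50, I_cam2 = rec$I_cam2 * 50))
  expect_identical(fluorLabel(classifyFluorophores(scaled, model)), lab1)
})

test_that("demixing separation improves monotonically with component distance", {
  err <- vapply(c(0.2, 0.3, 0.45), function(sep) {
    sim <- simulateTwoCameraEmitters(c(2000, 2000),
                                     ratioMeans = c(0.5 + sep / 2, 0.5 - sep / 2),
                                     seed = 17)
    tbl <- computePhotonRatio(sim$table)
    model <- fitDemixModel(photonRatio(tbl))
    lab <- fluorLabel(classifyFluorophores(tbl, model))
    keep <- lab %in% c("fluorA", "fluorB")
    mean(as.character(lab[keep]) != as.character(sim$labels[keep]))
  }, 0)
  expect_true(all(diff(err) <= 0))
  expect_lt(err[3], 1e-3)
})

test_that("drift estimation is null on drift-free data and needs two bins", {
  set.seed(31)
  ctr <- cbind(runif(15, 500, 3000), runif(15, 500, 3000))
  ci <- sample(15, 4000, replace = TRUE)
  tbl <- localizationTable(x = rnorm(4000, ctr[ci, 1], 50),
                           y = rnorm(4000, ctr[ci, 2], 50),
                           frame = sample(0:3999, 4000, replace = TRUE))
  dr <- estimateDrift(tbl, binFrames = 2000, grid = 20)
  expect_lte(max(abs(c(dr@dx, dr@dy))), 2)          # grid / 10

  one_bin <- localizationTable(x = rnorm(200), y = rnorm(200),
                               frame = rep(10, 200))
  expect_error(estimateDrift(one_bin, binFrames = 2000), "single time bin")
})

test_that("sparse bins are skipped with a warning and interpolated over", {
  set.seed(32)
  fr <- c(sample(0:1999, 2000, TRUE), sample(2000:3999, 10, TRUE),
          sample(4000:5999, 2000, TRUE))
  n <- length(fr)
  ctr <- cbind(runif(10, 500, 2500), runif(10, 500, 2500))
  ci <- sample(10, n, replace = TRUE)
  tbl <- localizationTable(x = rnorm(n, ctr[ci, 1], 40),
                           y = rnorm(n, ctr[ci, 2], 40), frame = fr)
  expect_warning(dr <- estimateDrift(tbl, binFrames = 2000, grid = 20),
                 "skipped")
  expect_length(dr@dx, 3L)
  expect_false(anyNA(dr@dx))
})

test_that("rendering bins counts at the requested pixel size", {
  tbl <- localizationTable(x = 105, y = 55)
  img <- renderImage(tbl, pixel = 10, origin = c(0, 0))
  expect_equal(dim(img), c(6L, 11L))
  expect_equal(sum(img), 1)
  expect_equal(img[6, 11], 1)                 # 0-based (row 5, col 10)

  set.seed(3)
  many <- localizationTable(x = runif(500, 0, 2000), y = runif(500, 0, 1000))
  img10 <- renderImage(many, pixel = 10)
  expect_equal(sum(img10), 500)               # rendering conserves counts
  img20 <- renderImage(many, pixel = 20)
  expect_equal(sum(img20), 500)
  expect_lte(abs(prod(dim(img10)) / prod(dim(img20)) - 4), 0.2)

  lab <- localizationTable(x = 1:4, y = 1:4, I_cam1 = rep(80, 4),
                           I_cam2 = rep(20, 4), fluor = rep("fluorA", 4))
  expect_equal(sum(renderImage(lab, 10, fluor = "fluorA")), 4)
  expect_error(renderImage(lab, 10, fluor = "fluorB"), "empty-image")
})

test_that("drift correction is idempotent", {
  set.seed(33)
  ctr <- cbind(runif(15, 500, 3000), runif(15, 500, 3000))
  n <- 6000
  ci <- sample(15, n, replace = TRUE)
  fr <- sample(0:5999, n, replace = TRUE)
  tbl <- localizationTable(x = rnorm(n, ctr[ci, 1], 50) + 80 * fr / 6000,
                           y = rnorm(n, ctr[ci, 2], 50), frame = fr)
  corrected <- applyDrift(tbl, estimateDrift(tbl, binFrames = 2000, grid = 20))
  re <- estimateDrift(corrected, binFrames = 2000, grid = 20)
  expect_lte(max(abs(c(re@dx, re@dy))), 2)          # grid / 10
})
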