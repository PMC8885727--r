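test_that("functional movie generator is deterministic and count-conserving", {
  cfg <- test_cfg()
  amps <- cbind(runif(20, 5, 30), runif(20, 20, 60))
  a <- simulateFunctionalMovie(cfg, 20, amps, noiseSd = 1.5, seed = 4)
  b <- simulateFunctionalMovie(cfg, 20, amps, noiseSd = 1.5, seed = 4)
  expect_identical(movieData(a$g), movieData(b$g))
  expect_identical(movieData(a$r), movieData(b$r))
  expect_equal(nrow(a$truth$centresPx), 20L)
  expect_equal(dim(a$truth$amplitudes), c(20L, 2L))

  expect_error(
    simulateFunctionalMovie(cfg, 2, cbind(c(1, 1), c(1, 1)),
                            centres = rbind(c(40, 40), c(44, 44))),
    "placement error")
})

test_that("noiseless single-bouton movie yields the programmed dR/R downstream", {
  cfg <- test_cfg()
  sim <- simulateFunctionalMovie(cfg, 1, cbind(0, 50), noiseSd = 0, seed = 1,
                                 baseline = c(G = 10, R = 100))
  tr <- extractTraces(sim$g, sim$r, sim$truth$centresPx, config = cfg)
  resp <- analyseResponse(tr, cfg)
  expect_equal(resp$dR_over_R, 0.5, tolerance = 1e-9)
})

test_that("two-camera emitter generator matches its programmed ratio model", {
  sim <- simulateTwoCameraEmitters(c(1000, 1000), seed = 2)
  tbl <- computePhotonRatio(sim$table)
  rho <- photonRatio(tbl)
  expect_true(all(rho >= 0 & rho <= 1))
  mA <- mean(rho[sim$labels == "fluorA"])
  expect_lt(abs(mA - 0.75), 3 * 0.05 / sqrt(1000))   # CLT bound
  mB <- mean(rho[sim$labels == "fluorB"])
  expect_lt(abs(mB - 0.30), 3 * 0.05 / sqrt(1000))

  empty <- simulateTwoCameraEmitters(c(0, 0), seed = 1)
  expect_equal(nLocs(empty$table), 0L)
  expect_error(simulateTwoCameraEmitters(ratioSd = 0), "ratioSd")
  expect_identical(records(simulateTwoCameraEmitters(seed = 9)$table),
                   records(simulateTwoCameraEmitters(seed = 9)$table))
})

test_that("synapse scenes carry exact ground-truth label partitions", {
  sc <- simulateSynapseScene(nSynapses = 2, ssdCountRange = c(2L, 2L),
                             backgroundDensity = 0, seed = 5)
  expect_true(all(sc$truth$labels2_ssd > 0))       # no background: all labelled
  expect_equal(sc$truth$ssdCounts, c(2L, 2L))
  expect_equal(length(sc$truth$labels1), nrow(sc$points1))
  expect_equal(length(sc$truth$labels2_synapse), nrow(sc$points2))
  # labelled point counts match the recorded per-SSD counts
  expect_equal(as.integer(table(sc$truth$labels2_synapse)),
               vapply(sc$truth$ssdPointCounts, sum, 0L))

  sc3 <- simulateSynapseScene(nSynapses = 4, ssdCountRange = c(3L, 3L), seed = 6)
  expect_true(all(sc3$truth$ssdCounts == 3L))

  expect_identical(simulateSynapseScene(nSynapses = 3, seed = 11)$points1,
                   simulateSynapseScene(nSynapses = 3, seed = 11)$points1)

  expect_error(simulateSynapseScene(nSynapses = 2,
                                    centres = rbind(c(0, 0, 500), c(500, 0, 500))),
               "placement error")
  expect_error(simulateSynapseScene(nSynapses = 1,
                                    centres = rbind(c(5000, 5000, 500)),
                                    box = rbind(c(0, 0, 0), c(1000, 1000, 1000))),
               "box too small")
})

test_that("correlative datasets honour the programmed coupling and landmarks", {
  cfg <- test_cfg()
  ds <- simulateCorrelativeDataset(cfg, nSynapses = 6, coupling = "positive",
                                   sigmaLog = 0, noiseSd = 0, seed = 3)
  ord <- order(ds$truth$ssdTotal)
  expect_true(all(diff(ds$truth$amplitudes[ord, 1]) > 0))  # dG increasing in SSD count

  pushed <- sweep(ds$landmarks$src %*% t(ds$truth$A), 2, ds$truth$t, "+")
  expect_equal(pushed, unname(ds$landmarks$dst), tolerance = 1e-12)
  expect_gt(abs(det(ds$truth$A)), 0)

  expect_warning(simulateCorrelativeDataset(cfg, nSynapses = 2,
                                            coupling = "positive", seed = 1),
                 "underpowered")
})
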