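test_that("trailing moving average matches its definition", {
  expect_equal(smoothTrace(rep(3.5, 20), 4), rep(3.5, 20))
  x <- rnorm(15)
  expect_equal(smoothTrace(x, 1), x)
  expect_equal(smoothTrace(c(0, 0, 0, 0, 4, 4, 4, 4), 4),
               c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_error(smoothTrace(1:3, 4), "window")
})

test_that("ROI extraction subtracts the background ROI mean per frame", {
  cfg <- test_cfg()
  arr <- array(7, dim = c(40, 40, 60))
  arr[1:15, 26:40, ] <- 2                       # darker background region
  mk <- function(a, ch) new("FluorescenceMovie", data = a, channel = ch,
                            pixelSize = 433, frameRate = 12.5, stimFrame = 40L)
  tr <- extractTraces(mk(arr, "G"), mk(arr, "R"), cbind(20, 20),
                      bgCentre = c(8, 33), config = cfg)
  expect_equal(tr@g[, 1], rep(5, 60))           # 7 - 2
  expect_equal(tr@r[, 1], rep(5, 60))

  expect_error(extractTraces(mk(arr, "G"), mk(arr, "R"), cbind(1, 1),
                             bgCentre = c(8, 33), config = cfg),
               "bouton 1")
})

test_that("noiseless responses are recovered exactly with correct ratios", {
  cfg <- test_cfg()
  amps <- cbind(c(25, 10, 0), c(50, 30, 40))
  sim <- simulateFunctionalMovie(cfg, 3, amps, noiseSd = 0, seed = 2,
                                 baseline = c(G = 10, R = 100))
  tr <- extractTraces(sim$g, sim$r, sim$truth$centresPx, config = cfg)
  # pre-stimulus trace is flat
  expect_lt(diff(range(tr@r[1:39, 1])), 1e-9)
  resp <- analyseResponse(tr, cfg)
  expect_equal(resp$dG, amps[, 1], tolerance = 1e-9)
  expect_equal(resp$dR, amps[, 2], tolerance = 1e-9)
  expect_equal(resp$dR_over_R, amps[, 2] / 100, tolerance = 1e-9)
  expect_equal(resp$dG_over_R, amps[, 1] / 100, tolerance = 1e-9)
  expect_equal(resp$dG_over_dR[1:2], (amps[, 1] / amps[, 2])[1:2],
               tolerance = 1e-9)
  expect_true(all(resp$calcium_responder))
  # zero dG: no release detected, and the release/calcium flags are independent
  expect_false(resp$release_detected[3])
  expect_true(resp$calcium_responder[3])
})

test_that("perfectly flat traces never classify as responding", {
  cfg <- test_cfg()
  flat <- new("TraceSet", g = matrix(5, 60, 1), r = matrix(80, 60, 1),
              bgG = numeric(60), bgR = numeric(60), centres = cbind(1, 1),
              bgCentre = c(1, 1), stimFrame = 40L, frameRate = 12.5)
  resp <- analyseResponse(flat, cfg)
  expect_equal(resp$dR, 0)
  expect_equal(resp$baseline_sd_R, 0)
  expect_false(resp$calcium_responder)
  expect_false(resp$release_detected)
})

test_that("boutons with non-positive baseline R0 are flagged invalid", {
  cfg <- test_cfg()
  ts <- new("TraceSet", g = matrix(5, 60, 1), r = matrix(-2, 60, 1),
            bgG = numeric(60), bgR = numeric(60), centres = cbind(1, 1),
            bgCentre = c(1, 1), stimFrame = 40L, frameRate = 12.5)
  expect_message(resp <- analyseResponse(ts, cfg), "excluded")
  expect_false(resp$valid)
  expect_match(resp$reason, "R0")
  expect_true(is.na(resp$dR_over_R))
})

test_that("normalised responses are scale-equivariant and offset-invariant", {
  cfg <- test_cfg()
  amps <- cbind(c(20, 8), c(45, 25))
  sim <- simulateFunctionalMovie(cfg, 2, amps, noiseSd = 0.5, seed = 13)
  scale_movie <- function(m, c, off = 0) {
    new("FluorescenceMovie", data = m@data * c + off, channel = m@channel,
        pixelSize = m@pixelSize, frameRate = m@frameRate,
        stimFrame = m@stimFrame)
  }
  base <- analyseResponse(
    extractTraces(sim$g, sim$r, sim$truth$centresPx, config = cfg), cfg)
  scaled <- analyseResponse(
    extractTraces(scale_movie(sim$g, 3), scale_movie(sim$r, 3),
                  sim$truth$centresPx, config = cfg), cfg)
  for (col in c("dG_over_R", "dR_over_R", "dG_over_dR")) {
    expect_equal(scaled[[col]], base[[col]], tolerance = 1e-12, info = col)
  }
  # adding a global constant to one channel leaves that channel's delta alone
  shifted <- analyseResponse(
    extractTraces(scale_movie(sim$g, 1, off = 37), sim$r,
                  sim$truth$centresPx, config = cfg), cfg)
  expect_equal(shifted$dG, base$dG, tolerance = 1e-9)
})

test_that("smoothing never lifts a non-negative step trace above its plateau", {
  set.seed(41)
  for (i in 1:20) {
    plateau <- runif(1, 1, 10)
    tr <- c(rep(0, sample(5:20, 1)), rep(plateau, sample(5:20, 1)))
    expect_lte(max(smoothTrace(tr, sample(1:4, 1))), plateau)
  }
})
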