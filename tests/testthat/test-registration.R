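test_that("maximum projection behaves as a per-pixel maximum", {
  arr <- array(rnorm(16 * 16 * 5), dim = c(16, 16, 5))
  m <- new("FluorescenceMovie", data = arr, channel = "G", pixelSize = 433,
           frameRate = 12.5, stimFrame = 2L)
  mp <- maxProjection(m)
  expect_true(all(mp >= apply(arr, c(1, 2), mean)))
  const <- new("FluorescenceMovie", data = array(4, c(3, 3, 6)),
               channel = "G", pixelSize = 433, frameRate = 12.5,
               stimFrame = 2L)
  expect_equal(maxProjection(const), matrix(4, 3, 3))
  single <- new("FluorescenceMovie", data = array(arr[, , 1], c(16, 16, 1)),
                channel = "G", pixelSize = 433, frameRate = 12.5,
                stimFrame = 1L)
  expect_equal(maxProjection(single), arr[, , 1])
})

test_that("affine fits are exact on noiseless landmarks", {
  src <- cbind(c(0, 10, 3, 7), c(0, 2, 9, 5))
  id <- fitAffine(src, src)
  expect_equal(id@A, diag(2), tolerance = 1e-12)
  expect_equal(id@t, c(0, 0), tolerance = 1e-12)
  expect_equal(id@rmse, 0, tolerance = 1e-12)

  theta <- 0.1
  A <- 43.3 * rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  tv <- c(1234, -567)
  dst <- sweep(src %*% t(A), 2, tv, "+")
  fit <- fitAffine(src, dst)
  expect_lt(max(abs(fit@A - A)) / max(abs(A)), 1e-9)
  expect_lt(max(abs(fit@t - tv)) / max(abs(tv)), 1e-9)
  expect_lt(fit@rmse, 1e-9)
  # fit-then-apply is the identity on the landmarks
  expect_equal(transformPoints(fit, src), dst, tolerance = 1e-9)

  expect_error(fitAffine(cbind(1:5, 2 * (1:5)), cbind(1:5, 1:5)),
               "rank-deficiency")
  expect_error(fitAffine(src, dst[1:3, ]), "same number")
  expect_error(fitAffine(src[1:2, ], dst[1:2, ]), "at least 3")
})

test_that("landmark RMSE reflects the injected landmark noise", {
  sigma <- 50
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    src <- cbind(runif(10, 0, 100), runif(10, 0, 100))
    A <- 43.3 * diag(2)
    dst <- src %*% t(A) + matrix(rnorm(20, 0, sigma), 10, 2)
    fit <- fitAffine(src, dst)
    fit@rmse >= 0.3 * sigma && fit@rmse <= 1.5 * sigma
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("synapse matching is one-to-one with an ambiguity guard", {
  resp <- data.frame(bouton = 1:3, dG_over_R = c(0.1, 0.2, 0.3),
                     dR_over_R = c(0.3, 0.4, 0.5),
                     calcium_responder = TRUE, release_detected = TRUE,
                     valid = TRUE)
  id <- new("AffineTransform2D", A = diag(2), t = c(0, 0), rmse = 0,
            nLandmarks = 4L)
  syn <- data.frame(cx = c(0, 5000, 800), cy = c(0, 0, 0), n_ssd = c(1, 2, 3))
  live <- cbind(c(0, 5000, 10000), c(0, 0, 0))
  m <- matchSynapses(resp, live, syn, id, maxDist = 500)
  expect_equal(nrow(m), 2L)                       # third bouton unmatched
  expect_equal(m$match_dist[m$bouton == 1], 0)
  expect_equal(m$n_ssd[m$bouton == 2], 2)

  # two candidates within 10%: excluded as ambiguous
  syn2 <- data.frame(cx = c(100, 105), cy = c(0, 0), n_ssd = c(1, 2))
  expect_message(
    m2 <- matchSynapses(resp[1, ], cbind(0, 0), syn2, id, maxDist = 500),
    "ambiguous")
  expect_equal(nrow(m2), 0L)

  # non-responders are never matched (inclusion rule)
  resp3 <- resp
  resp3$calcium_responder <- FALSE
  expect_equal(nrow(matchSynapses(resp3, live, syn, id)), 0L)
})
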