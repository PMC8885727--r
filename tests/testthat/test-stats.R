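test_that("Spearman correlation hits the exact extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanTest(x, 2 * x + 1)@statistic, 1)
  expect_equal(spearmanTest(x, -x)@statistic, -1)
  expect_error(spearmanTest(rep(1, 5), 1:5), "constant")
  expect_error(spearmanTest(1:2, 1:2), "at least 3")
})

test_that("small-sample Spearman p equals exhaustive permutation enumeration", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(spearmanTest(x, y)@p, oracle_spearman_p(x, y),
                 tolerance = 1e-12)
  }
  # ties via mid-ranks
  x <- c(1, 1, 2, 3, 4, 5)
  y <- c(2, 1, 1, 5, 3, 3)
  expect_equal(spearmanTest(x, y)@p, oracle_spearman_p(x, y), tolerance = 1e-12)
})

test_that("Spearman p-values agree with the t-approximation for larger n", {
  set.seed(52)
  x <- rnorm(25)
  y <- x + rnorm(25, 0, 2)
  res <- spearmanTest(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res@statistic, unname(ct$estimate), tolerance = 1e-12)
  r <- res@statistic
  tt <- r * sqrt(23 / (1 - r^2))
  expect_equal(res@p, 2 * pt(-abs(tt), 23), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(53)
  x <- rnorm(15)
  y <- rnorm(15)
  base <- spearmanTest(x, y)
  tr <- spearmanTest(exp(x), y^3 + 5 * y)
  expect_equal(tr@statistic, base@statistic, tolerance = 1e-12)
  expect_equal(tr@p, base@p, tolerance = 1e-12)
})

test_that("KS statistic matches the brute-force breakpoint sweep", {
  expect_equal(ksTest2(1:10, 1:10)@statistic, 0)
  expect_equal(ksTest2(1:10, 1:10)@p, 1)
  expect_equal(ksTest2(1:5, 11:15)@statistic, 1)
  set.seed(54)
  for (i in 1:5) {
    x <- rnorm(sample(4:9, 1))
    y <- rnorm(sample(4:9, 1), 0.5)
    res <- ksTest2(x, y)
    expect_equal(res@statistic, oracle_ks_D(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
    expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  expect_error(ksTest2(1, 1:5), "2 values")
})

test_that("KS asymptotic p matches base R on large samples", {
  set.seed(55)
  x <- rnorm(200)
  y <- rnorm(200, 0.2)
  res <- ksTest2(x, y)
  ref <- ks.test(x, y, exact = FALSE)
  expect_equal(res@p, ref$p.value, tolerance = 1e-6)
  expect_equal(res@statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("the correlation report runs its battery and logs skipped groups", {
  set.seed(56)
  n <- 30
  corr <- data.frame(
    dG_over_R = runif(n), dR_over_R = runif(n),
    dG_over_dR = runif(n), n_ssd = rep(c(1L, 2L, 3L), each = 10),
    release_detected = rep(c(TRUE, FALSE), 15),
    ssd_total_detections = rpois(n, 100),
    ssd_mean_density = runif(n, 1e-5, 1e-4))
  rep <- summariseCorrelated(corr)
  expect_s3_class(rep, "correlationReport")
  expect_true("dG/R vs dR/R (all synapses)" %in% rep$stats$comparison)
  expect_equal(rep$n, n)

  # identical release/no-release groups give D = 0
  corr2 <- corr
  corr2$ssd_total_detections <- rep(corr$ssd_total_detections[1:15], 2)
  corr2$ssd_mean_density <- rep(corr$ssd_mean_density[1:15], 2)
  corr2$release_detected <- rep(c(TRUE, FALSE), each = 15)
  corr2$n_ssd <- rep(corr$n_ssd[1:15], 2)
  rep2 <- summariseCorrelated(corr2)
  d_rel <- rep2$stats$statistic[rep2$stats$comparison ==
                                  "SSD detections: release vs no release"]
  expect_equal(d_rel, 0)

  # single-SSD group below the minimum: comparison skipped with a note
  corr3 <- corr[corr$n_ssd > 1, ]
  rep3 <- summariseCorrelated(corr3)
  expect_true(any(grepl("single", rep3$notes)))
})
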