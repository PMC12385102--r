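test_that("Wald ratio propagates effect and sign with first-order SE", {
  est <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(mrBeta(est), 0.5)
  expect_equal(mrSe(est), 0.1)
  expect_equal(mrBeta(waldRatio(0.1, 0.01, 0, 0.01)), 0)
  expect_equal(mrBeta(waldRatio(-0.1, 0.01, 0.05, 0.01)), -0.5)
  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "zero")
})

test_that("IVW equals the closed-form weighted slope and OLS-through-origin", {
  hd <- makeHarmonized(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.09),
                       rep(0.01, 3))
  est <- mrIvw(hd)
  expect_equal(mrBeta(est), 0.039 / 0.14, tolerance = 1e-12)
  # with equal weights IVW is OLS through the origin
  ols <- unname(coef(lm(c(0.02, 0.05, 0.09) ~ 0 + c(0.1, 0.2, 0.3))))
  expect_equal(mrBeta(est), ols, tolerance = 1e-12)
  # degenerate consistency: all ratios equal c means estimate c, Q = 0
  hd2 <- makeHarmonized(c(0.1, 0.2, 0.4), 0.3 * c(0.1, 0.2, 0.4),
                        c(0.01, 0.02, 0.015))
  expect_equal(mrBeta(mrIvw(hd2)), 0.3, tolerance = 1e-12)
  expect_equal(cochranQ(hd2)$q, 0, tolerance = 1e-20)
  # MRE never deflates below the fixed-effect SE, and equals it at Q = 0
  expect_equal(mrSe(mrIvw(hd2, "multiplicative_random")),
               mrSe(mrIvw(hd2, "fixed")))
  expect_error(mrIvw(makeHarmonized(0.1, 0.02, 0.01)), "waldRatio")
})

test_that("IVW matches a weighted-lm oracle on 100 random instances", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(3:30, 1)
    bx <- rnorm(k, 0, 0.1)
    by <- rnorm(k, 0.2 * bx, 0.02)
    sey <- runif(k, 0.01, 0.05)
    est <- mrIvw(makeHarmonized(bx, by, sey), "fixed")
    fit <- lm(by ~ 0 + bx, weights = 1 / sey^2)
    expect_equal(mrBeta(est), unname(coef(fit)), tolerance = 1e-10)
    expect_equal(mrSe(est),
                 unname(sqrt(diag(vcov(fit)))) /
                   summary(fit)$sigma,
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the weighted 50th percentile", {
  # odd equal-weight set: the middle ratio
  hd <- makeHarmonized(c(0.1, 0.1, 0.1),
                       c(0.01, 0.03, 0.08), rep(0.01, 3))
  est <- weightedMedian(hd, nBoot = 50, seed = 1)
  expect_equal(mrBeta(est), 0.3, tolerance = 1e-12)
  expect_true(mrSe(est) > 0)
  # brute-force quantile oracle over random instances
  set.seed(202)
  for (i in 1:100) {
    k <- sample(3:40, 1)
    bx <- rnorm(k, 0.1, 0.05)
    by <- rnorm(k, 0.02, 0.02)
    sey <- runif(k, 0.01, 0.05)
    est <- weightedMedian(makeHarmonized(bx, by, sey), nBoot = 0)
    oracle <- wmOracle(by / bx, (bx / sey)^2)
    expect_equal(mrBeta(est), oracle, tolerance = 1e-10)
  }
})

test_that("weighted median bootstrap is seed-reproducible", {
  hd <- makeHarmonized(rnorm(10, 0.1, 0.02), rnorm(10, 0.03, 0.01),
                       rep(0.02, 10))
  a <- weightedMedian(hd, nBoot = 200, seed = 7)
  b <- weightedMedian(hd, nBoot = 200, seed = 7)
  expect_identical(mrSe(a), mrSe(b))
  expect_error(weightedMedian(hd, nBoot = 10), "seed")
})

test_that("MR-Egger recovers exact linear data and honours orientation", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  by <- 0.02 + 0.3 * bx
  hd <- makeHarmonized(bx, by, rep(0.01, 5))
  fit <- mrEgger(hd)
  expect_equal(fit@intercept, 0.02, tolerance = 1e-10)
  expect_equal(mrBeta(eggerSlope(fit)), 0.3, tolerance = 1e-10)
  # agreement with a weighted lm oracle on noisy data
  set.seed(33)
  bx <- rnorm(20, 0.1, 0.05)
  by <- rnorm(20, 0.01 + 0.2 * bx, 0.02)
  sey <- runif(20, 0.01, 0.05)
  s <- sign(bx)
  ref <- lm(I(s * by) ~ I(s * bx), weights = 1 / sey^2)
  fit <- mrEgger(makeHarmonized(bx, by, sey))
  expect_equal(mrBeta(eggerSlope(fit)), unname(coef(ref)[2]),
               tolerance = 1e-10)
  expect_equal(fit@intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  sigma <- summary(ref)$sigma
  seLm <- sqrt(diag(vcov(ref))) * max(1, sigma) / sigma
  expect_equal(mrSe(eggerSlope(fit)), unname(seLm[2]),
               tolerance = 1e-10)
  # flipping any row's (bx, by) pair leaves the fit unchanged
  flip <- makeHarmonized(bx * c(-1, rep(1, 19)),
                         by * c(-1, rep(1, 19)), sey)
  expect_equal(mrBeta(eggerSlope(mrEgger(flip))),
               mrBeta(eggerSlope(fit)), tolerance = 1e-12)
  expect_error(mrEgger(makeHarmonized(c(0.1, 0.2), c(0.1, 0.2),
                                      c(0.01, 0.01))), "3")
})

test_that("all estimators are equivariant under a global sign flip", {
  set.seed(55)
  bx <- rnorm(15, 0.1, 0.03)
  by <- rnorm(15, 0.02, 0.01)
  sey <- runif(15, 0.01, 0.03)
  hd <- makeHarmonized(bx, by, sey)
  hdFlip <- makeHarmonized(-bx, -by, sey)
  expect_equal(mrBeta(mrIvw(hdFlip)), mrBeta(mrIvw(hd)))
  expect_equal(mrBeta(weightedMedian(hdFlip, nBoot = 0)),
               mrBeta(weightedMedian(hd, nBoot = 0)))
  expect_equal(mrBeta(eggerSlope(mrEgger(hdFlip))),
               mrBeta(eggerSlope(mrEgger(hd))))
})

test_that("triangulation requires IVW significance plus direction agreement", {
  mk <- function(beta, p) .mrEstimate("ivw_mre", beta,
                                      abs(beta) / 2, 10L, pvalue = p)
  eg <- function(beta) new("EggerFit",
                           slope = .mrEstimate("egger_slope", beta,
                                               abs(beta) / 2, 10L),
                           intercept = 0, interceptSe = 0.01,
                           interceptPvalue = 0.5)
  v <- triangulate(mk(0.1, 0.01), mk(0.12, 0.2), eg(0.08))
  expect_true(v$significant)
  v2 <- triangulate(mk(0.1, 0.01), mk(0.12, 0.2), eg(-0.05))
  expect_false(v2$significant)
  expect_false(v2$conditions[["egger_direction"]])
  v3 <- triangulate(mk(0.1, 0.35), mk(0.12, 0.2), eg(0.08))
  expect_false(v3$significant)
})

test_that("single-instrument Wald equals IVW on a duplicated row", {
  est1 <- waldRatio(0.1, 0.01, 0.04, 0.02)
  hd <- makeHarmonized(c(0.1, 0.1), c(0.04, 0.04), c(0.02, 0.02))
  expect_equal(mrBeta(mrIvw(hd)), mrBeta(est1), tolerance = 1e-12)
})

test_that("null-generator IVW rejects at close to the nominal rate", {
  # 300 replicates here as a smoke check; the acceptance suite runs
  # the full 1000-replicate calibration
  rej <- vapply(1:300, function(i) {
    b <- simulateTwoSample(simTruth(theta = 0, seed = 5000L + i))
    hd <- harmonize(b@exposure, b@outcome)
    mrPvalue(mrIvw(hd)) < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("Egger intercept p-values are calibrated under balanced pleiotropy", {
  ps <- vapply(1:300, function(i) {
    b <- simulateTwoSample(simTruth(
      theta = 0.11, pleiotropyMean = 0, pleiotropySd = 0.01,
      pleiotropyFraction = 1, seed = 6000L + i))
    mrEgger(harmonize(b@exposure, b@outcome))@interceptPvalue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
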