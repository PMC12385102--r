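test_that("multivariable IVW recovers generating coefficients exactly on noiseless data", {
  set.seed(1)
  dat <- makeMvData(k = 30, direct = c(0, 0.18), noiseless = TRUE)
  est <- mvmrIvw(dat)
  expect_equal(mrBeta(est@estimates$E1), 0, tolerance = 1e-10)
  expect_equal(mrBeta(est@estimates$E2), 0.18, tolerance = 1e-10)
  # agreement with a weighted-lm oracle on noisy data
  set.seed(2)
  dat <- makeMvData(k = 50)
  est <- mvmrIvw(dat)
  fit <- lm(dat@betaOutcome ~ 0 + dat@betaExposure,
            weights = 1 / dat@seOutcome^2)
  expect_equal(unname(vapply(est@estimates, mrBeta, numeric(1))),
               unname(coef(fit)), tolerance = 1e-10)
})

test_that("m = 1 multivariable IVW reduces to univariable IVW", {
  set.seed(3)
  bx <- rnorm(20, 0.1, 0.04)
  by <- rnorm(20, 0.2 * bx, 0.02)
  sey <- runif(20, 0.01, 0.04)
  dat <- new("MvDataset", exposureIds = "E1",
             variantIds = sprintf("s%02d", 1:20),
             betaExposure = matrix(bx, ncol = 1),
             seExposure = matrix(0.006, 20, 1),
             betaOutcome = by, seOutcome = sey,
             provenance = rep("E1", 20))
  uni <- mrIvw(makeHarmonized(bx, by, sey))
  expect_equal(mrBeta(mvmrIvw(dat)@estimates$E1), mrBeta(uni),
               tolerance = 1e-12)
})

test_that("estimates are invariant to exposure ordering and label permutation", {
  set.seed(4)
  dat <- makeMvData(k = 40, direct = c(0.12, 0.17, -0.2))
  est <- mvmrIvw(dat)
  perm <- new("MvDataset", exposureIds = dat@exposureIds[c(3, 1, 2)],
              variantIds = dat@variantIds,
              betaExposure = dat@betaExposure[, c(3, 1, 2)],
              seExposure = dat@seExposure[, c(3, 1, 2)],
              betaOutcome = dat@betaOutcome,
              seOutcome = dat@seOutcome,
              provenance = dat@provenance)
  estP <- mvmrIvw(perm)
  for (id in dat@exposureIds)
    expect_equal(mrBeta(estP@estimates[[id]]),
                 mrBeta(est@estimates[[id]]), tolerance = 1e-12)
})

test_that("collinear exposures raise an informative error", {
  set.seed(5)
  dat <- makeMvData(k = 20, direct = c(0.1, 0.2))
  dat@betaExposure[, 2] <- 2 * dat@betaExposure[, 1]
  expect_error(mvmrIvw(dat), "rank deficient")
})

test_that("multivariable Egger recovers a planted constant pleiotropy", {
  # noiseless: intercept and slopes exact
  set.seed(6)
  dat <- makeMvData(k = 30, direct = c(0.1, -0.05), noiseless = TRUE)
  s <- sign(dat@betaExposure[, 1])
  dat@betaOutcome <- dat@betaOutcome + s * 0.05
  # orientation exposure 1: after orientation the +0.05 offset is
  # constant, so the fit is exact
  eg <- mvmrEgger(dat)
  expect_equal(eg@intercept, 0.05, tolerance = 1e-10)
  expect_equal(mrBeta(eg@estimates$E1), 0.1, tolerance = 1e-10)
  expect_equal(mrBeta(eg@estimates$E2), -0.05, tolerance = 1e-10)
  # zero-intercept noiseless data: slopes equal the IVW slopes
  dat2 <- makeMvData(k = 30, direct = c(0.1, -0.05), noiseless = TRUE)
  eg2 <- mvmrEgger(dat2)
  ivw2 <- mvmrIvw(dat2)
  expect_equal(eg2@intercept, 0, tolerance = 1e-10)
  expect_equal(mrBeta(eg2@estimates$E2), mrBeta(ivw2@estimates$E2),
               tolerance = 1e-8)
  # stochastic recovery at the default noise scales
  set.seed(7)
  ints <- vapply(1:100, function(i) {
    d <- makeMvData(k = 67, direct = c(0.12, 0.17, -0.2))
    s <- sign(d@betaExposure[, 1])
    d@betaOutcome <- d@betaOutcome + s * 0.05
    mvmrEgger(d)@intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05),
            2 * sd(ints) / sqrt(100) + 0.002)
})

test_that("row orientation flips leave multivariable Egger slopes unchanged", {
  set.seed(8)
  dat <- makeMvData(k = 40, direct = c(0.12, -0.2))
  flip <- rep(c(-1, 1), 20)
  datF <- new("MvDataset", exposureIds = dat@exposureIds,
              variantIds = dat@variantIds,
              betaExposure = dat@betaExposure * flip,
              seExposure = dat@seExposure,
              betaOutcome = dat@betaOutcome * flip,
              seOutcome = dat@seOutcome, provenance = dat@provenance)
  a <- mvmrEgger(dat)
  b <- mvmrEgger(datF)
  for (id in dat@exposureIds)
    expect_equal(mrBeta(b@estimates[[id]]),
                 mrBeta(a@estimates[[id]]), tolerance = 1e-12)
})

test_that("assembleMvDataset unions, jointly clumps and harmonizes", {
  ld <- simulateLdBlocks(7, 1, 0)
  ids <- variantIds(ld)
  mk <- function(trait, idx, beta = 0.06) gwasTable(trait, data.frame(
    variant_id = ids[idx], chromosome = "1",
    position = ld@positions[idx], effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = beta, se = 0.006,
    pvalue = 1e-10, n = 3e5))
  outcome <- gwasTable("Y", data.frame(
    variant_id = ids, chromosome = "1", position = ld@positions,
    effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.01,
    se = 0.02, pvalue = 0.5, n = 4.6e5))
  # disjoint significant sets of 3 and 4 with no LD: union of 7, but
  # every variant must be present in BOTH exposures to be usable
  e1 <- mk("E1", 1:7)
  e1r <- gwasRecords(e1)
  e1r$pvalue[4:7] <- 0.5   # significant only for 1:3
  e2 <- mk("E2", 1:7)
  e2r <- gwasRecords(e2)
  e2r$pvalue[1:3] <- 0.5   # significant only for 4:7
  dat <- assembleMvDataset(list(E1 = gwasTable("E1", e1r),
                                E2 = gwasTable("E2", e2r)),
                           outcome, ld)
  expect_equal(length(dat@variantIds), 7L)
  expect_setequal(unique(dat@provenance), c("E1", "E2"))
  # shared instruments: clumped shared set
  dat2 <- assembleMvDataset(list(E1 = mk("E1", 1:5),
                                 E2 = mk("E2", 1:5)),
                            outcome, ld)
  expect_equal(length(dat2@variantIds), 5L)
  expect_equal(unique(dat2@provenance), "E1,E2")
})

test_that("joint clumping matches a brute-force union-then-clump oracle", {
  set.seed(9)
  ld <- simulateLdBlocks(6, 5, 0.9)
  ids <- variantIds(ld)
  p1 <- 10^-runif(30, 4, 12)
  p2 <- 10^-runif(30, 4, 12)
  mk <- function(trait, p) gwasTable(trait, data.frame(
    variant_id = ids, chromosome = "1", position = ld@positions,
    effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.06,
    se = 0.006, pvalue = p, n = 3e5))
  outcome <- gwasTable("Y", data.frame(
    variant_id = ids, chromosome = "1", position = ld@positions,
    effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 0.01,
    se = 0.02, pvalue = 0.5, n = 4.6e5))
  dat <- suppressMessages(assembleMvDataset(
    list(E1 = mk("E1", p1), E2 = mk("E2", p2)), outcome, ld))
  # brute force: union of significant IDs, greedy clump by min p
  sig <- union(ids[p1 < 5e-8], ids[p2 < 5e-8])
  minP <- pmin(p1, p2)[match(sig, ids)]
  ord <- order(minP, sig)
  alive <- sig[ord]
  kept <- character()
  while (length(alive)) {
    top <- alive[1]
    kept <- c(kept, top)
    i <- match(top, ids)
    j <- match(alive, ids)
    alive <- alive[!(ld@r2[j, i] >= 0.001 &
                     abs(ld@positions[j] - ld@positions[i]) <= 1e7)]
  }
  expect_setequal(dat@variantIds, kept)
})
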