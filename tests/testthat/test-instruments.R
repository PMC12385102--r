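test_that("significance filter is strict and order-preserving", {
  tab <- gwasTable("t", data.frame(
    variant_id = c("rs1", "rs2", "rs3"), effect_allele = "A",
    other_allele = "G", beta = 0.1, se = 0.01,
    pvalue = c(1e-9, 5e-8, 1e-7)))
  kept <- selectSignificant(tab)
  expect_equal(variantIds(kept), "rs1")  # 5e-8 is not < 5e-8
  expect_equal(variantIds(selectSignificant(tab, 1.0)),
               c("rs1", "rs2", "rs3"))
  expect_error(selectSignificant(tab, 1e-20), "no instruments")
})

test_that("greedy clumping dominates within window and spares independent pairs", {
  mk <- function(p) gwasTable("t", data.frame(
    variant_id = c("rsA", "rsB"), chromosome = "1",
    position = c(1e6, 1e6 + 5e6), effect_allele = "A",
    other_allele = "G", beta = 0.1, se = 0.01, pvalue = p))
  ld <- ldMatrix(c("rsA", "rsB"),
                 matrix(c(1, 0.5, 0.5, 1), 2), c(1e6, 6e6))
  expect_equal(ldClump(mk(c(1e-10, 1e-9)), ld), "rsA")
  expect_equal(ldClump(mk(c(1e-9, 1e-10)), ld), "rsB")
  # r2 below the threshold: both survive even at close range
  ld2 <- ldMatrix(c("rsA", "rsB"),
                  matrix(c(1, 5e-4, 5e-4, 1), 2), c(1e6, 6e6))
  expect_setequal(ldClump(mk(c(1e-10, 1e-9)), ld2), c("rsA", "rsB"))
  # different chromosomes are always independent
  tab <- mk(c(1e-10, 1e-9))
  r <- gwasRecords(tab)
  r$chromosome <- c("1", "2")
  expect_setequal(ldClump(gwasTable("t", r), ld), c("rsA", "rsB"))
  # candidate missing from the LD matrix is a configuration error
  ld3 <- ldMatrix("rsA", matrix(1), 1e6)
  expect_error(ldClump(mk(c(1e-10, 1e-9)), ld3), "rsB")
})

test_that("block LD fixture clumps to one SNP per block, the block minimum p", {
  ld <- simulateLdBlocks(4, 5, 0.9, positionsSpacingKb = 100)
  p <- 10^-(9 + (20:1) / 10)
  cand <- gwasTable("c", data.frame(
    variant_id = variantIds(ld), chromosome = "1",
    position = ld@positions, effect_allele = "A", other_allele = "G",
    beta = 0.05, se = 0.005, pvalue = p))
  kept <- ldClump(cand, ld)
  # exhaustive expectation: the minimum-p member of each block
  blocks <- split(variantIds(ld), rep(1:4, each = 5))
  expected <- vapply(blocks, function(ids)
    ids[which.min(p[match(ids, variantIds(ld))])], character(1))
  expect_setequal(kept, unname(expected))
  # with zero intra-block r2 nothing is removed
  ld0 <- simulateLdBlocks(4, 5, 0)
  expect_equal(length(ldClump(cand, ld0)), 20L)
})

test_that("clumping does not depend on candidate row order and respects both thresholds", {
  set.seed(7)
  ld <- simulateLdBlocks(4, 5, 0.9)
  cand <- gwasTable("c", data.frame(
    variant_id = variantIds(ld), chromosome = "1",
    position = ld@positions, effect_allele = "A", other_allele = "G",
    beta = 0.05, se = 0.005,
    pvalue = 10^-runif(20, 8, 12)))
  kept <- ldClump(cand, ld)
  for (i in 1:5) {
    perm <- gwasTable("c", gwasRecords(cand)[sample(20), ])
    expect_equal(sort(ldClump(perm, ld)), sort(kept))
  }
  # every retained pair is independent under the thresholds
  idx <- match(kept, variantIds(ld))
  for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
    r2 <- ld@r2[idx[a], idx[b]]
    dist <- abs(ld@positions[idx[a]] - ld@positions[idx[b]])
    expect_true(r2 < 0.001 || dist > 1e7)
  }
})

test_that("proxy search returns the strongest strict-threshold proxy", {
  ids <- c("rs1", "rs2", "rs3", "rs4")
  r2 <- diag(1, 4)
  r2[1, 2] <- r2[2, 1] <- 0.95
  r2[1, 3] <- r2[3, 1] <- 0.85
  r2[1, 4] <- r2[4, 1] <- 0.80
  ld <- ldMatrix(ids, r2, 1:4 * 1e5)
  out <- gwasTable("Y", data.frame(
    variant_id = c("rs2", "rs3", "rs4"), effect_allele = "A",
    other_allele = "G", beta = 0.01, se = 0.02, pvalue = 0.5))
  expect_equal(findProxy("rs1", out, ld)$proxy, "rs2")
  # only an exactly-at-threshold proxy available: strict >, so none
  out80 <- gwasTable("Y", data.frame(
    variant_id = "rs4", effect_allele = "A", other_allele = "G",
    beta = 0.01, se = 0.02, pvalue = 0.5))
  expect_null(findProxy("rs1", out80, ld))
  # the variant itself present: returned at r2 = 1
  outSelf <- gwasTable("Y", data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = "A",
    other_allele = "G", beta = 0.01, se = 0.02, pvalue = 0.5))
  hit <- findProxy("rs1", outSelf, ld)
  expect_equal(hit$proxy, "rs1")
  expect_equal(hit$r2, 1)
})

test_that("variance explained matches the printed formula and drops eaf", {
  expect_equal(varianceExplained(0, 0.01, 0.3, 1000), 0)
  expect_equal(varianceExplained(1, 1, 0.5, 99), 1 / 100)
  # the eaf factor cancels algebraically
  expect_equal(varianceExplained(0.07, 0.011, 0.1, 5e4),
               varianceExplained(0.07, 0.011, 0.4, 5e4))
  # long form equals the simplified form
  b <- 0.08; s <- 0.009; f <- 0.23; n <- 2e5
  long <- (2 * f * (1 - f) * b^2) /
    (2 * f * (1 - f) * b^2 + 2 * f * (1 - f) * n * s^2)
  expect_equal(varianceExplained(b, s, f, n), long)
  expect_equal(varianceExplained(b, s, f, n), b^2 / (b^2 + n * s^2))
  expect_error(varianceExplained(0.1, 0.01, 1, 1000), "degenerate")
})

test_that("F-statistic matches hand evaluation and is monotone in R2", {
  expect_equal(fStatistic(0, 1000, 5), 0)
  expect_equal(fStatistic(0.01, 99, 1), 0.01 * 97 / 0.99)
  expect_equal(fStatistic(0.5, 103, 1), 101)
  r2s <- seq(0.01, 0.9, by = 0.01)
  fs <- vapply(r2s, fStatistic, numeric(1), n = 5e4, k = 67)
  expect_true(all(diff(fs) > 0))
  expect_error(fStatistic(0.1, 10, 10), "insufficient")
})

test_that("selectInstruments chains filter, clump, proxy and diagnostics", {
  set.seed(11)
  ld <- simulateLdBlocks(4, 5, 0.9)
  ids <- variantIds(ld)
  exposure <- gwasTable("X", data.frame(
    variant_id = ids, chromosome = "1", position = ld@positions,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.06, se = 0.006, pvalue = 10^-(9 + (20:1) / 10),
    n = 3e5))
  # outcome lacks the lead SNP of block 1 (rs0001) but carries its
  # strong proxy rs0002 (r2 = 0.9 > 0.8)
  outcome <- gwasTable("Y", data.frame(
    variant_id = ids[-1], chromosome = "1",
    position = ld@positions[-1], effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = 0.01, se = 0.02,
    pvalue = 0.5, n = 4.6e5))
  inst <- suppressMessages(
    selectInstruments(exposure, ld, outcome))
  expect_equal(length(inst@variants), 4L)
  expect_true("rs0002" %in% inst@variants)
  expect_false("rs0001" %in% inst@variants)
  expect_equal(inst@proxies$original, "rs0001")
  expect_equal(inst@totalR2,
               sum(0.06^2 / (0.06^2 + 3e5 * 0.006^2)) * 4,
               tolerance = 1e-12)
  expect_gt(inst@fStatistic, 10)
})

test_that("LD matrices round-trip through the long-format files", {
  ld <- simulateLdBlocks(3, 4, 0.75)
  pairs <- tempfile(fileext = ".tsv")
  pos <- tempfile(fileext = ".tsv")
  writeLdMatrix(ld, pairs, pos)
  back <- readLdMatrix(pairs, pos)
  expect_equal(variantIds(back), variantIds(ld))
  expect_equal(back@r2, ld@r2)
  expect_equal(back@positions, ld@positions)
})
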