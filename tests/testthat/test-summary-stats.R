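test_that("delimited round trip preserves a GwasTable and drops bad rows", {
  tab <- gwasTable("t1", data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chromosome = "2",
    position = c(100, 200, 300),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.5, NA), beta = c(0.1, -0.2, 0.05),
    se = c(0.01, 0.02, 0.01), pvalue = c(1e-10, 1e-9, 0.5),
    n = c(1000, 1000, NA)))
  path <- tempfile(fileext = ".tsv")
  writeGwasTable(tab, path)
  back <- readGwasTable(path, traitId = "t1")
  expect_equal(gwasRecords(back), gwasRecords(tab))
  expect_identical(traitId(back), "t1")

  # a row with unparsable SE is dropped with a message
  lines <- readLines(path)
  lines[3] <- sub("0.02", "NA", lines[3], fixed = TRUE)
  writeLines(lines, path)
  expect_message(red <- readGwasTable(path), "dropped 1")
  expect_equal(nVariants(red), 2L)

  # missing mandatory column is a configuration error naming the field
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA", "rs1\tA\tG\t0.1"), bad)
  expect_error(readGwasTable(bad), "'se'")
  # header-only file is an explicit empty-input error
  empty <- tempfile(fileext = ".tsv")
  writeLines("SNP\tEA\tOA\tBETA\tSE\tP", empty)
  expect_error(readGwasTable(empty), "empty")
})

test_that("comma-separated input and custom column maps are accepted", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("rsid,a1,a2,effect,stderr,pval",
               "rs1,A,G,0.1,0.01,1e-8"), path)
  tab <- readGwasTable(path, columnMap = c(
    variant_id = "rsid", effect_allele = "a1", other_allele = "a2",
    beta = "effect", se = "stderr", pvalue = "pval"))
  expect_equal(nVariants(tab), 1L)
  expect_true(is.na(gwasRecords(tab)$eaf))
})

test_that("palindrome detection follows the complement rule", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("AT", "T"))
  expect_equal(isPalindromic(c("A", "G", "C"), c("T", "A", "G")),
               c(TRUE, FALSE, TRUE))
})

test_that("harmonize aligns, flips, and excludes per the allele rules", {
  ex <- gwasTable("X", data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "A", "A", "C"),
    other_allele = c("G", "T", "T", "G", "G"),
    eaf = c(0.3, 0.50, 0.10, 0.25, 0.4),
    beta = c(0.10, 0.08, 0.12, 0.09, 0.11), se = 0.01,
    pvalue = 1e-10))
  out <- gwasTable("Y", data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("G", "A", "A", "A"),
    other_allele = c("A", "T", "T", "C"),
    eaf = c(0.7, 0.5, 0.1, 0.3),
    beta = c(-0.05, 0.04, 0.06, 0.03), se = 0.02, pvalue = 1e-3))
  hd <- harmonize(ex, out)

  rows <- harmonizedRows(hd)
  excl <- exclusions(hd)
  # swapped alleles: beta negated
  expect_equal(rows$beta_outcome[rows$variant_id == "rs1"], 0.05)
  # palindromic with eaf 0.5: min(0.5, 0.5) > 0.42, dropped
  expect_equal(excl$reason[excl$variant_id == "rs2"],
               "palindromic_intermediate")
  # palindromic with MAF 0.10 <= 0.42 and agreeing frequencies: kept
  expect_equal(rows$beta_outcome[rows$variant_id == "rs3"], 0.06)
  # outcome alleles A/C cannot be reconciled with exposure A/G
  expect_equal(excl$reason[excl$variant_id == "rs4"],
               "allele_mismatch")
  expect_equal(excl$reason[excl$variant_id == "rs5"],
               "missing_in_outcome")
  # partition: every instrument lands in exactly one of rows/exclusions
  expect_equal(nrow(rows) + nrow(excl), 5L)
  expect_setequal(c(rows$variant_id, excl$variant_id),
                  variantIds(ex))
})

test_that("strand-complement matches are accepted and signed correctly", {
  ex <- gwasTable("X", data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("G", "G"), eaf = 0.3, beta = c(0.1, 0.1),
    se = 0.01, pvalue = 1e-10))
  # rs1 reported on the other strand (T/C ~ A/G); rs2 on the other
  # strand and swapped (C/T ~ G/A)
  out <- gwasTable("Y", data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = c("T", "C"),
    other_allele = c("C", "T"), eaf = 0.3, beta = c(0.07, 0.07),
    se = 0.02, pvalue = 1e-3))
  rows <- harmonizedRows(harmonize(ex, out))
  expect_equal(rows$beta_outcome, c(0.07, -0.07))
})

test_that("harmonizing a fully allele-swapped outcome negates betas and leaves IVW invariant", {
  bundle <- simulateTwoSample(simTruth(seed = 42L))
  out <- gwasRecords(bundle@outcome)
  swapped <- out
  swapped$effect_allele <- out$other_allele
  swapped$other_allele <- out$effect_allele
  swapped$beta <- -out$beta
  swapped$eaf <- 1 - out$eaf
  hd1 <- harmonize(bundle@exposure, bundle@outcome)
  hd2 <- harmonize(bundle@exposure, gwasTable("swapped", swapped))
  expect_equal(harmonizedRows(hd2)$beta_outcome,
               harmonizedRows(hd1)$beta_outcome)
  expect_equal(mrBeta(mrIvw(hd2)), mrBeta(mrIvw(hd1)))
})

test_that("palindrome filter is symmetric in eaf versus 1 - eaf", {
  mk <- function(eaf) gwasTable("X", data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "T",
    eaf = eaf, beta = 0.1, se = 0.01, pvalue = 1e-10))
  out <- gwasTable("Y", data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "T",
    eaf = 0.1, beta = 0.05, se = 0.02, pvalue = 1e-3))
  for (f in c(0.10, 0.30, 0.45, 0.50)) {
    a <- exclusions(harmonize(mk(f), out))
    b <- exclusions(harmonize(mk(1 - f), out))
    expect_equal(nrow(a), nrow(b))
  }
  # missing eaf on a palindrome: orientation unknowable, excluded
  ex <- gwasTable("X", data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "T",
    eaf = NA, beta = 0.1, se = 0.01, pvalue = 1e-10))
  expect_equal(exclusions(harmonize(ex, out))$reason,
               "palindromic_intermediate")
})

test_that("harmonized datasets serialize to TSV with an exclusions sidecar", {
  pair <- toyHarmonizationPair()
  hd <- harmonize(pair$exposure, pair$outcome)
  path <- tempfile(fileext = ".tsv")
  paths <- writeHarmonized(hd, path)
  rows <- read.delim(path)
  excl <- read.delim(paths[2])
  expect_equal(nrow(rows), nVariants(hd))
  expect_equal(nrow(excl), nrow(exclusions(hd)))
})
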