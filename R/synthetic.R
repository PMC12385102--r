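#' @include AllClasses.R summary-stats.R
NULL

## Truncated SNP-effect draws: normal(0, sd) redrawn until detectable
## at genome-wide significance given the per-SNP standard error.
.drawEffects <- function(k, sd, se) {
  zgw <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  g <- stats::rnorm(k, 0, sd)
  bad <- abs(g) <= zgw * se
  while (any(bad)) {
    g[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(g) <= zgw * se
  }
  g
}

.gwasFromEffects <- function(traitId, ids, chrom, pos, ea, oa, eaf,
                             trueBeta, se, n) {
  beta <- stats::rnorm(length(ids), trueBeta, se)
  gwasTable(traitId, data.frame(
    variant_id = ids, chromosome = chrom, position = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
    se = se, pvalue = pmax(2 * stats::pnorm(-abs(beta) / se),
                           .Machine$double.xmin),
    n = n, stringsAsFactors = FALSE))
}

#' Simulate a two-sample MR dataset
#'
#' Generates exposure and outcome summary statistics with the structure
#' two-sample MR assumes: per-SNP true effects on the exposure drawn
#' from a zero-mean normal truncated to genome-wide detectability,
#' outcome effects equal to \code{theta} times the SNP effect plus an
#' optional pleiotropic offset, and independent sampling noise on both
#' sides (two non-overlapping samples). Effect-allele frequencies are
#' uniform on (0.05, 0.95); standard errors are drawn within 20\% of
#' the stated scales; p-values are Wald. The log-odds scale is treated
#' as linear, the standard two-sample MR approximation for binary
#' traits.
#'
#' @param truth A [SimTruth-class]; all randomness derives from
#'   \code{truth@seed}.
#' @param plantedOutlier Optional \code{list(index =, seMultiple =)}
#'   adding a fixed pleiotropic offset of \code{seMultiple} times that
#'   SNP's outcome SE to one SNP, for outlier-detection tests.
#' @return A [SimBundle-class] whose LD matrix is the identity (use
#'   [simulateLdBlocks()] when LD structure is wanted).
#' @export
simulateTwoSample <- function(truth, plantedOutlier = NULL) {
  .withSeed(truth@seed, {
    k <- truth@nSnps
    ids <- sprintf("rs%04d", seq_len(k))
    pos <- 1e6 * seq_len(k)
    alleles <- cbind(c("A", "A", "C", "G"), c("G", "C", "T", "A"))
    pick <- sample.int(4, k, replace = TRUE)
    ea <- alleles[pick, 1]
    oa <- alleles[pick, 2]
    eaf <- stats::runif(k, 0.05, 0.95)
    seX <- truth@seXScale * stats::runif(k, 0.8, 1.2)
    seY <- truth@seYScale * stats::runif(k, 0.8, 1.2)
    gamma <- .drawEffects(k, truth@gammaSd, seX)
    alpha <- ifelse(stats::runif(k) < truth@pleiotropyFraction,
                    stats::rnorm(k, truth@pleiotropyMean,
                                 truth@pleiotropySd), 0)
    if (!is.null(plantedOutlier))
      alpha[plantedOutlier$index] <- alpha[plantedOutlier$index] +
        plantedOutlier$seMultiple * seY[plantedOutlier$index]
    ## pleiotropic offsets are defined on the exposure-increasing
    ## orientation: "directional" pleiotropy is only meaningful
    ## relative to the allele that raises the exposure, which is also
    ## the orientation MR-Egger fits under
    exposure <- .gwasFromEffects("sim_exposure", ids, "1", pos, ea, oa,
                                 eaf, gamma, seX, truth@nExposure)
    outcome <- .gwasFromEffects("sim_outcome", ids, "1", pos, ea, oa,
                                eaf,
                                truth@theta * gamma +
                                  sign(gamma) * alpha,
                                seY, truth@nOutcome)
    ld <- ldMatrix(ids, diag(1, k), pos)
    new("SimBundle", exposure = exposure, outcome = outcome,
        mediators = list(), ld = ld, truth = truth)
  })
}

#' Simulate a mediation triangle
#'
#' Generates exposure, mediator and outcome summary statistics forming
#' an exposure-to-mediator-to-outcome triangle. Exposure instruments
#' affect the mediator with effect \code{step1Phi} and the outcome with
#' total effect \code{theta = directEffect + step1Phi * step2Psi} (the
#' identity is enforced by [SimTruth-class] validity). The causal
#' mediator additionally has its own instruments (SNPs with no exposure
#' effect) whose outcome effects flow only through the mediator with
#' slope \code{step2Psi}, so the conditional mediator-to-outcome effect
#' is identified by multivariable MR. Decoy mediator traits (default
#' 730, emulating a 731-trait immune-cell screen) share the variant
#' grid; a decoy's exposure-instrument effects are
#' \code{decoyPhis[j] * gamma} (zero by default, i.e. null traits).
#'
#' @param truth A [SimTruth-class] with the triangle fields set.
#' @param nDecoys Number of decoy mediator traits (default 730).
#' @param decoyPhis Exposure-to-decoy effects, recycled to
#'   \code{nDecoys} (default all zero).
#' @param nMediatorSnps Instruments specific to the causal mediator
#'   (default 30).
#' @return A [SimBundle-class]; \code{mediators[[1]]} (named
#'   \code{"mediator_causal"}) is the causal mediator, decoys are named
#'   \code{decoy_0001} onwards.
#' @export
simulateMediationTriangle <- function(truth, nDecoys = 730,
                                      decoyPhis = 0,
                                      nMediatorSnps = 30) {
  if (anyNA(c(truth@step1Phi, truth@step2Psi, truth@directEffect)))
    stop("truth must set step1Phi, step2Psi and directEffect",
         call. = FALSE)
  decoyPhis <- rep_len(decoyPhis, nDecoys)
  .withSeed(truth@seed, {
    k <- truth@nSnps
    km <- nMediatorSnps
    ids <- c(sprintf("rs%04d", seq_len(k)),
             sprintf("rsM%03d", seq_len(km)))
    pos <- 1e6 * seq_len(k + km)
    alleles <- cbind(c("A", "A", "C", "G"), c("G", "C", "T", "A"))
    pick <- sample.int(4, k + km, replace = TRUE)
    ea <- alleles[pick, 1]
    oa <- alleles[pick, 2]
    eaf <- stats::runif(k + km, 0.05, 0.95)
    seX <- truth@seXScale * stats::runif(k + km, 0.8, 1.2)
    seY <- truth@seYScale * stats::runif(k + km, 0.8, 1.2)
    seM <- truth@seMScale * stats::runif(k + km, 0.8, 1.2)
    gamma <- .drawEffects(k, truth@gammaSd, seX[seq_len(k)])
    delta <- .drawEffects(km, truth@gammaSd, seM[k + seq_len(km)])
    alpha <- ifelse(stats::runif(k) < truth@pleiotropyFraction,
                    stats::rnorm(k, truth@pleiotropyMean,
                                 truth@pleiotropySd), 0)

    xTrue <- c(gamma, rep(0, km))
    mTrue <- c(truth@step1Phi * gamma, delta)
    yTrue <- c(truth@theta * gamma + sign(gamma) * alpha,
               truth@step2Psi * delta)

    exposure <- .gwasFromEffects("sim_exposure", ids, "1", pos, ea, oa,
                                 eaf, xTrue, seX, truth@nExposure)
    outcome <- .gwasFromEffects("sim_outcome", ids, "1", pos, ea, oa,
                                eaf, yTrue, seY, truth@nOutcome)
    mediators <- list(
      mediator_causal = .gwasFromEffects("mediator_causal", ids, "1",
                                         pos, ea, oa, eaf, mTrue, seM,
                                         3757))
    iExp <- seq_len(k)
    for (j in seq_len(nDecoys)) {
      nm <- sprintf("decoy_%04d", j)
      mediators[[nm]] <- .gwasFromEffects(
        nm, ids[iExp], "1", pos[iExp], ea[iExp], oa[iExp], eaf[iExp],
        decoyPhis[j] * gamma, seM[iExp], 3757)
    }
    ld <- ldMatrix(ids, diag(1, k + km), pos)
    new("SimBundle", exposure = exposure, outcome = outcome,
        mediators = mediators, ld = ld, truth = truth)
  })
}

#' Simulate block-structured LD
#'
#' Builds a block-diagonal r-squared matrix: \code{nBlocks} blocks of
#' \code{blockSize} variants with constant within-block r-squared and
#' zero between blocks, positions evenly spaced. The construction is
#' deterministic; the variant naming matches [simulateTwoSample()]'s
#' grid (\code{rs0001}, ...).
#'
#' @param nBlocks,blockSize Block count and size.
#' @param intraR2 Within-block squared correlation, in [0, 1].
#' @param positionsSpacingKb Spacing between adjacent variants in kb
#'   (default 100).
#' @return An [LdMatrix-class].
#' @export
simulateLdBlocks <- function(nBlocks, blockSize, intraR2,
                             positionsSpacingKb = 100) {
  if (intraR2 < 0 || intraR2 > 1)
    stop("intraR2 must lie in [0, 1]", call. = FALSE)
  n <- nBlocks * blockSize
  block <- matrix(intraR2, blockSize, blockSize)
  diag(block) <- 1
  r2 <- matrix(0, n, n)
  for (b in seq_len(nBlocks)) {
    i <- (b - 1) * blockSize + seq_len(blockSize)
    r2[i, i] <- block
  }
  ldMatrix(sprintf("rs%04d", seq_len(n)), r2,
           positionsSpacingKb * 1000 * seq_len(n))
}

#' Write the canonical fixture suite
#'
#' Emits the small plain-text fixtures the test suite exercises: a toy
#' harmonization pair covering the allele-flip, strand-complement,
#' palindrome and missing-variant cases; a 4-block LD bundle for
#' clumping; a mediation-triangle bundle; and a planted-outlier bundle
#' — plus a JSON manifest recording the generating truths and seeds.
#' Re-running with the same seeds rewrites byte-identical files (the
#' function is idempotent and restores deleted fixtures).
#'
#' @param directory Output directory (created if needed).
#' @param seed Base seed for the stochastic bundles (default 104729).
#' @return The manifest, invisibly (a list, also written to
#'   \code{manifest.json}).
#' @export
writeFixtureSuite <- function(directory, seed = 104729) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE))
    stop("cannot create fixture directory: ", directory, call. = FALSE)
  p <- function(...) file.path(directory, ...)

  ## -- toy harmonization pair (deterministic) -----------------------
  ex <- gwasTable("toy_exposure", data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6", "rs7"),
    chromosome = "1", position = 1e6 * (1:7),
    effect_allele = c("A", "A", "A", "A", "C", "C", "A"),
    other_allele  = c("G", "T", "T", "G", "T", "G", "C"),
    eaf = c(0.30, 0.50, 0.10, 0.25, 0.40, 0.60, 0.20),
    beta = c(0.10, 0.08, 0.12, 0.09, 0.11, 0.07, 0.10),
    se = 0.01, pvalue = 1e-10, n = 3e5))
  out <- gwasTable("toy_outcome", data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs6", "rs7"),
    chromosome = "1", position = 1e6 * c(1:4, 6:7),
    effect_allele = c("G", "A", "A", "A", "C", "T"),
    other_allele  = c("A", "T", "T", "C", "G", "G"),
    eaf = c(0.70, 0.50, 0.10, 0.50, 0.60, 0.20),
    beta = c(-0.05, 0.04, 0.06, 0.03, 0.04, 0.05),
    se = 0.02, pvalue = 1e-3, n = 4.6e5))
  writeGwasTable(ex, p("harmonization_exposure.tsv"))
  writeGwasTable(out, p("harmonization_outcome.tsv"))

  ## -- 4-block LD clumping bundle (deterministic) -------------------
  ldB <- simulateLdBlocks(4, 5, 0.9)
  writeLdMatrix(ldB, p("ld_blocks_pairs.tsv"),
                p("ld_blocks_positions.tsv"))
  cand <- gwasTable("ld_candidates", data.frame(
    variant_id = variantIds(ldB), chromosome = "1",
    position = ldB@positions, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.05,
    se = 0.005, pvalue = 10^-(9 + (20:1) / 10), n = 3e5))
  writeGwasTable(cand, p("ld_blocks_candidates.tsv"))

  ## -- mediation triangle bundle ------------------------------------
  triTruth <- simTruth(step1Phi = -0.13, step2Psi = -0.09,
                       seed = seed)
  tri <- simulateMediationTriangle(triTruth, nDecoys = 5)
  writeGwasTable(tri@exposure, p("triangle_exposure.tsv"))
  writeGwasTable(tri@outcome, p("triangle_outcome.tsv"))
  writeGwasTable(tri@mediators[[1]], p("triangle_mediator.tsv"))

  ## -- planted-outlier bundle ---------------------------------------
  outTruth <- simTruth(nSnps = 31L, seed = seed + 1)
  planted <- simulateTwoSample(outTruth,
                               plantedOutlier = list(index = 1L,
                                                     seMultiple = 10))
  writeGwasTable(planted@exposure, p("outlier_exposure.tsv"))
  writeGwasTable(planted@outcome, p("outlier_outcome.tsv"))

  manifest <- list(
    fixtures = list(
      harmonization = c("harmonization_exposure.tsv",
                        "harmonization_outcome.tsv"),
      ld_blocks = c("ld_blocks_pairs.tsv", "ld_blocks_positions.tsv",
                    "ld_blocks_candidates.tsv"),
      triangle = c("triangle_exposure.tsv", "triangle_outcome.tsv",
                   "triangle_mediator.tsv"),
      planted_outlier = c("outlier_exposure.tsv",
                          "outlier_outcome.tsv")),
    truths = list(
      triangle = list(theta = triTruth@theta, phi = triTruth@step1Phi,
                      psi = triTruth@step2Psi,
                      direct = triTruth@directEffect,
                      seed = triTruth@seed),
      planted_outlier = list(theta = outTruth@theta,
                             n_snps = outTruth@nSnps,
                             outlier = "rs0001", se_multiple = 10,
                             seed = outTruth@seed)),
    seed = seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             p("manifest.json"))
  invisible(manifest)
}
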