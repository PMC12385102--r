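#' @import methods
NULL

#' GWAS summary statistics for one trait
#'
#' A \code{GwasTable} holds per-variant summary associations for a single
#' trait: one row per variant with effect and other allele, effect-allele
#' frequency, per-allele effect (log odds ratio for binary traits),
#' standard error, p-value and sample size.
#'
#' @slot traitId Single string naming the trait (e.g. a GWAS accession).
#' @slot records \code{data.frame} with columns \code{variant_id},
#'   \code{chromosome}, \code{position}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se},
#'   \code{pvalue}, \code{n}. \code{eaf} and \code{n} may be \code{NA}.
#'
#' @section Validity:
#' Variant IDs are unique; \code{se > 0}; \code{eaf} in [0, 1] when
#' present; \code{effect_allele != other_allele}.
#'
#' @seealso [gwasTable()], [readGwasTable()]
#' @export
setClass("GwasTable",
         representation(traitId = "character", records = "data.frame"))

setValidity("GwasTable", function(object) {
  r <- object@records
  msg <- character()
  if (length(object@traitId) != 1L || is.na(object@traitId))
    msg <- c(msg, "traitId must be a single non-NA string")
  missing_cols <- setdiff(.GWAS_FIELDS, names(r))
  if (length(missing_cols))
    return(paste("records is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(r$variant_id))
    msg <- c(msg, "duplicate variant_id in records")
  if (any(!is.na(r$se) & r$se <= 0))
    msg <- c(msg, "all standard errors must be > 0")
  if (any(!is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1)))
    msg <- c(msg, "eaf must lie in [0, 1]")
  if (any(r$effect_allele == r$other_allele))
    msg <- c(msg, "effect_allele must differ from other_allele")
  if (length(msg)) msg else TRUE
})

#' Construct a GwasTable
#'
#' @param traitId Trait identifier.
#' @param records Data frame of per-variant summary statistics; missing
#'   optional columns (\code{eaf}, \code{n}, \code{chromosome},
#'   \code{position}) are filled with \code{NA}.
#' @return A [GwasTable-class] object.
#' @examples
#' gwasTable("toy", data.frame(
#'   variant_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.1, -0.2),
#'   se = c(0.01, 0.02), pvalue = c(1e-10, 1e-9)))
#' @export
gwasTable <- function(traitId, records) {
  records <- as.data.frame(records)
  for (f in .GWAS_FIELDS)
    if (is.null(records[[f]]))
      records[[f]] <- NA
  records <- records[, .GWAS_FIELDS]
  records$variant_id <- as.character(records$variant_id)
  records$chromosome <- as.character(records$chromosome)
  for (f in c("position", "eaf", "beta", "se", "pvalue", "n"))
    records[[f]] <- as.numeric(records[[f]])
  rownames(records) <- NULL
  new("GwasTable", traitId = as.character(traitId), records = records)
}

#' Exposure/outcome effects aligned to shared effect alleles
#'
#' Result of [harmonize()]: per-variant exposure and outcome effects with
#' both betas signed to the exposure's effect allele, plus the record of
#' instruments that had to be excluded and why
#' (\code{palindromic_intermediate}, \code{allele_mismatch} or
#' \code{missing_in_outcome}).
#'
#' @slot exposureId,outcomeId Trait identifiers.
#' @slot rows \code{data.frame}: \code{variant_id}, \code{beta_exposure},
#'   \code{se_exposure}, \code{beta_outcome}, \code{se_outcome},
#'   \code{eaf_exposure}.
#' @slot exclusions \code{data.frame}: \code{variant_id}, \code{reason}.
#' @export
setClass("HarmonizedData",
         representation(exposureId = "character", outcomeId = "character",
                        rows = "data.frame", exclusions = "data.frame"))

setValidity("HarmonizedData", function(object) {
  msg <- character()
  need <- c("variant_id", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome", "eaf_exposure")
  if (!all(need %in% names(object@rows)))
    msg <- c(msg, "rows lacks required columns")
  if (!all(c("variant_id", "reason") %in% names(object@exclusions)))
    msg <- c(msg, "exclusions lacks required columns")
  else if (!all(object@exclusions$reason %in%
                c("palindromic_intermediate", "allele_mismatch",
                  "missing_in_outcome")))
    msg <- c(msg, "unknown exclusion reason")
  if (any(object@rows$variant_id %in% object@exclusions$variant_id))
    msg <- c(msg, "a variant cannot be both retained and excluded")
  if (length(msg)) msg else TRUE
})

#' Linkage-disequilibrium matrix
#'
#' Symmetric matrix of squared allelic correlations (r-squared) with unit
#' diagonal, plus base-pair positions aligned to the variant order.
#'
#' @slot variantIds Character vector of variant IDs (row/column order).
#' @slot r2 Symmetric numeric matrix in [0, 1] with unit diagonal.
#' @slot positions Numeric base-pair coordinates aligned to
#'   \code{variantIds}.
#' @export
setClass("LdMatrix",
         representation(variantIds = "character", r2 = "matrix",
                        positions = "numeric"))

setValidity("LdMatrix", function(object) {
  msg <- character()
  k <- length(object@variantIds)
  if (!all(dim(object@r2) == c(k, k)))
    msg <- c(msg, "r2 dimensions do not match variantIds")
  else {
    if (max(abs(object@r2 - t(object@r2))) > 1e-8)
      msg <- c(msg, "r2 must be symmetric")
    if (any(abs(diag(object@r2) - 1) > 1e-8))
      msg <- c(msg, "r2 diagonal must be 1")
    if (any(object@r2 < -1e-8 | object@r2 > 1 + 1e-8))
      msg <- c(msg, "r2 values must lie in [0, 1]")
  }
  if (length(object@positions) != k)
    msg <- c(msg, "positions length does not match variantIds")
  if (length(msg)) msg else TRUE
})

#' Construct an LdMatrix
#'
#' @param variantIds Variant IDs in matrix order.
#' @param r2 Symmetric r-squared matrix.
#' @param positions Base-pair positions aligned to \code{variantIds}.
#' @return An [LdMatrix-class].
#' @export
ldMatrix <- function(variantIds, r2, positions) {
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(variantIds, variantIds)
  new("LdMatrix", variantIds = as.character(variantIds), r2 = r2,
      positions = as.numeric(positions))
}

#' Selected instruments with strength diagnostics
#'
#' @slot exposureId Trait the instruments were selected for.
#' @slot variants Retained variant IDs after significance filtering,
#'   clumping and (optionally) proxy substitution.
#' @slot perVariantR2 Variance in the exposure explained per instrument
#'   (\code{NA} where eaf or n was missing).
#' @slot totalR2 Sum of the per-variant R-squared values.
#' @slot fStatistic Overall F-statistic; values below 10 conventionally
#'   flag weak instruments.
#' @slot proxies \code{data.frame} (\code{original}, \code{proxy},
#'   \code{r2}) of LD-proxy substitutions performed.
#' @export
setClass("InstrumentSet",
         representation(exposureId = "character", variants = "character",
                        perVariantR2 = "numeric", totalR2 = "numeric",
                        fStatistic = "numeric", proxies = "data.frame"))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  if (length(object@perVariantR2) != length(object@variants))
    msg <- c(msg, "perVariantR2 length must equal number of variants")
  if (!is.na(object@totalR2) &&
      (object@totalR2 < 0 || object@totalR2 >= 1))
    msg <- c(msg, "totalR2 must lie in [0, 1)")
  if (!is.na(object@fStatistic) && object@fStatistic < 0)
    msg <- c(msg, "fStatistic must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A causal-effect estimate
#'
#' One Mendelian-randomization estimate on the log-odds scale with its
#' standard error, 95\% confidence interval, odds-ratio counterparts,
#' two-sided p-value and the number of instruments used.
#'
#' @slot method One of \code{wald}, \code{ivw_fixed}, \code{ivw_mre},
#'   \code{egger_slope}, \code{weighted_median}, \code{ivw_mv},
#'   \code{egger_mv}.
#' @slot beta,se Estimate and standard error (log odds ratio).
#' @slot ciLow,ciHigh 95\% interval on the beta scale.
#' @slot orValue,orLow,orHigh Exponentiated counterparts.
#' @slot pvalue Two-sided p-value.
#' @slot nSnps Number of instruments.
#' @export
setClass("MrEstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", orValue = "numeric",
                        orLow = "numeric", orHigh = "numeric",
                        pvalue = "numeric", nSnps = "integer"))

setValidity("MrEstimate", function(object) {
  msg <- character()
  if (!anyNA(c(object@beta, object@ciLow, object@ciHigh)) &&
      (object@ciLow > object@beta + 1e-12 ||
       object@ciHigh < object@beta - 1e-12))
    msg <- c(msg, "confidence interval must bracket the estimate")
  if (!is.na(object@beta) &&
      abs(object@orValue - exp(object@beta)) > 1e-8 * object@orValue)
    msg <- c(msg, "orValue must equal exp(beta)")
  if (!is.na(object@pvalue) &&
      (object@pvalue <= 0 || object@pvalue > 1))
    msg <- c(msg, "pvalue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

## Internal constructor: fills the CI/OR slots from beta and se.
.mrEstimate <- function(method, beta, se, nSnps, pvalue = NULL,
                        ci = NULL) {
  if (is.null(ci)) ci <- .ci95(beta, se)
  if (is.null(pvalue)) pvalue <- .pNorm2(beta, se)
  pvalue <- max(pvalue, .Machine$double.xmin)
  new("MrEstimate", method = method, beta = beta, se = se,
      ciLow = ci[1], ciHigh = ci[2], orValue = exp(beta),
      orLow = exp(ci[1]), orHigh = exp(ci[2]), pvalue = pvalue,
      nSnps = as.integer(nSnps))
}

#' MR-Egger regression fit
#'
#' @slot slope [MrEstimate-class] for the pleiotropy-adjusted slope.
#' @slot intercept,interceptSe Average directional pleiotropy estimate
#'   and its standard error.
#' @slot interceptPvalue Two-sided p-value for the intercept (t, k-2 df).
#' @export
setClass("EggerFit",
         representation(slope = "MrEstimate", intercept = "numeric",
                        interceptSe = "numeric",
                        interceptPvalue = "numeric"))

setValidity("EggerFit", function(object) {
  if (!is.na(object@interceptSe) && object@interceptSe <= 0)
    "interceptSe must be > 0" else TRUE
})

#' Multivariable MR dataset
#'
#' Joint per-variant associations with m exposures and one outcome, all
#' signed to a common effect allele.
#'
#' @slot exposureIds Ordered exposure identifiers (length m >= 2 for
#'   multivariable fitting; m = 1 is permitted for the univariable
#'   equivalence path).
#' @slot variantIds Variant IDs, one per row.
#' @slot betaExposure,seExposure k x m matrices of exposure effects/SEs.
#' @slot betaOutcome,seOutcome Outcome effect and SE vectors.
#' @slot provenance Character vector: for each variant, the
#'   comma-separated exposures whose significance filter selected it.
#' @export
setClass("MvDataset",
         representation(exposureIds = "character", variantIds = "character",
                        betaExposure = "matrix", seExposure = "matrix",
                        betaOutcome = "numeric", seOutcome = "numeric",
                        provenance = "character"))

setValidity("MvDataset", function(object) {
  k <- length(object@variantIds)
  m <- length(object@exposureIds)
  msg <- character()
  if (!all(dim(object@betaExposure) == c(k, m)))
    msg <- c(msg, "betaExposure must be k x m")
  if (!all(dim(object@seExposure) == c(k, m)))
    msg <- c(msg, "seExposure must be k x m")
  if (length(object@betaOutcome) != k || length(object@seOutcome) != k)
    msg <- c(msg, "outcome vectors must have one entry per variant")
  if (length(msg)) msg else TRUE
})

#' Multivariable MR result
#'
#' @slot method \code{ivw_mv} or \code{egger_mv}.
#' @slot estimates List of [MrEstimate-class], one per exposure, named by
#'   exposure ID.
#' @slot intercept,interceptSe,interceptPvalue Egger intercept triple
#'   (\code{NA} for the IVW variant).
#' @export
setClass("MvmrResult",
         representation(method = "character", estimates = "list",
                        intercept = "numeric", interceptSe = "numeric",
                        interceptPvalue = "numeric"))

#' Two-step mediation decomposition
#'
#' Product-of-coefficients mediation: the indirect effect is the product
#' of the exposure-to-mediator effect (step 1) and the conditional
#' mediator-to-outcome effect (step 2); the mediated proportion is the
#' indirect effect over the total effect, as a percentage.
#'
#' @slot mediatorId Mediator trait identifier.
#' @slot totalBeta,totalSe Total exposure-to-outcome effect.
#' @slot step1Beta,step1Se Exposure-to-mediator effect.
#' @slot step2Beta,step2Se Mediator-to-outcome effect conditional on the
#'   exposure.
#' @slot indirectBeta,indirectSe Product of coefficients and its
#'   delta-method standard error.
#' @slot indirectCiLow,indirectCiHigh 95\% interval for the indirect
#'   effect.
#' @slot proportionPct,proportionSe,proportionCiLow,proportionCiHigh
#'   Mediated proportion (percent) with delta-method uncertainty.
#' @slot pvalue Two-sided normal p-value for the indirect effect.
#' @export
setClass("MediationResult",
         representation(mediatorId = "character",
                        totalBeta = "numeric", totalSe = "numeric",
                        step1Beta = "numeric", step1Se = "numeric",
                        step2Beta = "numeric", step2Se = "numeric",
                        indirectBeta = "numeric", indirectSe = "numeric",
                        indirectCiLow = "numeric",
                        indirectCiHigh = "numeric",
                        proportionPct = "numeric",
                        proportionSe = "numeric",
                        proportionCiLow = "numeric",
                        proportionCiHigh = "numeric",
                        pvalue = "numeric"))

setValidity("MediationResult", function(object) {
  msg <- character()
  if (abs(object@indirectBeta - object@step1Beta * object@step2Beta) >
      1e-12 * max(1, abs(object@indirectBeta)))
    msg <- c(msg, "indirect effect must equal step1 * step2 exactly")
  if (abs(object@proportionPct * object@totalBeta -
          100 * object@indirectBeta) >
      1e-9 * max(1, abs(object@indirectBeta) * 100))
    msg <- c(msg, "proportion * total must equal 100 * indirect")
  if (length(msg)) msg else TRUE
})

#' Generating parameters of a synthetic study
#'
#' \code{SimTruth} records every parameter of the synthetic
#' summary-statistic generator, so a simulated dataset is fully
#' described by (truth, seed) and recovery tests know the ground truth.
#'
#' Defaults reproduce the study conditions the package's tests exercise:
#' a causal effect of 0.11 on the log-odds scale (odds ratio about
#' 1.12), 67 instruments, exposure/outcome/mediator sampling noise on
#' the scale of large-biobank binary-trait GWAS, and a mediation
#' triangle with step effects -0.13 and -0.09.
#'
#' @slot theta True exposure-to-outcome causal effect (log OR per unit
#'   exposure).
#' @slot pleiotropyMean,pleiotropySd Mean/SD of pleiotropic outcome
#'   offsets (directional when the mean is nonzero).
#' @slot pleiotropyFraction Share of instruments carrying a pleiotropic
#'   offset, in [0, 1].
#' @slot step1Phi Exposure-to-mediator effect (mediation triangle).
#' @slot step2Psi Conditional mediator-to-outcome effect.
#' @slot directEffect Outcome effect not through the mediator; the
#'   triangle enforces theta = directEffect + step1Phi * step2Psi.
#' @slot nSnps Number of exposure instruments.
#' @slot gammaSd SD of true SNP-exposure effects (truncated to
#'   genome-wide detectability).
#' @slot seXScale,seYScale,seMScale Sampling-noise scales for exposure,
#'   outcome and mediator summary statistics.
#' @slot nExposure,nOutcome Nominal GWAS sample sizes.
#' @slot seed Integer seed; every generated quantity depends only on
#'   (truth, seed).
#' @export
setClass("SimTruth",
         representation(theta = "numeric", pleiotropyMean = "numeric",
                        pleiotropySd = "numeric",
                        pleiotropyFraction = "numeric",
                        step1Phi = "numeric", step2Psi = "numeric",
                        directEffect = "numeric", nSnps = "integer",
                        gammaSd = "numeric", seXScale = "numeric",
                        seYScale = "numeric", seMScale = "numeric",
                        nExposure = "numeric", nOutcome = "numeric",
                        seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (object@nSnps < 2) msg <- c(msg, "nSnps must be >= 2")
  if (object@pleiotropyFraction < 0 || object@pleiotropyFraction > 1)
    msg <- c(msg, "pleiotropyFraction must lie in [0, 1]")
  if (object@gammaSd <= 0) msg <- c(msg, "gammaSd must be > 0")
  if (object@seXScale <= 0 || object@seYScale <= 0 ||
      object@seMScale <= 0)
    msg <- c(msg, "sampling-noise scales must be > 0")
  if (!is.na(object@step1Phi) && !is.na(object@step2Psi) &&
      !is.na(object@directEffect) &&
      abs(object@theta -
          (object@directEffect + object@step1Phi * object@step2Psi)) >
      1e-10)
    msg <- c(msg,
             "triangle inconsistent: theta must equal directEffect + step1Phi * step2Psi")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimTruth-class Constructor with the default study
#'   conditions. When all three of \code{step1Phi}, \code{step2Psi} and
#'   \code{theta} are supplied, \code{directEffect} is derived from the
#'   triangle identity unless given explicitly.
#' @param theta,pleiotropyMean,pleiotropySd,pleiotropyFraction,step1Phi,step2Psi,directEffect,nSnps,gammaSd,seXScale,seYScale,seMScale,nExposure,nOutcome,seed
#'   See the class slots.
#' @export
simTruth <- function(theta = 0.11, pleiotropyMean = 0, pleiotropySd = 0,
                     pleiotropyFraction = 0, step1Phi = NA_real_,
                     step2Psi = NA_real_, directEffect = NA_real_,
                     nSnps = 67L, gammaSd = 0.06, seXScale = 0.006,
                     seYScale = 0.02, seMScale = 0.022,
                     nExposure = 3e5, nOutcome = 4.6e5, seed = 1L) {
  if (is.na(directEffect) && !is.na(step1Phi) && !is.na(step2Psi))
    directEffect <- theta - step1Phi * step2Psi
  new("SimTruth", theta = theta, pleiotropyMean = pleiotropyMean,
      pleiotropySd = pleiotropySd,
      pleiotropyFraction = pleiotropyFraction, step1Phi = step1Phi,
      step2Psi = step2Psi, directEffect = directEffect,
      nSnps = as.integer(nSnps), gammaSd = gammaSd,
      seXScale = seXScale, seYScale = seYScale, seMScale = seMScale,
      nExposure = nExposure, nOutcome = nOutcome,
      seed = as.integer(seed))
}

#' A simulated study bundle
#'
#' @slot exposure,outcome [GwasTable-class] objects sharing variant IDs.
#' @slot mediators Named list of mediator [GwasTable-class] objects
#'   (may be empty).
#' @slot ld [LdMatrix-class] covering every variant.
#' @slot truth The [SimTruth-class] that generated the bundle.
#' @export
setClass("SimBundle",
         representation(exposure = "GwasTable", outcome = "GwasTable",
                        mediators = "list", ld = "LdMatrix",
                        truth = "SimTruth"))

#' Sensitivity-analysis battery results
#'
#' @slot qStatistic,qDf,qPvalue Cochran Q heterogeneity test (fixed
#'   -effect IVW residuals, k - 1 df).
#' @slot eggerIntercept,eggerInterceptSe,eggerInterceptPvalue Egger
#'   intercept pleiotropy test.
#' @slot pressoGlobalPvalue MR-PRESSO global test p-value.
#' @slot pressoOutliers Variant IDs flagged by the outlier test.
#' @slot pressoRerunPvalue Global p after outlier removal (\code{NA} if
#'   no outliers were removed).
#' @slot looEstimates \code{data.frame} of leave-one-out IVW estimates
#'   (one row per omitted variant plus the "All" row).
#' @export
setClass("SensitivityReport",
         representation(qStatistic = "numeric", qDf = "integer",
                        qPvalue = "numeric", eggerIntercept = "numeric",
                        eggerInterceptSe = "numeric",
                        eggerInterceptPvalue = "numeric",
                        pressoGlobalPvalue = "numeric",
                        pressoOutliers = "character",
                        pressoRerunPvalue = "numeric",
                        looEstimates = "data.frame"))

#' End-to-end study report
#'
#' Container for the table-shaped outputs of the pipeline runners plus
#' run metadata (configuration echo, seeds, exclusion tallies).
#'
#' @slot uvmr,mvmr,mediation Lists of result objects and report tables.
#' @slot metadata List: configuration echo, package version, seeds and
#'   instrument/exclusion accounting.
#' @export
setClass("StudyReport",
         representation(uvmr = "list", mvmr = "list", mediation = "list",
                        metadata = "list"))
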