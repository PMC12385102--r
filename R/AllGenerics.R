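#' @include AllClasses.R
NULL

#' Accessors for mrtriad classes
#'
#' Small accessor layer so user code never reaches into slots:
#' \code{traitId()} returns the trait identifier of a [GwasTable-class],
#' \code{gwasRecords()} its per-variant table, \code{variantIds()} the
#' variant identifiers of a table, LD matrix or harmonized dataset,
#' \code{nVariants()} their count, \code{harmonizedRows()} and
#' \code{exclusions()} the retained/excluded parts of a
#' [HarmonizedData-class].
#'
#' @param x An mrtriad object.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname accessors
#' @export
setMethod("traitId", "GwasTable", function(x) x@traitId)

#' @rdname accessors
#' @export
setGeneric("gwasRecords", function(x) standardGeneric("gwasRecords"))

#' @rdname accessors
#' @export
setMethod("gwasRecords", "GwasTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setMethod("variantIds", "GwasTable", function(x) x@records$variant_id)

#' @rdname accessors
#' @export
setMethod("variantIds", "LdMatrix", function(x) x@variantIds)

#' @rdname accessors
#' @export
setMethod("variantIds", "HarmonizedData", function(x) x@rows$variant_id)

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setMethod("nVariants", "GwasTable", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("nVariants", "HarmonizedData", function(x) nrow(x@rows))

#' @rdname accessors
#' @export
setGeneric("harmonizedRows", function(x) standardGeneric("harmonizedRows"))

#' @rdname accessors
#' @export
setMethod("harmonizedRows", "HarmonizedData", function(x) x@rows)

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname accessors
#' @export
setMethod("exclusions", "HarmonizedData", function(x) x@exclusions)

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname accessors
#' @export
setMethod("mrBeta", "MrEstimate", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("mrSe", function(x) standardGeneric("mrSe"))

#' @rdname accessors
#' @export
setMethod("mrSe", "MrEstimate", function(x) x@se)

#' @rdname accessors
#' @export
setGeneric("mrPvalue", function(x) standardGeneric("mrPvalue"))

#' @rdname accessors
#' @export
setMethod("mrPvalue", "MrEstimate", function(x) x@pvalue)

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setMethod("mrMethod", "MrEstimate", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("eggerSlope", function(x) standardGeneric("eggerSlope"))

#' @rdname accessors
#' @export
setMethod("eggerSlope", "EggerFit", function(x) x@slope)

#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))

#' @rdname accessors
#' @export
setMethod("eggerIntercept", "EggerFit", function(x)
  c(estimate = x@intercept, se = x@interceptSe,
    pvalue = x@interceptPvalue))

#' @rdname accessors
#' @export
setGeneric("mediatedProportion",
           function(x) standardGeneric("mediatedProportion"))

#' @rdname accessors
#' @export
setMethod("mediatedProportion", "MediationResult", function(x)
  c(pct = x@proportionPct, ciLow = x@proportionCiLow,
    ciHigh = x@proportionCiHigh))

#' @rdname accessors
#' @export
setGeneric("simTruthOf", function(x) standardGeneric("simTruthOf"))

#' @rdname accessors
#' @export
setMethod("simTruthOf", "SimBundle", function(x) x@truth)

## ---- coercion ------------------------------------------------------

#' @export
setMethod("as.data.frame", "GwasTable",
          function(x, ...) x@records)

#' @export
setMethod("as.data.frame", "HarmonizedData",
          function(x, ...) x@rows)

#' @export
setMethod("as.data.frame", "MrEstimate", function(x, ...)
  data.frame(method = x@method, n_snps = x@nSnps, beta = x@beta,
             se = x@se, ci_low = x@ciLow, ci_high = x@ciHigh,
             or_value = x@orValue, or_low = x@orLow, or_high = x@orHigh,
             pvalue = x@pvalue))

#' @export
setMethod("as.data.frame", "MvmrResult", function(x, ...) {
  tab <- do.call(rbind, lapply(names(x@estimates), function(id) {
    d <- as.data.frame(x@estimates[[id]])
    cbind(exposure = id, d)
  }))
  rownames(tab) <- NULL
  tab
})

#' @export
setMethod("as.data.frame", "MediationResult", function(x, ...)
  data.frame(mediator = x@mediatorId,
             total_beta = x@totalBeta, total_se = x@totalSe,
             step1_beta = x@step1Beta, step1_se = x@step1Se,
             step2_beta = x@step2Beta, step2_se = x@step2Se,
             indirect_beta = x@indirectBeta, indirect_se = x@indirectSe,
             indirect_ci_low = x@indirectCiLow,
             indirect_ci_high = x@indirectCiHigh,
             proportion_pct = x@proportionPct,
             proportion_ci_low = x@proportionCiLow,
             proportion_ci_high = x@proportionCiHigh,
             pvalue = x@pvalue))

## ---- show methods --------------------------------------------------

setMethod("show", "GwasTable", function(object) {
  cat("GwasTable:", object@traitId, "\n")
  cat(" ", nrow(object@records), "variants\n")
  if (nrow(object@records))
    print(utils::head(object@records, 3))
})

setMethod("show", "HarmonizedData", function(object) {
  cat("HarmonizedData:", object@exposureId, "->", object@outcomeId, "\n")
  cat(" ", nrow(object@rows), "retained,", nrow(object@exclusions),
      "excluded\n")
  if (nrow(object@exclusions))
    print(table(object@exclusions$reason))
})

setMethod("show", "LdMatrix", function(object) {
  cat("LdMatrix:", length(object@variantIds), "variants\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for", object@exposureId, "\n")
  cat("  k =", length(object@variants),
      " total R2 =", signif(object@totalR2, 4),
      " F =", signif(object@fStatistic, 5), "\n")
  if (nrow(object@proxies))
    cat(" ", nrow(object@proxies), "proxy substitutions\n")
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("MrEstimate [%s] (%d SNPs)\n", object@method,
              object@nSnps))
  cat(sprintf("  beta = %.4f (SE %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              object@beta, object@se, object@orValue, object@orLow,
              object@orHigh, object@pvalue))
})

setMethod("show", "EggerFit", function(object) {
  cat("MR-Egger fit\n  slope: ")
  show(object@slope)
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
              object@intercept, object@interceptSe,
              object@interceptPvalue))
})

setMethod("show", "MvmrResult", function(object) {
  cat(sprintf("Multivariable MR [%s], %d exposures\n", object@method,
              length(object@estimates)))
  print(as.data.frame(object))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                object@intercept, object@interceptSe,
                object@interceptPvalue))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult:", object@mediatorId, "\n")
  cat(sprintf("  total %.4f, step1 %.4f, step2 %.4f\n",
              object@totalBeta, object@step1Beta, object@step2Beta))
  cat(sprintf("  indirect %.5f (95%% CI %.5f to %.5f), p = %.3g\n",
              object@indirectBeta, object@indirectCiLow,
              object@indirectCiHigh, object@pvalue))
  cat(sprintf("  mediated proportion %.2f%% (95%% CI %.2f to %.2f)\n",
              object@proportionPct, object@proportionCiLow,
              object@proportionCiHigh))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: theta =", object@theta, ", k =", object@nSnps,
      ", seed =", object@seed, "\n")
  if (!is.na(object@step1Phi))
    cat("  triangle: phi =", object@step1Phi, ", psi =",
        object@step2Psi, ", direct =", object@directEffect, "\n")
})

setMethod("show", "SimBundle", function(object) {
  cat("SimBundle:", nVariants(object@exposure), "variants,",
      length(object@mediators), "mediators\n")
  show(object@truth)
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport\n")
  cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n",
              object@qStatistic, object@qDf, object@qPvalue))
  cat(sprintf("  Egger intercept p = %.3g\n",
              object@eggerInterceptPvalue))
  cat(sprintf("  MR-PRESSO global p = %.3g, outliers: %s\n",
              object@pressoGlobalPvalue,
              if (length(object@pressoOutliers))
                paste(object@pressoOutliers, collapse = ", ")
              else "none"))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport with sections:",
      paste(c(if (length(object@uvmr)) "uvmr",
              if (length(object@mvmr)) "mvmr",
              if (length(object@mediation)) "mediation"),
            collapse = ", "), "\n")
})
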