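#' @include AllClasses.R summary-stats.R instruments.R
NULL

## Orientation of a table's alleles against reference alleles at shared
## variants: +1 keep, -1 flip the beta, NA irreconcilable. Strand
## complements are accepted, as in harmonize().
.alleleSign <- function(refEA, refOA, ea, oa) {
  cea <- .complementAllele(ea)
  coa <- .complementAllele(oa)
  out <- rep(NA_real_, length(ea))
  out[ea == refEA & oa == refOA] <- 1
  out[is.na(out) & ea == refOA & oa == refEA] <- -1
  out[is.na(out) & cea == refEA & coa == refOA] <- 1
  out[is.na(out) & cea == refOA & coa == refEA] <- -1
  out
}

#' Assemble a multivariable MR dataset
#'
#' Takes the union of each exposure's genome-wide-significant variants,
#' clumps the union jointly (greedily by the minimum p-value across
#' exposures), keeps variants present in every exposure and in the
#' outcome, and signs all effects to the first exposure's effect
#' alleles. Palindromic variants with intermediate frequency (on the
#' first exposure) and variants whose alleles cannot be reconciled are
#' dropped; every drop is reported with a message.
#'
#' @param exposures Named list of [GwasTable-class] objects (m >= 2; a
#'   single exposure is allowed and reduces the fit to univariable
#'   IVW).
#' @param outcome [GwasTable-class] for the outcome.
#' @param ld [LdMatrix-class] covering the candidate union.
#' @param pThreshold,r2Threshold,windowKb Selection thresholds as in
#'   [selectInstruments()].
#' @param palindromeMafThreshold As in [harmonize()].
#' @return An [MvDataset-class].
#' @export
assembleMvDataset <- function(exposures, outcome, ld,
                              pThreshold = 5e-8, r2Threshold = 0.001,
                              windowKb = 10000,
                              palindromeMafThreshold = 0.42) {
  m <- length(exposures)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures))))
    names(exposures) <- vapply(exposures, traitId, character(1))
  ids <- names(exposures)

  sigSets <- lapply(exposures, function(e)
    variantIds(selectSignificant(e, pThreshold)))
  union <- unique(unlist(sigSets, use.names = FALSE))

  ## joint clumping keyed on the best p across exposures
  minP <- vapply(union, function(v) {
    ps <- vapply(exposures, function(e) {
      r <- gwasRecords(e)
      i <- match(v, r$variant_id)
      if (is.na(i)) NA_real_ else r$pvalue[i]
    }, numeric(1))
    min(ps, na.rm = TRUE)
  }, numeric(1))
  ## chromosome/position from whichever exposure carries the variant
  refRec <- do.call(rbind, lapply(exposures, gwasRecords))
  refRec <- refRec[!duplicated(refRec$variant_id), , drop = FALSE]
  refRec <- refRec[match(union, refRec$variant_id), , drop = FALSE]
  cand <- gwasTable("mv_candidates",
                    transform(refRec, pvalue = minP))
  kept <- ldClump(cand, ld, r2Threshold, windowKb)

  inAll <- vapply(kept, function(v)
    all(vapply(exposures, function(e) v %in% variantIds(e),
               logical(1))) && v %in% variantIds(outcome),
    logical(1))
  if (any(!inAll))
    message("assembleMvDataset: dropped ", sum(!inAll),
            " variant(s) absent from some exposure or the outcome")
  kept <- kept[inAll]

  ref <- gwasRecords(exposures[[1]])
  ref <- ref[match(kept, ref$variant_id), , drop = FALSE]

  betaE <- seE <- matrix(NA_real_, length(kept), m,
                         dimnames = list(kept, ids))
  ok <- rep(TRUE, length(kept))
  for (j in seq_len(m)) {
    r <- gwasRecords(exposures[[j]])
    i <- match(kept, r$variant_id)
    s <- if (j == 1) rep(1, length(kept)) else
      .alleleSign(ref$effect_allele, ref$other_allele,
                  r$effect_allele[i], r$other_allele[i])
    ok <- ok & !is.na(s)
    betaE[, j] <- s * r$beta[i]
    seE[, j] <- r$se[i]
  }
  ro <- gwasRecords(outcome)
  io <- match(kept, ro$variant_id)
  so <- .alleleSign(ref$effect_allele, ref$other_allele,
                    ro$effect_allele[io], ro$other_allele[io])
  ok <- ok & !is.na(so)

  pal <- isPalindromic(ref$effect_allele, ref$other_allele)
  maf <- pmin(ref$eaf, 1 - ref$eaf)
  ok <- ok & !(pal & (is.na(ref$eaf) | maf > palindromeMafThreshold))
  if (any(!ok))
    message("assembleMvDataset: dropped ", sum(!ok),
            " variant(s) (allele mismatch or intermediate palindrome)")

  prov <- vapply(kept, function(v)
    paste(ids[vapply(sigSets, function(s) v %in% s, logical(1))],
          collapse = ","), character(1))

  dat <- new("MvDataset", exposureIds = ids, variantIds = kept[ok],
             betaExposure = betaE[ok, , drop = FALSE],
             seExposure = seE[ok, , drop = FALSE],
             betaOutcome = (so * ro$beta[io])[ok],
             seOutcome = ro$se[io][ok],
             provenance = unname(prov[ok]))
  if (length(dat@variantIds) < m + 2L)
    stop("insufficient instruments for multivariable MR: ",
         length(dat@variantIds), " variants for ", m, " exposures",
         call. = FALSE)
  dat
}

## Shared multivariable WLS core. intercept = TRUE adds the Egger
## column; the orientation flip (rows signed so one exposure's beta is
## non-negative) is applied by the caller.
.mvmrFit <- function(X, y, w, ids, intercept, method, k) {
  m <- length(ids)
  D <- if (intercept) cbind(`(intercept)` = 1, X) else X
  fit <- .wlsFit(D, y, w)
  scale <- .mreScale(fit$rss, fit$df)
  se <- fit$se_unscaled * scale
  off <- as.integer(intercept)
  est <- stats::setNames(lapply(seq_len(m), function(j) {
    b <- fit$coef[j + off]
    s <- se[j + off]
    if (intercept) {
      tq <- stats::qt(0.975, df = fit$df)
      .mrEstimate(method, b, s, k, pvalue = .pT2(b, s, fit$df),
                  ci = c(b - tq * s, b + tq * s))
    } else .mrEstimate(method, b, s, k)
  }), ids)
  if (intercept)
    new("MvmrResult", method = method, estimates = est,
        intercept = fit$coef[1], interceptSe = se[1],
        interceptPvalue = max(.pT2(fit$coef[1], se[1], fit$df),
                              .Machine$double.xmin))
  else
    new("MvmrResult", method = method, estimates = est,
        intercept = NA_real_, interceptSe = NA_real_,
        interceptPvalue = NA_real_)
}

#' Multivariable IVW
#'
#' Weighted least squares of outcome effects on the m exposure-effect
#' columns with no intercept and weights \code{1/seOutcome^2}; each
#' coefficient is that exposure's direct effect conditional on the
#' others. Standard errors carry multiplicative overdispersion
#' inflation when the residual variance exceeds 1.
#'
#' @param data An [MvDataset-class] with at least m + 1 rows.
#' @return An [MvmrResult-class] with method \code{ivw_mv}.
#' @export
mvmrIvw <- function(data) {
  k <- length(data@variantIds)
  m <- length(data@exposureIds)
  if (k < m + 1L)
    stop("insufficient instruments: need at least m + 1 rows",
         call. = FALSE)
  .mvmrFit(data@betaExposure, data@betaOutcome, 1 / data@seOutcome^2,
           data@exposureIds, intercept = FALSE, method = "ivw_mv",
           k = k)
}

#' Multivariable MR-Egger
#'
#' As [mvmrIvw()] with a free intercept capturing average directional
#' pleiotropy. Rows are oriented so the chosen orientation exposure's
#' effect is non-negative (every beta in the row, including the
#' outcome's, is flipped together, leaving slopes unchanged).
#'
#' @param data An [MvDataset-class] with at least m + 2 rows.
#' @param orientationExposure Index (or name) of the exposure defining
#'   the orientation axis (default the first).
#' @return An [MvmrResult-class] with method \code{egger_mv} and the
#'   intercept triple filled in.
#' @export
mvmrEgger <- function(data, orientationExposure = 1L) {
  k <- length(data@variantIds)
  m <- length(data@exposureIds)
  if (k < m + 2L)
    stop("insufficient instruments: need at least m + 2 rows",
         call. = FALSE)
  if (is.character(orientationExposure))
    orientationExposure <- match(orientationExposure, data@exposureIds)
  s <- ifelse(data@betaExposure[, orientationExposure] < 0, -1, 1)
  .mvmrFit(data@betaExposure * s, s * data@betaOutcome,
           1 / data@seOutcome^2, data@exposureIds, intercept = TRUE,
           method = "egger_mv", k = k)
}
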