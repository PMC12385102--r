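#' @include AllClasses.R estimators.R mvmr.R
NULL

#' Screen candidate mediators for an exposure effect
#'
#' Step 1 of two-step mediation MR: for each candidate mediator, the
#' exposure's instruments are harmonized against the mediator's summary
#' statistics and the full univariable battery run (IVW, weighted
#' median, MR-Egger, triangulation). A mediator passes when the
#' triangulation verdict is significant at \code{alpha}; by design no
#' multiple-testing correction is applied (this is an exploratory
#' screen), though Benjamini-Hochberg adjustment of the IVW p-values
#' can be switched on. Mediators overlapping fewer than 3 instruments
#' are skipped with a message.
#'
#' @param exposure [GwasTable-class] for the exposure.
#' @param mediators Named list of mediator [GwasTable-class] objects.
#' @param instruments Character vector of selected exposure instrument
#'   IDs (from [selectInstruments()]).
#' @param alpha Screening significance level (default 0.05).
#' @param rule \code{"triangulate"} (default: IVW p < alpha and
#'   direction agreement of weighted median and Egger) or \code{"ivw"}
#'   (IVW p alone).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @param palindromeMafThreshold As in [harmonize()].
#' @return \code{data.frame}, one row per screened mediator:
#'   \code{mediator_id}, \code{n_snps}, \code{beta}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{pvalue} (IVW,
#'   exposure-to-mediator), \code{wm_beta}, \code{egger_beta},
#'   \code{significant}. Retained mediators are the rows with
#'   \code{significant == TRUE}.
#' @export
screenMediators <- function(exposure, mediators, instruments,
                            alpha = 0.05,
                            rule = c("triangulate", "ivw"),
                            adjust = c("none", "BH"),
                            palindromeMafThreshold = 0.42) {
  rule <- match.arg(rule)
  adjust <- match.arg(adjust)
  if (is.null(names(mediators)))
    names(mediators) <- vapply(mediators, traitId, character(1))
  rows <- lapply(names(mediators), function(id) {
    hd <- harmonize(exposure, mediators[[id]], instruments,
                    palindromeMafThreshold)
    if (nVariants(hd) < 3L) {
      message("screenMediators: skipped ", id, " (",
              nVariants(hd), " overlapping instruments)")
      return(NULL)
    }
    ivw <- mrIvw(hd)
    wm <- weightedMedian(hd, nBoot = 0)
    eg <- mrEgger(hd)
    data.frame(mediator_id = id, n_snps = ivw@nSnps,
               beta = mrBeta(ivw), se = mrSe(ivw),
               ci_low = ivw@ciLow, ci_high = ivw@ciHigh,
               pvalue = mrPvalue(ivw), wm_beta = mrBeta(wm),
               egger_beta = mrBeta(eggerSlope(eg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no mediator had enough overlapping instruments",
         call. = FALSE)
  p <- if (adjust == "BH") stats::p.adjust(out$pvalue, "BH")
       else out$pvalue
  dirOk <- sign(out$wm_beta) == sign(out$beta) &
    sign(out$egger_beta) == sign(out$beta)
  out$significant <- if (rule == "triangulate") p < alpha & dirOk
                     else p < alpha
  rownames(out) <- NULL
  out
}

#' Conditional mediator-to-outcome effect
#'
#' Step 2 of two-step mediation MR: the mediator's effect on the
#' outcome conditional on the exposure, estimated by multivariable IVW
#' over the jointly clumped union of the mediator's and the exposure's
#' instruments; the mediator's coefficient is returned.
#'
#' @param mediator,exposure,outcome [GwasTable-class] objects.
#' @param ld [LdMatrix-class] covering the instrument union.
#' @param pThreshold,r2Threshold,windowKb Selection thresholds as in
#'   [assembleMvDataset()].
#' @return The mediator's [MrEstimate-class] (method \code{ivw_mv}).
#' @export
mediatorToOutcome <- function(mediator, exposure, outcome, ld,
                              pThreshold = 5e-8, r2Threshold = 0.001,
                              windowKb = 10000) {
  dat <- assembleMvDataset(
    stats::setNames(list(mediator, exposure),
                    c(traitId(mediator), traitId(exposure))),
    outcome, ld, pThreshold, r2Threshold, windowKb)
  mvmrIvw(dat)@estimates[[traitId(mediator)]]
}

#' Product-of-coefficients mediation decomposition
#'
#' Combines the total exposure-to-outcome effect, the
#' exposure-to-mediator effect (step 1) and the conditional
#' mediator-to-outcome effect (step 2) into the indirect effect
#' \code{step1 * step2}, its delta-method standard error
#' \code{sqrt(step2^2 se1^2 + step1^2 se2^2)}, a two-sided normal
#' p-value, and the mediated proportion \code{100 * indirect / total}
#' with a delta-method interval (treating the total as independent of
#' the product). The proportion is positive exactly when the indirect
#' and total effects share a sign.
#'
#' @param total,step1,step2 Each a numeric vector \code{c(beta, se)} or
#'   a list/[MrEstimate-class] with \code{beta} and \code{se}. A bare
#'   length-1 number is accepted as a point estimate with zero SE.
#' @param mediatorId Label for the mediator (default "mediator").
#' @return A [MediationResult-class].
#' @examples
#' res <- mediationEffect(c(0.11, 0.033), c(-0.13, 0.041),
#'                        c(-0.09, 0.033))
#' mediatedProportion(res)["pct"]  # 10.64 (rounded to 2 dp)
#' @export
mediationEffect <- function(total, step1, step2,
                            mediatorId = "mediator") {
  grab <- function(x) {
    if (is(x, "MrEstimate")) return(c(mrBeta(x), mrSe(x)))
    if (is.list(x)) return(c(x$beta, x$se))
    if (length(x) == 1L) return(c(x, 0))
    as.numeric(x[1:2])
  }
  tt <- grab(total); s1 <- grab(step1); s2 <- grab(step2)
  if (tt[1] == 0)
    stop("mediated proportion undefined: total effect is zero",
         call. = FALSE)
  ind <- s1[1] * s2[1]
  seInd <- sqrt(s2[1]^2 * s1[2]^2 + s1[1]^2 * s2[2]^2)
  ciInd <- .ci95(ind, seInd)
  p <- if (seInd > 0) .pNorm2(ind, seInd) else as.numeric(ind == 0)
  prop <- 100 * ind / tt[1]
  seProp <- sqrt((100 / tt[1])^2 * seInd^2 +
                 (100 * ind / tt[1]^2)^2 * tt[2]^2)
  ciProp <- .ci95(prop, seProp)
  new("MediationResult", mediatorId = mediatorId,
      totalBeta = tt[1], totalSe = tt[2],
      step1Beta = s1[1], step1Se = s1[2],
      step2Beta = s2[1], step2Se = s2[2],
      indirectBeta = ind, indirectSe = seInd,
      indirectCiLow = ciInd[1], indirectCiHigh = ciInd[2],
      proportionPct = prop, proportionSe = seProp,
      proportionCiLow = ciProp[1], proportionCiHigh = ciProp[2],
      pvalue = max(p, .Machine$double.xmin))
}
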