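#' @include AllClasses.R
NULL

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: outcome effect over exposure effect,
#' with the first-order standard error \code{|seY / betaX|} and a
#' normal-approximation interval and p-value.
#'
#' @param betaX,seX Exposure association and SE (the SE enters only
#'   through higher-order terms and is ignored at first order).
#' @param betaY,seY Outcome association and SE.
#' @return An [MrEstimate-class] with method \code{wald}.
#' @export
waldRatio <- function(betaX, seX, betaY, seY) {
  if (betaX == 0)
    stop("undefined Wald ratio: exposure effect is zero", call. = FALSE)
  .mrEstimate("wald", betaY / betaX, abs(seY / betaX), 1L)
}

## Closed-form IVW slope and ingredients; shared with the sensitivity
## module.
.ivwCore <- function(bx, by, seY) {
  w <- 1 / seY^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, seFixed = sqrt(1 / sxx), q = q, k = length(bx))
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through
#' the origin with weights \code{1/seY^2}; the closed form is
#' \code{sum(w bx by) / sum(w bx^2)}. The default multiplicative
#' random-effects model inflates the fixed-effect standard error by
#' \code{sqrt(Q/(k-1))} when heterogeneity exceeds its expectation
#' (\code{Q/(k-1) > 1}) and equals the fixed-effect model otherwise;
#' the point estimate is identical under both models.
#'
#' @param data A [HarmonizedData-class] with at least 2 retained rows.
#' @param model \code{"multiplicative_random"} (default) or
#'   \code{"fixed"}.
#' @return An [MrEstimate-class].
#' @export
mrIvw <- function(data, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  r <- harmonizedRows(data)
  if (nrow(r) < 2L)
    stop("insufficient instruments for IVW (need >= 2); ",
         "use waldRatio() for a single instrument", call. = FALSE)
  core <- .ivwCore(r$beta_exposure, r$beta_outcome, r$se_outcome)
  se <- core$seFixed
  method <- "ivw_fixed"
  if (model == "multiplicative_random") {
    se <- se * .mreScale(core$q, core$k - 1)
    method <- "ivw_mre"
  }
  .mrEstimate(method, core$beta, se, core$k)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept (weights \code{1/seY^2}), after orienting every row
#' so the exposure effect is non-negative (the outcome effect's sign is
#' flipped together with it, so the fit is unchanged by any row's sign
#' convention). The intercept estimates average directional pleiotropy;
#' the slope is a pleiotropy-adjusted causal estimate. Standard errors
#' use multiplicative random-effects inflation with k - 2 residual
#' degrees of freedom; p-values and confidence limits use the t
#' distribution on k - 2 df.
#'
#' @param data A [HarmonizedData-class] with at least 3 retained rows.
#' @return An [EggerFit-class].
#' @export
mrEgger <- function(data) {
  r <- harmonizedRows(data)
  k <- nrow(r)
  if (k < 3L)
    stop("insufficient instruments for MR-Egger (need >= 3)",
         call. = FALSE)
  s <- ifelse(r$beta_exposure < 0, -1, 1)
  bx <- s * r$beta_exposure
  by <- s * r$beta_outcome
  w <- 1 / r$se_outcome^2
  fit <- .wlsFit(cbind(1, bx), by, w)
  scale <- .mreScale(fit$rss, k - 2)
  se <- fit$se_unscaled * scale
  tq <- stats::qt(0.975, df = k - 2)
  slope <- .mrEstimate(
    "egger_slope", fit$coef[2], se[2], k,
    pvalue = .pT2(fit$coef[2], se[2], k - 2),
    ci = c(fit$coef[2] - tq * se[2], fit$coef[2] + tq * se[2]))
  new("EggerFit", slope = slope, intercept = fit$coef[1],
      interceptSe = se[1],
      interceptPvalue = max(.pT2(fit$coef[1], se[1], k - 2),
                            .Machine$double.xmin))
}

## Interpolated weighted median of per-SNP ratio estimates: cumulative
## weight minus half the own weight, linearly interpolated at 0.5.
.weightedMedianEstimate <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (length(b) == 1L) return(b)
  stats::approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted 50th percentile of the per-SNP Wald ratios, with
#' weights \code{(bx/seY)^2} (the first-order inverse variance of each
#' ratio) normalised to sum to one; consistent when at least half the
#' weight comes from valid instruments. The standard error comes from a
#' parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred at the observed values with their
#' reported SEs, the estimate recomputed, and the SD over \code{nBoot}
#' draws taken.
#'
#' @param data A [HarmonizedData-class] with at least 3 retained rows.
#' @param nBoot Bootstrap draws (default 1000). \code{nBoot = 0} skips
#'   the bootstrap and returns the point estimate with \code{NA}
#'   uncertainty (useful when only the sign is needed).
#' @param seed Integer seed for the bootstrap (required when
#'   \code{nBoot > 0}).
#' @return An [MrEstimate-class] with method \code{weighted_median}.
#' @export
weightedMedian <- function(data, nBoot = 1000, seed = NULL) {
  r <- harmonizedRows(data)
  k <- nrow(r)
  if (k < 3L)
    stop("insufficient instruments for the weighted median (need >= 3)",
         call. = FALSE)
  ratios <- r$beta_outcome / r$beta_exposure
  weights <- (r$beta_exposure / r$se_outcome)^2
  est <- .weightedMedianEstimate(ratios, weights)
  if (nBoot == 0)
    return(.mrEstimate("weighted_median", est, NA_real_, k,
                       pvalue = NA_real_, ci = c(NA_real_, NA_real_)))
  boots <- .withSeed(seed, {
    bxs <- matrix(stats::rnorm(k * nBoot, r$beta_exposure,
                               r$se_exposure), nrow = k)
    bys <- matrix(stats::rnorm(k * nBoot, r$beta_outcome,
                               r$se_outcome), nrow = k)
    vapply(seq_len(nBoot), function(j)
      .weightedMedianEstimate(bys[, j] / bxs[, j],
                              (bxs[, j] / r$se_outcome)^2),
      numeric(1))
  })
  se <- stats::sd(boots)
  .mrEstimate("weighted_median", est, se, k)
}

#' Triangulation significance rule
#'
#' A univariable MR result is called significant when the IVW p-value
#' is below \code{alpha} \emph{and} the weighted-median and MR-Egger
#' slopes agree with the IVW estimate in direction. The verdict records
#' which of the three conditions held.
#'
#' @param ivwEst,wmEst [MrEstimate-class] objects from [mrIvw()] and
#'   [weightedMedian()] on the same dataset.
#' @param eggerFit [EggerFit-class] from [mrEgger()] on the same
#'   dataset.
#' @param alpha Significance level (default 0.05).
#' @return A list: \code{significant} (logical), \code{conditions}
#'   (named logical vector \code{ivw_significant},
#'   \code{wm_direction}, \code{egger_direction}), \code{ivwPvalue}.
#' @export
triangulate <- function(ivwEst, wmEst, eggerFit, alpha = 0.05) {
  conds <- c(
    ivw_significant = mrPvalue(ivwEst) < alpha,
    wm_direction = sign(mrBeta(wmEst)) == sign(mrBeta(ivwEst)),
    egger_direction =
      sign(mrBeta(eggerSlope(eggerFit))) == sign(mrBeta(ivwEst)))
  list(significant = all(conds), conditions = conds,
       ivwPvalue = mrPvalue(ivwEst))
}
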