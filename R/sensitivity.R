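#' @include AllClasses.R estimators.R
NULL

#' Cochran Q heterogeneity test
#'
#' \code{Q = sum(w (by - beta_ivw bx)^2)} with \code{w = 1/seY^2},
#' evaluated at the fixed-effect IVW slope (which minimises this
#' weighted residual sum of squares), on k - 1 degrees of freedom with
#' a chi-square upper-tail p-value. A p-value above 0.05 is read as no
#' significant heterogeneity.
#'
#' @param data A [HarmonizedData-class] with at least 2 retained rows.
#' @return A list: \code{q}, \code{df}, \code{pvalue}.
#' @export
cochranQ <- function(data) {
  r <- harmonizedRows(data)
  if (nrow(r) < 2L)
    stop("insufficient instruments for Cochran Q (need >= 2)",
         call. = FALSE)
  core <- .ivwCore(r$beta_exposure, r$beta_outcome, r$se_outcome)
  df <- core$k - 1L
  list(q = core$q, df = df,
       pvalue = stats::pchisq(core$q, df, lower.tail = FALSE))
}

#' Egger intercept pleiotropy test
#'
#' Flags directional horizontal pleiotropy when the MR-Egger intercept
#' p-value falls below \code{alpha}.
#'
#' @param fit An [EggerFit-class].
#' @param alpha Significance level (default 0.05).
#' @return A list: \code{directionalPleiotropy} (logical),
#'   \code{intercept}, \code{se}, \code{pvalue}.
#' @export
eggerInterceptTest <- function(fit, alpha = 0.05) {
  ic <- eggerIntercept(fit)
  list(directionalPleiotropy = unname(ic["pvalue"]) < alpha,
       intercept = unname(ic["estimate"]), se = unname(ic["se"]),
       pvalue = unname(ic["pvalue"]))
}

## Leave-one-out fixed-effect IVW slopes in O(k) via sum updates.
.looSlopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global and outlier tests
#'
#' Simulation-based pleiotropy residual test. The observed statistic is
#' the weighted residual sum of squares with leave-one-out IVW
#' predictions, \code{RSS = sum_j w_j (by_j - beta_(-j) bx_j)^2}. A
#' null distribution is built by simulating, \code{nSim} times,
#' exposure effects around their observed values and outcome effects
#' around the leave-one-out predictions (both at the reported SEs) and
#' recomputing the statistic. The global p-value is the add-one
#' smoothed proportion of simulated statistics at or above the observed
#' one. Per-SNP outlier p-values compare each SNP's observed weighted
#' squared residual with its simulated distribution, Bonferroni
#' -adjusted across the k SNPs; flagged SNPs are removed and the global
#' test re-run, returning the post-removal IVW estimate.
#'
#' @param data A [HarmonizedData-class] with at least 4 retained rows.
#' @param nSim Number of simulated datasets (default 1000).
#' @param seed Integer seed; results are bit-reproducible given
#'   (data, nSim, seed).
#' @param outlierAlpha Significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @return A list: \code{globalPvalue}; \code{outliers} (variant IDs);
#'   \code{outlierPvalues} (adjusted, named by variant);
#'   \code{rerunPvalue} (global p after outlier removal, \code{NA} when
#'   nothing was removed or too few SNPs remain);
#'   \code{correctedEstimate} ([MrEstimate-class] after removal, or
#'   \code{NULL}).
#' @export
mrPresso <- function(data, nSim = 1000, seed = NULL,
                     outlierAlpha = 0.05) {
  r <- harmonizedRows(data)
  k <- nrow(r)
  if (k < 4L)
    stop("insufficient instruments for MR-PRESSO (need >= 4)",
         call. = FALSE)
  bx <- r$beta_exposure
  by <- r$beta_outcome
  sx <- r$se_exposure
  sy <- r$se_outcome
  w <- 1 / sy^2
  bLoo <- .looSlopes(bx, by, w)
  resObs <- w * (by - bLoo * bx)^2
  rssObs <- sum(resObs)

  sim <- .withSeed(seed, {
    BX <- matrix(stats::rnorm(k * nSim, bx, sx), nrow = k)
    BY <- matrix(stats::rnorm(k * nSim, bLoo * bx, sy), nrow = k)
    SXY <- colSums(w * BX * BY)
    SXX <- colSums(w * BX^2)
    BLOO <- (rep(SXY, each = k) - w * BX * BY) /
      (rep(SXX, each = k) - w * BX^2)
    RES <- w * (BY - BLOO * BX)^2
    list(rss = colSums(RES),
         exceed = rowSums(RES >= resObs))
  })
  globalP <- (sum(sim$rss >= rssObs) + 1) / (nSim + 1)
  outlierP <- pmin(1, k * (sim$exceed + 1) / (nSim + 1))
  names(outlierP) <- r$variant_id
  outliers <- r$variant_id[outlierP < outlierAlpha]

  rerunP <- NA_real_
  corrected <- NULL
  if (length(outliers)) {
    keep <- !(r$variant_id %in% outliers)
    reduced <- new("HarmonizedData", exposureId = data@exposureId,
                   outcomeId = data@outcomeId,
                   rows = r[keep, , drop = FALSE],
                   exclusions = exclusions(data))
    if (sum(keep) >= 2L)
      corrected <- mrIvw(reduced)
    if (sum(keep) >= 4L)
      rerunP <- mrPresso(reduced, nSim = nSim, seed = seed,
                         outlierAlpha = outlierAlpha)$globalPvalue
  }
  list(globalPvalue = globalP, outliers = outliers,
       outlierPvalues = outlierP, rerunPvalue = rerunP,
       correctedEstimate = corrected)
}

#' Leave-one-out analysis
#'
#' Recomputes the IVW estimate with each instrument omitted in turn,
#' plus the all-instrument estimate labelled \code{"All"}; an estimate
#' that moves materially when one SNP is dropped points at that SNP as
#' influential.
#'
#' @param data A [HarmonizedData-class] with at least 3 retained rows.
#' @param model IVW model, as in [mrIvw()].
#' @return \code{data.frame} with columns \code{variant} (the omitted
#'   variant, or \code{"All"}), \code{beta}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{pvalue}.
#' @export
leaveOneOut <- function(data,
                        model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  r <- harmonizedRows(data)
  k <- nrow(r)
  if (k < 3L)
    stop("insufficient instruments for leave-one-out (need >= 3)",
         call. = FALSE)
  one <- function(est)
    data.frame(beta = mrBeta(est), se = mrSe(est),
               ci_low = est@ciLow, ci_high = est@ciHigh,
               pvalue = mrPvalue(est))
  rows <- lapply(seq_len(k), function(j) {
    sub <- new("HarmonizedData", exposureId = data@exposureId,
               outcomeId = data@outcomeId,
               rows = r[-j, , drop = FALSE],
               exclusions = exclusions(data))
    cbind(variant = r$variant_id[j], one(mrIvw(sub, model)))
  })
  all <- cbind(variant = "All", one(mrIvw(data, model)))
  out <- rbind(do.call(rbind, rows), all)
  rownames(out) <- NULL
  out
}

#' Run the full sensitivity battery
#'
#' Cochran Q, the Egger intercept test, MR-PRESSO (when at least 4
#' instruments are available) and leave-one-out, bundled into a
#' [SensitivityReport-class].
#'
#' @param data A [HarmonizedData-class].
#' @param nSim MR-PRESSO simulation count.
#' @param seed Seed for MR-PRESSO.
#' @param alpha Significance level for the Egger intercept and PRESSO
#'   outlier tests.
#' @return A [SensitivityReport-class].
#' @export
sensitivityBattery <- function(data, nSim = 1000, seed = NULL,
                               alpha = 0.05) {
  q <- cochranQ(data)
  eg <- mrEgger(data)
  presso <- if (nVariants(data) >= 4L)
    mrPresso(data, nSim = nSim, seed = seed, outlierAlpha = alpha)
  else list(globalPvalue = NA_real_, outliers = character(),
            rerunPvalue = NA_real_)
  new("SensitivityReport", qStatistic = q$q, qDf = as.integer(q$df),
      qPvalue = q$pvalue, eggerIntercept = eg@intercept,
      eggerInterceptSe = eg@interceptSe,
      eggerInterceptPvalue = eg@interceptPvalue,
      pressoGlobalPvalue = presso$globalPvalue,
      pressoOutliers = presso$outliers,
      pressoRerunPvalue = presso$rerunPvalue,
      looEstimates = leaveOneOut(data))
}
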