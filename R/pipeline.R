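#' @include AllClasses.R mediation.R sensitivity.R
NULL

#' Assemble a pipeline configuration
#'
#' Collects inputs and thresholds for the study runners into a
#' validated list. Inputs may be in-memory objects
#' ([GwasTable-class] / [LdMatrix-class] / [SimBundle-class]) or file
#' paths understood by [readGwasTable()] / [readLdMatrix()]. The
#' configuration is echoed verbatim into every report's metadata so a
#' run is fully auditable.
#'
#' @param exposure,outcome Exposure and outcome inputs.
#' @param exposures Named list of exposures (multivariable step).
#' @param mediators Named list of mediator inputs (mediation step).
#' @param ld LD input: an [LdMatrix-class] or
#'   \code{c(pairs =, positions =)} file paths.
#' @param bundle Optional [SimBundle-class]; its exposure, outcome,
#'   mediators and LD fill any of the above left \code{NULL}.
#' @param pThreshold,clumpR2,windowKb,proxyR2,palindromeMaf,alpha
#'   Analysis thresholds (defaults 5e-8, 0.001, 10000, 0.8, 0.42,
#'   0.05).
#' @param nBoot Weighted-median bootstrap draws (default 1000).
#' @param nPressoSim MR-PRESSO simulation count (default 1000).
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @param outputDir Optional directory for report files.
#' @return A \code{PipelineConfig} (classed list).
#' @export
pipelineConfig <- function(exposure = NULL, outcome = NULL,
                           exposures = NULL, mediators = NULL,
                           ld = NULL, bundle = NULL,
                           pThreshold = 5e-8, clumpR2 = 0.001,
                           windowKb = 10000, proxyR2 = 0.8,
                           palindromeMaf = 0.42, alpha = 0.05,
                           nBoot = 1000, nPressoSim = 1000,
                           seed = NULL, outputDir = NULL) {
  if (!is.null(bundle)) {
    if (is.null(exposure)) exposure <- bundle@exposure
    if (is.null(outcome)) outcome <- bundle@outcome
    if (is.null(mediators) && length(bundle@mediators))
      mediators <- bundle@mediators
    if (is.null(ld)) ld <- bundle@ld
  }
  if (is.null(seed) || is.na(seed))
    stop("pipelineConfig: a seed is mandatory", call. = FALSE)
  stopifnot(pThreshold > 0, pThreshold <= 1, clumpR2 >= 0,
            clumpR2 <= 1, windowKb > 0, proxyR2 >= 0, proxyR2 <= 1,
            palindromeMaf >= 0, palindromeMaf <= 0.5, alpha > 0,
            alpha < 1, nBoot >= 0, nPressoSim >= 1)
  structure(list(exposure = exposure, outcome = outcome,
                 exposures = exposures, mediators = mediators,
                 ld = ld, pThreshold = pThreshold, clumpR2 = clumpR2,
                 windowKb = windowKb, proxyR2 = proxyR2,
                 palindromeMaf = palindromeMaf, alpha = alpha,
                 nBoot = nBoot, nPressoSim = nPressoSim,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "PipelineConfig")
}

.resolveGwas <- function(x, what) {
  if (is(x, "GwasTable")) return(x)
  if (is.character(x) && length(x) == 1L) return(readGwasTable(x))
  stop("cannot resolve ", what,
       ": supply a GwasTable or a file path", call. = FALSE)
}

.resolveLd <- function(x) {
  if (is(x, "LdMatrix")) return(x)
  if (is.character(x) && length(x) == 2L)
    return(readLdMatrix(x[["pairs"]], x[["positions"]]))
  stop("cannot resolve LD input: supply an LdMatrix or ",
       "c(pairs =, positions =) paths", call. = FALSE)
}

.configEcho <- function(config)
  config[c("pThreshold", "clumpR2", "windowKb", "proxyR2",
           "palindromeMaf", "alpha", "nBoot", "nPressoSim", "seed")]

.estimateRow <- function(est, qPvalue = NA_real_) {
  d <- as.data.frame(est)
  d$q_pval <- qPvalue
  d
}

#' Run the univariable MR study
#'
#' Step 1 of the three-step design: instrument selection, harmonization
#' against the outcome, IVW / weighted-median / MR-Egger estimation
#' with the triangulation verdict, and the full sensitivity battery.
#' The forest-style result table carries, per method, the instrument
#' count, odds ratio with 95\% CI, p-value and the Cochran Q p-value.
#'
#' @param config A [pipelineConfig()] with \code{exposure},
#'   \code{outcome} and \code{ld} resolvable.
#' @return A [StudyReport-class]; the \code{uvmr} section holds the
#'   instrument set, harmonized data, estimate objects, verdict,
#'   [SensitivityReport-class] and the result table.
#' @export
runUvmrStudy <- function(config) {
  exposure <- .resolveGwas(config$exposure, "exposure")
  outcome <- .resolveGwas(config$outcome, "outcome")
  ld <- .resolveLd(config$ld)

  inst <- selectInstruments(exposure, ld, outcome,
                            pThreshold = config$pThreshold,
                            r2Threshold = config$clumpR2,
                            windowKb = config$windowKb,
                            proxyR2 = config$proxyR2)
  hd <- harmonize(exposure, outcome, inst@variants,
                  config$palindromeMaf)
  if (nVariants(hd) < 2L)
    stop("uvmr stage: fewer than 2 instruments survived harmonization",
         call. = FALSE)
  ivw <- mrIvw(hd)
  wm <- weightedMedian(hd, nBoot = config$nBoot, seed = config$seed)
  eg <- mrEgger(hd)
  verdict <- triangulate(ivw, wm, eg, config$alpha)
  sens <- sensitivityBattery(hd, nSim = config$nPressoSim,
                             seed = config$seed + 1L,
                             alpha = config$alpha)
  qp <- sens@qPvalue
  eggerRow <- .estimateRow(eggerSlope(eg), qp)
  forest <- rbind(.estimateRow(ivw, qp), .estimateRow(wm, qp), eggerRow)
  excl <- exclusions(hd)
  meta <- list(config = .configEcho(config),
               package_version = as.character(
                 utils::packageVersion("mrtriad")),
               exposure = traitId(exposure), outcome = traitId(outcome),
               instruments_selected = length(inst@variants),
               instruments_used = nVariants(hd),
               exclusions = as.list(table(excl$reason)),
               proxies = nrow(inst@proxies),
               f_statistic = inst@fStatistic,
               total_r2 = inst@totalR2)
  report <- new("StudyReport",
                uvmr = list(instruments = inst, harmonized = hd,
                            estimates = list(ivw = ivw,
                                             weighted_median = wm,
                                             egger = eg),
                            verdict = verdict, sensitivity = sens,
                            table = forest),
                mvmr = list(), mediation = list(), metadata = meta)
  if (!is.null(config$outputDir)) writeStudyReport(report,
                                                   config$outputDir)
  report
}

#' Run the multivariable MR study
#'
#' Step 2 of the three-step design: joint instrument assembly across
#' the exposures, multivariable IVW and multivariable MR-Egger (with
#' its intercept row), shaped as a per-exposure direct-effect table.
#'
#' @param config A [pipelineConfig()] with at least two entries in
#'   \code{exposures}, plus \code{outcome} and \code{ld}.
#' @return A [StudyReport-class] with the \code{mvmr} section filled.
#' @export
runMvmrStudy <- function(config) {
  if (is.null(config$exposures) || length(config$exposures) < 2L)
    stop("runMvmrStudy needs >= 2 exposures; ",
         "for a single exposure use runUvmrStudy()", call. = FALSE)
  exposures <- lapply(config$exposures, .resolveGwas, what = "exposure")
  outcome <- .resolveGwas(config$outcome, "outcome")
  ld <- .resolveLd(config$ld)

  dat <- assembleMvDataset(exposures, outcome, ld,
                           pThreshold = config$pThreshold,
                           r2Threshold = config$clumpR2,
                           windowKb = config$windowKb,
                           palindromeMafThreshold = config$palindromeMaf)
  ivw <- mvmrIvw(dat)
  eg <- mvmrEgger(dat)
  tab <- rbind(cbind(method = "ivw_mv", as.data.frame(ivw)),
               cbind(method = "egger_mv", as.data.frame(eg)))
  intercept <- data.frame(method = "egger_mv_intercept",
                          estimate = eg@intercept,
                          se = eg@interceptSe,
                          pvalue = eg@interceptPvalue)
  meta <- list(config = .configEcho(config),
               exposures = names(config$exposures),
               outcome = traitId(outcome),
               instruments_used = length(dat@variantIds))
  report <- new("StudyReport", uvmr = list(),
                mvmr = list(dataset = dat, ivw = ivw, egger = eg,
                            table = tab, intercept = intercept),
                mediation = list(), metadata = meta)
  if (!is.null(config$outputDir)) writeStudyReport(report,
                                                   config$outputDir)
  report
}

#' Run the two-step mediation study
#'
#' Step 3 of the three-step design. The total exposure-to-outcome
#' effect is estimated by univariable IVW on the selected instruments;
#' candidate mediators are screened for an exposure effect
#' ([screenMediators()]); for each survivor the conditional
#' mediator-to-outcome effect is estimated by multivariable IVW
#' ([mediatorToOutcome()]); survivors whose step-2 estimate is
#' significant at \code{alpha} and whose implied indirect effect shares
#' the total effect's direction enter the product-of-coefficients
#' decomposition ([mediationEffect()]). Every dropped mediator is
#' tallied in the metadata.
#'
#' @param config A [pipelineConfig()] with \code{exposure},
#'   \code{outcome}, \code{mediators} and \code{ld} resolvable.
#' @return A [StudyReport-class]; the \code{mediation} section holds
#'   the screening table, per-mediator [MediationResult-class] objects
#'   and the decomposition table.
#' @export
runMediationStudy <- function(config) {
  exposure <- .resolveGwas(config$exposure, "exposure")
  outcome <- .resolveGwas(config$outcome, "outcome")
  if (is.null(config$mediators) || !length(config$mediators))
    stop("runMediationStudy needs a mediator collection",
         call. = FALSE)
  mediators <- lapply(config$mediators, .resolveGwas,
                      what = "mediator")
  ld <- .resolveLd(config$ld)

  inst <- selectInstruments(exposure, ld, outcome,
                            pThreshold = config$pThreshold,
                            r2Threshold = config$clumpR2,
                            windowKb = config$windowKb,
                            proxyR2 = config$proxyR2)
  hd <- harmonize(exposure, outcome, inst@variants,
                  config$palindromeMaf)
  total <- mrIvw(hd)

  screen <- screenMediators(exposure, mediators, inst@variants,
                            alpha = config$alpha,
                            palindromeMafThreshold =
                              config$palindromeMaf)
  survivors <- screen$mediator_id[screen$significant]
  results <- list()
  dropped <- list(step2_failed = character(),
                  step2_not_significant = character(),
                  direction_inconsistent = character())
  for (id in survivors) {
    step2 <- tryCatch(
      mediatorToOutcome(mediators[[id]], exposure, outcome, ld,
                        pThreshold = config$pThreshold,
                        r2Threshold = config$clumpR2,
                        windowKb = config$windowKb),
      error = function(e) {
        message("mediation: step 2 failed for ", id, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(step2)) {
      dropped$step2_failed <- c(dropped$step2_failed, id)
      next
    }
    if (mrPvalue(step2) >= config$alpha) {
      dropped$step2_not_significant <-
        c(dropped$step2_not_significant, id)
      next
    }
    row <- screen[screen$mediator_id == id, ]
    indirect <- row$beta * mrBeta(step2)
    if (sign(indirect) != sign(mrBeta(total))) {
      dropped$direction_inconsistent <-
        c(dropped$direction_inconsistent, id)
      next
    }
    results[[id]] <- mediationEffect(
      total, list(beta = row$beta, se = row$se), step2,
      mediatorId = id)
  }
  medTable <- if (length(results))
    do.call(rbind, lapply(results, as.data.frame))
  else {
    message("mediation: no mediator passed both steps")
    data.frame()
  }
  rownames(medTable) <- NULL
  meta <- list(config = .configEcho(config),
               exposure = traitId(exposure), outcome = traitId(outcome),
               mediators_screened = nrow(screen),
               mediators_step1_retained = length(survivors),
               mediators_reported = length(results),
               dropped = dropped,
               instruments_used = nVariants(hd),
               exclusions = as.list(table(exclusions(hd)$reason)))
  report <- new("StudyReport", uvmr = list(total = total),
                mvmr = list(),
                mediation = list(screen = screen, results = results,
                                 table = medTable),
                metadata = meta)
  if (!is.null(config$outputDir)) writeStudyReport(report,
                                                   config$outputDir)
  report
}

#' Write a study report to disk
#'
#' Emits the table-shaped sections as TSVs (univariable forest table,
#' leave-one-out table, multivariable direct-effect table with its
#' intercept row, mediation decomposition table, mediator screening
#' table) and the metadata (configuration echo, seeds, exclusion
#' tallies, MR-PRESSO details) as JSON.
#'
#' @param report A [StudyReport-class].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create report directory: ", dir, call. = FALSE)
  written <- character()
  wtsv <- function(x, name) {
    path <- file.path(dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }
  if (length(report@uvmr) && !is.null(report@uvmr$table)) {
    wtsv(report@uvmr$table, "uvmr_forest.tsv")
    sens <- report@uvmr$sensitivity
    wtsv(sens@looEstimates, "uvmr_leave_one_out.tsv")
    presso <- list(global_pvalue = sens@pressoGlobalPvalue,
                   outliers = sens@pressoOutliers,
                   rerun_pvalue = sens@pressoRerunPvalue)
    writeLines(jsonlite::toJSON(
      list(q_statistic = sens@qStatistic, q_df = sens@qDf,
           q_pvalue = sens@qPvalue,
           egger_intercept = sens@eggerIntercept,
           egger_intercept_pvalue = sens@eggerInterceptPvalue,
           mr_presso = presso),
      auto_unbox = TRUE, pretty = TRUE, digits = NA),
      file.path(dir, "uvmr_sensitivity.json"))
    written <- c(written, file.path(dir, "uvmr_sensitivity.json"))
  }
  if (length(report@mvmr) && !is.null(report@mvmr$table)) {
    wtsv(report@mvmr$table, "mvmr_table.tsv")
    wtsv(report@mvmr$intercept, "mvmr_intercept.tsv")
  }
  if (length(report@mediation)) {
    if (!is.null(report@mediation$screen))
      wtsv(report@mediation$screen, "mediation_screen.tsv")
    if (!is.null(report@mediation$table) &&
        nrow(report@mediation$table))
      wtsv(report@mediation$table, "mediation_table.tsv")
  }
  writeLines(jsonlite::toJSON(report@metadata, auto_unbox = TRUE,
                              pretty = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "run_metadata.json"))
  written <- c(written, file.path(dir, "run_metadata.json"))
  invisible(written)
}
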