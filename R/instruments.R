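#' @include AllClasses.R
NULL

#' Filter a GWAS table to genome-wide-significant variants
#'
#' Keeps records with \code{pvalue < pThreshold} (strict inequality),
#' preserving the original row order.
#'
#' @param gwas A [GwasTable-class]; p-values must be present.
#' @param pThreshold Significance threshold (default 5e-8, genome-wide).
#' @return A [GwasTable-class] of survivors.
#' @export
selectSignificant <- function(gwas, pThreshold = 5e-8) {
  r <- gwasRecords(gwas)
  if (nrow(r) == 0L || !any(!is.na(r$pvalue) & r$pvalue < pThreshold))
    stop("no instruments reach p < ", format(pThreshold), " for trait ",
         traitId(gwas), call. = FALSE)
  gwasTable(traitId(gwas),
            r[!is.na(r$pvalue) & r$pvalue < pThreshold, , drop = FALSE])
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: candidates are sorted by ascending p-value
#' (ties broken lexicographically by variant ID); the top candidate is
#' kept and every remaining candidate on the same chromosome within
#' \code{windowKb} kilobases with squared correlation at or above
#' \code{r2Threshold} is removed, repeatedly. The retained set is
#' mutually independent: every retained pair has r-squared below the
#' threshold or lies further apart than the window (or on different
#' chromosomes). The result does not depend on the input row order.
#'
#' @param candidates A [GwasTable-class] of candidate instruments.
#' @param ld An [LdMatrix-class] covering every candidate.
#' @param r2Threshold Independence threshold on r-squared
#'   (default 0.001).
#' @param windowKb Clumping window in kilobases (default 10000).
#' @return Character vector of retained variant IDs.
#' @export
ldClump <- function(candidates, ld, r2Threshold = 0.001,
                    windowKb = 10000) {
  r <- gwasRecords(candidates)
  missing <- setdiff(r$variant_id, variantIds(ld))
  if (length(missing))
    stop("candidates absent from the LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ord <- order(r$pvalue, r$variant_id)
  r <- r[ord, , drop = FALSE]
  lidx <- match(r$variant_id, variantIds(ld))
  pos <- ld@positions[lidx]
  chr <- r$chromosome
  alive <- rep(TRUE, nrow(r))
  kept <- character(0)
  for (i in seq_len(nrow(r))) {
    if (!alive[i]) next
    kept <- c(kept, r$variant_id[i])
    later <- which(alive & seq_len(nrow(r)) > i)
    if (!length(later)) next
    sameChr <- !is.na(chr[later]) & !is.na(chr[i]) & chr[later] == chr[i]
    ## variants with unknown chromosome are conservatively treated as
    ## potentially linked to everything
    sameChr[is.na(chr[later]) | is.na(chr[i])] <- TRUE
    near <- sameChr & abs(pos[later] - pos[i]) <= windowKb * 1000
    linked <- ld@r2[lidx[later], lidx[i]] >= r2Threshold
    alive[later[near & linked]] <- FALSE
  }
  kept
}

#' Find an LD proxy present in the outcome
#'
#' Among variants present in both the LD matrix and the outcome table
#' with squared correlation strictly above \code{minR2} with the target
#' variant, returns the one with maximal r-squared (ties broken
#' lexicographically), or \code{NULL} when none qualifies — the caller
#' then drops the instrument.
#'
#' @param variant Variant ID needing a proxy.
#' @param outcome [GwasTable-class] the proxy must be present in.
#' @param ld [LdMatrix-class] containing \code{variant}.
#' @param minR2 Strict lower bound on proxy r-squared (default 0.8).
#' @return \code{list(proxy =, r2 =)} or \code{NULL}.
#' @export
findProxy <- function(variant, outcome, ld, minR2 = 0.8) {
  ids <- variantIds(ld)
  if (!variant %in% ids)
    stop("variant ", variant, " absent from the LD matrix",
         call. = FALSE)
  r2 <- ld@r2[, match(variant, ids)]
  ok <- ids %in% variantIds(outcome) & r2 > minR2
  if (!any(ok)) return(NULL)
  cand <- ids[ok]
  cr2 <- unname(r2[ok])
  best <- order(-cr2, cand)[1]
  list(proxy = cand[best], r2 = cr2[best])
}

#' Variance in the exposure explained by one variant
#'
#' Computes \code{2 eaf (1-eaf) beta^2 / (2 eaf (1-eaf) beta^2 +
#' 2 eaf (1-eaf) n se^2)}, which algebraically simplifies to
#' \code{beta^2 / (beta^2 + n se^2)} — the allele-frequency factor
#' cancels.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param n GWAS sample size.
#' @return Proportion of variance explained, in [0, 1).
#' @export
varianceExplained <- function(beta, se, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1))
    stop("degenerate allele frequency: eaf must lie strictly in (0, 1)",
         call. = FALSE)
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * n * se^2)
}

#' Instrument-strength F-statistic
#'
#' \code{F = R2 (n - k - 1) / (k (1 - R2))} for k instruments jointly
#' explaining a proportion \code{totalR2} of the exposure variance in a
#' sample of size n. Values below 10 conventionally flag weak
#' instruments.
#'
#' @param totalR2 Total variance explained, in [0, 1).
#' @param n Exposure GWAS sample size; must exceed \code{k + 1}.
#' @param k Number of instruments.
#' @return The F-statistic.
#' @export
fStatistic <- function(totalR2, n, k) {
  if (totalR2 < 0 || totalR2 >= 1)
    stop("totalR2 must lie in [0, 1)", call. = FALSE)
  if (n <= k + 1)
    stop("insufficient sample size: need n > k + 1", call. = FALSE)
  totalR2 * (n - k - 1) / (k * (1 - totalR2))
}

#' Select instruments for an exposure
#'
#' Full instrument-selection path: significance filtering
#' ([selectSignificant()]), greedy LD clumping ([ldClump()]), optional
#' LD-proxy substitution for instruments missing from the outcome
#' ([findProxy()]; instruments with no qualifying proxy are kept and
#' left for [harmonize()] to record as \code{missing_in_outcome}), and
#' strength diagnostics (per-variant and total R-squared,
#' F-statistic). A message flags weak instruments (F < 10).
#'
#' @param exposure [GwasTable-class] for the exposure.
#' @param ld [LdMatrix-class] covering the candidates.
#' @param outcome Optional [GwasTable-class]; when supplied, proxies are
#'   sought for clumped instruments absent from it.
#' @param pThreshold,r2Threshold,windowKb,proxyR2 Selection thresholds
#'   (defaults 5e-8, 0.001, 10000 kb, 0.8).
#' @return An [InstrumentSet-class].
#' @export
selectInstruments <- function(exposure, ld, outcome = NULL,
                              pThreshold = 5e-8, r2Threshold = 0.001,
                              windowKb = 10000, proxyR2 = 0.8) {
  sig <- selectSignificant(exposure, pThreshold)
  variants <- ldClump(sig, ld, r2Threshold, windowKb)
  proxies <- data.frame(original = character(), proxy = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  if (!is.null(outcome)) {
    absent <- setdiff(variants, variantIds(outcome))
    for (v in absent) {
      hit <- findProxy(v, outcome, ld, proxyR2)
      if (!is.null(hit) && hit$proxy %in% variantIds(exposure)) {
        variants[variants == v] <- hit$proxy
        proxies <- rbind(proxies,
                         data.frame(original = v, proxy = hit$proxy,
                                    r2 = hit$r2))
      }
    }
    variants <- unique(variants)
  }
  r <- gwasRecords(exposure)
  r <- r[match(variants, r$variant_id), , drop = FALSE]
  perR2 <- ifelse(!is.na(r$eaf) & r$eaf > 0 & r$eaf < 1 & !is.na(r$n),
                  r$beta^2 / (r$beta^2 + r$n * r$se^2), NA_real_)
  totalR2 <- if (all(is.na(perR2))) NA_real_ else
    sum(perR2, na.rm = TRUE)
  k <- length(variants)
  fstat <- if (is.na(totalR2)) NA_real_ else {
    nMed <- stats::median(r$n, na.rm = TRUE)
    fStatistic(totalR2, nMed, k)
  }
  if (!is.na(fstat) && fstat < 10)
    message("selectInstruments: F = ", signif(fstat, 4),
            " < 10, weak instruments for ", traitId(exposure))
  new("InstrumentSet", exposureId = traitId(exposure),
      variants = variants, perVariantR2 = perR2, totalR2 = totalR2,
      fStatistic = fstat, proxies = proxies)
}

#' Read / write an LD matrix in long format
#'
#' The long format is a 3-column TSV (\code{id_a}, \code{id_b},
#' \code{r2}) listing pairs with nonzero r-squared (the diagonal may be
#' omitted; unlisted pairs are 0), plus a positions TSV
#' (\code{variant_id}, \code{position}) fixing the variant order and
#' base-pair coordinates.
#'
#' @param pairsPath,positionsPath Paths to the two TSVs.
#' @return An [LdMatrix-class].
#' @export
readLdMatrix <- function(pairsPath, positionsPath) {
  pos <- utils::read.table(positionsPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ids <- as.character(pos$variant_id)
  k <- length(ids)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  pairs <- utils::read.table(pairsPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    ia <- match(as.character(pairs$id_a), ids)
    ib <- match(as.character(pairs$id_b), ids)
    ok <- !is.na(ia) & !is.na(ib)
    m[cbind(ia[ok], ib[ok])] <- pairs$r2[ok]
    m[cbind(ib[ok], ia[ok])] <- pairs$r2[ok]
  }
  diag(m) <- 1
  ldMatrix(ids, m, pos$position)
}

#' @rdname readLdMatrix
#' @param ld An [LdMatrix-class] to write.
#' @export
writeLdMatrix <- function(ld, pairsPath, positionsPath) {
  ids <- variantIds(ld)
  k <- length(ids)
  ut <- which(upper.tri(ld@r2) & ld@r2 > 0, arr.ind = TRUE)
  pairs <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                      r2 = ld@r2[ut])
  utils::write.table(pairs, pairsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(variant_id = ids,
                                position = ld@positions),
                     positionsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pairsPath, positionsPath))
}
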