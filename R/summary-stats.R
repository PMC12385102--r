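#' @include AllClasses.R
NULL

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (tab or comma separated, with a header)
#' into a [GwasTable-class]. Column names are mapped onto the standard
#' fields through \code{columnMap}; the default map matches common GWAS
#' summary-statistic exports (SNP, CHR, BP, EA, OA, EAF, BETA, SE, P,
#' N). Rows whose beta or standard error cannot be parsed as numbers
#' are dropped, and the number dropped is reported with a message.
#'
#' @param path Path to the file.
#' @param columnMap Named character vector mapping standard field names
#'   (\code{variant_id}, \code{chromosome}, \code{position},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}, \code{pvalue}, \code{n}) to source column names.
#'   Optional fields absent from the map or the file become \code{NA}.
#' @param traitId Trait identifier; defaults to the file name without
#'   extension.
#' @return A [GwasTable-class].
#' @export
readGwasTable <- function(path, columnMap = .DEFAULT_COLUMN_MAP,
                          traitId = sub("\\.[^.]*$", "", basename(path))) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  columnMap <- as.list(columnMap)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta",
                 "se", "pvalue")
  for (f in mandatory) {
    src <- columnMap[[f]]
    if (is.null(src) || !src %in% names(raw))
      stop("mandatory column for field '", f, "' (source name '",
           if (is.null(src)) "<unmapped>" else src,
           "') is missing from ", path, call. = FALSE)
  }
  if (nrow(raw) == 0L)
    stop("empty summary-statistic table: ", path, call. = FALSE)
  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in .GWAS_FIELDS) {
    src <- columnMap[[f]]
    rec[[f]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]]
                else NA
  }
  numf <- c("position", "eaf", "beta", "se", "pvalue", "n")
  for (f in numf)
    rec[[f]] <- suppressWarnings(as.numeric(rec[[f]]))
  bad <- is.na(rec$beta) | is.na(rec$se) | rec$se <= 0
  if (any(bad)) {
    message("readGwasTable: dropped ", sum(bad),
            " row(s) with unparsable beta/se in ", basename(path))
    rec <- rec[!bad, , drop = FALSE]
  }
  if (nrow(rec) == 0L)
    stop("no parsable rows in summary-statistic table: ", path,
         call. = FALSE)
  gwasTable(traitId, rec)
}

#' Write a GwasTable to a delimited file
#'
#' Emits the same dialect [readGwasTable()] reads by default: a
#' tab-separated table with header columns SNP, CHR, BP, EA, OA, EAF,
#' BETA, SE, P, N, so that a write/read round trip is the identity.
#'
#' @param x A [GwasTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGwasTable <- function(x, path) {
  r <- gwasRecords(x)
  out <- r
  names(out) <- .DEFAULT_COLUMN_MAP[names(r)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are each
#' other's complement: A/T or C/G. Multi-character alleles (indels) are
#' never palindromic.
#'
#' @param effectAllele,otherAllele Allele strings (vectorised).
#' @return Logical vector.
#' @examples
#' isPalindromic("A", "T")   # TRUE
#' isPalindromic("A", "G")   # FALSE
#' isPalindromic("AT", "T")  # FALSE (indel)
#' @export
isPalindromic <- function(effectAllele, otherAllele) {
  single <- nchar(effectAllele) == 1L & nchar(otherAllele) == 1L
  single & .complementAllele(effectAllele) == otherAllele
}

#' Harmonize outcome effects onto the exposure's effect alleles
#'
#' Aligns the outcome associations of a set of instruments so both betas
#' are signed to the exposure's effect allele. Outcome rows whose
#' alleles match the exposure's are kept as-is; swapped rows have their
#' beta negated; rows matching only after strand complementation are
#' accepted (complement-swapped rows are negated); anything else is
#' excluded as \code{allele_mismatch}. Palindromic SNPs with
#' intermediate allele frequency (minor-allele frequency above
#' \code{palindromeMafThreshold} on the exposure side) are excluded as
#' \code{palindromic_intermediate}, as are palindromic SNPs whose
#' exposure frequency is missing (their orientation cannot be inferred);
#' palindromic SNPs with extreme frequencies are retained and oriented
#' by frequency agreement. Instruments absent from the outcome are
#' excluded as \code{missing_in_outcome} (LD-proxy substitution, when
#' wanted, happens upstream via [findProxy()]).
#'
#' @param exposure,outcome [GwasTable-class] objects.
#' @param instruments Variant IDs to harmonize; must be a subset of the
#'   exposure's variants. Defaults to all exposure variants.
#' @param palindromeMafThreshold Minor-allele-frequency cutoff above
#'   which a palindromic SNP is considered ambiguous (default 0.42, so
#'   SNPs with effect-allele frequency in (0.42, 0.58) are dropped).
#' @return A [HarmonizedData-class]; every instrument appears exactly
#'   once, in \code{harmonizedRows()} or \code{exclusions()}.
#' @examples
#' ex <- gwasTable("X", data.frame(
#'   variant_id = "rs1", effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 1e-10))
#' out <- gwasTable("Y", data.frame(
#'   variant_id = "rs1", effect_allele = "G", other_allele = "A",
#'   eaf = 0.7, beta = -0.05, se = 0.01, pvalue = 1e-4))
#' harmonizedRows(harmonize(ex, out))$beta_outcome  # +0.05
#' @export
harmonize <- function(exposure, outcome,
                      instruments = variantIds(exposure),
                      palindromeMafThreshold = 0.42) {
  ex <- gwasRecords(exposure)
  if (!all(instruments %in% ex$variant_id))
    stop("instruments must be a subset of the exposure's variants",
         call. = FALSE)
  ex <- ex[match(instruments, ex$variant_id), , drop = FALSE]
  out <- gwasRecords(outcome)
  oidx <- match(instruments, out$variant_id)

  n <- length(instruments)
  keep <- logical(n)
  flip <- logical(n)
  reason <- rep(NA_character_, n)

  present <- !is.na(oidx)
  reason[!present] <- "missing_in_outcome"

  eEA <- ex$effect_allele
  eOA <- ex$other_allele
  oEA <- out$effect_allele[oidx]
  oOA <- out$other_allele[oidx]
  cEA <- .complementAllele(oEA)
  cOA <- .complementAllele(oOA)

  same <- present & oEA == eEA & oOA == eOA
  swapped <- present & !same & oEA == eOA & oOA == eEA
  compSame <- present & !same & !swapped & cEA == eEA & cOA == eOA
  compSwapped <- present & !same & !swapped & !compSame &
    cEA == eOA & cOA == eEA
  matched <- same | swapped | compSame | compSwapped
  reason[present & !matched] <- "allele_mismatch"

  pal <- isPalindromic(eEA, eOA)
  maf <- pmin(ex$eaf, 1 - ex$eaf)
  palDrop <- pal & matched & (is.na(ex$eaf) | maf > palindromeMafThreshold)
  reason[palDrop] <- "palindromic_intermediate"

  keep <- matched & !palDrop
  flip <- swapped | compSwapped

  ## Retained palindromes: orient by frequency agreement. The nominal
  ## orientation's aligned outcome frequency must sit on the same side
  ## of 0.5 as the exposure frequency; otherwise the strands disagree
  ## and the sign is flipped once more.
  palKeep <- which(pal & keep)
  if (length(palKeep)) {
    eafOut <- out$eaf[oidx[palKeep]]
    aligned <- ifelse(flip[palKeep], 1 - eafOut, eafOut)
    disagree <- !is.na(aligned) &
      (ex$eaf[palKeep] - 0.5) * (aligned - 0.5) < 0
    flip[palKeep] <- xor(flip[palKeep], disagree)
  }

  rows <- data.frame(
    variant_id = instruments[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = ifelse(flip[keep], -1, 1) * out$beta[oidx[keep]],
    se_outcome = out$se[oidx[keep]],
    eaf_exposure = ex$eaf[keep],
    stringsAsFactors = FALSE)
  excl <- data.frame(variant_id = instruments[!keep],
                     reason = reason[!keep],
                     stringsAsFactors = FALSE)
  rownames(rows) <- rownames(excl) <- NULL
  new("HarmonizedData", exposureId = traitId(exposure),
      outcomeId = traitId(outcome), rows = rows, exclusions = excl)
}

#' Write a harmonized dataset (TSV plus exclusions sidecar)
#'
#' @param x A [HarmonizedData-class].
#' @param path Output path for the retained rows; exclusions go to
#'   \code{<path minus extension>_exclusions.tsv}.
#' @return Paths written, invisibly.
#' @export
writeHarmonized <- function(x, path) {
  utils::write.table(harmonizedRows(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- paste0(sub("\\.[^.]*$", "", path), "_exclusions.tsv")
  utils::write.table(exclusions(x), side, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, side))
}
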