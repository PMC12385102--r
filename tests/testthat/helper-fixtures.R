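# Shared fixture builders. Everything is generated in code; no data
# files ship with the tests beyond what writeFixtureSuite() emits into
# tempdirs.

makeHarmonized <- function(bx, by, seY, seX = rep(0.01, length(bx)),
                           ids = sprintf("s%02d", seq_along(bx))) {
  new("HarmonizedData", exposureId = "X", outcomeId = "Y",
      rows = data.frame(variant_id = ids, beta_exposure = bx,
                        se_exposure = seX, beta_outcome = by,
                        se_outcome = seY, eaf_exposure = 0.3,
                        stringsAsFactors = FALSE),
      exclusions = data.frame(variant_id = character(),
                              reason = character(),
                              stringsAsFactors = FALSE))
}

# Loop-based interpolated weighted-quantile oracle, independent of the
# vectorised implementation under test.
wmOracle <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  j <- which(s >= 0.5)[1]
  b[j - 1] + (0.5 - s[j - 1]) * (b[j] - b[j - 1]) / (s[j] - s[j - 1])
}

# Correlated three-exposure multivariable dataset with known direct
# effects; exposures share a common factor (pairwise correlation about
# 0.5 between true SNP effects). Noise scales match the package's
# default study conditions.
makeMvData <- function(k = 67, direct = c(0.12, 0.17, -0.2),
                       seX = 0.006, seY = 0.02, gammaSd = 0.06,
                       noiseless = FALSE) {
  m <- length(direct)
  shared <- rnorm(k, 0, gammaSd / sqrt(2))
  G <- shared + matrix(rnorm(k * m, 0, gammaSd / sqrt(2)), k, m)
  if (noiseless) {
    BX <- G
    BY <- drop(G %*% direct)
  } else {
    BX <- G + matrix(rnorm(k * m, 0, seX), k, m)
    BY <- drop(G %*% direct) + rnorm(k, 0, seY)
  }
  new("MvDataset", exposureIds = paste0("E", seq_len(m)),
      variantIds = sprintf("s%03d", seq_len(k)),
      betaExposure = BX,
      seExposure = matrix(seX, k, m),
      betaOutcome = BY, seOutcome = rep(seY, k),
      provenance = rep("E1", k))
}

toyHarmonizationPair <- function() {
  dir <- tempfile("fixtures")
  writeFixtureSuite(dir)
  list(exposure = readGwasTable(file.path(dir,
                                          "harmonization_exposure.tsv")),
       outcome = readGwasTable(file.path(dir,
                                         "harmonization_outcome.tsv")),
       dir = dir)
}
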