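## Internal numerical helpers shared by the estimator, sensitivity and
## multivariable modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. All stochastic operations in
## the package route their randomness through this helper so that a
## single integer seed makes them bit-reproducible.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required for stochastic operations", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Closed-form weighted least squares. X: n x p design, y: response,
## w: positive weights. Returns coefficients, their unscaled standard
## errors (i.e. treating the weights as exact inverse variances), the
## weighted residual sum of squares and residual df. The caller decides
## how to handle over/under-dispersion; lm() is deliberately avoided so
## Monte-Carlo loops stay cheap (agreement with lm() is asserted in the
## test suite).
.wlsFit <- function(X, y, w) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  A <- XtW %*% X
  V <- tryCatch(solve(A), error = function(e)
    stop("design matrix is rank deficient (collinear exposures?)",
         call. = FALSE))
  coef <- unname(drop(V %*% (XtW %*% y)))
  res <- y - drop(X %*% coef)
  rss <- sum(w * res^2)
  df <- length(y) - ncol(X)
  list(coef = coef, se_unscaled = unname(sqrt(diag(V))), rss = rss,
       df = df, residuals = res)
}

## Multiplicative random-effects scale: residual SD bounded below at 1
## so standard errors are inflated under overdispersion but never
## deflated under apparent underdispersion.
.mreScale <- function(rss, df) {
  if (df <= 0) return(1)
  max(1, sqrt(rss / df))
}

.ci95 <- function(beta, se) c(beta - stats::qnorm(0.975) * se,
                              beta + stats::qnorm(0.975) * se)

.pNorm2 <- function(beta, se) 2 * stats::pnorm(-abs(beta) / se)

.pT2 <- function(beta, se, df) 2 * stats::pt(-abs(beta) / se, df = df)

## Standardised field order of a summary-statistic table.
.GWAS_FIELDS <- c("variant_id", "chromosome", "position", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pvalue", "n")

.DEFAULT_COLUMN_MAP <- c(variant_id = "SNP", chromosome = "CHR",
                         position = "BP", effect_allele = "EA",
                         other_allele = "OA", eaf = "EAF", beta = "BETA",
                         se = "SE", pvalue = "P", n = "N")

.complementAllele <- function(a) chartr("ACGT", "TGCA", a)
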