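---
title: "Methods: three-step Mendelian randomization in mrtriad"
author: "mrtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-step Mendelian randomization in mrtriad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriad)
```

# The model

Two-sample Mendelian randomization treats genetic variants as
instruments for a modifiable exposure. For SNP $j$, let
$\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association with the exposure
and $\beta_{Yj}$ (SE $\sigma_{Yj}$) its association with the outcome,
estimated in non-overlapping samples, both on the log-odds scale for
binary traits. Under the instrumental-variable assumptions (relevance,
independence of confounders, no pathway to the outcome other than the
exposure), each ratio $\beta_{Yj}/\beta_{Xj}$ estimates the same causal
effect $\theta$, and the package's estimators are different ways of
pooling those ratios that fail differently when the third assumption
(no horizontal pleiotropy) is violated:

* **IVW** fits $\beta_{Yj} = \theta\,\beta_{Xj}$ through the origin
  with weights $w_j = 1/\sigma_{Yj}^2$. It is the most efficient
  estimator and the headline one, but assumes all instruments valid.
* **MR-Egger** frees the intercept, $\beta_{Yj} = \mu +
  \theta\,\beta_{Xj}$, after orienting every row so
  $\beta_{Xj} \ge 0$. Under the InSIDE assumption (pleiotropic effects
  independent of instrument strength), $\mu$ estimates average
  directional pleiotropy and the slope is pleiotropy-adjusted.
* The **weighted median** is the interpolated weighted 50th percentile
  of the ratios, with weights $(\beta_{Xj}/\sigma_{Yj})^2$; it is
  consistent when at least half the weight sits on valid instruments.

A univariable result is declared significant only by **triangulation**:
IVW $p < \alpha$ *and* the weighted-median and Egger slopes share
IVW's sign. The mediator screen applies the same rule.

**Multivariable MR** regresses $\beta_{Yj}$ on the $m$ columns of
exposure effects jointly (no intercept; Egger variant adds one after
orienting rows on a chosen exposure), giving each exposure's direct
effect conditional on the others — the tool for separating correlated
exposures such as diabetes subtypes, and for step 2 of mediation.

**Two-step mediation** combines three estimates: the total effect
$\beta_{XZ}$ (univariable IVW), the exposure-to-mediator effect
$\beta_{XY}$ (univariable IVW on the exposure's instruments), and the
conditional mediator-to-outcome effect $\beta_{YZ}$ (the mediator's
coefficient in a multivariable IVW of the outcome on mediator and
exposure). The indirect effect is the product
$\beta_{XY}\beta_{YZ}$, with delta-method SE
$\sqrt{\beta_{YZ}^2\mathrm{SE}_{XY}^2 +
\beta_{XY}^2\mathrm{SE}_{YZ}^2}$, and the mediated proportion is
$100\,\beta_{XY}\beta_{YZ}/\beta_{XZ}$ percent. The proportion's CI is
also delta-method, treating the total as independent of the product;
this is one of several defensible interval constructions (bootstrap
and Fieller-type intervals exist), and the output labels the method so
downstream users know which was used. The identity
$\text{proportion}\times\text{total} = 100\times\text{indirect}$
holds exactly at the point-estimate level by construction.

```{r}
mediationEffect(c(0.11, 0.033), c(-0.13, 0.041), c(-0.09, 0.033))
```

# Instrument selection and harmonization

Defaults follow the field's conventions, and each is a tunable
argument:

| parameter | default | meaning |
|---|---|---|
| `pThreshold` | 5e-8 | genome-wide significance filter (strict `<`) |
| `r2Threshold` | 0.001 | clumping independence bound on $r^2$ |
| `windowKb` | 10000 | clumping window, kilobases |
| `proxyR2` | 0.8 | strict lower bound for an LD proxy |
| `palindromeMaf` | 0.42 | palindromic ambiguity cutoff on MAF |
| `alpha` | 0.05 | significance level throughout |

Clumping is greedy by ascending p-value (PLINK's convention), with
ties broken lexicographically by variant ID so the result is
independent of input row order; a pair is dependent when it shares a
chromosome, lies within the window, *and* has $r^2$ at or above the
threshold. The LD matrix is an explicit input (file or simulator) —
the package never downloads a reference panel.

Harmonization signs both betas to the exposure's effect allele:
matching alleles pass, swapped alleles negate the outcome beta, and
strand-complement (and complement-swapped) matches are accepted. That
last point is an interpretive choice: summary files rarely state
strand, and refusing complements would discard recoverable SNPs; the
cost is a small mis-orientation risk for mislabelled non-palindromic
SNPs. Palindromic SNPs (A/T, C/G) are genuinely strand-ambiguous, so
they are dropped when the exposure-side minor-allele frequency exceeds
0.42 (i.e. EAF in (0.42, 0.58)) — the "intermediate frequency" reading
under which frequency alignment is unreliable — and otherwise retained
and oriented by frequency agreement. A palindromic SNP with missing
EAF cannot be oriented and is excluded under the same label. Every
instrument lands in exactly one of the retained rows or the exclusion
record, so accounting is audit-complete.

Instrument strength uses the summary-data identity
$R^2_j = \beta_j^2/(\beta_j^2 + N\sigma_j^2)$ (the
$2\,\mathrm{EAF}(1-\mathrm{EAF})$ factors cancel; both forms are
computed and tested for agreement) and
$F = R^2(N-k-1)/(k(1-R^2))$, flagging $F < 10$.

# Sensitivity battery

* **Cochran Q** at the fixed-effect IVW slope (which minimises the
  weighted RSS), $k-1$ df, chi-square upper tail.
* **Egger intercept test**: directional pleiotropy flagged at
  $p < \alpha$ (t, $k-2$ df).
* **MR-PRESSO**: observed statistic
  $\sum_j w_j(\beta_{Yj} - \hat\theta_{(-j)}\beta_{Xj})^2$ with
  leave-one-out IVW predictions; the null distribution is built by
  simulating exposure effects around their observed values and
  outcome effects around the leave-one-out predictions at the
  reported SEs. Empirical p-values carry add-one smoothing
  ($(c+1)/(n_{\mathrm{sim}}+1)$) so they are never exactly zero.
  Outlier p-values are per-SNP tail probabilities,
  Bonferroni-adjusted across SNPs; flagged SNPs are removed, the
  global test re-run, and the post-removal IVW reported. The
  distortion test of the original procedure is out of scope. The
  simulation count (default 1000) trades p-value resolution against
  runtime.
* **Leave-one-out**: one IVW per omitted SNP plus the all-SNP "All"
  row.

All stochastic routines take an explicit integer seed and restore the
caller's RNG state, so every report is bit-reproducible from
(inputs, configuration, seed).

# The synthetic generator

`simulateTwoSample()` draws, per SNP: a true exposure effect
$\gamma_j \sim N(0, \sigma_\gamma^2)$ redrawn until detectable at
genome-wide significance given that SNP's exposure SE (instruments
are, by construction, the kind that pass the significance filter); an
optional pleiotropic offset $\alpha_j$ carried by a configurable
fraction of SNPs; and observed effects
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j +
\mathrm{sign}(\gamma_j)\,\alpha_j, \sigma_{Yj}^2)$ with independent
noise (two non-overlapping samples). Pleiotropic offsets enter on the
exposure-increasing allele orientation: with randomly signed effect
alleles, "directional" pleiotropy is only well defined relative to the
allele that raises the exposure — which is also the orientation
MR-Egger fits under; applied to raw reported alleles the offsets would
cancel in expectation and the Egger intercept would have nothing to
recover. `simulateMediationTriangle()` adds a mediator with step
effects $\phi$ (on the exposure's instruments) and $\psi$ (to the
outcome, through mediator-specific instruments the exposure does not
touch), enforcing $\theta = \text{direct} + \phi\psi$, plus decoy
mediator traits for screening calibration. `simulateLdBlocks()` builds
deterministic block-diagonal $r^2$ structure for clumping and proxy
tests.

Default study conditions (chosen once, as what a practitioner would
call realistic for a biobank exposure, a rare-outcome GWAS and
flow-cytometry mediator traits): $\theta = 0.11$ (odds ratio
$\approx 1.12$), $k = 67$ instruments, $\sigma_\gamma = 0.06$,
exposure SE scale 0.006 (instrument z-scores roughly 10–16), outcome
SE scale 0.02 (total-effect SE $\approx 0.033$), mediator SE scale
0.022 (step-1 SE $\approx 0.04$),
triangle $\phi = -0.13$, $\psi = -0.09$, direct $= 0.0983$ so the
implied total is 0.11, and 730 decoys for a 731-trait screen. EAFs
are uniform(0.05, 0.95) and per-SNP SEs vary within ±20% of their
scales.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: realistic allele-frequency
spectra and their coupling to effect sizes, sample overlap between
cohorts, winner's curse in the exposure effects, assortative mating or
dynastic effects, and real LD (blocks are idealised constants). The
log-odds scale is treated as linear throughout, the standard
summary-data approximation for binary traits; non-collapsibility of
the odds ratio is outside the model.

# Numerical choices

* Weighted least squares is solved in closed form
  ($X^\top W X$ inversion); agreement with `lm()` is asserted in the
  test suite. Rank deficiency raises a collinearity error rather than
  silently dropping a column.
* Multiplicative random-effects scaling is bounded below at 1:
  standard errors inflate under overdispersion and never deflate.
  IVW uses $k-1$ residual df, Egger $k-2$, multivariable fits
  $k-m(-1)$.
* p-values are two-sided normal for IVW, weighted median and
  multivariable IVW, and two-sided t for Egger slope and intercept
  (univariable $k-2$ df; multivariable residual df), matching the
  reference implementations' behaviour.
* The weighted median interpolates cumulative weights
  $s_j = \sum_{i\le j} w_i - w_j/2$ at 0.5, clamping to the extreme
  ratios when all mass lies on one side; its bootstrap SE resamples
  both exposure and outcome effects parametrically.
* Degenerate inputs fail loudly: zero exposure effect in a Wald
  ratio, fewer rows than each method's minimum (2 for IVW/Q, 3 for
  Egger/median/leave-one-out, 4 for MR-PRESSO, $m+1$ / $m+2$ for
  multivariable fits), allele frequencies at 0 or 1 in $R^2$, zero
  total effect in the mediated proportion.
* Empirical (simulation) p-values use add-one smoothing; exact-zero
  p-values are clamped to the smallest positive double so validity
  invariants ($p \in (0,1]$) hold.

# Design decisions

* **Screening rule.** The mediator screen applies the triangulation
  rule (not IVW-p alone), with no multiplicity correction by default —
  this is an exploratory screen and correction is deliberately left
  off, though a Benjamini–Hochberg option exists. An IVW-only mode is
  a flag.
* **Step-2 instruments** are the jointly clumped union of the
  mediator's and the exposure's genome-wide-significant SNPs, keyed on
  the minimum p across traits — the same machinery as the
  multivariable module, keeping the two steps consistent.
* **Mediation reporting** keeps survivors whose step-2 estimate is
  significant and whose implied indirect effect shares the total
  effect's direction (a mediator, not a suppressor); dropped
  candidates are tallied by reason in the run metadata.
* **Joint clumping** for multivariable assembly keys on the minimum
  p-value across exposures; the reference allele set is the first
  exposure's. Estimates are invariant to exposure order up to labels
  (tested).
* **Conditional instrument strength** for multivariable fits is a
  reported diagnostic, never a gate — gating would silently change
  results.
* **No shell CLI.** The package is driven from R, like the MR
  packages practitioners already use; `pipelineConfig()` plus the
  three `run*Study()` functions are the orchestration surface, and
  the acceptance script is the only Rscript entry point.
* **Proxy substitution** happens at instrument-selection time
  (`selectInstruments()`), upstream of harmonization, so
  `harmonize()` stays a pure allele-alignment operation and its
  exclusion record stays interpretable.

# Problem sizes in the test suite

The suite's Monte-Carlo checks run at: 1000 replicates for IVW null
calibration and Q uniformity, 200 for MR-PRESSO calibration and
planted-outlier detection (simulation count 1000, 31 SNPs), 500 for
univariable parameter recovery and mediation-proportion recovery, 300
for multivariable recovery, and one 731-trait screening pass. These
sizes keep Monte-Carlo error well inside the asserted tolerances
(which are stated as multiples of the empirical Monte-Carlo SE or
pre-registered binomial bands) while completing in minutes on one
core.

# Known limitations

* First-order Wald-ratio SEs and delta-method mediation intervals;
  no Fieller or bootstrap intervals for ratios of estimates.
* No Steiger directionality filtering, mode-based estimators,
  MR-RAPS, MVMR-median/Lasso, or the MR-PRESSO distortion test.
* Harmonization matches variants by ID only (both source databases
  key on rsID); no positional matching, liftover, GWAS-VCF parsing or
  multi-allelic decomposition.
* LD handling consumes a user-supplied or simulated $r^2$ matrix; the
  package does not compute LD from genotypes.
* The mediated-proportion CI method is a stated choice, not the only
  one; exact replication of any particular published interval is not
  attempted.
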