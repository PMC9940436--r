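#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

.recordCols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")

#' GWAS summary statistics for one trait
#'
#' One row per variant: rsID, chromosome, 1-based position, effect/other
#' allele, effect-allele frequency, per-allele association (log-odds for
#' binary traits, SD units for continuous traits), standard error, p-value
#' and sample size. The audit slot accumulates one row per filtering decision
#' (snp_id, action, reason).
#'
#' @slot trait trait name.
#' @slot traitType "binary" or "continuous"; fixes the scale of `beta`.
#' @slot ancestry ancestry label (metadata only).
#' @slot records data.frame of variant records.
#' @slot audit data.frame audit trail of dropped/kept decisions.
#' @exportClass SummaryDataset
setClass("SummaryDataset",
  representation(trait = "character", traitType = "character",
                 ancestry = "character", records = "data.frame",
                 audit = "data.frame"))

setValidity("SummaryDataset", function(object) {
  rec <- object@records
  msg <- character()
  if (!all(.recordCols %in% names(rec)))
    msg <- c(msg, paste("records must have columns:",
                        paste(setdiff(.recordCols, names(rec)), collapse = ", ")))
  else if (nrow(rec)) {
    if (anyDuplicated(rec$snp_id)) msg <- c(msg, "duplicated snp_id")
    if (!all(rec$se > 0)) msg <- c(msg, "all se must be > 0")
    if (!all(rec$eaf >= 0 & rec$eaf <= 1)) msg <- c(msg, "eaf outside [0, 1]")
    if (!all(rec$effect_allele %in% VALID_BASES &
             rec$other_allele %in% VALID_BASES))
      msg <- c(msg, "alleles must be single bases A/C/G/T")
    if (any(rec$effect_allele == rec$other_allele))
      msg <- c(msg, "effect and other allele identical")
  }
  if (!object@traitType %in% c("binary", "continuous"))
    msg <- c(msg, "traitType must be 'binary' or 'continuous'")
  if (length(msg)) msg else TRUE
})

#' Local LD reference: square allelic-correlation matrix keyed by rsID
#'
#' Stands in for an external reference panel; `r` holds signed allelic
#' correlations (r, not r-squared) with unit diagonal. Side-car coordinates
#' give each variant's chromosome and 1-based position for window logic.
#'
#' @slot snpIds variant identifiers, in matrix order.
#' @slot r square symmetric correlation matrix.
#' @slot chrom,pos per-variant coordinates.
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(snpIds = "character", r = "matrix",
                 chrom = "character", pos = "numeric"))

setValidity("LDMatrix", function(object) {
  msg <- character()
  n <- length(object@snpIds)
  if (!all(dim(object@r) == c(n, n))) msg <- c(msg, "r must be n x n")
  else {
    if (max(abs(object@r - t(object@r))) > 1e-8) msg <- c(msg, "r not symmetric")
    if (max(abs(diag(object@r) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (any(abs(object@r) > 1 + 1e-8)) msg <- c(msg, "entries outside [-1, 1]")
  }
  if (length(object@chrom) != n || length(object@pos) != n)
    msg <- c(msg, "chrom/pos must match snpIds length")
  if (length(msg)) msg else TRUE
})

#' Exposure-outcome aligned instrument table
#'
#' The unit every univariable estimator consumes: one row per instrument with
#' exposure and outcome associations expressed for the same effect allele on
#' the same strand. `proxy_of` records substituted variants; `palindromic`
#' and `eaf_flag` carry harmonization diagnostics.
#'
#' @slot data per-instrument data.frame.
#' @slot exposure,outcome trait names.
#' @slot exposureScale,outcomeScale "log-odds" or "sd".
#' @slot audit harmonization audit trail.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(data = "data.frame", exposure = "character",
                 outcome = "character", exposureScale = "character",
                 outcomeScale = "character", audit = "data.frame"))

.hsetCols <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
               "se_outcome", "eaf_exposure", "eaf_outcome", "palindromic",
               "proxy_of", "eaf_flag")

setValidity("HarmonizedSet", function(object) {
  d <- object@data
  msg <- character()
  if (!all(.hsetCols %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(.hsetCols, names(d)), collapse = ", ")))
  else if (nrow(d)) {
    if (anyDuplicated(d$snp_id)) msg <- c(msg, "duplicated snp_id")
    if (!all(d$se_exposure > 0 & d$se_outcome > 0)) msg <- c(msg, "all SEs must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' A causal-effect estimate
#'
#' @slot beta point estimate (log-odds per unit exposure, or SD units).
#' @slot se standard error.
#' @slot pvalue two-sided normal p-value.
#' @slot method estimator tag (wald, ivw_fixed, ivw_random, egger,
#'   weighted_median, mvmr_ivw, meta_fixed, loo:<snp>).
#' @slot k number of instruments used.
#' @slot outcomeScale "log-odds" or "sd".
#' @exportClass EffectEstimate
setClass("EffectEstimate",
  representation(beta = "numeric", se = "numeric", pvalue = "numeric",
                 method = "character", k = "integer",
                 outcomeScale = "character"))

setValidity("EffectEstimate", function(object) {
  msg <- character()
  if (object@se <= 0) msg <- c(msg, "se must be > 0")
  pref <- 2 * stats::pnorm(-abs(object@beta / object@se))
  if (is.finite(object@pvalue) && abs(object@pvalue - pref) > 1e-6)
    msg <- c(msg, "pvalue inconsistent with beta/se under normal approximation")
  if (length(msg)) msg else TRUE
})

#' Cochran's Q heterogeneity result
#' @slot Q statistic; @slot df k - 1; @slot pvalue upper-tail chi-square.
#' @exportClass QResult
setClass("QResult",
  representation(Q = "numeric", df = "numeric", pvalue = "numeric"))

setValidity("QResult", function(object) {
  msg <- character()
  if (object@Q < 0) msg <- c(msg, "Q must be >= 0")
  if (object@df < 1) msg <- c(msg, "df must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MR-Egger regression result
#' @slot slope the causal-slope \linkS4class{EffectEstimate}.
#' @slot intercept,interceptSE,interceptP the directional-pleiotropy test.
#' @exportClass EggerResult
setClass("EggerResult",
  representation(slope = "EffectEstimate", intercept = "numeric",
                 interceptSE = "numeric", interceptP = "numeric"))

#' MR-PRESSO result
#'
#' @slot rssObserved observed weighted residual sum of squares.
#' @slot globalP empirical global-test p (plus-one estimator, never 0).
#' @slot snpTable per-SNP residuals, raw and Bonferroni-adjusted p, flags.
#' @slot corrected IVW estimate on unflagged instruments (or NULL).
#' @slot distortionP empirical p for original-vs-corrected slope shift.
#' @slot nSim,seed simulation settings.
#' @exportClass PressoResult
setClass("PressoResult",
  representation(rssObserved = "numeric", globalP = "numeric",
                 snpTable = "data.frame", corrected = "ANY",
                 distortionP = "numeric", nSim = "integer", seed = "integer"))

setValidity("PressoResult", function(object) {
  msg <- character()
  lo <- 1 / (object@nSim + 1)
  if (object@globalP < lo - 1e-12 || object@globalP > 1)
    msg <- c(msg, "globalP outside [1/(nSim+1), 1]")
  if (length(msg)) msg else TRUE
})

#' Multi-exposure instrument table for multivariable MR
#'
#' @slot snpIds instrument identifiers (k rows).
#' @slot betaExposure,seExposure k x L matrices, one column per exposure.
#' @slot betaOutcome,seOutcome outcome associations.
#' @slot exposures,exposureScales,outcome,outcomeScale labels.
#' @exportClass MultiExposureSet
setClass("MultiExposureSet",
  representation(snpIds = "character", betaExposure = "matrix",
                 seExposure = "matrix", betaOutcome = "numeric",
                 seOutcome = "numeric", exposures = "character",
                 exposureScales = "character", outcome = "character",
                 outcomeScale = "character"))

setValidity("MultiExposureSet", function(object) {
  msg <- character()
  k <- length(object@snpIds); L <- length(object@exposures)
  if (k < L + 1) msg <- c(msg, "need k >= L + 1 instruments")
  if (!all(dim(object@betaExposure) == c(k, L)) ||
      !all(dim(object@seExposure) == c(k, L)))
    msg <- c(msg, "betaExposure/seExposure must be k x L")
  else if (any(colSums(object@betaExposure != 0) == 0))
    msg <- c(msg, "an exposure has all-zero instrument associations")
  if (length(object@betaOutcome) != k || length(object@seOutcome) != k)
    msg <- c(msg, "outcome vectors must have length k")
  else if (any(object@seOutcome <= 0)) msg <- c(msg, "all outcome SEs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Conditional instrument strength in multivariable MR
#' @slot F per-exposure conditional F statistic (named).
#' @slot k,L instrument and exposure counts.
#' @exportClass ConditionalStrength
setClass("ConditionalStrength",
  representation(F = "numeric", k = "integer", L = "integer"))

#' Ordered chain of stage effects for mediation
#'
#' Each stage is a causal effect on the additive scale (log-odds stages are
#' entered as logs). `from`/`to` label stage endpoints; the chain composes
#' head-to-tail.
#'
#' @slot labels stage labels (unique).
#' @slot theta stage point estimates.
#' @slot se stage standard errors.
#' @slot from,to stage endpoint trait names.
#' @exportClass PathwaySpec
setClass("PathwaySpec",
  representation(labels = "character", theta = "numeric", se = "numeric",
                 from = "character", to = "character"))

setValidity("PathwaySpec", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) msg <- c(msg, "stage labels must be unique")
  if (length(object@theta) != n || length(object@se) != n)
    msg <- c(msg, "theta/se must match labels length")
  if (any(object@se < 0)) msg <- c(msg, "stage ses must be >= 0")
  if (length(object@from) == n && length(object@to) == n && n > 1 &&
      !all(object@to[-n] == object@from[-1]))
    msg <- c(msg, "stage scales do not compose: to[i] must equal from[i+1]")
  if (length(msg)) msg else TRUE
})

#' An indirect (mediated) effect with delta-method uncertainty
#' @slot estimate indirect effect on the log-odds scale; @slot se delta SE.
#' @slot ciLow,ciHigh 95\% bounds; @slot pvalue two-sided normal.
#' @slot proportion percent of the supplied total effect mediated.
#' @slot grade evidence grade (strong/suggestive/none).
#' @slot path the generating \linkS4class{PathwaySpec}.
#' @exportClass MediationResult
setClass("MediationResult",
  representation(estimate = "numeric", se = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", pvalue = "numeric",
                 proportion = "numeric", grade = "character",
                 path = "PathwaySpec"))

setValidity("MediationResult", function(object) {
  if (object@estimate < object@ciLow - 1e-12 ||
      object@estimate > object@ciHigh + 1e-12)
    "confidence interval must contain the point estimate" else TRUE
})

#' LD-score regression fit
#' @slot h2 observed-scale SNP heritability; @slot h2SE block-jackknife SE.
#' @slot intercept,interceptSE regression intercept (near 1 absent confounding).
#' @slot M SNPs behind the LD scores; @slot N GWAS sample size.
#' @slot nBlocks jackknife blocks.
#' @exportClass LdscFit
setClass("LdscFit",
  representation(h2 = "numeric", h2SE = "numeric", intercept = "numeric",
                 interceptSE = "numeric", M = "numeric", N = "numeric",
                 nBlocks = "integer"))

#' Ground truth behind a synthetic GWAS study
#'
#' @slot config the generating configuration (list).
#' @slot snpIds,chrom,pos,maf,effectAllele,otherAllele variant frame.
#' @slot direct per-SNP direct effects on each node (m x traits).
#' @slot marginal implied marginal per-SNP effects (m x traits).
#' @slot theta the causal-chain coefficients.
#' @slot totalEffect analytic exposure-to-outcome total effect.
#' @slot traits node names, in `direct`/`marginal` column order.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(config = "list", snpIds = "character", chrom = "character",
                 pos = "numeric", maf = "numeric", effectAllele = "character",
                 otherAllele = "character", direct = "matrix",
                 marginal = "matrix", theta = "numeric",
                 totalEffect = "numeric", traits = "character"))

#' Structured report of the stepwise mediation analysis
#' @slot total,totalFiltered total-effect estimates (all instruments /
#'   obesity-SNP-excluded).
#' @slot stages data.frame of the fitted stage effects.
#' @slot pathways named list of \linkS4class{MediationResult}.
#' @slot conditionalF named list of \linkS4class{ConditionalStrength}.
#' @slot notes character log (e.g. stages marked not applicable).
#' @exportClass MediationReport
setClass("MediationReport",
  representation(total = "ANY", totalFiltered = "ANY", stages = "data.frame",
                 pathways = "list", conditionalF = "list",
                 notes = "character"))
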