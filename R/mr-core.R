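#' @include AllClasses.R
NULL

Z975 <- 1.959964

.newEstimate <- function(beta, se, method, k, outcomeScale = "log-odds") {
  new("EffectEstimate", beta = beta, se = se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)), method = method,
      k = as.integer(k), outcomeScale = outcomeScale)
}

.hsetCheck <- function(hset, kMin, what) {
  k <- nrow(hset@data)
  if (k < kMin) stop(what, " requires at least ", kMin,
                     " instruments (got ", k, ")")
  k
}

#' Wald ratio for a single instrument
#'
#' beta = beta_outcome / beta_exposure. The default standard error is the
#' first-order approximation se_outcome / |beta_exposure|; the second-order
#' form additionally propagates the exposure-side sampling error.
#'
#' @param betaExposure,betaOutcome,seOutcome instrument associations.
#' @param seExposure exposure-side SE (needed for `secondOrder`).
#' @param secondOrder use the second-order ratio SE.
#' @param outcomeScale passed through to the estimate.
#' @return an \linkS4class{EffectEstimate} with method "wald".
#' @export
waldRatio <- function(betaExposure, betaOutcome, seOutcome,
                      seExposure = NULL, secondOrder = FALSE,
                      outcomeScale = "log-odds") {
  if (betaExposure == 0) stop("undefined Wald ratio: beta_exposure is 0")
  b <- betaOutcome / betaExposure
  se <- if (secondOrder) {
    if (is.null(seExposure)) stop("secondOrder SE needs seExposure")
    sqrt(seOutcome^2 / betaExposure^2 +
         betaOutcome^2 * seExposure^2 / betaExposure^4)
  } else seOutcome / abs(betaExposure)
  .newEstimate(b, se, "wald", 1L, outcomeScale)
}

.ivwCore <- function(bx, by, sey) {
  w <- bx^2 / sey^2
  b <- sum(bx * by / sey^2) / sum(w)
  list(beta = b, seFixed = 1 / sqrt(sum(w)),
       Q = sum(w * (by / bx - b)^2), k = length(bx))
}

#' Inverse-variance weighted estimator
#'
#' beta = sum(bX*bY/seY^2) / sum(bX^2/seY^2). Fixed-effects SE is
#' 1/sqrt(sum(bX^2/seY^2)); the multiplicative random-effects SE inflates
#' it by max(1, sqrt(Q/(k-1))). `mode = "auto"` uses fixed effects with
#' three or fewer instruments and random effects otherwise.
#'
#' @param hset a \linkS4class{HarmonizedSet} with k >= 1 instruments.
#' @param mode "auto", "fixed" or "random".
#' @return an \linkS4class{EffectEstimate} (method "ivw_fixed" or
#'   "ivw_random"); with k = 1 this equals the Wald ratio.
#' @export
mrIVW <- function(hset, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  k <- .hsetCheck(hset, 1, "IVW")
  d <- hset@data
  f <- .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)
  if (mode == "auto") mode <- if (k <= 3) "fixed" else "random"
  se <- if (mode == "random" && k >= 2)
    f$seFixed * max(1, sqrt(f$Q / (k - 1))) else f$seFixed
  .newEstimate(f$beta, se, paste0("ivw_", mode), k, hset@outcomeScale)
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum(w_j (ratio_j - b_ivw)^2) with w_j = (bX_j/seY_j)^2, compared to
#' an upper-tail chi-square with k - 1 degrees of freedom.
#'
#' @param hset a \linkS4class{HarmonizedSet} with k >= 2 instruments.
#' @param estimate optional pre-computed IVW \linkS4class{EffectEstimate};
#'   recomputed when missing.
#' @return a \linkS4class{QResult}.
#' @export
cochranQ <- function(hset, estimate = NULL) {
  k <- .hsetCheck(hset, 2, "Cochran's Q")
  d <- hset@data
  b <- if (is.null(estimate))
    .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)$beta
  else estimate@beta
  w <- (d$beta_exposure / d$se_outcome)^2
  Q <- sum(w * (d$beta_outcome / d$beta_exposure - b)^2)
  new("QResult", Q = Q, df = k - 1,
      pvalue = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

.eggerFit <- function(bx, by, sey) {
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  if (stats::var(bx) == 0) stop("collinearity: no variance in exposure betas")
  w <- 1 / sey^2
  X <- cbind(intercept = 1, slope = bx)
  A <- solve(crossprod(X, w * X))
  coef <- drop(A %*% crossprod(X, w * by))
  resid <- by - drop(X %*% coef)
  sigma2 <- sum(w * resid^2) / (length(bx) - 2)
  seFixed <- sqrt(diag(A))
  list(coef = coef, se = seFixed * max(1, sqrt(sigma2)), sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept (weights 1/seY^2), after orienting all exposure betas
#' non-negative (row sign flips), so the result is invariant to input sign
#' conventions. Under InSIDE the intercept estimates the average directional
#' pleiotropy and its test is the directional-pleiotropy test; the slope is
#' a pleiotropy-robust causal estimate. SEs use the multiplicative
#' over-dispersion model with inflation floored at 1.
#'
#' @param hset a \linkS4class{HarmonizedSet} with k >= 3 instruments.
#' @return an \linkS4class{EggerResult}.
#' @export
mrEgger <- function(hset) {
  k <- .hsetCheck(hset, 3, "MR-Egger")
  d <- hset@data
  f <- .eggerFit(d$beta_exposure, d$beta_outcome, d$se_outcome)
  slope <- .newEstimate(f$coef[["slope"]], f$se[["slope"]], "egger", k,
                        hset@outcomeScale)
  new("EggerResult", slope = slope, intercept = f$coef[["intercept"]],
      interceptSE = f$se[["intercept"]],
      interceptP = 2 * stats::pnorm(-abs(f$coef[["intercept"]] /
                                         f$se[["intercept"]])))
}

#' Weighted-median point estimate from ratios and weights
#'
#' Sorts the per-instrument ratio estimates, forms cumulative weight
#' midpoints s_j = cumsum(p)_j - p_j/2 from the normalized weights, and
#' linearly interpolates ratio against s at 0.5.
#'
#' @param ratios per-instrument Wald ratios.
#' @param weights positive weights (normalized internally).
#' @return the weighted-median estimate.
#' @export
weightedMedianEstimate <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  p <- weights[ord] / sum(weights)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when instruments contributing more than half the weight are
#' valid. Weights are inverse Wald-ratio variances; the SE is the standard
#' deviation of the estimate over seeded parametric-bootstrap resamples of
#' the instrument associations.
#'
#' @param hset a \linkS4class{HarmonizedSet} with k >= 3 instruments.
#' @param nBoot bootstrap resamples for the SE.
#' @param seed RNG seed (same seed, identical SE).
#' @return an \linkS4class{EffectEstimate} with method "weighted_median".
#' @export
weightedMedian <- function(hset, nBoot = 1000, seed = 1) {
  k <- .hsetCheck(hset, 3, "weighted median")
  d <- hset@data
  wmOf <- function(bx, by) {
    ratio <- by / bx
    weightedMedianEstimate(ratio, (abs(bx) / d$se_outcome)^2)
  }
  est <- wmOf(d$beta_exposure, d$beta_outcome)
  sex <- d$se_exposure
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      wmOf(stats::rnorm(k, d$beta_exposure, sex),
           stats::rnorm(k, d$beta_outcome, d$se_outcome))
    }, numeric(1))
  })
  .newEstimate(est, stats::sd(boot), "weighted_median", k, hset@outcomeScale)
}

#' Leave-one-out analysis
#'
#' Recomputes the IVW (auto mode) estimate k times, leaving out one
#' instrument at a time, to expose influential variants.
#'
#' @param hset a \linkS4class{HarmonizedSet} with k >= 2 instruments.
#' @return a named list of \linkS4class{EffectEstimate}, method
#'   `loo:<snp>`; with k = 2 each equals the remaining single-SNP Wald
#'   ratio.
#' @export
leaveOneOut <- function(hset) {
  k <- .hsetCheck(hset, 2, "leave-one-out")
  out <- lapply(seq_len(k), function(j) {
    sub <- new("HarmonizedSet", data = hset@data[-j, ],
               exposure = hset@exposure, outcome = hset@outcome,
               exposureScale = hset@exposureScale,
               outcomeScale = hset@outcomeScale, audit = .audit())
    e <- mrIVW(sub, "auto")
    e@method <- paste0("loo:", hset@data$snp_id[j])
    e
  })
  stats::setNames(out, hset@data$snp_id)
}

#' Express a log-odds estimate as an odds ratio with CI
#'
#' @param estimate an \linkS4class{EffectEstimate} on the log-odds scale
#'   (continuous outcomes are refused: report beta directly).
#' @param level confidence level.
#' @return data.frame with OR, ciLow, ciHigh, pvalue, method.
#' @export
toOddsRatio <- function(estimate, level = 0.95) {
  if (estimate@outcomeScale != "log-odds")
    stop("outcome is on the SD scale; report beta directly, not an OR")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(method = estimate@method, OR = exp(estimate@beta),
             ciLow = exp(estimate@beta - z * estimate@se),
             ciHigh = exp(estimate@beta + z * estimate@se),
             pvalue = estimate@pvalue, stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates with weights 1/se^2: pooled beta = sum(w*b)/sum(w),
#' pooled se = 1/sqrt(sum(w)). All inputs must share one outcome scale.
#'
#' @param estimates list of \linkS4class{EffectEstimate} objects.
#' @return an \linkS4class{EffectEstimate} with method "meta_fixed".
#' @export
metaFixed <- function(estimates) {
  if (length(estimates) < 1) stop("need at least one estimate")
  scales <- vapply(estimates, function(e) e@outcomeScale, character(1))
  if (length(unique(scales)) > 1)
    stop("cannot pool estimates on mixed outcome scales: ",
         paste(unique(scales), collapse = ", "))
  b <- vapply(estimates, function(e) e@beta, numeric(1))
  w <- 1 / vapply(estimates, function(e) e@se, numeric(1))^2
  .newEstimate(sum(w * b) / sum(w), 1 / sqrt(sum(w)), "meta_fixed",
               sum(vapply(estimates, function(e) e@k, integer(1))),
               scales[1])
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded internals never disturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
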