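#' @include AllClasses.R
NULL

.zScores <- function(sumstats) {
  if (is(sumstats, "SummaryDataset")) {
    d <- sumstats@records
    return(data.frame(snp_id = d$snp_id, z = d$beta / d$se,
                      stringsAsFactors = FALSE))
  }
  d <- as.data.frame(sumstats)
  z <- if ("z" %in% names(d)) d$z
  else if (all(c("beta", "se") %in% names(d))) d$beta / d$se
  else if ("chi2" %in% names(d)) sqrt(d$chi2)
  else stop("sumstats needs z, beta/se, or chi2")
  data.frame(snp_id = d$snp_id, z = z, stringsAsFactors = FALSE)
}

# closed-form weighted simple regression with delete-one-block jackknife.
# Returns full-fit slope/intercept and one (slope, intercept) pair per
# deleted block; weights stay fixed across deletions.
.wlsJackknife <- function(x, y, w, blockId) {
  sums <- function(idx) c(sw = sum(w[idx]), swx = sum(w[idx] * x[idx]),
                          swy = sum(w[idx] * y[idx]),
                          swxx = sum(w[idx] * x[idx]^2),
                          swxy = sum(w[idx] * x[idx] * y[idx]))
  blocks <- split(seq_along(x), blockId)
  bs <- vapply(blocks, sums, numeric(5))
  tot <- rowSums(bs)
  solveFit <- function(s) {
    den <- s["sw"] * s["swxx"] - s["swx"]^2
    slope <- (s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / den
    c(slope = unname(slope),
      intercept = unname((s["swy"] - slope * s["swx"]) / s["sw"]))
  }
  full <- solveFit(tot)
  jack <- vapply(seq_along(blocks), function(b) solveFit(tot - bs[, b]),
                 numeric(2))
  list(slope = full["slope"], intercept = full["intercept"],
       jackSlope = jack["slope", ], jackIntercept = jack["intercept", ])
}

.jackSE <- function(theta) {
  b <- length(theta)
  sqrt((b - 1) / b * sum((theta - mean(theta))^2))
}

.matchLdsc <- function(sumstats, ldscores, nBlocks) {
  z <- .zScores(sumstats)
  m <- merge(z, as.data.frame(ldscores)[, c("snp_id", "l2")],
             by = "snp_id", sort = FALSE)
  if (nrow(m) < 2 * nBlocks)
    stop("insufficient matched SNPs: ", nrow(m), " < 2 * nBlocks")
  m
}

#' LD-score regression for observed-scale SNP heritability
#'
#' Regresses per-SNP association chi-squares on LD scores:
#' E[chi2_j] = 1 + N h2 l_j / M (+ confounding inflation in the
#' intercept), so slope * M / N estimates h2 and the intercept is near 1
#' absent confounding. Fitting is two-pass: an unweighted fit gives a
#' provisional h2 used to build heteroskedasticity weights
#' 1/(1 + N h2 l_j/M)^2, then the weighted fit is reported. Uncertainty is
#' by delete-one-block jackknife over `nBlocks` contiguous blocks in the
#' matched SNP order.
#'
#' @param sumstats a \linkS4class{SummaryDataset}, or data.frame with
#'   snp_id and z, beta/se, or chi2.
#' @param ldscores data.frame with snp_id and l2 columns.
#' @param N GWAS sample size.
#' @param M total SNPs behind the LD scores (defaults to
#'   `attr(ldscores, "M")`, else the number of score rows).
#' @param nBlocks jackknife blocks; needs >= 2*nBlocks matched SNPs.
#' @return an \linkS4class{LdscFit}.
#' @export
ldscH2 <- function(sumstats, ldscores, N, M = NULL, nBlocks = 200) {
  if (is.null(M)) M <- attr(ldscores, "M")
  if (is.null(M)) M <- nrow(as.data.frame(ldscores))
  m <- .matchLdsc(sumstats, ldscores, nBlocks)
  chi2 <- m$z^2
  blockId <- ceiling(seq_along(chi2) / (length(chi2) / nBlocks))
  pass1 <- .wlsJackknife(m$l2, chi2, rep(1, length(chi2)), blockId)
  h20 <- min(max(pass1$slope * M / N, 0), 1)
  w <- 1 / (1 + N * h20 * m$l2 / M)^2
  fit <- .wlsJackknife(m$l2, chi2, w, blockId)
  new("LdscFit", h2 = unname(fit$slope * M / N),
      h2SE = .jackSE(fit$jackSlope * M / N),
      intercept = unname(fit$intercept),
      interceptSE = .jackSE(fit$jackIntercept),
      M = M, N = N, nBlocks = as.integer(nBlocks))
}

#' Cross-trait LD-score regression genetic correlation
#'
#' Regresses z1_j * z2_j on LD scores: the slope times M/sqrt(N1 N2)
#' estimates the genetic covariance, and rg = gencov / sqrt(h2_1 h2_2)
#' with the heritabilities from \code{\link{ldscH2}}. The rg jackknife
#' recomputes all three regressions per deleted block (weights fixed).
#' No sample-overlap intercept is modeled (documented limitation);
#' `fixedIntercept` optionally pins the cross-trait intercept at a known
#' value instead of fitting it.
#'
#' @param sumstats1,sumstats2 per-trait inputs (as in
#'   \code{\link{ldscH2}}; need signed z or beta/se).
#' @param ldscores,N1,N2,M,nBlocks as in \code{\link{ldscH2}}.
#' @param fixedIntercept optional fixed cross-trait intercept.
#' @param products optional data.frame (snp_id, z1z2) replacing the
#'   observed z1*z2 products, used to validate the estimator against
#'   exactly model-generated cross-trait expectations.
#' @return list with rg, se, pvalue, gencov, and the two
#'   \linkS4class{LdscFit} objects.
#' @export
ldscRg <- function(sumstats1, sumstats2, ldscores, N1, N2, M = NULL,
                   nBlocks = 200, fixedIntercept = NULL, products = NULL) {
  if (is.null(M)) M <- attr(ldscores, "M")
  if (is.null(M)) M <- nrow(as.data.frame(ldscores))
  fit1 <- ldscH2(sumstats1, ldscores, N1, M, nBlocks)
  fit2 <- ldscH2(sumstats2, ldscores, N2, M, nBlocks)
  if (fit1@h2 <= 0 || fit2@h2 <= 0)
    stop("rg undefined: non-positive heritability estimate")
  z1 <- .zScores(sumstats1); z2 <- .zScores(sumstats2)
  m <- merge(merge(z1, stats::setNames(z2, c("snp_id", "z2")),
                   by = "snp_id", sort = FALSE),
             as.data.frame(ldscores)[, c("snp_id", "l2")],
             by = "snp_id", sort = FALSE)
  if (nrow(m) < 2 * nBlocks)
    stop("insufficient matched SNPs: ", nrow(m), " < 2 * nBlocks")
  y <- if (is.null(products)) m$z * m$z2
  else products$z1z2[match(m$snp_id, products$snp_id)]
  blockId <- ceiling(seq_len(nrow(m)) / (nrow(m) / nBlocks))
  # all three regressions share one weight family and one set of block
  # deletions, so the jackknifed ratio is internally consistent
  h1w <- 1 / (1 + N1 * fit1@h2 * m$l2 / M)^2
  h2w <- 1 / (1 + N2 * fit2@h2 * m$l2 / M)^2
  w <- sqrt(h1w * h2w)
  crossFit <- if (is.null(fixedIntercept))
    .wlsJackknife(m$l2, y, w, blockId)
  else {
    # fit through the origin after removing the pinned intercept
    sums <- function(idx) c(swxx = sum(w[idx] * m$l2[idx]^2),
                            swxy = sum(w[idx] * m$l2[idx] *
                                       (y - fixedIntercept)[idx]))
    blocks <- split(seq_len(nrow(m)), blockId)
    bs <- vapply(blocks, sums, numeric(2))
    tot <- rowSums(bs)
    list(slope = tot["swxy"] / tot["swxx"],
         jackSlope = vapply(seq_along(blocks), function(b) {
           s <- tot - bs[, b]; unname(s["swxy"] / s["swxx"])
         }, numeric(1)))
  }
  f1 <- .wlsJackknife(m$l2, m$z^2, h1w, blockId)
  f2 <- .wlsJackknife(m$l2, m$z2^2, h2w, blockId)
  rgOf <- function(cross, s1, s2)
    (cross * M / sqrt(N1 * N2)) /
      sqrt(pmax(s1 * M / N1, 1e-12) * pmax(s2 * M / N2, 1e-12))
  gencov <- unname(crossFit$slope) * M / sqrt(N1 * N2)
  rg <- unname(rgOf(crossFit$slope, f1$slope, f2$slope))
  jackRg <- rgOf(crossFit$jackSlope, f1$jackSlope, f2$jackSlope)
  se <- .jackSE(jackRg)
  p <- if (se > 0) 2 * stats::pnorm(-abs(rg / se)) else NA_real_
  list(rg = rg, se = se, pvalue = p, gencov = gencov,
       fit1 = fit1, fit2 = fit2)
}
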