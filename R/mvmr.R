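#' @include AllClasses.R mr-core.R summary-data.R
NULL

#' Construct a MultiExposureSet
#'
#' @param snpIds instrument identifiers.
#' @param betaExposure,seExposure k x L matrices (columns named by
#'   exposure).
#' @param betaOutcome,seOutcome outcome associations.
#' @param exposures,exposureScales exposure names and scales (default from
#'   column names / "sd").
#' @param outcome,outcomeScale outcome name and scale.
#' @return a \linkS4class{MultiExposureSet}.
#' @export
MultiExposureSet <- function(snpIds, betaExposure, seExposure, betaOutcome,
                             seOutcome, exposures = colnames(betaExposure),
                             exposureScales = rep("sd", length(exposures)),
                             outcome = "outcome",
                             outcomeScale = "log-odds") {
  betaExposure <- as.matrix(betaExposure)
  seExposure <- as.matrix(seExposure)
  if (is.null(exposures))
    exposures <- paste0("exposure", seq_len(ncol(betaExposure)))
  colnames(betaExposure) <- colnames(seExposure) <- exposures
  new("MultiExposureSet", snpIds = as.character(snpIds),
      betaExposure = betaExposure, seExposure = seExposure,
      betaOutcome = as.numeric(betaOutcome),
      seOutcome = as.numeric(seOutcome), exposures = exposures,
      exposureScales = exposureScales, outcome = outcome,
      outcomeScale = outcomeScale)
}

#' Assemble a multi-exposure instrument table from summary datasets
#'
#' Takes the union of each exposure's selected instruments, re-clumps the
#' union jointly (most significant variant across exposures wins), and
#' keeps variants with associations available in every exposure and in the
#' outcome, harmonized to the first exposure's effect-allele convention.
#'
#' @param exposureDatasets named list of \linkS4class{SummaryDataset} (full
#'   tables, used for instrument lookup across exposures).
#' @param outcomeDataset the outcome \linkS4class{SummaryDataset}.
#' @param ld an \linkS4class{LDMatrix} for the joint re-clump.
#' @param pThreshold,mafMin,palindromeEafBand instrument selection
#'   parameters (see \code{\link{selectInstruments}}).
#' @param windowKb,r2Max clumping parameters.
#' @return a \linkS4class{MultiExposureSet}.
#' @export
buildMultiExposureSet <- function(exposureDatasets, outcomeDataset, ld,
                                  pThreshold = 5e-8, mafMin = 0.01,
                                  palindromeEafBand = c(0.42, 0.58),
                                  windowKb = 10000, r2Max = 0.001) {
  stopifnot(length(exposureDatasets) >= 1)
  sel <- lapply(exposureDatasets, selectInstruments, pThreshold = pThreshold,
                mafMin = mafMin, palindromeEafBand = palindromeEafBand)
  union <- do.call(rbind, lapply(sel, function(s) s@records))
  # one row per rsID, keeping the smallest p across exposures for ordering
  union <- union[order(union$pvalue), ]
  union <- union[!duplicated(union$snp_id), ]
  pool <- SummaryDataset(union, trait = "joint", traitType = "continuous")
  clumped <- suppressWarnings(ldClump(pool, ld, windowKb, r2Max))
  ids <- clumped@records$snp_id

  ref <- clumped@records
  lookup <- function(ds) {
    m <- match(ids, ds@records$snp_id)
    rec <- ds@records[m, ]
    flip <- ifelse(!is.na(m) & rec$effect_allele != ref$effect_allele, -1, 1)
    list(beta = rec$beta * flip, se = rec$se)
  }
  ex <- lapply(exposureDatasets, lookup)
  out <- lookup(outcomeDataset)
  B <- do.call(cbind, lapply(ex, `[[`, "beta"))
  S <- do.call(cbind, lapply(ex, `[[`, "se"))
  ok <- stats::complete.cases(B) & stats::complete.cases(S) &
    is.finite(out$beta) & is.finite(out$se)
  scaleOf <- function(x) if (x@traitType == "binary") "log-odds" else "sd"
  MultiExposureSet(ids[ok], B[ok, , drop = FALSE], S[ok, , drop = FALSE],
                   out$beta[ok], out$se[ok],
                   exposures = names(exposureDatasets),
                   exposureScales = vapply(exposureDatasets, scaleOf,
                                           character(1)),
                   outcome = outcomeDataset@trait,
                   outcomeScale = scaleOf(outcomeDataset))
}

#' Multivariable IVW: direct effects conditional on co-exposures
#'
#' Weighted multivariable regression of the outcome associations on the L
#' exposure-association columns without intercept, weights 1/seY^2.
#' Coefficient j is the direct effect of exposure j conditional on the
#' others; SEs come from the weighted normal-equations covariance with the
#' multiplicative over-dispersion inflation floored at 1 (with L = 1 this
#' reduces exactly to the univariable random-effects IVW).
#'
#' @param mset a \linkS4class{MultiExposureSet}.
#' @return named list of \linkS4class{EffectEstimate}, one per exposure
#'   (method "mvmr_ivw").
#' @export
mvmrIVW <- function(mset) {
  X <- mset@betaExposure
  y <- mset@betaOutcome
  w <- 1 / mset@seOutcome^2
  k <- nrow(X); L <- ncol(X)
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < L) {
    bad <- mset@exposures[qrX$pivot[seq(qrX$rank + 1, L)]]
    stop("collinear exposure associations; offending exposure(s): ",
         paste(bad, collapse = ", "))
  }
  A <- solve(crossprod(X, w * X))
  coef <- drop(A %*% crossprod(X, w * y))
  sigma2 <- sum(w * (y - drop(X %*% coef))^2) / (k - L)
  se <- sqrt(diag(A)) * max(1, sqrt(sigma2))
  out <- lapply(seq_len(L), function(j)
    .newEstimate(unname(coef[j]), unname(se[j]), "mvmr_ivw", k,
                 mset@outcomeScale))
  stats::setNames(out, mset@exposures)
}

#' Conditional F statistics for multivariable MR
#'
#' For each exposure x, regresses its instrument associations on the other
#' exposures' associations (no intercept, weights 1/se_x^2) and forms the
#' weighted residual sum of squares Q_x; the conditional F is
#' Q_x / (k - L). With L = 1 this reduces to sum((beta/se)^2) / (k - 1),
#' the mean-F diagnostic. Values below 10 flag conditional weak-instrument
#' bias.
#'
#' @param mset a \linkS4class{MultiExposureSet} with k > L.
#' @return a \linkS4class{ConditionalStrength}.
#' @export
conditionalF <- function(mset) {
  X <- mset@betaExposure; S <- mset@seExposure
  k <- nrow(X); L <- ncol(X)
  if (k <= L) stop("conditional F needs k > L")
  Fx <- vapply(seq_len(L), function(j) {
    w <- 1 / S[, j]^2
    if (L == 1) resid <- X[, 1]
    else {
      Z <- X[, -j, drop = FALSE]
      coef <- solve(crossprod(Z, w * Z), crossprod(Z, w * X[, j]))
      resid <- X[, j] - drop(Z %*% coef)
    }
    sum(w * resid^2) / (k - L)
  }, numeric(1))
  new("ConditionalStrength", F = stats::setNames(Fx, mset@exposures),
      k = as.integer(k), L = as.integer(L))
}
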