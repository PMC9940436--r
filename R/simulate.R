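#' @include AllClasses.R mr-core.R summary-data.R
NULL

.simTraits <- c("U", "nafld", "fi", "fg", "shbg", "bt", "pcos")

#' Simulation configuration for the hepato-ovarian causal diagram
#'
#' Defines a liability-scale structural-equation system with an unmeasured
#' adiposity confounder U and the causal chain
#' NAFLD -> fasting insulin -> SHBG -> bioavailable testosterone -> PCOS:
#' NAFLD = sum(gamma_j G_j) + cN U; FI = theta6 NAFLD + cF U;
#' SHBG = theta5 FI + cS U; BT = theta4 SHBG + cB U;
#' PCOS = theta1 NAFLD + theta2 FI + theta3 BT + cP U + sum(alpha_j G_j).
#' Fasting glucose is a null node (own instruments, confounder loading, no
#' causal edges) so the multivariable null checks have defined truth.
#' Binary-trait effects are read on the log-odds scale via the
#' liability-to-log-odds linear approximation (valid for small effects).
#'
#' @param mSnps total simulated SNPs.
#' @param mafRange minor-allele-frequency range (uniform draw).
#' @param blockSize,rho LD block size and AR(1) within-block correlation.
#' @param nInstruments named counts of direct instruments per trait.
#' @param theta causal-chain coefficients theta1..theta6 (defaults at the
#'   magnitudes of the fitted hepato-ovarian chain).
#' @param confLoadings loadings of U on each trait.
#' @param nConfSnps SNPs assigned to U (obesity-associated instruments).
#' @param confSnpEffect per-SNP effect on U for those SNPs.
#' @param instrumentEffectRange |gamma| range for direct instrument effects.
#' @param pleioFrac,pleioMean,pleioSd fraction of exposure instruments with
#'   direct outcome effects alpha and their normal distribution, expressed
#'   relative to the exposure-increasing allele (balanced when
#'   pleioMean = 0, directional otherwise). A vector pleioMean is recycled
#'   across the invalid instruments, giving mixed-direction contamination
#'   whose net (weighted) pleiotropy is still nonzero.
#' @param n named per-GWAS sample sizes.
#' @param overlap sampling-overlap fraction between GWAS pairs (error
#'   correlation); named list like `list(c("fi","fg") = 0.5)` or a single
#'   number applied to all pairs.
#' @param seed mandatory RNG seed.
#' @return a validated configuration list (class "simConfig").
#' @export
simConfig <- function(mSnps = 2000, mafRange = c(0.05, 0.5),
                      blockSize = 10, rho = 0.5,
                      nInstruments = c(nafld = 20, fi = 20, fg = 15,
                                       shbg = 20, bt = 20),
                      theta = c(theta1 = 0.10, theta2 = 1.1, theta3 = 0.64,
                                theta4 = -0.93, theta5 = -0.28,
                                theta6 = 0.015),
                      confLoadings = c(nafld = 0.2, fi = 0.15, fg = 0.1,
                                       shbg = -0.1, bt = 0.1, pcos = 0.2),
                      nConfSnps = 0, confSnpEffect = 0.15,
                      instrumentEffectRange = c(0.08, 0.25),
                      pleioFrac = 0, pleioMean = 0, pleioSd = 0,
                      n = c(nafld = 2e5, fi = 2e5, fg = 2e5, shbg = 2e5,
                            bt = 2e5, pcos = 2e5),
                      overlap = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(mSnps %% blockSize == 0, abs(rho) < 1,
            all(mafRange > 0 & mafRange <= 0.5), all(n >= 100),
            pleioFrac >= 0, pleioFrac <= 1)
  cfg <- list(mSnps = mSnps, mafRange = mafRange, blockSize = blockSize,
              rho = rho, nInstruments = nInstruments, theta = theta,
              confLoadings = confLoadings, nConfSnps = nConfSnps,
              confSnpEffect = confSnpEffect,
              instrumentEffectRange = instrumentEffectRange,
              pleioFrac = pleioFrac, pleioMean = pleioMean,
              pleioSd = pleioSd, n = n, overlap = overlap,
              seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a block-diagonal AR(1) LD matrix
#'
#' Within each block of `blockSize` adjacent SNPs the allelic correlation
#' is rho^|i-j|; across blocks it is 0. The result is positive
#' semi-definite by construction.
#'
#' @param config a \code{\link{simConfig}} (uses mSnps, blockSize, rho),
#'   or NULL with the sizes given directly.
#' @param mSnps,blockSize,rho direct overrides.
#' @param rhoPerBlock optional per-block AR(1) correlations (length
#'   mSnps/blockSize), giving heterogeneous LD scores across blocks.
#' @return an \linkS4class{LDMatrix} with SNPs `snp1..snpm` laid 5 kb
#'   apart on chromosome 1.
#' @export
simulateLDMatrix <- function(config = NULL, mSnps = config$mSnps,
                             blockSize = config$blockSize,
                             rho = config$rho, rhoPerBlock = NULL) {
  if (any(abs(c(rho, rhoPerBlock)) >= 1)) stop("|rho| must be < 1")
  if (mSnps %% blockSize != 0) stop("block sizes must sum to mSnps")
  nb <- mSnps / blockSize
  if (is.null(rhoPerBlock)) rhoPerBlock <- rep(rho, nb)
  stopifnot(length(rhoPerBlock) == nb)
  r <- matrix(0, mSnps, mSnps)
  for (b in seq_len(nb)) {
    idx <- (b - 1) * blockSize + seq_len(blockSize)
    r[idx, idx] <- rhoPerBlock[b]^abs(outer(seq_len(blockSize),
                                            seq_len(blockSize), "-"))
  }
  ids <- paste0("snp", seq_len(mSnps))
  LDMatrix(r, snpIds = ids, chrom = rep("1", mSnps),
           pos = seq_len(mSnps) * 5000)
}

.structuralMatrix <- function(theta, conf) {
  A <- matrix(0, 7, 7, dimnames = list(.simTraits, .simTraits))
  A[names(conf), "U"] <- conf
  A["fi", "nafld"] <- theta[["theta6"]]
  A["shbg", "fi"] <- theta[["theta5"]]
  A["bt", "shbg"] <- theta[["theta4"]]
  A["pcos", "nafld"] <- theta[["theta1"]]
  A["pcos", "fi"] <- theta[["theta2"]]
  A["pcos", "bt"] <- theta[["theta3"]]
  A
}

#' Draw ground-truth per-SNP effects under the causal diagram
#'
#' Instruments for each trait are placed one per LD block (so they are
#' mutually unlinked) with |gamma| drawn uniformly from
#' `instrumentEffectRange` and random sign; optional confounder SNPs act
#' on U, and optional pleiotropic instruments get direct outcome effects
#' alpha. Marginal per-SNP effects on every trait follow by exact linear
#' propagation through the structural equations, so e.g. an exposure
#' instrument's marginal outcome effect is gamma_j * (theta1 +
#' theta2 theta6 + theta3 theta4 theta5 theta6) + alpha_j.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{SimulationTruth}.
#' @export
simulateDagTruth <- function(config) {
  cfg <- config
  m <- cfg$mSnps
  withSeed(cfg$seed, {
    maf <- stats::runif(m, cfg$mafRange[1], cfg$mafRange[2])
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("C", "T"), c("G", "A"), c("A", "T"), c("C", "G"))
    pick <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]

    direct <- matrix(0, m, 7, dimnames = list(NULL, .simTraits))
    nBlocks <- m / cfg$blockSize
    traits <- names(cfg$nInstruments)
    needed <- sum(cfg$nInstruments) + cfg$nConfSnps
    if (needed > nBlocks) stop("more instruments than LD blocks")
    blockPick <- sample.int(nBlocks, needed)
    # first SNP of each chosen block carries the causal effect
    slot <- (blockPick - 1) * cfg$blockSize + 1
    at <- 0
    instrumentOf <- stats::setNames(vector("list", length(traits)), traits)
    for (tr in traits) {
      idx <- slot[at + seq_len(cfg$nInstruments[[tr]])]
      at <- at + cfg$nInstruments[[tr]]
      eff <- stats::runif(length(idx), cfg$instrumentEffectRange[1],
                          cfg$instrumentEffectRange[2]) *
        sample(c(-1, 1), length(idx), replace = TRUE)
      direct[idx, tr] <- eff
      instrumentOf[[tr]] <- idx
    }
    confIdx <- integer(0)
    if (cfg$nConfSnps > 0) {
      confIdx <- slot[at + seq_len(cfg$nConfSnps)]
      direct[confIdx, "U"] <- cfg$confSnpEffect
    }
    pleioIdx <- integer(0)
    if (cfg$pleioFrac > 0 && length(instrumentOf$nafld)) {
      nP <- round(cfg$pleioFrac * length(instrumentOf$nafld))
      pleioIdx <- sample(instrumentOf$nafld, nP)
      # directional pleiotropy acts on the exposure-increasing allele:
      # orienting each instrument so gamma > 0 leaves a mean direct outcome
      # effect of pleioMean (what the Egger intercept estimates); a vector
      # pleioMean is recycled across the invalid instruments, giving
      # mixed-direction contamination with a nonzero net component
      direct[pleioIdx, "pcos"] <- direct[pleioIdx, "pcos"] +
        sign(direct[pleioIdx, "nafld"]) *
          stats::rnorm(nP, rep_len(cfg$pleioMean, nP), cfg$pleioSd)
    }
    A <- .structuralMatrix(cfg$theta, cfg$confLoadings)
    prop <- solve(diag(7) - A)              # node = prop %*% direct inputs
    marginal <- direct %*% t(prop)
    colnames(marginal) <- .simTraits
    th <- cfg$theta
    total <- th[["theta1"]] + th[["theta2"]] * th[["theta6"]] +
      th[["theta3"]] * th[["theta4"]] * th[["theta5"]] * th[["theta6"]]
    new("SimulationTruth", config = unclass(cfg),
        snpIds = paste0("snp", seq_len(m)), chrom = rep("1", m),
        pos = seq_len(m) * 5000, maf = maf, effectAllele = pick[, 1],
        otherAllele = pick[, 2], direct = direct, marginal = marginal,
        theta = th, totalEffect = unname(total), traits = .simTraits)
  })
}

#' Simulate two-sample GWAS summary statistics from a truth object
#'
#' For each trait, per-SNP estimates are drawn at the coefficient level:
#' beta-hat_j ~ Normal(marginal_j, se_j^2) with
#' se_j = 1/sqrt(2 n p_j (1 - p_j)) on the standardized scale (binary
#' traits use the same form on the log-odds scale, a documented
#' approximation). Estimation errors are independent across disjoint GWAS
#' samples and correlated with coefficient equal to the overlap fraction
#' otherwise. P-values use the normal approximation.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param seed RNG seed for the estimation noise (defaults to
#'   `config seed + 1` so truth and noise streams are distinct).
#' @param writeDir optional directory: datasets are additionally emitted
#'   as canonical TSVs with the generating seed in a header comment.
#' @return named list of \linkS4class{SummaryDataset}, one per observable
#'   trait (U is latent and never emitted).
#' @export
simulateSummaryStudy <- function(truth, seed = NULL, writeDir = NULL) {
  cfg <- truth@config
  if (is.null(seed)) seed <- cfg$seed + 1L
  m <- length(truth@snpIds)
  obs <- setdiff(truth@traits, "U")
  binary <- c("nafld", "pcos")
  se <- 1 / sqrt(2 * outer(truth@maf * (1 - truth@maf),
                           cfg$n[obs], "*"))
  colnames(se) <- obs
  ovl <- function(t1, t2) {
    if (is.numeric(cfg$overlap) && length(cfg$overlap) == 1)
      return(cfg$overlap)
    key <- paste(sort(c(t1, t2)), collapse = ",")
    if (!is.null(cfg$overlap[[key]])) cfg$overlap[[key]] else 0
  }
  datasets <- withSeed(seed, {
    eps <- matrix(stats::rnorm(m * length(obs)), m, length(obs),
                  dimnames = list(NULL, obs))
    # induce pairwise error correlation via shared components; a scalar
    # overlap shares one factor across all GWAS samples, named pairs mix
    # a factor per pair (each trait should appear in at most one pair)
    if (is.numeric(cfg$overlap) && length(cfg$overlap) == 1 &&
        cfg$overlap > 0) {
      f <- cfg$overlap
      common <- stats::rnorm(m)
      eps <- sqrt(1 - f) * eps + sqrt(f) * common
    } else if (is.list(cfg$overlap)) {
      for (i in seq_along(obs)) for (j in seq_along(obs)) {
        if (j <= i) next
        f <- ovl(obs[i], obs[j])
        if (f > 0) {
          common <- stats::rnorm(m)
          eps[, i] <- sqrt(1 - f) * eps[, i] + sqrt(f) * common
          eps[, j] <- sqrt(1 - f) * eps[, j] + sqrt(f) * common
        }
      }
    }
    lapply(obs, function(tr) {
      beta <- truth@marginal[, tr] + eps[, tr] * se[, tr]
      p <- 2 * stats::pnorm(-abs(beta / se[, tr]))
      p[p == 0] <- .Machine$double.xmin
      SummaryDataset(data.frame(
        snp_id = truth@snpIds, chrom = truth@chrom, pos = truth@pos,
        effect_allele = truth@effectAllele, other_allele = truth@otherAllele,
        eaf = truth@maf, beta = beta, se = se[, tr], pvalue = p,
        n = cfg$n[[tr]], stringsAsFactors = FALSE),
        trait = tr, traitType = if (tr %in% binary) "binary" else "continuous")
    })
  })
  names(datasets) <- obs
  if (!is.null(writeDir)) {
    dir.create(writeDir, showWarnings = FALSE, recursive = TRUE)
    for (tr in obs) {
      path <- file.path(writeDir, paste0(tr, ".tsv"))
      con <- file(path, "w")
      writeLines(sprintf("# mrpath synthetic GWAS; trait=%s seed=%d noise_seed=%d",
                         tr, cfg$seed, as.integer(seed)), con)
      utils::write.table(
        stats::setNames(datasets[[tr]]@records,
                        c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA",
                          "SE", "P", "N")),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    manifest <- list(seed = cfg$seed, theta = as.list(truth@theta),
                     totalEffect = truth@totalEffect,
                     n = as.list(cfg$n), mSnps = cfg$mSnps)
    jsonlite::write_json(manifest, file.path(writeDir, "truth_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  datasets
}

#' Simulate LD scores and chi-square summary statistics for LDSC
#'
#' LD scores are l_j = sum_i r2_ij from a simulated block AR(1) LD matrix
#' (so identity LD gives l_j = 1 exactly). By default the within-block
#' correlation is drawn per block from Uniform(0, rhoMax) so the LD scores
#' span a realistic range rather than collapsing to a single value, which
#' is what identifies the regression slope in noisy mode. Chi-squares
#' follow
#' E[chi2_j] = intercept + N h2 l_j / M: in noiseless mode the expectation
#' itself is returned (z = sqrt of it), in noisy mode z_j ~
#' Normal(0, sqrt(intercept + N h2 l_j / M)). For two traits with genetic
#' covariance `gencov`, paired z-scores are drawn jointly so that
#' E[z1 z2] = sqrt(N1 N2) gencov l_j / M.
#'
#' @param config a \code{\link{simConfig}} (LD geometry + seed).
#' @param h2 per-trait heritabilities (length 1 or 2).
#' @param gencov genetic covariance (used when length(h2) == 2).
#' @param N per-trait sample sizes (recycled).
#' @param intercept confounding intercept (1 = none).
#' @param noiseless return exact model expectations instead of draws.
#' @param rhoMax upper bound of the per-block LD correlation draw.
#' @return list with `ldscores` (data.frame snp_id, l2; attr M) and
#'   `sumstats` (one data.frame with snp_id, z per trait).
#' @export
simulateLdscInputs <- function(config, h2 = 0.4, gencov = 0,
                               N = 1e4, intercept = 1, noiseless = FALSE,
                               rhoMax = 0.95) {
  nb <- config$mSnps / config$blockSize
  rhoB <- withSeed(config$seed * 2L + 1L,
                   stats::runif(nb, 0, rhoMax))
  ld <- simulateLDMatrix(config, rhoPerBlock = rhoB)
  l2 <- colSums(ld@r^2)
  Mtot <- length(l2)
  N <- rep(N, length.out = length(h2))
  scores <- data.frame(snp_id = ld@snpIds, l2 = l2,
                       stringsAsFactors = FALSE)
  attr(scores, "M") <- Mtot
  sig2 <- vapply(seq_along(h2), function(t)
    intercept + N[t] * h2[t] * l2 / Mtot, numeric(Mtot))
  sumstats <- withSeed(config$seed, {
    if (noiseless) {
      z <- sqrt(sig2)
    } else if (length(h2) == 2) {
      rho <- sqrt(N[1] * N[2]) * gencov * l2 / Mtot /
        sqrt(sig2[, 1] * sig2[, 2])
      rho <- pmax(pmin(rho, 0.999), -0.999)
      e1 <- stats::rnorm(Mtot); e2 <- stats::rnorm(Mtot)
      z <- cbind(sqrt(sig2[, 1]) * e1,
                 sqrt(sig2[, 2]) * (rho * e1 + sqrt(1 - rho^2) * e2))
    } else {
      z <- matrix(stats::rnorm(Mtot, 0, sqrt(sig2)), ncol = 1)
    }
    z
  })
  out <- lapply(seq_len(ncol(sumstats)), function(t)
    data.frame(snp_id = ld@snpIds, z = sumstats[, t],
               stringsAsFactors = FALSE))
  names(out) <- paste0("trait", seq_along(out))
  list(ldscores = scores, sumstats = out)
}
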