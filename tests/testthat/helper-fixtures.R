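# Shared fixture builders and independent oracles.

makeHset <- function(bx, by, sey, sex = rep(1e-3, length(bx)),
                     ids = paste0("rs", seq_along(bx)),
                     exposureScale = "log-odds", outcomeScale = "log-odds") {
  n <- length(bx)
  new("HarmonizedSet",
      data = data.frame(snp_id = ids, beta_exposure = bx, se_exposure = sex,
                        beta_outcome = by, se_outcome = sey,
                        eaf_exposure = rep(0.3, n), eaf_outcome = rep(0.3, n),
                        palindromic = rep(FALSE, n),
                        proxy_of = rep(NA_character_, n),
                        eaf_flag = rep(FALSE, n), stringsAsFactors = FALSE),
      exposure = "exposure", outcome = "outcome",
      exposureScale = exposureScale, outcomeScale = outcomeScale,
      audit = data.frame(snp_id = character(), action = character(),
                         reason = character(), stringsAsFactors = FALSE))
}

makeRecords <- function(n, snp_id = paste0("rs", seq_len(n)),
                        chrom = "1", pos = seq_len(n) * 1e5,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, beta = 0.1, se = 0.01,
                        pvalue = 1e-10, nSample = 1e5) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = nSample,
             stringsAsFactors = FALSE)
}

makeDataset <- function(..., trait = "trait", traitType = "binary") {
  SummaryDataset(makeRecords(...), trait = trait, traitType = traitType)
}

extdataPath <- function(name) system.file("extdata", name, package = "mrpath")

readTable2 <- function() {
  read.delim(extdataPath("table2_instruments.tsv"), stringsAsFactors = FALSE)
}

readPrintedStages <- function() {
  s <- read.delim(extdataPath("printed_stage_estimates.tsv"),
                  stringsAsFactors = FALSE)
  # additive-scale estimates and delta SEs backed out of the printed CIs
  s$theta <- s$estimate
  isOR <- s$scale == "or"
  s$theta[isOR] <- log(s$estimate[isOR])
  s$se <- mapply(function(lo, hi, sc)
    seFromCI(lo, hi, scale = if (sc == "or") "log" else "identity"),
    s$ciLow, s$ciHigh, s$scale)
  rownames(s) <- s$stage
  s
}

# Independent greedy-clumping oracle: re-derives the kept set from the
# definition by repeated full scans over a plain data.frame, with no shared
# code with ldClump().
clumpOracle <- function(rec, rmat, windowKb, r2Max) {
  kept <- character()
  pool <- rec
  while (nrow(pool) > 0) {
    score <- order(pool$pvalue, -abs(pool$beta / pool$se), pool$snp_id)
    best <- pool[score[1], ]
    kept <- c(kept, best$snp_id)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      if (pool$snp_id[i] == best$snp_id) return(TRUE)
      if (pool$chrom[i] != best$chrom) return(FALSE)
      if (abs(pool$pos[i] - best$pos) > windowKb * 1000) return(FALSE)
      r2 <- rmat[best$snp_id, pool$snp_id[i]]^2
      r2 >= r2Max
    }, logical(1))
    pool <- pool[!drop, , drop = FALSE]
  }
  sort(kept)
}

# small helper: harmonized set from a truth + datasets pair for one
# exposure/outcome, skipping LD handling (independent SNPs)
quickHset <- function(datasets, exposure, outcome, p = 5e-8) {
  ins <- suppressWarnings(selectInstruments(datasets[[exposure]],
                                            pThreshold = p))
  harmonize(ins, datasets[[outcome]])
}
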