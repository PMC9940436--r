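test_that("readSummaryTable validates rows and reports drops", {
  tsv <- tempfile(fileext = ".tsv")
  tab <- data.frame(SNP = paste0("rs", 1:5), CHR = 1, POS = 1:5 * 1e5,
                    EA = "A", OA = "G", EAF = 0.3, BETA = 0.1, SE = 0.01,
                    P = 1e-9, N = 1e5)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- readSummaryTable(tsv, trait = "t")
  expect_s4_class(ds, "SummaryDataset")
  expect_equal(nrow(records(ds)), 5)

  tab2 <- tab
  tab2$SE[2] <- 0                      # invalid SE
  tab2$EA[4] <- "I"; tab2$OA[4] <- "D" # indel, not a SNV
  write.table(tab2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ds2 <- readSummaryTable(tsv, trait = "t"), "2 of 5")
  expect_equal(nrow(records(ds2)), 3)
  aud <- auditTrail(ds2)
  expect_setequal(aud$snp_id, c("rs2", "rs4"))
  expect_true(any(grepl("non-positive se", aud$reason)))
  expect_true(any(grepl("non-SNV", aud$reason)))
})

test_that("readSummaryTable maps arbitrary column names and hard-errors", {
  tsv <- tempfile(fileext = ".tsv")
  tab <- data.frame(rsid = "rs1", CHR = 1, POS = 100, EA = "A", OA = "G",
                    EAF = 0.2, BETA = 0.1, SE = 0.01, pval = 0.5, N = 1e4)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- readSummaryTable(tsv, columnMap = c(SNP = "rsid", P = "pval"))
  expect_equal(records(ds)$snp_id, "rs1")
  expect_error(readSummaryTable(tsv), "SNP -> 'SNP'")
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(readSummaryTable(empty), "empty")
})

test_that("duplicate rsIDs are dropped with a warning", {
  tsv <- tempfile(fileext = ".tsv")
  tab <- data.frame(SNP = c("rs1", "rs1", "rs2"), CHR = 1, POS = c(1, 1, 2) * 1e5,
                    EA = "A", OA = "G", EAF = 0.3, BETA = 0.1, SE = 0.01,
                    P = 1e-9, N = 1e5)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(expect_warning(ds <- readSummaryTable(tsv), "duplicate"))
  expect_equal(nrow(records(ds)), 2)
})

test_that("instrument selection mirrors the PCOS 14-to-13 exclusion", {
  # the 13 printed PCOS instruments plus a synthetic 14th candidate that is
  # palindromic with allele frequency 0.50 (the MAF-close-to-0.5 exclusion)
  t2 <- readTable2()
  pcos <- t2[t2$analysis == "primary" & t2$trait == "PCOS", ]
  extra <- makeRecords(1, snp_id = "rs853854", chrom = "3", pos = 1e6,
                       effect_allele = "A", other_allele = "T", eaf = 0.50,
                       beta = 0.1, se = 0.015, pvalue = 1e-10)
  rec <- rbind(data.frame(snp_id = pcos$SNP, chrom = pcos$CHR, pos = pcos$POS,
                          effect_allele = pcos$EA, other_allele = pcos$OA,
                          eaf = pcos$EAF, beta = pcos$BETA, se = pcos$SE,
                          pvalue = pcos$P, n = 113238), extra)
  ds <- SummaryDataset(rec, trait = "pcos")
  kept <- selectInstruments(ds)
  expect_equal(nrow(records(kept)), 13)
  expect_false("rs853854" %in% records(kept)$snp_id)
  aud <- auditTrail(kept)
  expect_match(aud$reason[aud$snp_id == "rs853854"], "palindromic")
})

test_that("selection thresholds are strict and reasons are recorded", {
  rec <- makeRecords(3, pvalue = c(5e-8, 1e-9, 1e-9),
                     eaf = c(0.3, 0.005, 0.3))
  ds <- SummaryDataset(rec, trait = "x")
  kept <- selectInstruments(ds)
  expect_equal(records(kept)$snp_id, "rs3")   # rs1 boundary p, rs2 MAF
  aud <- auditTrail(kept)
  expect_match(aud$reason[aud$snp_id == "rs1"], "significant")
  expect_match(aud$reason[aud$snp_id == "rs2"], "MAF")
  rec0 <- makeRecords(1, pvalue = 0.5)
  expect_warning(empty <- selectInstruments(SummaryDataset(rec0, trait = "x")),
                 "no instrument candidates")
  expect_equal(nrow(records(empty)), 0)
})

test_that("greedy clumping keeps the dominant SNP and respects the window", {
  r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(0.5)
  ld <- LDMatrix(r, snpIds = c("rs1", "rs2"), chrom = c("1", "1"),
                 pos = c(1e6, 1e6 + 1000))
  rec <- makeRecords(2, pos = c(1e6, 1e6 + 1000), pvalue = c(1e-10, 1e-9))
  out <- ldClump(SummaryDataset(rec, trait = "x"), ld)
  expect_equal(records(out)$snp_id, "rs1")

  ldFar <- LDMatrix(r, snpIds = c("rs1", "rs2"), chrom = c("1", "1"),
                    pos = c(1e6, 21e6))
  recFar <- makeRecords(2, pos = c(1e6, 21e6), pvalue = c(1e-10, 1e-9))
  outFar <- ldClump(SummaryDataset(recFar, trait = "x"), ldFar)
  expect_setequal(records(outFar)$snp_id, c("rs1", "rs2"))

  # unknown SNPs are unlinked-with-warning
  expect_warning(ldClump(SummaryDataset(makeRecords(1, snp_id = "rsX"),
                                        trait = "x"), ld),
                 "absent from LD reference")
})

test_that("greedy clumping matches the exhaustive oracle on 6-SNP instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- 6
    A <- matrix(rnorm(n * n), n)
    r <- cov2cor(crossprod(A) + diag(n) * 0.1)
    ids <- paste0("rs", 1:n)
    dimnames(r) <- list(ids, ids)
    pos <- sort(sample.int(30e6, n))
    ld <- LDMatrix(r, snpIds = ids, chrom = rep("1", n), pos = pos)
    rec <- makeRecords(n, pos = pos, beta = rnorm(n, 0, 0.2),
                       se = runif(n, 0.01, 0.05),
                       pvalue = 10^-runif(n, 8, 20))
    ds <- SummaryDataset(rec, trait = "x")
    got <- sort(records(ldClump(ds, ld, windowKb = 10000, r2Max = 0.1))$snp_id)
    expect_equal(got, clumpOracle(rec, r, 10000, 0.1), info = paste("seed", s))
    # order insensitivity
    perm <- SummaryDataset(rec[sample.int(n), ], trait = "x")
    gotPerm <- sort(records(ldClump(perm, ld, 10000, 0.1))$snp_id)
    expect_equal(gotPerm, got)
  }
})

test_that("clumped output never contains a linked pair within the window", {
  set.seed(99)
  n <- 12
  A <- matrix(rnorm(n * n), n)
  r <- cov2cor(crossprod(A) + diag(n) * 0.05)
  ids <- paste0("rs", 1:n)
  dimnames(r) <- list(ids, ids)
  pos <- sort(sample.int(50e6, n))
  ld <- LDMatrix(r, snpIds = ids, chrom = rep("1", n), pos = pos)
  rec <- makeRecords(n, pos = pos, pvalue = 10^-runif(n, 8, 20))
  kept <- records(ldClump(SummaryDataset(rec, trait = "x"), ld,
                          windowKb = 10000, r2Max = 0.2))
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i >= j) next
    if (abs(kept$pos[i] - kept$pos[j]) <= 1e7)
      expect_lt(r[kept$snp_id[i], kept$snp_id[j]]^2, 0.2)
  }
})

test_that("proxy lookup returns the best in-window variant or nothing", {
  ids <- c("target", "p1", "p2", "far")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- sqrt(0.85)
  r[1, 3] <- r[3, 1] <- sqrt(0.92)
  r[1, 4] <- r[4, 1] <- sqrt(0.95)
  ld <- LDMatrix(r, snpIds = ids, chrom = rep("1", 4),
                 pos = c(5e6, 5e6 + 1e4, 5e6 - 2e4, 5e6 + 2e6))
  outc <- SummaryDataset(makeRecords(3, snp_id = c("p1", "p2", "far"),
                                     pos = c(5e6 + 1e4, 5e6 - 2e4, 5e6 + 2e6)),
                         trait = "y")
  target <- data.frame(snp_id = "target", chrom = "1", pos = 5e6)
  hit <- findProxy(target, outc, ld)
  expect_equal(hit$snp_id, "p2")       # r2 0.92 beats 0.85; "far" outside 1 Mb
  none <- findProxy(target, outc, ld, r2Min = 0.93)
  expect_null(none)
  single <- findProxy(target,
                      SummaryDataset(makeRecords(1, snp_id = "p1",
                                                 pos = 5e6 + 1e4),
                                     trait = "y"), ld, r2Min = 0.8)
  expect_equal(single$snp_id, "p1")
})

test_that("harmonization resolves the full allele-configuration truth table", {
  # exposure record fixed at EA/OA = T/C, beta 0.3, eaf 0.2; expected
  # outcome beta worked out by hand for each of the 8 configurations of a
  # non-palindromic variant reported with beta -0.2
  cases <- data.frame(
    oEA = c("T", "C", "A", "G"),
    oOA = c("C", "T", "G", "A"),
    expected = c(-0.2, 0.2, -0.2, 0.2))   # same, swap, complement, comp+swap
  for (i in seq_len(nrow(cases))) {
    expo <- SummaryDataset(makeRecords(1, effect_allele = "T",
                                       other_allele = "C", beta = 0.3,
                                       eaf = 0.2), trait = "e")
    outc <- SummaryDataset(makeRecords(1, effect_allele = cases$oEA[i],
                                       other_allele = cases$oOA[i],
                                       beta = -0.2, eaf = if (cases$expected[i] < 0) 0.2 else 0.8),
                           trait = "o")
    h <- harmonize(expo, outc)
    expect_equal(harmonizedData(h)$beta_outcome, cases$expected[i],
                 info = paste(cases$oEA[i], cases$oOA[i]))
    expect_equal(harmonizedData(h)$eaf_outcome, 0.2)
  }
  # irreconcilable allele sets are dropped with a reason
  expo <- SummaryDataset(makeRecords(1, effect_allele = "T",
                                     other_allele = "C"), trait = "e")
  outc <- SummaryDataset(makeRecords(1, effect_allele = "A",
                                     other_allele = "C"), trait = "o")
  h <- harmonize(expo, outc)
  expect_equal(nrow(harmonizedData(h)), 0)
  expect_match(auditTrail(h)$reason, "irreconcilable")
})

test_that("palindromic variants follow the EAF-concordance policy", {
  expo <- SummaryDataset(makeRecords(1, effect_allele = "A",
                                     other_allele = "T", beta = 0.3,
                                     eaf = 0.2), trait = "e")
  concordant <- SummaryDataset(makeRecords(1, effect_allele = "A",
                                           other_allele = "T", beta = 0.1,
                                           eaf = 0.25), trait = "o")
  h <- harmonize(expo, concordant)
  expect_equal(harmonizedData(h)$beta_outcome, 0.1)
  discordant <- SummaryDataset(makeRecords(1, effect_allele = "A",
                                           other_allele = "T", beta = 0.1,
                                           eaf = 0.75), trait = "o")
  h2 <- harmonize(expo, discordant)
  expect_equal(harmonizedData(h2)$beta_outcome, -0.1)
  ambiguous <- SummaryDataset(makeRecords(1, effect_allele = "A",
                                          other_allele = "T", beta = 0.1,
                                          eaf = 0.5), trait = "o")
  expect_equal(nrow(harmonizedData(harmonize(expo, ambiguous))), 0)
  expect_equal(nrow(harmonizedData(harmonize(expo, concordant,
                                             palindromicPolicy = "drop"))), 0)
})

test_that("harmonization is idempotent and invariant to allele relabeling", {
  set.seed(11)
  n <- 8
  ea <- sample(c("A", "T", "C", "G"), n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(c("A", "C", "G", "T"),
                                              c(a, chartr("ACGT", "TGCA", a))), 1),
               character(1))
  expo <- SummaryDataset(makeRecords(n, effect_allele = ea, other_allele = oa,
                                     beta = rnorm(n, 0, 0.2),
                                     eaf = runif(n, 0.1, 0.4)), trait = "e")
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  orec <- records(expo)
  orec$beta <- rnorm(n, 0, 0.1)
  keepBeta <- orec$beta
  orec[swap, c("effect_allele", "other_allele")] <-
    orec[swap, c("other_allele", "effect_allele")]
  orec$beta[swap] <- -orec$beta[swap]
  orec$eaf[swap] <- 1 - orec$eaf[swap]
  outc <- SummaryDataset(orec, trait = "o")
  h1 <- harmonizedData(harmonize(expo, outc))
  expect_equal(h1$beta_outcome, keepBeta)

  # idempotence: harmonizing the already-aligned pair changes nothing
  alignedOut <- records(expo)
  alignedOut$beta <- h1$beta_outcome
  h2 <- harmonizedData(harmonize(expo, SummaryDataset(alignedOut,
                                                      trait = "o")))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)

  # relabeling the exposure effect allele flips both betas coherently
  erec <- records(expo)
  erec[, c("effect_allele", "other_allele")] <-
    erec[, c("other_allele", "effect_allele")]
  erec$beta <- -erec$beta
  erec$eaf <- 1 - erec$eaf
  h3 <- harmonizedData(harmonize(SummaryDataset(erec, trait = "e"), outc))
  expect_equal(h3$beta_outcome, -h1$beta_outcome)
  expect_equal(h3$beta_exposure, -h1$beta_exposure)
})

test_that("EAF discordance is flagged but retained", {
  expo <- SummaryDataset(makeRecords(1, eaf = 0.1), trait = "e")
  outc <- SummaryDataset(makeRecords(1, eaf = 0.45), trait = "o")
  h <- harmonize(expo, outc)
  expect_equal(nrow(harmonizedData(h)), 1)
  expect_true(harmonizedData(h)$eaf_flag)
})

test_that("harmonization substitutes proxies when the policy allows", {
  ids <- c("rs1", "prx")
  r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(0.9)
  ld <- LDMatrix(r, snpIds = ids, chrom = c("1", "1"), pos = c(1e6, 1.01e6))
  expo <- SummaryDataset(makeRecords(1, snp_id = "rs1", pos = 1e6,
                                     beta = 0.3), trait = "e")
  outc <- SummaryDataset(makeRecords(1, snp_id = "prx", pos = 1.01e6,
                                     beta = 0.12), trait = "o")
  h <- harmonize(expo, outc, ld)
  expect_equal(harmonizedData(h)$proxy_of, "rs1")
  expect_equal(harmonizedData(h)$beta_outcome, 0.12)
  hDrop <- harmonize(expo, outc, ld, proxyPolicy = "drop")
  expect_equal(nrow(harmonizedData(hDrop)), 0)
})

test_that("instrument F statistics follow the squared z definition", {
  expect_equal(fStatistic(0.603, 0.041), (0.603 / 0.041)^2)
  expect_equal(fStatistic(0.603, 0.041), 216.3, tolerance = 5e-4)
  # the printed value (219.1) comes from unrounded inputs; 2% agreement
  expect_equal(fStatistic(0.603, 0.041), 219.1, tolerance = 0.02)
  expect_equal(fStatistic(0.25, 0.25), 1)
  expect_equal(fStatistic(0, 0.1), 0)
  expect_error(fStatistic(0.1, 0), "se > 0")
})

test_that("LD matrices survive a write/read round trip", {
  ld <- simulateLDMatrix(mSnps = 6, blockSize = 3, rho = 0.4)
  mat <- tempfile(fileext = ".tsv"); side <- tempfile(fileext = ".tsv")
  writeLDMatrix(ld, mat, side)
  back <- readLDMatrix(mat, side)
  expect_equal(back@r, ld@r, tolerance = 1e-12)
  expect_equal(back@pos, ld@pos)
})
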