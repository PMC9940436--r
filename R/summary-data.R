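#' @include AllClasses.R
NULL

.complement <- function(a) chartr("ACGT", "TGCA", a)

.isPalindromic <- function(ea, oa) .complement(ea) == oa

.audit <- function(snp_id = character(), action = character(),
                   reason = character()) {
  n <- length(snp_id)
  data.frame(snp_id = snp_id, action = rep_len(action, n),
             reason = rep_len(reason, n), stringsAsFactors = FALSE)
}

#' Construct a SummaryDataset from a variant data.frame
#'
#' @param records data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n.
#' @param trait trait name.
#' @param traitType "binary" (beta on the log-odds scale) or "continuous"
#'   (SD units).
#' @param ancestry ancestry label.
#' @param audit optional pre-existing audit trail.
#' @return a \linkS4class{SummaryDataset}.
#' @export
SummaryDataset <- function(records, trait, traitType = "binary",
                           ancestry = "EUR", audit = .audit()) {
  records <- as.data.frame(records)[, .recordCols]
  records$chrom <- as.character(records$chrom)
  rownames(records) <- NULL
  new("SummaryDataset", trait = trait, traitType = traitType,
      ancestry = ancestry, records = records, audit = audit)
}

#' Construct an LDMatrix
#'
#' @param r square symmetric allelic-correlation matrix (r, not r-squared)
#'   with unit diagonal; row/column names are variant IDs unless `snpIds`
#'   is given.
#' @param snpIds,chrom,pos variant identifiers and coordinates.
#' @return an \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(r, snpIds = rownames(r), chrom, pos) {
  r <- as.matrix(r)
  dimnames(r) <- list(snpIds, snpIds)
  new("LDMatrix", snpIds = as.character(snpIds), r = r,
      chrom = as.character(chrom), pos = as.numeric(pos))
}

#' Read / write an LD reference
#'
#' The matrix file is a TSV whose first row and first column hold the
#' variant IDs; the side-car TSV has columns snp_id, chrom, pos.
#'
#' @param path matrix TSV path.
#' @param sidecarPath coordinates TSV path.
#' @return an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path, sidecarPath) {
  r <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  side <- utils::read.delim(sidecarPath, stringsAsFactors = FALSE)
  m <- match(rownames(r), side$snp_id)
  if (anyNA(m)) stop("side-car is missing coordinates for some variants")
  LDMatrix(r, snpIds = rownames(r), chrom = side$chrom[m], pos = side$pos[m])
}

#' @rdname readLDMatrix
#' @param ld an \linkS4class{LDMatrix} to write.
#' @export
writeLDMatrix <- function(ld, path, sidecarPath) {
  utils::write.table(data.frame(snp_id = ld@snpIds, ld@r,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(snp_id = ld@snpIds, chrom = ld@chrom,
                                pos = ld@pos),
                     sidecarPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.ldR2 <- function(ld, a, b) {
  i <- match(a, ld@snpIds); j <- match(b, ld@snpIds)
  if (is.na(i) || is.na(j)) return(NA_real_)
  ld@r[i, j]^2
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header, maps physical column names to
#' the canonical fields (SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N), and
#' validates each row: alleles must be single non-identical bases (so
#' insertion/deletion codes like "I"/"D" are rejected as non-SNV), se > 0,
#' eaf in [0, 1], p in (0, 1]. Failing rows and duplicate rsIDs are dropped
#' and counted in the audit trail.
#'
#' @param path file path of the tab-separated table.
#' @param columnMap named character vector mapping canonical names to the
#'   physical column names in the file, e.g. `c(SNP = "rsid", P = "pval")`.
#'   Canonical names not listed are assumed to appear verbatim.
#' @param trait,traitType,ancestry dataset metadata (see
#'   \code{\link{SummaryDataset}}).
#' @return a validated \linkS4class{SummaryDataset}; dropped-row counts are
#'   reported via `message()` and kept in `auditTrail()`.
#' @export
readSummaryTable <- function(path, columnMap = NULL, trait = "trait",
                             traitType = "binary", ancestry = "EUR") {
  if (!file.size(path) > 0) stop("empty summary-statistics file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path)
  canonical <- c(SNP = "snp_id", CHR = "chrom", POS = "pos",
                 EA = "effect_allele", OA = "other_allele", EAF = "eaf",
                 BETA = "beta", SE = "se", P = "pvalue", N = "n")
  physical <- stats::setNames(names(canonical), names(canonical))
  if (!is.null(columnMap)) physical[names(columnMap)] <- columnMap
  missing <- physical[!physical %in% names(raw)]
  if (length(missing))
    stop("mapped column(s) not found in ", path, ": ",
         paste(sprintf("%s -> '%s'", names(missing), missing), collapse = ", "))
  rec <- stats::setNames(raw[, physical], canonical)
  rec$effect_allele <- toupper(rec$effect_allele)
  rec$other_allele <- toupper(rec$other_allele)

  drop <- rep("", nrow(rec))
  bad <- !(rec$effect_allele %in% VALID_BASES &
           rec$other_allele %in% VALID_BASES)
  drop[bad & drop == ""] <- "non-SNV or invalid alleles"
  bad <- rec$effect_allele == rec$other_allele
  drop[bad & drop == ""] <- "identical alleles"
  suppressWarnings({
    num <- c("pos", "eaf", "beta", "se", "pvalue", "n")
    rec[num] <- lapply(rec[num], as.numeric)
  })
  bad <- !is.finite(rec$beta) | !is.finite(rec$se) | rec$se <= 0
  drop[bad & drop == ""] <- "missing beta or non-positive se"
  bad <- !is.finite(rec$eaf) | rec$eaf < 0 | rec$eaf > 1
  drop[bad & drop == ""] <- "eaf outside [0, 1]"
  bad <- !is.finite(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1
  drop[bad & drop == ""] <- "pvalue outside (0, 1]"
  bad <- duplicated(rec$snp_id)
  if (any(bad & drop == ""))
    warning("dropping ", sum(bad & drop == ""), " duplicate rsID record(s)")
  drop[bad & drop == ""] <- "duplicate rsID"

  dropped <- drop != ""
  audit <- .audit(rec$snp_id[dropped], "dropped", drop[dropped])
  if (any(dropped))
    message(sum(dropped), " of ", nrow(rec), " rows dropped reading ", path)
  SummaryDataset(rec[!dropped, ], trait = trait, traitType = traitType,
                 ancestry = ancestry, audit = audit)
}

#' Select candidate genetic instruments
#'
#' Keeps genome-wide significant variants (strictly p < `pThreshold`) with
#' minor allele frequency above `mafMin`, and removes palindromic (A/T or
#' C/G) variants whose effect-allele frequency falls inside the ambiguity
#' band around 0.5 (strand unresolvable from alleles, mirroring the
#' exclusion of instruments with MAF close to 0.5).
#'
#' @param dataset a \linkS4class{SummaryDataset}.
#' @param pThreshold genome-wide significance threshold (strict `<`).
#' @param mafMin minimum minor allele frequency (strict `>`).
#' @param palindromeEafBand open EAF interval within which palindromic
#'   variants are excluded (a frequency exactly at a band edge is kept).
#' @return a \linkS4class{SummaryDataset} of retained candidates; kept and
#'   excluded decisions (with reasons) are appended to the audit trail. Zero
#'   survivors yields an empty dataset with a warning.
#' @export
selectInstruments <- function(dataset, pThreshold = 5e-8, mafMin = 0.01,
                              palindromeEafBand = c(0.42, 0.58)) {
  rec <- dataset@records
  reason <- rep("", nrow(rec))
  reason[rec$pvalue >= pThreshold] <- "not genome-wide significant"
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  reason[reason == "" & maf <= mafMin] <- "MAF below threshold"
  pal <- .isPalindromic(rec$effect_allele, rec$other_allele)
  # open interval: an EAF exactly at the band edge is not "close to 0.5"
  amb <- pal & rec$eaf > palindromeEafBand[1] & rec$eaf < palindromeEafBand[2]
  reason[reason == "" & amb] <- "palindromic with EAF close to 0.5"
  keep <- reason == ""
  audit <- rbind(dataset@audit,
                 .audit(rec$snp_id, ifelse(keep, "kept", "excluded"),
                        ifelse(keep, "instrument candidate", reason)))
  if (!any(keep)) warning("no instrument candidates survive selection for ",
                          dataset@trait)
  SummaryDataset(rec[keep, ], trait = dataset@trait,
                 traitType = dataset@traitType, ancestry = dataset@ancestry,
                 audit = audit)
}

#' Greedy LD clumping of instrument candidates
#'
#' Sorts candidates by ascending p-value (ties broken by larger |beta/se|,
#' then lexicographic rsID), keeps the best, discards any remaining
#' candidate within `windowKb` of a kept variant (same chromosome, symmetric
#' inclusive window) with r-squared at or above `r2Max`, and repeats. The
#' single most significant candidate is always kept. Candidates absent from
#' the LD reference are treated as unlinked and kept, with a warning.
#'
#' @param candidates a \linkS4class{SummaryDataset} (e.g. from
#'   \code{\link{selectInstruments}}).
#' @param ld an \linkS4class{LDMatrix}.
#' @param windowKb clumping window half-width in kilobases.
#' @param r2Max maximum pairwise r-squared tolerated within the window.
#' @return a \linkS4class{SummaryDataset} of approximately independent
#'   instruments (empty in, empty out).
#' @export
ldClump <- function(candidates, ld, windowKb = 10000, r2Max = 0.001) {
  rec <- candidates@records
  if (nrow(rec) == 0) return(candidates)
  missing <- setdiff(rec$snp_id, ld@snpIds)
  if (length(missing))
    warning("candidate(s) absent from LD reference treated as unlinked: ",
            paste(missing, collapse = ", "))
  ord <- order(rec$pvalue, -abs(rec$beta / rec$se), rec$snp_id)
  rec <- rec[ord, ]
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(rec)) break
    for (j in seq(i + 1, nrow(rec))) {
      if (!alive[j]) next
      inWindow <- rec$chrom[j] == rec$chrom[i] &&
        abs(rec$pos[j] - rec$pos[i]) <= windowKb * 1000
      if (!inWindow) next
      r2 <- .ldR2(ld, rec$snp_id[i], rec$snp_id[j])
      if (!is.na(r2) && r2 >= r2Max) alive[j] <- FALSE
    }
  }
  audit <- rbind(candidates@audit,
                 .audit(rec$snp_id, ifelse(keep, "kept", "excluded"),
                        ifelse(keep, "clump index variant",
                               "clumped: in LD with a better candidate")))
  out <- rec[keep, ]
  out <- out[order(match(out$snp_id, candidates@records$snp_id)), ]
  SummaryDataset(out, trait = candidates@trait,
                 traitType = candidates@traitType,
                 ancestry = candidates@ancestry, audit = audit)
}

#' Find a proxy variant in the outcome dataset
#'
#' For an instrument absent from the outcome GWAS, searches outcome variants
#' within `windowKb` of the target (same chromosome) with r-squared at least
#' `r2Min` in the LD reference, and returns the highest-r2 candidate (ties:
#' closest position, then lexicographic rsID).
#'
#' @param targetSnp a single-row variant record (data.frame) with snp_id,
#'   chrom, pos.
#' @param outcomeDataset the outcome \linkS4class{SummaryDataset}.
#' @param ld an \linkS4class{LDMatrix} containing the target.
#' @param r2Min minimum r-squared for an acceptable proxy.
#' @param windowKb search window half-width in kilobases.
#' @return the proxy variant record (one-row data.frame) or NULL.
#' @export
findProxy <- function(targetSnp, outcomeDataset, ld, r2Min = 0.8,
                      windowKb = 1000) {
  rec <- outcomeDataset@records
  cand <- rec[rec$chrom == as.character(targetSnp$chrom) &
              abs(rec$pos - targetSnp$pos) <= windowKb * 1000 &
              rec$snp_id != targetSnp$snp_id, ]
  if (nrow(cand) == 0) return(NULL)
  r2 <- vapply(cand$snp_id, function(s) .ldR2(ld, targetSnp$snp_id, s),
               numeric(1))
  cand <- cand[!is.na(r2) & r2 >= r2Min, , drop = FALSE]
  r2 <- r2[!is.na(r2) & r2 >= r2Min]
  if (nrow(cand) == 0) return(NULL)
  ord <- order(-r2, abs(cand$pos - targetSnp$pos), cand$snp_id)
  cand[ord[1], ]
}

#' Harmonize exposure and outcome associations onto one strand
#'
#' Aligns each exposure instrument with its outcome record (looked up by
#' rsID, or substituted by \code{\link{findProxy}} when `proxyPolicy` is
#' "proxy" and an LD reference is supplied). If the outcome alleles are
#' swapped relative to the exposure, the outcome beta sign is flipped and
#' its EAF reflected; if they are on the opposite strand, alleles are
#' complemented before matching. Palindromic variants (complement equals
#' swap, so strand is unresolvable from alleles) are resolved by EAF
#' concordance when both EAFs lie outside `palindromeEafBand`
#' (`palindromicPolicy = "infer"`), otherwise dropped; rows whose
#' exposure/outcome EAFs differ by more than `eafFlagThreshold` are
#' retained but flagged.
#'
#' @param exposure,outcome \linkS4class{SummaryDataset} objects.
#' @param ld optional \linkS4class{LDMatrix} for proxy lookup.
#' @param proxyPolicy "proxy" to substitute missing instruments, "drop" to
#'   skip them.
#' @param palindromicPolicy "infer" (EAF concordance outside the band) or
#'   "drop" (drop all palindromic instruments).
#' @param palindromeEafBand EAF ambiguity band for palindromic variants.
#' @param eafFlagThreshold absolute EAF discordance above which a row is
#'   flagged (retained but reported).
#' @param proxyR2Min,proxyWindowKb proxy search parameters.
#' @return a \linkS4class{HarmonizedSet}.
#' @export
harmonize <- function(exposure, outcome, ld = NULL,
                      proxyPolicy = c("proxy", "drop"),
                      palindromicPolicy = c("infer", "drop"),
                      palindromeEafBand = c(0.42, 0.58),
                      eafFlagThreshold = 0.2,
                      proxyR2Min = 0.8, proxyWindowKb = 1000) {
  proxyPolicy <- match.arg(proxyPolicy)
  palindromicPolicy <- match.arg(palindromicPolicy)
  erec <- exposure@records
  orec <- outcome@records
  rows <- vector("list", nrow(erec))
  audit <- .audit()
  for (i in seq_len(nrow(erec))) {
    e <- erec[i, ]
    proxyOf <- NA_character_
    j <- match(e$snp_id, orec$snp_id)
    o <- if (!is.na(j)) orec[j, ] else NULL
    if (is.null(o) && proxyPolicy == "proxy" && !is.null(ld)) {
      o <- findProxy(e, outcome, ld, r2Min = proxyR2Min,
                     windowKb = proxyWindowKb)
      if (!is.null(o)) proxyOf <- e$snp_id
    }
    if (is.null(o)) {
      audit <- rbind(audit, .audit(e$snp_id, "dropped",
                                   "absent from outcome (no proxy)"))
      next
    }
    pal <- .isPalindromic(e$effect_allele, e$other_allele)
    oEA <- o$effect_allele; oOA <- o$other_allele
    oBeta <- o$beta; oEaf <- o$eaf
    matched <- FALSE
    if (pal && is.na(proxyOf)) {
      if (palindromicPolicy == "drop") {
        audit <- rbind(audit, .audit(e$snp_id, "dropped",
                                     "palindromic (policy: drop)"))
        next
      }
      inBand <- function(f) f > palindromeEafBand[1] & f < palindromeEafBand[2]
      if (!setequal(c(oEA, oOA), c(e$effect_allele, e$other_allele))) {
        audit <- rbind(audit, .audit(e$snp_id, "dropped",
                                     "irreconcilable alleles"))
        next
      }
      if (inBand(e$eaf) || inBand(oEaf)) {
        audit <- rbind(audit, .audit(e$snp_id, "dropped",
                                     "palindromic with ambiguous EAF"))
        next
      }
      # strand resolved by frequency concordance: flip when the outcome EAF
      # sits on the other side of 0.5 for the nominally matching allele
      if (oEA == e$effect_allele) {
        if ((e$eaf < 0.5) != (oEaf < 0.5)) { oBeta <- -oBeta; oEaf <- 1 - oEaf }
      } else {
        oBeta <- -oBeta; oEaf <- 1 - oEaf
        if ((e$eaf < 0.5) != (oEaf < 0.5)) { oBeta <- -oBeta; oEaf <- 1 - oEaf }
      }
      matched <- TRUE
    } else {
      if (oEA == e$effect_allele && oOA == e$other_allele) {
        matched <- TRUE
      } else if (oEA == e$other_allele && oOA == e$effect_allele) {
        oBeta <- -oBeta; oEaf <- 1 - oEaf; matched <- TRUE
      } else {
        cEA <- .complement(oEA); cOA <- .complement(oOA)
        if (cEA == e$effect_allele && cOA == e$other_allele) {
          matched <- TRUE
        } else if (cEA == e$other_allele && cOA == e$effect_allele) {
          oBeta <- -oBeta; oEaf <- 1 - oEaf; matched <- TRUE
        }
      }
      if (!matched && is.na(proxyOf)) {
        audit <- rbind(audit, .audit(e$snp_id, "dropped",
                                     "irreconcilable alleles"))
        next
      }
      # proxy rows: alleles belong to a different variant; orient by EAF
      if (!matched) {
        if ((e$eaf < 0.5) != (oEaf < 0.5)) { oBeta <- -oBeta; oEaf <- 1 - oEaf }
        matched <- TRUE
      }
    }
    flag <- abs(e$eaf - oEaf) > eafFlagThreshold
    if (flag)
      audit <- rbind(audit, .audit(e$snp_id, "flagged", "EAF discordance > threshold"))
    rows[[i]] <- data.frame(
      snp_id = e$snp_id, beta_exposure = e$beta, se_exposure = e$se,
      beta_outcome = oBeta, se_outcome = o$se, eaf_exposure = e$eaf,
      eaf_outcome = oEaf, palindromic = pal, proxy_of = proxyOf,
      eaf_flag = flag, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(d)) d <- data.frame(
    snp_id = character(), beta_exposure = numeric(), se_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(), eaf_exposure = numeric(),
    eaf_outcome = numeric(), palindromic = logical(), proxy_of = character(),
    eaf_flag = logical(), stringsAsFactors = FALSE)
  rownames(d) <- NULL
  scaleOf <- function(x) if (x@traitType == "binary") "log-odds" else "sd"
  new("HarmonizedSet", data = d, exposure = exposure@trait,
      outcome = outcome@trait, exposureScale = scaleOf(exposure),
      outcomeScale = scaleOf(outcome), audit = audit)
}

#' Instrument-strength F statistic
#'
#' Approximates the first-stage F statistic of a single instrument as the
#' squared z-score, F = (beta/se)^2. Values above 10 are conventionally
#' regarded as strong.
#'
#' @param beta,se association estimate and its standard error (vectorized);
#'   alternatively `beta` may be a data.frame with beta/se columns.
#' @return numeric vector of F values.
#' @export
fStatistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) { se <- beta$se; beta <- beta$beta }
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Write a filter audit trail as TSV
#'
#' @param object a \linkS4class{SummaryDataset} or
#'   \linkS4class{HarmonizedSet}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAuditTrail <- function(object, path) {
  utils::write.table(auditTrail(object), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
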