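#' @include AllClasses.R mr-core.R mvmr.R
NULL

#' Construct a PathwaySpec
#'
#' Stage estimates are entered on the additive scale: log-odds stages as
#' logs, SD-unit stages as-is. Optional `from`/`to` labels let the validity
#' check confirm the chain composes head-to-tail.
#'
#' @param labels unique stage labels, in causal order.
#' @param theta stage point estimates.
#' @param se stage standard errors.
#' @param from,to optional endpoint trait names per stage.
#' @return a \linkS4class{PathwaySpec}.
#' @export
PathwaySpec <- function(labels, theta, se, from = character(),
                        to = character()) {
  new("PathwaySpec", labels = labels, theta = as.numeric(theta),
      se = as.numeric(se), from = from, to = to)
}

#' Back out a standard error from a printed confidence interval
#'
#' se = (upper - lower) / (2 z) with z the 0.975 normal quantile
#' (1.959964). For odds-ratio-scale intervals take `scale = "log"`: the
#' bounds are logged first (non-positive bounds are an error).
#'
#' @param lower,upper interval bounds, upper > lower.
#' @param level confidence level of the printed interval.
#' @param scale "identity" for beta-scale CIs, "log" for OR-scale CIs.
#' @return the implied standard error.
#' @export
seFromCI <- function(lower, upper, level = 0.95,
                     scale = c("identity", "log")) {
  scale <- match.arg(scale)
  if (scale == "log") {
    if (any(c(lower, upper) <= 0))
      stop("odds-ratio bounds must be positive to take logs")
    lower <- log(lower); upper <- log(upper)
  }
  if (!all(upper > lower)) stop("upper bound must exceed lower bound")
  (upper - lower) / (2 * stats::qnorm(1 - (1 - level) / 2))
}

#' Product-of-coefficients indirect effect
#'
#' @param path a \linkS4class{PathwaySpec}.
#' @return the product of the stage point estimates (log-odds scale when
#'   the terminal stage is log-odds).
#' @export
productOfCoefficients <- function(path) prod(path@theta)

#' Multivariate delta-method SE of a product of stage effects
#'
#' Treating stages as independent (two-sample designs), the variance of the
#' product is sum_i sigma_i^2 * prod_{j != i} theta_j^2, the expanded
#' first-order delta form; it is symmetric under stage permutation and well
#' defined when a stage estimate is exactly 0.
#'
#' @param path a \linkS4class{PathwaySpec}.
#' @return the delta-method standard error of the product.
#' @export
deltaSEProduct <- function(path) {
  th <- path@theta; s <- path@se
  v <- vapply(seq_along(th), function(i) s[i]^2 * prod(th[-i]^2), numeric(1))
  sqrt(sum(v))
}

#' Proportion of the total effect mediated
#'
#' 100 * indirect / total on the log-odds scale. Opposite signs
#' (inconsistent mediation) yield a negative proportion with a warning.
#'
#' @param indirect,total effects on a common log-odds scale; total != 0.
#' @return percentage mediated.
#' @export
proportionMediated <- function(indirect, total) {
  if (total == 0) stop("total effect must be nonzero")
  if (indirect != 0 && sign(indirect) != sign(total))
    warning("inconsistent mediation: indirect and total effects have ",
            "opposite signs")
  100 * indirect / total
}

#' Grade MR evidence under the five-trait Bonferroni policy
#'
#' With five exposures examined, p < 0.01 (0.05/5) is strong evidence,
#' 0.01 <= p < 0.05 suggestive, and p >= 0.05 none.
#'
#' @param pvalue p-value(s) in (0, 1].
#' @param strongCut,suggestiveCut policy thresholds.
#' @return character vector of grades.
#' @export
classifyEvidence <- function(pvalue, strongCut = 0.01, suggestiveCut = 0.05) {
  ifelse(pvalue < strongCut, "strong",
         ifelse(pvalue < suggestiveCut, "suggestive", "none"))
}

#' Remove blacklisted (obesity-associated) instruments
#'
#' @param instruments a \linkS4class{SummaryDataset} or
#'   \linkS4class{HarmonizedSet}.
#' @param blacklist character vector of rsIDs, or path to a TSV whose first
#'   column is snp_id (optional reason column).
#' @return the filtered object; removals are logged in the audit trail.
#' @export
obesitySnpFilter <- function(instruments, blacklist) {
  if (is.character(blacklist) && length(blacklist) == 1 &&
      file.exists(blacklist))
    blacklist <- utils::read.delim(blacklist,
                                   stringsAsFactors = FALSE)[[1]]
  if (is(instruments, "HarmonizedSet")) {
    hit <- instruments@data$snp_id %in% blacklist
    instruments@audit <- rbind(instruments@audit,
      .audit(instruments@data$snp_id[hit], "excluded",
             "obesity-associated instrument"))
    instruments@data <- instruments@data[!hit, ]
    return(instruments)
  }
  rec <- instruments@records
  hit <- rec$snp_id %in% blacklist
  SummaryDataset(rec[!hit, ], trait = instruments@trait,
                 traitType = instruments@traitType,
                 ancestry = instruments@ancestry,
                 audit = rbind(instruments@audit,
                               .audit(rec$snp_id[hit], "excluded",
                                      "obesity-associated instrument")))
}

#' Mediation result for one pathway
#'
#' Combines the product of coefficients with its delta-method interval, a
#' two-sided normal p-value, the proportion of the supplied total effect
#' mediated, and the evidence grade.
#'
#' @param path a \linkS4class{PathwaySpec}.
#' @param total total effect on the log-odds scale (the denominator for the
#'   proportion; conventionally the obesity-SNP-excluded total effect).
#' @param level confidence level.
#' @return a \linkS4class{MediationResult}.
#' @export
mediationEffect <- function(path, total, level = 0.95) {
  est <- productOfCoefficients(path)
  se <- deltaSEProduct(path)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  new("MediationResult", estimate = est, se = se, ciLow = est - z * se,
      ciHigh = est + z * se, pvalue = p,
      proportion = proportionMediated(est, total),
      grade = classifyEvidence(p), path = path)
}

.naNote <- function(notes, stage, why) c(notes, paste0(stage,
  " not applicable: ", why))

#' Run the stepwise MR mediation analysis
#'
#' Executes the full causal-chain workup from summary datasets:
#' (i) total effect of the liver exposure on the reproductive outcome by
#' univariable IVW, with and without obesity-associated instruments;
#' (ii) multivariable MR of \{NAFLD, fasting insulin, fasting glucose,
#' SHBG, bioavailable testosterone\} on PCOS for the direct effects
#' theta1 (NAFLD), theta2 (insulin) and theta3 (testosterone), plus null
#' checks for glucose and SHBG; (iii) multivariable MR onto bioavailable
#' testosterone for theta4 (SHBG -> BT); (iv) multivariable MR onto SHBG
#' for theta5 (insulin -> SHBG); (v) univariable IVW of NAFLD on fasting
#' insulin after the obesity filter for theta6; (vi) both pathway products
#' (theta2 x theta6; theta3 x theta4 x theta5 x theta6) with delta-method
#' CIs and proportions mediated against the obesity-filtered total effect;
#' (vii) conditional F tables; (viii) evidence grades. A stage lacking the
#' minimum instruments is marked not applicable in the notes and the
#' report is still produced.
#'
#' @param datasets named list of \linkS4class{SummaryDataset}: nafld, fi,
#'   fg, shbg, bt, pcos.
#' @param ld an \linkS4class{LDMatrix}.
#' @param blacklist obesity-associated rsIDs (vector or TSV path).
#' @param pThreshold,mafMin,windowKb,r2Max selection/clumping thresholds.
#' @return a \linkS4class{MediationReport}.
#' @export
runStepwiseMediation <- function(datasets, ld, blacklist = character(),
                                 pThreshold = 5e-8, mafMin = 0.01,
                                 windowKb = 10000, r2Max = 0.001) {
  need <- c("nafld", "fi", "fg", "shbg", "bt", "pcos")
  stopifnot(all(need %in% names(datasets)))
  notes <- character()
  prep <- function(ds) suppressWarnings(
    ldClump(selectInstruments(ds, pThreshold, mafMin), ld, windowKb, r2Max))
  uniIVW <- function(expo, outc, filter = FALSE) {
    ins <- prep(datasets[[expo]])
    if (filter) ins <- obesitySnpFilter(ins, blacklist)
    if (nrow(ins@records) < 1) return(NULL)
    mrIVW(harmonize(ins, datasets[[outc]], ld), "auto")
  }
  mvStep <- function(expos, outc) {
    ms <- try(buildMultiExposureSet(datasets[expos], datasets[[outc]], ld,
                                    pThreshold, mafMin,
                                    windowKb = windowKb, r2Max = r2Max),
              silent = TRUE)
    if (inherits(ms, "try-error")) return(NULL)
    ids <- setdiff(ms@snpIds, if (is.character(blacklist)) blacklist else
      character())
    keep <- ms@snpIds %in% ids
    if (sum(keep) < length(ms@exposures) + 1) return(NULL)
    ms2 <- MultiExposureSet(ms@snpIds[keep],
                            ms@betaExposure[keep, , drop = FALSE],
                            ms@seExposure[keep, , drop = FALSE],
                            ms@betaOutcome[keep], ms@seOutcome[keep],
                            exposures = ms@exposures,
                            exposureScales = ms@exposureScales,
                            outcome = ms@outcome,
                            outcomeScale = ms@outcomeScale)
    list(est = mvmrIVW(ms2), condF = conditionalF(ms2))
  }

  total <- uniIVW("nafld", "pcos")
  totalF <- uniIVW("nafld", "pcos", filter = TRUE)
  if (is.null(totalF)) notes <- .naNote(notes, "total effect",
                                        "too few instruments after filter")

  stages <- data.frame(label = character(), from = character(),
                       to = character(), estimate = numeric(),
                       se = numeric(), pvalue = numeric(),
                       grade = character(), stringsAsFactors = FALSE)
  addStage <- function(stages, label, from, to, e) {
    rbind(stages, data.frame(label = label, from = from, to = to,
                             estimate = e@beta, se = e@se,
                             pvalue = e@pvalue,
                             grade = classifyEvidence(e@pvalue),
                             stringsAsFactors = FALSE))
  }

  condF <- list()
  s1 <- mvStep(c("nafld", "fi", "fg", "shbg", "bt"), "pcos")
  if (is.null(s1)) notes <- .naNote(notes, "MVMR onto PCOS",
                                    "too few instruments")
  else {
    stages <- addStage(stages, "theta1", "nafld", "pcos", s1$est$nafld)
    stages <- addStage(stages, "theta2", "fi", "pcos", s1$est$fi)
    stages <- addStage(stages, "theta3", "bt", "pcos", s1$est$bt)
    stages <- addStage(stages, "null_fg", "fg", "pcos", s1$est$fg)
    stages <- addStage(stages, "null_shbg", "shbg", "pcos", s1$est$shbg)
    condF$pcos <- s1$condF
  }
  s2 <- mvStep(c("nafld", "fi", "fg", "shbg"), "bt")
  if (is.null(s2)) notes <- .naNote(notes, "MVMR onto testosterone",
                                    "too few instruments")
  else {
    stages <- addStage(stages, "theta4", "shbg", "bt", s2$est$shbg)
    condF$bt <- s2$condF
  }
  s3 <- mvStep(c("nafld", "fi", "fg"), "shbg")
  if (is.null(s3)) notes <- .naNote(notes, "MVMR onto SHBG",
                                    "too few instruments")
  else {
    stages <- addStage(stages, "theta5", "fi", "shbg", s3$est$fi)
    condF$shbg <- s3$condF
  }
  theta6 <- uniIVW("nafld", "fi", filter = TRUE)
  if (is.null(theta6)) notes <- .naNote(notes, "theta6",
                                        "too few instruments after filter")
  else stages <- addStage(stages, "theta6", "nafld", "fi", theta6)

  pathways <- list()
  denom <- if (!is.null(totalF)) totalF else total
  get <- function(lab) {
    i <- match(lab, stages$label)
    if (is.na(i)) NULL else stages[i, ]
  }
  t2 <- get("theta2"); t3 <- get("theta3"); t4 <- get("theta4")
  t5 <- get("theta5"); t6 <- get("theta6")
  if (!is.null(denom) && !is.null(t2) && !is.null(t6)) {
    p <- PathwaySpec(c("theta6", "theta2"),
                     c(t6$estimate, t2$estimate), c(t6$se, t2$se),
                     from = c("nafld", "fi"), to = c("fi", "pcos"))
    pathways$insulin_only <- mediationEffect(p, denom@beta)
  } else notes <- .naNote(notes, "insulin-only pathway", "missing stages")
  if (!is.null(denom) && !all(vapply(list(t3, t4, t5, t6), is.null,
                                     logical(1)))) {
    if (!is.null(t3) && !is.null(t4) && !is.null(t5) && !is.null(t6)) {
      p <- PathwaySpec(c("theta6", "theta5", "theta4", "theta3"),
                       c(t6$estimate, t5$estimate, t4$estimate, t3$estimate),
                       c(t6$se, t5$se, t4$se, t3$se),
                       from = c("nafld", "fi", "shbg", "bt"),
                       to = c("fi", "shbg", "bt", "pcos"))
      pathways$insulin_shbg_bt <- mediationEffect(p, denom@beta)
    } else notes <- .naNote(notes, "four-stage pathway", "missing stages")
  }

  new("MediationReport",
      total = if (is.null(total)) NA else total,
      totalFiltered = if (is.null(totalF)) NA else totalF,
      stages = stages, pathways = pathways, conditionalF = condF,
      notes = notes)
}

#' Serialize a mediation report to JSON and TSV
#'
#' Writes `<stem>.json` (full structured report) and `<stem>_pathways.tsv`
#' (pathway, estimate, CI, OR view, p, proportion, grade).
#'
#' @param report a \linkS4class{MediationReport}.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
writeMediationReport <- function(report, stem) {
  estAsList <- function(e) if (is(e, "EffectEstimate"))
    list(beta = e@beta, se = e@se, pvalue = e@pvalue, method = e@method,
         k = e@k, scale = e@outcomeScale) else NULL
  pw <- lapply(report@pathways, function(m) list(
    estimate = m@estimate, se = m@se, ciLow = m@ciLow, ciHigh = m@ciHigh,
    OR = exp(m@estimate), orLow = exp(m@ciLow), orHigh = exp(m@ciHigh),
    pvalue = m@pvalue, proportion = m@proportion, grade = m@grade))
  json <- list(total = estAsList(report@total),
               totalFiltered = estAsList(report@totalFiltered),
               stages = report@stages, pathways = pw,
               conditionalF = lapply(report@conditionalF,
                                     function(cf) as.list(cf@F)),
               notes = report@notes)
  jsonPath <- paste0(stem, ".json")
  jsonlite::write_json(json, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tsvPath <- paste0(stem, "_pathways.tsv")
  tab <- do.call(rbind, lapply(names(pw), function(nm)
    data.frame(pathway = nm, as.data.frame(pw[[nm]]))))
  if (is.null(tab)) tab <- data.frame()
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
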