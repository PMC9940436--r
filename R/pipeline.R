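#' @include AllClasses.R summary-data.R mr-core.R mr-presso.R mvmr.R
#' @include mediation.R ldsc.R simulate.R
NULL

.defaultRunConfig <- function() {
  list(
    thresholds = list(p = 5e-8, maf = 0.01, clumpWindowKb = 10000,
                      clumpR2 = 0.001, proxyR2 = 0.8, proxyWindowKb = 1000,
                      palindromeBand = c(0.42, 0.58)),
    estimators = list(ivwMode = "auto", nBoot = 1000, nSim = 1000,
                      nBlocks = 50),
    simulate = list(),
    blacklist = character(),
    datasets = NULL, ldMatrix = NULL, ldSidecar = NULL)
}

.mergeConfig <- function(base, extra) {
  for (nm in names(extra)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      .mergeConfig(base[[nm]], extra[[nm]]) else extra[[nm]]
  }
  base
}

.loadInputs <- function(cfg, seed) {
  if (!is.null(cfg$datasets)) {
    binary <- c("nafld", "pcos")
    datasets <- lapply(names(cfg$datasets), function(nm)
      readSummaryTable(cfg$datasets[[nm]], trait = nm,
                       traitType = if (nm %in% binary) "binary"
                                   else "continuous"))
    names(datasets) <- names(cfg$datasets)
    ld <- if (!is.null(cfg$ldMatrix))
      readLDMatrix(cfg$ldMatrix, cfg$ldSidecar) else NULL
    truth <- NULL
  } else {
    simArgs <- cfg$simulate
    simArgs$seed <- seed
    sim <- do.call(simConfig, simArgs)
    truth <- simulateDagTruth(sim)
    datasets <- simulateSummaryStudy(truth)
    ld <- simulateLDMatrix(sim)
  }
  list(datasets = datasets, ld = ld, truth = truth)
}

.prepInstruments <- function(datasets, ld, th, trait) {
  sel <- selectInstruments(datasets[[trait]], th$p, th$maf, th$palindromeBand)
  suppressWarnings(ldClump(sel, ld, th$clumpWindowKb, th$clumpR2))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages of the summary-level MR workflow as
#' subcommands: `simulate` (emit a synthetic study with its truth
#' manifest), `instruments` (selection + clumping audit),
#' `mr` (univariable estimators, heterogeneity, leave-one-out),
#' `presso` (outlier test), `mvmr` (direct effects + conditional F),
#' `mediate` (the stepwise mediation report), `ldsc` (genetic
#' correlation on simulated inputs) and `report` (all of the above
#' collated into one JSON bundle). All randomness flows from `seed`;
#' outputs are deterministic given (subcommand, config, seed) and the
#' seed is recorded in every JSON artifact.
#'
#' @param subcommand one of simulate, instruments, mr, presso, mvmr,
#'   mediate, ldsc, report.
#' @param config NULL, a YAML file path, or a nested list overriding the
#'   defaults (thresholds, estimators, simulate, blacklist, datasets,
#'   ldMatrix/ldSidecar).
#' @param seed integer root seed.
#' @param outDir output directory (created if needed); NULL returns
#'   results without writing artifacts.
#' @return invisibly, a list of stage results.
#' @export
runPipeline <- function(subcommand = c("report", "simulate", "instruments",
                                       "mr", "presso", "mvmr", "mediate",
                                       "ldsc"),
                        config = NULL, seed = 1, outDir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- .defaultRunConfig()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) stop("invalid config key(s): ",
                              paste(unknown, collapse = ", "))
    cfg <- .mergeConfig(cfg, config)
  }
  seed <- as.integer(seed)
  th <- cfg$thresholds
  est <- cfg$estimators
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  emit <- function(name, obj) {
    if (!is.null(outDir))
      jsonlite::write_json(c(list(seed = seed), obj),
                           file.path(outDir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  asRow <- function(e) list(method = e@method, beta = e@beta, se = e@se,
                            pvalue = e@pvalue, k = e@k)

  inputs <- .loadInputs(cfg, seed)
  datasets <- inputs$datasets; ld <- inputs$ld
  results <- list(seed = seed)

  if (subcommand == "simulate") {
    if (is.null(inputs$truth)) stop("simulate stage needs a simulated study",
                                    " (datasets were supplied)")
    if (!is.null(outDir))
      simulateSummaryStudy(inputs$truth, writeDir = file.path(outDir, "data"))
    results$truth <- list(theta = as.list(inputs$truth@theta),
                          totalEffect = inputs$truth@totalEffect)
    emit("simulate", results["truth"])
    return(invisible(results))
  }

  exposure <- "nafld"; outcome <- "pcos"
  ins <- .prepInstruments(datasets, ld, th, exposure)
  if (subcommand %in% c("instruments")) {
    if (!is.null(outDir)) writeAuditTrail(ins, file.path(outDir,
                                                         "instruments_audit.tsv"))
    results$instruments <- ins@records$snp_id
    emit("instruments", list(instruments = results$instruments))
    return(invisible(results))
  }

  hset <- harmonize(ins, datasets[[outcome]], ld,
                    palindromeEafBand = th$palindromeBand,
                    proxyR2Min = th$proxyR2, proxyWindowKb = th$proxyWindowKb)
  k <- nrow(hset@data)
  if (k < 1) stop("insufficient instruments after harmonization")

  if (subcommand %in% c("mr", "report")) {
    ivw <- mrIVW(hset, est$ivwMode)
    if (est$ivwMode == "auto" && k <= 3)
      message("auto IVW: k = ", k, " <= 3, using fixed effects")
    mr <- list(ivw = asRow(ivw))
    if (k >= 2) {
      q <- cochranQ(hset, ivw)
      mr$cochranQ <- list(Q = q@Q, df = q@df, pvalue = q@pvalue)
      mr$leaveOneOut <- lapply(leaveOneOut(hset), asRow)
    }
    if (k >= 3) {
      eg <- mrEgger(hset)
      mr$egger <- c(asRow(eg@slope),
                    list(intercept = eg@intercept,
                         interceptSE = eg@interceptSE,
                         interceptP = eg@interceptP))
      mr$weightedMedian <- asRow(weightedMedian(hset, est$nBoot,
                                                seed = seed + 10L))
    }
    results$mr <- mr
    if (subcommand == "mr") { emit("mr", results["mr"]); return(invisible(results)) }
  }

  if (subcommand %in% c("presso", "report")) {
    results$presso <- if (k >= 4) {
      pr <- mrPresso(hset, est$nSim, seed = seed + 20L)
      list(rss = pr@rssObserved, globalP = pr@globalP,
           outliers = pr@snpTable$snp_id[pr@snpTable$flagged],
           corrected = if (!is.null(pr@corrected)) asRow(pr@corrected))
    } else list(notApplicable = paste("MR-PRESSO requires >= 4 instruments;",
                                      k, "available"))
    if (subcommand == "presso") { emit("presso", results["presso"])
      return(invisible(results)) }
  }

  if (subcommand %in% c("mvmr", "report")) {
    ms <- try(buildMultiExposureSet(
      datasets[c("nafld", "fi", "fg", "shbg", "bt")], datasets$pcos, ld,
      th$p, th$maf, th$palindromeBand, th$clumpWindowKb, th$clumpR2),
      silent = TRUE)
    results$mvmr <- if (inherits(ms, "try-error"))
      list(notApplicable = "could not assemble multi-exposure set")
    else list(direct = lapply(mvmrIVW(ms), asRow),
              conditionalF = as.list(conditionalF(ms)@F))
    if (subcommand == "mvmr") { emit("mvmr", results["mvmr"])
      return(invisible(results)) }
  }

  if (subcommand %in% c("mediate", "report")) {
    rep <- runStepwiseMediation(datasets, ld, cfg$blacklist, th$p, th$maf,
                                th$clumpWindowKb, th$clumpR2)
    if (!is.null(outDir))
      writeMediationReport(rep, file.path(outDir, "mediation"))
    results$mediate <- list(
      stages = rep@stages,
      pathways = lapply(rep@pathways, function(m) list(
        estimate = m@estimate, se = m@se, ciLow = m@ciLow,
        ciHigh = m@ciHigh, pvalue = m@pvalue, proportion = m@proportion,
        grade = m@grade)),
      notes = rep@notes)
    if (subcommand == "mediate") { emit("mediate", results["mediate"])
      return(invisible(results)) }
  }

  if (subcommand %in% c("ldsc", "report")) {
    simArgs <- cfg$simulate; simArgs$seed <- seed + 30L
    simArgs$mSnps <- simArgs$mSnps %||% 1000
    simCfg <- do.call(simConfig, simArgs)
    li <- simulateLdscInputs(simCfg, h2 = c(0.4, 0.25), gencov = 0.2,
                             N = c(5e4, 5e4))
    rg <- ldscRg(li$sumstats[[1]], li$sumstats[[2]], li$ldscores,
                 5e4, 5e4, nBlocks = est$nBlocks)
    results$ldsc <- list(rg = rg$rg, se = rg$se, pvalue = rg$pvalue,
                         h2_1 = rg$fit1@h2, h2_2 = rg$fit2@h2)
    if (subcommand == "ldsc") { emit("ldsc", results["ldsc"])
      return(invisible(results)) }
  }

  emit("report", results[setdiff(names(results), "seed")])
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
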