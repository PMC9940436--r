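#' @include AllClasses.R
NULL

#' Accessors for mrpath result objects
#'
#' `effectSize`, `stdError`, `pValue`, `nInstruments` and `methodTag` read
#' the corresponding fields of an \linkS4class{EffectEstimate};
#' `records` and `auditTrail` expose the variant table and the filter audit
#' of a \linkS4class{SummaryDataset}; `harmonizedData` returns the
#' per-instrument table of a \linkS4class{HarmonizedSet}.
#'
#' @param object an mrpath S4 object.
#' @return the requested field (numeric, character or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("effectSize", function(object) standardGeneric("effectSize"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nInstruments", function(object) standardGeneric("nInstruments"))
#' @rdname accessors
#' @export
setGeneric("methodTag", function(object) standardGeneric("methodTag"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("auditTrail", function(object) standardGeneric("auditTrail"))
#' @rdname accessors
#' @export
setGeneric("harmonizedData", function(object) standardGeneric("harmonizedData"))

#' @rdname accessors
setMethod("effectSize", "EffectEstimate", function(object) object@beta)
#' @rdname accessors
setMethod("stdError", "EffectEstimate", function(object) object@se)
#' @rdname accessors
setMethod("pValue", "EffectEstimate", function(object) object@pvalue)
#' @rdname accessors
setMethod("nInstruments", "EffectEstimate", function(object) object@k)
#' @rdname accessors
setMethod("methodTag", "EffectEstimate", function(object) object@method)
#' @rdname accessors
setMethod("stdError", "LdscFit", function(object) object@h2SE)
#' @rdname accessors
setMethod("pValue", "QResult", function(object) object@pvalue)
#' @rdname accessors
setMethod("records", "SummaryDataset", function(object) object@records)
#' @rdname accessors
setMethod("auditTrail", "SummaryDataset", function(object) object@audit)
#' @rdname accessors
setMethod("auditTrail", "HarmonizedSet", function(object) object@audit)
#' @rdname accessors
setMethod("harmonizedData", "HarmonizedSet", function(object) object@data)
#' @rdname accessors
setMethod("nInstruments", "HarmonizedSet", function(object) nrow(object@data))
#' @rdname accessors
setMethod("nInstruments", "MultiExposureSet",
          function(object) length(object@snpIds))

setMethod("show", "SummaryDataset", function(object) {
  cat("SummaryDataset:", object@trait, sprintf("(%s, %s)\n",
      object@traitType, object@ancestry))
  cat(" ", nrow(object@records), "variant records;",
      nrow(object@audit), "audit entries\n")
  if (nrow(object@records))
    print(utils::head(object@records, 3), row.names = FALSE)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s (%s) -> %s (%s), %d instruments\n",
              object@exposure, object@exposureScale,
              object@outcome, object@outcomeScale, nrow(object@data)))
  if (any(object@data$eaf_flag))
    cat(" ", sum(object@data$eaf_flag), "rows flagged for EAF discordance\n")
})

setMethod("show", "EffectEstimate", function(object) {
  cat(sprintf("EffectEstimate [%s] k=%d: beta %.4g (se %.4g), p %.3g [%s]\n",
              object@method, object@k, object@beta, object@se,
              object@pvalue, object@outcomeScale))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n",
              object@Q, as.integer(object@df), object@pvalue))
})

setMethod("show", "EggerResult", function(object) {
  cat("MR-Egger\n  slope:     ")
  show(object@slope)
  cat(sprintf("  intercept: %.4g (se %.4g), p %.3g\n",
              object@intercept, object@interceptSE, object@interceptP))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO (nSim = %d): RSS = %.4g, global p = %.4g\n",
              object@nSim, object@rssObserved, object@globalP))
  nf <- sum(object@snpTable$flagged)
  cat(" ", nf, "outlier(s) flagged")
  if (nf && !is.null(object@corrected))
    cat(sprintf("; corrected beta %.4g (distortion p %.3g)",
                object@corrected@beta, object@distortionP))
  cat("\n")
})

setMethod("show", "ConditionalStrength", function(object) {
  cat(sprintf("Conditional F (k = %d, L = %d):\n", object@k, object@L))
  print(round(object@F, 2))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Indirect effect %.5g (se %.3g), OR %.4f [%.4f, %.4f], p %.3g\n",
              object@estimate, object@se, exp(object@estimate),
              exp(object@ciLow), exp(object@ciHigh), object@pvalue))
  cat(sprintf("  proportion mediated %.1f%%; evidence: %s\n",
              object@proportion, object@grade))
})

setMethod("show", "LdscFit", function(object) {
  cat(sprintf("LDSC fit: h2 = %.4f (se %.4f), intercept = %.4f (se %.4f)\n",
              object@h2, object@h2SE, object@intercept, object@interceptSE))
})

setMethod("show", "MediationReport", function(object) {
  cat("Stepwise MR mediation report\n")
  if (is(object@total, "EffectEstimate")) {
    cat("  total effect:           "); show(object@total)
  }
  if (is(object@totalFiltered, "EffectEstimate")) {
    cat("  total (obesity-filtered): "); show(object@totalFiltered)
  }
  if (nrow(object@stages)) {
    cat("  stages:\n"); print(object@stages, row.names = FALSE)
  }
  for (nm in names(object@pathways)) {
    cat("  pathway", nm, ":\n    "); show(object@pathways[[nm]])
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
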