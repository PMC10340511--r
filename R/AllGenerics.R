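#' @name accessors
#' @title Accessors for histoneBurden S4 classes
#' @param object An S4 object from this package.
#' @description Slot access goes through these accessors, never through
#'   \code{@}.
NULL

#' @rdname accessors
#' @export
setGeneric("signatureMatrix", function(object) standardGeneric("signatureMatrix"))

#' @rdname accessors
#' @export
setGeneric("signatureNames", function(object) standardGeneric("signatureNames"))

#' @rdname accessors
#' @export
setGeneric("etiologyGroups", function(object) standardGeneric("etiologyGroups"))

#' @rdname accessors
#' @export
setGeneric("channelCounts", function(object) standardGeneric("channelCounts"))

#' @rdname accessors
#' @export
setGeneric("profileTotal", function(object) standardGeneric("profileTotal"))

#' @rdname accessors
#' @export
setGeneric("skippedRecords", function(object) standardGeneric("skippedRecords"))

#' @rdname accessors
#' @export
setGeneric("normalizedProfile", function(object) standardGeneric("normalizedProfile"))

#' @rdname accessors
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))

#' @rdname accessors
#' @export
setGeneric("activeSignatures", function(object) standardGeneric("activeSignatures"))

#' @rdname accessors
#' @export
setGeneric("exposureCI", function(object) standardGeneric("exposureCI"))

#' @rdname accessors
#' @export
setGeneric("patientSet1", function(object) standardGeneric("patientSet1"))

#' @rdname accessors
#' @export
setGeneric("patientSet2", function(object) standardGeneric("patientSet2"))

#' @rdname accessors
#' @export
setGeneric("variantGroups", function(object) standardGeneric("variantGroups"))

setMethod("signatureMatrix", "SignatureCatalog", function(object) object@matrix)
setMethod("signatureNames", "SignatureCatalog", function(object) colnames(object@matrix))
setMethod("etiologyGroups", "SignatureCatalog", function(object) object@etiologyGroups)

setMethod("channelCounts", "MutationalProfile", function(object) object@counts)
setMethod("profileTotal", "MutationalProfile", function(object) object@total)
setMethod("skippedRecords", "MutationalProfile", function(object) object@skipped)
setMethod("normalizedProfile", "MutationalProfile", function(object) {
  if (object@total <= 0) stop("cannot normalize an empty profile")
  object@counts / object@total
})

setMethod("exposures", "SignatureDecomposition", function(object) object@exposures)
setMethod("activeSignatures", "SignatureDecomposition", function(object) object@active)
setMethod("exposureCI", "SignatureDecomposition", function(object) {
  if (!length(object@ciLow)) stop("no bootstrap CIs: run bootstrapDecompose()")
  data.frame(signature = names(object@exposures),
             exposure = unname(object@exposures),
             bootstrap_mean = unname(object@bootstrapMean),
             ci_low = unname(object@ciLow),
             ci_high = unname(object@ciHigh),
             active = names(object@exposures) %in% object@active,
             row.names = NULL)
})

setMethod("patientSet1", "CohortPartition", function(object) object@patientSet1)
setMethod("patientSet2", "CohortPartition", function(object) object@patientSet2)
setMethod("variantGroups", "CohortPartition", function(object) object@variantGroup)

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog with", ncol(object@matrix), "signatures over 96 channels\n")
  cat("  signatures:", paste(utils::head(colnames(object@matrix), 8), collapse = ", "),
      if (ncol(object@matrix) > 8) "..." else "", "\n")
  if (length(object@etiologyGroups))
    cat("  etiology groups:", paste(names(object@etiologyGroups), collapse = ", "), "\n")
})

setMethod("show", "MutationalProfile", function(object) {
  cat("MutationalProfile", if (nzchar(object@label)) sQuote(object@label) else "",
      "\n  ", object@total, " SNVs over 96 channels (", object@skipped,
      " non-SNV records skipped)\n", sep = "")
  top <- sort(object@counts, decreasing = TRUE)[1:3]
  if (object@total > 0)
    cat("  top channels:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SignatureDecomposition", function(object) {
  cat("SignatureDecomposition over", length(object@exposures), "signatures\n")
  e <- sort(object@exposures, decreasing = TRUE)
  e <- e[e > 0.5]
  cat("  exposures (%):",
      paste(names(e), sprintf("%.1f", e), sep = "=", collapse = ", "), "\n")
  cat("  active (>5%):", paste(object@active, collapse = ", "), "\n")
  if (object@nBoot > 0)
    cat("  bootstrap: ", object@nBoot, " resamples, 95% percentile CIs\n", sep = "")
})

setMethod("show", "CohortPartition", function(object) {
  tab <- table(object@variantGroup)
  cat("CohortPartition\n")
  cat("  patient_set1 (>=1 histone mutation):", length(object@patientSet1), "patients\n")
  cat("  patient_set2:", length(object@patientSet2), "patients\n")
  cat("  mutations: gene_group1 =", tab[["gene_group1"]],
      "| gene_group2 =", tab[["gene_group2"]],
      "| gene_group3 =", tab[["gene_group3"]], "\n")
})
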