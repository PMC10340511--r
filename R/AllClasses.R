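#' SignatureCatalog: an SBS96 mutational-signature catalog
#'
#' Holds a 96 x K matrix of channel probabilities, one column per signature,
#' rows fixed to the canonical ordering of [sbs96Channels()], plus an optional
#' map from etiology group names (e.g. "UV", "MMR") to member signatures.
#' Every column is a probability distribution over the 96 channels.
#'
#' @slot matrix Numeric 96 x K matrix; rownames are the canonical channel
#'   labels, colnames the signature names; each column sums to 1.
#' @slot etiologyGroups Named list mapping group name to a character vector of
#'   member signature names.
#' @aliases SignatureCatalog-class
#' @exportClass SignatureCatalog
setClass("SignatureCatalog",
  representation(matrix = "matrix", etiologyGroups = "list"))

setValidity("SignatureCatalog", function(object) {
  m <- object@matrix
  if (nrow(m) != 96L) return("catalog must have exactly 96 channel rows")
  if (!identical(rownames(m), .SBS96))
    return("rows must follow the canonical SBS96 channel ordering")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("signature names must be present and unique")
  if (any(m < 0)) return("signature probabilities must be nonnegative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    return(sprintf("column(s) %s do not sum to 1 within 1e-6",
                   paste(colnames(m)[abs(cs - 1) > 1e-6], collapse = ", ")))
  TRUE
})

#' MutationalProfile: SBS96 substitution counts
#'
#' A 96-channel count vector in canonical ordering. Only single-nucleotide
#' substitutions contribute; the number of skipped non-SNV records is carried
#' alongside.
#'
#' @slot counts Named numeric vector of 96 nonnegative channel counts.
#' @slot total Numeric scalar; equals \code{sum(counts)}.
#' @slot skipped Numeric scalar; records (indels/MNVs) excluded during
#'   construction.
#' @slot label Character label for the profile (e.g. "gene_group1").
#' @aliases MutationalProfile-class
#' @exportClass MutationalProfile
setClass("MutationalProfile",
  representation(counts = "numeric", total = "numeric",
                 skipped = "numeric", label = "character"))

setValidity("MutationalProfile", function(object) {
  if (length(object@counts) != 96L) return("counts must have 96 channels")
  if (!identical(names(object@counts), .SBS96))
    return("counts must be named by the canonical SBS96 channels")
  if (any(object@counts < 0)) return("channel counts must be nonnegative")
  if (abs(sum(object@counts) - object@total) > 1e-9)
    return("total must equal the sum of channel counts")
  if (object@skipped < 0) return("skipped must be nonnegative")
  TRUE
})

#' SignatureDecomposition: exposures from maximum-likelihood refitting
#'
#' The result of decomposing a [MutationalProfile] into catalog signatures by
#' maximizing the multinomial log-likelihood over the exposure simplex.
#' Exposures are percentages of query mutations attributed to each signature
#' and sum to 100. Bootstrap slots are filled by [bootstrapDecompose()] and
#' empty (length 0) after a plain [decomposeProfile()].
#'
#' @slot exposures Named numeric vector of exposures in percent (sums to 100).
#' @slot logLik Achieved multinomial log-likelihood.
#' @slot active Character vector of signatures whose point-estimate exposure
#'   exceeds 5 percent.
#' @slot bootstrapMean,ciLow,ciHigh Named numeric vectors (percent): bootstrap
#'   means and 2.5/97.5 percentile bounds across resamples.
#' @slot nBoot Number of bootstrap resamples (0 when not bootstrapped).
#' @aliases SignatureDecomposition-class
#' @exportClass SignatureDecomposition
setClass("SignatureDecomposition",
  representation(exposures = "numeric", logLik = "numeric",
                 active = "character", bootstrapMean = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "numeric"))

setValidity("SignatureDecomposition", function(object) {
  if (abs(sum(object@exposures) - 100) > 1e-6)
    return("exposures must sum to 100")
  if (any(object@exposures < -1e-9)) return("exposures must be nonnegative")
  if (length(object@ciLow)) {
    if (any(object@ciLow > object@bootstrapMean + 1e-9) ||
        any(object@bootstrapMean > object@ciHigh + 1e-9))
      return("ciLow <= bootstrapMean <= ciHigh must hold elementwise")
  }
  TRUE
})

#' CohortPartition: patient sets and gene groups
#'
#' Splits a cohort by histone-mutation status: patient_set1 holds every
#' patient with at least one histone-gene mutation, patient_set2 the rest.
#' Mutations of set1 patients are split into histone (gene_group1) and
#' non-histone (gene_group2) records; every mutation of set2 patients forms
#' gene_group3. The per-variant assignment is stored aligned with the input
#' rows, so the three groups are a total, disjoint partition of the input.
#'
#' @slot patientSet1,patientSet2 Character vectors of patient IDs.
#' @slot variantGroup Factor (levels \code{gene_group1..3}), one entry per
#'   input variant row.
#' @aliases CohortPartition-class
#' @exportClass CohortPartition
setClass("CohortPartition",
  representation(patientSet1 = "character", patientSet2 = "character",
                 variantGroup = "factor"))

setValidity("CohortPartition", function(object) {
  if (length(intersect(object@patientSet1, object@patientSet2)))
    return("patient sets must be disjoint")
  if (!identical(levels(object@variantGroup),
                 c("gene_group1", "gene_group2", "gene_group3")))
    return("variantGroup must have levels gene_group1, gene_group2, gene_group3")
  if (anyNA(object@variantGroup))
    return("every variant must belong to exactly one gene group")
  TRUE
})
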