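#' Partition a cohort by histone-mutation status
#'
#' patient_set1 contains every patient with at least one mutation in a
#' histone gene (any registry gene with family != non_histone);
#' patient_set2 is the complement. Mutations of set1 patients split into
#' gene_group1 (histone genes) and gene_group2 (non-histone genes); all
#' mutations of set2 patients form gene_group3. Genes absent from the
#' registry are treated as non-histone.
#'
#' @param variants Variant data.frame.
#' @param registry Registry data.frame with histone families flagged.
#' @return A [CohortPartition-class].
#' @export
partitionCohort <- function(variants, registry) {
  v <- .validateVariants(variants)
  registry <- .validateRegistry(registry)
  histone_genes <- registry$gene_symbol[registry$is_histone]
  is_hist <- v$gene_symbol %in% histone_genes
  set1 <- unique(v$patient_id[is_hist])
  set2 <- setdiff(unique(v$patient_id), set1)
  in_set1 <- v$patient_id %in% set1
  grp <- ifelse(!in_set1, "gene_group3",
                ifelse(is_hist, "gene_group1", "gene_group2"))
  new("CohortPartition", patientSet1 = set1, patientSet2 = set2,
      variantGroup = factor(grp, levels = c("gene_group1", "gene_group2",
                                            "gene_group3")))
}

## Extract reference-strand 3-mer contexts for variant rows from reference
## sequences keyed by chrom. `reference` may be a Biostrings::DNAStringSet
## or a named character vector.
.contextFromReference <- function(variants, reference) {
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  stopifnot(is.character(reference), !is.null(names(reference)))
  miss <- setdiff(unique(variants$chrom), names(reference))
  if (length(miss))
    stop("no reference sequence for: ", paste(miss, collapse = ", "))
  seqs <- reference[variants$chrom]
  lens <- nchar(seqs)
  if (any(variants$pos < 2 | variants$pos > lens - 1))
    stop("variant position too close to a sequence end to extract a 3-mer")
  substr(seqs, variants$pos - 1L, variants$pos + 1L)
}

#' Build an SBS96 mutational profile
#'
#' Counts single-nucleotide substitutions into the 96 pyrimidine-centered
#' trinucleotide channels. The context is taken from the variant table's
#' context column when present, otherwise extracted from reference
#' sequences; purine-reference variants are reverse complemented onto the
#' pyrimidine channel. Indels and MNVs are skipped and counted in the
#' \code{skipped} slot.
#'
#' @param variants Variant data.frame (any subset, e.g. one gene group of a
#'   [partitionCohort()]).
#' @param reference Optional named character vector or
#'   \code{Biostrings::DNAStringSet} of reference sequences keyed by
#'   \code{chrom}, used for rows lacking a context.
#' @param label Profile label.
#' @return A [MutationalProfile-class].
#' @export
#' @examples
#' v <- data.frame(patient_id = "p1", gene_symbol = "g", chrom = "g",
#'                 pos = 2L, ref_allele = "G", alt_allele = "A",
#'                 classification = "missense", cancer_type = NA,
#'                 context = "TGC")
#' channelCounts(buildProfile(v))["G[C>T]A"]
buildProfile <- function(variants, reference = NULL, label = "") {
  v <- .validateVariants(variants)
  snv <- v$ref_allele %in% .BASES & v$alt_allele %in% .BASES
  skipped <- sum(!snv)
  v <- v[snv, , drop = FALSE]
  counts <- setNames(numeric(96), .SBS96)
  if (nrow(v)) {
    ctx <- v$context
    need <- is.na(ctx) | !nzchar(ctx)
    if (any(need)) {
      if (is.null(reference))
        stop("no context for ", sum(need), " SNV(s) and no reference ",
             "sequences supplied; first offending rows: ",
             paste(utils::head(which(need), 10), collapse = ", "))
      ctx[need] <- .contextFromReference(v[need, , drop = FALSE], reference)
      mism <- substr(ctx[need], 2L, 2L) != v$ref_allele[need]
      if (any(mism))
        stop("reference context disagrees with ref_allele for ",
             sum(mism), " variant(s)")
    }
    ch <- assignChannel(v$ref_allele, v$alt_allele, ctx)
    tab <- table(factor(ch, levels = .SBS96))
    counts[names(tab)] <- as.numeric(tab)
  }
  new("MutationalProfile", counts = counts, total = sum(counts),
      skipped = as.numeric(skipped), label = as.character(label))
}

#' Profiles for the three gene groups of a cohort partition
#'
#' @param variants Variant data.frame used to build the partition.
#' @param partition A [CohortPartition-class] for those variants.
#' @param reference Optional reference sequences (see [buildProfile()]).
#' @return Named list of three [MutationalProfile-class] objects.
#' @export
groupProfiles <- function(variants, partition, reference = NULL) {
  stopifnot(is(partition, "CohortPartition"),
            nrow(variants) == length(variantGroups(partition)))
  grp <- variantGroups(partition)
  setNames(lapply(levels(grp), function(g) {
    buildProfile(variants[grp == g, , drop = FALSE], reference = reference,
                 label = g)
  }), levels(grp))
}
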