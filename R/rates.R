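#' Count burden mutations per gene
#'
#' Counts the nine burden classes (see [countedClasses()]) per gene, together
#' with the number of distinct patients carrying at least one such mutation
#' in the gene. Exact duplicate calls (same patient, chrom, pos, alt) are
#' deduplicated with a message. Mutations in genes absent from the registry
#' are excluded from the per-gene table and returned in the
#' \code{"unknown_genes"} attribute with a warning.
#'
#' @param variants Variant data.frame.
#' @param registry Registry data.frame.
#' @param by \code{"pan"} for a single pan-cancer count per gene, or
#'   \code{"cancer_type"} for per-cancer-type counts.
#' @return data.frame with columns gene_symbol, cancer_type
#'   (\code{"pan-cancer"} when \code{by = "pan"}), m (mutation count) and
#'   patients_mutated.
#' @export
countMutations <- function(variants, registry, by = c("pan", "cancer_type")) {
  by <- match.arg(by)
  v <- .validateVariants(variants)
  registry <- .validateRegistry(registry)
  dup <- duplicated(v[c("patient_id", "chrom", "pos", "alt_allele")])
  if (any(dup)) {
    message("deduplicated ", sum(dup), " exact duplicate call(s)")
    v <- v[!dup, , drop = FALSE]
  }
  v <- v[v$classification %in% .COUNTED_CLASSES, , drop = FALSE]
  unknown <- setdiff(unique(v$gene_symbol), registry$gene_symbol)
  if (length(unknown)) {
    warning(sum(v$gene_symbol %in% unknown), " mutation(s) in ",
            length(unknown), " gene(s) absent from the registry; ",
            "excluded from per-gene counts")
  }
  keep <- v$gene_symbol %in% registry$gene_symbol
  unknown_tab <- v[!keep, , drop = FALSE]
  v <- v[keep, , drop = FALSE]
  ct <- if (by == "pan") rep("pan-cancer", nrow(v)) else
    ifelse(is.na(v$cancer_type), "unknown", v$cancer_type)
  if (nrow(v)) {
    dt <- data.table::data.table(gene_symbol = v$gene_symbol,
                                 cancer_type = ct,
                                 patient_id = v$patient_id)
    out <- dt[, list(m = .N,
                     patients_mutated = length(unique(patient_id))),
              by = c("gene_symbol", "cancer_type")]
    out <- as.data.frame(out)
  } else {
    out <- data.frame(gene_symbol = character(0), cancer_type = character(0),
                      m = integer(0), patients_mutated = integer(0))
  }
  attr(out, "unknown_genes") <- unknown_tab
  out
}

#' Redundancy-aware per-protein mutation rate
#'
#' For a protein encoded by n genes, the average observed mutation rate per
#' base pair pools counts and lengths across all encoding genes:
#' \deqn{r = \frac{\sum_{i=1}^{n} m_i}{\sum_{i=1}^{n} c_i}}
#' where \eqn{m_i} is the number of burden mutations in gene i and \eqn{c_i}
#' its coding-sequence length in base pairs. Pooling (rather than averaging
#' per-gene rates) makes the statistic robust to how the redundant copies
#' split the mutations.
#'
#' @param group One protein group from [buildProteinGroups()] (a registry
#'   sub-data.frame).
#' @param counts Per-gene counts from [countMutations()] (any cancer_type
#'   slice; rows for genes outside the group are ignored, member genes
#'   without a row count as 0).
#' @return List with protein_accession, n, m_total, c_total, r.
#' @export
#' @examples
#' reg <- data.frame(gene_symbol = c("A", "B"),
#'                   protein_accession = "P1", cds_length = c(300L, 600L),
#'                   family = "H4", histone_class = "canonical", chrom = "6")
#' grp <- buildProteinGroups(reg)[["P1"]]
#' counts <- data.frame(gene_symbol = c("A", "B"),
#'                      cancer_type = "pan-cancer",
#'                      m = c(2L, 4L), patients_mutated = c(2L, 3L))
#' proteinRate(grp, counts)$r   # 6/900
proteinRate <- function(group, counts) {
  stopifnot(is.data.frame(group), nrow(group) >= 1L)
  c_total <- sum(group$cds_length)
  if (c_total <= 0) stop("zero total coding length for protein group ",
                         group$protein_accession[1])
  m <- counts$m[match(group$gene_symbol, counts$gene_symbol)]
  m[is.na(m)] <- 0L
  m_total <- sum(m)
  list(protein_accession = group$protein_accession[1],
       n = nrow(group), m_total = m_total, c_total = c_total,
       r = m_total / c_total)
}

#' Protein-level mutation rates across a cohort
#'
#' Computes the pooled rate r for every protein group, pan-cancer and (when
#' \code{byCancerType}) per cancer type. Following the cohort-grouping rule,
#' per-type rates are reported only for cancer types with at least
#' \code{minPatients} patients; patients of below-threshold types still
#' contribute to the pan-cancer rates.
#'
#' @param variants Variant data.frame (cancer_type filled, e.g. via
#'   [mergeCancerType()]).
#' @param registry Registry data.frame.
#' @param clinical Optional clinical table; when given, patient totals per
#'   cancer type come from it (so unmutated patients count toward the
#'   threshold), otherwise from the patients observed in \code{variants}.
#' @param byCancerType Compute per-cancer-type rates as well as pan-cancer.
#' @param minPatients Minimum patients per cancer type (default 10).
#' @return data.frame with columns protein_accession, cancer_type, n_genes,
#'   m_total, c_total, r.
#' @export
proteinRates <- function(variants, registry, clinical = NULL,
                         byCancerType = TRUE, minPatients = 10) {
  registry <- .validateRegistry(registry)
  groups <- buildProteinGroups(registry)
  rateSlice <- function(counts, ct_label) {
    rows <- lapply(groups, function(g) {
      pr <- proteinRate(g, counts)
      data.frame(protein_accession = pr$protein_accession,
                 cancer_type = ct_label, n_genes = pr$n,
                 m_total = pr$m_total, c_total = pr$c_total, r = pr$r)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  pan <- suppressWarnings(countMutations(variants, registry, by = "pan"))
  out <- rateSlice(pan, "pan-cancer")
  if (byCancerType) {
    if (!is.null(clinical)) {
      pt <- table(clinical$cancer_type)
    } else {
      u <- unique(variants[c("patient_id", "cancer_type")])
      pt <- table(u$cancer_type)
    }
    eligible <- names(pt)[pt >= minPatients]
    if (length(eligible)) {
      per <- suppressWarnings(countMutations(variants, registry,
                                             by = "cancer_type"))
      for (ct in eligible) {
        out <- rbind(out, rateSlice(per[per$cancer_type == ct, , drop = FALSE],
                                    ct))
      }
    }
  }
  rownames(out) <- NULL
  out
}
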