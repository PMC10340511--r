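#' @importFrom stats chisq.test
NULL

#' Homogeneity of mutation counts across genes encoding one protein
#'
#' Goodness-of-fit chi-squared test asking whether the number of patients
#' mutated differs across the genes encoding a common protein, beyond what
#' the null model predicts. The null is either \code{"length"} (expected
#' counts proportional to coding-sequence length; for identical-length
#' paralogs, the common histone case, this reduces to uniform) or
#' \code{"uniform"}. For sparse tables - any expected count below 5 - the
#' p-value comes from Monte-Carlo simulation (default 10,000 multinomial
#' tables from the null at the observed total) with the conservative
#' \eqn{p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(B + 1)} correction;
#' otherwise the asymptotic chi-squared reference with n - 1 df is used.
#'
#' @param group A protein group (registry sub-data.frame) with >= 2 genes.
#' @param counts Per-gene counts from [countMutations()] (one cancer-type
#'   slice); the counting unit is \code{patients_mutated}. Member genes
#'   without a row count as 0.
#' @param null \code{"length"} (default) or \code{"uniform"}.
#' @param nSim Monte-Carlo replicates (default 10,000).
#' @param seed Optional seed for the Monte-Carlo path.
#' @return List with protein_accession, gene_symbols, observed, expected,
#'   method (\code{"asymptotic"} or \code{"monte_carlo"}), n_sim, chi2, p,
#'   skipped, reason.
#' @export
homogeneityTest <- function(group, counts, null = c("length", "uniform"),
                            nSim = 10000, seed = NULL) {
  null <- match.arg(null)
  stopifnot(is.data.frame(group))
  base <- list(protein_accession = group$protein_accession[1],
               gene_symbols = group$gene_symbol,
               observed = NULL, expected = NULL, method = NA_character_,
               n_sim = NA_integer_, chi2 = NA_real_, p = NA_real_,
               skipped = TRUE, reason = NA_character_)
  if (nrow(group) < 2L) {
    base$reason <- "protein encoded by a single gene"
    return(base)
  }
  obs <- counts$patients_mutated[match(group$gene_symbol, counts$gene_symbol)]
  obs[is.na(obs)] <- 0L
  base$observed <- setNames(as.integer(obs), group$gene_symbol)
  if (sum(obs) == 0L) {
    base$reason <- "no mutated gene in this protein group"
    return(base)
  }
  probs <- if (null == "length") group$cds_length / sum(group$cds_length)
           else rep(1 / nrow(group), nrow(group))
  expected <- sum(obs) * probs
  base$expected <- setNames(expected, group$gene_symbol)
  base$skipped <- FALSE
  if (any(expected < 5)) {
    base$method <- "monte_carlo"
    base$n_sim <- as.integer(nSim)
    if (!is.null(seed)) set.seed(seed)
    ct <- chisq.test(obs, p = probs, simulate.p.value = TRUE, B = nSim)
  } else {
    base$method <- "asymptotic"
    ct <- chisq.test(obs, p = probs)
  }
  base$chi2 <- unname(ct$statistic)
  base$p <- ct$p.value
  base
}

#' Homogeneity scan across all multi-gene proteins
#'
#' Runs [homogeneityTest()] for every protein encoded by at least two genes,
#' pan-cancer and per eligible cancer type, and BH-adjusts p-values across
#' proteins within each cancer type.
#'
#' @param variants Variant data.frame.
#' @param registry Registry data.frame.
#' @param clinical Optional clinical table (for the >= \code{minPatients}
#'   cancer-type filter).
#' @param byCancerType Also scan per cancer type.
#' @param minPatients Cancer-type patient minimum (default 10).
#' @inheritParams homogeneityTest
#' @return data.frame with one row per (protein, cancer_type) pair tested or
#'   skipped: chi2, p, q, method, skipped, reason.
#' @export
homogeneityScan <- function(variants, registry, clinical = NULL,
                            byCancerType = FALSE, minPatients = 10,
                            null = "length", nSim = 10000, seed = NULL) {
  registry <- .validateRegistry(registry)
  groups <- buildProteinGroups(registry)
  groups <- groups[vapply(groups, nrow, 0L) >= 2L]
  if (!length(groups)) stop("no protein is encoded by multiple genes")
  slices <- list("pan-cancer" = suppressWarnings(
    countMutations(variants, registry, by = "pan")))
  if (byCancerType) {
    pt <- if (!is.null(clinical)) table(clinical$cancer_type) else
      table(unique(variants[c("patient_id", "cancer_type")])$cancer_type)
    per <- suppressWarnings(countMutations(variants, registry,
                                           by = "cancer_type"))
    for (ct in names(pt)[pt >= minPatients])
      slices[[ct]] <- per[per$cancer_type == ct, , drop = FALSE]
  }
  rows <- list()
  for (ct in names(slices)) {
    res <- lapply(seq_along(groups), function(i) {
      h <- homogeneityTest(groups[[i]], slices[[ct]], null = null,
                           nSim = nSim,
                           seed = if (is.null(seed)) NULL else seed + i)
      data.frame(protein_accession = h$protein_accession, cancer_type = ct,
                 n_genes = length(h$gene_symbols),
                 total = if (is.null(h$observed)) 0L else sum(h$observed),
                 chi2 = h$chi2, p = h$p, method = h$method,
                 skipped = h$skipped, reason = h$reason)
    })
    slice <- do.call(rbind, res)
    slice$q <- NA_real_
    tested <- !slice$skipped
    if (any(tested)) slice$q[tested] <- bhAdjust(slice$p[tested])
    rows[[ct]] <- slice
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
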