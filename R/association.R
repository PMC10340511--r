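#' @importFrom stats phyper cor.test
NULL

#' One-sided exact test on a 2x2 co-occurrence table
#'
#' Exact hypergeometric (Fisher) test conditioning on both margins. The
#' odds ratio is the sample estimate \eqn{(a d)/(b c)}, with the 0.5
#' Haldane correction applied (and flagged) only when a zero cell occurs.
#' Any zero margin makes the table degenerate: p = 1, flagged.
#'
#' @param table 2x2 integer matrix: rows = query-gene status
#'   (mutated / not), columns = histone status (mutated / not), cell
#'   \code{[1, 1]} = both.
#' @param direction \code{"greater"} (enrichment, default) or
#'   \code{"less"}.
#' @return List with table, odds_ratio, p_one_sided, direction,
#'   haldane (logical), degenerate (logical).
#' @export
#' @examples
#' contingencyTest(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
contingencyTest <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  haldane <- !degenerate && any(table == 0)
  or <- if (degenerate) NA_real_
        else if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  if (degenerate) {
    p <- 1
  } else {
    ## margins: m histone-mutated, n not, k query-mutated draws
    m <- a + c_; n <- b + d; k <- a + b
    p <- if (direction == "greater")
      phyper(a - 1, m, n, k, lower.tail = FALSE)
    else
      phyper(a, m, n, k)
  }
  list(table = table, odds_ratio = or, p_one_sided = p,
       direction = direction, haldane = haldane, degenerate = degenerate)
}

#' Co-occurrence of histone mutations with mutations in query genes
#'
#' Classifies every patient on two axes - carries at least one histone-gene
#' mutation; carries at least one mutation in a query gene (optionally
#' restricted to a list of known driver positions) - and runs the one-sided
#' exact test for enrichment of joint carriers.
#'
#' @param variants Variant data.frame.
#' @param registry Registry data.frame.
#' @param queryGenes Character vector of query gene symbols (e.g.
#'   \code{"POLE"}).
#' @param driverPositions Optional data.frame (gene_symbol, pos,
#'   alt_allele): restrict the query axis to these exact driver mutations.
#' @param patients Optional character vector: the full patient universe
#'   (e.g. from the clinical table); defaults to the patients observed in
#'   \code{variants}.
#' @param direction Passed to [contingencyTest()].
#' @return A [contingencyTest()] result (table rows: query mutated / not;
#'   columns: histone mutated / not).
#' @export
cooccurrenceTest <- function(variants, registry, queryGenes,
                             driverPositions = NULL, patients = NULL,
                             direction = "greater") {
  v <- .validateVariants(variants)
  registry <- .validateRegistry(registry)
  if (is.null(patients)) patients <- unique(v$patient_id)
  histone_genes <- registry$gene_symbol[registry$is_histone]
  hist_mut <- patients %in% v$patient_id[v$gene_symbol %in% histone_genes]
  qv <- v[v$gene_symbol %in% queryGenes, , drop = FALSE]
  if (!is.null(driverPositions)) {
    key <- paste(qv$gene_symbol, qv$pos, qv$alt_allele)
    want <- paste(driverPositions$gene_symbol, driverPositions$pos,
                  driverPositions$alt_allele)
    qv <- qv[key %in% want, , drop = FALSE]
  }
  query_mut <- patients %in% qv$patient_id
  tab <- matrix(c(sum(query_mut & hist_mut), sum(query_mut & !hist_mut),
                  sum(!query_mut & hist_mut), sum(!query_mut & !hist_mut)),
                nrow = 2, byrow = TRUE,
                dimnames = list(query = c("mutated", "wild_type"),
                                histone = c("mutated", "wild_type")))
  contingencyTest(tab, direction = direction)
}

#' Per-gene pan-cancer mutation rates
#'
#' Gene-level counterpart of [proteinRates()]: one pooled rate
#' \eqn{m_i / c_i} per gene, the unit of the covariate analysis.
#'
#' @param variants Variant data.frame.
#' @param registry Registry data.frame.
#' @return data.frame with gene_symbol, m, cds_length, rate.
#' @export
geneRates <- function(variants, registry) {
  registry <- .validateRegistry(registry)
  counts <- suppressWarnings(countMutations(variants, registry, by = "pan"))
  m <- counts$m[match(registry$gene_symbol, counts$gene_symbol)]
  m[is.na(m)] <- 0L
  data.frame(gene_symbol = registry$gene_symbol, m = m,
             cds_length = registry$cds_length,
             rate = m / registry$cds_length)
}

#' Correlate gene-level mutation rate with genomic covariates
#'
#' Pearson correlation (two-sided t-test p) between per-gene pan-cancer
#' rates and each covariate column (expression, replication_time,
#' chromatin_state). Genes missing a covariate are dropped pairwise; a
#' zero-variance vector makes the correlation undefined and flagged.
#'
#' @param rates Output of [geneRates()] (or any data.frame with
#'   gene_symbol and rate).
#' @param covariates Covariate data.frame from [readCovariates()].
#' @return data.frame with one row per covariate: pcc, p, n_genes,
#'   undefined (logical).
#' @export
covariateCorrelation <- function(rates, covariates) {
  stopifnot(all(c("gene_symbol", "rate") %in% names(rates)))
  covs <- c("expression", "replication_time", "chromatin_state")
  stopifnot(all(covs %in% names(covariates)))
  rows <- lapply(covs, function(cv) {
    x <- rates$rate
    y <- covariates[[cv]][match(rates$gene_symbol, covariates$gene_symbol)]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3)
      stop("fewer than 3 genes with both rate and ", cv)
    if (stats::var(x) == 0 || stats::var(y) == 0)
      return(data.frame(covariate = cv, pcc = NA_real_, p = NA_real_,
                        n_genes = length(x), undefined = TRUE))
    ct <- cor.test(x, y, method = "pearson")
    data.frame(covariate = cv, pcc = unname(ct$estimate), p = ct$p.value,
               n_genes = length(x), undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
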