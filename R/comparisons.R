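#' @importFrom stats pwilcox pnorm pchisq kruskal.test p.adjust
NULL

#' Mann-Whitney U comparison of two rate sets with fold change
#'
#' Two-sided Mann-Whitney U test. When \code{length(a) * length(b) <= 200}
#' and there are no ties the p-value is exact (from the null U
#' distribution); otherwise a normal approximation with tie and continuity
#' corrections is used. Fold change is \code{mean(a) / mean(b)}, defined
#' only when both means are positive.
#'
#' @param a,b Numeric vectors (e.g. protein-level rates of two groups);
#'   both nonempty.
#' @return List with U (number of (a, b) pairs with a > b, ties counting
#'   one half), p (two-sided), fold_change, and method
#'   (\code{"exact"} or \code{"normal"}).
#' @export
#' @examples
#' compareTwoGroups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
compareTwoGroups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("NA values are not allowed")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (na * nb <= 200 && !has_ties) {
    method <- "exact"
    p <- if (U > na * nb / 2)
      2 * pwilcox(U - 1, na, nb, lower.tail = FALSE)
    else
      2 * pwilcox(U, na, nb)
    p <- min(1, p)
  } else {
    method <- "normal"
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
    sigma <- sqrt(na * nb / 12 * (na + nb + 1 - tie_term))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma   # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  fc <- if (mean(a) > 0 && mean(b) > 0) mean(a) / mean(b) else NA_real_
  list(U = U, p = p, fold_change = fc, method = method)
}

#' Kruskal-Wallis comparison of k groups with Dunn post hoc
#'
#' Kruskal-Wallis H (tie-corrected, chi-squared reference with k - 1 df).
#' When the omnibus p is below \code{dunnAlpha}, pairwise Dunn z-tests are
#' run and BH-adjusted. If all observations are identical the test is
#' degenerate: H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, each nonempty; at least 2.
#' @param dunnAlpha Omnibus threshold gating the post hoc (default 0.05).
#' @return List with H, df, p, and (possibly NULL) \code{dunn}: a data.frame
#'   of pairwise comparisons with z, p and BH q.
#' @export
compareKGroups <- function(groups, dunnAlpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(!lengths(groups))) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1, dunn = NULL))
  kw <- kruskal.test(x, g)
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              p = kw$p.value, dunn = NULL)
  if (out$p < dunnAlpha) out$dunn <- .dunnTest(x, g)
  out
}

## Dunn (1964) pairwise z-tests on mean ranks with tie correction; BH across
## the pairwise family.
.dunnTest <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z, p = p,
             q = p.adjust(p, method = "BH"), row.names = NULL)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  p.adjust(p, method = "BH")
}

#' Kruskal-Wallis comparison of rates across histone families
#'
#' Compares protein-level rates across the five histone families (H1, H2A,
#' H2B, H3, H4) within one cancer type. The test is only run when every
#' family has at least \code{minMutations} observed mutations in that cancer
#' type; otherwise it is skipped with a machine-readable reason.
#'
#' @param ratesByFamily Named list (families) of numeric rate vectors.
#' @param mutationTotals Named numeric vector of per-family mutation totals
#'   for the same cancer type.
#' @param minMutations Per-family mutation minimum (default 10).
#' @return List with \code{skipped} (logical), \code{reason} (when skipped),
#'   and the [compareKGroups()] fields otherwise.
#' @export
familyComparison <- function(ratesByFamily, mutationTotals,
                             minMutations = 10) {
  fams <- names(ratesByFamily)
  if (is.null(fams) || !all(fams %in% setdiff(.FAMILIES, "non_histone")))
    stop("ratesByFamily must be named by histone families (H1, H2A, H2B, H3, H4)")
  miss <- setdiff(fams, names(mutationTotals))
  if (length(miss)) mutationTotals[miss] <- 0
  low <- fams[mutationTotals[fams] < minMutations]
  if (length(low)) {
    return(list(skipped = TRUE,
                reason = sprintf("families below %d mutations: %s",
                                 minMutations, paste(low, collapse = ", "))))
  }
  c(list(skipped = FALSE, reason = NA_character_),
    compareKGroups(ratesByFamily))
}

#' Per-cancer-type comparison of one protein set against another
#'
#' Runs [compareTwoGroups()] on protein-level rates for every cancer type in
#' a [proteinRates()] table (histone proteins vs a comparison set, e.g. all
#' other proteins or CGC Tier-1 driver proteins with histones removed), then
#' BH-adjusts across cancer types. The output is volcano-plot-ready
#' (fold_change, minus_log10_q).
#'
#' @param rates Output of [proteinRates()].
#' @param accessionsA Protein accessions of the focal group (e.g. histones).
#' @param accessionsB Accessions of the comparison group; default: all other
#'   proteins in \code{rates}.
#' @return data.frame with one row per cancer type: n_a, n_b, U, p,
#'   fold_change, q, minus_log10_q.
#' @export
compareRatesByCancerType <- function(rates, accessionsA, accessionsB = NULL) {
  if (is.null(accessionsB))
    accessionsB <- setdiff(unique(rates$protein_accession), accessionsA)
  accessionsB <- setdiff(accessionsB, accessionsA)
  cts <- unique(rates$cancer_type)
  rows <- lapply(cts, function(ct) {
    sl <- rates[rates$cancer_type == ct, , drop = FALSE]
    a <- sl$r[sl$protein_accession %in% accessionsA]
    b <- sl$r[sl$protein_accession %in% accessionsB]
    if (!length(a) || !length(b)) return(NULL)
    cmp <- compareTwoGroups(a, b)
    data.frame(cancer_type = ct, n_a = length(a), n_b = length(b),
               U = cmp$U, p = cmp$p, fold_change = cmp$fold_change)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(out)
  out$q <- bhAdjust(out$p)
  out$minus_log10_q <- -log10(pmax(out$q, .Machine$double.xmin))
  rownames(out) <- NULL
  out
}
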