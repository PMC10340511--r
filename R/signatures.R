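#' @importFrom stats rmultinom quantile
NULL

## Multinomial maximum-likelihood refitting by EM. The exposures w live on
## the simplex; the model is p = S w and the log-likelihood
## sum_c n_c log(p_c). The problem is convex in w and the EM update
##   w_k <- w_k * (S^T (n / p))_k / N
## is monotone, so a uniform start plus a tight relative tolerance gives a
## deterministic global optimum without an external solver.
.mlDecompose <- function(n, S, tol = 1e-10, maxIter = 10000L) {
  K <- ncol(S)
  N <- sum(n)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  pos <- n > 0
  np <- n[pos]
  Sp <- S[pos, , drop = FALSE]
  for (it in seq_len(maxIter)) {
    p <- pmax(as.vector(Sp %*% w), 1e-300)
    ll <- sum(np * log(p))
    if (is.finite(ll_old) && ll - ll_old <= tol * abs(ll)) break
    ll_old <- ll
    w <- w * as.vector(crossprod(Sp, np / p)) / N
    w <- w / sum(w)
  }
  list(w = setNames(w, colnames(S)), logLik = ll, iterations = it)
}

.catalogMatrixFor <- function(profile, catalog, includeFlat) {
  stopifnot(is(profile, "MutationalProfile"), is(catalog, "SignatureCatalog"))
  if (profileTotal(profile) <= 0)
    stop("cannot decompose an empty profile")
  S <- signatureMatrix(catalog)
  if (includeFlat) {
    if ("flat" %in% colnames(S))
      stop("catalog already contains a signature named 'flat'")
    S <- cbind(S, flat = rep(1 / 96, 96))
  }
  S
}

#' Decompose a mutational profile into signature exposures
#'
#' Maximum-likelihood refitting of a profile against a signature catalog:
#' exposures maximize the multinomial log-likelihood
#' \eqn{\sum_c n_c \log(\sum_k w_k S_{ck})} over the simplex
#' (\eqn{w_k \ge 0}, \eqn{\sum_k w_k = 1}) and are reported as percentages
#' of query mutations explained by each mutational process. Optionally a
#' flat 1/96 column is appended to absorb context-free mutational
#' processes. The optimization is a convex EM with uniform initialization,
#' so results are deterministic.
#'
#' @param profile A [MutationalProfile-class] with positive total.
#' @param catalog A [SignatureCatalog-class].
#' @param includeFlat Append a uniform "flat" signature (default FALSE).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-10).
#' @param maxIter Iteration cap (default 10000).
#' @return A [SignatureDecomposition-class]; signatures with exposure above
#'   5 percent form the active set.
#' @export
decomposeProfile <- function(profile, catalog, includeFlat = FALSE,
                             tol = 1e-10, maxIter = 10000L) {
  S <- .catalogMatrixFor(profile, catalog, includeFlat)
  fit <- .mlDecompose(channelCounts(profile), S, tol = tol, maxIter = maxIter)
  expo <- 100 * fit$w / sum(fit$w)
  new("SignatureDecomposition", exposures = expo, logLik = fit$logLik,
      active = names(expo)[expo > 5],
      bootstrapMean = numeric(0), ciLow = numeric(0), ciHigh = numeric(0),
      nBoot = 0)
}

#' Bootstrap confidence intervals for signature exposures
#'
#' Resamples the profile \code{nBoot} times with replacement, drawing the
#' same number of mutations that built the profile (multinomial draws from
#' the normalized profile), decomposes each resample, and reports the mean
#' exposure and the 2.5/97.5 percentile bounds as the 95 percent confidence
#' interval. The point-estimate exposures and active set (exposure > 5
#' percent) come from the unresampled profile.
#'
#' @inheritParams decomposeProfile
#' @param nBoot Number of resamples (default 100).
#' @param seed Optional seed; fixed seed gives identical CIs across runs.
#' @return A [SignatureDecomposition-class] with bootstrap slots filled; see
#'   [exposureCI()].
#' @export
bootstrapDecompose <- function(profile, catalog, nBoot = 100, seed = NULL,
                               includeFlat = FALSE, tol = 1e-10,
                               maxIter = 10000L) {
  point <- decomposeProfile(profile, catalog, includeFlat = includeFlat,
                            tol = tol, maxIter = maxIter)
  S <- .catalogMatrixFor(profile, catalog, includeFlat)
  n <- channelCounts(profile)
  total <- profileTotal(profile)
  if (!is.null(seed)) set.seed(seed)
  draws <- rmultinom(nBoot, size = total, prob = n / total)
  boot <- apply(draws, 2, function(nb) {
    fit <- .mlDecompose(nb, S, tol = tol, maxIter = maxIter)
    100 * fit$w / sum(fit$w)
  })
  bm <- rowMeans(boot)
  lo <- apply(boot, 1, quantile, probs = 0.025, names = FALSE)
  hi <- apply(boot, 1, quantile, probs = 0.975, names = FALSE)
  ## percentile bounds can straddle the mean arbitrarily tightly; clamp for
  ## the elementwise ciLow <= mean <= ciHigh invariant
  new("SignatureDecomposition", exposures = exposures(point),
      logLik = point@logLik, active = activeSignatures(point),
      bootstrapMean = bm, ciLow = pmin(lo, bm), ciHigh = pmax(hi, bm),
      nBoot = nBoot)
}

#' Merge signature exposures by annotated etiology
#'
#' Sums exposures of signatures sharing an annotated etiology (e.g. UV =
#' SBS7a-d); ungrouped signatures pass through under their own names, so
#' the grand total stays 100. A group referencing a signature absent from
#' the decomposition triggers a warning and a partial sum.
#'
#' @param result A [SignatureDecomposition-class], or a named numeric vector
#'   of exposures.
#' @param groups Named list of signature-name vectors; see
#'   [cosmicEtiologyGroups()].
#' @return Named numeric vector: one entry per etiology group plus one per
#'   ungrouped signature.
#' @export
#' @examples
#' mergeEtiologies(c(SBS7a = 4, SBS7b = 5, SBS1 = 91),
#'                 list(UV = c("SBS7a", "SBS7b", "SBS7c", "SBS7d")))
mergeEtiologies <- function(result, groups) {
  expo <- if (is(result, "SignatureDecomposition")) exposures(result)
          else result
  stopifnot(is.numeric(expo), !is.null(names(expo)))
  out <- numeric(0)
  used <- character(0)
  for (g in names(groups)) {
    members <- groups[[g]]
    absent <- setdiff(members, names(expo))
    if (length(absent) == length(members)) next
    if (length(absent))
      warning("etiology group ", g, " references absent signature(s): ",
              paste(absent, collapse = ", "), "; partial sum used")
    present <- intersect(members, names(expo))
    out[g] <- sum(expo[present])
    used <- c(used, present)
  }
  rest <- expo[setdiff(names(expo), used)]
  c(out, rest)
}
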