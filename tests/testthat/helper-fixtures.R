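## Fixture builders and independent oracles shared across the suite.

mkVar <- function(patient_id = "p1", gene_symbol = "G1", chrom = "1",
                  pos = 100L, ref_allele = "C", alt_allele = "T",
                  classification = "missense", cancer_type = NA_character_,
                  context = NA_character_) {
  data.frame(patient_id = patient_id, gene_symbol = gene_symbol,
             chrom = chrom, pos = pos, ref_allele = ref_allele,
             alt_allele = alt_allele, classification = classification,
             cancer_type = cancer_type, context = context,
             stringsAsFactors = FALSE)
}

mkRegistry <- function(gene_symbol, protein_accession = gene_symbol,
                       cds_length = 300L, family = "non_histone",
                       histone_class = "not_applicable", chrom = "1") {
  data.frame(gene_symbol = gene_symbol,
             protein_accession = protein_accession,
             cds_length = cds_length, family = family,
             histone_class = histone_class, chrom = chrom,
             stringsAsFactors = FALSE)
}

## two-signature toy registry: two histone proteins (one multi-gene) plus
## non-histone background
toyRegistry <- function() {
  rbind(
    mkRegistry(c("HH.g1", "HH.g2"), "HHP", 300L, "H4", "canonical", "6"),
    mkRegistry("HX", "HXP", 600L, "H3", "canonical", "6"),
    mkRegistry(c("NG1", "NG2", "POLE"), c("NP1", "NP2", "POLE_P"),
               c(900L, 1200L, 6861L)))
}

## deterministic toy catalog: k columns concentrated on disjoint blocks
toyCatalog <- function(k = 2, seed = 99) syntheticSignatures(k, seed = seed)

## --- Oracles ----------------------------------------------------------

## Brute-force two-sided Mann-Whitney p by enumerating all assignments of
## the pooled values to group a (valid when there are no ties).
bruteMannWhitneyP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  uStat <- function(x, y) sum(rank(c(x, y))[seq_along(x)]) -
    length(x) * (length(x) + 1) / 2
  u_obs <- uStat(a, b)
  us <- apply(idx, 2, function(i) uStat(pool[i], pool[-i]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Exact p for a 2-gene goodness-of-fit table by binomial enumeration.
exactTwoGeneChiP <- function(obs, probs) {
  t <- sum(obs)
  expd <- t * probs
  chi <- function(k) sum((c(k, t - k) - expd)^2 / expd)
  chi_obs <- chi(obs[1])
  ks <- 0:t
  sum(stats::dbinom(ks[vapply(ks, chi, 0) >= chi_obs - 1e-9], t, probs[1]))
}

## Brute-force simplex grid search for the multinomial refit (K = 2 or 3).
gridDecompose <- function(n, S, res = 0.01) {
  K <- ncol(S)
  stopifnot(K %in% c(2L, 3L))
  grid <- if (K == 2L) {
    w1 <- seq(0, 1, by = res)
    rbind(w1, 1 - w1)
  } else {
    g <- expand.grid(w1 = seq(0, 1, by = res), w2 = seq(0, 1, by = res))
    g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
    rbind(g$w1, g$w2, pmax(0, 1 - g$w1 - g$w2))
  }
  P <- pmax(S %*% grid, 1e-300)
  ll <- as.vector(crossprod(n, log(P)))
  best <- which.max(ll)
  list(w = grid[, best], logLik = ll[best])
}

## One-sided hypergeometric tail by direct summation.
enumHyperGreaterP <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  xs <- a:min(k, m)
  sum(stats::dhyper(xs, m, n, k))
}

## reverse complement of arbitrary sequences (oracle-side helper)
rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
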