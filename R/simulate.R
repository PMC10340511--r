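#' @importFrom stats rnbinom runif rgamma rnorm
NULL

#' Simulate coding reference sequences for a registry
#'
#' Draws an i.i.d. nucleotide sequence of the requested coding length for
#' every registry gene, at a configurable GC content. Deterministic given
#' the seed.
#'
#' @param registry Registry data.frame (gene_symbol, cds_length); every
#'   cds_length must be at least 10.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @param gc GC content in (0, 1), default 0.5.
#' @return A \code{Biostrings::DNAStringSet} named by gene symbol.
#' @export
simulateReference <- function(registry, seed = NULL, gc = 0.5) {
  stopifnot(is.data.frame(registry),
            all(c("gene_symbol", "cds_length") %in% names(registry)))
  if (any(registry$cds_length < 10))
    stop("every cds_length must be >= 10 to simulate a reference")
  stopifnot(gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(registry$cds_length, function(L) {
    paste(sample(.BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, registry$gene_symbol))
}

#' Well-separated synthetic SBS96 signatures
#'
#' Builds k synthetic signature columns, each concentrating most of its
#' probability mass (default 94 percent) on its own substitution block
#' (C>A, C>G, C>T, T>A, T>C, T>G in turn), with the remainder spread evenly
#' over all other channels so every entry is positive. Within-block weights
#' are Dirichlet-distributed. These columns are near-orthogonal, which makes
#' mixture recovery identifiable in simulation studies.
#'
#' @param k Number of signatures (2..6).
#' @param seed Seed (default 1).
#' @param blockMass Probability mass on the home block (default 0.94).
#' @param names Signature names; default \code{"sigA"}, \code{"sigB"}, ...
#' @return A [SignatureCatalog-class].
#' @export
syntheticSignatures <- function(k = 3, seed = 1, blockMass = 0.94,
                                names = NULL) {
  stopifnot(k >= 2, k <= 6, blockMass > 0, blockMass < 1)
  if (is.null(names)) names <- paste0("sig", LETTERS[seq_len(k)])
  set.seed(seed)
  m <- matrix(0, 96, k, dimnames = list(.SBS96, names))
  for (j in seq_len(k)) {
    block <- (j - 1) * 16 + seq_len(16)
    w <- rgamma(16, shape = 1)
    col <- rep((1 - blockMass) / 80, 96)
    col[block] <- blockMass * w / sum(w)
    m[, j] <- col / sum(col)
  }
  SignatureCatalog(m)
}

#' Default synthetic registry emulating the histone gene complement
#'
#' A scaled-down redundancy map in the image of the human histone
#' complement: an 11-gene H4-like protein, a 10-gene H3.1-like protein,
#' multi-gene H2A/H2B/H3.2-like proteins, single-gene linker (H1) histones
#' including one variant histone, and a background of non-histone genes
#' (among them POLE, used by the co-occurrence analyses). Canonical histone
#' genes sit on the nominal cluster chromosomes (6 and 1).
#'
#' @param nNonHistone Number of non-histone background genes (default 40).
#' @param seed Seed controlling non-histone CDS lengths (default 1).
#' @return Registry data.frame with the extra column \code{group_label}
#'   (\code{"histone"} / \code{"non_histone"}) used to key signature
#'   mixtures.
#' @export
defaultRegistry <- function(nNonHistone = 40, seed = 1) {
  spec <- data.frame(
    protein_accession = c("HIST_H4", "HIST_H31", "HIST_H32", "HIST_H2B",
                          "HIST_H2A", "H1_2", "H1_4", "H1_5", "H1_8"),
    n_genes = c(11L, 10L, 3L, 6L, 5L, 1L, 1L, 1L, 1L),
    cds_length = c(312L, 411L, 411L, 381L, 393L, 642L, 660L, 681L, 612L),
    family = c("H4", "H3", "H3", "H2B", "H2A", "H1", "H1", "H1", "H1"),
    histone_class = c(rep("canonical", 8), "variant"),
    chrom = c("6", "6", "1", "6", "6", "6", "6", "6", "3"))
  reg <- makeRegistry(spec)
  set.seed(seed)
  nh_len <- as.integer(round(runif(nNonHistone, 900, 3000)))
  nh <- data.frame(
    gene_symbol = c("POLE", paste0("NHG", seq_len(nNonHistone - 1))),
    protein_accession = c("POLE_P", paste0("NHP", seq_len(nNonHistone - 1))),
    cds_length = c(6861L, nh_len[-1]),
    family = "non_histone", histone_class = "not_applicable",
    chrom = as.character(c(12, sample(1:22, nNonHistone - 1, replace = TRUE))))
  out <- rbind(reg, nh)
  out$group_label <- ifelse(out$family == "non_histone",
                            "non_histone", "histone")
  out
}

#' Expand a compact protein-level spec into a gene registry
#'
#' @param spec data.frame with columns protein_accession, n_genes,
#'   cds_length, family, histone_class, chrom; one row per protein.
#' @return Registry data.frame; member genes are named
#'   \code{<accession>.g<i>} for multi-gene proteins and
#'   \code{<accession>} otherwise.
#' @export
makeRegistry <- function(spec) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    syms <- if (s$n_genes == 1L) s$protein_accession
            else paste0(s$protein_accession, ".g", seq_len(s$n_genes))
    data.frame(gene_symbol = syms, protein_accession = s$protein_accession,
               cds_length = s$cds_length, family = s$family,
               histone_class = s$histone_class, chrom = s$chrom)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.DEFAULT_CLASS_PROBS <- c(
  missense = 0.720, silent = 0.240,          # the fixed 1:3 silent:missense
  nonsense = 0.015, nonstop = 0.001,
  frameshift_insertion = 0.004, frameshift_deletion = 0.004,
  splice_site = 0.005, splice_region = 0.005,
  translation_start_site = 0.001, other = 0.005)

#' Build a validated simulation configuration
#'
#' The stated world for the synthetic cohort: per-patient mutation counts
#' are negative-binomial (defaults mean 50, dispersion 2, emulating the
#' heavy-tailed burden of real cohorts); genes receive mutations with
#' probability proportional to coding length times a per-gene rate
#' multiplier; SBS96 channels are drawn from per-gene-group signature
#' mixtures; consequence classes follow a fixed 1:3 silent:missense ratio
#' with small probabilities for the remaining classes. An optional
#' hypermutator subset carries an extra signature and a burden factor.
#'
#' @param seed Master seed; all randomness flows from it.
#' @param nPatients Number of patients.
#' @param catalog A [SignatureCatalog-class] supplying the signatures.
#' @param mixture Named list: gene-group label (matching the registry's
#'   \code{group_label}) to a named weight vector over catalog signatures
#'   (each summing to 1 within 1e-9).
#' @param registry Registry data.frame with a \code{group_label} column
#'   (default [defaultRegistry()]).
#' @param cancerTypeWeights Named probability vector over cancer types
#'   (sums to 1 within 1e-9).
#' @param multipliers Named per-gene positive rate multipliers (default 1
#'   for every gene).
#' @param burdenMean,burdenDispersion Negative-binomial mean and dispersion
#'   (size) of per-patient mutation counts.
#' @param classProbs Named probability vector over consequence classes.
#' @param gc Reference GC content.
#' @param hypermutatorFraction Fraction of patients flagged hypermutator.
#' @param hypermutatorSignature Catalog signature mixed (at weight
#'   \code{hypermutatorWeight}) into every gene group for hypermutator
#'   patients.
#' @param hypermutatorWeight Mixing weight of the hypermutator signature.
#' @param hypermutatorBurdenFactor Burden multiplier for hypermutators
#'   (default 10).
#' @return A validated config list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(seed, nPatients, catalog, mixture,
                             registry = defaultRegistry(),
                             cancerTypeWeights = c(cohort = 1),
                             multipliers = NULL,
                             burdenMean = 50, burdenDispersion = 2,
                             classProbs = .DEFAULT_CLASS_PROBS,
                             gc = 0.5,
                             hypermutatorFraction = 0,
                             hypermutatorSignature = NULL,
                             hypermutatorWeight = 0.5,
                             hypermutatorBurdenFactor = 10) {
  stopifnot(is(catalog, "SignatureCatalog"), is.list(mixture))
  if (!"group_label" %in% names(registry))
    stop("registry must carry a group_label column keying the mixtures")
  .validateRegistry(registry)
  miss <- setdiff(unique(registry$group_label), names(mixture))
  if (length(miss))
    stop("no signature mixture for gene group(s): ",
         paste(miss, collapse = ", "))
  for (lab in names(mixture)) {
    w <- mixture[[lab]]
    if (abs(sum(w) - 1) > 1e-9)
      stop("mixture weights for ", lab, " must sum to 1 within 1e-9")
    if (any(w < 0)) stop("mixture weights must be nonnegative")
    unknown <- setdiff(names(w), signatureNames(catalog))
    if (length(unknown))
      stop("mixture for ", lab, " references unknown signature(s): ",
           paste(unknown, collapse = ", "))
  }
  if (abs(sum(cancerTypeWeights) - 1) > 1e-9)
    stop("cancer type weights must sum to 1 within 1e-9")
  if (is.null(multipliers))
    multipliers <- setNames(rep(1, nrow(registry)), registry$gene_symbol)
  if (any(multipliers <= 0)) stop("rate multipliers must be positive")
  miss_m <- setdiff(registry$gene_symbol, names(multipliers))
  if (length(miss_m)) multipliers[miss_m] <- 1
  if (abs(sum(classProbs) - 1) > 1e-9 ||
      !all(names(classProbs) %in% .CLASSIFICATIONS))
    stop("classProbs must be a probability vector over known classes")
  if (hypermutatorFraction > 0 && is.null(hypermutatorSignature))
    stop("hypermutatorSignature must name a catalog signature when ",
         "hypermutatorFraction > 0")
  if (!is.null(hypermutatorSignature) &&
      !hypermutatorSignature %in% signatureNames(catalog))
    stop("hypermutatorSignature is not in the catalog")
  structure(list(seed = seed, nPatients = nPatients, catalog = catalog,
                 mixture = mixture, registry = registry,
                 cancerTypeWeights = cancerTypeWeights,
                 multipliers = multipliers[registry$gene_symbol],
                 burdenMean = burdenMean,
                 burdenDispersion = burdenDispersion,
                 classProbs = classProbs, gc = gc,
                 hypermutatorFraction = hypermutatorFraction,
                 hypermutatorSignature = hypermutatorSignature,
                 hypermutatorWeight = hypermutatorWeight,
                 hypermutatorBurdenFactor = hypermutatorBurdenFactor),
            class = "simulationConfig")
}

## per-gene site index: positions 2..L-1 grouped by pyrimidine-collapsed
## trinucleotide
.siteIndex <- function(seq) {
  L <- nchar(seq)
  pos <- 2:(L - 1L)
  tri <- .collapseContext(substring(seq, pos - 1L, pos + 1L))
  split(pos, tri)
}

#' Simulate a cohort of signature-driven somatic mutations
#'
#' Generates reference sequences, patients and mutations under a known
#' ground truth. Each mutation is produced by (i) drawing a patient (burden
#' negative-binomial), (ii) drawing a gene with probability proportional to
#' coding length times its rate multiplier, (iii) drawing an SBS96 channel
#' from the gene group's signature mixture, restricted (with
#' renormalization) to channels for which the gene's sequence has at least
#' one eligible pyrimidine-collapsed trinucleotide site, and (iv) placing
#' the mutation uniformly on an eligible site, on the strand dictated by
#' the reference base. Consequence classes are drawn independently
#' (silent:missense fixed at 1:3); frameshift classes are materialized as
#' 1-bp indels and therefore drop out of profile construction.
#'
#' Ground truth records the configured mixtures, the availability-corrected
#' effective mixture per gene group (the channel distribution actually
#' sampled, marginalized over genes) and its maximum-likelihood exposure
#' projection, per-gene draw probabilities, multipliers, per-patient
#' burdens and hypermutator flags, so that recovery tests compare like with
#' like.
#'
#' @param config A [simulationConfig()].
#' @return List with \code{variants} (data.frame; \code{chrom} holds the
#'   gene symbol and \code{pos} the 1-based CDS coordinate),
#'   \code{clinical}, \code{registry}, \code{reference}
#'   (\code{DNAStringSet}) and \code{groundTruth}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  reg <- config$registry
  set.seed(config$seed)
  reference <- simulateReference(reg, seed = NULL, gc = config$gc)
  seqs <- as.character(reference)
  sites <- lapply(seqs, .siteIndex)

  S <- signatureMatrix(config$catalog)
  tri_of <- setNames(.channelTrinucleotide(), .SBS96)
  alt_of <- setNames(.channelAlt(), .SBS96)

  ## per-(gene, hyper) effective channel distributions
  mixQ <- function(w, hyper) {
    q <- as.vector(S[, names(w), drop = FALSE] %*% w)
    if (hyper && !is.null(config$hypermutatorSignature))
      q <- (1 - config$hypermutatorWeight) * q +
        config$hypermutatorWeight * S[, config$hypermutatorSignature]
    setNames(q, .SBS96)
  }
  effQ <- function(gene, hyper) {
    q <- mixQ(config$mixture[[reg$group_label[match(gene, reg$gene_symbol)]]],
              hyper)
    avail <- tri_of %in% names(sites[[gene]])
    q[!avail] <- 0
    if (sum(q) <= 0)
      stop("gene ", gene, " has no eligible site for any ",
           "positive-probability channel")
    q / sum(q)
  }

  patients <- sprintf("P%05d", seq_len(config$nPatients))
  cancer_type <- sample(names(config$cancerTypeWeights), config$nPatients,
                        replace = TRUE, prob = config$cancerTypeWeights)
  hyper <- runif(config$nPatients) < config$hypermutatorFraction
  mu <- ifelse(hyper, config$burdenMean * config$hypermutatorBurdenFactor,
               config$burdenMean)
  burden <- rnbinom(config$nPatients, size = config$burdenDispersion, mu = mu)
  N <- sum(burden)
  if (N == 0) stop("simulated zero mutations; increase burdenMean/nPatients")

  pidx <- rep(seq_len(config$nPatients), burden)
  gene_prob <- reg$cds_length * config$multipliers
  gene <- sample(reg$gene_symbol, N, replace = TRUE, prob = gene_prob)
  is_hyper <- hyper[pidx]

  chan <- character(N)
  pos <- integer(N)
  for (g in reg$gene_symbol) {         # deterministic registry order
    for (h in c(FALSE, TRUE)) {
      idx <- which(gene == g & is_hyper == h)
      if (!length(idx)) next
      q <- effQ(g, h)
      drawn <- sample(.SBS96, length(idx), replace = TRUE, prob = q)
      chan[idx] <- drawn
      tri <- tri_of[drawn]
      for (t in sort(unique(tri))) {
        tidx <- idx[tri == t]
        sl <- sites[[g]][[t]]
        pos[tidx] <- sl[sample.int(length(sl), length(tidx), replace = TRUE)]
      }
    }
  }

  ref <- substring(seqs[gene], pos, pos)
  ctx <- substring(seqs[gene], pos - 1L, pos + 1L)
  pyr <- ref %in% c("C", "T")
  alt <- ifelse(pyr, alt_of[chan], unname(.COMPLEMENT[alt_of[chan]]))

  cls <- sample(names(config$classProbs), N, replace = TRUE,
                prob = config$classProbs)
  v <- data.frame(patient_id = patients[pidx], gene_symbol = gene,
                  chrom = gene, pos = pos, ref_allele = ref,
                  alt_allele = unname(alt), classification = cls,
                  cancer_type = cancer_type[pidx], context = ctx)
  ins <- v$classification == "frameshift_insertion"
  del <- v$classification == "frameshift_deletion"
  if (any(ins)) {
    v$ref_allele[ins] <- "-"
    v$alt_allele[ins] <- sample(.BASES, sum(ins), replace = TRUE)
    v$context[ins] <- NA_character_
  }
  if (any(del)) {
    v$alt_allele[del] <- "-"
    v$context[del] <- NA_character_
  }
  v <- .validateVariants(v, source = "simulated cohort")

  ## availability-corrected effective mixture per gene group (non-hyper
  ## patients' channel law), plus its ML exposure projection
  truth_mix <- list()
  for (lab in unique(reg$group_label)) {
    in_lab <- reg$group_label == lab
    wg <- gene_prob[in_lab] / sum(gene_prob[in_lab])
    p_eff <- setNames(numeric(96), .SBS96)
    for (i in which(in_lab))
      p_eff <- p_eff + wg[match(i, which(in_lab))] *
        effQ(reg$gene_symbol[i], FALSE)
    fit <- .mlDecompose(p_eff * 1e6, S)
    truth_mix[[lab]] <- list(effective_profile = p_eff,
                             effective_exposures = 100 * fit$w,
                             configured = config$mixture[[lab]])
  }

  list(variants = v,
       clinical = data.frame(patient_id = patients,
                             cancer_type = cancer_type),
       registry = reg,
       reference = reference,
       groundTruth = list(
         mixtures = truth_mix,
         multipliers = config$multipliers,
         gene_draw_prob = setNames(gene_prob / sum(gene_prob),
                                   reg$gene_symbol),
         per_gene_counts = table(factor(gene, levels = reg$gene_symbol)),
         patient_burden = setNames(burden, patients),
         hypermutator = setNames(hyper, patients)))
}

#' Simulate a cohort with an exact designed-in co-occurrence odds ratio
#'
#' Draws per-patient (histone-mutated, query-gene-mutated) status from the
#' joint Bernoulli distribution with the requested marginals and odds ratio
#' (Plackett construction), then materializes one variant record per
#' status flag plus one background mutation per patient so every patient is
#' observable. This pins the true odds ratio exactly, which the
#' burden-driven hypermutator mechanism of [simulateCohort()] cannot.
#'
#' @param nPatients Number of patients.
#' @param pHistone,pQuery Marginal probabilities of carrying a histone /
#'   query-gene mutation.
#' @param oddsRatio Target odds ratio (> 0).
#' @param seed Seed.
#' @param registry Registry (default [defaultRegistry()]).
#' @param queryGene Query gene symbol (default \code{"POLE"}).
#' @return List with variants, clinical, registry, and groundTruth
#'   (joint cell probabilities and the designed odds ratio).
#' @export
simulateCooccurrenceCohort <- function(nPatients, pHistone = 0.25,
                                       pQuery = 0.1, oddsRatio = 6,
                                       seed = 1,
                                       registry = defaultRegistry(),
                                       queryGene = "POLE") {
  stopifnot(oddsRatio > 0, pHistone > 0, pHistone < 1, pQuery > 0,
            pQuery < 1, queryGene %in% registry$gene_symbol)
  p11 <- if (oddsRatio == 1) pHistone * pQuery else {
    s <- 1 + (pHistone + pQuery) * (oddsRatio - 1)
    (s - sqrt(s^2 - 4 * oddsRatio * (oddsRatio - 1) * pHistone * pQuery)) /
      (2 * (oddsRatio - 1))
  }
  cells <- c(both = p11, histone_only = pHistone - p11,
             query_only = pQuery - p11,
             neither = 1 - pHistone - pQuery + p11)
  stopifnot(all(cells >= -1e-12))
  set.seed(seed)
  status <- sample(names(cells), nPatients, replace = TRUE, prob = cells)
  patients <- sprintf("P%05d", seq_len(nPatients))
  is_hist <- registry$family != "non_histone"
  histone_genes <- registry$gene_symbol[is_hist]
  bg_genes <- setdiff(registry$gene_symbol[!is_hist], queryGene)
  mk <- function(pid, genes) {
    g <- if (length(genes) == 1L) rep(genes, length(pid))
         else sample(genes, length(pid), replace = TRUE)
    data.frame(patient_id = pid, gene_symbol = g, chrom = g,
               pos = 5L, ref_allele = "C", alt_allele = "T",
               classification = "missense", cancer_type = "cohort",
               context = NA_character_)
  }
  hist_p <- patients[status %in% c("both", "histone_only")]
  query_p <- patients[status %in% c("both", "query_only")]
  v <- rbind(mk(patients, bg_genes),
             if (length(hist_p)) mk(hist_p, histone_genes),
             if (length(query_p)) mk(query_p, queryGene))
  v <- .validateVariants(v, source = "co-occurrence cohort")
  list(variants = v,
       clinical = data.frame(patient_id = patients, cancer_type = "cohort"),
       registry = registry,
       groundTruth = list(cells = cells, odds_ratio = oddsRatio,
                          status = setNames(status, patients)))
}

#' Simulate gene-level covariates tied to rate multipliers
#'
#' Emulates the covariate structure of background-mutation-rate models:
#' replication time (100 very early ... 1500 very late) increases
#' monotonically with a gene's rate multiplier (late-replicating regions
#' accumulate more mutations), expression decreases with it, and chromatin
#' state (-50..50) is independent noise. Gaussian noise is added on the
#' latent scale and values are clamped to the conventional ranges.
#'
#' @param registry Registry data.frame.
#' @param multipliers Named per-gene multipliers (as in the simulation).
#' @param seed Seed.
#' @param noise Noise standard deviation on the latent 0..1 scale
#'   (default 0.1).
#' @return Covariate data.frame (gene_symbol, expression,
#'   replication_time, chromatin_state).
#' @export
simulateCovariates <- function(registry, multipliers, seed = 1,
                               noise = 0.1) {
  set.seed(seed)
  mult <- multipliers[registry$gene_symbol]
  mult[is.na(mult)] <- 1
  u <- rank(log(mult), ties.method = "average") / length(mult)
  jitter1 <- pmin(pmax(u + rnorm(length(u), 0, noise), 0), 1)
  jitter2 <- pmin(pmax(u + rnorm(length(u), 0, noise), 0), 1)
  data.frame(gene_symbol = registry$gene_symbol,
             expression = round(10 * (1 - jitter2), 4),
             replication_time = round(100 + 1400 * jitter1, 1),
             chromatin_state = round(runif(length(u), -50, 50), 1))
}
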