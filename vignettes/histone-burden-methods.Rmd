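---
title: "Methods: mutation burden in redundant histone gene families"
author: "histoneBurden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation burden in redundant histone gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneBurden)
```

# The problem

Histone proteins are encoded redundantly: a single protein such as H4 is
produced by up to 11 near-identical genes, most of them clustered in the
replication-dependent histone loci on chromosomes 6 and 1. Somatic-mutation
burden analyses that treat each gene independently therefore dilute any
signal across interchangeable copies, while analyses that ignore gene
identity miss the fact that mutagenesis acts on DNA, not on proteins. This
package implements both views and the statistics connecting them: a
protein-level pooled rate, gene-level homogeneity tests within each protein,
mutational-profile decomposition contrasting histone with non-histone
mutations, and association/covariate analyses for candidate mutagenic
drivers of the observed burden.

# The rate statistic

For a protein encoded by genes $i = 1 \dots n$ with coding lengths $c_i$
(bp) and mutation counts $m_i$, the observed rate is the pooled ratio

$$r = \frac{\sum_{i=1}^n m_i}{\sum_{i=1}^n c_i}.$$

Only nine consequence classes count toward $m_i$: missense, silent,
nonsense, nonstop, frameshift insertion, frameshift deletion, splice site,
splice region and translation start site. Everything else (UTR, intronic,
...) is retained in the variant table as `other` but excluded from burden.
The pooled ratio is a *mediant* of the per-gene rates, so it always lies
between $\min_i m_i/c_i$ and $\max_i m_i/c_i$ and is invariant under
replicating a gene set — both properties are enforced as tests. Exact
duplicate calls (same patient, chromosome, position, alternate allele) are
deduplicated with a logged count; the MAF's gene annotation is taken as-is,
and a record annotated to two genes as two rows counts once per gene.

Per-cancer-type rates are reported only for types with at least 10
patients; patients of smaller types still contribute to the pan-cancer
estimate.

# Group comparisons

The sampling unit for rate comparisons is the protein (one $r$ per protein
per cancer type). Two-group contrasts (histone proteins vs all others, or
vs a driver list with histones removed) use a two-sided Mann–Whitney U:
exact null distribution when $n_a n_b \le 200$ with no ties, otherwise the
normal approximation with tie and continuity corrections (verified against
`stats::wilcox.test` and a brute-force enumeration oracle). Fold change is
the ratio of group mean rates, defined only when both means are positive.
K-group contrasts (across the five histone families) use tie-corrected
Kruskal–Wallis with a BH-adjusted Dunn post hoc gated on the omnibus test;
the family contrast additionally requires at least 10 observed mutations in
every family in that cancer type, otherwise it is skipped with a recorded
reason. Benjamini–Hochberg adjustment is applied per analysis family,
across cancer types within one question.

# Homogeneity across genes encoding one protein

Whether mutations distribute unevenly across a protein's gene copies is
tested with a goodness-of-fit $\chi^2$ on the number of *patients* mutated
per gene (not raw mutation counts). The null expected counts are
proportional to CDS length by default — for the identical-length paralogs
typical of histone clusters this reduces to uniform, and a `uniform` null
is exposed as an option; the choice is deliberately configurable because
the two nulls answer subtly different questions (beyond-length vs absolute
imbalance). When any expected count falls below 5 the asymptotic reference
is unreliable and the p-value switches to Monte-Carlo: 10,000 multinomial
tables at the observed total, with the conservative
$p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(B+1)$ correction so $p = 0$
is impossible. The Monte-Carlo path is validated against exact binomial
enumeration on all two-gene tables with total $\le 6$. One numerical
caveat, found during validation and worth recording: for two-gene
(df = 1) tables the Monte-Carlo p *includes* the discrete point mass at the
observed statistic while the continuous asymptotic reference splits it, so
the two disagree by roughly half the central point mass (about 0.04 at a
total of 120) even when all expected counts are large. Agreement bands of
±0.02 are therefore only meaningful for tables with three or more cells or
very large totals, and the test suite checks the band on 3–5-gene tables.

# Profiles and signature refitting

Patients are split into `patient_set1` (at least one histone-gene
mutation) and `patient_set2` (none); mutations of set-1 patients split into
`gene_group1` (histone) and `gene_group2` (non-histone), and all mutations
of set-2 patients form `gene_group3`. The partition is total and disjoint
by construction and by test.

Each group's single-nucleotide substitutions are binned into the 96
pyrimidine-centered trinucleotide channels in the fixed COSMIC ordering
(substitution blocks C>A, C>G, C>T, T>A, T>C, T>G; flanks lexicographic),
so catalog files are bit-compatible with COSMIC SBS96 downloads.
Purine-reference variants are reverse complemented; indels and MNVs are
skipped with a count. Contexts come from the variant table when present
(reference strand, middle base equal to the reference allele — validated at
I/O) or are extracted from reference sequences.

Exposures are the maximizer of the multinomial log-likelihood
$\sum_c n_c \log \left(\sum_k w_k S_{ck}\right)$ over the simplex, reported
as percentages. The optimizer is the EM update
$w_k \leftarrow w_k \, (S^\top (n/p))_k / N$ with $p = Sw$: the objective
is concave in $w$, EM is monotone, and with uniform initialization and a
relative-likelihood tolerance of $10^{-10}$ (cap 10,000 iterations) the
result is deterministic without an external solver. Optimality is tested
against a brute-force simplex grid at resolution 0.01 for $K \le 3$. An
optional flat $1/96$ column absorbs context-free mutational processes.
Refitting against a provided catalog is the entire scope — no de-novo
extraction.

Bootstrap CIs resample the profile's total multinomially from the
normalized profile 100 times, decompose each resample, and take the
2.5/97.5 percentiles; the mean exposure is reported alongside. The 5%
activity threshold is applied to the point-estimate exposure (the CI and
bootstrap mean are reported so a reader can apply a different rule).
Etiology merging sums exposures within annotated groups (UV, MMR, POLE,
POLD1, tobacco, APOBEC); ungrouped signatures pass through, so the total
stays 100.

# Association and covariates

Histone/query-gene co-occurrence is a one-sided exact hypergeometric test
(direction "greater" for enrichment, configurable), with the sample odds
ratio $(ad)/(bc)$; the 0.5 Haldane correction is applied, and flagged, only
when a zero cell occurs, and a zero margin makes the result degenerate with
$p = 1$. The query axis can be restricted to a supplied list of known
driver mutations (gene, position, alternate allele). Covariate analysis
operates at gene level — one pooled pan-cancer rate $m_i/c_i$ per gene —
with Pearson correlations against expression, replication time
(100 = very early … 1500 = very late) and chromatin state (−50 … +50),
pairwise-complete and flagged when a vector is constant.

# The synthetic cohort: what it emulates and what it does not

The generator states a world and keeps it fixed:

* **Burden.** Per-patient mutation counts are negative binomial, mean 50,
  dispersion 2 — a heavy-tailed burden typical of multi-cancer WES cohorts.
* **Registry.** The default registry mirrors the histone complement's
  redundancy structure at reduced scale: an 11-gene H4-like protein, a
  10-gene H3.1-like protein, multi-gene H2A/H2B/H3.2 families, single-gene
  linker histones including one variant histone, and ~40 non-histone
  background genes (including POLE). CDS lengths are in the real histone
  range (312–681 bp; non-histone 900–3000 bp).
* **Mutations.** A gene is drawn with probability proportional to CDS
  length × a per-gene rate multiplier; an SBS96 channel is drawn from the
  gene group's signature mixture; a position is drawn uniformly among the
  gene's sites whose pyrimidine-collapsed trinucleotide matches the
  channel. Channels with no eligible site are removed with renormalization
  (rejection sampling); a gene with no eligible site at all is a hard
  error. Consequence classes are drawn independently with silent:missense
  fixed at 1:3 and small probabilities for the remaining classes;
  frameshift classes are materialized as 1-bp indels so profile
  construction must skip them.
* **Ground truth.** Because short CDS sequences have uneven trinucleotide
  composition, the channel law actually sampled differs from the nominal
  mixture $\sum_k w_k S_k$. The generator therefore records the
  availability-corrected *effective* mixture per gene group and its
  maximum-likelihood exposure projection, and recovery tests compare
  against that — otherwise they would conflate sampling bias with
  estimator bias.
* **Designed effects.** A hypermutator flag gives a patient subset an
  extra signature and a 10× burden. Because burden inflation cannot pin an
  odds ratio exactly, a second generator draws per-patient
  (histone-mutated, query-mutated) status from the joint Bernoulli
  distribution with requested marginals and odds ratio (the Plackett
  solution of $\psi = p_{11}p_{00}/(p_{10}p_{01})$) and materializes
  variant records from it.

Not emulated: indel sequence context, copy number, clustered mutational
processes (kataegis), inter-gene linkage of the histone loci, or
codon-level selection. A green recovery test therefore establishes that the
estimators are correct under multinomial sampling from a known mixture —
not that real cohorts satisfy those assumptions.

# Numerical and design choices

* Coordinates are 1-based inclusive (MAF convention); contexts are always
  stored on the reference strand and collapsed only in profile
  construction.
* Classification strings outside the MAF vocabulary map to `other` rather
  than erroring, so cohort files with extra consequence classes remain
  usable.
* The comparison p-value switches from exact to normal at
  $n_a n_b > 200$ or any tie; the continuity correction uses
  $\mathrm{sign}(U - \mu)/2$, so identical groups give exactly $p = 1$.
* All randomness flows from a single seed; the pipeline fans it out to
  per-stage seeds by stage-name hashing so stages can be rerun
  independently. Reruns are byte-identical.
* Configuration objects are validated R lists (JSON for serialized
  artifacts); no YAML dependency is available in the target environment.
* Tolerances: catalog columns must sum to 1 within $10^{-3}$ at I/O (then
  renormalized; within $10^{-6}$ in the class invariant); exposure sums are
  exact to $10^{-6}$; EM stops at relative log-likelihood change
  $10^{-10}$.

# Known limitations

* Exposures from the EM refit agree with any maximum-likelihood refitting
  of the stated multinomial objective, but published tools add their own
  regularization and preprocessing, so exposure values on real data may
  differ in detail from any specific external implementation.
* The per-protein rate has no covariate adjustment; identifying driver
  genes against a covariate-aware background model is explicitly out of
  scope (external tools exist for that), and the covariate module reports
  correlations only.
* Bootstrap percentile CIs undercover slightly for exposures near the
  simplex boundary (a pure-signature profile has a degenerate CI at 100);
  coverage is tested for interior mixtures.
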