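test_that("partitionCohort implements the patient-set/gene-group scheme", {
  reg <- toyRegistry()
  v <- rbind(mkVar("p1", "HH.g1", pos = 5L),    # histone
             mkVar("p1", "NG1", pos = 9L),      # non-histone, same patient
             mkVar("p2", "NG2", pos = 3L))      # patient without histone hit
  part <- partitionCohort(v, reg)
  expect_equal(patientSet1(part), "p1")
  expect_equal(patientSet2(part), "p2")
  expect_equal(as.character(variantGroups(part)),
               c("gene_group1", "gene_group2", "gene_group3"))

  ## no histone mutations anywhere
  part2 <- partitionCohort(v[3, , drop = FALSE], reg)
  expect_length(patientSet1(part2), 0L)
  expect_equal(as.character(variantGroups(part2)), "gene_group3")

  ## all mutations on histone genes
  part3 <- partitionCohort(v[1, , drop = FALSE], reg)
  expect_equal(as.character(variantGroups(part3)), "gene_group1")
})

test_that("partition is total and disjoint under random cohorts (property)", {
  reg <- toyRegistry()
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    v <- do.call(rbind, lapply(seq_len(n), function(i) {
      mkVar(paste0("p", sample(1:15, 1)), sample(reg$gene_symbol, 1),
            pos = i)
    }))
    part <- partitionCohort(v, reg)
    grp <- variantGroups(part)
    expect_equal(length(grp), n)                 # total
    expect_false(anyNA(grp))                     # each row exactly one group
    expect_length(intersect(patientSet1(part), patientSet2(part)), 0L)
    expect_setequal(c(patientSet1(part), patientSet2(part)),
                    unique(v$patient_id))
    ## group1/2 mutations belong to set1 patients, group3 to set2
    expect_true(all(v$patient_id[grp != "gene_group3"] %in% patientSet1(part)))
    expect_true(all(v$patient_id[grp == "gene_group3"] %in% patientSet2(part)))
  }
})

test_that("buildProfile maps contexts onto pyrimidine-centered channels", {
  ## G>A with context TGC reverse complements to G[C>T]A
  v1 <- mkVar(ref_allele = "G", alt_allele = "A", context = "TGC")
  p1 <- buildProfile(v1)
  expect_equal(unname(channelCounts(p1)["G[C>T]A"]), 1)
  expect_equal(profileTotal(p1), 1)

  ## C>T with context ACA lands in A[C>T]A directly
  v2 <- mkVar(ref_allele = "C", alt_allele = "T", context = "ACA")
  expect_equal(unname(channelCounts(buildProfile(v2))["A[C>T]A"]), 1)

  ## 10 SNVs + 2 indels: total 10, skipped 2
  set.seed(2)
  refs <- sample(c("C", "T"), 10, replace = TRUE)
  alts <- ifelse(refs == "C", "A", "G")
  snvs <- do.call(rbind, lapply(1:10, function(i) {
    mkVar(paste0("p", i), pos = i, ref_allele = refs[i],
          alt_allele = alts[i], context = paste0("A", refs[i], "A"))
  }))
  indels <- rbind(mkVar("q1", pos = 30L, ref_allele = "A", alt_allele = "-",
                        classification = "frameshift_deletion"),
                  mkVar("q2", pos = 31L, ref_allele = "-", alt_allele = "T",
                        classification = "frameshift_insertion"))
  p3 <- buildProfile(rbind(snvs, indels))
  expect_equal(profileTotal(p3), 10)
  expect_equal(skippedRecords(p3), 2)
})

test_that("strand collapse is an involution", {
  set.seed(14)
  bases <- c("A", "C", "G", "T")
  v <- do.call(rbind, lapply(1:50, function(i) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
    mkVar(paste0("p", i), pos = i, ref_allele = ref, alt_allele = alt,
          context = ctx)
  }))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- v
  v_rc$ref_allele <- unname(comp[v$ref_allele])
  v_rc$alt_allele <- unname(comp[v$alt_allele])
  v_rc$context <- rc(v$context)
  expect_equal(channelCounts(buildProfile(v_rc)),
               channelCounts(buildProfile(v)))
})

test_that("contexts can be recovered from reference sequences", {
  refseq <- c(G1 = "ACGTACGTAC")
  v <- mkVar(gene_symbol = "G1", chrom = "G1", pos = 3L,
             ref_allele = "G", alt_allele = "T", context = NA)
  p <- buildProfile(v, reference = refseq)
  ## context CGT, middle G purine -> revcomp ACG, G>T becomes C>A
  expect_equal(unname(channelCounts(p)["A[C>A]G"]), 1)

  expect_error(buildProfile(v), "no reference")
  v_bad <- v; v_bad$ref_allele <- "C"; v_bad$alt_allele <- "A"
  expect_error(buildProfile(v_bad, reference = refseq), "disagrees")
})

test_that("group profiles conserve SNV counts across the partition", {
  catalog <- toyCatalog(2)
  cfg <- simulationConfig(seed = 33, nPatients = 80, catalog = catalog,
                          mixture = list(histone = c(sigA = 0.6, sigB = 0.4),
                                         non_histone = c(sigA = 0.4, sigB = 0.6)),
                          burdenMean = 15)
  sim <- simulateCohort(cfg)
  part <- partitionCohort(sim$variants, sim$registry)
  profs <- groupProfiles(sim$variants, part, reference = sim$reference)
  n_snv <- sum(sim$variants$ref_allele %in% c("A", "C", "G", "T") &
                 sim$variants$alt_allele %in% c("A", "C", "G", "T"))
  expect_equal(sum(vapply(profs, profileTotal, 0)), n_snv)
  expect_equal(sum(vapply(profs, skippedRecords, 0)),
               nrow(sim$variants) - n_snv)
})
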