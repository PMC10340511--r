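test_that("MAF parsing normalizes classifications and handles empty files", {
  maf <- file.path(tempdir(), "toy.maf")
  writeLines(c(
    paste(c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Classification"), collapse = "\t"),
    "p1\tG1\t1\t100\tC\tT\tMissense_Mutation",
    "p2\tG1\t1\t150\tG\tA\tSilent",
    "p3\tG2\t2\t30\tA\t-\tFrame_Shift_Del"), maf)
  v <- readVariants(maf, "maf")
  expect_equal(nrow(v), 3L)
  expect_equal(v$classification,
               c("missense", "silent", "frameshift_deletion"))
  expect_equal(v$pos, c(100L, 150L, 30L))

  ## unknown classification strings are retained as "other"
  writeLines(c(readLines(maf)[1], "p4\tG1\t1\t10\tC\tA\t3'UTR"), maf)
  expect_equal(readVariants(maf, "maf")$classification, "other")

  ## header-only file -> empty table
  writeLines(readLines(maf)[1], maf)
  expect_equal(nrow(readVariants(maf, "maf")), 0L)
})

test_that("MAF reader fails hard on missing columns, bad positions, bad context", {
  maf <- file.path(tempdir(), "bad.maf")
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol\tChromosome",
               "p1\tG1\t1"), maf)
  expect_error(readVariants(maf, "maf"), "Start_Position")

  hdr <- paste(c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                 "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                 "Variant_Classification", "Trinucleotide_Context"),
               collapse = "\t")
  writeLines(c(hdr, "p1\tG1\t1\toops\tC\tT\tSilent\tACA"), maf)
  expect_error(readVariants(maf, "maf"), "position")

  ## context middle base must equal ref for SNVs; offending rows are named
  writeLines(c(hdr,
               "p1\tG1\t1\t5\tC\tT\tSilent\tACA",
               "p2\tG1\t1\t9\tC\tT\tSilent\tAGA",
               "p3\tG1\t1\t12\tC\tT\tSilent\tTCT"), maf)
  expect_error(readVariants(maf, "maf"), "middle base.*2")
})

test_that("variant tables round-trip through both dialects", {
  v <- rbind(
    mkVar("p1", "HH.g1", "6", 11L, "C", "T", "missense", "lung", "ACA"),
    mkVar("p1", "HX", "6", 40L, "G", "A", "silent", "lung", "TGC"),
    mkVar("p2", "NG1", "1", 7L, "A", "-", "frameshift_deletion", "colon"),
    mkVar("p3", "NG2", "2", 99L, "T", "G", "other", "colon", "CTA"))
  for (dialect in c("maf", "simple_tsv")) {
    path <- file.path(tempdir(), paste0("rt.", dialect))
    writeVariants(v, path, dialect)
    v2 <- readVariants(path, dialect)
    expect_equal(v2, v, info = dialect)
  }
})

test_that("buildProteinGroups partitions the registry by accession", {
  reg <- rbind(mkRegistry(c("H4C1", "H4C2"), "P62805", 312L, "H4", "canonical", "6"),
               mkRegistry(c("A", "B"), c("PA", "PB")))
  groups <- buildProteinGroups(reg)
  expect_length(groups, 3L)
  expect_equal(attr(groups[["P62805"]], "n"), 2L)
  expect_equal(attr(groups[["PA"]], "n"), 1L)

  ## 11-gene protein (the H4 situation)
  reg11 <- mkRegistry(paste0("H4C", 1:11), "P62805", 312L, "H4",
                      "canonical", "6")
  expect_equal(attr(buildProteinGroups(reg11)[["P62805"]], "n"), 11L)

  expect_error(buildProteinGroups(rbind(reg, reg[1, ])), "duplicate")
})

test_that("protein grouping is a total disjoint partition (property)", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    reg <- mkRegistry(paste0("G", seq_len(n)),
                      paste0("P", sample(ceiling(n / 2), n, replace = TRUE)),
                      sample(100:900, n, replace = TRUE))
    groups <- buildProteinGroups(reg)
    members <- unlist(lapply(groups, `[[`, "gene_symbol"), use.names = FALSE)
    expect_setequal(members, reg$gene_symbol)
    expect_equal(length(members), n)           # disjoint: no gene twice
    expect_equal(sum(vapply(groups, attr, 0L, "n")), n)
  }
})

test_that("signature catalog IO enforces the SBS96 contract", {
  cat2 <- toyCatalog(2)
  expect_length(signatureNames(cat2), 2L)
  path <- file.path(tempdir(), "cat.tsv")
  writeSignatureCatalog(cat2, path)
  expect_equal(signatureMatrix(readSignatureCatalog(path)),
               signatureMatrix(cat2), tolerance = 1e-12)

  ## shuffled rows map back onto canonical order
  d <- read.delim(path, check.names = FALSE)
  set.seed(1)
  shuf <- file.path(tempdir(), "cat_shuf.tsv")
  write.table(d[sample(96), ], shuf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(signatureMatrix(readSignatureCatalog(shuf)),
               signatureMatrix(cat2), tolerance = 1e-12)

  m <- signatureMatrix(cat2)
  expect_error(SignatureCatalog(m * 0.9), "sum to 1")
  m_neg <- m; m_neg[1, 1] <- -m_neg[1, 1]
  expect_error(SignatureCatalog(m_neg), "negative")
  expect_error(SignatureCatalog(m[1:95, , drop = FALSE]), "96")
})

test_that("clinical table wins cancer-type conflicts with a warning", {
  v <- rbind(mkVar("p1", cancer_type = "lung"),
             mkVar("p2", cancer_type = NA))
  clin <- data.frame(patient_id = c("p1", "p2"),
                     cancer_type = c("colon", "colon"))
  expect_warning(out <- mergeCancerType(v, clin), "clinical table wins")
  expect_equal(out$cancer_type, c("colon", "colon"))
})
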