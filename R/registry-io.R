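.datatable.aware <- TRUE

## Shared data model: variant tables and the gene registry are plain
## data.frames with fixed columns, validated on the way in. Central
## matrix-like objects (catalog, profile) are S4 (see AllClasses.R).

.VARIANT_COLS <- c("patient_id", "gene_symbol", "chrom", "pos", "ref_allele",
                   "alt_allele", "classification", "cancer_type", "context")

.CLASSIFICATIONS <- c("missense", "silent", "nonsense", "nonstop",
                      "frameshift_insertion", "frameshift_deletion",
                      "splice_site", "splice_region",
                      "translation_start_site", "other")

## the nine consequence classes counted toward mutation burden
.COUNTED_CLASSES <- setdiff(.CLASSIFICATIONS, "other")

.FAMILIES <- c("H1", "H2A", "H2B", "H3", "H4", "non_histone")

.MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Silent = "silent",
  Nonsense_Mutation = "nonsense",
  Nonstop_Mutation = "nonstop",
  Frame_Shift_Ins = "frameshift_insertion",
  Frame_Shift_Del = "frameshift_deletion",
  Splice_Site = "splice_site",
  Splice_Region = "splice_region",
  Translation_Start_Site = "translation_start_site")

.MAF_COLS <- c(Tumor_Sample_Barcode = "patient_id",
               Hugo_Symbol = "gene_symbol",
               Chromosome = "chrom",
               Start_Position = "pos",
               Reference_Allele = "ref_allele",
               Tumor_Seq_Allele2 = "alt_allele",
               Variant_Classification = "classification")

#' Names of the nine counted mutation classes
#'
#' Missense, silent, nonsense, nonstop, frameshift insertion/deletion, splice
#' site, splice region, and translation start site: the consequence classes
#' that contribute to gene- and protein-level mutation counts. Anything else
#' (UTR, intron, ...) is carried as \code{"other"} and excluded from burden.
#'
#' @return Character vector of length 9.
#' @export
countedClasses <- function() .COUNTED_CLASSES

.validateVariants <- function(v, source = "variant table") {
  stopifnot(is.data.frame(v))
  missing <- setdiff(setdiff(.VARIANT_COLS, c("cancer_type", "context")),
                     names(v))
  if (length(missing))
    stop(source, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"cancer_type" %in% names(v))
    v$cancer_type <- rep(NA_character_, nrow(v))
  if (!"context" %in% names(v)) v$context <- rep(NA_character_, nrow(v))
  bad_pos <- which(is.na(v$pos) | v$pos < 1)
  if (length(bad_pos))
    stop(source, ": unparseable or non-positive position at data row(s) ",
         paste(utils::head(bad_pos, 10), collapse = ", "))
  same <- which(v$ref_allele == v$alt_allele)
  if (length(same))
    stop(source, ": ref_allele equals alt_allele at data row(s) ",
         paste(utils::head(same, 10), collapse = ", "))
  v$classification[!v$classification %in% .CLASSIFICATIONS] <- "other"
  has_ctx <- !is.na(v$context) & nzchar(v$context)
  if (any(has_ctx)) {
    bad_len <- which(has_ctx & nchar(v$context) != 3L)
    if (length(bad_len))
      stop(source, ": context is not a 3-mer at data row(s) ",
           paste(utils::head(bad_len, 10), collapse = ", "))
    snv <- v$ref_allele %in% .BASES & v$alt_allele %in% .BASES
    mism <- which(has_ctx & snv & substr(v$context, 2L, 2L) != v$ref_allele)
    if (length(mism))
      stop(source, ": context middle base does not match ref_allele at data row(s) ",
           paste(utils::head(mism, 20), collapse = ", "))
  }
  v$pos <- as.integer(v$pos)
  v[.VARIANT_COLS]
}

#' Read a somatic variant table
#'
#' Ingests MAF-style tab-separated variant calls. The \code{"maf"} dialect
#' expects the GDC column names (Tumor_Sample_Barcode, Hugo_Symbol,
#' Chromosome, Start_Position, Reference_Allele, Tumor_Seq_Allele2,
#' Variant_Classification, optionally Trinucleotide_Context and Cancer_Type);
#' the \code{"simple_tsv"} dialect uses the package's internal column names
#' directly. MAF classification strings are normalized onto the internal
#' enum; unknown strings become \code{"other"} and are excluded from burden
#' counting but retained in the table.
#'
#' @param path Path to a tab-separated file.
#' @param dialect \code{"maf"} or \code{"simple_tsv"}.
#' @return A data.frame with columns patient_id, gene_symbol, chrom, pos,
#'   ref_allele, alt_allele, classification, cancer_type, context; one row
#'   per input data row. Coordinates are 1-based; context is reported on the
#'   reference strand (pyrimidine collapsing happens in profile construction,
#'   not at I/O).
#' @seealso [writeVariants()], [readClinical()]
#' @export
readVariants <- function(path, dialect = c("maf", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  chrom_col <- if (dialect == "maf") "Chromosome" else "chrom"
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = setNames("character", chrom_col),
                         data.table = FALSE, na.strings = c("NA", ""))
  if (dialect == "maf") {
    missing <- setdiff(names(.MAF_COLS), names(d))
    if (length(missing))
      stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
    v <- d[names(.MAF_COLS)]
    names(v) <- unname(.MAF_COLS)
    cls <- .MAF_CLASS_MAP[as.character(v$classification)]
    v$classification <- ifelse(is.na(cls), "other", unname(cls))
    v$cancer_type <- if ("Cancer_Type" %in% names(d))
      as.character(d$Cancer_Type) else rep(NA_character_, nrow(v))
    v$context <- if ("Trinucleotide_Context" %in% names(d))
      as.character(d$Trinucleotide_Context) else rep(NA_character_, nrow(v))
  } else {
    missing <- setdiff(setdiff(.VARIANT_COLS, c("cancer_type", "context")),
                       names(d))
    if (length(missing))
      stop("variant table is missing required column(s): ",
           paste(missing, collapse = ", "))
    v <- d[intersect(.VARIANT_COLS, names(d))]
  }
  pos_num <- suppressWarnings(as.numeric(v$pos))
  bad <- which(is.na(pos_num) & !is.na(v$pos))
  if (length(bad))
    stop("unparseable position at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  v$pos <- pos_num
  for (col in c("patient_id", "gene_symbol", "chrom", "ref_allele",
                "alt_allele", "classification"))
    v[[col]] <- as.character(v[[col]])
  .validateVariants(v, source = basename(path))
}

#' Write a variant table
#'
#' Inverse of [readVariants()]: the \code{"maf"} dialect writes GDC column
#' names and MAF classification strings (with \code{Trinucleotide_Context}
#' and \code{Cancer_Type} columns), \code{"simple_tsv"} writes internal
#' column names. Writing then re-reading reproduces identical in-memory
#' values.
#'
#' @param variants A validated variant data.frame.
#' @param path Output path.
#' @param dialect \code{"maf"} or \code{"simple_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeVariants <- function(variants, path, dialect = c("maf", "simple_tsv")) {
  dialect <- match.arg(dialect)
  v <- .validateVariants(variants)
  if (dialect == "maf") {
    inv <- c(setNames(names(.MAF_CLASS_MAP), .MAF_CLASS_MAP), other = "3'UTR")
    out <- data.frame(
      Tumor_Sample_Barcode = v$patient_id,
      Hugo_Symbol = v$gene_symbol,
      Chromosome = v$chrom,
      Start_Position = v$pos,
      Reference_Allele = v$ref_allele,
      Tumor_Seq_Allele2 = v$alt_allele,
      Variant_Classification = unname(inv[v$classification]),
      Cancer_Type = v$cancer_type,
      Trinucleotide_Context = v$context,
      check.names = FALSE)
  } else {
    out <- v
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read the gene registry
#'
#' The registry is the redundancy map: one row per gene with the encoded
#' protein accession, coding-sequence length in base pairs, histone family
#' (H1, H2A, H2B, H3, H4 or non_histone) and canonical/variant status.
#'
#' @param path TSV with columns gene_symbol, protein_accession, cds_length,
#'   family, histone_class, chrom.
#' @return Validated registry data.frame.
#' @export
readGeneRegistry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .validateRegistry(d, source = basename(path))
}

.validateRegistry <- function(d, source = "registry") {
  req <- c("gene_symbol", "protein_accession", "cds_length", "family",
           "histone_class", "chrom")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop(source, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(d$gene_symbol))
    stop(source, ": duplicate gene symbol(s): ",
         paste(unique(d$gene_symbol[duplicated(d$gene_symbol)]), collapse = ", "))
  if (any(is.na(d$cds_length) | d$cds_length <= 0))
    stop(source, ": cds_length must be a positive integer for every gene")
  bad_fam <- setdiff(unique(d$family), .FAMILIES)
  if (length(bad_fam))
    stop(source, ": unknown family value(s): ", paste(bad_fam, collapse = ", "))
  d$cds_length <- as.integer(d$cds_length)
  d$is_histone <- d$family != "non_histone"
  d[c(req, "is_histone")]
}

#' Group registry genes by encoded protein
#'
#' Genes are grouped together if they encode a common protein (same
#' protein accession). The grouping is a partition: every gene appears in
#' exactly one group and group sizes sum to the registry size.
#'
#' @param registry A validated registry data.frame.
#' @return Named list (by protein accession) of registry sub-data.frames;
#'   each element carries attribute \code{n} = number of member genes.
#' @export
#' @examples
#' reg <- data.frame(gene_symbol = c("H4C1", "H4C2", "TP53"),
#'                   protein_accession = c("P62805", "P62805", "P04637"),
#'                   cds_length = c(312L, 312L, 1182L),
#'                   family = c("H4", "H4", "non_histone"),
#'                   histone_class = c("canonical", "canonical", "not_applicable"),
#'                   chrom = c("6", "6", "17"))
#' groups <- buildProteinGroups(reg)
#' attr(groups[["P62805"]], "n")
buildProteinGroups <- function(registry) {
  registry <- .validateRegistry(registry)
  if (!nrow(registry)) stop("registry is empty")
  groups <- split(registry, registry$protein_accession)
  lapply(groups, function(g) { attr(g, "n") <- nrow(g); g })
}

#' Construct a SignatureCatalog
#'
#' @param matrix Numeric matrix with 96 rows (any row order; rownames must be
#'   SBS96 channel labels) and one column per signature. Columns whose sums
#'   are within 1e-3 of 1 are renormalized; larger deviations are an error.
#' @param etiologyGroups Optional named list mapping etiology group names to
#'   member signature names.
#' @return A [SignatureCatalog-class] object with rows in canonical order.
#' @export
SignatureCatalog <- function(matrix, etiologyGroups = list()) {
  if (nrow(matrix) != 96L)
    stop("signature catalog must have exactly 96 context rows, got ",
         nrow(matrix))
  if (is.null(rownames(matrix)))
    stop("catalog rows must be named by SBS96 channel labels")
  unknown <- setdiff(rownames(matrix), .SBS96)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  matrix <- matrix[.SBS96, , drop = FALSE]
  if (any(matrix < 0)) stop("signature catalog contains negative entries")
  cs <- colSums(matrix)
  off <- abs(cs - 1) > 1e-3
  if (any(off))
    stop("catalog column(s) do not sum to 1 (beyond 1e-3): ",
         paste(colnames(matrix)[off], collapse = ", "))
  matrix <- sweep(matrix, 2, cs, "/")
  new("SignatureCatalog", matrix = matrix, etiologyGroups = etiologyGroups)
}

#' Read a COSMIC-layout SBS96 signature catalog
#'
#' Expects a tab-separated file with a \code{Type} column holding channel
#' labels like \code{"A[C>A]A"} and one numeric column per signature. Rows
#' may be in any order; they are mapped onto the canonical SBS96 ordering.
#'
#' @param path Path to the catalog TSV.
#' @param etiologyGroups Optional etiology grouping (see
#'   [cosmicEtiologyGroups()]).
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path, etiologyGroups = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"Type" %in% names(d))
    stop("catalog must have a 'Type' column of SBS96 channel labels")
  m <- as.matrix(d[setdiff(names(d), "Type")])
  if (!is.numeric(m)) stop("catalog signature columns must be numeric")
  rownames(m) <- d$Type
  SignatureCatalog(m, etiologyGroups = etiologyGroups)
}

#' Write a SignatureCatalog in COSMIC layout
#' @param catalog A [SignatureCatalog-class].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "SignatureCatalog"))
  out <- data.frame(Type = rownames(signatureMatrix(catalog)),
                    signatureMatrix(catalog), check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' COSMIC etiology groupings used for exposure merging
#'
#' UV-light (SBS7a-d), mismatch-repair deficiency (SBS6, 15, 21, 26, 44),
#' POLE deficiency (SBS10a-b), POLD1 deficiency (SBS10c-d), tobacco smoking
#' (SBS4, 92) and APOBEC (SBS2, 13).
#'
#' @return Named list of signature-name character vectors.
#' @export
cosmicEtiologyGroups <- function() {
  list(UV = c("SBS7a", "SBS7b", "SBS7c", "SBS7d"),
       MMR = c("SBS6", "SBS15", "SBS21", "SBS26", "SBS44"),
       POLE = c("SBS10a", "SBS10b"),
       POLD1 = c("SBS10c", "SBS10d"),
       Tobacco = c("SBS4", "SBS92"),
       APOBEC = c("SBS2", "SBS13"))
}

#' Read a two-column clinical table (patient_id, cancer_type)
#' @param path TSV path.
#' @return data.frame with columns patient_id, cancer_type.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(c("patient_id", "cancer_type"), names(d))
  if (length(missing))
    stop("clinical table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(d$patient_id))
    stop("clinical table has duplicate patient_id entries")
  d[c("patient_id", "cancer_type")]
}

#' Attach cancer types from a clinical table to a variant table
#'
#' The clinical table wins over a cancer_type column already present in the
#' variants; conflicts are reported with a warning.
#'
#' @param variants Variant data.frame.
#' @param clinical Clinical data.frame from [readClinical()].
#' @return The variant table with cancer_type filled in.
#' @export
mergeCancerType <- function(variants, clinical) {
  v <- .validateVariants(variants)
  ct <- setNames(as.character(clinical$cancer_type), clinical$patient_id)
  new_ct <- unname(ct[v$patient_id])
  conflict <- !is.na(v$cancer_type) & !is.na(new_ct) & v$cancer_type != new_ct
  if (any(conflict))
    warning(sum(conflict), " variant row(s) had a cancer_type conflicting ",
            "with the clinical table; the clinical table wins")
  v$cancer_type <- ifelse(is.na(new_ct), v$cancer_type, new_ct)
  v
}

#' Read a gene-level covariate table
#'
#' Columns: gene_symbol, expression (arbitrary units), replication_time
#' (100 = very early ... 1500 = very late) and chromatin_state (-50 closed
#' ... +50 open).
#'
#' @param path TSV path.
#' @return data.frame of covariates.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("gene_symbol", "expression", "replication_time", "chromatin_state")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("covariate table is missing column(s): ", paste(missing, collapse = ", "))
  d[req]
}

#' Read a driver-gene list (one symbol per line)
#' @param path Text file path.
#' @return Character vector of gene symbols.
#' @export
readDriverList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
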