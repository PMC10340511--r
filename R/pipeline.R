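.PIPELINE_STAGES <- c("rates", "comparisons", "family", "homogeneity",
                      "signatures", "association", "covariates")

#' Build a validated pipeline configuration
#'
#' Inputs may be file paths (read with the package's readers) or in-memory
#' objects (variant/clinical/registry data.frames, a
#' [SignatureCatalog-class], ...). A single top-level seed is fanned out
#' deterministically to per-stage seeds (stage-name hashing) so stages can
#' be rerun independently and reproducibly.
#'
#' @param maf Variant table: path (MAF dialect) or data.frame.
#' @param registry Registry: path or data.frame.
#' @param catalog Signature catalog: path or [SignatureCatalog-class]
#'   (required for the signatures stage).
#' @param clinical Optional clinical table: path or data.frame.
#' @param covariates Optional covariate table: path or data.frame.
#' @param drivers Optional driver-gene list: path or character vector
#'   (comparison set for the comparisons stage, histones removed
#'   automatically).
#' @param reference Optional reference sequences: FASTA path, named
#'   character vector or \code{DNAStringSet} (for profile contexts when the
#'   variant table lacks a context column).
#' @param outDir Output directory for per-stage TSV/JSON and the manifest.
#' @param queryGenes Query genes for the association stage (default
#'   \code{"POLE"}).
#' @param minPatients Minimum patients per cancer type (default 10).
#' @param minMutationsPerFamily Per-family mutation filter (default 10).
#' @param fdr Target FDR (default 0.05; recorded, BH q-values are reported
#'   throughout).
#' @param nSim Monte-Carlo steps for sparse homogeneity tables
#'   (default 10000).
#' @param nBoot Bootstrap resamples for signature CIs (default 100).
#' @param seed Top-level seed.
#' @param stages Stages to run (subset of \code{"rates"},
#'   \code{"comparisons"}, \code{"family"}, \code{"homogeneity"},
#'   \code{"signatures"}, \code{"association"}, \code{"covariates"}).
#' @return A validated config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(maf, registry, catalog = NULL, clinical = NULL,
                           covariates = NULL, drivers = NULL,
                           reference = NULL, outDir = tempfile("hb_run_"),
                           queryGenes = "POLE", minPatients = 10,
                           minMutationsPerFamily = 10, fdr = 0.05,
                           nSim = 10000, nBoot = 100, seed = 1,
                           stages = .PIPELINE_STAGES) {
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  stopifnot(minPatients > 0, minMutationsPerFamily > 0, fdr > 0, fdr < 1,
            nSim > 0, nBoot > 0)
  if ("signatures" %in% stages && is.null(catalog))
    stop("the signatures stage requires a catalog")
  if ("covariates" %in% stages && is.null(covariates))
    stop("the covariates stage requires a covariate table")
  structure(list(maf = maf, registry = registry, catalog = catalog,
                 clinical = clinical, covariates = covariates,
                 drivers = drivers, reference = reference, outDir = outDir,
                 queryGenes = queryGenes, minPatients = minPatients,
                 minMutationsPerFamily = minMutationsPerFamily, fdr = fdr,
                 nSim = nSim, nBoot = nBoot, seed = seed, stages = stages),
            class = "pipelineConfig")
}

## deterministic per-stage seed below 2^31
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + h %% 100003L
}

.writeTSV <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on one cohort: protein-level rates, histone vs
#' non-histone (and vs driver) comparisons, family-level Kruskal-Wallis,
#' per-protein homogeneity scan, cohort partition + SBS96 profiles +
#' bootstrap signature decomposition with etiology merging, histone/query
#' co-occurrence, and covariate correlations. Per-stage TSV/JSON outputs
#' plus a run manifest (package version, seed, input checksums) are written
#' to the configured directory; skipped analyses carry machine-readable
#' reasons.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a named list of in-memory stage results plus
#'   \code{outDir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  loadInput <- function(x, reader, label) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      checksums[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }
  variants <- loadInput(config$maf, readVariants, "maf")
  registry <- loadInput(config$registry, readGeneRegistry, "registry")
  registry <- .validateRegistry(registry)
  clinical <- loadInput(config$clinical, readClinical, "clinical")
  catalog <- loadInput(config$catalog, readSignatureCatalog, "catalog")
  covariates <- loadInput(config$covariates, readCovariates, "covariates")
  drivers <- loadInput(config$drivers, readDriverList, "drivers")
  reference <- config$reference
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    checksums[["reference"]] <- unname(tools::md5sum(reference))
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!is.null(clinical)) variants <- mergeCancerType(variants, clinical)

  results <- list()
  manifest <- list(package = "histoneBurden",
                   version = as.character(utils::packageVersion("histoneBurden")),
                   seed = config$seed, stages = list(), inputs = checksums)
  histone_acc <- unique(registry$protein_accession[registry$is_histone])

  runStage <- function(stage, fn) {
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[stage]] <<- list(status = "ok",
                                      seed = .stageSeed(config$seed, stage))
    results[[stage]] <<- out
  }

  rates <- NULL
  needRates <- any(c("rates", "comparisons", "family") %in% config$stages)
  if (needRates)
    rates <- proteinRates(variants, registry, clinical = clinical,
                          minPatients = config$minPatients)

  if ("rates" %in% config$stages) runStage("rates", function() {
    .writeTSV(rates, config$outDir, "protein_rates")
    rates
  })

  if ("comparisons" %in% config$stages) runStage("comparisons", function() {
    out <- list(histone_vs_others =
                  compareRatesByCancerType(rates, histone_acc))
    .writeTSV(out$histone_vs_others, config$outDir,
              "comparison_histone_vs_others")
    if (!is.null(drivers)) {
      driver_genes <- setdiff(drivers,
                              registry$gene_symbol[registry$is_histone])
      driver_acc <- unique(registry$protein_accession[
        registry$gene_symbol %in% driver_genes])
      out$histone_vs_drivers <-
        compareRatesByCancerType(rates, histone_acc,
                                 accessionsB = setdiff(driver_acc,
                                                       histone_acc))
      .writeTSV(out$histone_vs_drivers, config$outDir,
                "comparison_histone_vs_drivers")
    }
    out
  })

  if ("family" %in% config$stages) runStage("family", function() {
    fams <- setdiff(.FAMILIES, "non_histone")
    rows <- lapply(unique(rates$cancer_type), function(ct) {
      sl <- rates[rates$cancer_type == ct, , drop = FALSE]
      byfam <- lapply(fams, function(f) {
        acc <- unique(registry$protein_accession[registry$family == f])
        sl$r[sl$protein_accession %in% acc]
      })
      names(byfam) <- fams
      byfam <- byfam[lengths(byfam) > 0]
      counts <- suppressWarnings(countMutations(
        variants, registry,
        by = if (ct == "pan-cancer") "pan" else "cancer_type"))
      if (ct != "pan-cancer")
        counts <- counts[counts$cancer_type == ct, , drop = FALSE]
      fam_of <- setNames(registry$family, registry$gene_symbol)
      totals <- tapply(counts$m, factor(fam_of[counts$gene_symbol],
                                        levels = fams), sum, default = 0)
      fc <- familyComparison(byfam, totals,
                             minMutations = config$minMutationsPerFamily)
      data.frame(cancer_type = ct, skipped = fc$skipped,
                 reason = if (fc$skipped) fc$reason else NA_character_,
                 H = if (fc$skipped) NA_real_ else fc$H,
                 p = if (fc$skipped) NA_real_ else fc$p)
    })
    tab <- do.call(rbind, rows)
    tested <- !tab$skipped
    tab$q <- NA_real_
    if (any(tested)) tab$q[tested] <- bhAdjust(tab$p[tested])
    .writeTSV(tab, config$outDir, "family_comparison")
    tab
  })

  if ("homogeneity" %in% config$stages) runStage("homogeneity", function() {
    scan <- homogeneityScan(variants, registry, clinical = clinical,
                            byCancerType = TRUE,
                            minPatients = config$minPatients,
                            nSim = config$nSim,
                            seed = .stageSeed(config$seed, "homogeneity"))
    .writeTSV(scan, config$outDir, "homogeneity")
    scan
  })

  if ("signatures" %in% config$stages) runStage("signatures", function() {
    part <- partitionCohort(variants, registry)
    profs <- groupProfiles(variants, part, reference = reference)
    groups <- etiologyGroups(catalog)
    decomp <- lapply(profs, function(pr) {
      if (profileTotal(pr) == 0) return(NULL)
      bootstrapDecompose(pr, catalog, nBoot = config$nBoot,
                         seed = .stageSeed(config$seed,
                                           paste0("boot_", pr@label)))
    })
    report <- list()
    for (g in names(decomp)) {
      if (is.null(decomp[[g]])) {
        report[[g]] <- list(skipped = TRUE, reason = "empty profile")
        next
      }
      ci <- exposureCI(decomp[[g]])
      .writeTSV(ci, config$outDir, paste0("signatures_", g))
      report[[g]] <- list(
        skipped = FALSE, total = profileTotal(profs[[g]]),
        exposures = as.list(exposures(decomp[[g]])),
        active = activeSignatures(decomp[[g]]),
        merged = if (length(groups))
          as.list(mergeEtiologies(decomp[[g]], groups)) else NULL)
    }
    jsonlite::write_json(report,
                         file.path(config$outDir, "signatures.json"),
                         auto_unbox = TRUE, digits = NA)
    list(partition = part, profiles = profs, decompositions = decomp,
         report = report)
  })

  if ("association" %in% config$stages) runStage("association", function() {
    res <- cooccurrenceTest(variants, registry, config$queryGenes,
                            patients = if (!is.null(clinical))
                              clinical$patient_id else NULL)
    jsonlite::write_json(
      list(table = res$table, odds_ratio = res$odds_ratio,
           p_one_sided = res$p_one_sided, direction = res$direction,
           degenerate = res$degenerate),
      file.path(config$outDir, "association.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    res
  })

  if ("covariates" %in% config$stages) runStage("covariates", function() {
    gr <- geneRates(variants, registry)
    gr <- gr[gr$gene_symbol %in%
               registry$gene_symbol[registry$is_histone], , drop = FALSE]
    cc <- covariateCorrelation(gr, covariates)
    .writeTSV(cc, config$outDir, "covariate_correlation")
    cc
  })

  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$outDir <- config$outDir
  invisible(results)
}
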