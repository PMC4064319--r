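#' Assemble a pipeline run configuration
#'
#' @param vcf,gff,panel required input paths (multi-sample VCF, miRBase-style
#'   GFF3, population panel TSV).
#' @param ids,disease,targets,pathways optional annotation tables (known-id,
#'   miRNA-disease, miRNA-target, gene-pathway-category TSVs).
#' @param out_dir output directory for report tables.
#' @param alpha significance level of the Hardy-Weinberg scan.
#' @param correction Yates continuity correction flag.
#' @param pca_k,min_coverage PCA parameters.
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   pins any downstream resampling).
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(vcf, gff, panel, ids = NULL, disease = NULL,
                      targets = NULL, pathways = NULL, out_dir,
                      alpha = 0.05, correction = TRUE, pca_k = 10,
                      min_coverage = 10, seed = 1L) {
  cfg <- list(vcf = vcf, gff = gff, panel = panel, ids = ids,
              disease = disease, targets = targets, pathways = pathways,
              out_dir = out_dir, alpha = alpha, correction = correction,
              pca_k = pca_k, min_coverage = min_coverage,
              seed = as.integer(seed))
  for (p in c("vcf", "gff", "panel"))
    if (!file.exists(cfg[[p]])) stop("input file missing: ", cfg[[p]])
  for (p in c("ids", "disease", "targets", "pathways"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file missing: ", cfg[[p]])
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  class(cfg) <- "RunConfig"
  cfg
}

.writeTsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeMatrixTsv <- function(m, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Table-1-style per-population summary
.populationSummary <- function(cohort, profiles, disease_table = NULL) {
  gt <- SummarizedExperiment::assay(cohort, "gt")
  rr <- SummarizedExperiment::rowRanges(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  key <- paste(as.character(seqnames(rr)), start(rr), rr$alt)
  pkey <- paste(profiles$chrom, profiles$pos, profiles$alt)
  mature <- pkey[grepl("miR", profiles$region, fixed = TRUE)]
  rows <- lapply(sort(unique(cd$population)), function(pop) {
    sub <- gt[, cd$population == pop, drop = FALSE]
    carrier <- rowSums(sub >= 1L, na.rm = TRUE) >= 1L
    het <- rowSums(sub == 1L, na.rm = TRUE) >= 1L
    hom <- rowSums(sub == 2L, na.rm = TRUE) >= 1L
    kk <- key[carrier]
    mir <- unique(profiles$premirna_id[pkey %in% kk])
    nd <- 0L; ndis <- 0L
    if (!is.null(disease_table) && nrow(disease_table)) {
      mm <- unique(c(mir, profiles$mature_id[pkey %in% kk]))
      hitrows <- disease_table$mirna %in% mm
      nd <- length(unique(disease_table$mirna[hitrows]))
      ndis <- length(unique(disease_table$disease[hitrows]))
    }
    data.frame(population = pop, group = cd$group[cd$population == pop][1],
               subjects = sum(cd$population == pop),
               snvs = sum(carrier),
               snvs_known = sum(carrier & !rr$is_novel, na.rm = TRUE),
               snvs_in_precursor = sum(kk %in% pkey),
               snvs_in_mature = sum(kk %in% mature),
               n_het_variants = sum(het), n_hom_variants = sum(hom),
               mirnas_with_disease = nd, diseases = ndis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full variability-map pipeline
#'
#' Orchestrates every stage: annotation parsing, VCF ingestion, variant
#' profiling, region occurrence, Hardy-Weinberg scan, burden and spectrum
#' summaries, shared-variant / disease / pathway matrices, hive edge lists
#' and the stratification PCA, writing each result as a TSV under
#' `out_dir`.  Re-running on identical inputs and seed reproduces the
#' tables byte for byte.  An empty VCF produces empty tables with a
#' warning rather than an error.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return (invisibly) a list with every computed object plus `files`, the
#'   named vector of written paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- readPanel(config$panel)
  mirnas <- readMirnaGff(config$gff)
  segments <- decomposeMirna(mirnas)
  cohort <- readCohortVcf(config$vcf, mirnas, panel)
  if (!is.null(config$ids))
    cohort <- annotateKnown(cohort, readIdTable(config$ids))
  profiles <- profileVariants(cohort, mirnas, segments)
  if (!nrow(profiles))
    warning("no profiled variants; report tables will be empty")
  files <- c()
  files["filter_log"] <- .writeTsv(metadata(cohort)$filter_log,
                                   config$out_dir, "filter_log.tsv")
  files["profiles"] <- .writeTsv(profiles, config$out_dir,
                                 "variant_profiles.tsv")
  files["region_occurrence"] <- .writeTsv(regionOccurrence(profiles),
                                          config$out_dir,
                                          "region_occurrence.tsv")
  seed_tab <- profiles[grepl("seed", profiles$region), , drop = FALSE]
  files["seed_variants"] <- .writeTsv(seed_tab, config$out_dir,
                                      "seed_variants.tsv")
  hwe <- hweScan(cohort, alpha = config$alpha,
                 correction = config$correction)
  files["hwe_all"] <- .writeTsv(hwe, config$out_dir, "hwe_scan.tsv")
  files["hwe_significant"] <- .writeTsv(
    hwe[hwe$significant, , drop = FALSE], config$out_dir,
    "hwe_significant.tsv")
  burden <- burdenPerIndividual(cohort)
  files["burden_samples"] <- .writeTsv(burden$samples, config$out_dir,
                                       "burden_samples.tsv")
  files["burden_groups"] <- .writeTsv(burden$groups, config$out_dir,
                                      "burden_groups.tsv")
  gt <- SummarizedExperiment::assay(cohort, "gt")
  spectrum <- NULL
  if (nrow(gt)) {
    freqs <- rowSums(gt, na.rm = TRUE) / (2 * rowSums(!is.na(gt)))
    spectrum <- afSpectrum(freqs[freqs > 0])
    files["spectrum"] <- .writeTsv(spectrum, config$out_dir,
                                   "af_spectrum.tsv")
  }
  shared_all <- sharedVariantMatrix(cohort, profiles, "all")
  shared_seed <- sharedVariantMatrix(cohort, profiles, "seed")
  files["shared_all"] <- .writeMatrixTsv(shared_all, config$out_dir,
                                         "shared_variants_all.tsv")
  files["shared_seed"] <- .writeMatrixTsv(shared_seed, config$out_dir,
                                          "shared_variants_seed.tsv")
  disease_table <- NULL; disease_matrix <- NULL; hive <- NULL
  if (!is.null(config$disease)) {
    disease_table <- readDiseaseTable(config$disease)
    disease_matrix <- populationDiseaseMatrix(cohort, profiles,
                                              disease_table)
    files["disease_matrix"] <- .writeMatrixTsv(disease_matrix,
                                               config$out_dir,
                                               "disease_matrix.tsv")
    hive <- hiveEdges(cohort, profiles, disease_table)
    files["hive_population"] <- .writeTsv(hive$mirna_population,
                                          config$out_dir,
                                          "hive_mirna_population.tsv")
    files["hive_category"] <- .writeTsv(hive$mirna_category,
                                        config$out_dir,
                                        "hive_mirna_category.tsv")
  }
  pathway_profile <- NULL
  if (!is.null(config$targets) && !is.null(config$pathways)) {
    pathway_profile <- pathwayCategoryProfile(
      cohort, profiles, readTargetTable(config$targets),
      readPathwayTable(config$pathways))
    files["pathway_profile"] <- .writeMatrixTsv(pathway_profile,
                                                config$out_dir,
                                                "pathway_profile.tsv")
  }
  pca <- tryCatch({
    res <- cohortPca(cohort, k = config$pca_k,
                     min_coverage = config$min_coverage)
    co <- pcaCoords(res)
    cd <- SummarizedExperiment::colData(cohort)
    files["pca_coordinates"] <- .writeTsv(
      data.frame(sample = rownames(co),
                 population = cd[rownames(co), "population"],
                 group = cd[rownames(co), "group"], co),
      config$out_dir, "pca_coordinates.tsv")
    files["pca_eigenvalues"] <- .writeTsv(
      data.frame(component = seq_along(pcaEigenvalues(res)),
                 eigenvalue = pcaEigenvalues(res)),
      config$out_dir, "pca_eigenvalues.tsv")
    res
  }, error = function(e) {
    warning("PCA skipped: ", conditionMessage(e))
    NULL
  })
  files["population_summary"] <- .writeTsv(
    .populationSummary(cohort, profiles, disease_table),
    config$out_dir, "population_summary.tsv")
  invisible(list(cohort = cohort, mirnas = mirnas, segments = segments,
                 profiles = profiles, hwe = hwe, burden = burden,
                 spectrum = spectrum, shared_all = shared_all,
                 shared_seed = shared_seed, disease_matrix = disease_matrix,
                 hive = hive, pathway_profile = pathway_profile,
                 pca = pca, files = files))
}
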