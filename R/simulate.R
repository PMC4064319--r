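#' Default multi-population panel mirroring the study cohort
#'
#' Fifteen populations over four geographic groups totalling 1,152
#' individuals, with Balding-Nichols divergence values per group and a
#' site-density multiplier giving African populations their documented
#' excess of variable sites.
#'
#' @return data.frame with `name`, `size`, `F`, `group`, `density`.
#' @export
defaultPopulations <- function() {
  data.frame(
    name = c("TSI", "FIN", "GBR", "CEU", "IBS", "AND",
             "CHB", "CHS", "JPT", "MXL", "PUR", "CLM",
             "YRI", "LWK", "ASW"),
    size = c(98, 93, 89, 85, 14, 60, 97, 100, 89, 66, 55, 60, 88, 97, 61),
    F = c(rep(0.02, 6), rep(0.08, 3), rep(0.05, 3), rep(0.12, 3)),
    group = c(rep("EUR", 6), rep("ASI", 3), rep("AMR", 3), rep("AFR", 3)),
    density = c(rep(1, 12), rep(1.4, 3)),
    stringsAsFactors = FALSE)
}

#' Build and validate a simulation configuration
#'
#' Defaults describe the emulated study cohort: the 15-population /
#' 1,152-sample panel of [defaultPopulations()], 720 precursor hairpins,
#' per-region variant placement densities increasing from seed to flanking
#' arms, a rare-variant-skewed ancestral frequency distribution, ten sites
#' with a planted inbreeding distortion (f = 0.5), and 35% of sites absent
#' from the known-id table.  Tests and examples pass smaller panels and
#' precursor counts through the same interface.
#'
#' @param populations panel data.frame (`name`, `size`, `F`, `group`,
#'   optional `density`).
#' @param n_precursors number of precursor hairpins.
#' @param site_rate per-base variant placement rate before region weighting.
#' @param region_weights relative placement density for `seed`, `rom`,
#'   `loop` and `mir` (flanking) bases.
#' @param ancestral_shape Beta shape parameters of the ancestral allele
#'   frequency distribution.
#' @param n_planted,planted_f number of sites carrying a planted
#'   Hardy-Weinberg distortion and its inbreeding coefficient.
#' @param novel_fraction fraction of sites left out of the known-id table.
#' @param n_diseases,n_disease_categories,disease_link_prob disease-table
#'   size and per-miRNA linking probability.
#' @param n_genes,n_pathways,n_pathway_categories pathway-table sizes.
#' @param seed integer random seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(populations = defaultPopulations(),
                             n_precursors = 720,
                             site_rate = 0.011,
                             region_weights = c(seed = 0.35, rom = 0.55,
                                                loop = 0.75, mir = 1),
                             ancestral_shape = c(0.3, 3),
                             n_planted = 10, planted_f = 0.5,
                             novel_fraction = 0.35,
                             n_diseases = 57, n_disease_categories = 10,
                             disease_link_prob = 0.6,
                             n_genes = 400, n_pathways = 150,
                             n_pathway_categories = 51,
                             seed = 1L) {
  if (is.null(populations$density)) populations$density <- 1
  cfg <- list(populations = populations, n_precursors = n_precursors,
              site_rate = site_rate, region_weights = region_weights,
              ancestral_shape = ancestral_shape, n_planted = n_planted,
              planted_f = planted_f, novel_fraction = novel_fraction,
              n_diseases = n_diseases,
              n_disease_categories = n_disease_categories,
              disease_link_prob = disease_link_prob, n_genes = n_genes,
              n_pathways = n_pathways,
              n_pathway_categories = n_pathway_categories,
              seed = as.integer(seed))
  p <- cfg$populations
  if (!all(c("name", "size", "F", "group") %in% names(p)))
    stop("populations need name, size, F, group columns")
  if (any(p$size < 1)) stop("population sizes must be >= 1")
  if (any(p$F < 0 | p$F >= 1)) stop("F must lie in [0, 1)")
  if (any(p$density < 0)) stop("densities must be >= 0")
  if (cfg$planted_f < 0 || cfg$planted_f >= 1)
    stop("planted_f must lie in [0, 1)")
  if (cfg$n_precursors < 1) stop("n_precursors must be >= 1")
  if (cfg$site_rate <= 0 || cfg$site_rate >= 0.5)
    stop("site_rate must lie in (0, 0.5)")
  if (any(cfg$region_weights < 0)) stop("region weights must be >= 0")
  if (cfg$novel_fraction < 0 || cfg$novel_fraction > 1)
    stop("novel_fraction must lie in [0, 1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

# random synthetic precursor annotation (geometry only, no sequence)
.simulateAnnotation <- function(cfg) {
  n <- cfg$n_precursors
  armcase <- sample(c("both", "5p", "3p", "none"), n, replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.1))
  f5 <- sample(8:16, n, TRUE); f3 <- sample(8:16, n, TRUE)
  a1 <- sample(20:24, n, TRUE); a2 <- sample(20:24, n, TRUE)
  lp <- sample(8:20, n, TRUE)
  strand <- sample(c("+", "-"), n, TRUE)
  chroms <- paste0("chr", (seq_len(n) - 1L) %% 22 + 1L)
  offset <- integer(n)
  nextpos <- stats::setNames(rep(1000L, 22), paste0("chr", 1:22))
  pre <- vector("list", n); mat <- vector("list", n)
  for (i in seq_len(n)) {
    L <- f5[i] + a1[i] + lp[i] + a2[i] + f3[i]
    s <- nextpos[chroms[i]]
    e <- s + L - 1L
    nextpos[chroms[i]] <- e + 500L
    pid <- sprintf("sim-mir-%04d", i)
    pre[[i]] <- data.frame(chrom = chroms[i], start = s, end = e,
                           strand = strand[i], ID = pid)
    # transcribed arm intervals
    t5 <- c(f5[i] + 1L, f5[i] + a1[i])
    t3 <- c(f5[i] + a1[i] + lp[i] + 1L, f5[i] + a1[i] + lp[i] + a2[i])
    gen <- function(tt) {
      if (strand[i] == "+") c(s + tt[1] - 1L, s + tt[2] - 1L)
      else c(e - tt[2] + 1L, e - tt[1] + 1L)
    }
    rows <- list()
    if (armcase[i] %in% c("both", "5p")) {
      g <- gen(t5)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chroms[i], start = g[1], end = g[2], strand = strand[i],
        ID = paste0(sub("mir", "miR", pid), "-5p"), Derives_from = pid,
        arm = "5p")
    }
    if (armcase[i] %in% c("both", "3p")) {
      g <- gen(t3)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chroms[i], start = g[1], end = g[2], strand = strand[i],
        ID = paste0(sub("mir", "miR", pid), "-3p"), Derives_from = pid,
        arm = "3p")
    }
    mat[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  pre <- do.call(rbind, pre)
  mat <- do.call(rbind, Filter(Negate(is.null), mat))
  preGR <- GRanges(pre$chrom, IRanges(pre$start, pre$end),
                   strand = pre$strand, ID = pre$ID)
  matGR <- if (!is.null(mat))
    GRanges(mat$chrom, IRanges(mat$start, mat$end), strand = mat$strand,
            ID = mat$ID, Derives_from = mat$Derives_from, arm = mat$arm)
    else GRanges()
  MirnaSet(preGR, matGR)
}

.regionClass <- function(region) {
  ifelse(grepl("seed", region), "seed",
         ifelse(grepl("rom", region), "rom",
                ifelse(region == "loop", "loop", "mir")))
}

#' Simulate a multi-population miRNA variation cohort
#'
#' Generates a complete synthetic input bundle with known ground truth:
#' precursor annotation (GFF3), a multi-sample VCF with GT/DP/AD, a
#' population panel, a known-id table, and disease / target / pathway
#' annotation tables.  Variant sites are placed per base with a
#' region-dependent density (seed lowest, flanking arms highest); each
#' site's ancestral frequency is Beta-distributed and per-population
#' frequencies follow a Balding-Nichols draw with that population's F.
#' Genotypes are drawn under Hardy-Weinberg proportions except at planted
#' sites, where an inbreeding coefficient f deflates heterozygosity
#' (`P(het) = 2pq(1-f)`).  Populations with a `density` multiplier above 1
#' receive additional group-private sites.  Only sites with at least one
#' carrier are emitted.  A fixed seed makes the output byte-identical.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth` (a `CohortTruth`
#'   list: per-site frequencies and labels, per-population frequency
#'   matrix, planted f, annotation tables, panel, config) and `mirnas`
#'   (the in-memory [MirnaSet]).
#' @export
simulateCohort <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  pops <- config$populations
  n_samp <- sum(pops$size)
  samples <- unlist(mapply(function(nm, sz) sprintf("%s_%03d", nm, seq_len(sz)),
                           pops$name, pops$size, SIMPLIFY = FALSE))
  popv <- rep(pops$name, pops$size)
  groupv <- rep(pops$group, pops$size)

  mirnas <- .simulateAnnotation(config)
  segments <- decomposeMirna(mirnas)

  # per-base site placement table
  per_base <- data.frame(
    chrom = rep(as.character(seqnames(segments)), width(segments)),
    pos = unlist(lapply(seq_along(segments),
                        function(i) seq(start(segments)[i], end(segments)[i]))),
    premirna_id = rep(segments$premirna_id, width(segments)),
    region = rep(as.character(segments$region), width(segments)),
    mix = rep(segments$mix, width(segments)),
    stringsAsFactors = FALSE)
  w <- config$region_weights[.regionClass(per_base$region)]
  base_rate <- pmin(config$site_rate * w, 0.45)
  hit <- stats::runif(nrow(per_base)) < base_rate
  scope <- rep("all", sum(hit))
  sites <- per_base[hit, , drop = FALSE]
  # group-private extra sites for groups with density > 1
  for (g in unique(pops$group)) {
    d <- max(pops$density[pops$group == g])
    if (d <= 1) next
    extra <- stats::runif(nrow(per_base)) < base_rate * (d - 1)
    extra <- extra & !hit
    if (!any(extra)) next
    sites <- rbind(sites, per_base[extra, , drop = FALSE])
    scope <- c(scope, rep(g, sum(extra)))
    hit <- hit | extra
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  scope <- scope[ord]
  ns <- nrow(sites)
  if (!ns) stop("no variant sites generated; raise site_rate or sizes")

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))
  p0 <- pmin(pmax(stats::rbeta(ns, config$ancestral_shape[1],
                               config$ancestral_shape[2]), 0.005), 0.95)
  f <- numeric(ns)
  if (config$n_planted > 0 && ns >= 1)
    f[sample(ns, min(config$n_planted, ns))] <- config$planted_f

  p_pop <- matrix(0, ns, nrow(pops), dimnames = list(NULL, pops$name))
  for (j in seq_len(nrow(pops))) {
    Fj <- pops$F[j]
    pj <- if (Fj > 0)
      stats::rbeta(ns, p0 * (1 - Fj) / Fj, (1 - p0) * (1 - Fj) / Fj)
      else p0
    off <- scope != "all" & scope != pops$group[j]
    pj[off] <- 0
    p_pop[, j] <- pj
  }

  gt <- matrix(0L, ns, n_samp, dimnames = list(NULL, samples))
  for (j in seq_len(nrow(pops))) {
    cols <- which(popv == pops$name[j])
    q <- p_pop[, j]
    P2 <- q^2 + f * q * (1 - q)
    P1 <- pmax(2 * q * (1 - q) * (1 - f), 0)
    P0 <- pmax(1 - P1 - P2, 0)
    for (s in seq_len(ns)) {
      if (q[s] <= 0) next
      gt[s, cols] <- sample(0:2, length(cols), TRUE,
                            prob = c(P0[s], P1[s], P2[s]))
    }
  }
  carried <- rowSums(gt >= 1L) >= 1L
  sites <- sites[carried, , drop = FALSE]
  scope <- scope[carried]
  ref <- ref[carried]; alt <- alt[carried]
  p0 <- p0[carried]; f <- f[carried]
  p_pop <- p_pop[carried, , drop = FALSE]
  gt <- gt[carried, , drop = FALSE]
  ns <- nrow(sites)

  dp <- matrix(stats::rpois(ns * n_samp, 40), ns, n_samp,
               dimnames = list(NULL, samples))
  altFrac <- matrix(0, ns, n_samp, dimnames = list(NULL, samples))
  het <- gt == 1L & dp > 0
  altFrac[het] <- stats::rbinom(sum(het), dp[het], 0.5) / dp[het]
  altFrac[gt == 2L] <- 1
  altFrac[dp == 0] <- NA_real_

  known <- stats::runif(ns) >= config$novel_fraction
  rsid <- ifelse(known, sprintf("rs%07d", sample.int(9999999, ns)), NA)

  # annotation tables
  dcats <- sprintf("disease_category_%02d", seq_len(config$n_disease_categories))
  diseases <- data.frame(disease = sprintf("disease_%03d",
                                           seq_len(config$n_diseases)),
                         category = sample(dcats, config$n_diseases, TRUE))
  pre_ids <- precursors(mirnas)$ID
  linked <- pre_ids[stats::runif(length(pre_ids)) < config$disease_link_prob]
  disease_tab <- if (length(linked)) do.call(rbind, lapply(linked, function(m) {
    dd <- diseases[sample(nrow(diseases), sample(1:4, 1)), ]
    data.frame(mirna = m, disease = dd$disease, category = dd$category,
               stringsAsFactors = FALSE)
  })) else data.frame(mirna = character(), disease = character(),
                      category = character())
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  pcats <- sprintf("pathway_category_%02d",
                   seq_len(config$n_pathway_categories))
  pw <- data.frame(pathway = sprintf("pathway_%03d",
                                     seq_len(config$n_pathways)),
                   category = sample(pcats, config$n_pathways, TRUE))
  pathway_tab <- do.call(rbind, lapply(seq_len(nrow(pw)), function(i) {
    gg <- sample(genes, sample(3:12, 1))
    data.frame(gene = gg, pathway = pw$pathway[i],
               category = pw$category[i], stringsAsFactors = FALSE)
  }))
  target_tab <- do.call(rbind, lapply(pre_ids, function(m)
    data.frame(mirna = m, gene = sample(genes, sample(1:8, 1)),
               stringsAsFactors = FALSE)))

  # assemble the cohort object and emit files
  rr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                ref = ref, alt = alt, known_id = rsid, is_novel = !known)
  cd <- DataFrame(population = popv, group = groupv, row.names = samples)
  cohort <- new("MirnaCohort", SummarizedExperiment::SummarizedExperiment(
    assays = list(gt = gt, dp = dp, altFrac = altFrac),
    rowRanges = rr, colData = cd))

  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                gff = file.path(dir, "mirna.gff3"),
                panel = file.path(dir, "panel.tsv"),
                ids = file.path(dir, "known_ids.tsv"),
                disease = file.path(dir, "disease.tsv"),
                targets = file.path(dir, "targets.tsv"),
                pathways = file.path(dir, "pathways.tsv"),
                truth_sites = file.path(dir, "truth_sites.tsv"))
  writeCohortVcf(cohort, paths$vcf)
  writeMirnaGff(mirnas, paths$gff)
  utils::write.table(data.frame(sample = samples, population = popv,
                                group = groupv),
                     paths$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idtab <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                      alt = alt, rsid = rsid)[known, ]
  utils::write.table(idtab, paths$ids, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(disease_tab, paths$disease, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(target_tab, paths$targets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pathway_tab, paths$pathways, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_sites <- data.frame(sites, ref = ref, alt = alt, p0 = p0, f = f,
                            scope = scope, rsid = rsid,
                            stringsAsFactors = FALSE)
  utils::write.table(truth_sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(sites = truth_sites, p_pop = p_pop,
                populations = pops, disease_table = disease_tab,
                target_table = target_tab, pathway_table = pathway_tab,
                config = config)
  class(truth) <- "CohortTruth"
  list(paths = paths, truth = truth, mirnas = mirnas, cohort = cohort)
}

#' Write a MirnaSet as miRBase-dialect GFF3
#'
#' @param mirnas a [MirnaSet].
#' @param path output file.
#' @export
writeMirnaGff <- function(mirnas, path) {
  pre <- precursors(mirnas)
  mat <- matureArms(mirnas)
  pre$type <- "miRNA_primary_transcript"
  pre$Name <- pre$ID
  out <- pre
  if (length(mat)) {
    mat$type <- "miRNA"
    mat$Name <- mat$ID
    mcols(mat)$arm <- NULL
    out <- suppressWarnings(c(pre, mat))
  }
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Compare pipeline output with generator truth
#'
#' Measures how well the pipeline recovered the synthetic ground truth:
#' per-population allele-frequency RMSE, the region-label confusion matrix
#' (truth vs pipeline label, diagonal when recovery is exact), the
#' Hardy-Weinberg scan's empirical power at planted sites and type-I error
#' at unplanted sites, and (when a [PcaResult] and the mclust package are
#' available) the adjusted Rand index between k-means clusters on PC1/PC2
#' and the true geographic groups.
#'
#' @param cohort the [MirnaCohort] read back by the pipeline.
#' @param profiles [profileVariants()] output.
#' @param hwe [hweScan()] output.
#' @param truth `CohortTruth` from [simulateCohort()].
#' @param pca optional [PcaResult].
#' @return list with `af_rmse`, `region_confusion`, `hwe_power`,
#'   `hwe_type1`, `pca_ari`.
#' @export
truthCompare <- function(cohort, profiles, hwe, truth, pca = NULL) {
  rr <- SummarizedExperiment::rowRanges(cohort)
  key <- paste(as.character(seqnames(rr)), start(rr), rr$alt)
  tkey <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$alt)
  if (!setequal(key, tkey))
    stop("site sets of cohort and truth do not match")
  idx <- match(key, tkey)

  gt <- SummarizedExperiment::assay(cohort, "gt")
  popv <- SummarizedExperiment::colData(cohort)$population
  pops <- truth$populations$name
  emp <- sapply(pops, function(pop) {
    sub <- gt[, popv == pop, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  })
  af_rmse <- sqrt(mean((emp - truth$p_pop[idx, pops])^2, na.rm = TRUE))

  pkey <- paste(profiles$chrom, profiles$pos, profiles$alt,
                profiles$premirna_id)
  tkey2 <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$alt,
                 truth$sites$premirna_id)
  m <- match(pkey, tkey2)
  confusion <- table(truth = truth$sites$region[m[!is.na(m)]],
                     observed = profiles$region[!is.na(m)])

  fvec <- truth$sites$f[idx]
  planted_keys <- key[fvec > 0]
  hkey <- paste(hwe$chrom, hwe$pos, hwe$alt)
  hwe_power <- if (length(planted_keys) && any(hkey %in% planted_keys))
    mean(hwe$significant[hkey %in% planted_keys]) else NA_real_
  hwe_type1 <- if (any(!hkey %in% planted_keys))
    mean(hwe$significant[!hkey %in% planted_keys]) else NA_real_

  pca_ari <- NA_real_
  if (!is.null(pca) && requireNamespace("mclust", quietly = TRUE)) {
    co <- pcaCoords(pca)
    groups <- SummarizedExperiment::colData(cohort)[rownames(co), "group"]
    km <- stats::kmeans(co[, 1:2], centers = length(unique(groups)),
                        nstart = 25)
    pca_ari <- mclust::adjustedRandIndex(km$cluster, groups)
  }
  list(af_rmse = af_rmse, region_confusion = confusion,
       hwe_power = hwe_power, hwe_type1 = hwe_type1, pca_ari = pca_ari)
}

#' Draw genotypes under the Balding-Nichols divergence model
#'
#' A minimal structured-population genotype sampler used for PCA
#' calibration: each site has an ancestral allele frequency drawn uniformly
#' from `ancestral_range`; each population's frequency is a Beta draw with
#' that population's divergence F around the ancestral value; genotypes are
#' binomial (Hardy-Weinberg) within populations.
#'
#' @param sizes integer vector of population sizes.
#' @param Fs divergence values in [0, 1), one per population.
#' @param n_sites number of sites.
#' @param ancestral_range range of the uniform ancestral frequency.
#' @return list with `gt` (sites x samples dosage matrix) and `pop`
#'   (population index per sample).
#' @export
simulateBnGenotypes <- function(sizes, Fs, n_sites,
                                ancestral_range = c(0.05, 0.95)) {
  stopifnot(length(sizes) == length(Fs), all(Fs >= 0 & Fs < 1))
  p0 <- stats::runif(n_sites, ancestral_range[1], ancestral_range[2])
  n <- sum(sizes)
  gt <- matrix(0L, n_sites, n)
  pop <- rep(seq_along(sizes), sizes)
  for (j in seq_along(sizes)) {
    Fj <- Fs[j]
    pj <- if (Fj > 0)
      stats::rbeta(n_sites, p0 * (1 - Fj) / Fj, (1 - p0) * (1 - Fj) / Fj)
      else p0
    cols <- which(pop == j)
    gt[, cols] <- stats::rbinom(n_sites * length(cols), 2L,
                                rep(pj, length(cols)))
  }
  colnames(gt) <- sprintf("s%04d", seq_len(n))
  rownames(gt) <- sprintf("site%04d", seq_len(n_sites))
  list(gt = gt, pop = pop)
}
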