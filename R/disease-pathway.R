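#' Read a miRNA-disease association table
#'
#' @param path TSV with columns `mirna`, `disease`, `category`.
#' @return data.frame; empty disease names or diseases without a category
#'   are an error.
#' @export
readDiseaseTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "disease", "category")
  if (!all(need %in% names(t)))
    stop("disease table must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(t$disease))) stop("empty disease names")
  if (any(!nzchar(t$category) | is.na(t$category)))
    stop("every disease needs a category")
  t
}

#' Read a miRNA-target table
#'
#' @param path TSV with columns `mirna`, `gene`.
#' @export
readTargetTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(t)))
    stop("target table must have columns: mirna, gene")
  t
}

#' Read a gene-pathway-category table
#'
#' @param path TSV with columns `gene`, `pathway`, `category`; every pathway
#'   must map to exactly one category.
#' @export
readPathwayTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway", "category") %in% names(t)))
    stop("pathway table must have columns: gene, pathway, category")
  pc <- unique(t[, c("pathway", "category")])
  if (anyDuplicated(pc$pathway))
    stop("a pathway maps to more than one category")
  t
}

# per-population sets of variant keys (chrom:pos:alt), optionally restricted
# to seed regions via the profiles
.populationSiteSets <- function(cohort, profiles = NULL, seed_only = FALSE) {
  gt <- SummarizedExperiment::assay(cohort, "gt")
  rr <- SummarizedExperiment::rowRanges(cohort)
  key <- paste0(as.character(seqnames(rr)), ":", start(rr), ":", rr$alt)
  keep <- rep(TRUE, length(key))
  if (seed_only) {
    if (is.null(profiles)) stop("seed_only needs profiles")
    seedkeys <- unique(with(
      profiles[grepl("seed", profiles$region), , drop = FALSE],
      paste0(chrom, ":", pos, ":", alt)))
    keep <- key %in% seedkeys
  }
  popv <- SummarizedExperiment::colData(cohort)$population
  sets <- lapply(sort(unique(popv)), function(pop) {
    sub <- gt[, popv == pop, drop = FALSE]
    key[keep & rowSums(sub >= 1L, na.rm = TRUE) >= 1L]
  })
  names(sets) <- sort(unique(popv))
  sets
}

#' Population-by-population shared-variant matrix
#'
#' Counts, for every pair of populations, the variant positions (keyed by
#' chromosome, position and alternative allele) carried in both.  The
#' diagonal is each population's own variant count.  With
#' `scope = "seed"` only seed-region variants enter the comparison.
#'
#' @param cohort a [MirnaCohort].
#' @param profiles [profileVariants()] output (needed for `scope = "seed"`).
#' @param scope `"all"` or `"seed"`.
#' @return symmetric integer matrix, populations x populations.
#' @export
sharedVariantMatrix <- function(cohort, profiles = NULL,
                                scope = c("all", "seed")) {
  scope <- match.arg(scope)
  sets <- .populationSiteSets(cohort, profiles, seed_only = scope == "seed")
  pops <- names(sets)
  m <- matrix(0L, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops))
    for (j in seq_len(i))
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

# map each profiled variant key to the miRNA identifiers it can be matched
# under in annotation tables (precursor and, when applicable, mature names)
.variantMirnas <- function(profiles) {
  if (!nrow(profiles))
    return(data.frame(key = character(), premirna_id = character(),
                      region = character(),
                      ids = I(list())))
  ids <- mapply(function(p, m) unique(stats::na.omit(c(p, m))),
                profiles$premirna_id, profiles$mature_id, SIMPLIFY = FALSE)
  data.frame(key = paste0(profiles$chrom, ":", profiles$pos, ":",
                          profiles$alt),
             premirna_id = profiles$premirna_id,
             region = profiles$region,
             ids = I(unname(ids)))
}

#' Population-by-disease-category matrix
#'
#' Entry (P, D) counts the variant positions present in population P whose
#' miRNA (precursor or mature) is linked to at least one disease of
#' category D.  A variant in a pleiotropic miRNA counts toward every linked
#' category.  miRNAs absent from the table contribute nothing.
#'
#' @param cohort a [MirnaCohort].
#' @param profiles [profileVariants()] output.
#' @param disease_table data.frame from [readDiseaseTable()].
#' @param seed_only restrict to seed-region variants.
#' @return integer matrix, populations x disease categories.
#' @export
populationDiseaseMatrix <- function(cohort, profiles, disease_table,
                                    seed_only = FALSE) {
  sets <- .populationSiteSets(cohort, profiles, seed_only = seed_only)
  cats <- sort(unique(disease_table$category))
  m <- matrix(0L, length(sets), length(cats),
              dimnames = list(names(sets), cats))
  if (!nrow(profiles) || !nrow(disease_table)) return(m)
  vm <- .variantMirnas(profiles)
  if (seed_only) vm <- vm[grepl("seed", vm$region), , drop = FALSE]
  # variant key -> set of linked categories
  keycat <- lapply(split(vm$ids, vm$key), function(idlists) {
    mir <- unique(unlist(idlists))
    sort(unique(disease_table$category[disease_table$mirna %in% mir]))
  })
  for (pop in names(sets)) {
    for (key in intersect(sets[[pop]], names(keycat))) {
      cc <- keycat[[key]]
      if (length(cc)) m[pop, cc] <- m[pop, cc] + 1L
    }
  }
  m
}

#' Pathway-category profile per population
#'
#' A pathway is counted as affected in population P when at least one of its
#' genes is targeted by a miRNA carrying a seed-region variant present in P.
#' The profile reports, per population and pathway category, the percentage
#' of that category's pathways affected.
#'
#' @param cohort a [MirnaCohort].
#' @param profiles [profileVariants()] output.
#' @param target_table data.frame from [readTargetTable()].
#' @param pathway_table data.frame from [readPathwayTable()].
#' @return numeric matrix (percent), populations x pathway categories.
#' @export
pathwayCategoryProfile <- function(cohort, profiles, target_table,
                                   pathway_table) {
  sets <- .populationSiteSets(cohort, profiles, seed_only = TRUE)
  pc <- unique(pathway_table[, c("pathway", "category")])
  cats <- sort(unique(pc$category))
  denom <- table(factor(pc$category, levels = cats))
  m <- matrix(0, length(sets), length(cats),
              dimnames = list(names(sets), cats))
  vm <- .variantMirnas(profiles)
  vm <- vm[grepl("seed", vm$region), , drop = FALSE]
  for (pop in names(sets)) {
    mir <- unique(unlist(vm$ids[vm$key %in% sets[[pop]]]))
    genes <- unique(target_table$gene[target_table$mirna %in% mir])
    aff <- unique(pathway_table$pathway[pathway_table$gene %in% genes])
    hit <- table(factor(pc$category[pc$pathway %in% aff], levels = cats))
    m[pop, ] <- 100 * as.numeric(hit) / as.numeric(denom)
  }
  m[, denom == 0] <- NA_real_
  m
}

#' Bipartite edge lists for hive plotting
#'
#' Emits the two weighted edge lists behind the miRNA / population /
#' category hive plot: miRNA-population edges (weight = variant positions of
#' that miRNA carried in the population) and miRNA-category edges (weight =
#' variant positions in the miRNA, attached to every category the miRNA is
#' linked to).  Summing miRNA-population weights over the miRNAs linked to a
#' category reproduces the corresponding [populationDiseaseMatrix()] entry.
#'
#' @param cohort a [MirnaCohort].
#' @param profiles [profileVariants()] output.
#' @param annotation_table a disease table (`mirna`, `category`) or pathway
#'   category mapping with the same columns.
#' @param seed_only restrict to seed-region variants.
#' @return list of data.frames `mirna_population` and `mirna_category`.
#' @export
hiveEdges <- function(cohort, profiles, annotation_table,
                      seed_only = FALSE) {
  sets <- .populationSiteSets(cohort, profiles, seed_only = seed_only)
  vm <- .variantMirnas(profiles)
  if (seed_only) vm <- vm[grepl("seed", vm$region), , drop = FALSE]
  mp <- list()
  for (pop in names(sets)) {
    sub <- vm[vm$key %in% sets[[pop]], , drop = FALSE]
    if (!nrow(sub)) next
    w <- table(sub$premirna_id[!duplicated(paste(sub$key, sub$premirna_id))])
    mp[[pop]] <- data.frame(mirna = names(w), population = pop,
                            weight = as.integer(w))
  }
  mp <- if (length(mp)) do.call(rbind, mp) else
    data.frame(mirna = character(), population = character(),
               weight = integer())
  rownames(mp) <- NULL
  mc <- list()
  uvm <- vm[!duplicated(paste(vm$key, vm$premirna_id)), , drop = FALSE]
  for (i in seq_len(nrow(uvm))) {
    cats <- unique(annotation_table$category[
      annotation_table$mirna %in% uvm$ids[[i]]])
    for (cc in cats)
      mc[[length(mc) + 1L]] <- data.frame(mirna = uvm$premirna_id[i],
                                          category = cc, weight = 1L)
  }
  mc <- if (length(mc)) {
    mc <- do.call(rbind, mc)
    stats::aggregate(weight ~ mirna + category, mc, sum)
  } else data.frame(mirna = character(), category = character(),
                    weight = integer())
  list(mirna_population = mp, mirna_category = mc)
}

#' Agglomerative ordering of a matrix for heat-map export
#'
#' Hierarchical agglomerative clustering on Euclidean distances (complete
#' linkage by default, configurable) of rows and columns; returns the leaf
#' orders and merge trees.  A constant matrix yields an arbitrary but
#' deterministic order.
#'
#' @param m numeric matrix with at least 2 rows.
#' @param method linkage passed to [stats::hclust()].
#' @return list with `row_order`, `col_order`, `row_tree`, `col_tree`.
#' @export
clusterOrder <- function(m, method = "complete") {
  if (nrow(m) < 2L) stop("need at least 2 rows")
  rt <- stats::hclust(stats::dist(m), method = method)
  ct <- if (ncol(m) >= 2L)
    stats::hclust(stats::dist(t(m)), method = method) else NULL
  list(row_order = rt$order,
       col_order = if (is.null(ct)) seq_len(ncol(m)) else ct$order,
       row_tree = rt, col_tree = ct)
}
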