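#' Read a population panel table
#'
#' @param path TSV with columns `sample`, `population`, `group` (geographic
#'   group, e.g. EUR/ASI/AMR/AFR).
#' @return data.frame with those columns.
#' @export
readPanel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "group")
  if (!all(need %in% names(p)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(p$sample))
    stop("duplicated sample ids in panel: ",
         paste(unique(p$sample[duplicated(p$sample)]), collapse = ", "))
  p
}

# parse one GT string vector for alternative-allele index k:
# dosage = number of alleles equal to k; any missing or half call -> NA
.gtDosage <- function(gt, k) {
  u <- unique(gt)
  du <- vapply(strsplit(u, "[/|]"), function(al) {
    if (length(al) != 2L || any(al == ".") || any(al == ""))
      return(NA_integer_)
    sum(al == as.character(k))
  }, integer(1))
  du[match(gt, u)]
}

#' Read cohort variants from a multi-sample VCF
#'
#' Reads a VCF 4.x file (GT required; DP and AD used when present), keeps
#' only records whose position falls inside a supplied precursor, splits
#' multiallelic records into one biallelic record per alternative allele and
#' drops non-SNV alleles (counted in the filter log).  Genotypes are coded
#' as alternative-allele dosage 0/1/2; missing and half calls are `NA`.
#'
#' @param path VCF file.
#' @param mirnas a [MirnaSet]; only variants inside its precursors are kept.
#' @param panel data.frame from [readPanel()]; every VCF sample must appear
#'   in it (orphan samples are an error).
#' @return A [MirnaCohort]; `metadata(x)$filter_log` records counts at each
#'   filtering step (records read, non-SNV alleles dropped, outside
#'   precursors, retained).
#' @export
readCohortVcf <- function(path, mirnas, panel) {
  stopifnot(is(mirnas, "MirnaSet"))
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("VCF has no GT field")
  samples <- colnames(vcf)
  orphans <- setdiff(samples, panel$sample)
  if (length(orphans))
    stop("VCF samples not covered by the panel: ",
         paste(orphans, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  gtm <- VariantAnnotation::geno(vcf)$GT
  hasDP <- "DP" %in% names(VariantAnnotation::geno(vcf))
  hasAD <- "AD" %in% names(VariantAnnotation::geno(vcf))
  dpm <- if (hasDP) VariantAnnotation::geno(vcf)$DP else NULL
  adm <- if (hasAD) VariantAnnotation::geno(vcf)$AD else NULL

  n_read <- length(rr)
  rows <- list(); n_nonsnv <- 0L
  for (i in seq_len(n_read)) {
    alts <- as.character(altL[[i]])
    for (k in seq_along(alts)) {
      if (nchar(ref[i]) != 1L || nchar(alts[k]) != 1L ||
          !alts[k] %in% c("A", "C", "G", "T")) {
        n_nonsnv <- n_nonsnv + 1L
        next
      }
      rows[[length(rows) + 1L]] <- list(i = i, k = k, alt = alts[k])
    }
  }
  n_snv <- length(rows)
  # precursor intersection (position-based, strand-ignorant)
  keep <- logical(n_snv)
  if (n_snv) {
    pos <- GRanges(seqnames(rr)[vapply(rows, `[[`, 1L, "i")],
                   IRanges(start(rr)[vapply(rows, `[[`, 1L, "i")], width = 1L))
    keep <- IRanges::overlapsAny(pos, precursors(mirnas), ignore.strand = TRUE)
  }
  rows <- rows[keep]
  n_in <- length(rows)

  gt <- matrix(NA_integer_, nrow = n_in, ncol = length(samples),
               dimnames = list(NULL, samples))
  dp <- if (hasDP) matrix(NA_real_, n_in, length(samples),
                          dimnames = list(NULL, samples)) else NULL
  af <- if (hasAD) matrix(NA_real_, n_in, length(samples),
                          dimnames = list(NULL, samples)) else NULL
  out_chrom <- character(n_in); out_pos <- integer(n_in)
  out_ref <- character(n_in); out_alt <- character(n_in)
  for (j in seq_len(n_in)) {
    i <- rows[[j]]$i; k <- rows[[j]]$k
    out_chrom[j] <- as.character(seqnames(rr))[i]
    out_pos[j] <- start(rr)[i]
    out_ref[j] <- ref[i]
    out_alt[j] <- rows[[j]]$alt
    gt[j, ] <- .gtDosage(gtm[i, ], k)
    if (hasDP) dp[j, ] <- suppressWarnings(as.numeric(dpm[i, ]))
    if (hasAD) {
      ad <- adm[i, ]
      af[j, ] <- vapply(ad, function(a) {
        if (length(a) < k + 1L || anyNA(a)) return(NA_real_)
        tot <- sum(a)
        if (tot == 0) NA_real_ else a[k + 1L] / tot
      }, numeric(1))
    }
  }
  rr_out <- GRanges(out_chrom, IRanges(out_pos, width = 1L),
                    ref = out_ref, alt = out_alt,
                    known_id = rep(NA_character_, n_in),
                    is_novel = rep(NA, n_in))
  cd <- DataFrame(panel[match(samples, panel$sample),
                        c("population", "group")], row.names = samples)
  assays <- list(gt = gt)
  if (hasDP) assays$dp <- dp
  if (hasAD) assays$altFrac <- af
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr_out, colData = cd)
  obj <- new("MirnaCohort", se)
  metadata(obj)$filter_log <- data.frame(
    step = c("records_read", "alleles_nonsnv_dropped",
             "snvs_outside_precursor", "snvs_retained"),
    n = c(n_read, n_nonsnv, n_snv - n_in, n_in))
  obj
}

#' Write cohort variants to a VCF file
#'
#' Emits the retained biallelic records as a VCF 4.2 file with GT (and DP /
#' AD when present) so that re-reading with [readCohortVcf()] reproduces
#' positions, alleles and genotypes exactly.
#'
#' @param cohort a [MirnaCohort].
#' @param path output file.
#' @export
writeCohortVcf <- function(cohort, path) {
  rr <- SummarizedExperiment::rowRanges(cohort)
  gt <- SummarizedExperiment::assay(cohort, "gt")
  an <- SummarizedExperiment::assayNames(cohort)
  hasDP <- "dp" %in% an
  hasAD <- "altFrac" %in% an & hasDP
  dp <- if (hasDP) SummarizedExperiment::assay(cohort, "dp") else NULL
  af <- if (hasAD) SummarizedExperiment::assay(cohort, "altFrac") else NULL
  samples <- colnames(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mirvarmap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (hasDP) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               if (hasAD) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  gtstr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gtstr[is.na(gt)] <- "./."
  fmt <- paste(c("GT", if (hasDP) "DP", if (hasAD) "AD"), collapse = ":")
  for (i in seq_len(nrow(gt))) {
    cells <- gtstr[i, ]
    if (hasDP) {
      d <- dp[i, ]
      cells <- paste(cells, ifelse(is.na(d), ".", as.integer(d)), sep = ":")
      if (hasAD) {
        a <- af[i, ]
        altd <- ifelse(is.na(a) | is.na(d), NA, round(a * d))
        adstr <- ifelse(is.na(altd), ".,.",
                        paste(as.integer(d - altd), as.integer(altd), sep = ","))
        cells <- paste(cells, adstr, sep = ":")
      }
    }
    id <- rr$known_id[i]
    writeLines(paste(c(as.character(seqnames(rr))[i], start(rr)[i],
                       ifelse(is.na(id), ".", id), rr$ref[i], rr$alt[i],
                       ".", "PASS", ".", fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a known-variant id table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @return data.frame; conflicting duplicate entries (same variant, two
#'   different ids) are an error.
#' @export
readIdTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "rsid")
  if (!all(need %in% names(t)))
    stop("id table must have columns: ", paste(need, collapse = ", "))
  key <- paste(t$chrom, t$pos, t$ref, t$alt)
  if (any(tapply(t$rsid, key, function(x) length(unique(x))) > 1))
    stop("conflicting ids for the same variant in the id table")
  t[!duplicated(key), ]
}

#' Flag known vs novel variants
#'
#' Matches each cohort variant against a dbSNP-style id table; matching is
#' allele-aware (chromosome, position, ref and alt must all agree — a
#' different alternative allele at a known position stays novel).
#'
#' @param cohort a [MirnaCohort].
#' @param id_table data.frame from [readIdTable()] (may have zero rows:
#'   everything is then novel).
#' @return The cohort with `known_id` and `is_novel` filled in.
#' @export
annotateKnown <- function(cohort, id_table) {
  rr <- SummarizedExperiment::rowRanges(cohort)
  key <- paste(as.character(seqnames(rr)), start(rr), rr$ref, rr$alt)
  tkey <- paste(id_table$chrom, id_table$pos, id_table$ref, id_table$alt)
  idx <- match(key, tkey)
  rr$known_id <- ifelse(is.na(idx), NA_character_, id_table$rsid[idx])
  rr$is_novel <- is.na(idx)
  SummarizedExperiment::rowRanges(cohort) <- rr
  cohort
}

#' Build per-variant profiles
#'
#' Summarizes every variant against the substructure map: carriers (samples
#' with at least one alternative allele), het / hom-alt counts, pooled
#' carrier frequency in percent over the full cohort (missing genotypes
#' count as non-carriers), mean coverage, mean alternative-allele read
#' fraction over heterozygous calls, novelty, and the substructure region.
#' A variant overlapped by several precursors yields one row per precursor.
#' Variants with no carriers are excluded from the map.
#'
#' @param cohort a [MirnaCohort].
#' @param mirnas the [MirnaSet] the cohort was built against.
#' @param segments optional precomputed [decomposeMirna()] output.
#' @return A data.frame, one row per (variant, precursor).
#' @export
profileVariants <- function(cohort, mirnas,
                            segments = decomposeMirna(mirnas)) {
  rr <- SummarizedExperiment::rowRanges(cohort)
  gt <- SummarizedExperiment::assay(cohort, "gt")
  an <- SummarizedExperiment::assayNames(cohort)
  dp <- if ("dp" %in% an) SummarizedExperiment::assay(cohort, "dp") else NULL
  af <- if ("altFrac" %in% an) SummarizedExperiment::assay(cohort, "altFrac") else NULL
  mat <- matureArms(mirnas)
  total_n <- ncol(cohort)
  if (total_n == 0L) stop("empty cohort")
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    g <- gt[i, ]
    n_het <- sum(g == 1L, na.rm = TRUE)
    n_hom <- sum(g == 2L, na.rm = TRUE)
    if (n_het + n_hom == 0L) next
    loc <- locateRegion(segments, as.character(seqnames(rr))[i], start(rr)[i])
    if (!nrow(loc)) next
    mean_cov <- if (!is.null(dp)) mean(dp[i, ], na.rm = TRUE) else NA_real_
    maf <- if (!is.null(af)) {
      v <- af[i, g == 1L & !is.na(g)]
      if (length(v) && any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
    } else NA_real_
    for (j in seq_len(nrow(loc))) {
      mature_id <- NA_character_
      if (grepl("miR", loc$region[j], fixed = TRUE)) {
        hit <- mat[mcols(mat)$Derives_from == loc$premirna_id[j] &
                     start(mat) <= start(rr)[i] & end(mat) >= start(rr)[i]]
        if (length(hit)) mature_id <- hit$ID[1]
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(seqnames(rr))[i], pos = start(rr)[i],
        ref = rr$ref[i], alt = rr$alt[i],
        known_id = rr$known_id[i], is_novel = rr$is_novel[i],
        premirna_id = loc$premirna_id[j], mature_id = mature_id,
        region = loc$region[j], mix = loc$mix[j], label = loc$label[j],
        n_carriers = n_het + n_hom, n_het = n_het, n_hom_alt = n_hom,
        n_missing = sum(is.na(g)),
        pooled_frequency_pct = 100 * (n_het + n_hom) / total_n,
        mean_coverage = mean_cov, mean_alt_fraction = maf,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      known_id = character(), is_novel = logical(),
                      premirna_id = character(), mature_id = character(),
                      region = character(), mix = logical(),
                      label = character(), n_carriers = integer(),
                      n_het = integer(), n_hom_alt = integer(),
                      n_missing = integer(), pooled_frequency_pct = numeric(),
                      mean_coverage = numeric(),
                      mean_alt_fraction = numeric()))
  do.call(rbind, out)
}

#' Variant occurrence per substructure region
#'
#' Tallies profiled variants over the seven region labels, with regions
#' carrying the `(mix)` qualifier counted separately.
#'
#' @param profiles data.frame from [profileVariants()].
#' @return data.frame with `region`, `mix`, `count`; counts sum to
#'   `nrow(profiles)`.
#' @export
regionOccurrence <- function(profiles) {
  if (!nrow(profiles))
    return(data.frame(region = character(), mix = logical(),
                      count = integer()))
  agg <- stats::aggregate(list(count = rep(1L, nrow(profiles))),
                          by = list(region = profiles$region,
                                    mix = profiles$mix), FUN = sum)
  agg$region <- factor(agg$region, levels = regionLevels)
  agg[order(agg$region, agg$mix), ]
}
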