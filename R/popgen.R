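#' Alternative-allele frequency from genotype counts
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectors recycle).
#' @return `(n_het + 2 n_hom_alt) / (2 n)`; an all-missing slice (n = 0) is
#'   an error.
#' @export
alleleFrequency <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (any(n == 0)) stop("no genotyped samples")
  (n_het + 2 * n_hom_alt) / (2 * n)
}

#' Chi-square test for Hardy-Weinberg deviation
#'
#' Tests observed genotype counts against the Hardy-Weinberg expectation
#' computed from the observed allele frequency (expected counts
#' \eqn{np^2, 2npq, nq^2}).  With the continuity (Yates) correction on — the
#' default — the statistic is \eqn{\sum (\max(|O-E|-0.5, 0))^2 / E}; the
#' p-value comes from the chi-square distribution with one degree of
#' freedom.  Monomorphic counts return p = 1 by convention so scan totals
#' stay stable.
#'
#' All arguments are vectorized.
#'
#' @param n_hom_ref,n_het,n_hom_alt observed genotype counts.
#' @param correction apply the Yates continuity correction (default `TRUE`).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with counts, `n_total`, `alt_allele_freq`, `chi2`,
#'   `p_value` and `significant`.
#' @export
hweTest <- function(n_hom_ref, n_het, n_hom_alt, correction = TRUE,
                    alpha = 0.05) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (any(n < 1)) stop("need at least one genotyped sample")
  q <- (n_het + 2 * n_hom_alt) / (2 * n)
  p <- 1 - q
  cc <- if (correction) 0.5 else 0
  chi2 <- numeric(length(n))
  mono <- q <= 0 | q >= 1
  for (i in seq_along(n)) {
    if (mono[i]) { chi2[i] <- 0; next }
    e <- n[i] * c(p[i]^2, 2 * p[i] * q[i], q[i]^2)
    o <- c(n_hom_ref[i], n_het[i], n_hom_alt[i])
    d <- pmax(abs(o - e) - cc, 0)
    chi2[i] <- sum(d^2 / e)
  }
  pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[mono] <- 1
  data.frame(n_total = n, n_hom_ref = n_hom_ref, n_het = n_het,
             n_hom_alt = n_hom_alt, alt_allele_freq = q, chi2 = chi2,
             p_value = pv, significant = pv < alpha)
}

#' Scan all (variant, population) pairs for Hardy-Weinberg deviations
#'
#' Runs [hweTest()] once per population per variant with at least one
#' carrier in that population.  Within each population, samples with missing
#' genotypes at a site are excluded from that site's counts; all genotyped
#' non-carriers count as hom-ref, so `n_total` is the genotyped population
#' size.  No multiple-testing correction is applied by default (raw
#' p-values; Benjamini-Hochberg is available through `adjust`).
#'
#' @param cohort a [MirnaCohort].
#' @param alpha significance level.
#' @param correction Yates continuity correction flag.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by population, chromosome and position, one row
#'   per tested pair, with a `significant` flag.
#' @export
hweScan <- function(cohort, alpha = 0.05, correction = TRUE,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  gt <- SummarizedExperiment::assay(cohort, "gt")
  rr <- SummarizedExperiment::rowRanges(cohort)
  popv <- SummarizedExperiment::colData(cohort)$population
  out <- list()
  for (pop in sort(unique(popv))) {
    sub <- gt[, popv == pop, drop = FALSE]
    n_het <- rowSums(sub == 1L, na.rm = TRUE)
    n_hom <- rowSums(sub == 2L, na.rm = TRUE)
    n_gen <- rowSums(!is.na(sub))
    keep <- which(n_het + n_hom >= 1L & n_gen >= 1L)
    if (!length(keep)) next
    res <- hweTest(n_gen[keep] - n_het[keep] - n_hom[keep],
                   n_het[keep], n_hom[keep],
                   correction = correction, alpha = alpha)
    out[[pop]] <- cbind(
      data.frame(population = pop,
                 chrom = as.character(seqnames(rr))[keep],
                 pos = start(rr)[keep],
                 ref = rr$ref[keep], alt = rr$alt[keep],
                 stringsAsFactors = FALSE),
      res)
  }
  if (!length(out))
    return(data.frame(population = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      n_total = integer(), n_hom_ref = integer(),
                      n_het = integer(), n_hom_alt = integer(),
                      alt_allele_freq = numeric(), chi2 = numeric(),
                      p_value = numeric(), significant = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$population, res$chrom, res$pos), ]
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
    res$significant <- res$p_adjusted < alpha
  }
  res
}

#' Per-individual variant burden
#'
#' Counts, per sample, the variant sites carried (at least one alternative
#' allele) and summarizes the counts by geographic group.
#'
#' @param cohort a [MirnaCohort].
#' @return list with `samples` (sample, population, group, burden) and
#'   `groups` (group, n, mean, median, q25, q75).
#' @export
burdenPerIndividual <- function(cohort) {
  gt <- SummarizedExperiment::assay(cohort, "gt")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  burden <- if (nrow(gt)) colSums(gt >= 1L, na.rm = TRUE) else
    stats::setNames(rep(0L, ncol(gt)), colnames(gt))
  samples <- data.frame(sample = colnames(cohort),
                        population = cd$population, group = cd$group,
                        burden = as.integer(burden),
                        stringsAsFactors = FALSE)
  if (!nrow(samples))
    return(list(samples = samples,
                groups = data.frame(group = character(), n = integer(),
                                    mean = numeric(), median = numeric(),
                                    q25 = numeric(), q75 = numeric())))
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(s)
    data.frame(group = s$group[1], n = nrow(s), mean = mean(s$burden),
               median = stats::median(s$burden),
               q25 = unname(stats::quantile(s$burden, 0.25)),
               q75 = unname(stats::quantile(s$burden, 0.75)))))
  rownames(groups) <- NULL
  list(samples = samples, groups = groups)
}

#' Allele-frequency spectrum
#'
#' Histogram of per-site alternative-allele frequencies over (0, 1].
#'
#' @param freqs numeric frequencies, each in (0, 1].
#' @param bin_edges increasing edges partitioning (0, 1]; default deciles.
#' @return data.frame with `lower`, `upper`, `count`; counts sum to
#'   `length(freqs)`.
#' @export
afSpectrum <- function(freqs, bin_edges = seq(0, 1, by = 0.1)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  if (bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1)
    stop("bin edges must span (0, 1]")
  if (any(freqs <= 0 | freqs > 1))
    stop("frequencies must lie in (0, 1]")
  bins <- cut(freqs, breaks = bin_edges, right = TRUE)
  data.frame(lower = bin_edges[-length(bin_edges)],
             upper = bin_edges[-1],
             count = as.integer(table(bins)))
}

#' Functional-variant ratio against a reference
#'
#' Divides a count of putatively functional variants by the number of
#' elements harbouring them and compares the ratio with an external
#' reference (e.g. the genome-wide rate of loss-of-function variants per
#' protein-coding gene).
#'
#' @param n_functional,n_elements numerator and denominator counts.
#' @param reference_ratio positive reference rate.
#' @return list with `ratio` and `fold_vs_reference`.
#' @export
functionalRatio <- function(n_functional, n_elements, reference_ratio) {
  if (n_elements <= 0) stop("n_elements must be positive")
  if (reference_ratio <= 0) stop("reference_ratio must be positive")
  ratio <- n_functional / n_elements
  list(ratio = ratio, fold_vs_reference = ratio / reference_ratio)
}
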