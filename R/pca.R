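#' Select sites for the stratification PCA
#'
#' Retains sites with coverage strictly above `min_coverage` in the anchor
#' cohort (mean depth over the anchor samples) and, optionally, at least one
#' carrier.  When the cohort has no depth assay the coverage filter is
#' skipped with a warning.
#'
#' @param cohort a [MirnaCohort].
#' @param anchor_samples samples whose coverage anchors the filter (default:
#'   all samples).
#' @param min_coverage strict lower bound on mean depth (default 10, i.e.
#'   `>10x`).
#' @param require_carrier drop sites with no carrier (default `TRUE`).
#' @return integer indices of retained sites.
#' @export
filterSitesForPca <- function(cohort, anchor_samples = colnames(cohort),
                              min_coverage = 10, require_carrier = TRUE) {
  gt <- SummarizedExperiment::assay(cohort, "gt")
  keep <- rep(TRUE, nrow(gt))
  if ("dp" %in% SummarizedExperiment::assayNames(cohort)) {
    dp <- SummarizedExperiment::assay(cohort, "dp")
    anchor <- intersect(anchor_samples, colnames(cohort))
    if (!length(anchor)) stop("no anchor samples present in the cohort")
    cov <- rowMeans(dp[, anchor, drop = FALSE], na.rm = TRUE)
    keep <- keep & !is.na(cov) & cov > min_coverage
  } else {
    warning("cohort has no depth assay; coverage filter skipped")
  }
  if (require_carrier)
    keep <- keep & rowSums(gt >= 1L, na.rm = TRUE) >= 1L
  which(keep)
}

#' Eigenstrat-style principal component analysis
#'
#' Normalizes a sites-by-samples dosage matrix the Eigenstrat way — each
#' site centered by its mean dosage and scaled by
#' \eqn{\sqrt{\hat p (1-\hat p)}}, with missing genotypes mean-imputed per
#' site — then eigendecomposes the sample-by-sample covariance.  By default
#' \eqn{\hat p} is the shrunk estimator \eqn{(1 + \sum g_i)/(2 + 2n)}, which
#' stabilizes the scaling of rare sites on small cohorts; `shrink = FALSE`
#' uses the plain maximum-likelihood frequency.  Sites that are monomorphic
#' after imputation carry no information and are dropped with a warning.
#' Component signs are canonicalized: the largest-magnitude sample
#' coordinate on each component is made positive.
#'
#' @param gt integer matrix, sites x samples, dosages 0/1/2 (`NA` allowed).
#' @param k number of components to return.
#' @param shrink use the shrunk allele-frequency estimator (default `TRUE`).
#' @return A [PcaResult].
#' @export
eigenstratPca <- function(gt, k = 10, shrink = TRUE) {
  if (nrow(gt) < 2L) stop("PCA needs at least 2 sites")
  if (ncol(gt) < 3L) stop("PCA needs at least 3 samples")
  n <- ncol(gt)
  mu <- rowMeans(gt, na.rm = TRUE)
  # mean imputation of missing genotypes
  X <- gt
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- mu[nas[, 1]]
  pmle <- rowSums(X) / (2 * n)
  poly <- pmle > 0 & pmle < 1
  if (!all(poly)) {
    warning(sum(!poly), " site(s) with allele frequency 0 or 1 dropped before PCA")
    X <- X[poly, , drop = FALSE]
    mu <- mu[poly]
    if (nrow(X) < 2L) stop("fewer than 2 usable sites remain")
  }
  phat <- if (shrink) (1 + rowSums(X)) / (2 + 2 * n) else rowSums(X) / (2 * n)
  X <- (X - mu) / sqrt(phat * (1 - phat))
  C <- crossprod(X) / nrow(X)          # samples x samples
  eg <- eigen(C, symmetric = TRUE)
  k <- min(k, n)
  coords <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(gt)
  colnames(coords) <- paste0("PC", seq_len(k))
  sites <- rownames(gt)
  if (is.null(sites)) sites <- as.character(which(poly))
  else sites <- sites[poly]
  new("PcaResult", coords = coords,
      eigenvalues = pmax(eg$values, 0), sites = sites)
}

#' Run the stratification PCA on a cohort
#'
#' Convenience wrapper: applies [filterSitesForPca()] and runs
#' [eigenstratPca()] on the retained sites.
#'
#' @inheritParams filterSitesForPca
#' @inheritParams eigenstratPca
#' @return A [PcaResult]; fails when fewer than 2 sites survive the filter.
#' @export
cohortPca <- function(cohort, k = 10, anchor_samples = colnames(cohort),
                      min_coverage = 10, require_carrier = TRUE,
                      shrink = TRUE) {
  idx <- filterSitesForPca(cohort, anchor_samples, min_coverage,
                           require_carrier)
  if (length(idx) < 2L) {
    warning("fewer than 2 sites pass the PCA filter")
    stop("PCA refuses to run on <2 sites")
  }
  gt <- SummarizedExperiment::assay(cohort, "gt")[idx, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(cohort)[idx]
  rownames(gt) <- paste0(as.character(seqnames(rr)), ":", start(rr), "_",
                         rr$ref, "/", rr$alt)
  eigenstratPca(gt, k = k, shrink = shrink)
}
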