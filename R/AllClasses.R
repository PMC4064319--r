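#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#'   findOverlaps granges
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges rowRanges<-
NULL

#' The seven functional regions of a pre-miRNA hairpin
#'
#' Canonical region labels of the precursor substructure taxonomy, ordered
#' 5' to 3' along the transcribed strand: 5' flanking arm, rest-of-mature and
#' seed of the 5p mature product, the terminal loop, seed and rest-of-mature
#' of the 3p product, and the 3' flanking arm.  Regions on a side lacking an
#' annotated mature product additionally carry a `(mix)` qualifier (see
#' [decomposeMirna()]).
#'
#' @format Character vector of length 7.
#' @export
regionLevels <- c("5' mir", "5' rom miR", "5' seed miR", "loop",
                  "3' seed miR", "3' rom miR", "3' mir")

#' Format a region label with its (mix) qualifier
#'
#' @param region character vector of region labels (see [regionLevels]).
#' @param mix logical vector; `TRUE` where the region lies on an arm side
#'   with no annotated mature product.
#' @return Character vector such as `"5' mir (mix)"`.
#' @export
formatRegionLabel <- function(region, mix) {
  ifelse(isTRUE(mix) | (is.logical(mix) & mix), paste0(region, " (mix)"),
         as.character(region))
}

#' MirnaSet: precursor and mature miRNA annotation
#'
#' Holds miRBase-style annotation as two parallel [GenomicRanges::GRanges]:
#' hairpin precursors (`precursors`, with an `ID` metadata column) and mature
#' products (`matures`, with `ID`, `Derives_from` and an `arm` column in
#' `{5p, 3p}`).  Validity enforces that every mature product is contained in
#' its parent precursor, lies on the same strand, and that the (at most two)
#' arms of a precursor do not overlap.
#'
#' @slot precursors GRanges of precursor hairpins.
#' @slot matures GRanges of mature miRNAs.
#' @export
setClass("MirnaSet",
         representation(precursors = "GRanges", matures = "GRanges"))

setValidity("MirnaSet", function(object) {
  pre <- object@precursors
  mat <- object@matures
  msgs <- character()
  if (is.null(mcols(pre)$ID)) msgs <- c(msgs, "precursors need an ID column")
  if (anyDuplicated(mcols(pre)$ID))
    msgs <- c(msgs, "duplicated precursor IDs")
  if (length(mat)) {
    need <- c("ID", "Derives_from", "arm")
    if (!all(need %in% names(mcols(mat))))
      return("matures need ID, Derives_from and arm columns")
    idx <- match(mcols(mat)$Derives_from, mcols(pre)$ID)
    if (anyNA(idx)) {
      orphans <- mcols(mat)$ID[is.na(idx)]
      return(sprintf("mature records with no parent precursor: %s",
                     paste(orphans, collapse = ", ")))
    }
    parent <- pre[idx]
    bad <- start(mat) < start(parent) | end(mat) > end(parent) |
      as.character(seqnames(mat)) != as.character(seqnames(parent))
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "mature outside its precursor: %s (in %s)",
        paste(mcols(mat)$ID[bad], collapse = ","),
        paste(mcols(mat)$Derives_from[bad], collapse = ",")))
    if (any(as.character(strand(mat)) != as.character(strand(parent))))
      msgs <- c(msgs, "mature strand differs from precursor strand")
    if (!all(mcols(mat)$arm %in% c("5p", "3p")))
      msgs <- c(msgs, "arm must be 5p or 3p")
    # arms of the same precursor must not overlap each other
    for (pid in unique(mcols(mat)$Derives_from)) {
      arms <- mat[mcols(mat)$Derives_from == pid]
      if (length(arms) > 2)
        msgs <- c(msgs, sprintf("precursor %s has >2 mature arms", pid))
      if (length(arms) == 2 &&
          start(arms)[2] <= end(arms)[1] && start(arms)[1] <= end(arms)[2])
        msgs <- c(msgs, sprintf("overlapping mature arms in %s", pid))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MirnaSet-class constructor.
#' @param precursors,matures GRanges as described above.
#' @export
MirnaSet <- function(precursors, matures = GRanges()) {
  new("MirnaSet", precursors = precursors, matures = matures)
}

#' @describeIn MirnaSet-class precursor ranges.
#' @param x a MirnaSet.
#' @export
precursors <- function(x) x@precursors

#' @describeIn MirnaSet-class mature ranges.
#' @export
matureArms <- function(x) x@matures

setMethod("show", "MirnaSet", function(object) {
  cat(sprintf("MirnaSet with %d precursors and %d mature miRNAs\n",
              length(object@precursors), length(object@matures)))
})

#' MirnaCohort: cohort genotypes at miRNA variant sites
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] of biallelic SNVs
#' (rows) by cohort samples (columns).  Row ranges carry `ref`, `alt` and
#' optionally `known_id` / `is_novel`; `colData` carries the population panel
#' (`population`, `group`).  Assays: `gt` (integer alternative-allele dosage
#' 0/1/2, `NA` for missing or half calls), and optionally `dp` (read depth)
#' and `altFrac` (per-call alternative-allele read fraction).
#'
#' @export
setClass("MirnaCohort", contains = "RangedSummarizedExperiment")

setValidity("MirnaCohort", function(object) {
  msgs <- character()
  if (!"gt" %in% SummarizedExperiment::assayNames(object))
    return("assay 'gt' is required")
  gt <- SummarizedExperiment::assay(object, "gt")
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    msgs <- c(msgs, "gt values must be 0, 1, 2 or NA")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("population", "group") %in% names(cd)))
    msgs <- c(msgs, "colData needs population and group columns")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (!all(c("ref", "alt") %in% names(mcols(rr))))
      msgs <- c(msgs, "rowRanges need ref and alt columns")
    else if (!all(nchar(mcols(rr)$ref) == 1L & nchar(mcols(rr)$alt) == 1L))
      msgs <- c(msgs, "only biallelic SNVs are allowed (1-base alleles)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Eigenstrat-style PCA result
#'
#' @slot coords numeric matrix, samples by retained components; per-component
#'   sign is canonicalized so the largest-magnitude coordinate is positive.
#' @slot eigenvalues numeric, all eigenvalues in non-increasing order.
#' @slot sites character, identifiers of the sites that entered the PCA.
#' @export
setClass("PcaResult",
         representation(coords = "matrix", eigenvalues = "numeric",
                        sites = "character"))

setValidity("PcaResult", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-8))
    return("eigenvalues must be non-increasing")
  TRUE
})

#' @describeIn PcaResult-class sample coordinates.
#' @param x a PcaResult.
#' @export
pcaCoords <- function(x) x@coords

#' @describeIn PcaResult-class eigenvalues.
#' @export
pcaEigenvalues <- function(x) x@eigenvalues

#' @describeIn PcaResult-class retained site identifiers.
#' @export
pcaSites <- function(x) x@sites

setMethod("show", "PcaResult", function(object) {
  ev <- object@eigenvalues
  pct <- if (sum(ev) > 0) 100 * ev[seq_len(min(3, length(ev)))] / sum(ev)
         else rep(0, min(3, length(ev)))
  cat(sprintf(
    "PcaResult: %d samples x %d components (%d sites); top eigenvalue share: %s\n",
    nrow(object@coords), ncol(object@coords), length(object@sites),
    paste(sprintf("%.1f%%", pct), collapse = ", ")))
})
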