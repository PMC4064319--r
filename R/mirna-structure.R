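#' Read miRBase-style GFF3 annotation
#'
#' Parses a GFF3 file in the miRBase dialect (feature types
#' `miRNA_primary_transcript` and `miRNA`, mature records pointing at their
#' precursor through a `Derives_from` attribute) into a [MirnaSet].
#' Coordinates are kept 1-based inclusive throughout the package.
#'
#' Arm assignment (`5p`/`3p`) uses the mature name suffix when present
#' (`-5p`/`-3p`); otherwise the arm is classified by the position of the
#' mature midpoint relative to the precursor midpoint on the transcribed
#' strand.
#'
#' @param path GFF3 file.
#' @return A [MirnaSet]; mature records with no parent, or extending outside
#'   their precursor, raise a validity error naming the offending IDs.
#' @export
readMirnaGff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path,
                                          "': ", conditionMessage(e)))
  type <- as.character(gr$type)
  pre <- gr[type == "miRNA_primary_transcript"]
  mat <- gr[type == "miRNA"]
  if (!length(pre)) stop("no miRNA_primary_transcript records in ", path)
  pid <- if (!is.null(pre$Name)) pre$Name else pre$ID
  mcols(pre) <- DataFrame(ID = as.character(pid))
  if (length(mat)) {
    df <- if (!is.null(mat$Derives_from)) as.character(mat$Derives_from)
          else stop("mature miRNA records lack Derives_from attributes")
    # Derives_from points at the precursor's ID attribute; translate to Name
    # when precursors are named by Name (miRBase uses accession IDs there).
    key <- as.character(if (!is.null(gr$ID)) gr$ID[type == "miRNA_primary_transcript"] else pid)
    tr <- match(df, key)
    parent <- ifelse(is.na(tr), df, as.character(pid)[tr])
    mid <- if (!is.null(mat$Name)) mat$Name else mat$ID
    mcols(mat) <- DataFrame(ID = as.character(mid), Derives_from = parent)
    mat$arm <- assignArms(pre, mat)
  }
  MirnaSet(precursors = pre, matures = mat)
}

# 5p/3p from the name suffix when available, else the transcribed-orientation
# midpoint rule: an arm whose midpoint precedes the precursor midpoint in
# transcription order is 5p.
assignArms <- function(pre, mat) {
  idx <- match(mat$Derives_from, pre$ID)
  if (anyNA(idx))
    stop("mature records with no parent precursor: ",
         paste(mat$ID[is.na(idx)], collapse = ", "))
  arm <- rep(NA_character_, length(mat))
  suff <- ifelse(grepl("-5p$", mat$ID), "5p",
                 ifelse(grepl("-3p$", mat$ID), "3p", NA))
  arm <- suff
  need <- is.na(arm)
  if (any(need)) {
    pm <- (start(pre)[idx] + end(pre)[idx]) / 2
    mm <- (start(mat) + end(mat)) / 2
    minus <- as.character(strand(pre))[idx] == "-"
    before <- ifelse(minus, mm > pm, mm < pm)
    arm[need] <- ifelse(before[need], "5p", "3p")
  }
  arm
}

# genomic position -> transcribed offset (1-based from the 5' end)
.toTranscribed <- function(pos, pstart, pend, minus) {
  if (minus) pend - pos + 1L else pos - pstart + 1L
}
# transcribed interval [s,e] -> genomic interval (start,end)
.toGenomic <- function(s, e, pstart, pend, minus) {
  if (minus) c(pend - e + 1L, pend - s + 1L) else c(pstart + s - 1L, pstart + e - 1L)
}

# Decompose one precursor given transcribed-coordinate arms.
# arms: data.frame(a, b, arm) in transcribed coordinates, possibly 0 rows.
.decomposeOne <- function(L, arms, pid) {
  seg <- function(s, e, region, mix) {
    if (e < s) return(NULL)
    data.frame(s = s, e = e, region = region, mix = mix)
  }
  armSegs <- function(a, b, side) {
    m <- b - a + 1L
    rom <- paste0(side, " rom miR")
    sd <- paste0(side, " seed miR")
    if (m < 8L)
      warning(sprintf("mature arm in %s is %d nt; seed truncated to positions 2..%d",
                      pid, m, m), call. = FALSE)
    out <- list(seg(a, a, rom, FALSE))
    if (m >= 2L) out <- c(out, list(seg(a + 1L, min(a + 7L, b), sd, FALSE)))
    if (b >= a + 8L) out <- c(out, list(seg(a + 8L, b, rom, FALSE)))
    out
  }
  segs <- list()
  if (nrow(arms) == 0L) {
    half <- ceiling(L / 2)
    segs <- list(seg(1L, half, "5' mir", TRUE),
                 seg(half + 1L, L, "3' mir", TRUE))
  } else if (nrow(arms) == 2L) {
    arms <- arms[order(arms$a), ]
    a1 <- arms$a[1]; b1 <- arms$b[1]
    a2 <- arms$a[2]; b2 <- arms$b[2]
    if (a2 <= b1) stop("overlapping mature arms in ", pid)
    segs <- c(list(seg(1L, a1 - 1L, "5' mir", FALSE)),
              armSegs(a1, b1, "5'"),
              list(seg(b1 + 1L, a2 - 1L, "loop", FALSE)),
              armSegs(a2, b2, "3'"),
              list(seg(b2 + 1L, L, "3' mir", FALSE)))
  } else {
    a <- arms$a[1]; b <- arms$b[1]
    if (arms$arm[1] == "5p") {
      segs <- c(list(seg(1L, a - 1L, "5' mir", FALSE)),
                armSegs(a, b, "5'"),
                list(seg(b + 1L, L, "3' mir", TRUE)))
    } else {
      segs <- c(list(seg(1L, a - 1L, "5' mir", TRUE)),
                armSegs(a, b, "3'"),
                list(seg(b + 1L, L, "3' mir", FALSE)))
    }
  }
  do.call(rbind, Filter(Negate(is.null), segs))
}

#' Decompose precursors into substructure segments
#'
#' Splits every precursor of a [MirnaSet], strand-aware, into the
#' substructure taxonomy of [regionLevels]: each annotated mature arm
#' contributes a 7-nt seed (mature positions 2 to 8 on the transcribed
#' strand) flanked by rest-of-mature (position 1 and positions 9 to the arm
#' end); the stretch strictly between two arms is the loop; precursor
#' sequence outside the arms is the 5' or 3' flanking region (`5' mir` /
#' `3' mir`).  On an arm side with no annotated mature product the flanking
#' region extends over the putative star strand and carries the `(mix)`
#' qualifier; a precursor with no mature annotation at all yields
#' `5' mir (mix)` and `3' mir (mix)` split at the transcribed midpoint.
#'
#' Arms shorter than 8 nt get a truncated seed (positions 2 to the arm end)
#' with a warning.  Abutting arms produce no loop segment.  The segments of
#' each precursor are pairwise disjoint and cover it exactly.
#'
#' @param mirnas a [MirnaSet].
#' @return A [GenomicRanges::GRanges] of segments with metadata columns
#'   `premirna_id`, `region` (one of [regionLevels]), `mix` (logical) and
#'   `rank` (1-based 5' to 3' order within the precursor).
#' @export
decomposeMirna <- function(mirnas) {
  stopifnot(is(mirnas, "MirnaSet"))
  validObject(mirnas)
  pre <- precursors(mirnas)
  mat <- matureArms(mirnas)
  out <- vector("list", length(pre))
  for (i in seq_along(pre)) {
    pid <- pre$ID[i]
    ps <- start(pre)[i]; pe <- end(pre)[i]
    minus <- as.character(strand(pre))[i] == "-"
    L <- pe - ps + 1L
    am <- mat[mcols(mat)$Derives_from == pid]
    arms <- if (length(am)) {
      t1 <- .toTranscribed(start(am), ps, pe, minus)
      t2 <- .toTranscribed(end(am), ps, pe, minus)
      data.frame(a = pmin(t1, t2), b = pmax(t1, t2), arm = am$arm)
    } else data.frame(a = integer(), b = integer(), arm = character())
    d <- .decomposeOne(L, arms, pid)
    g <- t(mapply(.toGenomic, d$s, d$e,
                  MoreArgs = list(pstart = ps, pend = pe, minus = minus)))
    out[[i]] <- GRanges(seqnames = as.character(seqnames(pre))[i],
                        ranges = IRanges(g[, 1], g[, 2]),
                        strand = as.character(strand(pre))[i],
                        premirna_id = pid,
                        region = d$region, mix = d$mix,
                        rank = seq_len(nrow(d)))
  }
  res <- suppressWarnings(do.call(c, out))
  names(res) <- NULL
  res
}

#' Locate a genomic position within the substructure map
#'
#' @param segments segment GRanges from [decomposeMirna()].
#' @param chrom,pos chromosome and 1-based position to classify.
#' @return A data.frame with one row per precursor containing the position
#'   (`premirna_id`, `region`, `mix`, `label`); zero rows when the position
#'   falls in no precursor (the caller skips such variants).
#' @export
locateRegion <- function(segments, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos, pos))
  hits <- findOverlaps(q, segments, ignore.strand = TRUE)
  idx <- S4Vectors::subjectHits(hits)
  data.frame(premirna_id = segments$premirna_id[idx],
             region = segments$region[idx],
             mix = segments$mix[idx],
             label = formatRegionLabel(segments$region[idx],
                                       segments$mix[idx]),
             stringsAsFactors = FALSE)
}

#' Export substructure segments as BED6
#'
#' Writes the segment map in BED6 (0-based half-open, per the BED
#' convention); the name field is `<precursor>|<region label>`.
#'
#' @param segments GRanges from [decomposeMirna()].
#' @param path output file.
#' @export
exportSegmentsBed <- function(segments, path) {
  seg <- segments
  mcols(seg) <- NULL
  seg$name <- paste(segments$premirna_id,
                    formatRegionLabel(segments$region, segments$mix),
                    sep = "|")
  seg$score <- 0L
  rtracklayer::export(seg, path, format = "BED")
  invisible(path)
}
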