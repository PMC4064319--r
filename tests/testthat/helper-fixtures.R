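suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Toy two-arm precursor used across tests: plus strand, 1-80, arms 5-26 and
# 50-71 (transcribed == genomic coordinates on the plus strand).
toyMirnaSet <- function(chrom = "chrT", strand = "+") {
  if (strand == "+") {
    pre <- GRanges(chrom, IRanges(1, 80), strand = "+", ID = "toy-mir-1")
    mat <- GRanges(chrom, IRanges(c(5, 50), c(26, 71)), strand = "+",
                   ID = c("toy-miR-1-5p", "toy-miR-1-3p"),
                   Derives_from = "toy-mir-1", arm = c("5p", "3p"))
  } else {
    # strand mirror: transcribed intervals 5-26 / 50-71 map to genomic
    # 55-76 / 10-31 on the minus strand of a 1-80 precursor
    pre <- GRanges(chrom, IRanges(1, 80), strand = "-", ID = "toy-mir-1")
    mat <- GRanges(chrom, IRanges(c(55, 10), c(76, 31)), strand = "-",
                   ID = c("toy-miR-1-5p", "toy-miR-1-3p"),
                   Derives_from = "toy-mir-1", arm = c("5p", "3p"))
  }
  MirnaSet(pre, mat)
}

# Independent per-base labeling oracle in transcribed coordinates.
# arms: named list with optional elements `5p` and `3p`, each c(a, b).
oracleLabels <- function(L, arms) {
  a5 <- arms[["5p"]]; a3 <- arms[["3p"]]
  lab <- character(L); mix <- logical(L)
  for (t in seq_len(L)) {
    if (!is.null(a5) && t >= a5[1] && t <= a5[2]) {
      rel <- t - a5[1] + 1
      lab[t] <- if (rel >= 2 && rel <= 8) "5' seed miR" else "5' rom miR"
    } else if (!is.null(a3) && t >= a3[1] && t <= a3[2]) {
      rel <- t - a3[1] + 1
      lab[t] <- if (rel >= 2 && rel <= 8) "3' seed miR" else "3' rom miR"
    } else if (!is.null(a5) && !is.null(a3) && t > a5[2] && t < a3[1]) {
      lab[t] <- "loop"
    } else if (!is.null(a5) && !is.null(a3)) {
      lab[t] <- if (t < a5[1]) "5' mir" else "3' mir"
    } else if (!is.null(a5)) {
      if (t < a5[1]) lab[t] <- "5' mir"
      else { lab[t] <- "3' mir"; mix[t] <- TRUE }
    } else if (!is.null(a3)) {
      if (t < a3[1]) { lab[t] <- "5' mir"; mix[t] <- TRUE }
      else lab[t] <- "3' mir"
    } else {
      if (t <= ceiling(L / 2)) { lab[t] <- "5' mir"; mix[t] <- TRUE }
      else { lab[t] <- "3' mir"; mix[t] <- TRUE }
    }
  }
  data.frame(t = seq_len(L), region = lab, mix = mix)
}

# random precursor geometry for fuzzing (independent of the simulator)
randomToyPrecursor <- function(chrom = "chrF", offset = 0) {
  f5 <- sample(3:12, 1); f3 <- sample(3:12, 1)
  la <- sample(9:24, 1); lb <- sample(9:24, 1)
  lp <- sample(2:15, 1)
  case <- sample(c("both", "5p", "3p", "none"), 1)
  L <- f5 + la + lp + lb + f3
  strand <- sample(c("+", "-"), 1)
  s <- offset + 1L; e <- offset + L
  t5 <- c(f5 + 1, f5 + la)
  t3 <- c(f5 + la + lp + 1, f5 + la + lp + lb)
  gen <- function(tt) if (strand == "+") offset + tt else
    c(e - tt[2] + 1, e - tt[1] + 1)
  pre <- GRanges(chrom, IRanges(s, e), strand = strand, ID = "fuzz-mir")
  arms <- list()
  rows <- NULL
  if (case %in% c("both", "5p")) {
    g <- gen(t5)
    rows <- rbind(rows, data.frame(s = g[1], e = g[2], ID = "fuzz-miR-5p",
                                   arm = "5p"))
    arms[["5p"]] <- t5
  }
  if (case %in% c("both", "3p")) {
    g <- gen(t3)
    rows <- rbind(rows, data.frame(s = g[1], e = g[2], ID = "fuzz-miR-3p",
                                   arm = "3p"))
    arms[["3p"]] <- t3
  }
  mat <- if (is.null(rows)) GRanges() else
    GRanges(chrom, IRanges(rows$s, rows$e), strand = strand, ID = rows$ID,
            Derives_from = "fuzz-mir", arm = rows$arm)
  list(set = MirnaSet(pre, mat), L = L, arms = arms, strand = strand,
       start = s, end = e)
}

# build a MirnaCohort directly from a dosage matrix
makeCohort <- function(gt, chrom, pos, ref, alt, population, group,
                       dp = NULL, altFrac = NULL) {
  samples <- sprintf("s%04d", seq_len(ncol(gt)))
  colnames(gt) <- samples
  rr <- GRanges(chrom, IRanges(pos, width = 1), ref = ref, alt = alt,
                known_id = NA_character_, is_novel = NA)
  assays <- list(gt = gt)
  if (!is.null(dp)) { colnames(dp) <- samples; assays$dp <- dp }
  if (!is.null(altFrac)) { colnames(altFrac) <- samples
    assays$altFrac <- altFrac }
  cd <- S4Vectors::DataFrame(population = population, group = group,
                             row.names = samples)
  new("MirnaCohort",
      SummarizedExperiment(assays = assays, rowRanges = rr, colData = cd))
}

# single-precursor MirnaSet covering positions 1..n on chrom (both arms)
spanMirnaSet <- function(chrom = "chr1", L = 100) {
  pre <- GRanges(chrom, IRanges(1, L), strand = "+", ID = "span-mir")
  mat <- GRanges(chrom, IRanges(c(10, 60), c(31, 81)), strand = "+",
                 ID = c("span-miR-5p", "span-miR-3p"),
                 Derives_from = "span-mir", arm = c("5p", "3p"))
  MirnaSet(pre, mat)
}

smallPanel <- function(sizes = c(P1 = 30, P2 = 30),
                       groups = c("EUR", "AFR")) {
  data.frame(name = names(sizes), size = unname(sizes),
             F = rep(0.05, length(sizes)), group = groups,
             density = rep(1, length(sizes)), stringsAsFactors = FALSE)
}

writeLinesTmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
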