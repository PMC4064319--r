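# a tiny 3-sample VCF: one SNV inside the span precursor, one outside,
# one multiallelic and one indel inside
.vcfLines <- function() {
  h <- c("##fileformat=VCFv4.2",
         '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
         '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
         '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
         paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sA", "sB", "sC"), collapse = "\t"))
  rec <- function(pos, ref, alt, ...) paste(
    c("chr1", pos, ".", ref, alt, ".", "PASS", ".", "GT:DP:AD", ...),
    collapse = "\t")
  c(h,
    rec(15, "A", "G", "0/1:20:10,10", "0/0:18:18,0", "1/1:22:0,22"),
    rec(500, "C", "T", "0/1:20:10,10", "0/0:20:20,0", "0/0:20:20,0"),
    rec(40, "G", "A,T", "1/2:30:10,10,10", "0/1:30:15,15,0", "./.:.:."),
    rec(70, "AT", "A", "0/1:20:10,10", "0/0:20:20,0", "0/0:20:20,0"))
}

.vcfPanel <- data.frame(sample = c("sA", "sB", "sC"),
                        population = c("P1", "P1", "P2"),
                        group = c("EUR", "EUR", "AFR"))

test_that("VCF ingestion filters to precursors, splits multiallelics, drops indels", {
  vcf <- writeLinesTmp(.vcfLines(), ".vcf")
  ms <- spanMirnaSet()
  cohort <- readCohortVcf(vcf, ms, .vcfPanel)
  rr <- rowRanges(cohort)
  # in-precursor: pos 15 (1 alt) and pos 40 (2 alts); pos 500 outside;
  # pos 70 indel dropped
  expect_equal(start(rr), c(15L, 40L, 40L))
  expect_equal(rr$alt, c("G", "A", "T"))
  log <- metadata(cohort)$filter_log
  expect_equal(log$n[log$step == "alleles_nonsnv_dropped"], 1L)
  expect_equal(log$n[log$step == "snvs_retained"], 3L)
  expect_equal(log$n[log$step == "snvs_outside_precursor"], 1L)
  gt <- assay(cohort, "gt")
  expect_equal(unname(gt[1, ]), c(1L, 0L, 2L))
  # 1/2 call splits into one het per alternative allele; ./. is missing
  expect_equal(unname(gt[2, ]), c(1L, 1L, NA))
  expect_equal(unname(gt[3, ]), c(1L, 0L, NA))
})

test_that("multiallelic split conserves allele counts", {
  vcf <- writeLinesTmp(.vcfLines(), ".vcf")
  cohort <- readCohortVcf(vcf, spanMirnaSet(), .vcfPanel)
  gt <- assay(cohort, "gt")
  # split oracle: at pos 40 the original calls 1/2, 0/1, ./. carry one copy
  # of alt A and one of alt T in genotyped samples
  expect_equal(sum(gt[2, ], na.rm = TRUE) + sum(gt[3, ], na.rm = TRUE), 3L)
})

test_that("samples missing from the panel are an error listing the orphans", {
  vcf <- writeLinesTmp(.vcfLines(), ".vcf")
  expect_error(readCohortVcf(vcf, spanMirnaSet(), .vcfPanel[1:2, ]), "sC")
})

test_that("half calls are treated as missing genotypes", {
  expect_equal(mirvarmap:::.gtDosage(c("0/1", "./1", "1|1", ".", "./."), 1),
               c(1L, NA, 2L, NA, NA))
})

test_that("known-id annotation is allele-aware", {
  gt <- matrix(c(1L, 1L), nrow = 2)
  cohort <- makeCohort(gt, "chr1", c(10, 20), c("A", "C"), c("G", "T"),
                       population = "P1", group = "EUR")
  tab <- data.frame(chrom = "chr1", pos = c(10, 20), ref = c("A", "C"),
                    alt = c("G", "A"), rsid = c("rs1", "rs2"))
  ann <- annotateKnown(cohort, tab)
  rr <- rowRanges(ann)
  expect_equal(rr$known_id, c("rs1", NA))
  # same position, different alt allele stays novel
  expect_equal(rr$is_novel, c(FALSE, TRUE))
  # empty table: everything novel
  ann0 <- annotateKnown(cohort, tab[0, ])
  expect_true(all(rowRanges(ann0)$is_novel))
  # conflicting duplicate ids are rejected
  bad <- rbind(tab, data.frame(chrom = "chr1", pos = 10, ref = "A",
                               alt = "G", rsid = "rs99"))
  tf <- tempfile(); utils::write.table(bad, tf, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  expect_error(readIdTable(tf), "conflicting")
})

test_that("carrier frequencies reproduce the cohort arithmetic", {
  ms <- spanMirnaSet()
  n <- 1152
  mk <- function(n_het, n_hom) {
    g <- matrix(0L, 1, n)
    if (n_het) g[1, seq_len(n_het)] <- 1L
    if (n_hom) g[1, n_het + seq_len(n_hom)] <- 2L
    makeCohort(g, "chr1", 15, "A", "G",
               population = rep("P1", n), group = rep("EUR", n))
  }
  p1 <- profileVariants(mk(261, 40), ms)
  expect_equal(p1$n_carriers, 301L)
  expect_equal(round(p1$pooled_frequency_pct, 4), 26.1285)
  p2 <- profileVariants(mk(1, 0), ms)
  expect_equal(round(p2$pooled_frequency_pct, 4), 0.0868)
  expect_equal(p2$n_het, 1L)
  expect_equal(p2$n_hom_alt, 0L)
})

test_that("zero-carrier variants are excluded and counts partition the cohort", {
  g <- matrix(c(0L, 0L, 0L,
                1L, 2L, NA), nrow = 2, byrow = TRUE)
  cohort <- makeCohort(g, "chr1", c(15, 16), c("A", "C"), c("G", "T"),
                       population = rep("P1", 3), group = rep("EUR", 3))
  p <- profileVariants(cohort, spanMirnaSet())
  expect_equal(nrow(p), 1L)
  expect_equal(p$pos, 16L)
  expect_equal(p$n_het + p$n_hom_alt, p$n_carriers)
  expect_equal(p$n_het + p$n_hom_alt + p$n_missing +
                 (3 - p$n_carriers - p$n_missing), 3)
})

test_that("profiles carry region, mature id, coverage and alt fraction", {
  g <- matrix(c(1L, 0L, 1L), nrow = 1)
  dp <- matrix(c(20, 30, 40), nrow = 1)
  af <- matrix(c(0.45, 0, 0.55), nrow = 1)
  cohort <- makeCohort(g, "chr1", 12, "A", "G",
                       population = c("P1", "P1", "P2"),
                       group = c("EUR", "EUR", "AFR"), dp = dp, altFrac = af)
  p <- profileVariants(cohort, spanMirnaSet())
  # span precursor arm 10-31: position 12 is mature position 3 -> seed
  expect_equal(p$region, "5' seed miR")
  expect_equal(p$mature_id, "span-miR-5p")
  expect_equal(p$mean_coverage, 30)
  expect_equal(p$mean_alt_fraction, 0.5)  # mean over the two het calls
})

test_that("a variant under two overlapping precursors yields two rows", {
  pre <- GRanges("chr1", IRanges(c(1, 50), c(100, 160)), strand = "+",
                 ID = c("mir-a", "mir-b"))
  ms <- MirnaSet(pre)
  g <- matrix(1L, nrow = 1, ncol = 2)
  cohort <- makeCohort(g, "chr1", 60, "A", "G",
                       population = c("P1", "P1"), group = c("EUR", "EUR"))
  p <- profileVariants(cohort, ms)
  expect_equal(nrow(p), 2L)
  expect_setequal(p$premirna_id, c("mir-a", "mir-b"))
})

test_that("region occurrence equals a brute-force tally", {
  set.seed(11)
  sim <- simulateCohort(simulationConfig(
    populations = smallPanel(), n_precursors = 40, site_rate = 0.03,
    seed = 5), tempfile())
  p <- profileVariants(sim$cohort, sim$mirnas)
  occ <- regionOccurrence(p)
  expect_equal(sum(occ$count), nrow(p))
  brute <- table(paste(p$region, p$mix))
  expect_equal(sort(as.integer(brute)), sort(occ$count))
})

test_that("VCF round-trip reproduces positions, alleles and genotypes", {
  sim <- simulateCohort(simulationConfig(
    populations = smallPanel(), n_precursors = 30, site_rate = 0.03,
    seed = 9), tempfile())
  path <- tempfile(fileext = ".vcf")
  writeCohortVcf(sim$cohort, path)
  panel <- data.frame(sample = colnames(sim$cohort),
                      population = colData(sim$cohort)$population,
                      group = colData(sim$cohort)$group)
  back <- readCohortVcf(path, sim$mirnas, panel)
  expect_equal(start(rowRanges(back)), start(rowRanges(sim$cohort)))
  expect_equal(rowRanges(back)$ref, rowRanges(sim$cohort)$ref)
  expect_equal(rowRanges(back)$alt, rowRanges(sim$cohort)$alt)
  expect_equal(assay(back, "gt"), assay(sim$cohort, "gt"))
})
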