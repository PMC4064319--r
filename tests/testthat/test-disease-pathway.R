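# small fixture: 2 populations, 3 variants (2 seed, 1 loop) in 2 precursors
.dpFixture <- function() {
  pre <- GRanges("chr1", IRanges(c(1, 200), c(100, 300)), strand = "+",
                 ID = c("mir-a", "mir-b"))
  mat <- GRanges("chr1", IRanges(c(10, 210), c(31, 231)), strand = "+",
                 ID = c("miR-a-5p", "miR-b-5p"),
                 Derives_from = c("mir-a", "mir-b"), arm = c("5p", "5p"))
  ms <- MirnaSet(pre, mat)
  #            s1  s2  s3  s4   (P1: s1,s2 / P2: s3,s4)
  gt <- rbind(c(1L, 0L, 0L, 0L),   # pos 12, seed of mir-a, P1 only
              c(0L, 1L, 1L, 0L),   # pos 212, seed of mir-b, both pops
              c(0L, 0L, 0L, 2L))   # pos 50, downstream of arm in mir-a, P2
  cohort <- makeCohort(gt, "chr1", c(12, 212, 50),
                       c("A", "C", "G"), c("G", "T", "A"),
                       population = c("P1", "P1", "P2", "P2"),
                       group = c("EUR", "EUR", "AFR", "AFR"))
  list(ms = ms, cohort = cohort,
       profiles = profileVariants(cohort, ms))
}

test_that("shared-variant matrices are symmetric with correct diagonals", {
  fx <- .dpFixture()
  m <- sharedVariantMatrix(fx$cohort, fx$profiles, "all")
  expect_equal(m, t(m))
  expect_equal(diag(m), c(P1 = 2L, P2 = 2L))
  expect_equal(m["P1", "P2"], 1L)   # only the shared mir-b seed site
  ms <- sharedVariantMatrix(fx$cohort, fx$profiles, "seed")
  expect_true(all(ms <= m))
  expect_equal(diag(ms), c(P1 = 2L, P2 = 1L))
  # disjoint site sets give a zero off-diagonal
  gt <- rbind(c(1L, 0L), c(0L, 1L))
  c2 <- makeCohort(gt, "chr1", c(12, 50), c("A", "G"), c("G", "A"),
                   population = c("P1", "P2"), group = c("EUR", "AFR"))
  p2 <- profileVariants(c2, fx$ms)
  m2 <- sharedVariantMatrix(c2, p2, "all")
  expect_equal(m2["P1", "P2"], 0L)
})

test_that("fuzzed shared-variant matrices equal brute-force intersections", {
  sim <- simulateCohort(simulationConfig(
    populations = smallPanel(sizes = c(P1 = 20, P2 = 20, P3 = 20),
                             groups = c("EUR", "ASI", "AFR")),
    n_precursors = 60, site_rate = 0.03, seed = 13), tempfile())
  p <- profileVariants(sim$cohort, sim$mirnas)
  m <- sharedVariantMatrix(sim$cohort, p, "all")
  gt <- assay(sim$cohort, "gt")
  rr <- rowRanges(sim$cohort)
  key <- paste0(seqnames(rr), ":", start(rr), ":", rr$alt)
  popv <- colData(sim$cohort)$population
  for (a in rownames(m)) for (b in colnames(m)) {
    sa <- key[rowSums(gt[, popv == a, drop = FALSE] >= 1, na.rm = TRUE) > 0]
    sb <- key[rowSums(gt[, popv == b, drop = FALSE] >= 1, na.rm = TRUE) > 0]
    expect_equal(m[a, b], length(intersect(sa, sb)))
  }
})

test_that("disease matrix preserves pleiotropy and skips unannotated miRNAs", {
  fx <- .dpFixture()
  dtab <- data.frame(mirna = c("mir-a", "mir-a", "mir-b"),
                     disease = c("d1", "d2", "d3"),
                     category = c("catX", "catY", "catX"))
  m <- populationDiseaseMatrix(fx$cohort, fx$profiles, dtab)
  # P1 carries mir-a (1 site) and mir-b (1 site): catX gets both, catY one
  expect_equal(m["P1", "catX"], 2L)
  expect_equal(m["P1", "catY"], 1L)
  # P2 carries mir-b site and the mir-a loop-side site
  expect_equal(m["P2", "catX"], 2L)
  expect_equal(m["P2", "catY"], 1L)
  # empty table gives a zero matrix
  m0 <- populationDiseaseMatrix(fx$cohort, fx$profiles, dtab[0, ])
  expect_equal(dim(m0), c(2L, 0L))
  # unannotated miRNA contributes nothing
  m1 <- populationDiseaseMatrix(fx$cohort, fx$profiles,
                                dtab[dtab$mirna == "mir-b", ])
  expect_equal(m1["P1", "catX"], 1L)
})

test_that("pathway profile computes percentage of affected pathways per category", {
  fx <- .dpFixture()
  targets <- data.frame(mirna = c("mir-a", "mir-b"),
                        gene = c("g1", "g2"))
  pathways <- data.frame(
    gene = c("g1", "g3", "g4", "g5", "g2"),
    pathway = c("pw1", "pw2", "pw3", "pw4", "pw5"),
    category = c(rep("c4", 4), "c1"))
  m <- pathwayCategoryProfile(fx$cohort, fx$profiles, targets, pathways)
  # P1 seed miRNAs: mir-a, mir-b -> genes g1, g2 -> pw1 (c4, 1 of 4) and
  # pw5 (c1, 1 of 1)
  expect_equal(m["P1", "c4"], 25)
  expect_equal(m["P1", "c1"], 100)
  # P2 seed miRNAs: mir-b only -> g2 -> pw5
  expect_equal(m["P2", "c4"], 0)
  expect_equal(m["P2", "c1"], 100)
  # no seed variants -> all-zero profile
  none <- fx$profiles[!grepl("seed", fx$profiles$region), , drop = FALSE]
  m0 <- pathwayCategoryProfile(fx$cohort, none, targets, pathways)
  expect_true(all(m0 == 0))
})

test_that("hive edge weights marginalize to the matrix entries", {
  fx <- .dpFixture()
  dtab <- data.frame(mirna = c("mir-a", "mir-a", "mir-b"),
                     disease = c("d1", "d2", "d3"),
                     category = c("catX", "catY", "catX"))
  edges <- hiveEdges(fx$cohort, fx$profiles, dtab)
  m <- populationDiseaseMatrix(fx$cohort, fx$profiles, dtab)
  for (pop in rownames(m)) for (cat in colnames(m)) {
    linked <- unique(dtab$mirna[dtab$category == cat])
    ep <- edges$mirna_population
    expect_equal(sum(ep$weight[ep$population == pop & ep$mirna %in% linked]),
                 m[pop, cat])
  }
  # single-miRNA degenerate input: one population edge, one category edge
  one <- fx$profiles[fx$profiles$premirna_id == "mir-b", , drop = FALSE]
  gt1 <- assay(fx$cohort, "gt")[2, , drop = FALSE]
  c1 <- makeCohort(gt1, "chr1", 212, "C", "T",
                   population = c("P1", "P1", "P2", "P2"),
                   group = c("EUR", "EUR", "AFR", "AFR"))
  e1 <- hiveEdges(c1, one, dtab)
  expect_equal(nrow(e1$mirna_population), 2L)  # mir-b in both populations
  expect_equal(nrow(e1$mirna_category), 1L)
  # empty map gives empty edge lists
  e0 <- hiveEdges(fx$cohort, fx$profiles[0, ], dtab)
  expect_equal(nrow(e0$mirna_population), 0L)
  expect_equal(nrow(e0$mirna_category), 0L)
})

test_that("agglomerative ordering merges identical rows first and is deterministic", {
  m <- rbind(a = c(0, 0), b = c(5, 5), c = c(0, 0.1), d = c(9, 9))
  co <- clusterOrder(m)
  # a and c (distance 0.1) merge before anything else
  expect_equal(sort(co$row_tree$merge[1, ]), c(-3, -1))
  # 3-point colinear toy: (0), (1), (3) -> first merge 0 and 1; complete
  # linkage then merges at height 3
  m2 <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("x", "y", "z"), NULL))
  co2 <- clusterOrder(m2)
  expect_equal(sort(co2$row_tree$merge[1, ]), c(-2, -1))
  expect_equal(co2$row_tree$height, c(1, 3))
  # permutation invariance of the merge heights
  perm <- c(3, 1, 2)
  co3 <- clusterOrder(m2[perm, , drop = FALSE])
  expect_equal(co3$row_tree$height, co2$row_tree$height)
  # constant matrix: deterministic order
  mc <- matrix(1, 3, 2)
  expect_equal(clusterOrder(mc)$row_order, clusterOrder(mc)$row_order)
  expect_error(clusterOrder(m[1, , drop = FALSE]), "at least 2 rows")
})
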