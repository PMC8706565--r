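# small SummarizedExperiment straight from a count matrix
seFromCounts <- function(counts, group = NULL, totals = NULL) {
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(group)) cd$group <- group
  if (!is.null(totals)) cd$total_aligned <- totals
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

test_that("CPM normalisation follows count / total x 1e6 and sums to 1e6 per sample", {
  counts <- matrix(c(5L, 15L, 0L, 10L, 20L, 10L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  se <- countsToCPM(seFromCounts(counts))
  cpm <- SummarizedExperiment::assay(se, "cpm")
  expect_equal(cpm["a", "s1"], 250000)
  expect_equal(cpm["c", "s1"], 0)
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-6)

  # explicit totals (species outside the matrix in the denominator)
  se2 <- countsToCPM(seFromCounts(counts), totals = c(40, 80))
  expect_equal(SummarizedExperiment::assay(se2, "cpm")["a", "s1"], 125000)

  zero <- seFromCounts(matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(countsToCPM(zero), "zero total")
})

test_that("abundance filter is strict ('more than 20') and enforced in every sample", {
  counts <- matrix(1L, 3, 2, dimnames = list(c("keep", "edge", "low"), c("s1", "s2")))
  se <- seFromCounts(counts, totals = c(1e6, 1e6))
  SummarizedExperiment::assays(se)$cpm <- matrix(
    c(25, 25, 20, 25, 5, 25), nrow = 3, byrow = TRUE,
    dimnames = dimnames(counts))
  f <- filterAbundance(se, threshold = 20)
  expect_identical(rownames(f), "keep")       # 20 exactly and 5 both drop

  fmean <- filterAbundance(se, threshold = 20, perSample = FALSE)
  expect_identical(rownames(fmean), c("keep", "edge"))  # mean 22.5 > 20

  f0 <- filterAbundance(se, threshold = 0)
  expect_identical(nrow(f0), 3L)
})

test_that("relative expression is the ratio of group mean CPM to control mean CPM", {
  counts <- matrix(1L, 1, 4, dimnames = list("sp", paste0("s", 1:4)))
  se <- seFromCounts(counts, group = c("ctrl", "ctrl", "d1", "d2"))
  SummarizedExperiment::assays(se)$cpm <- matrix(
    c(18, 22, 30, 10), 1, dimnames = dimnames(counts))
  fc <- relativeExpression(se, "ctrl")
  expect_equal(fc$fc_ctrl, 1)
  expect_equal(fc$fc_d1, 1.5)    # 30 / mean(18, 22)
  expect_equal(fc$fc_d2, 0.5)
  expect_error(relativeExpression(se, "nope"), "not present")
})

test_that("the 1.5-fold screen applies symmetric thresholds with a consistent-direction intersection", {
  fc <- data.frame(
    species = c("down_all", "down_mixed", "up_all", "weak"),
    fc_ctrl = 1,
    fc_a = c(0.60, 0.60, 1.6, 1.2),
    fc_b = c(0.62, 0.60, 1.6, 1.3),
    fc_c = c(0.50, 0.80, 1.6, 0.9),
    fc_d = c(0.55, 0.50, 1.6, 1.0))
  attr(fc, "controlGroup") <- "ctrl"
  sc <- screenFoldChange(fc, factor = 1.5)
  tab <- screenTable(sc)
  expect_identical(tab$direction,
                   c("down", "mixed", "up", "none"))
  expect_identical(intersectionSpecies(sc), c("down_all", "up_all"))
  # 0.80 > 1/1.5 breaks the intersection for down_mixed
  expect_false(tab$in_intersection[tab$species == "down_mixed"])
  # Venn consistency: intersection within every per-dose pass set
  for (s in perDoseSets(sc))
    expect_true(all(intersectionSpecies(sc) %in% s))
})

test_that("the screen is invariant to global CPM rescaling", {
  dp <- doseResponseParams(replicates = 2, dispersion = 0.05)
  se <- simulateExpressionMatrix(nSpecies = 60, doseParams = dp, nUp = 5,
                                 nDown = 4, seed = 21)
  se <- countsToCPM(se)
  fc1 <- relativeExpression(se, "0")
  se2 <- se
  SummarizedExperiment::assays(se2)$cpm <-
    SummarizedExperiment::assay(se, "cpm") * 37.5
  fc2 <- relativeExpression(se2, "0")
  s1 <- screenFoldChange(fc1)
  s2 <- screenFoldChange(fc2)
  expect_equal(screenTable(s1), screenTable(s2))
})

test_that("planted 2-fold effects at low dispersion are recovered exactly", {
  dp <- doseResponseParams(replicates = 3, dispersion = 0.05)
  se <- simulateExpressionMatrix(nSpecies = 200, doseParams = dp,
                                 nUp = 17, nDown = 9, effectUp = 2,
                                 effectDown = 0.5, seed = 11)
  se <- countsToCPM(se)
  se <- filterAbundance(se, 20)
  sc <- screenFoldChange(relativeExpression(se, "0"))
  tab <- screenTable(sc)
  rd <- SummarizedExperiment::rowData(se)
  expect_setequal(tab$species[tab$in_intersection & tab$direction == "up"],
                  rownames(rd)[rd$planted == "up"])
  expect_setequal(tab$species[tab$in_intersection & tab$direction == "down"],
                  rownames(rd)[rd$planted == "down"])
})

test_that("candidate ranking takes top control counts per direction with deterministic ties", {
  counts <- matrix(rep(c(100L, 100L, 50L, 80L, 70L), 5), nrow = 5,
                   dimnames = list(c("b_up", "a_up", "c_up", "x_down", "y_down"),
                                   paste0("s", 1:5)))
  se <- seFromCounts(counts, group = c("0", "1", "2", "3", "4"))
  fc <- data.frame(species = rownames(counts), fc_0 = 1,
                   fc_1 = c(2, 2, 2, 0.4, 0.4), fc_2 = c(2, 2, 2, 0.4, 0.4),
                   fc_3 = c(2, 2, 2, 0.4, 0.4), fc_4 = c(2, 2, 2, 0.4, 0.4))
  attr(fc, "controlGroup") <- "0"
  sc <- screenFoldChange(fc)
  cand <- rankCandidates(sc, se, kUp = 2, kDown = 1)
  # ties at count 100 break lexicographically: a_up before b_up
  expect_identical(cand$species[cand$direction == "up"], c("a_up", "b_up"))
  expect_identical(cand$species[cand$direction == "down"], "x_down")
  expect_false(attr(cand, "clamped"))

  expect_warning(cand2 <- rankCandidates(sc, se, kUp = 2, kDown = 5),
                 "fewer")
  expect_identical(sum(cand2$direction == "down"), 2L)
  expect_true(attr(cand2, "clamped"))
})

test_that("expression matrices built from fragment calls carry counts and totals", {
  rs <- generateReferenceSet(8, 2, 3, seed = 15)
  libs <- lapply(c(a = 31, b = 32), function(s)
    simulateReadLibrary(rs, nReads = 800, seed = s))
  alns <- lapply(libs, function(l) hierarchicalAlign(l$reads, rs))
  calls <- lapply(alns, classifyFragments, refset = rs)
  se <- buildExpressionMatrix(calls, alns,
                              colData = data.frame(group = c("0", "1")))
  counts <- SummarizedExperiment::assay(se, "counts")
  expect_equal(unname(colSums(counts)),
               vapply(calls, nrow, numeric(1), USE.NAMES = FALSE))
  expect_identical(
    unname(SummarizedExperiment::colData(se)$total_aligned),
    vapply(alns, function(a) sum(a$class != "unmapped"), integer(1),
           USE.NAMES = FALSE))
  rd <- SummarizedExperiment::rowData(se)
  expect_true(all(rd$label == paste0(rd$subtype, "-", rd$target)))
})
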