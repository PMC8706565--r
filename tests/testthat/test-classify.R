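test_that("length filter keeps exactly the 14-40 nt window, preserving order", {
  reads <- Biostrings::DNAStringSet(c(
    r13 = strrep("A", 13), r14 = strrep("C", 14),
    r40 = strrep("G", 40), r41 = strrep("T", 41)))
  out <- lengthFilter(reads)
  expect_identical(names(out$reads), c("r14", "r40"))
  expect_identical(out$dropped, 2L)

  empty <- lengthFilter(Biostrings::DNAStringSet())
  expect_identical(length(empty$reads), 0L)
  expect_identical(empty$dropped, 0L)

  all30 <- lengthFilter(Biostrings::DNAStringSet(rep(strrep("A", 30), 5)))
  expect_identical(length(all30$reads), 5L)
})

test_that("single-read alignment handles exact, one-mismatch and unmatchable reads", {
  rs <- tinyRefSet()
  mat <- matureSeqs(rs)
  read <- refSub(mat, "Glu-TTC-003", 0, 29)
  hit <- alignOneMismatch(read, mat)
  expect_equal(hit[c("target", "start", "end", "mismatches")],
               list(target = "Glu-TTC-003", start = 0L, end = 29L,
                    mismatches = 0L))

  hit1 <- alignOneMismatch(mutateAt(read, 10), mat)
  expect_equal(hit1$mismatches, 1L)
  expect_equal(hit1$start, 0L)

  # distance >= 2 from every window (verified by the oracle) -> no hit
  far <- mutateAt(mutateAt(read, 10), 20)
  expect_null(oracleBest(far, mat))
  expect_null(alignOneMismatch(far, mat))
})

test_that("alignment equals the brute-force all-window Hamming oracle with identical tie-breaks", {
  set.seed(77)
  refs <- generateReferenceSet(nTRNA = 20, nPre = 0, nMiRNA = 0, seed = 20)
  mat <- matureSeqs(refs)
  reads <- character(500)
  for (i in 1:500) {
    kind <- i %% 4
    if (kind == 0) {
      reads[i] <- randomReads(1, 14:36, seed = 1000 + i)
    } else {
      src <- sample(length(mat), 1)
      L <- sample(14:36, 1)
      st <- sample(0:(Biostrings::width(mat)[src] - L), 1)
      r <- refSub(mat, src, st, st + L)
      if (kind == 2) r <- mutateAt(r, sample(L, 1))
      if (kind == 3) r <- mutateAt(mutateAt(r, 1), 3)
      reads[i] <- r
    }
  }
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(reads), refs)
  for (i in seq_len(500)) {
    ob <- oracleBest(reads[i], mat)
    if (is.null(ob)) {
      expect_identical(aln$class[i], "unmapped")
    } else {
      expect_identical(aln$target[i], ob$target)
      expect_identical(aln$start[i], as.integer(ob$start))
      expect_identical(aln$mismatches[i], as.integer(ob$mismatches))
    }
  }
})

test_that("the tier hierarchy prefers mature, then precursor, then miRNA", {
  rs <- tinyRefSet()
  # a read present verbatim in both the mature tRNA and the miRNA tier
  shared <- refSub(matureSeqs(rs), "Glu-TTC-003", 0, 22)
  rs2 <- ReferenceSet(
    mature = matureSeqs(rs), annotation = loopAnnotation(rs),
    precursor = precursorSeqs(rs), precursorMap = precursorMap(rs),
    mirna = Biostrings::DNAStringSet(c(`mmu-miR-0002` = shared)))
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = shared)), rs2)
  expect_identical(aln$class, "mature")

  # read only in the precursor 3' trailer
  trailer <- refSub(precursorSeqs(rs), "pre-Glu-TTC-003", 78, 95)
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = trailer)), rs)
  expect_identical(aln$class, "precursor")
  expect_gt(aln$end, precursorMap(rs)$mature_end)

  # miRNA-only read
  mir <- as.character(mirnaSeqs(rs)[[1]])
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = mir)), rs)
  expect_identical(aln$class, "mirna")

  # unmatchable read
  junk <- strrep("AC", 15)
  if (is.null(oracleBest(junk, matureSeqs(rs))) &&
      is.null(oracleBest(junk, precursorSeqs(rs))) &&
      is.null(oracleBest(junk, mirnaSeqs(rs)))) {
    aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = junk)), rs)
    expect_identical(aln$class, "unmapped")
  }
})

test_that("precursor hits inside the embedded mature interval are re-credited to the mature reference", {
  # mature reference differs at two positions from the precursor's embedded
  # body, so the read reaches the precursor tier, lands inside the mature
  # interval and is shifted onto the mature coordinate system
  set.seed(5)
  body <- paste(sample(c("A", "C", "G", "T"), 73, replace = TRUE), collapse = "")
  matSeq <- mutateAt(mutateAt(paste0(body, "CCA"), 20), 25)
  pre <- paste0(strrep("T", 10), body, strrep("G", 10))
  rs <- ReferenceSet(
    mature = Biostrings::DNAStringSet(c(m1 = matSeq)),
    annotation = data.frame(id = "m1", acloop_start = 31, acloop_end = 38,
                            anticodon_start = 33, anticodon_end = 36),
    precursor = Biostrings::DNAStringSet(c(p1 = pre)),
    precursorMap = data.frame(id = "p1", mature_start = 10, mature_end = 83,
                              mature_id = "m1"))
  read <- substring(pre, 26, 55)  # positions [25, 55) on the precursor
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = read)), rs)
  expect_identical(aln$class, "mature")
  expect_identical(aln$target, "m1")
  expect_identical(aln$start, 15L)   # 25 - mature_start
  expect_identical(aln$end, 45L)
})

test_that("the subtype decision table follows the anticodon-loop geometry", {
  # loop [31, 38) on a 76-nt mature tRNA
  cases <- data.frame(
    start = c(0L, 0L, 50L, 0L, 0L, 33L, 10L, 0L),
    end = c(34L, 29L, 76L, 15L, 22L, 76L, 34L, 76L),
    expected = c("tiRNA-5", "tRF-5c", "tRF-3", "tRF-5a", "tRF-5b",
                 "tiRNA-3", "tRF-i", "tiRNA-5"))
  # the last case: full-length read starting at 5' with end-1 = 75 outside
  # the loop is 5' -anchored, length 76 -> falls through to tRF-5b
  cases$expected[8] <- "tRF-5b"
  got <- classifySubtype(cases$start, cases$end, matureLength = 76L,
                         loopStart = 31L, loopEnd = 38L)
  expect_identical(got, cases$expected)
})

test_that("fragment calls require annotation and report precursor trailer reads as tRF-1", {
  rs <- tinyRefSet()
  aln <- data.frame(read_id = "r1", class = "mature", target = "Ghost",
                    start = 0L, end = 20L, mismatches = 0L,
                    stringsAsFactors = FALSE)
  expect_error(classifyFragments(aln, rs), "Ghost")

  trailerRead <- refSub(precursorSeqs(rs), "pre-Glu-TTC-003", 75, 93)
  aln <- hierarchicalAlign(Biostrings::DNAStringSet(c(r1 = trailerRead)), rs)
  calls <- classifyFragments(aln, rs)
  expect_identical(calls$subtype, "tRF-1")
  expect_identical(calls$class, "precursor")
})

test_that("composition summaries partition reads and sum to one", {
  rs <- generateReferenceSet(10, 3, 5, seed = 4)
  lib <- simulateReadLibrary(rs, nReads = 2000, seed = 6)
  aln <- hierarchicalAlign(lib$reads, rs)
  calls <- classifyFragments(aln, rs)
  cs <- summarizeComposition(aln, calls)
  expect_identical(sum(cs$classCounts), nrow(aln))
  expect_equal(sum(cs$classProp), 1, tolerance = 1e-12)
  expect_equal(sum(cs$subtypeProp), 1, tolerance = 1e-12)
  expect_identical(sum(cs$subtypeCounts),
                   sum(calls$class == "mature"))
  expect_equal(colSums(cs$lengthHist[, c("mature", "precursor", "mirna")]),
               c(mature = unname(cs$classCounts["mature"]),
                 precursor = unname(cs$classCounts["precursor"]),
                 mirna = unname(cs$classCounts["mirna"])))
})

test_that("classification is pure: read order does not change per-read results", {
  rs <- generateReferenceSet(8, 2, 3, seed = 5)
  lib <- simulateReadLibrary(rs, nReads = 300, seed = 8)
  fwd <- hierarchicalAlign(lib$reads, rs)
  rev <- hierarchicalAlign(rev(lib$reads), rs)
  rev <- rev[match(fwd$read_id, rev$read_id), ]
  rownames(rev) <- NULL
  expect_identical(fwd, rev)
})

test_that("error-free synthetic libraries recover manifest truth", {
  rs <- generateReferenceSet(20, 5, 10, seed = 7)
  lib <- simulateReadLibrary(rs, nReads = 5000, seed = 3)
  aln <- hierarchicalAlign(lengthFilter(lib$reads)$reads, rs)
  calls <- classifyFragments(aln, rs)
  m <- merge(aln, lib$manifest, by = "read_id", suffixes = c("", ".true"))
  expected <- ifelse(m$class.true == "noise", "unmapped", m$class.true)
  expect_gte(mean(m$class == expected), 0.99)

  cm <- merge(calls, lib$manifest, by = "read_id",
              suffixes = c(".call", ".true"))
  mature <- cm[cm$class.true == "mature", ]
  expect_true(all(mature$subtype.call == mature$subtype.true))
})

test_that("reads with substitution errors still map through the 1-mismatch allowance", {
  rs <- generateReferenceSet(10, 0, 0, seed = 9)
  lib <- simulateReadLibrary(rs, compositionParams(1, 0, 0, 0),
                             nReads = 400, seed = 10, errorRate = 0.01)
  aln <- hierarchicalAlign(lib$reads, rs)
  # per-base error 1% on ~25 nt reads: ~2% of reads carry 2+ errors
  expect_gte(mean(aln$class == "mature"), 0.95)
  expect_gte(sum(aln$mismatches == 1, na.rm = TRUE), 1)
})
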