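#' Retain reads of 14–40 nt
#'
#' The profiling window for serum small RNAs: only reads of 14–40 nt are
#' carried into alignment. Order is preserved.
#'
#' @param reads a [Biostrings::DNAStringSet] (or character vector).
#' @param minLen,maxLen inclusive length bounds.
#' @return list with `reads` (retained, original order) and `dropped`
#'   (count removed).
#' @export
lengthFilter <- function(reads, minLen = 14, maxLen = 40) {
  reads <- as(reads, "DNAStringSet")
  w <- Biostrings::width(reads)
  keep <- w >= minLen & w <= maxLen
  list(reads = reads[keep], dropped = sum(!keep))
}

#' Best one-mismatch placement of a read on an ordered reference set
#'
#' Scans every offset of every reference for a full-length ungapped
#' placement with Hamming distance at most 1 (no indels, no
#' soft-clipping, sense strand only). Among qualifying placements the
#' best hit prefers fewer mismatches, then a smaller start coordinate,
#' then the earlier reference in set order.
#'
#' @param read a single sequence (character or DNAString).
#' @param refs named [Biostrings::DNAStringSet] (or named character
#'   vector) in file order.
#' @param maxMismatch maximum Hamming distance (default 1).
#' @return `NULL` if no placement qualifies, else a list with `target`,
#'   `start`, `end` (0-based half-open) and `mismatches`.
#' @export
alignOneMismatch <- function(read, refs, maxMismatch = 1) {
  seq <- as.character(read)
  if (!length(refs)) return(NULL)
  hits <- .scanAllHits(seq, as.character(refs), as.integer(maxMismatch))
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(hits$mm, hits$start0, hits$ref), , drop = FALSE][1, ]
  list(target = names(refs)[best$ref], start = best$start0,
       end = best$start0 + nchar(seq), mismatches = best$mm)
}

#' Hierarchical one-mismatch alignment: mature, then precursor, then miRNA
#'
#' Each read is tried against the mature tRNA references first; only reads
#' without a qualifying placement proceed to the precursor tier, then to
#' the miRNA tier; the rest are unmapped. Exactly one alignment record is
#' produced per read. A precursor hit falling entirely within the
#' embedded mature interval is re-credited to the corresponding mature
#' reference with coordinates shifted onto it (when the mature partner is
#' known and present).
#'
#' Duplicate read sequences are aligned once and the result reused, so the
#' per-read classification is pure and independent of input order.
#'
#' @param reads named [Biostrings::DNAStringSet] (names become `read_id`).
#' @param refset a [ReferenceSet-class].
#' @param maxMismatch maximum Hamming distance per placement (default 1).
#' @return `data.frame`: `read_id`, `class`
#'   (`mature`/`precursor`/`mirna`/`unmapped`), `target`, `start`, `end`
#'   (0-based half-open), `mismatches`.
#' @export
hierarchicalAlign <- function(reads, refset, maxMismatch = 1) {
  reads <- as(reads, "DNAStringSet")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  seqs <- as.character(reads)
  uniq <- unique(seqs)
  nu <- length(uniq)
  mat <- matureSeqs(refset)
  pre <- precursorSeqs(refset)
  mir <- mirnaSeqs(refset)
  pmap <- precursorMap(refset)

  cls <- rep("unmapped", nu)
  target <- rep(NA_character_, nu)
  start <- end <- mm <- rep(NA_integer_, nu)
  len <- nchar(uniq)

  fillTier <- function(pending, refs, class) {
    h <- .scanReads(uniq[pending], as.character(refs), as.integer(maxMismatch))
    hit <- h$ref > 0L
    i <- pending[hit]
    cls[i] <<- class
    target[i] <<- names(refs)[h$ref[hit]]
    start[i] <<- h$start0[hit]
    end[i] <<- h$start0[hit] + len[i]
    mm[i] <<- h$mm[hit]
    pending[!hit]
  }

  pending <- seq_len(nu)
  pending <- fillTier(pending, mat, "mature")
  if (length(pre) && length(pending)) {
    pending <- fillTier(pending, pre, "precursor")
    # precursor hits entirely inside the embedded mature portion are
    # re-credited to the corresponding mature reference, coordinate-shifted
    ip <- which(cls == "precursor")
    if (length(ip) && nrow(pmap)) {
      pi <- match(target[ip], pmap$id)
      inside <- !is.na(pi) & !is.na(pmap$mature_id[pi]) &
        pmap$mature_id[pi] %in% names(mat) &
        start[ip] >= pmap$mature_start[pi] & end[ip] <= pmap$mature_end[pi]
      i <- ip[inside]
      if (length(i)) {
        shift <- as.integer(pmap$mature_start[pi[inside]])
        cls[i] <- "mature"
        target[i] <- pmap$mature_id[pi[inside]]
        start[i] <- start[i] - shift
        end[i] <- end[i] - shift
      }
    }
  }
  if (length(mir) && length(pending))
    pending <- fillTier(pending, mir, "mirna")

  idx <- match(seqs, uniq)
  data.frame(
    read_id = names(reads),
    class = cls[idx],
    target = target[idx],
    start = start[idx],
    end = end[idx],
    mismatches = mm[idx],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign a tsRNA subtype from mature-tRNA alignment coordinates
#'
#' Decision table, evaluated top-down, with `L = end - start` the fragment
#' length, `M` the mature tRNA length and `[loopStart, loopEnd)` the
#' anticodon loop:
#'
#' 1. starts at the 5' end and ends inside the loop -> `tiRNA-5`;
#' 2. starts at the 5' end, ends at/before the loop, `L >= 28` -> `tRF-5c`;
#' 3. starts at the 5' end, `14 <= L <= 16` -> `tRF-5a`;
#' 4. starts at the 5' end otherwise -> `tRF-5b`;
#' 5. ends at the mature 3' terminus (CCA) and starts inside the loop ->
#'    `tiRNA-3`;
#' 6. ends at the mature 3' terminus otherwise -> `tRF-3`;
#' 7. otherwise -> `tRF-i`.
#'
#' All arguments are vectorised.
#'
#' @param start,end 0-based half-open alignment interval on the mature
#'   sequence.
#' @param matureLength mature tRNA length `M`.
#' @param loopStart,loopEnd 0-based half-open anticodon-loop interval.
#' @return character vector of subtypes.
#' @export
classifySubtype <- function(start, end, matureLength, loopStart, loopEnd) {
  L <- end - start
  last <- end - 1L
  out <- rep("tRF-i", length(start))
  at5 <- start == 0L
  at3 <- end == matureLength
  out[at5] <- "tRF-5b"
  out[at5 & L >= 14 & L <= 16] <- "tRF-5a"
  out[at5 & end <= loopStart & L >= 28] <- "tRF-5c"
  out[at5 & last >= loopStart & last < loopEnd] <- "tiRNA-5"
  cond3 <- !at5 & at3
  out[cond3] <- "tRF-3"
  out[cond3 & start >= loopStart & start < loopEnd] <- "tiRNA-3"
  out
}

#' Call fragment subtypes for a table of alignments
#'
#' Produces one [FragmentCall][classifyFragments] row per mature-class
#' alignment using the anticodon-loop annotation, and one `tRF-1` row per
#' precursor-class alignment overlapping the 3' trailer (reported with
#' class `precursor`, outside the mature subtype tally). miRNA, unmapped
#' and leader-overlap precursor alignments yield no call.
#'
#' @param alignments `data.frame` from [hierarchicalAlign()].
#' @param refset the [ReferenceSet-class] used for alignment.
#' @return `data.frame`: `read_id`, `target_id`, `class`, `subtype`,
#'   `start`, `end`, `length`.
#' @export
classifyFragments <- function(alignments, refset) {
  ann <- loopAnnotation(refset)
  mat <- matureSeqs(refset)
  pmap <- precursorMap(refset)
  out <- list()

  m <- alignments[alignments$class == "mature", , drop = FALSE]
  if (nrow(m)) {
    ai <- match(m$target, ann$id)
    if (anyNA(ai))
      stop("no anticodon-loop annotation for target(s): ",
           paste(unique(m$target[is.na(ai)]), collapse = ", "))
    M <- Biostrings::width(mat)[match(m$target, names(mat))]
    sub <- classifySubtype(m$start, m$end, M,
                           ann$acloop_start[ai], ann$acloop_end[ai])
    out$mature <- data.frame(read_id = m$read_id, target_id = m$target,
                             class = "mature", subtype = sub,
                             start = m$start, end = m$end,
                             length = m$end - m$start,
                             stringsAsFactors = FALSE)
  }

  p <- alignments[alignments$class == "precursor", , drop = FALSE]
  if (nrow(p) && nrow(pmap)) {
    pe <- pmap$mature_end[match(p$target, pmap$id)]
    trf1 <- !is.na(pe) & p$end > pe
    p <- p[trf1, , drop = FALSE]
    if (nrow(p))
      out$trf1 <- data.frame(read_id = p$read_id, target_id = p$target,
                             class = "precursor", subtype = "tRF-1",
                             start = p$start, end = p$end,
                             length = p$end - p$start,
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_id = character(), target_id = character(),
                      class = character(), subtype = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise library composition
#'
#' Read counts and proportions per alignment class, subtype counts and
#' proportions among mature-tRNA fragments, and per-class length
#' histograms over 14–40 nt.
#'
#' @param alignments `data.frame` from [hierarchicalAlign()].
#' @param calls `data.frame` from [classifyFragments()].
#' @return list with `classCounts`, `classProp` (both named over
#'   mature/precursor/mirna/unmapped), `subtypeCounts`, `subtypeProp`
#'   (among mature calls), and `lengthHist` (`data.frame` length x class
#'   counts).
#' @export
summarizeComposition <- function(alignments, calls) {
  lev <- c("mature", "precursor", "mirna", "unmapped")
  cls <- factor(alignments$class, levels = lev)
  classCounts <- table(cls)
  n <- nrow(alignments)
  classProp <- if (n > 0) classCounts / n else classCounts * NA_real_

  msub <- calls$subtype[calls$class == "mature"]
  slev <- c("tRF-5a", "tRF-5b", "tRF-5c", "tiRNA-5", "tiRNA-3", "tRF-3", "tRF-i")
  subtypeCounts <- table(factor(msub, levels = slev))
  subtypeProp <- if (length(msub) > 0) subtypeCounts / length(msub) else
    subtypeCounts * NA_real_

  len <- alignments$end - alignments$start
  # unmapped reads have no coordinates; histogram covers mapped classes
  hist <- matrix(0L, nrow = 27, ncol = 3,
                 dimnames = list(14:40, c("mature", "precursor", "mirna")))
  for (cl in colnames(hist)) {
    l <- len[alignments$class == cl]
    l <- l[l >= 14 & l <= 40]
    t <- table(factor(l, levels = 14:40))
    hist[, cl] <- as.integer(t)
  }
  list(classCounts = c(classCounts), classProp = c(classProp),
       subtypeCounts = c(subtypeCounts), subtypeProp = c(subtypeProp),
       lengthHist = data.frame(length = 14:40, hist, check.names = FALSE,
                               row.names = NULL))
}
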