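#' Construct a ReferenceSet
#'
#' Assemble mature tRNA, precursor tRNA and miRNA references into a
#' [ReferenceSet-class]. Sequences are kept in input order (used downstream
#' for alignment tie-breaking).
#'
#' @param mature named [Biostrings::DNAStringSet] (or named character
#'   vector) of mature tRNA sequences, 3' CCA included.
#' @param annotation `data.frame` with columns `id`, `acloop_start`,
#'   `acloop_end`, `anticodon_start`, `anticodon_end`, 0-based half-open on
#'   the mature sequence.
#' @param precursor named [Biostrings::DNAStringSet] of precursor tRNAs
#'   (may be empty).
#' @param precursorMap `data.frame` with columns `id`, `mature_start`,
#'   `mature_end`, `mature_id` (may be empty).
#' @param mirna named [Biostrings::DNAStringSet] of miRNAs (may be empty).
#' @param validate if `TRUE` (default) reject sets with any violation
#'   reported by [validateReferenceSet()]; set `FALSE` to build an invalid
#'   set for inspection.
#' @return A [ReferenceSet-class].
#' @examples
#' seq <- paste0(paste(rep("ACGT", 18), collapse = ""), "CCA") # 75 nt
#' rs <- ReferenceSet(
#'   mature = Biostrings::DNAStringSet(c(`Glu-TTC-003` = seq)),
#'   annotation = data.frame(id = "Glu-TTC-003", acloop_start = 31,
#'     acloop_end = 38, anticodon_start = 33, anticodon_end = 36)
#' )
#' matureSeqs(rs)
#' @export
ReferenceSet <- function(mature = Biostrings::DNAStringSet(),
                         annotation = emptyAnnotation(),
                         precursor = Biostrings::DNAStringSet(),
                         precursorMap = emptyPrecursorMap(),
                         mirna = Biostrings::DNAStringSet(),
                         validate = TRUE) {
  obj <- new("ReferenceSet",
    mature = as(mature, "DNAStringSet"),
    annotation = as.data.frame(annotation),
    precursor = as(precursor, "DNAStringSet"),
    precursorMap = as.data.frame(precursorMap),
    mirna = as(mirna, "DNAStringSet"))
  if (validate) {
    v <- validateReferenceSet(obj)
    if (nrow(v) > 0)
      stop("invalid ReferenceSet:\n", paste0("  - ", v$problem, collapse = "\n"))
  }
  obj
}

emptyAnnotation <- function() {
  data.frame(id = character(), acloop_start = integer(), acloop_end = integer(),
             anticodon_start = integer(), anticodon_end = integer(),
             stringsAsFactors = FALSE)
}

emptyPrecursorMap <- function() {
  data.frame(id = character(), mature_start = integer(), mature_end = integer(),
             mature_id = character(), stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("matureSeqs", "ReferenceSet", function(x) x@mature)
#' @rdname accessors
#' @export
setMethod("precursorSeqs", "ReferenceSet", function(x) x@precursor)
#' @rdname accessors
#' @export
setMethod("mirnaSeqs", "ReferenceSet", function(x) x@mirna)
#' @rdname accessors
#' @export
setMethod("loopAnnotation", "ReferenceSet", function(x) x@annotation)
#' @rdname accessors
#' @export
setMethod("precursorMap", "ReferenceSet", function(x) x@precursorMap)

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet\n")
  cat(sprintf("  mature tRNA : %d (widths %s)\n", length(object@mature),
              if (length(object@mature)) paste(range(Biostrings::width(object@mature)), collapse = "-") else "-"))
  cat(sprintf("  precursor   : %d\n", length(object@precursor)))
  cat(sprintf("  miRNA       : %d\n", length(object@mirna)))
  cat(sprintf("  annotated   : %d mature ids with anticodon-loop coordinates\n",
              nrow(object@annotation)))
})

#' Read one reference FASTA tier
#'
#' Reads a FASTA file of mature tRNA, precursor tRNA or miRNA sequences.
#' RNA alphabet is normalised to DNA (U -> T) and sequences are
#' uppercased; ids are the header token before the first whitespace;
#' record order is preserved.
#'
#' @param path FASTA file path.
#' @param kind one of `"mature"`, `"precursor"`, `"mirna"` (controls error
#'   messages only; tier-specific invariants are checked by
#'   [validateReferenceSet()]).
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
readReferenceFasta <- function(path, kind = c("mature", "precursor", "mirna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("%s FASTA not found: %s", kind, path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop(sprintf("empty %s FASTA: %s", kind, path))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop(sprintf("%s FASTA has a record with an empty id", kind))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate id(s) in %s FASTA: %s", kind, paste(dup, collapse = ", ")))
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop(sprintf("non-nucleotide characters in %s record(s): %s",
                 kind, paste(ids[bad], collapse = ", ")))
  if (any(nchar(seqs) == 0))
    stop(sprintf("empty sequence in %s record(s): %s",
                 kind, paste(ids[nchar(seqs) == 0], collapse = ", ")))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read the tRNA structural annotation sidecar
#'
#' Tab-delimited table with header `id`, `acloop_start`, `acloop_end`,
#' `anticodon_start`, `anticodon_end`; all coordinates 0-based half-open on
#' the mature sequence. When `mature` is supplied every annotation id must
#' exist in the FASTA and every interval is validated against the mature
#' tRNA invariants (7-nt loop, 3-nt anticodon strictly inside, loop inside
#' the sequence).
#'
#' @param path TSV file path.
#' @param mature optional named [Biostrings::DNAStringSet] of mature tRNAs
#'   to validate against.
#' @return `data.frame` with the five columns above.
#' @export
readTRNAAnnotation <- function(path, mature = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "acloop_start", "acloop_end", "anticodon_start", "anticodon_end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  ann <- ann[, need]
  for (col in need[-1]) ann[[col]] <- as.integer(ann[[col]])
  if (anyDuplicated(ann$id))
    stop("duplicate annotation id(s): ",
         paste(unique(ann$id[duplicated(ann$id)]), collapse = ", "))
  if (!is.null(mature)) {
    missing <- setdiff(ann$id, names(mature))
    if (length(missing))
      stop("annotation id(s) absent from mature FASTA: ",
           paste(missing, collapse = ", "))
    v <- checkAnnotation(ann, stats::setNames(Biostrings::width(mature), names(mature)))
    if (length(v)) stop("invalid annotation:\n", paste0("  - ", v, collapse = "\n"))
  }
  ann
}

# annotation interval checks against mature lengths; returns violations
checkAnnotation <- function(ann, matureLen) {
  v <- character()
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    L <- matureLen[[r$id]]
    if (r$acloop_end - r$acloop_start != 7L)
      v <- c(v, sprintf("%s: anticodon loop must be 7 nt wide, got %d",
                        r$id, r$acloop_end - r$acloop_start))
    if (!(r$acloop_start > 0 && r$acloop_start < r$acloop_end && r$acloop_end < L))
      v <- c(v, sprintf("%s: loop interval [%d,%d) not strictly inside [0,%d)",
                        r$id, r$acloop_start, r$acloop_end, L))
    if (r$anticodon_end - r$anticodon_start != 3L)
      v <- c(v, sprintf("%s: anticodon must be 3 nt wide", r$id))
    if (!(r$anticodon_start > r$acloop_start && r$anticodon_end < r$acloop_end))
      v <- c(v, sprintf("%s: anticodon [%d,%d) not strictly inside loop [%d,%d)",
                        r$id, r$anticodon_start, r$anticodon_end,
                        r$acloop_start, r$acloop_end))
  }
  v
}

#' Validate a ReferenceSet
#'
#' Checks every domain invariant and returns a report instead of raising:
#' mature tRNAs 60–100 nt ending in CCA with a valid 7-nt anticodon loop
#' and interior 3-nt anticodon; precursor mature intervals within bounds;
#' miRNAs 18–26 nt; ids unique within each tier (uniqueness across tiers
#' is not required).
#'
#' @param refset a [ReferenceSet-class] (possibly built with
#'   `validate = FALSE`).
#' @return `data.frame` with columns `kind`, `id`, `problem`; zero rows
#'   means the set is valid.
#' @export
validateReferenceSet <- function(refset) {
  viol <- function(kind, id, problem)
    data.frame(kind = kind, id = id, problem = problem, stringsAsFactors = FALSE)
  out <- list()
  mat <- refset@mature
  w <- Biostrings::width(mat)
  for (i in seq_along(mat)) {
    id <- names(mat)[i]
    if (w[i] < 60 || w[i] > 100)
      out[[length(out) + 1L]] <- viol("mature", id,
        sprintf("mature '%s': length %d outside [60, 100]", id, w[i]))
    if (substring(as.character(mat[[i]]), w[i] - 2L, w[i]) != "CCA")
      out[[length(out) + 1L]] <- viol("mature", id,
        sprintf("mature '%s': sequence does not end with CCA", id))
  }
  ann <- refset@annotation
  if (nrow(ann)) {
    missing <- setdiff(ann$id, names(mat))
    for (id in missing)
      out[[length(out) + 1L]] <- viol("annotation", id,
        sprintf("annotation id '%s' has no mature sequence", id))
    ok <- ann[ann$id %in% names(mat), , drop = FALSE]
    for (p in checkAnnotation(ok, stats::setNames(w, names(mat))))
      out[[length(out) + 1L]] <- viol("annotation", sub(":.*", "", p), p)
  }
  pm <- refset@precursorMap
  pre <- refset@precursor
  if (nrow(pm)) {
    for (i in seq_len(nrow(pm))) {
      r <- pm[i, ]
      if (!r$id %in% names(pre)) {
        out[[length(out) + 1L]] <- viol("precursor", r$id,
          sprintf("precursor map id '%s' has no precursor sequence", r$id))
        next
      }
      L <- Biostrings::width(pre)[match(r$id, names(pre))]
      if (!(r$mature_start >= 0 && r$mature_start < r$mature_end && r$mature_end <= L))
        out[[length(out) + 1L]] <- viol("precursor", r$id,
          sprintf("precursor '%s': mature interval [%d,%d) outside [0,%d]",
                  r$id, r$mature_start, r$mature_end, L))
    }
  }
  wm <- Biostrings::width(refset@mirna)
  for (i in seq_along(refset@mirna)) {
    if (wm[i] < 18 || wm[i] > 26)
      out[[length(out) + 1L]] <- viol("mirna", names(refset@mirna)[i],
        sprintf("miRNA '%s': length %d outside [18, 26]", names(refset@mirna)[i], wm[i]))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), id = character(), problem = character(),
               stringsAsFactors = FALSE)
}

#' Read a complete reference set from disk
#'
#' @param matureFasta,annotationPath mature tRNA FASTA and its structural
#'   annotation TSV (both required).
#' @param precursorFasta,precursorMapPath optional precursor FASTA and its
#'   mature-interval map TSV (columns `id`, `mature_start`, `mature_end`,
#'   `mature_id`).
#' @param mirnaFasta optional miRNA FASTA.
#' @return A validated [ReferenceSet-class].
#' @export
readReferenceSet <- function(matureFasta, annotationPath,
                             precursorFasta = NULL, precursorMapPath = NULL,
                             mirnaFasta = NULL) {
  mature <- readReferenceFasta(matureFasta, "mature")
  ann <- readTRNAAnnotation(annotationPath, mature)
  precursor <- Biostrings::DNAStringSet()
  pmap <- emptyPrecursorMap()
  if (!is.null(precursorFasta)) {
    precursor <- readReferenceFasta(precursorFasta, "precursor")
    if (is.null(precursorMapPath))
      stop("precursorFasta given without precursorMapPath")
    pmap <- utils::read.delim(precursorMapPath, stringsAsFactors = FALSE)
    need <- c("id", "mature_start", "mature_end", "mature_id")
    if (!all(need %in% names(pmap)))
      stop("precursor map must have columns: ", paste(need, collapse = ", "))
    pmap <- pmap[, need]
  }
  mirna <- if (is.null(mirnaFasta)) Biostrings::DNAStringSet() else
    readReferenceFasta(mirnaFasta, "mirna")
  ReferenceSet(mature, ann, precursor, pmap, mirna)
}

#' Write a reference set to disk
#'
#' Writes `mature.fa`, `annotation.tsv` and, when present,
#' `precursor.fa`, `precursor_map.tsv` and `mirna.fa` under `dir`.
#' [readReferenceSet()] on the written files reproduces ids, sequences and
#' order exactly.
#'
#' @param refset a [ReferenceSet-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeReferenceSet <- function(refset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mature = file.path(dir, "mature.fa"),
             annotation = file.path(dir, "annotation.tsv"))
  Biostrings::writeXStringSet(refset@mature, paths[["mature"]])
  utils::write.table(refset@annotation, paths[["annotation"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(refset@precursor)) {
    paths["precursor"] <- file.path(dir, "precursor.fa")
    paths["precursor_map"] <- file.path(dir, "precursor_map.tsv")
    Biostrings::writeXStringSet(refset@precursor, paths[["precursor"]])
    utils::write.table(refset@precursorMap, paths[["precursor_map"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(refset@mirna)) {
    paths["mirna"] <- file.path(dir, "mirna.fa")
    Biostrings::writeXStringSet(refset@mirna, paths[["mirna"]])
  }
  invisible(paths)
}

#' Coordinate convention converters
#'
#' All intervals are 0-based half-open internally; text reports use
#' 1-based closed coordinates. `toOneBased()` and `toZeroBased()` convert
#' between the two; composing them is the identity.
#'
#' @param start,end 0-based half-open interval.
#' @param first,last 1-based closed interval.
#' @return A list with the converted pair.
#' @examples
#' toOneBased(0, 15)    # first = 1, last = 15
#' toZeroBased(1, 15)   # start = 0, end = 15
#' @export
toOneBased <- function(start, end) list(first = start + 1L, last = end)

#' @rdname toOneBased
#' @export
toZeroBased <- function(first, last) list(start = first - 1L, end = last)
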