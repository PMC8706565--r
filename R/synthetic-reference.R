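# amino-acid / anticodon pairs used to label synthetic tRNA genes
TRNA_ISOTYPES <- data.frame(
  aa = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
         "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"),
  anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "CTG", "TTC", "GCC", "GTG",
                "AAT", "CAA", "CTT", "CAT", "GAA", "AGG", "AGA", "AGT", "CCA",
                "GTA", "AAC"),
  stringsAsFactors = FALSE
)

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference set
#'
#' Builds a seeded, fully synthetic [ReferenceSet-class]: mature tRNAs of
#' 73–90 nt (random body plus the post-transcriptional 3' CCA) carrying a
#' 7-nt anticodon loop starting at position 30 or 31 with the labelled
#' anticodon placed at the loop centre; precursors embedding the first
#' `nPre` mature bodies (without CCA) between random 5' leaders and 3'
#' trailers of 5–20 nt; and miRNAs of 18–26 nt. Identical seeds give
#' byte-identical output.
#'
#' @param nTRNA,nPre,nMiRNA record counts per tier (`nPre <= nTRNA`).
#' @param seed integer RNG seed.
#' @return A validated [ReferenceSet-class].
#' @examples
#' rs <- generateReferenceSet(nTRNA = 5, nPre = 2, nMiRNA = 3, seed = 7)
#' nrow(validateReferenceSet(rs)) == 0
#' @export
generateReferenceSet <- function(nTRNA = 20, nPre = 5, nMiRNA = 10, seed = 1) {
  stopifnot(nTRNA >= 1, nPre >= 0, nMiRNA >= 0, nPre <= nTRNA)
  set.seed(seed)
  iso <- TRNA_ISOTYPES[sample.int(nrow(TRNA_ISOTYPES), nTRNA, replace = nTRNA > nrow(TRNA_ISOTYPES)), ]
  ids <- sprintf("%s-%s-%03d", iso$aa, iso$anticodon, seq_len(nTRNA))

  bodyLen <- sample(70:87, nTRNA, replace = TRUE)   # + CCA -> 73-90 nt
  loopStart <- sample(30:31, nTRNA, replace = TRUE)
  seqs <- character(nTRNA)
  for (i in seq_len(nTRNA)) {
    body <- strsplit(randomDNA(bodyLen[i]), "")[[1]]
    # place the labelled anticodon at the centre of the 7-nt loop
    acStart <- loopStart[i] + 2L                    # 0-based
    body[(acStart + 1L):(acStart + 3L)] <- strsplit(iso$anticodon[i], "")[[1]]
    seqs[i] <- paste0(paste(body, collapse = ""), "CCA")
  }
  mature <- Biostrings::DNAStringSet(seqs)
  names(mature) <- ids
  ann <- data.frame(
    id = ids,
    acloop_start = loopStart,
    acloop_end = loopStart + 7L,
    anticodon_start = loopStart + 2L,
    anticodon_end = loopStart + 5L,
    stringsAsFactors = FALSE
  )

  precursor <- Biostrings::DNAStringSet()
  pmap <- emptyPrecursorMap()
  if (nPre > 0) {
    leader <- sample(5:20, nPre, replace = TRUE)
    trailer <- sample(5:20, nPre, replace = TRUE)
    pseqs <- character(nPre)
    for (i in seq_len(nPre)) {
      matBody <- substr(seqs[i], 1L, bodyLen[i])    # genomic body, no CCA
      pseqs[i] <- paste0(randomDNA(leader[i]), matBody, randomDNA(trailer[i]))
    }
    precursor <- Biostrings::DNAStringSet(pseqs)
    names(precursor) <- paste0("pre-", ids[seq_len(nPre)])
    pmap <- data.frame(
      id = names(precursor),
      mature_start = leader,
      mature_end = leader + bodyLen[seq_len(nPre)],
      mature_id = ids[seq_len(nPre)],
      stringsAsFactors = FALSE
    )
  }

  mirna <- Biostrings::DNAStringSet()
  if (nMiRNA > 0) {
    mlen <- sample(18:26, nMiRNA, replace = TRUE)
    mirna <- Biostrings::DNAStringSet(vapply(mlen, randomDNA, character(1)))
    names(mirna) <- sprintf("mmu-miR-%04d", seq_len(nMiRNA))
  }

  ReferenceSet(mature, ann, precursor, pmap, mirna)
}
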