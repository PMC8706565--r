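# Independent brute-force oracles and tiny fixture builders used across
# the suite. The oracles are deliberately naive pure-R implementations,
# sharing no code with the package internals.

# every placement of `read` on every reference with Hamming distance <=
# maxMismatch, by character-wise window comparison
oracleHits <- function(read, refs, maxMismatch = 1) {
  rchars <- strsplit(read, "")[[1]]
  L <- length(rchars)
  out <- list()
  for (j in seq_along(refs)) {
    s <- strsplit(as.character(refs[[j]]), "")[[1]]
    if (length(s) < L) next
    for (st in 0:(length(s) - L)) {
      mm <- sum(s[(st + 1):(st + L)] != rchars)
      if (mm <= maxMismatch)
        out[[length(out) + 1]] <- data.frame(ref = j, start0 = st, mm = mm)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# best hit under the package's tie order: fewer mismatches, smaller start,
# earlier reference
oracleBest <- function(read, refs, maxMismatch = 1) {
  h <- oracleHits(read, refs, maxMismatch)
  if (is.null(h)) return(NULL)
  h <- h[order(h$mm, h$start0, h$ref), , drop = FALSE][1, ]
  list(target = names(refs)[h$ref], start = h$start0,
       end = h$start0 + nchar(read), mismatches = h$mm)
}

# Mann-Whitney concordance probability (ties count one half)
oracleConcordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# a small hand-built reference set with known coordinates:
# one 76-nt mature tRNA (73-nt body + CCA), loop [31, 38), its precursor
# with a 10-nt leader and 12-nt trailer, and one 22-nt miRNA
tinyRefSet <- function() {
  set.seed(424242)
  body <- paste(sample(c("A", "C", "G", "T"), 73, replace = TRUE),
                collapse = "")
  matSeq <- paste0(body, "CCA")
  leader <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                  collapse = "")
  trailer <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                   collapse = "")
  preSeq <- paste0(leader, body, trailer)
  mirSeq <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                  collapse = "")
  ReferenceSet(
    mature = Biostrings::DNAStringSet(c(`Glu-TTC-003` = matSeq)),
    annotation = data.frame(id = "Glu-TTC-003", acloop_start = 31,
                            acloop_end = 38, anticodon_start = 33,
                            anticodon_end = 36),
    precursor = Biostrings::DNAStringSet(c(`pre-Glu-TTC-003` = preSeq)),
    precursorMap = data.frame(id = "pre-Glu-TTC-003", mature_start = 10,
                              mature_end = 83, mature_id = "Glu-TTC-003"),
    mirna = Biostrings::DNAStringSet(c(`mmu-miR-0001` = mirSeq)))
}

# substring helper on a DNAStringSet element, 0-based half-open
refSub <- function(refs, id, start, end) {
  substring(as.character(refs[[id]]), start + 1, end)
}

randomReads <- function(n, lens, seed) {
  set.seed(seed)
  vapply(sample(lens, n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# mutate one position of a sequence to a different base
mutateAt <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  b[pos] <- setdiff(c("A", "C", "G", "T"), b[pos])[1]
  paste(b, collapse = "")
}
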