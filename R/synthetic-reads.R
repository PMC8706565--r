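#' Composition parameters for the serum read simulator
#'
#' Mixture proportions of read origins and the fragment subtype mix used
#' by [simulateReadLibrary()]. Defaults emulate serum small-RNA libraries:
#' 78% of reads from mature tRNA fragments, 1% from precursor-specific
#' regions, 1% from miRNA and the remainder random-sequence noise, with a
#' tRF-5c-dominant subtype mix (tiRNA-5 at 4.5%) and a bimodal read-length
#' model peaking at 19–24 nt and 28–32 nt.
#'
#' @param fracMature,fracPre,fracMirna origin proportions in `[0, 1]`.
#' @param fracNoise remainder; defaults to `1 - fracMature - fracPre -
#'   fracMirna` and must agree with it within 1e-9 when given.
#' @param subtypeMix named proportions over `tRF-5a`, `tRF-5b`, `tRF-5c`,
#'   `tiRNA-5`, `tRF-3`, `tRF-i`; must sum to 1 within 1e-9.
#' @param lengthPeaks list with `short` and `long` length ranges (inclusive
#'   2-vectors) and `weights` for (short, long, uniform-14–40) components;
#'   applies to noise/precursor reads (mature fragment lengths follow the
#'   subtype-conditional ranges, which produce the same two peaks).
#' @return A `CompositionParams` list.
#' @export
compositionParams <- function(fracMature = 0.78, fracPre = 0.01,
                              fracMirna = 0.01, fracNoise = NULL,
                              subtypeMix = c("tRF-5a" = 0.05, "tRF-5b" = 0.15,
                                             "tRF-5c" = 0.55, "tiRNA-5" = 0.045,
                                             "tRF-3" = 0.12, "tRF-i" = 0.085),
                              lengthPeaks = list(short = c(19, 24),
                                                 long = c(28, 32),
                                                 weights = c(0.45, 0.45, 0.10))) {
  rest <- 1 - fracMature - fracPre - fracMirna
  if (is.null(fracNoise)) fracNoise <- rest
  fr <- c(mature = fracMature, precursor = fracPre, mirna = fracMirna,
          noise = fracNoise)
  if (any(fr < 0) || any(fr > 1))
    stop("composition fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("composition fractions must sum to 1 (got ", sum(fr), ")")
  need <- c("tRF-5a", "tRF-5b", "tRF-5c", "tiRNA-5", "tRF-3", "tRF-i")
  if (!setequal(names(subtypeMix), need))
    stop("subtypeMix must be named over: ", paste(need, collapse = ", "))
  subtypeMix <- subtypeMix[need]
  if (any(subtypeMix < 0) || abs(sum(subtypeMix) - 1) > 1e-9)
    stop("subtypeMix proportions must be non-negative and sum to 1")
  structure(list(fractions = fr, subtypeMix = subtypeMix,
                 lengthPeaks = lengthPeaks),
            class = "CompositionParams")
}

#' Dose-response parameters for planted radiation effects
#'
#' Describes the absorbed-dose design and the planted dose response of
#' selected tsRNA species in synthetic data: which species respond, by
#' which abundance multiplier at each non-control dose, and the log-normal
#' dispersion of species abundance between samples.
#'
#' @param doses absorbed doses in Gy; must contain 0 (the sham control).
#' @param replicates samples per dose group (>= 1).
#' @param responsiveIds character vector of responding species ids
#'   (`"<subtype>-<tRNA id>"`, see [fragmentSpecies()]).
#' @param effect named list (by species id) of abundance multipliers, each
#'   a single value applied at every non-control dose or a vector with one
#'   value per non-control dose; all > 0 (< 1 suppression, > 1 induction).
#' @param dispersion log-normal sd of per-species per-sample abundance
#'   noise.
#' @param abundanceBoost optional base-abundance multiplier for responsive
#'   species (default 1). CPM fold changes are compositional (shares of a
#'   fixed library), so planted species should stay a modest fraction of
#'   total library weight for planted effects to survive normalisation.
#' @return A `DoseResponseParams` list.
#' @export
doseResponseParams <- function(doses = c(0, 0.05, 0.1, 0.5, 1),
                               replicates = 3,
                               responsiveIds = character(),
                               effect = list(),
                               dispersion = 0.05,
                               abundanceBoost = 1) {
  if (!0 %in% doses) stop("dose 0 (sham control) must be present")
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(responsiveIds) != length(effect) && length(effect) > 0 &&
      !all(responsiveIds %in% names(effect)))
    stop("effect must be named by responsiveIds")
  if (any(unlist(effect) <= 0)) stop("effect multipliers must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(doses = doses, replicates = replicates,
                 responsiveIds = responsiveIds, effect = effect,
                 dispersion = dispersion, abundanceBoost = abundanceBoost),
            class = "DoseResponseParams")
}

# effect multiplier for one species at one dose
effectAt <- function(doseParams, species, dose) {
  if (dose == 0 || !species %in% doseParams$responsiveIds) return(1)
  eff <- doseParams$effect[[species]]
  if (is.null(eff)) return(1)
  if (length(eff) == 1L) return(eff)
  nz <- doseParams$doses[doseParams$doses != 0]
  i <- match(dose, nz)
  if (is.na(i)) stop("dose ", dose, " not among non-control doses")
  eff[[i]]
}

#' Enumerate the fragment species of a reference set
#'
#' The simulator's fragment universe: one species per (mature tRNA,
#' subtype), with coordinates fixed deterministically from the anticodon
#' loop annotation so the same species recurs identically across samples.
#' Species ids are `"<subtype>-<tRNA id>"` (e.g. `"tRF-5c-Glu-TTC-003"`),
#' matching the field's fragment naming.
#'
#' @param refset a [ReferenceSet-class].
#' @return `data.frame`: `species`, `target`, `subtype`, `start`, `end`
#'   (0-based half-open on the mature sequence), `length`, `base_weight`
#'   (fixed abundance profile of the reference set, before subtype mix and
#'   planted effects).
#' @export
fragmentSpecies <- function(refset) {
  ann <- loopAnnotation(refset)
  mat <- matureSeqs(refset)
  ann <- ann[match(names(mat), ann$id), , drop = FALSE]
  if (anyNA(ann$id))
    stop("annotation missing for mature id(s): ",
         paste(names(mat)[is.na(ann$id)], collapse = ", "))
  M <- Biostrings::width(mat)
  n <- length(mat)
  subtypes <- c("tRF-5a", "tRF-5b", "tRF-5c", "tiRNA-5", "tRF-3", "tRF-i")
  rows <- vector("list", n * length(subtypes))
  bw <- detLogNormal(n)
  k <- 0L
  for (i in seq_len(n)) {
    acs <- ann$acloop_start[i]; ace <- ann$acloop_end[i]
    len5a <- 14L + (i %% 3L)
    len5b <- min(19L + (i %% 6L), acs - 1L)
    len5c <- min(28L + (i %% max(1L, acs - 28L + 1L)), acs)
    lenti <- acs + 1L + (i %% 3L)
    len3  <- 18L + (i %% 5L)
    starti <- ace + 2L
    leni   <- min(19L + (i %% 6L), M[i] - starti - 1L)
    co <- list("tRF-5a" = c(0L, len5a), "tRF-5b" = c(0L, len5b),
               "tRF-5c" = c(0L, len5c), "tiRNA-5" = c(0L, lenti),
               "tRF-3" = c(M[i] - len3, M[i]), "tRF-i" = c(starti, starti + leni))
    for (s in subtypes) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        species = paste0(s, "-", names(mat)[i]), target = names(mat)[i],
        subtype = s, start = co[[s]][1], end = co[[s]][2],
        length = co[[s]][2] - co[[s]][1], base_weight = bw[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# deterministic log-normal-like abundance profile (LCG; independent of the
# global RNG so the profile is a property of the set size, not the seed)
detLogNormal <- function(n, sdlog = 0.7) {
  s <- 97L
  u <- numeric(n)
  for (i in seq_len(n)) {
    s <- (69069 * s + 1) %% 16777216
    u[i] <- (s + 0.5) / 16777216
  }
  exp(stats::qnorm(u) * sdlog)
}

# sample read lengths from the two-peak mixture
sampleLengths <- function(n, lengthPeaks) {
  if (n == 0) return(integer())
  comp <- sample.int(3, n, replace = TRUE, prob = lengthPeaks$weights)
  out <- integer(n)
  sh <- lengthPeaks$short; lo <- lengthPeaks$long
  out[comp == 1] <- sample(sh[1]:sh[2], sum(comp == 1), replace = TRUE)
  out[comp == 2] <- sample(lo[1]:lo[2], sum(comp == 2), replace = TRUE)
  out[comp == 3] <- sample(14:40, sum(comp == 3), replace = TRUE)
  out
}

#' Simulate one serum small-RNA read library
#'
#' Draws reads from the fragment universe of `refset` under the origin
#' mixture in `comp`, multiplying the abundance of planted responsive
#' species by their effect at `dose` and applying per-species log-normal
#' sample noise. Every read is an exact substring of its source unless
#' `errorRate > 0`, in which case bases are substituted independently (to
#' exercise the 1-mismatch alignment path). Identical seeds and parameters
#' give identical output.
#'
#' Precursor-origin reads overlap the 5' leader (by at least 3 nt) or the
#' 3' trailer (truth subtype `tRF-1`), so they cannot be mapped to the
#' mature tier. miRNA reads are full-length mature miRNAs. Noise reads are
#' uniform random sequence with the two-peak length model.
#'
#' @param refset a [ReferenceSet-class].
#' @param comp a [compositionParams()] object.
#' @param doseParams a [doseResponseParams()] object.
#' @param dose absorbed dose in Gy; must be one of `doseParams$doses`.
#' @param nReads number of reads (>= 1).
#' @param seed integer RNG seed.
#' @param errorRate per-base substitution probability (default 0).
#' @param path optional output file; writes FASTA (or FASTQ with constant
#'   quality `I` if `format = "fastq"`), with the seed recorded in a
#'   leading comment-style record description.
#' @param format `"fasta"` or `"fastq"` (only used when `path` is given).
#' @return list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `manifest` (`data.frame`: `read_id`, `class` in
#'   mature/precursor/mirna/noise, `source_id`, `start`, `end`, `subtype`,
#'   `species`), plus `seed` and `dose`.
#' @export
simulateReadLibrary <- function(refset, comp = compositionParams(),
                                doseParams = doseResponseParams(), dose = 0,
                                nReads = 10000, seed = 1, errorRate = 0,
                                path = NULL, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(nReads >= 1)
  if (!dose %in% doseParams$doses)
    stop("dose ", dose, " not in doseParams$doses")
  frag <- fragmentSpecies(refset)
  if (length(doseParams$responsiveIds)) {
    missing <- setdiff(doseParams$responsiveIds, frag$species)
    if (length(missing))
      stop("responsive species not present in refset: ",
           paste(missing, collapse = ", "))
  }
  set.seed(seed)

  # per-read origin class
  classes <- c("mature", "precursor", "mirna", "noise")
  avail <- c(TRUE, length(precursorSeqs(refset)) > 0,
             length(mirnaSeqs(refset)) > 0, TRUE)
  fr <- comp$fractions
  if (any(fr[!avail] > 0))
    stop("composition assigns mass to an empty reference tier: ",
         paste(classes[!avail & fr > 0], collapse = ", "))
  cls <- sample(classes, nReads, replace = TRUE, prob = fr)

  # mature fragment abundances at this dose
  w <- frag$base_weight * comp$subtypeMix[frag$subtype]
  resp <- frag$species %in% doseParams$responsiveIds
  w[resp] <- w[resp] * doseParams$abundanceBoost
  effs <- vapply(seq_len(nrow(frag)),
                 function(i) effectAt(doseParams, frag$species[i], dose),
                 numeric(1))
  w <- w * effs * stats::rlnorm(nrow(frag), 0, doseParams$dispersion)

  mat <- matureSeqs(refset)
  matChar <- as.character(mat)
  pre <- precursorSeqs(refset)
  preChar <- as.character(pre)
  pmap <- precursorMap(refset)
  mir <- mirnaSeqs(refset)
  mirChar <- as.character(mir)

  nr <- nReads
  seqs <- character(nr)
  man <- data.frame(read_id = sprintf("read_%06d", seq_len(nr)),
                    class = cls, source_id = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    subtype = NA_character_, species = NA_character_,
                    stringsAsFactors = FALSE)

  im <- which(cls == "mature")
  if (length(im)) {
    pick <- sample.int(nrow(frag), length(im), replace = TRUE, prob = w)
    man$source_id[im] <- frag$target[pick]
    man$start[im] <- frag$start[pick]
    man$end[im] <- frag$end[pick]
    man$subtype[im] <- frag$subtype[pick]
    man$species[im] <- frag$species[pick]
    seqs[im] <- substring(matChar[frag$target[pick]],
                          frag$start[pick] + 1L, frag$end[pick])
  }

  ip <- which(cls == "precursor")
  if (length(ip)) {
    pick <- sample.int(length(pre), length(ip), replace = TRUE)
    L <- pmin(pmax(sampleLengths(length(ip), comp$lengthPeaks), 14L), 40L)
    trailerSide <- stats::runif(length(ip)) < 0.5
    for (j in seq_along(ip)) {
      i <- ip[j]
      pid <- names(pre)[pick[j]]
      pm <- pmap[match(pid, pmap$id), ]
      plen <- nchar(preChar[pid])
      if (trailerSide[j] && plen - pm$mature_end >= 3) {
        b <- min(3L + sample.int(6L, 1L) - 1L, plen - pm$mature_end) # 3-8 nt into trailer
        end <- pm$mature_end + b
        start <- max(0L, end - L[j])
        sub <- "tRF-1"
      } else {
        a <- min(3L + sample.int(6L, 1L) - 1L, pm$mature_start)      # 3-8 nt into leader
        start <- pm$mature_start - a
        end <- min(plen, start + L[j])
        sub <- NA_character_
      }
      if (end - start < 14L) end <- min(plen, start + 14L)
      man$source_id[i] <- pid
      man$start[i] <- start
      man$end[i] <- end
      man$subtype[i] <- sub
      seqs[i] <- substring(preChar[pid], start + 1L, end)
    }
  }

  ii <- which(cls == "mirna")
  if (length(ii)) {
    pick <- sample.int(length(mir), length(ii), replace = TRUE)
    man$source_id[ii] <- names(mir)[pick]
    man$start[ii] <- 0L
    man$end[ii] <- nchar(mirChar[pick])
    seqs[ii] <- mirChar[pick]
  }

  ino <- which(cls == "noise")
  if (length(ino)) {
    L <- pmin(pmax(sampleLengths(length(ino), comp$lengthPeaks), 14L), 40L)
    seqs[ino] <- vapply(L, randomDNA, character(1))
  }

  if (errorRate > 0) {
    for (i in seq_len(nr)) {
      b <- strsplit(seqs[i], "")[[1]]
      hit <- which(stats::runif(length(b)) < errorRate)
      for (h in hit) b[h] <- sample(setdiff(c("A", "C", "G", "T"), b[h]), 1L)
      if (length(hit)) seqs[i] <- paste(b, collapse = "")
    }
  }

  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- man$read_id
  if (!is.null(path)) {
    labelled <- reads
    names(labelled)[1] <- paste0(names(labelled)[1],
                                 sprintf(" seed=%d dose=%g", seed, dose))
    if (format == "fasta") {
      Biostrings::writeXStringSet(labelled, path)
    } else {
      qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(labelled)))
      Biostrings::writeXStringSet(labelled, path, format = "fastq",
                                  qualities = qual)
    }
  }
  list(reads = reads, manifest = man, seed = seed, dose = dose)
}
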