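#' Parameters for the qPCR Ct-table simulator
#'
#' Describes a validation qPCR experiment with an exogenous spike-in
#' normaliser (a cel-miR-39 analogue added before extraction): per-target
#' baseline Ct in the control group, spike-in Ct, per-group true relative
#' expression, Gaussian Ct noise and replication.
#'
#' @param targets character vector of panel target ids.
#' @param foldChange per-group true relative expression: a named list
#'   (group label -> single value or named vector per target) or a
#'   targets-by-groups numeric matrix. The control group must be present
#'   (normally all 1).
#' @param controlGroup label of the control group in `foldChange`.
#' @param baselineCt mean target Ct in the control group (scalar or named
#'   per-target vector), cycles.
#' @param spikeCt spike-in Ct, cycles.
#' @param ctSd Gaussian noise sd on target Ct measurements, cycles.
#' @param spikeSd noise sd on the spike-in Ct (defaults to `ctSd`); the
#'   spike-in is measured once per sample, so its error is shared across
#'   that sample's targets.
#' @param nPerGroup replicate samples per group.
#' @return A `QPCRSimParams` list.
#' @export
qpcrSimParams <- function(targets, foldChange, controlGroup = "0",
                          baselineCt = 27, spikeCt = 20, ctSd = 0.2,
                          spikeSd = ctSd, nPerGroup = 6) {
  if (is.matrix(foldChange)) {
    fc <- foldChange
    if (is.null(rownames(fc)) || is.null(colnames(fc)))
      stop("foldChange matrix needs target rownames and group colnames")
  } else {
    groups <- names(foldChange)
    fc <- vapply(groups, function(g) {
      v <- foldChange[[g]]
      if (length(v) == 1L && is.null(names(v))) rep(v, length(targets))
      else as.numeric(v[targets])
    }, numeric(length(targets)))
    if (length(targets) == 1L) fc <- matrix(fc, nrow = 1L, dimnames = list(targets, groups))
    rownames(fc) <- targets
  }
  if (!all(targets %in% rownames(fc)))
    stop("foldChange missing target(s): ",
         paste(setdiff(targets, rownames(fc)), collapse = ", "))
  fc <- fc[targets, , drop = FALSE]
  if (!controlGroup %in% colnames(fc))
    stop("control group '", controlGroup, "' missing from foldChange")
  if (anyNA(fc) || any(fc <= 0)) stop("fold changes must be > 0")
  if (length(baselineCt) == 1L)
    baselineCt <- stats::setNames(rep(baselineCt, length(targets)), targets)
  structure(list(targets = targets, foldChange = fc,
                 controlGroup = controlGroup, baselineCt = baselineCt,
                 spikeCt = spikeCt, ctSd = ctSd, spikeSd = spikeSd,
                 nPerGroup = nPerGroup),
            class = "QPCRSimParams")
}

#' Simulate a qPCR Ct table
#'
#' Generates `Ct(target) = baselineCt - log2(foldChange) + noise` and one
#' spike-in measurement `Ct(spike) = spikeCt + noise` per sample (shared
#' across the sample's targets, as a single spike-in reaction would be).
#' With `ctSd = 0`, applying [deltaDeltaCt()] to the table returns the true
#' fold changes exactly.
#'
#' @param params a [qpcrSimParams()] object.
#' @param seed integer RNG seed.
#' @param path optional TSV output path (columns `sample`, `group`,
#'   `target`, `ct_target`, `ct_spike`).
#' @return list with `ct` (the Ct `data.frame`) and `manifest`
#'   (`data.frame`: `target`, `group`, `true_fold`), plus `seed`.
#' @export
simulateQPCRTable <- function(params, seed = 1, path = NULL) {
  stopifnot(inherits(params, "QPCRSimParams"))
  set.seed(seed)
  groups <- colnames(params$foldChange)
  rows <- list()
  for (g in groups) {
    for (r in seq_len(params$nPerGroup)) {
      sampleId <- sprintf("%s_rep%02d", g, r)
      spike <- params$spikeCt + stats::rnorm(1, 0, params$spikeSd)
      ctT <- params$baselineCt[params$targets] -
        log2(params$foldChange[params$targets, g]) +
        stats::rnorm(length(params$targets), 0, params$ctSd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sampleId, group = g, target = params$targets,
        ct_target = as.numeric(ctT), ct_spike = spike,
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  if (any(ct$ct_target <= 10 | ct$ct_target >= 40))
    warning("simulated target Ct outside (10, 40); check baselineCt/foldChange")
  manifest <- do.call(rbind, lapply(groups, function(g)
    data.frame(target = params$targets, group = g,
               true_fold = params$foldChange[params$targets, g],
               stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL
  if (!is.null(path))
    utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(ct = ct, manifest = manifest, seed = seed)
}

#' Simulate a species-level CPM expression matrix with planted effects
#'
#' Emulates the sequencing-level screen input: `nSpecies` fragment species
#' over a control group and the non-control dose groups of `doseParams`,
#' with `nUp` species planted at `effectUp`-fold increase and `nDown` at
#' `effectDown`-fold decrease in every irradiation group. Per-sample
#' expected counts are `baseline * effect * exp(N(0, dispersion))`, scaled
#' to `libSize` and rounded; baselines are log-uniform (planted species
#' drawn from the high-abundance range, as validated biomarkers are).
#'
#' @param nSpecies total species count.
#' @param doseParams a [doseResponseParams()] object (its `doses`,
#'   `replicates` and `dispersion` are used).
#' @param nUp,nDown planted up-/down-regulated species counts.
#' @param effectUp,effectDown planted fold effects (> 0).
#' @param libSize target total counts per sample.
#' @param seed integer RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` columns `sample`, `group`, `dose`, `replicate`,
#'   and `rowData` columns `planted` (`"up"`/`"down"`/`"none"`) and
#'   `true_effect`.
#' @export
simulateExpressionMatrix <- function(nSpecies = 200,
                                     doseParams = doseResponseParams(),
                                     nUp = 17, nDown = 9,
                                     effectUp = 2, effectDown = 0.5,
                                     libSize = 2e6, seed = 1) {
  stopifnot(nUp + nDown <= nSpecies, effectUp > 0, effectDown > 0)
  set.seed(seed)
  species <- sprintf("sp%04d", seq_len(nSpecies))
  planted <- rep("none", nSpecies)
  idx <- sample.int(nSpecies, nUp + nDown)
  planted[idx[seq_len(nUp)]] <- "up"
  planted[idx[nUp + seq_len(nDown)]] <- "down"
  baseline <- 10^stats::runif(nSpecies, log10(2), log10(10000))
  hi <- planted != "none"
  baseline[hi] <- 10^stats::runif(sum(hi), log10(500), log10(5000))
  effect <- ifelse(planted == "up", effectUp,
                   ifelse(planted == "down", effectDown, 1))

  doses <- sort(unique(doseParams$doses))
  reps <- doseParams$replicates
  nSamp <- length(doses) * reps
  counts <- matrix(0L, nSpecies, nSamp)
  cd <- data.frame(sample = character(nSamp), group = character(nSamp),
                   dose = numeric(nSamp), replicate = integer(nSamp),
                   stringsAsFactors = FALSE)
  scale <- libSize / sum(baseline)
  j <- 0L
  for (d in doses) {
    for (r in seq_len(reps)) {
      j <- j + 1L
      eff <- if (d == 0) 1 else effect
      lam <- baseline * eff * stats::rlnorm(nSpecies, 0, doseParams$dispersion)
      counts[, j] <- as.integer(round(lam * scale))
      cd$sample[j] <- sprintf("d%s_rep%02d", format(d), r)
      cd$group[j] <- format(d)
      cd$dose[j] <- d
      cd$replicate[j] <- r
    }
  }
  rownames(counts) <- species
  colnames(counts) <- cd$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample),
    rowData = S4Vectors::DataFrame(planted = planted, true_effect = effect,
                                   row.names = species))
}
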