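#' Build a species-level expression matrix from fragment calls
#'
#' Aggregates per-sample fragment calls into a species x sample count
#' matrix. A species is the exact fragment identity — target id, subtype
#' and coordinates — since named biomarkers are individual fragments, not
#' parent tRNAs. The per-sample total of aligned reads (any class) is
#' stored for CPM normalisation.
#'
#' @param callsList named list of per-sample call `data.frame`s from
#'   [classifyFragments()]; names are sample ids.
#' @param alignmentsList named list of the matching alignment
#'   `data.frame`s from [hierarchicalAlign()] (used for total aligned
#'   reads per sample).
#' @param colData optional `data.frame` of sample metadata (`dose`,
#'   `group`, ...), one row per sample in `callsList` order.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData` columns `target`, `subtype`, `start`, `end`,
#'   `label` (`"<subtype>-<target>"`), and `colData` including
#'   `total_aligned`.
#' @export
buildExpressionMatrix <- function(callsList, alignmentsList, colData = NULL) {
  stopifnot(length(callsList) == length(alignmentsList))
  samples <- names(callsList)
  if (is.null(samples)) stop("callsList must be named by sample id")
  keyOf <- function(df) paste(df$target_id, df$subtype, df$start, df$end, sep = "|")
  allKeys <- unique(unlist(lapply(callsList, keyOf)))
  counts <- matrix(0L, length(allKeys), length(samples),
                   dimnames = list(allKeys, samples))
  for (s in samples) {
    t <- table(keyOf(callsList[[s]]))
    counts[names(t), s] <- as.integer(t)
  }
  totals <- vapply(alignmentsList,
                   function(a) sum(a$class != "unmapped"), integer(1))
  parts <- strsplit(allKeys, "|", fixed = TRUE)
  rd <- S4Vectors::DataFrame(
    target = vapply(parts, `[`, character(1), 1L),
    subtype = vapply(parts, `[`, character(1), 2L),
    start = as.integer(vapply(parts, `[`, character(1), 3L)),
    end = as.integer(vapply(parts, `[`, character(1), 4L)),
    row.names = allKeys)
  rd$label <- paste0(rd$subtype, "-", rd$target)
  cd <- if (is.null(colData))
    S4Vectors::DataFrame(sample = samples, row.names = samples)
  else S4Vectors::DataFrame(colData, row.names = samples)
  cd$total_aligned <- as.integer(totals[samples])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Counts-per-million normalisation
#'
#' `CPM = count / total aligned reads x 1e6` per sample. The totals are
#' taken from the `total_aligned` column of `colData` when present
#' (so species outside the matrix still count toward the denominator),
#' otherwise from the per-sample column sums, in which case the per-sample
#' CPM over all species sums to 1e6 exactly.
#'
#' @param se a `SummarizedExperiment` with assay `counts`.
#' @param totals optional numeric vector of per-sample totals overriding
#'   the above.
#' @return `se` with a `cpm` assay added.
#' @export
countsToCPM <- function(se, totals = NULL) {
  counts <- SummarizedExperiment::assay(se, "counts")
  if (is.null(totals)) {
    cd <- SummarizedExperiment::colData(se)
    totals <- if ("total_aligned" %in% names(cd)) as.numeric(cd$total_aligned)
      else colSums(counts)
  }
  if (any(totals <= 0))
    stop("zero total aligned reads for sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  SummarizedExperiment::assays(se)$cpm <-
    sweep(counts, 2, totals, "/") * 1e6
  se
}

#' Abundance filter: CPM above threshold in every sample
#'
#' Species are retained only when their CPM strictly exceeds `threshold`
#' in every sample ("more than 20" read strictly, enforced per sample);
#' set `perSample = FALSE` for the mean-CPM variant. Row order is
#' preserved.
#'
#' @param se a `SummarizedExperiment` with a `cpm` assay (see
#'   [countsToCPM()]).
#' @param threshold CPM threshold (default 20).
#' @param perSample if `TRUE` (default) require the criterion in every
#'   sample; otherwise on the per-species mean CPM.
#' @return The filtered `SummarizedExperiment`.
#' @export
filterAbundance <- function(se, threshold = 20, perSample = TRUE) {
  stopifnot(threshold >= 0)
  cpm <- SummarizedExperiment::assay(se, "cpm")
  keep <- if (perSample) apply(cpm > threshold, 1, all)
    else rowMeans(cpm) > threshold
  se[keep, ]
}

#' Relative expression versus the control group
#'
#' Per species, `FC_d` = mean CPM in dose group `d` / mean CPM in the
#' control group (arithmetic group means; single-sample groups — e.g.
#' pooled libraries — are supported).
#'
#' @param se a `SummarizedExperiment` with a `cpm` assay and a `group`
#'   column in `colData`.
#' @param controlGroup label of the control group.
#' @return `data.frame` with `species` and one `fc_<group>` column per
#'   group (control included, identically 1).
#' @export
relativeExpression <- function(se, controlGroup) {
  cd <- SummarizedExperiment::colData(se)
  if (!"group" %in% names(cd)) stop("colData must have a 'group' column")
  groups <- unique(as.character(cd$group))
  if (!controlGroup %in% groups)
    stop("control group '", controlGroup, "' not present")
  cpm <- SummarizedExperiment::assay(se, "cpm")
  gm <- vapply(groups, function(g)
    rowMeans(cpm[, cd$group == g, drop = FALSE]), numeric(nrow(cpm)))
  if (nrow(cpm) == 1L) gm <- matrix(gm, nrow = 1L, dimnames = list(rownames(cpm), groups))
  ctrl <- gm[, controlGroup]
  if (any(ctrl == 0))
    stop("zero control-group mean CPM for species: ",
         paste(rownames(cpm)[ctrl == 0], collapse = ", "))
  fc <- gm / ctrl
  out <- data.frame(species = rownames(cpm), stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("fc_", g)]] <- fc[, g]
  attr(out, "controlGroup") <- controlGroup
  out
}

#' All-dose-group fold-change screen
#'
#' A species passes a dose group when `FC >= factor` (up) or
#' `FC <= 1/factor` (down) — the symmetric 1.5-fold screen on the log
#' scale. The intersection holds species passing in every non-control
#' dose group with a consistent direction; per-dose pass sets (the Venn
#' layers) are retained.
#'
#' @param fc fold-change table from [relativeExpression()].
#' @param factor screening factor (> 1, default 1.5).
#' @param controlGroup control label; defaults to the attribute stored by
#'   [relativeExpression()].
#' @return A [ScreenResult-class].
#' @export
screenFoldChange <- function(fc, factor = 1.5, controlGroup = NULL) {
  stopifnot(factor > 1)
  if (is.null(controlGroup)) controlGroup <- attr(fc, "controlGroup")
  if (is.null(controlGroup)) stop("controlGroup must be given")
  fcCols <- grep("^fc_", names(fc), value = TRUE)
  doseCols <- setdiff(fcCols, paste0("fc_", controlGroup))
  if (!length(doseCols)) stop("need at least one non-control dose group")
  m <- as.matrix(fc[, doseCols, drop = FALSE])
  up <- m >= factor
  down <- m <= 1 / factor
  pass <- up | down
  nUp <- rowSums(up); nDown <- rowSums(down); nd <- length(doseCols)
  direction <- ifelse(nUp == nd, "up",
                ifelse(nDown == nd, "down",
                 ifelse(nUp + nDown > 0, "mixed", "none")))
  inInter <- direction %in% c("up", "down")
  tab <- data.frame(species = fc$species, stringsAsFactors = FALSE)
  for (dc in doseCols) tab[[dc]] <- fc[[dc]]
  for (i in seq_along(doseCols))
    tab[[sub("^fc_", "pass_", doseCols[i])]] <- pass[, i]
  tab$direction <- direction
  tab$in_intersection <- inInter
  perDose <- stats::setNames(
    lapply(seq_along(doseCols), function(i) fc$species[pass[, i]]),
    sub("^fc_", "", doseCols))
  new("ScreenResult", table = tab, perDose = perDose, factor = factor,
      controlGroup = controlGroup)
}

#' @rdname accessors
#' @export
setMethod("screenTable", "ScreenResult", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("intersectionSpecies", "ScreenResult", function(x)
  x@table$species[x@table$in_intersection])
#' @rdname accessors
#' @export
setMethod("perDoseSets", "ScreenResult", function(x) x@perDose)
#' @rdname accessors
#' @export
setMethod("controlGroup", "ScreenResult", function(x) x@controlGroup)

setMethod("show", "ScreenResult", function(object) {
  t <- object@table
  cat(sprintf("ScreenResult: %d species screened at %.2g-fold vs '%s'\n",
              nrow(t), object@factor, object@controlGroup))
  cat(sprintf("  intersection: %d (%d up, %d down)\n",
              sum(t$in_intersection),
              sum(t$direction == "up" & t$in_intersection),
              sum(t$direction == "down" & t$in_intersection)))
})

#' Rank intersection species for validation
#'
#' Within each direction, intersection species are sorted by mean control
#' raw count (descending; ties broken by species id) and the top `kUp`
#' up-regulated and `kDown` down-regulated species are selected — the
#' higher-read-count candidates one would carry into qPCR validation. If a
#' direction holds fewer species than requested, all are returned and the
#' result is flagged.
#'
#' @param screen a [ScreenResult-class].
#' @param se the `SummarizedExperiment` the screen was computed from
#'   (assay `counts`, `group` in `colData`).
#' @param kUp,kDown candidates per direction (defaults 4 and 6).
#' @param controlGroup control label; defaults to the screen's.
#' @return `data.frame`: `species`, `direction`, `mean_control_count`,
#'   `rank`; attribute `clamped` is `TRUE` when a direction was exhausted.
#' @export
rankCandidates <- function(screen, se, kUp = 4, kDown = 6,
                           controlGroup = NULL) {
  if (is.null(controlGroup)) controlGroup <- screen@controlGroup
  cd <- SummarizedExperiment::colData(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  ctrlMean <- rowMeans(counts[, cd$group == controlGroup, drop = FALSE])
  tab <- screen@table[screen@table$in_intersection, , drop = FALSE]
  clamped <- FALSE
  pick <- function(dir, k) {
    s <- tab$species[tab$direction == dir]
    if (length(s) < k) clamped <<- TRUE
    mc <- ctrlMean[s]
    s <- s[order(-mc, s)]
    utils::head(s, k)
  }
  upS <- pick("up", kUp)
  downS <- pick("down", kDown)
  out <- data.frame(
    species = c(upS, downS),
    direction = c(rep("up", length(upS)), rep("down", length(downS))),
    mean_control_count = ctrlMean[c(upS, downS)],
    rank = c(seq_along(upS), seq_along(downS)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (clamped) warning("fewer intersection species than requested; returning all")
  attr(out, "clamped") <- clamped
  out
}
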