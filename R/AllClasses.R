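#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Reference collection for tsRNA classification
#'
#' Holds the three reference tiers used by the hierarchical aligner —
#' mature tRNA (3' CCA included), precursor tRNA (with 5' leader and 3'
#' trailer) and miRNA — together with the anticodon-loop annotation of the
#' mature tRNAs and the mature-interval map of the precursors. All
#' coordinates are stored 0-based half-open; conversion to 1-based closed
#' happens only at text-report boundaries (see [toOneBased()]).
#'
#' @slot mature [Biostrings::DNAStringSet] of mature tRNA sequences, named
#'   by id in amino-acid–anticodon–family form (e.g. `"Glu-TTC-003"`).
#' @slot annotation `data.frame` with columns `id`, `acloop_start`,
#'   `acloop_end`, `anticodon_start`, `anticodon_end` (0-based half-open on
#'   the mature sequence; the anticodon loop is always 7 nt wide and the
#'   3-nt anticodon lies strictly inside it).
#' @slot precursor [Biostrings::DNAStringSet] of precursor tRNA sequences.
#' @slot precursorMap `data.frame` with columns `id`, `mature_start`,
#'   `mature_end`, `mature_id` locating the embedded mature portion
#'   (without the post-transcriptional CCA) inside each precursor;
#'   `mature_id` may be `NA` when the mature partner is unknown.
#' @slot mirna [Biostrings::DNAStringSet] of mature miRNA sequences
#'   (18–26 nt).
#'
#' @seealso [readReferenceSet()], [generateReferenceSet()],
#'   [validateReferenceSet()]
#' @export
setClass("ReferenceSet",
  representation(
    mature       = "DNAStringSet",
    annotation   = "data.frame",
    precursor    = "DNAStringSet",
    precursorMap = "data.frame",
    mirna        = "DNAStringSet"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  ann <- object@annotation
  need <- c("id", "acloop_start", "acloop_end", "anticodon_start", "anticodon_end")
  if (!all(need %in% names(ann)))
    msg <- c(msg, sprintf("annotation must have columns: %s", paste(need, collapse = ", ")))
  pm <- object@precursorMap
  needp <- c("id", "mature_start", "mature_end", "mature_id")
  if (nrow(pm) > 0 && !all(needp %in% names(pm)))
    msg <- c(msg, sprintf("precursorMap must have columns: %s", paste(needp, collapse = ", ")))
  for (slotnm in c("mature", "precursor", "mirna")) {
    nms <- names(slot(object, slotnm))
    if (length(slot(object, slotnm)) > 0 && (is.null(nms) || anyNA(nms) || any(nms == "")))
      msg <- c(msg, sprintf("all %s sequences must be named", slotnm))
    if (anyDuplicated(nms))
      msg <- c(msg, sprintf("duplicate ids in %s set: %s", slotnm,
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Result of the all-dose-group fold-change screen
#'
#' Per-species fold changes against the control group at every irradiation
#' dose, per-dose pass flags at the (symmetric) screening factor, the
#' consistent-direction intersection across all dose groups, and the
#' per-dose pass sets (the layers of the Venn diagram).
#'
#' @slot table `data.frame` with one row per screened species: `species`,
#'   one `fc_<group>` column per non-control group, `direction`
#'   (`"up"`/`"down"`/`"mixed"`/`"none"`), one `pass_<group>` logical per
#'   group, and `in_intersection`.
#' @slot perDose named `list` of character vectors: species passing the
#'   screen in each dose group (either direction).
#' @slot factor numeric screening factor (default 1.5); a species passes a
#'   dose group when FC >= factor (up) or FC <= 1/factor (down).
#' @slot controlGroup label of the control group.
#' @export
setClass("ScreenResult",
  representation(
    table        = "data.frame",
    perDose      = "list",
    factor       = "numeric",
    controlGroup = "character"
  )
)

#' Relative quantification of a qPCR Ct table
#'
#' Per-sample 2^-ddCt relative expression with spike-in normalisation:
#' dCt = Ct(target) - Ct(spike); ddCt = dCt - mean control dCt for the
#' target; RQ = 2^-ddCt. Group-level summaries (mean RQ, standard error,
#' t-test vs control, one-way ANOVA across groups) are attached by
#' [groupStats()].
#'
#' @slot samples `data.frame`: `sample`, `group`, `target`, `ct_target`,
#'   `ct_spike`, `dct`, `ddct`, `rq`.
#' @slot groups `data.frame` of per-(group, target) summaries (empty until
#'   [groupStats()] is called).
#' @slot controlGroup label of the control group used as ddCt reference.
#' @export
setClass("RelQuant",
  representation(
    samples      = "data.frame",
    groups       = "data.frame",
    controlGroup = "character"
  )
)

#' Multi-marker linear exposure-risk model
#'
#' Exposure risk score ERS = beta0 + sum_i beta_i * x_i over the relative
#' expression of a tsRNA marker panel, fitted by ordinary least squares of
#' numeric exposure degree (ED) on marker values, or loaded as a published
#' coefficient fixture (see [ersModel()]).
#'
#' @slot radiationType label (e.g. `"carbon"`, `"xray"`, `"proton"`).
#' @slot markerIds ordered character vector of predictor marker ids.
#' @slot intercept numeric beta0.
#' @slot coefficients named numeric vector of partial regression
#'   coefficients, one per marker, in `markerIds` order.
#' @slot fitInfo list of fit metadata (`n`, `sigma`, `r_squared`; empty
#'   for fixtures).
#' @export
setClass("ERSModel",
  representation(
    radiationType = "character",
    markerIds     = "character",
    intercept     = "numeric",
    coefficients  = "numeric",
    fitInfo       = "list"
  )
)

setValidity("ERSModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@markerIds))
    msg <- c(msg, "number of coefficients must equal number of marker ids")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' ROC curve with AUC and Youden-optimal cutoff
#'
#' Threshold sweep over the score values (plus sentinels), true/false
#' positive rate arrays, trapezoidal AUC (equal to the Mann–Whitney
#' concordance probability, ties counting one half), and the cutoff
#' maximising Youden's J = TPR - FPR with its sensitivity/specificity.
#'
#' @slot thresholds numeric vector of score cutoffs (descending;
#'   `score >= cutoff` predicts positive, after any direction flip).
#' @slot tpr,fpr numeric vectors in `[0, 1]`, non-decreasing along the sweep.
#' @slot auc numeric area under the curve.
#' @slot cutoff numeric Youden-optimal cutoff (on the possibly negated
#'   score scale).
#' @slot sensitivity,specificity numeric rates at the optimal cutoff.
#' @slot direction `"higher"` or `"lower"`: whether higher or lower raw
#'   scores indicate the positive class.
#' @export
setClass("ROCResult",
  representation(
    thresholds  = "numeric",
    tpr         = "numeric",
    fpr         = "numeric",
    auc         = "numeric",
    cutoff      = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    direction   = "character"
  )
)
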