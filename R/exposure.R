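#' Map absorbed doses to ordinal exposure degrees
#'
#' The triage target: ED0 is the sham control (exactly 0 Gy) and the
#' positive degrees partition `(0, max(breaks)]` at the given breakpoints.
#' Defaults give three degrees — ED0 = {0}, ED1 = (0, 0.1] Gy,
#' ED2 = (0.1, 2] Gy — separating low-dose from higher-dose exposure; the
#' partition is fully configurable.
#'
#' @param doses numeric absorbed doses in Gy (>= 0).
#' @param breaks increasing positive breakpoints; degree `k` (k >= 1) is
#'   `(breaks[k-1], breaks[k]]` with `breaks[0] = 0`.
#' @return Ordered factor with levels `ED0 < ED1 < ...`.
#' @examples
#' assignED(c(0, 0.05, 0.1, 0.5, 1))
#' @export
assignED <- function(doses, breaks = c(0.1, 2)) {
  if (any(doses < 0)) stop("doses must be >= 0")
  if (any(diff(breaks) <= 0) || any(breaks <= 0))
    stop("breaks must be positive and strictly increasing")
  if (any(doses > max(breaks)))
    stop("dose(s) above the top break (", max(breaks), " Gy): ",
         paste(unique(doses[doses > max(breaks)]), collapse = ", "))
  k <- findInterval(doses, c(0, breaks), left.open = TRUE)
  levels <- paste0("ED", 0:length(breaks))
  factor(paste0("ED", k), levels = levels, ordered = TRUE)
}

#' Fit the multi-marker linear exposure-risk model
#'
#' Ordinary least squares of numeric exposure degree on the relative
#' expression of the marker panel: `ED ~ beta0 + sum_i beta_i x_i`. The
#' fitted coefficients define the exposure risk score
#' `ERS = beta0 + sum_i beta_i x_i` (see [scoreERS()]). A marker subset
#' may be fitted (panels sometimes drop a predictor). A binary logistic
#' alternative (exposed vs sham) is available via `logistic = TRUE`, in
#' which case the score is the linear predictor.
#'
#' @param x `data.frame` or matrix of marker relative expression, samples
#'   in rows, markers in columns (named).
#' @param ed exposure degrees from [assignED()] (or any numeric response).
#' @param markers optional character subset of column names to fit.
#' @param radiationType label stored on the model.
#' @param logistic fit binomial GLM of (ED > 0) instead of OLS.
#' @return An [ERSModel-class].
#' @export
fitERS <- function(x, ed, markers = NULL, radiationType = "custom",
                   logistic = FALSE) {
  x <- as.data.frame(x)
  if (is.null(markers)) markers <- colnames(x)
  missing <- setdiff(markers, colnames(x))
  if (length(missing))
    stop("marker(s) absent from x: ", paste(missing, collapse = ", "))
  x <- x[, markers, drop = FALSE]
  y <- if (is.factor(ed)) as.numeric(ed) - 1 else as.numeric(ed)
  if (length(y) != nrow(x)) stop("length(ed) must equal nrow(x)")
  if (length(unique(y)) < 2) stop("ed must have at least two distinct levels")
  const <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    stop("constant (non-informative) marker(s): ",
         paste(markers[const], collapse = ", "))
  dat <- data.frame(.y = if (logistic) as.integer(y > 0) else y, x,
                    check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", markers),
                                                collapse = " + ")))
  fit <- if (logistic) stats::glm(form, data = dat, family = stats::binomial())
    else stats::lm(form, data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop("rank-deficient design; collinear marker(s): ",
         paste(gsub("`", "", bad), collapse = ", "))
  }
  info <- list(n = nrow(x), logistic = logistic)
  if (!logistic) {
    # noise-free responses trigger a harmless "essentially perfect fit"
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    info$sigma <- sm$sigma
    info$r_squared <- sm$r.squared
  }
  new("ERSModel", radiationType = radiationType, markerIds = markers,
      intercept = unname(co[1]),
      coefficients = stats::setNames(unname(co[-1]), markers),
      fitInfo = info)
}

#' @rdname accessors
#' @export
setMethod("markerIds", "ERSModel", function(x) x@markerIds)
#' @rdname accessors
#' @export
setMethod("modelIntercept", "ERSModel", function(x) x@intercept)
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "ERSModel", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("radiationType", "ERSModel", function(x) x@radiationType)

setMethod("show", "ERSModel", function(object) {
  cat(sprintf("ERSModel (%s): ERS = %.4g", object@radiationType,
              object@intercept))
  for (i in seq_along(object@markerIds))
    cat(sprintf(" %s %.4g x [%s]",
                ifelse(object@coefficients[i] < 0, "-", "+"),
                abs(object@coefficients[i]), object@markerIds[i]))
  cat("\n")
})

#' Score samples with an exposure-risk model
#'
#' `ERS = beta0 + sum_i beta_i x_i`, exactly linear. `x` may be a single
#' marker vector (named, or positional in `markerIds` order) or a
#' samples-by-markers matrix / data.frame.
#'
#' @param model an [ERSModel-class].
#' @param x marker relative-expression values.
#' @param ... unused.
#' @return Numeric score(s).
#' @examples
#' m <- ersModel("carbon")
#' scoreERS(m, rep(0, 5))   # the model intercept
#' @export
setMethod("scoreERS", "ERSModel", function(model, x, ...) {
  ids <- model@markerIds
  if (is.null(dim(x))) {
    if (!is.null(names(x))) {
      missing <- setdiff(ids, names(x))
      if (length(missing))
        stop("missing marker(s): ", paste(missing, collapse = ", "))
      x <- x[ids]
    } else if (length(x) != length(ids)) {
      stop("expected ", length(ids), " marker values, got ", length(x))
    }
    return(unname(model@intercept + sum(model@coefficients * as.numeric(x))))
  }
  x <- as.data.frame(x)
  missing <- setdiff(ids, colnames(x))
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "))
  as.numeric(model@intercept +
               as.matrix(x[, ids, drop = FALSE]) %*% model@coefficients)
})

#' Published exposure-risk coefficient fixtures
#'
#' Read-only multi-factor model coefficients for carbon-ion, X-ray and
#' proton exposure over the five serum tsRNA biomarkers
#' (tiRNA-Glu-TTC-003, tRF-Val-AAC-024, tRF-Gln-CTG-018, tRF-Lys-CTT-008,
#' tRF-Lys-TTT-019; the X-ray panel uses four of the five). These are
#' usable for scoring without refitting.
#'
#' @param type `"carbon"`, `"xray"` or `"proton"`.
#' @param path optional path to a model JSON (defaults to the fixtures
#'   shipped with the package).
#' @return `ersModel()`: an [ERSModel-class]; `listERSModels()`: the
#'   available fixture names.
#' @export
ersModel <- function(type = c("carbon", "xray", "proton"), path = NULL) {
  type <- match.arg(type)
  if (is.null(path))
    path <- system.file("extdata", "ers_models.json", package = "tsRNAtriage",
                        mustWork = TRUE)
  all <- jsonlite::fromJSON(path)
  if (!type %in% names(all)) stop("no fixture model '", type, "' in ", path)
  m <- all[[type]]
  new("ERSModel", radiationType = m$radiation_type,
      markerIds = names(m$coefficients), intercept = m$intercept,
      coefficients = unlist(m$coefficients), fitInfo = list(source = "fixture"))
}

#' @rdname ersModel
#' @export
listERSModels <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ers_models.json", package = "tsRNAtriage",
                        mustWork = TRUE)
  names(jsonlite::fromJSON(path))
}

#' Write / read an ERSModel as JSON
#'
#' @param model an [ERSModel-class].
#' @param path JSON file path.
#' @return `writeERSModel()` returns `path` invisibly; `readERSModel()`
#'   the model.
#' @export
writeERSModel <- function(model, path) {
  obj <- list(radiation_type = model@radiationType,
              marker_ids = model@markerIds,
              intercept = model@intercept,
              coefficients = as.list(model@coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeERSModel
#' @export
readERSModel <- function(path) {
  m <- jsonlite::fromJSON(path)
  new("ERSModel", radiationType = m$radiation_type,
      markerIds = as.character(m$marker_ids), intercept = m$intercept,
      coefficients = stats::setNames(unlist(m$coefficients)[m$marker_ids],
                                     m$marker_ids),
      fitInfo = list(source = path))
}

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' Sweeps the decision threshold over the observed score values (plus
#' sentinels), computing TPR and FPR at each cutoff (`score >= cutoff`
#' predicts positive) and the trapezoidal AUC, which equals the
#' Mann–Whitney concordance probability with ties counting one half. For
#' markers suppressed by exposure use `direction = "lower"`: scores are
#' negated so that an informative marker yields AUC >= 0.5. The reported
#' cutoff maximises Youden's J = TPR - FPR (first maximum along the
#' sweep).
#'
#' @param scores numeric scores.
#' @param labels binary exposure indicator (0/1, logical, or two-level
#'   factor; the second level is positive).
#' @param direction `"higher"` (default) or `"lower"`: which end of the
#'   score scale indicates the positive class.
#' @return A [ROCResult-class].
#' @examples
#' r <- rocCurve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
#' auc(r)   # 1: perfect separation
#' @export
rocCurve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present in labels")
  s <- if (direction == "lower") -scores else scores
  ord <- order(s, decreasing = TRUE)
  sSorted <- s[ord]; lSorted <- labels[ord]
  # cumulative TP/FP at each distinct threshold
  runs <- rle(sSorted)
  thr <- runs$values
  grpEnd <- cumsum(runs$lengths)
  tp <- cumsum(lSorted)[grpEnd]
  fp <- cumsum(1L - lSorted)[grpEnd]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  thresholds <- c(Inf, thr)
  aucVal <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which.max(j)
  new("ROCResult", thresholds = thresholds, tpr = unname(tpr),
      fpr = unname(fpr), auc = aucVal, cutoff = unname(thresholds[best]),
      sensitivity = unname(tpr[best]), specificity = unname(1 - fpr[best]),
      direction = direction)
}

#' @rdname accessors
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("rocPoints", "ROCResult", function(x)
  data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr))

setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROCResult: AUC %.4f | Youden cutoff %.4g (sens %.3f, spec %.3f), direction: %s\n",
    object@auc, object@cutoff, object@sensitivity, object@specificity,
    object@direction))
})

#' Compare the fitted panel against each single marker
#'
#' Computes the triage AUC (exposed vs sham, or any binary labelling) of
#' the panel ERS and of every marker alone, sorted by AUC descending. The
#' direction of each single marker is chosen from the data (lower values
#' positive when the marker is suppressed in the positive class), as one
#' would orient a down-regulated biomarker; the panel score is always
#' higher-is-positive.
#'
#' @param model an [ERSModel-class].
#' @param x samples-by-markers relative expression (must cover the model's
#'   markers).
#' @param labels binary exposure indicator.
#' @return `data.frame`: `predictor` (`"panel"` or marker id), `auc`,
#'   `direction`, `cutoff`, `sensitivity`, `specificity`; attribute
#'   `panel_is_max` flags whether the panel attains the maximal AUC.
#' @export
comparePanelVsSingle <- function(model, x, labels) {
  x <- as.data.frame(x)
  panelScores <- scoreERS(model, x)
  rows <- list()
  rPanel <- rocCurve(panelScores, labels, "higher")
  rows[["panel"]] <- data.frame(predictor = "panel", auc = rPanel@auc,
                                direction = "higher", cutoff = rPanel@cutoff,
                                sensitivity = rPanel@sensitivity,
                                specificity = rPanel@specificity,
                                stringsAsFactors = FALSE)
  lab <- as.integer(as.logical(if (is.factor(labels)) as.integer(labels) - 1L
                               else labels))
  for (mk in model@markerIds) {
    v <- x[[mk]]
    dir <- if (mean(v[lab == 1L]) < mean(v[lab == 0L])) "lower" else "higher"
    r <- rocCurve(v, labels, dir)
    rows[[mk]] <- data.frame(predictor = mk, auc = r@auc, direction = dir,
                             cutoff = r@cutoff, sensitivity = r@sensitivity,
                             specificity = r@specificity,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel_is_max") <- out$auc[out$predictor == "panel"] >=
    max(out$auc[out$predictor != "panel"])
  out
}
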