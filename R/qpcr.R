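#' Read a qPCR Ct table
#'
#' Tab-delimited with header `sample`, `group`, `target`, `ct_target`,
#' `ct_spike`. Ct values must be finite and in (0, 45]; each
#' (sample, target) pair must be unique.
#'
#' @param path TSV file path.
#' @return The validated Ct `data.frame`.
#' @export
readCtTable <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateCtTable(ct)
  ct
}

validateCtTable <- function(ct) {
  need <- c("sample", "group", "target", "ct_target", "ct_spike")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  vals <- c(ct$ct_target, ct$ct_spike)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 45))
    stop("Ct values must be finite and in (0, 45]")
  key <- paste(ct$sample, ct$target)
  if (anyDuplicated(key))
    stop("duplicate (sample, target) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(ct)
}

#' Relative quantification by 2^-ddCt with spike-in normalisation
#'
#' Per (sample, target): `dCt = Ct(target) - Ct(spike)`;
#' `ddCt = dCt - mean control dCt` for that target (arithmetic mean over
#' control samples, so the control-group log-mean RQ is zero and the
#' geometric mean of control RQ is 1); `RQ = 2^-ddCt`. A designated
#' calibrator sample may be used as the ddCt reference instead.
#'
#' @param ct Ct `data.frame` (see [readCtTable()]).
#' @param controlGroup label of the control group.
#' @param calibrator optional sample id to use as the ddCt reference in
#'   place of the control-group mean.
#' @return A [RelQuant-class] (group summaries empty until
#'   [groupStats()]).
#' @export
deltaDeltaCt <- function(ct, controlGroup, calibrator = NULL) {
  validateCtTable(ct)
  if (!controlGroup %in% ct$group)
    stop("control group '", controlGroup, "' not present in Ct table")
  ct$dct <- ct$ct_target - ct$ct_spike
  targets <- unique(ct$target)
  if (is.null(calibrator)) {
    ctrl <- ct[ct$group == controlGroup, , drop = FALSE]
    missing <- setdiff(targets, ctrl$target)
    if (length(missing))
      stop("target(s) missing from control group: ",
           paste(missing, collapse = ", "))
    ref <- tapply(ctrl$dct, ctrl$target, mean)
  } else {
    cal <- ct[ct$sample == calibrator, , drop = FALSE]
    missing <- setdiff(targets, cal$target)
    if (length(missing))
      stop("target(s) missing from calibrator sample: ",
           paste(missing, collapse = ", "))
    ref <- stats::setNames(cal$dct, cal$target)
  }
  ct$ddct <- as.numeric(ct$dct - ref[ct$target])
  ct$rq <- 2^(-ct$ddct)
  new("RelQuant", samples = ct, groups = data.frame(),
      controlGroup = controlGroup)
}

#' @rdname accessors
#' @export
setMethod("sampleRQ", "RelQuant", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("groupSummary", "RelQuant", function(x) x@groups)
#' @rdname accessors
#' @export
setMethod("controlGroup", "RelQuant", function(x) x@controlGroup)

setMethod("show", "RelQuant", function(object) {
  s <- object@samples
  cat(sprintf("RelQuant: %d targets x %d samples (%d groups), control '%s'\n",
              length(unique(s$target)), length(unique(s$sample)),
              length(unique(s$group)), object@controlGroup))
  if (nrow(object@groups)) cat("  group summaries attached\n")
})

#' Per-group summaries with significance tests
#'
#' Per (group, target): arithmetic mean RQ, standard error and n (the
#' reporting convention mean +/- standard error; a geometric-mean option
#' is available), a two-sided two-sample t-test of each treated group
#' against the control (Welch by default; classical pooled-variance by
#' `welch = FALSE`), significance tiers (`*` p < 0.05, `**` p < 0.01),
#' and a one-way ANOVA across all groups per target. Groups with fewer
#' than two samples skip the test and are flagged. No multiple-testing
#' correction is applied by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg column across each target panel.
#'
#' @param rq a [RelQuant-class].
#' @param welch use Welch's unequal-variance t-test (default `TRUE`).
#' @param geometric summarise with geometric instead of arithmetic means.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The [RelQuant-class] with its `groups` slot filled:
#'   `group`, `target`, `n`, `mean_rq`, `se`, `p_value`, `tier`,
#'   `test_skipped`, `p_anova` (repeated per target), and `p_adj` when
#'   requested.
#' @export
groupStats <- function(rq, welch = TRUE, geometric = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  s <- rq@samples
  ctrlG <- rq@controlGroup
  groups <- unique(s$group)
  targets <- unique(s$target)
  rows <- list()
  for (tg in targets) {
    st <- s[s$target == tg, , drop = FALSE]
    ctrlVals <- st$rq[st$group == ctrlG]
    pAnova <- NA_real_
    if (length(groups) > 1 && all(table(st$group) >= 2) &&
        stats::var(st$rq) > 0) {
      fit <- stats::aov(rq ~ group, data = st)
      pAnova <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    for (g in groups) {
      v <- st$rq[st$group == g]
      mu <- if (geometric) exp(mean(log(v))) else mean(v)
      se <- stats::sd(v) / sqrt(length(v))
      p <- NA_real_
      skipped <- FALSE
      if (g != ctrlG) {
        if (length(v) >= 2 && length(ctrlVals) >= 2) {
          # degenerate zero-variance groups: t = 0 when means agree
          p <- tryCatch(stats::t.test(v, ctrlVals, var.equal = !welch)$p.value,
                        error = function(e)
                          if (isTRUE(all.equal(mean(v), mean(ctrlVals)))) 1
                          else 0)
        } else skipped <- TRUE
      }
      tier <- if (is.na(p)) "ns" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, target = tg, n = length(v), mean_rq = mu, se = se,
        p_value = p, tier = tier, test_skipped = skipped, p_anova = pAnova,
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  if (adjust == "BH") {
    g$p_adj <- NA_real_
    treated <- !is.na(g$p_value)
    g$p_adj[treated] <- stats::p.adjust(g$p_value[treated], method = "BH")
  }
  rq@groups <- g
  rq
}

#' Long-form dose-response table with a monotonic-trend flag
#'
#' Maps group labels to numeric absorbed doses and reports, per target
#' and dose, the group mean RQ, standard error and significance tier,
#' together with a per-target trend flag: `TRUE` when mean RQ is
#' non-increasing with dose (the suppression pattern expected of
#' radiation-responsive serum tsRNAs), `NA` when fewer than two dose
#' levels are present.
#'
#' @param rq a [RelQuant-class]; [groupStats()] is applied if group
#'   summaries are absent.
#' @param doses named numeric vector mapping group labels to Gy; by
#'   default group labels are parsed as numbers.
#' @return `data.frame`: `target`, `dose`, `group`, `mean_rq`, `se`,
#'   `tier`, `monotone_decreasing`.
#' @export
doseResponseTable <- function(rq, doses = NULL) {
  if (!nrow(rq@groups)) rq <- groupStats(rq)
  g <- rq@groups
  if (is.null(doses)) {
    doses <- suppressWarnings(as.numeric(unique(g$group)))
    names(doses) <- unique(g$group)
    if (anyNA(doses))
      stop("group labels are not numeric doses; supply `doses`")
  }
  g$dose <- doses[g$group]
  if (anyNA(g$dose)) stop("no dose mapping for group(s): ",
                          paste(unique(g$group[is.na(g$dose)]), collapse = ", "))
  g <- g[order(g$target, g$dose), , drop = FALSE]
  out <- list()
  for (tg in unique(g$target)) {
    gt <- g[g$target == tg, , drop = FALSE]
    flag <- if (nrow(gt) < 2) NA else all(diff(gt$mean_rq) <= 1e-9)
    gt$monotone_decreasing <- flag
    out[[tg]] <- gt[, c("target", "dose", "group", "mean_rq", "se", "tier",
                        "monotone_decreasing")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
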