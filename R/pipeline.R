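# the five serum tsRNA biomarkers used as the default validation panel
PANEL_MARKERS <- c("tiRNA-Glu-TTC-003", "tRF-Val-AAC-024", "tRF-Gln-CTG-018",
                   "tRF-Lys-CTT-008", "tRF-Lys-TTT-019")

# element-wise dose formatting (format() on a vector pads to common width)
fmtDose <- function(x) vapply(x, format, character(1))

#' Default pipeline configuration
#'
#' Nested list of every stage parameter; the defaults reproduce the
#' study settings: 14–40 nt length window, 1-mismatch hierarchical
#' alignment, CPM > 20 abundance filter, symmetric 1.5-fold all-dose
#' screen with 4 up / 6 down candidates, 2^-ddCt quantification, and an
#' OLS exposure-risk model over three exposure degrees (0 / (0,0.1] /
#' (0.1,2] Gy). The simulate block plants 17 up- and 9 down-regulated
#' fragment species at 2-fold / 0.5-fold in all irradiation groups and a
#' five-marker qPCR panel suppressed 30–60% with dose.
#'
#' @param ... named overrides, nested lists merged by key (unknown keys
#'   are rejected).
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    seed = 1,
    output_dir = "tsrna-run",
    simulate = list(
      n_trna = 20, n_pre = 5, n_mirna = 10,
      n_reads = 100000,
      composition = list(frac_mature = 0.78, frac_pre = 0.01,
                         frac_mirna = 0.01),
      doses = c(0, 0.05, 0.1, 0.5, 1),
      n_up = 17, n_down = 9, effect_up = 3, effect_down = 0.333,
      dispersion = 0.05,
      qpcr = list(n_per_group = 10, ct_sd = 0.45, spike_sd = 0.15,
                  baseline_ct = 27, spike_ct = 20,
                  fold_by_dose = c(0.70, 0.60, 0.45, 0.40),
                  marker_scale = c(1.00, 0.90, 1.10, 0.95, 1.05))
    ),
    classify = list(min_len = 14, max_len = 40, max_mismatch = 1),
    screen = list(cpm_threshold = 20, fold_factor = 1.5, k_up = 4, k_down = 6,
                  control_group = "0"),
    model = list(ed_breaks = c(0.1, 2), control_group = "0",
                 logistic = FALSE, fixture = NULL)
  )
  mergeConfig(defaults, list(...), path = "config")
}

mergeConfig <- function(defaults, overrides, path) {
  if (!length(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- mergeConfig(defaults[[k]], overrides[[k]],
                                   paste0(path, "$", k))
    else defaults[k] <- overrides[k]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipelineConfig()]; unknown keys are rejected before any
#' stage runs.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

pipelineSeeds <- function(seed) {
  base <- (as.integer(seed) %% 1000000L) * 1000L
  list(refs = base + 7L, reads = base + 100L, matrix = base + 11L,
       qpcr = base + 23L, plant = base + 57L)
}

#' Stage 1: generate the synthetic study inputs
#'
#' Writes, under `output_dir`: the reference set (`refs/`), one read
#' library per dose with its truth manifest (`reads/`), the planted
#' responsive-species table (`truth/`), and the five-marker validation Ct
#' table with its truth manifest (`qpcr/`). Everything is a pure function
#' of (config, seed): identical runs are diff-identical.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with `refset`, `libraries` (per dose),
#'   `responsive`, `ct`, and the output paths.
#' @export
runSimulate <- function(config = pipelineConfig()) {
  sc <- config$simulate
  seeds <- pipelineSeeds(config$seed)
  out <- config$output_dir
  for (d in c("refs", "reads", "truth", "qpcr"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  refset <- generateReferenceSet(sc$n_trna, sc$n_pre, sc$n_mirna,
                                 seed = seeds$refs)
  writeReferenceSet(refset, file.path(out, "refs"))

  frag <- fragmentSpecies(refset)
  set.seed(seeds$plant)
  planted <- sample(frag$species, sc$n_up + sc$n_down)
  upIds <- planted[seq_len(sc$n_up)]
  downIds <- planted[sc$n_up + seq_len(sc$n_down)]
  effect <- c(stats::setNames(rep(sc$effect_up, sc$n_up), upIds),
              stats::setNames(rep(sc$effect_down, sc$n_down), downIds))
  dp <- doseResponseParams(doses = sc$doses, replicates = 1,
                           responsiveIds = planted,
                           effect = as.list(effect),
                           dispersion = sc$dispersion)
  truth <- data.frame(species = planted,
                      direction = c(rep("up", sc$n_up), rep("down", sc$n_down)),
                      effect = unname(effect), stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(out, "truth", "responsive_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  comp <- compositionParams(fracMature = sc$composition$frac_mature,
                            fracPre = sc$composition$frac_pre,
                            fracMirna = sc$composition$frac_mirna)
  libraries <- list()
  for (i in seq_along(sc$doses)) {
    d <- sc$doses[i]
    lib <- simulateReadLibrary(refset, comp, dp, dose = d,
                               nReads = sc$n_reads,
                               seed = seeds$reads + i,
                               path = file.path(out, "reads",
                                                sprintf("dose_%s.fa", format(d))))
    utils::write.table(lib$manifest,
                       file.path(out, "reads",
                                 sprintf("dose_%s.manifest.tsv", format(d))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    libraries[[format(d)]] <- lib
  }

  qp <- sc$qpcr
  nz <- sc$doses[sc$doses != 0]
  fold <- cbind(1, vapply(seq_along(nz), function(j)
    pmin(1, qp$fold_by_dose[j] * qp$marker_scale), numeric(length(PANEL_MARKERS))))
  dimnames(fold) <- list(PANEL_MARKERS, fmtDose(c(0, nz)))
  params <- qpcrSimParams(PANEL_MARKERS, fold, controlGroup = "0",
                          baselineCt = qp$baseline_ct, spikeCt = qp$spike_ct,
                          ctSd = qp$ct_sd, spikeSd = qp$spike_sd,
                          nPerGroup = qp$n_per_group)
  ct <- simulateQPCRTable(params, seed = seeds$qpcr,
                          path = file.path(out, "qpcr", "ct_table.tsv"))
  utils::write.table(ct$manifest, file.path(out, "qpcr", "ct_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(config, file.path(out, "config_echo.yaml"))
  invisible(list(refset = refset, libraries = libraries, responsive = truth,
                 ct = ct$ct, paths = list(root = out)))
}

#' Stage 2: classify reads and screen for dose-responsive species
#'
#' Chains length filter, hierarchical 1-mismatch alignment, subtype
#' calling, expression-matrix assembly, CPM normalisation, the CPM > 20
#' abundance filter, relative expression versus control, the symmetric
#' 1.5-fold all-dose-group screen and candidate ranking. Inputs are taken
#' from `sim` when given, else read back from `output_dir`.
#'
#' @param config a [pipelineConfig()] list.
#' @param sim optional result of [runSimulate()].
#' @return Invisibly, a list with `compositions` (per dose),
#'   `se` (filtered expression matrix), `fc`, `screen`, `candidates` and
#'   `counts` (stage attrition log).
#' @export
runClassifyScreen <- function(config = pipelineConfig(), sim = NULL) {
  out <- config$output_dir
  cl <- config$classify
  scr <- config$screen
  if (is.null(sim)) {
    refset <- readReferenceSet(
      file.path(out, "refs", "mature.fa"), file.path(out, "refs", "annotation.tsv"),
      precursorFasta = file.path(out, "refs", "precursor.fa"),
      precursorMapPath = file.path(out, "refs", "precursor_map.tsv"),
      mirnaFasta = file.path(out, "refs", "mirna.fa"))
    readFiles <- sort(list.files(file.path(out, "reads"), pattern = "\\.fa$",
                                 full.names = TRUE))
    if (!length(readFiles)) stop("classify stage: no read libraries under ", out)
    doses <- as.numeric(sub("^dose_(.*)\\.fa$", "\\1", basename(readFiles)))
    reads <- lapply(readFiles, function(f) {
      x <- Biostrings::readDNAStringSet(f)
      names(x) <- sub("\\s.*$", "", names(x))
      x
    })
    names(reads) <- fmtDose(doses)
  } else {
    refset <- sim$refset
    reads <- lapply(sim$libraries, `[[`, "reads")
    doses <- as.numeric(names(reads))
  }
  ord <- order(doses)
  doses <- doses[ord]; reads <- reads[ord]

  alignments <- list(); calls <- list(); compositions <- list()
  counts <- list()
  for (g in names(reads)) {
    lf <- lengthFilter(reads[[g]], cl$min_len, cl$max_len)
    aln <- hierarchicalAlign(lf$reads, refset, maxMismatch = cl$max_mismatch)
    cls <- classifyFragments(aln, refset)
    alignments[[g]] <- aln
    calls[[g]] <- cls
    compositions[[g]] <- summarizeComposition(aln, cls)
    counts[[g]] <- c(reads_in = length(reads[[g]]), dropped = lf$dropped,
                     aligned = sum(aln$class != "unmapped"))
  }
  cd <- data.frame(sample = names(reads), group = names(reads),
                   dose = doses, stringsAsFactors = FALSE)
  se <- buildExpressionMatrix(calls, alignments, cd)
  se <- countsToCPM(se)
  seF <- filterAbundance(se, threshold = scr$cpm_threshold)
  fc <- relativeExpression(seF, controlGroup = scr$control_group)
  screen <- screenFoldChange(fc, factor = scr$fold_factor)
  candidates <- rankCandidates(screen, seF, kUp = scr$k_up, kDown = scr$k_down)

  compTab <- do.call(rbind, lapply(names(compositions), function(g)
    data.frame(group = g, class = names(compositions[[g]]$classProp),
               proportion = as.numeric(compositions[[g]]$classProp),
               stringsAsFactors = FALSE)))
  utils::write.table(compTab, file.path(out, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mat <- cbind(
    data.frame(species = rownames(seF),
               as.data.frame(SummarizedExperiment::rowData(seF))),
    as.data.frame(SummarizedExperiment::assay(seF, "cpm")))
  utils::write.table(mat, file.path(out, "expression_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screenTable(screen), file.path(out, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(lapply(perDoseSets(screen), as.list),
      list(intersection = as.list(intersectionSpecies(screen)))),
    file.path(out, "venn.json"), auto_unbox = FALSE)
  utils::write.table(candidates, file.path(out, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(compositions = compositions, se = seF, fc = fc,
                 screen = screen, candidates = candidates, counts = counts))
}

#' Stage 3: quantify the validation panel and fit/evaluate the risk model
#'
#' Chains 2^-ddCt relative quantification with spike-in normalisation,
#' group statistics and the dose-response table, exposure-degree
#' assignment, OLS fitting of the exposure risk score (or scoring with a
#' published fixture when `config$model$fixture` names one), ROC analysis
#' of exposed vs sham, and the panel-vs-single-marker comparison. A JSON
#' run report with per-stage row counts and headline results is written.
#'
#' @param config a [pipelineConfig()] list.
#' @param ct optional Ct `data.frame`; defaults to the table under
#'   `output_dir`.
#' @return Invisibly, a list with `rq`, `doseResponse`, `model`,
#'   `roc`, `comparison` and `report`.
#' @export
runModel <- function(config = pipelineConfig(), ct = NULL) {
  out <- config$output_dir
  mc <- config$model
  if (is.null(ct)) ct <- readCtTable(file.path(out, "qpcr", "ct_table.tsv"))
  if (!mc$control_group %in% ct$group)
    stop("model stage: control group '", mc$control_group,
         "' absent from Ct table")
  rq <- deltaDeltaCt(ct, controlGroup = mc$control_group)
  rq <- groupStats(rq)
  dr <- doseResponseTable(rq)

  s <- sampleRQ(rq)
  wide <- stats::reshape(
    s[, c("sample", "group", "target", "rq")],
    idvar = c("sample", "group"), timevar = "target", direction = "wide")
  names(wide) <- sub("^rq\\.", "", names(wide))
  markers <- setdiff(names(wide), c("sample", "group"))
  ed <- assignED(as.numeric(wide$group), breaks = mc$ed_breaks)
  if (length(unique(ed)) < 2)
    stop("model stage: exposure degrees collapse to a single class")
  model <- if (!is.null(mc$fixture)) ersModel(mc$fixture)
    else fitERS(wide[, markers, drop = FALSE], ed,
                radiationType = "synthetic", logistic = mc$logistic)
  scores <- scoreERS(model, wide[, markerIds(model), drop = FALSE])
  exposed <- as.integer(ed > "ED0")
  roc <- rocCurve(scores, exposed, "higher")
  comparison <- comparePanelVsSingle(model, wide[, markerIds(model),
                                                 drop = FALSE], exposed)

  utils::write.table(s, file.path(out, "rq_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(groupSummary(rq), file.path(out, "rq_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dr, file.path(out, "dose_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeERSModel(model, file.path(out, "ers_model.json"))
  utils::write.table(rocPoints(roc), file.path(out, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison, file.path(out, "auc_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("tsRNAtriage")),
    n_samples = nrow(wide), n_targets = length(markers),
    ed_breaks = mc$ed_breaks,
    model = list(radiation_type = radiationType(model),
                 intercept = modelIntercept(model),
                 coefficients = as.list(modelCoefficients(model))),
    panel_auc = auc(roc),
    auc_table = comparison[, c("predictor", "auc")],
    panel_is_max = isTRUE(attr(comparison, "panel_is_max")))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(rq = rq, doseResponse = dr, model = model, roc = roc,
                 comparison = comparison, report = report))
}

#' Run the whole pipeline
#'
#' [runSimulate()], [runClassifyScreen()] and [runModel()] in order,
#' under one output directory and one seed.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with the three stage results (`sim`,
#'   `screen`, `model`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  sim <- runSimulate(config)
  screen <- runClassifyScreen(config, sim = sim)
  model <- runModel(config, ct = sim$ct)
  invisible(list(sim = sim, screen = screen, model = model))
}
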