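## End-to-end orchestration: simulate -> label -> split -> train four models
## -> evaluate -> survival-validate, fully seeded.

#' Configure an end-to-end experiment
#'
#' A single global seed fans out deterministically to per-stage seeds
#' (cohort, split, one per model, bootstrap) via a fixed offset scheme, so
#' any stage can be reproduced in isolation.
#'
#' @param cohort A [CohortConfig] (its own seed is overridden by the stage
#'   seed derived from `seed`), or an existing [PacCohort].
#' @param tResistant,tSensitive PFS labelling thresholds in months.
#' @param validationFraction Split fraction (default 0.2).
#' @param ageCutoffYoung Young-onset age cutoff.
#' @param models Named list of [ModelSpec] objects; default: all four kinds
#'   with default hyperparameters.
#' @param nBoot Bootstrap resamples for AUROC CIs.
#' @param threshold Classification threshold.
#' @param vocabularyPolicy `"train_only"` (default) builds the variant
#'   vocabulary from training patients only (validation-only variants are
#'   ignored at prediction time); `"all_patients"` mirrors the leakier
#'   all-cohort vocabulary, where variants unseen in training keep their
#'   initial embedding rows / zero baseline coefficients.
#' @param seed Global integer seed.
#' @param outDir Optional output directory for [writeReport()].
#' @return Validated configuration list of class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(cohort,
                             tResistant = 3, tSensitive = 6,
                             validationFraction = 0.2,
                             ageCutoffYoung = 40,
                             models = NULL,
                             nBoot = 2000L, threshold = 0.5,
                             vocabularyPolicy = c("train_only",
                                                  "all_patients"),
                             seed = 1L, outDir = NULL) {
  vocabularyPolicy <- match.arg(vocabularyPolicy)
  stopifnot(is(cohort, "CohortConfig") || is(cohort, "PacCohort"))
  if (is.null(models))
    models <- list(
      random_forest = modelSpec("random_forest"),
      logistic_regression = modelSpec("logistic_regression"),
      ann = modelSpec("ann"),
      ann_with_ge = modelSpec("ann_with_ge"))
  stopifnot(all(vapply(models, is, TRUE, "ModelSpec")))
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m@kind, "")
  structure(list(cohort = cohort, tResistant = tResistant,
                 tSensitive = tSensitive,
                 validationFraction = validationFraction,
                 ageCutoffYoung = ageCutoffYoung, models = models,
                 nBoot = as.integer(nBoot), threshold = threshold,
                 vocabularyPolicy = vocabularyPolicy,
                 seed = as.integer(seed), outDir = outDir),
            class = "ExperimentConfig")
}

.modelStageSeed <- function(seed, kind) {
  .stageSeed(seed, switch(kind,
    random_forest = "model_rf", logistic_regression = "model_lr",
    ann = "model_ann", ann_with_ge = "model_ann_ge"))
}

#' Run the full experiment
#'
#' Executes every stage in order and returns an [ExperimentReport]. Training
#' uses the training split only: the variant vocabulary is built from
#' training patients under the default policy, and an internal assertion
#' fails if any validation index reaches a fitting routine. Two runs with
#' the same configuration and seed produce byte-identical outputs.
#'
#' @param config An `ExperimentConfig` from [experimentConfig()].
#' @return An [ExperimentReport]; artifacts are also written to
#'   `config$outDir` when set.
#' @examples
#' \donttest{
#' cfg <- experimentConfig(cohortConfig(nPatients = 120, seed = 1),
#'                         nBoot = 50, seed = 1)
#' report <- runExperiment(cfg)
#' }
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  stage <- "simulate"
  report <- tryCatch({
    seed <- config$seed
    cohort <- if (is(config$cohort, "PacCohort")) config$cohort else {
      cc <- config$cohort
      cc@seed <- .stageSeed(seed, "cohort")
      generateCohort(cc)
    }

    stage <- "label"
    labels <- assignLabel(pfsMonths(cohort), pfsEvent(cohort),
                          config$tResistant, config$tSensitive)
    labeled <- which(labels != "excluded")
    if (length(unique(labels[labeled])) < 2L)
      stop("labelled cohort contains a single class")

    stage <- "split"
    sp <- stratifiedSplit(as.character(labels[labeled]),
                          config$validationFraction,
                          seed = .stageSeed(seed, "split"))
    trainIdx <- labeled[sp$train]
    valIdx <- labeled[sp$validation]
    stopifnot(length(intersect(trainIdx, valIdx)) == 0L)

    stage <- "features"
    vocab <- if (config$vocabularyPolicy == "train_only")
      buildVariantVocabulary(cohort[, trainIdx])
    else buildVariantVocabulary(cohort)
    features <- buildFeatureSet(cohort, vocab,
                                tResistant = config$tResistant,
                                tSensitive = config$tSensitive,
                                ageCutoffYoung = config$ageCutoffYoung,
                                unknownVariants = "drop")

    stage <- "train"
    models <- list()
    for (nm in names(config$models)) {
      spec <- config$models[[nm]]
      spec@seed <- .modelStageSeed(seed, spec@kind)
      # train/validation hygiene: fitting must never see validation rows
      stopifnot(length(intersect(trainIdx, valIdx)) == 0L)
      models[[nm]] <- fitClassifier(spec, features, trainIdx)
    }

    stage <- "evaluate"
    metrics <- list(); rocCurves <- list()
    for (nm in names(models)) {
      pTrain <- predictProba(models[[nm]], features, trainIdx)
      pVal <- predictProba(models[[nm]], features, valIdx)
      bootSeed <- .stageSeed(seed, "bootstrap")
      metrics[[nm]] <- list(
        training = .metricsReport(pTrain, features@labels[trainIdx],
                                  config$threshold, config$nBoot,
                                  seed = bootSeed),
        validation = .metricsReport(pVal, features@labels[valIdx],
                                    config$threshold, config$nBoot,
                                    seed = bootSeed))
      rocCurves[[nm]] <- rocCurve(pVal, features@labels[valIdx])
    }

    stage <- "survival"
    survivalComparisons <- lapply(models, function(m) list(
      pfs = comparePredictedGroups(m, features, cohort, valIdx, "pfs",
                                   config$threshold),
      os = comparePredictedGroups(m, features, cohort, valIdx, "os",
                                  config$threshold)))

    stage <- "baselines"
    baselines <- list(
      train_vs_validation = summarizeCohort(
        cohort[, trainIdx], cohort[, valIdx],
        subsetNames = c("training", "validation")),
      sensitive_vs_resistant_training = summarizeCohort(
        cohort[, trainIdx[labels[trainIdx] == "sensitive"]],
        cohort[, trainIdx[labels[trainIdx] == "resistant"]],
        subsetNames = c("sensitive", "resistant")))

    prov <- list(seed = seed,
                 stageSeeds = list(
                   cohort = .stageSeed(seed, "cohort"),
                   split = .stageSeed(seed, "split"),
                   bootstrap = .stageSeed(seed, "bootstrap")),
                 nPatients = ncol(cohort),
                 nLabelled = length(labeled),
                 nTrain = length(trainIdx), nValidation = length(valIdx),
                 vocabularyPolicy = config$vocabularyPolicy,
                 vocabularySize = length(vocab@ids),
                 thresholds = c(resistant = config$tResistant,
                                sensitive = config$tSensitive),
                 packageVersion =
                   as.character(utils::packageVersion("pacsense")))

    new("ExperimentReport", metrics = metrics,
        survivalComparisons = survivalComparisons,
        baselines = baselines,
        split = list(train = trainIdx, validation = valIdx),
        rocCurves = rocCurves, provenance = prov)
  }, error = function(e) {
    stop(sprintf("experiment stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$outDir)) writeReport(report, config$outDir)
  report
}

#' Load a cohort from the documented CSV formats
#'
#' Strictly validates both headers, refuses duplicate patient identifiers
#' and variant rows referencing unknown patients. Round-trips with
#' [writePatientCSV()] / [writeVariantCSV()] byte-for-byte.
#'
#' @param patientCSV Path to the patient table.
#' @param variantCSV Path to the long-format variant table.
#' @return A [PacCohort].
#' @export
loadCohort <- function(patientCSV, variantCSV) {
  pat <- read.csv(patientCSV, stringsAsFactors = FALSE)
  needP <- c("patient_id", "age_years", "sex", "histology",
             "clinical_setting", "prior_gastrectomy", "prior_trastuzumab",
             "first_line_duration", "pfs_months", "pfs_event", "os_months",
             "os_event")
  miss <- setdiff(needP, colnames(pat))
  if (length(miss))
    stop("patient CSV misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(pat$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(pat$patient_id[duplicated(pat$patient_id)]),
               collapse = ", "), call. = FALSE)
  var <- read.csv(variantCSV, stringsAsFactors = FALSE,
                  colClasses = "character")
  needV <- c("patient_id", "gene", "variant_id", "variant_class",
             "pathogenicity")
  miss <- setdiff(needV, colnames(var))
  if (length(miss))
    stop("variant CSV misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(var$patient_id, pat$patient_id)
  if (length(unknown))
    stop("variant rows reference unknown patient_id: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)

  panel <- unique(var[, c("variant_id", "gene", "variant_class",
                          "pathogenicity")])
  panel <- panel[order(panel$gene, panel$variant_id, method = "radix"), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  n <- nrow(pat); V <- nrow(panel)
  occ <- matrix(0L, V, n, dimnames = list(panel$variant_id, pat$patient_id))
  if (nrow(var)) {
    ri <- match(var$variant_id, panel$variant_id)
    ci <- match(var$patient_id, pat$patient_id)
    occ[cbind(ri, ci)] <- 1L
  }
  cd <- DataFrame(pat)
  rownames(cd) <- pat$patient_id
  se <- SummarizedExperiment(assays = list(occurrence = occ),
                             rowData = panel, colData = cd)
  out <- new("PacCohort", se)
  validObject(out)
  out
}

.metricsToDF <- function(metrics) {
  rows <- list()
  for (nm in names(metrics)) for (split in names(metrics[[nm]])) {
    m <- metrics[[nm]][[split]]
    rows[[paste(nm, split)]] <- data.frame(
      model = nm, split = split, auroc = m$auroc,
      auroc_ci_lower = m$auroc_ci_lower, auroc_ci_upper = m$auroc_ci_upper,
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, f1 = m$f1, threshold = m$threshold,
      n_pos = m$n_pos, n_neg = m$n_neg)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write all report artifacts
#'
#' Emits, into `outDir`: `metrics.csv` and `metrics.json`, the two baseline
#' tables as CSV, per-model validation ROC points (`roc_<model>.csv`) and KM
#' curves (`km_<model>_<endpoint>.csv`), a provenance block
#' (`provenance.json`) and a human-readable `summary.txt`. Numeric CSV cells
#' are printed with 17 significant digits so every file re-parses to the
#' in-memory values exactly; re-running on the same report overwrites
#' identically.
#'
#' @param report An [ExperimentReport].
#' @param outDir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(is(report, "ExperimentReport"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }

  mdf <- .metricsToDF(report@metrics)
  .writeCSVExact(mdf, w(file.path(outDir, "metrics.csv")))
  jsonlite::write_json(report@metrics, w(file.path(outDir, "metrics.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report@baselines))
    writeBaselineTable(report@baselines[[nm]],
                       w(file.path(outDir, paste0("baseline_", nm, ".csv"))))
  for (nm in names(report@rocCurves))
    .writeCSVExact(report@rocCurves[[nm]],
                   w(file.path(outDir, paste0("roc_", nm, ".csv"))))
  for (nm in names(report@survivalComparisons))
    for (ep in c("pfs", "os"))
      writeSurvivalCSV(report@survivalComparisons[[nm]][[ep]],
                       w(file.path(outDir,
                                   paste0("km_", nm, "_", ep, ".csv"))))
  jsonlite::write_json(report@provenance,
                       w(file.path(outDir, "provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lines <- c("pacsense experiment summary",
             sprintf("  seed %d; %d patients (%d labelled: %d train / %d validation)",
                     report@provenance$seed, report@provenance$nPatients,
                     report@provenance$nLabelled, report@provenance$nTrain,
                     report@provenance$nValidation),
             sprintf("  vocabulary: %d variants (%s policy)",
                     report@provenance$vocabularySize,
                     report@provenance$vocabularyPolicy), "")
  for (nm in names(report@metrics)) {
    tr <- report@metrics[[nm]]$training; va <- report@metrics[[nm]]$validation
    sc <- report@survivalComparisons[[nm]]
    lines <- c(lines, sprintf("model %s", nm),
      sprintf("  training   AUROC %.3f (95%% CI %.3f-%.3f)",
              tr$auroc, tr$auroc_ci_lower, tr$auroc_ci_upper),
      sprintf("  validation AUROC %.3f (95%% CI %.3f-%.3f); sens %.3f spec %.3f acc %.3f F1 %.3f",
              va$auroc, va$auroc_ci_lower, va$auroc_ci_upper,
              va$sensitivity, va$specificity, va$accuracy, va$f1),
      sprintf("  validation PFS median %s vs %s months, log-rank p %s",
              .fmtMedian(sc$pfs@medians[1]), .fmtMedian(sc$pfs@medians[2]),
              .fmtP(sc$pfs)),
      sprintf("  validation OS  median %s vs %s months, log-rank p %s",
              .fmtMedian(sc$os@medians[1]), .fmtMedian(sc$os@medians[2]),
              .fmtP(sc$os)))
  }
  writeLines(lines, w(file.path(outDir, "summary.txt")))
  invisible(paths)
}

.fmtMedian <- function(x) if (is.na(x)) "NR" else sprintf("%.2f", x)
.fmtP <- function(sc) {
  if (sc@testDefined) sprintf("%.4f", sc@pValue) else "undefined"
}
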