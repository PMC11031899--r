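#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---- planted-signal specification -----------------------------------------

#' Planted benefit-signal coefficients
#'
#' Coefficients of the latent log-benefit score used by the synthetic cohort
#' generator. The score acts multiplicatively on the median progression-free
#' survival (accelerated-time form); `betaVariantOS` acts on the
#' post-progression time that separates overall from progression-free
#' survival. `gammaPairs` carries pairwise variant interaction terms so that a
#' non-additive signal can be planted which a main-effects model cannot fully
#' capture.
#'
#' @slot beta0 Intercept of the benefit score.
#' @slot betaClinical Named numeric, one coefficient per binary clinical
#'   feature (see [buildClinicalFeatures()] for the fixed order).
#' @slot betaVariant Numeric, one coefficient per panel variant.
#' @slot gammaPairs Three-column numeric matrix `(j, k, gamma)`; rows are
#'   pairwise interactions active when a patient carries both variants.
#' @slot betaVariantOS Numeric, per-variant effect on post-progression time.
#' @export
setClass("EffectSpec", representation(
  beta0 = "numeric",
  betaClinical = "numeric",
  betaVariant = "numeric",
  gammaPairs = "matrix",
  betaVariantOS = "numeric"
))

setValidity("EffectSpec", function(object) {
  V <- length(object@betaVariant)
  if (length(object@beta0) != 1L) return("beta0 must be scalar")
  if (length(object@betaVariantOS) != V)
    return("betaVariant and betaVariantOS must have equal length")
  gp <- object@gammaPairs
  if (ncol(gp) != 3L) return("gammaPairs must have 3 columns (j, k, gamma)")
  if (nrow(gp) > 0L) {
    idx <- as.vector(gp[, 1:2])
    if (any(idx < 1L | idx > V | idx != as.integer(idx)))
      return("gammaPairs reference variant indices outside the panel")
  }
  TRUE
})

## ---- cohort configuration --------------------------------------------------

#' Synthetic cohort configuration
#'
#' Stated world of the generator: panel composition (default 73 SNVs and 29
#' CNVs over 87 genes), per-variant and clinical prevalences, the planted
#' [EffectSpec], baseline survival medians (defaults 2.70 months PFS, 13.28
#' months OS), an administrative censoring rate, and the seed.
#'
#' @slot nPatients,nGenes,nSNV,nCNV Panel/cohort sizes.
#' @slot variantPrevalences Per-variant carrier probability in \[0, 1\].
#' @slot clinicalPrevalences Named probabilities for the binary clinical
#'   covariates and the three-level first-line duration.
#' @slot ageMean,ageSD,ageMin,ageMax Truncated-normal age model (years).
#' @slot effect An [EffectSpec].
#' @slot basePFSMedian,baseOSMedian Null-score survival medians in months.
#' @slot ppsMedian Calibrated post-progression median (derived, months).
#' @slot censoringRate Target fraction of OS observations censored.
#' @slot censoringMax Derived administrative censoring horizon (months).
#' @slot seed Integer seed.
#' @export
setClass("CohortConfig", representation(
  nPatients = "integer",
  nGenes = "integer",
  nSNV = "integer",
  nCNV = "integer",
  variantPrevalences = "numeric",
  clinicalPrevalences = "numeric",
  ageMean = "numeric",
  ageSD = "numeric",
  ageMin = "numeric",
  ageMax = "numeric",
  effect = "EffectSpec",
  basePFSMedian = "numeric",
  baseOSMedian = "numeric",
  ppsMedian = "numeric",
  censoringRate = "numeric",
  censoringMax = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  V <- object@nSNV + object@nCNV
  if (length(object@variantPrevalences) != V)
    return("variantPrevalences must have length nSNV + nCNV")
  if (any(object@variantPrevalences < 0 | object@variantPrevalences > 1))
    return("variantPrevalences must lie in [0, 1]")
  need <- c("male", "intestinal", "initially_metastatic", "prior_gastrectomy",
            "prior_trastuzumab", "duration_lt3", "duration_ge6")
  if (!all(need %in% names(object@clinicalPrevalences)))
    return(paste("clinicalPrevalences must name:", paste(need, collapse = ", ")))
  cp <- object@clinicalPrevalences[need]
  if (any(cp < 0 | cp > 1)) return("clinical prevalences must lie in [0, 1]")
  if (cp[["duration_lt3"]] + cp[["duration_ge6"]] > 1)
    return("duration_lt3 + duration_ge6 must not exceed 1")
  if (object@basePFSMedian <= 0 || object@baseOSMedian <= 0)
    return("survival medians must be positive")
  if (object@baseOSMedian <= object@basePFSMedian)
    return("baseOSMedian must exceed basePFSMedian")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    return("censoringRate must lie in [0, 1)")
  if (length(object@effect@betaVariant) != V)
    return("effect spec variant length disagrees with the panel size")
  TRUE
})

## ---- cohort container ------------------------------------------------------

#' Advanced gastric cancer cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"occurrence"`, binary variants x patients), `rowData` describing the
#' variant panel (`variant_id`, `gene`, `variant_class`, `pathogenicity`) and
#' `colData` holding clinical covariates and survival outcomes
#' (`pfs_months`, `pfs_event`, `os_months`, `os_event`).
#'
#' @export
setClass("PacCohort", contains = "SummarizedExperiment")

setValidity("PacCohort", function(object) {
  cd <- colData(object)
  need <- c("patient_id", "age_years", "sex", "histology", "clinical_setting",
            "prior_gastrectomy", "prior_trastuzumab", "first_line_duration",
            "pfs_months", "pfs_event", "os_months", "os_event")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) return(paste("colData misses:", paste(miss, collapse = ", ")))
  if (!"occurrence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'occurrence' missing")
  if (anyDuplicated(cd$patient_id)) return("duplicate patient_id")
  if (ncol(object) > 0L) {
    if (any(cd$pfs_months < 0) || any(cd$os_months < 0))
      return("survival times must be non-negative")
    if (!all(cd$pfs_event %in% c(0L, 1L)) || !all(cd$os_event %in% c(0L, 1L)))
      return("event flags must be 0/1")
    both <- cd$pfs_event == 1L & cd$os_event == 1L
    if (any(cd$os_months[both] < cd$pfs_months[both] - 1e-9))
      return("os_months < pfs_months with both events observed")
    occ <- assay(object, "occurrence")
    if (!all(occ %in% c(0L, 1L))) return("occurrence assay must be binary")
  }
  TRUE
})

## ---- feature machinery -----------------------------------------------------

#' Ordered variant vocabulary
#'
#' Deterministically ordered (lexicographic by gene, then variant id) mapping
#' from variant identifier to embedding-row / matrix-column index. Indices are
#' 1-based, the R convention.
#'
#' @slot ids Character vector of unique variant identifiers.
#' @slot gene Character vector, the gene of each identifier.
#' @export
setClass("VariantVocabulary",
         representation(ids = "character", gene = "character"))

setValidity("VariantVocabulary", function(object) {
  if (anyDuplicated(object@ids)) return("variant identifiers must be unique")
  if (length(object@gene) != length(object@ids))
    return("gene annotation length mismatch")
  TRUE
})

#' Supervised-learning view of a cohort
#'
#' Binary clinical matrix, variant index sets and presence matrix, PFS-derived
#' labels and the [VariantVocabulary] used, for all patients of a cohort (the
#' `excluded` label marks patients outside both PFS threshold classes).
#'
#' @slot patientIDs Character.
#' @slot clinical n x k binary matrix with feature names.
#' @slot variantSets List of 1-based integer index sets.
#' @slot variantMatrix n x V binary presence matrix.
#' @slot labels Factor with levels sensitive/resistant/excluded.
#' @slot vocabulary A [VariantVocabulary].
#' @export
setClass("PacFeatureSet", representation(
  patientIDs = "character",
  clinical = "matrix",
  variantSets = "list",
  variantMatrix = "matrix",
  labels = "factor",
  vocabulary = "VariantVocabulary"
))

setValidity("PacFeatureSet", function(object) {
  n <- length(object@patientIDs)
  V <- length(object@vocabulary@ids)
  if (nrow(object@clinical) != n || nrow(object@variantMatrix) != n ||
      length(object@variantSets) != n || length(object@labels) != n)
    return("row counts disagree across fields")
  if (ncol(object@variantMatrix) != V)
    return("variantMatrix width disagrees with the vocabulary")
  if (!identical(levels(object@labels),
                 c("sensitive", "resistant", "excluded")))
    return("labels must have levels sensitive/resistant/excluded")
  for (i in seq_len(n)) {
    s <- object@variantSets[[i]]
    if (!identical(unname(sort(unique(as.integer(s)))),
                   unname(which(object@variantMatrix[i, ] != 0))))
      return("variantMatrix and variantSets disagree")
  }
  TRUE
})

## ---- models ----------------------------------------------------------------

#' Classifier specification
#'
#' @slot kind One of `random_forest`, `logistic_regression`, `ann`,
#'   `ann_with_ge`.
#' @slot hyper Named list of hyperparameters (defaults filled by
#'   [modelSpec()]).
#' @slot seed Integer seed honoured by every back-end.
#' @export
setClass("ModelSpec", representation(
  kind = "character", hyper = "list", seed = "integer"
))

setValidity("ModelSpec", function(object) {
  kinds <- c("random_forest", "logistic_regression", "ann", "ann_with_ge")
  if (!(length(object@kind) == 1L && object@kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  h <- object@hyper
  if (!is.null(h$embedding_dim) && h$embedding_dim < 1)
    return("embedding_dim must be positive")
  if (!is.null(h$hidden_units) && h$hidden_units < 1)
    return("hidden_units must be positive")
  TRUE
})

#' Parameters of the variant-embedding network
#'
#' @slot E V x d embedding matrix (one row per vocabulary variant).
#' @slot W1 (k + d) x h hidden-layer weights; @slot b1 hidden bias (length h).
#' @slot w2 Output weights (length h); @slot b2 output bias (scalar).
#' @export
setClass("EmbedNetParams", representation(
  E = "matrix", W1 = "matrix", b1 = "numeric", w2 = "numeric", b2 = "numeric"
))

setValidity("EmbedNetParams", function(object) {
  h <- ncol(object@W1)
  if (length(object@b1) != h || length(object@w2) != h)
    return("hidden-layer shapes disagree")
  if (length(object@b2) != 1L) return("b2 must be scalar")
  ok <- all(is.finite(object@E)) && all(is.finite(object@W1)) &&
    all(is.finite(object@b1)) && all(is.finite(object@w2)) &&
    is.finite(object@b2)
  if (!ok) return("all parameters must be finite")
  TRUE
})

#' Fitted classifier
#'
#' @slot spec The [ModelSpec] used.
#' @slot fit Back-end state ([EmbedNetParams] for `ann_with_ge`; an opaque
#'   handle otherwise).
#' @slot vocabulary The training [VariantVocabulary] (prediction refuses a
#'   feature set built on a different vocabulary).
#' @slot clinicalNames Clinical feature layout the model expects.
#' @export
setClass("PacModel", representation(
  spec = "ModelSpec", fit = "ANY", vocabulary = "VariantVocabulary",
  clinicalNames = "character"
))

## ---- survival --------------------------------------------------------------

#' Kaplan-Meier curve
#'
#' Product-limit estimate: one row per distinct event time.
#'
#' @slot time Increasing positive event times.
#' @slot surv Survival probability after each event time (non-increasing).
#' @slot nRisk Number at risk just before each event time.
#' @slot nEvent Number of events at each time.
#' @export
setClass("SurvivalCurve", representation(
  time = "numeric", surv = "numeric", nRisk = "numeric", nEvent = "numeric"
))

setValidity("SurvivalCurve", function(object) {
  n <- length(object@time)
  if (length(object@surv) != n || length(object@nRisk) != n ||
      length(object@nEvent) != n) return("field lengths disagree")
  if (n > 0L) {
    if (is.unsorted(object@time, strictly = TRUE))
      return("event times must be strictly increasing")
    if (any(diff(object@surv) > 1e-12)) return("surv must be non-increasing")
    if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
      return("surv must lie in [0, 1]")
    if (any(diff(object@nRisk) > 0)) return("nRisk must be non-increasing")
    if (any(object@nEvent < 1)) return("each row needs >= 1 event")
  }
  TRUE
})

#' Two-group survival comparison
#'
#' KM curves and medians per predicted group plus the log-rank test.
#' `testDefined` is FALSE when the statistic is undefined (one empty group or
#' zero log-rank variance).
#'
#' @slot groups Group labels.
#' @slot curves Named list of [SurvivalCurve].
#' @slot medians Named numeric medians (NA when a curve never reaches 0.5).
#' @slot nPerGroup Named integer group sizes.
#' @slot statistic,pValue Log-rank chi-square (df = 1) and two-sided p-value.
#' @slot testDefined Logical flag.
#' @export
setClass("SurvivalComparison", representation(
  groups = "character", curves = "list", medians = "numeric",
  nPerGroup = "integer", statistic = "numeric", pValue = "numeric",
  testDefined = "logical"
))

## ---- report ----------------------------------------------------------------

#' End-to-end experiment report
#'
#' @slot metrics Per-model list of training/validation metric lists.
#' @slot survivalComparisons Per-model list with `pfs` and `os`
#'   [SurvivalComparison] objects on the validation split.
#' @slot baselines Named list of baseline-characteristics data frames.
#' @slot split List with `train`/`validation` cohort column indices.
#' @slot rocCurves Per-model validation ROC data frames.
#' @slot provenance Seeds, configuration summary and package version.
#' @export
setClass("ExperimentReport", representation(
  metrics = "list", survivalComparisons = "list", baselines = "list",
  split = "list", rocCurves = "list", provenance = "list"
))
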