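## Synthetic advanced-gastric-cancer cohorts with a planted benefit signal.

.clinFeatureNames <- c("young_onset", "male", "intestinal_histology",
                       "prior_trastuzumab", "duration_lt3", "duration_ge6")

#' Latent benefit score of one patient
#'
#' Deterministic log-scale benefit score: intercept + clinical terms +
#' per-variant main effects + pairwise interaction terms for variant pairs the
#' patient carries completely. The generator multiplies the median PFS by
#' `exp(score)` (accelerated-time form).
#'
#' @param clinical Numeric binary vector of length 6 in the
#'   [buildClinicalFeatures()] order.
#' @param variantIdx Integer set of 1-based variant indices carried.
#' @param spec An [EffectSpec].
#' @return A single numeric score.
#' @examples
#' benefitScore(numeric(6), c(1, 2),
#'              effectSpec(10, gammaPairs = cbind(1, 2, 2)))
#' @export
benefitScore <- function(clinical, variantIdx, spec) {
  stopifnot(is(spec, "EffectSpec"))
  V <- length(spec@betaVariant)
  variantIdx <- unique(as.integer(variantIdx))
  if (length(variantIdx) && any(variantIdx < 1L | variantIdx > V))
    stop("unknown variant index: ",
         paste(variantIdx[variantIdx < 1L | variantIdx > V], collapse = ", "),
         call. = FALSE)
  clinical <- rep_len(as.numeric(clinical), length(spec@betaClinical))
  s <- spec@beta0 + sum(spec@betaClinical * clinical) +
    sum(spec@betaVariant[variantIdx])
  if (nrow(spec@gammaPairs)) {
    has <- logical(V); has[variantIdx] <- TRUE
    both <- has[spec@gammaPairs[, 1L]] & has[spec@gammaPairs[, 2L]]
    s <- s + sum(spec@gammaPairs[both, 3L])
  }
  s
}

# vectorised scores for a whole cohort (Clin: n x 6, M: n x V binary)
.benefitScores <- function(Clin, M, spec) {
  s <- spec@beta0 + drop(Clin %*% spec@betaClinical) +
    drop(M %*% spec@betaVariant)
  gp <- spec@gammaPairs
  for (r in seq_len(nrow(gp)))
    s <- s + gp[r, 3L] * (M[, gp[r, 1L]] * M[, gp[r, 2L]])
  s
}

#' Draw one variant profile
#'
#' Each panel variant is included independently with its configured
#' prevalence. Uses the current RNG stream (seed with `set.seed()`).
#'
#' @param config A [CohortConfig].
#' @return Sorted integer vector of 1-based variant indices (a set).
#' @export
sampleVariantProfile <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  p <- config@variantPrevalences
  which(runif(length(p)) < p)
}

#' Draw survival endpoints given benefit scores
#'
#' PFS is exponential with median `basePFSMedian * exp(score)`; OS adds an
#' independent exponential post-progression time whose null-score median is
#' calibrated so that the cohort OS median equals `baseOSMedian`, scaled by
#' `exp(scoreOS)`. One administrative censoring time per patient, uniform on
#' `[0, censoringMax]`, truncates both endpoints consistently (a censored OS
#' implies a censored or earlier-observed PFS). Vectorised over scores; uses
#' the current RNG stream.
#'
#' @param score,scoreOS Numeric benefit scores (recycled to a common length).
#' @param config A [CohortConfig].
#' @return `data.frame` with `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event`.
#' @export
sampleSurvival <- function(score, scoreOS, config) {
  stopifnot(is(config, "CohortConfig"))
  if (config@basePFSMedian <= 0 || config@baseOSMedian <= 0)
    stop("survival medians must be positive", call. = FALSE)
  n <- max(length(score), length(scoreOS))
  score <- rep_len(as.numeric(score), n)
  scoreOS <- rep_len(as.numeric(scoreOS), n)
  tPFS <- rexp(n, rate = log(2) / (config@basePFSMedian * exp(score)))
  tPPS <- rexp(n, rate = log(2) / (config@ppsMedian * exp(scoreOS)))
  tOS <- tPFS + tPPS
  if (config@censoringRate > 0) {
    cens <- runif(n, 0, config@censoringMax)
  } else {
    cens <- rep(Inf, n)
  }
  data.frame(pfs_months = pmin(tPFS, cens),
             pfs_event = as.integer(tPFS <= cens),
             os_months = pmin(tOS, cens),
             os_event = as.integer(tOS <= cens))
}

.drawDuration <- function(n, pLt3, pGe6) {
  u <- runif(n)
  ifelse(u < pLt3, "lt3", ifelse(u < pLt3 + pGe6, "ge6", "mid"))
}

#' Generate a synthetic cohort
#'
#' Draws clinical covariates, variant profiles and survival endpoints under
#' the configured stated world. Fully deterministic given `config@seed`.
#'
#' @param config A [CohortConfig].
#' @return A [PacCohort] with `nPatients` columns.
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 20, seed = 7))
#' pfsMonths(cohort)[1:5]
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  n <- config@nPatients
  V <- config@nSNV + config@nCNV
  panel <- .panelTable(config)
  cp <- config@clinicalPrevalences

  set.seed(config@seed)
  # truncated-normal ages via the inverse-CDF on the truncated range
  plo <- stats::pnorm((config@ageMin - config@ageMean) / config@ageSD)
  phi <- stats::pnorm((config@ageMax - config@ageMean) / config@ageSD)
  age <- round(config@ageMean +
                 config@ageSD * qnorm(runif(n, plo, phi)))
  age <- pmin(pmax(age, config@ageMin), config@ageMax)
  sex <- ifelse(runif(n) < cp[["male"]], "male", "female")
  histology <- ifelse(runif(n) < cp[["intestinal"]], "intestinal", "diffuse")
  setting <- ifelse(runif(n) < cp[["initially_metastatic"]],
                    "initially_metastatic", "recurrent")
  gastrectomy <- as.integer(runif(n) < cp[["prior_gastrectomy"]])
  trastuzumab <- as.integer(runif(n) < cp[["prior_trastuzumab"]])
  duration <- .drawDuration(n, cp[["duration_lt3"]], cp[["duration_ge6"]])

  M <- if (n > 0)
    matrix(runif(n * V), n, V) <
      matrix(config@variantPrevalences, n, V, byrow = TRUE)
  else matrix(FALSE, 0L, V)
  storage.mode(M) <- "integer"

  Clin <- cbind(young_onset = as.integer(age < 40),
                male = as.integer(sex == "male"),
                intestinal_histology = as.integer(histology == "intestinal"),
                prior_trastuzumab = trastuzumab,
                duration_lt3 = as.integer(duration == "lt3"),
                duration_ge6 = as.integer(duration == "ge6"))
  score <- .benefitScores(Clin, M, config@effect)
  scoreOS <- drop(M %*% config@effect@betaVariantOS)
  surv <- sampleSurvival(score, scoreOS, config)

  cd <- DataFrame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_years = as.integer(age),
    sex = sex, histology = histology, clinical_setting = setting,
    prior_gastrectomy = gastrectomy, prior_trastuzumab = trastuzumab,
    first_line_duration = duration,
    pfs_months = surv$pfs_months, pfs_event = surv$pfs_event,
    os_months = surv$os_months, os_event = surv$os_event)
  rownames(cd) <- cd$patient_id

  se <- SummarizedExperiment(
    assays = list(occurrence = t(M)),
    rowData = panel, colData = cd)
  rownames(se) <- panel$variant_id
  meta <- list(seed = config@seed, nPatients = n, panel = dim(panel))
  out <- new("PacCohort", se)
  metadata(out)$config <- meta
  validObject(out)
  out
}

## ---- tabular writers -------------------------------------------------------

#' Write the documented cohort CSV formats
#'
#' `writePatientCSV()` writes one row per patient with the fixed column set
#' `patient_id, age_years, sex, histology, clinical_setting,
#' prior_gastrectomy, prior_trastuzumab, first_line_duration, pfs_months,
#' pfs_event, os_months, os_event`. `writeVariantCSV()` writes the long-format
#' variant table `patient_id, gene, variant_id, variant_class, pathogenicity`
#' (variants sorted by gene then identifier within each patient, a canonical
#' order that makes write/load/write round trips byte-identical). Survival
#' times are printed with 17 significant digits so they re-parse exactly.
#'
#' @param cohort A [PacCohort].
#' @param path Output file path.
#' @return The path, invisibly.
#' @seealso [loadCohort()]
#' @export
writePatientCSV <- function(cohort, path) {
  stopifnot(is(cohort, "PacCohort"))
  cd <- as.data.frame(colData(cohort))
  cols <- c("patient_id", "age_years", "sex", "histology", "clinical_setting",
            "prior_gastrectomy", "prior_trastuzumab", "first_line_duration",
            "pfs_months", "pfs_event", "os_months", "os_event")
  .writeCSVExact(cd[, cols, drop = FALSE], path)
}

#' @rdname writePatientCSV
#' @export
writeVariantCSV <- function(cohort, path) {
  stopifnot(is(cohort, "PacCohort"))
  rd <- as.data.frame(rowData(cohort))
  occ <- assay(cohort, "occurrence")
  pid <- patientIDs(cohort)
  rows <- lapply(seq_len(ncol(occ)), function(j) {
    idx <- which(occ[, j] != 0)
    if (!length(idx)) return(NULL)
    sub <- rd[idx, c("gene", "variant_id", "variant_class", "pathogenicity")]
    sub <- sub[order(sub$gene, sub$variant_id, method = "radix"), ]
    cbind(patient_id = pid[j], sub)
  })
  rows <- Filter(Negate(is.null), rows)
  df <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(patient_id = character(), gene = character(),
               variant_id = character(), variant_class = character(),
               pathogenicity = character())
  .writeCSVExact(df[, c("patient_id", "gene", "variant_id", "variant_class",
                        "pathogenicity")], path)
}
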