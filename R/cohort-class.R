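#' Accessors for PacCohort objects
#'
#' Convenience accessors over the `colData` of a [PacCohort]: survival
#' endpoints, event flags, patient identifiers and per-patient variant sets.
#'
#' @param x A [PacCohort].
#' @param ... For `variantSets`, `as` chooses `"id"` (variant identifiers,
#'   default) or `"index"` (1-based row indices into the cohort panel).
#' @return Numeric/integer/character vectors; for `variantSets` a named list,
#'   one element per patient.
#' @aliases pfsMonths pfsEvent osMonths osEvent patientIDs variantSets
#' @name PacCohort-accessors
NULL

#' @rdname PacCohort-accessors
#' @export
setMethod("pfsMonths", "PacCohort", function(x) colData(x)$pfs_months)
#' @rdname PacCohort-accessors
#' @export
setMethod("pfsEvent", "PacCohort", function(x) colData(x)$pfs_event)
#' @rdname PacCohort-accessors
#' @export
setMethod("osMonths", "PacCohort", function(x) colData(x)$os_months)
#' @rdname PacCohort-accessors
#' @export
setMethod("osEvent", "PacCohort", function(x) colData(x)$os_event)
#' @rdname PacCohort-accessors
#' @export
setMethod("patientIDs", "PacCohort", function(x) colData(x)$patient_id)

#' @rdname PacCohort-accessors
#' @export
setMethod("variantSets", "PacCohort", function(x, as = c("id", "index")) {
  as <- match.arg(as)
  occ <- assay(x, "occurrence")
  ids <- rowData(x)$variant_id
  out <- lapply(seq_len(ncol(occ)), function(j) {
    idx <- which(occ[, j] != 0)
    if (as == "id") ids[idx] else idx
  })
  names(out) <- patientIDs(x)
  out
})

setMethod("show", "PacCohort", function(object) {
  cd <- colData(object)
  cat("PacCohort:", ncol(object), "patients,", nrow(object),
      "panel variants\n")
  if (ncol(object)) {
    cat(sprintf("  PFS events %d/%d, OS events %d/%d\n",
                sum(cd$pfs_event), ncol(object),
                sum(cd$os_event), ncol(object)))
    cat(sprintf("  mean variant burden %.2f\n",
                mean(colSums(assay(object, "occurrence") != 0))))
  }
  invisible(object)
})

#' Utilities for VariantVocabulary
#'
#' `variantVocabulary()` builds a vocabulary from identifier/gene vectors
#' (sorting lexicographically by gene then identifier); `variantIndex()` maps
#' identifiers to 1-based indices, erroring on unknown identifiers.
#'
#' @param ids Character variant identifiers.
#' @param gene Character gene symbols, parallel to `ids`.
#' @param vocab A [VariantVocabulary].
#' @return `variantVocabulary()` a [VariantVocabulary]; `variantIndex()` an
#'   integer vector.
#' @name VariantVocabulary-utils
#' @export
variantVocabulary <- function(ids, gene = rep(NA_character_, length(ids))) {
  stopifnot(length(ids) == length(gene))
  keep <- !duplicated(ids)
  ids <- as.character(ids)[keep]; gene <- as.character(gene)[keep]
  ord <- order(gene, ids, method = "radix")
  new("VariantVocabulary", ids = ids[ord], gene = gene[ord])
}

#' @rdname VariantVocabulary-utils
#' @export
setMethod("variantIndex", "VariantVocabulary", function(vocab, ids) {
  idx <- match(ids, vocab@ids)
  if (anyNA(idx))
    stop("unknown variant identifier(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
})

#' @export
setMethod("length", "VariantVocabulary", function(x) length(x@ids))

setMethod("show", "VariantVocabulary", function(object) {
  cat("VariantVocabulary with", length(object@ids), "variants\n")
  if (length(object@ids))
    cat("  first:", paste(utils::head(object@ids, 3L), collapse = ", "), "\n")
  invisible(object)
})

#' Accessors for PacFeatureSet objects
#'
#' @param x A [PacFeatureSet].
#' @return `featureLabels()` the label factor; `vocabulary()` the
#'   [VariantVocabulary].
#' @name PacFeatureSet-accessors
NULL

#' @rdname PacFeatureSet-accessors
#' @export
setMethod("featureLabels", "PacFeatureSet", function(x) x@labels)
#' @rdname PacFeatureSet-accessors
#' @export
setMethod("vocabulary", "PacFeatureSet", function(x) x@vocabulary)

setMethod("show", "PacFeatureSet", function(object) {
  cat("PacFeatureSet:", length(object@patientIDs), "patients,",
      ncol(object@clinical), "clinical features,",
      length(object@vocabulary@ids), "vocabulary variants\n")
  print(table(object@labels))
  invisible(object)
})

setMethod("show", "SurvivalCurve", function(object) {
  cat("SurvivalCurve with", length(object@time), "event times\n")
  if (length(object@time))
    cat(sprintf("  last time %.3g, final S = %.4f\n",
                max(object@time), min(object@surv)))
  invisible(object)
})

setMethod("show", "SurvivalComparison", function(object) {
  cat("SurvivalComparison:",
      paste(sprintf("%s (n=%d, median=%.3g)", object@groups,
                    object@nPerGroup[object@groups],
                    object@medians[object@groups]), collapse = " vs "), "\n")
  if (object@testDefined)
    cat(sprintf("  log-rank chi-square = %.4f, p = %.4g\n",
                object@statistic, object@pValue))
  else cat("  log-rank test undefined for this stratification\n")
  invisible(object)
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@kind, "(seed", paste0(object@seed, ")"), "\n")
  invisible(object)
})

setMethod("show", "PacModel", function(object) {
  cat("PacModel:", object@spec@kind, "fitted on",
      length(object@vocabulary@ids), "vocabulary variants +",
      length(object@clinicalNames), "clinical features\n")
  invisible(object)
})
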