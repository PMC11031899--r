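#' @rdname PacCohort-accessors
#' @export
setGeneric("pfsMonths", function(x) standardGeneric("pfsMonths"))
#' @rdname PacCohort-accessors
#' @export
setGeneric("pfsEvent", function(x) standardGeneric("pfsEvent"))
#' @rdname PacCohort-accessors
#' @export
setGeneric("osMonths", function(x) standardGeneric("osMonths"))
#' @rdname PacCohort-accessors
#' @export
setGeneric("osEvent", function(x) standardGeneric("osEvent"))
#' @rdname PacCohort-accessors
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))
#' @rdname PacCohort-accessors
#' @export
setGeneric("variantSets", function(x, ...) standardGeneric("variantSets"))

#' @rdname VariantVocabulary-utils
#' @export
setGeneric("variantIndex", function(vocab, ids) standardGeneric("variantIndex"))

#' @rdname predictProba
#' @export
setGeneric("predictProba",
           function(model, features, indices, ...) standardGeneric("predictProba"))

#' @rdname PacFeatureSet-accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))
#' @rdname PacFeatureSet-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
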