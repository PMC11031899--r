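## PFS-threshold labelling, binary feature construction, stratified split.

#' Label patients by PFS thresholds
#'
#' A patient with observed PFS strictly above `tSensitive` months is
#' paclitaxel-sensitive (an event is not required: a censoring time beyond the
#' threshold already proves survival past it). A patient progressing (event)
#' strictly before `tResistant` months is paclitaxel-resistant. Everything
#' else is indeterminate and excluded: censored before `tResistant`, or any
#' observation inside `[tResistant, tSensitive]`.
#'
#' @param pfsMonths Non-negative observed PFS times (vectorised).
#' @param pfsEvent 0/1 event flags.
#' @param tResistant,tSensitive Thresholds in months, `0 < tResistant <=
#'   tSensitive` (defaults 3 and 6).
#' @return Factor with levels `sensitive`, `resistant`, `excluded`.
#' @examples
#' assignLabel(c(2, 6.5, 2, 4), c(1, 1, 0, 1))
#' @export
assignLabel <- function(pfsMonths, pfsEvent, tResistant = 3, tSensitive = 6) {
  if (!(tResistant > 0 && tResistant <= tSensitive))
    stop("thresholds must satisfy 0 < tResistant <= tSensitive", call. = FALSE)
  if (any(is.na(pfsMonths)) || any(pfsMonths < 0))
    stop("pfsMonths must be non-negative", call. = FALSE)
  stopifnot(length(pfsMonths) == length(pfsEvent),
            all(pfsEvent %in% c(0, 1)))
  out <- rep("excluded", length(pfsMonths))
  out[pfsMonths > tSensitive] <- "sensitive"
  out[pfsMonths < tResistant & pfsEvent == 1] <- "resistant"
  factor(out, levels = c("sensitive", "resistant", "excluded"))
}

#' Binary clinical feature matrix
#'
#' Fixed-order encoding used throughout the package: `young_onset` (age below
#' the cutoff, default 40 years), `male`, `intestinal_histology` (mixed-type
#' histology is folded into diffuse upstream), `prior_trastuzumab`, and two
#' dummies `duration_lt3` / `duration_ge6` encoding the three-level first-line
#' duration with the middle category as reference.
#'
#' @param cohort A [PacCohort] (or its `colData` as a data.frame).
#' @param ageCutoffYoung Young-onset age cutoff in years (default 40).
#' @return n x 6 integer matrix with column names.
#' @export
buildClinicalFeatures <- function(cohort, ageCutoffYoung = 40) {
  cd <- if (is(cohort, "PacCohort")) as.data.frame(colData(cohort))
        else as.data.frame(cohort)
  histology <- as.character(cd$histology)
  histology[histology == "mixed"] <- "diffuse"
  okH <- histology %in% c("intestinal", "diffuse")
  if (!all(okH))
    stop("unknown value in field 'histology': ",
         paste(unique(histology[!okH]), collapse = ", "), call. = FALSE)
  sex <- as.character(cd$sex)
  if (!all(sex %in% c("male", "female")))
    stop("unknown value in field 'sex'", call. = FALSE)
  dur <- as.character(cd$first_line_duration)
  if (!all(dur %in% c("lt3", "mid", "ge6")))
    stop("unknown value in field 'first_line_duration'", call. = FALSE)
  m <- cbind(young_onset = as.integer(cd$age_years < ageCutoffYoung),
             male = as.integer(sex == "male"),
             intestinal_histology = as.integer(histology == "intestinal"),
             prior_trastuzumab = as.integer(cd$prior_trastuzumab),
             duration_lt3 = as.integer(dur == "lt3"),
             duration_ge6 = as.integer(dur == "ge6"))
  rownames(m) <- cd$patient_id
  m
}

#' Build the variant vocabulary of a cohort
#'
#' Every pathogenic variant observed in at least one patient of `cohort` gets
#' one index; ordering is deterministic (lexicographic by gene, then variant
#' identifier).
#'
#' @param cohort A [PacCohort].
#' @return A [VariantVocabulary].
#' @export
buildVariantVocabulary <- function(cohort) {
  stopifnot(is(cohort, "PacCohort"))
  occ <- assay(cohort, "occurrence")
  seen <- rowSums(occ != 0) > 0
  rd <- rowData(cohort)
  variantVocabulary(rd$variant_id[seen], rd$gene[seen])
}

#' Binary variant presence matrix
#'
#' @param cohort A [PacCohort].
#' @param vocab A [VariantVocabulary] defining the column layout.
#' @param unknownVariants `"error"` (default) refuses variants outside the
#'   vocabulary; `"drop"` silently ignores them (used for validation patients
#'   under the train-only vocabulary policy).
#' @return n x V integer 0/1 matrix (patients x vocabulary variants).
#' @export
buildVariantMatrix <- function(cohort, vocab,
                               unknownVariants = c("error", "drop")) {
  stopifnot(is(cohort, "PacCohort"), is(vocab, "VariantVocabulary"))
  unknownVariants <- match.arg(unknownVariants)
  occ <- assay(cohort, "occurrence")
  ids <- rowData(cohort)$variant_id
  pos <- match(ids, vocab@ids)
  carried <- rowSums(occ != 0) > 0
  if (unknownVariants == "error" && any(carried & is.na(pos)))
    stop("variant(s) outside the vocabulary: ",
         paste(ids[carried & is.na(pos)], collapse = ", "), call. = FALSE)
  n <- ncol(occ)
  m <- matrix(0L, n, length(vocab@ids),
              dimnames = list(colnames(occ), vocab@ids))
  keep <- !is.na(pos)
  if (any(keep))
    m[, pos[keep]] <- t(occ[keep, , drop = FALSE] != 0) + 0L
  m
}

#' Assemble the supervised-learning feature set
#'
#' Combines PFS labels, binary clinical features, and the variant
#' representation (both as index sets and as a presence matrix) for all
#' patients of the cohort.
#'
#' @inheritParams buildVariantMatrix
#' @param tResistant,tSensitive Label thresholds, see [assignLabel()].
#' @param ageCutoffYoung See [buildClinicalFeatures()].
#' @return A [PacFeatureSet].
#' @export
buildFeatureSet <- function(cohort, vocab = buildVariantVocabulary(cohort),
                            tResistant = 3, tSensitive = 6,
                            ageCutoffYoung = 40,
                            unknownVariants = c("error", "drop")) {
  unknownVariants <- match.arg(unknownVariants)
  vm <- buildVariantMatrix(cohort, vocab, unknownVariants)
  sets <- lapply(seq_len(nrow(vm)), function(i) unname(which(vm[i, ] != 0)))
  new("PacFeatureSet",
      patientIDs = patientIDs(cohort),
      clinical = buildClinicalFeatures(cohort, ageCutoffYoung),
      variantSets = sets,
      variantMatrix = vm,
      labels = assignLabel(pfsMonths(cohort), pfsEvent(cohort),
                           tResistant, tSensitive),
      vocabulary = vocab)
}

#' Outcome-stratified train/validation split
#'
#' Validation size is `ceiling(n * fraction)`; per-class validation counts are
#' allocated by largest remainder of `classCount * fraction` (ties broken
#' toward the larger class), then membership is drawn at random within class
#' under the seed. With 288 labelled patients and fraction 0.2 this yields the
#' 230/58 split of the motivating study design.
#'
#' @param labels Two-class vector (factor, character or 0/1) of length n;
#'   patients labelled `excluded` must be removed beforehand.
#' @param validationFraction Fraction in (0, 1), default 0.2.
#' @param seed Integer seed.
#' @return List with sorted integer `train` and `validation` indices.
#' @examples
#' stratifiedSplit(rep(c("sensitive", "resistant"), c(116, 172)), seed = 1)
#' @export
stratifiedSplit <- function(labels, validationFraction = 0.2, seed = 1L) {
  if (!(validationFraction > 0 && validationFraction < 1))
    stop("validationFraction must lie in (0, 1)", call. = FALSE)
  labels <- as.character(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("stratified split needs exactly two classes, got ",
         length(classes), call. = FALSE)
  counts <- table(factor(labels, classes))
  valN <- as.integer(ceiling(n * validationFraction))
  quota <- as.numeric(counts) * validationFraction
  alloc <- floor(quota)
  extra <- valN - sum(alloc)
  if (extra > 0) {
    rem <- quota - alloc
    ord <- order(-rem, -as.numeric(counts))  # ties toward the larger class
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1
  }
  set.seed(seed)
  val <- integer(0)
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    k <- alloc[ci]
    if (k > 0) val <- c(val, members[sample.int(length(members), k)])
  }
  list(train = sort(setdiff(seq_len(n), val)), validation = sort(val))
}
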