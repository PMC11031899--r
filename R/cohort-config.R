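## Survival model internals: PFS ~ Exp(rate a); OS = PFS + PPS with
## PPS ~ Exp(rate b) (post-progression survival). The OS survivor function is
## hypoexponential: S(t) = (a e^{-bt} - b e^{-at}) / (a - b), a != b.

.hypoexpSurv <- function(t, a, b) {
  if (abs(a - b) < 1e-12) return(exp(-a * t) * (1 + a * t))
  (a * exp(-b * t) - b * exp(-a * t)) / (a - b)
}

# integral of the hypoexponential survivor function on [0, c]
.hypoexpSurvInt <- function(cc, a, b) {
  if (abs(a - b) < 1e-12)
    return((2 - exp(-a * cc) * (2 + a * cc)) / a)
  (a * (1 - exp(-b * cc)) / b - b * (1 - exp(-a * cc)) / a) / (a - b)
}

# post-progression median m2 such that the null-score OS median equals osMed
.calibratePPSMedian <- function(pfsMed, osMed) {
  a <- log(2) / pfsMed
  f <- function(m2) .hypoexpSurv(osMed, a, log(2) / m2) - 0.5
  uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-12)$root
}

# administrative censoring horizon hitting the target OS censoring fraction
# (computed at null score; the realised fraction shifts with planted effects)
.calibrateCensoringMax <- function(rate, pfsMed, ppsMed) {
  if (rate <= 0) return(Inf)
  a <- log(2) / pfsMed
  b <- log(2) / ppsMed
  f <- function(cc) .hypoexpSurvInt(cc, a, b) / cc - rate
  uniroot(f, lower = 1e-6, upper = 1e7, tol = 1e-10)$root
}

#' Construct a planted-effect specification
#'
#' All coefficients default to zero: an all-zero spec yields outcomes
#' independent of every covariate. `gammaPairs` plants pairwise variant
#' interactions (both variants must be carried for the term to fire), the
#' mechanism by which a non-additive benefit signal is simulated.
#'
#' @param nVariants Panel size the spec refers to (default 102).
#' @param beta0 Intercept.
#' @param betaClinical Named or length-6 numeric; clinical coefficients in the
#'   [buildClinicalFeatures()] order.
#' @param betaVariant Per-variant main effects (recycled scalar allowed).
#' @param gammaPairs NULL or a 3-column matrix / data.frame `(j, k, gamma)` of
#'   1-based variant indices and interaction coefficients.
#' @param betaVariantOS Per-variant effects on post-progression time.
#' @return An [EffectSpec].
#' @examples
#' effectSpec(10, gammaPairs = cbind(1, 2, 1.5))
#' @export
effectSpec <- function(nVariants = 102L, beta0 = 0,
                       betaClinical = numeric(6), betaVariant = 0,
                       gammaPairs = NULL, betaVariantOS = 0) {
  nVariants <- .assertCount(nVariants, "nVariants", allowZero = TRUE)
  clinNames <- c("young_onset", "male", "intestinal_histology",
                 "prior_trastuzumab", "duration_lt3", "duration_ge6")
  if (is.null(names(betaClinical))) {
    stopifnot(length(betaClinical) %in% c(1L, 6L))
    betaClinical <- rep_len(betaClinical, 6L)
    names(betaClinical) <- clinNames
  } else {
    full <- stats::setNames(numeric(6), clinNames)
    bad <- setdiff(names(betaClinical), clinNames)
    if (length(bad)) stop("unknown clinical coefficient(s): ",
                          paste(bad, collapse = ", "))
    full[names(betaClinical)] <- betaClinical
    betaClinical <- full
  }
  betaVariant <- rep_len(as.numeric(betaVariant), nVariants)
  betaVariantOS <- rep_len(as.numeric(betaVariantOS), nVariants)
  if (is.null(gammaPairs)) {
    gammaPairs <- matrix(numeric(0), 0L, 3L)
  } else {
    gammaPairs <- as.matrix(gammaPairs)
    storage.mode(gammaPairs) <- "numeric"
  }
  colnames(gammaPairs) <- c("j", "k", "gamma")
  new("EffectSpec", beta0 = as.numeric(beta0), betaClinical = betaClinical,
      betaVariant = betaVariant, gammaPairs = gammaPairs,
      betaVariantOS = betaVariantOS)
}

#' Configure the synthetic cohort generator
#'
#' Defaults encode the stated world this generator emulates: a panel of 73
#' SNVs and 29 CNVs over 87 genes (round-robin variant-to-gene assignment, so
#' some genes carry both an SNV and a CNV), clinical covariate prevalences
#' taken from the printed marginal distribution of the source cohort (65.6%
#' male, 64.2% intestinal, 16.7% prior trastuzumab, first-line duration split
#' 25.3% / 37.9% / 36.8% for <3 / 3-6 / >=6 months), age from a truncated
#' normal (mean 63, sd 12, range 25-91), and exponential survival calibrated
#' so the null-score Kaplan-Meier medians equal 2.70 months (PFS) and 13.28
#' months (OS). The post-progression median is solved numerically at
#' construction time (the OS median of a sum of exponentials is not the sum of
#' the medians), as is the administrative censoring horizon for
#' `censoringRate`.
#'
#' @param nPatients Cohort size.
#' @param nGenes,nSNV,nCNV Panel composition.
#' @param variantPrevalences Length `nSNV + nCNV` carrier probabilities in
#'   \[0, 1\] (scalar recycled; default 0.08 per variant, a realistic
#'   pathogenic-variant burden of ~8 variants per patient).
#' @param clinicalPrevalences Named probabilities; see Details for names.
#' @param effect An [EffectSpec]; default all-zero (null world).
#' @param basePFSMedian,baseOSMedian Null-score medians in months.
#' @param censoringRate Target fraction of OS observations administratively
#'   censored (uniform censoring on \[0, cMax\]); 0 disables censoring.
#' @param ageMean,ageSD,ageMin,ageMax Age model in years.
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A validated [CohortConfig].
#' @examples
#' cfg <- cohortConfig(nPatients = 50, seed = 1)
#' cohort <- generateCohort(cfg)
#' @export
cohortConfig <- function(nPatients,
                         nGenes = 87L, nSNV = 73L, nCNV = 29L,
                         variantPrevalences = 0.08,
                         clinicalPrevalences = c(
                           male = 189 / 288, intestinal = 185 / 288,
                           initially_metastatic = 192 / 288,
                           prior_gastrectomy = 146 / 288,
                           prior_trastuzumab = 48 / 288,
                           duration_lt3 = 73 / 288, duration_ge6 = 106 / 288),
                         effect = effectSpec(nSNV + nCNV),
                         basePFSMedian = 2.70, baseOSMedian = 13.28,
                         censoringRate = 0,
                         ageMean = 63, ageSD = 12, ageMin = 25, ageMax = 91,
                         seed = 1L) {
  nPatients <- .assertCount(nPatients, "nPatients", allowZero = TRUE)
  nGenes <- .assertCount(nGenes, "nGenes")
  nSNV <- .assertCount(nSNV, "nSNV")
  nCNV <- .assertCount(nCNV, "nCNV")
  V <- nSNV + nCNV
  variantPrevalences <- rep_len(.assertProb(variantPrevalences,
                                            "variantPrevalences"), V)
  if (basePFSMedian <= 0 || baseOSMedian <= 0)
    stop("survival medians must be positive", call. = FALSE)
  ppsMedian <- .calibratePPSMedian(basePFSMedian, baseOSMedian)
  censoringMax <- .calibrateCensoringMax(censoringRate, basePFSMedian,
                                         ppsMedian)
  new("CohortConfig",
      nPatients = nPatients, nGenes = nGenes, nSNV = nSNV, nCNV = nCNV,
      variantPrevalences = variantPrevalences,
      clinicalPrevalences = clinicalPrevalences,
      ageMean = as.numeric(ageMean), ageSD = as.numeric(ageSD),
      ageMin = as.numeric(ageMin), ageMax = as.numeric(ageMax),
      effect = effect,
      basePFSMedian = as.numeric(basePFSMedian),
      baseOSMedian = as.numeric(baseOSMedian),
      ppsMedian = ppsMedian,
      censoringRate = as.numeric(censoringRate),
      censoringMax = censoringMax,
      seed = as.integer(seed))
}

# panel layout: variant i -> gene ((i - 1) mod nGenes) + 1, SNVs first
.panelTable <- function(config) {
  V <- config@nSNV + config@nCNV
  gene <- sprintf("GENE%03d", ((seq_len(V) - 1L) %% config@nGenes) + 1L)
  class <- rep(c("SNV", "CNV"), c(config@nSNV, config@nCNV))
  id <- paste0(gene, "_", class)
  # disambiguate if a gene receives several variants of one class
  dup <- ave(seq_along(id), id, FUN = seq_along)
  id <- ifelse(ave(seq_along(id), id, FUN = length) > 1L,
               paste0(id, dup), id)
  data.frame(variant_id = id, gene = gene, variant_class = class,
             pathogenicity = "pathogenic", stringsAsFactors = FALSE)
}
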