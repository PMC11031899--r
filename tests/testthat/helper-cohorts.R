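# Programmatic fixtures: hand-built cohorts with fully controlled clinical
# fields, outcomes and variant assignments.

# cd: data.frame with any subset of the colData fields (missing ones get
# defaults); variants: named list patient_id -> character vector of variant
# ids; panel: data.frame(variant_id, gene) describing the panel.
makeCohort <- function(n = nrow(cd), cd = data.frame(row = seq_len(n)),
                       variants = list(),
                       panel = data.frame(variant_id = character(),
                                          gene = character())) {
  defaults <- data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    age_years = 60L, sex = "male", histology = "intestinal",
    clinical_setting = "initially_metastatic",
    prior_gastrectomy = 0L, prior_trastuzumab = 0L,
    first_line_duration = "mid",
    pfs_months = 5, pfs_event = 1L, os_months = 12, os_event = 1L,
    stringsAsFactors = FALSE)
  for (nm in intersect(names(cd), names(defaults))) defaults[[nm]] <- cd[[nm]]
  cd <- defaults
  if (nrow(panel) == 0L && length(variants))
    panel <- data.frame(variant_id = sort(unique(unlist(variants))),
                        gene = "GENEX", stringsAsFactors = FALSE)
  panel$variant_class <- if (nrow(panel)) "SNV" else character()
  panel$pathogenicity <- if (nrow(panel)) "pathogenic" else character()
  occ <- matrix(0L, nrow(panel), n,
                dimnames = list(panel$variant_id, cd$patient_id))
  for (pid in names(variants)) {
    hit <- match(variants[[pid]], panel$variant_id)
    occ[hit, pid] <- 1L
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(occurrence = occ), rowData = panel,
    colData = S4Vectors::DataFrame(cd, row.names = cd$patient_id))
  new("PacCohort", se)
}

# small separable modelling problem: variant VA implies sensitive
separableFeatureSet <- function() {
  cd <- data.frame(
    pfs_months = c(8, 9, 1, 2), pfs_event = 1L,
    os_months = c(12, 13, 3, 4))
  co <- makeCohort(cd = cd,
                   variants = list(T0001 = "VA", T0002 = "VA",
                                   T0003 = "VB", T0004 = "VB"),
                   panel = data.frame(variant_id = c("VA", "VB"),
                                      gene = c("G1", "G2")))
  buildFeatureSet(co)
}

# default-world random cohort at a given size/seed
smallCohort <- function(n, seed, ...) {
  generateCohort(cohortConfig(nPatients = n, seed = seed, ...))
}

# labelled feature set + split for a generated cohort
fitReady <- function(cohort, splitSeed = 1L, fraction = 0.2) {
  fs <- buildFeatureSet(cohort)
  lab <- which(featureLabels(fs) != "excluded")
  sp <- stratifiedSplit(as.character(featureLabels(fs)[lab]), fraction,
                        seed = splitSeed)
  list(fs = fs, train = lab[sp$train], validation = lab[sp$validation])
}

# the frozen planted-signal worlds used by the signal-recovery benchmark:
# two 4-cycles of +/- gamma pairwise terms have exactly zero additive
# projection when the four prevalences are equal
epistasisCycle <- function(v, g)
  cbind(c(v[1], v[3], v[1], v[2]), c(v[2], v[4], v[3], v[4]), c(g, g, -g, -g))

interactionWorld <- function(gamma = 1.5, prevSignal = 0.3) {
  list(effect = effectSpec(102, gammaPairs = rbind(epistasisCycle(1:4, gamma),
                                                   epistasisCycle(5:8, gamma))),
       prev = { pr <- rep(0.08, 102); pr[1:8] <- prevSignal; pr })
}

additiveWorld <- function(beta = 0.5, prevSignal = 0.3) {
  list(effect = effectSpec(102, betaVariant = c(rep(beta, 10), rep(0, 92))),
       prev = { pr <- rep(0.08, 102); pr[1:10] <- prevSignal; pr })
}

# benchmark recipe for the embedding net (see the methods vignette)
embedBenchSpec <- function(seed)
  modelSpec("ann_with_ge", aggregation = "sum", learning_rate = 0.01,
            monitor = "auc", seed = seed)

# validation AUROC of one model kind on one generated world
worldAUROC <- function(world, spec, seed) {
  cfg <- cohortConfig(nPatients = 2000, variantPrevalences = world$prev,
                      effect = world$effect, seed = seed)
  fr <- fitReady(generateCohort(cfg), splitSeed = seed + 1L)
  m <- fitClassifier(spec, fr$fs, fr$train)
  auroc(predictProba(m, fr$fs, fr$validation),
        featureLabels(fr$fs)[fr$validation])
}
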