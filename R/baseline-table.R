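## Baseline-characteristics tables and the between-group categorical test.

#' Pearson chi-square balance test with Fisher fallback
#'
#' Pearson chi-square without continuity correction on a 2 x c contingency
#' table (two cohort subsets in rows), df = c - 1, p-value from the
#' chi-square upper tail. For 2 x 2 tables with any expected count below 5
#' the p-value is replaced by the Fisher exact test (the Pearson statistic is
#' still reported).
#'
#' @param tab 2 x c matrix of non-negative integer counts.
#' @return List with `statistic`, `p.value`, `df`, `method`.
#' @examples
#' categoricalBalanceTest(rbind(c(20, 10), c(10, 20)))
#' @export
categoricalBalanceTest <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("need a 2 x c table with c >= 2", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: a row or column sums to zero", call. = FALSE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  method <- "pearson"
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  if (ncol(tab) == 2L && any(expected < 5)) {
    method <- "fisher"
    p <- fisher.test(tab)$p.value
  }
  list(statistic = stat, p.value = p, df = df, method = method)
}

.characteristicLevels <- list(
  age_group = c("lt40", "40to69", "ge70"),
  sex = c("male", "female"),
  histology = c("intestinal", "diffuse"),
  clinical_setting = c("initially_metastatic", "recurrent"),
  prior_gastrectomy = c("yes", "no"),
  prior_trastuzumab = c("yes", "no"),
  first_line_duration = c("lt3", "mid", "ge6")
)

.characteristicValue <- function(cd, char) {
  switch(char,
    age_group = cut(cd$age_years, c(-Inf, 39.5, 69.5, Inf),
                    labels = c("lt40", "40to69", "ge70")),
    prior_gastrectomy = ifelse(cd$prior_gastrectomy == 1, "yes", "no"),
    prior_trastuzumab = ifelse(cd$prior_trastuzumab == 1, "yes", "no"),
    as.character(cd[[char]]))
}

#' Baseline-characteristics table
#'
#' Per-characteristic counts and one-decimal percentages (half rounded away
#' from zero, as in printed clinical tables) for one or two cohort subsets;
#' with two subsets a per-characteristic balance test p-value
#' ([categoricalBalanceTest()]) is attached. Age is additionally summarised
#' as median (range) in the `"ageSummary"` attribute.
#'
#' @param cohort A [PacCohort] (first subset).
#' @param cohort2 Optional second subset for a two-group table.
#' @param subsetNames Length-1 or 2 character names used in column labels.
#' @return `data.frame` with columns `characteristic`, `level`,
#'   `count_<name>`, `pct_<name>` per subset and `p_value` (NA for a
#'   single-subset table); attributes `n` (subset sizes) and `ageSummary`.
#' @export
summarizeCohort <- function(cohort, cohort2 = NULL,
                            subsetNames = c("group1", "group2")) {
  stopifnot(is(cohort, "PacCohort"), ncol(cohort) > 0)
  subsets <- list(as.data.frame(colData(cohort)))
  if (!is.null(cohort2)) {
    stopifnot(is(cohort2, "PacCohort"), ncol(cohort2) > 0)
    subsets <- c(subsets, list(as.data.frame(colData(cohort2))))
  }
  nms <- subsetNames[seq_along(subsets)]
  sizes <- vapply(subsets, nrow, 0L)

  rows <- list()
  for (char in names(.characteristicLevels)) {
    lv <- .characteristicLevels[[char]]
    counts <- vapply(subsets, function(cd)
      as.numeric(table(factor(.characteristicValue(cd, char), lv))),
      numeric(length(lv)))
    counts <- matrix(counts, nrow = length(lv))
    p <- NA_real_
    if (length(subsets) == 2L) {
      tab <- t(counts)
      keep <- colSums(tab) > 0
      if (sum(keep) >= 2L)
        p <- categoricalBalanceTest(tab[, keep, drop = FALSE])$p.value
    }
    df <- data.frame(characteristic = char, level = lv,
                     stringsAsFactors = FALSE)
    for (s in seq_along(subsets)) {
      df[[paste0("count_", nms[s])]] <- as.integer(counts[, s])
      df[[paste0("pct_", nms[s])]] <- pctOf(counts[, s], sizes[s])
    }
    df$p_value <- c(p, rep(NA_real_, length(lv) - 1L))
    rows[[char]] <- df
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "n") <- stats::setNames(sizes, nms)
  attr(out, "ageSummary") <- vapply(subsets, function(cd)
    sprintf("%g (%g-%g)", median(cd$age_years), min(cd$age_years),
            max(cd$age_years)), character(1))
  out
}

#' Export a baseline table
#'
#' Writes the [summarizeCohort()] data frame as CSV (`path`) and, optionally,
#' a human-readable text rendering (`textPath`).
#'
#' @param table A baseline table from [summarizeCohort()].
#' @param path CSV output path.
#' @param textPath Optional text output path.
#' @return `path`, invisibly.
#' @export
writeBaselineTable <- function(table, path, textPath = NULL) {
  .writeCSVExact(table, path)
  if (!is.null(textPath)) {
    n <- attr(table, "n")
    lines <- c("Baseline characteristics",
               paste0("  n = ", paste(sprintf("%s: %d", names(n), n),
                                      collapse = ", ")),
               paste0("  median age (range): ",
                      paste(attr(table, "ageSummary"), collapse = " vs ")), "")
    for (i in seq_len(nrow(table))) {
      cnt <- unlist(table[i, grep("^count_", names(table)), drop = TRUE])
      pct <- unlist(table[i, grep("^pct_", names(table)), drop = TRUE])
      lines <- c(lines, sprintf(
        "  %-22s %-22s %s%s", table$characteristic[i], table$level[i],
        paste(sprintf("%d (%.1f%%)", cnt, pct), collapse = "  vs  "),
        ifelse(is.na(table$p_value[i]), "",
               sprintf("   P = %.3f", table$p_value[i]))))
    }
    writeLines(lines, textPath)
  }
  invisible(path)
}
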