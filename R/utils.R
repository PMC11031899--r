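#' @import methods
#' @importFrom stats rnorm runif rexp rbinom plogis pchisq qnorm quantile
#'   uniroot rank fisher.test median
#' @importFrom utils read.csv
NULL

# round half away from zero, as printed clinical tables do
roundHalfAway <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage as printed in baseline-characteristics tables
#'
#' Computes `100 * count / total` rounded to one decimal place with halves
#' rounded away from zero (so 48/288 prints as 16.7, 44/93 as 47.3).
#'
#' @param count Non-negative count.
#' @param total Positive total.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
pctOf <- function(count, total, digits = 1) {
  stopifnot(all(total > 0), all(count >= 0))
  roundHalfAway(100 * count / total, digits)
}

# scalar formatting that round-trips doubles exactly through text
.fmtNum <- function(x) {
  if (is.integer(x) || is.logical(x)) return(as.character(as.integer(x)))
  sprintf("%.17g", x)
}

# write a data.frame as CSV with exact (round-trippable) numeric formatting
.writeCSVExact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), "NA", sprintf("%.17g", col))
    } else {
      as.character(col)
    }
  })
  body <- if (nrow(df) > 0L)
    apply(do.call(cbind, cols), 1L, paste, collapse = ",")
  else character(0)
  lines <- c(paste(names(df), collapse = ","), body)
  writeLines(lines, path)
  invisible(path)
}

.assertCount <- function(x, name, allowZero = FALSE) {
  lo <- if (allowZero) 0L else 1L
  if (length(x) != 1L || is.na(x) || x < lo || x != as.integer(x))
    stop(sprintf("'%s' must be a single %s integer",
                 name, if (allowZero) "non-negative" else "positive"),
         call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name, open = FALSE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad)
    stop(sprintf("'%s' must lie in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  as.numeric(x)
}

# deterministic per-stage seeds fanned out from one experiment seed
.stageSeed <- function(seed, stage) {
  offsets <- c(cohort = 0L, split = 1L, model_rf = 11L, model_lr = 12L,
               model_ann = 13L, model_ann_ge = 14L, bootstrap = 21L,
               survival = 31L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}
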