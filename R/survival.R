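## Kaplan-Meier estimation, median survival and the two-group log-rank test,
## implemented from first principles (risk-set counting).

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `n_i` the
#' number at risk just before `t_i`. Subjects censored at `t` are still at
#' risk at `t` (events precede censorings at ties, the standard convention).
#' With no censoring the estimate equals one minus the empirical CDF.
#'
#' @param times Positive observed times.
#' @param events 0/1 event flags (0 = censored).
#' @return A [SurvivalCurve]; zero-length when no events occur (S(t) = 1
#'   everywhere).
#' @examples
#' kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  evTimes <- sort(unique(times[events == 1]))
  if (!length(evTimes))
    return(new("SurvivalCurve", time = numeric(0), surv = numeric(0),
               nRisk = numeric(0), nEvent = numeric(0)))
  sortedAll <- sort(times)
  sortedEv <- sort(times[events == 1])
  # at risk just before t: #{T_obs >= t} = n - #{T_obs < t}
  nRisk <- length(times) - findInterval(evTimes, sortedAll, left.open = TRUE)
  nEvent <- findInterval(evTimes, sortedEv) -
    findInterval(evTimes, sortedEv, left.open = TRUE)
  surv <- cumprod(1 - nEvent / nRisk)
  new("SurvivalCurve", time = evTimes, surv = surv,
      nRisk = as.numeric(nRisk), nEvent = as.numeric(nEvent))
}

#' Median survival from a Kaplan-Meier curve
#'
#' Smallest event time at which the survival probability drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5 (median undefined).
#'
#' @param curve A [SurvivalCurve].
#' @return Numeric months, or `NA_real_`.
#' @export
kmMedian <- function(curve) {
  stopifnot(is(curve, "SurvivalCurve"))
  hit <- which(curve@surv <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve@time[hit[1L]]
}

#' Two-group log-rank test
#'
#' At each distinct pooled event time the observed events in group A are
#' compared with the hypergeometric expectation given the risk sets; the
#' statistic is `(sum(O - E))^2 / sum(V)` referred to a chi-square with one
#' degree of freedom (two-sided, no continuity correction).
#'
#' @param timesA,eventsA Observed times and 0/1 event flags, group A.
#' @param timesB,eventsB Same for group B.
#' @return List with `statistic`, `p.value`, `observedA`, `expectedA`,
#'   `defined` (FALSE when the variance is zero, e.g. a group compared with
#'   itself never separating; statistic and p are then `NA`).
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) == length(eventsA),
            length(timesB) == length(eventsB),
            length(timesA) > 0, length(timesB) > 0,
            all(c(eventsA, eventsB) %in% c(0, 1)))
  if (sum(eventsA) + sum(eventsB) == 0)
    stop("no events in either group", call. = FALSE)
  evTimes <- sort(unique(c(timesA[eventsA == 1], timesB[eventsB == 1])))
  sortA <- sort(timesA); sortB <- sort(timesB)
  sortEvA <- sort(timesA[eventsA == 1]); sortEvB <- sort(timesB[eventsB == 1])
  n1 <- length(timesA) - findInterval(evTimes, sortA, left.open = TRUE)
  n2 <- length(timesB) - findInterval(evTimes, sortB, left.open = TRUE)
  d1 <- findInterval(evTimes, sortEvA) -
    findInterval(evTimes, sortEvA, left.open = TRUE)
  d2 <- findInterval(evTimes, sortEvB) -
    findInterval(evTimes, sortEvB, left.open = TRUE)
  nTot <- n1 + n2; dTot <- d1 + d2
  expA <- dTot * n1 / nTot
  vr <- ifelse(nTot > 1,
               dTot * (n1 / nTot) * (n2 / nTot) * (nTot - dTot) / (nTot - 1),
               0)
  sumV <- sum(vr)
  if (sumV <= 0)
    return(list(statistic = NA_real_, p.value = NA_real_,
                observedA = sum(d1), expectedA = sum(expA), defined = FALSE))
  stat <- (sum(d1) - sum(expA))^2 / sumV
  list(statistic = stat,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       observedA = sum(d1), expectedA = sum(expA), defined = TRUE)
}

#' Compare survival between predicted sensitivity strata
#'
#' Classifies the requested patients with a fitted model at `threshold`,
#' stratifies their *raw* observed endpoint times and event flags (not the
#' discretised labels) by predicted class, and returns per-group
#' Kaplan-Meier curves, medians and the log-rank test. When every patient
#' lands in one predicted class the comparison is returned with the test
#' flagged undefined.
#'
#' @param model A fitted [PacModel].
#' @param features The [PacFeatureSet] the model was trained against.
#' @param cohort The [PacCohort] carrying the raw outcomes.
#' @param indices Cohort column indices to compare (e.g. the validation
#'   split).
#' @param endpoint `"pfs"` or `"os"`.
#' @param threshold Classification threshold (default 0.5).
#' @return A [SurvivalComparison] with groups `predicted_sensitive` and
#'   `predicted_resistant`.
#' @export
comparePredictedGroups <- function(model, features, cohort, indices,
                                   endpoint = c("pfs", "os"),
                                   threshold = 0.5) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(indices) > 0)
  p <- predictProba(model, features, indices)
  times <- if (endpoint == "pfs") pfsMonths(cohort)[indices]
           else osMonths(cohort)[indices]
  events <- if (endpoint == "pfs") pfsEvent(cohort)[indices]
            else osEvent(cohort)[indices]
  sens <- p >= threshold
  groups <- c("predicted_sensitive", "predicted_resistant")
  nPer <- stats::setNames(c(sum(sens), sum(!sens)), groups)
  curves <- list(); medians <- stats::setNames(rep(NA_real_, 2L), groups)
  for (g in groups) {
    sel <- if (g == "predicted_sensitive") sens else !sens
    if (any(sel)) {
      cv <- kmEstimate(times[sel], events[sel])
      curves[[g]] <- cv
      medians[[g]] <- kmMedian(cv)
    }
  }
  if (all(nPer > 0)) {
    lr <- logrankTest(times[sens], events[sens], times[!sens], events[!sens])
  } else {
    lr <- list(statistic = NA_real_, p.value = NA_real_, defined = FALSE)
  }
  new("SurvivalComparison", groups = groups, curves = curves,
      medians = medians, nPerGroup = nPer,
      statistic = lr$statistic, pValue = lr$p.value,
      testDefined = isTRUE(lr$defined))
}

#' Export a Kaplan-Meier comparison as CSV
#'
#' Long format: `group, time, survival, n_at_risk, n_events`, enough to
#' replot stratified survival panels.
#'
#' @param comparison A [SurvivalComparison].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSurvivalCSV <- function(comparison, path) {
  rows <- lapply(names(comparison@curves), function(g) {
    cv <- comparison@curves[[g]]
    if (!length(cv@time)) return(NULL)
    data.frame(group = g, time = cv@time, survival = cv@surv,
               n_at_risk = cv@nRisk, n_events = cv@nEvent)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(group = character(), time = numeric(),
                     survival = numeric(), n_at_risk = numeric(),
                     n_events = numeric())
  .writeCSVExact(df, path)
}
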