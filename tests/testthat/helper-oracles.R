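# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package: brute-force pair
# counting for the AUROC, explicit risk-set counting for the log-rank test,
# and the empirical survivor fraction for censoring-free Kaplan-Meier.

aurocBrute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

logrankBrute <- function(timesA, eventsA, timesB, eventsB) {
  evTimes <- sort(unique(c(timesA[eventsA == 1], timesB[eventsB == 1])))
  num <- 0; den <- 0
  for (t in evTimes) {
    n1 <- sum(timesA >= t); n2 <- sum(timesB >= t)
    d1 <- sum(timesA == t & eventsA == 1)
    d2 <- sum(timesB == t & eventsB == 1)
    n <- n1 + n2; d <- d1 + d2
    num <- num + d1 - d * n1 / n
    if (n > 1)
      den <- den + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  num^2 / den
}

survFracBrute <- function(times, t) mean(times > t)
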