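## Shared fixtures, built in code. Small planted and null cohorts are
## memoized per test run so several test files can reuse them.

.fixtureEnv <- new.env()

plantedCohort <- function() {
  if (is.null(.fixtureEnv$planted)) {
    .fixtureEnv$planted <- generateCohort(cohortSpec(
      n_patients = 90, n_genes = 400, signature_genes = 25,
      signature_effect = 2, treatment_effect_genes = 40,
      treatment_effect_size = 1, seed = 421))
  }
  .fixtureEnv$planted
}

nullCohort <- function() {
  if (is.null(.fixtureEnv$null)) {
    .fixtureEnv$null <- generateCohort(cohortSpec(
      n_patients = 80, n_genes = 300, signature_genes = 0,
      signature_effect = 0, treatment_effect_genes = 0, seed = 77))
  }
  .fixtureEnv$null
}

labeledTraining <- function(coh) {
  cl <- clinicalData(coh)
  lab <- stratifyRisk(cl$dfs_months, cl$event)
  sel <- lab %in% c("high", "low")
  list(expr = exprMatrix(coh)[, sel, drop = FALSE],
       labels = droplevels(lab[sel]),
       time = cl$dfs_months[sel], event = cl$event[sel],
       clinical = cl[sel, ])
}

## A toy 3-gene, 6-sample expression set with mixed up/down signature
## directions (correlation-based centroids need both).
toyExpr <- function() {
  e <- rbind(
    g1 = c(2.0, 1.9, 2.1, 0.0, 0.1, -0.1),   # up in high
    g2 = c(-1.8, -2.1, -2.0, 0.1, 0.0, -0.2), # down in high
    g3 = c(1.1, 0.8, 1.0, -0.9, -1.1, -1.0))  # up in high
  colnames(e) <- paste0("s", 1:6)
  list(expr = e,
       labels = factor(c("high", "high", "high", "low", "low", "low"),
                       levels = c("high", "low")))
}

## Expand a 2x2 count table (rows = variable levels, cols = high/low) into
## a per-patient records/labels pair for baselineComparison.
expandTable <- function(tab, var, levels) {
  n <- sum(tab)
  lev <- rep(rep(levels, 2), as.vector(tab))
  grp <- rep(c("high", "low"), colSums(tab))
  rec <- data.frame(patient_id = sprintf("p%03d", seq_len(n)), x = lev)
  colnames(rec)[2] <- var
  list(records = rec, labels = grp)
}

## Two-sided Fisher exact p by hypergeometric enumeration (independent of
## stats::fisher.test): sum of point probabilities <= the observed one.
fisherEnum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - nn); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, nn, k)
  pObs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Log-rank chi-square by direct hypergeometric increments (oracle).
logrankEnum <- function(time, event, group) {
  group <- factor(group)
  ut <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    atRisk <- time >= t
    n1 <- sum(atRisk & group == levels(group)[1])
    n <- sum(atRisk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == levels(group)[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}
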