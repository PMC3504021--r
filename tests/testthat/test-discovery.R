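test_that("risk stratification applies the two rule clauses and nothing else", {
  r <- riskRule()
  expect_equal(as.character(stratifyRisk(10, 1, r)), "high")
  expect_equal(as.character(stratifyRisk(14, 0, r)), "low")
  expect_equal(as.character(stratifyRisk(8, 0, r)), "unlabelable")
  expect_equal(as.character(stratifyRisk(14, 1, r)), "low")
  expect_equal(as.character(stratifyRisk(12, 1, r)), "high")
  expect_error(stratifyRisk(-1, 1, r), "DFS")
  expect_error(riskRule(24, 6), "<=")

  ## the stricter 6/24 rule labels a subset of the default rule's patients
  set.seed(41)
  tm <- runif(200, 0, 40); ev <- rbinom(200, 1, 0.6)
  labA <- stratifyRisk(tm, ev, riskRule(12, 12))
  labB <- stratifyRisk(tm, ev, riskRule(6, 24))
  expect_lt(sum(labB != "unlabelable"), sum(labA != "unlabelable"))
  expect_true(all(labA[labB == "high"] == "high"))
  expect_true(all(labA[labB == "low"] == "low"))
})

test_that("gene ranking metrics match direct per-gene recomputation", {
  set.seed(42)
  e <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  lab <- factor(rep(c("high", "low"), each = 6), levels = c("high", "low"))
  e[2, lab == "high"] <- e[2, lab == "high"] + 3

  ## Welch t oracle: stats::t.test per gene
  rt <- rankGenes(e, lab, metric = "tstat")
  tOracle <- apply(e, 1, function(x)
    t.test(x[lab == "high"], x[lab == "low"])$statistic)
  expect_equal(rt$score[match(rownames(e), rt$gene)], unname(tOracle),
               tolerance = 1e-9)
  expect_equal(rt$rank[rt$gene == "g2"], 1L)

  ## snr formula oracle
  rs <- rankGenes(e, lab, metric = "snr")
  snrOracle <- apply(e, 1, function(x) {
    (mean(x[lab == "high"]) - mean(x[lab == "low"])) /
      (sd(x[lab == "high"]) + sd(x[lab == "low"]))
  })
  expect_equal(rs$score[match(rownames(e), rs$gene)], unname(snrOracle))

  ## Cox Wald z oracle: survival::coxph per gene (Breslow ties)
  tm <- rexp(12, 0.1); ev <- rbinom(12, 1, 0.8); ev[1] <- 1
  rc <- rankGenes(e, time = tm, event = ev, metric = "coxz")
  zOracle <- apply(e, 1, function(x) {
    f <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow")
    unname(coef(f) / sqrt(diag(f$var)))
  })
  expect_equal(rc$score[match(rownames(e), rc$gene)], unname(zOracle),
               tolerance = 1e-3)
})

test_that("degenerate genes score zero with a warning and rank last", {
  e <- rbind(g1 = c(1, 1, 1, 0, 0, 0), g2 = rep(2, 6))
  colnames(e) <- paste0("s", 1:6)
  lab <- factor(rep(c("high", "low"), each = 3), levels = c("high", "low"))
  expect_warning(r <- rankGenes(e, lab, metric = "snr"), "zero variance")
  expect_equal(r$score[r$gene == "g2"], 0)
  expect_equal(r$rank[r$gene == "g2"], 2L)
  ## separation with tiny sds ranks first with a large score
  expect_gt(abs(r$score[r$gene == "g1"]), 10)
  expect_equal(r$rank[r$gene == "g1"], 1L)
})

test_that("nearest-mean classification reproduces hand-computed correlations", {
  toy <- toyExpr()
  m <- nearestMeanFit(toy$expr, toy$labels, rownames(toy$expr))
  p <- nearestMeanPredict(m, toy$expr)
  expect_equal(as.character(p$class), as.character(toy$labels))

  ## manual recomputation of one score
  xs <- (toy$expr - m@center) / m@scale
  sc1 <- cor(xs[, 1], m@centroids[, "low"]) -
    cor(xs[, 1], m@centroids[, "high"])
  expect_equal(p$score[1], sc1)
  expect_equal(p$risk_score, -p$score)

  ## a sample equal to the high centroid is classified high with score < 0
  xh <- m@centroids[, "high"] * m@scale + m@center
  ph <- nearestMeanPredict(m, matrix(xh, 3, 1,
                                     dimnames = list(rownames(toy$expr), "t")))
  expect_equal(as.character(ph$class), "high")
  expect_lt(ph$score, 0)

  ## single-gene signatures use the signed standardized distance, and a
  ## sample exactly midway between the centroids ties to high risk
  m1 <- nearestMeanFit(toy$expr, toy$labels, "g1")
  p1 <- nearestMeanPredict(m1, toy$expr)
  expect_equal(as.character(p1$class), as.character(toy$labels))
  ## exactly representable tie: class values 2/0, midpoint 1
  eT <- matrix(c(2, 2, 2, 0, 0, 0), 1, 6,
               dimnames = list("g1", paste0("s", 1:6)))
  mT <- nearestMeanFit(eT, toy$labels, "g1")
  pm <- nearestMeanPredict(mT, matrix(1, 1, 1, dimnames = list("g1", "t")))
  expect_identical(pm$score, 0)
  expect_equal(as.character(pm$class), "high")
})

test_that("combined AUC equals exhaustive pair counting with ties at 1/2", {
  expect_equal(combinedAUC(c(5, 4, 2, 1), rep(c("high", "low"), each = 2),
                           n_boot = 0)$auc, 1)
  expect_equal(combinedAUC(rep(1, 6), rep(c("high", "low"), 3),
                           n_boot = 0)$auc, 0.5)
  set.seed(43)
  for (i in 1:5) {
    s <- sample(0:5, 10, replace = TRUE)   # forces ties
    l <- rep(c("high", "low"), each = 5)
    pairSum <- 0
    for (a in which(l == "high")) for (b in which(l == "low"))
      pairSum <- pairSum + (s[a] > s[b]) + 0.5 * (s[a] == s[b])
    expect_equal(combinedAUC(s, l, n_boot = 0)$auc, pairSum / 25)
  }
  expect_error(combinedAUC(1:4, rep("high", 4), n_boot = 0), "both classes")
})

test_that("a single multiple-sampling iteration equals a manual pass", {
  tr <- labeledTraining(nullCohort())
  seed <- 99
  d <- multipleSampling(tr$expr, tr$labels, tr$time, tr$event,
                        iterations = 1, top_k = 20, n_boot = 0, seed = seed)
  ## replicate the single stratified draw
  hiIdx <- which(tr$labels == "high"); loIdx <- which(tr$labels == "low")
  nH <- min(max(2L, round(2 / 3 * length(hiIdx))), length(hiIdx) - 1L)
  nL <- min(max(2L, round(2 / 3 * length(loIdx))), length(loIdx) - 1L)
  draw <- recurSig:::withSeed(seed, c(sample(hiIdx, nH), sample(loIdx, nL)))
  hold <- setdiff(seq_len(ncol(tr$expr)), draw)
  eTr <- tr$expr[, draw]; lTr <- tr$labels[draw]
  rks <- cbind(
    rankGenes(eTr, lTr, metric = "snr")$rank[
      order(rankGenes(eTr, lTr, metric = "snr")$gene)],
    rankGenes(eTr, lTr, metric = "tstat")$rank[
      order(rankGenes(eTr, lTr, metric = "tstat")$gene)],
    rankGenes(eTr, time = tr$time[draw], event = tr$event[draw],
              metric = "coxz")$rank[
      order(rankGenes(eTr, time = tr$time[draw], event = tr$event[draw],
                      metric = "coxz")$gene)])
  genes <- sort(rownames(tr$expr))
  avg <- rowMeans(rks)
  combined <- integer(length(genes))
  combined[order(avg, genes)] <- seq_along(genes)
  top <- genes[order(combined)][1:20]
  model <- nearestMeanFit(eTr, lTr, top)
  pred <- nearestMeanPredict(model, tr$expr[, hold])
  ## the discovery result pools exactly these held-out risk scores
  expect_setequal(d@pooled$sample_id, pred$sample_id)
  expect_equal(d@pooled$risk_score[match(pred$sample_id, d@pooled$sample_id)],
               pred$risk_score)
  ## and its ranking is this iteration's combined ranking
  rk <- averagedRanking(d)
  expect_equal(rk$avg_rank[match(genes, rk$gene)], as.numeric(combined))
})

test_that("multiple sampling recovers a planted signature", {
  coh <- plantedCohort()
  tr <- labeledTraining(coh)
  d <- multipleSampling(tr$expr, tr$labels, tr$time, tr$event,
                        iterations = 60, top_k = 75, n_boot = 200,
                        seed = 7)
  planted <- S4Vectors::metadata(coh)$signature_genes
  top75 <- averagedRanking(d)$gene[1:75]
  expect_gte(mean(planted %in% top75), 0.8)
  expect_gt(d@auc$auc, 0.8)
  expect_true(d@auc$ci[1] > 0.5)
})

test_that("forward selection matches brute-force LOOCV and breaks ties small", {
  toy <- toyExpr()
  sig <- forwardSelect(toy$expr, toy$labels, rownames(toy$expr),
                       max_size = 3)
  ## brute-force oracle over all 6 leave-outs x 3 sizes
  oracle <- sapply(1:3, function(k) {
    genes <- rownames(toy$expr)[1:k]
    mean(vapply(1:6, function(i) {
      m <- nearestMeanFit(toy$expr[, -i, drop = FALSE], toy$labels[-i],
                          genes)
      p <- nearestMeanPredict(m, toy$expr[, i, drop = FALSE])
      as.character(p$class) == as.character(toy$labels[i])
    }, logical(1)))
  })
  expect_equal(sig@accuracyCurve$accuracy, unname(oracle))
  ## flat curves select the smallest size
  expect_equal(sig@size, as.integer(which.max(oracle)))
  if (oracle[1] == max(oracle)) expect_equal(sig@size, 1L)
})

test_that("forward selection on a planted cohort finds an accurate signature", {
  tr <- labeledTraining(plantedCohort())
  d <- multipleSampling(tr$expr, tr$labels, tr$time, tr$event,
                        iterations = 40, top_k = 60, n_boot = 0, seed = 8)
  sig <- forwardSelect(tr$expr, tr$labels, d, max_size = 60)
  expect_gt(max(sig@accuracyCurve$accuracy), 0.8)
  expect_gte(sig@size, 1L)
  ## resubstitution accuracy is at least the LOOCV optimum (optimism)
  resub <- nearestMeanPredict(sig@model, tr$expr)
  acc <- mean(as.character(resub$class) == as.character(tr$labels))
  expect_gte(acc, max(sig@accuracyCurve$accuracy) - 0.05)
})

test_that("validation never sees training samples and reports survival splits", {
  coh <- plantedCohort()
  cl <- clinicalData(coh)
  split <- splitCohort(cl$patient_id, seed = 5)
  trainClin <- cl[cl$patient_id %in% split$train, ]
  lab <- stratifyRisk(trainClin$dfs_months, trainClin$event)
  sel <- lab %in% c("high", "low")
  eTr <- exprMatrix(coh)[, trainClin$patient_id[sel]]
  model <- nearestMeanFit(eTr, droplevels(lab[sel]),
                          S4Vectors::metadata(coh)$signature_genes)
  val <- validateSignature(model, exprMatrix(coh)[, split$validation],
                           cl[cl$patient_id %in% split$validation, ])
  expect_equal(nrow(val$predictions), length(split$validation))
  expect_true(!is.null(val$logrank))
  ## a strong planted signature separates validation survival
  expect_lt(val$logrank$p, 0.05)
  expect_gt(val$logrank$hazard_ratio, 1)

  ## overlap is a hard error
  expect_error(validateSignature(model, eTr, trainClin), "overlap")
})

test_that("validation data cannot influence training artifacts", {
  coh <- plantedCohort()
  cl <- clinicalData(coh)
  run1 <- runPipeline(coh, iterations = 15, top_k = 40, max_size = 20,
                      n_boot = 0, seed = 12)
  ## permute expression among validation samples only
  e2 <- exprMatrix(coh)
  vid <- run1$split$validation
  set.seed(1)
  e2[, vid] <- e2[sample(nrow(e2)), vid]
  run2 <- runPipeline(list(expr = e2, clinical = cl), iterations = 15,
                      top_k = 40, max_size = 20, n_boot = 0, seed = 12)
  expect_identical(run1$signature@genes, run2$signature@genes)
  expect_identical(averagedRanking(run1$discovery),
                   averagedRanking(run2$discovery))
  expect_equal(run1$discovery@auc$auc, run2$discovery@auc$auc)
  expect_false(isTRUE(all.equal(run1$validation$predictions$risk_score,
                                run2$validation$predictions$risk_score)))
})
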