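#' Construct a risk stratification rule
#'
#' @param high_max_months recurrence at or before this many months labels a
#'   patient high risk (default 12; the stricter variant uses 6).
#' @param low_min_months follow-up (event or censoring) beyond this many
#'   months labels a patient low risk (default 12; stricter variant 24).
#' @return a \linkS4class{RiskRule}.
#' @export
riskRule <- function(high_max_months = 12, low_min_months = 12) {
  new("RiskRule", highMaxMonths = high_max_months,
      lowMinMonths = low_min_months)
}

#' Stratify patients into high / low / unlabelable risk
#'
#' High risk: recurrence observed at \code{dfs <= highMaxMonths}. Low risk:
#' DFS (event or censoring) beyond \code{lowMinMonths}. Patients censored
#' before the high-risk cutoff satisfy neither clause and are unlabelable:
#' they are excluded from signature discovery but retained for survival
#' validation.
#'
#' @param time DFS in months (>= 0).
#' @param event 0/1 recurrence flag.
#' @param rule a \code{\link{riskRule}}.
#' @return factor with levels high, low, unlabelable.
#' @examples
#' stratifyRisk(c(10, 14, 8), c(1, 0, 0), riskRule())
#' @export
stratifyRisk <- function(time, event, rule = riskRule()) {
  stopIfNot(all(is.finite(time)) && all(time >= 0), "time",
            "DFS must be finite and >= 0")
  stopIfNot(isFlag01(event), "event", "must be 0/1")
  validObject(rule)
  lab <- rep("unlabelable", length(time))
  lab[event == 1 & time <= rule@highMaxMonths] <- "high"
  lab[time > rule@lowMinMonths] <- "low"
  factor(lab, levels = c("high", "low", "unlabelable"))
}

## ---- per-gene ranking metrics ---------------------------------------------

.classStats <- function(expr, labels) {
  hi <- labels == "high"
  lo <- labels == "low"
  nH <- sum(hi); nL <- sum(lo)
  G <- nrow(expr)
  eH <- expr[, hi, drop = FALSE]
  eL <- expr[, lo, drop = FALSE]
  mH <- .rowMeans(eH, G, nH)
  mL <- .rowMeans(eL, G, nL)
  vH <- .rowSums((eH - mH)^2, G, nH) / (nH - 1)
  vL <- .rowSums((eL - mL)^2, G, nL) / (nL - 1)
  list(mH = mH, mL = mL, vH = vH, vL = vL, nH = nH, nL = nL)
}

.snrScores <- function(expr, labels, stats = NULL) {
  s <- if (is.null(stats)) .classStats(expr, labels) else stats
  num <- s$mH - s$mL
  den <- sqrt(s$vH) + sqrt(s$vL)
  out <- ifelse(num == 0, 0, num / den)   # 0/0 -> 0; x/0 -> +-Inf
  if (any(den == 0 & num == 0))
    warning("gene(s) with zero variance in both classes scored 0")
  out
}

.welchScores <- function(expr, labels, stats = NULL) {
  s <- if (is.null(stats)) .classStats(expr, labels) else stats
  num <- s$mH - s$mL
  den <- sqrt(s$vH / s$nH + s$vL / s$nL)
  out <- ifelse(num == 0, 0, num / den)
  if (any(den == 0 & num == 0))
    warning("gene(s) with zero variance in both classes scored 0")
  out
}

## Vectorised per-gene univariate Cox (Breslow ties): a few Newton steps on
## the partial likelihood, identical update for every gene via matrix
## algebra over risk-set sums (one indicator-matrix crossprod per sum,
## evaluated only at event times). Returns the Wald z statistic per gene.
.coxWaldZ <- function(expr, time, event, newton_steps = 3) {
  ord <- order(time)
  tt <- time[ord]
  dd <- event[ord]
  Xg <- expr[, ord, drop = FALSE]             # genes x samples, time-sorted
  G <- nrow(Xg); n <- ncol(Xg)
  ## first index of each tie group (risk sets include tied times)
  first <- match(tt, tt)
  ev <- which(dd == 1)
  fe <- first[ev]
  ne <- length(ev)
  ## ind[j, k] = 1 iff sample j is at risk at the k-th event time
  ind <- matrix(0, n, ne)
  ind[rep(seq_len(n), ne) >= rep(fe, each = n)] <- 1
  xev <- .rowSums(Xg[, ev, drop = FALSE], G, ne)
  beta <- numeric(G)
  info <- numeric(G)
  X2 <- Xg * Xg
  for (it in seq_len(newton_steps)) {
    W <- exp(Xg * beta)                       # beta recycles down columns
    S0 <- W %*% ind
    mu <- ((W * Xg) %*% ind) / S0
    U <- xev - .rowSums(mu, G, ne)
    info <- .rowSums(((W * X2) %*% ind) / S0 - mu * mu, G, ne)
    step <- ifelse(info > 1e-10, U / info, 0)
    step <- pmin(pmax(step, -2), 2)           # damp early overshoot
    beta <- beta + step
  }
  z <- ifelse(info > 1e-10, beta * sqrt(info), 0)
  z
}

#' Rank genes by a prognostic metric
#'
#' Scores every gene by one of three metrics computed on the labeled
#' training samples: \code{snr} — signal-to-noise ratio
#' (mean_high - mean_low) / (sd_high + sd_low); \code{tstat} — Welch
#' two-sample t statistic; \code{coxz} — Wald z of a per-gene univariate
#' Cox regression on continuous expression (so protective and adverse genes
#' rank symmetrically). Ranks are descending by |score| with ties broken by
#' gene id.
#'
#' @param expr genes x samples matrix (labeled samples only for
#'   \code{snr}/\code{tstat}).
#' @param labels factor of high/low labels (one per column).
#' @param time,event survival data, required for \code{metric = "coxz"}.
#' @param metric one of \code{"snr"}, \code{"tstat"}, \code{"coxz"}.
#' @return data.frame: gene, score, rank (1 = strongest).
#' @export
rankGenes <- function(expr, labels = NULL, time = NULL, event = NULL,
                      metric = c("snr", "tstat", "coxz")) {
  metric <- match.arg(metric)
  if (metric %in% c("snr", "tstat")) {
    stopifnot(!is.null(labels))
    labels <- factor(as.character(labels), levels = c("high", "low"))
    stopIfNot(all(table(labels) >= 2), "labels",
              "need >= 2 samples per class")
    score <- if (metric == "snr") .snrScores(expr, labels) else
      .welchScores(expr, labels)
  } else {
    stopifnot(!is.null(time), !is.null(event))
    stopIfNot(sum(event) >= 1, "event", "need >= 1 event")
    score <- .coxWaldZ(expr, time, event)
  }
  data.frame(gene = rownames(expr), score = unname(score),
             rank = rankByAbsScore(score, rownames(expr)),
             row.names = NULL)
}

## ---- nearest-mean classifier ----------------------------------------------

#' Fit a nearest-mean (centroid) classifier
#'
#' @param expr genes x samples training matrix.
#' @param labels high/low factor, one per training column.
#' @param genes ordered signature gene ids (rows of \code{expr}).
#' @return a \linkS4class{NearestMeanModel}.
#' @export
nearestMeanFit <- function(expr, labels, genes) {
  stopIfNot(all(genes %in% rownames(expr)), "genes",
            "all signature genes must be rows of expr")
  labels <- factor(as.character(labels), levels = c("high", "low"))
  stopIfNot(all(table(labels) >= 1), "labels",
            "both classes must be present in training")
  x <- expr[genes, , drop = FALSE]
  ctr <- rowMeans(x)
  scl <- sqrt(rowSums((x - ctr)^2) / (ncol(x) - 1))
  if (any(scl <= 0))
    stop(sprintf("zero training variance for gene(s): %s",
                 paste(genes[scl <= 0], collapse = ", ")))
  xs <- (x - ctr) / scl
  cen <- cbind(high = rowMeans(xs[, labels == "high", drop = FALSE]),
               low = rowMeans(xs[, labels == "low", drop = FALSE]))
  new("NearestMeanModel", genes = genes, centroids = cen,
      center = stats::setNames(ctr, genes), scale = stats::setNames(scl, genes),
      trainingIds = colnames(expr))
}

#' Predict with a nearest-mean model
#'
#' Continuous score = cor(sample, centroid_low) - cor(sample,
#' centroid_high) over the standardized signature genes; class = high when
#' score <= 0 (conservative tie rule). \code{risk_score} is the negated
#' score (higher = more high-risk), the orientation pooled for AUC. For a
#' single-gene signature (correlation undefined) the signed standardized
#' distance difference |x - c_high| - |x - c_low| replaces the correlation
#' score.
#'
#' @param model a \linkS4class{NearestMeanModel}.
#' @param expr genes x samples matrix containing the signature genes.
#' @return data.frame: sample_id, score, risk_score, class.
#' @export
nearestMeanPredict <- function(model, expr) {
  stopIfNot(all(model@genes %in% rownames(expr)), "expr",
            "missing signature genes")
  xs <- (expr[model@genes, , drop = FALSE] - model@center) / model@scale
  if (length(model@genes) == 1L) {
    score <- as.numeric(abs(xs - model@centroids[, "high"]) -
                          abs(xs - model@centroids[, "low"]))
  } else {
    score <- as.numeric(cor(xs, model@centroids[, "low"]) -
                          cor(xs, model@centroids[, "high"]))
  }
  data.frame(sample_id = colnames(expr), score = score,
             risk_score = -score,
             class = factor(ifelse(score <= 0, "high", "low"),
                            levels = c("high", "low")),
             row.names = NULL)
}

## ---- pooled AUC ------------------------------------------------------------

#' Area under the ROC curve of pooled out-of-fold scores
#'
#' AUC = P(score_high > score_low) with ties counted 1/2, computed by the
#' rank (Mann-Whitney) identity. The 95\% CI comes from a stratified
#' bootstrap over patients: patients are resampled within each label
#' stratum and all their pooled scores follow them, respecting the
#' repeated-measures structure of multiple-sampling predictions.
#'
#' @param scores continuous risk scores (higher = predicted higher risk).
#' @param labels true high/low labels, one per score.
#' @param patient optional patient id per score (defaults to one patient
#'   per row).
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return list: auc, ci (length 2 or NULL), n_boot.
#' @export
combinedAUC <- function(scores, labels, patient = NULL, n_boot = 2000,
                        seed = 1) {
  labels <- factor(as.character(labels), levels = c("high", "low"))
  if (any(is.na(labels))) stop("labels must be high/low")
  if (nlevels(droplevels(labels)) < 2)
    stop("AUC undefined: both classes must be present")
  aucOf <- function(s, l) {
    r <- rank(s)
    nH <- sum(l == "high"); nL <- sum(l == "low")
    (sum(r[l == "high"]) - nH * (nH + 1) / 2) / (nH * nL)
  }
  auc <- aucOf(scores, labels)
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(patient)) patient <- seq_along(scores)
    byPat <- split(seq_along(scores), patient)
    patLab <- vapply(byPat, function(i) as.character(labels[i[1]]),
                     character(1))
    hiPat <- which(patLab == "high")
    loPat <- which(patLab == "low")
    ci <- withSeed(seed, {
      stats <- vapply(seq_len(n_boot), function(b) {
        ph <- sample(hiPat, length(hiPat), replace = TRUE)
        pl <- sample(loPat, length(loPat), replace = TRUE)
        idx <- unlist(byPat[c(ph, pl)], use.names = FALSE)
        aucOf(scores[idx], labels[idx])
      }, numeric(1))
      unname(quantile(stats, c(0.025, 0.975)))
    })
  }
  list(auc = auc, ci = ci, n_boot = n_boot)
}

## ---- multiple-sampling discovery ------------------------------------------

#' Multiple-sampling gene ranking with pooled cross-validated AUC
#'
#' The discovery engine: in each of \code{iterations} iterations a
#' stratified draw of \code{fraction} of the labeled training samples is
#' taken (class ratio preserved; degenerate draws redrawn); genes are
#' ranked on the draw by each of the three metrics (signal-to-noise, Welch
#' t, Cox Wald z) and the three ranks averaged into one combined
#' within-iteration ranking; a nearest-mean model over the \code{top_k}
#' combined-rank genes is fitted on the draw and scores the held-out
#' samples; held-out risk scores are pooled over all iterations into one
#' combined AUC, and the combined per-iteration rankings are averaged over
#' iterations into the final gene ranking.
#'
#' @param expr genes x samples matrix of the labeled training samples.
#' @param labels high/low factor, one per column.
#' @param time,event survival data per column (for the Cox metric).
#' @param iterations number of resampling iterations (default 1000).
#' @param fraction training fraction per draw (default 2/3).
#' @param top_k signature size used for held-out scoring (default 75).
#' @param metrics ranking metrics to combine.
#' @param n_boot bootstrap resamples for the pooled-AUC CI.
#' @param seed integer seed; each iteration derives its own substream.
#' @return a \linkS4class{DiscoveryResult}.
#' @export
multipleSampling <- function(expr, labels, time, event, iterations = 1000,
                             fraction = 2 / 3, top_k = 75,
                             metrics = c("snr", "tstat", "coxz"),
                             n_boot = 2000, seed = 1) {
  labels <- factor(as.character(labels), levels = c("high", "low"))
  stopIfNot(!any(is.na(labels)), "labels",
            "only labeled (high/low) samples enter discovery")
  stopIfNot(all(table(labels) >= 3), "labels",
            "need >= 3 samples per class")
  stopIfNot(top_k <= nrow(expr), "top_k", "cannot exceed gene count")
  genes <- rownames(expr)
  G <- length(genes)
  n <- ncol(expr)
  hiIdx <- which(labels == "high")
  loIdx <- which(labels == "low")
  nDrawH <- max(2L, round(fraction * length(hiIdx)))
  nDrawL <- max(2L, round(fraction * length(loIdx)))
  nDrawH <- min(nDrawH, length(hiIdx) - 1L)
  nDrawL <- min(nDrawL, length(loIdx) - 1L)

  rankSum <- numeric(G)
  metricRankSum <- matrix(0, G, length(metrics),
                          dimnames = list(genes, metrics))
  pooled <- vector("list", iterations)

  withSeed(seed, {
    for (it in seq_len(iterations)) {
      repeat {
        draw <- c(sample(hiIdx, nDrawH), sample(loIdx, nDrawL))
        if (length(unique(labels[draw])) == 2L) break
        message("degenerate draw redrawn at iteration ", it)
      }
      hold <- setdiff(seq_len(n), draw)
      eTr <- expr[, draw, drop = FALSE]
      lTr <- labels[draw]
      rk <- matrix(0L, G, length(metrics))
      cs <- if (any(metrics %in% c("snr", "tstat")))
        .classStats(eTr, lTr) else NULL
      for (m in seq_along(metrics)) {
        sc <- switch(metrics[m],
                     snr = .snrScores(eTr, lTr, cs),
                     tstat = .welchScores(eTr, lTr, cs),
                     coxz = .coxWaldZ(eTr, time[draw], event[draw]))
        rk[, m] <- rankByAbsScore(sc, genes)
      }
      combined <- rankAscending(rowMeans(rk), genes)
      rankSum <- rankSum + combined
      metricRankSum <- metricRankSum + rk
      top <- genes[order(combined)][seq_len(top_k)]
      model <- nearestMeanFit(eTr, lTr, top)
      pred <- nearestMeanPredict(model, expr[, hold, drop = FALSE])
      pooled[[it]] <- data.frame(iteration = it, sample_id = pred$sample_id,
                                 risk_score = pred$risk_score,
                                 label = as.character(labels[hold]))
    }
  })
  pooled <- do.call(rbind, pooled)
  auc <- combinedAUC(pooled$risk_score, pooled$label,
                     patient = pooled$sample_id, n_boot = n_boot,
                     seed = childSeed(seed, 1))
  ranking <- data.frame(gene = genes, avg_rank = rankSum / iterations,
                        metricRankSum / iterations,
                        check.names = FALSE, row.names = NULL)
  colnames(ranking)[-(1:2)] <- paste0("avg_rank_", metrics)
  ranking <- ranking[order(ranking$avg_rank, ranking$gene), ]
  rownames(ranking) <- NULL
  new("DiscoveryResult", ranking = ranking, pooled = pooled,
      auc = auc,
      config = list(iterations = iterations, fraction = fraction,
                    top_k = top_k, metrics = metrics, seed = seed,
                    n_high = length(hiIdx), n_low = length(loIdx)))
}

## ---- forward selection -----------------------------------------------------

## LOOCV predictions for all signature sizes 1..max_size in one pass per
## left-out sample, using cumulative-sum correlation over the rank-ordered
## gene prefix.
.loocvAccuracyCurve <- function(expr, labels, orderedGenes, max_size) {
  x <- expr[orderedGenes, , drop = FALSE]
  n <- ncol(x)
  K <- length(orderedGenes)
  lab <- as.character(labels)
  S <- rowSums(x)
  S2 <- rowSums(x * x)
  sumsBy <- list(high = rowSums(x[, lab == "high", drop = FALSE]),
                 low = rowSums(x[, lab == "low", drop = FALSE]))
  nBy <- c(high = sum(lab == "high"), low = sum(lab == "low"))
  correct <- matrix(FALSE, n, max_size)
  for (i in seq_len(n)) {
    xi <- x[, i]
    m <- (S - xi) / (n - 1)
    v <- (S2 - xi^2 - (n - 1) * m^2) / (n - 2)
    s <- sqrt(pmax(v, 1e-12))
    cenRaw <- list(high = sumsBy$high, low = sumsBy$low)
    nC <- nBy
    cenRaw[[lab[i]]] <- cenRaw[[lab[i]]] - xi
    nC[lab[i]] <- nC[lab[i]] - 1L
    cH <- (cenRaw$high / nC["high"] - m) / s
    cL <- (cenRaw$low / nC["low"] - m) / s
    xs <- (xi - m) / s
    ## prefix correlations via cumulative sums
    k <- seq_len(K)
    cx <- cumsum(xs); cx2 <- cumsum(xs^2)
    score <- numeric(K)
    for (cen in list(list(v = cH, sgn = -1), list(v = cL, sgn = 1))) {
      cy <- cumsum(cen$v); cy2 <- cumsum(cen$v^2); cxy <- cumsum(xs * cen$v)
      num <- k * cxy - cx * cy
      den <- sqrt(pmax(k * cx2 - cx^2, 0) * pmax(k * cy2 - cy^2, 0))
      r <- ifelse(den > 0, num / den, 0)
      score <- score + cen$sgn * r
    }
    ## size-1 signature: signed standardized distance, not correlation
    score[1] <- abs(xs[1] - cH[1]) - abs(xs[1] - cL[1])
    pred <- ifelse(score <= 0, "high", "low")
    correct[i, ] <- pred[seq_len(max_size)] == lab[i]
  }
  data.frame(size = seq_len(max_size), accuracy = colMeans(correct))
}

#' Forward selection of the final signature size
#'
#' Starting from the best averaged-rank gene and adding the next ranked
#' gene at each step, computes the leave-one-out cross-validated accuracy
#' of the nearest-mean classifier on the full training set for every
#' prefix size 1..\code{max_size}; the selected signature is the smallest
#' size attaining the maximum accuracy.
#'
#' @param expr genes x samples training matrix (labeled samples).
#' @param labels high/low factor.
#' @param ranking a \linkS4class{DiscoveryResult}, or a data.frame with
#'   columns gene and avg_rank, or an ordered character vector of gene ids.
#' @param max_size largest signature size to consider (default 75).
#' @return a \linkS4class{GeneSignature} with the accuracy curve and the
#'   nearest-mean model refitted on all labeled training samples at the
#'   selected size.
#' @export
forwardSelect <- function(expr, labels, ranking, max_size = 75) {
  if (is(ranking, "DiscoveryResult")) ranking <- ranking@ranking
  orderedGenes <- if (is.character(ranking)) ranking else
    ranking$gene[order(ranking$avg_rank, ranking$gene)]
  stopIfNot(max_size <= length(orderedGenes), "max_size",
            "cannot exceed the ranked gene list")
  orderedGenes <- orderedGenes[seq_len(max_size)]
  labels <- factor(as.character(labels), levels = c("high", "low"))
  curve <- .loocvAccuracyCurve(expr, labels, orderedGenes, max_size)
  best <- which.max(curve$accuracy)   # ties -> smallest size
  sel <- orderedGenes[seq_len(best)]
  model <- nearestMeanFit(expr, labels, sel)
  new("GeneSignature", genes = sel, size = as.integer(best),
      accuracyCurve = curve, model = model)
}

## ---- validation ------------------------------------------------------------

#' Validate a signature on an independent cohort
#'
#' Predicts the risk class of every validation sample (including patients
#' whose outcome was unlabelable for discovery) and compares the DFS of the
#' predicted-high versus predicted-low groups by Kaplan-Meier estimation
#' and the Mantel-Cox log-rank test, with the hazard ratio (predicted-high
#' vs predicted-low) and its 95\% CI from a companion Cox fit. Training /
#' validation overlap is a hard error: no validation sample may have
#' influenced the model.
#'
#' @param model a \linkS4class{NearestMeanModel} (or
#'   \linkS4class{GeneSignature}, whose model is used).
#' @param expr_validation genes x samples validation matrix.
#' @param clinical_validation clinical data.frame with patient_id,
#'   dfs_months, event for the validation samples.
#' @return list: predictions (data.frame), logrank
#'   (\code{logrank_result} or NULL when only one class was predicted),
#'   km (per-group Kaplan-Meier table), n_high, n_low.
#' @export
validateSignature <- function(model, expr_validation, clinical_validation) {
  if (is(model, "GeneSignature")) model <- model@model
  overlap <- intersect(model@trainingIds, colnames(expr_validation))
  if (length(overlap))
    stop(sprintf("training/validation overlap: %s",
                 paste(head(overlap, 5), collapse = ", ")))
  idx <- match(colnames(expr_validation), clinical_validation$patient_id)
  stopIfNot(!anyNA(idx), "clinical_validation",
            "every validation sample needs a clinical row")
  clin <- clinical_validation[idx, ]
  pred <- nearestMeanPredict(model, expr_validation)
  grp <- factor(as.character(pred$class), levels = c("low", "high"))
  lr <- NULL
  km <- NULL
  if (nlevels(droplevels(grp)) == 2 && sum(clin$event) >= 1) {
    lr <- logrankTest(clin$dfs_months, clin$event, grp)
    km <- kmEstimate(clin$dfs_months, clin$event, grp)
  }
  list(predictions = cbind(pred, dfs_months = clin$dfs_months,
                           event = clin$event),
       logrank = lr, km = km,
       n_high = sum(grp == "high"), n_low = sum(grp == "low"))
}
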