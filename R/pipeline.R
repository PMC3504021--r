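#' Random training / validation split
#'
#' Seeded random split of a cohort into a training and a validation set
#' (75 / 44 by default, scaled proportionally when the cohort size
#' differs). The validation samples never touch ranking, standardization,
#' centroids or signature-size selection.
#'
#' @param ids patient ids.
#' @param n_train number of training patients for a 119-patient cohort;
#'   scaled by \code{length(ids)/119} otherwise.
#' @param seed integer seed.
#' @return list: \code{train}, \code{validation} (character id vectors).
#' @export
splitCohort <- function(ids, n_train = 75, seed = 1) {
  n <- length(ids)
  k <- if (n == 119) n_train else max(4L, round(n_train * n / 119))
  stopIfNot(k < n, "n_train", "split sizes must be below cohort size")
  withSeed(seed, {
    tr <- sort(sample(ids, k))
    list(train = tr, validation = sort(setdiff(ids, tr)))
  })
}

#' Balance neoadjuvant treatment across risk classes
#'
#' Down-samples the majority treatment stratum within each risk class so
#' that the treated:untreated ratio is as equal as possible between the
#' high- and low-risk groups, removing the treatment confound from a
#' training set. Greedy removal, one patient at a time, from whichever
#' class-stratum reduces the treated-fraction gap the most; removed ids
#' are recorded.
#'
#' @param ids patient ids (labeled training samples).
#' @param labels high/low risk label per id.
#' @param treated 0/1 neoadjuvant flag per id.
#' @param seed seed (which patient of a stratum is dropped).
#' @return list: \code{kept}, \code{removed} (character id vectors).
#' @export
balanceTreatment <- function(ids, labels, treated, seed = 1) {
  stopifnot(length(ids) == length(labels), length(ids) == length(treated))
  labels <- as.character(labels)
  treated <- as.integer(treated)
  keep <- rep(TRUE, length(ids))
  frac <- function(cls) {
    i <- keep & labels == cls
    if (!any(i)) return(NA_real_)
    mean(treated[i])
  }
  gap <- function() abs(frac("high") - frac("low"))
  withSeed(seed, {
    ord <- sample(seq_along(ids))   # random tie-breaking order
    repeat {
      g0 <- gap()
      if (!is.finite(g0) || g0 == 0) break
      best <- NULL
      bestGap <- g0
      for (cls in c("high", "low")) {
        for (tr in c(0L, 1L)) {
          cand <- ord[keep[ord] & labels[ord] == cls & treated[ord] == tr]
          if (length(cand) <= 1) next
          keep[cand[1]] <- FALSE
          g1 <- gap()
          keep[cand[1]] <- TRUE
          if (is.finite(g1) && g1 < bestGap - 1e-12) {
            bestGap <- g1
            best <- cand[1]
          }
        }
      }
      if (is.null(best)) break
      keep[best] <- FALSE
    }
  })
  list(kept = ids[keep], removed = ids[!keep])
}

#' Run the full discovery-and-validation pipeline
#'
#' Orchestrates one experimental design end to end: risk stratification,
#' optional centre and treatment filters (including the bias-balanced
#' variant), the seeded training/validation split, multiple-sampling gene
#' ranking with pooled cross-validated AUC, forward selection of the final
#' signature, and survival validation of its predictions on the held-out
#' patients. A manifest records every seed, the configuration, input
#' checksums and the split, so a run is reproducible from its manifest.
#'
#' @param cohort a \linkS4class{RecurrenceCohort} (or list with
#'   \code{expr} matrix and \code{clinical} data.frame).
#' @param rule a \code{\link{riskRule}}.
#' @param center_filter \code{"all"}, \code{"A"} or \code{"B"}.
#' @param treatment_filter \code{"all"}, \code{"treated"},
#'   \code{"untreated"} or \code{"balanced"} (down-sample to equalize the
#'   treated fraction across risk classes in the training set).
#' @param n_train training-set size for a 119-patient cohort (scaled
#'   otherwise).
#' @param iterations,top_k,max_size discovery configuration (see
#'   \code{\link{multipleSampling}} and \code{\link{forwardSelect}}).
#' @param n_boot bootstrap resamples for the pooled-AUC CI.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory: writes signature TSV, accuracy-curve
#'   CSV, pooled-score CSV, AUC JSON, validation report JSON and the
#'   manifest JSON.
#' @return list of class \code{pipeline_run}: discovery
#'   (\linkS4class{DiscoveryResult}), signature
#'   (\linkS4class{GeneSignature}), validation (see
#'   \code{\link{validateSignature}}), split, manifest.
#' @export
runPipeline <- function(cohort, rule = riskRule(),
                        center_filter = c("all", "A", "B"),
                        treatment_filter = c("all", "treated", "untreated",
                                             "balanced"),
                        n_train = 75, iterations = 1000, top_k = 75,
                        max_size = 75, n_boot = 2000, seed = 1,
                        out_dir = NULL) {
  center_filter <- match.arg(center_filter)
  treatment_filter <- match.arg(treatment_filter)
  if (is(cohort, "RecurrenceCohort")) {
    expr <- exprMatrix(cohort)
    clinical <- clinicalData(cohort)
  } else {
    expr <- cohort$expr
    clinical <- cohort$clinical
  }
  missing_ids <- setdiff(colnames(expr), clinical$patient_id)
  if (length(missing_ids))
    stop(sprintf("expression samples without clinical rows: %s",
                 paste(head(missing_ids, 5), collapse = ", ")))
  clinical <- clinical[match(colnames(expr), clinical$patient_id), ]

  if (center_filter != "all") {
    keep <- clinical$center == center_filter
    if (!any(keep)) stop("center filter leaves no samples")
    expr <- expr[, keep, drop = FALSE]
    clinical <- clinical[keep, , drop = FALSE]
  }
  if (treatment_filter %in% c("treated", "untreated")) {
    keep <- clinical$neoadjuvant == (treatment_filter == "treated")
    if (!any(keep)) stop("treatment filter leaves no samples")
    expr <- expr[, keep, drop = FALSE]
    clinical <- clinical[keep, , drop = FALSE]
  }

  split <- splitCohort(clinical$patient_id, n_train = n_train,
                       seed = childSeed(seed, 1))
  trainClin <- clinical[clinical$patient_id %in% split$train, ]
  valClin <- clinical[clinical$patient_id %in% split$validation, ]

  labAll <- stratifyRisk(trainClin$dfs_months, trainClin$event, rule)
  labeled <- labAll %in% c("high", "low")
  trainIds <- trainClin$patient_id[labeled]
  trainLab <- droplevels(labAll[labeled])
  removed <- character(0)
  if (treatment_filter == "balanced") {
    bal <- balanceTreatment(trainIds, trainLab,
                            trainClin$neoadjuvant[labeled],
                            seed = childSeed(seed, 2))
    removed <- bal$removed
    keep <- trainIds %in% bal$kept
    trainIds <- trainIds[keep]
    trainLab <- trainLab[keep]
  }
  if (!length(trainIds)) stop("no labeled training samples after filtering")
  eTr <- expr[, trainIds, drop = FALSE]
  cTr <- trainClin[match(trainIds, trainClin$patient_id), ]

  discovery <- multipleSampling(eTr, trainLab, cTr$dfs_months, cTr$event,
                                iterations = iterations, top_k = top_k,
                                n_boot = n_boot,
                                seed = childSeed(seed, 3))
  signature <- forwardSelect(eTr, trainLab, discovery, max_size = max_size)
  validation <- validateSignature(signature,
                                  expr[, split$validation, drop = FALSE],
                                  valClin)

  manifest <- list(
    seed = seed,
    stage_seeds = list(split = childSeed(seed, 1),
                       balance = childSeed(seed, 2),
                       discovery = childSeed(seed, 3)),
    rule = list(high_max_months = rule@highMaxMonths,
                low_min_months = rule@lowMinMonths),
    center_filter = center_filter, treatment_filter = treatment_filter,
    config = list(iterations = iterations, top_k = top_k,
                  max_size = max_size, n_boot = n_boot),
    n_genes = nrow(expr), n_samples = ncol(expr),
    n_train_labeled = length(trainIds), n_validation = length(split$validation),
    train_ids = trainIds, validation_ids = split$validation,
    balanced_removed = removed,
    input_checksum = sprintf("%.6f", sum(expr) + sum(clinical$dfs_months)),
    signature = list(size = signature@size, genes = signature@genes),
    combined_auc = discovery@auc$auc,
    validation_logrank_p = if (is.null(validation$logrank)) NA else
      validation$logrank$p)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(rank = seq_along(signature@genes),
                           gene = signature@genes),
                file.path(out_dir, "signature.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.csv(signature@accuracyCurve,
              file.path(out_dir, "accuracy_curve.csv"), row.names = FALSE)
    write.csv(discovery@pooled, file.path(out_dir, "pooled_scores.csv"),
              row.names = FALSE)
    jsonlite::write_json(discovery@auc, file.path(out_dir, "auc.json"),
                         auto_unbox = TRUE, digits = NA)
    vr <- list(n_high = validation$n_high, n_low = validation$n_low,
               logrank_p = manifest$validation_logrank_p,
               hazard_ratio = if (is.null(validation$logrank)) NA else
                 validation$logrank$hazard_ratio)
    jsonlite::write_json(vr, file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(discovery = discovery, signature = signature,
                 validation = validation, split = split,
                 manifest = manifest), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "Pipeline run: %d labeled training, %d validation samples\n",
    x$manifest$n_train_labeled, x$manifest$n_validation))
  cat(sprintf("  combined AUC %.3f; signature size %d; validation log-rank p %s\n",
              x$manifest$combined_auc, x$manifest$signature$size,
              format(x$manifest$validation_logrank_p, digits = 3)))
  invisible(x)
}
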