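## Probability that a patient destined for early (resp. late) recurrence
## actually recurs within 12 months; fixed anchors of the latent two-class
## survival model (see the methods vignette).
.P12_HIGH <- 0.92
.P12_LOW  <- 0.12

#' Specify a synthetic cohort
#'
#' Parameter bundle for \code{\link{generateCohort}}. Defaults emulate the
#' structure of a two-centre colorectal liver-metastasis cohort: 119
#' patients, ~20,000 genes measured as log2 ratios versus a common
#' reference, a disease-free-survival (DFS) distribution with ~60\% early
#' recurrence and censoring, a neoadjuvant-chemotherapy expression shift
#' affecting hundreds of genes, and no planted prognostic signature (the
#' null that a well-calibrated discovery pipeline should not mistake for
#' signal). A prognostic signature can be planted with
#' \code{signature_genes}/\code{signature_effect} for power studies.
#'
#' @param n_patients,n_genes cohort dimensions.
#' @param frac_center_a fraction of patients from centre A.
#' @param event_rate_1yr target fraction of patients with observed
#'   recurrence within 1 year.
#' @param signature_genes,signature_effect number of planted prognostic
#'   genes and the log2-unit expression shift between patients destined for
#'   early versus late recurrence.
#' @param treatment_effect_genes,treatment_effect_size number of genes
#'   shifted by neoadjuvant treatment and the log2-unit treated-vs-untreated
#'   shift.
#' @param center_batch_sd sd (log2 units) of per-gene centre-B batch offsets.
#' @param noise_sd residual expression noise sd (log2 units), > 0.
#' @param censor_rate probability of early random censoring (dropout) in
#'   addition to administrative censoring at staggered follow-up.
#' @param overlap_effects if \code{TRUE}, treatment-effect genes may overlap
#'   the planted signature; disjoint by default.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(n_patients = 119, n_genes = 20000,
                       frac_center_a = 0.5, event_rate_1yr = 0.6,
                       signature_genes = 0, signature_effect = 0,
                       treatment_effect_genes = 875,
                       treatment_effect_size = 1,
                       center_batch_sd = 0.2, noise_sd = 1,
                       censor_rate = 0.15, overlap_effects = FALSE,
                       seed = 1) {
  spec <- list(n_patients = n_patients, n_genes = n_genes,
               frac_center_a = frac_center_a, event_rate_1yr = event_rate_1yr,
               signature_genes = signature_genes,
               signature_effect = signature_effect,
               treatment_effect_genes = treatment_effect_genes,
               treatment_effect_size = treatment_effect_size,
               center_batch_sd = center_batch_sd, noise_sd = noise_sd,
               censor_rate = censor_rate, overlap_effects = overlap_effects,
               seed = seed)
  stopIfNot(n_patients >= 4, "n_patients", "must be >= 4")
  stopIfNot(n_genes >= 1, "n_genes", "must be >= 1")
  for (f in c("frac_center_a", "event_rate_1yr", "censor_rate"))
    stopIfNot(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must be in [0, 1]")
  stopIfNot(signature_genes >= 0, "signature_genes", "must be >= 0")
  stopIfNot(treatment_effect_genes >= 0, "treatment_effect_genes",
            "must be >= 0")
  if (!overlap_effects)
    stopIfNot(signature_genes + treatment_effect_genes <= n_genes,
              "signature_genes",
              "signature_genes + treatment_effect_genes must be <= n_genes")
  stopIfNot(noise_sd > 0, "noise_sd", "must be > 0")
  stopIfNot(center_batch_sd >= 0, "center_batch_sd", "must be >= 0")
  class(spec) <- "CohortSpec"
  spec
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the latent two-class survival model: each patient is
#' destined for early recurrence with probability calibrated so that the
#' expected fraction with observed recurrence within 1 year matches
#' \code{event_rate_1yr}; event times are exponential with a class-specific
#' rate (a log-linear function of the latent risk indicator); censoring
#' combines staggered administrative follow-up (uniform 12-60 months) with
#' early dropout at rate \code{censor_rate}. Planted signature genes are
#' shifted by \code{signature_effect} log2 units between the latent classes;
#' neoadjuvant-treated patients (treatment probability depends on the latent
#' risk, reproducing the treated-more-often-when-high-risk confound) have
#' \code{treatment_effect_genes} genes shifted by
#' \code{treatment_effect_size}; centre B adds per-gene batch offsets.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a \linkS4class{RecurrenceCohort}; \code{metadata()} carries the
#'   ground truth (\code{signature_genes}, \code{treatment_genes},
#'   \code{latent_high}) and the per-sample QC table (\code{qc}).
#' @examples
#' coh <- generateCohort(cohortSpec(n_patients = 30, n_genes = 50, seed = 7))
#' dim(exprMatrix(coh))
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  withSeed(spec$seed, {
    n <- spec$n_patients
    G <- spec$n_genes
    ids <- sprintf("p%04d", seq_len(n))
    genes <- sprintf("g%05d", seq_len(G))

    ## latent risk class, calibrated to the 1-year observed-recurrence rate
    p_z <- (spec$event_rate_1yr - .P12_LOW) / (.P12_HIGH - .P12_LOW)
    p_z <- min(max(p_z, 0), 1)
    z <- rbinom(n, 1, p_z)

    rate_high <- -log(1 - .P12_HIGH) / 12
    rate_low  <- -log(1 - .P12_LOW) / 12
    t_event <- rexp(n, rate = ifelse(z == 1, rate_high, rate_low))
    admin <- runif(n, 12, 60)
    drop <- ifelse(runif(n) < spec$censor_rate, runif(n, 3, 36), Inf)
    c_time <- pmin(admin, drop)
    dfs <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)

    center <- ifelse(runif(n) < spec$frac_center_a, "A", "B")
    neoadjuvant <- as.integer(runif(n) < (0.40 + 0.22 * z))
    adjuvant <- as.integer(runif(n) < (0.75 - 0.29 * z))

    synchronous <- runif(n) < 0.49
    interval <- ifelse(synchronous, runif(n, 0, 2), 2 + rexp(n, 1 / 20))
    clinical <- data.frame(
      patient_id = ids,
      center = center,
      sex = sample(c("male", "female"), n, TRUE, prob = c(0.65, 0.35)),
      age = pmin(pmax(round(rnorm(n, 61.4, 11.4), 1), 18), 92),
      primary_site = sample(c("colon", "rectum"), n, TRUE,
                            prob = c(0.75, 0.25)),
      differentiation = sample(c("good", "moderate", "poor"), n, TRUE,
                               prob = c(0.134, 0.723, 0.143)),
      primary_stage = sample(1:4, n, TRUE, prob = c(0.08, 0.22, 0.45, 0.25)),
      nodal_status = sample(c("positive", "negative", "missing"), n, TRUE,
                            prob = c(0.555, 0.336, 0.109)),
      interval_to_metastasis = round(interval, 1),
      n_metastases = 1L + rpois(n, 1.6),
      largest_metastasis_cm = round(rlnorm(n, log(4), 0.55), 1),
      distribution = sample(c("unilobar", "bilobar"), n, TRUE,
                            prob = c(0.58, 0.42)),
      preop_cea = round(rlnorm(n, log(20), 1.5), 1),
      neoadjuvant = neoadjuvant,
      adjuvant = adjuvant,
      resection_extent = sample(c("minor", "major"), n, TRUE,
                                prob = c(0.64, 0.36)),
      margin = sample(c("R0", "R1"), n, TRUE, prob = c(0.76, 0.24)),
      hepatoduodenal_nodes = sample(c("unknown", "negative", "positive"), n,
                                    TRUE, prob = c(0.85, 0.12, 0.03)),
      blood_transfusion = as.integer(runif(n) < 0.26),
      dfs_months = round(dfs, 2),
      event = event,
      stringsAsFactors = FALSE)

    ## expression: noise + planted signature + treatment shift + centre batch
    expr <- matrix(rnorm(G * n, 0, spec$noise_sd), G, n,
                   dimnames = list(genes, ids))
    sig_idx <- integer(0)
    if (spec$signature_genes > 0) {
      sig_idx <- sample.int(G, spec$signature_genes)
      dir_sig <- sample(c(-1, 1), spec$signature_genes, TRUE)
      expr[sig_idx, ] <- expr[sig_idx, ] +
        outer(dir_sig * spec$signature_effect, z - 0.5)
    }
    trt_idx <- integer(0)
    if (spec$treatment_effect_genes > 0) {
      pool <- if (spec$overlap_effects) seq_len(G) else setdiff(seq_len(G),
                                                                sig_idx)
      trt_idx <- sample(pool, spec$treatment_effect_genes)
      dir_trt <- sample(c(-1, 1), spec$treatment_effect_genes, TRUE)
      expr[trt_idx, ] <- expr[trt_idx, ] +
        outer(dir_trt * spec$treatment_effect_size, neoadjuvant - 0.5)
    }
    if (spec$center_batch_sd > 0 && any(center == "B")) {
      batch <- rnorm(G, 0, spec$center_batch_sd)
      expr[, center == "B"] <- expr[, center == "B"] + batch
    }

    qc <- data.frame(
      sample_id = ids,
      rin = round(runif(n, 6.2, 9.8), 1),
      crna_yield_ng = round(runif(n, 2500, 12000)),
      median_fragment_nt = round(runif(n, 600, 1500)),
      cy_incorporation_pct = round(runif(n, 1.6, 2.9), 2),
      amplification_failed = 0L,
      stringsAsFactors = FALSE)

    coh <- RecurrenceCohort(expr, clinical, qc = qc)
    S4Vectors::metadata(coh)$signature_genes <- genes[sort(sig_idx)]
    S4Vectors::metadata(coh)$treatment_genes <- genes[sort(trt_idx)]
    S4Vectors::metadata(coh)$latent_high <- stats::setNames(z, ids)
    S4Vectors::metadata(coh)$spec <- spec
    coh
  })
}

## Categorical variables reported in a baseline table, with their fixed
## level order (empty levels are reported as zero counts, not dropped).
.MARGIN_VARS <- list(
  sex = c("male", "female"),
  primary_site = c("rectum", "colon"),
  differentiation = c("good", "moderate", "poor"),
  nodal_status = c("positive", "negative", "missing"),
  interval_group = c("metachronous", "synchronous"),
  neoadjuvant = c("1", "0"),
  resection_extent = c("minor", "major"),
  margin = c("R0", "R1"),
  blood_transfusion = c("0", "1"),
  distribution = c("bilobar", "unilobar"),
  adjuvant = c("1", "0")
)

#' Baseline contingency table in the layout of a high/low risk comparison
#'
#' Splits patients at one year of disease-free survival (DFS <= 12 months
#' versus > 12 months) and tabulates the categorical baseline variables as
#' high-risk / low-risk counts, for direct comparison of synthetic cohort
#' marginals against a published baseline table. Empty category levels are
#' reported with count 0, not dropped.
#'
#' @param records clinical data.frame (see \code{\link{RecurrenceCohort}}).
#' @param cutoff_months DFS split point in months (default 12).
#' @return data.frame: variable, level, high, low, total.
#' @export
emulatePaperMargins <- function(records, cutoff_months = 12) {
  stopIfNot(nrow(records) > 0, "records", "must be nonempty")
  high <- records$dfs_months <= cutoff_months
  records$interval_group <- ifelse(records$interval_to_metastasis <= 2,
                                   "synchronous", "metachronous")
  out <- list()
  out[["total"]] <- data.frame(variable = "total", level = "patients",
                               high = sum(high), low = sum(!high),
                               total = length(high))
  for (v in names(.MARGIN_VARS)) {
    if (!v %in% colnames(records)) next
    lv <- .MARGIN_VARS[[v]]
    x <- factor(as.character(records[[v]]), levels = lv)
    th <- table(x[high])
    tl <- table(x[!high])
    out[[v]] <- data.frame(variable = v, level = lv,
                           high = as.integer(th[lv]),
                           low = as.integer(tl[lv]),
                           total = as.integer(th[lv] + tl[lv]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct a QC manifest with prescribed failure groups
#'
#' Builds a sample-level QC annotation table in which a chosen number of
#' samples fail the RNA-integrity/yield criteria, the amplification step and
#' the labelling criteria respectively (disjoint groups), with all remaining
#' samples passing. Useful for exercising the QC exclusion cascade at the
#' counts reported for a real profiling campaign (148 processed, 13 + 8 + 8
#' excluded, 119 retained).
#'
#' @param n_total total number of samples.
#' @param n_rin_yield,n_amplification,n_labeling failure counts per stage.
#' @param seed integer seed (ordering of samples).
#' @return data.frame of QC annotations (columns as in the cohort QC table).
#' @export
emulateQcManifest <- function(n_total = 148, n_rin_yield = 13,
                              n_amplification = 8, n_labeling = 8,
                              seed = 1) {
  stopIfNot(n_rin_yield + n_amplification + n_labeling <= n_total,
            "n_total", "failure groups exceed total")
  withSeed(seed, {
    ids <- sprintf("s%04d", sample.int(n_total))
    qc <- data.frame(
      sample_id = ids,
      rin = round(runif(n_total, 6.2, 9.8), 1),
      crna_yield_ng = round(runif(n_total, 2500, 12000)),
      median_fragment_nt = round(runif(n_total, 600, 1500)),
      cy_incorporation_pct = round(runif(n_total, 1.6, 2.9), 2),
      amplification_failed = 0L,
      stringsAsFactors = FALSE)
    i <- seq_len(n_rin_yield)
    qc$rin[i] <- round(runif(n_rin_yield, 2.5, 5.9), 1)
    j <- n_rin_yield + seq_len(n_amplification)
    qc$amplification_failed[j] <- 1L
    k <- n_rin_yield + n_amplification + seq_len(n_labeling)
    qc$cy_incorporation_pct[k] <-
      round(ifelse(runif(n_labeling) < 0.5, runif(n_labeling, 0.2, 1.4),
                   runif(n_labeling, 3.1, 5.0)), 2)
    qc[sample.int(n_total), , drop = FALSE]
  })
}
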