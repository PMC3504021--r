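#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## Column names required of a clinical table (one row per patient).
CLINICAL_FIELDS <- c(
  "patient_id", "center", "sex", "age", "primary_site", "differentiation",
  "primary_stage", "nodal_status", "interval_to_metastasis", "n_metastases",
  "largest_metastasis_cm", "distribution", "preop_cea", "neoadjuvant",
  "adjuvant", "resection_extent", "margin", "hepatoduodenal_nodes",
  "blood_transfusion", "dfs_months", "event"
)

#' Cohort container: expression plus clinical annotation
#'
#' A \code{RecurrenceCohort} is a
#' \linkS4class{SummarizedExperiment} holding a genes-in-rows,
#' samples-in-columns matrix of log2 expression ratios against a common
#' reference (assay \code{"lratio"}), with the per-patient clinical table in
#' \code{colData}. The clinical table carries disease-free survival
#' (\code{dfs_months}), the recurrence event flag (\code{event}) and the
#' clinicopathological covariates used by the clinical risk scores.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @export
setClass("RecurrenceCohort", contains = "SummarizedExperiment")

setValidity("RecurrenceCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(c("patient_id", "dfs_months", "event"), colnames(cd))
  if (length(miss))
    return(sprintf("colData lacks required column(s): %s",
                   paste(miss, collapse = ", ")))
  if (any(cd$dfs_months < 0)) return("dfs_months must be >= 0")
  if (!isFlag01(cd$event)) return("event must be 0/1")
  if (!"lratio" %in% SummarizedExperiment::assayNames(object))
    return("assay 'lratio' missing")
  TRUE
})

#' Risk stratification rule
#'
#' Maps observed (DFS, event) pairs to \{high, low, unlabelable\}. A patient
#' is high risk only when recurrence was observed at
#' \code{dfs <= highMaxMonths}; low risk when follow-up (event or censoring)
#' exceeds \code{lowMinMonths}; anything else (typically censoring before the
#' high-risk cutoff) is unlabelable and excluded from signature discovery.
#'
#' @slot highMaxMonths numeric(1), months; default 12.
#' @slot lowMinMonths numeric(1), months; default 12.
#' @export
setClass("RiskRule",
         representation(highMaxMonths = "numeric", lowMinMonths = "numeric"))

setValidity("RiskRule", function(object) {
  if (length(object@highMaxMonths) != 1L || length(object@lowMinMonths) != 1L)
    return("thresholds must be scalar")
  if (object@highMaxMonths <= 0) return("highMaxMonths must be > 0")
  if (object@highMaxMonths > object@lowMinMonths)
    return("highMaxMonths must be <= lowMinMonths")
  TRUE
})

#' Nearest-mean (centroid) classifier over a gene set
#'
#' Genes are standardized by their training mean and standard deviation;
#' each risk class is represented by the centroid of its standardized
#' training samples. A new sample is scored by
#' \code{cor(sample, centroidLow) - cor(sample, centroidHigh)}; scores
#' \code{<= 0} classify as high risk (conservative tie rule). For a
#' single-gene signature, where correlation is undefined, the signed
#' standardized distance difference is used instead.
#'
#' @slot genes ordered character vector of signature gene ids.
#' @slot centroids numeric matrix, genes x 2, columns \code{high}, \code{low}.
#' @slot center,scale per-gene training mean / sd (named).
#' @slot trainingIds sample ids the model was fitted on (split hygiene).
#' @export
setClass("NearestMeanModel",
         representation(genes = "character", centroids = "matrix",
                        center = "numeric", scale = "numeric",
                        trainingIds = "character"))

setValidity("NearestMeanModel", function(object) {
  if (nrow(object@centroids) != length(object@genes))
    return("centroids must have one row per gene")
  if (!identical(colnames(object@centroids), c("high", "low")))
    return("centroid columns must be 'high', 'low'")
  if (any(object@scale <= 0)) return("per-gene sd must be > 0")
  TRUE
})

#' Result of the multiple-sampling discovery procedure
#'
#' @slot ranking data.frame with per-gene average combined rank over
#'   iterations and per-metric average ranks.
#' @slot pooled data.frame of pooled out-of-fold continuous risk scores with
#'   true labels, sample ids and iteration index.
#' @slot auc list: \code{auc}, \code{ci} (length 2), \code{n_boot}.
#' @slot config list of the resampling configuration actually used.
#' @export
setClass("DiscoveryResult",
         representation(ranking = "data.frame", pooled = "data.frame",
                        auc = "list", config = "list"))

#' A selected gene signature with its training accuracy curve
#'
#' @slot genes ordered gene ids of the selected signature.
#' @slot size selected signature size (smallest maximiser of LOOCV accuracy).
#' @slot accuracyCurve data.frame (size, accuracy) over candidate sizes.
#' @slot model the \linkS4class{NearestMeanModel} fitted on the full
#'   training set at the selected size.
#' @export
setClass("GeneSignature",
         representation(genes = "character", size = "integer",
                        accuracyCurve = "data.frame",
                        model = "NearestMeanModel"))

setValidity("GeneSignature", function(object) {
  if (object@size < 1L) return("signature size must be >= 1")
  if (length(object@genes) != object@size)
    return("genes must have length equal to size")
  TRUE
})

#' A clinical risk-score rubric
#'
#' A points-based prognostic index: each criterion is a predicate over one
#' clinical field awarding a fixed number of points; patients at or above
#' \code{threshold} total points are high risk. Rubrics ship as editable YAML
#' files (see \code{defaultRubrics}).
#'
#' @slot name rubric name (fong, nordlinger, iwatsuki, mayo, basingstoke).
#' @slot threshold high-risk threshold in points.
#' @slot basePoints points every patient starts with (Iwatsuki grades start
#'   at 1).
#' @slot criteria data.frame: label, field, op, value, points, enabled.
#' @export
setClass("ScoreRubric",
         representation(name = "character", threshold = "numeric",
                        basePoints = "numeric", criteria = "data.frame"))

setValidity("ScoreRubric", function(object) {
  need <- c("label", "field", "op", "value", "points", "enabled")
  if (!all(need %in% colnames(object@criteria)))
    return("criteria must have columns label/field/op/value/points/enabled")
  if (any(object@criteria$points < 0)) return("points must be >= 0")
  ok_ops <- c("eq", "ne", "lt", "le", "gt", "ge")
  if (!all(object@criteria$op %in% ok_ops))
    return(sprintf("op must be one of %s", paste(ok_ops, collapse = ", ")))
  TRUE
})

#' A raw two-channel (two-colour) microarray
#'
#' Spot-level mean intensities from one hybridization of a sample against
#' the common reference, with the print-tip group of every spot.
#' \code{dyeOrientation} records which channel carries the sample:
#' \code{"sample_cy5"} means channel 2 (Cy5) is the sample.
#'
#' @slot arrayId,sampleId identifiers.
#' @slot dyeOrientation \code{"sample_cy5"} or \code{"sample_cy3"}.
#' @slot spots data.frame: spot_id, gene_id, printtip_group, ch1, ch2,
#'   control_flag.
#' @export
setClass("TwoChannelArray",
         representation(arrayId = "character", sampleId = "character",
                        dyeOrientation = "character", spots = "data.frame"))

setValidity("TwoChannelArray", function(object) {
  need <- c("spot_id", "gene_id", "printtip_group", "ch1", "ch2",
            "control_flag")
  if (!all(need %in% colnames(object@spots)))
    return(sprintf("spots must have columns %s", paste(need, collapse = ", ")))
  if (!object@dyeOrientation %in% c("sample_cy5", "sample_cy3"))
    return("dyeOrientation must be 'sample_cy5' or 'sample_cy3'")
  if (any(object@spots$ch1 <= 0) || any(object@spots$ch2 <= 0))
    return("intensities must be > 0")
  TRUE
})

#' A normalized single-sample expression profile
#'
#' Per-gene M (log2 sample/reference ratio) and A (mean log2 intensity)
#' values after within-array normalization; control spots removed,
#' replicate spots per gene averaged.
#'
#' @slot sampleId sample identifier.
#' @slot dyeOrientation orientation of the array(s) the profile came from;
#'   \code{"merged"} after dye-swap merging.
#' @slot values data.frame: gene_id, M, A.
#' @export
setClass("NormalizedProfile",
         representation(sampleId = "character", dyeOrientation = "character",
                        values = "data.frame"))

setValidity("NormalizedProfile", function(object) {
  if (!all(c("gene_id", "M", "A") %in% colnames(object@values)))
    return("values must have columns gene_id, M, A")
  if (any(!is.finite(object@values$M))) return("M must be finite")
  if (anyDuplicated(object@values$gene_id)) return("one value per gene")
  TRUE
})
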