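#' Construct a RecurrenceCohort
#'
#' Bundles a genes-in-rows log2-ratio matrix with its clinical table (and
#' optional QC annotations) into a \linkS4class{RecurrenceCohort}.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = patient ids), log2 ratios versus the common
#'   reference.
#' @param clinical data.frame, one row per patient, containing at least
#'   \code{patient_id}, \code{dfs_months} and \code{event}; rows are matched
#'   to expression columns by \code{patient_id}.
#' @param qc optional data.frame of per-sample QC annotations (stored in
#'   \code{metadata(x)$qc}).
#' @return a \code{RecurrenceCohort}.
#' @examples
#' expr <- matrix(rnorm(20), 5, 4,
#'                dimnames = list(paste0("g", 1:5), paste0("p", 1:4)))
#' clin <- data.frame(patient_id = paste0("p", 1:4),
#'                    dfs_months = c(3, 15, 30, 8), event = c(1, 1, 0, 0))
#' RecurrenceCohort(expr, clin)
#' @export
RecurrenceCohort <- function(expr, clinical, qc = NULL) {
  stopIfNot(is.matrix(expr) && is.numeric(expr), "expr", "numeric matrix")
  stopIfNot(!is.null(rownames(expr)), "expr", "rownames (gene ids) required")
  stopIfNot(!is.null(colnames(expr)), "expr", "colnames (sample ids) required")
  stopIfNot(all(c("patient_id", "dfs_months", "event") %in% colnames(clinical)),
            "clinical", "needs patient_id, dfs_months, event")
  idx <- match(colnames(expr), clinical$patient_id)
  stopIfNot(!anyNA(idx), "clinical",
            "every expression column needs a clinical row")
  clinical <- clinical[idx, , drop = FALSE]
  rownames(clinical) <- clinical$patient_id
  md <- if (is.null(qc)) list() else list(qc = qc)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lratio = expr),
    colData = S4Vectors::DataFrame(clinical, check.names = FALSE),
    metadata = md)
  new("RecurrenceCohort", se)
}

#' Read / write cohort tables
#'
#' Expression is exchanged as tab-separated text (first column \code{gene_id},
#' header row of sample ids); clinical and QC tables as CSV.
#'
#' @param path file path.
#' @param expr,clinical as in \code{\link{RecurrenceCohort}}.
#' @return \code{readExpression} a numeric matrix; \code{readClinical} a
#'   data.frame; writers return \code{path} invisibly.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort-io
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(colnames(df)[1] == "gene_id", "expression file",
            "first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname cohort-io
#' @export
writeClinical <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort-io
#' @export
readClinical <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @importFrom utils write.table
NULL
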