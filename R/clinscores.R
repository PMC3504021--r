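#' Load a clinical risk-score rubric
#'
#' Rubrics are human-editable YAML files: a name, the high-risk points
#' threshold, optional base points, and a list of criteria, each with a
#' label, the clinical field tested, a comparator (\code{eq, ne, lt, le,
#' gt, ge}), a cut-off value and the points awarded. The shipped defaults
#' (Fong, Nordlinger, Iwatsuki, Mayo/Zakaria, Basingstoke) use the
#' published dichotomization thresholds; their component criteria are
#' transcribed from the scores' original publications and are meant to be
#' reviewed/edited for any serious use — the files live under
#' \code{system.file("extdata/rubrics", package = "recurSig")}.
#' Extrahepatic-disease criteria ship disabled (cohorts restricted to
#' liver-only disease cannot score them).
#'
#' @param path path to a rubric YAML file.
#' @return a \linkS4class{ScoreRubric}.
#' @export
loadRubric <- function(path) {
  y <- yaml::read_yaml(path)
  cr <- do.call(rbind, lapply(y$criteria, function(cc) {
    data.frame(label = cc$label, field = cc$field, op = cc$op,
               value = as.character(cc$value), points = as.numeric(cc$points),
               enabled = if (is.null(cc$enabled)) TRUE else
                 isTRUE(cc$enabled))
  }))
  new("ScoreRubric", name = y$name, threshold = as.numeric(y$high_risk_threshold),
      basePoints = if (is.null(y$base_points)) 0 else as.numeric(y$base_points),
      criteria = cr)
}

#' The five shipped rubrics
#'
#' @return named list of \linkS4class{ScoreRubric}s (fong, nordlinger,
#'   iwatsuki, mayo, basingstoke).
#' @export
defaultRubrics <- function() {
  dir <- system.file("extdata", "rubrics", package = "recurSig")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  rubs <- lapply(files, loadRubric)
  names(rubs) <- vapply(rubs, function(r) r@name, character(1))
  rubs[c("fong", "nordlinger", "iwatsuki", "mayo", "basingstoke")]
}

.MISSING_VALUES <- c("missing", "unknown")

.evalCriterion <- function(record, field, op, value) {
  if (!field %in% names(record)) return(NA)          # field not recorded
  x <- record[[field]]
  if (is.na(x) || (is.character(x) && x %in% .MISSING_VALUES)) return(NA)
  if (op %in% c("eq", "ne")) {
    hit <- as.character(x) == value
    return(if (op == "eq") hit else !hit)
  }
  xv <- suppressWarnings(as.numeric(x))
  cv <- suppressWarnings(as.numeric(value))
  if (is.na(xv) || is.na(cv)) return(NA)
  switch(op, lt = xv < cv, le = xv <= cv, gt = xv > cv, ge = xv >= cv)
}

#' Score one patient under a rubric
#'
#' Evaluates every enabled criterion; criteria whose inputs are missing
#' (field absent, NA, or a missing/unknown level) contribute 0 points and
#' set \code{completeness = FALSE} — so, e.g., unknown hepatoduodenal nodal
#' status silently caps the attainable Mayo/Zakaria score. Risk class is
#' high iff total points reach the rubric threshold.
#'
#' @param record one clinical row (data.frame row or named list).
#' @param rubric a \linkS4class{ScoreRubric} (or rubric name, resolved
#'   against \code{\link{defaultRubrics}}).
#' @return list of class \code{score_value}: patient_id, rubric, points,
#'   breakdown (data.frame), risk_class, complete.
#' @export
scorePatient <- function(record, rubric) {
  if (is.character(rubric)) {
    rubs <- defaultRubrics()
    if (!rubric %in% names(rubs))
      stop(sprintf("unknown rubric '%s'", rubric))
    rubric <- rubs[[rubric]]
  }
  validObject(rubric)
  record <- as.list(record)
  cr <- rubric@criteria[rubric@criteria$enabled, , drop = FALSE]
  met <- mapply(.evalCriterion, field = cr$field, op = cr$op,
                value = cr$value, MoreArgs = list(record = record))
  awarded <- ifelse(is.na(met), 0, met) * cr$points
  total <- rubric@basePoints + sum(awarded)
  structure(list(
    patient_id = if (!is.null(record$patient_id)) record$patient_id else NA,
    rubric = rubric@name,
    points = total,
    breakdown = data.frame(label = cr$label, met = met, points = awarded,
                           row.names = NULL),
    risk_class = if (total >= rubric@threshold) "high" else "low",
    complete = !any(is.na(met))), class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("%s score for %s: %g points -> %s risk%s\n", x$rubric,
              x$patient_id, x$points, x$risk_class,
              if (x$complete) "" else " (incomplete inputs)"))
  invisible(x)
}

#' Score a whole cohort under one rubric
#'
#' @param records clinical data.frame.
#' @inheritParams scorePatient
#' @return data.frame: patient_id, rubric, points, risk_class, complete.
#' @export
scoreCohort <- function(records, rubric) {
  rows <- lapply(seq_len(nrow(records)), function(i)
    scorePatient(records[i, ], rubric))
  data.frame(patient_id = records$patient_id,
             rubric = vapply(rows, `[[`, character(1), "rubric"),
             points = vapply(rows, `[[`, numeric(1), "points"),
             risk_class = vapply(rows, `[[`, character(1), "risk_class"),
             complete = vapply(rows, `[[`, logical(1), "complete"),
             row.names = NULL)
}

#' Survival validation of clinical risk scores
#'
#' Dichotomizes each patient under every rubric at its published threshold
#' and compares DFS of high- versus low-scored patients: Kaplan-Meier
#' estimates, Mantel-Cox log-rank test, and the Cox hazard ratio
#' (low vs high, so HR < 1 means the score separates as intended).
#' Rubrics placing all patients in one class are flagged non-evaluable.
#'
#' @param records clinical data.frame with dfs_months and event.
#' @param rubrics list of \linkS4class{ScoreRubric}s (default all five).
#' @return list per rubric: scores, evaluable, logrank, km, hr_low_vs_high.
#' @export
evaluateRubrics <- function(records, rubrics = defaultRubrics()) {
  stopIfNot(all(c("dfs_months", "event") %in% colnames(records)),
            "records", "DFS columns required")
  out <- lapply(rubrics, function(r) {
    sc <- scoreCohort(records, r)
    grp <- factor(sc$risk_class, levels = c("high", "low"))
    if (nlevels(droplevels(grp)) < 2 || sum(records$event) < 1)
      return(list(rubric = r@name, scores = sc, evaluable = FALSE,
                  logrank = NULL, km = NULL, hr_low_vs_high = NA))
    lr <- logrankTest(records$dfs_months, records$event, grp)
    list(rubric = r@name, scores = sc, evaluable = TRUE, logrank = lr,
         km = kmEstimate(records$dfs_months, records$event, grp),
         hr_low_vs_high = lr$hazard_ratio)
  })
  names(out) <- vapply(rubrics, function(r) r@name, character(1))
  out
}
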