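#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the disease-free-survival function, optionally
#' per group, via \code{survival::survfit}.
#'
#' @param time event/censoring times in months (>= 0).
#' @param event 0/1 event indicator (1 = recurrence observed).
#' @param group optional grouping factor.
#' @return data.frame: (group,) time, n_risk, n_event, surv — one row per
#'   observed time point, \code{surv} nonincreasing within group, S(0) = 1.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' @export
kmEstimate <- function(time, event, group = NULL) {
  stopIfNot(all(time >= 0) && all(is.finite(time)), "time",
            "must be finite and >= 0")
  stopIfNot(isFlag01(event), "event", "must be 0/1")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    g <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
  }
}

#' Mantel-Cox log-rank test with hazard ratio
#'
#' Two-group log-rank (observed minus expected, 1 df) via
#' \code{survival::survdiff}; the hazard ratio and its Wald 95\% CI come
#' from a companion single-covariate Cox fit (Efron ties). The hazard ratio
#' is reported for the second factor level relative to the first.
#'
#' @inheritParams kmEstimate
#' @param group two-level factor (or coercible).
#' @return list of class \code{"logrank_result"}: \code{chi_square},
#'   \code{p}, \code{hazard_ratio}, \code{hr_ci}, \code{table} (per-group
#'   n, observed and expected events).
#' @export
logrankTest <- function(time, event, group) {
  stopIfNot(all(time >= 0), "time", "must be >= 0")
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank test needs two groups")
  if (nlevels(group) > 2) stop("only two-group comparison supported")
  if (sum(event) < 1) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- as.numeric(sd$chisq)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group,
                        ties = "efron")
  hr <- unname(exp(coef(cx)))
  se <- sqrt(unname(diag(cx$var)))
  ci <- exp(unname(coef(cx)) + c(-1, 1) * qnorm(0.975) * se)
  structure(list(
    chi_square = chi, p = p, hazard_ratio = hr, hr_ci = ci,
    table = data.frame(group = levels(group), n = as.vector(sd$n),
                       observed = as.vector(sd$obs),
                       expected = as.vector(sd$exp))),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square %.3f (1 df), p = %.4g; HR %.3f (95%% CI %.3f-%.3f)\n",
              x$chi_square, x$p, x$hazard_ratio, x$hr_ci[1], x$hr_ci[2]))
  print(x$table)
  invisible(x)
}

#' Univariate / multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood fits with Efron tie handling. In univariate mode each
#' covariate is fitted alone; in multivariate mode all requested covariates
#' enter one model, and with \code{auto_select = TRUE} only those with
#' univariate Wald p < \code{select_p} are entered (the usual screening
#' rule for baseline risk-factor tables).
#'
#' @param data data.frame containing \code{time_col}, \code{event_col} and
#'   the covariates.
#' @param covariates character vector of covariate column names.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @param time_col,event_col column names for time and event.
#' @param auto_select,select_p screening of multivariate covariates by
#'   univariate p value.
#' @return data.frame: covariate, term, hr, ci_lower, ci_upper, p, mode.
#' @export
coxFit <- function(data, covariates, mode = c("univariate", "multivariate"),
                   time_col = "dfs_months", event_col = "event",
                   auto_select = FALSE, select_p = 0.1) {
  mode <- match.arg(mode)
  stopIfNot(all(covariates %in% colnames(data)), "covariates",
            "must be columns of data")
  for (v in covariates)
    if (length(unique(na.omit(data[[v]]))) < 2)
      stop(sprintf("covariate '%s' is constant", v))
  y <- survival::Surv(data[[time_col]], data[[event_col]])
  tidyFit <- function(fit, mode, covs) {
    s <- summary(fit)
    co <- s$coefficients
    term2cov <- vapply(rownames(co), function(tm) {
      hit <- covs[startsWith(tm, covs)]
      if (length(hit)) hit[which.max(nchar(hit))] else tm
    }, character(1))
    data.frame(covariate = unname(term2cov),
               term = rownames(co),
               hr = unname(co[, "exp(coef)"]),
               ci_lower = unname(s$conf.int[, "lower .95"]),
               ci_upper = unname(s$conf.int[, "upper .95"]),
               p = unname(co[, "Pr(>|z|)"]),
               mode = mode, row.names = NULL)
  }
  uni <- do.call(rbind, lapply(covariates, function(v) {
    fit <- tryCatch(
      survival::coxph(stats::reformulate(v, response = "y"),
                      data = data, ties = "efron"),
      warning = function(w) {
        f <- suppressWarnings(
          survival::coxph(stats::reformulate(v, response = "y"),
                          data = data, ties = "efron"))
        if (any(!is.finite(sqrt(diag(f$var)))) ||
            any(abs(coef(f)) > 15))
          stop(sprintf("Cox fit for '%s' did not converge (|coef| = %.2g)",
                       v, max(abs(coef(f)))), call. = FALSE)
        f
      })
    out <- tidyFit(fit, "univariate", v)
    out$covariate <- v
    out
  }))
  if (mode == "univariate") return(uni)
  keep <- covariates
  if (auto_select) {
    minp <- vapply(covariates, function(v) min(uni$p[uni$covariate == v]),
                   numeric(1))
    keep <- covariates[minp < select_p]
    if (!length(keep)) stop("no covariate passes the univariate screen")
  }
  if (sum(data[[event_col]]) < length(keep))
    stop("fewer events than covariates in multivariate mode")
  fit <- survival::coxph(stats::reformulate(keep, response = "y"),
                         data = data, ties = "efron")
  tidyFit(fit, "multivariate", keep)
}

#' Power of the two-group log-rank test (Schoenfeld approximation)
#'
#' \deqn{power = \Phi(|\log hr| \sqrt{d\,p(1-p)} - z_{1-\alpha/2})}
#' where \code{d} is the total number of events and \code{p} the allocation
#' fraction.
#'
#' @param hr hazard ratio (> 0).
#' @param n_events total number of events.
#' @param allocation fraction of patients in one group (default 0.5).
#' @param alpha two-sided significance level.
#' @return power in [0, 1] (vectorised over \code{hr} and \code{n_events}).
#' @export
logrankPower <- function(hr, n_events, allocation = 0.5, alpha = 0.05) {
  stopIfNot(all(hr > 0), "hr", "must be > 0")
  stopIfNot(alpha > 0 && alpha < 1, "alpha", "must be in (0, 1)")
  pnorm(abs(log(hr)) * sqrt(n_events * allocation * (1 - allocation)) -
          qnorm(1 - alpha / 2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), with
#' input validation.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, elementwise >= \code{p}.
#' @export
bhAdjust <- function(p) {
  stopIfNot(all(is.finite(p)) && all(p >= 0) && all(p <= 1), "p",
            "must be in [0, 1]")
  p.adjust(p, method = "BH")
}

## Variables treated as continuous in baseline comparisons.
.CONTINUOUS_VARS <- c("age", "interval_to_metastasis", "n_metastases",
                      "largest_metastasis_cm", "preop_cea", "dfs_months")
.MISSING_TOKENS <- c("missing", "unknown", NA)

#' Baseline-table group comparison
#'
#' Compares clinical variables between two patient groups: two-sided
#' Fisher's exact test for categorical variables (missing-value rows
#' excluded from the tested table and reported separately) and the
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test for continuous ones.
#'
#' @param records clinical data.frame.
#' @param labels two-level grouping (e.g. high/low risk), one per row.
#' @param variables columns to test (defaults to all clinical covariates
#'   present).
#' @param categorical_test \code{"fisher"} (exact, default) or
#'   \code{"chisq"} (Pearson chi-square without continuity correction; the
#'   variant many clinical statistics packages report for baseline tables).
#' @return data.frame: variable, test, p, n_missing.
#' @export
baselineComparison <- function(records, labels, variables = NULL,
                               categorical_test = c("fisher", "chisq")) {
  categorical_test <- match.arg(categorical_test)
  labels <- factor(labels)
  stopIfNot(nlevels(labels) == 2, "labels", "need exactly two groups")
  if (is.null(variables))
    variables <- setdiff(intersect(CLINICAL_FIELDS, colnames(records)),
                         c("patient_id", "dfs_months", "event"))
  out <- lapply(variables, function(v) {
    x <- records[[v]]
    if (v %in% .CONTINUOUS_VARS || (is.numeric(x) &&
                                    length(unique(na.omit(x))) > 6)) {
      keep <- !is.na(x)
      p <- suppressWarnings(
        wilcox.test(x[keep] ~ labels[keep], exact = FALSE)$p.value)
      data.frame(variable = v, test = "mann_whitney", p = p,
                 n_missing = sum(!keep))
    } else {
      xx <- as.character(x)
      keep <- !(xx %in% .MISSING_TOKENS)
      tab <- table(xx[keep], labels[keep])
      if (nrow(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning(sprintf("variable '%s' skipped: empty category", v))
        return(NULL)
      }
      p <- if (categorical_test == "fisher") fisher.test(tab)$p.value else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(variable = v,
                 test = if (categorical_test == "fisher") "fisher_exact" else
                   "chisq", p = p, n_missing = sum(!keep))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confusion-matrix metrics for dichotomous DFS prediction
#'
#' Accuracy, sensitivity and specificity of predicted risk classes against
#' dichotomous outcome labels; patients with unlabelable outcome are
#' excluded from the metrics and counted.
#'
#' @param predicted factor/character of predicted classes (high/low).
#' @param truth factor/character of true classes (high/low/unlabelable).
#' @param positive the class treated as positive (default "high").
#' @return list: accuracy, sensitivity, specificity, n_evaluated,
#'   n_unlabelable, confusion (2x2 table).
#' @export
classificationMetrics <- function(predicted, truth, positive = "high") {
  keep <- truth %in% c("high", "low")
  pred <- factor(as.character(predicted[keep]), levels = c("high", "low"))
  tru <- factor(as.character(truth[keep]), levels = c("high", "low"))
  tab <- table(predicted = pred, truth = tru)
  tp <- tab[positive, positive]
  neg <- setdiff(c("high", "low"), positive)
  tn <- tab[neg, neg]
  list(accuracy = (tp + tn) / sum(tab),
       sensitivity = tp / sum(tab[, positive]),
       specificity = tn / sum(tab[, neg]),
       n_evaluated = sum(keep), n_unlabelable = sum(!keep),
       confusion = tab)
}
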