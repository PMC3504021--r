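test_that("Kaplan-Meier estimates follow the product-limit arithmetic", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  ## no events: survival stays at 1
  km0 <- kmEstimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  ## censoring before the first event decrements at-risk without a drop
  km1 <- kmEstimate(c(1, 2, 3), c(0, 1, 1))
  ev <- km1[km1$n_event > 0, ]
  expect_equal(ev$n_risk, c(2, 1))
  expect_equal(ev$surv, c(1 / 2, 0))

  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "time")
})

test_that("log-rank statistic matches the hypergeometric-increment oracle", {
  ## identical groups: statistic 0, p 1
  tm <- c(2, 4, 6, 8); evs <- c(1, 0, 1, 1)
  lr0 <- logrankTest(c(tm, tm), c(evs, evs), rep(c("a", "b"), each = 4))
  expect_lt(lr0$chi_square, 1e-9)
  expect_equal(lr0$p, 1)

  ## 6-patient toy with 4 events
  time <- c(1, 3, 5, 2, 6, 9)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("a", "b"), each = 3)
  lr <- logrankTest(time, event, grp)
  expect_equal(lr$chi_square, logrankEnum(time, event, grp),
               tolerance = 1e-8)

  ## invariances: time rescaling and group-label swap
  lr_scaled <- logrankTest(time * 30.44, event, grp)
  expect_equal(lr_scaled$chi_square, lr$chi_square, tolerance = 1e-8)
  lr_swap <- logrankTest(time, event, ifelse(grp == "a", "b", "a"))
  expect_equal(lr_swap$p, lr$p, tolerance = 1e-8)

  expect_error(logrankTest(time, event, rep("a", 6)), "two groups")
  expect_error(logrankTest(time, rep(0, 6), grp), "at least one event")
})

test_that("Cox fits are consistent with the log-rank HR and fail gracefully", {
  set.seed(21)
  n <- 120
  grp <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.04 * exp(0.8 * grp))
  event <- as.integer(runif(n) > 0.2)
  d <- data.frame(dfs_months = time, event = event, g = grp,
                  junk = rnorm(n))
  lr <- logrankTest(time, event, factor(grp))
  cx <- coxFit(d, "g")
  expect_equal(cx$hr, lr$hazard_ratio, tolerance = 1e-3)

  ## multivariate auto-screen keeps only univariate p < 0.1 covariates
  mv <- coxFit(d, c("g", "junk"), mode = "multivariate", auto_select = TRUE)
  expect_true("g" %in% mv$covariate)
  expect_false("junk" %in% mv$covariate)

  expect_error(coxFit(d, "nope"), "covariates")
  d$const <- 1
  expect_error(coxFit(d, "const"), "constant")
  ## one patient per group, one event: error, not a crash
  d2 <- data.frame(dfs_months = c(2, 10), event = c(1, 0), g = c(1, 0))
  expect_error(coxFit(d2, "g"), "converge")
})

test_that("Cox Wald CIs cover the null HR at the nominal rate", {
  cover <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    n <- 120
    x <- rnorm(n)
    d <- data.frame(dfs_months = rexp(n, 0.05), event = rbinom(n, 1, 0.8),
                    x = x)
    cx <- coxFit(d, "x")
    cx$ci_lower <= 1 && cx$ci_upper >= 1
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("Schoenfeld log-rank power matches its closed form and a simulation", {
  expect_equal(logrankPower(1, 100), pnorm(-qnorm(0.975)))
  ## monotone in events and effect size
  expect_true(all(diff(logrankPower(2, c(20, 50, 100, 200))) > 0))
  expect_true(all(diff(logrankPower(c(1.2, 1.5, 2, 3), 88)) > 0))

  ## simulation oracle: hr = 2, 88 events, equal allocation
  target <- logrankPower(2, 88, 0.5, 0.05)
  rej <- vapply(1:2500, function(s) {
    set.seed(5000 + s)
    g <- rep(c(0, 1), each = 44)
    tm <- rexp(88, 0.05 * 2^g)
    logrankTest(tm, rep(1, 88), g)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - target), 0.03)
})

test_that("Benjamini-Hochberg adjustment follows step-up arithmetic", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  ## independent step-up oracle
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(adj[o], pmin(stepup, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "p")
})

test_that("baseline comparisons reproduce a published-style 2x2 analysis", {
  neo <- expandTable(matrix(c(45, 27, 19, 28), 2), "neoadjuvant",
                     c("1", "0"))
  out <- baselineComparison(neo$records, neo$labels,
                            variables = "neoadjuvant")
  expect_equal(out$test, "fisher_exact")
  expect_equal(out$p, fisherEnum(matrix(c(45, 27, 19, 28), 2)),
               tolerance = 1e-9)

  ## identical group proportions at large n: p near 1
  bal <- expandTable(matrix(c(40, 40, 40, 40), 2), "flag", c("1", "0"))
  out2 <- baselineComparison(bal$records, bal$labels, variables = "flag")
  expect_gt(out2$p, 0.99)

  ## missing rows are excluded from the table and counted
  rec <- data.frame(patient_id = sprintf("p%02d", 1:40),
                    nodal_status = c(rep(c("positive", "negative"), 18),
                                     rep("missing", 4)),
                    age = rnorm(40, 60, 10))
  lab <- rep(c("high", "low"), 20)
  out3 <- baselineComparison(rec, lab,
                             variables = c("nodal_status", "age"))
  expect_equal(out3$n_missing[out3$variable == "nodal_status"], 4)
  expect_equal(out3$test[out3$variable == "age"], "mann_whitney")
})

test_that("classification metrics match a hand confusion matrix", {
  pred <- c("high", "high", "low", "low", "high", "low", "high", "low",
            "high", "low")
  tru <- c("high", "high", "high", "low", "low", "low", "high", "high",
           "unlabelable", "unlabelable")
  m <- classificationMetrics(pred, tru)
  ## evaluated 8: TP 3 (of 5 true high), TN 2 (of 3 true low)
  expect_equal(m$n_evaluated, 8)
  expect_equal(m$n_unlabelable, 2)
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 5 / 8)

  perf <- classificationMetrics(c("high", "low"), c("high", "low"))
  expect_equal(perf$accuracy, 1)
  allHigh <- classificationMetrics(rep("high", 4),
                                   c("high", "high", "low", "low"))
  expect_equal(allHigh$sensitivity, 1)
  expect_equal(allHigh$specificity, 0)
})
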