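## Build a spot table in sample-vs-reference coordinates: given target M
## and A per spot, reconstruct the two channel intensities.
spotsFromMA <- function(M, A, tip, orient = "sample_cy5",
                        control = rep(0, length(M))) {
  ref <- 2^(A - M / 2)
  smp <- 2^(A + M / 2)
  if (orient == "sample_cy5") {
    ch1 <- ref; ch2 <- smp
  } else {
    ch1 <- smp; ch2 <- ref
  }
  data.frame(spot_id = sprintf("sp%04d", seq_along(M)),
             gene_id = sprintf("g%04d", seq_along(M)),
             printtip_group = tip, ch1 = ch1, ch2 = ch2,
             control_flag = control)
}

test_that("loess normalization is the identity on unbiased arrays", {
  set.seed(11)
  A <- runif(300, 6, 14)
  arr <- TwoChannelArray("a1", "p1", "sample_cy5",
                         spotsFromMA(rep(0, 300), A, rep(1:3, each = 100)))
  pr <- printtipLoessNormalize(arr)
  expect_lt(max(abs(pr@values$M)), 1e-8)
})

test_that("an injected intensity-dependent bias is removed per tip group", {
  set.seed(12)
  A <- runif(600, 6, 14)
  tip <- rep(1:4, each = 150)
  arr <- TwoChannelArray("a1", "p1", "sample_cy5",
                         spotsFromMA(0.5 * A, A, tip))
  pr <- printtipLoessNormalize(arr)
  expect_lt(mean(abs(pr@values$M)), 0.05)
})

test_that("tip groups with opposite constant offsets are centered independently", {
  set.seed(13)
  A <- runif(200, 6, 14)
  tip <- rep(1:2, each = 100)
  M <- ifelse(tip == 1, 1, -1)
  arr <- TwoChannelArray("a1", "p1", "sample_cy5", spotsFromMA(M, A, tip))
  pr <- printtipLoessNormalize(arr)
  expect_lt(max(abs(pr@values$M)), 1e-6)
})

test_that("re-normalizing an already normalized (smooth-bias) array is a no-op", {
  set.seed(14)
  A <- runif(240, 6, 14)
  tip <- rep(1:2, each = 120)
  arr <- TwoChannelArray("a1", "p1", "sample_cy5",
                         spotsFromMA(0.3 * A - 1, A, tip))
  p1 <- printtipLoessNormalize(arr)
  arr2 <- TwoChannelArray("a1b", "p1", "sample_cy5",
                          spotsFromMA(p1@values$M, p1@values$A,
                                      rep(1:2, each = 120)))
  p2 <- printtipLoessNormalize(arr2)
  expect_lt(mean(abs(p2@values$M - p1@values$M)), 1e-6)
})

test_that("small tip groups fall back to the global fit with a warning", {
  set.seed(15)
  A <- runif(110, 6, 14)
  tip <- c(rep(1, 100), rep(2, 10))          # group 2 below the minimum
  arr <- TwoChannelArray("a1", "p1", "sample_cy5",
                         spotsFromMA(0.2 * A, A, tip))
  expect_warning(pr <- printtipLoessNormalize(arr), "global loess")
  expect_lt(mean(abs(pr@values$M)), 0.05)
})

test_that("control spots are excluded from fitting and output", {
  set.seed(16)
  A <- runif(220, 6, 14)
  ctl <- c(rep(0, 200), rep(1, 20))
  sp <- spotsFromMA(c(rep(0, 200), rep(5, 20)), A, rep(1, 220),
                    control = ctl)
  arr <- TwoChannelArray("a1", "p1", "sample_cy5", sp)
  pr <- printtipLoessNormalize(arr)
  expect_equal(nrow(pr@values), 200)
  expect_lt(max(abs(pr@values$M)), 1e-6)   # control spikes did not bend the fit
})

test_that("nonpositive intensities are rejected", {
  sp <- spotsFromMA(rep(0, 30), runif(30, 6, 14), rep(1, 30))
  sp$ch1[1] <- 0
  expect_error(TwoChannelArray("a1", "p1", "sample_cy5", sp) |>
                 printtipLoessNormalize(), "intensities")
})

mkProfile <- function(M, id = "p1", orient = "sample_cy5",
                      genes = sprintf("g%03d", seq_along(M))) {
  new("NormalizedProfile", sampleId = id, dyeOrientation = orient,
      values = data.frame(gene_id = genes, M = M, A = rep(10, length(M))))
}

test_that("dye-swap decomposition recovers signal and bias exactly", {
  set.seed(17)
  s <- rnorm(50); b <- rnorm(50, 0, 0.3)
  r <- correctDyeBiasAndMerge(mkProfile(s + b), mkProfile(-s + b,
                                                          orient = "sample_cy3"))
  expect_equal(unname(r$merged@values$M), s, tolerance = 1e-12)
  expect_equal(unname(r$dye_bias), b, tolerance = 1e-12)

  ## pure biological signal: M2 = -M1 -> merged = M1, bias = 0
  r2 <- correctDyeBiasAndMerge(mkProfile(s), mkProfile(-s,
                                                       orient = "sample_cy3"))
  expect_equal(unname(r2$merged@values$M), s)
  expect_equal(max(abs(r2$dye_bias)), 0)

  ## pure dye bias: M1 = M2 = b -> merged = 0
  r3 <- correctDyeBiasAndMerge(mkProfile(b), mkProfile(b,
                                                       orient = "sample_cy3"))
  expect_equal(max(abs(r3$merged@values$M)), 0)

  ## the worked single-gene case: s = 0.7, b = 0.3
  r4 <- correctDyeBiasAndMerge(mkProfile(c(1.0, 0)), mkProfile(c(-0.4, 0),
                                                               orient = "sample_cy3"))
  expect_equal(r4$merged@values$M[1], 0.7)
  expect_equal(unname(r4$dye_bias[1]), 0.3)
})

test_that("mismatched gene sets in a swap pair are an error", {
  p1 <- mkProfile(rnorm(5))
  p2 <- mkProfile(rnorm(5), orient = "sample_cy3",
                  genes = sprintf("h%03d", 1:5))
  expect_error(correctDyeBiasAndMerge(p1, p2), "gene sets differ")
})

test_that("replicate profiles average genewise", {
  p1 <- mkProfile(c(1, 2, 3))
  p2 <- mkProfile(c(3, 2, 1))
  av <- averageReplicateProfiles(list(p1, p2))
  expect_equal(av@values$M, c(2, 2, 2))
})

test_that("the QC cascade reproduces the 148 -> 119 exclusion partition", {
  qc <- emulateQcManifest(148, 13, 8, 8, seed = 5)
  f <- qcFilterSamples(qc)
  expect_equal(length(f$kept), 119)
  rep <- setNames(f$report$n, f$report$reason)
  expect_equal(unname(rep[c("rin_yield", "amplification", "labeling")]),
               c(13, 8, 8))
  ## every sample in exactly one of kept / excluded
  expect_setequal(c(f$kept, f$excluded$sample_id), qc$sample_id)
  expect_equal(length(intersect(f$kept, f$excluded$sample_id)), 0)
})

test_that("all-passing manifests keep everything; failures attribute to the first stage", {
  qc <- emulateQcManifest(20, 0, 0, 0, seed = 6)
  f <- qcFilterSamples(qc)
  expect_equal(length(f$kept), 20)
  expect_equal(nrow(f$excluded), 0)

  ## 3-sample toy: s1 fails RIN and labeling -> counted once, under RIN
  toy <- data.frame(sample_id = c("s1", "s2", "s3"),
                    rin = c(4, 8, 8), crna_yield_ng = 5000,
                    median_fragment_nt = 900,
                    cy_incorporation_pct = c(0.5, 2, 2),
                    amplification_failed = c(0L, 1L, 0L))
  f2 <- qcFilterSamples(toy)
  expect_equal(f2$excluded$reason[f2$excluded$sample_id == "s1"],
               "rin_yield")
  expect_equal(f2$excluded$reason[f2$excluded$sample_id == "s2"],
               "amplification")
  expect_equal(f2$kept, "s3")

  expect_error(qcFilterSamples(toy[, -2]), "lacks field")
})
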