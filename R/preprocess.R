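#' Construct a TwoChannelArray
#'
#' @param array_id,sample_id identifiers.
#' @param dye_orientation \code{"sample_cy5"} (sample in channel 2) or
#'   \code{"sample_cy3"}.
#' @param spots data.frame with columns spot_id, gene_id, printtip_group,
#'   ch1, ch2, control_flag (ch1 = Cy3, ch2 = Cy5 mean intensities, > 0).
#' @return a \linkS4class{TwoChannelArray}.
#' @export
TwoChannelArray <- function(array_id, sample_id, dye_orientation, spots) {
  new("TwoChannelArray", arrayId = as.character(array_id),
      sampleId = as.character(sample_id),
      dyeOrientation = dye_orientation,
      spots = as.data.frame(spots))
}

#' Read a spot table
#'
#' Tab-separated spot-level file with required columns spot_id, gene_id,
#' printtip_group, ch1, ch2, control_flag.
#'
#' @param path file path.
#' @inheritParams TwoChannelArray
#' @return a \linkS4class{TwoChannelArray}.
#' @export
readSpotTable <- function(path, array_id, sample_id, dye_orientation) {
  spots <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "gene_id", "printtip_group", "ch1", "ch2",
            "control_flag")
  miss <- setdiff(need, colnames(spots))
  if (length(miss))
    stop(sprintf("spot table lacks column(s): %s", paste(miss, collapse = ", ")))
  TwoChannelArray(array_id, sample_id, dye_orientation, spots)
}

## M/A values of an array in sample-vs-reference orientation.
.arrayMA <- function(array) {
  sp <- array@spots
  if (array@dyeOrientation == "sample_cy5") {
    m <- log2(sp$ch2 / sp$ch1)
  } else {
    m <- log2(sp$ch1 / sp$ch2)
  }
  data.frame(spot_id = sp$spot_id, gene_id = sp$gene_id,
             printtip_group = sp$printtip_group,
             control = sp$control_flag != 0,
             M = m, A = 0.5 * log2(sp$ch1 * sp$ch2))
}

#' Print-tip loess normalization
#'
#' Within each print-tip group, fits a robust local linear regression of M
#' (log2 sample/reference ratio) on A (mean log2 intensity) over the
#' non-control spots and subtracts the fit, removing intensity-dependent
#' dye bias separately per spotting pen. Degree-1 local regression with
#' tricube weights and three robustness iterations; print-tip groups with
#' fewer than \code{min_spots} usable spots fall back to the global
#' (all-spot) loess fit with a warning. Control spots are excluded from
#' fitting and from the output; replicate spots per gene are averaged.
#'
#' @param array a \linkS4class{TwoChannelArray}.
#' @param span loess span (fraction of spots in each local window).
#' @param min_spots minimum usable spots per print-tip group.
#' @return a \linkS4class{NormalizedProfile}.
#' @export
printtipLoessNormalize <- function(array, span = 0.4, min_spots = 20) {
  stopifnot(is(array, "TwoChannelArray"))
  validObject(array)
  ma <- .arrayMA(array)
  use <- !ma$control
  if (!any(use)) stop("no non-control spots")
  fitLoess <- function(df) {
    if (diff(range(df$A)) < .Machine$double.eps^0.5 ||
        diff(range(df$M)) < .Machine$double.eps^0.5)
      return(function(a) rep(mean(df$M), length(a)))
    ## robust (tricube + biweight) fit; an exact fit makes the robustness
    ## scale collapse, in which case the plain fit is already right
    fit <- tryCatch(
      loess(M ~ A, data = df, span = span, degree = 1,
            family = "symmetric", surface = "direct",
            control = loess.control(iterations = 4)),
      error = function(e)
        loess(M ~ A, data = df, span = span, degree = 1,
              family = "gaussian", surface = "direct"))
    function(a) {
      out <- predict(fit, data.frame(A = a))
      ## direct-surface prediction is defined everywhere; guard regardless
      out[is.na(out)] <- mean(df$M)
      out
    }
  }
  globalFit <- fitLoess(ma[use, ])
  corrected <- ma$M
  for (g in unique(ma$printtip_group)) {
    sel <- ma$printtip_group == g & use
    if (sum(sel) < min_spots) {
      warning(sprintf(
        "print-tip group '%s' has %d usable spots (< %d); using global loess",
        g, sum(sel), min_spots))
      f <- globalFit
    } else {
      f <- fitLoess(ma[sel, ])
    }
    idx <- ma$printtip_group == g
    corrected[idx] <- ma$M[idx] - f(ma$A[idx])
  }
  keep <- ma[use, ]
  keep$M <- corrected[use]
  agg <- stats::aggregate(cbind(M, A) ~ gene_id, data = keep, FUN = mean)
  new("NormalizedProfile", sampleId = array@sampleId,
      dyeOrientation = array@dyeOrientation,
      values = agg[order(agg$gene_id), c("gene_id", "M", "A")])
}

#' Dye-bias correction and dye-swap merging
#'
#' For a dye-swap pair measured in array (channel) coordinates, the log
#' ratio decomposes as \eqn{M_1 = s + b}, \eqn{M_2 = -s + b}: the biological
#' signal \eqn{s} flips sign with the swap while the per-gene dye bias
#' \eqn{b} does not. The within-pair bias estimate is
#' \eqn{\hat b = (M_1 + M_2)/2}, removed exactly by the orientation-corrected
#' average \eqn{\hat s = (M_1 - M_2)/2}. Profiles must cover identical gene
#' sets.
#'
#' @param profile1,profile2 \linkS4class{NormalizedProfile}s of the same
#'   sample in opposite dye orientations. \code{profile2}'s M values are
#'   interpreted in its own channel coordinates (sign not yet flipped to the
#'   sample-vs-reference orientation of \code{profile1}).
#' @return list: \code{merged} (a \code{NormalizedProfile} with the
#'   bias-free M), \code{dye_bias} (named per-gene vector).
#' @export
correctDyeBiasAndMerge <- function(profile1, profile2) {
  stopifnot(is(profile1, "NormalizedProfile"),
            is(profile2, "NormalizedProfile"))
  g1 <- profile1@values$gene_id
  g2 <- profile2@values$gene_id
  if (!setequal(g1, g2)) {
    dif <- c(setdiff(g1, g2), setdiff(g2, g1))
    stop(sprintf("gene sets differ between dye-swap profiles: %s",
                 paste(head(dif, 10), collapse = ", ")))
  }
  v1 <- profile1@values[order(g1), ]
  v2 <- profile2@values[order(g2), ]
  s <- (v1$M - v2$M) / 2
  b <- (v1$M + v2$M) / 2
  merged <- new("NormalizedProfile", sampleId = profile1@sampleId,
                dyeOrientation = "merged",
                values = data.frame(gene_id = v1$gene_id, M = s,
                                    A = (v1$A + v2$A) / 2))
  list(merged = merged, dye_bias = stats::setNames(b, v1$gene_id))
}

#' Average replicate profiles of one sample
#'
#' @param profiles list of \linkS4class{NormalizedProfile}s over identical
#'   gene sets (e.g. several merged dye-swap pairs of one biopsy).
#' @return a single averaged \code{NormalizedProfile}.
#' @export
averageReplicateProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]@values$gene_id
  ms <- sapply(profiles, function(p) {
    stopifnot(setequal(p@values$gene_id, ref))
    p@values$M[match(ref, p@values$gene_id)]
  })
  as_ <- sapply(profiles, function(p)
    p@values$A[match(ref, p@values$gene_id)])
  new("NormalizedProfile", sampleId = profiles[[1]]@sampleId,
      dyeOrientation = "merged",
      values = data.frame(gene_id = ref, M = rowMeans(as.matrix(ms)),
                          A = rowMeans(as.matrix(as_))))
}

#' Sample QC exclusion cascade
#'
#' Applies the sample-quality gates in their processing order — (1) RNA
#' integrity / yield (RIN, cRNA yield, median fragment length), (2)
#' amplification failure, (3) labelling (Cy-dye incorporation window) — and
#' attributes every excluded sample to the FIRST stage it fails, so each
#' sample appears in exactly one of kept/excluded.
#'
#' @param annotations QC data.frame: sample_id, rin, crna_yield_ng,
#'   median_fragment_nt, cy_incorporation_pct, amplification_failed.
#' @param thresholds list: rin_min (6), crna_min_ng (2000), fragment_min_nt
#'   (500), cy_pct_range (c(1.5, 3)).
#' @return list: \code{kept} (sample ids), \code{excluded} (data.frame
#'   sample_id, reason), \code{report} (per-reason counts incl. kept).
#' @export
qcFilterSamples <- function(annotations,
                            thresholds = list(rin_min = 6,
                                              crna_min_ng = 2000,
                                              fragment_min_nt = 500,
                                              cy_pct_range = c(1.5, 3.0))) {
  need <- c("sample_id", "rin", "crna_yield_ng", "median_fragment_nt",
            "cy_incorporation_pct", "amplification_failed")
  miss <- setdiff(need, colnames(annotations))
  if (length(miss))
    stop(sprintf("QC annotation lacks field(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyNA(annotations[need]))
    stop("QC annotation contains missing values")
  fail1 <- annotations$rin < thresholds$rin_min |
    annotations$crna_yield_ng < thresholds$crna_min_ng |
    annotations$median_fragment_nt < thresholds$fragment_min_nt
  fail2 <- annotations$amplification_failed != 0
  fail3 <- annotations$cy_incorporation_pct < thresholds$cy_pct_range[1] |
    annotations$cy_incorporation_pct > thresholds$cy_pct_range[2]
  reason <- rep(NA_character_, nrow(annotations))
  reason[fail3] <- "labeling"
  reason[fail2] <- "amplification"   # earlier stages overwrite later ones
  reason[fail1] <- "rin_yield"
  kept <- annotations$sample_id[is.na(reason)]
  excluded <- data.frame(sample_id = annotations$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  report <- data.frame(
    reason = c("rin_yield", "amplification", "labeling", "kept"),
    n = c(sum(reason == "rin_yield", na.rm = TRUE),
          sum(reason == "amplification", na.rm = TRUE),
          sum(reason == "labeling", na.rm = TRUE),
          length(kept)))
  list(kept = kept, excluded = excluded, report = report)
}
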