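#' Build a two-channel ANOVA design from sample log-ratios
#'
#' Expands a genes x samples log2-ratio matrix into the channel-level
#' observation layout of the fixed-effects ANOVA: each sample is
#' hybridized on one array against the common reference, contributing a
#' sample channel (the sample's log2 value) and a reference channel
#' (reference RNA, mean 0 with dispersion \code{ref_sd}). Dye orientation
#' alternates \emph{within} each treatment group, so the treatment
#' contrast is never aliased with the dye effect. Optional array and dye
#' nuisance effects can be injected to exercise their estimation. The
#' residual-permutation test assumes observation-level errors of
#' comparable dispersion in both channels, so \code{ref_sd} should match
#' the per-gene noise of \code{expr}.
#'
#' @param expr genes x samples matrix of log2 sample/reference ratios.
#' @param treated logical/0-1 vector per sample (neoadjuvant treated).
#' @param ref_sd sd of the reference-channel values (log2 units;
#'   default 1, matching the default cohort noise).
#' @param array_sd,dye_effect sd of per-array offsets and a fixed dye
#'   offset added to Cy5 channels (log2 units; defaults 0).
#' @param seed RNG seed for the reference channels and nuisance effects.
#' @return list of class \code{DiffexpDesign}: \code{obs} (data.frame:
#'   array, dye, sample_id, group with levels reference/untreated/treated)
#'   and \code{Y} (genes x observations matrix of channel log2
#'   intensities).
#' @export
buildDyeSwapDesign <- function(expr, treated, ref_sd = 1, array_sd = 0,
                               dye_effect = 0, seed = 1) {
  stopIfNot(ncol(expr) == length(treated), "treated",
            "one flag per sample")
  n <- ncol(expr)
  withSeed(seed, {
    arr <- rep(seq_len(n), each = 2)
    dye <- rep(c("cy3", "cy5"), n)
    ## alternate dye orientation within each treatment group so that
    ## treatment and dye are never confounded
    sampleInCy5 <- logical(n)
    for (grp_idx in list(which(as.logical(treated)),
                         which(!as.logical(treated))))
      sampleInCy5[grp_idx] <- rep(c(TRUE, FALSE),
                                  length.out = length(grp_idx))
    isSample <- ifelse(rep(sampleInCy5, each = 2), dye == "cy5",
                       dye == "cy3")
    grp <- ifelse(isSample,
                  ifelse(rep(as.logical(treated), each = 2), "treated",
                         "untreated"),
                  "reference")
    aEff <- rnorm(n, 0, array_sd)[arr]
    dEff <- ifelse(dye == "cy5", dye_effect, 0)
    Y <- matrix(0, nrow(expr), 2L * n,
                dimnames = list(rownames(expr), paste0("a", arr, "_", dye)))
    Y[, isSample] <- expr
    Y[, !isSample] <- rnorm(nrow(expr) * n, 0, ref_sd)
    Y <- sweep(Y, 2, aEff + dEff, `+`)
    obs <- data.frame(array = factor(arr), dye = factor(dye),
                      sample_id = ifelse(isSample, colnames(expr)[arr],
                                         "reference"),
                      group = factor(grp, levels = c("reference",
                                                     "untreated", "treated")))
    structure(list(obs = obs, Y = Y), class = "DiffexpDesign")
  })
}

#' Permutation F-test for a treatment effect in a fixed-effects ANOVA
#'
#' Per gene, fits the fixed-effects model with array, dye and
#' sample-vs-reference group effects (channel-level observations) and
#' tests the treated-versus-untreated contrast with an F statistic whose
#' denominator shrinks the gene-specific residual mean square towards the
#' across-genes pooled residual mean square (weight \code{pool_weight};
#' 0.5 averages the two, the hybrid "F2"-type statistic). The null
#' distribution is built by residual permutation in the Freedman-Lane
#' scheme: residuals of the reduced (no-treatment) model are shuffled —
#' by default globally, one shared observation permutation applied to all
#' genes per shuffle, preserving inter-gene correlation of the null
#' statistics — added back to the reduced fit, and the treatment F
#' recomputed. p = (1 + #\{perm F >= observed\}) / (1 + n_perm), so p is
#' never 0 and finite-sample valid. Benjamini-Hochberg adjustment is
#' applied across genes.
#'
#' @param design a \code{DiffexpDesign} (see
#'   \code{\link{buildDyeSwapDesign}}).
#' @param n_perm number of permutations (>= 100; default 5000).
#' @param pool_weight weight of the pooled residual mean square in the
#'   denominator (0 = per-gene F, 1 = fully pooled).
#' @param shuffle \code{"global"} (shared permutation) or
#'   \code{"per_gene"} (independent permutation per gene; slower).
#' @param seed RNG seed for the permutations.
#' @return data.frame: gene, F, p, p_adjusted, direction (up/down in
#'   treated).
#' @export
permutationFTest <- function(design, n_perm = 5000, pool_weight = 0.5,
                             shuffle = c("global", "per_gene"), seed = 1) {
  shuffle <- match.arg(shuffle)
  stopIfNot(n_perm >= 100, "n_perm", "must be >= 100")
  obs <- design$obs
  Y <- design$Y
  stopIfNot(nrow(obs) == ncol(Y), "design", "obs/Y dimension mismatch")
  for (lev in c("treated", "untreated"))
    if (sum(obs$group == lev) < 2)
      stop(sprintf("need >= 2 observations in group '%s'", lev))

  X1 <- model.matrix(~ array + dye + group, data = obs)
  grp0 <- factor(ifelse(obs$group == "reference", "reference", "sample"))
  X0 <- model.matrix(~ array + dye + grp0, data = obs)
  q1 <- qr(X1); q0 <- qr(X0)
  if (q1$rank != q0$rank + 1L)
    stop("confounded design: treatment is aliased with array/dye effects")
  n <- nrow(X1)
  dfE <- n - q1$rank
  if (dfE < 1) stop("no residual degrees of freedom")
  Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  ## unit vector spanning the treatment contrast within span(X1)\span(X0);
  ## oriented so that a positive projection means higher in treated
  xt <- as.numeric(obs$group == "treated")
  v <- xt - Q0 %*% crossprod(Q0, xt)
  v <- as.numeric(v / sqrt(sum(v * v)))

  fStat <- function(Ymat) {
    num <- as.numeric(Ymat %*% v)^2
    B <- Ymat %*% Q1
    rss1 <- rowSums(Ymat * Ymat) - rowSums(B * B)
    s2g <- rss1 / dfE
    s2 <- (1 - pool_weight) * s2g + pool_weight * mean(s2g)
    ifelse(num < 1e-10, 0, num / pmax(s2, 1e-300))
  }
  fObs <- fStat(Y)
  dirEst <- as.numeric(Y %*% v)

  R0 <- Y - (Y %*% Q0) %*% t(Q0)
  rss0const <- rowSums(R0 * R0)
  exceed <- numeric(nrow(Y))
  withSeed(seed, {
    for (b in seq_len(n_perm)) {
      if (shuffle == "global") {
        Rp <- R0[, sample.int(n), drop = FALSE]
      } else {
        Rp <- t(apply(R0, 1, sample))
      }
      num <- as.numeric(Rp %*% v)^2
      B <- Rp %*% Q1
      ## Yp = fit0 + Rp; fit0 lies in span(X0) so it drops out of both the
      ## treatment-contrast numerator and the full-model residual
      rss1 <- rss0const - rowSums(B * B)
      s2g <- rss1 / dfE
      s2 <- (1 - pool_weight) * s2g + pool_weight * mean(s2g)
      fp <- ifelse(num < 1e-10, 0, num / pmax(s2, 1e-300))
      exceed <- exceed + (fp >= fObs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(gene = rownames(Y), F = fObs, p = p, p_adjusted = bhAdjust(p),
             direction = ifelse(dirEst >= 0, "up", "down"),
             row.names = NULL)
}
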