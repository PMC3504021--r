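#' @importFrom methods new is validObject slot
#' @importFrom stats coef cor loess loess.control lm median na.omit p.adjust
#'   pchisq pnorm predict qnorm quantile rbinom rexp rnorm rpois runif sd
#'   t.test wilcox.test fisher.test model.matrix pt var rlnorm
#' @importFrom utils head read.csv read.delim write.csv
NULL

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards. All stochastic package operations route
## through this so nothing leaks into (or depends on) global RNG state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

## Derive a child seed from a parent seed; keeps results < 2^31 - 1.
childSeed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483629
}

stopIfNot <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

isFlag01 <- function(x) all(x %in% c(0L, 1L, 0, 1))

## rank scores descending by |score|, ties broken by gene id (lexicographic);
## NA scores (unscorable genes) go last.
rankByAbsScore <- function(score, ids) {
  s <- abs(score)
  s[is.na(s)] <- -Inf
  ord <- order(-s, ids)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

## rank ascending values (e.g. averaged ranks), ties by id.
rankAscending <- function(value, ids) {
  ord <- order(value, ids)
  r <- integer(length(value))
  r[ord] <- seq_along(value)
  r
}

## reverse cumulative sums down the rows of a matrix (risk-set sums),
## computed as a triangular matrix product so it vectorises over columns.
revCumsumRows <- function(m) {
  n <- nrow(m)
  tri <- upper.tri(matrix(0, n, n), diag = TRUE) * 1
  tri %*% m
}
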