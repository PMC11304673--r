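#' Derive a substream seed from a master seed
#'
#' All randomness in the package flows from one user-visible integer seed.
#' Stages (cohort generation, restarts, folds, SMOTE, model fits) draw their
#' own seeds through this counter-based derivation so that any stage can be
#' re-run in isolation and still reproduce the full-run stream.
#'
#' The derivation is a fixed affine step modulo the Mersenne prime 2^31 - 1:
#' `(seed * 48271 + 97 * stage + index) mod (2^31 - 1)`, with a floor of 1 so
#' the result is always a valid positive integer seed.
#'
#' @param seed master integer seed.
#' @param stage integer code for the pipeline stage (each caller uses a fixed
#'   small constant).
#' @param index within-stage counter (restart, repeat, fold, ...).
#' @return a positive integer seed below 2^31 - 1.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + 97 * as.double(stage) + as.double(index)
  s <- s %% m
  as.integer(max(1, s))
}

# Round half away from zero to `digits` decimals, the convention used by the
# printed tables this package mirrors (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a formatted message, no call
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: stratified fold assignment; returns integer vector of fold ids
# 1..k. Classes smaller than k are pooled into one stratum for splitting only
# (caller warns); true labels are untouched. `canon` is an optional rank
# vector giving a content-based canonical row order: folds are then drawn
# over that order, which makes the assignment invariant to the input row
# order (interchangeable rows aside).
stratified_folds <- function(y, k, seed, canon = seq_along(y)) {
  y <- as.character(y)
  n <- length(y)
  tab <- table(y)
  small <- names(tab)[tab < k]
  strata <- y
  if (length(small) > 0) strata[strata %in% small] <- ".pooled."
  folds <- integer(n)
  set.seed(seed)
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    idx <- idx[order(canon[idx])]
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# internal: canonical content rank of rows of (covariates, labels); rows
# identical in content get adjacent ranks, so downstream seeded draws depend
# on the data multiset, not the storage order
canonical_rank <- function(covariates, labels) {
  args <- c(unname(as.list(covariates)), list(labels))
  ord <- do.call(order, args)
  rk <- integer(length(labels))
  rk[ord] <- seq_along(labels)
  rk
}
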