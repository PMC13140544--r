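#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx ave cor cor.test fft mad median mvfft p.adjust
#'   predict quantile rnorm runif sd var wilcox.test aov TukeyHSD setNames
#' @importFrom utils head tail
#' @importFrom tools md5sum
NULL

## Deterministic per-unit seed derivation: master seed + counter, kept < 2^31.
## Stages / hemispheres re-run independently given the same master seed.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 10007 + as.numeric(counter) * 7919) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Weighted sample quantile (type-7-like on the weighted CDF); used by the
## KDE bandwidth rule.
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    x[i]
  }, numeric(1))
}

weighted_sd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

## Effective sample size of a weighted sample (Kish).
effective_n <- function(w) sum(w)^2 / sum(w^2)

## Two-tailed permutation p-value of obs among null draws, with the
## add-one correction so the test is exactly level-alpha under
## exchangeability: p_tail = (1 + #{null at least as extreme})/(n + 1).
perm_p_two_tailed <- function(obs, null) {
  n <- length(null)
  p_hi <- (1 + sum(null >= obs)) / (n + 1)
  p_lo <- (1 + sum(null <= obs)) / (n + 1)
  min(1, 2 * min(p_hi, p_lo))
}

fdr_adjust <- function(p) p.adjust(p, method = "BH")
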