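## internal helpers shared across modules

#' Truncated-normal sampler
#'
#' Inverse-CDF sampler for a normal distribution truncated to `[lo, hi]`.
#' Used for segment lengths and bouton diameter distributions.
#'
#' @param n number of draws
#' @param mean,sd untruncated normal parameters
#' @param lo,hi truncation bounds
#' @return numeric vector of length `n`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  stopifnot(hi > lo, sd > 0)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

## Deterministic child seed from a master seed and a stream index.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 9973 * as.numeric(index)) %%
               2147483647)
}

## run a block with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## standard error of the mean; NA for n < 2
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
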