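#' Derive a child seed from a master seed and a stage label
#'
#' One pipeline seed fans out to per-stage seeds so stages are reproducible
#' yet statistically independent. The derivation is a stable integer hash of
#' the label folded into the master seed; results stay below 2^31.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Population standard deviation
#'
#' SD with the 1/n normalization (not the sample 1/(n-1)); returns 0 for
#' fewer than two values.
#' @param x numeric vector.
#' @return non-negative scalar.
#' @export
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

## linear-interpolation percentile (quantile type 7), the convention used by
## the shuffle tests
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Smooth a trace with a Gaussian kernel
#'
#' Truncated at 4 sigma; edges renormalized so a constant trace is preserved.
#' @param x numeric vector.
#' @param sigma kernel SD in samples.
#' @return smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sigma = 2) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  n <- length(x)
  num <- stats::convolve(c(rep(0, r), x, rep(0, r)), rev(k), type = "filter")
  den <- stats::convolve(c(rep(0, r), rep(1, n), rep(0, r)), rev(k),
                         type = "filter")
  num / den
}

## stop() with call. = FALSE everywhere
fail <- function(...) stop(..., call. = FALSE)
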