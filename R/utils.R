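#' @useDynLib nmphtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif quantile sd coef predict lm.fit dgamma
#'   median qnorm
#' @importFrom utils head tail write.csv read.csv read.delim
NULL

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Pearson correlation that errors informatively on zero-variance input
safe_cor <- function(a, b, what = "input") {
  if (sd(a) == 0 || sd(b) == 0)
    stopf("undefined correlation: zero-variance activation vector (%s)", what)
  cor(a, b)
}

# Fisher z with clamping so perfect correlations stay finite
#' Fisher z-transform with clamping
#'
#' Computes \code{atanh(r)} after capping \code{|r|} at \code{1 - 1e-7} so a
#' perfect correlation maps to a large finite value rather than infinity.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @return Fisher-transformed value(s).
#' @export
fisher_z <- function(r) {
  clamped <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  if (any(abs(r) >= 1, na.rm = TRUE))
    warning("correlation of |r| = 1 clamped before Fisher transform")
  atanh(clamped)
}
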